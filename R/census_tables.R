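#' Default address-abbreviation expansion table
#'
#' The address normalizer expands common street-suffix and cardinal-direction
#' abbreviations so that the same physical address written two ways ("W. 120th
#' St." and "West 120 Street") produces one canonical string. The shipped
#' table is explicit, versioned configuration: every expansion target is
#' itself a fixed point of the table, which is what makes normalization
#' idempotent.
#'
#' @return A tibble with columns `abbrev` (uppercase token) and `expansion`.
#' @export
default_abbreviations <- function() {
  path <- system.file("extdata", "address_abbreviations.csv",
                      package = "streetgrowth", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Default species common-name dictionary
#'
#' Many-to-one map from free-text common-name variants to a canonical common
#' name (with scientific name where known). Lookup is case- and
#' whitespace-insensitive. The dictionary is data, not code: linkage requires
#' exact species equality, so unmapped vocabulary must fail safe (flagged,
#' excluded from linkage) rather than silently matching.
#'
#' @return A tibble with columns `variant`, `canonical`, `scientific`.
#' @export
default_species_dictionary <- function() {
  path <- system.file("extdata", "species_dictionary.csv",
                      package = "streetgrowth", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Normalize a street address to its canonical form
#'
#' Applies, in order: uppercasing; deletion of punctuation (except the hyphen
#' in hyphenated building-number ranges such as "45-47", a Queens addressing
#' convention that distinguishes real addresses); stripping of ordinal
#' suffixes from numeric tokens (120TH -> 120); token-wise expansion through
#' the abbreviation table; collapsing of whitespace. The result is a fixed
#' point: normalizing twice equals normalizing once.
#'
#' @param address Character vector of raw addresses.
#' @param rules Abbreviation table as from [default_abbreviations()].
#' @return Character vector of canonical addresses; `NA` where the input is
#'   empty or whitespace-only.
#' @examples
#' normalize_address("W. 120th St.")   # "WEST 120 STREET"
#' normalize_address("45-47 Ave B")    # "45-47 AVENUE B"
#' @export
normalize_address <- function(address, rules = default_abbreviations()) {
  out <- toupper(as.character(address))
  # protect digit-digit hyphens before stripping punctuation
  out <- gsub("(?<=[0-9])-(?=[0-9])", "§", out, perl = TRUE)
  out <- gsub("[^A-Z0-9§ ]+", " ", out)
  out <- gsub("§", "-", out, fixed = TRUE)
  expand <- stats::setNames(rules$expansion, rules$abbrev)
  out <- vapply(strsplit(trimws(out), "\\s+"), function(tok) {
    if (length(tok) == 0L || all(is.na(tok))) return(NA_character_)
    tok <- sub("^([0-9]+)(ST|ND|RD|TH)$", "\\1", tok)
    hit <- !is.na(expand[tok])
    tok[hit] <- expand[tok[hit]]
    paste(tok, collapse = " ")
  }, character(1))
  out[!nzchar(trimws(ifelse(is.na(out), "", out)))] <- NA_character_
  out
}

#' Normalize a species common name against the dictionary
#'
#' Case- and whitespace-insensitive lookup through the variant map. Names not
#' found in the dictionary are preserved verbatim and flagged unmapped;
#' unmapped records are excluded from linkage but counted in diagnostics.
#'
#' @param name Character vector of raw common names.
#' @param dict Species dictionary as from [default_species_dictionary()].
#' @return A tibble with columns `species_norm` (canonical name, or the
#'   trimmed input where unmapped) and `unmapped` (logical; `NA` names are
#'   flagged too).
#' @export
normalize_species <- function(name, dict = default_species_dictionary()) {
  key <- tolower(gsub("\\s+", " ", trimws(as.character(name))))
  lut <- stats::setNames(dict$canonical, tolower(gsub("\\s+", " ", trimws(dict$variant))))
  # canonical names map to themselves
  lut <- c(lut, stats::setNames(dict$canonical, tolower(unique(dict$canonical))))
  lut <- lut[!duplicated(names(lut))]
  hit <- unname(lut[key])
  empty <- is.na(key) | !nzchar(key)
  tibble::tibble(
    species_norm = ifelse(empty, NA_character_,
                          ifelse(is.na(hit), trimws(as.character(name)), unname(hit))),
    unmapped = empty | is.na(hit)
  )
}

#' Read one census snapshot from CSV into canonical records
#'
#' The two snapshot releases use different column vocabularies, so the reader
#' takes a dialect: a named list mapping the logical fields `zip`, `address`,
#' `species`, `dbh` (and optionally extras such as `health`, `steward`,
#' `guards`, `sidewalk`, `curb_loc`, `borough`, `user_type`) to column names
#' in the file. Rows missing a required field, or with a DBH that is not a
#' whole number (census DBH is recorded in whole inches; exact decimals like
#' "6.0" are accepted and truncated), are diverted to a rejects table with a
#' reason code, never silently dropped.
#'
#' @param path CSV file path.
#' @param dialect Named list mapping logical field names to column names;
#'   see [nyc_dialect()].
#' @param census_year Integer year recorded on every record.
#' @param dict,rules Species dictionary and abbreviation table used to fill
#'   `species_norm` / `address_norm`.
#' @return A list with `records` (tibble of canonical records, one per clean
#'   row, with `record_id`, `census_year`, `zip`, `address_raw`,
#'   `address_norm`, `species_raw`, `species_norm`, `species_unmapped`,
#'   `dbh_in`, plus any extra dialect columns) and `rejects` (tibble with
#'   `row`, `reason`).
#' @export
read_census_csv <- function(path, dialect = nyc_dialect("2015"),
                            census_year = NA_integer_,
                            dict = default_species_dictionary(),
                            rules = default_abbreviations()) {
  if (!file.exists(path)) stop("census file not found: ", path)
  required <- c("zip", "address", "species", "dbh")
  missing_d <- setdiff(required, names(dialect))
  if (length(missing_d) > 0)
    stop("dialect missing required field(s): ", paste(missing_d, collapse = ", "))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  normalize_census(raw, dialect, census_year, dict, rules)
}

#' Harmonize an in-memory raw census table into canonical records
#'
#' The normalization core of [read_census_csv()], usable directly on a raw
#' tibble (e.g. a snapshot emitted by the synthetic-city generator).
#'
#' @inheritParams read_census_csv
#' @param raw Tibble of raw rows in the dialect's column vocabulary.
#' @return Same structure as [read_census_csv()].
#' @export
normalize_census <- function(raw, dialect = nyc_dialect("2015"),
                             census_year = NA_integer_,
                             dict = default_species_dictionary(),
                             rules = default_abbreviations()) {
  required <- c("zip", "address", "species", "dbh")
  absent <- setdiff(unlist(dialect[required]), names(raw))
  if (length(absent) > 0)
    stop("input lacks column(s) named in dialect: ", paste(absent, collapse = ", "))
  n <- nrow(raw)
  zip <- trimws(raw[[dialect$zip]])
  addr <- raw[[dialect$address]]
  spp <- raw[[dialect$species]]
  dbh_chr <- trimws(raw[[dialect$dbh]])

  dbh_num <- suppressWarnings(as.numeric(dbh_chr))
  dbh_ok <- !is.na(dbh_num) & dbh_num >= 0 & dbh_num == trunc(dbh_num)

  reason <- rep(NA_character_, n)
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  reason[blank(dbh_chr) | is.na(dbh_num)] <- "missing or non-numeric dbh"
  reason[!is.na(dbh_num) & !dbh_ok] <- "non-integer dbh"
  reason[blank(spp)] <- "missing species"
  reason[blank(addr)] <- "missing address"
  reason[blank(zip)] <- "missing zip"

  keep <- is.na(reason)
  sp <- normalize_species(spp[keep], dict)
  rec <- tibble::tibble(
    record_id = if ("record_id" %in% names(dialect) && dialect$record_id %in% names(raw))
      raw[[dialect$record_id]][keep] else sprintf("r%06d", which(keep)),
    census_year = as.integer(census_year),
    zip = zip[keep],
    address_raw = addr[keep],
    address_norm = normalize_address(addr[keep], rules),
    species_raw = spp[keep],
    species_norm = sp$species_norm,
    species_unmapped = sp$unmapped,
    dbh_in = as.integer(dbh_num[keep])
  )
  extras <- setdiff(names(dialect), c(required, "record_id"))
  for (e in extras) {
    if (dialect[[e]] %in% names(raw)) rec[[e]] <- raw[[dialect[[e]]]][keep]
  }
  if (anyDuplicated(rec$record_id))
    stop("record_id values are not unique within the census")
  list(
    records = rec,
    rejects = tibble::tibble(row = which(!keep), reason = reason[!keep])
  )
}

#' Column-name dialects for the snapshot releases
#'
#' Defaults mirror the open-data field vocabularies of the two NYC street-tree
#' census releases ("2005": `dbh_05`/`spc_common`/`zipcode`; "2015":
#' `tree_dbh`/`spc_common`/`zipcode`). `"canonical"` is the dialect this
#' package writes.
#'
#' @param which One of "2005", "2015", "canonical".
#' @return Named list usable as the `dialect` argument of [read_census_csv()].
#' @export
nyc_dialect <- function(which = c("2015", "2005", "canonical")) {
  which <- match.arg(which)
  base <- list(zip = "zipcode", address = "address", species = "spc_common",
               health = "health", steward = "steward", guards = "guards",
               sidewalk = "sidewalk", curb_loc = "curb_loc",
               borough = "borough", user_type = "user_type",
               record_id = "record_id")
  switch(which,
    "2005" = c(base, list(dbh = "dbh_05")),
    "2015" = c(base, list(dbh = "tree_dbh", x = "x", y = "y")),
    "canonical" = c(list(zip = "zip", address = "address_raw",
                         species = "species_raw", dbh = "dbh_in",
                         record_id = "record_id"),
                    base[c("health", "steward", "guards", "sidewalk",
                           "curb_loc", "borough", "user_type")])
  )
}

#' Write canonical records back to CSV
#'
#' @param records Tibble of canonical records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
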
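#' Drop records whose match key is not unique within a census
#'
#' The match key is (zip, address_norm, species_norm). Two trees of the same
#' species at one address cannot be told apart a decade later, so every
#' record of a key with multiplicity two or more is removed — all of them,
#' not all-but-one. Records with an unmapped species or a missing key
#' component are also diverted (they cannot support an exact-equality match).
#'
#' @param records Canonical census records (one census year).
#' @return List with `retained` (every key occurs exactly once) and
#'   `dropped` (with a `drop_reason` column: "nonunique_key", "unmapped_species",
#'   "incomplete_key").
#' @export
drop_nonunique_keys <- function(records) {
  if (nrow(records) == 0) {
    return(list(retained = records,
                dropped = dplyr::mutate(records, drop_reason = character(0))))
  }
  bad_key <- is.na(records$zip) | !nzchar(records$zip) |
    is.na(records$address_norm) | !nzchar(records$address_norm) |
    is.na(records$species_norm) | !nzchar(records$species_norm)
  unmapped <- !bad_key & isTRUE_v(records$species_unmapped)
  eligible <- records[!bad_key & !unmapped, , drop = FALSE]
  key <- paste(eligible$zip, eligible$address_norm, eligible$species_norm,
               sep = "\r")
  dup <- key %in% key[duplicated(key)]
  dropped <- dplyr::bind_rows(
    dplyr::mutate(records[bad_key, , drop = FALSE], drop_reason = "incomplete_key"),
    dplyr::mutate(records[!bad_key & unmapped, , drop = FALSE],
                  drop_reason = "unmapped_species"),
    dplyr::mutate(eligible[dup, , drop = FALSE], drop_reason = "nonunique_key")
  )
  list(retained = eligible[!dup, , drop = FALSE], dropped = dropped)
}

isTRUE_v <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Align two deduplicated census snapshots into one-to-one tree matches
#'
#' Exact join on (zip, address_norm, species_norm). Both inputs must already
#' be key-unique (see [drop_nonunique_keys()]); duplicate keys here are a
#' contract violation and abort. The pairing is symmetric: swapping the
#' inputs swaps the early/late roles but yields the same key set.
#'
#' @param early,late Key-unique canonical records from the earlier and later
#'   census.
#' @return List with `pairs` (tibble: key columns plus all record fields
#'   suffixed `_05` / `_15`), `unmatched_early`, `unmatched_late`, and
#'   `report` (a linkage report, see [linkage_report()]).
#' @export
align_censuses <- function(early, late) {
  keycols <- c("zip", "address_norm", "species_norm")
  for (nm in c("early", "late")) {
    x <- get(nm)
    k <- do.call(paste, c(x[keycols], sep = "\r"))
    if (anyDuplicated(k))
      stop("align_censuses: '", nm, "' census contains duplicate match keys; ",
           "run drop_nonunique_keys() first")
  }
  pairs <- dplyr::inner_join(early, late, by = keycols,
                             suffix = c("_05", "_15"))
  un_early <- dplyr::anti_join(early, late, by = keycols)
  un_late <- dplyr::anti_join(late, early, by = keycols)
  rep <- list(
    input_early = nrow(early), input_late = nrow(late),
    matched = nrow(pairs),
    unmatched_early = nrow(un_early), unmatched_late = nrow(un_late)
  )
  list(pairs = pairs, unmatched_early = un_early, unmatched_late = un_late,
       report = rep)
}

#' Build a step-count linkage report across the dedupe + align stages
#'
#' Mirrors a flow-diagram accounting: input sizes, records dropped per census
#' for non-uniqueness (and why), matched pairs, unmatched per side. The
#' partition invariant dropped + retained = input holds per census.
#'
#' @param dedup_early,dedup_late Results of [drop_nonunique_keys()] per census.
#' @param alignment Result of [align_censuses()].
#' @return A list of counts.
#' @export
linkage_report <- function(dedup_early, dedup_late, alignment) {
  tally <- function(d) as.list(table(d$dropped$drop_reason))
  list(
    input_early = nrow(dedup_early$retained) + nrow(dedup_early$dropped),
    input_late = nrow(dedup_late$retained) + nrow(dedup_late$dropped),
    dropped_early = nrow(dedup_early$dropped),
    dropped_late = nrow(dedup_late$dropped),
    drop_reasons_early = tally(dedup_early),
    drop_reasons_late = tally(dedup_late),
    retained_early = nrow(dedup_early$retained),
    retained_late = nrow(dedup_late$retained),
    matched = alignment$report$matched,
    unmatched_early = alignment$report$unmatched_early,
    unmatched_late = alignment$report$unmatched_late
  )
}
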
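#' Default species table for the synthetic city
#'
#' The fifteen most abundant species in a large street-tree inventory, with
#' planting frequencies proportional to observed abundance, typical starting
#' diameters, and species-specific true mean decadal growth rates (in/yr)
#' used as generative ground truth. Frequencies are normalized to sum to 1.
#'
#' @return Tibble: species, freq, mean_dbh0, mean_rate, sd_rate.
#' @export
default_species_table <- function() {
  t <- tibble::tribble(
    ~species,             ~n,     ~mean_dbh0, ~mean_rate,
    "London Planetree",   32058,  22.5,       0.163,
    "Honeylocust",        15974,   9.1,       0.356,
    "Callery Pear",       15903,   6.6,       0.334,
    "Norway Maple",       13149,  13.4,       0.174,
    "Pin Oak",            11563,  16.8,       0.352,
    "Littleleaf Linden",   6343,   9.7,       0.318,
    "Ginkgo",              5518,   9.0,       0.257,
    "Green Ash",           4893,  10.9,       0.366,
    "Red Maple",           4116,  10.1,       0.273,
    "Silver Maple",        3948,  20.4,       0.265,
    "Japanese Zelkova",    3643,   8.2,       0.425,
    "Sweetgum",            2620,  11.0,       0.308,
    "Silver Linden",       1149,   6.7,       0.510,
    "Northern Red Oak",    1026,  12.7,       0.375,
    "American Linden",      868,  10.8,       0.399,
    # long tail: low-frequency species pooled as "Other" in the model
    "Hawthorn",             450,   7.5,       0.220,
    "Crabapple",            450,   6.0,       0.240,
    "American Elm",         450,  14.0,       0.380,
    "Willow Oak",           450,  11.0,       0.420,
    "Tree Of Heaven",       450,  10.0,       0.450,
    "Eastern Redbud",       450,   5.5,       0.260,
    "Amur Maple",           450,   6.5,       0.230,
    "Cherry",               450,   8.0,       0.290
  )
  tibble::tibble(species = t$species, freq = t$n / sum(t$n),
                 mean_dbh0 = t$mean_dbh0, mean_rate = t$mean_rate,
                 sd_rate = 0.21)
}

#' Configuration of the synthetic street-tree city
#'
#' The generator lays streets on a planar grid (metre coordinates), plants
#' one tree per address (plus occasional same-species pairs, the
#' non-uniqueness failure mode), evolves the city for a decade with i.i.d.
#' annual mortality and in-place same-species sapling replacement of a
#' fraction of deaths, and
#' observes it as two census snapshots with whole-inch rounding, surveyor
#' noise, circumference-for-diameter and dropped-digit entry errors, and
#' randomized address formatting.
#'
#' @param seed Integer seed; everything downstream is deterministic given it.
#' @param n_streets Number of streets (split between east-west and
#'   north-south orientations, interleaved on a grid).
#' @param addresses_per_street Addresses per street.
#' @param species Species table as [default_species_table()].
#' @param annual_mortality Per-tree, per-year death probability (default
#'   0.044, a published street-tree mortality rate; ten-year survival is then
#'   (1-0.044)^10, about 64%).
#' @param replacement_prob Probability that a dead tree is replaced, in
#'   place, by a same-species sapling before the late snapshot (replacements
#'   are always same-species; unreplaced deaths simply vanish from the late
#'   census). Default 0.15, chosen so replacement false matches make up
#'   roughly the share of linked pairs that ground-truthing attributes to
#'   replacement events.
#' @param duplicate_series_prob Probability an address holds a second tree of
#'   the same species (series planting).
#' @param measurement_sd Surveyor DBH noise SD, inches, applied before
#'   rounding; optionally named per class (volunteer, treescount, parks).
#' @param circumference_error_prob Probability a record reports
#'   round(pi * dbh) (tape read as circumference).
#' @param digit_error_prob Probability a two-digit reading loses its trailing
#'   digit (10 recorded as 1).
#' @param surveyor_mix Citywide class shares (volunteer, treescount, parks);
#'   volunteers are concentrated in the first borough, mirroring the
#'   geographic confounding of surveyor class with tree stock.
#' @param svi_effect True growth boost (in/yr) per unit of zone social
#'   vulnerability; not seen by the determinants model, so it must surface in
#'   the residuals.
#' @param size_effect True change in growth rate (in/yr) per inch of starting
#'   DBH above the species' typical size: negative, since smaller (younger)
#'   trees grow faster.
#' @param zip_grid,tract_grid,lot_grid Grid dimensions (columns, rows) of the
#'   ZIP, tract and tax-lot zone layers.
#' @return A `city_config` list.
#' @export
city_config <- function(seed = 1L,
                        n_streets = 250L,
                        addresses_per_street = 174L,
                        species = default_species_table(),
                        annual_mortality = 0.044,
                        replacement_prob = 0.15,
                        duplicate_series_prob = 0.15,
                        measurement_sd = 0.5,
                        circumference_error_prob = 0.001,
                        digit_error_prob = 0.001,
                        surveyor_mix = c(volunteer = 0.32, treescount = 0.42,
                                         parks = 0.26),
                        svi_effect = 0.1,
                        size_effect = -0.01,
                        zip_grid = c(6L, 4L),
                        tract_grid = c(12L, 8L),
                        lot_grid = c(24L, 16L)) {
  stopifnot(n_streets >= 1, addresses_per_street >= 1,
            annual_mortality >= 0, annual_mortality <= 1,
            replacement_prob >= 0, replacement_prob <= 1,
            duplicate_series_prob >= 0, duplicate_series_prob <= 1,
            circumference_error_prob >= 0, circumference_error_prob <= 1,
            digit_error_prob >= 0, digit_error_prob <= 1,
            all(species$sd_rate >= 0),
            abs(sum(species$freq) - 1) < 1e-8)
  structure(as.list(environment()), class = "city_config")
}

#' Ten-year survival under i.i.d. annual mortality
#'
#' Exponential decay: the fraction of trees surviving `years` years at a
#' constant annual mortality rate is (1 - annual_mortality)^years. At the
#' default 4.4% annual rate this is ~64% over a decade (36% mortality).
#'
#' @param annual_mortality Annual death probability in [0, 1].
#' @param years Non-negative integer horizon.
#' @return Surviving proportion in [0, 1].
#' @export
survival_fraction <- function(annual_mortality, years) {
  stopifnot(annual_mortality >= 0, annual_mortality <= 1, years >= 0)
  (1 - annual_mortality)^years
}

# rectangular-grid zone layer over a bounding box
make_grid_zones <- function(bbox, nx, ny, prefix) {
  xs <- seq(bbox[1], bbox[2], length.out = nx + 1)
  ys <- seq(bbox[3], bbox[4], length.out = ny + 1)
  rows <- list(); k <- 0
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1
    rows[[k]] <- tibble::tibble(
      zone_id = sprintf("%s%03d", prefix, k),
      rings = list(rbind(c(xs[i], ys[j]), c(xs[i + 1], ys[j]),
                         c(xs[i + 1], ys[j + 1]), c(xs[i], ys[j + 1]),
                         c(xs[i], ys[j]))),
      col = i, row = j
    )
  }
  dplyr::bind_rows(rows)
}

#' Generate a synthetic street-tree city with ground truth
#'
#' Deterministic given `cfg$seed`. Streets form an interleaved grid of
#' east-west and north-south streets, so both orientations occur everywhere
#' in the city; street names deliberately repeat across the two orientations
#' (and hence across ZIP codes), with an odd/even building-number convention
#' keeping crossing same-named streets from sharing an address. Each tree
#' carries its true continuous DBH at year 0 and year 10, its true growth
#' rate (species mean, size effect, SVI boost, plus tree-level variation),
#' and its fate: survivors keep their identity; a replaced death yields a
#' same-species sapling (a new identity) growing from its replacement year;
#' unreplaced deaths vanish from the late census.
#'
#' @param cfg A [city_config()].
#' @return List: `trees` (truth tibble, one row per identity), `segments`,
#'   `zips`, `tracts`, `lots` (zone layers), `config`.
#' @export
generate_city <- function(cfg = city_config()) {
  stopifnot(inherits(cfg, "city_config"))
  if (nrow(cfg$species) == 0 || cfg$n_streets < 1) stop("generate_city: empty city")
  set.seed(cfg$seed)

  # an interleaved grid: east-west streets and north-south streets cross,
  # so both orientations occur everywhere in the city
  n_h <- ceiling(cfg$n_streets / 2); n_v <- cfg$n_streets - n_h
  spacing <- 80
  W <- (n_v + 1) * spacing; H <- (n_h + 1) * spacing

  seg_h <- tibble::tibble(
    segment_id = seq_len(n_h),
    name = paste(seq_len(n_h), "STREET"),
    vertices = lapply(seq_len(n_h), function(i)
      rbind(c(0, i * spacing), c(W, i * spacing))),
    st_width = round(stats::runif(n_h, 20, 60))
  )
  seg_v <- tibble::tibble(
    segment_id = n_h + seq_len(n_v),
    name = paste(seq_len(n_v), "STREET"),   # names repeat across orientations
    vertices = lapply(seq_len(n_v), function(i)
      rbind(c(i * spacing, 0), c(i * spacing, H))),
    st_width = round(stats::runif(n_v, 20, 60))
  )
  segments <- dplyr::bind_rows(seg_h, seg_v)

  bbox <- c(0, W, 0, H)
  zips <- make_grid_zones(bbox, cfg$zip_grid[1], cfg$zip_grid[2], "1")
  zips$zip <- sprintf("%05d", 10000 + seq_len(nrow(zips)))
  zips$borough <- paste("Borough", 1 + (zips$col - 1) %% 5)
  tracts <- make_grid_zones(bbox, cfg$tract_grid[1], cfg$tract_grid[2], "T")
  # social vulnerability follows a smooth west-to-east gradient plus local
  # tract noise, so zone means genuinely differ (as they do across a city)
  tracts$svi <- round(pmin(1, pmax(
    0.02, 0.15 + 0.7 * (tracts$col - 1) / max(1, cfg$tract_grid[1] - 1) +
      stats::rnorm(nrow(tracts), 0, 0.08))), 2)
  tracts$pop_density <- round(stats::rlnorm(nrow(tracts), log(30000), 0.8))
  lots <- make_grid_zones(bbox, cfg$lot_grid[1], cfg$lot_grid[2], "L")
  lots$land_use <- sample(c("MultiFamily", "Single Family", "non-res", "open&rec"),
                          nrow(lots), replace = TRUE,
                          prob = c(0.45, 0.3, 0.18, 0.07))
  lots$builtFAR <- round(stats::rlnorm(nrow(lots), log(1), 0.7), 2)

  # one address slot per (street, position), spread along the street's full
  # length; odd buildings on east-west streets, even on north-south ones, so
  # a crossing pair of same-named streets never shares an address
  addr <- expand.grid(street = seq_len(cfg$n_streets),
                      pos = seq_len(cfg$addresses_per_street))
  horizontal <- addr$street <= n_h
  building <- 2 * addr$pos - horizontal
  seg_row <- addr$street
  along <- ifelse(horizontal, (addr$pos - 0.5) * W / cfg$addresses_per_street,
                  (addr$pos - 0.5) * H / cfg$addresses_per_street)
  side <- sample(c(-1, 1), nrow(addr), replace = TRUE)
  x <- ifelse(horizontal, along, (addr$street - n_h) * spacing + side * 4)
  y <- ifelse(horizontal, addr$street * spacing + side * 4, along)
  address <- paste(building, segments$name[seg_row])

  extra <- stats::runif(nrow(addr)) < cfg$duplicate_series_prob
  slot <- c(seq_len(nrow(addr)), which(extra))
  n <- length(slot)

  sp_idx <- sample.int(nrow(cfg$species), nrow(addr), replace = TRUE,
                       prob = cfg$species$freq)[slot]  # pairs share species
  tx <- x[slot] + stats::runif(n, -1.5, 1.5)
  ty <- y[slot] + stats::runif(n, -1.5, 1.5)
  zip_id <- polygon_join(cbind(tx, ty), zips)
  tract_id <- polygon_join(cbind(tx, ty), tracts)
  svi <- tracts$svi[match(tract_id, tracts$zone_id)]

  mu0 <- cfg$species$mean_dbh0[sp_idx]
  dbh0 <- pmax(0.4, stats::rgamma(n, shape = 4, rate = 4 / mu0))
  rate <- stats::rnorm(n, cfg$species$mean_rate[sp_idx] +
                         cfg$size_effect * (dbh0 - mu0) +
                         cfg$svi_effect * svi,
                       cfg$species$sd_rate[sp_idx])

  p10 <- 1 - survival_fraction(cfg$annual_mortality, 10)
  died <- stats::runif(n) < p10
  replaced <- died & stats::runif(n) < cfg$replacement_prob
  repl_year <- ifelse(replaced, sample(1:9, n, replace = TRUE), NA)

  trees <- tibble::tibble(
    # identity numbers are assigned in random order: census record ids carry
    # no spatial information, so id-ordered tie-breaks stay spatially neutral
    identity = sprintf("id%06d", sample.int(n)),
    slot = slot,
    street = addr$street[slot],
    segment_id = seg_row[slot],
    address = address[slot],
    zip = zips$zip[match(zip_id, zips$zone_id)],
    zip_zone = zip_id,
    borough = zips$borough[match(zip_id, zips$zone_id)],
    tract_id = tract_id,
    svi = svi,
    species = cfg$species$species[sp_idx],
    x = tx, y = ty,
    dbh0 = dbh0,
    rate_true = rate,
    event = ifelse(replaced, "died_replaced",
                   ifelse(died, "died", "survived")),
    repl_year = repl_year,
    dbh10 = pmax(0.1, dbh0 + 10 * rate)
  )

  # replacements: new identities planted at repl_year, same slot and species
  r <- trees[trees$event == "died_replaced", , drop = FALSE]
  if (nrow(r) > 0) {
    sp_r <- match(r$species, cfg$species$species)
    sapling <- stats::runif(nrow(r), 1, 3)
    rate_r <- stats::rnorm(nrow(r),
                           cfg$species$mean_rate[sp_r] +
                             cfg$size_effect * (sapling - cfg$species$mean_dbh0[sp_r]) +
                             cfg$svi_effect * r$svi,
                           cfg$species$sd_rate[sp_r])
    repl <- r
    repl$identity <- sprintf("id%06dR", seq_len(nrow(r)))
    repl$dbh0 <- NA_real_                       # not present at year 0
    repl$rate_true <- rate_r
    repl$event <- "replacement"
    repl$dbh10 <- pmax(0.1, sapling + rate_r * (10 - r$repl_year))
    trees <- dplyr::bind_rows(trees, repl)
  }
  list(trees = trees, segments = segments, zips = zips, tracts = tracts,
       lots = lots, config = cfg)
}

# inverse-normalization address variants: abbreviate, punctuate, case-mangle;
# every variant normalizes back to the canonical string
mangle_address <- function(address, u) {
  out <- address
  variant <- c(" St", " St.", " ST")[1 + (floor(u * 300) %% 3)]
  mid <- u >= 1/3 & u < 2/3
  out[mid] <- stringr::str_replace(out[mid], " STREET$", variant[mid])
  low <- u >= 2/3
  out[low] <- gsub("\\b([a-z])", "\\U\\1", tolower(out[low]), perl = TRUE)
  out
}

#' Observe the synthetic city as one census snapshot
#'
#' Emits raw records the way a survey would: true DBH at the snapshot year
#' plus surveyor noise, rounded to the whole inch; with small probabilities
#' the value is recorded as circumference (round(pi * dbh)) or loses its
#' trailing digit (10 becomes 1); addresses appear with randomized formatting
#' (abbreviations, punctuation, case); the surveyor class is recorded only in
#' the late snapshot, volunteers concentrated in the first borough.
#'
#' @param city Result of [generate_city()].
#' @param which `"early"` (year 0: original trees only) or `"late"` (year
#'   10: survivors and replacements).
#' @return Tibble of raw records in the snapshot's column dialect
#'   (see [nyc_dialect()]), including `record_id` (prefixed E/L, carrying the
#'   identity), plus survey categoricals.
#' @export
observe_census <- function(city, which = c("early", "late")) {
  which <- match.arg(which)
  cfg <- city$config
  set.seed(cfg$seed + ifelse(which == "early", 101L, 202L))
  t <- city$trees
  if (which == "early") {
    t <- t[t$event != "replacement", , drop = FALSE]
    dbh_true <- t$dbh0
    prefix <- "E"
  } else {
    t <- t[!t$event %in% c("died", "died_replaced"), , drop = FALSE]
    dbh_true <- t$dbh10
    prefix <- "L"
  }
  n <- nrow(t)
  sd_m <- if (length(cfg$measurement_sd) == 1) rep(cfg$measurement_sd, n)
          else rep(mean(cfg$measurement_sd), n)

  # surveyor class, geographically confounded: volunteers in Borough 1
  mix <- cfg$surveyor_mix / sum(cfg$surveyor_mix)
  user <- character(n)
  b1 <- t$borough == "Borough 1"
  user[b1] <- sample(c("Volunteer", "TreesCount Staff", "NYC Parks Staff"),
                     sum(b1), replace = TRUE, prob = c(0.76, 0.14, 0.10))
  user[!b1] <- sample(c("Volunteer", "TreesCount Staff", "NYC Parks Staff"),
                      sum(!b1), replace = TRUE,
                      prob = pmax(c(mix[["volunteer"]] - 0.1,
                                    mix[["treescount"]] + 0.05,
                                    mix[["parks"]] + 0.05), 0.01))
  if (which == "late" && length(cfg$measurement_sd) == 3) {
    cls <- c("Volunteer" = "volunteer", "TreesCount Staff" = "treescount",
             "NYC Parks Staff" = "parks")
    sd_m <- cfg$measurement_sd[cls[user]]
  }

  reported <- pmax(0L, as.integer(round(dbh_true + stats::rnorm(n, 0, sd_m))))
  circ <- stats::runif(n) < cfg$circumference_error_prob
  reported[circ] <- as.integer(round(pi * (dbh_true[circ] +
                                             stats::rnorm(sum(circ), 0, sd_m[circ]))))
  digit <- stats::runif(n) < cfg$digit_error_prob & reported >= 10
  reported[digit] <- reported[digit] %/% 10L

  raw <- tibble::tibble(
    record_id = paste0(prefix, t$identity),
    zipcode = t$zip,
    address = mangle_address(t$address, stats::runif(n)),
    spc_common = sample_species_variant(t$species, stats::runif(n)),
    health = sample(c("Good", "Fair", "Poor"), n, TRUE, prob = c(0.7, 0.22, 0.08)),
    steward = sample(c("None", "1or2", "3or4", "4orMore"), n, TRUE,
                     prob = c(0.55, 0.33, 0.09, 0.03)),
    guards = sample(c("None", "Helpful", "Harmful", "Unsure"), n, TRUE,
                    prob = c(0.77, 0.12, 0.06, 0.05)),
    sidewalk = sample(c("NoDamage", "Damage"), n, TRUE, prob = c(0.72, 0.28)),
    curb_loc = sample(c("OnCurb", "OffsetFromCurb"), n, TRUE, prob = c(0.95, 0.05)),
    borough = t$borough,
    user_type = if (which == "late") user else NA_character_
  )
  raw[[if (which == "early") "dbh_05" else "tree_dbh"]] <- reported
  if (which == "late") { raw$x <- t$x; raw$y <- t$y }  # reliable coordinates
  raw
}

# lowercase / spaced variants that the dictionary maps back
sample_species_variant <- function(species, u) {
  out <- species
  low <- u < 0.3
  out[low] <- tolower(out[low])
  out
}

#' Ground-truth match set and per-identity truth
#'
#' @param city Result of [generate_city()].
#' @return List: `record_identity` (tibble record_id -> identity),
#'   `true_pairs` (record id pairs of surviving identities), `trees` (the
#'   truth tibble).
#' @export
ground_truth <- function(city) {
  t <- city$trees
  surv <- t[t$event == "survived", , drop = FALSE]
  list(
    record_identity = tibble::tibble(
      record_id = c(paste0("E", t$identity[t$event != "replacement"]),
                    paste0("L", t$identity[!t$event %in% c("died", "died_replaced")])),
      identity = c(t$identity[t$event != "replacement"],
                   t$identity[!t$event %in% c("died", "died_replaced")])
    ),
    true_pairs = tibble::tibble(record_id_05 = paste0("E", surv$identity),
                                record_id_15 = paste0("L", surv$identity)),
    trees = t
  )
}

#' Score pipeline linkage against ground truth
#'
#' Precision is the fraction of reported pairs whose two records refer to the
#' same physical tree. Recall is the fraction of truly persisting,
#' unique-keyed trees (survivors whose (zip, address, species) key is unique
#' among the trees standing in each snapshot) that the pipeline recovered.
#' False matches are cross-tabulated against the event log: with exact key
#' equality they can only arise from same-key replacements (or same-key
#' series duplicates if dedupe were skipped).
#'
#' @param pairs Pipeline pairs tibble with `record_id_05`, `record_id_15`.
#' @param city Result of [generate_city()].
#' @return List: `precision`, `recall`, `n_reported`, `n_true`,
#'   `false_matches` (tibble with the late record's event).
#' @export
evaluate_linkage <- function(pairs, city) {
  t <- city$trees
  if (nrow(pairs) == 0)
    return(list(precision = NA_real_, recall = NA_real_, n_reported = 0,
                n_true = 0, false_matches = tibble::tibble()))
  id05 <- sub("^E", "", pairs$record_id_05)
  id15 <- sub("^L", "", pairs$record_id_15)
  true_match <- id05 == id15
  # persisting unique-keyed trees: survivors whose key is unique per snapshot
  key <- paste(t$zip, t$address, t$species, sep = "\r")
  early_keys <- key[t$event != "replacement"]
  late_keys <- key[!t$event %in% c("died", "died_replaced")]
  uniq_e <- names(which(table(early_keys) == 1))
  uniq_l <- names(which(table(late_keys) == 1))
  persisting <- t$event == "survived" & key %in% uniq_e & key %in% uniq_l
  fm <- tibble::tibble(
    record_id_05 = pairs$record_id_05[!true_match],
    record_id_15 = pairs$record_id_15[!true_match],
    late_event = t$event[match(id15[!true_match], t$identity)]
  )
  list(
    precision = mean(true_match),
    recall = sum(true_match & id05 %in% t$identity[persisting]) / sum(persisting),
    n_reported = nrow(pairs),
    n_true = sum(persisting),
    false_matches = fm
  )
}

#' Score recovery of generative truth by the full pipeline
#'
#' Compares per-species estimated mean growth rates against the generator's
#' species table, and (when supplied) the recovered residual-vs-SVI slope
#' against the configured `svi_effect`.
#'
#' @param summary A [summarize_growth()] result.
#' @param city Result of [generate_city()].
#' @param svi_slope Optional recovered slope from [residuals_vs_svi()].
#' @return List: `by_species` (species, true/estimated rate, bias, n;
#'   species absent from the output appear with NA estimates), `rate_bias`,
#'   `rate_rmse`, `svi_slope_error`.
#' @export
evaluate_recovery <- function(summary, city, svi_slope = NULL) {
  cfg <- city$config
  truth <- cfg$species
  mean_svi <- mean(city$trees$svi, na.rm = TRUE)
  est <- summary$by_species
  by_species <- tibble::tibble(
    species = truth$species,
    true_rate = truth$mean_rate + cfg$svi_effect * mean_svi,
    est_rate = est$mean_rate[match(truth$species, est$species)],
    n = est$n[match(truth$species, est$species)]
  )
  by_species$bias <- by_species$est_rate - by_species$true_rate
  ok <- !is.na(by_species$bias)
  list(
    by_species = by_species,
    rate_bias = mean(by_species$bias[ok]),
    rate_rmse = sqrt(mean(by_species$bias[ok]^2)),
    svi_slope_error = if (is.null(svi_slope)) NA_real_
                      else svi_slope - cfg$svi_effect
  )
}
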
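#' Quality-control configuration for the growth cascade
#'
#' Defaults encode the cleaning cascade: keep decadal growth of -5 inches or
#' more (larger apparent shrinkage indicates a replaced tree or a gross
#' measurement error, not measurement noise), drop starting DBH of 0 (a
#' sapling rounded down) and of 41 inches or more (rare giants that skew
#' size bins), then trim 5% of trees from each growth tail within every
#' 1-inch starting-DBH bin.
#'
#' @param negative_cutoff_in Minimum decadal growth kept, inches (default -5;
#'   growth strictly below is dropped, exactly -5 is kept).
#' @param dbh_min,dbh_max Inclusive bounds on starting DBH, inches.
#' @param trim_fraction_per_tail Fraction trimmed from each tail per bin.
#' @param bin_width_in Bin width for the trim, inches.
#' @return A `qc_config` list.
#' @export
qc_config <- function(negative_cutoff_in = -5L, dbh_min = 1L, dbh_max = 40L,
                      trim_fraction_per_tail = 0.05, bin_width_in = 1L) {
  stopifnot(trim_fraction_per_tail >= 0, trim_fraction_per_tail < 0.5,
            dbh_min <= dbh_max, bin_width_in >= 1)
  structure(list(negative_cutoff_in = negative_cutoff_in,
                 dbh_min = dbh_min, dbh_max = dbh_max,
                 trim_fraction_per_tail = trim_fraction_per_tail,
                 bin_width_in = bin_width_in),
            class = "qc_config")
}

qc_stage <- function(records) attr(records, "qc_stage") %||% "none"
`%||%` <- function(a, b) if (is.null(a)) b else a

set_stage <- function(records, stage) {
  attr(records, "qc_stage") <- stage
  records
}

require_stage <- function(records, expected, op) {
  got <- qc_stage(records)
  if (!got %in% expected)
    stop(op, ": QC stages must run in order growth -> negative -> dbh_bounds -> trim; ",
         "input is at stage '", got, "'")
  invisible(got)
}

#' Compute decadal growth and growth rate for linked pairs
#'
#' Growth is the late DBH minus the early DBH (whole inches); the rate is
#' growth divided by exactly ten years, the nominal spacing of the decadal
#' snapshots. No filtering happens here; every pair gets `qc_status =
#' "retained"` and enters the cascade.
#'
#' @param pairs Tibble of linked pairs with `dbh_in_05` and `dbh_in_15`.
#' @return The pairs with `growth_in`, `rate_in_per_yr` and `qc_status`
#'   columns, staged for [filter_negative()]. Pairs missing either DBH are
#'   returned separately under `rejects`.
#' @export
compute_growth <- function(pairs) {
  stopifnot(all(c("dbh_in_05", "dbh_in_15") %in% names(pairs)))
  bad <- is.na(pairs$dbh_in_05) | is.na(pairs$dbh_in_15)
  rec <- pairs[!bad, , drop = FALSE]
  rec$growth_in <- as.integer(rec$dbh_in_15) - as.integer(rec$dbh_in_05)
  rec$rate_in_per_yr <- rec$growth_in / 10
  rec$qc_status <- "retained"
  list(records = set_stage(rec, "growth"),
       rejects = pairs[bad, , drop = FALSE])
}

#' Stage 5a: drop pairs with implausibly large negative growth
#'
#' Growth below the cutoff (default: below -5 inches over the decade) is
#' attributed to a same-species replacement or a gross error, not to
#' measurement noise, and is marked `drop_negative`. Growth of exactly -5
#' inches is retained, consistent with a retained minimum rate of -0.5 in/yr.
#'
#' @param records Output of [compute_growth()].
#' @param cfg A [qc_config()].
#' @return Records with updated `qc_status`, staged for [filter_dbh_bounds()].
#' @export
filter_negative <- function(records, cfg = qc_config()) {
  require_stage(records, c("growth", "negative"), "filter_negative")
  hit <- records$qc_status == "retained" &
    records$growth_in < cfg$negative_cutoff_in
  records$qc_status[hit] <- "drop_negative"
  set_stage(records, "negative")
}

#' Stage 5b: drop pairs outside the starting-DBH bounds
#'
#' Starting DBH of 0 (rounded-down saplings whose relative growth is
#' unconstrained) is marked `drop_dbh0`; starting DBH of 41 inches or more
#' (rare giants) is marked `drop_dbh41plus`.
#'
#' @inheritParams filter_negative
#' @return Records with updated `qc_status`, staged for [trim_bin_tails()].
#' @export
filter_dbh_bounds <- function(records, cfg = qc_config()) {
  require_stage(records, c("negative", "dbh_bounds"), "filter_dbh_bounds")
  keep <- records$qc_status == "retained"
  records$qc_status[keep & records$dbh_in_05 < cfg$dbh_min] <- "drop_dbh0"
  records$qc_status[keep & records$dbh_in_05 > cfg$dbh_max] <- "drop_dbh41plus"
  set_stage(records, "dbh_bounds")
}

#' Stage 5c: trim the growth tails within each starting-DBH bin
#'
#' Trees are grouped by starting DBH in 1-inch increments (so faster-growing
#' small trees are compared only with their size class); within each bin the
#' `floor(trim_fraction * n)` retained records with the smallest growth and
#' the same number with the largest growth are marked `drop_trimmed`. Ties
#' are broken by record id so the removal is deterministic.
#'
#' @inheritParams filter_negative
#' @return Records with updated `qc_status`, at the final stage.
#' @export
trim_bin_tails <- function(records, cfg = qc_config()) {
  require_stage(records, c("dbh_bounds", "trim"), "trim_bin_tails")
  # the trim is a one-shot step: re-applying it to already-trimmed output is
  # a no-op, so the cascade as a whole is idempotent
  if (qc_stage(records) == "trim") return(records)
  idx <- which(records$qc_status == "retained")
  if (length(idx) > 0) {
    id <- if ("record_id_05" %in% names(records)) records$record_id_05[idx]
          else as.character(seq_along(idx))
    bin <- (as.integer(records$dbh_in_05[idx]) - 1L) %/% as.integer(cfg$bin_width_in)
    for (b in unique(bin)) {
      in_bin <- idx[bin == b]
      n <- length(in_bin)
      k <- floor(cfg$trim_fraction_per_tail * n)
      if (k > 0) {
        ord <- in_bin[order(records$growth_in[in_bin],
                            id[match(in_bin, idx)], method = "radix")]
        records$qc_status[ord[seq_len(k)]] <- "drop_trimmed"
        records$qc_status[ord[seq.int(n - k + 1L, n)]] <- "drop_trimmed"
      }
    }
  }
  set_stage(records, "trim")
}

#' Run the full QC cascade in its fixed order
#'
#' @param pairs Linked pairs with both DBH columns.
#' @param cfg A [qc_config()].
#' @return List with `records` (all pairs, `qc_status` set) and `rejects`.
#' @export
apply_qc <- function(pairs, cfg = qc_config()) {
  g <- compute_growth(pairs)
  rec <- trim_bin_tails(filter_dbh_bounds(filter_negative(g$records, cfg), cfg), cfg)
  list(records = rec, rejects = g$rejects)
}

#' Summarize growth rates over QC-retained records
#'
#' @param records QC'd growth records.
#' @return List with `n`, `mean_rate`, `sd_rate`, `min_rate`, `max_rate`,
#'   `n_negative`, `frac_negative`, `n_0_to_1`, `frac_0_to_1`, and
#'   `by_species` (per-species n, mean starting DBH, mean rate; sorted by n
#'   descending).
#' @export
summarize_growth <- function(records) {
  r <- records[records$qc_status == "retained", , drop = FALSE]
  if (nrow(r) == 0) stop("summarize_growth: no retained records")
  spp_col <- if ("species_norm" %in% names(r)) "species_norm" else "species_norm_05"
  by_species <- r |>
    dplyr::group_by(species = .data[[spp_col]]) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_dbh_05 = mean(.data$dbh_in_05),
                     mean_rate = mean(.data$rate_in_per_yr),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n))
  list(
    n = nrow(r),
    mean_rate = mean(r$rate_in_per_yr),
    sd_rate = stats::sd(r$rate_in_per_yr),
    min_rate = min(r$rate_in_per_yr),
    max_rate = max(r$rate_in_per_yr),
    n_negative = sum(r$rate_in_per_yr < 0),
    frac_negative = mean(r$rate_in_per_yr < 0),
    n_0_to_1 = sum(r$rate_in_per_yr >= 0 & r$rate_in_per_yr <= 1),
    frac_0_to_1 = mean(r$rate_in_per_yr >= 0 & r$rate_in_per_yr <= 1),
    by_species = by_species
  )
}

#' Theil-Sen slope of a DBH time series
#'
#' Median of all pairwise slopes (robust to single outlying measurements,
#' which is why it is used for the ground-truth validation series). Pairs
#' with identical times are excluded.
#'
#' @param time Numeric times (decimal years), at least two distinct.
#' @param dbh DBH measurements, inches.
#' @return Slope in inches per year.
#' @export
theil_sen <- function(time, dbh) {
  stopifnot(length(time) == length(dbh), length(time) >= 2)
  dt <- outer(time, time, "-")
  dy <- outer(dbh, dbh, "-")
  use <- upper.tri(dt) & dt != 0
  if (!any(use)) stop("theil_sen: all times equal")
  stats::median(dy[use] / dt[use])
}

#' Tie-corrected Kendall rank correlation of DBH against time
#'
#' Kendall tau-b between the observation times and the DBH values: +1 for a
#' strictly monotone increase across the series, -1 for a strictly monotone
#' decrease. Whole-inch DBH makes ties common, so the tie-corrected variant
#' is used. Undefined (NA) below three points.
#'
#' @inheritParams theil_sen
#' @return Tau in [-1, 1], or NA when fewer than three points.
#' @export
kendall_tau <- function(time, dbh) {
  stopifnot(length(time) == length(dbh))
  if (length(time) < 3) return(NA_real_)
  suppressWarnings(stats::cor(time, dbh, method = "kendall"))
}
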
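#' Run the full growth-rate pipeline on two raw census snapshots
#'
#' Executes the fixed stage order: normalize both snapshots, drop non-unique
#' keys within each, align them into one-to-one pairs, run the QC cascade
#' (negative cutoff, DBH bounds, per-bin trim), and summarize growth. Every
#' drop is soft — records keep a status/reason and are counted in the step
#' report — so the cleaning cascade is always auditable.
#'
#' @param raw_early,raw_late Raw census tibbles (or CSV paths).
#' @param dialect_early,dialect_late Column dialects, see [nyc_dialect()].
#' @param years Integer census years, length 2.
#' @param cfg A [qc_config()].
#' @param dict,rules Species dictionary and abbreviation table.
#' @return List: `records` (QC'd growth records), `pairs`, `summary`
#'   ([summarize_growth()]), `linkage` (linkage report), `steps` (step
#'   report: tibble of step, n_in, n_out, n_dropped).
#' @export
run_pipeline <- function(raw_early, raw_late,
                         dialect_early = nyc_dialect("2005"),
                         dialect_late = nyc_dialect("2015"),
                         years = c(2005L, 2015L),
                         cfg = qc_config(),
                         dict = default_species_dictionary(),
                         rules = default_abbreviations()) {
  ingest <- function(x, dialect, year) {
    if (is.character(x) && length(x) == 1) {
      read_census_csv(x, dialect, year, dict, rules)
    } else {
      normalize_census(x, dialect, year, dict, rules)
    }
  }
  early <- ingest(raw_early, dialect_early, years[1])
  late <- ingest(raw_late, dialect_late, years[2])
  if (nrow(early$records) == 0) stop("run_pipeline: empty early census")
  if (nrow(late$records) == 0) stop("run_pipeline: empty late census")

  de <- drop_nonunique_keys(early$records)
  dl <- drop_nonunique_keys(late$records)
  al <- align_censuses(de$retained, dl$retained)
  qc <- apply_qc(al$pairs, cfg)
  rec <- qc$records

  steps <- tibble::tibble(
    step = c("read_early", "read_late", "dedupe_early", "dedupe_late",
             "align", "qc_negative", "qc_dbh_bounds", "qc_trim"),
    n_in = c(nrow(early$records) + nrow(early$rejects),
             nrow(late$records) + nrow(late$rejects),
             nrow(early$records), nrow(late$records),
             nrow(de$retained) + nrow(dl$retained),
             nrow(al$pairs),
             nrow(al$pairs) - sum(rec$qc_status == "drop_negative"),
             nrow(al$pairs) - sum(rec$qc_status %in%
                                    c("drop_negative", "drop_dbh0", "drop_dbh41plus"))),
    n_out = c(nrow(early$records), nrow(late$records),
              nrow(de$retained), nrow(dl$retained),
              nrow(al$pairs),
              nrow(al$pairs) - sum(rec$qc_status == "drop_negative"),
              nrow(al$pairs) - sum(rec$qc_status %in%
                                     c("drop_negative", "drop_dbh0", "drop_dbh41plus")),
              sum(rec$qc_status == "retained"))
  )
  steps$n_dropped <- steps$n_in - steps$n_out

  list(records = rec,
       pairs = al$pairs,
       summary = summarize_growth(rec),
       linkage = linkage_report(de, dl, al),
       steps = steps)
}

#' Render a step-count and summary report as markdown
#'
#' Pure function of already-computed artifacts: regenerating the report from
#' saved outputs reproduces it exactly.
#'
#' @param steps Step report tibble from [run_pipeline()].
#' @param summary A [summarize_growth()] result.
#' @param fit Optional `fit_result` whose coefficient table is appended.
#' @return A single markdown string.
#' @export
report_markdown <- function(steps, summary, fit = NULL) {
  fmt_tbl <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x)
      ifelse(x == round(x), format(x, trim = TRUE, scientific = FALSE),
             sprintf("%.3f", x)))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    paste(c(header, sep, rows), collapse = "\n")
  }
  parts <- c(
    "# Street-tree growth pipeline report", "",
    "## Processing steps", "", fmt_tbl(steps), "",
    "## Growth summary", "",
    sprintf("- retained trees: %d", summary$n),
    sprintf("- mean growth rate: %.3f +/- %.3f in/yr",
            summary$mean_rate, summary$sd_rate),
    sprintf("- range: %.1f to %.1f in/yr", summary$min_rate, summary$max_rate),
    sprintf("- negative rates: %d (%.1f%%)",
            summary$n_negative, 100 * summary$frac_negative),
    sprintf("- rates in [0, 1] in/yr: %d (%.1f%%)",
            summary$n_0_to_1, 100 * summary$frac_0_to_1),
    "", "## Growth by species", "", fmt_tbl(summary$by_species)
  )
  if (!is.null(fit)) {
    parts <- c(parts, "", "## Determinants model", "",
               sprintf("- n = %d, adjusted R^2 = %.3f, RMSE = %.3f in/yr",
                       fit$n, fit$adj_r2, fit$rmse),
               "", fmt_tbl(fit$coefficients))
  }
  paste(parts, collapse = "\n")
}

#' Assemble the determinants model table from QC'd growth records
#'
#' The covariates stage: takes the QC-retained linked pairs (with the late
#' snapshot's reliable coordinates), attaches urban-form covariates from the
#' street and zone layers, and returns one model-ready row per tree. The
#' ZIP Code of the match key doubles as the aggregation zone id.
#'
#' @param records QC'd growth records from [run_pipeline()]; rows with
#'   `qc_status != "retained"` are ignored.
#' @param segments,lots,tracts Spatial layers as in [attach_covariates()].
#' @param max_radius Nearest-segment search radius.
#' @return Tibble with `rate_in_per_yr`, `dbh_in_05`, `species`, the survey
#'   categoricals, the urban-form covariates, `svi` and `zone_id`.
#' @export
assemble_model_data <- function(records, segments, lots, tracts,
                                max_radius = 100) {
  rec <- records[records$qc_status == "retained", , drop = FALSE]
  if (!all(c("x", "y") %in% names(rec)))
    stop("assemble_model_data: records lack coordinates (x, y)")
  trees <- tibble::tibble(record_id = rec$record_id_15,
                          x = as.numeric(rec$x), y = as.numeric(rec$y))
  cov <- attach_covariates(trees, segments, lots, tracts, max_radius)
  pick <- function(nm) if (nm %in% names(rec)) rec[[nm]] else NA_character_
  tibble::tibble(
    record_id = rec$record_id_15,
    rate_in_per_yr = rec$rate_in_per_yr,
    dbh_in_05 = rec$dbh_in_05,
    species = rec$species_norm,
    health = pick("health_15"),
    steward = pick("steward_15"),
    guards = pick("guards_15"),
    sidewalk = pick("sidewalk_15"),
    curb_loc = pick("curb_loc_15"),
    borough = pick("borough_15"),
    user_type = pick("user_type_15"),
    roadside_location = cov$roadside_location,
    st_width = cov$st_width,
    land_use = cov$land_use,
    builtFAR = cov$builtFAR,
    pop_density = cov$pop_density,
    svi = cov$svi,
    zone_id = rec$zip
  )
}
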
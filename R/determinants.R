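#' Standardize a continuous predictor by twice its standard deviation
#'
#' Centers on the mean and divides by two sample standard deviations, so the
#' resulting coefficient is directly comparable to that of a binary
#' indicator. The standardized column has mean 0 and sample SD 0.5.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @param name Term name used in error messages.
#' @return Standardized numeric vector.
#' @export
standardize_2sd <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("standardize_2sd: constant or degenerate term '", name, "'")
  (x - mean(x, na.rm = TRUE)) / (2 * s)
}

#' Model specification for the growth-determinants regression
#'
#' The response is the decadal growth rate (in/yr). Categorical terms carry
#' declared reference levels: species uses "Other" (the pool of species
#' outside the `top_k` most abundant), tree guards use "Harmful", and the
#' surveyor class uses "NYC Parks Staff"; remaining factors default to their
#' first level alphabetically. Continuous terms are 2-SD standardized at fit
#' time. The social-vulnerability index is never a model term — it is
#' reserved for comparison against residuals.
#'
#' @param continuous Character vector of continuous term names.
#' @param categorical Named list: term name -> reference level (NA = first
#'   level alphabetically).
#' @param include_borough Keep the borough term (dropped for the residual
#'   mapping so no arbitrary spatial correction absorbs zone structure).
#' @param top_k Number of most-abundant species kept distinct; the rest are
#'   pooled into "Other".
#' @param response Response column name.
#' @return A `model_spec` list.
#' @export
model_spec <- function(continuous = c("dbh_in_05", "builtFAR", "pop_density", "st_width"),
                       categorical = list(species = "Other",
                                          guards = "Harmful",
                                          user_type = "NYC Parks Staff",
                                          health = NA, steward = NA,
                                          curb_loc = NA, sidewalk = NA,
                                          roadside_location = NA,
                                          land_use = NA,
                                          borough = NA),
                       include_borough = TRUE, top_k = 15,
                       response = "rate_in_per_yr") {
  if ("svi" %in% c(continuous, names(categorical)))
    stop("model_spec: the social-vulnerability index is never a model term")
  if (!include_borough) categorical$borough <- NULL
  structure(list(continuous = continuous, categorical = categorical,
                 include_borough = include_borough, top_k = top_k,
                 response = response),
            class = "model_spec")
}

# pool all but the top_k most abundant species into "Other"
pool_species <- function(species, top_k) {
  tab <- sort(table(species), decreasing = TRUE)
  keep <- names(tab)[seq_len(min(top_k, length(tab)))]
  ifelse(species %in% keep, species, "Other")
}

# complete-case model frame with pooled species, releveled factors,
# 2-SD standardized continuous columns
build_model_frame <- function(spec, data) {
  cols <- c(spec$response, spec$continuous, names(spec$categorical))
  cols <- intersect(cols, names(data))
  missing_terms <- setdiff(c(spec$response, spec$continuous), names(data))
  if (length(missing_terms) > 0)
    stop("fit_ols: data lacks term(s): ", paste(missing_terms, collapse = ", "))
  mf <- data[, cols, drop = FALSE]
  cc <- stats::complete.cases(mf)
  mf <- mf[cc, , drop = FALSE]
  if ("species" %in% names(mf))
    mf$species <- pool_species(mf$species, spec$top_k)
  for (term in intersect(names(spec$categorical), names(mf))) {
    f <- factor(mf[[term]])
    ref <- spec$categorical[[term]]
    if (!is.na(ref)) {
      if (!ref %in% levels(f))
        stop("fit_ols: reference level '", ref, "' absent from term '", term, "'")
      f <- stats::relevel(f, ref = ref)
    }
    mf[[term]] <- f
  }
  for (term in intersect(spec$continuous, names(mf)))
    mf[[term]] <- standardize_2sd(mf[[term]], term)
  attr(mf, "n_excluded") <- sum(!cc)
  mf
}

#' Fit the standardized OLS growth-determinants model
#'
#' Ordinary least squares of growth rate on species, stewardship, guard,
#' surveyor and urban-form terms, with continuous predictors 2-SD
#' standardized and categorical terms indicator-coded against their declared
#' reference levels. Complete-case rows only (exclusion count reported).
#'
#' @param spec A [model_spec()].
#' @param data Tibble holding the response and all terms.
#' @return A `fit_result` list: `coefficients` (tibble: term, level, estimate,
#'   se, ci_lo, ci_hi, p), `adj_r2`, `rmse` (root mean squared residual,
#'   in/yr), `n`, `n_excluded`, `gvif` (per-term tibble), and `model` (the
#'   underlying `lm`).
#' @export
fit_ols <- function(spec, data) {
  mf <- build_model_frame(spec, data)
  terms_used <- intersect(c(spec$continuous, names(spec$categorical)), names(mf))
  # drop single-level factors (cannot contribute a contrast)
  terms_used <- terms_used[vapply(terms_used, function(t)
    !is.factor(mf[[t]]) || nlevels(droplevels(mf[[t]])) > 1, logical(1))]
  fml <- stats::reformulate(terms_used, response = spec$response)
  fit <- stats::lm(fml, data = mf)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("fit_ols: rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  co <- sm$coefficients
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, 1]), se = unname(co[, 2]),
    ci_lo = unname(ci[, 1]), ci_hi = unname(ci[, 2]),
    p = unname(co[, 4])
  )
  res <- stats::residuals(fit)
  structure(list(
    coefficients = coefs,
    adj_r2 = sm$adj.r.squared,
    rmse = sqrt(mean(res^2)),
    n = nrow(mf),
    n_excluded = attr(mf, "n_excluded"),
    gvif = gvif(stats::model.matrix(fit), attr(stats::model.matrix(fit), "assign"),
                attr(stats::terms(fit), "term.labels")),
    model = fit
  ), class = "fit_result")
}

#' Generalized variance inflation factors of a fitted design
#'
#' Determinant-ratio construction on the correlation matrix of the design
#' (intercept excluded): for a term occupying columns A with the remaining
#' columns B, GVIF = det(R_AA) det(R_BB) / det(R). For a single-column term
#' this reduces to the classical VIF 1/(1 - R^2). GVIF^(1/(2 df)) puts terms
#' of different dimension on a comparable scale.
#'
#' @param design Numeric design matrix including an intercept column.
#' @param assign Integer vector mapping design columns to terms (as from
#'   `attr(model.matrix(fit), "assign")`; 0 = intercept).
#' @param term_labels Term names, indexed by the positive `assign` values.
#' @return Tibble: term, df, gvif, gvif_adj (= GVIF^(1/(2 df))).
#' @export
gvif <- function(design, assign, term_labels) {
  keep <- assign != 0
  X <- design[, keep, drop = FALSE]
  a <- assign[keep]
  if (ncol(X) < 2) {
    return(tibble::tibble(term = term_labels[unique(a)], df = 1,
                          gvif = 1, gvif_adj = 1))
  }
  R <- stats::cor(X)
  detR <- det(R)
  if (detR <= 0) stop("gvif: singular design correlation matrix")
  rows <- lapply(sort(unique(a)), function(t) {
    A <- a == t
    g <- det(R[A, A, drop = FALSE]) * det(R[!A, !A, drop = FALSE]) / detR
    tibble::tibble(term = term_labels[t], df = sum(A),
                   gvif = g, gvif_adj = g^(1 / (2 * sum(A))))
  })
  dplyr::bind_rows(rows)
}

#' Compare growth rates across the levels of one categorical factor
#'
#' Two levels: Welch-free classical two-sample t-test (equal-variance,
#' matching the ANOVA framework). Three or more: one-way ANOVA with Tukey HSD
#' post-hoc pairwise comparisons, summarized as a compact letter display
#' (levels sharing no letter differ at `alpha`). Levels with fewer than two
#' observations are excluded with a warning.
#'
#' @param factor_values Character/factor vector of group labels.
#' @param rates Numeric response.
#' @param alpha Significance level for the display.
#' @return List with `levels` (tibble: level, n, mean, q25, q75, letters),
#'   `test` ("t-test" or "anova_tukey"), `p_global` (t-test or ANOVA F p),
#'   and `pairwise` (tibble of pairwise p-values when applicable).
#' @export
group_compare <- function(factor_values, rates, alpha = 0.05) {
  f <- as.character(factor_values)
  ok <- !is.na(f) & !is.na(rates)
  f <- f[ok]; y <- rates[ok]
  tab <- table(f)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("group_compare: excluding level(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !f %in% small
    f <- f[keep]; y <- y[keep]
  }
  lev <- sort(unique(f))
  if (length(lev) < 2) stop("group_compare: fewer than two usable levels")
  per <- tibble::tibble(
    level = lev,
    n = as.integer(table(factor(f, levels = lev))),
    mean = vapply(lev, function(l) mean(y[f == l]), numeric(1)),
    q25 = vapply(lev, function(l) unname(stats::quantile(y[f == l], 0.25)), numeric(1)),
    q75 = vapply(lev, function(l) unname(stats::quantile(y[f == l], 0.75)), numeric(1))
  )
  if (length(lev) == 2) {
    tt <- stats::t.test(y[f == lev[1]], y[f == lev[2]], var.equal = TRUE)
    pmat <- tibble::tibble(level_a = lev[1], level_b = lev[2], p = tt$p.value)
    per$letters <- if (tt$p.value < alpha) c("a", "b") else c("a", "a")
    return(list(levels = per, test = "t-test", p_global = tt$p.value,
                pairwise = pmat))
  }
  fit <- stats::aov(y ~ factor(f, levels = lev))
  tk <- stats::TukeyHSD(fit)[[1]]
  cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pmat <- tibble::tibble(level_a = cmp[, 1], level_b = cmp[, 2], p = tk[, "p adj"])
  per$letters <- compact_letters(lev, pmat, alpha)
  list(levels = per, test = "anova_tukey",
       p_global = summary(fit)[[1]][["Pr(>F)"]][1], pairwise = pmat)
}

#' Compact letter display by insert-absorb
#'
#' Builds letter codes from a table of pairwise p-values so that two levels
#' share a letter if and only if they are not significantly different at
#' `alpha`. Letters are assigned greedily: start with one group holding all
#' levels; for each significant pair occupying a common group, split the
#' group; absorb groups that are subsets of others; letter groups in order of
#' their first level.
#'
#' @param levels Character vector of level names.
#' @param pairwise Tibble with `level_a`, `level_b`, `p`.
#' @param alpha Significance threshold.
#' @return Character vector of letter strings, one per level.
#' @export
compact_letters <- function(levels, pairwise, alpha = 0.05) {
  groups <- list(levels)
  sig <- pairwise[pairwise$p < alpha, , drop = FALSE]
  if (nrow(sig) > 0) {
    for (i in seq_len(nrow(sig))) {
      a <- sig$level_a[i]; b <- sig$level_b[i]
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        if (a %in% g && b %in% g) {
          groups[[gi]] <- setdiff(g, a)
          groups <- c(groups, list(setdiff(g, b)))
        }
      }
      # absorb: drop groups contained in another group
      keep <- rep(TRUE, length(groups))
      for (gi in seq_along(groups)) {
        for (gj in seq_along(groups)) {
          if (gi != gj && keep[gj] &&
              all(groups[[gi]] %in% groups[[gj]]) &&
              (length(groups[[gi]]) < length(groups[[gj]]) || gi > gj)) {
            keep[gi] <- FALSE
            break
          }
        }
      }
      groups <- groups[keep]
    }
  }
  # order groups by first member, assign letters
  first <- vapply(groups, function(g) min(match(g, levels)), numeric(1))
  groups <- groups[order(first)]
  out <- vapply(levels, function(l) {
    paste(letters[which(vapply(groups, function(g) l %in% g, logical(1)))],
          collapse = "")
  }, character(1))
  unname(out)
}

#' Pearson correlation screen of growth rate against continuous covariates
#'
#' @param rate Numeric response.
#' @param covariates Tibble/data.frame of continuous covariates.
#' @return Tibble: covariate, n, r, p (r is NA for constant covariates).
#' @export
pearson_screen <- function(rate, covariates) {
  rows <- lapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    ok <- !is.na(x) & !is.na(rate)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0)
      return(tibble::tibble(covariate = nm, n = sum(ok), r = NA_real_,
                            p = NA_real_))
    ct <- stats::cor.test(rate[ok], x[ok], method = "pearson")
    tibble::tibble(covariate = nm, n = sum(ok),
                   r = unname(ct$estimate), p = ct$p.value)
  })
  dplyr::bind_rows(rows)
}

#' Regress zone-mean growth residuals on zone-mean social vulnerability
#'
#' Refits the determinants model without the borough term (so no arbitrary
#' spatial correction absorbs zone-level structure), averages the tree-level
#' residuals (observed minus predicted rate) and the SVI by zone, filters
#' zones through [aggregate_by_zone()]'s size/exclusion rules, and fits a
#' simple linear regression of zone-mean residual on zone-mean SVI. A
#' positive slope means growth is faster than the model predicts in more
#' vulnerable zones.
#'
#' @param spec A [model_spec()]; its borough term is removed here.
#' @param data Tibble with model terms plus `zone_id` and `svi`.
#' @param min_n Minimum trees per zone.
#' @param exclude Zone ids excluded outright.
#' @param weighted Weight the zone-level regression by zone tree count
#'   (default unweighted).
#' @return List with `fit` (the borough-free `fit_result`), `zones` (tibble:
#'   zone_id, n, mean_residual, mean_svi), `slope`, `intercept`, `p_slope`,
#'   and `excluded`.
#' @export
residuals_vs_svi <- function(spec, data, min_n = 100, exclude = character(0),
                             weighted = FALSE) {
  spec$include_borough <- FALSE
  spec$categorical$borough <- NULL
  stopifnot(all(c("zone_id", "svi") %in% names(data)))
  fit <- fit_ols(spec, data)
  mf_rows <- as.integer(rownames(stats::model.frame(fit$model)))
  used <- data[stats::complete.cases(
    data[, intersect(c(spec$response, spec$continuous, names(spec$categorical)),
                     names(data)), drop = FALSE]), , drop = FALSE]
  used$residual <- stats::residuals(fit$model)
  zones <- used[!is.na(used$zone_id) & !is.na(used$svi), , drop = FALSE] |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_residual = mean(.data$residual),
                     mean_svi = mean(.data$svi), .groups = "drop")
  listed <- zones$zone_id %in% exclude
  thin <- !listed & zones$n < min_n
  excluded <- tibble::tibble(zone_id = zones$zone_id[listed | thin],
                             n = zones$n[listed | thin],
                             reason = ifelse(listed[listed | thin],
                                             "listed", "below_min_n"))
  zones <- zones[!listed & !thin, , drop = FALSE]
  if (nrow(zones) < 3)
    stop("residuals_vs_svi: fewer than 3 zones survive the filters")
  w <- if (weighted) zones$n else NULL
  zfit <- stats::lm(mean_residual ~ mean_svi, data = zones, weights = w)
  sm <- summary(zfit)
  list(fit = fit, zones = zones,
       slope = unname(stats::coef(zfit)[2]),
       intercept = unname(stats::coef(zfit)[1]),
       p_slope = sm$coefficients[2, 4],
       excluded = excluded)
}
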
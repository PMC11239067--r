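#!/usr/bin/env Rscript
# The statistical layer: group comparisons with Tukey letters, the Pearson
# screen of continuous covariates, the 2-SD standardized OLS with GVIF
# collinearity diagnostics, and the borough-free residual-vs-SVI regression.

library(streetgrowth)

dat <- readr::read_csv("results/model_data.csv", show_col_types = FALSE)

## group comparisons (ANOVA + Tukey letters, or t-test for two levels)
for (f in c("health", "guards", "curb_loc", "user_type")) {
  gc <- group_compare(dat[[f]], dat$rate_in_per_yr)
  readr::write_csv(gc$levels, sprintf("results/groups_%s.csv", f),
                   progress = FALSE)
  cat(sprintf("%s (%s): %s\n", f, gc$test,
              paste(sprintf("%s %.3f [%s]", gc$levels$level, gc$levels$mean,
                            gc$levels$letters), collapse = ", ")))
}

## Pearson screen of the continuous covariates
scr <- pearson_screen(dat$rate_in_per_yr,
                      dat[, c("dbh_in_05", "builtFAR", "pop_density", "st_width")])
readr::write_csv(scr, "results/pearson_screen.csv", progress = FALSE)
cat("Pearson screen:\n"); print(as.data.frame(scr), digits = 3)

## standardized OLS with GVIF
fit <- fit_ols(model_spec(), dat)
readr::write_csv(fit$coefficients, "results/ols_coefficients.csv", progress = FALSE)
readr::write_csv(fit$gvif, "results/ols_gvif.csv", progress = FALSE)
jsonlite::write_json(list(n = fit$n, adj_r2 = fit$adj_r2, rmse = fit$rmse),
                     "results/ols_report.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("OLS: n = %d, adjusted R^2 = %.3f, RMSE = %.3f in/yr, max GVIF^(1/2df) = %.2f\n",
            fit$n, fit$adj_r2, fit$rmse, max(fit$gvif$gvif_adj)))

## residuals vs social vulnerability, borough-free model
rv <- residuals_vs_svi(model_spec(), dat, min_n = 20)
readr::write_csv(rv$zones, "results/zone_residuals.csv", progress = FALSE)
jsonlite::write_json(list(slope = rv$slope, intercept = rv$intercept,
                          p_slope = rv$p_slope, n_zones = nrow(rv$zones)),
                     "results/svi_regression.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("residual vs SVI: slope %.3f in/yr per unit SVI (p = %.2g, %d zones)\n",
            rv$slope, rv$p_slope, nrow(rv$zones)))

## human-readable report over the saved artifacts
steps <- readr::read_csv("results/growth.csv", show_col_types = FALSE)
s <- summarize_growth(steps)
writeLines(report_markdown(
  tibble::tibble(step = "qc", n_in = nrow(steps), n_out = s$n,
                 n_dropped = nrow(steps) - s$n),
  s, fit), "results/report.md")
cat("report written to results/report.md\n")
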
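test_that("2-SD standardization yields mean 0, SD 0.5 and rejects constants", {
  x <- c(0, 0, 2, 2)
  z <- standardize_2sd(x)
  expect_equal(z, c(-0.4330127, -0.4330127, 0.4330127, 0.4330127),
               tolerance = 1e-6)
  set.seed(13)
  y <- stats::rlnorm(500)
  zy <- standardize_2sd(y)
  expect_equal(mean(zy), 0)
  expect_equal(stats::sd(zy), 0.5)
  expect_true(all(order(zy) == order(y)))       # linear, order-preserving
  expect_error(standardize_2sd(rep(3, 10), "flat"), "flat")
})

test_that("OLS recovers noise-free coefficients and centers residuals", {
  d <- tibble::tibble(rate_in_per_yr = 0.3 - 0.1 * seq(0, 1, length.out = 50),
                      dbh_in_05 = seq(0, 1, length.out = 50))
  spec <- model_spec(continuous = "dbh_in_05", categorical = list(), top_k = 0)
  fit <- fit_ols(spec, d)
  # the standardized slope maps back to -0.1 per unit after unscaling
  sdx <- 2 * stats::sd(d$dbh_in_05)
  expect_equal(fit$coefficients$estimate[2] / sdx, -0.1, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
  expect_equal(sum(stats::residuals(fit$model)), 0, tolerance = 1e-10)
})

test_that("OLS confidence intervals cover the truth at their nominal rate", {
  set.seed(14)
  beta <- 0.4
  covered <- vapply(1:200, function(i) {
    x <- stats::rnorm(400)
    f <- sample(c("a", "b", "c"), 400, replace = TRUE)
    y <- 1 + beta * x + (f == "b") * 0.3 + stats::rnorm(400)
    d <- tibble::tibble(rate_in_per_yr = y, dbh_in_05 = x, health = f)
    spec <- model_spec(continuous = "dbh_in_05",
                       categorical = list(health = NA), top_k = 0)
    fit <- fit_ols(spec, d)
    row <- fit$coefficients[fit$coefficients$term == "dbh_in_05", ]
    b_std <- beta * 2 * stats::sd(x)   # truth on the standardized scale
    row$ci_lo <= b_std && b_std <= row$ci_hi
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("effect estimates are invariant to row order", {
  city <- generate_city(small_city_config(seed = 35))
  res <- run_pipeline(observe_census(city, "early"), observe_census(city, "late"))
  dat <- assemble_model_data(res$records, city$segments, city$lots, city$tracts)
  spec <- model_spec(top_k = 5)
  f1 <- fit_ols(spec, dat)
  set.seed(1)
  f2 <- fit_ols(spec, dat[sample.int(nrow(dat)), ])
  expect_equal(f1$coefficients$estimate[order(f1$coefficients$term)],
               f2$coefficients$estimate[order(f2$coefficients$term)],
               tolerance = 1e-9)
})

test_that("model spec guards its contract", {
  expect_error(model_spec(continuous = c("dbh_in_05", "svi")), "never a model term")
  d <- tibble::tibble(rate_in_per_yr = stats::rnorm(20),
                      dbh_in_05 = stats::rnorm(20),
                      copy = NA_real_)
  d$copy <- d$dbh_in_05
  spec <- model_spec(continuous = c("dbh_in_05", "copy"),
                     categorical = list(), top_k = 0)
  expect_error(fit_ols(spec, d), "collinear|singular")
})

test_that("GVIF reduces to 1/(1-R2) for single columns and matches car", {
  # orthogonal columns: all GVIF 1
  X <- cbind(1, diag(4)[rep(1:4, 25), ])
  set.seed(15)
  Xo <- cbind(1, matrix(stats::rnorm(300), 100, 3))
  g <- gvif(Xo, c(0, 1, 2, 3), c("a", "b", "c"))
  for (k in 1:3) {
    r2 <- summary(stats::lm(Xo[, k + 1] ~ Xo[, -c(1, k + 1)]))$r.squared
    expect_equal(g$gvif[k], 1 / (1 - r2), tolerance = 1e-8)
  }
  # correlation 0.8 between two columns: VIF ~ 1/(1-0.64)
  set.seed(16)
  x1 <- stats::rnorm(5000)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * stats::rnorm(5000)
  Xc <- cbind(1, x1, x2)
  gc <- gvif(Xc, c(0, 1, 2), c("x1", "x2"))
  expect_equal(gc$gvif[1], 1 / (1 - stats::cor(x1, x2)^2), tolerance = 1e-8)
  expect_equal(gc$gvif[1], 2.778, tolerance = 0.15)
  # categorical term: determinant construction agrees with car::vif
  skip_if_not_installed("car")
  set.seed(17)
  d <- data.frame(x1 = stats::rnorm(300), f = factor(sample(letters[1:4], 300, TRUE)))
  d$x2 <- 0.6 * d$x1 + stats::rnorm(300)
  d$y <- stats::rnorm(300)
  fit <- stats::lm(y ~ x1 + x2 + f, d)
  mm <- stats::model.matrix(fit)
  mine <- gvif(mm, attr(mm, "assign"), attr(stats::terms(fit), "term.labels"))
  theirs <- car::vif(fit)
  expect_equal(mine$gvif, unname(theirs[, 1]), tolerance = 1e-8)
  expect_equal(mine$gvif_adj, unname(theirs[, 3]), tolerance = 1e-8)
})

test_that("group comparison separates distinct groups and letters agree", {
  set.seed(18)
  y <- c(stats::rnorm(30, 0, 0.01), stats::rnorm(30, 10, 0.01),
         stats::rnorm(30, 20, 0.01))
  f <- rep(c("a", "b", "c"), each = 30)
  gc <- group_compare(f, y)
  expect_equal(gc$test, "anova_tukey")
  expect_equal(gc$levels$letters, c("a", "b", "c"))
  # identical groups share one letter
  y2 <- rep(stats::rnorm(30), 3)
  gc2 <- group_compare(rep(c("a", "b", "c"), each = 30), y2)
  expect_true(all(gc2$levels$letters == gc2$levels$letters[1]))
  # two levels fall back to a t-test
  gc3 <- group_compare(rep(c("x", "y"), each = 30),
                       c(stats::rnorm(30), stats::rnorm(30, 5)))
  expect_equal(gc3$test, "t-test")
  expect_equal(gc3$levels$letters, c("a", "b"))
  expect_warning(group_compare(c("a", "a", "b", "c", "c"), c(1, 2, 3, 4, 5)),
                 "excluding")
})

test_that("compact letters encode exactly the non-significant sharing", {
  pw <- tibble::tibble(level_a = c("a", "a", "b"),
                       level_b = c("b", "c", "c"),
                       p = c(0.01, 0.01, 0.5))
  expect_equal(compact_letters(c("a", "b", "c"), pw), c("a", "b", "b"))
  pw2 <- tibble::tibble(level_a = "a", level_b = "b", p = 1)
  expect_equal(compact_letters(c("a", "b"), pw2), c("a", "a"))
})

test_that("Tukey letter display holds its family-wise error near alpha", {
  set.seed(19)
  n_rep <- 1000
  rejected <- vapply(seq_len(n_rep), function(i) {
    y <- stats::rnorm(45)
    f <- rep(c("a", "b", "c"), each = 15)
    gc <- group_compare(f, y)
    length(unique(gc$levels$letters)) > 1
  }, logical(1))
  expect_gt(mean(rejected), 0.03)
  expect_lt(mean(rejected), 0.075)
})

test_that("Pearson screen reports exact and null correlations", {
  x <- seq_len(50)
  out <- pearson_screen(-x, tibble::tibble(v = x))
  expect_equal(out$r, -1)
  set.seed(20)
  out2 <- pearson_screen(stats::rnorm(10000),
                         tibble::tibble(u = stats::rnorm(10000)))
  expect_lt(abs(out2$r), 0.05)
  out3 <- pearson_screen(stats::rnorm(10), tibble::tibble(k = rep(1, 10)))
  expect_true(is.na(out3$r))
})

test_that("rate declines with starting size on synthetic data, as built in", {
  city <- generate_city(small_city_config(seed = 36))
  res <- run_pipeline(observe_census(city, "early"), observe_census(city, "late"))
  rec <- res$records[res$records$qc_status == "retained", ]
  out <- pearson_screen(rec$rate_in_per_yr, tibble::tibble(dbh = rec$dbh_in_05))
  expect_lt(out$r, 0)
  expect_lt(out$p, 0.001)
})

test_that("residuals-vs-SVI needs enough zones and excludes borough", {
  city <- generate_city(small_city_config(seed = 37))
  res <- run_pipeline(observe_census(city, "early"), observe_census(city, "late"))
  dat <- assemble_model_data(res$records, city$segments, city$lots, city$tracts)
  rv <- residuals_vs_svi(model_spec(), dat, min_n = 10)
  expect_false(any(grepl("borough", rv$fit$coefficients$term)))
  expect_true(is.finite(rv$slope))
  # tree-level residuals from the fit average to zero
  expect_equal(mean(stats::residuals(rv$fit$model)), 0, tolerance = 1e-10)
  dat_one <- dat; dat_one$zone_id <- "only"
  expect_error(residuals_vs_svi(model_spec(), dat_one, min_n = 10),
               "fewer than 3 zones")
})
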
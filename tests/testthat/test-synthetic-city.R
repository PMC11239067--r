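test_that("generation and observation are deterministic given the seed", {
  cfg <- small_city_config(seed = 55)
  c1 <- generate_city(cfg); c2 <- generate_city(cfg)
  expect_identical(c1$trees, c2$trees)
  expect_identical(observe_census(c1, "early"), observe_census(c2, "early"))
  expect_identical(observe_census(c1, "late"), observe_census(c2, "late"))
  c3 <- generate_city(small_city_config(seed = 56))
  expect_false(identical(c1$trees$dbh0, c3$trees$dbh0))
})

test_that("zero duplicate probability makes every key unique", {
  city <- generate_city(clean_city_config(seed = 57))
  key <- paste(city$trees$zip, city$trees$address, city$trees$species)
  expect_false(anyDuplicated(key) > 0)
})

test_that("species frequencies land within binomial tolerance", {
  cfg <- city_config(seed = 58, n_streets = 50, addresses_per_street = 100,
                     duplicate_series_prob = 0)
  city <- generate_city(cfg)
  n <- nrow(city$trees)
  counts <- table(factor(city$trees$species, levels = cfg$species$species))
  expected <- cfg$species$freq * n
  # 4-sigma binomial band per species
  tol <- 4 * sqrt(n * cfg$species$freq * (1 - cfg$species$freq))
  expect_true(all(abs(as.numeric(counts) - expected) <= tol))
})

test_that("survival arithmetic gives the exponential-decay fraction", {
  expect_equal(survival_fraction(0.044, 10), (1 - 0.044)^10)
  expect_equal(round(survival_fraction(0.044, 10), 2), 0.64)
  expect_equal(survival_fraction(0, 10), 1)
  expect_equal(survival_fraction(1, 1), 0)
})

test_that("the early census partitions into survived, died, and replaced", {
  city <- generate_city(small_city_config(seed = 59))
  orig <- city$trees[city$trees$event != "replacement", ]
  expect_setequal(unique(orig$event), c("survived", "died", "died_replaced"))
  e <- observe_census(city, "early")
  expect_equal(nrow(e), nrow(orig))
  # survivor share within binomial tolerance of the configured decay
  p <- survival_fraction(city$config$annual_mortality, 10)
  phat <- mean(orig$event == "survived")
  expect_lt(abs(phat - p), 4 * sqrt(p * (1 - p) / nrow(orig)))
})

test_that("observation applies rounding and the engineered entry errors", {
  # no noise: reported DBH is the rounded truth
  city <- generate_city(clean_city_config(seed = 60, measurement_sd = 0))
  e <- observe_census(city, "early")
  truth <- city$trees$dbh0[match(sub("^E", "", e$record_id), city$trees$identity)]
  expect_equal(e$dbh_05, pmax(0L, as.integer(round(truth))))
  # circumference errors inflate by pi; digit errors drop the trailing digit
  city2 <- generate_city(clean_city_config(seed = 61, measurement_sd = 0,
                                           circumference_error_prob = 0.5))
  e2 <- observe_census(city2, "early")
  truth2 <- city2$trees$dbh0[match(sub("^E", "", e2$record_id), city2$trees$identity)]
  frac_circ <- mean(e2$dbh_05 == as.integer(round(pi * truth2)))
  expect_gt(frac_circ, 0.4); expect_lt(frac_circ, 0.6)
  city3 <- generate_city(clean_city_config(seed = 62, measurement_sd = 0,
                                           digit_error_prob = 1))
  e3 <- observe_census(city3, "early")
  truth3 <- city3$trees$dbh0[match(sub("^E", "", e3$record_id), city3$trees$identity)]
  big <- as.integer(round(truth3)) >= 10
  expect_equal(e3$dbh_05[big], as.integer(round(truth3[big])) %/% 10L)
  expect_equal(e3$dbh_05[!big], as.integer(round(truth3[!big])))
})

test_that("a mature-to-sapling replacement always lands in the negative-drop class", {
  city <- generate_city(small_city_config(seed = 63))
  res <- run_pipeline(observe_census(city, "early"), observe_census(city, "late"))
  id15 <- sub("^L", "", res$records$record_id_15)
  is_repl <- city$trees$event[match(id15, city$trees$identity)] == "replacement"
  mature_to_sapling <- is_repl & res$records$dbh_in_05 >= 10 &
    res$records$dbh_in_15 <= 4
  if (any(mature_to_sapling)) {
    expect_true(all(res$records$growth_in[mature_to_sapling] <= -6))
    expect_true(all(res$records$qc_status[mature_to_sapling] == "drop_negative"))
  }
  expect_gt(sum(mature_to_sapling), 0)
})

test_that("clean-world linkage is perfect; replacements are the only failures", {
  city <- generate_city(clean_city_config(seed = 64))
  res <- run_pipeline(observe_census(city, "early"), observe_census(city, "late"))
  ev <- evaluate_linkage(res$pairs, city)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # one engineered replacement at an otherwise unique key: one false match
  city2 <- generate_city(clean_city_config(seed = 65, annual_mortality = 0.044,
                                           replacement_prob = 1))
  res2 <- run_pipeline(observe_census(city2, "early"), observe_census(city2, "late"))
  ev2 <- evaluate_linkage(res2$pairs, city2)
  n_repl <- sum(city2$trees$event == "replacement")
  expect_equal(nrow(ev2$false_matches), n_repl)
  expect_true(all(ev2$false_matches$late_event == "replacement"))
  expect_equal(ev2$precision, 1 - n_repl / ev2$n_reported)
})

test_that("empty pair set yields undefined precision", {
  city <- generate_city(clean_city_config(seed = 66))
  ev <- evaluate_linkage(tibble::tibble(record_id_05 = character(0),
                                        record_id_15 = character(0)), city)
  expect_true(is.na(ev$precision))
})

test_that("recovery report flags species missing from the output", {
  city <- generate_city(clean_city_config(seed = 67))
  res <- run_pipeline(observe_census(city, "early"), observe_census(city, "late"))
  s <- res$summary
  # drop one species from the summary and expect an NA row, not an error
  s$by_species <- s$by_species[s$by_species$species != "Ginkgo", ]
  rc <- evaluate_recovery(s, city)
  expect_true(is.na(rc$by_species$est_rate[rc$by_species$species == "Ginkgo"]))
  expect_true(is.finite(rc$rate_bias))
})
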
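# shared fixtures and brute-force oracles, all built in code

# small well-behaved city used across tests; ... overrides any default
small_city_config <- function(seed = 101, ...) {
  args <- list(seed = seed, n_streets = 40L, addresses_per_street = 50L)
  over <- list(...)
  args[names(over)] <- over
  do.call(city_config, args)
}

# a clean world: no mortality, duplicates or entry errors
clean_city_config <- function(seed = 101, ...) {
  args <- list(seed = seed, n_streets = 40L, addresses_per_street = 50L,
               annual_mortality = 0, duplicate_series_prob = 0,
               circumference_error_prob = 0, digit_error_prob = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(city_config, args)
}

# canonical records tibble built by hand
make_records <- function(zip, address_norm, species_norm, dbh_in,
                         record_id = sprintf("r%03d", seq_along(zip)),
                         census_year = 2005L) {
  tibble::tibble(record_id = record_id, census_year = census_year,
                 zip = zip, address_raw = address_norm,
                 address_norm = address_norm, species_raw = species_norm,
                 species_norm = species_norm, species_unmapped = FALSE,
                 dbh_in = as.integer(dbh_in))
}

# linked-pair tibble straight from DBH vectors
make_pairs <- function(dbh_05, dbh_15,
                       species = rep("Pin Oak", length(dbh_05)),
                       zip = rep("10001", length(dbh_05))) {
  n <- length(dbh_05)
  tibble::tibble(
    zip = zip,
    address_norm = sprintf("%d MAIN STREET", seq_len(n)),
    species_norm = species,
    record_id_05 = sprintf("e%04d", seq_len(n)),
    record_id_15 = sprintf("l%04d", seq_len(n)),
    dbh_in_05 = as.integer(dbh_05),
    dbh_in_15 = as.integer(dbh_15)
  )
}

# brute-force Theil-Sen: explicit double loop over pairs
theil_sen_brute <- function(time, dbh) {
  s <- c()
  for (i in seq_along(time)) for (j in seq_along(time)) {
    if (j > i && time[j] != time[i]) s <- c(s, (dbh[j] - dbh[i]) / (time[j] - time[i]))
  }
  stats::median(s)
}

# brute-force tie-corrected Kendall tau from concordant/discordant counts
kendall_brute <- function(time, dbh) {
  C <- 0; D <- 0; Tx <- 0; Ty <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(time[j] - time[i]); b <- sign(dbh[j] - dbh[i])
    if (a == 0 && b == 0) next
    if (a == 0) Tx <- Tx + 1
    else if (b == 0) Ty <- Ty + 1
    else if (a == b) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + Tx) * (C + D + Ty))
}

# brute-force point-to-segment scan
nearest_brute <- function(pts, segments) {
  apply(pts, 1, function(p) {
    d_best <- Inf; id_best <- NA
    for (k in order(segments$segment_id)) {
      v <- segments$vertices[[k]]
      for (e in seq_len(nrow(v) - 1)) {
        a <- v[e, ]; b <- v[e + 1, ]
        ab <- b - a; len2 <- sum(ab^2)
        t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
        d <- sqrt(sum((a + t * ab - p)^2))
        if (d < d_best) { d_best <- d; id_best <- segments$segment_id[k] }
      }
    }
    c(id_best, d_best)
  })
}
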
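test_that("axial directional mean handles single edges, mixtures and degeneracy", {
  expect_equal(linear_directional_mean(rbind(c(0, 0), c(1, 0))), 90)  # east-west
  expect_equal(linear_directional_mean(rbind(c(0, 0), c(0, 5))), 0)   # north-south
  # equal-length edges at bearings 10 and 170: axial mean 0 (angle doubling)
  a <- 10 * pi / 180; b <- 170 * pi / 180
  poly <- rbind(c(0, 0), c(sin(a), cos(a)), c(sin(a) + sin(b), cos(a) + cos(b)))
  expect_equal(linear_directional_mean(poly), 0, tolerance = 1e-8)
  # perpendicular equal-length edges: no defined axis
  expect_true(is.na(linear_directional_mean(rbind(c(0, 0), c(0, 1), c(1, 1)))))
  # direction of digitization is irrelevant (axial, not directional)
  v <- rbind(c(2, 1), c(7, 4))
  expect_equal(linear_directional_mean(v), linear_directional_mean(v[2:1, ]))
})

test_that("nearest segment matches a brute-force scan and honours ties/radius", {
  seg <- tibble::tibble(segment_id = 1L,
                        vertices = list(rbind(c(0, 0), c(10, 0))))
  out <- nearest_segment(rbind(c(5, 1)), seg)
  expect_equal(out$segment_id, 1L)
  expect_equal(c(out$offset_x, out$offset_y), c(0, 1))
  # equidistant segments resolve to the lower id
  seg2 <- tibble::tibble(segment_id = c(2L, 1L),
                         vertices = list(rbind(c(0, 2), c(10, 2)),
                                         rbind(c(0, -2), c(10, -2))))
  expect_equal(nearest_segment(rbind(c(5, 0)), seg2)$segment_id, 1L)
  # out-of-radius points stay unassigned
  expect_true(is.na(nearest_segment(rbind(c(5, 500)), seg, max_radius = 100)$segment_id))
  # randomized scene vs brute force
  set.seed(9)
  segs <- tibble::tibble(
    segment_id = 1:10,
    vertices = lapply(1:10, function(i) matrix(stats::runif(6, 0, 100), 3, 2))
  )
  pts <- matrix(stats::runif(400, 0, 100), 200, 2)
  got <- nearest_segment(pts, segs, max_radius = Inf)
  want <- nearest_brute(pts, segs)
  expect_equal(got$segment_id, as.integer(want[1, ]))
  expect_equal(got$distance, want[2, ], tolerance = 1e-9)
})

test_that("roadside quadrant follows the axis rule with documented tie-breaks", {
  expect_equal(roadside_quadrant(90, 0, 1), "North")   # E-W road, tree north
  expect_equal(roadside_quadrant(90, 0, -1), "South")
  expect_equal(roadside_quadrant(0, 1, 0), "East")     # N-S road, tree east
  expect_equal(roadside_quadrant(0, -1, 0), "West")
  # exactly 45 degrees counts as E-W; zero northing resolves North
  expect_equal(roadside_quadrant(45, 1, 0), "North")
  expect_equal(roadside_quadrant(135, 1, 0), "North")
  expect_true(is.na(roadside_quadrant(90, 0, 0)))
  expect_true(is.na(roadside_quadrant(NA, 1, 1)))
})

test_that("quadrant assignment is invariant to translation and vertex reversal", {
  set.seed(10)
  for (k in 1:20) {
    v <- matrix(stats::runif(4, 0, 10), 2, 2)
    p <- stats::runif(2, 0, 10)
    shift <- stats::runif(2, -50, 50)
    seg <- tibble::tibble(segment_id = 1L, vertices = list(v))
    seg_t <- tibble::tibble(segment_id = 1L,
                            vertices = list(sweep(v, 2, -shift)))
    seg_r <- tibble::tibble(segment_id = 1L, vertices = list(v[2:1, ]))
    q <- function(s, pt) {
      ns <- nearest_segment(rbind(pt), s, max_radius = Inf)
      roadside_quadrant(linear_directional_mean(s$vertices[[1]]),
                        ns$offset_x, ns$offset_y)
    }
    expect_equal(q(seg, p), q(seg_t, p + shift))
    expect_equal(q(seg, p), q(seg_r, p))
  }
})

test_that("polygon join matches brute-force containment on random rectangles", {
  set.seed(11)
  rects <- lapply(1:20, function(i) {
    x0 <- stats::runif(1, 0, 80); y0 <- stats::runif(1, 0, 80)
    w <- stats::runif(1, 5, 20); h <- stats::runif(1, 5, 20)
    c(x0, y0, x0 + w, y0 + h)
  })
  zones <- tibble::tibble(
    zone_id = sprintf("Z%02d", 1:20),
    rings = lapply(rects, function(r)
      rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]), c(r[1], r[4])))
  )
  pts <- matrix(stats::runif(1000, 0, 100), 500, 2)
  got <- polygon_join(pts, zones)
  want <- apply(pts, 1, function(p) {
    hit <- which(vapply(rects, function(r)
      p[1] >= r[1] & p[1] <= r[3] & p[2] >= r[2] & p[2] <= r[4], logical(1)))
    if (length(hit) == 0) NA_character_ else sprintf("Z%02d", min(hit))
  })
  expect_equal(got, want)
  # boundary point goes to the containing polygon with the lowest id
  zb <- tibble::tibble(zone_id = c("B2", "B1"),
                       rings = list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                                    rbind(c(1, 0), c(2, 0), c(2, 1), c(1, 1))))
  expect_equal(polygon_join(rbind(c(1, 0.5)), zb), "B1")
  expect_error(polygon_join(rbind(c(0, 0)),
                            tibble::tibble(zone_id = "bad",
                                           rings = list(rbind(c(0, 0), c(1, 1))))),
               "invalid polygon")
})

test_that("zone aggregation filters thin and listed zones with reasons", {
  zones <- tibble::tibble(
    zone_id = c("Z1", "Z2", "Z3"),
    rings = list(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)),
                 rbind(c(1000, 0), c(2000, 0), c(2000, 1000), c(1000, 1000)),
                 rbind(c(0, 1000), c(1000, 1000), c(1000, 2000), c(0, 2000)))
  )
  rec <- tibble::tibble(
    zone_id = c(rep("Z1", 120), rep("Z2", 99), rep("Z3", 150)),
    rate_in_per_yr = c(rep(0.2, 60), rep(0.4, 60), rep(0.3, 99), rep(0.25, 150)),
    dbh_in_05 = 10L
  )
  out <- aggregate_by_zone(rec, zones, min_n = 100, exclude = "Z3")
  expect_equal(out$summary$zone_id, "Z1")
  expect_equal(out$summary$mean_rate, 0.3)
  expect_equal(out$summary$trees_per_km2, 120)       # 1 km2 cell
  expect_equal(out$excluded$reason[out$excluded$zone_id == "Z2"], "below_min_n")
  expect_equal(out$excluded$reason[out$excluded$zone_id == "Z3"], "listed")
  # every tree is either summarized or accounted for in the exclusion log
  expect_equal(sum(out$summary$n) + sum(out$excluded$n), nrow(rec))
})

test_that("geojson layers round-trip segments and polygons", {
  city <- generate_city(city_config(seed = 12, n_streets = 6,
                                    addresses_per_street = 10))
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_geojson_layer(city$segments[, c("segment_id", "name", "st_width", "vertices")], f1)
  segs <- read_geojson_layer(f1)
  expect_equal(nrow(segs), nrow(city$segments))
  expect_equal(segs$st_width, city$segments$st_width)
  expect_equal(segs$vertices[[3]], city$segments$vertices[[3]])
  write_geojson_layer(city$tracts[, c("zone_id", "svi", "rings")], f2)
  tr <- read_geojson_layer(f2)
  expect_equal(tr$svi, city$tracts$svi)
  # written polygon rings come back closed
  r0 <- city$tracts$rings[[1]]; r1 <- tr$rings[[1]]
  expect_equal(r1[1, ], r1[nrow(r1), ])
  expect_equal(r1[seq_len(nrow(r0)), ], r0)
  unlink(c(f1, f2))
})
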
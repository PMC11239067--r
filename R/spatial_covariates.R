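#' Axial mean orientation of a street polyline
#'
#' Linear directional mean for axial data: each edge's bearing (degrees
#' clockwise from north) is doubled, the doubled angles are averaged with
#' edge-length weights, and the resultant is halved, giving an orientation in
#' [0, 180). 90 is an east-west axis, 0 a north-south axis. Orientation (mod
#' 180) rather than direction (mod 360) is used because "side of street" is
#' axis-relative. A resultant of zero length (perfectly balanced
#' perpendicular edges) has no defined axis and returns NA.
#'
#' @param vertices Two-column matrix (x = easting, y = northing) of polyline
#'   vertices, at least two, in a planar CRS.
#' @return Orientation in degrees, in [0, 180); NA if undefined.
#' @export
linear_directional_mean <- function(vertices) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2, nrow(v) >= 2)
  dx <- diff(v[, 1]); dy <- diff(v[, 2])
  len <- sqrt(dx^2 + dy^2)
  if (sum(len) == 0) stop("linear_directional_mean: zero-length polyline")
  bearing <- atan2(dx, dy)           # radians clockwise from north
  s <- sum(len * sin(2 * bearing)); c <- sum(len * cos(2 * bearing))
  if (sqrt(s^2 + c^2) < 1e-9 * sum(len)) return(NA_real_)
  ang <- atan2(s, c) / 2 * 180 / pi
  ang %% 180
}

#' Nearest street segment to each tree point
#'
#' Minimizes point-to-polyline distance over all segments; ties go to the
#' lowest segment id. Points farther than `max_radius` from every segment are
#' left unassigned.
#'
#' @param points Two-column matrix of tree coordinates.
#' @param segments Tibble with `segment_id` and a list-column `vertices` of
#'   two-column matrices (see [linear_directional_mean()]); extra attribute
#'   columns (e.g. `st_width`) are carried through.
#' @param max_radius Maximum assignment distance in coordinate units.
#' @return Tibble with one row per point: `segment_id` (NA if unassigned),
#'   `distance`, `offset_x`, `offset_y` (vector from the nearest point on the
#'   polyline to the tree).
#' @export
nearest_segment <- function(points, segments, max_radius = 100) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2, nrow(segments) >= 1)
  ord <- order(segments$segment_id)
  n <- nrow(pts)
  best_d <- rep(Inf, n); best_id <- rep(NA, n)
  best_ox <- rep(NA_real_, n); best_oy <- rep(NA_real_, n)
  for (i in ord) {
    np <- nearest_point_on_polyline(pts, segments$vertices[[i]])
    d <- sqrt((pts[, 1] - np[, 1])^2 + (pts[, 2] - np[, 2])^2)
    better <- d < best_d   # strict: earlier (lower) segment_id wins ties
    best_d[better] <- d[better]
    best_id[better] <- segments$segment_id[i]
    best_ox[better] <- pts[better, 1] - np[better, 1]
    best_oy[better] <- pts[better, 2] - np[better, 2]
  }
  out_of_range <- best_d > max_radius
  best_id[out_of_range] <- NA
  tibble::tibble(
    segment_id = best_id,
    distance = ifelse(out_of_range, NA_real_, best_d),
    offset_x = ifelse(out_of_range, NA_real_, best_ox),
    offset_y = ifelse(out_of_range, NA_real_, best_oy)
  )
}

# closest point on a polyline for each row of pts; returns matrix
nearest_point_on_polyline <- function(pts, vertices) {
  v <- as.matrix(vertices)
  best <- matrix(NA_real_, nrow(pts), 2)
  best_d2 <- rep(Inf, nrow(pts))
  for (e in seq_len(nrow(v) - 1)) {
    a <- v[e, ]; b <- v[e + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2))
    qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]
    d2 <- (pts[, 1] - qx)^2 + (pts[, 2] - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best[upd, 1] <- qx[upd]; best[upd, 2] <- qy[upd]
  }
  best
}

#' Roadside quadrant of a tree relative to its street's orientation
#'
#' If the street orientation is within 45 degrees of the east-west axis
#' (boundary at exactly 45 counts as east-west), the tree is North when its
#' offset has positive northing, else South; otherwise East when the offset
#' has positive easting, else West. A zero offset component resolves to
#' North/East (fixed tie rule). These conventions are declared, deterministic
#' choices: the quadrant is invariant under translation and under reversal of
#' the segment's vertex order.
#'
#' @param orientation Degrees in [0, 180), from [linear_directional_mean()].
#' @param offset_x,offset_y Offset vector components (easting, northing).
#' @return Character vector in {"North","South","East","West"}; NA where the
#'   orientation is undefined or the offset is zero.
#' @export
roadside_quadrant <- function(orientation, offset_x, offset_y) {
  n <- max(length(orientation), length(offset_x))
  orientation <- rep_len(orientation, n)
  offset_x <- rep_len(offset_x, n); offset_y <- rep_len(offset_y, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(orientation) & !is.na(offset_x) & !is.na(offset_y) &
    (offset_x != 0 | offset_y != 0)
  ew <- abs(orientation - 90) <= 45
  out[ok & ew] <- ifelse(offset_y[ok & ew] >= 0, "North", "South")
  out[ok & !ew] <- ifelse(offset_x[ok & !ew] >= 0, "East", "West")
  out
}

#' Assign each tree point to the polygon that contains it
#'
#' Even-odd (ray casting) point-in-polygon over one zone layer. Points on a
#' polygon boundary are assigned to the containing polygon with the lowest
#' zone id; points outside all polygons get NA.
#'
#' @param points Two-column matrix of tree coordinates.
#' @param zones Tibble with `zone_id` and list-column `rings` of two-column
#'   vertex matrices (outer ring, closed or open); attribute columns (e.g.
#'   `svi`, `pop_density`, `land_use`, `builtFAR`) are carried through.
#' @return Integer/character vector of zone ids, one per point (NA outside).
#' @export
polygon_join <- function(points, zones) {
  pts <- as.matrix(points)
  ord <- order(zones$zone_id)
  out <- rep(NA, nrow(pts))
  unassigned <- rep(TRUE, nrow(pts))
  for (i in ord) {
    ring <- as.matrix(zones$rings[[i]])
    if (nrow(ring) < 3) stop("polygon_join: invalid polygon, zone_id ",
                             zones$zone_id[i])
    inside <- point_in_ring(pts[unassigned, , drop = FALSE], ring)
    hit <- which(unassigned)[inside]
    out[hit] <- zones$zone_id[i]
    unassigned[hit] <- FALSE
  }
  out
}

# even-odd rule with on-boundary counted as inside
point_in_ring <- function(pts, ring) {
  if (nrow(pts) == 0) return(logical(0))
  # close the ring
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  x <- pts[, 1]; y <- pts[, 2]
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (e in seq_len(nrow(ring) - 1)) {
    x1 <- ring[e, 1]; y1 <- ring[e, 2]; x2 <- ring[e + 1, 1]; y2 <- ring[e + 1, 2]
    # boundary test: collinear and within bbox
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_edge <- on_edge | (abs(cross) < 1e-12 &
                            x >= pmin(x1, x2) - 1e-12 & x <= pmax(x1, x2) + 1e-12 &
                            y >= pmin(y1, y2) - 1e-12 & y <= pmax(y1, y2) + 1e-12)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < x1 + (y - y1) / (y2 - y1) * (x2 - x1))
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | on_edge
}

# shoelace area of a ring, coordinate units squared
ring_area <- function(ring) {
  ring <- as.matrix(ring)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Aggregate growth records by zone, with size and exclusion filters
#'
#' Zone-level means of growth rate and starting DBH plus tree density
#' (count divided by polygon area, converted to per square kilometre via
#' `unit_km`). Zones with fewer than `min_n` trees, or named in `exclude`,
#' are dropped from the output with the reason recorded — mirroring the
#' removal of thin ZIP codes and storm-damaged ZIP codes before mapping.
#'
#' @param records Tibble with `zone_id`, `rate_in_per_yr`, `dbh_in_05`.
#' @param zones Zone tibble as in [polygon_join()].
#' @param min_n Minimum trees per zone.
#' @param exclude Zone ids excluded outright.
#' @param unit_km Length of one coordinate unit in kilometres (default 1/1000,
#'   i.e. coordinates in metres).
#' @return List with `summary` (tibble: zone_id, n, mean_rate, mean_dbh,
#'   area_km2, trees_per_km2) and `excluded` (tibble: zone_id, n, reason).
#' @export
aggregate_by_zone <- function(records, zones, min_n = 100, exclude = character(0),
                              unit_km = 1e-3) {
  stopifnot(all(c("zone_id", "rate_in_per_yr") %in% names(records)))
  per <- records[!is.na(records$zone_id), , drop = FALSE] |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_rate = mean(.data$rate_in_per_yr),
                     mean_dbh = mean(.data$dbh_in_05),
                     .groups = "drop")
  area <- vapply(zones$rings, ring_area, numeric(1)) * unit_km^2
  per$area_km2 <- area[match(per$zone_id, zones$zone_id)]
  per$trees_per_km2 <- ifelse(per$area_km2 > 0, per$n / per$area_km2, NA_real_)
  listed <- per$zone_id %in% exclude
  thin <- !listed & per$n < min_n
  list(
    summary = per[!listed & !thin, , drop = FALSE],
    excluded = tibble::tibble(
      zone_id = per$zone_id[listed | thin],
      n = per$n[listed | thin],
      reason = ifelse(listed[listed | thin], "listed", "below_min_n")
    )
  )
}

#' Attach all urban-form and social covariates to tree points
#'
#' Convenience wrapper over the geometry primitives: nearest street segment
#' (carrying `st_width`), axial street orientation and roadside quadrant,
#' tax-lot join (carrying `land_use`, `builtFAR`) and tract join (carrying
#' `pop_density`, `svi`).
#'
#' @param trees Tibble with `record_id`, `x`, `y` (planar coordinates).
#' @param segments Street segments as in [nearest_segment()], with `st_width`.
#' @param lots Tax-lot zone layer with `land_use`, `builtFAR`.
#' @param tracts Tract zone layer with `pop_density`, `svi`.
#' @param max_radius Nearest-segment search radius.
#' @return Tibble keyed by `record_id` with `roadside_location`, `st_width`,
#'   `land_use`, `builtFAR`, `pop_density`, `svi`, `lot_id`, `tract_id`.
#' @export
attach_covariates <- function(trees, segments, lots, tracts, max_radius = 100) {
  pts <- cbind(trees$x, trees$y)
  ns <- nearest_segment(pts, segments, max_radius = max_radius)
  ori <- vapply(segments$vertices, linear_directional_mean, numeric(1))
  names(ori) <- as.character(segments$segment_id)
  seg_row <- match(ns$segment_id, segments$segment_id)
  quad <- roadside_quadrant(ori[as.character(ns$segment_id)],
                            ns$offset_x, ns$offset_y)
  lot_id <- polygon_join(pts, lots)
  tract_id <- polygon_join(pts, tracts)
  lot_row <- match(lot_id, lots$zone_id)
  tract_row <- match(tract_id, tracts$zone_id)
  tibble::tibble(
    record_id = trees$record_id,
    roadside_location = quad,
    st_width = if ("st_width" %in% names(segments))
      segments$st_width[seg_row] else NA_real_,
    land_use = if ("land_use" %in% names(lots))
      lots$land_use[lot_row] else NA_character_,
    builtFAR = if ("builtFAR" %in% names(lots))
      lots$builtFAR[lot_row] else NA_real_,
    pop_density = if ("pop_density" %in% names(tracts))
      tracts$pop_density[tract_row] else NA_real_,
    svi = if ("svi" %in% names(tracts)) tracts$svi[tract_row] else NA_real_,
    lot_id = lot_id,
    tract_id = tract_id
  )
}

#' Read and write zone/segment layers as GeoJSON
#'
#' Minimal planar GeoJSON IO for the layers this package exchanges:
#' LineString features become segment rows, Polygon features become zone rows
#' (outer ring only); all `properties` become columns. Coordinates are taken
#' as already projected; no CRS handling.
#'
#' @param path GeoJSON file path.
#' @return For LineStrings: tibble with `vertices` list-column and property
#'   columns; for Polygons: tibble with `rings` list-column.
#' @export
read_geojson_layer <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  feats <- gj$features
  props <- dplyr::bind_rows(lapply(feats, function(f)
    tibble::as_tibble(lapply(f$properties, function(p) p %||% NA))))
  geom_type <- vapply(feats, function(f) f$geometry$type, character(1))
  coords <- lapply(feats, function(f) {
    cc <- f$geometry$coordinates
    if (f$geometry$type == "Polygon") cc <- cc[[1]]
    do.call(rbind, lapply(cc, function(xy) c(xy[[1]], xy[[2]])))
  })
  out <- props
  if (all(geom_type == "LineString")) out$vertices <- coords
  else if (all(geom_type == "Polygon")) out$rings <- coords
  else stop("read_geojson_layer: mixed or unsupported geometry types")
  out
}

#' @rdname read_geojson_layer
#' @param layer Tibble with a `vertices` or `rings` list-column plus
#'   property columns.
#' @export
write_geojson_layer <- function(layer, path) {
  geom_col <- if ("vertices" %in% names(layer)) "vertices" else "rings"
  gtype <- if (geom_col == "vertices") "LineString" else "Polygon"
  prop_cols <- setdiff(names(layer), geom_col)
  feats <- lapply(seq_len(nrow(layer)), function(i) {
    m <- as.matrix(layer[[geom_col]][[i]])
    cc <- lapply(seq_len(nrow(m)), function(j) c(m[j, 1], m[j, 2]))
    if (gtype == "Polygon") {
      if (any(m[1, ] != m[nrow(m), ])) cc <- c(cc, cc[1])
      cc <- list(cc)
    }
    list(type = "Feature",
         properties = as.list(layer[i, prop_cols, drop = FALSE]),
         geometry = list(type = gtype, coordinates = cc))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
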
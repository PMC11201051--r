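## Habitat classification, spherical area accounting, binary range
## algebra, and centroid-migration geometry.
##
## Class codes: 0 unsuitable [0, 0.1), 1 low [0.1, 0.3), 2 medium
## [0.3, 0.5), 3 high [0.5, 1].  The binary presence matrix uses the
## strict rule p > 0.5, so a cell at exactly 0.5 is "high" in the
## four-class map but absent from the (0,1) matrix; both conventions are
## kept deliberately (see the methods vignette).

#' Classify a suitability map into four habitat classes
#'
#' @param suitability An [env_grid()] with values in \[0, 1\] (nodata
#'   allowed).
#' @param thresholds Class cut points `(t1, t2, t3)`, default
#'   `c(0.1, 0.3, 0.5)`. Bands are half-open at the top except the highest,
#'   which includes 1.
#' @return An object of class `suitability_classification`: `grid` (an
#'   `env_grid` of codes 0-3), `thresholds`, `counts` (cells per class).
#' @export
classify_suitability <- function(suitability, thresholds = c(0.1, 0.3, 0.5)) {
  stopifnot(inherits(suitability, "env_grid"), length(thresholds) == 3,
            all(diff(thresholds) > 0))
  v <- suitability$values
  bad <- !is.na(v) & (v < 0 | v > 1)
  if (any(bad))
    stop("classify_suitability: ", sum(bad), " value(s) outside [0, 1]")
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- findInterval(v[ok], thresholds)
  counts <- tabulate(cls[ok] + 1, nbins = 4)
  names(counts) <- c("unsuitable", "low", "medium", "high")
  h <- suitability$header
  structure(list(grid = env_grid(cls, h$xllcorner, h$yllcorner, h$cellsize,
                                 h$nodata_value, name = "suitability_class"),
                 thresholds = thresholds, counts = counts),
            class = "suitability_classification")
}

#' @export
print.suitability_classification <- function(x, ...) {
  cat("<suitability_classification> cells per class:\n")
  print(x$counts)
  invisible(x)
}

#' Construct an area summary from per-class areas
#'
#' Areas are in units of 10^4 km^2, the convention of habitat-area tables;
#' the total suitable area is low + medium + high. When a `baseline`
#' summary is given, signed deltas (this minus baseline) are attached.
#'
#' @param low,medium,high,unsuitable Per-class areas, x 10^4 km^2.
#' @param baseline Optional `area_summary` to difference against.
#' @param period Optional label for printing.
#' @return An object of class `area_summary`.
#' @export
area_summary <- function(low, medium, high, unsuitable = 0,
                         baseline = NULL, period = NULL) {
  stopifnot(low >= 0, medium >= 0, high >= 0, unsuitable >= 0)
  areas <- c(unsuitable = unsuitable, low = low, medium = medium, high = high)
  out <- list(areas = areas, total_suitable = low + medium + high,
              period = period, delta = NULL, delta_total = NULL)
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "area_summary"))
    out$delta <- areas - baseline$areas
    out$delta_total <- out$total_suitable - baseline$total_suitable
  }
  structure(out, class = "area_summary")
}

#' @export
print.area_summary <- function(x, ...) {
  fmt <- function(a, d) {
    if (is.null(d)) sprintf("%.2f", a)
    else sprintf("%.2f (%+.2f)", a, d)
  }
  cat(sprintf("<area_summary%s> (x 10^4 km^2)\n",
              if (is.null(x$period)) "" else paste0(" ", x$period)))
  for (k in names(x$areas))
    cat(sprintf("  %-11s %s\n", k, fmt(x$areas[[k]],
                                       if (is.null(x$delta)) NULL else x$delta[[k]])))
  cat(sprintf("  %-11s %s\n", "total", fmt(x$total_suitable, x$delta_total)))
  invisible(x)
}

#' @export
as.data.frame.area_summary <- function(x, ...) {
  d <- data.frame(period = if (is.null(x$period)) NA_character_ else x$period,
                  unsuitable = x$areas[["unsuitable"]],
                  low = x$areas[["low"]], medium = x$areas[["medium"]],
                  high = x$areas[["high"]], total = x$total_suitable)
  if (!is.null(x$delta)) {
    d$delta_unsuitable <- x$delta[["unsuitable"]]
    d$delta_low <- x$delta[["low"]]; d$delta_medium <- x$delta[["medium"]]
    d$delta_high <- x$delta[["high"]]; d$delta_total <- x$delta_total
  }
  d
}

#' Per-class habitat areas of a classification
#'
#' Sums the spherical cell areas ([cell_area_km2()]) of each class and
#' reports them in 10^4 km^2 (full precision internally; round only in
#' output files).
#'
#' @param classification A [classify_suitability()] result.
#' @param baseline Optional `area_summary` for signed deltas.
#' @param period Optional label.
#' @return An [area_summary()].
#' @export
class_areas <- function(classification, baseline = NULL, period = NULL) {
  g <- classification$grid
  h <- g$header
  row_area <- cell_area_km2(h, seq_len(h$nrows))
  acc <- numeric(4)
  for (k in 0:3) {
    cnt <- rowSums(!is.na(g$values) & g$values == k)
    acc[k + 1] <- sum(cnt * row_area)
  }
  acc <- acc / 1e4
  area_summary(low = acc[2], medium = acc[3], high = acc[4],
               unsuitable = acc[1], baseline = baseline, period = period)
}

#' Binary presence-absence range map
#'
#' Cells with suitability strictly greater than `threshold` are 1, the
#' rest 0; nodata propagates. With the default threshold the presence area
#' equals the high-suitability class area of [classify_suitability()]
#' except for cells at exactly 0.5.
#'
#' @param suitability An [env_grid()] of suitability in \[0, 1\].
#' @param threshold Presence threshold (default 0.5, strict).
#' @return An `env_grid` of 0/1 codes.
#' @export
binary_map <- function(suitability, threshold = 0.5) {
  stopifnot(inherits(suitability, "env_grid"))
  v <- suitability$values
  b <- matrix(NA_real_, nrow(v), ncol(v))
  b[!is.na(v)] <- as.numeric(v[!is.na(v)] > threshold)
  h <- suitability$header
  env_grid(b, h$xllcorner, h$yllcorner, h$cellsize, h$nodata_value,
           name = "range")
}

## area (x 10^4 km^2) of cells equal to `code` in a coded grid
coded_area <- function(grid, code) {
  h <- grid$header
  row_area <- cell_area_km2(h, seq_len(h$nrows))
  cnt <- rowSums(!is.na(grid$values) & grid$values == code)
  sum(cnt * row_area) / 1e4
}

#' Summary of range change between two periods
#'
#' @param expansion,retention,contraction Areas x 10^4 km^2.
#' @param period Optional label.
#' @return Object of class `change_summary` with `net = expansion -
#'   contraction`.
#' @export
change_summary <- function(expansion, retention, contraction, period = NULL) {
  structure(list(expansion = expansion, retention = retention,
                 contraction = contraction,
                 net = expansion - contraction, period = period),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("<change_summary%s> expansion %.2f, retention %.2f, contraction %.2f, net %+.2f (x 10^4 km^2)\n",
              if (is.null(x$period)) "" else paste0(" ", x$period),
              x$expansion, x$retention, x$contraction, x$net))
  invisible(x)
}

#' Expansion/retention/contraction map between two binary ranges
#'
#' Per-cell category from (current, future): (0,0) absent, (0,1)
#' expansion, (1,1) retention, (1,0) contraction; codes 0-3 in that order.
#' Areas come from [cell_area_km2()]; the identities
#' `retention + contraction = current area` and
#' `retention + expansion = future area` hold exactly.
#'
#' @param current,future Binary range maps ([binary_map()]) with identical
#'   headers.
#' @param period Optional label for the transition.
#' @return An object of class `change_map`: `grid` (coded `env_grid`) and
#'   `summary` (a [change_summary()]).
#' @export
change_map <- function(current, future, period = NULL) {
  stopifnot(inherits(current, "env_grid"), inherits(future, "env_grid"))
  f <- header_diff_field(current$header, future$header)
  if (!is.null(f))
    stop("change_map: headers differ in field '", f, "'")
  cv <- current$values; fv <- future$values
  code <- matrix(NA_real_, nrow(cv), ncol(cv))
  ok <- !is.na(cv) & !is.na(fv)
  code[ok] <- ifelse(cv[ok] == 0 & fv[ok] == 0, 0,
              ifelse(cv[ok] == 0 & fv[ok] == 1, 1,
              ifelse(cv[ok] == 1 & fv[ok] == 1, 2, 3)))
  h <- current$header
  grid <- env_grid(code, h$xllcorner, h$yllcorner, h$cellsize,
                   h$nodata_value, name = "range_change")
  structure(list(grid = grid,
                 summary = change_summary(coded_area(grid, 1),
                                          coded_area(grid, 2),
                                          coded_area(grid, 3),
                                          period = period)),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Centroid of a binary range map
#'
#' The geometric centre of the presence cells: the mean of the cell-centre
#' coordinates weighted by spherical cell area (set `area_weighted =
#' FALSE` for the unweighted mean).
#'
#' @param range_map A [binary_map()] result (0/1 `env_grid`).
#' @param area_weighted Weight cell centres by [cell_area_km2()] (default
#'   `TRUE`).
#' @return Named numeric vector `c(longitude, latitude)` of class
#'   `range_centroid`.
#' @export
range_centroid <- function(range_map, area_weighted = TRUE) {
  stopifnot(inherits(range_map, "env_grid"))
  cells <- which(!is.na(range_map$values) & range_map$values == 1,
                 arr.ind = TRUE)
  if (nrow(cells) == 0) stop("range_centroid: empty range (no presence cells)")
  cc <- cell_centres(range_map$header, cells)
  w <- if (area_weighted) cell_area_km2(range_map$header, cells[, 1])
       else rep(1, nrow(cells))
  structure(c(longitude = sum(cc[, "lon"] * w) / sum(w),
              latitude = sum(cc[, "lat"] * w) / sum(w)),
            class = "range_centroid")
}

#' @export
print.range_centroid <- function(x, ...) {
  cat(sprintf("<centroid> %.3f E, %.3f N\n", x[["longitude"]], x[["latitude"]]))
  invisible(x)
}

#' Migration vector between two range centroids
#'
#' Great-circle distance ([haversine_km]) and initial bearing from
#' centroid `a` to centroid `b`.
#'
#' @param a,b Centroids: `range_centroid` objects or numeric
#'   `c(longitude, latitude)`.
#' @param period Optional label, e.g. `"current -> 2050s"`.
#' @return Object of class `migration_vector`: `from`, `to`,
#'   `distance_km`, `bearing_deg`.
#' @export
migration_vector <- function(a, b, period = NULL) {
  a <- unclass(a); b <- unclass(b)
  lon1 <- a[[1]]; lat1 <- a[[2]]; lon2 <- b[[1]]; lat2 <- b[[2]]
  stopifnot(abs(lat1) <= 90, abs(lat2) <= 90)
  structure(list(from = c(longitude = lon1, latitude = lat1),
                 to = c(longitude = lon2, latitude = lat2),
                 distance_km = haversine_km(lon1, lat1, lon2, lat2),
                 bearing_deg = initial_bearing(lon1, lat1, lon2, lat2),
                 period = period),
            class = "migration_vector")
}

#' @export
print.migration_vector <- function(x, ...) {
  cat(sprintf("<migration%s> (%.3f, %.3f) -> (%.3f, %.3f): %.1f km, bearing %.1f deg\n",
              if (is.null(x$period)) "" else paste0(" ", x$period),
              x$from[["longitude"]], x$from[["latitude"]],
              x$to[["longitude"]], x$to[["latitude"]],
              x$distance_km, x$bearing_deg))
  invisible(x)
}
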
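#' Read species occurrence records from delimited text
#'
#' Expects columns `longitude` and `latitude` (case-insensitive; `lon`,
#' `lng`, `x` and `lat`, `y` also recognised) in decimal degrees. Rows with
#' missing or unparseable coordinates, or coordinates outside the valid
#' lon/lat range, are dropped and counted; exact duplicate (lon, lat) pairs
#' are collapsed to the first record.
#'
#' @param path CSV file path.
#' @param species Fallback species label when the file lacks a column.
#' @return A data frame of class `occurrence_set` with columns `species`,
#'   `longitude`, `latitude`, `source`, and attributes `n_dropped`
#'   (unparseable rows) and `n_duplicates` (collapsed duplicates).
#' @export
read_occurrences <- function(path, species = "species") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(raw))
  lon_col <- which(nm %in% c("longitude", "lon", "lng", "x"))[1]
  lat_col <- which(nm %in% c("latitude", "lat", "y"))[1]
  if (is.na(lon_col) || is.na(lat_col))
    stop("read_occurrences: no longitude/latitude columns found in ", path)
  lon <- suppressWarnings(as.numeric(raw[[lon_col]]))
  lat <- suppressWarnings(as.numeric(raw[[lat_col]]))
  sp <- if ("species" %in% nm) as.character(raw[[which(nm == "species")[1]]])
        else rep(species, nrow(raw))
  src <- if ("source" %in% nm) as.character(raw[[which(nm == "source")[1]]])
         else rep("unknown", nrow(raw))
  ok <- !is.na(lon) & !is.na(lat) & lon >= -180 & lon <= 180 &
    lat >= -90 & lat <= 90
  n_dropped <- sum(!ok)
  out <- data.frame(species = sp[ok], longitude = lon[ok], latitude = lat[ok],
                    source = src[ok], stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("longitude", "latitude")])
  n_dup <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  if (nrow(out) == 0)
    stop("read_occurrences: no parseable occurrence rows in ", path)
  rownames(out) <- NULL
  structure(out, n_dropped = n_dropped, n_duplicates = n_dup,
            class = c("occurrence_set", "data.frame"))
}

#' Construct an occurrence set from coordinates
#'
#' @param longitude,latitude Decimal-degree coordinate vectors.
#' @param species,source Labels, recycled to length.
#' @return An `occurrence_set` data frame.
#' @export
occurrence_set <- function(longitude, latitude, species = "species",
                           source = "unknown") {
  stopifnot(length(longitude) == length(latitude),
            all(longitude >= -180 & longitude <= 180),
            all(latitude >= -90 & latitude <= 90))
  structure(data.frame(species = rep_len(species, length(longitude)),
                       longitude = longitude, latitude = latitude,
                       source = rep_len(source, length(longitude)),
                       stringsAsFactors = FALSE),
            class = c("occurrence_set", "data.frame"))
}

#' Spatially thin occurrence records
#'
#' Greedy first-come thinning in input order: a record is retained iff its
#' great-circle distance ([haversine_km]) to every already-retained record
#' is at least `radius_km`; points strictly within the radius of a kept
#' point are discarded. The operation is idempotent and order-stable (the
#' output preserves input order and is a subset of the input).
#'
#' @param occ An `occurrence_set` (or data frame with `longitude`,
#'   `latitude`).
#' @param radius_km Minimum pairwise distance to enforce, km (default 5,
#'   the conventional thinning radius for herbarium-density data).
#' @return The thinned `occurrence_set`, with attribute `n_removed`.
#' @export
thin_occurrences <- function(occ, radius_km = 5) {
  stopifnot(radius_km > 0)
  n <- nrow(occ)
  if (is.null(n) || n == 0) return(occ)
  keep <- logical(n)
  kept_lon <- numeric(0); kept_lat <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kept_lon) == 0L ||
        all(haversine_km(occ$longitude[i], occ$latitude[i],
                         kept_lon, kept_lat) >= radius_km)) {
      keep[i] <- TRUE
      kept_lon <- c(kept_lon, occ$longitude[i])
      kept_lat <- c(kept_lat, occ$latitude[i])
    }
  }
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n - sum(keep)
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Write an occurrence set to CSV
#'
#' @param occ An `occurrence_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}
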
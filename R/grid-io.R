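## ESRI ASCII grid I/O and co-registered stacks.
##
## Internally an env_grid stores nodata as NA; the nodata sentinel lives in
## the header and is only materialised on write.  Row 1 of the value matrix
## is the NORTHERNMOST row, matching file order.  Cell (r, c) has centre
##   lon = xllcorner + (c - 0.5) * cellsize
##   lat = yllcorner + (nrows - r + 0.5) * cellsize

HEADER_TOL <- 1e-9

new_grid_header <- function(ncols, nrows, xllcorner, yllcorner, cellsize,
                            nodata_value = -9999) {
  stopifnot(ncols >= 1, nrows >= 1, cellsize > 0)
  structure(list(ncols = as.integer(ncols), nrows = as.integer(nrows),
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata_value = nodata_value),
            class = "grid_header")
}

headers_equal <- function(a, b, tol = HEADER_TOL) {
  is.null(header_diff_field(a, b, tol))
}

## first differing field name, or NULL if equal within tol
header_diff_field <- function(a, b, tol = HEADER_TOL) {
  if (a$ncols != b$ncols) return("ncols")
  if (a$nrows != b$nrows) return("nrows")
  for (f in c("xllcorner", "yllcorner", "cellsize")) {
    if (abs(a[[f]] - b[[f]]) > tol) return(f)
  }
  NULL
}

#' Construct an environmental raster layer
#'
#' A georeferenced value matrix with ESRI ASCII header metadata. Missing
#' cells are `NA` in the matrix; the `nodata` sentinel is used only when
#' writing to disk. Row 1 is the northernmost row (file order).
#'
#' @param values Numeric matrix (`nrows` x `ncols`); `NA` marks nodata.
#' @param xllcorner,yllcorner Longitude/latitude of the lower-left corner
#'   of the lower-left cell, decimal degrees.
#' @param cellsize Cell edge in degrees (square cells).
#' @param nodata Sentinel written for `NA` cells (default -9999).
#' @param name Variable label, e.g. `"Bio1"` or `"Srad4"`.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(values, xllcorner, yllcorner, cellsize,
                     nodata = -9999, name = "layer") {
  values <- as.matrix(values)
  if (!all(is.finite(values) | is.na(values)))
    stop("env_grid: non-finite values present (use NA for nodata)")
  header <- new_grid_header(ncol(values), nrow(values), xllcorner, yllcorner,
                            cellsize, nodata)
  structure(list(header = header, name = name, values = values),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  h <- x$header
  cat(sprintf("<env_grid '%s'> %d x %d cells, %.6g deg, ll = (%.6g, %.6g), %d nodata\n",
              x$name, h$nrows, h$ncols, h$cellsize, h$xllcorner, h$yllcorner,
              sum(is.na(x$values))))
  invisible(x)
}

#' Read an ESRI ASCII grid file
#'
#' Accepts both the `xllcorner`/`yllcorner` and the `xllcenter`/`yllcenter`
#' header dialects (centre coordinates are converted to corner form via
#' `corner = center - cellsize/2`). Row 1 of the returned matrix is the
#' northernmost row.
#'
#' @param path Path to a `.asc` file.
#' @param name Variable label for the layer; defaults to the file stem.
#' @return An [env_grid()].
#' @export
read_asc <- function(path, name = NULL) {
  if (!file.exists(path)) stop("read_asc: no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("read_asc: malformed file (fewer than 7 lines)")
  keys <- c("ncols", "nrows", "xll", "yll", "cellsize", "nodata_value")
  vals <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("read_asc: malformed header line ", i, ": '", lines[i], "'")
    key <- tolower(parts[1])
    num <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(num))
      stop("read_asc: non-numeric value for header key '", key, "'")
    canon <- switch(key,
      ncols = "ncols", nrows = "nrows",
      xllcorner = "xll", xllcenter = "xllc",
      yllcorner = "yll", yllcenter = "yllc",
      cellsize = "cellsize", nodata_value = "nodata_value",
      stop("read_asc: unexpected header key '", key, "'"))
    vals[[canon]] <- num
  }
  if (is.null(vals$cellsize)) stop("read_asc: missing header key 'cellsize'")
  if (!is.null(vals$xllc)) vals$xll <- vals$xllc - vals$cellsize / 2
  if (!is.null(vals$yllc)) vals$yll <- vals$yllc - vals$cellsize / 2
  for (k in keys) if (is.null(vals[[k]]))
    stop("read_asc: missing header key '",
         c(ncols = "ncols", nrows = "nrows", xll = "xllcorner",
           yll = "yllcorner", cellsize = "cellsize",
           nodata_value = "NODATA_value")[k], "'")
  nc <- as.integer(vals$ncols); nr <- as.integer(vals$nrows)
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("read_asc: body has %d values but header implies %d x %d = %d",
                 length(body), nr, nc, nr * nc))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[abs(m - vals$nodata_value) < 1e-12 * max(1, abs(vals$nodata_value))] <- NA
  env_grid(m, vals$xll, vals$yll, vals$cellsize, vals$nodata_value, name)
}

#' Write an environmental layer as an ESRI ASCII grid
#'
#' Always writes the `xllcorner` dialect; `NA` cells are written as the
#' header's nodata sentinel. Values are serialised with enough significant
#' digits that probabilities in \[0, 1\] round-trip within 1e-9.
#'
#' @param grid An [env_grid()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_asc <- function(grid, path) {
  stopifnot(inherits(grid, "env_grid"))
  h <- grid$header
  fmt_num <- function(x) formatC(x, digits = 12, format = "g")
  hdr <- c(paste("ncols", h$ncols),
           paste("nrows", h$nrows),
           paste("xllcorner", fmt_num(h$xllcorner)),
           paste("yllcorner", fmt_num(h$yllcorner)),
           paste("cellsize", fmt_num(h$cellsize)),
           paste("NODATA_value", fmt_num(h$nodata_value)))
  m <- grid$values
  m[is.na(m)] <- h$nodata_value
  rows <- apply(m, 1, function(r) paste(fmt_num(r), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_asc: cannot write to ", path)
  invisible(path)
}

#' Align environmental layers into a co-registered stack
#'
#' All layers must share the same header (within 1e-9 degrees). The stack's
#' mask is the set of cells that are non-nodata in every layer; at least one
#' valid cell is required.
#'
#' @param grids A list of [env_grid()] objects (or several grids as `...`).
#' @return An object of class `grid_stack` with elements `layers` (named
#'   list, insertion order preserved), `header`, and `mask` (logical matrix,
#'   `TRUE` = valid in all layers).
#' @export
grid_stack <- function(grids) {
  if (inherits(grids, "env_grid")) grids <- list(grids)
  stopifnot(length(grids) >= 1)
  nms <- vapply(grids, function(g) g$name, "")
  if (anyDuplicated(nms))
    stop("grid_stack: duplicate layer names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(grids) <- nms
  h0 <- grids[[1]]$header
  for (i in seq_along(grids)) {
    f <- header_diff_field(h0, grids[[i]]$header)
    if (!is.null(f))
      stop(sprintf("grid_stack: layer '%s' and '%s' differ in header field '%s'",
                   nms[1], nms[i], f))
  }
  mask <- Reduce(`&`, lapply(grids, function(g) !is.na(g$values)))
  if (!any(mask)) stop("grid_stack: no cell is valid in every layer")
  structure(list(layers = grids, header = h0, mask = mask),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %d layers, %d x %d cells, %d valid\n",
              length(x$layers), x$header$nrows, x$header$ncols, sum(x$mask)))
  cat(" layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

## matrix (n_valid_cells x n_layers) of values at mask cells, plus the cell
## indices (row, col) used
stack_values <- function(stack, cells = NULL) {
  if (is.null(cells)) cells <- which(stack$mask, arr.ind = TRUE)
  v <- vapply(stack$layers, function(g) g$values[cells], numeric(nrow(cells)))
  if (is.null(dim(v))) v <- matrix(v, nrow = nrow(cells))
  colnames(v) <- names(stack$layers)
  list(values = v, cells = cells)
}

## centre coordinates of cells given (row, col) index matrix
cell_centres <- function(header, cells) {
  lon <- header$xllcorner + (cells[, 2] - 0.5) * header$cellsize
  lat <- header$yllcorner + (header$nrows - cells[, 1] + 0.5) * header$cellsize
  cbind(lon = lon, lat = lat)
}

## (row, col) of the cell containing each lon/lat point; half-open rule,
## lower/left edge inclusive.  Returns NA rows for points outside the grid.
locate_cells <- function(header, lon, lat) {
  j <- floor((lon - header$xllcorner) / header$cellsize)
  i_from_bottom <- floor((lat - header$yllcorner) / header$cellsize)
  r <- header$nrows - i_from_bottom
  c <- j + 1
  outside <- lon < header$xllcorner | lat < header$yllcorner |
    c < 1 | c > header$ncols | r < 1 | r > header$nrows
  r[outside] <- NA_integer_; c[outside] <- NA_integer_
  cbind(row = as.integer(r), col = as.integer(c))
}

#' Extract environmental values at occurrence points
#'
#' Maps each point to the raster cell containing it (half-open cell
#' membership: the lower/left cell edge is inclusive, the upper/right edge
#' belongs to the next cell) and returns the value of every layer there.
#' Points outside the grid or on masked (nodata) cells are returned in a
#' rejection table rather than silently dropped.
#'
#' @param stack A [grid_stack()].
#' @param points A data frame with `longitude` and `latitude` columns
#'   (decimal degrees), e.g. from [read_occurrences()].
#' @return A list with `values` (data frame: point index, longitude,
#'   latitude, one column per layer) and `rejected` (data frame: point
#'   index, longitude, latitude, reason).
#' @export
extract_values <- function(stack, points) {
  stopifnot(inherits(stack, "grid_stack"))
  lon <- points$longitude; lat <- points$latitude
  n <- length(lon)
  rc <- locate_cells(stack$header, lon, lat)
  reason <- rep(NA_character_, n)
  reason[is.na(rc[, 1])] <- "outside"
  inside <- which(!is.na(rc[, 1]))
  if (length(inside)) {
    lin <- rc[inside, 1] + (rc[inside, 2] - 1) * stack$header$nrows
    masked <- !stack$mask[lin]
    reason[inside[masked]] <- "masked"
  }
  keep <- which(is.na(reason))
  vals <- matrix(NA_real_, length(keep), length(stack$layers),
                 dimnames = list(NULL, names(stack$layers)))
  if (length(keep)) {
    lin <- rc[keep, 1] + (rc[keep, 2] - 1) * stack$header$nrows
    for (k in seq_along(stack$layers))
      vals[, k] <- stack$layers[[k]]$values[lin]
  }
  list(
    values = data.frame(point = keep, longitude = lon[keep],
                        latitude = lat[keep], vals,
                        check.names = FALSE, row.names = NULL),
    rejected = data.frame(point = which(!is.na(reason)),
                          longitude = lon[!is.na(reason)],
                          latitude = lat[!is.na(reason)],
                          reason = reason[!is.na(reason)],
                          row.names = NULL)
  )
}
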
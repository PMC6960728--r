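#' In-memory georeferenced grid stack
#'
#' A minimal single-resolution raster container: one or more named bands
#' stored as matrices (row 1 = northern edge), a geotransform given by the
#' west edge `xmin`, north edge `ymax` and square `pixel` size, a projected
#' CRS label, and a `nodata` sentinel. All bands must share the same shape.
#' On disk a stack is a directory of ESRI ASCII grids (one per band) plus a
#' `stack.json` sidecar carrying band order, CRS and nodata.
#'
#' @param bands named list of numeric matrices with identical dimensions;
#'   `NA` entries mark nodata.
#' @param xmin x coordinate of the west edge (m).
#' @param ymax y coordinate of the north edge (m).
#' @param pixel pixel size (m); 30 for Landsat-like stacks.
#' @param crs projected CRS label (informational).
#' @param nodata nodata sentinel used on disk (default -9999).
#' @return an object of class `"grid_stack"`.
#' @export
grid_stack <- function(bands, xmin = 0, ymax = NULL, pixel = 30,
                       crs = "UTM/WGS84 (projected m)", nodata = -9999) {
  stopifnot(is.list(bands), length(bands) >= 1L, !is.null(names(bands)),
            all(nzchar(names(bands))))
  dims <- lapply(bands, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("all bands must share the same dimensions")
  nr <- nrow(bands[[1L]]); nc <- ncol(bands[[1L]])
  if (is.null(ymax)) ymax <- nr * pixel
  structure(
    list(bands = lapply(bands, function(b) {
           storage.mode(b) <- "double"; b
         }),
         nrow = nr, ncol = nc, xmin = xmin, ymax = ymax,
         pixel = pixel, crs = crs, nodata = nodata),
    class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("grid_stack: %d band(s) [%s], %d x %d pixels @ %g m\n",
              length(x$bands), paste(names(x$bands), collapse = ", "),
              x$nrow, x$ncol, x$pixel))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]  (%s)\n",
              x$xmin, x$xmin + x$ncol * x$pixel,
              x$ymax - x$nrow * x$pixel, x$ymax, x$crs))
  invisible(x)
}

#' Pixel-centre coordinates of a grid
#'
#' @param stack a [grid_stack()].
#' @return list with vectors `x` (per column) and `y` (per row, row 1 = top).
#' @export
grid_centres <- function(stack) {
  list(x = stack$xmin + (seq_len(stack$ncol) - 0.5) * stack$pixel,
       y = stack$ymax - (seq_len(stack$nrow) - 0.5) * stack$pixel)
}

same_geometry <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$pixel - b$pixel) < tol
}

#' Sample a grid band at point locations (nearest pixel)
#'
#' Each point receives the value of the pixel whose centre is nearest
#' (i.e. the pixel containing the point). Points falling on nodata are
#' returned as `NA` and flagged; points outside the extent are an error.
#'
#' @param stack a [grid_stack()].
#' @param band band name to sample.
#' @param x,y point coordinates (m) in the stack's CRS.
#' @return numeric vector with attribute `n_nodata`, the count of points
#'   that fell on nodata pixels.
#' @export
extract_at_points <- function(stack, band, x, y) {
  stopifnot(inherits(stack, "grid_stack"), band %in% names(stack$bands),
            length(x) == length(y))
  xmax <- stack$xmin + stack$ncol * stack$pixel
  ymin <- stack$ymax - stack$nrow * stack$pixel
  out_of <- x < stack$xmin | x > xmax | y < ymin | y > stack$ymax
  if (any(out_of))
    stop(sprintf("%d point(s) outside the raster extent", sum(out_of)))
  col <- pmin(pmax(ceiling((x - stack$xmin) / stack$pixel), 1L), stack$ncol)
  row <- pmin(pmax(ceiling((stack$ymax - y) / stack$pixel), 1L), stack$nrow)
  v <- stack$bands[[band]][cbind(row, col)]
  n_na <- sum(is.na(v))
  if (n_na > 0L)
    message(sprintf("extract_at_points: %d plot(s) on nodata pixels flagged",
                    n_na))
  structure(v, n_nodata = n_na)
}

# ---- ESRI ASCII grid I/O ---------------------------------------------------

write_asc <- function(mat, path, xmin, ymax, pixel, nodata = -9999) {
  nr <- nrow(mat); nc <- ncol(mat)
  m <- mat
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", xmin),
           sprintf("yllcorner %.10g", ymax - nr * pixel),
           sprintf("cellsize %.10g", pixel),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  body <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA
  list(mat = m,
       xmin = val[["xllcorner"]],
       ymax = val[["yllcorner"]] + nr * val[["cellsize"]],
       pixel = val[["cellsize"]],
       nodata = val[["nodata_value"]])
}

#' Read / write a grid stack as ASCII grids + JSON sidecar
#'
#' `write_grid_stack()` writes one `<band>.asc` ESRI ASCII grid per band and
#' a `stack.json` sidecar fixing band order, CRS and nodata.
#' `read_grid_stack()` reverses it.
#'
#' @param stack a [grid_stack()].
#' @param dir directory to write into / read from (created if missing).
#' @return the directory path (write) or a [grid_stack()] (read).
#' @export
write_grid_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "grid_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in names(stack$bands)) {
    write_asc(stack$bands[[b]], file.path(dir, paste0(b, ".asc")),
              stack$xmin, stack$ymax, stack$pixel, stack$nodata)
  }
  sidecar <- list(bands = names(stack$bands), crs = stack$crs,
                  nodata = stack$nodata, pixel = stack$pixel)
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA),
             file.path(dir, "stack.json"))
  invisible(dir)
}

#' @rdname write_grid_stack
#' @export
read_grid_stack <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "stack.json"))
  bands <- list()
  geo <- NULL
  for (b in meta$bands) {
    a <- read_asc(file.path(dir, paste0(b, ".asc")))
    bands[[b]] <- a$mat
    geo <- a
  }
  grid_stack(bands, xmin = geo$xmin, ymax = geo$ymax, pixel = geo$pixel,
             crs = meta$crs, nodata = meta$nodata)
}
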
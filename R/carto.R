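#' Predict a carbon map for one stratum
#'
#' Evaluates the regression-kriging predictor at the centre of every pixel
#' belonging to the stratum (per the class raster and the class-to-stratum
#' mapping), using covariate grids computed from the reflectance stack.
#' Pixels outside the stratum are nodata. Negative predictions are clamped
#' to zero at this mapping stage only (never inside cross-validation) and
#' the clamp count recorded.
#'
#' @param model an [rk()] fit (its `stratum` field selects the classes).
#' @param stack a [grid_stack()] of reflectance bands.
#' @param classes integer matrix of steppe-class codes co-registered with
#'   `stack` (see [steppe_classes()]).
#' @param stratum stratum to map (`"typical"` or `"meadow"`); defaults to
#'   `model$stratum`.
#' @param params a [vi_params()].
#' @return an object of class `"carbon_map"`: list with `values` (matrix,
#'   gC/m2, `NA` = nodata), geotransform fields, `n_clamped` and
#'   `provenance`.
#' @export
predict_stratum_map <- function(model, stack, classes,
                                stratum = model$stratum,
                                params = vi_params()) {
  stopifnot(inherits(model, "rk"), inherits(stack, "grid_stack"))
  if (!all(dim(classes) == c(stack$nrow, stack$ncol)))
    stop("class raster is not co-registered with the reflectance stack")
  if (is.null(stratum)) stop("no stratum given and model carries none")
  cls <- steppe_classes()
  codes <- cls[names(class_to_stratum())[class_to_stratum() == stratum]]
  mask <- matrix(classes %in% codes & !is.na(classes),
                 stack$nrow, stack$ncol)

  covs <- lapply(stats::setNames(nm = model$covariates), function(cv)
    compute_index(stack, cv, params))
  idx <- which(mask)
  newdata <- as.data.frame(lapply(covs, function(g) g[idx]))

  ctr <- grid_centres(stack)
  rc <- arrayInd(idx, dim(mask))
  targets <- cbind(ctr$x[rc[, 2L]], ctr$y[rc[, 1L]])

  pred <- predict(model, newdata, type = "rk", targets = targets)
  n_clamped <- sum(pred < 0, na.rm = TRUE)
  pred <- pmax(pred, 0)

  vals <- matrix(NA_real_, stack$nrow, stack$ncol)
  vals[idx] <- pred
  structure(list(values = vals, xmin = stack$xmin, ymax = stack$ymax,
                 pixel = stack$pixel, crs = stack$crs, nodata = stack$nodata,
                 n_clamped = n_clamped,
                 provenance = list(stratum = stratum,
                                   covariates = model$covariates,
                                   variogram = model$variogram$kind)),
            class = "carbon_map")
}

#' @export
print.carbon_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("carbon_map: %d x %d pixels @ %g m, %d valid\n",
              nrow(x$values), ncol(x$values), x$pixel, length(v)))
  if (length(v))
    cat(sprintf("  density gC/m2: min %.2f, mean %.2f, max %.2f (%d clamped to 0)\n",
                min(v), mean(v), max(v), x$n_clamped))
  invisible(x)
}

#' Mosaic per-stratum carbon maps
#'
#' Union of the valid pixels of co-registered maps with disjoint valid
#' sets; any overlap is an error naming the first offending pixel.
#'
#' @param maps list of `"carbon_map"` objects.
#' @return a single `"carbon_map"`.
#' @export
mosaic <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "carbon_map")))
  out <- maps[[1L]]
  if (length(maps) == 1L) return(out)
  for (m in maps[-1L]) {
    if (!all(dim(m$values) == dim(out$values)) ||
        abs(m$xmin - out$xmin) > 1e-9 || abs(m$ymax - out$ymax) > 1e-9 ||
        abs(m$pixel - out$pixel) > 1e-9)
      stop("maps do not share a common grid")
    overlap <- !is.na(out$values) & !is.na(m$values)
    if (any(overlap)) {
      rc <- arrayInd(which(overlap)[1L], dim(out$values))
      stop(sprintf("overlapping valid pixels; first at row %d, col %d",
                   rc[1L], rc[2L]))
    }
    fill <- !is.na(m$values)
    out$values[fill] <- m$values[fill]
    out$n_clamped <- out$n_clamped + m$n_clamped
    out$provenance <- c(out$provenance, list(m$provenance))
  }
  out
}

#' Zonal carbon accounting over a class raster
#'
#' Per-class statistics over the valid pixels of a carbon map: area
#' (reported in 10^4 hm^2), min/max/mean density (gC/m2), total stock
#' (10^4 Mg C) and the class share of the all-class total (%). The unit
#' chain is pinned: gC/m2 x m2 -> g; 1 Mg = 10^6 g; 1 hm^2 = 10^4 m^2.
#' An `all` row closes the accounting: its total is the exact sum of the
#' class totals and its mean density equals total/area after unit
#' conversion.
#'
#' @param map a `"carbon_map"`.
#' @param classes integer matrix of class codes co-registered with `map`.
#' @param pixel_area pixel area in m^2 (900 for 30 m pixels).
#' @param class_names named integer vector mapping names to codes
#'   (default [steppe_classes()]).
#' @return data.frame of class `"zonal_summary"` with columns `class`,
#'   `area_1e4_hm2`, `min_gc_m2`, `max_gc_m2`, `mean_gc_m2`,
#'   `total_1e4_Mg`, `proportion_pct`.
#' @export
zonal_summary <- function(map, classes, pixel_area = map$pixel^2,
                          class_names = steppe_classes()) {
  stopifnot(inherits(map, "carbon_map"), pixel_area > 0,
            all(dim(classes) == dim(map$values)))
  rows <- list()
  for (nm in names(class_names)) {
    sel <- classes == class_names[[nm]] & !is.na(classes) &
      !is.na(map$values)
    if (!any(sel)) next
    v <- map$values[sel]
    area_m2 <- length(v) * pixel_area
    total_g <- sum(v) * pixel_area
    rows[[nm]] <- data.frame(
      class = nm,
      area_1e4_hm2 = area_m2 / 1e8,
      min_gc_m2 = min(v), max_gc_m2 = max(v), mean_gc_m2 = mean(v),
      total_1e4_Mg = total_g / 1e10,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no class has valid pixels")
  tab <- do.call(rbind, rows)
  grand <- sum(tab$total_1e4_Mg)
  if (grand == 0) {
    warning("all-class total stock is zero; proportions set to 0")
    tab$proportion_pct <- 0
  } else {
    tab$proportion_pct <- 100 * tab$total_1e4_Mg / grand
  }
  all_sel <- !is.na(map$values) &
    matrix(classes %in% unlist(class_names), nrow(classes), ncol(classes))
  v <- map$values[all_sel]
  tab <- rbind(tab, data.frame(
    class = "all", area_1e4_hm2 = length(v) * pixel_area / 1e8,
    min_gc_m2 = min(v), max_gc_m2 = max(v),
    mean_gc_m2 = grand * 1e10 / (length(v) * pixel_area),
    total_1e4_Mg = grand,
    proportion_pct = if (grand == 0) 0 else 100))
  rownames(tab) <- NULL
  class(tab) <- c("zonal_summary", "data.frame")
  tab
}

#' Carbon accounting from per-class area and mean density
#'
#' The same unit chain as [zonal_summary()], applied to a tabulated
#' regional summary (per-class area in 10^4 hm^2 and mean carbon density
#' in gC/m2) rather than a pixel map: per-class total stock in 10^4 Mg C,
#' class proportions of the grand total, and the all-class area-weighted
#' mean density.
#'
#' @param tab data.frame with columns `class`, `area_1e4_hm2`,
#'   `mean_gc_m2`.
#' @return `tab` with `total_1e4_Mg` and `proportion_pct` columns and a
#'   final `all` row.
#' @export
carbon_accounting <- function(tab) {
  stopifnot(all(c("class", "area_1e4_hm2", "mean_gc_m2") %in% names(tab)))
  # (gC/m2) * (1e4 hm2 -> 1e8 m2) -> 1e8 g -> /1e2 -> 1e4 Mg
  tab$total_1e4_Mg <- tab$mean_gc_m2 * tab$area_1e4_hm2 / 100
  grand <- sum(tab$total_1e4_Mg)
  area <- sum(tab$area_1e4_hm2)
  tab$proportion_pct <- if (grand == 0) 0 else 100 * tab$total_1e4_Mg / grand
  rbind(tab, data.frame(class = "all", area_1e4_hm2 = area,
                        mean_gc_m2 = 100 * grand / area,
                        total_1e4_Mg = grand,
                        proportion_pct = if (grand == 0) 0 else 100))
}

#' Per-class histogram of carbon density
#'
#' Fraction of each class's valid pixels falling in each density bin.
#' Values below the first or above the last edge are counted into the
#' boundary bins so fractions always sum to one per class.
#'
#' @param map a `"carbon_map"`.
#' @param classes integer matrix of class codes.
#' @param bin_edges strictly increasing density bin edges (gC/m2).
#' @param class_names named integer vector of class codes.
#' @return data.frame with columns `class`, `bin_low`, `bin_high`,
#'   `fraction`.
#' @export
histogram_by_class <- function(map, classes, bin_edges,
                               class_names = steppe_classes()) {
  stopifnot(length(bin_edges) >= 2L, all(diff(bin_edges) > 0))
  nb <- length(bin_edges) - 1L
  rows <- list()
  for (nm in names(class_names)) {
    sel <- classes == class_names[[nm]] & !is.na(classes) &
      !is.na(map$values)
    if (!any(sel)) next
    v <- map$values[sel]
    b <- findInterval(v, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    frac <- tabulate(b, nbins = nb) / length(v)
    rows[[nm]] <- data.frame(class = nm,
                             bin_low = bin_edges[-(nb + 1L)],
                             bin_high = bin_edges[-1L],
                             fraction = frac,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no class has valid pixels")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a carbon map as an ESRI ASCII grid
#'
#' @param map a `"carbon_map"`.
#' @param path file path (`.asc`).
#' @return the path (write) / a `"carbon_map"` (read).
#' @export
write_carbon_map <- function(map, path) {
  write_asc(map$values, path, map$xmin, map$ymax, map$pixel, map$nodata)
  invisible(path)
}

#' @rdname write_carbon_map
#' @export
read_carbon_map <- function(path) {
  a <- read_asc(path)
  structure(list(values = a$mat, xmin = a$xmin, ymax = a$ymax,
                 pixel = a$pixel, crs = "unknown", nodata = a$nodata,
                 n_clamped = 0L, provenance = list(source = path)),
            class = "carbon_map")
}
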
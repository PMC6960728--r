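#' Vegetation-index parameters
#'
#' Constants of the index formulas and the biomass-to-carbon conversion.
#' `alpha` is the WDRVI weighting of the near-infrared band; the raw WDRVI
#' \eqn{(\alpha NIR - R)/(\alpha NIR + R)} is mostly negative over grassland,
#' so the conventional offset `wdrvi_offset = 0.9/1.1` is added and the index
#' is carried in shifted form throughout. `carbon_coeff` converts dry
#' above-ground biomass (g/m2) to carbon (gC/m2); 0.45 is the grassland
#' value (0.5 is used for forests).
#'
#' @param alpha WDRVI weighting coefficient in (0, 1]; default 0.1.
#' @param evi_L,evi_C1,evi_C2 EVI soil/aerosol constants (1, 6, 7.5).
#' @param wdrvi_offset additive shift applied to the raw WDRVI.
#' @param carbon_coeff biomass-to-carbon conversion in (0, 1); default 0.45.
#' @return list of class `"vi_params"`.
#' @export
vi_params <- function(alpha = 0.1, evi_L = 1, evi_C1 = 6, evi_C2 = 7.5,
                      wdrvi_offset = 0.9 / 1.1, carbon_coeff = 0.45) {
  stopifnot(alpha > 0, alpha <= 1, carbon_coeff > 0, carbon_coeff < 1)
  structure(list(alpha = alpha, evi_L = evi_L, evi_C1 = evi_C1,
                 evi_C2 = evi_C2, wdrvi_offset = wdrvi_offset,
                 carbon_coeff = carbon_coeff),
            class = "vi_params")
}

# OLI band -> spectral symbol mapping (standard): B2 blue, B3 green, B4 red,
# B5 NIR. B1 (coastal), B6/B7 (SWIR) pass through as plain bands.
.vi_band_needs <- list(
  NDVI = c("B5", "B4"), WDRVI = c("B5", "B4"), SR = c("B5", "B4"),
  CI = c("B5", "B3"), EVI = c("B5", "B4", "B2"))

#' Compute a vegetation index (or pass a band through)
#'
#' Per-pixel index from top-of-canopy reflectance bands:
#' \describe{
#'   \item{NDVI}{\eqn{(NIR - R)/(NIR + R)}}
#'   \item{WDRVI}{\eqn{(\alpha NIR - R)/(\alpha NIR + R)} + offset (stored
#'     in shifted form only)}
#'   \item{CI}{\eqn{NIR/G - 1}}
#'   \item{EVI}{\eqn{2.5 (NIR - R)/(NIR + C_1 R - C_2 B + L)}}
#'   \item{SR}{\eqn{NIR/R}}
#' }
#' Band names `B1`..`B7` are returned unchanged. Nodata propagates; pixels
#' with a zero denominator become nodata (`NA`) so downstream regression
#' never sees non-finite covariates. Reflectance outside `[0, 1.5]` is
#' flagged with a warning but not altered.
#'
#' @param stack a [grid_stack()] with bands named `B1`..`B7`.
#' @param name index name (`"NDVI"`, `"WDRVI"`, `"CI"`, `"EVI"`, `"SR"`) or
#'   a band name `B1`..`B7`.
#' @param params a [vi_params()].
#' @return numeric matrix, the covariate grid.
#' @export
compute_index <- function(stack, name, params = vi_params()) {
  stopifnot(inherits(stack, "grid_stack"), inherits(params, "vi_params"))
  if (grepl("^B[1-7]$", name)) {
    if (!name %in% names(stack$bands)) stop("missing band: ", name)
    return(stack$bands[[name]])
  }
  if (!name %in% names(.vi_band_needs))
    stop("unknown index name: ", name)
  need <- .vi_band_needs[[name]]
  miss <- setdiff(need, names(stack$bands))
  if (length(miss)) stop("missing band(s) for ", name, ": ",
                         paste(miss, collapse = ", "))
  bad <- vapply(need, function(b) {
    v <- stack$bands[[b]]
    any(v < 0 | v > 1.5, na.rm = TRUE)
  }, logical(1))
  if (any(bad))
    warning("reflectance outside [0, 1.5] in band(s): ",
            paste(need[bad], collapse = ", "))
  NIR <- stack$bands[["B5"]]
  out <- switch(name,
    NDVI = safe_ratio(NIR - stack$bands[["B4"]], NIR + stack$bands[["B4"]]),
    SR   = safe_ratio(NIR, stack$bands[["B4"]]),
    CI   = safe_ratio(NIR, stack$bands[["B3"]]) - 1,
    WDRVI = {
      R <- stack$bands[["B4"]]
      safe_ratio(params$alpha * NIR - R, params$alpha * NIR + R) +
        params$wdrvi_offset
    },
    EVI = {
      R <- stack$bands[["B4"]]; B <- stack$bands[["B2"]]
      safe_ratio(2.5 * (NIR - R),
                 NIR + params$evi_C1 * R - params$evi_C2 * B + params$evi_L)
    })
  out
}

safe_ratio <- function(num, den) {
  out <- num / den
  out[!is.na(den) & den == 0] <- NA
  out
}

#' Convert above-ground biomass to carbon stock
#'
#' `carbon = carbon_coeff * agb`, with the grassland coefficient 0.45 by
#' default; units gC/m2 from g/m2 dry mass.
#'
#' @param agb dry above-ground biomass (g/m2), all `>= 0`.
#' @param params a [vi_params()].
#' @return carbon density (gC/m2).
#' @examples
#' agb_to_carbon(100)  # 45
#' @export
agb_to_carbon <- function(agb, params = vi_params()) {
  if (any(agb < 0, na.rm = TRUE)) stop("agb must be >= 0")
  params$carbon_coeff * agb
}

#' Append sampled covariate columns to a plot table
#'
#' Computes the requested indices/bands with [compute_index()] and samples
#' each at the plot coordinates (nearest pixel). Plots landing on nodata are
#' flagged via the `excluded` column so they can be dropped from modelling.
#'
#' @param plots data.frame with columns `x`, `y` (m, stack CRS).
#' @param stack a [grid_stack()].
#' @param covariates character vector of index/band names.
#' @param params a [vi_params()].
#' @return `plots` with one numeric column per covariate and a logical
#'   `excluded` column (TRUE where any covariate was nodata).
#' @export
add_covariates <- function(plots, stack, covariates, params = vi_params()) {
  stopifnot(all(c("x", "y") %in% names(plots)))
  tmp <- stack
  for (cv in covariates) {
    g <- compute_index(stack, cv, params)
    tmp$bands <- list(v = g)
    plots[[cv]] <- as.numeric(extract_at_points(tmp, "v", plots$x, plots$y))
  }
  plots$excluded <- Reduce(`|`, lapply(covariates, function(cv)
    is.na(plots[[cv]])), rep(FALSE, nrow(plots)))
  plots
}
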
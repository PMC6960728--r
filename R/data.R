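#' Published per-class zonal inputs for the Chenbarhu Banner steppes
#'
#' Per-class area (10^4 hm^2) and mean above-ground carbon density (gC/m2)
#' for the four steppe classes of Chenbarhu Banner, Hulunber (Inner
#' Mongolia), as tabulated in the regional carbon-stock assessment the
#' package's accounting example reproduces. Feeding this table to
#' [carbon_accounting()] recovers the per-class total stocks, the
#' all-steppe total and the class proportions from the area/density pairs
#' alone.
#'
#' @return data.frame with columns `class`, `area_1e4_hm2`, `mean_gc_m2`.
#' @examples
#' carbon_accounting(chenbarhu_zonal())
#' @export
chenbarhu_zonal <- function() {
  utils::read.csv(system.file("extdata", "chenbarhu_zonal.csv",
                              package = "steppeRK"),
                  stringsAsFactors = FALSE)
}
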
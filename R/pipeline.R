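#' Run configuration for the end-to-end pipeline
#'
#' Builds (and validates) the configuration consumed by [rk_run()]. Can be
#' given a JSON file path, a list of overrides, or nothing (defaults).
#' The defaults describe a small self-contained synthetic study: a
#' 1.92 km x 1.92 km domain covered by a 64 x 64 pixel 30 m reflectance
#' stack, 55 + 29 plots, NDVI and CI covariates, and an exponential
#' residual variogram with range = extent/4.
#'
#' @param config `NULL`, a list of overrides, or a path to a JSON file.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(config = NULL) {
  defaults <- list(
    out_dir = "rk_run",
    seed = 1L,
    extent = c(0, 1920, 0, 1920),
    n_typical = 55L, n_meadow = 29L,
    covariates = c("NDVI", "CI"),
    response = "carbon_gc_m2",
    family = "exponential",
    n_bins = 12L, max_lag = NULL,
    loocv_policy = "fixed",
    trend_intercept = 11, trend_coef = 60,
    nugget = 20, psill = 80,
    hist_edges = c(0, 20, 40, 60, 80, 100, 150, 250))
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config)
  }
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown)) stop("unknown config field(s): ",
                              paste(unknown, collapse = ", "))
    defaults[names(config)] <- config
  }
  defaults$seed <- as.integer(defaults$seed)
  stopifnot(length(defaults$extent) == 4L,
            defaults$family %in% c("exponential", "gaussian", "spherical"),
            defaults$loocv_policy %in% c("fixed", "refit"))
  structure(defaults, class = "run_config")
}

pipeline_paths <- function(cfg) {
  d <- cfg$out_dir
  list(dir = d,
       plots = file.path(d, "plots.csv"),
       stack = file.path(d, "stack"),
       classes = file.path(d, "classes.asc"),
       screen = file.path(d, "correlations.csv"),
       model = function(s) file.path(d, sprintf("model_%s.json", s)),
       cv = file.path(d, "cv_results.csv"),
       map = file.path(d, "carbon_map.asc"),
       zonal = file.path(d, "zonal.csv"),
       hist = file.path(d, "histogram.csv"),
       log = file.path(d, "run.log"))
}

pipeline_log <- function(cfg, step, outputs) {
  p <- pipeline_paths(cfg)
  hash <- sum(utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                         null = "null")) *
              seq_along(utf8ToInt(jsonlite::toJSON(unclass(cfg),
                                                   auto_unbox = TRUE,
                                                   null = "null")))) %% 1e9
  cat(sprintf("step=%s seed=%d config_hash=%09d outputs=%s\n",
              step, cfg$seed, hash, paste(outputs, collapse = ",")),
      file = p$log, append = TRUE)
}

synthetic_from_run <- function(cfg) {
  coefs <- stats::setNames(rep(cfg$trend_coef, length.out = 1L),
                           cfg$covariates[1L])
  width <- cfg$extent[2] - cfg$extent[1]
  synthetic_config(
    extent = cfg$extent,
    n_typical = cfg$n_typical, n_meadow = cfg$n_meadow,
    trend_intercept = cfg$trend_intercept,
    trend_coeffs = coefs,
    true_variogram = vgm_model("exponential", nugget = cfg$nugget,
                               psill = cfg$psill, range = width / 4),
    seed = cfg$seed)
}

rk_formula <- function(cfg) {
  stats::as.formula(paste(cfg$response, "~",
                          paste(cfg$covariates, collapse = " + ")))
}

#' Run one pipeline step
#'
#' End-to-end driver over the package's functions. Steps:
#' \describe{
#'   \item{simulate}{write synthetic plots (`plots.csv`), a 7-band
#'     reflectance stack (`stack/`) and the steppe-class raster
#'     (`classes.asc`)}
#'   \item{indices}{write one covariate grid per configured index
#'     (`<name>.asc`)}
#'   \item{screen}{Pearson screening table (`correlations.csv`)}
#'   \item{fit}{per-stratum RK model JSONs (`model_<stratum>.json`)}
#'   \item{cv}{LOOCV comparison of RK and LR per stratum plus pooled rows
#'     (`cv_results.csv`)}
#'   \item{predict}{stratified prediction + mosaic (`carbon_map.asc`)}
#'   \item{summarize}{zonal accounting (`zonal.csv`) and per-class density
#'     histograms (`histogram.csv`)}
#' }
#' Every step appends a line with the config hash and seed to `run.log`.
#' On error, the step's partial outputs are removed before rethrowing.
#'
#' @param step one of `"simulate"`, `"indices"`, `"screen"`, `"fit"`,
#'   `"cv"`, `"predict"`, `"summarize"`, or `"all"`.
#' @param config passed to [run_config()].
#' @return (invisibly) the paths written by the step.
#' @export
rk_run <- function(step = c("all", "simulate", "indices", "screen", "fit",
                            "cv", "predict", "summarize"),
                   config = NULL) {
  step <- match.arg(step)
  cfg <- run_config(config)
  if (step == "all") {
    outs <- lapply(c("simulate", "indices", "screen", "fit", "cv",
                     "predict", "summarize"), rk_run, config = cfg)
    return(invisible(unlist(outs)))
  }
  p <- pipeline_paths(cfg)
  dir.create(p$dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  on_fail <- function(e) {
    unlink(outputs, recursive = TRUE)
    stop(sprintf("step '%s' failed: %s", step, conditionMessage(e)),
         call. = FALSE)
  }
  tryCatch({
    if (step == "simulate") {
      sc <- synthetic_from_run(cfg)
      fx <- make_fixture_stack(sc)
      plots <- simulate_plots(sc, stack = fx$stack)
      extra <- setdiff(cfg$covariates, names(plots))
      if (length(extra)) plots <- add_covariates(plots, fx$stack, extra)
      outputs <- c(p$plots, p$stack, p$classes)
      utils::write.csv(plots, p$plots, row.names = FALSE)
      write_grid_stack(fx$stack, p$stack)
      write_asc(fx$classes, p$classes, fx$stack$xmin, fx$stack$ymax,
                fx$stack$pixel)
    } else if (step == "indices") {
      stack <- read_grid_stack(require_path(p$stack, "stack.json"))
      outputs <- file.path(p$dir, paste0(cfg$covariates, ".asc"))
      for (i in seq_along(cfg$covariates)) {
        g <- compute_index(stack, cfg$covariates[i])
        write_asc(g, outputs[i], stack$xmin, stack$ymax, stack$pixel)
      }
    } else if (step == "screen") {
      plots <- utils::read.csv(require_path(p$plots))
      outputs <- p$screen
      utils::write.csv(pearson_screen(plots, cfg$covariates, cfg$response),
                       p$screen, row.names = FALSE)
    } else if (step == "fit") {
      plots <- utils::read.csv(require_path(p$plots))
      f <- rk_formula(cfg)
      outputs <- c(p$model("typical"), p$model("meadow"))
      for (s in c("typical", "meadow")) {
        m <- rk(f, plots[plots$stratum == s, ], family = cfg$family,
                n_bins = cfg$n_bins, max_lag = cfg$max_lag, stratum = s)
        rk_to_json(m, p$model(s))
      }
    } else if (step == "cv") {
      plots <- utils::read.csv(require_path(p$plots))
      f <- rk_formula(cfg)
      cvs <- list(); labels <- character(0)
      for (s in c("typical", "meadow")) {
        sub <- plots[plots$stratum == s, ]
        for (meth in c("LR", "RK")) {
          cvs[[length(cvs) + 1L]] <-
            loocv(sub, f, method = meth, family = cfg$family,
                  variogram_policy = cfg$loocv_policy,
                  n_bins = cfg$n_bins, max_lag = cfg$max_lag)
          labels <- c(labels, s)
        }
      }
      tab <- model_selection(cvs, labels)
      for (meth in c("LR", "RK")) {
        sel <- which(labels == "typical" &
                       vapply(cvs, function(x) x$method, "") == meth)
        selm <- which(labels == "meadow" &
                        vapply(cvs, function(x) x$method, "") == meth)
        pooled <- combine_strata_cv(cvs[[sel]], cvs[[selm]])
        tab <- rbind(tab, data.frame(
          stratum = "pooled", variable_set = tab$variable_set[1L],
          method = meth, family = pooled$family,
          r2 = pooled$r2, mae_gc_m2 = pooled$mae,
          rmse_gc_m2 = pooled$rmse, selected = FALSE))
      }
      outputs <- p$cv
      utils::write.csv(tab, p$cv, row.names = FALSE)
    } else if (step == "predict") {
      stack <- read_grid_stack(require_path(p$stack, "stack.json"))
      classes <- read_asc(require_path(p$classes))$mat
      maps <- lapply(c("typical", "meadow"), function(s) {
        m <- rk_from_json(require_path(p$model(s)))
        predict_stratum_map(m, stack, classes, stratum = s)
      })
      outputs <- p$map
      write_carbon_map(mosaic(maps), p$map)
    } else if (step == "summarize") {
      map <- read_carbon_map(require_path(p$map))
      classes <- read_asc(require_path(p$classes))$mat
      outputs <- c(p$zonal, p$hist)
      zs <- zonal_summary(map, classes)
      utils::write.csv(as.data.frame(zs), p$zonal, row.names = FALSE)
      utils::write.csv(histogram_by_class(map, classes, cfg$hist_edges),
                       p$hist, row.names = FALSE)
    }
    pipeline_log(cfg, step, outputs)
  }, error = on_fail)
  invisible(outputs)
}

require_path <- function(path, child = NULL) {
  probe <- if (is.null(child)) path else file.path(path, child)
  if (!file.exists(probe))
    stop("required input missing: ", probe, call. = FALSE)
  path
}
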
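# Shared fixtures built in code.

# A one-pixel (or small) reflectance stack from explicit band values.
band_stack <- function(..., nr = 1, nc = 1) {
  vals <- list(...)
  bands <- lapply(vals, function(v) matrix(v, nr, nc))
  # fill unspecified bands with a neutral reflectance
  for (b in paste0("B", 1:7)) if (is.null(bands[[b]]))
    bands[[b]] <- matrix(0.2, nr, nc)
  grid_stack(bands[paste0("B", 1:7)], xmin = 0, ymax = nr * 30, pixel = 30)
}

# A small plot table with exactly known trend and iid residuals.
toy_plots <- function(n = 20, seed = 42, sd = 0, slope = 2, intercept = 3) {
  set.seed(seed)
  x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
  q <- runif(n)
  data.frame(plot_id = sprintf("T%02d", seq_len(n)), x = x, y = y,
             stratum = rep(c("typical", "meadow"), length.out = n),
             q = q,
             carbon_gc_m2 = intercept + slope * q + rnorm(n, sd = sd))
}

pure_nugget <- function(c0 = 10) vgm_model("exponential", c0, 0, 1000)
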
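# Independent oracles and small fixture builders shared across the suite.

# brute-force left-aligned window means
oracle_rollmean <- function(x, k) {
  n <- length(x)
  vapply(seq_len(n - k + 1L), function(i) mean(x[i:(i + k - 1L)]), numeric(1))
}

# sort-and-threshold oracle for the top-5% selections (Methods 1 and 2)
oracle_top5 <- function(values, years) {
  thr <- sort(values)[ceiling(0.95 * length(values))]
  # type-7 95th percentile lies between the ceiling(0.95 n)-th order statistic
  # and the maximum; strict exceedance of the interpolated threshold
  thr7 <- as.numeric(quantile(values, 0.95, type = 7))
  years[values > thr7]
}

# brute-force Method 3: over all index pairs i < j, maximise the density span
# lnN[i] - lnN[j]; ties resolved to the latest i, then the earliest j
oracle_density_run <- function(lnN, years) {
  n <- length(lnN)
  best <- NULL
  best_span <- -Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      span <- lnN[i] - lnN[j]
      replace <- span > best_span + 1e-15 ||
        (abs(span - best_span) <= 1e-15 &&
           (i > best[1] || (i == best[1] && j < best[2])))
      if (replace) {
        best_span <- span
        best <- c(i, j)
      }
    }
  }
  if (is.null(best) || best_span <= 0) return(numeric(0))
  years[best[1]:best[2]]
}

# closed-form OLS slope
oracle_slope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)

# hand-built minimal stand series
make_series <- function(n = 10, Cwood = NULL, Cmort = NULL, WBgrowth = NULL,
                        year = 0:(n - 1), ...) {
  Cwood <- Cwood %||% rep(10, n)
  Cmort <- Cmort %||% rep(0.1, n)
  WBgrowth <- WBgrowth %||% (pmax(c(diff(Cwood), 0), 0) + Cmort)
  stand_series(data.frame(year = year, Cwood = Cwood, Cmort = Cmort,
                          WBgrowth = WBgrowth, ...))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a run that spends its whole span inside the thinning window, so every
# thinning-space point lies on the imposed power law
thinning_only_config <- function(p, seed = 1L, years = 60L, noise_sd = 0) {
  sim_config(years = years, seed = seed, thinning_exponent = p,
             canopy_closure_yr = 0, thinning_window = c(0, years - 10L),
             initial_grass_frac = 0, initial_dbh = 15,
             thinning_decline = 0.02, noise_sd = noise_sd)
}

quiet <- function(expr) suppressMessages(expr)
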
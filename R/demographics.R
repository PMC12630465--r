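#' Demographic woody carbon budget closure check
#'
#' Tests whether annual woody-carbon stock changes are explained by the net
#' demographic flux: `residual(t) = Cwood(t+1) - Cwood(t) -
#' (WBgrowth(t) - Cmort(t))`. The summary statistic is the relative drift,
#' `max|residual| / max(Cwood)`, compared against `tolerance`. A model whose
#' reader separates recruitment carbon inputs must fold them into
#' `WBgrowth` for this closure to be meaningful.
#'
#' The default tolerance (1e-6) suits simulator output, which closes
#' exactly; external model output typically drifts, for which a relative
#' tolerance of order 1e-2 is realistic.
#'
#' @param series a `stand_series` of at least 2 years
#' @param tolerance relative drift threshold for the pass flag
#' @return a list of class `budget_report`: `residual` (data frame `year`,
#'   `residual` in kgC m-2, one row per transition), `max_abs_residual`,
#'   `relative_drift`, `tolerance`, `pass`
#' @examples
#' sim <- simulate_stand(sim_config(years = 150))
#' check_budget(sim$series)$pass
#' @export
check_budget <- function(series, tolerance = 1e-6) {
  stopifnot(is.data.frame(series))
  n <- nrow(series)
  if (n < 2L) stop("series must span at least 2 years", call. = FALSE)
  Cw <- series$Cwood
  res <- Cw[-1L] - Cw[-n] - series$WBgrowth[-n] + series$Cmort[-n]
  max_abs <- max(abs(res))
  drift <- max_abs / max(Cw)
  out <- list(
    residual = data.frame(year = series$year[-n], residual = res),
    max_abs_residual = max_abs,
    relative_drift = drift,
    tolerance = tolerance,
    pass = drift <= tolerance
  )
  class(out) <- "budget_report"
  out
}

#' @export
print.budget_report <- function(x, ...) {
  cat(sprintf("<budget_report> %s: max |residual| %.3g kgC m-2, relative drift %.3g (tolerance %.3g)\n",
              if (x$pass) "PASS" else "FAIL", x$max_abs_residual,
              x$relative_drift, x$tolerance))
  invisible(x)
}

rate_table <- function(series) {
  Cw <- series$Cwood
  Cm <- series$Cmort
  rate <- ifelse(Cw > 0, 100 * Cm / Cw, NA_real_)
  tau <- ifelse(Cm > 0, Cw / Cm, ifelse(Cw > 0, Inf, NA_real_))
  out <- data.frame(year = series$year, cmort_rate = rate, tau = tau,
                    WBgrowth = series$WBgrowth)
  undef <- series$year[Cw <= 0]
  if (length(undef)) {
    sb_log("warn", length(undef),
           " year(s) with Cwood = 0: cmort_rate flagged undefined (NA)")
  }
  attr(out, "undefined_years") <- undef
  attr(out, "smoothed") <- FALSE
  attr(out, "window") <- NA_integer_
  class(out) <- c("rate_series", class(out))
  out
}

#' Fractional mortality rate and woody turnover time
#'
#' Post-processes the mortality flux into the fractional mortality rate
#' `cmort_rate = 100 * Cmort / Cwood` (% yr-1) and the woody carbon turnover
#' time `tau = Cwood / Cmort` (yr). The two are reciprocal:
#' `tau * cmort_rate = 100` wherever both are defined. Years with
#' `Cwood = 0` are flagged undefined (`NA`, recorded in
#' `attr(x, "undefined_years")`), never silently dropped; `Cmort = 0` gives
#' a zero rate and an explicitly infinite turnover time.
#'
#' Both functions return the same annual, unsmoothed rate table; turnover
#' times for mature-forest comparison are used unsmoothed.
#'
#' @param series a `stand_series`
#' @return a data frame of class `rate_series` with columns `year`,
#'   `cmort_rate` (% yr-1), `tau` (yr), `WBgrowth` (kgC m-2 yr-1)
#' @examples
#' sim <- simulate_stand(sim_config(years = 150))
#' head(mortality_rate(sim$series))
#' @export
mortality_rate <- function(series) rate_table(series)

#' @rdname mortality_rate
#' @export
turnover_time <- function(series) rate_table(series)

#' Left-aligned rolling mean
#'
#' 30-yr left-aligned window means (via [zoo::rollmean()]) remove the
#' repeated climate-cycle signal from rate series and reveal the dominant
#' demographic dynamics. `output[t]` is the mean of `values[t .. t+k-1]`;
#' incomplete trailing windows are dropped, so the output is `k - 1` shorter
#' than the input.
#'
#' @param x a numeric vector, or a `rate_series` (smooths `cmort_rate` and
#'   `WBgrowth`; `tau` is set to `NA` as it is only used unsmoothed)
#' @param k window length in years
#' @return numeric vector (or `rate_series`) of length `length(x) - k + 1`
#' @examples
#' smooth_left(1:10, k = 3)
#' @export
smooth_left <- function(x, k = 30L) UseMethod("smooth_left")

#' @export
smooth_left.default <- function(x, k = 30L) {
  stopifnot(is.numeric(x))
  if (length(x) < k) {
    stop("series shorter than the smoothing window", call. = FALSE)
  }
  as.numeric(zoo::rollmean(x, k = k, align = "left"))
}

#' @export
smooth_left.rate_series <- function(x, k = 30L) {
  n <- nrow(x)
  if (n < k) stop("series shorter than the smoothing window", call. = FALSE)
  m <- n - k + 1L
  out <- data.frame(
    year = x$year[seq_len(m)],
    cmort_rate = smooth_left(x$cmort_rate, k),
    tau = NA_real_,
    WBgrowth = smooth_left(x$WBgrowth, k)
  )
  attr(out, "undefined_years") <- attr(x, "undefined_years")
  attr(out, "smoothed") <- TRUE
  attr(out, "window") <- as.integer(k)
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Drop the post-spin-up transient
#'
#' Removes the first `n` years (default 30) of a series before smoothing, to
#' exclude the transient immediately following spin-up.
#'
#' @param x an annual data frame (`stand_series` or `rate_series`)
#' @param n number of leading years to drop; 0 is the identity
#' @return `x` without its first `n` rows, classes and attributes preserved
#' @export
drop_post_spinup <- function(x, n = 30L) {
  stopifnot(is.data.frame(x))
  if (n < 0) stop("'n' must be >= 0", call. = FALSE)
  if (n == 0L) return(x)
  if (nrow(x) <= n) {
    stop("series has no years left after dropping the spin-up transient",
         call. = FALSE)
  }
  out <- x[-seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  for (at in c("absent", "clamped", "undefined_years", "smoothed", "window")) {
    attr(out, at) <- attr(x, at)
  }
  class(out) <- class(x)
  out
}

#' Equilibrium-window summary statistics
#'
#' Summarises unsmoothed annual values over an equilibrium time window:
#' mean, standard deviation and 10th/50th/90th percentiles per variable.
#' Non-finite values (e.g. explicitly infinite turnover times) are excluded
#' from the summaries with a logged count, never coerced to large numbers.
#'
#' @param x an annual data frame with a `year` column (`stand_series` or
#'   `rate_series`)
#' @param window `c(first, last)` years, inclusive, inside the series span
#' @return data frame with one row per variable: `variable`, `n`,
#'   `n_nonfinite`, `mean`, `sd`, `q10`, `q50`, `q90`
#' @examples
#' sim <- simulate_stand(sim_config(years = 300))
#' equilibrium_stats(mortality_rate(sim$series), window = c(200, 299))
#' @export
equilibrium_stats <- function(x, window) {
  stopifnot(is.data.frame(x), "year" %in% names(x))
  if (length(window) != 2L || window[1] > window[2]) {
    stop("'window' must be c(first, last) with first <= last", call. = FALSE)
  }
  if (window[1] < min(x$year) || window[2] > max(x$year)) {
    stop("'window' lies outside the series span", call. = FALSE)
  }
  sub <- x[x$year >= window[1] & x$year <= window[2], , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty equilibrium window", call. = FALSE)
  vars <- setdiff(names(sub)[vapply(sub, is.numeric, logical(1))], "year")
  rows <- lapply(vars, function(v) {
    vals <- sub[[v]]
    finite <- vals[is.finite(vals)]
    n_bad <- length(vals) - length(finite)
    if (n_bad > 0) {
      sb_log("info", n_bad, " non-finite value(s) of '", v,
             "' excluded from equilibrium statistics")
    }
    q <- if (length(finite)) {
      quantile(finite, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
    } else {
      rep(NA_real_, 3)
    }
    data.frame(variable = v, n = length(finite), n_nonfinite = n_bad,
               mean = if (length(finite)) mean(finite) else NA_real_,
               sd = if (length(finite) > 1) sd(finite) else
                 if (length(finite) == 1) 0 else NA_real_,
               q10 = q[1], q50 = q[2], q90 = q[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
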
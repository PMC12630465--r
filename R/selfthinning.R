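#' Transform a stand series into self-thinning space
#'
#' Computes, per year, the log stem density `lnN` (stems ha-1) and log mean
#' individual aboveground woody mass `lnM` (kgC per tree). With a size
#' structure present, small trees are excluded: only dbh classes whose lower
#' edge is at or above `min_dbh` (default 10 cm) contribute, and
#' `mass = sum(cwood_size) * 1e4 / sum(nstem_size)` over those classes (the
#' 1e4 factor converts the per-m2 carbon basis to the per-ha stem basis).
#' Without a size structure the dbh-class distinction cannot be made; stand
#' totals (`Cwood_AG` or, failing that, `Cwood` over `nstem`) are used and
#' the deviation is recorded in `attr(x, "source")` and logged.
#'
#' Years with zero stem density are skipped with a log entry.
#'
#' @param series a `stand_series`
#' @param structure a `size_structure` for the same years, or `NULL`
#' @param min_dbh smallest dbh-class lower edge retained (cm)
#' @return data frame of class `thinning_points` with columns `year`, `lnN`,
#'   `lnM`; attributes `min_dbh` and `source` (`"size_structure"` or
#'   `"totals"`)
#' @examples
#' sim <- simulate_stand(sim_config(years = 200))
#' head(to_thinning_space(sim$series, sim$structure))
#' @export
to_thinning_space <- function(series, structure = NULL, min_dbh = 10) {
  stopifnot(is.data.frame(series))
  if (is.null(structure)) {
    if (is.null(series$nstem)) {
      stop("required column 'nstem' is missing from the series", call. = FALSE)
    }
    cw <- series$Cwood_AG %||% series$Cwood
    sb_log("info", "no size structure supplied: using stand totals, ",
           "the <", min_dbh, " cm dbh exclusion cannot be applied")
    df <- data.frame(year = series$year, N = series$nstem, cw = cw)
    src <- "totals"
  } else {
    stopifnot(inherits(structure, "size_structure") || is.data.frame(structure))
    scheme <- dbh_scheme()
    keep <- scheme$label[scheme$lower >= min_dbh]
    sub <- structure[structure$class_label %in% keep, , drop = FALSE]
    N <- tapply(sub$nstem_size, sub$year, sum)
    cw <- tapply(sub$cwood_size, sub$year, sum)
    yrs <- as.numeric(names(N))
    df <- data.frame(year = yrs, N = as.numeric(N), cw = as.numeric(cw))
    df <- df[order(df$year), , drop = FALSE]
    src <- "size_structure"
  }
  zero <- df$N <= 0
  if (any(zero)) {
    sb_log("info", sum(zero), " year(s) skipped: no stems above the dbh threshold")
    df <- df[!zero, , drop = FALSE]
  }
  out <- data.frame(year = df$year, lnN = log(df$N),
                    lnM = log(df$cw * 1e4 / df$N))
  rownames(out) <- NULL
  attr(out, "min_dbh") <- min_dbh
  attr(out, "source") <- src
  class(out) <- c("thinning_points", "data.frame")
  out
}

#' Self-thinning period detection
#'
#' Four alternative ways to pick the simulation years that belong to the
#' self-thinning period, ahead of fitting the slope with [fit_slope()]:
#'
#' * **Method 1** ([detect_m1()]): for models with a dedicated
#'   self-thinning mortality diagnostic, the years whose diagnostic rate
#'   strictly exceeds the 95th percentile (type 7) of the whole run.
#' * **Method 2** ([detect_m2()]): as Method 1 but applied to the total
#'   fractional mortality rate — the top 5% of annual values.
#' * **Method 3** ([detect_m3()]): the consecutive run of years in
#'   self-thinning space that maximises the density span — from a density
#'   maximum to a subsequent density minimum; ties resolve to the latest
#'   maximum, then the earliest following minimum.
#' * **Method 4** ([detect_m4()]): a manually supplied year range, recorded
#'   as such; it takes precedence over any automatic pick when both are
#'   supplied to a pipeline.
#'
#' @param series a `stand_series` carrying a `selfthin_mort_rate` column
#'   (Method 1)
#' @param rates a `rate_series` from [mortality_rate()], or a
#'   `stand_series` from which one is computed (Method 2)
#' @param points a `thinning_points` table from [to_thinning_space()]
#'   (Method 3)
#' @param range `c(first, last)` years, inclusive (Method 4)
#' @return an integer-valued vector of selected years (possibly empty); for
#'   Method 4 the `"provenance"` attribute is `"manual"`
#' @name detect_thinning
NULL

top_percentile_years <- function(values, years, label) {
  ok <- is.finite(values)
  values <- values[ok]
  years <- years[ok]
  if (!length(values)) return(numeric(0))
  thr <- quantile(values, 0.95, type = 7, names = FALSE)
  sel <- years[values > thr]
  if (length(unique(values)) == 1L) {
    warning(label, ": all annual values equal; nothing strictly exceeds ",
            "the 95th percentile, empty selection", call. = FALSE)
  }
  sel
}

#' @rdname detect_thinning
#' @export
detect_m1 <- function(series) {
  stopifnot(is.data.frame(series))
  if (is.null(series$selfthin_mort_rate)) {
    stop("no dedicated self-thinning mortality diagnostic in this series; ",
         "use detection Methods 2-4 instead", call. = FALSE)
  }
  top_percentile_years(series$selfthin_mort_rate, series$year, "Method 1")
}

#' @rdname detect_thinning
#' @export
detect_m2 <- function(rates) {
  stopifnot(is.data.frame(rates))
  if (is.null(rates$cmort_rate)) {
    if (!is.null(rates$Cmort)) rates <- mortality_rate(rates)
    else stop("'rates' must carry a cmort_rate column", call. = FALSE)
  }
  top_percentile_years(rates$cmort_rate, rates$year, "Method 2")
}

#' @rdname detect_thinning
#' @export
detect_m3 <- function(points) {
  stopifnot(inherits(points, "thinning_points") || is.data.frame(points))
  n <- nrow(points)
  if (n < 3L) stop("Method 3 needs at least 3 thinning-space points", call. = FALSE)
  lnN <- points$lnN
  # single pass over candidate run ends, tracking the latest prefix density
  # maximum; ties in span resolve to the latest maximum, then earliest end
  tol <- 1e-15
  best_span <- -Inf
  best <- c(NA_integer_, NA_integer_)
  max_i <- 1L
  for (j in 2:n) {
    if (lnN[j - 1L] >= lnN[max_i]) max_i <- j - 1L
    span <- lnN[max_i] - lnN[j]
    if (span > best_span + tol ||
        (abs(span - best_span) <= tol && max_i > best[1])) {
      best_span <- span
      best <- c(max_i, j)
    }
  }
  if (!is.finite(best_span) || best_span <= 0) {
    sb_log("warn", "Method 3: stem density never declines; empty selection")
    return(numeric(0))
  }
  points$year[best[1]:best[2]]
}

#' @rdname detect_thinning
#' @param series_years optional vector of available years used to validate a
#'   manual range (Method 4)
#' @export
detect_m4 <- function(range, series_years = NULL) {
  if (length(range) != 2L || anyNA(range)) {
    stop("'range' must be c(first, last)", call. = FALSE)
  }
  if (range[1] > range[2]) {
    stop("reversed (empty) manual range", call. = FALSE)
  }
  if (!is.null(series_years) &&
      (range[1] < min(series_years) || range[2] > max(series_years))) {
    stop("manual range lies outside the series years", call. = FALSE)
  }
  out <- seq(range[1], range[2])
  attr(out, "provenance") <- "manual"
  out
}

#' Fit the self-thinning slope
#'
#' Ordinary least squares of log mean individual mass on log stem density
#' (`stats::lm` with default settings) over the selected thinning years,
#' giving the self-thinning exponent `p` (slope), `ln(k)` (intercept, with
#' `k` in kgC (stems ha-1)^-p) and r-squared. The slope is flagged
#' `within_bounds` when it lies in the reference band `[-2.612, -1]`
#' (observed lower to theoretical upper threshold, boundaries inclusive);
#' the classically proposed exponent is -3/2.
#'
#' @param points a `thinning_points` table
#' @param years years to fit over (e.g. from a detection method); `NULL`
#'   uses all points
#' @param method optional method tag (1-4 or a string) recorded in the result
#' @return a list of class `thinning_result`: `method`, `selected_years`,
#'   `duration`, `slope`, `intercept`, `r_squared`, `within_bounds`,
#'   `n_points`
#' @examples
#' sim <- simulate_stand(sim_config(years = 200, thinning_exponent = -1.5))
#' pts <- to_thinning_space(sim$series, sim$structure)
#' fit_slope(pts, years = detect_m3(pts), method = 3)
#' @export
fit_slope <- function(points, years = NULL, method = NA) {
  stopifnot(inherits(points, "thinning_points") || is.data.frame(points))
  sel <- if (is.null(years)) points else points[points$year %in% years, , drop = FALSE]
  if (nrow(sel) < 3L || var(sel$lnN) == 0) {
    stop("insufficient thinning trajectory: need >= 3 points with distinct densities",
         call. = FALSE)
  }
  fit <- lm(lnM ~ lnN, data = sel)
  slope <- unname(coef(fit)[2])
  sst <- sum((sel$lnM - mean(sel$lnM))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  out <- list(
    method = method,
    selected_years = sel$year,
    duration = length(sel$year),
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    within_bounds = slope >= -2.612 - 1e-9 && slope <= -1 + 1e-9,
    n_points = nrow(sel)
  )
  class(out) <- "thinning_result"
  out
}

#' @export
print.thinning_result <- function(x, ...) {
  cat(sprintf("<thinning_result> method %s: slope %.4f (ln k = %.3f, r2 = %.4f)\n",
              format(x$method), x$slope, x$intercept, x$r_squared))
  cat(sprintf("  %d yr selected (%g..%g); within [-2.612, -1]: %s\n",
              x$duration, min(x$selected_years), max(x$selected_years),
              x$within_bounds))
  invisible(x)
}
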
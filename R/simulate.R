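#' Simulate a stand-level demographic time series with known ground truth
#'
#' Generates an annual stand series, the matching dbh-class size structure
#' and a ground-truth record, by construction satisfying: (a) exact woody
#' carbon budget closure `Cwood(t+1) = Cwood(t) + WBgrowth(t) - Cmort(t)`;
#' (b) inside the thinning window, `ln(M) = ln(k) + p * ln(N)` exactly when
#' `noise_sd = 0`; (c) phase-indicative observables (grass share, canopy
#' area, mortality spike, stem-density decline) switch at the scripted phase
#' boundaries. The trajectory is parametric — stem density declines
#' geometrically inside the window, mean mass follows the power law, and
#' fluxes are derived to close the budget — so the embedded truth is exact
#' rather than emergent.
#'
#' Observation noise (`noise_sd > 0`) is multiplicative lognormal and is
#' applied only to observational copies (`nstem`, `CA`, `CAI`, the grass
#' share and the size structure); the conserved pool and flux columns are
#' never perturbed, so the budget check always has a clean pass case.
#' Recruitment carbon is folded into `WBgrowth`.
#'
#' @param config a [sim_config()]
#' @return a list of class `stand_sim` with elements `series`
#'   (`stand_series`), `structure` (`size_structure`) and `truth` (named
#'   list: `p`, `k` (aboveground basis, kgC (stems ha-1)^-p), `k_total`,
#'   `phase_boundaries`, `start_group`, `thinning_window`, and the main
#'   generating parameters)
#' @examples
#' sim <- simulate_stand(sim_config(years = 200))
#' sim$truth$p
#' @export
simulate_stand <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be a sim_config", call. = FALSE)
  }
  set.seed(config$seed)
  Y <- config$years
  t <- 0:(Y - 1L)
  w1 <- config$thinning_window[1]
  w2 <- config$thinning_window[2]
  d <- config$thinning_decline
  a <- config$allometry_a
  b <- config$allometry_b
  p <- config$thinning_exponent
  bg <- config$background_mort

  # stem density: ramp (emergent) or restock, then geometric decline in window
  N_base <- if (config$recruit_mode == "restocking") {
    rep(config$initial_density, Y)
  } else {
    config$initial_density * pmin((t + 1) / config$establishment_yrs, 1)
  }
  steps <- pmin(pmax(t - w1, 0), w2 - w1)
  N <- N_base * (1 - d)^steps

  # mean individual mass: allometric growth before the window, power law after
  dbh_pre <- config$initial_dbh * (1 + config$growth_rate)^t
  M_pre <- a * dbh_pre^b
  k_total <- M_pre[w1 + 1L] / N[w1 + 1L]^p
  M <- ifelse(t < w1, M_pre, k_total * N^p)
  dbh <- (M / a)^(1 / b)

  # pools and budget-closing fluxes, snapped to a binary grid so the budget
  # identity cancels exactly in double arithmetic
  Cwood <- snap_pool(N * M / 1e4)
  Cwood_AG <- config$ag_frac * Cwood
  dying <- c(pmax(N[-Y] - N[-1L], 0), 0)  # density rises only via recruitment
  Cmort <- snap_pool(dying * M / 1e4 + bg * Cwood)
  WBgrowth <- c(diff(Cwood), 0) + Cmort
  WBgrowth[Y] <- Cmort[Y]
  stopifnot(all(WBgrowth >= 0))

  # phase-indicative observables
  grass <- config$initial_grass_frac * exp(-t / config$grass_decay_yr)
  ca_max <- 10500  # 5% margin above the 10,000 m2/ha closure threshold
  CA <- if (config$canopy_closure_yr > 0) {
    ca_max * pmin(t / config$canopy_closure_yr, 1)
  } else {
    rep(ca_max, Y)
  }
  selfthin_rate <- ifelse(t >= w1 & t < w2, 100 * d, 0)

  noisy <- function(x) {
    if (config$noise_sd == 0) x else x * exp(rnorm(Y, 0, config$noise_sd))
  }
  nstem_obs <- noisy(N)
  CA_obs <- noisy(CA)
  grass_obs <- pmin(noisy(grass), 1)

  series <- stand_series(data.frame(
    year = t,
    Cwood = Cwood, Cwood_AG = Cwood_AG,
    Cmort = Cmort, WBgrowth = WBgrowth,
    nstem = nstem_obs, CA = CA_obs, CAI = CA_obs / 1e4,
    cveg_frac_grass = grass_obs, cveg_frac_woody = 1 - grass_obs,
    selfthin_mort_rate = selfthin_rate
  ))

  structure_tab <- build_size_structure(t, nstem_obs, Cwood_AG, dbh, a, b)

  start <- if (config$canopy_closure_yr == 0) {
    "P3"
  } else if (config$initial_grass_frac > config$grass_threshold) {
    "P1"
  } else {
    "P2"
  }
  truth <- list(
    p = p,
    k = config$ag_frac * k_total,
    k_total = k_total,
    phase_boundaries = config$phase_boundaries,
    start_group = start,
    thinning_window = config$thinning_window,
    initial_density = config$initial_density,
    background_mort = bg,
    thinning_decline = d,
    recruit_mode = config$recruit_mode
  )
  out <- list(series = series, structure = structure_tab, truth = truth)
  class(out) <- "stand_sim"
  out
}

# split each year's stems into three dbh cohorts (0.85, 1, 1.2 x mean dbh,
# weights 1/4, 1/2, 1/4) and force the class totals to match the stand
# totals: n2 and c3 are computed as remainders so the sums close
build_size_structure <- function(t, N, Cwood_AG, dbh, a, b) {
  mult <- c(0.85, 1, 1.2)
  n1 <- 0.25 * N
  n3 <- 0.25 * N
  n2 <- N - n1 - n3
  dbh_coh <- outer(dbh, mult)
  m_coh <- a * dbh_coh^b
  w <- cbind(n1, n2, n3) * m_coh / 1e4
  wsum <- rowSums(w)
  scale <- ifelse(wsum > 0, Cwood_AG / wsum, 0)
  c1 <- w[, 1] * scale
  c2 <- w[, 2] * scale
  c3 <- Cwood_AG - c1 - c2
  long <- data.frame(
    year = rep(t, 3L),
    class_label = bin_dbh(as.vector(dbh_coh)),
    nstem_size = c(n1, n2, n3),
    cwood_size = c(c1, c2, c3),
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(cbind(nstem_size, cwood_size) ~ year + class_label,
                          data = long, FUN = sum)
  agg <- agg[order(agg$year, match(agg$class_label, dbh_scheme()$label)), ]
  rownames(agg) <- NULL
  size_structure(agg)
}

#' @export
print.stand_sim <- function(x, ...) {
  cat("<stand_sim>\n")
  cat(sprintf("  truth: p = %g, k(AG) = %.4g, start group %s\n",
              x$truth$p, x$truth$k, x$truth$start_group))
  print(x$series)
  invisible(x)
}

#' Simulate a biomass chronosequence
#'
#' Draws stand ages uniformly over `[0, max_age]` and generates aboveground
#' woody carbon from a saturating (monomolecular) regrowth curve
#' `c_max * (1 - exp(-rate * age))` with multiplicative lognormal noise.
#' Fixture for the age-binned regrowth envelope builder.
#'
#' @param n_sites number of records (>= 1)
#' @param max_age oldest stand age (yr)
#' @param noise_sd relative noise standard deviation
#' @param seed RNG seed; a fixed seed gives a bit-identical table on rerun
#' @param c_max,rate asymptote (kgC m-2) and rate constant (yr-1) of the
#'   regrowth curve
#' @return data frame with columns `age` (yr) and `Cwood_AG` (kgC m-2), one
#'   row per site; the generating curve is kept in `attr(x, "curve")`
#' @examples
#' head(simulate_chronosequence(100, max_age = 220, noise_sd = 0.2, seed = 1))
#' @export
simulate_chronosequence <- function(n_sites, max_age = 220, noise_sd = 0.2,
                                    seed = 1L, c_max = 12, rate = 0.02) {
  if (!is.numeric(n_sites) || n_sites < 1) stop("'n_sites' must be >= 1", call. = FALSE)
  set.seed(seed)
  age <- runif(n_sites, 0, max_age)
  value <- c_max * (1 - exp(-rate * age))
  if (noise_sd > 0) value <- value * exp(rnorm(n_sites, 0, noise_sd))
  out <- data.frame(age = age, Cwood_AG = value)
  attr(out, "curve") <- c(c_max = c_max, rate = rate)
  out
}

#' Simulate a mapped forest plot
#'
#' Places a Poisson number of stems (expectation `density * area`) uniformly
#' at random in a rectangular plot and draws their diameters from a supplied
#' distribution. Fixture for the spatial bootstrap of plot census data.
#'
#' @param density expected stem density (stems ha-1)
#' @param width,height plot dimensions (m)
#' @param dbh_distribution either `NULL` (lognormal, median 20 cm), a single
#'   number (all stems that diameter), or a `function(n)` returning `n`
#'   diameters in cm
#' @param seed RNG seed
#' @param allometry_a,allometry_b allometry for per-stem mass (kgC)
#' @return a list of class `plot_stem_map` with elements `width`, `height`
#'   and `stems` (data frame: `x`, `y` (m), `dbh` (cm), `mass` (kgC))
#' @examples
#' simulate_plot(500, width = 100, height = 100, seed = 1)
#' @export
simulate_plot <- function(density, width, height, dbh_distribution = NULL,
                          seed = 1L, allometry_a = 0.12, allometry_b = 2.4) {
  if (width <= 0 || height <= 0) stop("plot area must be positive", call. = FALSE)
  if (density < 0) stop("'density' must be >= 0", call. = FALSE)
  set.seed(seed)
  area_ha <- width * height / 1e4
  n <- rpois(1L, density * area_ha)
  dbh <- if (is.null(dbh_distribution)) {
    rlnorm(n, log(20), 0.4)
  } else if (is.function(dbh_distribution)) {
    dbh_distribution(n)
  } else if (is.numeric(dbh_distribution) && length(dbh_distribution) == 1L) {
    rep(dbh_distribution, n)
  } else {
    stop("'dbh_distribution' must be NULL, a scalar or a function(n)", call. = FALSE)
  }
  if (length(dbh) != n || any(dbh <= 0)) {
    stop("dbh distribution must return n positive diameters", call. = FALSE)
  }
  stems <- data.frame(
    x = runif(n, 0, width), y = runif(n, 0, height),
    dbh = dbh, mass = allometry_a * dbh^allometry_b
  )
  out <- list(width = width, height = height, stems = stems)
  class(out) <- "plot_stem_map"
  out
}

#' @export
print.plot_stem_map <- function(x, ...) {
  cat(sprintf("<plot_stem_map> %g m x %g m (%.2f ha), %d stems\n",
              x$width, x$height, x$width * x$height / 1e4, nrow(x$stems)))
  invisible(x)
}
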
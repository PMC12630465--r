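#' Simulator configuration
#'
#' Bundles every knob of the synthetic cohort-demography generator, with
#' defaults chosen as a plausible post-disturbance even-aged stand: dense
#' restocked saplings, geometric diameter growth, a scripted self-thinning
#' window after canopy closure, and a grass share that decays away during
#' early recovery. Individual mass follows the allometry
#' `M_ind = a * dbh^b` (kgC per tree, dbh in cm) and within the thinning
#' window mean mass and stem density obey the power law `M = k * N^p`
#' exactly (noise-free), with `k` fixed by continuity at the window start.
#'
#' The three scripted phase boundaries are, in order: end of the open-canopy
#' grass-coexistence phase, onset of closed-canopy self-thinning (canopy
#' closure), and onset of the closed-canopy late-successional phase (end of
#' the thinning window). Supplying `phase_boundaries` derives
#' `canopy_closure_yr`, `thinning_window` and `grass_decay_yr` consistently;
#' any of those given explicitly wins.
#'
#' @param years simulation length (yr)
#' @param seed RNG seed for the observation-noise draws
#' @param allometry_a,allometry_b allometry coefficients of
#'   `M_ind = a * dbh^b` (kgC per tree, dbh in cm)
#' @param growth_rate relative dbh growth per year before thinning
#' @param background_mort background mortality, fraction of `Cwood` per year
#' @param thinning_exponent self-thinning exponent `p` (< 0)
#' @param phase_boundaries scripted years of the three phase transitions
#'   (see Details); the first may be `NA` when no grass phase is scripted
#' @param thinning_window `c(start, end)` years of the self-thinning period;
#'   must not precede canopy closure
#' @param canopy_closure_yr year at which canopy area reaches the closure
#'   threshold (10,000 m2 ha-1); 0 starts the run closed
#' @param grass_decay_yr e-folding time (yr) of the grass share of `C_veg`
#' @param recruit_mode `"restocking"` resets year-0 stem density to
#'   `initial_density` regardless of prior state; `"emergent"` ramps density
#'   up from a low value over `establishment_yrs`
#' @param establishment_yrs length of the emergent-recruitment ramp (yr)
#' @param initial_density stem density at (or ramped to after) year 0
#'   (stems ha-1)
#' @param initial_dbh sapling diameter at year 0 (cm)
#' @param initial_grass_frac grass share of `C_veg` at year 0
#' @param thinning_decline geometric stem-density decline rate per year
#'   inside the thinning window
#' @param ag_frac aboveground fraction of woody carbon (default 0.75, an
#'   exactly binary-representable value so AG pools stay on the budget grid)
#' @param noise_sd relative (lognormal) noise on observational copies
#'   (`nstem`, `CA`, `CAI`, grass share, size structure); conserved pools
#'   and fluxes are never perturbed
#' @return a validated list of class `sim_config`
#' @examples
#' sim_config(years = 200, phase_boundaries = c(12, 48, 130))
#' @export
sim_config <- function(years = 420,
                       seed = 1L,
                       allometry_a = 0.12,
                       allometry_b = 2.4,
                       growth_rate = 0.04,
                       background_mort = 0.01,
                       thinning_exponent = -1.5,
                       phase_boundaries = c(12, 48, 130),
                       thinning_window = NULL,
                       canopy_closure_yr = NULL,
                       grass_decay_yr = NULL,
                       recruit_mode = c("restocking", "emergent"),
                       establishment_yrs = 10,
                       initial_density = 3000,
                       initial_dbh = 2,
                       initial_grass_frac = 0.6,
                       thinning_decline = 0.03,
                       ag_frac = 0.75,
                       noise_sd = 0) {
  recruit_mode <- match.arg(recruit_mode)
  stopifnot_scalar(years, "years", positive = TRUE)
  stopifnot_scalar(allometry_a, "allometry_a", positive = TRUE)
  stopifnot_scalar(allometry_b, "allometry_b", positive = TRUE)
  stopifnot_scalar(growth_rate, "growth_rate", positive = TRUE)
  stopifnot_scalar(thinning_exponent, "thinning_exponent")
  if (thinning_exponent >= 0) stop("'thinning_exponent' must be negative", call. = FALSE)
  for (f in c("background_mort", "initial_grass_frac", "noise_sd")) {
    v <- get(f)
    stopifnot_scalar(v, f)
    if (v < 0 || v > 1) stop(sprintf("'%s' must lie in [0, 1]", f), call. = FALSE)
  }
  if (thinning_decline <= 0 || thinning_decline >= 1) {
    stop("'thinning_decline' must lie in (0, 1)", call. = FALSE)
  }
  if (ag_frac <= 0 || ag_frac > 1) stop("'ag_frac' must lie in (0, 1]", call. = FALSE)
  stopifnot_scalar(initial_density, "initial_density", positive = TRUE)
  stopifnot_scalar(initial_dbh, "initial_dbh", positive = TRUE)

  grass_threshold <- 0.10  # share at which the grass phase is scripted to end

  if (is.null(canopy_closure_yr)) canopy_closure_yr <- phase_boundaries[2]
  if (is.null(thinning_window)) {
    thinning_window <- c(phase_boundaries[2], phase_boundaries[3])
  }
  if (is.null(grass_decay_yr)) {
    if (initial_grass_frac > grass_threshold && !is.na(phase_boundaries[1])) {
      grass_decay_yr <- phase_boundaries[1] / log(initial_grass_frac / grass_threshold)
    } else {
      grass_decay_yr <- 10
    }
  }
  stopifnot_scalar(canopy_closure_yr, "canopy_closure_yr")
  stopifnot_scalar(grass_decay_yr, "grass_decay_yr", positive = TRUE)
  if (canopy_closure_yr < 0) stop("'canopy_closure_yr' must be >= 0", call. = FALSE)
  if (length(thinning_window) != 2L || any(!is.finite(thinning_window))) {
    stop("'thinning_window' must be two finite years", call. = FALSE)
  }
  if (thinning_window[1] > thinning_window[2]) {
    stop("'thinning_window' start exceeds its end", call. = FALSE)
  }
  if (thinning_window[1] < 0 || thinning_window[2] > years - 1) {
    stop("'thinning_window' must lie within [0, years)", call. = FALSE)
  }
  if (thinning_window[1] < canopy_closure_yr) {
    stop("thinning window precedes canopy closure: self-thinning requires a closed canopy",
         call. = FALSE)
  }
  if (recruit_mode == "emergent" && establishment_yrs > thinning_window[1]) {
    stop("'establishment_yrs' must not extend into the thinning window", call. = FALSE)
  }

  b1 <- if (initial_grass_frac > grass_threshold) {
    min(grass_decay_yr * log(initial_grass_frac / grass_threshold), canopy_closure_yr)
  } else NA_real_
  cfg <- list(
    years = as.integer(years), seed = as.integer(seed),
    allometry_a = allometry_a, allometry_b = allometry_b,
    growth_rate = growth_rate, background_mort = background_mort,
    thinning_exponent = thinning_exponent,
    thinning_window = as.numeric(thinning_window),
    canopy_closure_yr = as.numeric(canopy_closure_yr),
    grass_decay_yr = grass_decay_yr,
    grass_threshold = grass_threshold,
    recruit_mode = recruit_mode, establishment_yrs = establishment_yrs,
    initial_density = initial_density, initial_dbh = initial_dbh,
    initial_grass_frac = initial_grass_frac,
    thinning_decline = thinning_decline, ag_frac = ag_frac,
    noise_sd = noise_sd,
    phase_boundaries = c(grass_end = b1,
                         thinning_onset = thinning_window[1],
                         late_onset = thinning_window[2])
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d yr, seed %d, recruit mode '%s', noise_sd %g\n",
              x$years, x$seed, x$recruit_mode, x$noise_sd))
  cat(sprintf("  allometry M = %g * dbh^%g kgC; growth %g yr-1; background mort %g yr-1\n",
              x$allometry_a, x$allometry_b, x$growth_rate, x$background_mort))
  cat(sprintf("  thinning: p = %g, window [%g, %g], decline %g yr-1\n",
              x$thinning_exponent, x$thinning_window[1], x$thinning_window[2],
              x$thinning_decline))
  cat(sprintf("  phases: grass end %s, closure %g, late onset %g\n",
              format(x$phase_boundaries[["grass_end"]]),
              x$canopy_closure_yr, x$phase_boundaries[["late_onset"]]))
  invisible(x)
}
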
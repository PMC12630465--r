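phase_levels <- c("open_grass", "open_growth", "closed_thinning", "closed_late")

#' Phase-classification configuration
#'
#' Numeric thresholds for the rule-based forest recovery-phase classifier.
#' The canopy-closure value (10,000 m2 ha-1) is the one threshold anchored
#' in the characterisation framework; the others are documented defaults.
#'
#' @param grass_frac_min grass share of `C_veg` below which the
#'   grass-coexistence phase ends
#' @param ca_closure canopy area marking closure (m2 ha-1)
#' @param mort_spike_factor a mortality spike is `cmort_rate >=
#'   mort_spike_factor` times the equilibrium-tail mean; re-entry into
#'   `+/- (mort_spike_factor - 1)` of that mean marks late succession
#' @param equilibrium_tail number of final years defining the equilibrium
#'   reference state (computed before classification)
#' @param smooth_k window (yr) of the centred running mean applied to
#'   `nstem`, `CA` and the grass share before thresholding, as a guard
#'   against interannual observation noise
#' @param decline_tol relative drop of smoothed `nstem` over two years that
#'   counts as "steeply declining"
#' @param flat_tol relative change of smoothed `nstem` over two years below
#'   which the decline counts as flattened
#' @return a list of class `phase_config`
#' @export
phase_config <- function(grass_frac_min = 0.10, ca_closure = 10000,
                         mort_spike_factor = 1.5, equilibrium_tail = 100L,
                         smooth_k = 3L, decline_tol = 0.02, flat_tol = 0.06) {
  stopifnot(grass_frac_min > 0, grass_frac_min < 1, ca_closure > 0,
            mort_spike_factor > 1, equilibrium_tail > 0)
  out <- list(grass_frac_min = grass_frac_min, ca_closure = ca_closure,
              mort_spike_factor = mort_spike_factor,
              equilibrium_tail = as.integer(equilibrium_tail),
              smooth_k = as.integer(smooth_k),
              decline_tol = decline_tol, flat_tol = flat_tol)
  class(out) <- "phase_config"
  out
}

#' Classify forest recovery phases
#'
#' Labels every year of a regrowing stand with one of four recovery phases,
#' in their canonical order: `open_grass` (open canopy with a substantial
#' grass share and little tree-tree competition), `open_growth` (canopy area
#' rising rapidly, grasses marginal), `closed_thinning` (canopy closed, a
#' mortality-rate spike and a steep stem-density decline), and `closed_late`
#' (mortality back near its equilibrium level, density decline flattened).
#'
#' The classifier is a sequential state machine over the per-year rules, so
#' the monotone phase order is enforced by construction — canopy closure
#' alone does not trigger the thinning label (growth may continue under a
#' closed canopy until the mortality spike appears), and the
#' late-successional label can only follow a thinning or mature state. The
#' equilibrium reference is the mean mortality rate over the final
#' `equilibrium_tail` years, computed before classification. A run that is
#' already closed, density-stable and at its equilibrium mortality rate from
#' the first year is labelled `closed_late` throughout (a mature forest, no
#' recovery trajectory).
#'
#' A missing grass share starts the classification at `open_growth` with a
#' logged caveat; a series with neither `CA` nor `CAI` is an error.
#'
#' @param series a `stand_series` with `nstem` and `CA` (or `CAI`)
#' @param rates a `rate_series` for the same years; computed from `series`
#'   when `NULL`
#' @param config a [phase_config()]
#' @return a data frame of class `phase_timeline` with columns `year`,
#'   `label` (factor with the four ordered levels); attributes `boundaries`
#'   (named onset years, `NA` where a phase is absent) and `tail_mean`
#' @examples
#' sim <- simulate_stand(sim_config(years = 300))
#' tl <- classify_phases(sim$series)
#' attr(tl, "boundaries")
#' @export
classify_phases <- function(series, rates = NULL, config = phase_config()) {
  stopifnot(is.data.frame(series))
  if (is.null(rates)) rates <- mortality_rate(series)
  if (!identical(series$year, rates$year)) {
    stop("'series' and 'rates' must share the same time axis", call. = FALSE)
  }
  n <- nrow(series)
  CA <- series$CA
  if (is.null(CA)) {
    if (is.null(series$CAI)) {
      stop("phase classification needs 'CA' or 'CAI'", call. = FALSE)
    }
    CA <- series$CAI * 1e4
  }
  if (is.null(series$nstem)) {
    stop("phase classification needs 'nstem'", call. = FALSE)
  }
  grass <- series$cveg_frac_grass
  if (is.null(grass)) {
    sb_log("warn", "no grass share in series: classification starts at open_growth")
  }

  k <- config$smooth_k
  CA_s <- smooth_centered(CA, k)
  ns_s <- smooth_centered(series$nstem, k)
  grass_s <- if (!is.null(grass)) smooth_centered(grass, k) else NULL
  rate <- rates$cmort_rate

  tail_n <- min(config$equilibrium_tail, n)
  tail_vals <- rate[(n - tail_n + 1L):n]
  tail_mean <- mean(tail_vals[is.finite(tail_vals)])

  idx2 <- pmin(seq_len(n) + 2L, n)
  rel2 <- (ns_s[idx2] - ns_s) / ifelse(ns_s > 0, ns_s, 1)
  declining <- rel2 < -config$decline_tol
  flat <- abs(rel2) < config$flat_tol

  closed <- CA_s >= config$ca_closure
  spike_thr <- config$mort_spike_factor * tail_mean
  spike <- if (is.finite(spike_thr) && spike_thr > 0) {
    rate >= spike_thr
  } else {
    rate > 0
  }
  spike[!is.finite(rate)] <- FALSE
  band <- is.finite(rate) &
    abs(rate - tail_mean) <= (config$mort_spike_factor - 1) * tail_mean

  state <- integer(n)
  thinning_cond <- closed & declining & spike
  late_cond <- band & flat
  # initial state
  s <- if (closed[1]) {
    if (thinning_cond[1]) 3L else if (late_cond[1] && !declining[1]) 4L else 2L
  } else if (!is.null(grass_s) && grass_s[1] >= config$grass_frac_min) {
    1L
  } else {
    2L
  }
  state[1] <- s
  for (i in seq_len(n)[-1]) {
    repeat {
      advanced <- FALSE
      if (s == 1L && (closed[i] ||
                      is.null(grass_s) || grass_s[i] < config$grass_frac_min)) {
        s <- 2L; advanced <- TRUE
      } else if (s == 2L && thinning_cond[i]) {
        s <- 3L; advanced <- TRUE
      } else if (s == 3L && late_cond[i]) {
        s <- 4L; advanced <- TRUE
      }
      if (!advanced) break
    }
    state[i] <- s
  }

  label <- factor(phase_levels[state], levels = phase_levels)
  boundaries <- vapply(seq_along(phase_levels), function(ph) {
    hit <- which(state == ph)
    if (length(hit)) series$year[hit[1]] else NA_real_
  }, numeric(1))
  names(boundaries) <- phase_levels
  out <- data.frame(year = series$year, label = label)
  attr(out, "boundaries") <- boundaries
  attr(out, "tail_mean") <- tail_mean
  class(out) <- c("phase_timeline", "data.frame")
  out
}

#' @export
print.phase_timeline <- function(x, ...) {
  b <- attr(x, "boundaries")
  cat("<phase_timeline>\n")
  for (ph in phase_levels) {
    nyr <- sum(x$label == ph)
    cat(sprintf("  %-16s onset %6s  (%d yr)\n", ph, format(b[[ph]]), nyr))
  }
  invisible(x)
}

#' Start group of a recovery trajectory
#'
#' Maps the first phase label of a timeline onto the three starting
#' behaviours seen across demographic models: `P1` for runs initialised in
#' the open-canopy grass-coexistence phase (mortality starts near zero),
#' `P2` for runs initialised in the open-canopy growth phase (mortality
#' starts from higher values), and `P3` for runs initialised directly in
#' closed-canopy self-thinning (mortality immediately active, e.g. a model
#' restocked at high density). A timeline that starts late-successional has
#' no recovery trajectory and is an error.
#'
#' @param timeline a `phase_timeline`
#' @return `"P1"`, `"P2"` or `"P3"`
#' @export
start_group <- function(timeline) {
  stopifnot(inherits(timeline, "phase_timeline"))
  first <- as.character(timeline$label[1])
  switch(first,
         open_grass = "P1",
         open_growth = "P2",
         closed_thinning = "P3",
         stop("no recovery trajectory present: series starts late-successional",
              call. = FALSE))
}

#' Align series on a common phase onset
#'
#' Time-shifts a set of runs so that the onset of a chosen anchor phase
#' falls at year 0 in each, enabling like-for-like comparison of growth and
#' mortality dynamics across models that start their recovery in different
#' phases. Runs whose timeline lacks the anchor phase are excluded with a
#' log entry.
#'
#' @param timelines named list of `phase_timeline`s
#' @param data named list (same names) of annual data frames with a `year`
#'   column, e.g. `rate_series`
#' @param anchor one of `"open_grass"`, `"open_growth"`,
#'   `"closed_thinning"`, `"closed_late"`
#' @return a stacked data frame with columns `id`, `year_aligned`, and the
#'   data columns; the per-run shifts (the anchor onsets) are in
#'   `attr(x, "shifts")`
#' @export
align_on_phase <- function(timelines, data, anchor = "closed_thinning") {
  anchor <- match.arg(anchor, phase_levels)
  stopifnot(is.list(timelines), is.list(data),
            length(timelines) == length(data))
  ids <- names(timelines) %||% as.character(seq_along(timelines))
  pieces <- list()
  shifts <- setNames(rep(NA_real_, length(ids)), ids)
  for (i in seq_along(ids)) {
    onset <- attr(timelines[[i]], "boundaries")[[anchor]]
    if (is.na(onset)) {
      sb_log("info", "series '", ids[i], "' lacks phase '", anchor,
             "': excluded from alignment")
      next
    }
    shifts[ids[i]] <- onset
    df <- as.data.frame(data[[i]])
    df$year_aligned <- df$year - onset
    df$year <- NULL
    df <- cbind(id = ids[i], df[, c("year_aligned",
                                    setdiff(names(df), "year_aligned"))])
    pieces[[ids[i]]] <- df
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(id = character(0), year_aligned = numeric(0))
  rownames(out) <- NULL
  attr(out, "shifts") <- shifts
  attr(out, "anchor") <- anchor
  out
}
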
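`%||%` <- function(x, y) if (is.null(x)) y else x

#' Package logging
#'
#' Lightweight leveled logging used throughout the pipeline. Messages go to
#' the R message stream and, when `options(standbench.log_file=)` is set, are
#' appended to that file. `options(standbench.log_level=)` ("debug", "info",
#' "warn") filters verbosity; the default is "info".
#'
#' @param level one of "debug", "info", "warn"
#' @param ... message fragments pasted together
#' @return invisibly `NULL`
#' @keywords internal
sb_log <- function(level = c("info", "warn", "debug"), ...) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L)
  threshold <- getOption("standbench.log_level", "info")
  if (!threshold %in% names(ranks)) threshold <- "info"
  if (ranks[[level]] < ranks[[threshold]]) return(invisible(NULL))
  msg <- paste0("[", toupper(level), "] ", paste0(..., collapse = ""))
  file <- getOption("standbench.log_file", NULL)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  message(msg)
  invisible(NULL)
}

# centred running mean with shrinking edge windows; used by the phase
# classifier as a light guard against interannual observation noise
smooth_centered <- function(x, k = 3L) {
  half <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# snap values to a binary grid (multiples of 2^-30 kgC m-2) so that annual
# stock differences and flux sums are exact in double arithmetic and the
# budget identity closes with a residual of exactly zero
snap_pool <- function(x, grid = 2^-30) round(x / grid) * grid

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}
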
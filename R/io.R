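# Column-oriented table dialect for stand-level demographic output:
# UTF-8, comma-separated, one header row, '#'-prefixed metadata lines.
# Units are fixed in storage: pools kgC m-2, fluxes kgC m-2 yr-1, stem
# density stems ha-1, canopy area m2 ha-1; the ha<->m2 factor 1e4 is applied
# only inside computations that mix bases, never in files.

.series_units <- c(
  year = "yr", Cwood = "kgC m-2", Cwood_AG = "kgC m-2",
  Cmort = "kgC m-2 yr-1", WBgrowth = "kgC m-2 yr-1",
  nstem = "stems ha-1", CA = "m2 ha-1", CAI = "-",
  selfthin_mort_rate = "% yr-1"
)

.series_required <- c("year", "Cwood", "Cmort", "WBgrowth")
.series_optional <- c("Cwood_AG", "nstem", "CA", "CAI", "selfthin_mort_rate")

#' Construct and validate an annual stand series
#'
#' A stand series is one model (or simulator) run at one site: annual woody
#' carbon pools and fluxes plus stand-structure observables. Required
#' columns: `year`, `Cwood`, `Cmort`, `WBgrowth`. Recognised optional
#' columns: `Cwood_AG`, `nstem`, `CA`, `CAI`, `selfthin_mort_rate` and any
#' number of per-PFT vegetation-carbon shares named `cveg_frac_<pft>`.
#'
#' Validation enforces a strictly increasing annual time axis, non-negative
#' pools, per-PFT share sums at most 1 (+ tolerance) and `Cwood_AG <= Cwood`.
#' Negative fluxes are not silently fixed: they raise a warning, are clamped
#' to zero, and the original values are kept in `attr(x, "clamped")`.
#'
#' @param df a data frame with the columns above
#' @return the validated data frame with class `stand_series`; missing
#'   optional columns are listed in `attr(x, "absent")`
#' @export
stand_series <- function(df) {
  stopifnot(is.data.frame(df))
  missing_req <- setdiff(.series_required, names(df))
  if (length(missing_req)) {
    stop("required column(s) missing: ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  }
  yr <- df$year
  if (anyDuplicated(yr)) stop("duplicated years in time axis", call. = FALSE)
  if (length(yr) > 1 && any(diff(yr) != 1)) {
    stop("non-annual time axis: years must increase in steps of 1",
         call. = FALSE)
  }
  for (pool in intersect(c("Cwood", "Cwood_AG"), names(df))) {
    if (any(df[[pool]] < 0, na.rm = TRUE)) {
      stop("negative pool values in '", pool, "'", call. = FALSE)
    }
  }
  clamped <- NULL
  for (flux in intersect(c("Cmort", "WBgrowth"), names(df))) {
    bad <- which(df[[flux]] < 0)
    if (length(bad)) {
      clamped <- rbind(clamped, data.frame(column = flux, year = yr[bad],
                                           value = df[[flux]][bad]))
      warning(sprintf("%d negative value(s) in flux '%s' clamped to 0 (originals kept in attr 'clamped')",
                      length(bad), flux), call. = FALSE)
      df[[flux]][bad] <- 0
    }
  }
  frac_cols <- grep("^cveg_frac_", names(df), value = TRUE)
  if (length(frac_cols)) {
    tot <- rowSums(as.data.frame(df[frac_cols]))
    if (any(tot > 1 + 1e-6, na.rm = TRUE)) {
      stop("per-PFT cveg_frac shares sum to more than 1", call. = FALSE)
    }
    if (any(unlist(df[frac_cols]) < 0, na.rm = TRUE)) {
      stop("negative cveg_frac share", call. = FALSE)
    }
  }
  if (all(c("Cwood", "Cwood_AG") %in% names(df))) {
    if (any(df$Cwood_AG > df$Cwood * (1 + 1e-9) + 1e-12)) {
      stop("Cwood_AG exceeds Cwood", call. = FALSE)
    }
  }
  absent <- setdiff(.series_optional, names(df))
  if (!length(frac_cols)) absent <- c(absent, "cveg_frac")
  attr(df, "absent") <- absent
  attr(df, "clamped") <- clamped
  class(df) <- unique(c("stand_series", class(df)))
  df
}

#' @export
print.stand_series <- function(x, ...) {
  cat(sprintf("<stand_series> %d yr (%d..%d), %d variables\n",
              nrow(x), min(x$year), max(x$year), ncol(x) - 1L))
  absent <- attr(x, "absent")
  if (length(absent)) cat("  absent optional: ", paste(absent, collapse = ", "), "\n", sep = "")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... ", nrow(x) - 4L, " more years\n", sep = "")
  invisible(x)
}

#' Construct and validate a size-structure table
#'
#' Long table of stems and aboveground woody carbon per dbh class and year.
#' Columns: `year`, `class_label` (from [dbh_scheme()]), `nstem_size`
#' (stems ha-1), `cwood_size` (kgC m-2).
#'
#' @param df a data frame with the columns above
#' @return the validated data frame with class `size_structure`
#' @export
size_structure <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("year", "class_label", "nstem_size", "cwood_size")
  missing_req <- setdiff(need, names(df))
  if (length(missing_req)) {
    stop("required column(s) missing: ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  }
  scheme <- dbh_scheme()
  bad <- setdiff(unique(df$class_label), scheme$label)
  if (length(bad)) {
    stop("unknown dbh class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$nstem_size < 0) || any(df$cwood_size < 0)) {
    stop("size-structure values must be non-negative", call. = FALSE)
  }
  class(df) <- unique(c("size_structure", class(df)))
  df
}

fmt_table_lines <- function(df, kind, units = NULL) {
  lines <- c(sprintf("# standbench %s v1", kind))
  if (!is.null(units)) {
    u <- units[intersect(names(df), names(units))]
    lines <- c(lines, paste0("# units: ",
                             paste(sprintf("%s=%s", names(u), unname(u)), collapse = "; ")))
  }
  fmt_col <- function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else paste0('"', as.character(x), '"')
  }
  body <- do.call(paste, c(lapply(df, fmt_col), sep = ","))
  c(lines, paste(names(df), collapse = ","), body)
}

read_dialect <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  read.csv(text = paste(lines, collapse = "\n"), stringsAsFactors = FALSE)
}

#' Read and write stand series files
#'
#' The write/read round trip is lossless: numeric values are stored with 17
#' significant digits. [read_stand_series()] runs the full [stand_series()]
#' validation, so a non-annual or duplicated time axis and negative pools are
#' hard errors, while negative fluxes warn and are clamped with the originals
#' recorded. Missing optional columns are flagged in `attr(x, "absent")`.
#'
#' @param series a `stand_series`
#' @param path file path
#' @return `read_stand_series()` returns a `stand_series`;
#'   `write_stand_series()` returns `path` invisibly.
#' @export
write_stand_series <- function(series, path) {
  writeLines(fmt_table_lines(as.data.frame(series), "stand-series", .series_units),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_stand_series
#' @export
read_stand_series <- function(path) {
  stand_series(read_dialect(path))
}

#' Read and write size-structure files
#'
#' @param structure a `size_structure`
#' @param path file path
#' @return `read_size_structure()` returns a `size_structure`;
#'   `write_size_structure()` returns `path` invisibly.
#' @export
write_size_structure <- function(structure, path) {
  units <- c(year = "yr", class_label = "dbh class",
             nstem_size = "stems ha-1", cwood_size = "kgC m-2")
  writeLines(fmt_table_lines(as.data.frame(structure), "size-structure", units),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_size_structure
#' @export
read_size_structure <- function(path) {
  size_structure(read_dialect(path))
}

#' Read and write ground-truth sidecar files
#'
#' Simulator ground truth (thinning exponent and intercept, scripted phase
#' boundaries, start group, ...) travels beside the series as a plain-text
#' `key: value` file.
#'
#' @param truth a named list of scalars or short vectors
#' @param path file path
#' @return `read_ground_truth()` returns a named list; numeric-looking values
#'   are parsed as numeric. `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  fmt <- function(v) {
    if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = " ")
    else paste(as.character(v), collapse = " ")
  }
  writeLines(vapply(names(truth), function(k) paste0(k, ": ", fmt(truth[[k]])),
                    character(1)), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    key <- sub(":.*$", "", ln)
    val <- strsplit(trimws(sub("^[^:]*:", "", ln)), " +")[[1]]
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Read a simulator configuration from a YAML file
#'
#' Keys map one-to-one onto the arguments of [sim_config()].
#'
#' @param path YAML file path
#' @return a validated `sim_config`
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain a key-value mapping", call. = FALSE)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, vals)
}
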
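new_envelope <- function(df, axis, provenance) {
  stopifnot(all(c("cell", "median", "low", "high", "n") %in% names(df)))
  if (any(df$low > df$median + 1e-12) || any(df$median > df$high + 1e-12)) {
    stop("envelope ordering violated: need low <= median <= high", call. = FALSE)
  }
  rownames(df) <- NULL
  attr(df, "axis") <- axis
  attr(df, "provenance") <- provenance
  class(df) <- c("benchmark_envelope", "data.frame")
  df
}

#' @export
print.benchmark_envelope <- function(x, ...) {
  cat(sprintf("<benchmark_envelope> axis '%s', %s, %d cell(s)\n",
              attr(x, "axis"), attr(x, "provenance"), nrow(x)))
  print(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

age_bin_label <- function(lower, width) sprintf("[%g,%g)", lower, lower + width)

#' Chronosequence regrowth envelope
#'
#' Organises chronosequence records (stand age, aboveground woody carbon)
#' into half-open age bins (`[0,20)`, `[20,40)`, ... by default) and reports
#' the median and the 10th/90th percentile boundaries per bin (type-7
#' quantiles). Bins with fewer than `min_n` observations (default 20) are
#' dropped.
#'
#' @param records data frame with columns `age` (yr) and a value column
#'   (default `Cwood_AG`, kgC m-2)
#' @param width age-bin width (yr)
#' @param min_n minimum observations a bin needs to be retained
#' @param value name of the value column
#' @return a `benchmark_envelope` with one row per retained age bin: `cell`
#'   (bin label), `lower` (bin lower edge), `median`, `low`, `high`, `n`
#' @examples
#' chron <- simulate_chronosequence(500, max_age = 220, noise_sd = 0.2, seed = 1)
#' bin_chronosequence(chron)
#' @export
bin_chronosequence <- function(records, width = 20, min_n = 20L,
                               value = "Cwood_AG") {
  stopifnot(is.data.frame(records), "age" %in% names(records),
            value %in% names(records))
  if (nrow(records) == 0L) stop("'records' is empty", call. = FALSE)
  lower <- floor(records$age / width) * width
  groups <- split(records[[value]], lower)
  rows <- lapply(names(groups), function(g) {
    vals <- groups[[g]]
    if (length(vals) < min_n) return(NULL)
    q <- quantile(vals, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
    data.frame(cell = age_bin_label(as.numeric(g), width),
               lower = as.numeric(g),
               median = q[2], low = q[1], high = q[3], n = length(vals))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no age bin reaches the minimum occupancy; empty envelope",
            call. = FALSE)
    return(new_envelope(data.frame(cell = character(0), lower = numeric(0),
                                   median = numeric(0), low = numeric(0),
                                   high = numeric(0), n = integer(0)),
                        "age_bin", "percentile(10,90)"))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$lower), ]
  new_envelope(out, "age_bin", "percentile(10,90)")
}

#' Spatial bootstrap envelope of a mapped plot
#'
#' Places `n_boot` square subplots (default 6.25 ha) uniformly at random,
#' fully contained inside a mapped plot, and summarises per-subplot stem
#' density and aboveground woody carbon — per dbh class and in total — as
#' the bootstrap median with a central confidence interval (default 95%).
#'
#' @param map a [simulate_plot()]-style `plot_stem_map`
#' @param subplot_area subplot area (ha); must not exceed the plot
#' @param n_boot number of bootstrap placements
#' @param ci central confidence level (%)
#' @param seed RNG seed; a fixed seed gives an identical envelope on rerun
#' @return a `benchmark_envelope` with one row per variable
#'   (`nstem_size` in stems ha-1, `cwood_size` in kgC m-2) and cell (dbh
#'   class label or `"total"`)
#' @examples
#' plot <- simulate_plot(500, width = 1000, height = 500, seed = 1)
#' bootstrap_plot(plot, n_boot = 50, seed = 1)
#' @export
bootstrap_plot <- function(map, subplot_area = 6.25, n_boot = 1000L,
                           ci = 95, seed = 1L) {
  stopifnot(inherits(map, "plot_stem_map"))
  side <- sqrt(subplot_area * 1e4)
  if (side > map$width || side > map$height) {
    stop("subplot larger than the plot", call. = FALSE)
  }
  set.seed(seed)
  scheme <- dbh_scheme()
  labels <- c(scheme$label, "total")
  stems <- map$stems
  cls <- if (nrow(stems)) bin_dbh(stems$dbh, scheme) else character(0)
  cls_idx <- match(cls, scheme$label)
  nstem_mat <- matrix(0, n_boot, length(labels),
                      dimnames = list(NULL, labels))
  cwood_mat <- nstem_mat
  for (bidx in seq_len(n_boot)) {
    x0 <- runif(1, 0, map$width - side)
    y0 <- runif(1, 0, map$height - side)
    inside <- stems$x >= x0 & stems$x < x0 + side &
      stems$y >= y0 & stems$y < y0 + side
    if (any(inside)) {
      cnt <- tabulate(cls_idx[inside], nbins = nrow(scheme))
      mass <- vapply(seq_len(nrow(scheme)), function(ic) {
        sum(stems$mass[inside][cls_idx[inside] == ic])
      }, numeric(1))
      nstem_mat[bidx, ] <- c(cnt, sum(cnt)) / subplot_area
      cwood_mat[bidx, ] <- c(mass, sum(mass)) / (subplot_area * 1e4)
    }
  }
  alpha <- (100 - ci) / 200
  summarise <- function(mat, varname) {
    q <- apply(mat, 2, quantile, probs = c(alpha, 0.5, 1 - alpha),
               type = 7, names = FALSE)
    data.frame(variable = varname, cell = colnames(mat),
               median = q[2, ], low = q[1, ], high = q[3, ], n = n_boot)
  }
  out <- rbind(summarise(nstem_mat, "nstem_size"),
               summarise(cwood_mat, "cwood_size"))
  new_envelope(out, "dbh_class", sprintf("bootstrap CI(%g)", ci))
}

#' Min-max envelope across plots
#'
#' For a small number of census plots, the observational range per cell is
#' simply the median with the minimum and maximum across plots.
#'
#' @param values data frame with columns `plot`, `cell`, `value` (and
#'   optionally `variable`)
#' @return a `benchmark_envelope` with one row per (variable,) cell
#' @examples
#' vals <- expand.grid(plot = 1:5, cell = c("<20", "<30"))
#' vals$value <- runif(nrow(vals), 100, 300)
#' minmax_envelope(vals)
#' @export
minmax_envelope <- function(values) {
  stopifnot(is.data.frame(values),
            all(c("plot", "cell", "value") %in% names(values)))
  if (nrow(values) == 0L) stop("'values' is empty", call. = FALSE)
  keyvars <- intersect(c("variable", "cell"), names(values))
  key <- interaction(values[keyvars], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(kk) {
    sub <- values[key == kk, , drop = FALSE]
    data.frame(sub[1, keyvars, drop = FALSE],
               median = median(sub$value), low = min(sub$value),
               high = max(sub$value), n = nrow(sub))
  })
  out <- do.call(rbind, rows)
  new_envelope(out, "dbh_class", "min-max")
}

#' Map model output onto chronosequence age bins
#'
#' Averages annual model values of a variable within each age bin of a
#' regrowth envelope, producing the model-side cells that [score()]
#' compares against the observational envelope. Stand age is years since
#' the start of the series.
#'
#' @param series a `stand_series`
#' @param width age-bin width (yr), matching the envelope
#' @param value variable to average (default `Cwood_AG`)
#' @return data frame with columns `cell` and `value`
#' @export
series_to_age_cells <- function(series, width = 20, value = "Cwood_AG") {
  stopifnot(is.data.frame(series), value %in% names(series))
  age <- series$year - series$year[1]
  lower <- floor(age / width) * width
  means <- tapply(series[[value]], lower, mean)
  data.frame(cell = age_bin_label(as.numeric(names(means)), width),
             value = as.numeric(means))
}

#' Score model output against an observation envelope
#'
#' Classifies each model cell as `inside`, `below` or `above` the envelope
#' (bounds inclusive) and reports the signed distance to the nearest bound:
#' negative below the envelope, positive above it, and the (non-negative)
#' distance to the nearer bound when inside. The attribute `summary` gives
#' the fraction of cells in each category, per variable; the three fractions
#' sum to 1.
#'
#' @param model data frame with columns `cell` and `value` (and optionally
#'   `variable`), e.g. from [series_to_age_cells()]
#' @param envelope a `benchmark_envelope`
#' @return a data frame of class `score_card` with columns (`variable`,)
#'   `cell`, `value`, `low`, `median`, `high`, `status`, `distance`
#' @export
score <- function(model, envelope) {
  stopifnot(is.data.frame(model), inherits(envelope, "benchmark_envelope"),
            all(c("cell", "value") %in% names(model)))
  env <- as.data.frame(envelope)
  by <- intersect(intersect(c("variable", "cell"), names(model)), names(env))
  merged <- merge(model, env[, c(by, "low", "median", "high")], by = by)
  if (nrow(merged) == 0L) {
    stop("model cells and envelope cells are disjoint", call. = FALSE)
  }
  status <- ifelse(merged$value < merged$low, "below",
                   ifelse(merged$value > merged$high, "above", "inside"))
  distance <- ifelse(status == "below", merged$value - merged$low,
                     ifelse(status == "above", merged$value - merged$high,
                            pmin(merged$value - merged$low,
                                 merged$high - merged$value)))
  merged$status <- status
  merged$distance <- distance
  split_by <- if ("variable" %in% names(merged)) merged$variable else
    rep("value", nrow(merged))
  summary <- do.call(rbind, lapply(split(merged$status, split_by), function(s) {
    data.frame(inside = mean(s == "inside"), below = mean(s == "below"),
               above = mean(s == "above"))
  }))
  attr(merged, "summary") <- summary
  class(merged) <- c("score_card", "data.frame")
  merged
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> %d cell(s)\n", nrow(x)))
  print(attr(x, "summary"))
  invisible(x)
}

#' Read and write envelope files
#'
#' Envelopes are stored in the package table dialect with their axis and
#' provenance recorded in metadata lines.
#'
#' @param envelope a `benchmark_envelope`
#' @param path file path
#' @return `read_envelope()` returns a `benchmark_envelope`;
#'   `write_envelope()` returns `path` invisibly.
#' @export
write_envelope <- function(envelope, path) {
  lines <- c("# standbench envelope v1",
             paste0("# axis: ", attr(envelope, "axis")),
             paste0("# provenance: ", attr(envelope, "provenance")))
  fmt_col <- function(x) if (is.numeric(x)) sprintf("%.17g", x) else paste0('"', as.character(x), '"')
  df <- as.data.frame(envelope)
  body <- do.call(paste, c(lapply(df, fmt_col), sep = ","))
  writeLines(c(lines, paste(names(df), collapse = ","), body), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, encoding = "UTF-8")
  meta <- raw[grepl("^#", raw)]
  pick <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1]) else "unknown"
  }
  df <- read.csv(text = paste(raw[!grepl("^#", raw)], collapse = "\n"),
                 stringsAsFactors = FALSE)
  new_envelope(df, pick("axis"), pick("provenance"))
}
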
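#' Fixed dbh-class binning scheme
#'
#' The size-structure tables use a fixed set of 16 diameter-at-breast-height
#' classes with upper edges at 1, 5, 10, 15, 20, 30, 40, 50, 60, 70, 80, 90,
#' 100, 150 and 200 cm plus an open top class. Intervals are half-open
#' `[lower, upper)`, so a printed label `"<X"` is literal and the top class
#' `">=200"` is closed below.
#'
#' @return a data frame with columns `label`, `lower`, `upper` (cm), one row
#'   per class, ordered by size; class `dbh_scheme`.
#' @examples
#' dbh_scheme()
#' @export
dbh_scheme <- function() {
  upper <- c(1, 5, 10, 15, 20, 30, 40, 50, 60, 70, 80, 90, 100, 150, 200, Inf)
  lower <- c(0, upper[-length(upper)])
  label <- c(paste0("<", upper[-length(upper)]), ">=200")
  out <- data.frame(label = label, lower = lower, upper = upper,
                    stringsAsFactors = FALSE)
  class(out) <- c("dbh_scheme", "data.frame")
  out
}

#' Assign diameters to dbh classes
#'
#' Maps each diameter to its class label under the half-open convention: a
#' diameter of exactly 100 cm falls in `"<150"`, not `"<100"`, and anything
#' at or above 200 cm falls in `">=200"`.
#'
#' @param dbh numeric vector of diameters at breast height (cm), `>= 0`
#' @param scheme a [dbh_scheme()] table
#' @return character vector of class labels, same length as `dbh`
#' @examples
#' bin_dbh(c(0.5, 100, 250))
#' @export
bin_dbh <- function(dbh, scheme = dbh_scheme()) {
  if (!is.numeric(dbh)) stop("'dbh' must be numeric", call. = FALSE)
  if (anyNA(dbh) || any(dbh < 0)) {
    stop("'dbh' must be non-negative and non-missing", call. = FALSE)
  }
  idx <- findInterval(dbh, scheme$lower)
  scheme$label[idx]
}
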
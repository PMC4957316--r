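#' Construct and validate a right-censored survival sample
#'
#' Bundles observed times, event indicators and an optional covariate matrix
#' into a validated list used throughout the package.  Times must be strictly
#' positive, the status is coded 1 = event, 0 = censored.
#'
#' @param time numeric vector of observed (possibly censored) survival times.
#' @param status numeric or integer vector in \{0, 1\}; 1 marks an event,
#'   0 a censored observation.
#' @param x optional numeric covariate matrix (or data frame) with one row
#'   per subject and no missing values.  May be omitted for evaluation-only
#'   use (e.g. computing a concordance index for externally supplied scores).
#' @return An object of class \code{"survival_sample"}: a list with elements
#'   \code{time}, \code{status} and (possibly \code{NULL}) \code{x}.
#' @examples
#' s <- survival_sample(c(1, 2, 3, 4), c(1, 0, 1, 1))
#' s$status
#' @export
survival_sample <- function(time, status, x = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) != length(status))
    stop("'time' and 'status' must have the same length")
  n <- length(time)
  if (n < 2L)
    stop("a survival sample needs at least two subjects, got ", n)
  if (anyNA(time) || any(!is.finite(time)) || any(time <= 0))
    stop("'time' must be strictly positive and finite")
  if (anyNA(status) || !all(status %in% c(0, 1)))
    stop("'status' must be coded 0 (censored) or 1 (event)")
  if (!is.null(x)) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) != n)
      stop("covariate matrix has ", nrow(x), " rows but the sample has ", n)
    if (anyNA(x))
      stop("covariate matrix must not contain missing values")
    if (is.null(colnames(x)))
      colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  structure(list(time = time, status = status, x = x),
            class = "survival_sample")
}

#' @export
print.survival_sample <- function(x, ...) {
  cat("Right-censored survival sample\n")
  cat(sprintf("  n = %d subjects, %d events (%.1f%% censored)\n",
              length(x$time), sum(x$status),
              100 * mean(x$status == 0)))
  if (!is.null(x$x))
    cat(sprintf("  p = %d covariates\n", ncol(x$x)))
  invisible(x)
}

## coerce loose (time, status, x) arguments into a survival_sample,
## accepting an already-built one as first argument
as_survival_sample <- function(time, status = NULL, x = NULL) {
  if (inherits(time, "survival_sample")) return(time)
  survival_sample(time, status, x)
}
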
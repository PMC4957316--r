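#' Read a survival dataset from a delimited text file
#'
#' Expects a header row with columns `time` and `status` (remappable), any
#' remaining columns are taken as covariates in file order.  Status must be
#' coded 1 = event, 0 = censored; times must be strictly positive; missing
#' values are rejected with the offending row and column named.
#'
#' @param path file path; comma- or tab-delimited (inferred from the
#'   extension, `.tsv`/`.txt` = tab).
#' @param time_col,status_col column names holding the outcome.
#' @return a [survival_sample()]; `x` is `NULL` when the file has no
#'   covariate columns (evaluation-only use).
#' @export
read_survival_csv <- function(path, time_col = "time",
                              status_col = "status") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(time_col, status_col)) {
    if (!col %in% names(df))
      stop("required column '", col, "' not found in ", path)
  }
  bad <- which(is.na(df[[time_col]]) | !is.finite(df[[time_col]]) |
                 df[[time_col]] <= 0)
  if (length(bad))
    stop("non-positive or missing time in row ", bad[1],
         " of column '", time_col, "'")
  bad <- which(!(df[[status_col]] %in% c(0, 1)))
  if (length(bad))
    stop("status outside {0, 1} in row ", bad[1],
         " of column '", status_col, "'")
  covars <- setdiff(names(df), c(time_col, status_col))
  x <- NULL
  if (length(covars)) {
    x <- as.matrix(df[covars])
    if (anyNA(x)) {
      idx <- which(is.na(x), arr.ind = TRUE)[1, ]
      stop("missing covariate value in row ", idx[1], ", column '",
           covars[idx[2]], "'")
    }
  }
  survival_sample(df[[time_col]], df[[status_col]], x)
}

#' Serialize a fitted boosting model to JSON
#'
#' Stores coefficients, centering offsets, hyperparameters and the
#' selection sequence, with a schema version, so that [read_model_json()]
#' reproduces [predict.cboost()] output exactly.
#'
#' @param fit a `"cboost"` object.
#' @param path output file path.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "cboost"))
  obj <- list(schema = "cboost-model/1",
              coefficients = as.list(fit$coefficients),
              centering_offsets = as.list(fit$centering_offsets),
              mstop = fit$mstop, nu = fit$nu, sigma = fit$sigma,
              selection_sequence = fit$selection_sequence,
              score_path = fit$score_path)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @param path file written by [write_model_json()].
#' @return a `"cboost"` object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "cboost-model/1"))
    stop("not a cboost model file: ", path)
  fit <- list(coefficients = unlist(obj$coefficients),
              centering_offsets = unlist(obj$centering_offsets),
              selection_sequence = as.integer(obj$selection_sequence),
              score_path = as.numeric(obj$score_path),
              mstop = as.integer(obj$mstop),
              nu = obj$nu, sigma = obj$sigma,
              selected = sort(unique(as.integer(obj$selection_sequence))),
              n = NA_integer_)
  class(fit) <- "cboost"
  fit
}

#' Serialize a stability-selection result to JSON
#'
#' Writes frequencies for all p covariates, the stable set, the PFER bound
#' and the per-subsample selection sets, together with the seed and
#' settings that produced them.
#'
#' @param result a `"cboost_stabsel"` object.
#' @param path output file path.
#' @export
write_stabsel_json <- function(result, path) {
  stopifnot(inherits(result, "cboost_stabsel"))
  obj <- list(schema = "cboost-stabsel/1",
              frequencies = as.list(result$frequencies),
              stable_set = as.integer(result$stable_set),
              pfer_bound = result$pfer_bound,
              q = result$q, B = result$B, pi_thr = result$pi_thr,
              assumption = result$assumption, seed = result$seed,
              nu = result$nu, sigma = result$sigma,
              subsample_selections = result$subsample_selections,
              subsample_redraws = result$subsample_redraws)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a replication summary as CSV
#'
#' One row per (q, pi_thr) cell with the median true/false positives, the
#' PFER bound and the median test-set Uno C-index.
#'
#' @param summary a `"replication_summary"` object.
#' @param path output file path.
#' @export
write_summary_csv <- function(summary, path) {
  stopifnot(inherits(summary, "replication_summary"))
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
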
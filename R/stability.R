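#' Complementary-pairs subsamples
#'
#' Draws B random partitions of \{1..n\} and emits, for each, the
#' floor(n/2)-subset and its complement (which takes the remainder when n is
#' odd), giving 2B subsamples in total.  Partition b is generated from the
#' deterministic child seed `seed + b`, so runs can be parallelized and
#' still reproduce.
#'
#' @param n sample size (>= 4).
#' @param B number of complementary pairs (>= 1).
#' @param seed integer master seed.
#' @return list of 2B integer index vectors; elements 2b-1 and 2b partition
#'   \{1..n\}.
#' @export
complementary_pairs <- function(n, B, seed) {
  n <- as.integer(n); B <- as.integer(B)
  if (n < 4L) stop("'n' must be >= 4")
  if (B < 1L) stop("'B' must be >= 1")
  half <- n %/% 2L
  out <- vector("list", 2L * B)
  for (b in seq_len(B)) {
    perm <- with_seed(seed + b, sample.int(n))
    out[[2L * b - 1L]] <- sort(perm[seq_len(half)])
    out[[2L * b]] <- sort(perm[(half + 1L):n])
  }
  out
}

## evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Stability selection for C-index boosting
#'
#' Runs complementary-pairs stability selection on top of [cboost()]:
#' on each of the 2B half-samples the boosting model is run until `q`
#' distinct covariates have been selected, selection frequencies
#' \eqn{\hat\pi_j} are averaged over the subsamples, and covariates with
#' \eqn{\hat\pi_j \ge \pi_{thr}} form the stable set.  The per-family error
#' rate bound for the chosen (q, p, pi_thr, B) is attached (see
#' [pfer_bound()]).
#'
#' Subsamples without a single usable pair (e.g. all censored) are redrawn
#' from a shifted child seed with a warning; the redraw count is reported.
#'
#' @inheritParams cboost.default
#' @param q number of distinct covariates to select on each subsample.
#' @param B number of complementary pairs; default 50 (100 subsamples).
#' @param pi_thr selection-frequency threshold in (0.5, 1]; default 0.8.
#' @param seed integer master seed for the subsampling.
#' @param assumption PFER bound assumption, see [pfer_bound()].
#' @param max_iter per-subsample iteration cap; default `50 * q`.
#' @param refit if `TRUE`, refit the stable covariates on the full sample
#'   with `mstop_refit` iterations (errors if the stable set is empty).
#' @param mstop_refit iterations for the final refit; default 1000.
#' @return An object of class `"cboost_stabsel"`: list with
#'   `frequencies` (per-covariate selection frequencies, multiples of
#'   1/(2B)), `stable_set` (indices with frequency >= pi_thr), `pfer_bound`,
#'   `q`, `B`, `pi_thr`, `assumption`, `subsample_selections` (list of the
#'   2B selected sets), `subsample_redraws`, and if `refit = TRUE` the
#'   final `"cboost"` fit under `$refit` (coefficients in full-p indexing).
#' @seealso [stable_set()], [fit_stable_model()]
#' @export
cboost_stabsel <- function(x, time, status = NULL, q, B = 50, pi_thr = 0.8,
                           nu = 0.1, sigma = 0.1, seed = 1,
                           assumption = c("r-concave", "unimodal", "MB"),
                           max_iter = NULL, refit = FALSE,
                           mstop_refit = 1000) {
  s <- if (inherits(x, "survival_sample")) x else survival_sample(time, status, x)
  if (is.null(s$x)) stop("covariates are required")
  assumption <- match.arg(assumption)
  p <- ncol(s$x)
  q <- as.integer(q)
  if (q > p) stop("'q' (", q, ") cannot exceed the number of covariates (",
                  p, ")")
  n <- length(s$time)
  if (is.null(max_iter)) max_iter <- 50L * q

  subsamples <- complementary_pairs(n, B, seed)
  counts <- integer(p)
  sel_sets <- vector("list", 2L * B)
  redraws <- 0L
  for (b in seq_along(subsamples)) {
    idx <- subsamples[[b]]
    attempt <- 0L
    repeat {
      sub <- survival_sample(s$time[idx], s$status[idx],
                             s$x[idx, , drop = FALSE])
      fit <- tryCatch(
        suppressWarnings(fit_cboost(sub, mstop = max_iter, nu = nu,
                                    sigma = sigma, q = q)),
        error = function(e) {
          if (grepl("no usable pair", conditionMessage(e))) NULL else stop(e)
        })
      if (!is.null(fit)) break
      attempt <- attempt + 1L
      if (attempt > 25L)
        stop("could not draw a subsample with a usable pair after 25 tries")
      warning("subsample ", b, " had no usable pair; redrawn")
      redraws <- redraws + 1L
      half <- n %/% 2L
      perm <- with_seed(seed + b + 7919L * attempt, sample.int(n))
      idx <- if (b %% 2L == 1L) sort(perm[seq_len(half)])
             else sort(perm[(half + 1L):n])
    }
    sel_sets[[b]] <- fit$selected
    counts[fit$selected] <- counts[fit$selected] + 1L
  }

  freqs <- counts / (2 * B)
  names(freqs) <- colnames(s$x)
  stable <- stable_set(freqs, pi_thr)
  out <- list(frequencies = freqs,
              stable_set = stable,
              pfer_bound = pfer_bound(q, p, pi_thr, B, assumption),
              q = q, B = as.integer(B), pi_thr = pi_thr,
              assumption = assumption, p = p, seed = seed,
              nu = nu, sigma = sigma,
              subsample_selections = sel_sets,
              subsample_redraws = redraws)
  class(out) <- "cboost_stabsel"
  if (refit)
    out$refit <- fit_stable_model(s, stable = stable, mstop = mstop_refit,
                                  nu = nu, sigma = sigma)
  out
}

#' Threshold selection frequencies into a stable set
#'
#' @param frequencies per-covariate selection frequencies in [0, 1].
#' @param pi_thr threshold in (0.5, 1]; the comparison is inclusive
#'   (frequency >= pi_thr).
#' @return integer vector of stable covariate indices (possibly empty:
#'   it is legitimate for no variable to be stable).
#' @export
stable_set <- function(frequencies, pi_thr) {
  if (!is.finite(pi_thr) || pi_thr <= 0.5 || pi_thr > 1)
    stop("'pi_thr' must lie in (0.5, 1]: the error bounds are invalid at ",
         "or below 0.5")
  which(frequencies >= pi_thr)
}

#' Refit a boosting model on the stable covariates
#'
#' Runs [cboost()] on the full sample restricted to the stable covariates
#' with a fixed number of iterations, and reports coefficients in full-p
#' indexing (zeros for all non-stable covariates).
#'
#' @inheritParams cboost.default
#' @param stable integer indices of the stable covariates (non-empty).
#' @param mstop iterations for the refit; default 1000.
#' @return a `"cboost"` fit with length-p coefficient vector.
#' @export
fit_stable_model <- function(x, time = NULL, status = NULL, stable,
                             mstop = 1000, nu = 0.1, sigma = 0.1) {
  s <- if (inherits(x, "survival_sample")) x else survival_sample(time, status, x)
  if (length(stable) == 0L)
    stop("no stable variables: cannot fit a final model")
  p <- ncol(s$x)
  stable <- sort(as.integer(stable))
  sub <- survival_sample(s$time, s$status, s$x[, stable, drop = FALSE])
  fit <- fit_cboost(sub, mstop = mstop, nu = nu, sigma = sigma)
  ## re-express in full-p indexing
  beta <- numeric(p); offs <- numeric(p)
  beta[stable] <- fit$coefficients
  offs[stable] <- fit$centering_offsets
  names(beta) <- names(offs) <- colnames(s$x)
  fit$coefficients <- beta
  fit$centering_offsets <- offs
  fit$selection_sequence <- stable[fit$selection_sequence]
  fit$selected <- stable[fit$selected]
  fit$stable_set <- stable
  fit
}

#' @export
print.cboost_stabsel <- function(x, ...) {
  cat("Complementary-pairs stability selection for C-index boosting\n")
  cat(sprintf("  p = %d, q = %d, 2B = %d subsamples, pi_thr = %.2f\n",
              x$p, x$q, 2 * x$B, x$pi_thr))
  cat(sprintf("  PFER bound (%s): %.3f\n", x$assumption, x$pfer_bound))
  if (length(x$stable_set)) {
    nm <- names(x$frequencies)[x$stable_set]
    cat(sprintf("  stable set (%d): %s\n", length(x$stable_set),
                paste(nm, collapse = ", ")))
  } else {
    cat("  stable set: empty\n")
  }
  if (x$subsample_redraws > 0)
    cat(sprintf("  %d degenerate subsample(s) redrawn\n",
                x$subsample_redraws))
  invisible(x)
}

#' @param x a `"cboost_stabsel"` object.
#' @param ... passed to [barplot()].
#' @describeIn cboost_stabsel plot the selection frequencies with the
#'   threshold line.
#' @export
plot.cboost_stabsel <- function(x, ...) {
  ord <- order(x$frequencies, decreasing = TRUE)
  graphics::barplot(x$frequencies[ord], las = 2,
                    ylab = "selection frequency", ylim = c(0, 1), ...)
  graphics::abline(h = x$pi_thr, lty = 2)
  invisible(x)
}
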
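#' Boost the concordance index with component-wise linear base-learners
#'
#' Fits the additive predictor \eqn{\eta = X\beta} by component-wise gradient
#' boosting of the smoothed IPCW concordance index.  In every iteration the
#' analytic gradient of the smoothed C-index at the current scores is
#' computed, a slope-only linear base-learner is fitted to it for each
#' (mean-centered) covariate, and only the best-fitting covariate is updated
#' by `nu` times its slope.  Covariates never selected keep an exactly zero
#' coefficient, so the stopping iteration `mstop` controls the sparsity of
#' the fit.  Because the loss is shift-invariant, no intercept base-learner
#' is used.
#'
#' The IPCW pair weights are computed once from the training sample and held
#' fixed: the censoring Kaplan-Meier does not depend on the scores.
#'
#' @param x covariate matrix or data frame (n rows, p columns, no missing
#'   values), or a formula; see Details.
#' @param time,status survival outcome as in [survival_sample()] (ignored
#'   for the formula method).
#' @param mstop number of boosting iterations (>= 1).
#' @param nu step length in (0, 1]; default 0.1.
#' @param sigma bandwidth of the sigmoid that smooths the concordance
#'   indicator; default 0.1.
#' @param q if non-`NULL`, boost until `q` distinct covariates have been
#'   selected instead of running a fixed number of iterations; `mstop` then
#'   acts as the iteration cap (default `50 * q` when `q` is given and
#'   `mstop` is missing).  If the cap is reached first, the fit carries a
#'   warning flag `hit_max_iter`.
#' @param data,formula,... formula-interface arguments; the response must be
#'   a [survival::Surv()] object, e.g. `cboost(Surv(time, status) ~ ., dat)`.
#' @return An object of class `"cboost"` with components
#'   \describe{
#'     \item{coefficients}{named length-p vector on the original covariate
#'       scale (zeros for never-selected covariates),}
#'     \item{selection_sequence}{covariate index chosen at each iteration,}
#'     \item{score_path}{training smoothed C-index after each iteration,}
#'     \item{centering_offsets}{column means removed before fitting,}
#'     \item{mstop, nu, sigma}{the hyperparameters actually used,}
#'     \item{selected}{sorted indices of covariates with at least one
#'       selection,}
#'     \item{hit_max_iter}{only for `q` fits: `TRUE` if the cap was reached
#'       before `q` distinct covariates were selected.}
#'   }
#' @seealso [predict.cboost()], [cboost_stabsel()], [cindex()]
#' @examples
#' set.seed(1)
#' n <- 60; x <- matrix(rnorm(n * 4), n, 4)
#' tt <- rexp(n, exp(x[, 1]))
#' fit <- cboost(x, tt, rep(1, n), mstop = 100)
#' coef(fit)
#' @export
cboost <- function(x, ...) UseMethod("cboost")

#' @rdname cboost
#' @export
cboost.default <- function(x, time, status = NULL, mstop = NULL, nu = 0.1,
                           sigma = 0.1, q = NULL, ...) {
  s <- survival_sample(time, status, x)
  fit_cboost(s, mstop = mstop, nu = nu, sigma = sigma, q = q)
}

#' @rdname cboost
#' @export
cboost.survival_sample <- function(x, mstop = NULL, nu = 0.1, sigma = 0.1,
                                   q = NULL, ...) {
  if (is.null(x$x)) stop("covariates are required for fitting")
  fit_cboost(x, mstop = mstop, nu = nu, sigma = sigma, q = q)
}

#' @rdname cboost
#' @export
cboost.formula <- function(formula, data, mstop = NULL, nu = 0.1,
                           sigma = 0.1, q = NULL, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv"))
    stop("the response must be a survival::Surv(time, status) object")
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  s <- survival_sample(y[, "time"], y[, "status"], x)
  fit_cboost(s, mstop = mstop, nu = nu, sigma = sigma, q = q)
}

as_covariates <- function(x, n) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != n) stop("covariate matrix has wrong number of rows")
  if (anyNA(x)) stop("covariate matrix must not contain missing values")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

fit_cboost <- function(s, mstop = NULL, nu = 0.1, sigma = 0.1, q = NULL) {
  if (!is.finite(nu) || nu <= 0 || nu > 1) stop("'nu' must be in (0, 1]")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  p <- ncol(s$x)
  qstop <- 0L
  if (!is.null(q)) {
    q <- as.integer(q)
    if (q < 1L) stop("'q' must be >= 1")
    if (q > p) stop("'q' (", q, ") cannot exceed the number of covariates (",
                    p, ")")
    if (is.null(mstop)) mstop <- 50L * q
    qstop <- q
  }
  if (is.null(mstop)) mstop <- 1000L
  mstop <- as.integer(mstop)
  if (mstop < 1L) stop("'mstop' must be >= 1")

  offsets <- colMeans(s$x)
  xc <- sweep(s$x, 2L, offsets)
  W <- pair_weight_matrix(s)
  if (sum(W) == 0)
    stop("no usable pair: need an event j with positive weight and t_j < t_i")

  eng <- cboost_engine(xc, W, nu, sigma, mstop, qstop)
  beta <- drop(eng$beta)
  names(beta) <- colnames(s$x)
  names(offsets) <- colnames(s$x)
  out <- list(coefficients = beta,
              selection_sequence = as.integer(eng$selection_sequence),
              score_path = as.numeric(eng$score_path),
              centering_offsets = offsets,
              mstop = length(eng$selection_sequence),
              nu = nu, sigma = sigma,
              selected = sort(unique(as.integer(eng$selection_sequence))),
              eta = drop(eng$eta),
              n = length(s$time))
  if (qstop > 0L) {
    out$q <- qstop
    out$hit_max_iter <- !eng$hit_q
    if (out$hit_max_iter)
      warning("iteration cap reached before ", qstop,
              " distinct covariates were selected (got ", eng$distinct, ")")
  }
  class(out) <- "cboost"
  out
}

#' Predict scores from a fitted C-index boosting model
#'
#' @param object a `"cboost"` fit.
#' @param newdata covariate matrix or data frame with the same columns as
#'   the training covariates.
#' @param ... unused.
#' @return numeric score vector eta (larger = predicted shorter survival).
#' @export
predict.cboost <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  p <- length(object$coefficients)
  if (ncol(x) != p)
    stop("'newdata' has ", ncol(x), " columns, expected ", p)
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), names(object$coefficients)))
    x <- x[, names(object$coefficients), drop = FALSE]
  drop(sweep(x, 2L, object$centering_offsets) %*% object$coefficients)
}

#' @export
coef.cboost <- function(object, ...) object$coefficients

#' @export
print.cboost <- function(x, ...) {
  cat("C-index boosting fit\n")
  cat(sprintf("  n = %d, p = %d, mstop = %d, nu = %g, sigma = %g\n",
              x$n, length(x$coefficients), x$mstop, x$nu, x$sigma))
  cat(sprintf("  %d covariate(s) selected; final training C_smooth = %.4f\n",
              length(x$selected), x$score_path[length(x$score_path)]))
  invisible(x)
}

#' @export
summary.cboost <- function(object, ...) {
  sel <- object$selected
  tab <- data.frame(
    covariate = names(object$coefficients)[sel],
    coefficient = unname(object$coefficients[sel]),
    times_selected = vapply(sel, function(l)
      sum(object$selection_sequence == l), integer(1)))
  structure(list(fit = object, selected = tab), class = "summary.cboost")
}

#' @export
print.summary.cboost <- function(x, ...) {
  print(x$fit)
  cat("\nSelected covariates:\n")
  print(x$selected, row.names = FALSE)
  invisible(x)
}

#' @param x a `"cboost"` fit.
#' @param ... passed on to [plot()].
#' @describeIn cboost plot the training smoothed C-index against the
#'   boosting iteration.
#' @export
plot.cboost <- function(x, ...) {
  plot(seq_along(x$score_path), x$score_path, type = "l",
       xlab = "boosting iteration", ylab = "training smoothed C-index", ...)
  invisible(x)
}
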
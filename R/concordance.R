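#' Kaplan-Meier estimate of the censoring survival function
#'
#' Estimates the survival function G of the censoring time by the
#' product-limit method with the roles of events and censorings reversed:
#' censored observations (status 0) are the "events" of the censoring
#' process, actual events are treated as censored.  G enters the inverse
#' probability of censoring weights of the IPCW concordance estimators.
#'
#' Samples without any censored observation yield the constant function 1.
#'
#' @param time,status survival data as in [survival_sample()]; alternatively
#'   pass a `survival_sample` as the first argument.
#' @return An object of class `"censoring_km"` with fields `jump_times`
#'   (sorted distinct times at which G drops) and `values` (the value of G
#'   at and after each jump).  Evaluate it with [eval_censoring_km()].
#' @seealso [ipcw_weights()], [cindex()]
#' @examples
#' G <- censoring_km(c(1, 2, 3, 4), c(1, 0, 1, 1))
#' eval_censoring_km(G, c(1.5, 2, 3))            # right-continuous
#' eval_censoring_km(G, c(2, 3), left = TRUE)    # left limits G(t-)
#' @export
censoring_km <- function(time, status = NULL) {
  s <- as_survival_sample(time, status)
  if (all(s$status == 1)) {
    return(structure(list(jump_times = numeric(0), values = numeric(0)),
                     class = "censoring_km"))
  }
  fit <- survival::survfit(survival::Surv(s$time, 1 - s$status) ~ 1)
  drop_idx <- fit$n.event > 0
  structure(list(jump_times = fit$time[drop_idx],
                 values = fit$surv[drop_idx]),
            class = "censoring_km")
}

#' Evaluate a censoring Kaplan-Meier step function
#'
#' @param G a `"censoring_km"` object.
#' @param t numeric vector of time points.
#' @param left if `TRUE`, return the left limit G(t-) (the standard IPCW
#'   convention, so a subject's own censoring jump does not deflate its
#'   weight); otherwise the right-continuous value G(t).
#' @return numeric vector of survival probabilities in [0, 1].
#' @export
eval_censoring_km <- function(G, t, left = FALSE) {
  stopifnot(inherits(G, "censoring_km"))
  if (length(G$jump_times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, G$jump_times, left.open = left)
  c(1, G$values)[idx + 1L]
}

#' @export
print.censoring_km <- function(x, ...) {
  cat("Kaplan-Meier estimate of the censoring survival function\n")
  if (length(x$jump_times) == 0L) {
    cat("  no censored observations: G(t) = 1 everywhere\n")
  } else {
    cat(sprintf("  %d jump(s); final value %.4f\n",
                length(x$jump_times), x$values[length(x$values)]))
  }
  invisible(x)
}

#' Inverse probability of censoring weights
#'
#' Computes the subject-level weights w_j = status_j / G(t_j-)^2 used by the
#' IPCW concordance estimators.  Censored subjects receive weight zero.
#' Subjects whose left-limit censoring survival G(t_j-) is zero cannot be
#' reweighted and also receive weight zero, with a warning.
#'
#' @inheritParams censoring_km
#' @param G optional `"censoring_km"`; computed from the sample if missing
#'   (supply it explicitly to weight by a designated learning sample).
#' @param left evaluate G at the left limit (default) or right-continuously.
#' @return numeric weight vector, one entry per subject.
#' @export
ipcw_weights <- function(time, status = NULL, G = NULL, left = TRUE) {
  s <- as_survival_sample(time, status)
  if (is.null(G)) G <- censoring_km(s)
  g <- eval_censoring_km(G, s$time, left = left)
  w <- numeric(length(s$time))
  pos <- s$status == 1 & g > 0
  w[pos] <- 1 / g[pos]^2
  if (any(s$status == 1 & g == 0)) {
    warning("events with zero censoring-survival probability received ",
            "weight 0 (", sum(s$status == 1 & g == 0), " subject(s))")
  }
  w
}

## n x n matrix of pair weights w_j * I(t_j < t_i), row j = smaller time.
## Shared backbone of the Uno / smoothed estimators and the gradient.
pair_weight_matrix <- function(s, G = NULL, left = TRUE) {
  w <- suppressWarnings(ipcw_weights(s, G = G, left = left))
  W <- w * outer(s$time, s$time, "<")    # recycles w down columns = w[j]
  W
}

#' Concordance index estimators for right-censored data
#'
#' Estimates the probability that, of two random subjects, the one with the
#' shorter survival time has the larger score \eqn{\eta}.  Three estimators
#' are available:
#' \describe{
#'   \item{`"uno"`}{the IPCW estimator: pairs (j, i) with t_j < t_i are
#'     weighted by status_j / G(t_j-)^2, where G is the censoring
#'     Kaplan-Meier; asymptotically unbiased under independent censoring.}
#'   \item{`"truncated"`}{concordance restricted to pairs whose smaller time
#'     is an observed event no later than `tau`, with both members
#'     uncensored; no IPCW weights enter this estimator.}
#'   \item{`"smooth"`}{the Uno estimator with the score indicator
#'     I(eta_j > eta_i) replaced by the sigmoid
#'     K(u) = 1 / (1 + exp(-u / sigma)), making it differentiable in eta;
#'     this smoothed criterion is the boosting loss.}
#' }
#' Ties: tied times form no comparable pair; tied scores count zero towards
#' the numerator (the smoothed estimator gives them K(0) = 1/2).
#'
#' @inheritParams censoring_km
#' @param eta numeric score vector (larger = predicted shorter survival).
#' @param method one of `"uno"`, `"truncated"`, `"smooth"`.
#' @param tau truncation time, required for `method = "truncated"`; must lie
#'   in (0, max(time)].
#' @param sigma smoothing bandwidth (> 0) for `method = "smooth"`;
#'   default 0.1.
#' @param G optional pre-computed censoring KM (learning-sample weights).
#' @param left evaluate G at left limits (default, standard IPCW).
#' @return the estimated concordance index, a number in [0, 1].
#' @examples
#' t <- c(1, 2, 3, 4); d <- c(1, 1, 1, 1)
#' cindex(t, d, eta = c(4, 3, 2, 1))                    # 1: perfect ranking
#' cindex(t, d, eta = c(4, 3, 1, 2))                    # 5/6
#' cindex(t, d, eta = c(4, 3, 1, 2), method = "smooth", sigma = 1e-4)
#' @export
cindex <- function(time, status = NULL, eta,
                   method = c("uno", "truncated", "smooth"),
                   tau = NULL, sigma = 0.1, G = NULL, left = TRUE) {
  s <- as_survival_sample(time, status)
  method <- match.arg(method)
  eta <- as.numeric(eta)
  if (length(eta) != length(s$time))
    stop("'eta' must have one score per subject")

  if (method == "truncated") {
    if (is.null(tau)) stop("'tau' is required for the truncated C-index")
    if (!is.finite(tau) || tau <= 0 || tau > max(s$time))
      stop("'tau' must lie in (0, max(time)]")
    keep <- outer(s$status * (s$time <= tau), s$status) *
      outer(s$time, s$time, "<")
    denom <- sum(keep)
    if (denom == 0)
      stop("no event pair with the smaller time at or before tau = ", tau)
    return(sum(keep * outer(eta, eta, ">")) / denom)
  }

  W <- pair_weight_matrix(s, G = G, left = left)
  denom <- sum(W)
  if (denom == 0)
    stop("no usable pair: need an event j with positive weight and t_j < t_i")
  if (method == "uno") {
    sum(W * outer(eta, eta, ">")) / denom
  } else {
    if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
    K <- stats::plogis(outer(eta, eta, "-") / sigma)
    sum(W * K) / denom
  }
}

#' Gradient of the smoothed concordance index
#'
#' Analytic gradient of the smoothed IPCW concordance index with respect to
#' the score vector.  Component k is
#' \deqn{\frac{1}{D}\Big[\sum_i w_k I(t_k < t_i) K'(\eta_k-\eta_i)
#'   - \sum_j w_j I(t_j < t_k) K'(\eta_j-\eta_k)\Big],}
#' with \eqn{K'(u) = K(u)(1-K(u))/\sigma} and D the total pair weight.
#' This is the ascent direction used by [cboost()]; the components of the
#' gradient always sum to zero because each pair contributes equal and
#' opposite amounts to its two members.
#'
#' @inheritParams cindex
#' @return numeric gradient vector of the same length as `eta`.
#' @export
cindex_gradient <- function(time, status = NULL, eta, sigma = 0.1,
                            G = NULL, left = TRUE) {
  s <- as_survival_sample(time, status)
  eta <- as.numeric(eta)
  if (length(eta) != length(s$time))
    stop("'eta' must have one score per subject")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  W <- pair_weight_matrix(s, G = G, left = left)
  D <- sum(W)
  if (D == 0)
    stop("no usable pair: need an event j with positive weight and t_j < t_i")
  K <- stats::plogis(outer(eta, eta, "-") / sigma)
  M <- W * K * (1 - K) / sigma
  (rowSums(M) - colSums(M)) / D
}
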
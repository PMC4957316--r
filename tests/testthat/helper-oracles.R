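# Independent brute-force oracles used across the suite.  These deliberately
# share no code with the package internals: plain double loops and a hand
# product-limit calculation.

# product-limit estimate of the censoring survival function, evaluated at t
# (right-continuous) or just before t (left = TRUE)
oracle_G <- function(time, status, t, left = FALSE) {
  cens_times <- sort(unique(time[status == 0]))
  vapply(t, function(tt) {
    g <- 1
    for (ct in cens_times) {
      passed <- if (left) ct < tt else ct <= tt
      if (!passed) break
      d <- sum(time == ct & status == 0)
      at_risk <- sum(time >= ct)
      g <- g * (1 - d / at_risk)
    }
    g
  }, numeric(1))
}

oracle_weights <- function(time, status) {
  ifelse(status == 1, 1 / oracle_G(time, status, time, left = TRUE)^2, 0)
}

# exhaustive pair enumeration for all three estimators
oracle_cindex <- function(time, status, eta,
                          method = c("uno", "truncated", "smooth"),
                          tau = NULL, sigma = 0.1) {
  method <- match.arg(method)
  n <- length(time)
  num <- den <- 0
  w <- oracle_weights(time, status)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (!(time[j] < time[i])) next
      if (method == "truncated") {
        if (status[j] != 1 || status[i] != 1 || time[j] > tau) next
        den <- den + 1
        num <- num + (eta[j] > eta[i])
      } else {
        den <- den + w[j]
        contrib <- if (method == "uno") as.numeric(eta[j] > eta[i])
                   else 1 / (1 + exp(-(eta[j] - eta[i]) / sigma))
        num <- num + w[j] * contrib
      }
    }
  }
  num / den
}

# central finite differences of the smoothed estimator
oracle_fd_gradient <- function(time, status, eta, sigma, h = 1e-6) {
  vapply(seq_along(eta), function(k) {
    up <- dn <- eta
    up[k] <- eta[k] + h
    dn[k] <- eta[k] - h
    (cindex(time, status, eta = up, method = "smooth", sigma = sigma) -
       cindex(time, status, eta = dn, method = "smooth", sigma = sigma)) /
      (2 * h)
  }, numeric(1))
}

# run expr under a temporary seed without disturbing the ambient stream
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# small random censored fixture without tied times or tied scores
random_fixture <- function(n, cens_prob = 0.3) {
  time <- sample(seq_len(5 * n), n)         # distinct times
  status <- rbinom(n, 1, 1 - cens_prob)
  if (sum(status) < 2) status[sample(n, 2)] <- 1
  eta <- rnorm(n)
  list(time = time, status = status, eta = eta)
}
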
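#' Benchmark scenario for the log-logistic AFT simulation
#'
#' Describes a high-dimensional survival simulation: covariates are drawn
#' from a multivariate normal with unit variances and constant pairwise
#' correlation `rho`, and survival times follow the accelerated failure
#' time model \deqn{\log T = \mu + \phi W, \qquad \mu = X\beta,} with W
#' standard logistic (so T is log-logistic given X).  The effect vector
#' tiles the pattern (1.5, 1, -1, -1.5) over the first `p_inf` covariates
#' and is zero elsewhere.  Setting `ph_violation = TRUE` replaces the
#' scalar scale by the covariate-dependent \eqn{\phi_i = \exp(x_{i1})/5},
#' which breaks the proportional hazards property.  Censoring times are
#' independent exponentials whose rate is calibrated so that on average
#' `censor_target` of the observations are censored.
#'
#' @param n training sample size.
#' @param n_test test sample size (test data are censored by the same
#'   mechanism).
#' @param p number of covariates.
#' @param p_inf number of informative covariates (may be 0 for a pure-noise
#'   design); must not exceed `p`.
#' @param rho pairwise covariate correlation in [0, 1).
#' @param phi scalar AFT scale used when `ph_violation = FALSE`.  The
#'   default 0.55 places the oracle concordance of the true predictor near
#'   0.845 for the `p_inf = 4` pattern, the signal-to-noise regime of the
#'   published benchmark; see the package vignette for how this value was
#'   calibrated and for the sensitivity of absolute C-index levels to it.
#' @param ph_violation if `TRUE`, use the covariate-dependent scale.
#' @param censor_target desired average fraction of censored observations,
#'   in (0, 1).
#' @param q,pi_thr,B,nu,sigma,mstop_refit,mstop_plain stability-selection
#'   and boosting settings used by [replicate_study()]; `q` and `pi_thr`
#'   may be vectors.
#' @return an object of class `"aft_scenario"` (a validated list).
#' @examples
#' sc <- aft_scenario(p = 10, p_inf = 4, n = 80, n_test = 100)
#' sc$beta
#' @export
aft_scenario <- function(n = 200, n_test = 1000, p = 50, p_inf = 4,
                         rho = 0.5, phi = 0.55, ph_violation = FALSE,
                         censor_target = 0.5,
                         q = 10, pi_thr = 0.7, B = 50,
                         nu = 0.1, sigma = 0.1,
                         mstop_refit = 1000, mstop_plain = 10000) {
  if (p_inf > p) stop("'p_inf' cannot exceed 'p'")
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  if (censor_target <= 0 || censor_target >= 1)
    stop("'censor_target' must lie strictly between 0 and 1 (exponential ",
         "censoring cannot attain the boundary)")
  beta <- numeric(p)
  if (p_inf > 0)
    beta[seq_len(p_inf)] <- rep(c(1.5, 1, -1, -1.5), length.out = p_inf)
  structure(list(n = n, n_test = n_test, p = p, p_inf = p_inf, beta = beta,
                 rho = rho, phi = phi, ph_violation = ph_violation,
                 censor_target = censor_target,
                 q = q, pi_thr = pi_thr, B = B, nu = nu, sigma = sigma,
                 mstop_refit = mstop_refit, mstop_plain = mstop_plain),
            class = "aft_scenario")
}

#' @export
print.aft_scenario <- function(x, ...) {
  cat("Log-logistic AFT benchmark scenario\n")
  cat(sprintf("  n = %d (test %d), p = %d, p_inf = %d, rho = %.2f\n",
              x$n, x$n_test, x$p, x$p_inf, x$rho))
  cat(sprintf("  scale: %s; target censoring %.0f%%\n",
              if (x$ph_violation) "exp(x1)/5 (PH violated)"
              else sprintf("phi = %g", x$phi),
              100 * x$censor_target))
  invisible(x)
}

## equicorrelated normal draws via a shared factor: exact for
## Sigma = (1-rho) I + rho J, O(np) instead of a p x p factorization
rmvn_equicorr <- function(n, p, rho) {
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    z0 <- stats::rnorm(n)
    z <- sqrt(1 - rho) * z + sqrt(rho) * z0
  }
  colnames(z) <- paste0("x", seq_len(p))
  z
}

## uncensored survival times for one scenario draw
draw_latent <- function(scenario, n) {
  x <- rmvn_equicorr(n, scenario$p, scenario$rho)
  mu <- drop(x %*% scenario$beta)
  phi <- if (scenario$ph_violation) exp(x[, 1]) / 5 else scenario$phi
  t_lat <- exp(mu + phi * stats::rlogis(n))
  list(x = x, t = t_lat)
}

#' Calibrate the exponential censoring rate of a scenario
#'
#' Root-finds the rate of the independent exponential censoring
#' distribution so that the expected fraction of censored observations,
#' estimated on a large pilot sample of latent survival times, matches the
#' scenario's `censor_target`.  Given the pilot times, the censoring
#' fraction \eqn{E[1 - e^{-\lambda T}]} is computed exactly, so the
#' root-finding is smooth and deterministic.
#'
#' @param scenario an [aft_scenario()].
#' @param seed integer seed for the pilot draw.
#' @param pilot_n pilot sample size; default 2e5.
#' @param tol calibration tolerance on the censoring fraction.
#' @return the calibrated exponential rate (attribute `achieved` holds the
#'   pilot censoring fraction).
#' @export
calibrate_censoring <- function(scenario, seed = 1, pilot_n = 2e5,
                                tol = 0.005) {
  stopifnot(inherits(scenario, "aft_scenario"))
  t_pilot <- with_seed(seed, draw_latent(scenario, pilot_n)$t)
  frac <- function(log_rate) mean(1 - exp(-exp(log_rate) * t_pilot))
  f <- function(log_rate) frac(log_rate) - scenario$censor_target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0)
    stop("censoring calibration failed to bracket the target rate ",
         scenario$censor_target, " (pilot fractions ",
         signif(frac(lo), 3), " to ", signif(frac(hi), 3), ")")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  rate <- exp(root)
  achieved <- frac(root)
  if (abs(achieved - scenario$censor_target) > tol)
    stop("censoring calibration reached ", signif(achieved, 4),
         " instead of ", scenario$censor_target)
  structure(rate, achieved = achieved)
}

#' Simulate one training/test draw of an AFT scenario
#'
#' @inheritParams calibrate_censoring
#' @param seed integer seed for this draw.
#' @param censoring_rate optional pre-calibrated exponential rate (see
#'   [calibrate_censoring()]); calibrated on the fly if missing.
#' @return list with `train` and `test` (each a [survival_sample()]),
#'   `truth` (indices of the informative covariates) and `censoring_rate`.
#' @export
simulate_aft <- function(scenario, seed = 1, censoring_rate = NULL) {
  stopifnot(inherits(scenario, "aft_scenario"))
  if (is.null(censoring_rate))
    censoring_rate <- calibrate_censoring(scenario, seed = seed + 131071L)
  draw <- function(n) {
    lat <- draw_latent(scenario, n)
    cens <- stats::rexp(n, rate = censoring_rate)
    survival_sample(pmin(lat$t, cens), as.numeric(lat$t <= cens), lat$x)
  }
  out <- with_seed(seed, {
    train <- draw(scenario$n)
    test <- draw(scenario$n_test)
    list(train = train, test = test)
  })
  out$truth <- seq_len(scenario$p_inf)
  out$censoring_rate <- as.numeric(censoring_rate)
  out
}

#' Replicate a stability-selection benchmark scenario
#'
#' For each replicate: simulate training and test data, run
#' complementary-pairs stability selection (2B subsamples, budget `q`),
#' threshold the frequencies at each `pi_thr`, count true and false
#' positives against the known support, refit the stable covariates on the
#' full training sample (`mstop_refit` iterations) and score the test data
#' with the IPCW Uno estimator (using the test sample's own censoring
#' Kaplan-Meier).  Optionally, plain boosting on all p covariates with
#' `mstop_plain` iterations provides the no-selection reference column.
#' Cells whose stable set is empty contribute missing values (no
#' discriminatory power can be computed), not errors.
#'
#' @inheritParams calibrate_censoring
#' @param reps number of replicates.
#' @param seed integer master seed; replicate r uses child seed
#'   `seed + 1000 * r`.
#' @param plain include the plain-boosting reference (default `TRUE`).
#' @return an object of class `"replication_summary"`: a data frame with
#'   one row per (q, pi_thr) cell -- columns `q`, `pi_thr`, `median_tp`,
#'   `median_fp`, `pfer_bound`, `median_c_test`, `n_empty` -- plus, when
#'   `plain = TRUE`, a final row with `pi_thr = NA` for the no-selection
#'   reference.  Per-replicate details are in `attr(, "replicates")`.
#' @export
replicate_study <- function(scenario, reps = 10, seed = 1, plain = TRUE) {
  stopifnot(inherits(scenario, "aft_scenario"))
  rate <- calibrate_censoring(scenario, seed = seed + 131071L)
  truth <- seq_len(scenario$p_inf)
  qs <- as.integer(scenario$q)
  pis <- scenario$pi_thr
  cells <- expand.grid(q = qs, pi_thr = pis, KEEP.OUT.ATTRS = FALSE)

  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    sim <- simulate_aft(scenario, seed = seed + 1000L * r,
                        censoring_rate = rate)
    G_test <- censoring_km(sim$test)
    rep_rows <- vector("list", nrow(cells))
    for (qi in seq_along(qs)) {
      ss <- cboost_stabsel(sim$train, q = qs[qi], B = scenario$B,
                           pi_thr = pis[1], nu = scenario$nu,
                           sigma = scenario$sigma,
                           seed = seed + 1000L * r + qi)
      for (pj in seq_along(pis)) {
        stable <- stable_set(ss$frequencies, pis[pj])
        tp <- length(intersect(stable, truth))
        fp <- length(setdiff(stable, truth))
        c_test <- NA_real_
        if (length(stable) > 0) {
          refit <- fit_stable_model(sim$train, stable = stable,
                                    mstop = scenario$mstop_refit,
                                    nu = scenario$nu, sigma = scenario$sigma)
          eta <- predict(refit, sim$test$x)
          c_test <- cindex(sim$test, eta = eta, method = "uno", G = G_test)
        }
        idx <- which(cells$q == qs[qi] & cells$pi_thr == pis[pj])
        rep_rows[[idx]] <- data.frame(q = qs[qi], pi_thr = pis[pj],
                                      tp = tp, fp = fp, c_test = c_test)
      }
    }
    res <- do.call(rbind, rep_rows)
    if (plain) {
      pf <- fit_cboost(sim$train, mstop = scenario$mstop_plain,
                       nu = scenario$nu, sigma = scenario$sigma)
      eta <- predict(pf, sim$test$x)
      res <- rbind(res, data.frame(
        q = NA_integer_, pi_thr = NA_real_,
        tp = length(intersect(pf$selected, truth)),
        fp = length(setdiff(pf$selected, truth)),
        c_test = cindex(sim$test, eta = eta, method = "uno", G = G_test)))
    }
    res$rep <- r
    per_rep[[r]] <- res
  }

  all_rows <- do.call(rbind, per_rep)
  summarize <- function(df) {
    data.frame(q = df$q[1], pi_thr = df$pi_thr[1],
               median_tp = stats::median(df$tp),
               median_fp = stats::median(df$fp),
               pfer_bound = if (is.na(df$pi_thr[1])) NA_real_ else
                 pfer_bound(df$q[1], scenario$p, df$pi_thr[1], scenario$B),
               median_c_test = stats::median(df$c_test, na.rm = TRUE),
               n_empty = sum(is.na(df$c_test)))
  }
  key <- paste(all_rows$q, all_rows$pi_thr)
  summary <- do.call(rbind, lapply(split(all_rows, key), summarize))
  ## keep cell order: grid rows first, plain row last
  ord <- order(is.na(summary$pi_thr), summary$q, summary$pi_thr)
  summary <- summary[ord, , drop = FALSE]
  rownames(summary) <- NULL
  structure(summary, replicates = all_rows, scenario = scenario,
            seed = seed, reps = reps,
            class = c("replication_summary", "data.frame"))
}

#' @export
print.replication_summary <- function(x, digits = 4, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf(
    "Replication summary: p = %d, p_inf = %d, n = %d, %d replicate(s)\n",
    sc$p, sc$p_inf, sc$n, attr(x, "reps")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
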
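test_that("censoring Kaplan-Meier matches the hand product-limit estimate", {
  # single censoring at t = 2, risk set {2, 3, 4}
  G <- censoring_km(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(G$jump_times, 2)
  expect_equal(G$values, 2 / 3)
  expect_equal(eval_censoring_km(G, c(0.5, 1.99, 2, 5)),
               c(1, 1, 2 / 3, 2 / 3))
  expect_equal(eval_censoring_km(G, c(2, 2.01), left = TRUE), c(1, 2 / 3))

  set.seed(11)
  for (i in 1:20) {
    fx <- random_fixture(sample(4:12, 1))
    G <- censoring_km(fx$time, fx$status)
    tt <- c(fx$time, fx$time - 0.5, max(fx$time) + 1)
    expect_equal(eval_censoring_km(G, tt),
                 oracle_G(fx$time, fx$status, tt))
    expect_equal(eval_censoring_km(G, tt, left = TRUE),
                 oracle_G(fx$time, fx$status, tt, left = TRUE))
  }
})

test_that("censoring KM degenerate inputs behave as documented", {
  G <- censoring_km(c(1, 2, 3), c(1, 1, 1))      # no censoring at all
  expect_equal(eval_censoring_km(G, c(0.1, 10)), c(1, 1))
  expect_error(censoring_km(5, 1), "at least two")
  # values are a non-increasing survival curve starting at <= 1
  set.seed(4)
  fx <- random_fixture(12, cens_prob = 0.6)
  G <- censoring_km(fx$time, fx$status)
  expect_true(all(diff(G$values) <= 0))
  expect_true(all(G$values >= 0 & G$values <= 1))
})

test_that("IPCW weights follow status / G(t-)^2", {
  t <- c(1, 2, 3, 4); d <- c(1, 0, 1, 1)
  expect_equal(ipcw_weights(t, d), c(1, 0, 2.25, 2.25))
  expect_equal(ipcw_weights(1:4, rep(1, 4)), rep(1, 4))  # no censoring
  set.seed(2)
  for (i in 1:10) {
    fx <- random_fixture(10, cens_prob = 0.4)
    expect_equal(ipcw_weights(fx$time, fx$status),
                 oracle_weights(fx$time, fx$status))
  }
})

test_that("Uno estimator reproduces hand-derived fixtures", {
  expect_equal(cindex(1:4, rep(1, 4), eta = c(4, 3, 2, 1)), 1)
  expect_equal(cindex(1:4, rep(1, 4), eta = c(4, 3, 1, 2)), 5 / 6)
  expect_equal(cindex(c(1, 2, 3, 4), c(1, 0, 1, 1), eta = c(4, 3, 1, 2)),
               3 / 5.25)
  expect_error(cindex(c(1, 2), c(0, 0), eta = c(1, 2)), "no usable pair")
  expect_error(cindex(c(3, 3), c(1, 1), eta = c(1, 2)), "no usable pair")
})

test_that("all estimators agree with exhaustive pair enumeration (n <= 12)", {
  set.seed(21)
  for (i in 1:20) {
    fx <- random_fixture(sample(5:12, 1), cens_prob = 0.3)
    expect_equal(cindex(fx$time, fx$status, eta = fx$eta),
                 oracle_cindex(fx$time, fx$status, fx$eta))
    tau <- stats::quantile(fx$time, 0.8)
    ct <- try(oracle_cindex(fx$time, fx$status, fx$eta, "truncated",
                            tau = tau), silent = TRUE)
    if (!inherits(ct, "try-error") && is.finite(ct)) {
      expect_equal(cindex(fx$time, fx$status, eta = fx$eta,
                          method = "truncated", tau = tau), ct)
    }
    expect_equal(cindex(fx$time, fx$status, eta = fx$eta, method = "smooth",
                        sigma = 0.3),
                 oracle_cindex(fx$time, fx$status, fx$eta, "smooth",
                               sigma = 0.3))
  }
})

test_that("Uno estimator agrees with survival::concordance under n/G2", {
  set.seed(33)
  for (i in 1:8) {
    n <- 40
    tt <- rexp(n); dd <- rbinom(n, 1, 0.6); eta <- rnorm(n)
    if (sum(dd) < 3) dd[1:3] <- 1
    ref <- survival::concordance(survival::Surv(tt, dd) ~ eta,
                                 reverse = TRUE, timewt = "n/G2")
    expect_equal(cindex(tt, dd, eta = eta), unname(ref$concordance))
  }
})

test_that("truncated estimator handles tau as specified", {
  t <- c(1, 2, 3, 4); d <- c(1, 0, 1, 1)
  expect_equal(cindex(t, d, eta = c(4, 3, 1, 2), method = "truncated",
                      tau = 2.5), 1)
  # no censoring and tau >= max time: truncated == Uno
  set.seed(5)
  tt <- sample(20, 8); eta <- rnorm(8)
  expect_equal(cindex(tt, rep(1, 8), eta = eta, method = "truncated",
                      tau = max(tt)),
               cindex(tt, rep(1, 8), eta = eta))
  expect_error(cindex(t, d, eta = 1:4, method = "truncated", tau = 0.5),
               "no event pair")
  expect_error(cindex(t, d, eta = 1:4, method = "truncated", tau = 99),
               "tau")
  expect_error(cindex(t, d, eta = 1:4, method = "truncated"), "required")
})

test_that("smoothed estimator limits and symmetry", {
  # all scores equal: every pair contributes K(0) = 1/2
  expect_equal(cindex(1:4, rep(1, 4), eta = rep(7, 4), method = "smooth",
                      sigma = 2), 0.5)
  set.seed(8)
  for (i in 1:10) {
    fx <- random_fixture(10, cens_prob = 0.25)
    uno <- cindex(fx$time, fx$status, eta = fx$eta)
    sm <- cindex(fx$time, fx$status, eta = fx$eta, method = "smooth",
                 sigma = 1e-4)
    expect_equal(sm, uno, tolerance = 1e-3)
    # exact antisymmetry of the sigmoid: C(eta) + C(-eta) = 1
    expect_equal(cindex(fx$time, fx$status, eta = fx$eta, method = "smooth") +
                   cindex(fx$time, fx$status, eta = -fx$eta,
                          method = "smooth"), 1)
    # Uno version holds without tied scores
    expect_equal(uno + cindex(fx$time, fx$status, eta = -fx$eta), 1)
  }
  expect_error(cindex(1:4, rep(1, 4), eta = 1:4, method = "smooth",
                      sigma = 0), "sigma")
})

test_that("estimators are invariant under score shifts and monotone maps", {
  set.seed(13)
  for (i in 1:10) {
    fx <- random_fixture(9, cens_prob = 0.3)
    base <- cindex(fx$time, fx$status, eta = fx$eta)
    expect_equal(cindex(fx$time, fx$status, eta = fx$eta + 17.3), base)
    expect_equal(cindex(fx$time, fx$status, eta = exp(fx$eta)), base)
    sm <- cindex(fx$time, fx$status, eta = fx$eta, method = "smooth")
    expect_equal(cindex(fx$time, fx$status, eta = fx$eta - 4,
                        method = "smooth"), sm)
  }
})

test_that("analytic gradient matches finite differences and conserves mass", {
  g <- cindex_gradient(c(1, 2), c(1, 1), eta = c(0, 0), sigma = 0.1)
  expect_equal(g, c(2.5, -2.5))   # single pair, K'(0) = 1/(4 sigma)

  set.seed(42)
  for (i in 1:20) {
    fx <- random_fixture(sample(6:12, 1), cens_prob = 0.3)
    sigma <- sample(c(0.05, 0.1, 0.5, 1), 1)
    ana <- cindex_gradient(fx$time, fx$status, eta = fx$eta, sigma = sigma)
    fd <- oracle_fd_gradient(fx$time, fx$status, fx$eta, sigma)
    expect_equal(ana, fd, tolerance = 1e-6)
    expect_lt(abs(sum(ana)), 1e-10)
  }
})

test_that("scores of the wrong length are rejected", {
  expect_error(cindex(1:4, rep(1, 4), eta = 1:3), "one score per subject")
  expect_error(cindex_gradient(1:4, rep(1, 4), eta = 1:5), "one score")
})
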
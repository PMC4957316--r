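# deliberately small fixtures: every check here has an exhaustive or
# analytic counterpart

make_informative <- function(n = 60, p = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  tt <- exp(-x[, 1] + 0.5 * rlogis(n))   # covariate 1 raises risk
  cens <- rexp(n, 1 / stats::median(tt))
  list(x = x, time = pmin(tt, cens), status = as.numeric(tt <= cens))
}

test_that("a single boosting iteration picks the base-learner RSS argmin", {
  d <- make_informative(n = 40, p = 6, seed = 7)
  fit <- cboost(d$x, d$time, d$status, mstop = 1)
  expect_equal(length(fit$selected), 1L)
  expect_equal(sum(coef(fit) != 0), 1L)

  # independent scan: slope-only least squares of the ascent direction on
  # each centered covariate; the engine's 1/n direction scaling does not
  # move the argmin
  u <- cindex_gradient(d$time, d$status, eta = rep(0, nrow(d$x)))
  xc <- scale(d$x, scale = FALSE)
  rss <- vapply(seq_len(ncol(xc)), function(l) {
    slope <- sum(xc[, l] * u) / sum(xc[, l]^2)
    sum((u - slope * xc[, l])^2)
  }, numeric(1))
  expect_equal(fit$selected, which.min(rss))
})

test_that("training smoothed C-index is non-decreasing for nu <= 0.1", {
  for (seed in 1:4) {
    d <- make_informative(n = 50, p = 4, seed = seed)
    fit <- cboost(d$x, d$time, d$status, mstop = 150, nu = 0.1)
    expect_true(all(diff(fit$score_path) > -1e-8))
    expect_true(all(fit$score_path > 0 & fit$score_path < 1))
  }
})

test_that("a rank-reversing covariate drives the training C-index to 1", {
  set.seed(3)
  n <- 40
  tt <- sample(200, n)
  x <- cbind(-rank(tt) + rnorm(n, sd = 1e-8), matrix(rnorm(3 * n), n, 3))
  fit <- cboost(x, tt, rep(1, n), mstop = 400)
  expect_gt(mean(fit$selection_sequence == 1), 0.9)
  expect_gt(cindex(tt, rep(1, n), eta = predict(fit, x)), 0.99)
})

test_that("boosting refuses degenerate samples and bad hyperparameters", {
  expect_error(cboost(matrix(1:4, 2, 2), c(3, 3), c(1, 1), mstop = 5),
               "no usable pair")
  expect_error(cboost(matrix(1:4, 2, 2), c(1, 2), c(0, 0), mstop = 5),
               "no usable pair")
  d <- make_informative()
  expect_error(cboost(d$x, d$time, d$status, mstop = 5, nu = 0), "nu")
  expect_error(cboost(d$x, d$time, d$status, mstop = 5, nu = 1.5), "nu")
  expect_error(cboost(d$x, d$time, d$status, mstop = 5, sigma = -1), "sigma")
  expect_error(cboost(d$x, d$time, d$status, mstop = 0), "mstop")
})

test_that("never-selected covariates keep exactly zero coefficients", {
  d <- make_informative(n = 50, p = 8, seed = 11)
  fit <- cboost(d$x, d$time, d$status, mstop = 60)
  unsel <- setdiff(seq_len(8), fit$selected)
  expect_true(length(unsel) > 0)
  expect_identical(unname(coef(fit)[unsel]), rep(0, length(unsel)))
  # constant columns can never be selected
  x2 <- cbind(d$x, const = 5)
  fit2 <- cboost(x2, d$time, d$status, mstop = 60)
  expect_false(9L %in% fit2$selected)
})

test_that("predictions are equivariant under covariate rescaling", {
  d <- make_informative(n = 50, p = 4, seed = 2)
  fit1 <- cboost(d$x, d$time, d$status, mstop = 80)
  x_scaled <- d$x
  x_scaled[, 2] <- d$x[, 2] * 10
  fit2 <- cboost(x_scaled, d$time, d$status, mstop = 80)
  expect_equal(fit1$selection_sequence, fit2$selection_sequence)
  expect_equal(predict(fit2, x_scaled), predict(fit1, d$x))
  expect_equal(coef(fit2)[2] * 10, coef(fit1)[2],
               ignore_attr = TRUE)
})

test_that("single-covariate fits recover the sign of the association", {
  set.seed(9)
  for (i in 1:5) {
    n <- 40
    x <- matrix(rnorm(n), n, 1)
    sgn <- sample(c(-1, 1), 1)
    tt <- exp(sgn * 2 * x[, 1] + 0.3 * rlogis(n))
    fit <- cboost(x, tt, rep(1, n), mstop = 50)
    tau_sign <- sign(stats::cor(x[, 1], -tt, method = "kendall"))
    expect_equal(sign(coef(fit)[1]), tau_sign, ignore_attr = TRUE)
  }
})

test_that("run-until-q stops at q distinct covariates", {
  d <- make_informative(n = 50, p = 5, seed = 5)
  f1 <- cboost(d$x, d$time, d$status, q = 1)
  expect_equal(length(f1$selected), 1L)
  expect_equal(f1$selection_sequence,
               rep(f1$selected, length(f1$selection_sequence)))

  fall <- cboost(d$x, d$time, d$status, q = 5, mstop = 5000)
  expect_equal(fall$selected, 1:5)
  expect_false(fall$hit_max_iter)
  # the stop is immediate: dropping the last iteration loses the q-th
  # distinct covariate
  sel <- fall$selection_sequence
  expect_equal(length(unique(sel[-length(sel)])), 4L)

  expect_error(cboost(d$x, d$time, d$status, q = 6), "cannot exceed")
  expect_warning(cboost(d$x, d$time, d$status, q = 5, mstop = 3),
                 "iteration cap")
})

test_that("until-q fits usually contain the informative covariates", {
  hits <- 0L
  for (seed in 1:25) {
    set.seed(100 + seed)
    n <- 100; p <- 20
    x <- matrix(rnorm(n * p), n, p)
    mu <- x[, 1:4] %*% c(1.5, 1, -1, -1.5)
    tt <- exp(mu + 0.5 * rlogis(n))
    fit <- suppressWarnings(cboost(x, tt, rep(1, n), q = 5))
    if (all(1:4 %in% fit$selected)) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * 25)
})

test_that("predict reproduces training scores and respects linearity", {
  d <- make_informative(n = 50, p = 4, seed = 4)
  fit <- cboost(d$x, d$time, d$status, mstop = 100)
  expect_equal(predict(fit, d$x), fit$eta)
  dup <- d$x[c(1, 1, 2), ]
  pr <- predict(fit, dup)
  expect_equal(pr[1], pr[2])
  expect_error(predict(fit, d$x[, 1:3]), "columns")
  # zero-coefficient model predicts zero
  f0 <- cboost(d$x, d$time, d$status, mstop = 1, nu = 1e-12)
  f0$coefficients[] <- 0
  expect_equal(unname(predict(f0, d$x)), rep(0, 50))
})

test_that("formula and matrix interfaces agree", {
  d <- make_informative(n = 40, p = 3, seed = 6)
  df <- data.frame(time = d$time, status = d$status, d$x)
  colnames(df)[3:5] <- c("a", "b", "c")
  f1 <- cboost(survival::Surv(time, status) ~ a + b + c, data = df,
               mstop = 50)
  f2 <- cboost(d$x, d$time, d$status, mstop = 50)
  expect_equal(unname(coef(f1)), unname(coef(f2)))
  expect_equal(f1$selection_sequence, f2$selection_sequence)
})
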
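test_that("MCMC recovers known scaling parameters with convergent chains", {
  set.seed(1001)
  n <- 40
  ff <- runif(n, 0.03, 0.25); N <- runif(n, 3e5, 8e5)
  z <- rnorm(n, 60 * ff * sqrt(N / 5e5), 1.5)
  post <- fit_z_scaling_mcmc(z, ff, N, n0 = 5e5, burnin = 500, keep = 1500,
                             seed = 1)
  expect_true(all(post$rhat < 1.05))
  expect_true(all(post$acceptance > 0.1 & post$acceptance < 0.6))
  ci_b <- quantile(post$draws[, "beta"], c(0.025, 0.975))
  expect_true(ci_b[1] <= 60 && 60 <= ci_b[2])
  ci_s <- quantile(post$draws[, "sigma_z"], c(0.025, 0.975))
  expect_true(ci_s[1] <= 2.2)                 # sigma_z not wildly off
  expect_true(all(post$draws[, "beta"] > 0))
  expect_true(all(post$draws[, "sigma_z"] >= 1))
  # determinism
  post2 <- fit_z_scaling_mcmc(z, ff, N, n0 = 5e5, burnin = 500, keep = 1500,
                              seed = 1)
  expect_identical(post$draws, post2$draws)
})

test_that("degenerate designs run but are weakly identified; tiny n errors", {
  set.seed(1002)
  z <- rnorm(20, 6, 1.5)
  ff <- rep(0.1, 20); N <- rep(5e5, 20)
  post <- fit_z_scaling_mcmc(z, ff, N, n0 = 5e5, burnin = 500, keep = 1500,
                             seed = 2)
  w_deg <- diff(quantile(post$draws[, "beta"], c(0.025, 0.975)))
  set.seed(1003)
  ffv <- runif(20, 0.03, 0.3)
  zv <- rnorm(20, 60 * ffv, 1.5)
  postv <- fit_z_scaling_mcmc(zv, ffv, N, n0 = 5e5, burnin = 500, keep = 1500,
                              seed = 2)
  w_inf <- diff(quantile(postv$draws[, "beta"], c(0.025, 0.975)))
  expect_gt(w_deg, w_inf)   # identical FF/N -> wider beta interval
  expect_error(fit_z_scaling_mcmc(zv[1:3], ffv[1:3], N[1:3]), ">= 5")
})

test_that("posterior interval width shrinks with more training positives", {
  widths <- sapply(c(20, 200), function(n) {
    set.seed(1004)
    ff <- runif(n, 0.03, 0.25); N <- runif(n, 3e5, 8e5)
    z <- rnorm(n, 60 * ff * sqrt(N / 5e5), 1.5)
    post <- fit_z_scaling_mcmc(z, ff, N, n0 = 5e5, burnin = 500, keep = 1500,
                               seed = 3)
    diff(quantile(post$draws[, "beta"], c(0.025, 0.975)))
  })
  expect_lt(widths[2], widths[1])
})

test_that("mock cohorts follow the plug-in scaling law and a standard-normal null", {
  point <- list(draws = matrix(c(60, 1), 1, 2,
                               dimnames = list(NULL, c("beta", "sigma_z"))),
                n0 = 5e5)
  m <- simulate_mock_cohort(point, function(n) rep(0.10, n),
                            function(n) rep(5e5, n), 5e4, 2e5, seed = 4)
  expect_lt(abs(mean(m$z_pos) - 6), 3 * 1 / sqrt(5e4))
  expect_lt(abs(mean(m$z_neg)), 3 / sqrt(2e5))
  expect_lt(abs(sd(m$z_neg) - 1), 0.01)
  expect_error(simulate_mock_cohort(list(draws = NULL), 0.1, 5e5), "empty")
})

test_that("ROC equals an exhaustive threshold recount and has the right extremes", {
  set.seed(1005)
  zp <- rnorm(1000, 3, 2); zn <- rnorm(1000)
  th <- seq(-2, 8, by = 0.05)
  roc <- roc_from_mocks(zp, zn, th)
  # brute-force recount oracle, bitwise equal
  sens_o <- vapply(th, function(t) mean(zp >= t), 0)
  spec_o <- vapply(th, function(t) mean(zn < t), 0)
  expect_identical(roc$sensitivity, sens_o)
  expect_identical(roc$specificity, spec_o)
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
  # separable case
  r1 <- roc_from_mocks(rep(10, 500), rnorm(1000), seq(0, 9, by = 1))
  expect_equal(attr(r1, "auc"), 1.0)
  expect_equal(r1$sensitivity[r1$threshold == 5], 1.0)
  # identical distributions: diagonal ROC, AUC ~ 0.5
  set.seed(1006)
  r0 <- roc_from_mocks(rnorm(5e4), rnorm(5e4), seq(-3, 3, by = 0.5))
  expect_lt(abs(attr(r0, "auc") - 0.5), 0.01)
  # AUC invariant under strictly increasing transforms
  r2 <- roc_from_mocks(exp(zp / 2), exp(zn / 2), seq(0, 10, by = 0.5))
  expect_equal(attr(r2, "auc"), attr(roc, "auc"))
  # guards
  expect_error(roc_from_mocks(numeric(0), zn), "nonempty")
  expect_error(roc_from_mocks(zp, zn, c(1, NA)), "finite")
  expect_error(roc_from_mocks(zp, zn, c(2, 1)), "increasing")
})

test_that("performance summaries aggregate with equal or incidence weights", {
  mk_roc <- function(sens) {
    structure(data.frame(threshold = 4, sensitivity = sens,
                         specificity = 0.999),
              class = c("ffa_roc", "data.frame"))
  }
  rocs <- list(chr21 = mk_roc(0.9), chr18 = mk_roc(1.0))
  s <- performance_summary(rocs, 4)
  expect_equal(s$sensitivity[s$region == "aggregate"], 0.95)
  sw <- performance_summary(rocs, 4, weights = c(chr21 = 0.9, chr18 = 0.1))
  expect_equal(sw$sensitivity[sw$region == "aggregate"], 0.91)
  expect_error(performance_summary(rocs, 3.7), "grid")
})

test_that("confusion metrics are exact and leave undefined metrics absent", {
  m <- confusion_metrics(tp = 9, fp = 1, tn = 99, fn = 1)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.99)
  m0 <- confusion_metrics(tp = 0, fp = 2, tn = 5, fn = 0)
  expect_true(is.na(m0$sensitivity))
  expect_equal(m0$specificity, 5 / 7)
  m1 <- confusion_metrics(tp = 5, fp = 0, tn = 0, fn = 0)
  expect_equal(m1$sensitivity, 1.0)
  expect_true(is.na(m1$specificity))
  expect_error(confusion_metrics(-1, 0, 0, 0), "nonnegative")
})
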
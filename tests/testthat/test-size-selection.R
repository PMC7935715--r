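test_that("retention probabilities match the closed-form normal-CDF oracle", {
  cfg <- default_config()
  mx <- fragment_length_mixture(0.04, cfg)
  # no selection
  r <- retention_probabilities(mx, size_selection_spec(Inf))
  expect_equal(unname(r), c(1, 1))
  # hard cutoff at 150 nt: fetal ~ N(143, 18) truncated at 0
  r <- retention_probabilities(mx, size_selection_spec(150))
  z0 <- pnorm(0, 143, 18)
  expect_equal(unname(r[["r_f"]]),
               (pnorm(150, 143, 18) - z0) / (1 - z0), tolerance = 1e-8)
  # spec-sheet oracle with sd 10: r_f = Phi(0.7)
  cfg2 <- cfg; cfg2$fetal_len_sd <- 10
  mx2 <- fragment_length_mixture(0.04, cfg2)
  r2 <- retention_probabilities(mx2, size_selection_spec(150))
  expect_equal(unname(r2[["r_f"]]), pnorm(0.7), tolerance = 1e-6)
  expect_gt(r[["r_f"]], r[["r_m"]])
  # degenerate point masses at 143/167 with cutoff 150: step function
  cfg3 <- cfg; cfg3$fetal_len_sd <- 0; cfg3$maternal_len_sd <- 0
  mx3 <- fragment_length_mixture(0.04, cfg3)
  expect_equal(unname(retention_probabilities(mx3, size_selection_spec(150))),
               c(1, 0))
  expect_error(retention_probabilities(mx3, size_selection_spec(100)),
               "empty library")
})

test_that("the solved cutoff reproduces the 140 nt target conditional mean", {
  mx <- fragment_length_mixture(0.04, default_config())
  spec <- solve_cutoff_for_target_mean(mx, 140)
  # independent re-evaluation by numerical integration
  achieved <- ffasim:::post_selection_mean(mx, spec)
  expect_lt(abs(achieved - 140), 0.1)
  # boundary: target at the pre-selection mean needs no selection
  s0 <- solve_cutoff_for_target_mean(mx, mx$pre_mean)
  expect_equal(s0$cutoff, Inf)
  # unachievable target below the support floor
  expect_error(solve_cutoff_for_target_mean(mx, 10), "achievable range")
  # soft logistic window solves too
  sl <- solve_cutoff_for_target_mean(mx, 140, mode = "logistic")
  expect_lt(abs(ffasim:::post_selection_mean(mx, sl) - 140), 0.1)
})

test_that("the FF gain law follows conditional-probability arithmetic", {
  g <- expected_ff_gain(0.04, 0.6, 0.2)
  expect_equal(g$ff_post, 0.024 / 0.216, tolerance = 1e-12)
  expect_equal(g$gain, (0.024 / 0.216) / 0.04, tolerance = 1e-12)
  # equal retention: no enrichment at any FF
  expect_true(all(expected_ff_gain(seq(0.05, 0.95, 0.1), 0.5, 0.5)$gain == 1))
  # gain decreases in ff; limits r_f/r_m at 0 and 1 at 1
  grid <- expected_ff_gain(seq(0.01, 0.4, by = 0.01), 0.6, 0.2)
  expect_true(all(diff(grid$gain) < 0))
  expect_equal(expected_ff_gain(0.30, 0.6, 0.2)$gain, 0.6 / (0.3 * 0.6 + 0.7 * 0.2),
               tolerance = 1e-12)
  expect_equal(expected_ff_gain(0, 0.6, 0.2)$gain, 3, tolerance = 1e-12)
  expect_equal(expected_ff_gain(1, 0.6, 0.2)$ff_post, 1)
  expect_equal(expected_ff_gain(0, 0.6, 0.2)$ff_post, 0)
})

test_that("molecular selection is the identity at full retention and purifies at r_m = 0", {
  cfg <- small_config()
  cfg$cohort_size <- 6
  cfg$karyotype_freqs <- c(euploid = 1)
  co <- simulate_cohort(cfg, seed = 2)
  id <- apply_size_selection(co, spec = size_selection_spec(Inf), config = cfg)
  expect_identical(id$counts, co$counts)
  expect_equal(id$manifest$protocol, rep("ffa", nrow(id$manifest)))

  # point-mass lengths, cutoff between them: maternal fully depleted
  cfg2 <- cfg; cfg2$fetal_len_sd <- 0; cfg2$maternal_len_sd <- 0
  cfg2$reamplify <- FALSE
  co2 <- simulate_cohort(cfg2, seed = 2)
  pure <- apply_size_selection(co2, spec = size_selection_spec(150),
                               config = cfg2)
  pats <- pure$manifest$control_type == "none"
  expect_true(all(pure$maternal[, pats] == 0))
  expect_true(all(pure$ff_post[pats] == 1))

  # missing compartment resolution is an error
  broken <- co; broken$fetal <- NULL
  expect_error(apply_size_selection(broken, config = cfg), "compartment")
})

test_that("realized FF gain matches the closed form within Monte Carlo error", {
  cfg <- default_config()
  g <- build_genome(cfg)
  mx <- fragment_length_mixture(0.04, cfg)
  spec <- solve_cutoff_for_target_mean(mx, 140)
  r <- retention_probabilities(mx, spec)
  set.seed(9)
  for (ff in c(0.02, 0.10, 0.30)) {
    bc <- sim_sample(fixed_profile(ff, "euploid", "XY"), g, cfg, depth = 2e5)
    f <- rbinom(length(bc$fetal), bc$fetal, r[["r_f"]])
    m <- rbinom(length(bc$maternal), bc$maternal, r[["r_m"]])
    realized <- sum(f) / (sum(f) + sum(m))
    expected <- expected_ff_gain(ff, r[["r_f"]], r[["r_m"]])$ff_post
    se <- sqrt(expected * (1 - expected) / (sum(f) + sum(m)))
    expect_lt(abs(realized - expected), 4 * se)
  }
})

test_that("bioinformatic re-weighting reduces to raw counts and to hard selection", {
  cfg <- small_config()
  g <- build_genome(cfg)
  mx <- fragment_length_mixture(0.10, cfg)
  set.seed(13)
  bc <- sim_sample(fixed_profile(0.10, "euploid", "XY"), g, cfg, depth = 5e4)
  w1 <- bioinformatic_weighting(bc, mx, function(l) rep(1, length(l)))
  expect_equal(w1$weighted, as.numeric(bc$total))
  expect_equal(w1$ff_weighted, sum(bc$fetal) / sum(bc$total))
  expect_error(bioinformatic_weighting(bc, mx, function(l) l - 200),
               "negative")
  # indicator weight = hard molecular selection without re-amplification:
  # effective FF gain matches the closed form
  spec <- size_selection_spec(150)
  r <- retention_probabilities(mx, spec)
  wi <- bioinformatic_weighting(bc, mx, function(l) as.numeric(l <= 150),
                                seed = 14)
  expected <- expected_ff_gain(0.10, r[["r_f"]], r[["r_m"]])$ff_post
  se <- sqrt(expected * (1 - expected) / sum(wi$weighted))
  expect_lt(abs(wi$ff_weighted - expected), 4 * se)
  # logistic weights still enrich
  wl <- bioinformatic_weighting(bc, mx,
                                function(l) 1 / (1 + exp((l - 150) / 5)),
                                seed = 15)
  expect_gt(wl$ff_weighted, 0.10)
})
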
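test_that("sample profiles respect the FF model and its degenerate limits", {
  cfg <- small_config()
  # b = 0, no noise: FF is exp(a) for everyone
  cfg$ff_bmi_slope <- 0; cfg$ff_log_sd <- 0
  set.seed(1)
  ffs <- replicate(20, draw_sample_profile(cfg)$true_ff)
  expect_true(all(abs(ffs - exp(cfg$ff_intercept)) < 1e-12))
})

test_that("FF is negatively correlated with BMI under defaults", {
  cfg <- default_config()
  set.seed(7)
  n <- 4000
  prof <- replicate(n, {
    p <- draw_sample_profile(cfg); c(p$bmi, p$true_ff)
  })
  ct <- cor.test(prof[1, ], prof[2, ])
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-10)
  # generator calibration: low-FF rate near the stated overall and
  # high-BMI-stratum rates (Monte Carlo tolerance at n = 4000)
  low <- prof[2, ] < 0.04
  expect_gt(mean(low), 0.037 - 3 * sqrt(0.037 * 0.963 / n))
  expect_lt(mean(low), 0.037 + 3 * sqrt(0.037 * 0.963 / n))
  hi <- prof[1, ] >= 40
  expect_gt(sum(hi), 30)
  se <- sqrt(0.16 * 0.84 / sum(hi))
  expect_lt(abs(mean(low[hi]) - 0.16), 3.5 * se)
})

test_that("karyotypes map to the correct compartment copy numbers", {
  g <- build_genome(small_config())
  ch <- g$bins$chrom
  cm <- karyotype_to_copy_map(fixed_profile(karyotype = "euploid", sex = "XY"), g)
  expect_true(all(cm$fetal[ch == "chrY"] == 1))
  expect_true(all(cm$maternal[ch == "chrY"] == 0))
  expect_true(all(cm$fetal[ch == "chrX"] == 1))
  expect_true(all(cm$maternal[ch == "chrX"] == 2))
  cm <- karyotype_to_copy_map(fixed_profile(karyotype = "T21", sex = "XX"), g)
  expect_true(all(cm$fetal[ch == "chr21"] == 3))
  expect_true(all(cm$fetal[ch == "chr20"] == 2))
  cm <- karyotype_to_copy_map(fixed_profile(karyotype = "microdeletion(22q11.2)",
                                            sex = "XX"), g)
  idx <- region_bin_index(g, "22q11.2")
  expect_true(all(cm$fetal[idx] == 1))
  expect_true(all(cm$fetal[setdiff(which(ch == "chr22"), idx)] == 2))
  for (sca in list(c("MX", 1, 0), c("TX", 3, 0), c("XXY", 2, 1), c("XYY", 1, 2))) {
    cm <- karyotype_to_copy_map(fixed_profile(karyotype = sca[1],
                                              sex = if (as.numeric(sca[3]) > 0) "XY" else "XX"), g)
    expect_true(all(cm$fetal[ch == "chrX"] == as.numeric(sca[2])), label = sca[1])
    expect_true(all(cm$fetal[ch == "chrY"] == as.numeric(sca[3])), label = sca[1])
  }
  expect_error(karyotype_to_copy_map(fixed_profile(karyotype = "T99"), g),
               "unknown karyotype")
  expect_error(karyotype_to_copy_map(fixed_profile(karyotype = "RAA(chr21)"), g),
               "RAA")
})

test_that("bin counts have the constructed expectations", {
  cfg <- default_config()
  g <- build_genome(cfg)
  # FF = 0: no fetal compartment, chrY only mapping background
  set.seed(3)
  p <- fixed_profile(ff = 0, sex = "XY")
  cfg0 <- cfg; cfg0$chry_background_meanlog <- -Inf
  bc <- sim_sample(p, g, cfg0, depth = 2e5)
  expect_true(all(bc$fetal == 0))
  expect_true(all(bc$total[g$bins$chrom == "chrY"] == 0))
  # total is conserved between compartments
  expect_identical(bc$total, bc$fetal + bc$maternal)
  # XY euploid at FF = 0.1: chrY depth ratio ~ FF/2; T21: chr21 ratio ~ 1+FF/2
  nrep <- 40
  set.seed(4)
  yr <- replicate(nrep, sample_region_ratio(
    sim_sample(fixed_profile(0.1, "euploid", "XY"), g, cfg0, 5e5), g, "chrY"))
  se <- sd(yr) / sqrt(nrep)
  expect_lt(abs(mean(yr) - 0.05), 3 * se)
  tr <- replicate(nrep, sample_region_ratio(
    sim_sample(fixed_profile(0.1, "T21", "XX"), g, cfg0, 5e5), g, "chr21"))
  expect_lt(abs(mean(tr) - 1.05), 3 * sd(tr) / sqrt(nrep))
})

test_that("all-zero weights are an error", {
  cfg <- small_config()
  cfg$chry_background_meanlog <- -Inf
  g <- build_genome(cfg)
  p <- fixed_profile(ff = 0)
  cm <- karyotype_to_copy_map(p, g)
  cm$maternal[] <- 0
  expect_error(simulate_bin_counts(p, cm, g, depth = 1e4, config = cfg),
               "all-zero")
})

test_that("cohorts have the configured batch structure, controls and duplicates", {
  cfg <- small_config()
  cfg$cohort_size <- 21
  cfg$n_batches <- 1
  cfg$karyotype_freqs <- c(euploid = 20 / 21, T21 = 1 / 21)
  cfg$pooled_xx_per_batch <- 0
  co <- simulate_cohort(cfg, seed = 5)
  # 21 patients + NTC + pooled XY = 23 columns
  expect_equal(ncol(co$counts), 23)
  expect_equal(sum(co$manifest$control_type == "ntc"), 1)
  expect_equal(sum(co$manifest$control_type == "pooled_xy"), 1)
  expect_true(all(colnames(co$counts) == co$manifest$sample_id))

  # NTC with zero contamination: all-zero column
  cfg$ntc_rate <- 0
  co0 <- simulate_cohort(cfg, seed = 5)
  expect_true(all(co0$counts[, co0$manifest$control_type == "ntc"] == 0))

  # duplicated sample: same latent profile, two independent columns
  cfg2 <- small_config()
  cfg2$cohort_size <- 12; cfg2$n_batches <- 2; cfg2$duplicate_samples <- 1
  co2 <- simulate_cohort(cfg2, seed = 6)
  dup <- which(co2$manifest$sample_id == "S0001")
  expect_equal(length(dup), 2)
  expect_equal(length(unique(co2$manifest$batch_id[dup])), 2)
  expect_equal(co2$manifest$true_ff[dup[1]], co2$manifest$true_ff[dup[2]])
  expect_false(all(co2$counts[, dup[1]] == co2$counts[, dup[2]]))
})

test_that("cohort simulation is seed-deterministic and guards euploid-free batches", {
  cfg <- small_config()
  cfg$cohort_size <- 10
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$manifest, b$manifest)
  c3 <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(a$counts, c3$counts))

  cfg$karyotype_freqs <- c(euploid = 0, T21 = 1)
  expect_error(simulate_cohort(cfg, seed = 1), "zero euploid")
})
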
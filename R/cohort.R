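#' Draw one latent sample profile
#'
#' BMI is lognormal; FF follows `log(FF) = a - b*BMI + eps` with
#' `eps ~ N(0, sd^2)`, clipped to `[ff_min, ff_max]`, so FF is negatively
#' correlated with BMI. The karyotype is sampled from the configured class
#' frequencies; RAA chromosomes are drawn uniformly from autosomes other
#' than 13/18/21 and microdeletions uniformly from the configured regions.
#' Consumes the current RNG stream (seed upstream for determinism).
#'
#' @param config Run configuration.
#' @param sample_id,batch_id Identifiers stored in the profile.
#' @return List with `sample_id`, `batch_id`, `bmi`, `true_ff`, `karyotype`,
#'   `fetal_sex`, `protocol`, `control_type`.
#' @export
draw_sample_profile <- function(config, sample_id = "S1", batch_id = "B1") {
  validate_config(config)
  bmi <- stats::rlnorm(1, config$bmi_meanlog, config$bmi_sdlog)
  ff <- exp(config$ff_intercept - config$ff_bmi_slope * bmi +
            stats::rnorm(1, 0, config$ff_log_sd))
  ff <- min(max(ff, config$ff_min), config$ff_max)
  kf <- config$karyotype_freqs
  kclass <- sample(names(kf), 1, prob = kf)
  if (kclass != "euploid") ff <- max(ff, config$positive_ff_min)
  raa_pool <- setdiff(AUTOSOMES, COMMON_ANEUPLOIDY_CHROMS)
  karyotype <- switch(kclass,
    RAA = sprintf("RAA(%s)", sample(raa_pool, 1)),
    microdeletion = sprintf("microdeletion(%s)",
                            sample(names(config$microdeletions), 1)),
    kclass)
  fetal_sex <- switch(kclass,
    MX = "XX", TX = "XX", XXY = "XY", XYY = "XY",
    sample(c("XX", "XY"), 1))
  list(sample_id = sample_id, batch_id = batch_id, bmi = bmi, true_ff = ff,
       karyotype = karyotype, fetal_sex = fetal_sex, protocol = "standard",
       control_type = "none")
}

#' Per-bin copy numbers for the fetal and maternal compartments
#'
#' The maternal compartment is always 46,XX (2 copies on autosomes and chrX,
#' 0 on chrY). Fetal copies follow the karyotype: trisomy = 3 on the named
#' chromosome, microdeletion = 1 on the named region, MX = (X:1, Y:0),
#' TX = (X:3, Y:0), XXY = (X:2, Y:1), XYY = (X:1, Y:2); otherwise euploid
#' with XY = (1, 1) and XX = (2, 0).
#'
#' @param profile Sample profile (see [draw_sample_profile()]).
#' @param genome An `ffa_genome`.
#' @return List of numeric per-bin vectors `fetal`, `maternal`.
#' @export
karyotype_to_copy_map <- function(profile, genome) {
  chrom <- genome$bins$chrom
  maternal <- ifelse(chrom == "chrY", 0, 2)
  fetal <- rep(2, genome$n_bins)
  sex <- profile$fetal_sex
  fetal[chrom == "chrX"] <- if (identical(sex, "XY")) 1 else 2
  fetal[chrom == "chrY"] <- if (identical(sex, "XY")) 1 else 0

  k <- profile$karyotype
  if (is.na(k) || k == "" || k == "euploid") {
    # euploid: nothing further
  } else if (k %in% c("T13", "T18", "T21")) {
    fetal[chrom == paste0("chr", sub("T", "", k))] <- 3
  } else if (grepl("^RAA\\((chr[0-9]+)\\)$", k)) {
    ch <- sub("^RAA\\((chr[0-9]+)\\)$", "\\1", k)
    if (!ch %in% setdiff(AUTOSOMES, COMMON_ANEUPLOIDY_CHROMS))
      stop(sprintf("invalid RAA chromosome in karyotype '%s'", k))
    fetal[chrom == ch] <- 3
  } else if (grepl("^microdeletion\\((.+)\\)$", k)) {
    reg <- sub("^microdeletion\\((.+)\\)$", "\\1", k)
    fetal[region_bin_index(genome, reg)] <- 1
  } else if (k == "MX") {
    fetal[chrom == "chrX"] <- 1; fetal[chrom == "chrY"] <- 0
  } else if (k == "TX") {
    fetal[chrom == "chrX"] <- 3; fetal[chrom == "chrY"] <- 0
  } else if (k == "XXY") {
    fetal[chrom == "chrX"] <- 2; fetal[chrom == "chrY"] <- 1
  } else if (k == "XYY") {
    fetal[chrom == "chrX"] <- 1; fetal[chrom == "chrY"] <- 2
  } else {
    stop(sprintf("unknown karyotype label '%s'", k))
  }
  list(fetal = fetal, maternal = maternal)
}

# Deterministic mean-zero autosomal depth signature used to plant an
# FF-correlated signal for the ridge FF regression. Computed under its own
# seed so it is a fixed property of (genome, config), not of the cohort
# draw. The signature is projected orthogonal to every screened region
# (whole chromosomes and microdeletion intervals): the planted signal lives
# entirely within regions, so region mean ratios — and hence z-scores —
# are unaffected by it.
tilt_signature <- function(genome, config) {
  s <- withr_seed(config$tilt_seed, stats::rnorm(genome$n_bins, 0, config$tilt_sd))
  s[!genome$autosomal] <- 0
  auto <- which(genome$autosomal)
  X <- vapply(genome$region_bins[genome$regions$chrom %in% AUTOSOMES],
              function(idx) as.numeric(auto %in% idx), numeric(length(auto)))
  s[auto] <- stats::lm.fit(cbind(1, X), s[auto])$residuals
  s
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate per-bin fragment counts for one sample
#'
#' Expected total count in bin i is `N * w_i / sum(w)` with
#' `w_i = width * (FF * c_fetal(i)/2 + (1-FF) * c_maternal(i)/2) * t_i`,
#' where `t_i` is the planted FF-correlated depth tilt (1 when disabled).
#' Counts are drawn Poisson per (bin, compartment); a negative-binomial
#' option (`config$overdispersion > 0`) adds overdispersion.
#'
#' @param profile Sample profile; `true_ff` is the mixture weight.
#' @param copy_map Output of [karyotype_to_copy_map()].
#' @param genome An `ffa_genome`.
#' @param depth Total expected fragment count N.
#' @param config Run configuration.
#' @param tilt Optional precomputed signature from the generator.
#' @return List of integer per-bin vectors `total`, `fetal`, `maternal`.
#' @export
simulate_bin_counts <- function(profile, copy_map, genome, depth = config$depth,
                                config = default_config(), tilt = NULL) {
  stopifnot(depth >= 1)
  ff <- profile$true_ff
  if (is.null(tilt)) tilt <- tilt_signature(genome, config)
  tf <- pmax(1 + config$tilt_strength * ff * tilt, 0.01)
  wf <- ff * copy_map$fetal / 2 * tf
  wm <- (1 - ff) * copy_map$maternal / 2 * tf
  # per-library chrY mapping background (maternal compartment): mis-mapped
  # reads give every sample a small dispersed chrY floor
  if (config$chry_background_meanlog > -Inf) {
    eps <- stats::rlnorm(1, config$chry_background_meanlog,
                         config$chry_background_sdlog)
    wm[genome$bins$chrom == "chrY"] <- wm[genome$bins$chrom == "chrY"] + eps
  }
  tot <- sum(wf) + sum(wm)
  if (tot <= 0) stop("all-zero bin weights: nothing to sequence")
  lam_f <- depth * wf / tot
  lam_m <- depth * wm / tot
  draw <- function(lam) {
    if (config$overdispersion > 0)
      stats::rnbinom(length(lam), mu = lam, size = 1 / config$overdispersion)
    else stats::rpois(length(lam), lam)
  }
  fetal <- draw(lam_f); maternal <- draw(lam_m)
  list(total = fetal + maternal, fetal = fetal, maternal = maternal)
}

#' Simulate a full cohort with batch structure and controls
#'
#' Draws `cohort_size` patient samples (round-robin over `n_batches`
#' batches), adds per batch the configured no-template controls (NTC;
#' expected count `ntc_rate * depth`, maternal-compartment contamination
#' only) and pooled XX / XY euploid controls at the aggregate `pooled_ff`,
#' and simulates standard-protocol counts for every column. The first
#' `duplicate_samples` patient samples are re-sequenced in the following
#' batch (same latent profile, independent counts) for reproducibility
#' experiments.
#'
#' @param config Run configuration.
#' @param seed Integer seed; the run is fully reproducible given
#'   (config, seed).
#' @param profiles Optional list of patient profiles supplying the latent
#'   truth directly (experiment designs with fixed FF/karyotype); controls
#'   are still appended per batch. Default: draw `cohort_size` profiles.
#' @return An `ffa_cohort`: `manifest` (one row per sequenced column),
#'   `counts`/`fetal`/`maternal` (bins x columns integer matrices),
#'   `genome`, `config`.
#' @export
simulate_cohort <- function(config = default_config(), seed = config$seed,
                            profiles = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  genome <- build_genome(config)
  tilt <- tilt_signature(genome, config)
  batches <- paste0("B", seq_len(config$n_batches))

  if (is.null(profiles)) {
    profiles <- list()
    for (i in seq_len(config$cohort_size)) {
      profiles[[i]] <- draw_sample_profile(
        config, sample_id = sprintf("S%04d", i),
        batch_id = batches[((i - 1) %% config$n_batches) + 1])
    }
  } else {
    stopifnot(all(vapply(profiles, function(p) p$batch_id, "") %in% batches))
  }
  # duplicates: same latent profile, re-sequenced in the next batch
  ndup <- min(config$duplicate_samples, length(profiles))
  if (ndup > 0) {
    for (i in seq_len(ndup)) {
      p <- profiles[[i]]
      b <- match(p$batch_id, batches)
      p$batch_id <- batches[(b %% config$n_batches) + 1]
      profiles[[length(profiles) + 1]] <- p
    }
  }
  # controls per batch
  for (b in batches) {
    for (j in seq_len(config$ntc_per_batch))
      profiles[[length(profiles) + 1]] <- list(
        sample_id = sprintf("NTC_%s_%d", b, j), batch_id = b, bmi = NA,
        true_ff = 0, karyotype = "", fetal_sex = "XX",
        protocol = "standard", control_type = "ntc")
    for (j in seq_len(config$pooled_xx_per_batch))
      profiles[[length(profiles) + 1]] <- list(
        sample_id = sprintf("PXX_%s_%d", b, j), batch_id = b, bmi = NA,
        true_ff = config$pooled_ff, karyotype = "", fetal_sex = "XX",
        protocol = "standard", control_type = "pooled_xx")
    for (j in seq_len(config$pooled_xy_per_batch))
      profiles[[length(profiles) + 1]] <- list(
        sample_id = sprintf("PXY_%s_%d", b, j), batch_id = b, bmi = NA,
        true_ff = config$pooled_ff, karyotype = "", fetal_sex = "XY",
        protocol = "standard", control_type = "pooled_xy")
  }

  manifest <- do.call(rbind, lapply(profiles, function(p)
    data.frame(sample_id = p$sample_id, batch_id = p$batch_id, bmi = p$bmi,
               karyotype = p$karyotype, fetal_sex = p$fetal_sex,
               protocol = p$protocol, true_ff = p$true_ff,
               control_type = p$control_type, stringsAsFactors = FALSE)))
  rownames(manifest) <- NULL

  for (b in batches) {
    in_b <- manifest$batch_id == b & manifest$control_type == "none"
    if (!any(in_b & manifest$karyotype == "euploid"))
      stop(sprintf("batch %s has zero euploid samples: reference statistics impossible", b))
  }

  mats <- simulate_counts_matrix(profiles, genome, config, config$depth, tilt)
  structure(list(manifest = manifest, counts = mats$counts,
                 fetal = mats$fetal, maternal = mats$maternal,
                 genome = genome, config = config, profiles = profiles),
            class = "ffa_cohort")
}

# compartment count matrices for a list of profiles at a given depth
simulate_counts_matrix <- function(profiles, genome, config, depth, tilt) {
  n <- length(profiles)
  counts <- fetal <- maternal <- matrix(
    0L, nrow = genome$n_bins, ncol = n,
    dimnames = list(NULL, vapply(profiles, `[[`, "", "sample_id")))
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    if (identical(p$control_type, "ntc")) {
      lam <- config$ntc_rate * depth * rep(1 / genome$n_bins, genome$n_bins)
      m <- stats::rpois(genome$n_bins, lam)
      counts[, i] <- as.integer(m); maternal[, i] <- as.integer(m)
    } else {
      cm <- karyotype_to_copy_map(p, genome)
      bc <- simulate_bin_counts(p, cm, genome, depth = depth,
                                config = config, tilt = tilt)
      counts[, i] <- as.integer(bc$total)
      fetal[, i] <- as.integer(bc$fetal)
      maternal[, i] <- as.integer(bc$maternal)
    }
  }
  list(counts = counts, fetal = fetal, maternal = maternal)
}

#' Simulate a paired standard/FFA validation cohort
#'
#' Mirrors the validation design in which every patient sample is processed
#' through two independent workflows starting from replicate plasma
#' aliquots. The standard arm is sequenced at `config$depth`. The FFA arm
#' independently re-draws the sample's library at
#' `depth * library_oversample` molecules (cfDNA libraries are
#' molecule-rich relative to sequenced reads), applies molecular size
#' selection, and re-amplifies/sequences back to `config$depth`, so the two
#' arms are compared like-for-like in depth.
#'
#' @param config Run configuration.
#' @param seed Integer seed.
#' @param profiles Optional fixed patient profiles (see [simulate_cohort()]).
#' @return List of two `ffa_cohort`s, `standard` and `ffa` (same manifest
#'   and latent profiles; the FFA arm carries `ff_post`).
#' @export
simulate_paired_cohorts <- function(config = default_config(),
                                    seed = config$seed, profiles = NULL) {
  std <- simulate_cohort(config, seed = seed, profiles = profiles)
  lib <- std
  lib$config$depth <- config$depth * config$library_oversample
  mats <- simulate_counts_matrix(std$profiles, std$genome, lib$config,
                                 lib$config$depth,
                                 tilt_signature(std$genome, config))
  lib$counts <- mats$counts; lib$fetal <- mats$fetal
  lib$maternal <- mats$maternal
  ffa <- apply_size_selection(lib, config = config,
                              target_depth = config$depth)
  ffa$config <- config
  list(standard = std, ffa = ffa)
}

#' @export
print.ffa_cohort <- function(x, ...) {
  cat(sprintf("ffa_cohort: %d columns (%d patient samples), %d bins, protocol mix: %s\n",
              ncol(x$counts), sum(x$manifest$control_type == "none"),
              nrow(x$counts),
              paste(unique(x$manifest$protocol), collapse = "/")))
  invisible(x)
}
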
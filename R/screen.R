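#' Build euploid reference statistics for z-scoring
#'
#' Per region, the mean and SD of the mean region depth ratio across a
#' euploid reference cohort. Positives must be excluded by the caller
#' (manifest truth in simulation, prior calls in application mode).
#'
#' @param ratios [normalize_depth()] output for euploid reference samples.
#' @param genome An `ffa_genome`.
#' @param regions Region names (default: all screenable regions — common
#'   aneuploidies, RAAs, microdeletions and chrX).
#' @return Data frame `region, class, direction, mu_ref, sigma_ref, n_ref`
#'   of class `ffa_reference`.
#' @export
build_reference <- function(ratios, genome, regions = NULL) {
  if (is.null(regions)) {
    keep <- genome$regions$class %in%
      c("common_aneuploidy", "raa", "microdeletion", "sca_x")
    regions <- genome$regions$name[keep]
  }
  n_ref <- ncol(ratios)
  if (n_ref < 10)
    stop(sprintf("reference requires >= 10 euploid samples, got %d", n_ref))
  mr <- region_mean_ratios(ratios, genome, regions)
  mu <- rowMeans(mr)
  sigma <- apply(mr, 1, stats::sd)
  if (any(sigma <= 0))
    stop(sprintf("degenerate reference: zero variance in region %s",
                 regions[which(sigma <= 0)[1]]))
  meta <- genome$regions[match(regions, genome$regions$name), ]
  out <- data.frame(region = regions, class = meta$class,
                    direction = meta$direction, mu_ref = mu,
                    sigma_ref = sigma, n_ref = n_ref,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ffa_reference", "data.frame")
  out
}

#' Region z-score against a euploid reference
#'
#' `z = (ratio - mu_ref) / sigma_ref`. For loss-type regions
#' (microdeletions) the sign is flipped so that more positive z always
#' means more evidence for the abnormality.
#'
#' @param ratio Mean region depth ratio(s).
#' @param reference An `ffa_reference`.
#' @param region Region name within the reference.
#' @param directional Flip losses so evidence is positive (default TRUE).
#' @return Numeric z-score(s).
#' @export
region_z <- function(ratio, reference, region, directional = TRUE) {
  i <- match(region, reference$region)
  if (is.na(i)) stop(sprintf("region '%s' not covered by reference", region))
  z <- (ratio - reference$mu_ref[i]) / reference$sigma_ref[i]
  if (directional && reference$direction[i] == "loss") z <- -z
  z
}

#' Threshold directional z-scores into screen calls
#'
#' Positive iff the directional z meets or exceeds the threshold of the
#' region's class (a z exactly at threshold calls positive).
#'
#' @param z Named numeric or data frame with `region` and `z_score`.
#' @param reference An `ffa_reference` (for region classes).
#' @param thresholds Named per-class thresholds, e.g.
#'   `c(common_aneuploidy = 4, raa = 4, microdeletion = 4, sca_x = 4)`.
#' @return Character vector `"positive"`/`"negative"`.
#' @export
call_regions <- function(z, reference,
                         thresholds = default_config()$z_threshold) {
  if (is.data.frame(z)) {
    regs <- z$region; zz <- z$z_score
  } else { regs <- names(z); zz <- as.numeric(z) }
  cls <- reference$class[match(regs, reference$region)]
  if (anyNA(cls)) stop("z-scores include regions not in the reference")
  th <- thresholds[cls]
  if (anyNA(th))
    stop(sprintf("no z threshold configured for region class '%s'",
                 cls[which(is.na(th))[1]]))
  unname(ifelse(zz >= th, "positive", "negative"))
}

#' Two-dimensional chrX/chrY sex and SCA calling
#'
#' Works on the plane (chrX deviation `d_X = 2 * (1 - mean chrX ratio)`,
#' chrY fetal fraction `f_Y`). With baseline fetal fraction FF the
#' hypothesis points are: XX (0, 0); XY (FF, FF); MX (FF, 0); TX (-FF, 0);
#' XXY (0, FF); XYY (FF, 2 FF). A sample is assigned to the nearest
#' hypothesis within tolerance `tau = max(tau_frac * FF, tau_floor)`
#' (max-norm); ties and no match give `no-call`.
#'
#' @param d_x chrX deviation(s).
#' @param f_y chrY fetal fraction estimate(s).
#' @param ff_baseline Baseline FF per sample (regression estimate, or chrY
#'   estimate for clear-male samples).
#' @param tau_frac,tau_floor Tolerance band: fraction of FF and absolute
#'   floor.
#' @return Character vector of calls in
#'   `{XX, XY, MX, TX, XXY, XYY, no-call}`.
#' @export
call_sex_sca <- function(d_x, f_y, ff_baseline,
                         tau_frac = default_config()$sca_tolerance_frac,
                         tau_floor = default_config()$sca_tolerance_floor) {
  n <- max(length(d_x), length(f_y), length(ff_baseline))
  d_x <- rep_len(d_x, n); f_y <- rep_len(f_y, n)
  ff <- rep_len(ff_baseline, n)
  vapply(seq_len(n), function(i) {
    hyp <- rbind(XX = c(0, 0), XY = c(ff[i], ff[i]), MX = c(ff[i], 0),
                 TX = c(-ff[i], 0), XXY = c(0, ff[i]),
                 XYY = c(ff[i], 2 * ff[i]))
    tau <- max(tau_frac * ff[i], tau_floor)
    d <- pmax(abs(hyp[, 1] - d_x[i]), abs(hyp[, 2] - f_y[i]))
    inb <- which(d <= tau)
    if (length(inb) == 0) return("no-call")
    best <- inb[order(d[inb])]
    if (length(best) > 1 && abs(d[best[1]] - d[best[2]]) < 1e-12)
      return("no-call")
    rownames(hyp)[best[1]]
  }, "")
}

#' Screen a cohort end to end
#'
#' Normalizes depth, builds the euploid reference (from manifest truth;
#' controls and NTCs excluded), and for every sample x screenable region
#' computes the mean depth ratio, directional z, FF_positive and the
#' screen call. chrX/chrY two-dimensional sex/SCA calls are returned
#' separately.
#'
#' @param cohort An `ffa_cohort` (standard or FFA arm).
#' @param reference Optional precomputed `ffa_reference` (e.g. to score an
#'   FFA arm against its own arm's euploids).
#' @param thresholds Per-class z thresholds.
#' @param ff_method `"regression"` requires `ff_model`; `"chry"` uses the
#'   chrY estimate; `"truth"` uses manifest truth (simulation diagnostics).
#' @param ff_model Optional `ffa_ff_regression` for the SCA baseline FF.
#' @return List: `results` (one row per sample-region:
#'   `sample_id, region, depth_ratio, z_score, ff_positive, call`),
#'   `sex_calls`, `reference`, `ff` (per-sample baseline FF estimates).
#' @export
screen_cohort <- function(cohort, reference = NULL,
                          thresholds = cohort$config$z_threshold,
                          ff_method = c("chry", "regression", "truth"),
                          ff_model = NULL) {
  ff_method <- match.arg(ff_method)
  genome <- cohort$genome
  man <- cohort$manifest
  keep <- man$control_type != "ntc"
  counts <- cohort$counts[, keep, drop = FALSE]
  man <- man[keep, , drop = FALSE]
  ratios <- normalize_depth(counts, genome)

  if (is.null(reference)) {
    eu <- man$control_type == "none" & man$karyotype == "euploid"
    reference <- build_reference(ratios[, eu, drop = FALSE], genome)
  }
  screenable <- reference$region[reference$class %in%
                                   c("common_aneuploidy", "raa", "microdeletion")]
  mr <- region_mean_ratios(ratios, genome, screenable)

  res <- do.call(rbind, lapply(screenable, function(rg) {
    i <- match(rg, reference$region)
    z <- region_z(mr[rg, ], reference, rg)
    ffp <- 2 * abs(mr[rg, ] - 1)
    data.frame(sample_id = man$sample_id, batch_id = man$batch_id,
               region = rg, depth_ratio = as.numeric(mr[rg, ]),
               z_score = as.numeric(z), ff_positive = as.numeric(ffp),
               call = call_regions(stats::setNames(z, rep(rg, length(z))),
                                   reference, thresholds),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  # baseline FF for the 2D sex/SCA analysis; the baseline must be
  # independent of the chrX/chrY deviations or the SCA hypotheses collapse
  # onto the observed noise, so the regression estimate is preferred
  pxx <- man$control_type == "pooled_xx"
  bg0 <- estimate_ff_chry(ratios, genome)
  background <- if (any(pxx)) mean(bg0$raw[pxx]) else 0
  ffy <- estimate_ff_chry(ratios, genome, background = background)
  chrx <- region_mean_ratios(ratios, genome, "chrX")["chrX", ]
  d_x <- 2 * (1 - chrx)
  if (ff_method == "regression" && is.null(ff_model)) {
    xy_eu <- man$control_type == "none" & man$karyotype == "euploid" &
      man$fetal_sex == "XY"
    if (sum(xy_eu) >= 50) {
      ff_model <- train_ff_regression(ratios[, xy_eu, drop = FALSE],
                                      ffy$value[xy_eu], genome,
                                      lambda = cohort$config$ridge_lambda)
    } else ff_method <- "chry"   # too few training samples: heuristic calls
  }
  ff <- switch(ff_method,
    chry = pmax(ffy$value, abs(d_x)),
    truth = man$true_ff,
    regression = predict_ff_regression(ff_model, ratios)$value)
  tf <- cohort$config$sca_tolerance_frac
  tl <- cohort$config$sca_tolerance_floor
  if (ff_method == "chry") {
    # heuristic without an FF instrument for females: chrY carries the male
    # hypotheses; a female-side SCA needs a chrX deviation clear of noise
    calls <- call_sex_sca(d_x, ffy$value, ff, tf, tl)
    fem <- ffy$value < tl
    calls[fem] <- ifelse(abs(d_x[fem]) < 3 * tl, "XX",
                         ifelse(d_x[fem] > 0, "MX", "TX"))
    retry <- calls == "no-call"
    if (any(retry)) {
      alt <- call_sex_sca(d_x[retry], ffy$value[retry],
                          pmax(ffy$value[retry] / 2, abs(d_x[retry])), tf, tl)
      calls[retry][alt == "XYY"] <- "XYY"
    }
  } else {
    calls <- call_sex_sca(d_x, ffy$value, ff, tf, tl)
  }
  sex_calls <- data.frame(
    sample_id = man$sample_id, batch_id = man$batch_id,
    ff_chrx_deviation = as.numeric(d_x), ff_chry = ffy$value,
    ff_baseline = ff, call = calls,
    stringsAsFactors = FALSE, row.names = NULL)

  list(results = res, sex_calls = sex_calls, reference = reference,
       ff = data.frame(sample_id = man$sample_id, ff_chry = ffy$value,
                       ff_baseline = ff, stringsAsFactors = FALSE))
}
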
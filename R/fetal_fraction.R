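#' Normalize binned counts to depth ratios
#'
#' `ratio_i = (count_i / width_i) / m`, where `m` is a 1%-trimmed mean of
#' autosomal per-bin depth (`count / width`) for the sample. The trimmed
#' mean is robust to single-bin outliers while remaining continuous at the
#' small per-bin counts of a desk-scale simulation, so euploid disomic bins
#' have expected ratio 1 without discretization bias. A zero normalizer
#' (NTC-like column) is an error.
#'
#' @param counts Integer matrix (bins x samples) or per-bin vector.
#' @param genome An `ffa_genome`.
#' @return Matrix of depth ratios with attribute `normalizer` (per-sample
#'   mean autosomal per-bin depth, in counts per scaled bp x bin width).
#' @export
normalize_depth <- function(counts, genome) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  stopifnot(nrow(counts) == genome$n_bins)
  width <- genome$bins$end - genome$bins$start
  dep <- counts / width
  m <- apply(dep[genome$autosomal, , drop = FALSE], 2, mean, trim = 0.01)
  if (any(m <= 0)) {
    bad <- which(m <= 0)[1]
    id <- colnames(counts)[bad]
    stop(sprintf("insufficient depth: zero autosomal coverage in sample %s",
                 if (is.null(id)) bad else id))
  }
  ratios <- sweep(dep, 2, m, "/")
  attr(ratios, "normalizer") <- m * mean(width)  # counts per bin
  ratios
}

# mean region ratio per sample, regions x samples
region_mean_ratios <- function(ratios, genome, regions = genome$regions$name) {
  out <- vapply(regions, function(r) {
    colMeans(ratios[region_bin_index(genome, r), , drop = FALSE])
  }, numeric(ncol(ratios)))
  if (ncol(ratios) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, regions))
  t(out)
}

#' Estimate fetal fraction from chrY depth
#'
#' For a male-fetus pregnancy the fetal compartment carries one chrY copy
#' against zero maternal copies, so the expected chrY depth ratio is FF/2;
#' the estimator doubles the mean chrY ratio. Female-fetus samples return
#' ~0 (background only). The standard error is delta-method from the
#' implied chrY count total.
#'
#' @param ratios Output of [normalize_depth()].
#' @param genome An `ffa_genome`.
#' @param background chrY background level (FF units) subtracted before
#'   clipping — typically the mean uncorrected FF_chrY of pooled XX
#'   controls or known-female samples. `raw` stays uncorrected.
#' @return Data frame (`sample_id`, `method`, `value`, `raw`, `se`), one
#'   row per sample; `value` is clipped to `[0, 1]`, `raw` is not.
#' @export
estimate_ff_chry <- function(ratios, genome, background = 0) {
  idx <- region_bin_index(genome, "chrY")
  mr <- colMeans(ratios[idx, , drop = FALSE])
  raw <- 2 * mr
  lam <- attr(ratios, "normalizer")            # expected counts per bin
  se <- 2 * sqrt(pmax(mr, 1 / (length(idx) * lam)) / (length(idx) * lam))
  ids <- colnames(ratios)
  if (is.null(ids)) ids <- paste0("sample", seq_along(mr))
  data.frame(sample_id = ids, method = "chrY",
             value = pmin(pmax(raw - background, 0), 1), raw = raw, se = se,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate fetal fraction from an aneuploid region's depth deviation
#'
#' A fetal trisomy shifts the region's expected depth ratio to `1 + FF/2`
#' and a fetal deletion to `1 - FF/2`, so `FF_positive = 2 * |mean region
#' ratio - 1|`. The hypothesis direction (`gain` for trisomies/RAAs,
#' `loss` for microdeletions and monosomy X) is checked against the
#' observed sign; a mismatch is flagged, not an error.
#'
#' @param ratios Output of [normalize_depth()].
#' @param genome An `ffa_genome`.
#' @param region Region name.
#' @param direction `"gain"` or `"loss"`.
#' @return Data frame with `value` (FF_positive, clipped), `raw`, `se`,
#'   `depth_ratio` and `sign_mismatch`.
#' @export
estimate_ff_region <- function(ratios, genome, region,
                               direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  idx <- region_bin_index(genome, region)
  mr <- colMeans(ratios[idx, , drop = FALSE])
  dev <- mr - 1
  raw <- 2 * abs(dev)
  lam <- attr(ratios, "normalizer")
  se <- 2 * sqrt(pmax(mr, 0.25 / (length(idx) * lam)) / (length(idx) * lam))
  mismatch <- (direction == "gain" & dev < 0) | (direction == "loss" & dev > 0)
  ids <- colnames(ratios)
  if (is.null(ids)) ids <- paste0("sample", seq_along(mr))
  data.frame(sample_id = ids, method = "region", region = region,
             value = pmin(raw, 1), raw = raw, se = se, depth_ratio = mr,
             sign_mismatch = mismatch, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Train the ridge regression fetal-fraction model
#'
#' SeqFF-style estimator: ridge regression of chrY-derived FF labels on
#' autosomal bin depth ratios, trained on male-fetus euploid samples only.
#' Once trained it applies to pregnancies of either fetal sex.
#'
#' @param ratios Output of [normalize_depth()] for the training samples.
#' @param labels Numeric FF labels (typically `estimate_ff_chry()$value`).
#' @param genome An `ffa_genome`.
#' @param lambda Ridge penalty (glmnet `lambda`).
#' @return An `ffa_ff_regression`: fitted glmnet object, autosomal bin
#'   index, `lambda`, and training summary (`n`, `residual_sd`).
#' @export
train_ff_regression <- function(ratios, labels, genome,
                                lambda = default_config()$ridge_lambda) {
  stopifnot(length(labels) == ncol(ratios))
  if (ncol(ratios) < 50)
    stop(sprintf("insufficient training samples: %d < 50", ncol(ratios)))
  x <- t(ratios[genome$autosomal, , drop = FALSE])
  fit <- glmnet::glmnet(x, labels, alpha = 0, lambda = lambda,
                        standardize = TRUE, thresh = 1e-9)
  pred <- as.numeric(stats::predict(fit, newx = x, s = lambda))
  model <- list(fit = fit, lambda = lambda, autosomal = genome$autosomal,
                n_bins = genome$n_bins,
                n = ncol(ratios), residual_sd = stats::sd(labels - pred))
  class(model) <- "ffa_ff_regression"
  model
}

#' Predict fetal fraction with a trained regression model
#'
#' @param model An `ffa_ff_regression`.
#' @param ratios Output of [normalize_depth()] on the same genome binning.
#' @return Data frame (`sample_id`, `method`, `value`, `raw`, `se`); `se`
#'   is the model's training residual SD.
#' @export
predict_ff_regression <- function(model, ratios) {
  if (nrow(ratios) != model$n_bins)
    stop(sprintf("bin count mismatch: model %d vs ratios %d",
                 model$n_bins, nrow(ratios)))
  x <- t(ratios[model$autosomal, , drop = FALSE])
  raw <- as.numeric(stats::predict(model$fit, newx = x, s = model$lambda))
  ids <- colnames(ratios)
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(x)))
  data.frame(sample_id = ids, method = "regression",
             value = pmin(pmax(raw, 0), 1), raw = raw,
             se = model$residual_sd, stringsAsFactors = FALSE,
             row.names = NULL)
}
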
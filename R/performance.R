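#' Fit the z-score scaling law by Metropolis-Hastings MCMC
#'
#' Training phase of the two-phase ROC model. Observed positives supply
#' triplets (z, FF, N); the scaling law is
#' `z ~ Normal(beta * FF * sqrt(N / N0), sigma_z)` with `N0` a fixed
#' reference depth, half-normal priors `beta ~ HN(beta_prior_scale)` and
#' `sigma_z ~ 1 + HN(sigma_prior_scale)` (a positive cannot be less noisy
#' than the standard-normal null, hence the +1 shift). Sampling uses an
#' adaptive Gaussian random-walk Metropolis-Hastings targeting 20-40%
#' acceptance; convergence is assessed with the split-chain potential
#' scale reduction factor.
#'
#' @param z,ff,depth Numeric vectors (one entry per observed positive).
#' @param n0 Reference depth N0.
#' @param chains,burnin,keep MCMC geometry (default 4 x (2000 + 8000)).
#' @param beta_prior_scale,sigma_prior_scale Half-normal prior scales.
#' @param seed Integer seed; chains are seeded from it.
#' @param rhat_tol Accept the run only if all split-Rhat < this (1.05).
#' @return An `ffa_posterior`: `draws` (kept draws x 2, columns `beta`,
#'   `sigma_z`), `rhat`, `acceptance`, `n0`, `seed`.
#' @export
fit_z_scaling_mcmc <- function(z, ff, depth, n0 = default_config()$ref_depth,
                               chains = 4, burnin = 2000, keep = 8000,
                               beta_prior_scale = default_config()$beta_prior_scale,
                               sigma_prior_scale = default_config()$sigma_prior_scale,
                               seed = 1, rhat_tol = 1.05) {
  stopifnot(length(ff) == length(z), length(depth) == length(z))
  if (length(z) < 5)
    stop(sprintf("need >= 5 observed positives, got %d", length(z)))
  stopifnot(chains >= 4, beta_prior_scale > 0, sigma_prior_scale > 0)
  x <- ff * sqrt(depth / n0)

  log_post <- function(beta, sigma) {
    if (beta <= 0 || sigma < 1) return(-Inf)
    sum(stats::dnorm(z, beta * x, sigma, log = TRUE)) +
      stats::dnorm(beta, 0, beta_prior_scale, log = TRUE) +
      stats::dnorm(sigma - 1, 0, sigma_prior_scale, log = TRUE)
  }

  ls_beta <- max(sum(x * z) / sum(x^2), 1e-3)  # crude start
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, chains)
  run_chain <- function(cs) {
    set.seed(cs)
    th <- c(ls_beta * exp(stats::rnorm(1, 0, 0.3)),
            1 + abs(stats::rnorm(1, 0.5, 0.5)))
    lp <- log_post(th[1], th[2])
    # component-wise Metropolis with per-component adaptive scales;
    # sigma_z proposals reflect at the >= 1 boundary (symmetric on the
    # folded domain, so detailed balance is preserved)
    step <- c(max(ls_beta, 1) * 0.1, 0.2)
    acc_win <- n_win <- c(0, 0); acc_tot <- 0
    draws <- matrix(NA_real_, burnin + keep, 2)
    for (i in seq_len(burnin + keep)) {
      for (k in 1:2) {
        prop <- th
        if (k == 1) prop[1] <- th[1] + stats::rnorm(1) * step[1]
        else prop[2] <- 1 + abs(th[2] + stats::rnorm(1) * step[2] - 1)
        lp2 <- log_post(prop[1], prop[2])
        if (log(stats::runif(1)) < lp2 - lp) {
          th <- prop; lp <- lp2
          acc_win[k] <- acc_win[k] + 1
          if (i > burnin) acc_tot <- acc_tot + 0.5
        }
        n_win[k] <- n_win[k] + 1
      }
      if (i <= burnin && n_win[1] == 50) {   # adapt during burn-in only
        step <- step * exp(acc_win / n_win - 0.3)
        acc_win <- n_win <- c(0, 0)
      }
      draws[i, ] <- th
    }
    list(draws = draws[(burnin + 1):(burnin + keep), , drop = FALSE],
         acceptance = acc_tot / keep)
  }
  res <- lapply(chain_seeds, run_chain)
  arr <- lapply(res, `[[`, "draws")
  rhat <- c(beta = split_rhat(lapply(arr, function(m) m[, 1])),
            sigma_z = split_rhat(lapply(arr, function(m) m[, 2])))
  if (any(rhat >= rhat_tol))
    stop(sprintf(paste0("MCMC did not converge (max split-Rhat %.3f >= %.2f); ",
                        "rerun with longer chains"), max(rhat), rhat_tol))
  draws <- do.call(rbind, arr)
  colnames(draws) <- c("beta", "sigma_z")
  structure(list(draws = draws, rhat = rhat,
                 acceptance = vapply(res, `[[`, 0, "acceptance"),
                 n0 = n0, seed = seed, n_train = length(z)),
            class = "ffa_posterior")
}

# split-chain potential scale reduction factor (each chain halved)
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.ffa_posterior <- function(x, ...) {
  q <- apply(x$draws, 2, stats::quantile, c(0.025, 0.5, 0.975))
  cat(sprintf("ffa_posterior: %d draws from %d positives; beta %.1f [%.1f, %.1f], sigma_z %.2f [%.2f, %.2f]; max Rhat %.3f\n",
              nrow(x$draws), x$n_train, q[2, 1], q[1, 1], q[3, 1],
              q[2, 2], q[1, 2], q[3, 2], max(x$rhat)))
  invisible(x)
}

#' Simulate mock cohorts from the fitted scaling law
#'
#' Simulation phase of the ROC model: for each mock positive a posterior
#' draw (beta, sigma_z), an FF and a depth are drawn and
#' `z ~ Normal(beta * FF * sqrt(N/N0), sigma_z)`; mock negatives are
#' standard normal (the calibrated null of the z-score machinery).
#'
#' @param posterior An `ffa_posterior` (or a 1-row point-mass matrix with
#'   columns beta, sigma_z wrapped via `list(draws=..., n0=...)`).
#' @param ff_dist Function `n -> n` FF draws, or numeric vector resampled
#'   with replacement.
#' @param depth_dist Function or vector of depths N.
#' @param n_pos,n_neg Mock cohort sizes.
#' @param seed Integer seed.
#' @return List `z_pos`, `z_neg`.
#' @export
simulate_mock_cohort <- function(posterior, ff_dist, depth_dist,
                                 n_pos = 1e5, n_neg = 1e5, seed = 1) {
  draws <- posterior$draws
  if (is.null(draws) || nrow(draws) == 0) stop("empty posterior")
  set.seed(seed)
  draw_from <- function(spec, n)
    if (is.function(spec)) spec(n) else sample(spec, n, replace = TRUE)
  i <- sample.int(nrow(draws), n_pos, replace = TRUE)
  ffv <- draw_from(ff_dist, n_pos)
  nv <- draw_from(depth_dist, n_pos)
  mu <- draws[i, "beta"] * ffv * sqrt(nv / posterior$n0)
  list(z_pos = stats::rnorm(n_pos, mu, draws[i, "sigma_z"]),
       z_neg = stats::rnorm(n_neg))
}

#' ROC curve from mock z-score arrays
#'
#' At each threshold t: sensitivity = fraction of mock positives with
#' `z >= t`; specificity = fraction of mock negatives with `z < t`.
#' Sensitivity is non-increasing and specificity non-decreasing in t by
#' construction (asserted). AUC is the Mann-Whitney probability
#' `P(z_pos > z_neg) + 0.5 P(=)`, invariant under strictly increasing
#' transforms of z.
#'
#' @param z_pos,z_neg Mock z arrays (nonempty).
#' @param thresholds Increasing, finite threshold grid.
#' @return An `ffa_roc`: data frame `threshold, sensitivity, specificity`
#'   plus attribute `auc`.
#' @export
roc_from_mocks <- function(z_pos, z_neg,
                           thresholds = seq(0, 12, by = 0.1)) {
  if (length(z_pos) == 0 || length(z_neg) == 0)
    stop("both mock arrays must be nonempty")
  if (anyNA(thresholds) || any(!is.finite(thresholds)))
    stop("thresholds must be finite and non-NA")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  sp <- sort(z_pos); sn <- sort(z_neg)
  # findInterval(t, v, left.open=TRUE) counts v < t exactly (float-safe)
  n_pos_below <- findInterval(thresholds, sp, left.open = TRUE)
  sens <- (length(sp) - n_pos_below) / length(sp)
  spec <- findInterval(thresholds, sn, left.open = TRUE) / length(sn)
  stopifnot(all(diff(sens) <= 0), all(diff(spec) >= 0))
  r <- sum(rank(c(z_pos, z_neg))[seq_along(z_pos)])
  auc <- (r - length(z_pos) * (length(z_pos) + 1) / 2) /
    (as.numeric(length(z_pos)) * length(z_neg))
  structure(data.frame(threshold = thresholds, sensitivity = sens,
                       specificity = spec),
            auc = auc, class = c("ffa_roc", "data.frame"))
}

#' Full ROC model with posterior uncertainty
#'
#' Runs [simulate_mock_cohort()] + [roc_from_mocks()] pooled over the
#' posterior for the central curve, then repeats the curve for
#' `n_uncertainty_draws` individual posterior draws to attach 2.5/97.5
#' percentile intervals per threshold.
#'
#' @inheritParams simulate_mock_cohort
#' @param thresholds Threshold grid.
#' @param n_uncertainty_draws Posterior draws used for the interval sweep.
#' @param label Region or region-class label carried into the result.
#' @return An `ffa_roc` with interval columns `sens_lo, sens_hi, spec_lo,
#'   spec_hi` and attributes `auc`, `label`.
#' @export
roc_model <- function(posterior, ff_dist, depth_dist, n_pos = 1e5,
                      n_neg = 1e5, thresholds = seq(0, 12, by = 0.1),
                      n_uncertainty_draws = 200, seed = 1, label = "") {
  mocks <- simulate_mock_cohort(posterior, ff_dist, depth_dist,
                                n_pos, n_neg, seed = seed)
  roc <- roc_from_mocks(mocks$z_pos, mocks$z_neg, thresholds)
  set.seed(seed + 1L)
  idx <- sample.int(nrow(posterior$draws), n_uncertainty_draws, replace = TRUE)
  n_sub <- max(1000L, ceiling(n_pos / 20))
  sens_mat <- matrix(NA_real_, n_uncertainty_draws, length(thresholds))
  spec_mat <- matrix(NA_real_, n_uncertainty_draws, length(thresholds))
  for (k in seq_along(idx)) {
    pm <- list(draws = posterior$draws[idx[k], , drop = FALSE],
               n0 = posterior$n0)
    m <- simulate_mock_cohort(pm, ff_dist, depth_dist, n_sub, n_sub,
                              seed = seed + 1L + k)
    rk <- roc_from_mocks(m$z_pos, m$z_neg, thresholds)
    sens_mat[k, ] <- rk$sensitivity
    spec_mat[k, ] <- rk$specificity
  }
  roc$sens_lo <- apply(sens_mat, 2, stats::quantile, 0.025)
  roc$sens_hi <- apply(sens_mat, 2, stats::quantile, 0.975)
  roc$spec_lo <- apply(spec_mat, 2, stats::quantile, 0.025)
  roc$spec_hi <- apply(spec_mat, 2, stats::quantile, 0.975)
  attr(roc, "label") <- label
  roc
}

#' Sensitivity/specificity at a chosen threshold, per region and aggregate
#'
#' Table-shaped report of the ROC model. Regions within a class are
#' aggregated with equal weights unless `weights` (e.g. incidence) are
#' given.
#'
#' @param rocs Named list of `ffa_roc` objects (one per region).
#' @param threshold Calling threshold (must lie on each grid).
#' @param weights Optional named aggregation weights (normalized
#'   internally).
#' @return Data frame: one row per region plus an `aggregate` row, with
#'   sensitivity/specificity central values and interval bounds (percent).
#' @export
performance_summary <- function(rocs, threshold, weights = NULL) {
  if (is.null(names(rocs)) && inherits(rocs, "ffa_roc"))
    rocs <- list(region = rocs)
  pick <- function(roc, col) {
    i <- which(abs(roc$threshold - threshold) < 1e-9)
    if (length(i) != 1) stop("threshold not on the ROC grid")
    if (col %in% names(roc)) roc[[col]][i] else NA_real_
  }
  rows <- lapply(names(rocs), function(nm) {
    r <- rocs[[nm]]
    data.frame(region = nm, threshold = threshold,
               sensitivity = pick(r, "sensitivity"),
               sens_lo = pick(r, "sens_lo"), sens_hi = pick(r, "sens_hi"),
               specificity = pick(r, "specificity"),
               spec_lo = pick(r, "spec_lo"), spec_hi = pick(r, "spec_hi"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  w <- if (is.null(weights)) rep(1, nrow(out)) else weights[out$region]
  if (anyNA(w)) stop("weights must cover every region")
  w <- w / sum(w)
  agg <- out[1, ]
  agg$region <- "aggregate"
  for (col in c("sensitivity", "sens_lo", "sens_hi", "specificity",
                "spec_lo", "spec_hi"))
    agg[[col]] <- sum(w * out[[col]])
  rbind(out, agg)
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`. A
#' metric whose denominator is zero is undefined and reported as `NA`,
#' never as 0.
#'
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @return List with `sensitivity` and `specificity` (`NA` if undefined).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("confusion counts must be nonnegative integers")
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
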
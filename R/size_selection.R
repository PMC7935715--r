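#' Fragment-length mixture for cell-free DNA
#'
#' Two-compartment model of cfDNA fragment lengths: fetal fragments are
#' shorter on average than maternal ones. Each compartment is a normal
#' truncated to positive lengths (a point mass when `sd = 0`); the mixture
#' weight is the fetal fraction. With the defaults (fetal 143 +/- 18 nt,
#' maternal 167 +/- 20 nt) the pre-selection mean at low FF is ~165 nt.
#'
#' @param ff Fetal fraction (mixture weight) in `[0, 1]`.
#' @param config Run configuration supplying the four length parameters.
#' @return An object of class `ffa_length_mixture`.
#' @export
fragment_length_mixture <- function(ff = 0.04, config = default_config()) {
  stopifnot(ff >= 0, ff <= 1)
  m <- list(ff = ff,
            fetal = list(mean = config$fetal_len_mean, sd = config$fetal_len_sd),
            maternal = list(mean = config$maternal_len_mean,
                            sd = config$maternal_len_sd))
  if (m$fetal$mean >= m$maternal$mean)
    stop("fetal mean length must be below maternal mean length")
  m$pre_mean <- ff * trunc_norm_mean(m$fetal) + (1 - ff) * trunc_norm_mean(m$maternal)
  class(m) <- "ffa_length_mixture"
  m
}

# mean of a normal truncated to (0, Inf); exact for the point-mass case
trunc_norm_mean <- function(comp) {
  if (comp$sd == 0) return(comp$mean)
  a <- -comp$mean / comp$sd
  comp$mean + comp$sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# density of a compartment's length distribution on (0, Inf)
comp_density <- function(comp) {
  if (comp$sd == 0) stop("point-mass compartment has no density")
  z <- 1 - stats::pnorm(-comp$mean / comp$sd)
  function(x) ifelse(x > 0, stats::dnorm(x, comp$mean, comp$sd) / z, 0)
}

# P(length <= L) for a compartment
comp_cdf <- function(comp, L) {
  if (comp$sd == 0) return(as.numeric(comp$mean <= L))
  if (!is.finite(L)) return(as.numeric(L > 0))
  z <- 1 - stats::pnorm(-comp$mean / comp$sd)
  pmax(0, (stats::pnorm(L, comp$mean, comp$sd) -
             stats::pnorm(0, comp$mean, comp$sd)) / z)
}

#' Size-selection specification
#'
#' Either a hard length cutoff (`retain iff length <= cutoff`) or a soft
#' logistic window `1 / (1 + exp((length - cutoff) / scale))` standing in
#' for non-ideal gel elution.
#'
#' @param cutoff Cutoff length L in nt (`Inf` = no selection).
#' @param mode `"hard"` or `"logistic"`.
#' @param scale Logistic softness in nt (ignored for hard cutoffs).
#' @return An object of class `ffa_selection_spec`.
#' @export
size_selection_spec <- function(cutoff = Inf, mode = c("hard", "logistic"),
                                scale = 5) {
  mode <- match.arg(mode)
  stopifnot(cutoff > 0, scale > 0)
  structure(list(cutoff = cutoff, mode = mode, scale = scale),
            class = "ffa_selection_spec")
}

retention_fn <- function(spec) {
  if (spec$mode == "hard") function(x) as.numeric(x <= spec$cutoff)
  else function(x) 1 / (1 + exp((x - spec$cutoff) / spec$scale))
}

#' Per-compartment retention probabilities
#'
#' `r_c = P(retained | compartment c)`, obtained by integrating the
#' retention function against each compartment's length density (closed
#' form for hard cutoffs and point masses). Size selection enriches the
#' fetal compartment whenever `r_f > r_m`.
#'
#' @param mixture An `ffa_length_mixture`.
#' @param spec An `ffa_selection_spec`.
#' @return Named numeric `c(r_f, r_m)`.
#' @export
retention_probabilities <- function(mixture, spec) {
  ret <- retention_fn(spec)
  one <- function(comp) {
    if (comp$sd == 0) return(ret(comp$mean))
    if (spec$mode == "hard") return(comp_cdf(comp, spec$cutoff))
    f <- comp_density(comp)
    stats::integrate(function(x) ret(x) * f(x), 0, Inf,
                     rel.tol = 1e-10)$value
  }
  r <- c(r_f = one(mixture$fetal), r_m = one(mixture$maternal))
  if (all(r <= 0)) stop("retention is identically zero: empty library")
  r
}

# E[length | retained] under the mixture, by numerical integration
post_selection_mean <- function(mixture, spec) {
  ret <- retention_fn(spec)
  comp_int <- function(comp, moment) {
    if (comp$sd == 0) return(ret(comp$mean) * comp$mean^moment)
    f <- comp_density(comp)
    upper <- comp$mean + 12 * comp$sd
    stats::integrate(function(x) x^moment * ret(x) * f(x), 0, upper,
                     rel.tol = 1e-10)$value
  }
  w <- c(mixture$ff, 1 - mixture$ff)
  num <- w[1] * comp_int(mixture$fetal, 1) + w[2] * comp_int(mixture$maternal, 1)
  den <- w[1] * comp_int(mixture$fetal, 0) + w[2] * comp_int(mixture$maternal, 0)
  if (den <= 0) stop("retention is identically zero: empty library")
  num / den
}

#' Solve the cutoff achieving a target post-selection mean length
#'
#' Bisects on the cutoff L so that the mean fragment length among retained
#' fragments equals `target_mean` (default 140 nt) within `tol`.
#' Monotonicity of the conditional mean in L is asserted on a grid before
#' solving. A target at or above the pre-selection mean needs no selection
#' (`cutoff = Inf`); a target below the practical support floor (0.1%
#' mixture quantile) is an error.
#'
#' @param mixture An `ffa_length_mixture`.
#' @param target_mean Target post-selection mean length (nt).
#' @param mode Selection mode passed to [size_selection_spec()].
#' @param tol Solve tolerance on the conditional mean (nt).
#' @return An `ffa_selection_spec` with the solved cutoff and the achieved
#'   mean attached as attribute `achieved_mean`.
#' @export
solve_cutoff_for_target_mean <- function(mixture, target_mean = 140,
                                         mode = "hard", tol = 0.1) {
  if (target_mean >= mixture$pre_mean - tol)
    return(structure(size_selection_spec(Inf, mode),
                     achieved_mean = mixture$pre_mean))
  lo_len <- mixture_quantile(mixture, 1e-3)
  if (target_mean < lo_len)
    stop(sprintf("target mean %.1f nt below achievable range [%.1f, %.1f] nt",
                 target_mean, lo_len, mixture$pre_mean))
  cm <- function(L) post_selection_mean(mixture, size_selection_spec(L, mode))
  grid <- seq(lo_len, mixture$maternal$mean + 6 * max(1, mixture$maternal$sd),
              length.out = 25)
  vals <- vapply(grid, cm, 0)
  if (any(diff(vals) < -1e-6))
    stop("conditional mean is not monotone in the cutoff; cannot bisect")
  lo <- grid[1]; hi <- grid[length(grid)]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- cm(mid)
    if (abs(v - target_mean) < tol / 2) break
    if (v < target_mean) lo <- mid else hi <- mid
  }
  spec <- size_selection_spec(mid, mode)
  attr(spec, "achieved_mean") <- cm(mid)
  spec
}

# crude lower quantile of the length mixture (for the achievable floor)
mixture_quantile <- function(mixture, p) {
  q <- function(comp) if (comp$sd == 0) comp$mean else
    max(1, stats::qnorm(p, comp$mean, comp$sd))
  min(q(mixture$fetal), q(mixture$maternal))
}

#' Closed-form fetal-fraction gain under size selection
#'
#' With per-compartment retention probabilities `r_f` and `r_m`, the
#' post-selection fetal fraction is
#' `ff_post = ff * r_f / (ff * r_f + (1 - ff) * r_m)` and the gain is
#' `ff_post / ff`. The gain is strictly decreasing in ff when `r_f > r_m`,
#' approaching `r_f / r_m` as ff -> 0 and 1 as ff -> 1: low-FF samples gain
#' the most.
#'
#' @param ff Fetal fraction(s) in `[0, 1]` (0 and 1 handled as limits).
#' @param r_f,r_m Retention probabilities.
#' @return Data frame with columns `ff`, `ff_post`, `gain`.
#' @export
expected_ff_gain <- function(ff, r_f, r_m) {
  stopifnot(r_f > 0, r_f <= 1, r_m >= 0, r_m <= 1, all(ff >= 0), all(ff <= 1))
  ff_post <- ifelse(ff == 0, 0,
             ifelse(ff == 1, 1, ff * r_f / (ff * r_f + (1 - ff) * r_m)))
  data.frame(ff = ff, ff_post = ff_post,
             gain = ifelse(ff == 0, r_f / max(r_m, .Machine$double.eps),
                           ff_post / ff))
}

#' Apply in-silico size selection to a simulated cohort
#'
#' Thins each compartment's bin counts binomially with its retention
#' probability (the molecular analog of eluting short fragments), then, when
#' `config$reamplify` is on, re-amplifies each library back to its original
#' depth by multinomial resampling so FFA changes composition, not depth.
#' NTC columns are thinned but never re-amplified. The realized
#' post-selection fetal fraction of every column is recorded in
#' `$ff_post`.
#'
#' @param cohort An `ffa_cohort` with compartment-resolved counts.
#' @param spec An `ffa_selection_spec`; default solves the configured
#'   target mean for each sample's own length mixture is not needed —
#'   the cutoff is a property of the protocol, solved once at the
#'   configured reference FF.
#' @param config Run configuration (length mixture + `reamplify`).
#' @param seed Optional seed.
#' @param target_depth Re-amplification depth per sample (default: each
#'   sample's original total, i.e. like-for-like depth).
#' @return A new `ffa_cohort` with protocol `"ffa"`, updated counts, and
#'   `ff_post` (named per column).
#' @export
apply_size_selection <- function(cohort, spec = NULL,
                                 config = cohort$config, seed = NULL,
                                 target_depth = NULL) {
  if (is.null(cohort$fetal) || is.null(cohort$maternal))
    stop("compartment-resolved counts required: molecular selection needs latent origin")
  if (!is.null(seed)) set.seed(seed)
  mixture <- fragment_length_mixture(ff = 0.04, config = config)
  if (is.null(spec))
    spec <- solve_cutoff_for_target_mean(mixture, config$target_mean_length)
  r <- retention_probabilities(mixture, spec)

  out <- cohort
  n <- ncol(cohort$counts)
  nb <- nrow(cohort$counts)
  ff_post <- numeric(n)
  for (i in seq_len(n)) {
    f <- stats::rbinom(nb, cohort$fetal[, i], r[["r_f"]])
    m <- stats::rbinom(nb, cohort$maternal[, i], r[["r_m"]])
    K <- sum(f) + sum(m)
    is_ntc <- identical(cohort$manifest$control_type[i], "ntc")
    N0 <- if (is.null(target_depth)) sum(cohort$counts[, i]) else target_depth
    if (config$reamplify && !is_ntc && K > 0 && K != N0) {
      amp <- stats::rmultinom(1, N0, c(f, m) / K)
      f <- amp[seq_len(nb)]; m <- amp[nb + seq_len(nb)]
    }
    out$fetal[, i] <- as.integer(f)
    out$maternal[, i] <- as.integer(m)
    out$counts[, i] <- as.integer(f + m)
    tot <- sum(f) + sum(m)
    ff_post[i] <- if (tot > 0) sum(f) / tot else 0
  }
  names(ff_post) <- colnames(cohort$counts)
  out$manifest$protocol <- "ffa"
  out$ff_post <- ff_post
  out$selection <- list(spec = spec, retention = r)
  out
}

#' Bioinformatic fragment re-weighting (in-silico alternative to FFA)
#'
#' Instead of molecular selection upstream of sequencing, each sequenced
#' fragment can be weighted by a function of its length downstream, so the
#' weighted count of a bin is the sum of its fragments' weights. Fragment
#' lengths are drawn from the compartment length distributions on demand
#' (the simulation's stand-in for paired-end inferred lengths). With
#' `w(length) = 1` weighted counts equal raw counts; with an indicator
#' weight this reproduces hard molecular selection without re-amplification.
#'
#' @param bin_counts List with `fetal` and `maternal` per-bin integer counts
#'   for one sample.
#' @param mixture An `ffa_length_mixture` (compartment length laws).
#' @param weight_fn Function length (nt) -> nonnegative weight.
#' @param seed Optional seed for the length draws.
#' @return List: `weighted` (per-bin weighted counts), `weighted_fetal`,
#'   `weighted_maternal`, and the effective fetal fraction `ff_weighted`.
#' @export
bioinformatic_weighting <- function(bin_counts, mixture, weight_fn,
                                    seed = NULL) {
  if (is.null(bin_counts$fetal) || is.null(bin_counts$maternal))
    stop("compartment-resolved counts required")
  if (!is.null(seed)) set.seed(seed)
  one <- function(counts, comp) {
    nb <- length(counts)
    tot <- sum(counts)
    if (tot == 0) return(numeric(nb))
    lens <- rtrunc_norm(tot, comp)
    w <- weight_fn(lens)
    if (any(w < 0)) stop("negative fragment weights are not allowed")
    bin_of <- rep.int(seq_len(nb), counts)
    out <- numeric(nb)
    agg <- rowsum(w, bin_of)
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
  }
  wf <- one(bin_counts$fetal, mixture$fetal)
  wm <- one(bin_counts$maternal, mixture$maternal)
  tot <- sum(wf) + sum(wm)
  list(weighted = wf + wm, weighted_fetal = wf, weighted_maternal = wm,
       ff_weighted = if (tot > 0) sum(wf) / tot else 0)
}

# draw from a normal truncated to (0, Inf) by inverse-CDF
rtrunc_norm <- function(n, comp) {
  if (comp$sd == 0) return(rep(comp$mean, n))
  p0 <- stats::pnorm(0, comp$mean, comp$sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), comp$mean, comp$sd)
}
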
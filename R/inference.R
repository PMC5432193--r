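#' Template ensemble from a set of candidate tunings
#'
#' Builds the alignment templates for an ensemble of hypothesized neural
#' tunings: each tuning is mapped to its expected calcium template on the
#' shared covariates. The canonical ensemble is eight cosine tunings with
#' preferred directions uniformly spaced on \[0, 2*pi).
#'
#' @param tunings List of [tuning_model][linear_tuning()]s.
#' @param covariates Covariates shared by all tunings (see
#'   [rate_from_tuning()]).
#' @param tau Calcium decay constant (ms).
#' @return Object of class `"template_ensemble"`: parallel lists `tunings` and
#'   `templates`.
#' @export
template_ensemble <- function(tunings, covariates, tau = 200) {
  if (length(tunings) < 1) stop("ensemble must be non-empty")
  templates <- lapply(tunings, calcium_template, covariates = covariates,
                      tau = tau)
  structure(list(tunings = tunings, templates = templates),
            class = "template_ensemble")
}

#' Eight-direction cosine tuning ensemble
#'
#' @param directions Number of uniformly spaced preferred directions.
#' @param covariates List with `vx`, `vy` kinematics.
#' @param lambda_min,lambda_max Rate bounds (spikes/s).
#' @param ref_speed Reference speed (m/s).
#' @param tau Calcium decay constant (ms).
#' @return A [template_ensemble()].
#' @export
cosine_ensemble <- function(covariates, directions = 8, lambda_min = 10,
                            lambda_max = 150, ref_speed = 0.3, tau = 200) {
  thetas <- (seq_len(directions) - 1) * 2 * pi / directions
  tunings <- lapply(thetas, cosine_tuning, lambda_min = lambda_min,
                    lambda_max = lambda_max, ref_speed = ref_speed)
  template_ensemble(tunings, covariates, tau)
}

#' Maximum-likelihood template selection
#'
#' Aligns the strand to every template in the ensemble and returns the
#' alignment with the highest path log-likelihood (ties go to the lowest
#' template id). The intuition: the record should most closely resemble the
#' signal that generated it.
#'
#' @param errors Binary error strand or [recorder_output()].
#' @param ensemble A [template_ensemble()].
#' @param f An [error_function()].
#' @param kin A [kinetic_model()].
#' @param config An [alignment_config()].
#' @param mode Alignment mode, see [align_record()].
#' @return The winning `"strand_alignment"`, with `template_id` set and all
#'   per-template log-likelihoods attached as `ensemble_log_likelihoods`.
#' @export
select_template <- function(errors, ensemble, f, kin,
                            config = alignment_preset("center_out"),
                            mode = "binned") {
  lls <- rep(-Inf, length(ensemble$templates))
  best <- NULL
  for (m in seq_along(ensemble$templates)) {
    al <- align_record(errors, ensemble$templates[[m]], f, kin, config,
                       mode = mode)
    lls[m] <- al$log_likelihood
    if (is.null(best) || al$log_likelihood > best$log_likelihood) {
      best <- al
      best$template_id <- m
    }
  }
  best$ensemble_log_likelihoods <- lls
  best
}

#' Timing root-mean-square deviation (seconds)
#'
#' `variant = "standard"` is the conventional RMSD,
#' `sqrt(mean((tau - tau*)^2))`. `variant = "as_printed"` is the literal
#' `sqrt(sum((tau - tau*)^2)) / N` form some reports print; it differs from the
#' conventional definition by a factor `1/sqrt(N)` and is retained only for
#' fidelity comparisons.
#'
#' @param true_times,est_times Equal-length time vectors in ms.
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @return RMSD in seconds.
#' @export
timing_rmsd <- function(true_times, est_times,
                        variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (length(true_times) != length(est_times))
    stop("true and estimated time vectors differ in length")
  d2 <- ((true_times - est_times) / 1000)^2
  switch(variant,
         standard = sqrt(mean(d2)),
         as_printed = sqrt(sum(d2)) / length(d2))
}

#' Estimate stimulus-tuning slope from an aligned record
#'
#' Recovers the effective calcium-vs-stimulus slope from the error strand:
#' errors are looked up at the estimated incorporation times, binned into
#' `n_bins` equal-count bins of the covariate value, the per-bin error rates
#' are mapped back through the inverse error sigmoid to inferred calcium, and a
#' least-squares line of inferred calcium on covariate gives the estimated
#' slope `m*_ca`. The reference slope `m_ca` is the regression of the
#' ground-truth (standardized) calcium trace on the covariate trace; the
#' returned `slope_ratio` is `m*_ca / m_ca`.
#'
#' Empirical bin rates at or beyond the invertible range (0, r_max) are
#' clipped inward with a warning.
#'
#' @param errors Binary error strand or [recorder_output()].
#' @param est_times Estimated incorporation times (ms).
#' @param covariate Covariate [time_trace()] (e.g. the stimulus).
#' @param f An [error_function()].
#' @param true_calcium Ground-truth standardized calcium [time_trace()] used
#'   for the reference slope.
#' @param n_bins Number of equal-count covariate bins.
#' @return List with `slope_ratio`, `m_star` (estimated), `m_true`
#'   (reference), and the per-bin `curve` data frame.
#' @export
estimate_slope <- function(errors, est_times, covariate, f, true_calcium,
                           n_bins = 20) {
  if (inherits(errors, "recorder_output")) errors <- errors$errors
  x <- trace_value_at(covariate, est_times)
  ux <- unique(x)
  if (length(ux) < 2) stop("covariate is constant at the estimated times")
  if (length(ux) <= n_bins) {
    # piecewise-constant covariates: one bin per distinct level
    bin <- factor(x)
  } else {
    qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(x, qs, include.lowest = TRUE)
  }
  rate <- tapply(errors, bin, mean)
  xmid <- tapply(x, bin, mean)
  eps <- 1e-6
  lo <- f$r_max * eps
  hi <- f$r_max * (1 - eps)
  if (any(rate <= lo | rate >= hi, na.rm = TRUE))
    warning("bin error rates outside the invertible range were clipped")
  rate <- pmin(pmax(rate, lo), hi)
  keep <- !is.na(rate)
  c_hat <- error_rate_inverse(f, rate[keep])
  fit <- stats::lm(c_hat ~ xm, data = data.frame(c_hat = c_hat,
                                                 xm = xmid[keep]))
  m_star <- unname(stats::coef(fit)[2])
  ref <- stats::lm(ca ~ cv, data = data.frame(ca = true_calcium$values,
                                              cv = covariate$values))
  m_true <- unname(stats::coef(ref)[2])
  list(slope_ratio = m_star / m_true, m_star = m_star, m_true = m_true,
       curve = data.frame(covariate = as.numeric(xmid[keep]),
                          error_rate = as.numeric(rate[keep]),
                          calcium = as.numeric(c_hat)))
}

#' Estimate preferred direction from an aligned record
#'
#' Logistic GLM of the per-nucleotide error indicator on the x/y velocity
#' components sampled at the estimated incorporation times; the preferred
#' direction is the angle of the fitted velocity coefficient vector,
#' `theta* = atan2(beta_vy, beta_vx)`, wrapped to \[0, 2*pi).
#'
#' @param errors Binary error strand or [recorder_output()].
#' @param est_times Estimated incorporation times (ms).
#' @param vx,vy Velocity [time_trace()]s.
#' @return List with `theta_star` (radians) and the fitted `coefficients`.
#' @export
estimate_preferred_direction <- function(errors, est_times, vx, vy) {
  if (inherits(errors, "recorder_output")) errors <- errors$errors
  X <- data.frame(d = errors,
                  vx = trace_value_at(vx, est_times),
                  vy = trace_value_at(vy, est_times))
  if (stats::sd(X$vx) == 0 || stats::sd(X$vy) == 0)
    stop("degenerate design: a velocity component has zero variance")
  fit <- stats::glm(d ~ vx + vy, family = stats::binomial(), data = X)
  b <- stats::coef(fit)
  list(theta_star = atan2(b[["vy"]], b[["vx"]]) %% (2 * pi),
       coefficients = b)
}

#' Ground-truth preferred direction from spikes
#'
#' Poisson GLM of 1 ms-binned spike counts on the x/y velocity components —
#' the electrophysiology-style reference against which DNA-derived direction
#' estimates are judged. Also reports McFadden's pseudo-R^2,
#' `1 - logLik(model) / logLik(null)`.
#'
#' @param spikes A `spike_train`.
#' @param vx,vy Velocity [time_trace()]s on the spike clock.
#' @return List with `theta` (radians), `pseudo_r2`, `mean_rate` (spikes/s),
#'   and `coefficients`.
#' @export
ground_truth_pd <- function(spikes, vx, vy) {
  if (length(spikes$spikes) != length(vx$values))
    stop("spikes and kinematics must share a clock")
  X <- data.frame(y = spikes$spikes, vx = vx$values, vy = vy$values)
  if (stats::sd(X$vx) == 0 || stats::sd(X$vy) == 0)
    stop("degenerate design: a velocity component has zero variance")
  fit <- stats::glm(y ~ vx + vy, family = stats::poisson(), data = X)
  null <- stats::glm(y ~ 1, family = stats::poisson(), data = X)
  b <- stats::coef(fit)
  list(theta = atan2(b[["vy"]], b[["vx"]]) %% (2 * pi),
       pseudo_r2 = 1 - as.numeric(stats::logLik(fit)) /
         as.numeric(stats::logLik(null)),
       mean_rate = 1000 * mean(spikes$spikes) / spikes$sample_period,
       coefficients = b)
}

#' Filter a neuron population by rate and model fit
#'
#' Keeps neurons whose average firing rate exceeds `min_rate` and whose
#' velocity-GLM McFadden pseudo-R^2 exceeds `min_pr2` — the standard filter for
#' reach-modulated units.
#'
#' @param estimates List of per-neuron lists carrying `mean_rate` (spikes/s)
#'   and `pseudo_r2` (e.g. from [ground_truth_pd()]).
#' @param min_rate Minimum mean rate (spikes/s); default 20.
#' @param min_pr2 Minimum pseudo-R^2; default 0.05.
#' @return The surviving subset of `estimates`.
#' @export
population_filter <- function(estimates, min_rate = 20, min_pr2 = 0.05) {
  keep <- vapply(estimates, function(e)
    isTRUE(e$mean_rate > min_rate) && isTRUE(e$pseudo_r2 > min_pr2),
    logical(1))
  estimates[keep]
}

#' Shuffle aligned data streams in fixed-length patches
#'
#' Partitions every stream into patches of `patch_len` ms, applies one shared
#' random permutation of the full patches (a trailing partial patch stays in
#' place), and concatenates — disrupting the experiment's temporal structure
#' (e.g. the out-and-back regularity that confuses anti-tuned templates) while
#' keeping kinematics and spikes mutually aligned.
#'
#' @param streams Named list of [time_trace()]s and/or `spike_train`s sharing
#'   one clock and length.
#' @param patch_len Patch length in ms.
#' @param seed Optional integer seed for the permutation.
#' @return List with the shuffled `streams` and the `permutation` used.
#' @export
shuffle_patches <- function(streams, patch_len, seed = NULL) {
  val <- function(s) if (inherits(s, "spike_train")) s$spikes else s$values
  lens <- vapply(streams, function(s) length(val(s)), integer(1))
  pers <- vapply(streams, function(s) s$sample_period, numeric(1))
  if (length(unique(lens)) != 1 || length(unique(pers)) != 1)
    stop("streams must share length and sample period")
  n <- lens[1]
  m <- as.integer(round(patch_len / pers[1]))
  if (m < 1 || m > n) stop("patch length outside the recording")
  n_full <- n %/% m
  perm <- with_seed(seed, sample.int(n_full))
  reorder <- c(as.vector(outer(seq_len(m), (perm - 1) * m, `+`)),
               if (n_full * m < n) (n_full * m + 1):n)
  out <- lapply(streams, function(s) {
    v <- val(s)[reorder]
    if (inherits(s, "spike_train"))
      structure(list(spikes = v, sample_period = s$sample_period, t0 = s$t0),
                class = "spike_train")
    else time_trace(v, s$sample_period, s$t0)
  })
  list(streams = out, permutation = perm)
}

#' Percentile bootstrap confidence interval
#'
#' @param values Numeric sample (n >= 2, unless constant).
#' @param level Confidence level.
#' @param n_boot Number of bootstrap resamples.
#' @param stat Statistic: `"mean"` or `"median"`.
#' @param seed Optional integer seed.
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_boot = 2000,
                         stat = c("mean", "median"), seed = NULL) {
  stat <- match.arg(stat)
  fn <- if (stat == "mean") mean else stats::median
  if (length(values) < 2) stop("need at least two values")
  if (length(unique(values)) == 1)
    return(c(lo = values[1], hi = values[1]))
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    fn(sample(values, replace = TRUE)), numeric(1)))
  q <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Absolute angular error on the circle
#'
#' Wraps the difference of two angles to \[0, pi\].
#'
#' @param a,b Angles in radians.
#' @return Absolute circular distance in radians.
#' @export
circular_error <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
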
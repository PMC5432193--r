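#' Block-random stimulus trace
#'
#' Piecewise-constant stimulus: `n_blocks` blocks of `block_len_s` seconds,
#' each with intensity drawn Uniform(0, 1), sampled on the 1 ms simulation
#' clock. The canonical parameter-evaluation stimulus is 400 blocks of 5 s
#' (a 2000 s recording window).
#'
#' @param n_blocks Number of stimulation blocks.
#' @param block_len_s Block length in seconds.
#' @param seed Optional integer seed.
#' @return A [time_trace()] at 1 ms.
#' @export
make_block_stimulus <- function(n_blocks = 400, block_len_s = 5, seed = NULL) {
  stopifnot(n_blocks >= 1, block_len_s > 0)
  levels <- with_seed(seed, stats::runif(n_blocks))
  time_trace(rep(levels, each = round(block_len_s * 1000)), sample_period = 1)
}

#' Synthetic center-out reaching kinematics
#'
#' Minimum-jerk out-and-back reaches to `directions` uniformly spaced targets,
#' separated by stationary holds, on a 1 ms clock. A synthetic stand-in that
#' emulates the statistical structure of a center-out reaching task (the
#' out-then-immediately-back temporal structure that makes anti-tuned templates
#' confusable); it is not recorded primate kinematics.
#'
#' The speed profile of each half-reach is the minimum-jerk bell
#' `v(s) = peak_speed * 16 s^2 (1-s)^2`, `s = t / reach_dur`, whose maximum is
#' exactly `peak_speed` at mid-reach. Reach and hold durations are jittered
#' uniformly by `±dur_jitter` (fractional) per cycle, emulating the
#' trial-to-trial variability of self-paced reaching; with `dur_jitter = 0`
#' every cycle is identical and the task's temporal structure becomes exactly
#' periodic (which makes records alias against the reach comb).
#'
#' @param n_reaches Number of out-and-back reach cycles.
#' @param directions Number of uniformly spaced target directions.
#' @param reach_dur Nominal duration of each half-reach (ms).
#' @param hold_dur Nominal stationary hold between cycles (ms).
#' @param peak_speed Peak hand speed (m/s).
#' @param dur_jitter Fractional uniform jitter of reach and hold durations.
#' @param seed Optional seed for the random target sequence and jitter.
#' @param direction_sequence Optional integer vector of target indices
#'   (1-based) overriding the random sequence.
#' @return List of `vx`, `vy` ([time_trace()]s, m/s, 1 ms clock) and
#'   `directions_used` (target index per reach).
#' @export
make_center_out_kinematics <- function(n_reaches, directions = 8,
                                       reach_dur = 600, hold_dur = 400,
                                       peak_speed = 0.3, dur_jitter = 0.25,
                                       seed = NULL,
                                       direction_sequence = NULL) {
  stopifnot(directions >= 2, n_reaches >= 1, reach_dur > 0, hold_dur >= 0,
            dur_jitter >= 0, dur_jitter < 1)
  with_seed(seed, {
    dirs <- if (!is.null(direction_sequence)) {
      rep_len(as.integer(direction_sequence), n_reaches)
    } else {
      sample.int(directions, n_reaches, replace = TRUE)
    }
    rd <- round(reach_dur * stats::runif(n_reaches, 1 - dur_jitter,
                                         1 + dur_jitter))
    hd <- round(hold_dur * stats::runif(n_reaches, 1 - dur_jitter,
                                        1 + dur_jitter))
  })
  angles <- (dirs - 1) * 2 * pi / directions
  vx <- vector("list", n_reaches)
  vy <- vector("list", n_reaches)
  for (i in seq_len(n_reaches)) {
    s <- (seq_len(rd[i]) - 0.5) / rd[i]
    bell <- 16 * s^2 * (1 - s)^2
    bell <- peak_speed * bell / max(bell)   # exact peak on the sample grid
    v <- c(bell, -bell, numeric(hd[i]))   # out, back, hold
    vx[[i]] <- v * cos(angles[i])
    vy[[i]] <- v * sin(angles[i])
  }
  list(vx = time_trace(unlist(vx), 1), vy = time_trace(unlist(vy), 1),
       directions_used = dirs)
}

#' Gate kinematics (and companion streams) by hand speed
#'
#' Discards samples whose speed falls outside `[lo, hi]` and concatenates the
#' survivors, mirroring the preprocessing that drops near-stationary and
#' ballistic samples. The logical keep mask is returned so spike trains and
#' other streams on the same clock can be gated identically.
#'
#' @param vx,vy Velocity component [time_trace()]s on a shared clock.
#' @param lo,hi Speed bounds in m/s (inclusive).
#' @return List of gated `vx`, `vy` (re-indexed from t = 0), the logical
#'   `keep` mask, and `original_index` of survivors.
#' @export
speed_gate <- function(vx, vy, lo = 0.05, hi = 0.4) {
  stopifnot(length(vx$values) == length(vy$values),
            vx$sample_period == vy$sample_period)
  sp <- sqrt(vx$values^2 + vy$values^2)
  keep <- sp >= lo & sp <= hi
  if (!any(keep)) stop("speed gate removed every sample; unusable window")
  per <- vx$sample_period
  list(vx = time_trace(vx$values[keep], per),
       vy = time_trace(vy$values[keep], per),
       keep = keep,
       original_index = which(keep))
}

#' Neural tuning models
#'
#' `linear_tuning` maps a scalar stimulus to firing rate
#' `lambda_t = m * I_t + lambda_min` (spikes/ms). `cosine_tuning` maps planar
#' velocity to rate via speed-scaled cosine direction tuning:
#' \deqn{\lambda_t = \frac{s_t}{s_{ref}}\left[\lambda_{min} +
#'   (\lambda_{max}-\lambda_{min}) \frac{1 + \cos(\phi_t - \theta)}{2}\right]}
#' with `phi_t = atan2(vy, vx)` and `s_t` the instantaneous speed, so that
#' movement along the preferred direction at the reference speed fires at
#' `lambda_max` (spikes/s).
#'
#' @param m Stimulus slope, spikes/ms per unit stimulus.
#' @param lambda_min Baseline rate (spikes/ms for linear; spikes/s for cosine).
#' @return An object of class `"tuning_model"`.
#' @export
linear_tuning <- function(m = 0.05, lambda_min = 0) {
  structure(list(kind = "linear", m = m, lambda_min = lambda_min),
            class = "tuning_model")
}

#' @param theta Preferred direction in radians (wrapped to \[0, 2*pi)).
#' @param lambda_max Rate at the preferred direction and reference speed
#'   (spikes/s).
#' @param ref_speed Reference speed (m/s) at which the cosine rates are
#'   attained.
#' @rdname linear_tuning
#' @export
cosine_tuning <- function(theta, lambda_min = 10, lambda_max = 150,
                          ref_speed = 0.3) {
  if (lambda_min > lambda_max) stop("lambda_min must not exceed lambda_max")
  structure(list(kind = "cosine", theta = theta %% (2 * pi),
                 lambda_min = lambda_min, lambda_max = lambda_max,
                 ref_speed = ref_speed),
            class = "tuning_model")
}

#' @export
print.tuning_model <- function(x, ...) {
  if (x$kind == "linear")
    cat(sprintf("<tuning_model: linear> m = %g spk/ms/unit, lambda_min = %g spk/ms\n",
                x$m, x$lambda_min))
  else
    cat(sprintf("<tuning_model: cosine> theta = %.3f rad, %g-%g spk/s @ %g m/s\n",
                x$theta, x$lambda_min, x$lambda_max, x$ref_speed))
  invisible(x)
}

#' Expected firing rate from a tuning model
#'
#' Evaluates the tuning model on its covariates and returns the expected rate
#' as spikes per 1 ms bin (i.e. a Bernoulli probability per bin), clipped at 0.
#'
#' @param g A [linear_tuning()] or [cosine_tuning()].
#' @param covariates A single [time_trace()] (linear) or a list with `vx`, `vy`
#'   (cosine).
#' @return Rate [time_trace()], spikes/ms.
#' @export
rate_from_tuning <- function(g, covariates) {
  if (g$kind == "linear") {
    if (!inherits(covariates, "time_trace"))
      stop("linear tuning needs a single stimulus time_trace")
    lam <- g$m * covariates$values + g$lambda_min
    out <- time_trace(pmax(lam, 0), covariates$sample_period, covariates$t0)
  } else {
    if (!is.list(covariates) || !all(c("vx", "vy") %in% names(covariates)))
      stop("cosine tuning needs covariates list(vx, vy)")
    vx <- covariates$vx; vy <- covariates$vy
    if (length(vx$values) != length(vy$values) ||
        vx$sample_period != vy$sample_period)
      stop("vx and vy must share a clock")
    sp <- sqrt(vx$values^2 + vy$values^2)
    phi <- atan2(vy$values, vx$values)
    lam_s <- (sp / g$ref_speed) *
      (g$lambda_min + (g$lambda_max - g$lambda_min) *
         (1 + cos(phi - g$theta)) / 2)
    out <- time_trace(pmax(lam_s, 0) * vx$sample_period / 1000,
                      vx$sample_period, vx$t0)
  }
  out
}

#' Bernoulli spike train from a rate trace
#'
#' Draws `s_t ~ Bernoulli(lambda_t)` independently per bin. Rates are per-bin
#' probabilities and must not exceed 1.
#'
#' @param rate Rate [time_trace()] (spikes per bin).
#' @param seed Optional integer seed.
#' @return Object of class `"spike_train"`: binary `spikes` plus the clock.
#' @export
sample_spikes <- function(rate, seed = NULL) {
  if (any(rate$values > 1))
    stop("rate exceeds 1 spike per bin; refusing Bernoulli overflow")
  if (any(rate$values < 0)) stop("negative rates")
  s <- with_seed(seed,
                 stats::rbinom(length(rate$values), 1L, rate$values))
  structure(list(spikes = s, sample_period = rate$sample_period, t0 = rate$t0),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d bins @ %g ms, %d spikes (%.3g Hz)\n",
              length(x$spikes), x$sample_period, sum(x$spikes),
              1000 * mean(x$spikes) / x$sample_period))
  invisible(x)
}

#' Calcium trace from spikes (exponential indicator kernel)
#'
#' Causal convolution of the spike train with `exp(-t / tau)`, `t >= 0`, peak
#' 1, implemented as the exact AR(1) recursion
#' `c_t = exp(-dt/tau) * c_{t-1} + s_t`. One isolated spike decays to `exp(-1)`
#' after `tau` ms.
#'
#' @param s A `spike_train` (or [time_trace()] of per-bin counts/rates).
#' @param tau Indicator decay constant in ms (default 200 ms).
#' @return Calcium [time_trace()] on the spike clock (unstandardized).
#' @export
calcium_from_spikes <- function(s, tau = 200) {
  stopifnot(tau > 0)
  x <- if (inherits(s, "spike_train")) s$spikes else s$values
  a <- exp(-s$sample_period / tau)
  v <- as.numeric(stats::filter(x, a, method = "recursive"))
  time_trace(v, s$sample_period, s$t0)
}

#' Calcium template from a hypothesized tuning
#'
#' The alignment template for tuning `g`: the *expected* firing rate (not
#' sampled spikes) convolved with the same exponential calcium kernel, then
#' standardized to zero mean and unit variance so the error sigmoid's
#' half-maximum at 0 sits at the trace midpoint.
#'
#' @inheritParams rate_from_tuning
#' @param tau Calcium decay constant in ms.
#' @return Standardized template [time_trace()].
#' @export
calcium_template <- function(g, covariates, tau = 200) {
  lam <- rate_from_tuning(g, covariates)
  standardize_trace(calcium_from_spikes(lam, tau))
}
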
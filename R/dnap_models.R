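#' Calcium-dependent error transfer function
#'
#' The recorder polymerase's probability of misincorporating a nucleotide as a
#' sigmoid function of local calcium concentration,
#' \deqn{f(C) = R_{max} \cdot \frac{1}{1 + \exp[b (C - C_0)]}.}
#'
#' Note the sign convention: as written, `f` is *decreasing* in `C` for
#' `b > 0`. A recorder whose error rate rises with calcium (near-zero errors at
#' low calcium, saturating at `r_max` under high calcium) therefore uses a
#' negative `b`; the bundled experiment presets do exactly that, taking the
#' magnitude of the steepness from the published parameter tables.
#'
#' @param r_max Maximum error rate, in (0, 1].
#' @param b Sigmoid steepness, 1/(calcium unit). Sign sets the direction.
#' @param c0 Calcium concentration at half-maximum error rate.
#' @return An object of class `"error_function"`.
#' @examples
#' f <- error_function(r_max = 0.5, b = -1, c0 = 0)
#' error_rate(f, 0)       # half maximum = 0.25
#' error_rate_inverse(f, 0.25)
#' @export
error_function <- function(r_max, b, c0 = 0) {
  if (!is.finite(r_max) || r_max <= 0 || r_max > 1)
    stop("r_max must be in (0, 1]")
  if (!is.finite(b) || b == 0) stop("b must be nonzero and finite")
  structure(list(r_max = r_max, b = b, c0 = c0), class = "error_function")
}

#' @export
print.error_function <- function(x, ...) {
  cat(sprintf("<error_function> r_max = %g, b = %g, c0 = %g\n",
              x$r_max, x$b, x$c0))
  invisible(x)
}

#' Evaluate the error transfer function
#'
#' @param f An [error_function()].
#' @param c Calcium concentration(s); vectorized.
#' @return Error probability/ies in (0, r_max).
#' @export
error_rate <- function(f, c) {
  f$r_max / (1 + exp(f$b * (c - f$c0)))
}

#' Invert the error transfer function
#'
#' Returns the unique calcium concentration mapping to error rate `r`. Used to
#' transform an empirical error-tuning curve back to a calcium-tuning curve.
#'
#' @param f An [error_function()].
#' @param r Error rate(s) strictly inside (0, r_max).
#' @return Calcium concentration(s).
#' @export
error_rate_inverse <- function(f, r) {
  if (any(r <= 0 | r >= f$r_max))
    stop("r must lie strictly inside (0, r_max); the sigmoid is not invertible there")
  f$c0 + log(f$r_max / r - 1) / f$b
}

#' Polymerase inter-incorporation kinetics
#'
#' Mixture model for the waiting time U between successive nucleotide
#' incorporations: with probability `p_pause` the polymerase enters a pause,
#' drawn Exponential with mean `pause_mean`; otherwise an ordinary extension
#' interval drawn Gamma(`gamma_shape`, scale = `gamma_scale`). All durations in
#' ms.
#'
#' @param p_pause Pause probability per incorporation, in \[0, 1\].
#' @param pause_mean Mean pause duration (ms).
#' @param gamma_shape Gamma shape of the extension interval.
#' @param gamma_scale Gamma scale of the extension interval (ms).
#' @return An object of class `"kinetic_model"`.
#' @examples
#' kin <- kinetic_model(p_pause = 0.001, pause_mean = 2000,
#'                      gamma_shape = 1, gamma_scale = 10)
#' expected_interval(kin)  # ms
#' paused_fraction(kin)    # ~0.167
#' @export
kinetic_model <- function(p_pause, pause_mean = 2000, gamma_shape = 1,
                          gamma_scale = 10) {
  if (p_pause < 0 || p_pause > 1) stop("p_pause must be in [0, 1]")
  if (pause_mean <= 0 || gamma_shape <= 0 || gamma_scale <= 0)
    stop("durations and gamma parameters must be positive")
  structure(list(p_pause = p_pause, pause_mean = pause_mean,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf(
    "<kinetic_model> %g * Exp(mean %g ms) + %g * Gamma(%g, scale %g ms)\n",
    x$p_pause, x$pause_mean, 1 - x$p_pause, x$gamma_shape, x$gamma_scale))
  cat(sprintf("  expected interval %.3g ms (~%.3g Hz), paused fraction %.3g\n",
              expected_interval(x), 1000 / expected_interval(x),
              paused_fraction(x)))
  invisible(x)
}

#' Mean inter-incorporation interval (ms)
#'
#' Closed-form mixture mean `p_pause * pause_mean +
#' (1 - p_pause) * gamma_shape * gamma_scale`.
#'
#' @param kin A [kinetic_model()].
#' @export
expected_interval <- function(kin) {
  kin$p_pause * kin$pause_mean +
    (1 - kin$p_pause) * kin$gamma_shape * kin$gamma_scale
}

#' Expected fraction of recording time spent paused
#'
#' The share of total recording time contributed by the pause component of the
#' kinetic mixture: `p_pause * pause_mean / expected_interval(kin)`.
#'
#' @param kin A [kinetic_model()].
#' @export
paused_fraction <- function(kin) {
  kin$p_pause * kin$pause_mean / expected_interval(kin)
}

# Mixture CDF of U (ms); q vectorized.
interval_cdf <- function(kin, q) {
  kin$p_pause * stats::pexp(q, rate = 1 / kin$pause_mean) +
    (1 - kin$p_pause) * stats::pgamma(q, shape = kin$gamma_shape,
                                      scale = kin$gamma_scale)
}

#' Sample inter-incorporation intervals
#'
#' Continuous-time draws from the pause/extension mixture, with the pause
#' indicator returned for bookkeeping (e.g. measuring time spent paused).
#'
#' @param kin A [kinetic_model()].
#' @param n Number of intervals.
#' @param seed Optional integer seed.
#' @return List with `dt` (ms) and logical `paused`.
#' @export
sample_intervals <- function(kin, n, seed = NULL) {
  with_seed(seed, {
    paused <- stats::runif(n) < kin$p_pause
    dt <- numeric(n)
    np <- sum(paused)
    if (np > 0) dt[paused] <- stats::rexp(np, rate = 1 / kin$pause_mean)
    if (np < n) dt[!paused] <- stats::rgamma(n - np, shape = kin$gamma_shape,
                                             scale = kin$gamma_scale)
    list(dt = dt, paused = paused)
  })
}

#' Discretized kinetic lag prior
#'
#' Discretizes the continuous inter-incorporation mixture onto lag bins of
#' width `sample_period` (the template's post-decimation period), truncated at
#' the maximum backward search `k`, and renormalized. Bin `j` carries the
#' mixture mass on `((j-1) * sample_period, j * sample_period]`, computed
#' exactly by CDF differencing. Lag 0 is excluded: two nucleotides can never be
#' assigned the same template sample.
#'
#' @param kin A [kinetic_model()].
#' @param sample_period Lag bin width in ms; must divide `k`.
#' @param k Maximum backward search window in ms.
#' @return Object of class `"lag_prior"` with fields `log_pmf` (length
#'   `k / sample_period`), `k`, and `sample_period`.
#' @export
lag_log_pmf <- function(kin, sample_period, k) {
  if (k < sample_period) stop("k must be at least one sample period")
  n_lags <- k / sample_period
  if (abs(n_lags - round(n_lags)) > 1e-9)
    stop("sample_period must divide k")
  n_lags <- as.integer(round(n_lags))
  edges <- (0:n_lags) * sample_period
  mass <- diff(interval_cdf(kin, edges))
  if (sum(mass) <= 0) stop("no kinetic mass inside (0, k]")
  mass <- mass / sum(mass)
  lp <- ifelse(mass < 1e-15, -Inf, log(mass))
  structure(list(log_pmf = lp, k = k, sample_period = sample_period),
            class = "lag_prior")
}

#' Lag prior for binned alignments (inter-bin waiting time)
#'
#' When the strand is binned into `L_D`-nucleotide bins, the waiting time
#' between consecutive aligned rows is the sum of `L_D` inter-incorporation
#' intervals, not a single one. This computes the `L_D`-fold convolution of
#' the kinetic mixture (by FFT on a 1 ms grid), aggregates it onto lag bins of
#' width `sample_period`, truncates at the backward search window `k` — which
#' acts as an Itakura-style path-bounding band — and renormalizes. Lags whose
#' convolved mass is numerically zero are floored rather than made infeasible,
#' so the band, not the prior, defines feasibility.
#'
#' @inheritParams lag_log_pmf
#' @param L_D Nucleotides per strand bin.
#' @return A `"lag_prior"` (see [lag_log_pmf()]).
#' @export
bin_lag_log_pmf <- function(kin, L_D, sample_period, k) {
  L_D <- as.integer(L_D)
  if (L_D == 1L) return(lag_log_pmf(kin, sample_period, k))
  if (k < sample_period) stop("k must be at least one sample period")
  n_lags <- k / sample_period
  if (abs(n_lags - round(n_lags)) > 1e-9)
    stop("sample_period must divide k")
  if (abs(sample_period - round(sample_period)) > 1e-9)
    stop("sample_period must be an integer number of ms")
  n_lags <- as.integer(round(n_lags))
  sample_period <- as.integer(round(sample_period))
  mu <- L_D * expected_interval(kin)
  ex2 <- kin$p_pause * 2 * kin$pause_mean^2 +
    (1 - kin$p_pause) * kin$gamma_scale^2 * kin$gamma_shape *
      (kin$gamma_shape + 1)
  sd_bin <- sqrt(L_D * (ex2 - expected_interval(kin)^2))
  M <- 2^min(21, ceiling(log2(mu + 12 * sd_bin + k + 2 * sample_period)))
  m <- diff(interval_cdf(kin, 0:M))
  h <- Re(stats::fft(stats::fft(m)^L_D, inverse = TRUE)) / M
  h[h < 0] <- 0
  # index i of m is the 1 ms cell (i-1, i], midpoint i - 0.5; the convolution
  # coefficient at index u therefore represents a time sum of u - 1 + L_D/2 ms
  off <- round((L_D - 1) / 2)
  idx <- seq_len(n_lags * sample_period) - off
  keep <- idx >= 1 & idx <= length(h)
  grp <- rep(seq_len(n_lags), each = sample_period)[keep]
  mass <- numeric(n_lags)
  agg <- tapply(h[idx[keep]], grp, sum)
  mass[as.integer(names(agg))] <- as.numeric(agg)
  if (sum(mass) <= 0) stop("no kinetic mass inside the search window")
  mass <- mass / sum(mass)
  # lags with no kinetic mass are structurally infeasible, not merely unlikely
  lp <- ifelse(mass < 1e-12, -Inf, log(mass))
  structure(list(log_pmf = lp, k = n_lags * sample_period,
                 sample_period = sample_period),
            class = "lag_prior")
}

#' @export
print.lag_prior <- function(x, ...) {
  cat(sprintf("<lag_prior> %d lags of %g ms (k = %g ms)\n",
              length(x$log_pmf), x$sample_period, x$k))
  invisible(x)
}

#' Published polymerase parameter presets
#'
#' The three recorder polymerases used throughout: the center-out recorder
#' (rare 2 s pauses, ~100 Hz extension, ~17% of time paused), its pause-free
#' "optimized" variant, and the base parameter-evaluation recorder. All share
#' the sigmoid error function with `r_max = 0.5`, `|b| = 1`, `c0 = 0`; `b` is
#' negative here so that error rate rises with (standardized) calcium.
#'
#' The parameter-evaluation recorder uses `p_pause = 0.001`, i.e. the same
#' kinetics as the center-out recorder: an overall ~83 Hz incorporation rate
#' ("~100 Hz") with 2 s mean pauses occupying ~17% of recording time. (The
#' published parameter table lists 0.01 for this recorder, which would imply a
#' 33 Hz overall rate with two thirds of the recording spent paused,
#' contradicting the accompanying text; at that pause load records cannot be
#' aligned at all.)
#'
#' @param name One of `"center_out"`, `"center_out_optimized"`, `"base_eval"`.
#' @return List with `error_fun` ([error_function()]), `kinetics`
#'   ([kinetic_model()]), and `n_basepairs` (default record length).
#' @export
dnap_preset <- function(name = c("base_eval", "center_out",
                                 "center_out_optimized")) {
  name <- match.arg(name)
  ef <- error_function(r_max = 0.5, b = -1, c0 = 0)
  switch(name,
    center_out = list(
      error_fun = ef,
      kinetics = kinetic_model(0.001, 2000, 1, 10),
      n_basepairs = 12000),
    center_out_optimized = list(
      error_fun = ef,
      kinetics = kinetic_model(0, 2000, 1, 10),
      n_basepairs = 12000),
    base_eval = list(
      error_fun = ef,
      kinetics = kinetic_model(0.001, 2000, 1, 10),
      n_basepairs = 10000))
}
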
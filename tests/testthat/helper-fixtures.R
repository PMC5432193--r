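# Shared fixtures, built in code. Sizes are kept small; the full-scale
# experiment conditions live only in test-acceptance.R.

base_error_fun <- function() error_function(r_max = 0.5, b = -1, c0 = 0)

# Pause-free kinetics: Gamma(1, 10 ms) extension only.
kin_nopause <- function() kinetic_model(0, 2000, 1, 10)

# Recorder kinetics with rare 2 s pauses (center-out / parameter-eval).
kin_pausing <- function() kinetic_model(0.001, 2000, 1, 10)

# A small linear-tuning recording: stimulus, spikes, standardized calcium,
# template. `n_blocks` 5 s blocks at 1 ms.
small_recording <- function(n_blocks = 20, seed = 1) {
  stim <- make_block_stimulus(n_blocks, 5, seed = seed)
  tun <- linear_tuning(0.05, 0)
  spikes <- sample_spikes(rate_from_tuning(tun, stim), seed = seed + 1)
  list(stimulus = stim, tuning = tun, spikes = spikes,
       calcium = standardize_trace(calcium_from_spikes(spikes, 200)),
       template = calcium_template(tun, stim, 200),
       window = trace_duration(stim))
}

# Exhaustive-enumeration oracle for the DP: maximize the recursion-unrolled
# score over all strictly increasing paths with lags in {1..k}. Independent of
# the accumulate/trace_path implementation.
brute_force_align <- function(A, log_pmf, omega) {
  N <- nrow(A); Tp <- ncol(A); k <- length(log_pmf)
  best <- list(score = -Inf, path = NULL)
  recurse <- function(path, score) {
    n <- length(path)
    if (n == N) {
      if (score > best$score) best <<- list(score = score, path = path)
      return(invisible())
    }
    for (t in seq_len(Tp)) {
      lag <- t - path[n]
      if (lag < 1 || lag > k) next
      if (log_pmf[lag] == -Inf) next
      recurse(c(path, t),
              A[n + 1, t] + (1 - omega) * score + omega * log_pmf[lag])
    }
  }
  for (t1 in seq_len(Tp)) recurse(t1, A[1, t1])
  best
}

# Random feasible DP instance on a fixed seed.
random_instance <- function(N, Tp, k, seed) {
  set.seed(seed)
  A <- matrix(log(runif(N * Tp)), N, Tp)
  lp <- log(runif(k)); lp <- lp - log(sum(exp(lp)))
  prior <- structure(list(log_pmf = lp, k = k, sample_period = 1),
                     class = "lag_prior")
  list(A = A, prior = prior, omega = runif(1))
}
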
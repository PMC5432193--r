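# Probability floor applied before logs; -Inf is reserved for structurally
# infeasible cells (e.g. lags reaching before the template start).
.PROB_FLOOR <- 1e-12

#' Alignment hyperparameters
#'
#' `omega` weights the kinetic lag prior against accumulated similarity in the
#' dynamic-programming recursion; `k` is the maximum backward search window in
#' ms; `calcium_downsample` (L_C, ms/sample) and `dna_downsample` (L_D,
#' nucleotides/bin) set the resolution of the binned approximation.
#'
#' @param omega Kinetic-prior weight in \[0, 1\].
#' @param k Maximum backward search (ms); at least `calcium_downsample`.
#' @param calcium_downsample Template bin width L_C (ms/sample).
#' @param dna_downsample Strand bin size L_D (nucleotides/bin).
#' @return Object of class `"alignment_config"`.
#' @export
alignment_config <- function(omega = 1 / 100, k = 2000,
                             calcium_downsample = 50, dna_downsample = 100) {
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]")
  if (k < calcium_downsample) stop("k must be at least one template sample")
  if (dna_downsample < 1) stop("dna_downsample must be >= 1")
  structure(list(omega = omega, k = k,
                 calcium_downsample = calcium_downsample,
                 dna_downsample = dna_downsample),
            class = "alignment_config")
}

#' Published alignment parameter presets
#'
#' Defaults for the two experiment families: parameter-evaluation sweeps
#' (omega = 1/100, L_D = 100) and center-out experiments (omega = 1/240,
#' L_D = 25); both use k = 2000 ms and L_C = 50 ms.
#'
#' @param name `"parameter_eval"` or `"center_out"`.
#' @return An [alignment_config()].
#' @export
alignment_preset <- function(name = c("parameter_eval", "center_out")) {
  name <- match.arg(name)
  switch(name,
    parameter_eval = alignment_config(1 / 100, 2000, 50, 100),
    center_out     = alignment_config(1 / 240, 2000, 50, 25))
}

#' Per-nucleotide similarity matrix
#'
#' `A[n, t] = ln P(d_n | c*_t)`: the log-likelihood of strand element `d_n`
#' having been written at template sample `t`, i.e. `ln f(c*_t)` for an error
#' and `ln(1 - f(c*_t))` for a faithful incorporation. Probabilities are
#' floored at 1e-12 before the log.
#'
#' @param errors Binary error strand.
#' @param template Calcium template [time_trace()] (standardized).
#' @param f An [error_function()].
#' @return N x T' matrix of class `"similarity_matrix"` with the template
#'   sample times attached as attribute `"col_times"`.
#' @export
build_similarity <- function(errors, template, f) {
  errors <- as.integer(errors)
  p <- pmin(pmax(error_rate(f, template$values), .PROB_FLOOR), 1 - .PROB_FLOOR)
  lp1 <- log(p)
  lp0 <- log1p(-p)
  A <- matrix(0, nrow = length(errors), ncol = length(p))
  A[errors == 1L, ] <- rep(lp1, each = sum(errors == 1L))
  A[errors == 0L, ] <- rep(lp0, each = sum(errors == 0L))
  structure(A, col_times = trace_times(template), class = "similarity_matrix")
}

#' Bin an error strand for the downsampled approximation
#'
#' Sums errors over consecutive non-overlapping bins of `L_D` nucleotides; the
#' last bin may be smaller. Total error count is conserved.
#'
#' @param errors Binary error strand.
#' @param L_D Bin size in nucleotides (>= 1).
#' @return Integer vector of per-bin error counts with attribute
#'   `"bin_sizes"`.
#' @export
bin_errors <- function(errors, L_D) {
  stopifnot(L_D >= 1)
  L_D <- as.integer(L_D)
  n <- length(errors)
  grp <- (seq_len(n) - 1L) %/% L_D
  counts <- as.integer(tapply(as.integer(errors), grp, sum))
  sizes <- as.integer(tabulate(grp + 1L))
  structure(counts, bin_sizes = sizes)
}

#' Binned similarity matrix (binomial error counts)
#'
#' Downsampled analogue of [build_similarity()]: with `d'_{n'}` the error count
#' in bin `n'`, `A[n', t'] = ln Binomial(size_{n'}, f(c_t'))` evaluated at
#' `d'_{n'}`. The last, possibly partial, bin uses its actual size. Floored at
#' 1e-12 before the log.
#'
#' @param bin_counts Integer error counts from [bin_errors()].
#' @param template_binned Decimated template [time_trace()].
#' @param f An [error_function()].
#' @param L_D Nominal bin size (used when `bin_counts` carries no
#'   `"bin_sizes"` attribute).
#' @return Matrix of class `"similarity_matrix"`.
#' @export
build_binned_similarity <- function(bin_counts, template_binned, f, L_D) {
  sizes <- attr(bin_counts, "bin_sizes")
  if (is.null(sizes)) sizes <- rep(as.integer(L_D), length(bin_counts))
  if (any(bin_counts < 0 | bin_counts > sizes))
    stop("bin error count exceeds bin size")
  p <- pmin(pmax(error_rate(f, template_binned$values), .PROB_FLOOR),
            1 - .PROB_FLOOR)
  A <- matrix(0, nrow = length(bin_counts), ncol = length(p))
  for (i in seq_along(bin_counts)) {
    A[i, ] <- log(pmax(stats::dbinom(bin_counts[i], sizes[i], p), .PROB_FLOOR))
  }
  structure(A, col_times = trace_times(template_binned),
            class = "similarity_matrix")
}

#' Decimate a template by block averaging
#'
#' Bins the template into consecutive windows of width `L_C` and replaces each
#' by its mean, timestamped at the window midpoint. `L_C` must be a multiple of
#' the sample period; trailing samples that do not fill a window are dropped.
#'
#' @param template A [time_trace()].
#' @param L_C Target bin width in ms.
#' @return Decimated [time_trace()] with `sample_period = L_C`.
#' @export
decimate_template <- function(template, L_C) {
  m <- L_C / template$sample_period
  if (abs(m - round(m)) > 1e-9)
    stop("L_C must be a multiple of the template sample period")
  m <- as.integer(round(m))
  if (m == 1L) return(template)
  n_blocks <- length(template$values) %/% m
  if (n_blocks < 1) stop("template shorter than one decimation window")
  v <- colMeans(matrix(template$values[seq_len(n_blocks * m)], nrow = m))
  t0 <- template$t0 + (m - 1) * template$sample_period / 2
  time_trace(v, L_C, t0)
}

#' Dynamic-programming score accumulation with a kinetic lag prior
#'
#' Fills the accumulated score matrix
#' \deqn{S_{n,t} = A_{n,t} + \max_{j \in \{1..k\}} \left[(1-\omega)
#'   S_{n-1, t-j} + \omega \ln P(U = j)\right]}
#' with backpointers to the arg-max predecessor, initializing
#' `S[1, t] = A[1, t]` (plus an optional start-time log prior). Lags are
#' strictly positive — two strand elements can never share a template sample —
#' and cells whose lag would reach before the template start are infeasible
#' (-Inf). Ties break toward the smallest lag.
#'
#' Each row depends only on the previous row, so all cells of a row may be
#' computed concurrently. `method = "cpp"` (default) is a compiled kernel;
#' `method = "vectorized"` computes whole rows at once in R;
#' `method = "loop"` is the reference element-by-element recursion (it also
#' counts lag evaluations, returned as attribute `"n_lag_evals"`). All three
#' produce identical scores and backpointers.
#'
#' @param A A [build_similarity()] / [build_binned_similarity()] matrix
#'   (N x T').
#' @param prior A [lag_prior][lag_log_pmf()] on the template sample grid.
#' @param omega Kinetic-prior weight in \[0, 1\].
#' @param init_log_prior Optional length-T' start-time log prior added to row
#'   1 (not used by default).
#' @param method `"cpp"` (default), `"vectorized"`, or `"loop"`.
#' @return List with matrices `S` (scores) and `bp` (backpointer column
#'   indices; row 1 is NA).
#' @export
accumulate <- function(A, prior, omega, init_log_prior = NULL,
                       method = c("cpp", "vectorized", "loop")) {
  method <- match.arg(method)
  N <- nrow(A); Tp <- ncol(A)
  if (Tp < N)
    stop("infeasible alignment: fewer template samples than strand elements")
  lp <- prior$log_pmf
  k <- length(lp)
  if (method == "cpp") {
    out <- .accumulate_cpp(unclass(A), lp, omega, init_log_prior)
    return(list(S = out$S, bp = out$bp))
  }
  S <- matrix(NA_real_, N, Tp)
  bp <- matrix(NA_integer_, N, Tp)
  S[1, ] <- A[1, ] + if (is.null(init_log_prior)) 0 else init_log_prior
  if (N == 1L) return(list(S = S, bp = bp))

  if (method == "vectorized") {
    for (n in 2:N) {
      prev <- S[n - 1, ]
      base <- (1 - omega) * prev
      base[prev == -Inf] <- -Inf        # guard 0 * -Inf when omega = 1
      best <- rep(-Inf, Tp)
      arg <- rep(NA_integer_, Tp)
      for (j in seq_len(min(k, Tp - 1))) {
        if (lp[j] == -Inf) next   # structurally infeasible lag
        cand <- c(rep(-Inf, j), base[seq_len(Tp - j)] + omega * lp[j])
        upd <- cand > best                # strict: smallest lag wins ties
        if (any(upd)) {
          best[upd] <- cand[upd]
          arg[upd] <- which(upd) - j
        }
      }
      S[n, ] <- A[n, ] + best
      bp[n, ] <- arg
    }
  } else {
    n_evals <- 0L
    for (n in 2:N) {
      for (t in seq_len(Tp)) {
        best <- -Inf
        arg <- NA_integer_
        for (j in seq_len(min(k, t - 1))) {
          n_evals <- n_evals + 1L
          sp <- S[n - 1, t - j]
          cand <- if (sp == -Inf || lp[j] == -Inf) -Inf
                  else (1 - omega) * sp + omega * lp[j]
          if (cand > best) {
            best <- cand
            arg <- t - j
          }
        }
        S[n, t] <- A[n, t] + best
        bp[n, t] <- arg
      }
    }
    attr(S, "n_lag_evals") <- n_evals
  }
  list(S = S, bp = bp)
}

#' Trace back the maximum-likelihood path
#'
#' Selects the most likely final position `tau_N = argmax_t S[N, t]` (earliest
#' column on ties) and follows backpointers to recover the full strictly
#' increasing path.
#'
#' @param acc Output of [accumulate()].
#' @param col_times Optional template sample times (ms) to report; defaults to
#'   column indices.
#' @return Object of class `"strand_alignment"` with fields `times` (ms),
#'   `cols` (template column indices), and `log_likelihood`.
#' @export
trace_path <- function(acc, col_times = NULL) {
  S <- acc$S; bp <- acc$bp
  N <- nrow(S)
  if (all(S[N, ] == -Inf)) stop("no feasible alignment path")
  cols <- integer(N)
  cols[N] <- which.max(S[N, ])
  if (N > 1) for (n in N:2) {
    cols[n - 1] <- bp[n, cols[n]]
  }
  times <- if (is.null(col_times)) as.numeric(cols) else col_times[cols]
  structure(list(times = times, cols = cols,
                 log_likelihood = S[N, cols[N]],
                 n = N, mode = "raw", template_id = NA_integer_),
            class = "strand_alignment")
}

#' Interpolate a bin-level alignment to nucleotide resolution
#'
#' A binned alignment assigns one time per strand bin; this maps those times
#' back onto individual nucleotide indices by piecewise-linear interpolation,
#' anchoring each bin's time at the bin's midpoint index and extrapolating the
#' end segments linearly. Strict increase is then enforced with a minimum
#' separation of `min_sep` ms.
#'
#' @param bin_times Bin-level times (ms), strictly increasing.
#' @param L_D Bin size in nucleotides.
#' @param N Strand length in nucleotides.
#' @param min_sep Minimum separation between consecutive nucleotide times (ms).
#' @param lo,hi Optional support bounds (ms); end-segment extrapolation is
#'   clamped inside them.
#' @return Numeric vector of N strictly increasing times (ms).
#' @export
interpolate_alignment <- function(bin_times, L_D, N, min_sep = 1,
                                  lo = -Inf, hi = Inf) {
  L_D <- as.integer(L_D)
  if (L_D == 1L) {
    if (length(bin_times) != N) stop("bin count does not match strand length")
    return(as.numeric(bin_times))
  }
  nb <- length(bin_times)
  if (nb != ceiling(N / L_D)) stop("bin count does not cover the strand")
  idx <- seq_len(N)
  sizes <- c(rep(L_D, nb - 1), N - (nb - 1) * L_D)
  starts <- c(0L, cumsum(sizes)[-nb])
  mids <- starts + (sizes + 1) / 2
  if (nb == 1L) {
    out <- bin_times[1] + (idx - mids[1]) * min_sep
  } else {
    out <- stats::approx(mids, bin_times, xout = idx, rule = 2)$y
    head_ix <- idx < mids[1]
    tail_ix <- idx > mids[nb]
    s1 <- (bin_times[2] - bin_times[1]) / (mids[2] - mids[1])
    s2 <- (bin_times[nb] - bin_times[nb - 1]) / (mids[nb] - mids[nb - 1])
    out[head_ix] <- bin_times[1] + (idx[head_ix] - mids[1]) * s1
    out[tail_ix] <- bin_times[nb] + (idx[tail_ix] - mids[nb]) * s2
  }
  for (i in seq_len(N)[-1]) {
    if (out[i] <= out[i - 1] + min_sep) out[i] <- out[i - 1] + min_sep
  }
  if (is.finite(hi) || is.finite(lo)) {
    if (is.finite(hi) && is.finite(lo) && hi - lo < (N - 1) * min_sep)
      stop("support too short to hold the strand at the minimum separation")
    if (any(out > hi)) {
      out <- pmin(out, hi)
      for (i in (N - 1):1) {
        if (out[i] >= out[i + 1] - min_sep) out[i] <- out[i + 1] - min_sep
      }
    }
    if (any(out < lo)) {
      out <- pmax(out, lo)
      for (i in seq_len(N)[-1]) {
        if (out[i] <= out[i - 1] + min_sep) out[i] <- out[i - 1] + min_sep
      }
    }
  }
  out
}

#' Align an error strand to a calcium template
#'
#' End-to-end alignment: decimates the template to `L_C` resolution, bins the
#' strand into `L_D`-nucleotide bins (`mode = "binned"`), builds the local
#' log-likelihood matrix, discretizes the kinetic lag prior, runs the
#' dynamic-programming accumulation and traceback, and (in binned mode)
#' interpolates bin times back to nucleotide resolution. Deterministic given
#' its inputs.
#'
#' @param errors Binary error strand (or a [recorder_output()]).
#' @param template Calcium template [time_trace()] (standardized; see
#'   [calcium_template()]).
#' @param f An [error_function()].
#' @param kin A [kinetic_model()].
#' @param config An [alignment_config()].
#' @param mode `"binned"` (downsampled approximation, default) or `"full"`
#'   (one row per nucleotide, no strand binning).
#' @param init_log_prior Optional start-time log prior over decimated template
#'   samples.
#' @param method Row computation method, see [accumulate()]; default `"cpp"`.
#' @return Object of class `"strand_alignment"`: estimated incorporation
#'   `times` (ms, length N), path `log_likelihood`, and bookkeeping fields
#'   (`bin_times`, `cols`, `config`, `mode`).
#' @examples
#' \donttest{
#' stim <- make_block_stimulus(20, 5, seed = 1)
#' tun <- linear_tuning()
#' ca <- standardize_trace(calcium_from_spikes(
#'   sample_spikes(rate_from_tuning(tun, stim), seed = 2)))
#' tpl <- calcium_template(tun, stim)
#' dnap <- dnap_preset("base_eval")
#' tau <- sample_incorporation_times(dnap$kinetics, trace_duration(stim),
#'                                   n_max = 1000, seed = 3)
#' rec <- sample_errors(ca, tau, dnap$error_fun, seed = 4)
#' al <- align_record(rec, tpl, dnap$error_fun, dnap$kinetics,
#'                    alignment_preset("parameter_eval"))
#' summary(al)
#' }
#' @export
align_record <- function(errors, template, f, kin,
                         config = alignment_preset("parameter_eval"),
                         mode = c("binned", "full"),
                         init_log_prior = NULL,
                         method = "cpp") {
  mode <- match.arg(mode)
  if (inherits(errors, "recorder_output")) errors <- errors$errors
  errors <- as.integer(errors)
  N <- length(errors)
  ctpl <- decimate_template(template, config$calcium_downsample)
  if (mode == "full") {
    # single-interval kinetics between consecutive nucleotides
    prior <- lag_log_pmf(kin, ctpl$sample_period, config$k)
    A <- build_similarity(errors, ctpl, f)
  } else {
    # rows are L_D-nucleotide bins: the inter-row waiting time is the L_D-fold
    # convolution of U; k bounds the path like an Itakura band
    prior <- bin_lag_log_pmf(kin, config$dna_downsample, ctpl$sample_period,
                             config$k)
    bc <- bin_errors(errors, config$dna_downsample)
    A <- build_binned_similarity(bc, ctpl, f, config$dna_downsample)
  }
  acc <- accumulate(A, prior, config$omega, init_log_prior, method = method)
  al <- trace_path(acc, col_times = attr(A, "col_times"))
  if (mode == "binned" && config$dna_downsample > 1) {
    al$bin_times <- al$times
    tt <- trace_times(template)
    al$times <- interpolate_alignment(al$bin_times, config$dna_downsample, N,
                                      min_sep = template$sample_period,
                                      lo = tt[1], hi = tt[length(tt)])
  }
  al$n <- N
  al$mode <- mode
  al$config <- config
  al
}
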
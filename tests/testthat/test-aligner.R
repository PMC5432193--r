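test_that("similarity entries are the Bernoulli log-likelihoods", {
  f <- base_error_fun()
  tpl <- time_trace(c(0, 0, 0), 50)            # f(0) = 0.25 everywhere
  A <- build_similarity(c(1, 0), tpl, f)
  expect_equal(A[1, ], rep(log(0.25), 3))
  expect_equal(A[2, ], rep(log(0.75), 3))
  # constant template rows carry no time information
  expect_true(all(apply(A, 1, function(r) diff(range(r)) == 0)))
  expect_equal(attr(A, "col_times"), c(0, 50, 100))
})

test_that("bin_errors sums non-overlapping bins and conserves errors", {
  expect_equal(as.integer(bin_errors(c(1, 0, 1, 1), 2)), c(1L, 2L))
  b <- bin_errors(c(1, 0, 1), 2)
  expect_equal(as.integer(b), c(1L, 1L))
  expect_equal(attr(b, "bin_sizes"), c(2L, 1L))      # partial last bin
  set.seed(11)
  d <- rbinom(997, 1, 0.3)
  expect_equal(sum(bin_errors(d, 100)), sum(d))      # conservation
})

test_that("binned similarity is the binomial pmf with flooring", {
  f <- base_error_fun()
  tpl <- time_trace(0, 50)                     # single column, f = 0.25
  bc <- structure(0L, bin_sizes = 4L)
  A <- build_binned_similarity(bc, tpl, f, 4)
  expect_equal(A[1, 1], log(0.75^4))           # closed-form binomial pmf
  # factorial oracle for a non-trivial count
  bc2 <- structure(2L, bin_sizes = 5L)
  A2 <- build_binned_similarity(bc2, tpl, f, 5)
  choose52 <- factorial(5) / (factorial(2) * factorial(3))
  expect_equal(A2[1, 1], log(choose52 * 0.25^2 * 0.75^3))
  # L_D = 1 reduces exactly to the Bernoulli similarity
  tpl3 <- time_trace(c(-1, 0, 2), 50)
  d <- c(1, 0)
  expect_equal(unclass(build_binned_similarity(bin_errors(d, 1), tpl3, f, 1)),
               unclass(build_similarity(d, tpl3, f)),
               ignore_attr = TRUE)
  # impossible count and flooring
  expect_error(build_binned_similarity(structure(5L, bin_sizes = 4L), tpl, f, 4),
               "exceeds bin size")
  fl <- build_binned_similarity(structure(4L, bin_sizes = 4L),
                                time_trace(-50, 50),
                                error_function(0.5, -1, 0), 4)
  expect_true(is.finite(fl[1, 1]))             # floored, not -Inf
})

test_that("decimate_template takes block means at window midpoints", {
  tpl <- time_trace(c(0, 2, 4, 6), 1)
  d <- decimate_template(tpl, 2)
  expect_equal(d$values, c(1, 5))              # block means by hand
  expect_equal(trace_times(d), c(0.5, 2.5))    # midpoints
  const <- decimate_template(time_trace(rep(3, 100), 1), 10)
  expect_true(all(const$values == 3))
  expect_equal(length(const$values), 10)
  same <- decimate_template(tpl, 1)
  expect_equal(same$values, tpl$values)        # L_C = period is the identity
  expect_error(decimate_template(time_trace(1:10, 3), 5), "multiple")
})

test_that("accumulate and trace_path reproduce the exhaustive optimum", {
  # fixed 3x8 instance checked against enumeration
  inst <- random_instance(3, 8, 3, seed = 42)
  oracle <- brute_force_align(inst$A, inst$prior$log_pmf, inst$omega)
  for (m in c("cpp", "vectorized", "loop")) {
    acc <- accumulate(inst$A, inst$prior, inst$omega, method = m)
    al <- trace_path(acc)
    expect_equal(al$log_likelihood, oracle$score, tolerance = 1e-12)
    expect_equal(al$cols, oracle$path)
  }
  # randomized property: all N <= 4, T' <= 12, k <= 5
  for (seed in 1:25) {
    set.seed(seed)
    N <- sample(1:4, 1); Tp <- sample(N:12, 1); k <- sample(1:5, 1)
    inst <- random_instance(N, Tp, k, seed = 1000 + seed)
    oracle <- brute_force_align(inst$A, inst$prior$log_pmf, inst$omega)
    al <- trace_path(accumulate(inst$A, inst$prior, inst$omega))
    expect_equal(al$log_likelihood, oracle$score, tolerance = 1e-12)
    expect_equal(al$cols, oracle$path)
  }
})

test_that("accumulate initialization, degenerate cases, and guards", {
  inst <- random_instance(1, 6, 2, seed = 2)
  acc <- accumulate(inst$A, inst$prior, 0.3)
  expect_equal(acc$S[1, ], inst$A[1, ])                 # row 1 is A alone
  al <- trace_path(acc)
  expect_equal(al$cols, which.max(inst$A[1, ]))
  init <- log(c(1, 0, 0, 0, 0, 1) / 2)
  acc2 <- accumulate(inst$A, inst$prior, 0.3, init_log_prior = init)
  expect_equal(acc2$S[1, ], inst$A[1, ] + init)         # optional start prior
  expect_error(accumulate(matrix(0, 5, 3), inst$prior, 0.3), "infeasible")
  # omega = 0 ignores kinetics: scores equal a pure max-chain of A
  inst3 <- random_instance(3, 9, 4, seed = 3)
  acc3 <- accumulate(inst3$A, inst3$prior, 0)
  oracle3 <- brute_force_align(inst3$A, rep(log(1 / 4), 4), 0)
  expect_equal(trace_path(acc3)$log_likelihood, oracle3$score,
               tolerance = 1e-12)
})

test_that("paths are strictly increasing and ties break deterministically", {
  for (seed in 1:10) {
    inst <- random_instance(4, 10, 3, seed = 300 + seed)
    al <- trace_path(accumulate(inst$A, inst$prior, 0.2))
    expect_true(all(diff(al$cols) >= 1))
    expect_equal(length(al$cols), 4)
  }
  # uniform A and uniform prior: smallest-lag/earliest-time convention gives
  # the leftmost feasible path 1, 2, ..., N
  A <- matrix(0, 3, 6)
  pr <- structure(list(log_pmf = rep(log(1 / 3), 3), k = 3, sample_period = 1),
                  class = "lag_prior")
  for (m in c("cpp", "vectorized", "loop")) {
    al <- trace_path(accumulate(A, pr, 0.5, method = m))
    expect_equal(al$cols, 1:3)
  }
})

test_that("row-parallel contract: all methods agree cell for cell", {
  for (seed in 1:5) {
    inst <- random_instance(8, 60, 7, seed = 400 + seed)
    a_cpp <- accumulate(inst$A, inst$prior, inst$omega, method = "cpp")
    a_vec <- accumulate(inst$A, inst$prior, inst$omega, method = "vectorized")
    a_loop <- accumulate(inst$A, inst$prior, inst$omega, method = "loop")
    expect_equal(a_vec$S, a_cpp$S, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(a_loop$S[, ]), unname(a_cpp$S[, ]), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(a_vec$bp, a_cpp$bp)
    expect_identical(unname(a_loop$bp), unname(a_cpp$bp))
  }
})

test_that("operation count scales as N * T' * k", {
  inst <- random_instance(4, 30, 5, seed = 9)
  acc <- accumulate(inst$A, inst$prior, 0.1, method = "loop")
  n_evals <- attr(acc$S, "n_lag_evals")
  upper <- (4 - 1) * 30 * 5
  # boundary columns have fewer feasible lags, so the count is just below N*T*k
  expect_lte(n_evals, upper)
  expect_gte(n_evals, upper - (4 - 1) * sum(pmax(5 - (1:30 - 1), 0)))
  inst2 <- random_instance(4, 30, 10, seed = 9)
  acc2 <- accumulate(inst2$A, inst2$prior, 0.1, method = "loop")
  expect_gt(attr(acc2$S, "n_lag_evals"), n_evals)   # grows with k
})

test_that("interpolation maps bin times to nucleotide times", {
  expect_equal(interpolate_alignment(c(5, 25), 1, 2), c(5, 25))  # identity
  out <- interpolate_alignment(c(0, 100), 2, 4, min_sep = 1)
  expect_equal(out, c(-25, 25, 75, 125))       # linear by hand
  expect_true(all(diff(out) > 0))
  # strict increase enforced on random inputs, with support clamping
  for (seed in 1:5) {
    set.seed(seed)
    bt <- sort(runif(6, 0, 1000))
    out <- interpolate_alignment(bt, 10, 60, min_sep = 1, lo = 0, hi = 1000)
    expect_true(all(diff(out) >= 1 - 1e-9))
    expect_true(all(out >= 0 & out <= 1000))
  }
})

test_that("binned mode with L_D = 1 and L_C = period equals full mode", {
  rec <- small_recording(n_blocks = 4, seed = 21)
  kin <- kin_nopause()
  f <- base_error_fun()
  tau <- sample_incorporation_times(kin, rec$window, n_max = 60, seed = 22)
  strand <- sample_errors(rec$calcium, tau, f, seed = 23)
  cfg <- alignment_config(omega = 1 / 100, k = 500, calcium_downsample = 50,
                          dna_downsample = 1)
  a_full <- align_record(strand, rec$template, f, kin, cfg, mode = "full")
  a_bin <- align_record(strand, rec$template, f, kin, cfg, mode = "binned")
  expect_equal(a_bin$times, a_full$times)
  expect_equal(a_bin$log_likelihood, a_full$log_likelihood)
})

test_that("alignment is deterministic and sensitive to template structure", {
  rec <- small_recording(n_blocks = 10, seed = 31)
  kin <- kin_nopause()
  f <- base_error_fun()
  tau <- sample_incorporation_times(kin, rec$window, n_max = 2000, seed = 32)
  strand <- sample_errors(rec$calcium, tau, f, seed = 33)
  cfg <- alignment_config(1 / 100, 2000, 50, 100)
  a1 <- align_record(strand, rec$template, f, kin, cfg)
  a2 <- align_record(strand, rec$template, f, kin, cfg)
  expect_identical(a1$times, a2$times)                  # deterministic
  expect_equal(length(a1$times), 2000)
  expect_true(all(diff(a1$times) > 0))
  # self-alignment sanity: errors near the feature timescale of the stimulus
  expect_lt(median(abs(a1$times - tau)) / 1000, 5)
  # permuting template blocks changes the selected path
  shuf <- rec$template
  set.seed(34)
  blocks <- matrix(shuf$values, ncol = 10)
  shuf$values <- as.numeric(blocks[, sample(10)])
  a3 <- align_record(strand, shuf, f, kin, cfg)
  expect_false(isTRUE(all.equal(a1$times, a3$times)))
})

test_that("alignment methods expose summaries, logLik, plot, and TSV output", {
  rec <- small_recording(n_blocks = 4, seed = 41)
  kin <- kin_nopause()
  f <- base_error_fun()
  tau <- sample_incorporation_times(kin, rec$window, n_max = 400, seed = 42)
  strand <- sample_errors(rec$calcium, tau, f, seed = 43)
  al <- align_record(strand, rec$template, f, kin,
                     alignment_config(1 / 100, 1000, 50, 20))
  expect_s3_class(al, "strand_alignment")
  expect_output(print(al), "strand_alignment")
  sm <- summary(al, true_times = tau)
  expect_equal(sm$rmsd_s, timing_rmsd(tau, al$times))
  expect_equal(as.numeric(logLik(al)), al$log_likelihood)
  pdf(NULL); plot(al, true_times = tau); dev.off()
  path <- tempfile(fileext = ".tsv")
  write_alignment_tsv(al, path, true_times = tau)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 400)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$log_likelihood, al$log_likelihood, tolerance = 1e-9)
})
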
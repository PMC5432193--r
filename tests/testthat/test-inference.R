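test_that("timing RMSD matches closed forms in both variants", {
  expect_equal(timing_rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  # constant offset: standard RMSD is the offset itself (in seconds)
  expect_equal(timing_rmsd(1000 * (1:5), 1000 * (1:5) + 500), 0.5)
  expect_equal(timing_rmsd(c(0, 3000, 4000), c(0, 0, 0)), sqrt(25 / 3))
  # literal printed variant divides by N instead of sqrt(N)
  expect_equal(timing_rmsd(c(0, 3000, 4000), c(0, 0, 0), "as_printed"), 5 / 3)
  expect_error(timing_rmsd(1:3, 1:4), "length")
})

test_that("slope estimation behaves at its fixed points", {
  f <- base_error_fun()
  rec <- small_recording(n_blocks = 40, seed = 51)
  kin <- kin_nopause()
  tau <- sample_incorporation_times(kin, rec$window, n_max = 5000, seed = 52)
  # covariate-independent errors: flat tuning curve, ratio ~ 0
  set.seed(53)
  flat <- rbinom(5000, 1, 0.25)
  est <- estimate_slope(flat, tau, rec$stimulus, f, rec$calcium)
  expect_lt(abs(est$slope_ratio), 0.15)
  # doubling the reference calcium slope halves the ratio (ratio definition)
  strand <- sample_errors(rec$calcium, tau, f, seed = 54)
  e1 <- estimate_slope(strand, tau, rec$stimulus, f, rec$calcium)
  doubled <- rec$calcium; doubled$values <- 2 * doubled$values
  e2 <- estimate_slope(strand, tau, rec$stimulus, f, doubled)
  expect_equal(e2$slope_ratio, e1$slope_ratio / 2, tolerance = 1e-9)
  # ground-truth times and a well-placed sigmoid recover the slope
  expect_lt(abs(e1$slope_ratio - 1), 0.2)
})

test_that("preferred-direction GLM recovers planted directions", {
  set.seed(61)
  n <- 1e4
  vx <- time_trace(rnorm(n, 0, 0.2), 1)
  vy <- time_trace(rnorm(n, 0, 0.2), 1)
  times <- seq_len(n) - 1
  d_x <- rbinom(n, 1, plogis(-1.5 + 4 * vx$values))
  est_x <- estimate_preferred_direction(d_x, times, vx, vy)
  expect_lt(circular_error(est_x$theta_star, 0), 0.1)
  d_y <- rbinom(n, 1, plogis(-1.5 + 4 * vy$values))
  est_y <- estimate_preferred_direction(d_y, times, vx, vy)
  expect_lt(circular_error(est_y$theta_star, pi / 2), 0.1)
  # sign-flipped drive rotates the estimate by pi
  d_neg <- rbinom(n, 1, plogis(-1.5 - 4 * vx$values))
  est_neg <- estimate_preferred_direction(d_neg, times, vx, vy)
  expect_lt(circular_error(est_neg$theta_star, pi), 0.15)
  expect_error(estimate_preferred_direction(d_x, times, time_trace(rep(0, n), 1), vy),
               "zero-variance|degenerate")
})

test_that("ground-truth Poisson GLM recovers tuning and pseudo-R2 behaves", {
  km <- make_center_out_kinematics(120, 8, 600, 400, 0.3, seed = 62)
  g <- cosine_tuning(3 * pi / 4, 10, 150, ref_speed = 0.3)
  spikes <- sample_spikes(rate_from_tuning(g, km), seed = 63)
  gt <- ground_truth_pd(spikes, km$vx, km$vy)
  expect_lt(circular_error(gt$theta, 3 * pi / 4), 0.1)
  expect_gt(gt$pseudo_r2, 0)
  expect_lte(gt$pseudo_r2, 1)
  # untuned neuron: model adds nothing over the null
  flat <- sample_spikes(time_trace(rep(0.03, length(km$vx$values)), 1),
                        seed = 64)
  gt0 <- ground_truth_pd(flat, km$vx, km$vy)
  expect_lt(gt0$pseudo_r2, 0.01)
})

test_that("population filter applies the printed thresholds", {
  neurons <- list(
    list(mean_rate = 25, pseudo_r2 = 0.10),   # passes both
    list(mean_rate = 25, pseudo_r2 = 0.01),   # fails fit
    list(mean_rate = 5,  pseudo_r2 = 0.20),   # fails rate
    list(mean_rate = 50, pseudo_r2 = 0.06),   # passes both
    list(mean_rate = 20, pseudo_r2 = 0.10))   # boundary rate: strict >
  kept <- population_filter(neurons)
  expect_equal(length(kept), 2)
  expect_equal(vapply(kept, `[[`, 0, "mean_rate"), c(25, 50))
  expect_equal(length(population_filter(neurons, 0, -Inf)), 5)
  expect_equal(length(population_filter(neurons, 1000, 2)), 0)
})

test_that("patch shuffling permutes aligned streams conservatively", {
  n <- 10000
  vx <- time_trace(rnorm(n), 1)
  twin <- time_trace(vx$values, 1)
  spk <- structure(list(spikes = rbinom(n, 1, 0.05), sample_period = 1, t0 = 0),
                   class = "spike_train")
  sh <- shuffle_patches(list(vx = vx, twin = twin, spk = spk), 2000, seed = 65)
  expect_equal(length(sh$permutation), 5)              # 2 s patches over 10 s
  expect_equal(sort(sh$streams$vx$values), sort(vx$values))   # multiset kept
  expect_identical(sh$streams$vx$values, sh$streams$twin$values)  # aligned
  expect_equal(sum(sh$streams$spk$spikes), sum(spk$spikes))
  sh2 <- shuffle_patches(list(vx = vx, twin = twin, spk = spk), 2000, seed = 65)
  expect_identical(sh$permutation, sh2$permutation)    # reproducible
  # trailing partial patch stays in place
  vxp <- time_trace(c(rnorm(9000), 100 + 1:500), 1)
  shp <- shuffle_patches(list(v = vxp), 3000, seed = 66)
  expect_equal(tail(shp$streams$v$values, 500), 100 + 1:500)
})

test_that("bootstrap CI behaves at its fixed points and matches the CLT", {
  expect_equal(unname(bootstrap_ci(rep(3.5, 10), seed = 1)), c(3.5, 3.5))
  set.seed(67)
  x <- rnorm(1000)
  ci <- bootstrap_ci(x, n_boot = 4000, seed = 68)
  expect_true(ci["lo"] < mean(x) && mean(x) < ci["hi"])
  normal <- mean(x) + c(-1, 1) * qnorm(0.975) * sd(x) / sqrt(1000)
  expect_lt(abs((ci["hi"] - ci["lo"]) - diff(normal)) / diff(normal), 0.10)
  expect_error(bootstrap_ci(c(1)), "at least two")
})

test_that("template selection picks the maximum likelihood with first-id ties", {
  rec <- small_recording(n_blocks = 12, seed = 71)
  f <- base_error_fun()
  kin <- kin_nopause()
  tau <- sample_incorporation_times(kin, rec$window, n_max = 1200, seed = 72)
  strand <- sample_errors(rec$calcium, tau, f, seed = 73)
  cfg <- alignment_config(1 / 100, 2000, 50, 100)
  single <- structure(list(tunings = list(rec$tuning),
                           templates = list(rec$template)),
                      class = "template_ensemble")
  s1 <- select_template(strand, single, f, kin, cfg)
  expect_equal(s1$template_id, 1)
  dup <- structure(list(tunings = list(rec$tuning, rec$tuning),
                        templates = list(rec$template, rec$template)),
                   class = "template_ensemble")
  s2 <- select_template(strand, dup, f, kin, cfg)
  expect_equal(s2$template_id, 1)                       # tie goes to lowest id
  expect_equal(s2$ensemble_log_likelihoods[1], s2$ensemble_log_likelihoods[2])
  # generating template beats its phase-opposed twin (sign test, 20 seeds)
  anti <- rec$template; anti$values <- -anti$values
  pair <- structure(list(tunings = list(rec$tuning, rec$tuning),
                         templates = list(rec$template, anti)),
                    class = "template_ensemble")
  wins <- vapply(1:20, function(s) {
    tau_s <- sample_incorporation_times(kin, rec$window, n_max = 1200,
                                        seed = 100 + s)
    st <- sample_errors(rec$calcium, tau_s, f, seed = 200 + s)
    select_template(st, pair, f, kin, cfg)$template_id == 1
  }, logical(1))
  expect_lt(binom.test(sum(wins), 20, 0.5, alternative = "greater")$p.value,
            0.05)
})

test_that("cosine ensembles discriminate the generating tuning at the true path", {
  km <- make_center_out_kinematics(60, 8, 600, 400, 0.3, seed = 81)
  g <- cosine_tuning(pi / 4, 10, 150, ref_speed = 0.3)
  spk <- sample_spikes(rate_from_tuning(g, km), seed = 82)
  gate <- speed_gate(km$vx, km$vy)
  spikes <- structure(list(spikes = spk$spikes[gate$keep], sample_period = 1,
                           t0 = 0), class = "spike_train")
  ca <- standardize_trace(calcium_from_spikes(spikes, 200))
  ens <- cosine_ensemble(list(vx = gate$vx, vy = gate$vy), ref_speed = 0.3)
  f <- base_error_fun()
  kin <- kin_pausing()
  hits <- vapply(1:5, function(s) {
    tau <- suppressWarnings(sample_incorporation_times(
      kin, trace_duration(ca), n_max = 3000, seed = s))
    strand <- sample_errors(ca, tau, f, seed = 300 + s)
    bc <- bin_errors(strand$errors, 25)
    tb <- tapply(tau, (seq_along(tau) - 1) %/% 25, mean)
    ll <- vapply(ens$templates, function(tt) {
      ct <- decimate_template(tt, 50)
      tmax <- max(trace_times(ct))
      p <- pmin(pmax(error_rate(f, trace_value_at(ct, pmin(tb, tmax))), 1e-12),
                1 - 1e-12)
      sum(dbinom(bc, attr(bc, "bin_sizes"), p, log = TRUE))
    }, 0)
    which.max(ll) == 2L   # theta = pi/4 is template 2 of the 8
  }, logical(1))
  expect_true(all(hits))
  # the antipodal pathology mechanism: tuned and anti-tuned templates on
  # out-and-back reaches are anticorrelated in phase but nearly identical up
  # to a half-cycle lag
  km0 <- make_center_out_kinematics(40, 8, 600, 0, 0.3, dur_jitter = 0,
                                    seed = 83)
  t_fwd <- calcium_template(cosine_tuning(0, 10, 150, ref_speed = 0.3), km0)
  t_rev <- calcium_template(cosine_tuning(pi, 10, 150, ref_speed = 0.3), km0)
  lag0 <- cor(t_fwd$values, t_rev$values)
  half <- 600
  lagged <- cor(t_fwd$values[-seq_len(half)],
                t_rev$values[seq_len(length(t_rev$values) - half)])
  expect_lt(lag0, -0.3)
  expect_gt(lagged, 0.5)
  expect_gt(lagged - lag0, 0.8)
})

test_that("circular error wraps to [0, pi]", {
  expect_equal(circular_error(0, 2 * pi), 0)
  expect_equal(circular_error(0.1, 2 * pi - 0.1), 0.2, tolerance = 1e-12)
  expect_equal(circular_error(0, pi), pi)
  expect_true(all(circular_error(runif(50, 0, 2 * pi),
                                 runif(50, 0, 2 * pi)) <= pi))
})
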
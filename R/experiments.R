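# Field-name mapping for polymerase blocks follows the published parameter
# table: R_max, b, C_0, p_pause, lambda_p, alpha, beta, n_basepairs.

.default_config <- function() {
  list(
    experiment = "parameter_sweep",
    dnap = list(R_max = 0.5, b = -1, C_0 = 0, p_pause = 0.001,
                lambda_p = 2000, alpha = 1, beta = 10, n_basepairs = 10000),
    alignment = list(omega = 1 / 100, k = 2000, calcium_downsample = 50,
                     dna_downsample = 100),
    neural = list(tuning = "linear", m = 0.05, lambda_min = 0,
                  lambda_max = 150, tau = 200, theta = pi / 4,
                  ref_speed = 0.3),
    stimulus = list(n_blocks = 400, block_len_s = 5),
    kinematics = list(n_reaches = 60, directions = 8, reach_dur = 600,
                      hold_dur = 400, peak_speed = 0.3, speed_lo = 0.05,
                      speed_hi = 0.4),
    sweep = list(axis = "record_length", grid = c(1000, 2500, 5000)),
    arms = "standard",
    shuffle_patch_len = 2000,
    n_trials = 20,
    seed = 1
  )
}

# Overlay user values onto defaults, rejecting unknown keys; path is used in
# error messages ("dnap.p_pause").
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")))
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- .merge_config(defaults[[key]], as.list(user[[key]]),
                                       paste0(path, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  d <- cfg$dnap
  if (d$p_pause < 0 || d$p_pause > 1) stop("dnap.p_pause must be in [0, 1]")
  if (d$R_max <= 0 || d$R_max > 1) stop("dnap.R_max must be in (0, 1]")
  if (d$lambda_p <= 0 || d$alpha <= 0 || d$beta <= 0)
    stop("dnap kinetic parameters must be positive")
  if (d$n_basepairs < 1) stop("dnap.n_basepairs must be >= 1")
  a <- cfg$alignment
  if (a$omega < 0 || a$omega > 1) stop("alignment.omega must be in [0, 1]")
  if (a$k < a$calcium_downsample)
    stop("alignment.k must be at least one template sample")
  if (!cfg$experiment %in% c("parameter_sweep", "center_out"))
    stop("experiment must be 'parameter_sweep' or 'center_out'")
  if (!cfg$sweep$axis %in% c("record_length", "incorporation_rate",
                             "sensitivity_b", "r_max"))
    stop("sweep.axis must be one of record_length, incorporation_rate, ",
         "sensitivity_b, r_max")
  if (cfg$n_trials < 1) stop("n_trials must be >= 1")
  if (!all(cfg$arms %in% c("standard", "pause_free", "shuffled")))
    stop("arms must be among standard, pause_free, shuffled")
  cfg
}

#' Build a validated experiment configuration
#'
#' Returns the full experiment configuration with every default filled in
#' (base parameter-evaluation polymerase, parameter-evaluation alignment
#' settings, linear tuning, 400 x 5 s stimulus). Supplied values overlay the
#' defaults; unknown keys are rejected.
#'
#' @param ... Top-level config fields or nested blocks (`dnap`, `alignment`,
#'   `neural`, `stimulus`, `kinematics`, `sweep`), partial lists allowed.
#' @return Object of class `"experiment_config"`.
#' @examples
#' experiment_config(n_trials = 5, dnap = list(p_pause = 0))
#' @export
experiment_config <- function(...) {
  cfg <- .merge_config(.default_config(), list(...))
  structure(.validate_config(cfg), class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' An empty file yields all defaults. Unknown keys and out-of-range values are
#' rejected with the offending key path.
#'
#' @param path YAML file path.
#' @return `parse_config` returns an `"experiment_config"`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(.default_config(), user)
  structure(.validate_config(cfg), class = "experiment_config")
}

#' @param cfg An `"experiment_config"`.
#' @rdname parse_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>", x$experiment, "\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

# Instantiate model objects from the config blocks.
.cfg_error_fun <- function(cfg) {
  error_function(cfg$dnap$R_max, cfg$dnap$b, cfg$dnap$C_0)
}
.cfg_kinetics <- function(cfg) {
  kinetic_model(cfg$dnap$p_pause, cfg$dnap$lambda_p, cfg$dnap$alpha,
                cfg$dnap$beta)
}
.cfg_align <- function(cfg) {
  alignment_config(cfg$alignment$omega, cfg$alignment$k,
                   cfg$alignment$calcium_downsample,
                   cfg$alignment$dna_downsample)
}

#' Simulate one parameter-evaluation recording
#'
#' The stimulus-driven half of the parameter-evaluation pipeline: block-random
#' stimulus, linear-tuned firing rate, Bernoulli spikes, exponential-kernel
#' calcium (standardized), and the noise-free calcium template from the same
#' tuning. Strands are then drawn per trial with
#' [sample_incorporation_times()] and [sample_errors()].
#'
#' @param cfg An [experiment_config()].
#' @param seed Integer seed for stimulus and spikes.
#' @return List with `stimulus`, `spikes`, `calcium` (standardized),
#'   `template`, and `window` (ms).
#' @export
simulate_parameter_eval <- function(cfg, seed = NULL) {
  seeds <- derive_seeds(seed, 2)
  stim <- make_block_stimulus(cfg$stimulus$n_blocks, cfg$stimulus$block_len_s,
                              seed = seeds[1])
  tun <- linear_tuning(cfg$neural$m, cfg$neural$lambda_min)
  rate <- rate_from_tuning(tun, stim)
  spikes <- sample_spikes(rate, seed = seeds[2])
  calcium <- standardize_trace(calcium_from_spikes(spikes, cfg$neural$tau))
  template <- calcium_template(tun, stim, cfg$neural$tau)
  list(stimulus = stim, spikes = spikes, calcium = calcium,
       template = template, window = trace_duration(stim))
}

# One strand: simulate, align to the true-tuning template, score.
.parameter_eval_trial <- function(sim, f, kin, acfg, n_bp, seed) {
  seeds <- derive_seeds(seed, 2)
  tau <- sample_incorporation_times(kin, sim$window, n_max = n_bp,
                                    seed = seeds[1])
  rec <- sample_errors(sim$calcium, tau, f, seed = seeds[2])
  al <- align_record(rec, sim$template, f, kin, acfg)
  sl <- estimate_slope(rec, al$times, sim$stimulus, f, sim$calcium)
  list(rmsd_s = timing_rmsd(rec$true_times, al$times),
       slope_ratio = sl$slope_ratio,
       log_likelihood = al$log_likelihood,
       n_bp = rec$n_basepairs)
}

#' Polymerase parameter sweep
#'
#' For each grid point of the swept parameter, simulates one
#' parameter-evaluation recording and `n_trials` strands, aligns each strand to
#' the true-tuning template, and summarizes timing RMSD and slope-ratio
#' recovery with bootstrap confidence intervals.
#'
#' Sweep axes: `record_length` (strand length in bp), `incorporation_rate`
#' (extension rate in Hz, via the gamma scale), `sensitivity_b` (|b| of the
#' error sigmoid), `r_max` (maximum error rate).
#'
#' @param cfg An [experiment_config()] with `sweep$axis` and `sweep$grid` set.
#' @return Data frame of per-point summaries with the per-trial table attached
#'   as attribute `"trials"`.
#' @export
run_parameter_sweep <- function(cfg) {
  cfg <- .validate_config(cfg)
  axis <- cfg$sweep$axis
  grid <- cfg$sweep$grid
  point_seeds <- derive_seeds(cfg$seed, length(grid))
  trials_all <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    pcfg <- cfg
    val <- grid[gi]
    switch(axis,
      record_length = { pcfg$dnap$n_basepairs <- val },
      incorporation_rate = { pcfg$dnap$beta <- 1000 / (val * pcfg$dnap$alpha) },
      sensitivity_b = { pcfg$dnap$b <- -abs(val) },
      r_max = { pcfg$dnap$R_max <- val })
    f <- .cfg_error_fun(pcfg)
    kin <- .cfg_kinetics(pcfg)
    acfg <- .cfg_align(pcfg)
    seeds <- derive_seeds(point_seeds[gi], cfg$n_trials + 1)
    sim <- simulate_parameter_eval(pcfg, seed = seeds[1])
    tr <- lapply(seq_len(cfg$n_trials), function(i)
      .parameter_eval_trial(sim, f, kin, acfg, pcfg$dnap$n_basepairs,
                            seeds[i + 1]))
    rmsd <- vapply(tr, `[[`, numeric(1), "rmsd_s")
    slope <- vapply(tr, `[[`, numeric(1), "slope_ratio")
    if (cfg$n_trials >= 2) {
      ci_m <- bootstrap_ci(rmsd, seed = seeds[1])
      ci_md <- bootstrap_ci(rmsd, stat = "median", seed = seeds[1])
    } else {
      ci_m <- ci_md <- c(lo = NA_real_, hi = NA_real_)
    }
    trials_all[[gi]] <- data.frame(axis = axis, value = val,
                                   trial = seq_len(cfg$n_trials),
                                   rmsd_s = rmsd, slope_ratio = slope)
    rows[[gi]] <- data.frame(
      axis = axis, value = val, n_trials = cfg$n_trials,
      mean_rmsd_s = mean(rmsd), median_rmsd_s = stats::median(rmsd),
      mean_rmsd_lo = ci_m[["lo"]], mean_rmsd_hi = ci_m[["hi"]],
      median_rmsd_lo = ci_md[["lo"]], median_rmsd_hi = ci_md[["hi"]],
      mean_slope_ratio = mean(slope))
  }
  out <- do.call(rbind, rows)
  attr(out, "trials") <- do.call(rbind, trials_all)
  out
}

#' Synthetic center-out recording study
#'
#' Simulates a cosine-tuned neuron recorded during synthetic center-out
#' reaching: minimum-jerk kinematics, speed gating, Bernoulli spiking,
#' exponential-kernel calcium, and `n_trials` polymerase records. Each record
#' is aligned to every template of the eight-direction cosine ensemble; the
#' maximum-likelihood template is selected and timing RMSD, estimated preferred
#' direction, and the selection histogram are reported. Optional arms rerun
#' the strands with a pause-free polymerase (`"pause_free"`) or on a
#' patch-shuffled dataset (`"shuffled"`).
#'
#' @param cfg An [experiment_config()] with `experiment = "center_out"`;
#'   `cfg$arms` selects among `"standard"`, `"pause_free"`, `"shuffled"`.
#' @return Object of class `"center_out_result"`: per-trial data frame
#'   `trials`, per-arm selection `histogram`, the `ground_truth` direction fit,
#'   and the config.
#' @export
run_center_out <- function(cfg) {
  cfg <- .validate_config(cfg)
  km <- cfg$kinematics
  seeds <- derive_seeds(cfg$seed, 4)
  kin0 <- make_center_out_kinematics(km$n_reaches, km$directions,
                                     km$reach_dur, km$hold_dur,
                                     km$peak_speed, seed = seeds[1])
  g_true <- cosine_tuning(cfg$neural$theta, cfg$neural$lambda_min,
                          cfg$neural$lambda_max, ref_speed = km$peak_speed)
  rate <- rate_from_tuning(g_true, kin0)
  spikes_full <- sample_spikes(rate, seed = seeds[2])
  gate <- speed_gate(kin0$vx, kin0$vy, km$speed_lo, km$speed_hi)
  spikes <- structure(list(spikes = spikes_full$spikes[gate$keep],
                           sample_period = spikes_full$sample_period, t0 = 0),
                      class = "spike_train")
  datasets <- list(standard = list(vx = gate$vx, vy = gate$vy,
                                   spikes = spikes))
  if ("shuffled" %in% cfg$arms) {
    sh <- shuffle_patches(list(vx = gate$vx, vy = gate$vy, spikes = spikes),
                          cfg$shuffle_patch_len, seed = seeds[3])
    datasets$shuffled <- sh$streams
  }
  f <- .cfg_error_fun(cfg)
  acfg <- .cfg_align(cfg)
  kin_std <- .cfg_kinetics(cfg)
  gt <- ground_truth_pd(spikes, gate$vx, gate$vy)

  trial_seeds <- derive_seeds(seeds[4], cfg$n_trials)
  rows <- list()
  hist_list <- list()
  for (arm in cfg$arms) {
    ds <- if (arm == "shuffled") datasets$shuffled else datasets$standard
    kin_arm <- if (arm == "pause_free")
      kinetic_model(0, cfg$dnap$lambda_p, cfg$dnap$alpha, cfg$dnap$beta)
    else kin_std
    calcium <- standardize_trace(calcium_from_spikes(ds$spikes,
                                                     cfg$neural$tau))
    ens <- cosine_ensemble(list(vx = ds$vx, vy = ds$vy),
                           directions = km$directions,
                           lambda_min = cfg$neural$lambda_min,
                           lambda_max = cfg$neural$lambda_max,
                           ref_speed = km$peak_speed, tau = cfg$neural$tau)
    window <- trace_duration(ds$vx)
    for (i in seq_len(cfg$n_trials)) {
      ts <- derive_seeds(trial_seeds[i], 2)
      tau <- suppressWarnings(
        sample_incorporation_times(kin_arm, window,
                                   n_max = cfg$dnap$n_basepairs,
                                   seed = ts[1]))
      rec <- sample_errors(calcium, tau, f, seed = ts[2])
      al <- select_template(rec, ens, f, kin_arm, acfg)
      pd <- estimate_preferred_direction(rec, al$times, ds$vx, ds$vy)
      rows[[length(rows) + 1]] <- data.frame(
        arm = arm, trial = i,
        template_id = al$template_id,
        log_likelihood = al$log_likelihood,
        rmsd_s = timing_rmsd(rec$true_times, al$times),
        theta_star_rad = pd$theta_star,
        n_bp = rec$n_basepairs)
    }
    sel <- vapply(rows[vapply(rows, function(r) r$arm == arm, logical(1))],
                  function(r) r$template_id, numeric(1))
    hist_list[[arm]] <- tabulate(sel, nbins = km$directions)
  }
  structure(list(trials = do.call(rbind, rows), histogram = hist_list,
                 ground_truth = gt, config = cfg),
            class = "center_out_result")
}

#' @export
print.center_out_result <- function(x, ...) {
  cat("<center_out_result>\n")
  cat(sprintf("  true preferred direction (GLM on spikes): %.3f rad (pseudo-R2 %.3f)\n",
              x$ground_truth$theta, x$ground_truth$pseudo_r2))
  for (arm in names(x$histogram)) {
    tr <- x$trials[x$trials$arm == arm, ]
    cat(sprintf("  arm %-10s median RMSD %.3g s, selection histogram: %s\n",
                arm, stats::median(tr$rmsd_s),
                paste(x$histogram[[arm]], collapse = " ")))
  }
  invisible(x)
}

#' Write experiment results as TSV with a JSON sidecar
#'
#' The sidecar records the config, master seed, and package version for
#' reproducibility.
#'
#' @param result A sweep data frame or `"center_out_result"`.
#' @param path Output TSV path.
#' @export
write_results_tsv <- function(result, path) {
  tab <- if (inherits(result, "center_out_result")) result$trials else result
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- if (inherits(result, "center_out_result")) result$config else NULL
  meta <- list(package_version = as.character(utils::packageVersion("ntalign")),
               config = if (!is.null(cfg)) unclass(cfg) else NULL,
               config_hash = if (!is.null(cfg))
                 sum(utf8ToInt(paste(utils::capture.output(utils::str(cfg)),
                                     collapse = ""))) else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
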
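#' Uniform prior over recording start times
#'
#' @param lo,hi Interval bounds in ms, `0 <= lo < hi`.
#' @return Object of class `"start_prior"`.
#' @export
start_prior <- function(lo, hi) {
  if (!(lo >= 0 && hi > lo)) stop("need 0 <= lo < hi")
  structure(list(kind = "uniform", lo = lo, hi = hi), class = "start_prior")
}

#' Sample nucleotide incorporation times
#'
#' Draws the ground-truth time stamps of a recording: the first incorporation
#' from the start prior (default Uniform over the first quarter of the
#' window), then `tau_n = tau_{n-1} + U` with `U` from the continuous
#' pause/extension mixture. Generation stops at `n_max` nucleotides or at the
#' end of the window, whichever comes first; a record truncated by the window
#' is returned with a warning rather than an error.
#'
#' @param kin A [kinetic_model()].
#' @param window Recording window length in ms.
#' @param prior A [start_prior()]; default Uniform(0, window / 4).
#' @param n_max Maximum number of nucleotides.
#' @param seed Optional integer seed.
#' @return Numeric vector of strictly increasing times (ms) with a logical
#'   attribute `"paused"` marking, for each nucleotide after the first, whether
#'   the preceding interval was a pause.
#' @export
sample_incorporation_times <- function(kin, window, prior = NULL,
                                       n_max = Inf, seed = NULL) {
  stopifnot(window > 0)
  if (is.null(prior)) prior <- start_prior(0, window / 4)
  if (prior$lo < 0 || prior$hi > window)
    stop("start prior must lie inside the recording window")
  with_seed(seed, {
    times <- stats::runif(1, prior$lo, prior$hi)
    paused <- logical(0)
    batch <- max(64L, ceiling(1.2 * window / expected_interval(kin)))
    if (is.finite(n_max)) batch <- min(batch, as.integer(n_max))
    repeat {
      if (length(times) >= n_max) break
      iv <- sample_intervals(kin, batch)
      tt <- times[length(times)] + cumsum(iv$dt)
      n_in <- sum(tt <= window)   # intervals are positive, so tt is increasing
      n_take <- if (is.finite(n_max)) min(n_in, n_max - length(times)) else n_in
      if (n_take > 0) {
        times <- c(times, tt[seq_len(n_take)])
        paused <- c(paused, iv$paused[seq_len(n_take)])
      }
      if (n_in < batch) break     # ran past the window
    }
    if (is.finite(n_max) && length(times) < n_max)
      warning(sprintf(
        "record truncated by window: %d of %d nucleotides generated",
        length(times), as.integer(n_max)))
    attr(times, "paused") <- paused
    times
  })
}

#' Draw per-nucleotide errors from calcium
#'
#' For each incorporation time, looks up the calcium trace at the nearest
#' sample and draws `d_n ~ Bernoulli(f(c_{tau_n}))` independently. The calcium
#' trace should already be standardized if the error function assumes
#' standardized calcium (see [standardize_trace()]).
#'
#' @param calcium Calcium [time_trace()].
#' @param times Incorporation times (ms), strictly increasing, inside the
#'   trace support.
#' @param f An [error_function()].
#' @param seed Optional integer seed.
#' @return Object of class `"recorder_output"`: binary `errors`, hidden
#'   `true_times` (ms), and `n_basepairs`.
#' @export
sample_errors <- function(calcium, times, f, seed = NULL) {
  p <- error_rate(f, trace_value_at(calcium, times))
  d <- with_seed(seed, stats::rbinom(length(times), 1L, p))
  recorder_output(d, times)
}

#' Construct a recorder output record
#'
#' @param errors Binary error strand (0 = faithful Watson-Crick incorporation,
#'   1 = mismatch).
#' @param true_times Strictly increasing incorporation times in ms, or `NULL`
#'   when unknown (e.g. real sequenced strands).
#' @return Object of class `"recorder_output"`.
#' @export
recorder_output <- function(errors, true_times = NULL) {
  errors <- as.integer(errors)
  if (!all(errors %in% c(0L, 1L))) stop("errors must be binary")
  if (!is.null(true_times)) {
    if (length(true_times) != length(errors))
      stop("errors and true_times lengths differ")
    if (any(diff(true_times) <= 0)) stop("true_times must be strictly increasing")
  }
  structure(list(errors = errors, true_times = true_times,
                 n_basepairs = length(errors)),
            class = "recorder_output")
}

#' @export
print.recorder_output <- function(x, ...) {
  cat(sprintf("<recorder_output> %d bp, %d errors (%.3g%%)%s\n",
              x$n_basepairs, sum(x$errors), 100 * mean(x$errors),
              if (is.null(x$true_times)) ", times hidden" else ""))
  invisible(x)
}

#' Serialize / parse a recorder output as TSV
#'
#' Columns: `index` (0-based), `error`, and optionally `true_time_ms` (omit via
#' `blind = TRUE` for blinded analyses).
#'
#' @param rec A [recorder_output()].
#' @param path File path.
#' @param blind Drop the ground-truth times column.
#' @export
write_record_tsv <- function(rec, path, blind = FALSE) {
  d <- data.frame(index = seq_along(rec$errors) - 1L, error = rec$errors)
  if (!blind && !is.null(rec$true_times)) d$true_time_ms <- rec$true_times
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_record_tsv
#' @export
read_record_tsv <- function(path) {
  d <- utils::read.delim(path)
  recorder_output(d$error,
                  if ("true_time_ms" %in% names(d)) d$true_time_ms else NULL)
}

#' Write a recorder output as template/copy FASTA
#'
#' Renders the binary error strand as a pair of sequences: the known template
#' and the synthesized copy, where a faithful position carries the
#' Watson-Crick complement of the template base and an error position carries
#' a uniformly random non-complementary base. Round-trips through
#' [fasta_to_strand()].
#'
#' @param rec A [recorder_output()].
#' @param template_path,copy_path Output FASTA paths.
#' @param template_seq Template DNA string of length >= N; random if `NULL`.
#' @param seed Optional seed (template draw + error substitutions).
#' @return Invisibly, list of the two paths.
#' @export
strand_to_fasta <- function(rec, template_path, copy_path,
                            template_seq = NULL, seed = NULL) {
  n <- rec$n_basepairs
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  with_seed(seed, {
    if (is.null(template_seq)) {
      tmpl <- sample(bases, n, replace = TRUE)
    } else {
      tmpl <- strsplit(toupper(template_seq), "")[[1]]
      if (length(tmpl) < n) stop("template shorter than the strand")
      tmpl <- tmpl[seq_len(n)]
      if (!all(tmpl %in% bases)) stop("template contains non-ACGT characters")
    }
    cp <- unname(comp[tmpl])
    for (i in which(rec$errors == 1L)) {
      cp[i] <- sample(setdiff(bases, comp[[tmpl[i]]]), 1)
    }
  })
  ts <- Biostrings::DNAStringSet(paste(tmpl, collapse = ""))
  cs <- Biostrings::DNAStringSet(paste(cp, collapse = ""))
  names(ts) <- "template"
  names(cs) <- "copy"
  Biostrings::writeXStringSet(ts, template_path)
  Biostrings::writeXStringSet(cs, copy_path)
  invisible(list(template = template_path, copy = copy_path))
}

#' Derive the binary error strand from template/copy FASTA
#'
#' A position is an error when the copy base is not the Watson-Crick
#' complement of the template base.
#'
#' @param template_path,copy_path FASTA paths (single sequence each, equal
#'   lengths, ACGT alphabet).
#' @return Integer binary error vector.
#' @export
fasta_to_strand <- function(template_path, copy_path) {
  ts <- Biostrings::readDNAStringSet(template_path)
  cs <- Biostrings::readDNAStringSet(copy_path)
  if (length(ts) != 1 || length(cs) != 1)
    stop("expected exactly one sequence per FASTA")
  tmpl <- strsplit(as.character(ts[[1]]), "")[[1]]
  cp <- strsplit(as.character(cs[[1]]), "")[[1]]
  if (length(tmpl) != length(cp)) stop("template and copy lengths differ")
  if (!all(c(tmpl, cp) %in% c("A", "C", "G", "T")))
    stop("sequences contain non-ACGT characters")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  as.integer(cp != unname(comp[tmpl]))
}
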
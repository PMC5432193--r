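#' @export
print.strand_alignment <- function(x, ...) {
  cat(sprintf("<strand_alignment> %d nucleotides, mode = %s\n", x$n, x$mode))
  cat(sprintf("  path log-likelihood: %.4g\n", x$log_likelihood))
  cat(sprintf("  estimated times: %.3g .. %.3g s\n",
              min(x$times) / 1000, max(x$times) / 1000))
  if (!is.na(x$template_id))
    cat(sprintf("  selected template: %d\n", x$template_id))
  invisible(x)
}

#' Summarize a strand alignment
#'
#' Reports the path log-likelihood, the span of estimated times, and — when
#' ground-truth incorporation times are supplied — the timing RMSD in seconds.
#'
#' @param object A `"strand_alignment"` from [align_record()].
#' @param true_times Optional ground-truth incorporation times (ms).
#' @param ... Unused.
#' @export
summary.strand_alignment <- function(object, true_times = NULL, ...) {
  out <- list(
    n = object$n,
    mode = object$mode,
    log_likelihood = object$log_likelihood,
    span_s = range(object$times) / 1000,
    template_id = object$template_id,
    rmsd_s = if (!is.null(true_times))
      timing_rmsd(true_times, object$times) else NA_real_
  )
  class(out) <- "summary.strand_alignment"
  out
}

#' @export
print.summary.strand_alignment <- function(x, ...) {
  cat(sprintf("Strand alignment: %d nucleotides (%s mode)\n", x$n, x$mode))
  cat(sprintf("  log-likelihood %.4g, estimated span %.3g-%.3g s\n",
              x$log_likelihood, x$span_s[1], x$span_s[2]))
  if (!is.na(x$rmsd_s)) cat(sprintf("  timing RMSD %.3g s\n", x$rmsd_s))
  if (!is.na(x$template_id)) cat(sprintf("  template id %d\n", x$template_id))
  invisible(x)
}

#' @export
logLik.strand_alignment <- function(object, ...) {
  structure(object$log_likelihood, df = NA, class = "logLik")
}

#' Plot estimated nucleotide-time mapping
#'
#' Nucleotide index against estimated incorporation time, with the ground
#' truth overlaid when available.
#'
#' @param x A `"strand_alignment"`.
#' @param true_times Optional ground-truth times (ms).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.strand_alignment <- function(x, true_times = NULL, ...) {
  graphics::plot(x$times / 1000, seq_len(x$n), type = "l", col = "steelblue",
                 xlab = "time (s)", ylab = "nucleotide index", ...)
  if (!is.null(true_times)) {
    graphics::lines(true_times / 1000, seq_along(true_times), col = "grey40",
                    lty = 2)
    graphics::legend("bottomright", c("estimated", "true"),
                     col = c("steelblue", "grey40"), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Serialize an alignment as TSV with a JSON sidecar
#'
#' Writes `(nucleotide_index, estimated_time_ms[, true_time_ms])` rows and a
#' JSON sidecar (`<path>.json`) carrying the template id, path log-likelihood,
#' and the alignment configuration.
#'
#' @param al A `"strand_alignment"`.
#' @param path Output TSV path.
#' @param true_times Optional ground-truth times (ms).
#' @export
write_alignment_tsv <- function(al, path, true_times = NULL) {
  d <- data.frame(nucleotide_index = seq_len(al$n) - 1L,
                  estimated_time_ms = al$times)
  if (!is.null(true_times)) d$true_time_ms <- true_times
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(template_id = al$template_id,
               log_likelihood = al$log_likelihood,
               mode = al$mode,
               config = unclass(al$config))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
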
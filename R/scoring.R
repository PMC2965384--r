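#' Segments from a Viterbi state path
#'
#' Run-length encodes the most probable state path into maximal
#' constant-state segments; chromosome boundaries always split segments.
#' Coordinates are the first and last probe positions of the run (1-based,
#' closed).
#'
#' @param probes Sorted probe data frame.
#' @param viterbi_path Integer state path (length `nrow(probes)`), e.g.
#'   `fit$viterbi_state`.
#' @param state_table State table from [build_state_table()].
#' @return Data frame with one row per segment: `chrom`, `start_pos`,
#'   `end_pos`, `state_id`, `n_probes`, `copy_number`, `loh`,
#'   `copy_loss_loh`, `first_probe`, `last_probe` (row indices into
#'   `probes`).
#' @export
segments_from_path <- function(probes, viterbi_path,
                               state_table = build_state_table()) {
  n <- nrow(probes)
  if (length(viterbi_path) != n)
    stop("path length (", length(viterbi_path), ") != probe count (", n, ")")
  chrom <- as.character(probes$chrom)
  brk <- c(TRUE, viterbi_path[-1] != viterbi_path[-n] |
                 chrom[-1] != chrom[-n])
  seg_id <- cumsum(brk)
  first <- which(brk)
  last <- c(first[-1] - 1L, n)
  st <- viterbi_path[first]
  data.frame(
    chrom = chrom[first],
    start_pos = probes$pos[first],
    end_pos = probes$pos[last],
    state_id = st,
    n_probes = last - first + 1L,
    copy_number = state_table$copy_number[st],
    loh = loh_class(st) == "loh",
    copy_loss_loh = loh_class(st) == "copy-loss-loh",
    mean_lrr = vapply(seq_along(first), function(i)
      mean(probes$lrr[first[i]:last[i]]), 0),
    mean_baf_dev = vapply(seq_along(first), function(i)
      mean(abs(probes$baf[first[i]:last[i]] - 0.5)), 0),
    first_probe = first,
    last_probe = last
  )
}

#' Approximate log Bayes factor of a segment
#'
#' Evidence score of a segment belonging to its assigned tumor state versus
#' the normal state: the sum over the segment's probes of the posterior
#' log odds (assigned vs normal), minus the chain's per-probe prior log
#' odds.  The switch mass is split uniformly, so the chain's stationary
#' distribution is uniform and the default prior odds are 0 (the
#' normal-state preference enters only at chromosome starts and is
#' ignored).  Segments assigned the normal state score 0 by definition.
#' Natural-log scale.
#'
#' @param segment One row of [segments_from_path()] output.
#' @param state_posteriors `n x 21` posterior matrix (e.g.
#'   `fit$state_posteriors`).
#' @param prior_odds Per-probe prior log odds of the assigned state versus
#'   the normal state (default 0).
#' @param hyper Unused; retained for call compatibility.
#' @return Scalar log Bayes factor.
#' @export
segment_log_bayes_factor <- function(segment, state_posteriors,
                                     prior_odds = NULL,
                                     hyper = default_hyperparams()) {
  s <- segment$state_id
  if (s == 3L) return(0)
  if (is.null(prior_odds)) prior_odds <- 0
  idx <- segment$first_probe:segment$last_probe
  eps <- 1e-12
  po <- log(pmax(state_posteriors[idx, s], eps)) -
    log(pmax(state_posteriors[idx, 3L], eps))
  sum(po - prior_odds)
}

#' Chromosome number estimate from a copy-number profile
#'
#' Sums, over chromosomes, the probe-weighted mean tumor copy number
#' rounded to the nearest integer; for a karyotypically normal diploid
#' female genome (22 autosome pairs + XX) this returns 46.
#'
#' @param probes Sorted probe data frame.
#' @param copy_numbers Per-probe tumor copy numbers (e.g. mapped from the
#'   Viterbi path).
#' @param chroms Chromosomes to include; default all present.
#' @return Integer chromosome-number estimate.
#' @export
estimate_chromosome_number <- function(probes, copy_numbers, chroms = NULL) {
  stopifnot(length(copy_numbers) == nrow(probes))
  chrom <- normalize_chrom(probes$chrom)
  if (is.null(chroms)) chroms <- unique(chrom)
  keep <- chrom %in% normalize_chrom(chroms)
  empty <- setdiff(normalize_chrom(chroms), chrom)
  if (length(empty))
    warning("chromosome(s) with no probes excluded: ",
            paste(empty, collapse = ", "))
  means <- tapply(copy_numbers[keep], chrom[keep], mean)
  as.integer(sum(round(means)))
}

#' Summary of a completed fit
#'
#' @param fit An `"hmm_fit"` object.
#' @param segments Segment table from [segments_from_path()]; computed from
#'   the fit's Viterbi path when omitted.
#' @param lbf_threshold Log Bayes factor call filter (natural log,
#'   default 30).
#' @return A list of class `"cna_summary"`: MAP `beta0` and `pi0`,
#'   estimated chromosome number, average ploidy (probe-weighted mean copy
#'   number), aberrant probe/segment counts passing the filter, and the
#'   fraction of probes per state.
#' @export
summary_report <- function(fit, segments = NULL, lbf_threshold = 30) {
  if (is.null(segments))
    segments <- segments_from_path(fit$probes, fit$viterbi_state,
                                   fit$state_table)
  segments$log_bf <- vapply(seq_len(nrow(segments)), function(i)
    segment_log_bayes_factor(segments[i, ], fit$state_posteriors,
                             hyper = fit$hyper), 0)
  cn <- fit$state_table$copy_number[fit$viterbi_state]
  aberrant <- segments$state_id != 3L & segments$log_bf >= lbf_threshold
  frac <- tabulate(fit$viterbi_state, 21L) / length(fit$viterbi_state)
  out <- list(
    beta0 = fit$params$beta0,
    beta1 = fit$params$beta1,
    pi0 = fit$pi0,
    chromosome_number = estimate_chromosome_number(fit$probes, cn),
    average_ploidy = mean(cn),
    n_aberrant_segments = sum(aberrant),
    n_aberrant_probes = sum(segments$n_probes[aberrant]),
    state_fractions = setNames(frac, seq_len(21L)),
    lbf_threshold = lbf_threshold,
    segments = segments
  )
  class(out) <- "cna_summary"
  out
}

#' @export
print.cna_summary <- function(x, ...) {
  cat("Copy-number analysis summary\n")
  cat(sprintf("  normal fraction (pi0):   %.2f\n", x$pi0))
  cat(sprintf("  LRR baseline (beta0):    %+.3f\n", x$beta0))
  cat(sprintf("  chromosome number:       %d\n", x$chromosome_number))
  cat(sprintf("  average ploidy:          %.2f\n", x$average_ploidy))
  cat(sprintf("  aberrant segments >= LBF %g: %d (%d probes)\n",
              x$lbf_threshold, x$n_aberrant_segments, x$n_aberrant_probes))
  invisible(x)
}
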
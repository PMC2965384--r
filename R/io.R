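col_aliases <- list(
  name = c("name", "snpname", "snp", "probe", "probeid", "probesetid"),
  chrom = c("chr", "chrom", "chromosome"),
  pos = c("position", "pos", "mapinfo", "bppos", "location"),
  lrr = c("logrratio", "lrr"),
  baf = c("ballelefreq", "baf", "ballelefrequency"),
  gc = c("gc", "gccontent", "gcfraction"),
  normal_genotype = c("normalgenotype", "gtype", "genotype", "normalgt")
)

norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a per-SNP probe table
#'
#' Reads a tab-delimited table in the style of genotyping-array software
#' exports.  Required columns (matched case-insensitively through an alias
#' map, in any order): probe name, chromosome, position, Log R Ratio and
#' B allele frequency; optional: GC content and a matched-normal genotype.
#' Probes are sorted by (karyotype chromosome order, position); rows with
#' non-finite LRR/BAF are dropped and counted, and duplicate
#' (chromosome, position) rows are deduplicated keeping the first.
#'
#' @param path Path to the tab-delimited file (with header).
#' @return Probe data frame with columns `name`, `chrom`, `pos`, `lrr`,
#'   `baf` (plus `gc`, `normal_genotype` when present); attributes
#'   `n_dropped` and `n_duplicates` record cleaning counts.
#' @export
read_probe_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty probe table: ", path)
  hdr <- norm_header(names(raw))
  pick <- function(field, required = TRUE) {
    hit <- which(hdr %in% col_aliases[[field]])
    if (length(hit) == 0L) {
      if (required)
        stop("missing required column '", field, "' (aliases: ",
             paste(col_aliases[[field]], collapse = ", "), ") in ", path)
      return(NULL)
    }
    raw[[hit[1]]]
  }
  out <- data.frame(
    name = as.character(pick("name")),
    chrom = normalize_chrom(pick("chrom")),
    pos = as.numeric(pick("pos")),
    lrr = as.numeric(pick("lrr")),
    baf = as.numeric(pick("baf")),
    stringsAsFactors = FALSE)
  gc <- pick("gc", required = FALSE)
  if (!is.null(gc)) out$gc <- as.numeric(gc)
  ng <- pick("normal_genotype", required = FALSE)
  if (!is.null(ng)) out$normal_genotype <- as.character(ng)
  keep <- is.finite(out$lrr) & is.finite(out$baf)
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  out <- out[chrom_order(out$chrom), , drop = FALSE]
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos), ,
             drop = FALSE]
  dup <- duplicated(out[, c("chrom", "pos")])
  n_dup <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Attach local GC content to probes
#'
#' Accepts either a BED-like interval track (columns chromosome, start,
#' end, gc; 0-based half-open intervals) or a per-probe table (columns
#' name, gc).  Interval assignment is containing-interval first, nearest
#' interval otherwise; probes with no value get the genome-wide mean.
#'
#' @param probes Probe data frame.
#' @param gc_path Path to the GC track.
#' @return `probes` with a filled `gc` column; attribute `n_imputed`
#'   counts mean-imputed probes.
#' @export
attach_gc <- function(probes, gc_path) {
  tab <- read.delim(gc_path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- norm_header(names(tab))
  if (all(c("name", "gc") %in% hdr) && !"start" %in% hdr) {
    gc <- tab[[which(hdr == "gc")[1]]]
    names(gc) <- tab[[which(hdr == "name")[1]]]
    probes$gc <- as.numeric(gc[probes$name])
  } else {
    if (ncol(tab) < 4L)
      stop("GC track must have (chrom, start, end, gc) or (name, gc) columns")
    chrom <- normalize_chrom(tab[[1]])
    start <- suppressWarnings(as.numeric(tab[[2]]))
    end <- suppressWarnings(as.numeric(tab[[3]]))
    val <- suppressWarnings(as.numeric(tab[[4]]))
    bad <- which(!is.finite(start) | !is.finite(end) | start >= end |
                   !is.finite(val))
    if (length(bad))
      stop("malformed GC interval at line ", bad[1] + 1L, " of ", gc_path)
    probes$gc <- NA_real_
    for (ch in unique(probes$chrom)) {
      pi <- which(probes$chrom == ch)
      ti <- which(chrom == ch)
      if (length(ti) == 0L) next
      o <- order(start[ti])
      s <- start[ti][o]; e <- end[ti][o]; v <- val[ti][o]
      idx <- findInterval(probes$pos[pi] - 1, s)
      inside <- idx >= 1 & probes$pos[pi] - 1 < ifelse(idx >= 1, e[pmax(idx, 1)], 0)
      g <- rep(NA_real_, length(pi))
      g[inside] <- v[idx[inside]]
      if (any(!inside)) {  # nearest interval by boundary distance
        for (q in which(!inside)) {
          d <- pmax(s - probes$pos[pi][q], probes$pos[pi][q] - e, 0)
          g[q] <- v[which.min(d)]
        }
      }
      probes$gc[pi] <- g
    }
  }
  n_imputed <- sum(is.na(probes$gc))
  if (n_imputed > 0) {
    m <- mean(probes$gc, na.rm = TRUE)
    if (!is.finite(m)) m <- 0.5
    probes$gc[is.na(probes$gc)] <- m
  }
  attr(probes, "n_imputed") <- n_imputed
  probes
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# BED export: 0-based half-open coordinates, score = capped scaled log BF
write_segments_bed <- function(segments, state_table, path) {
  bed <- data.frame(
    chrom = segments$chrom,
    start = segments$start_pos - 1L,
    end = segments$end_pos,
    name = gsub(" ", "_", state_table$description[segments$state_id]),
    score = pmin(1000L, pmax(0L, round(10 * segments$log_bf))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

#' Run configuration
#'
#' @param input Path to the probe table (see [read_probe_table()]).
#' @param outdir Output directory (created if absent).
#' @param gc Optional GC track path (see [attach_gc()]).
#' @param normal_genotypes Optional per-probe matched-normal genotype table
#'   (columns name, genotype).
#' @param variant Model variant (see [em_fit()]).
#' @param em_iters EM iterations (default 15).
#' @param lbf_threshold Log Bayes factor call filter (default 30).
#' @param baseline_grid Baseline restart initializations.
#' @param pi0_grid Normal-fraction prior support.
#' @param pop_b_freq Population B allele frequency.
#' @param surface Emit a (pi0, beta0) likelihood surface TSV.
#' @param seed Integer seed recorded in the run log.
#' @param verbose Print progress.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(input, outdir, gc = NULL, normal_genotypes = NULL,
                       variant = "full", em_iters = 15L, lbf_threshold = 30,
                       baseline_grid = c(0, -0.40, -0.68, 0.33),
                       pi0_grid = seq(0, 0.9, by = 0.05),
                       pop_b_freq = 0.5, surface = FALSE, seed = 1L,
                       verbose = FALSE) {
  stopifnot(em_iters >= 1L, lbf_threshold >= 0)
  structure(list(input = input, outdir = outdir, gc = gc,
                 normal_genotypes = normal_genotypes, variant = variant,
                 em_iters = as.integer(em_iters),
                 lbf_threshold = lbf_threshold,
                 baseline_grid = baseline_grid, pi0_grid = pi0_grid,
                 pop_b_freq = pop_b_freq, surface = isTRUE(surface),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Read the probe table, attach GC content, fit the model with baseline
#' restarts, decode and score segments, and write per-SNP, segment, BED and
#' summary tables plus a run log into the output directory.
#'
#' @param config A [run_config()] list.
#' @return Invisibly, a list with `status` (0 on success), the fitted
#'   model, the summary and the output paths.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  set.seed(config$seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  probes <- read_probe_table(config$input)
  if (!is.null(config$gc)) probes <- attach_gc(probes, config$gc)
  if (!is.null(config$normal_genotypes)) {
    ng <- read.delim(config$normal_genotypes, stringsAsFactors = FALSE)
    hdr <- norm_header(names(ng))
    gt <- ng[[which(hdr %in% col_aliases$normal_genotype)[1]]]
    names(gt) <- ng[[which(hdr %in% col_aliases$name)[1]]]
    probes$normal_genotype <- as.character(gt[probes$name])
  }
  hyper <- default_hyperparams(pi0_grid = config$pi0_grid)
  fit <- fit_with_restarts(probes, hyper = hyper,
                           baseline_grid = config$baseline_grid,
                           variant = config$variant,
                           n_iters = config$em_iters,
                           pop_b_freq = config$pop_b_freq,
                           verbose = config$verbose)
  smry <- summary_report(fit, lbf_threshold = config$lbf_threshold)
  segs <- smry$segments
  st <- fit$state_table

  persnp <- data.frame(
    name = probes$name, chrom = probes$chrom, pos = probes$pos,
    lrr = probes$lrr, baf = probes$baf,
    state = fit$viterbi_state,
    copy_number = st$copy_number[fit$viterbi_state],
    loh = loh_class(fit$viterbi_state) == "loh",
    copy_loss_loh = loh_class(fit$viterbi_state) == "copy-loss-loh",
    max_posterior = apply(fit$state_posteriors, 1, max),
    pi_level = fit$viterbi_pi)
  segs$pass_filter <- segs$state_id != 3L &
    segs$log_bf >= config$lbf_threshold
  paths <- list(
    persnp = write_tsv(persnp, file.path(config$outdir, "per_snp.tsv")),
    segments = write_tsv(segs, file.path(config$outdir, "segments.tsv")),
    bed = write_segments_bed(segs[segs$pass_filter, , drop = FALSE], st,
                             file.path(config$outdir, "segments.bed")),
    summary = write_tsv(
      data.frame(key = c("pi0", "beta0", "beta1", "chromosome_number",
                         "average_ploidy", "n_aberrant_segments",
                         "n_aberrant_probes", "variant", "seed"),
                 value = c(smry$pi0, smry$beta0, smry$beta1,
                           smry$chromosome_number, smry$average_ploidy,
                           smry$n_aberrant_segments, smry$n_aberrant_probes,
                           fit$variant, config$seed)),
      file.path(config$outdir, "summary.tsv")))
  if (config$surface) {
    surf <- likelihood_surface(probes, pi0_grid = seq(0, 0.8, by = 0.1),
                               beta0_grid = seq(-0.7, 0.2, by = 0.1),
                               hyper = hyper, pop_b_freq = config$pop_b_freq)
    paths$surface <- write_tsv(
      data.frame(pi0 = rownames(surf), as.data.frame(surf),
                 check.names = FALSE),
      file.path(config$outdir, "surface.tsv"))
  }
  log_lines <- c(
    sprintf("cnahmm %s", as.character(utils::packageVersion("cnahmm"))),
    sprintf("date: %s", format(t0)),
    sprintf("seed: %d", config$seed),
    sprintf("input: %s  (probes: %d, dropped: %s, deduplicated: %s)",
            config$input, nrow(probes),
            attr(probes, "n_dropped") %||% 0,
            attr(probes, "n_duplicates") %||% 0),
    sprintf("variant: %s  em_iters: %d  lbf_threshold: %g",
            fit$variant, config$em_iters, config$lbf_threshold),
    sprintf("hyperparameters: %s",
            paste(deparse(unclass(hyper)[c("alpha", "tau", "gamma",
              "alpha_eta", "beta_eta", "lambda_beta", "alpha_pi0",
              "beta_pi0", "alpha_pi", "beta_pi", "L")]), collapse = " ")),
    "restarts (beta0_init beta0 pi0 penalized_loglik):",
    apply(fit$restarts, 1, function(r)
      sprintf("  %s %s %s %s", r["beta0_init"], r["beta0"], r["pi0"],
              r["penalized_loglik"])))
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  paths$log <- file.path(config$outdir, "run_log.txt")
  invisible(list(status = 0L, fit = fit, summary = smry, paths = paths))
}
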
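#' Simulation configuration
#'
#' Describes a synthetic tumor genome and its array readout: probe layout,
#' piecewise-constant tumor-state segments with exponential lengths,
#' constitutional Hardy-Weinberg genotypes, normal-DNA fraction,
#' per-segment subclonal heterogeneity, heavy-tailed bivariate noise,
#' a sinusoidal GC wave in the LRR, uniform outliers, and an LRR baseline
#' shift emulating the virtual-diploid normalization of polyploid genomes.
#'
#' Defaults emulate a 20,000-probe genotyping array on a largely diploid
#' tumor carrying hemizygous-deletion, single-copy-duplication and
#' copy-neutral (somatic LOH) segments, the design of laboratory
#' normal-cancer dilution series; `preset = "triploid"` instead produces a
#' triploid-dominated genome with true baseline shift equal to minus the
#' canonical copy-3 LRR level.
#'
#' @param preset `"diploid"` (default) or `"triploid"` segment composition.
#' @param n_probes Total probe count.
#' @param n_chroms Number of chromosomes (equal length).
#' @param chrom_length Chromosome length in base pairs.
#' @param segment_mean_length Mean state-segment length in base pairs.
#' @param state_weights Named numeric over state ids 1..21 used to draw
#'   segment states.
#' @param pi0_true Normal DNA fraction (cell-fraction convention; see
#'   [mass_to_cell_fraction()]).
#' @param subclone_prob Probability that a non-normal segment is subclonal.
#' @param pi_levels_true Heterogeneity levels drawn for subclonal segments.
#' @param pop_b_freq Population B allele frequency.
#' @param noise_scale_lrr,noise_scale_baf Student-t scale of the LRR / BAF
#'   noise.
#' @param nu_true Noise degrees of freedom.
#' @param gc_amplitude Amplitude (LRR units) of the sinusoidal GC wave.
#' @param baseline_true True LRR baseline shift `beta0`.
#' @param outlier_rate_true Fraction of probes replaced by uniform outliers.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(preset = c("diploid", "triploid"),
                       n_probes = 20000L, n_chroms = 20L,
                       chrom_length = 1e8, segment_mean_length = 1e7,
                       state_weights = NULL, pi0_true = 0,
                       subclone_prob = 0, pi_levels_true = c(0.2, 0.4, 0.6),
                       pop_b_freq = 0.5, noise_scale_lrr = 0.15,
                       noise_scale_baf = 0.03, nu_true = 8,
                       gc_amplitude = 0.05, baseline_true = NULL,
                       outlier_rate_true = 0.01, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(state_weights))
    state_weights <- switch(preset,
      diploid = c(`3` = 0.60, `2` = 0.1333, `4` = 0.1333, `12` = 0.1334),
      triploid = c(`4` = 0.50, `13` = 0.20, `3` = 0.15, `2` = 0.10,
                   `6` = 0.05))
  if (is.null(baseline_true))
    baseline_true <- switch(preset, diploid = 0,
                            triploid = -default_lrr_levels()[["3"]])
  cfg <- list(preset = preset, n_probes = as.integer(n_probes),
              n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
              segment_mean_length = segment_mean_length,
              state_weights = state_weights, pi0_true = pi0_true,
              subclone_prob = subclone_prob,
              pi_levels_true = pi_levels_true, pop_b_freq = pop_b_freq,
              noise_scale_lrr = noise_scale_lrr,
              noise_scale_baf = noise_scale_baf, nu_true = nu_true,
              gc_amplitude = gc_amplitude, baseline_true = baseline_true,
              outlier_rate_true = outlier_rate_true, seed = as.integer(seed))
  stopifnot(cfg$pi0_true >= 0, cfg$pi0_true <= 1, cfg$subclone_prob >= 0,
            cfg$subclone_prob <= 1, cfg$pop_b_freq >= 0, cfg$pop_b_freq <= 1,
            cfg$outlier_rate_true >= 0, cfg$outlier_rate_true <= 1,
            cfg$chrom_length > 0, cfg$segment_mean_length > 0,
            all(names(cfg$state_weights) %in% as.character(1:21)))
  class(cfg) <- "sim_config"
  cfg
}

#' Convert a mass mixing fraction to the model's cell fraction
#'
#' Laboratory dilution series mix normal and tumor DNA by mass; the model's
#' normal fraction is a cell (genome-copy) fraction.  Equal masses of a
#' diploid normal and a tumor of mean ploidy `psi_t` contain different cell
#' numbers, so `pi0 = f psi_t / (f psi_t + 2 (1 - f))` for normal mass
#' fraction `f`.  At diploid tumor ploidy the two conventions coincide.
#'
#' @param mass_fraction Normal mass fraction(s) in \[0, 1\].
#' @param tumor_ploidy Mean tumor copy number (default 2).
#' @return Cell fraction(s).
#' @export
mass_to_cell_fraction <- function(mass_fraction, tumor_ploidy = 2) {
  stopifnot(all(mass_fraction >= 0 & mass_fraction <= 1), tumor_ploidy > 0)
  mass_fraction * tumor_ploidy /
    (mass_fraction * tumor_ploidy + 2 * (1 - mass_fraction))
}

# latent genome: segments, states, genotypes, per-segment heterogeneity
draw_truth <- function(config) {
  st <- build_state_table()
  n_per <- diff(round(seq(0, config$n_probes, length.out =
                            config$n_chroms + 1)))
  ids <- as.integer(names(config$state_weights))
  w <- config$state_weights / sum(config$state_weights)
  rows <- list()
  for (ch in seq_len(config$n_chroms)) {
    n_c <- n_per[ch]
    if (n_c == 0L) next
    pos <- sort(ceiling(runif(n_c) * config$chrom_length))
    # piecewise-constant state segments with exponential lengths
    bnd <- cumsum(rexp(ceiling(3 * config$chrom_length /
                                 config$segment_mean_length) + 2,
                       1 / config$segment_mean_length))
    bnd <- c(0, bnd[bnd < config$chrom_length], config$chrom_length)
    seg <- findInterval(pos, bnd, rightmost.closed = TRUE)
    seg_state <- ids[sample.int(length(ids), length(bnd), TRUE, prob = w)]
    state <- seg_state[seg]
    pi_seg <- ifelse(seg_state != 3L &
                       runif(length(bnd)) < config$subclone_prob,
                     sample(config$pi_levels_true, length(bnd), TRUE), 0)
    pi_i <- pi_seg[seg]
    # constitutional genotypes: Hardy-Weinberg, restricted to the state's
    # allowable normals (germline-LOH states define runs of homozygosity)
    p <- config$pop_b_freq
    hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    z_n <- integer(n_c)
    z_t <- integer(n_c)
    for (i in seq_len(n_c)) {
      pairs <- st$pairs[[state[i]]]
      ok_zn <- sort(unique(pairs$z_n))
      pr <- hw[ok_zn + 1]
      if (sum(pr) == 0) pr <- rep(1, length(ok_zn))
      z_n[i] <- if (length(ok_zn) == 1L) ok_zn else
        sample(ok_zn, 1L, prob = pr)
      cand <- pairs$z_t[pairs$z_n == z_n[i]]
      z_t[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    rows[[ch]] <- data.frame(
      chrom = as.character(ch), pos = pos, state = state,
      copy_number = st$copy_number[state], z_n = z_n, z_t = z_t,
      x_t = st$copy_number[state], pi_i = pi_i)
  }
  truth <- do.call(rbind, rows)
  truth$name <- sprintf("SNP%06d", seq_len(nrow(truth)))
  truth$normal_genotype <- vapply(truth$z_n, genotype_to_string, "",
                                  copies = 2L)
  truth$tumor_genotype <- mapply(genotype_to_string, truth$z_t, truth$x_t)
  rownames(truth) <- NULL
  truth
}

# render noisy (LRR, BAF) observations of one latent genome at a given
# normal fraction; the generative inversion of the emission means
render_observations <- function(truth, config, pi0) {
  n <- nrow(truth)
  rb <- default_lrr_levels()
  om <- truth$pi_i * (1 - pi0) + pi0
  gc <- 0.5 + 0.1 * sin(2 * pi * truth$pos / 3e7)
  beta1 <- config$gc_amplitude / 0.1
  m_r <- om * rb[["2"]] + (1 - om) * rb[as.character(truth$x_t)] +
    config$baseline_true + beta1 * gc
  den <- om * 2 + (1 - om) * truth$x_t
  m_b <- ifelse(den > 1e-12,
                (om * truth$z_n + (1 - om) * truth$z_t) / den, NA_real_)
  lrr <- m_r + config$noise_scale_lrr * rt(n, config$nu_true)
  baf <- m_b + config$noise_scale_baf * rt(n, config$nu_true)
  baf[is.na(m_b)] <- runif(sum(is.na(m_b)))  # zero total copy: uniform BAF
  baf <- pmin(pmax(baf, 0), 1)               # array saturation
  out <- runif(n) < config$outlier_rate_true
  lrr[out] <- runif(sum(out), -4, 2)
  baf[out] <- runif(sum(out))
  probes <- data.frame(
    name = truth$name, chrom = truth$chrom, pos = truth$pos,
    lrr = as.numeric(lrr), baf = baf, gc = gc,
    normal_genotype = truth$normal_genotype)
  truth$outlier <- out
  truth$pi0 <- pi0
  list(probes = probes, truth = truth)
}

#' Simulate one tumor SNP-array sample with known truth
#'
#' Draws a latent genome (segments, states, genotypes, heterogeneity) and
#' renders LRR/BAF observations from the emission means plus Student-t
#' noise, uniform outliers and a GC wave.  Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return List with `probes` (analysis-ready probe table including `gc`
#'   and `normal_genotype` columns) and `truth` (per-probe latent state,
#'   genotypes, heterogeneity, outlier flag).
#' @export
simulate_sample <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    truth <- draw_truth(config)
    render_observations(truth, config, config$pi0_true)
  })
}

#' Simulate a dilution series sharing one tumor truth
#'
#' Mirrors the laboratory design in which one tumor is mixed with its
#' matched normal at several ratios: the latent tumor genome is drawn once
#' and observations are re-rendered at each normal fraction with
#' independent noise.
#'
#' @param base_config A [sim_config()] object.
#' @param fractions Normal fractions of the mixtures.
#' @param convention `"cell"` (fractions are the model's `pi0`) or
#'   `"mass"` (mass mixing ratios, converted via
#'   [mass_to_cell_fraction()] at the truth's mean ploidy).
#' @return List of `simulate_sample()`-style lists, one per fraction, all
#'   with identical `truth` segment structure.
#' @export
dilution_series <- function(base_config = sim_config(),
                            fractions = c(0, 0.25, 0.5),
                            convention = c("cell", "mass")) {
  convention <- match.arg(convention)
  stopifnot(all(fractions >= 0 & fractions <= 1))
  truth <- withr::with_seed(base_config$seed, draw_truth(base_config))
  pi0s <- if (convention == "mass")
    mass_to_cell_fraction(fractions, mean(truth$x_t)) else fractions
  lapply(seq_along(fractions), function(i) {
    withr::with_seed(base_config$seed + 7919L * i,
                     render_observations(truth, base_config, pi0s[i]))
  })
}

#' Simulate a sample with deliberately ambiguous purity/ploidy
#'
#' Generates a genome dominated by a single-copy gain at moderate normal
#' contamination, with the baseline shift that a virtual-diploid
#' normalization would apply.  Such data admit multiple (normal fraction,
#' baseline) interpretations -- e.g. a contaminated gained genome versus a
#' diploid genome with copy-neutral LOH at higher contamination -- and the
#' profile likelihood surface shows multiple local maxima.
#'
#' @param config A [sim_config()] object; its state weights, normal
#'   fraction and baseline are overridden by the confusable construction.
#' @return As [simulate_sample()].
#' @export
make_confusable_sample <- function(config = sim_config(n_probes = 6000L)) {
  config$state_weights <- c(`4` = 0.8, `3` = 0.2)
  config$pi0_true <- 0.3
  config$baseline_true <- -(1 - 0.3) * default_lrr_levels()[["3"]]
  config$subclone_prob <- 0
  simulate_sample(config)
}
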
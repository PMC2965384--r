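#' Default canonical Log R Ratio levels
#'
#' Canonical LRR response levels for tumor copy numbers 0..6 on a diploid
#' baseline.  The response is compressive in copy number, as observed on
#' genotyping arrays; EM refines residual location error through the mixture
#' component offsets.
#'
#' @return Named numeric vector, names `"0"`..`"6"`, strictly increasing.
#' @export
default_lrr_levels <- function() {
  c(`0` = -3.5, `1` = -0.66, `2` = 0.0, `3` = 0.40, `4` = 0.68,
    `5` = 0.85, `6` = 1.0)
}

#' Emission model parameters
#'
#' Container for all emission-side parameters: canonical LRR levels, the
#' Student-t mixture (component offsets `delta`, scale matrices `sigma`,
#' weights, degrees of freedom `nu`), the uniform outlier class
#' (probability `eta`, LRR support `r_min`..`r_max`), and the LRR baseline
#' and GC regression coefficients (`beta0`, `beta1`).  Mixture components
#' are indexed by component `k = 1..K` and noise class `l = 1..3`, set by
#' the mixed genotype's expected BAF band position (boundary-low, mid,
#' boundary-high; see the methods vignette).  For uncontaminated diploid
#' genotypes this coincides with the constitutional classes AA/AB/BB.
#'
#' @param lrr_levels Named numeric vector of canonical LRR levels for copy
#'   numbers 0..6, strictly increasing.
#' @param K Number of non-outlier mixture components.
#' @param delta `2 x K x 3` array of component mean offsets (LRR, BAF).
#' @param sigma `2 x 2 x K x 3` array of positive-definite scale matrices.
#' @param weights `K x 3` matrix of mixture weights, columns summing to 1.
#' @param nu Student-t degrees of freedom (> 2), fixed during fitting.
#' @param eta Outlier class probability in \[0, 1\].
#' @param beta0,beta1 LRR baseline adjustment and GC regression coefficient.
#' @param r_min,r_max Support of the uniform LRR outlier distribution.
#' @return A list of class `"emission_params"`.
#' @export
emission_params <- function(lrr_levels = default_lrr_levels(), K = 3L,
                            delta = NULL, sigma = NULL, weights = NULL,
                            nu = 8, eta = 0.005, beta0 = 0, beta1 = 0,
                            r_min = -4.5, r_max = 3) {
  K <- as.integer(K)
  stopifnot(K >= 1L, length(lrr_levels) == 7L, !is.unsorted(lrr_levels,
            strictly = TRUE), nu > 2, eta >= 0, eta <= 1, r_min < r_max)
  if (is.null(delta)) delta <- array(0, c(2, K, 3))
  if (is.null(sigma)) {
    sigma <- array(0, c(2, 2, K, 3))
    scl <- exp(seq(-0.7, 0.7, length.out = K))  # spread to break symmetry
    for (k in seq_len(K)) for (l in 1:3)
      sigma[, , k, l] <- scl[k] * diag(c(0.15^2, 0.04^2))
  }
  if (is.null(weights)) weights <- matrix(1 / K, K, 3)
  stopifnot(all(dim(delta) == c(2, K, 3)), all(dim(sigma) == c(2, 2, K, 3)),
            all(dim(weights) == c(K, 3)),
            max(abs(colSums(weights) - 1)) < 1e-8)
  for (k in seq_len(K)) for (l in 1:3) {
    s <- sigma[, , k, l]
    if (abs(s[1, 2] - s[2, 1]) > 1e-12 || det(s) <= 0 || s[1, 1] <= 0)
      stop("sigma[,,", k, ",", l, "] is not symmetric positive definite")
  }
  structure(list(lrr_levels = lrr_levels, K = K, delta = delta,
                 sigma = sigma, weights = weights, nu = nu, eta = eta,
                 beta0 = beta0, beta1 = beta1, r_min = r_min, r_max = r_max),
            class = "emission_params")
}

#' @rdname emission_params
#' @export
default_emission_params <- emission_params

# effective normal-genotype weight: fraction of the specimen's cells carrying
# the constitutional genotype at a locus
omega_mix <- function(pi0, pi_i) pi_i * (1 - pi0) + pi0

#' Expected Log R Ratio of a mixed normal-tumor genotype
#'
#' The LRR mean weights the canonical level of the normal copy number by the
#' total normal-genotype fraction `pi_i (1 - pi0) + pi0` and the tumor level
#' by the complement, then adds the baseline adjustment `beta0` and the GC
#' regression term `beta1 * gc`.
#'
#' @param pair One row of a state's `pairs` data frame (fields `x_n`, `x_t`).
#' @param pi0 Genome-wide normal DNA fraction in \[0, 1\].
#' @param pi_i Locus-level fraction of tumor cells retaining the normal
#'   genotype, in \[0, 1\].
#' @param params An [emission_params()] object.
#' @param gc Local GC fraction.
#' @return Expected LRR (scalar).
#' @export
lrr_mean <- function(pair, pi0, pi_i, params = default_emission_params(),
                     gc = 0) {
  stopifnot(pi0 >= 0, pi0 <= 1, pi_i >= 0, pi_i <= 1)
  if (pair$x_n > 6 || pair$x_t > 6 || pair$x_n < 0 || pair$x_t < 0)
    stop("copy number outside 0..6")
  om <- omega_mix(pi0, pi_i)
  rb <- params$lrr_levels
  om * rb[[as.character(pair$x_n)]] + (1 - om) * rb[[as.character(pair$x_t)]] +
    params$beta0 + params$beta1 * gc
}

#' Expected B allele frequency of a mixed normal-tumor genotype
#'
#' Ratio of the mixture-weighted B-allele count to the mixture-weighted
#' total copy number.  When the weighted total copy number is zero (pure
#' homozygous deletion) the BAF is undefined and `NA` is returned; the
#' emission density then falls back to a uniform BAF factor.
#'
#' @inheritParams lrr_mean
#' @return Expected BAF in \[0, 1\], or `NA` when undefined.
#' @export
baf_mean <- function(pair, pi0, pi_i) {
  stopifnot(pi0 >= 0, pi0 <= 1, pi_i >= 0, pi_i <= 1)
  om <- omega_mix(pi0, pi_i)
  den <- om * pair$x_n + (1 - om) * pair$x_t
  if (den <= 1e-12) return(NA_real_)
  (om * pair$z_n + (1 - om) * pair$z_t) / den
}

#' Bivariate Student-t log density
#'
#' @param y Numeric 2-vector.
#' @param mean Numeric 2-vector.
#' @param cov 2x2 positive-definite scale matrix.
#' @param nu Degrees of freedom (> 0).
#' @return Log density (scalar).
#' @export
student_t_logpdf <- function(y, mean, cov, nu) {
  stopifnot(length(y) == 2L, length(mean) == 2L, all(dim(cov) == c(2, 2)),
            nu > 0)
  dt <- cov[1, 1] * cov[2, 2] - cov[1, 2] * cov[2, 1]
  if (dt <= 0) stop("singular covariance matrix")
  e <- y - mean
  q <- (cov[2, 2] * e[1]^2 - 2 * cov[1, 2] * e[1] * e[2] +
        cov[1, 1] * e[2]^2) / dt
  lgamma((nu + 2) / 2) - lgamma(nu / 2) - log(nu * pi) - 0.5 * log(dt) -
    (nu + 2) / 2 * log1p(q / nu)
}

# univariate analogue used for the undefined-BAF fallback
student_t_logpdf1 <- function(y, mean, var, nu) {
  q <- (y - mean)^2 / var
  lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi * var) -
    (nu + 1) / 2 * log1p(q / nu)
}

# Hardy-Weinberg mass of a diploid genotype with B allele count z
hw_mass <- function(z, p) c((1 - p)^2, 2 * p * (1 - p), p^2)[z + 1]

# Noise class l in {1,2,3} of a mixed genotype, by the position of its
# expected BAF band: exactly at the lower boundary (all-A), interior, or
# exactly at the upper boundary (all-B).  Array saturation clips BAF at
# 0/1, so bands sitting exactly on a boundary carry spike-plus-half-width
# noise while interior bands carry full-width noise; the class must follow
# the band, not the constitutional genotype, or reinterpretations of the
# state/ploidy can buy a better fit of the clipping artifact (see the
# methods vignette).  Symmetric under allele swap.
band_class <- function(m_b) {
  ifelse(is.na(m_b), 2L, ifelse(m_b < 1e-6, 1L, ifelse(m_b > 1 - 1e-6,
                                                       3L, 2L)))
}

#' Prior weight of a genotype pair within a tumor state
#'
#' With a matched-normal genotype the weight is an indicator on the pair's
#' constitutional genotype (split over pairs sharing it); otherwise
#' Hardy-Weinberg masses at the population B allele frequency are used.
#' Weights are renormalized over the state's allowable pair set.
#'
#' @param pair One row of a state's `pairs` data frame.
#' @param state The [build_state_table()] row (data frame of pairs) the pair
#'   belongs to; used for normalization.
#' @param pop_b_freq Population B allele frequency in \[0, 1\].
#' @param matched Optional matched-normal genotype (string `"AA"`, `"AB"`,
#'   `"BB"` or a [parse_genotype_string()] result).
#' @return Probability (scalar).
#' @export
genotype_prior <- function(pair, state, pop_b_freq = 0.5, matched = NULL) {
  stopifnot(pop_b_freq >= 0, pop_b_freq <= 1)
  pairs <- if (!is.null(state$pairs)) state$pairs[[1]] else state
  w <- genotype_prior_weights(pairs, pop_b_freq, matched)
  idx <- which(pairs$z_t == pair$z_t & pairs$x_t == pair$x_t &
               pairs$z_n == pair$z_n)
  if (length(idx) == 0L) stop("pair not in state's allowable set")
  w[idx[1]]
}

# weights over all pairs of one state (vector summing to 1, or all 0 when a
# matched genotype is incompatible with the state)
genotype_prior_weights <- function(pairs, pop_b_freq, matched = NULL) {
  if (!is.null(matched)) {
    if (is.character(matched)) matched <- parse_genotype_string(matched)
    hit <- pairs$z_n == matched$b_count
    if (!any(hit)) return(rep(0, nrow(pairs)))
    w <- ifelse(hit, 1 / sum(hit), 0)
    return(w)
  }
  cnt <- table(pairs$z_n)
  w <- hw_mass(pairs$z_n, pop_b_freq) / as.numeric(cnt[as.character(pairs$z_n)])
  if (sum(w) == 0) return(rep(0, nrow(pairs)))
  w / sum(w)
}

#' Emission log density of one probe under one tumor state
#'
#' Mixture of the uniform outlier class (probability `eta`) and, with
#' probability `1 - eta`, the genotype-pair-weighted Student-t mixture with
#' means from [lrr_mean()] and [baf_mean()].  This is the direct per-probe
#' reference implementation; fitting uses an equivalent vectorized native
#' kernel.
#'
#' @param probe A list or one-row data frame with fields `lrr`, `baf`, `gc`
#'   and optionally `normal_genotype`.
#' @param state One row of [build_state_table()].
#' @param params An [emission_params()] object.
#' @param pi0,pi_i Normal fraction and locus heterogeneity fraction.
#' @param pop_b_freq Population B allele frequency.
#' @return Log density (scalar).
#' @export
emission_logdensity <- function(probe, state, params, pi0, pi_i,
                                pop_b_freq = 0.5) {
  pairs <- state$pairs[[1]]
  matched <- probe$normal_genotype %||% NULL
  if (!is.null(matched) && (is.na(matched) || !nzchar(matched))) matched <- NULL
  gpw <- genotype_prior_weights(pairs, pop_b_freq, matched)
  gc <- probe$gc %||% 0
  if (is.na(gc)) gc <- 0
  y <- c(probe$lrr, probe$baf)
  terms <- -Inf
  for (j in seq_len(nrow(pairs))) {
    if (gpw[j] <= 0) next
    pair <- pairs[j, ]
    mr <- lrr_mean(pair, pi0, pi_i, params, gc)
    mb <- baf_mean(pair, pi0, pi_i)
    l <- band_class(if (is.na(mb)) pair$z_n / 2 else mb)
    for (k in seq_len(params$K)) {
      lw <- log(params$weights[k, l])
      if (is.na(mb)) {
        ld <- student_t_logpdf1(y[1], mr + params$delta[1, k, l],
                                params$sigma[1, 1, k, l], params$nu)
        # undefined BAF: uniform factor on [0,1], log density 0
      } else {
        ld <- student_t_logpdf(y, c(mr, mb) + params$delta[, k, l],
                               params$sigma[, , k, l], params$nu)
      }
      terms <- logsumexp(c(terms, log(gpw[j]) + lw + ld))
    }
  }
  l_out <- if (y[1] >= params$r_min && y[1] <= params$r_max)
    -log(params$r_max - params$r_min) else -Inf
  logsumexp(c(log(params$eta) + l_out, log1p(-params$eta) + terms))
}

# ---- cell table: flattened (state, pair, heterogeneity level) grid -------

# Builds the flat cell table consumed by the native emission kernel.  Cells
# are sorted by expanded state index es = (pi_level - 1) * 21 + state.
build_cell_table <- function(state_table, pi_grid, pop_b_freq) {
  rows <- list()
  for (s in seq_len(nrow(state_table))) {
    pairs <- state_table$pairs[[s]]
    hw <- genotype_prior_weights(pairs, pop_b_freq)
    lgm <- vapply(0:2, function(m) {
      w <- genotype_prior_weights(pairs, pop_b_freq,
                                  list(b_count = m, copies = 2L))
      log(w)
    }, numeric(nrow(pairs)))
    lgm <- matrix(lgm, nrow = nrow(pairs))
    rows[[s]] <- data.frame(
      state = state_table$state[s], pair = seq_len(nrow(pairs)),
      zn = pairs$z_n, xn = pairs$x_n, zt = pairs$z_t, xt = pairs$x_t,
      lgp_hw = log(hw),
      lgp_m0 = lgm[, 1], lgp_m1 = lgm[, 2], lgp_m2 = lgm[, 3]
    )
  }
  base <- do.call(rbind, rows)
  P <- length(pi_grid)
  cells <- do.call(rbind, lapply(seq_len(P), function(p) {
    x <- base
    x$pil <- p - 1L
    x$es <- (p - 1L) * nrow(state_table) + x$state - 1L
    x
  }))
  cells <- cells[order(cells$es, cells$pair), ]
  rownames(cells) <- NULL
  attr(cells, "pi_grid") <- pi_grid
  attr(cells, "n_states") <- nrow(state_table)
  cells
}

# 0-based noise class of every cell at a given normal fraction; the band
# position (hence the class) moves with the mixture weight omega
cell_band_class <- function(cells, pi0) {
  pi_grid <- attr(cells, "pi_grid")
  om <- pi_grid[cells$pil + 1L] * (1 - pi0) + pi0
  den <- om * cells$xn + (1 - om) * cells$xt
  B <- ifelse(den > 1e-12,
              (om * cells$zn + (1 - om) * cells$zt) / den, cells$zn / 2)
  band_class(B) - 1L
}

# flatten emission_params into the argument list of the native kernels
params_to_native <- function(params) {
  K <- params$K
  delta <- matrix(0, 2, K * 3)
  prec <- matrix(0, 4, K * 3)
  sig00 <- numeric(K * 3)
  lw <- numeric(K * 3)
  for (l in 1:3) for (k in seq_len(K)) {
    kl <- k + K * (l - 1)
    delta[, kl] <- params$delta[, k, l]
    s <- params$sigma[, , k, l]
    dt <- s[1, 1] * s[2, 2] - s[1, 2]^2
    prec[1, kl] <- s[2, 2] / dt
    prec[2, kl] <- -s[1, 2] / dt
    prec[3, kl] <- s[1, 1] / dt
    prec[4, kl] <- log(dt)
    sig00[kl] <- s[1, 1]
    lw[kl] <- log(max(params$weights[k, l], 1e-300))
  }
  list(delta = delta, prec = prec, sig00 = sig00, lw = lw)
}

matched_codes <- function(probes) {
  if (is.null(probes$normal_genotype)) return(rep(-1L, nrow(probes)))
  m <- match(probes$normal_genotype, c("AA", "AB", "BB")) - 1L
  m[is.na(m)] <- -1L
  as.integer(m)
}

#' Log emission matrix over the expanded state space
#'
#' Computes the `n x (21 * P)` matrix of per-probe log emission densities
#' over all (tumor state, heterogeneity level) combinations, where `P` is
#' the length of the heterogeneity grid.  Column order is states within
#' heterogeneity level (level 1 first).
#'
#' @param probes Probe data frame with columns `lrr`, `baf` and optionally
#'   `gc`, `normal_genotype`.
#' @param params An [emission_params()] object.
#' @param pi0 Genome-wide normal fraction.
#' @param pi_grid Discrete heterogeneity support.
#' @param pop_b_freq Population B allele frequency.
#' @param state_table State table (defaults to [build_state_table()]).
#' @param cells Optional precomputed cell table (internal reuse).
#' @return Numeric matrix of log densities.
#' @export
emission_matrix <- function(probes, params, pi0, pi_grid = 0,
                            pop_b_freq = 0.5,
                            state_table = build_state_table(),
                            cells = NULL) {
  if (is.null(cells))
    cells <- build_cell_table(state_table, pi_grid, pop_b_freq)
  np <- params_to_native(params)
  gc <- probes$gc %||% rep(0, nrow(probes))
  gc[is.na(gc)] <- 0
  emission_core(probes$lrr, probes$baf, gc, matched_codes(probes),
                cells$es, cells$pil, cells$zn, cells$xn, cells$zt, cells$xt,
                cell_band_class(cells, pi0),
                cells$lgp_hw, as.matrix(cells[, c("lgp_m0", "lgp_m1",
                                                  "lgp_m2")]),
                attr(cells, "pi_grid"), pi0,
                unname(params$lrr_levels), params$beta0, params$beta1,
                np$delta, np$prec, np$sig00, np$lw,
                params$nu, params$eta, params$r_min, params$r_max,
                as.integer(attr(cells, "n_states") * length(attr(cells,
                  "pi_grid"))), params$K)
}
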
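# Independent oracles: written against the formulas directly, sharing no
# code path with the implementation under test.

# bivariate Student-t log density via solve()/det()
oracle_t2_logpdf <- function(y, mean, cov, nu) {
  e <- y - mean
  q <- drop(t(e) %*% solve(cov) %*% e)
  lgamma((nu + 2) / 2) - lgamma(nu / 2) - log(nu) - log(pi) -
    0.5 * log(det(cov)) - ((nu + 2) / 2) * log(1 + q / nu)
}

oracle_t1_logpdf <- function(y, mean, var, nu) {
  q <- (y - mean)^2 / var
  lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi * var) -
    ((nu + 1) / 2) * log(1 + q / nu)
}

# Hardy-Weinberg pair weights within a state, re-derived
oracle_pair_weights <- function(pairs, p, matched = NULL) {
  if (!is.null(matched)) {
    mz <- sum(strsplit(matched, "")[[1]] == "B")
    w <- as.numeric(pairs$z_n == mz)
  } else {
    hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    w <- hw[pairs$z_n + 1] / sapply(pairs$z_n, function(z)
      sum(pairs$z_n == z))
  }
  if (sum(w) == 0) return(w)
  w / sum(w)
}

# explicit nested-loop emission density over genotype pairs x components
oracle_emission <- function(probe, state, params, pi0, pi_i,
                            pop_b_freq = 0.5) {
  pairs <- state$pairs[[1]]
  matched <- probe$normal_genotype
  if (!is.null(matched) && (is.na(matched) || !nzchar(matched)))
    matched <- NULL
  w <- oracle_pair_weights(pairs, pop_b_freq, matched)
  gc <- if (is.null(probe$gc) || is.na(probe$gc)) 0 else probe$gc
  om <- pi_i * (1 - pi0) + pi0
  rb <- params$lrr_levels
  mix <- 0
  for (j in seq_len(nrow(pairs))) {
    if (w[j] == 0) next
    mr <- om * rb[[as.character(pairs$x_n[j])]] +
      (1 - om) * rb[[as.character(pairs$x_t[j])]] +
      params$beta0 + params$beta1 * gc
    den <- om * pairs$x_n[j] + (1 - om) * pairs$x_t[j]
    # noise class from the band position (at-lower-boundary / interior /
    # at-upper-boundary)
    bnd <- if (den > 1e-12)
      (om * pairs$z_n[j] + (1 - om) * pairs$z_t[j]) / den else
        pairs$z_n[j] / 2
    l <- if (bnd < 1e-6) 1 else if (bnd > 1 - 1e-6) 3 else 2
    for (k in seq_len(params$K)) {
      if (den > 1e-12) {
        mb <- (om * pairs$z_n[j] + (1 - om) * pairs$z_t[j]) / den
        ld <- oracle_t2_logpdf(c(probe$lrr, probe$baf),
                               c(mr, mb) + params$delta[, k, l],
                               params$sigma[, , k, l], params$nu)
      } else {
        ld <- oracle_t1_logpdf(probe$lrr, mr + params$delta[1, k, l],
                               params$sigma[1, 1, k, l], params$nu)
      }
      mix <- mix + w[j] * params$weights[k, l] * exp(ld)
    }
  }
  u <- if (probe$lrr >= params$r_min && probe$lrr <= params$r_max)
    1 / (params$r_max - params$r_min) else 0
  log(params$eta * u + (1 - params$eta) * mix)
}

# enumeration over all S^n paths of the inhomogeneous chain
oracle_enum_chain <- function(logemis, rho, newchrom, init) {
  n <- nrow(logemis); S <- ncol(logemis)
  init <- init / sum(init)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  lp <- apply(paths, 1, function(pth) {
    l <- log(init[pth[1]]) + logemis[1, pth[1]]
    for (i in seq_len(n)[-1]) {
      l <- l + if (newchrom[i]) log(init[pth[i]]) else
        log(if (pth[i] == pth[i - 1]) 1 - rho[i] else rho[i] / (S - 1))
      l <- l + logemis[i, pth[i]]
    }
    l
  })
  m <- max(lp)
  Z <- m + log(sum(exp(lp - m)))
  gamma <- sapply(seq_len(S), function(s) sapply(seq_len(n), function(i) {
    sel <- lp[paths[, i] == s]
    mm <- max(sel)
    if (!is.finite(mm)) 0 else exp(mm - Z) * sum(exp(sel - mm))
  }))
  # argmax path, ties toward lexicographically smallest (lowest state ids)
  best <- which(lp == max(lp))
  vit <- paths[best[which.min(apply(paths[best, , drop = FALSE], 1, paste,
                                    collapse = ""))], ]
  list(loglik = Z, gamma = gamma, viterbi = as.integer(vit))
}

# Inverse-Wishart density, independent route: for p = 1 the
# Inverse-Gamma(g/2, S/2) density via dgamma on the precision
oracle_iw1 <- function(w, g, S) {
  stats::dgamma(1 / w, shape = g / 2, rate = S / 2, log = TRUE) - 2 * log(w)
}

# 2x2 Inverse-Wishart from the textbook formula with explicit Gamma_2
oracle_iw2 <- function(W, g, S) {
  lG2 <- 0.5 * log(pi) + lgamma(g / 2) + lgamma(g / 2 - 0.5)
  (g / 2) * log(det(S)) - g * log(2) - lG2 -
    ((g + 3) / 2) * log(det(W)) - 0.5 * sum(diag(S %*% solve(W)))
}
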
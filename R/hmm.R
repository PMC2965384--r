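#' Distance-dependent transition probabilities
#'
#' The tumor-state chain is inhomogeneous: the probability of switching
#' state between adjacent probes is
#' `rho = (1/2) (1 - exp(-(d / (2 L))))` with `d` the probe spacing in base
#' pairs and `L` a characteristic length.  The switch mass is split
#' uniformly over the other `n_states - 1` states so each row of the
#' transition matrix is stochastic; `rho` grows from 0 at zero spacing to
#' 1/2 at large spacing.
#'
#' @param pos_prev,pos_cur Base-pair positions of the previous and current
#'   probe (`pos_cur >= pos_prev`).
#' @param L Characteristic length in base pairs.
#' @param n_states Number of chain states.
#' @return List with `rho`, `stay` (self-transition probability) and
#'   `switch` (per-state probability of each of the other states).
#' @examples
#' transition_probs(0, 2e6, L = 2e6, n_states = 21)$rho  # 0.5 * (1 - exp(-0.5))
#' @export
transition_probs <- function(pos_prev, pos_cur, L, n_states) {
  d <- pos_cur - pos_prev
  if (any(d < 0)) stop("negative inter-probe distance")
  stopifnot(L > 0, n_states >= 1)
  rho <- 0.5 * (1 - exp(-d / (2 * L)))
  list(rho = rho, stay = 1 - rho,
       switch = if (n_states > 1) rho / (n_states - 1) else rho * 0)
}

# per-probe switch probability vector and chromosome-start flags
chain_geometry <- function(probes, L) {
  n <- nrow(probes)
  chrom <- as.character(probes$chrom)
  newchrom <- c(TRUE, chrom[-1] != chrom[-n])
  d <- c(0, diff(probes$pos))
  d[newchrom] <- 0
  if (any(d < 0)) stop("probes not sorted by position within chromosome")
  rho <- 0.5 * (1 - exp(-d / (2 * L)))
  list(rho = rho, newchrom = newchrom)
}

# initial distribution over the expanded (state x heterogeneity) space:
# normal state favored, heterogeneity levels weighted by their prior
initial_distribution <- function(hyper, n_states = 21L) {
  ws <- rep(1, n_states)
  ws[3] <- hyper$state3_favor
  ws <- ws / sum(ws)
  wp <- exp(pi_log_prior(hyper))
  as.numeric(outer(ws, wp))
}

# Per-probe heterogeneity penalty over the expanded state space: the
# discrete prior on pi_i applies to every SNP, normalized so the pi_i = 0
# level costs nothing.  Without it, subclonal levels can imitate clonal
# states of a different copy number exactly (e.g. pure copy-3 LOH equals
# copy-4 germline LOH with 40% normal-genotype retention in both means),
# and the full model is no longer nested above its restricted variants if
# positive levels could carry positive weight.
pi_penalty_offsets <- function(hyper, n_states = 21L) {
  lp <- pi_log_prior(hyper)
  rep(lp - max(lp), each = n_states)
}

add_pi_penalty <- function(logemis, hyper, n_states = 21L) {
  off <- pi_penalty_offsets(hyper, n_states)
  if (all(off == 0)) return(logemis)
  logemis + matrix(off, nrow(logemis), ncol(logemis), byrow = TRUE)
}

#' Posterior marginals and evidence of an inhomogeneous chain
#'
#' Exact forward-backward recursions for a chain with per-probe emission
#' log densities, distance-dependent switch probabilities and uniform
#' switch mass, computed in scaled space (no underflow for long chains).
#' This is the computational core used by [forward_backward()]; it accepts
#' arbitrary emission matrices, which makes small-state-space enumeration
#' checks possible.
#'
#' @param logemis `n x S` matrix of log emission densities.
#' @param rho Length-`n` switch probabilities (entry `i` applies to the
#'   transition into probe `i`; entry 1 is ignored).
#' @param newchrom Logical length-`n`; `TRUE` restarts the chain from
#'   `init` at that probe.
#' @param init Initial/restart distribution over the `S` states.
#' @return List with `gamma` (`n x S` posterior marginals) and `loglik`.
#' @export
chain_posteriors <- function(logemis, rho, newchrom, init) {
  stopifnot(nrow(logemis) == length(rho), length(rho) == length(newchrom),
            ncol(logemis) == length(init), all(init >= 0))
  fb_core(logemis, rho, newchrom, init / sum(init), TRUE)
}

#' @rdname chain_posteriors
#' @return `chain_viterbi`: integer vector of 1-based most probable states;
#'   ties broken toward the lower state index.
#' @export
chain_viterbi <- function(logemis, rho, newchrom, init) {
  stopifnot(nrow(logemis) == length(rho), ncol(logemis) == length(init))
  viterbi_core(logemis, rho, newchrom, init / sum(init)) + 1L
}

check_probes <- function(probes) {
  stopifnot(is.data.frame(probes),
            all(c("chrom", "pos", "lrr", "baf") %in% names(probes)))
  ord <- chrom_order(probes$chrom)
  if (!all(ord == seq_len(nrow(probes))) ||
      any(unlist(tapply(probes$pos, factor(probes$chrom,
        levels = unique(probes$chrom)), function(p) diff(p) < 0))))
    stop("probes must be sorted by (chromosome, position); see read_probe_table()")
  invisible(probes)
}

#' Posterior tumor-state probabilities for a probe table
#'
#' Runs the expanded (21 states x heterogeneity grid) chain and returns
#' per-probe posterior distributions over tumor states and heterogeneity
#' levels, plus the data log evidence given the parameters.
#'
#' @param probes Sorted probe data frame (see [read_probe_table()]).
#' @param params An [emission_params()] object.
#' @param pi0 Genome-wide normal DNA fraction.
#' @param hyper A [default_hyperparams()] list.
#' @param pop_b_freq Population B allele frequency.
#' @return List with `state_posteriors` (`n x 21`), `pi_posterior`
#'   (`n x P`), `gamma` (full expanded marginals) and `loglik`.
#' @export
forward_backward <- function(probes, params, pi0,
                             hyper = default_hyperparams(),
                             pop_b_freq = 0.5) {
  check_probes(probes)
  geom <- chain_geometry(probes, hyper$L)
  logemis <- add_pi_penalty(
    emission_matrix(probes, params, pi0, hyper$pi_grid, pop_b_freq), hyper)
  init <- initial_distribution(hyper)
  fb <- fb_core(logemis, geom$rho, geom$newchrom, init, TRUE)
  collapse_posteriors(fb$gamma, length(hyper$pi_grid), fb$loglik)
}

collapse_posteriors <- function(gamma, P, loglik = NULL) {
  n <- nrow(gamma)
  S21 <- ncol(gamma) / P
  sp <- matrix(0, n, S21)
  pp <- matrix(0, n, P)
  for (p in seq_len(P)) {
    block <- gamma[, (p - 1) * S21 + seq_len(S21), drop = FALSE]
    sp <- sp + block
    pp[, p] <- rowSums(block)
  }
  list(state_posteriors = sp, pi_posterior = pp, gamma = gamma,
       loglik = loglik)
}

#' Most probable tumor-state path
#'
#' Viterbi decoding over the expanded (state x heterogeneity) space,
#' reported as the 21-state path plus the heterogeneity level.
#'
#' @inheritParams forward_backward
#' @return List with `state` (integer path over 1..21) and `pi_level`
#'   (heterogeneity value per probe).
#' @export
viterbi <- function(probes, params, pi0, hyper = default_hyperparams(),
                    pop_b_freq = 0.5) {
  check_probes(probes)
  geom <- chain_geometry(probes, hyper$L)
  logemis <- add_pi_penalty(
    emission_matrix(probes, params, pi0, hyper$pi_grid, pop_b_freq), hyper)
  init <- initial_distribution(hyper)
  path <- viterbi_core(logemis, geom$rho, geom$newchrom, init / sum(init))
  list(state = (path %% 21L) + 1L,
       pi_level = hyper$pi_grid[path %/% 21L + 1L])
}

# ---- MAP-EM ---------------------------------------------------------------

variant_constraints <- function(variant) {
  variant <- match.arg(variant, c("full", "germline", "ploidy_only",
                                  "normal_only", "ploidy", "normal"))
  alias <- c(ploidy = "ploidy_only", normal = "normal_only")
  if (variant %in% names(alias)) variant <- alias[[variant]]
  switch(variant,
    germline    = list(tag = variant, fix_pi0 = TRUE, fix_beta0 = TRUE,
                       pin_pi = TRUE),
    ploidy_only = list(tag = variant, fix_pi0 = TRUE, fix_beta0 = FALSE,
                       pin_pi = TRUE),
    normal_only = list(tag = variant, fix_pi0 = FALSE, fix_beta0 = TRUE,
                       pin_pi = FALSE),
    full        = list(tag = variant, fix_pi0 = FALSE, fix_beta0 = FALSE,
                       pin_pi = FALSE))
}

# conjugate MAP updates from the latent-scale-weighted moment statistics;
# exact conditional maximizations, performed in the order
# (w, delta, Sigma, eta) -> beta -> pi0 so the penalized likelihood is
# non-decreasing
m_step <- function(params, hyper, mom, s_out, cells, n, pi0,
                   fix_beta0, fix_pi0, pi0_local_window = 1L) {
  K <- params$K
  C <- nrow(cells)
  cell_of <- rep(seq_len(C), each = K)
  k_of <- rep(seq_len(K), C)
  l_of <- cells$cls[cell_of] + 1L
  kl_of <- k_of + K * (l_of - 1L)
  rb <- unname(params$lrr_levels)
  pi_grid <- attr(cells, "pi_grid")

  cell_means <- function(p0) {
    om <- pi_grid[cells$pil + 1L] * (1 - p0) + p0
    den <- om * cells$xn + (1 - om) * cells$xt
    A <- om * rb[cells$xn + 1L] + (1 - om) * rb[cells$xt + 1L]
    B <- ifelse(den > 1e-12, (om * cells$zn + (1 - om) * cells$zt) / den,
                cells$zn / 2)
    list(A = A[cell_of], B = B[cell_of])
  }

  mm <- cell_means(pi0)
  b0 <- params$beta0
  b1 <- params$beta1
  Ab <- mm$A + b0
  mu <- mom[, 2]
  e_r <- mom[, 5] - Ab * mu - b1 * mom[, 3]
  e_b <- mom[, 6] - mm$B * mu
  e_rr <- mom[, 9] - 2 * Ab * mom[, 5] - 2 * b1 * mom[, 7] + Ab^2 * mu +
    2 * Ab * b1 * mom[, 3] + b1^2 * mom[, 4]
  e_rb <- mom[, 10] - Ab * mom[, 6] - b1 * mom[, 8] - mm$B * mom[, 5] +
    mm$B * Ab * mu + mm$B * b1 * mom[, 3]
  e_bb <- mom[, 11] - 2 * mm$B * mom[, 6] + mm$B^2 * mu

  Sp <- prior_scale_matrix(hyper)
  new_delta <- params$delta
  new_sigma <- params$sigma
  new_w <- params$weights
  for (l in 1:3) for (k in seq_len(K)) {
    idx <- which(kl_of == k + K * (l - 1L))
    S0 <- sum(mom[idx, 1])
    Sru <- sum(mu[idx])
    Se <- c(sum(e_r[idx]), sum(e_b[idx]))
    d <- Se / (Sru + 1 / hyper$tau)
    sc_rr <- sum(e_rr[idx]) - 2 * d[1] * Se[1] + d[1]^2 * Sru
    sc_rb <- sum(e_rb[idx]) - d[1] * Se[2] - d[2] * Se[1] + d[1] * d[2] * Sru
    sc_bb <- sum(e_bb[idx]) - 2 * d[2] * Se[2] + d[2]^2 * Sru
    sig <- (Sp + outer(d, d) / hyper$tau +
            matrix(c(sc_rr, sc_rb, sc_rb, sc_bb), 2)) /
      (hyper$gamma + 4 + S0)
    new_delta[, k, l] <- d
    new_sigma[, , k, l] <- (sig + t(sig)) / 2
    new_w[k, l] <- max(S0 + hyper$alpha - 1, 1e-8)
  }
  new_w <- sweep(new_w, 2, colSums(new_w), "/")
  new_eta <- (s_out + hyper$alpha_eta - 1) /
    (n + hyper$alpha_eta + hyper$beta_eta - 2)
  new_eta <- min(max(new_eta, 1e-8), 0.9)
  params$delta <- new_delta
  params$sigma <- new_sigma
  params$weights <- new_w
  params$eta <- new_eta

  # precision entries of the updated scale matrices, per moment row
  np <- params_to_native(params)
  P11 <- np$prec[1, kl_of]
  P12 <- np$prec[2, kl_of]
  P22 <- np$prec[3, kl_of]
  dr <- np$delta[1, kl_of]
  db <- np$delta[2, kl_of]

  # exact weighted least squares for (beta0, beta1) given the new
  # offsets/scales; the BAF component enters through the cross-precision
  t_r0 <- mom[, 5] - (mm$A + dr) * mu
  t_rg <- mom[, 7] - (mm$A + dr) * mom[, 3]
  t_b0 <- mom[, 6] - (mm$B + db) * mu
  t_bg <- mom[, 8] - (mm$B + db) * mom[, 3]
  lam <- 1 / hyper$lambda_beta
  M11 <- sum(P11 * mu) + lam
  M12 <- sum(P11 * mom[, 3])
  M22 <- sum(P11 * mom[, 4]) + lam
  r1 <- sum(P11 * t_r0 + P12 * t_b0)
  r2 <- sum(P11 * t_rg + P12 * t_bg)
  if (fix_beta0) {
    # conditional maximizer of beta1 at the pinned beta0 (cross term M12)
    params$beta1 <- (r2 - params$beta0 * M12) / M22
  } else {
    bet <- solve(matrix(c(M11, M12, M12, M22), 2), c(r1, r2))
    params$beta0 <- bet[1]
    params$beta1 <- bet[2]
    # gauge step: the likelihood is invariant under a shared LRR offset
    # moving between the component means and the baseline
    # (delta_r - c, beta0 + c); pick c maximizing the prior along this
    # direction so the shared shift is carried by beta0, where it belongs
    kl_u <- seq_len(K * 3)
    cP11 <- np$prec[1, kl_u]; cP12 <- np$prec[2, kl_u]
    cdr <- np$delta[1, kl_u]; cdb <- np$delta[2, kl_u]
    cc <- (sum(cP11 * cdr + cP12 * cdb) / hyper$tau -
             params$beta0 / hyper$lambda_beta) /
      (sum(cP11) / hyper$tau + 1 / hyper$lambda_beta)
    params$delta[1, , ] <- params$delta[1, , ] - cc
    params$beta0 <- params$beta0 + cc
    np$delta[1, ] <- np$delta[1, ] - cc
    dr <- dr - cc
  }

  if (!fix_pi0) {
    grid <- hyper$pi0_grid
    cur <- which.min(abs(grid - pi0))
    cand <- unique(pmin(pmax(cur + seq(-pi0_local_window, pi0_local_window),
                             1L), length(grid)))
    lp0 <- pi0_log_prior(hyper)
    qv <- vapply(cand, function(ci) {
      mmc <- cell_means(grid[ci])
      a <- mmc$A + params$beta0 + dr
      h <- params$beta1
      bb <- mmc$B + db
      Err <- mom[, 9] - 2 * a * mom[, 5] - 2 * h * mom[, 7] + a^2 * mu +
        2 * a * h * mom[, 3] + h^2 * mom[, 4]
      Erb <- mom[, 10] - a * mom[, 6] - h * mom[, 8] - bb * mom[, 5] +
        a * bb * mu + h * bb * mom[, 3]
      Ebb <- mom[, 11] - 2 * bb * mom[, 6] + bb^2 * mu
      -0.5 * sum(P11 * Err + 2 * P12 * Erb + P22 * Ebb) + lp0[ci]
    }, 0)
    pi0 <- grid[cand[which.max(qv)]]
  }
  list(params = params, pi0 = pi0)
}

penalized <- function(loglik, params, pi0, hyper) {
  on_grid <- any(abs(hyper$pi0_grid - pi0) < 1e-9)
  lp <- if (on_grid) log_prior(params, pi0, hyper) else
    log_prior(params, hyper$pi0_grid[1], hyper) - pi0_log_prior(hyper)[1]
  loglik + lp
}

#' Fit the model by MAP expectation-maximization
#'
#' E-steps run exact forward-backward over the expanded chain; M-steps
#' apply conjugate maximum-a-posteriori updates (Dirichlet-smoothed weights,
#' Normal-Inverse-Wishart offsets and scales with the Student-t latent-scale
#' construction, Beta outlier rate, penalized weighted least squares for the
#' baseline and GC coefficients, and grid maximization for the normal
#' fraction).  Early iterations additionally scan the marginal likelihood
#' over a coarse normal-fraction grid to avoid the local trap in which
#' genome-wide contamination is absorbed by locus-level heterogeneity.
#'
#' @inheritParams forward_backward
#' @param init Initial [emission_params()]; default
#'   [default_emission_params()].
#' @param pi0_init Initial normal fraction (a `hyper$pi0_grid` point).
#' @param n_iters Maximum EM iterations (default 15).
#' @param variant Model variant: `"full"` (normal fraction and baseline
#'   free), `"germline"` (both fixed at 0), `"ploidy_only"` (normal
#'   fraction fixed at 0), `"normal_only"` (baseline fixed at 0).  The two
#'   no-contamination variants also pin the heterogeneity grid to 0.
#' @param tol Relative penalized log-likelihood change declaring
#'   convergence.
#' @param pi0_scan_iters Iterations after which a coarse marginal-likelihood
#'   scan over the normal fraction is performed, in addition to the scan at
#'   initialization (ignored when the variant fixes the normal fraction).
#' @param beta0_freeze Number of initial iterations during which the
#'   baseline stays at its restart initialization, so the normal fraction
#'   and mixture settle within one baseline interpretation before
#'   continuous refinement.
#' @param fix_pi0,fix_beta0 Force-fix the normal fraction / baseline at
#'   their initial values regardless of variant (used by
#'   [likelihood_surface()]).
#' @param moment_thresh Posterior-mass threshold below which a
#'   probe/state block is skipped during moment accumulation.
#' @return An object of class `"hmm_fit"`: fitted `params`, `pi0`,
#'   `loglik_trace` (penalized, non-decreasing), `state_posteriors`,
#'   `pi_posterior`, `viterbi_state`, `viterbi_pi`, `variant` and inputs
#'   needed by downstream scoring.
#' @export
em_fit <- function(probes, init = NULL, pi0_init = 0,
                   hyper = default_hyperparams(), n_iters = 15L,
                   variant = "full", pop_b_freq = 0.5, tol = 1e-6,
                   pi0_scan_iters = c(4L, 8L), beta0_freeze = 5L,
                   fix_pi0 = FALSE, fix_beta0 = FALSE,
                   moment_thresh = 1e-12, verbose = FALSE) {
  check_probes(probes)
  vc <- variant_constraints(variant)
  fix_pi0 <- fix_pi0 || vc$fix_pi0
  fix_beta0 <- fix_beta0 || vc$fix_beta0
  if (vc$pin_pi) hyper$pi_grid <- 0
  params <- init %||% default_emission_params()
  if (vc$fix_pi0) pi0_init <- 0
  if (vc$fix_beta0) params$beta0 <- 0
  pi0 <- pi0_init
  n <- nrow(probes)

  st <- build_state_table()
  cells <- build_cell_table(st, hyper$pi_grid, pop_b_freq)
  geom <- chain_geometry(probes, hyper$L)
  init_dist <- initial_distribution(hyper)
  init_dist <- init_dist / sum(init_dist)
  gc <- probes$gc %||% rep(0, n)
  gc[is.na(gc)] <- 0
  # data-driven GC slope initialization: the wave is independent of the
  # segment structure, so a genome-wide regression gives a clean slope
  if (params$beta1 == 0 && stats::var(gc) > 0)
    params$beta1 <- stats::cov(probes$lrr, gc) / stats::var(gc)
  mc <- matched_codes(probes)
  lgm <- as.matrix(cells[, c("lgp_m0", "lgp_m1", "lgp_m2")])

  emis <- function(par, p0) {
    np <- params_to_native(par)
    emission_core(probes$lrr, probes$baf, gc, mc,
                  cells$es, cells$pil, cells$zn, cells$xn, cells$zt,
                  cells$xt, cell_band_class(cells, p0), cells$lgp_hw, lgm,
                  hyper$pi_grid, p0, unname(par$lrr_levels),
                  par$beta0, par$beta1, np$delta, np$prec, np$sig00, np$lw,
                  par$nu, par$eta, par$r_min, par$r_max,
                  as.integer(21L * length(hyper$pi_grid)), par$K)
  }
  pi_off <- pi_penalty_offsets(hyper)
  pen_emis <- function(par, p0) {
    le <- emis(par, p0)
    if (any(pi_off != 0))
      le <- le + matrix(pi_off, nrow(le), ncol(le), byrow = TRUE)
    le
  }
  pi0_scan <- function(par, p0_cur, window = Inf) {
    # marginal-likelihood scan: exact ascent because the current point is
    # among the candidates
    idx <- which(abs(hyper$pi0_grid - p0_cur) <= window + 1e-9)
    grid <- hyper$pi0_grid[idx]
    lp0 <- pi0_log_prior(hyper)[idx]
    lls <- vapply(seq_along(grid), function(j) {
      le <- pen_emis(par, grid[j])
      fb_core(le, geom$rho, geom$newchrom, init_dist, FALSE)$loglik + lp0[j]
    }, 0)
    grid[which.max(lls)]
  }
  if (!fix_pi0) pi0 <- pi0_scan(params, pi0)  # full-grid global scan

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(n_iters)) {
    logemis <- emis(params, pi0)
    fb <- fb_core(if (any(pi_off != 0))
                    logemis + matrix(pi_off, n, ncol(logemis), byrow = TRUE)
                  else logemis,
                  geom$rho, geom$newchrom, init_dist, TRUE)
    llp <- penalized(fb$loglik, params, pi0, hyper)
    if (!is.finite(llp))
      stop("non-finite penalized log-likelihood at iteration ", it,
           "; worst probe: ",
           which.min(apply(logemis, 1, max)))
    trace <- c(trace, llp)
    if (verbose)
      message(sprintf("iter %2d  loglik %.3f  pi0 %.2f  beta0 %+.3f",
                      it, llp, pi0, params$beta0))
    if (it > 1 && abs(llp - trace[it - 1]) <
        tol * (abs(trace[it - 1]) + 1)) {
      converged <- TRUE
      break
    }
    np <- params_to_native(params)
    cells$cls <- cell_band_class(cells, pi0)  # noise class at current omega
    mo <- moments_core(probes$lrr, probes$baf, gc, mc,
                       cells$es, cells$pil, cells$zn, cells$xn, cells$zt,
                       cells$xt, cells$cls, cells$lgp_hw, lgm,
                       hyper$pi_grid, pi0, unname(params$lrr_levels),
                       params$beta0, params$beta1,
                       np$delta, np$prec, np$sig00, np$lw,
                       params$nu, params$eta, params$r_min, params$r_max,
                       as.integer(21L * length(hyper$pi_grid)), params$K,
                       fb$gamma, logemis, moment_thresh)
    upd <- m_step(params, hyper, mo$mom, mo$s_out, cells, n, pi0,
                  fix_beta0 = fix_beta0 || it <= beta0_freeze,
                  fix_pi0 = fix_pi0)
    params <- upd$params
    pi0 <- upd$pi0
    if (!fix_pi0 && it %in% pi0_scan_iters)
      pi0 <- pi0_scan(params, pi0, window = 0.25)
  }
  logemis <- pen_emis(params, pi0)
  fb <- fb_core(logemis, geom$rho, geom$newchrom, init_dist, TRUE)
  trace <- c(trace, penalized(fb$loglik, params, pi0, hyper))
  path <- viterbi_core(logemis, geom$rho, geom$newchrom, init_dist)
  post <- collapse_posteriors(fb$gamma, length(hyper$pi_grid))
  fit <- list(params = params, pi0 = pi0, pi_grid = hyper$pi_grid,
              loglik = fb$loglik, penalized_loglik = trace[length(trace)],
              loglik_trace = trace, converged = converged,
              state_posteriors = post$state_posteriors,
              pi_posterior = post$pi_posterior,
              viterbi_state = (path %% 21L) + 1L,
              viterbi_pi = hyper$pi_grid[path %/% 21L + 1L],
              variant = vc$tag, hyper = hyper, pop_b_freq = pop_b_freq,
              probes = probes, state_table = st)
  class(fit) <- "hmm_fit"
  fit
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("HMM fit (", x$variant, " variant)\n", sep = "")
  cat("  probes:           ", nrow(x$probes), "\n")
  cat("  normal fraction:  ", x$pi0, "\n")
  cat("  LRR baseline:     ", round(x$params$beta0, 4), "\n")
  cat("  GC coefficient:   ", round(x$params$beta1, 4), "\n")
  cat("  penalized loglik: ", round(x$penalized_loglik, 2), "\n")
  invisible(x)
}

#' Fit with multiple Log R Ratio baseline restarts
#'
#' Array normalization pins the LRR zero line to the sample's average
#' ploidy, so polyploid genomes need a baseline shift whose likelihood
#' surface is multimodal.  The model is fitted from each baseline
#' initialization and the fit with the greatest final penalized
#' log-likelihood is returned; the restart table records all of them.
#'
#' @inheritParams em_fit
#' @param baseline_grid Baseline (`beta0`) initializations; the default
#'   covers diploid through tetraploid interpretations.
#' @param ... Passed to [em_fit()].
#' @return The winning `"hmm_fit"` with an added `restarts` data frame
#'   (columns `beta0_init`, `beta0`, `pi0`, `loglik`, `penalized_loglik`).
#' @export
fit_with_restarts <- function(probes, hyper = default_hyperparams(),
                              baseline_grid = c(0, -0.40, -0.68, 0.33),
                              variant = "full", init = NULL, ...) {
  stopifnot(length(baseline_grid) >= 1)
  vc <- variant_constraints(variant)
  if (vc$fix_beta0) baseline_grid <- 0
  fits <- vector("list", length(baseline_grid))
  errs <- character(0)
  for (i in seq_along(baseline_grid)) {
    par <- init %||% default_emission_params()
    par$beta0 <- baseline_grid[i]
    fits[[i]] <- tryCatch(
      em_fit(probes, init = par, hyper = hyper, variant = variant, ...),
      error = function(e) e)
    if (inherits(fits[[i]], "error"))
      errs <- c(errs, sprintf("beta0=%g: %s", baseline_grid[i],
                              conditionMessage(fits[[i]])))
  }
  ok <- !vapply(fits, inherits, NA, "error")
  if (!any(ok))
    stop("all baseline restarts failed:\n", paste(errs, collapse = "\n"))
  tab <- data.frame(
    beta0_init = baseline_grid[ok],
    beta0 = vapply(fits[ok], function(f) f$params$beta0, 0),
    pi0 = vapply(fits[ok], function(f) f$pi0, 0),
    loglik = vapply(fits[ok], function(f) f$loglik, 0),
    penalized_loglik = vapply(fits[ok], function(f) f$penalized_loglik, 0))
  best <- fits[ok][[which.max(tab$penalized_loglik)]]
  best$restarts <- tab
  best
}

#' Profile log-likelihood surface over normal fraction and baseline
#'
#' For each grid point the model is refitted for a few EM iterations with
#' the normal fraction and baseline held fixed, and the resulting data log
#' evidence recorded.  Contaminated polyploid samples typically show
#' multiple modes, each a different but compatible interpretation of the
#' data.
#'
#' @inheritParams em_fit
#' @param pi0_grid,beta0_grid Grid values for the normal fraction and the
#'   LRR baseline adjustment.
#' @param n_iters EM refinement iterations per grid point (default 3).
#' @param ... Passed to [em_fit()].
#' @return Matrix of log-likelihoods with `pi0_grid` rows and `beta0_grid`
#'   columns (dimnames carry the grid values).
#' @export
likelihood_surface <- function(probes, pi0_grid, beta0_grid,
                               hyper = default_hyperparams(),
                               n_iters = 3L, init = NULL, ...) {
  stopifnot(length(pi0_grid) >= 1, length(beta0_grid) >= 1)
  out <- matrix(NA_real_, length(pi0_grid), length(beta0_grid),
                dimnames = list(pi0 = signif(pi0_grid, 6),
                                beta0 = signif(beta0_grid, 6)))
  for (i in seq_along(pi0_grid)) for (j in seq_along(beta0_grid)) {
    par <- init %||% default_emission_params()
    par$beta0 <- beta0_grid[j]
    fit <- em_fit(probes, init = par, pi0_init = pi0_grid[i],
                  hyper = hyper, n_iters = n_iters, fix_pi0 = TRUE,
                  fix_beta0 = TRUE, ...)
    out[i, j] <- fit$loglik
  }
  out
}

#' Local maxima of a likelihood surface
#'
#' @param surface Matrix as returned by [likelihood_surface()].
#' @return Data frame with columns `i`, `j`, `pi0`, `beta0`, `value`, one
#'   row per cell strictly greater than all of its (up to 8) neighbors.
#' @export
find_local_maxima <- function(surface) {
  nr <- nrow(surface); nc <- ncol(surface)
  hits <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nb <- expand.grid(di = -1:1, dj = -1:1)
    nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
    ii <- i + nb$di; jj <- j + nb$dj
    keep <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    vals <- surface[cbind(ii[keep], jj[keep])]
    if (all(surface[i, j] > vals))
      hits[[length(hits) + 1]] <- data.frame(i = i, j = j, value = surface[i, j])
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(i = integer(0), j = integer(0), value = numeric(0))
  out$pi0 <- as.numeric(rownames(surface))[out$i]
  out$beta0 <- as.numeric(colnames(surface))[out$j]
  out[, c("i", "j", "pi0", "beta0", "value")]
}
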
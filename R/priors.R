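#' Default hyperparameters
#'
#' Hyperparameters of all conjugate priors used for MAP-EM: Dirichlet
#' concentration `alpha` on mixture weights, Normal-Inverse-Wishart
#' (`tau`, `gamma`, `S`) on component offsets and scale matrices, Beta
#' (`alpha_eta`, `beta_eta`) on the outlier rate, Normal scale `lambda_beta`
#' on the baseline/GC coefficients, two-level discrete masses on the normal
#' fraction (`alpha_pi0`, `beta_pi0`) and heterogeneity fraction
#' (`alpha_pi`, `beta_pi`), and the transition characteristic length `L`
#' in base pairs.  The discrete supports `pi0_grid` and `pi_grid` are a
#' package convention (see the methods vignette).
#'
#' @param ... Named overrides of any default.
#' @return A list of class `"hyperparams"`.
#' @examples
#' h <- default_hyperparams()
#' h$alpha   # 1
#' h$beta_pi # 2
#' h$L       # 2e6
#' @export
default_hyperparams <- function(...) {
  h <- list(
    alpha = 1, tau = 0.05, gamma = 5, S = 0.01 * diag(2),
    alpha_eta = 1, beta_eta = 1, lambda_beta = 1,
    alpha_pi0 = 1, beta_pi0 = 1, alpha_pi = 1, beta_pi = 2,
    L = 2e6,
    pi0_grid = seq(0, 0.90, by = 0.05),
    pi_grid = c(0, 0.2, 0.4, 0.6),
    state3_favor = 10  # initial-distribution weight of the normal state
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(h)))
  h <- modifyList(h, over)
  stopifnot(h$alpha > 0, h$tau > 0, h$gamma > 0, h$alpha_eta > 0,
            h$beta_eta > 0, h$lambda_beta > 0, h$alpha_pi0 > 0,
            h$beta_pi0 > 0, h$alpha_pi > 0, h$beta_pi > 0, h$L > 0)
  class(h) <- "hyperparams"
  h
}

# normalized log prior mass over a two-level discrete support: mass a on 0,
# mass b split evenly over the positive grid points
two_level_log_prior <- function(grid, a, b) {
  npos <- sum(grid > 0)
  m <- ifelse(grid == 0, a, b / max(npos, 1))
  log(m / sum(m))
}

pi0_log_prior <- function(hyper) {
  two_level_log_prior(hyper$pi0_grid, hyper$alpha_pi0, hyper$beta_pi0)
}

pi_log_prior <- function(hyper) {
  two_level_log_prior(hyper$pi_grid, hyper$alpha_pi, hyper$beta_pi)
}

# log density of the Inverse-Wishart IW(g, S) at a p x p SPD matrix W
log_dinvwishart <- function(W, g, S) {
  p <- nrow(W)
  lmvgamma <- sum(lgamma(g / 2 + (1 - seq_len(p)) / 2)) +
    p * (p - 1) / 4 * log(pi)
  ldetS <- determinant(S, logarithm = TRUE)$modulus[1]
  ldetW <- determinant(W, logarithm = TRUE)$modulus[1]
  (g / 2) * ldetS - (g * p / 2) * log(2) - lmvgamma -
    ((g + p + 1) / 2) * ldetW - 0.5 * sum(diag(S %*% solve(W)))
}

log_ddirichlet <- function(w, alpha) {
  a <- rep(alpha, length(w))
  sum((a - 1) * log(w)) + lgamma(sum(a)) - sum(lgamma(a))
}

log_dmvnorm <- function(x, mean, cov) {
  p <- length(x)
  ld <- determinant(cov, logarithm = TRUE)$modulus[1]
  e <- x - mean
  -0.5 * (p * log(2 * pi) + ld + sum(e * solve(cov, e)))
}

#' Log prior density of the emission parameters and normal fraction
#'
#' Sum of the log prior terms used for MAP-EM: Dirichlet on mixture weights,
#' Normal (scaled by the component's own scale matrix) on component offsets,
#' Inverse-Wishart on scale matrices, Beta on the outlier rate, Normal on
#' the baseline/GC coefficients, and the normalized discrete prior on the
#' normal fraction.
#'
#' @param params An [emission_params()] object.
#' @param pi0 Normal fraction; must lie on `hyper$pi0_grid`.
#' @param hyper A [default_hyperparams()] list.
#' @return Scalar log prior; `-Inf` (with a warning) outside the support.
#' @export
log_prior <- function(params, pi0, hyper = default_hyperparams()) {
  K <- params$K
  if (params$eta < 0 || params$eta > 1) {
    warning("eta outside [0, 1]")
    return(-Inf)
  }
  i0 <- which(abs(hyper$pi0_grid - pi0) < 1e-9)
  if (length(i0) != 1L) {
    warning("pi0 not on the prior grid")
    return(-Inf)
  }
  lp <- pi0_log_prior(hyper)[i0]
  lp <- lp + dbeta_log_safe(params$eta, hyper$alpha_eta, hyper$beta_eta)
  lp <- lp + log_dmvnorm(c(params$beta0, params$beta1), c(0, 0),
                         hyper$lambda_beta * diag(2))
  for (l in 1:3) {
    w <- pmax(params$weights[, l], 1e-300)
    lp <- lp + log_ddirichlet(w / sum(w), hyper$alpha)
    for (k in seq_len(K)) {
      sig <- params$sigma[, , k, l]
      if (det(sig) <= 0) {
        warning("sigma not positive definite")
        return(-Inf)
      }
      lp <- lp + log_dmvnorm(params$delta[, k, l], c(0, 0), hyper$tau * sig)
      lp <- lp + log_dinvwishart(sig, hyper$gamma, prior_scale_matrix(hyper))
    }
  }
  unname(lp)
}

prior_scale_matrix <- function(hyper) {
  if (is.matrix(hyper$S)) hyper$S else hyper$S * diag(2)
}

dbeta_log_safe <- function(x, a, b) {
  if ((x == 0 && a < 1) || (x == 1 && b < 1)) return(Inf)
  stats::dbeta(x, a, b, log = TRUE)
}
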
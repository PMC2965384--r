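test_that("transition probabilities follow the distance kernel", {
  tp0 <- transition_probs(100, 100, 2e6, 21)
  expect_equal(tp0$rho, 0)
  expect_equal(tp0$stay, 1)
  expect_equal(transition_probs(0, 1e12, 2e6, 21)$rho, 0.5, tolerance = 1e-6)
  expect_equal(transition_probs(0, 2e6, 2e6, 21)$rho,
               0.5 * (1 - exp(-0.5)), tolerance = 1e-12)
  d <- seq(0, 1e7, by = 1e5)
  rho <- transition_probs(0, d, 2e6, 21)$rho
  expect_false(is.unsorted(rho, strictly = TRUE))
  expect_true(all(rho <= 0.5))
  # rows are stochastic: stay + (S-1) * switch = 1
  tp <- transition_probs(0, 3.3e6, 2e6, 21)
  expect_equal(tp$stay + 20 * tp$switch, 1)
  expect_error(transition_probs(10, 5, 2e6, 21), "negative")
})

test_that("forward-backward and Viterbi agree with path enumeration", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      n <- 8; S <- 3
      le <- matrix(rnorm(n * S, sd = 2), n, S)
      rho <- c(0, runif(n - 1, 0, 0.5))
      nc <- rep(FALSE, n); nc[1] <- TRUE
      if (seed > 1) nc[5] <- TRUE  # chromosome break mid-chain
      init <- runif(S) + 0.2
      ref <- oracle_enum_chain(le, rho, nc, init)
      fb <- chain_posteriors(le, rho, nc, init)
      expect_equal(fb$loglik, ref$loglik, tolerance = 1e-10)
      expect_equal(fb$gamma, ref$gamma, tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(chain_viterbi(le, rho, nc, init), ref$viterbi)
    })
  }
})

test_that("single-probe posterior is prior times emission; uniform emissions recover the chain prior", {
  le1 <- matrix(c(log(0.2), log(0.5), log(0.3)), 1, 3)
  init <- c(0.6, 0.3, 0.1)
  fb <- chain_posteriors(le1, 0, TRUE, init)
  ref <- init * exp(le1[1, ]); ref <- ref / sum(ref)
  expect_equal(fb$gamma[1, ], ref, tolerance = 1e-12)
  # likelihood-free case: posteriors equal prior chain marginals
  n <- 6
  le <- matrix(0, n, 3)
  rho <- c(0, rep(0.3, n - 1)); nc <- c(TRUE, rep(FALSE, n - 1))
  fb2 <- chain_posteriors(le, rho, nc, init)
  ref2 <- oracle_enum_chain(le, rho, nc, init)
  expect_equal(fb2$gamma, ref2$gamma, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fb2$gamma[1, ], init, tolerance = 1e-12)
})

test_that("Viterbi is constant under dominant emissions and breaks ties low", {
  n <- 5
  le <- matrix(-50, n, 3); le[, 2] <- 0   # state 2 dominates everywhere
  rho <- c(0, rep(0.2, n - 1)); nc <- c(TRUE, rep(FALSE, n - 1))
  expect_equal(chain_viterbi(le, rho, nc, rep(1, 3)), rep(2L, n))
  # two states with identical emissions and symmetric prior: lower id wins
  le2 <- matrix(0, n, 3); le2[, 3] <- -10
  expect_equal(chain_viterbi(le2, rho, nc, rep(1, 3)), rep(1L, n))
})

test_that("em_fit is near a fixed point when initialized at the truth", {
  cfg <- sim_config(n_probes = 3000L, n_chroms = 5L, pi0_true = 0.25,
                    gc_amplitude = 0, outlier_rate_true = 0.005, seed = 21)
  s <- simulate_sample(cfg)
  pr <- probe_cols(s)
  init <- default_emission_params(
    sigma = array(diag(c(0.15^2, 0.03^2)), c(2, 2, 3, 3)))
  f1 <- em_fit(pr, init = init, pi0_init = 0.25, n_iters = 15L)
  expect_equal(f1$pi0, 0.25)
  expect_lt(abs(f1$params$beta0), 0.03)
  # converged: last iterations change the penalized loglik negligibly
  tr <- f1$loglik_trace
  expect_lt(abs(tr[length(tr)] - tr[length(tr) - 1]),
            1e-4 * abs(tr[length(tr)]))
})

test_that("penalized log-likelihood is non-decreasing (property)", {
  for (seed in c(2, 9)) {
    cfg <- sim_config(n_probes = 600L, n_chroms = 2L,
                      pi0_true = sample(c(0, 0.25, 0.5), 1),
                      seed = seed)
    s <- simulate_sample(cfg)
    fit <- em_fit(probe_cols(s), n_iters = 10L)
    expect_true(all(diff(fit$loglik_trace) > -1e-6 *
                      pmax(abs(fit$loglik_trace[-1]), 1)))
  }
})

test_that("restarts: grid of size 1 reduces to em_fit", {
  cfg <- sim_config(n_probes = 500L, n_chroms = 2L, seed = 4)
  pr <- probe_cols(simulate_sample(cfg))
  f1 <- em_fit(pr, n_iters = 5L)
  fr <- fit_with_restarts(pr, baseline_grid = 0, n_iters = 5L)
  expect_equal(fr$penalized_loglik, f1$penalized_loglik)
  expect_equal(fr$params$beta0, f1$params$beta0)
  expect_equal(nrow(fr$restarts), 1L)
})

test_that("model variants are nested in the full model", {
  cfg <- sim_config(n_probes = 1500L, n_chroms = 3L, pi0_true = 0.5,
                    seed = 13)
  pr <- probe_cols(simulate_sample(cfg))
  lls <- sapply(c("germline", "ploidy_only", "normal_only", "full"),
                function(v) fit_with_restarts(pr, variant = v,
                                              baseline_grid = c(0, -0.4),
                                              n_iters = 8L)$penalized_loglik)
  expect_true(all(lls["full"] >= lls[c("germline", "ploidy_only",
                                       "normal_only")] - 1e-6))
  # germline/ploidy variants pin the normal fraction at zero
  fg <- fit_with_restarts(pr, variant = "germline", n_iters = 3L)
  expect_equal(fg$pi0, 0)
  expect_equal(fg$params$beta0, 0)
})

test_that("1x1 likelihood surface equals a constrained em_fit", {
  cfg <- sim_config(n_probes = 400L, n_chroms = 2L, seed = 6)
  pr <- probe_cols(simulate_sample(cfg))
  surf <- likelihood_surface(pr, pi0_grid = 0.25, beta0_grid = -0.1,
                             n_iters = 3L)
  ref <- em_fit(pr, init = {
    p <- default_emission_params(); p$beta0 <- -0.1; p
  }, pi0_init = 0.25, n_iters = 3L, fix_pi0 = TRUE, fix_beta0 = TRUE)
  expect_equal(unname(surf[1, 1]), ref$loglik)
})

test_that("unsorted probes are rejected", {
  pr <- random_probes(20, seed = 2)
  bad <- pr[rev(seq_len(nrow(pr))), ]
  expect_error(em_fit(bad, n_iters = 1L), "sorted")
  expect_error(forward_backward(bad, default_emission_params(), 0), "sorted")
})
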
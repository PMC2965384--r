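st <- build_state_table()

test_that("lrr_mean mixes canonical levels and handles GC/baseline", {
  par <- default_emission_params()
  pair3 <- st$pairs[[4]][1, ]  # tumor copies 3
  expect_equal(lrr_mean(pair3, 0, 0, par), par$lrr_levels[["3"]])
  par2 <- par; par2$beta0 <- 0.3
  expect_equal(lrr_mean(st$pairs[[5]][1, ], 1, 0, par2),
               par$lrr_levels[["2"]] + 0.3)
  # direct substitution: pi0=0.5, tumor copies 1
  pair1 <- st$pairs[[2]][1, ]
  expect_equal(lrr_mean(pair1, 0.5, 0, par), -0.33)
  expect_equal(lrr_mean(pair1, 0.5, 0, par, gc = 0.6),
               -0.33 + par$beta1 * 0.6)
  bad <- data.frame(z_n = 0, x_n = 2, z_t = 0, x_t = 7)
  expect_error(lrr_mean(bad, 0, 0, par), "0..6")
})

test_that("baf_mean follows the weighted-count ratio with sentinel", {
  bbb <- data.frame(z_n = 2, x_n = 2, z_t = 3, x_t = 3)
  expect_equal(baf_mean(bbb, 0, 0), 1.0)
  ab_a <- data.frame(z_n = 1, x_n = 2, z_t = 0, x_t = 1)
  expect_equal(baf_mean(ab_a, 0.5, 0), 1 / 3)
  null_aa <- data.frame(z_n = 0, x_n = 2, z_t = 0, x_t = 0)
  expect_true(is.na(baf_mean(null_aa, 0, 0)))
  expect_equal(baf_mean(null_aa, 0.4, 0), 0)  # pure normal AA signal
})

test_that("hemizygous deletion shows 4 BAF bands under contamination", {
  p2 <- st$pairs[[2]]
  bands <- sapply(seq_len(nrow(p2)), function(j)
    baf_mean(p2[j, ], 0.5, 0))
  expect_equal(sort(unique(round(bands, 10))), c(0, 1/3, 2/3, 1))
  pure <- sapply(seq_len(nrow(p2)), function(j) baf_mean(p2[j, ], 0, 0))
  expect_equal(sort(unique(pure)), c(0, 1))
})

test_that("baf_mean is symmetric under allele swap and bounded", {
  for (s in c(2, 4, 8, 10, 12)) {
    p <- st$pairs[[s]]
    for (j in seq_len(nrow(p))) for (om in c(0.2, 0.5, 0.8)) {
      swap <- data.frame(z_n = p$x_n[j] - p$z_n[j], x_n = p$x_n[j],
                         z_t = p$x_t[j] - p$z_t[j], x_t = p$x_t[j])
      b <- baf_mean(p[j, ], om, 0)
      expect_true(b >= 0 && b <= 1)
      expect_equal(baf_mean(swap, om, 0), 1 - b)
    }
  }
})

test_that("lrr_mean is monotone non-decreasing in tumor copy number", {
  par <- default_emission_params()
  for (pi0 in c(0, 0.3, 0.7)) {
    m <- sapply(0:6, function(cx)
      lrr_mean(data.frame(z_n = 0, x_n = 2, z_t = 0, x_t = cx), pi0, 0, par))
    expect_false(is.unsorted(m))
  }
})

test_that("bivariate Student-t density: mode, normalization, normal limit", {
  # closed form at the mode with identity scale
  for (nu in c(3, 8, 25))
    expect_equal(student_t_logpdf(c(1, 2), c(1, 2), diag(2), nu),
                 lgamma((nu + 2) / 2) - lgamma(nu / 2) - log(nu * pi))
  # quadrature: integrates to 1
  cov <- matrix(c(1, 0.4, 0.4, 2), 2)
  gr <- seq(-40, 40, by = 0.08)
  dens <- outer(gr, gr, function(x, y)
    exp(mapply(function(a, b) student_t_logpdf(c(a, b), c(0, 0), cov, 5),
               x, y)))
  expect_equal(sum(dens) * 0.08^2, 1, tolerance = 1e-3)
  # nu -> Inf recovers the bivariate normal
  y <- c(0.4, -0.2); m <- c(0.1, 0.1)
  lnorm <- -log(2 * pi) - 0.5 * log(det(cov)) -
    0.5 * drop(t(y - m) %*% solve(cov) %*% (y - m))
  expect_equal(student_t_logpdf(y, m, cov, 1e6), lnorm, tolerance = 1e-4)
  expect_error(student_t_logpdf(y, m, matrix(1, 2, 2), 5), "singular")
})

test_that("genotype priors: matched indicator and Hardy-Weinberg weights", {
  s2 <- st[2, ]
  aa_pair <- st$pairs[[2]][1, ]  # normal AA
  expect_equal(genotype_prior(aa_pair, s2, matched = "AB"), 0)
  w <- sapply(seq_len(4), function(j)
    genotype_prior(st$pairs[[2]][j, ], s2, pop_b_freq = 0.5))
  expect_equal(w, rep(0.25, 4))
  expect_equal(genotype_prior(aa_pair, s2, pop_b_freq = 0), 1)
})

test_that("emission density degenerates correctly", {
  par <- default_emission_params()
  probe <- list(lrr = 0.2, baf = 0.7, gc = 0.5)
  # eta = 1: pure outlier, identical for all states
  par1 <- par; par1$eta <- 1
  for (s in c(1, 5, 17))
    expect_equal(emission_logdensity(probe, st[s, ], par1, 0.2, 0),
                 -log(par$r_max - par$r_min))
  # K = 1, delta = 0, eta = 0, matched genotype: collapses to one Student-t
  par0 <- emission_params(K = 1L, sigma = array(diag(c(0.02, 0.002)),
                                                c(2, 2, 1, 3)), eta = 0)
  pr <- list(lrr = -0.3, baf = 0.45, gc = 0, normal_genotype = "BB")
  pair <- st$pairs[[12]][4, ]  # BB/BB in 2n somatic LOH
  ref <- student_t_logpdf(c(pr$lrr, pr$baf),
                          c(lrr_mean(pair, 0.3, 0, par0),
                            baf_mean(pair, 0.3, 0)),
                          par0$sigma[, , 1, 1], par0$nu)
  expect_equal(emission_logdensity(pr, st[12, ], par0, 0.3, 0), ref)
})

test_that("emission matches the nested-loop oracle on all 21 states", {
  withr::with_seed(7, {
    par <- default_emission_params()
    par$delta <- array(rnorm(18, 0, 0.03), c(2, 3, 3))
    par$weights <- prop.table(matrix(runif(9) + 0.2, 3, 3), 2)
    par$beta0 <- -0.2; par$beta1 <- 0.6; par$eta <- 0.015
    hyper <- default_hyperparams()
    probes <- data.frame(name = paste0("p", 1:5), chrom = "1",
                         pos = sort(sample.int(1e7, 5)),
                         lrr = rnorm(5, 0, 0.8), baf = runif(5),
                         gc = runif(5),
                         normal_genotype = c("AA", "AB", "BB", NA, "AB"))
    for (pi0 in c(0, 0.25)) {
      M <- emission_matrix(probes, par, pi0, hyper$pi_grid)
      for (i in 1:5) for (p in seq_along(hyper$pi_grid)) for (s in 1:21) {
        ref <- oracle_emission(probes[i, ], st[s, ], par, pi0,
                               hyper$pi_grid[p])
        expect_equal(M[i, (p - 1) * 21 + s], ref, tolerance = 1e-10,
                     label = sprintf("probe %d state %d level %d", i, s, p))
      }
    }
  })
})
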
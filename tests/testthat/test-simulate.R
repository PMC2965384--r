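test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_probes = 500L, n_chroms = 2L, pi0_true = 0.3,
                    subclone_prob = 0.2, seed = 42)
  s1 <- simulate_sample(cfg)
  s2 <- simulate_sample(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_sample(sim_config(n_probes = 500L, n_chroms = 2L,
                                   pi0_true = 0.3, subclone_prob = 0.2,
                                   seed = 43))
  expect_false(identical(s1$probes$lrr, s3$probes$lrr))
})

test_that("noiseless pure-tumor hemizygous deletion yields BAF in {0,1}", {
  cfg <- sim_config(n_probes = 800L, n_chroms = 1L, pi0_true = 0,
                    state_weights = c(`2` = 1), noise_scale_lrr = 0,
                    noise_scale_baf = 0, outlier_rate_true = 0,
                    gc_amplitude = 0, seed = 7)
  s <- simulate_sample(cfg)
  expect_true(all(s$probes$baf %in% c(0, 1)))
  expect_equal(unique(round(s$probes$lrr - default_lrr_levels()[["1"]], 8)),
               0)
})

test_that("50% mixture reproduces the four deletion BAF bands", {
  cfg <- sim_config(n_probes = 2000L, n_chroms = 1L, pi0_true = 0.5,
                    state_weights = c(`2` = 1), noise_scale_baf = 0.01,
                    outlier_rate_true = 0, seed = 8)
  s <- simulate_sample(cfg)
  bands <- c(0, 1/3, 2/3, 1)
  grp <- apply(abs(outer(s$probes$baf, bands, "-")), 1, which.min)
  centers <- tapply(s$probes$baf, grp, mean)
  expect_equal(length(centers), 4L)
  expect_true(all(abs(centers - bands) < 0.01))
})

test_that("empirical moments converge to the emission means", {
  cfg <- sim_config(n_probes = 4000L, n_chroms = 2L, pi0_true = 0.25,
                    noise_scale_lrr = 0.02, noise_scale_baf = 0.005,
                    outlier_rate_true = 0, gc_amplitude = 0, seed = 12)
  s <- simulate_sample(cfg)
  st <- build_state_table()
  for (sid in intersect(unique(s$truth$state), c(2, 4, 12))) {
    sel <- s$truth$state == sid & s$truth$z_n == 1
    pairs <- st$pairs[[sid]]
    for (zt in unique(s$truth$z_t[sel])) {
      ss <- sel & s$truth$z_t == zt
      if (sum(ss) < 30) next
      pair <- pairs[pairs$z_n == 1 & pairs$z_t == zt, ][1, ]
      expect_equal(mean(s$probes$baf[ss]), baf_mean(pair, 0.25, 0),
                   tolerance = 0.01)
      expect_equal(mean(s$probes$lrr[ss]),
                   lrr_mean(pair, 0.25, 0, default_emission_params()),
                   tolerance = 0.01)
    }
  }
})

test_that("dilution series shares one truth and attenuates aberrations", {
  base <- sim_config(n_probes = 3000L, n_chroms = 3L, seed = 19,
                     noise_scale_lrr = 0.05)
  sams <- dilution_series(base, fractions = c(0, 0.25, 0.5))
  expect_length(sams, 3L)
  expect_identical(sams[[1]]$truth$state, sams[[2]]$truth$state)
  expect_identical(sams[[1]]$truth$z_t, sams[[3]]$truth$z_t)
  expect_equal(sams[[2]]$truth$pi0[1], 0.25)
  # deletion LRR magnitude strictly decreases with normal fraction
  del <- sams[[1]]$truth$state == 2
  mags <- sapply(sams, function(s) abs(mean(s$probes$lrr[del] -
                                              0.5 * s$probes$gc[del])))
  expect_true(all(diff(mags) < 0))
  # full dilution: mean structure indistinguishable from a normal genome
  s100 <- dilution_series(base, fractions = 1)[[1]]
  expect_lt(abs(mean(s100$probes$lrr[del] - 0.5 * s100$probes$gc[del])),
            0.02)
  het <- s100$truth$z_n == 1
  expect_lt(abs(mean(s100$probes$baf[het]) - 0.5), 0.01)
})

test_that("mass and cell fraction conventions convert correctly", {
  expect_equal(mass_to_cell_fraction(0.5, 2), 0.5)     # diploid: identical
  expect_equal(mass_to_cell_fraction(0.5, 3), 3 / 5)   # triploid tumor
  expect_equal(mass_to_cell_fraction(c(0, 1), 3), c(0, 1))
  sams <- dilution_series(sim_config(n_probes = 200L, n_chroms = 1L,
                                     seed = 3),
                          fractions = 0.5, convention = "mass")
  expect_equal(sams[[1]]$truth$pi0[1],
               mass_to_cell_fraction(0.5, mean(sams[[1]]$truth$x_t)))
})

test_that("subclonal segments carry heterogeneity levels from the grid", {
  cfg <- sim_config(n_probes = 2000L, n_chroms = 4L, subclone_prob = 0.5,
                    seed = 23)
  s <- simulate_sample(cfg)
  expect_true(all(s$truth$pi_i %in% c(0, 0.2, 0.4, 0.6)))
  expect_true(any(s$truth$pi_i > 0))
  expect_true(all(s$truth$pi_i[s$truth$state == 3] == 0))
})

test_that("confusable sample is deterministic and dominated by gain", {
  cs1 <- make_confusable_sample(sim_config(n_probes = 500L, seed = 77))
  cs2 <- make_confusable_sample(sim_config(n_probes = 500L, seed = 77))
  expect_identical(cs1, cs2)
  expect_gt(mean(cs1$truth$state == 4), 0.5)
  expect_equal(cs1$truth$pi0[1], 0.3)
})
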
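mk_probes <- function(chrom, pos) {
  data.frame(name = paste0("p", seq_along(pos)), chrom = chrom, pos = pos,
             lrr = 0, baf = 0.5)
}

test_that("segments are maximal constant-state runs split at chromosomes", {
  pr <- mk_probes(rep("1", 6), c(10, 20, 30, 40, 50, 60))
  seg <- segments_from_path(pr, c(3, 3, 2, 2, 2, 3))
  expect_equal(nrow(seg), 3L)
  expect_equal(seg$n_probes, c(2L, 3L, 1L))
  expect_equal(seg$state_id, c(3L, 2L, 3L))
  expect_equal(seg$start_pos, c(10, 30, 60))
  expect_equal(seg$end_pos, c(20, 50, 60))
  expect_equal(seg$copy_number, c(2L, 1L, 2L))

  one <- segments_from_path(mk_probes(rep("1", 4), 1:4), rep(5, 4))
  expect_equal(nrow(one), 1L)

  # identical state across a chromosome boundary still splits
  pr2 <- mk_probes(c("1", "1", "2", "2"), c(10, 20, 10, 20))
  seg2 <- segments_from_path(pr2, rep(4, 4))
  expect_equal(nrow(seg2), 2L)
  expect_equal(seg2$chrom, c("1", "2"))

  expect_error(segments_from_path(pr, c(1, 2)), "path length")
})

test_that("segment probe counts partition each chromosome", {
  withr::with_seed(31, {
    pr <- random_probes(200, seed = 31, n_chroms = 4)
    path <- sample(c(2, 3, 4, 12), 200, TRUE)
    seg <- segments_from_path(pr, path)
    per_chrom <- tapply(seg$n_probes, seg$chrom, sum)
    expect_equal(sort(as.integer(per_chrom)),
                 sort(as.integer(table(pr$chrom))))
  })
})

test_that("log Bayes factor: zero at even odds, additive, thresholdable", {
  pr <- mk_probes(rep("1", 10), 1:10)
  post <- matrix(0, 10, 21)
  post[, 2] <- 0.5; post[, 3] <- 0.5
  seg <- segments_from_path(pr, rep(2L, 10))
  expect_equal(segment_log_bayes_factor(seg[1, ], post), 0)

  # per-probe odds e^1 over 10 probes -> log BF 10
  post2 <- matrix(0, 10, 21)
  p2 <- exp(1) / (1 + exp(1))
  post2[, 2] <- p2; post2[, 3] <- 1 - p2
  expect_equal(segment_log_bayes_factor(seg[1, ], post2), 10)

  # normal-state segments score 0 by definition
  segN <- segments_from_path(pr, rep(3L, 10))
  expect_equal(segment_log_bayes_factor(segN[1, ], post2), 0)

  # additivity under splits
  path <- c(rep(4L, 6), rep(4L, 4))
  segW <- segments_from_path(pr, path)
  post3 <- matrix(runif(210, 0.01, 1), 10, 21)
  post3 <- post3 / rowSums(post3)
  whole <- segment_log_bayes_factor(segW[1, ], post3)
  segA <- segments_from_path(pr[1:6, ], rep(4L, 6))
  segB <- segments_from_path(pr[7:10, ], rep(4L, 4))
  segB$first_probe <- segB$first_probe + 6L
  segB$last_probe <- segB$last_probe + 6L
  expect_equal(segment_log_bayes_factor(segA[1, ], post3) +
                 segment_log_bayes_factor(segB[1, ], post3), whole)

  # the filter keeps a segment iff log BF >= 30
  expect_true(segment_log_bayes_factor(segW[1, ], post2) >= 30 ||
                nrow(segW) > 0)  # 10 probes at e^1 odds: log BF = 10 < 30
  expect_lt(segment_log_bayes_factor(segW[1, ], post2), 30)
})

test_that("chromosome number sums rounded per-chromosome mean copies", {
  chroms <- c(as.character(1:22), "X")
  pr <- mk_probes(rep(chroms, each = 10), rep(seq(1e6, 1e7, 1e6), 23))
  expect_equal(estimate_chromosome_number(pr, rep(2, 230)), 46L)
  cn3 <- ifelse(pr$chrom == "X", 2, 3)
  expect_equal(estimate_chromosome_number(pr, cn3), 68L)
  # invariance to probe density that preserves per-chromosome means
  pr2 <- mk_probes(c(rep("1", 100), rep("2", 10)),
                   c(seq_len(100) * 1e5, seq_len(10) * 1e6))
  cn <- c(rep(3, 100), rep(1, 10))
  pr3 <- mk_probes(c(rep("1", 10), rep("2", 100)),
                   c(seq_len(10) * 1e6, seq_len(100) * 1e5))
  cn_b <- c(rep(3, 10), rep(1, 100))
  expect_equal(estimate_chromosome_number(pr2, cn),
               estimate_chromosome_number(pr3, cn_b))
  expect_warning(estimate_chromosome_number(pr, rep(2, 230),
                                            chroms = c(chroms, "Y")),
                 "no probes")
})

test_that("summary_report aggregates a fit faithfully", {
  cfg <- sim_config(n_probes = 1200L, n_chroms = 3L, pi0_true = 0,
                    seed = 17)
  s <- simulate_sample(cfg)
  fit <- em_fit(probe_cols(s), n_iters = 6L)
  sm <- summary_report(fit)
  expect_s3_class(sm, "cna_summary")
  expect_equal(sum(sm$state_fractions), 1)
  expect_equal(sm$pi0, fit$pi0)
  expect_true(sm$average_ploidy > 1 && sm$average_ploidy < 3)
  expect_true(all(sm$segments$n_probes >= 1))
  # aberrant segments counted only above the filter
  expect_equal(sm$n_aberrant_segments,
               sum(sm$segments$state_id != 3 & sm$segments$log_bf >= 30))
})
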
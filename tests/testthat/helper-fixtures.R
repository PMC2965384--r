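# Shared fixtures.  Heavy fits used by several acceptance criteria are
# computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

probe_cols <- function(sample) {
  sample$probes[, c("name", "chrom", "pos", "lrr", "baf", "gc")]
}

# small sorted probe frame with random data (not model-generated)
random_probes <- function(n, seed = 1, n_chroms = 2) {
  withr::with_seed(seed, {
    chrom <- sort(rep_len(as.character(seq_len(n_chroms)), n))
    data.frame(name = paste0("p", seq_len(n)), chrom = chrom,
               pos = as.numeric(unlist(tapply(
                 sample.int(5e7, n, replace = TRUE), chrom, sort))),
               lrr = rnorm(n, 0, 0.4), baf = runif(n),
               gc = runif(n, 0.3, 0.7))
  })
}

# full 4-restart fit on a 20k dilution sample; key by (pi0, seed)
dilution_fit <- function(pi0_true, seed) {
  cached(sprintf("dil_%s_%s", pi0_true, seed), {
    s <- dilution_series(sim_config(pi0_true = 0, seed = seed),
                         fractions = pi0_true)[[1]]
    fit <- fit_with_restarts(probe_cols(s))
    list(sample = s, fit = fit)
  })
}

triploid_sample <- function(seed = 5) {
  cached(sprintf("tri_samples_%s", seed), {
    dilution_series(sim_config(preset = "triploid", seed = seed),
                    fractions = c(0, 0.5))
  })
}

triploid_pure_fit <- function(seed = 5) {
  cached(sprintf("tri_pure_%s", seed), {
    s <- triploid_sample(seed)[[1]]
    list(sample = s, fit = fit_with_restarts(probe_cols(s)))
  })
}

triploid_mix_fit <- function(variant, seed = 5) {
  cached(sprintf("tri_mix_%s_%s", variant, seed), {
    s <- triploid_sample(seed)[[2]]
    list(sample = s, fit = fit_with_restarts(probe_cols(s),
                                             variant = variant))
  })
}
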
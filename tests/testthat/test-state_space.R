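test_that("parse_genotype_string counts alleles and rejects junk", {
  expect_equal(parse_genotype_string("-")[c("b_count", "copies")],
               list(b_count = 0L, copies = 0L))
  expect_equal(parse_genotype_string("AAB")$b_count, 1L)
  expect_equal(parse_genotype_string("AAB")$copies, 3L)
  expect_equal(parse_genotype_string("BBBB")$b_count, 4L)
  expect_error(parse_genotype_string("AXB"), "invalid genotype")
  expect_error(parse_genotype_string(""), "invalid genotype")
})

test_that("state table has 21 states matching the reference tumor-state table", {
  st <- build_state_table()
  expect_equal(nrow(st), 21L)
  expect_equal(st$state, 1:21)
  expect_setequal(unique(st$copy_number), 0:6)

  p2 <- st$pairs[[2]]
  expect_equal(st$copy_number[2], 1L)
  expect_equal(st$description[2], "Hemizygous deletion")
  expect_setequal(paste0(p2$tumor, "/", p2$normal),
                  c("A/AA", "A/AB", "B/AB", "B/BB"))

  p17 <- st$pairs[[17]]
  expect_equal(st$copy_number[17], 2L)
  expect_equal(st$description[17], "2n germline LOH")
  expect_setequal(paste0(p17$tumor, "/", p17$normal), c("AA/AA", "BB/BB"))

  # normalized rows: "Normal" carries diploid tumor genotypes; germline-LOH
  # copy numbers follow the genotype strings
  expect_setequal(st$pairs[[3]]$tumor, c("AA", "AB", "BB"))
  expect_equal(st$copy_number[18:21], 3:6)

  # every pair's tumor genotype length equals the state's copy number and
  # the constitutional genotype is diploid
  for (s in 1:21) {
    p <- st$pairs[[s]]
    expect_true(all(p$x_t == st$copy_number[s]), label = paste("state", s))
    expect_true(all(p$x_n == 2L))
  }
})

test_that("pair sets are closed under the allele-swap map", {
  st <- build_state_table()
  for (s in 1:21) {
    p <- st$pairs[[s]]
    key <- paste(p$z_n, p$z_t)
    swapped <- paste(p$x_n - p$z_n, p$x_t - p$z_t)
    expect_setequal(key, swapped)
  }
})

test_that("build_state_table is deterministic and idempotent", {
  expect_identical(build_state_table(), build_state_table())
})

test_that("LOH flags follow the heterozygosity-loss predicate", {
  expect_true(is_loh(12))
  expect_false(is_loh(4))
  expect_false(is_loh(6))
  expect_equal(which(is_loh(1:21)), c(1:2, 12:21))
  expect_equal(loh_class(c(1, 2)), rep("copy-loss-loh", 2))
  expect_equal(loh_class(12:21), rep("loh", 10))
  expect_equal(loh_class(c(3, 4, 6)), rep("none", 3))
})

test_that("state table exports to TSV with one row per state", {
  path <- withr::local_tempfile(fileext = ".tsv")
  export_state_table(path = path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 21L)
  expect_equal(tab$state, 1:21)
  expect_match(tab$genotype_pairs[17], "AA/AA,BB/BB")
})
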
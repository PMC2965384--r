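#' Parse an allele string into a genotype
#'
#' Genotypes are written as strings over the alphabet \{A, B\} ("AAB" is two
#' A alleles and one B allele); the null genotype of a homozygous deletion is
#' written "-".
#'
#' @param text Allele string such as `"AAB"`, `"BB"` or `"-"`.
#' @return A list with elements `b_count` (number of B alleles) and `copies`
#'   (total allele copies); class `"genotype"`.
#' @examples
#' parse_genotype_string("AAB")  # b_count 1, copies 3
#' parse_genotype_string("-")    # the null genotype (0, 0)
#' @export
parse_genotype_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (text == "-") {
    g <- list(b_count = 0L, copies = 0L)
  } else {
    chars <- strsplit(text, "")[[1]]
    if (length(chars) == 0L || !all(chars %in% c("A", "B")))
      stop("invalid genotype string: ", text)
    g <- list(b_count = sum(chars == "B"), copies = length(chars))
  }
  class(g) <- "genotype"
  g
}

genotype_to_string <- function(b_count, copies) {
  if (copies == 0L) return("-")
  paste0(strrep("A", copies - b_count), strrep("B", b_count))
}

# Raw tumor-state definitions: tumor genotype listed first, constitutional
# (normal) genotype second.  Typographical inconsistencies of circulating
# tabulations are normalized here (see the methods vignette): the "Normal" state
# uses 2-copy tumor genotypes matching its copy-number column; 6n states
# with truncated 5-allele strings are completed to 6 alleles; "germline LOH"
# states take their copy number from the genotype string length.
state_defs <- function() {
  list(
    list(1L, 0L, "Homozygous deletion",
         c("-/AA", "-/AB", "-/BB")),
    list(2L, 1L, "Hemizygous deletion",
         c("A/AA", "A/AB", "B/AB", "B/BB")),
    list(3L, 2L, "Normal",
         c("AA/AA", "AB/AB", "BB/BB")),
    list(4L, 3L, "Single copy duplication",
         c("AAA/AA", "AAB/AB", "ABB/AB", "BBB/BB")),
    list(5L, 4L, "4n monoallelic amplification",
         c("AAAA/AA", "AAAB/AB", "ABBB/AB", "BBBB/BB")),
    list(6L, 4L, "4n balanced amplification",
         c("AAAA/AA", "AABB/AB", "BBBB/BB")),
    list(7L, 5L, "5n monoallelic amplification",
         c("AAAAA/AA", "AAAAB/AB", "ABBBB/AB", "BBBBB/BB")),
    list(8L, 5L, "5n unbalanced amplification",
         c("AAAAA/AA", "AAABB/AB", "AABBB/AB", "BBBBB/BB")),
    list(9L, 6L, "6n unbalanced amplification",
         c("AAAAAA/AA", "AAAAAB/AB", "ABBBBB/AB", "BBBBBB/BB")),
    list(10L, 6L, "6n unbalanced amplification",
         c("AAAAAA/AA", "AAAABB/AB", "AABBBB/AB", "BBBBBB/BB")),
    list(11L, 6L, "6n balanced amplification",
         c("AAAAAA/AA", "AAABBB/AB", "BBBBBB/BB")),
    list(12L, 2L, "2n somatic LOH",
         c("AA/AA", "AA/AB", "BB/AB", "BB/BB")),
    list(13L, 3L, "3n somatic LOH",
         c("AAA/AA", "AAA/AB", "BBB/AB", "BBB/BB")),
    list(14L, 4L, "4n somatic LOH",
         c("AAAA/AA", "AAAA/AB", "BBBB/AB", "BBBB/BB")),
    list(15L, 5L, "5n somatic LOH",
         c("AAAAA/AA", "AAAAA/AB", "BBBBB/AB", "BBBBB/BB")),
    list(16L, 6L, "6n somatic LOH",
         c("AAAAAA/AA", "AAAAAA/AB", "BBBBBB/AB", "BBBBBB/BB")),
    list(17L, 2L, "2n germline LOH", c("AA/AA", "BB/BB")),
    list(18L, 3L, "3n germline LOH", c("AAA/AA", "BBB/BB")),
    list(19L, 4L, "4n germline LOH", c("AAAA/AA", "BBBB/BB")),
    list(20L, 5L, "5n germline LOH", c("AAAAA/AA", "BBBBB/BB")),
    list(21L, 6L, "6n germline LOH", c("AAAAAA/AA", "BBBBBB/BB"))
  )
}

#' Build the 21-state tumor genotype table
#'
#' Each tumor state is a tumor copy number together with the set of allowable
#' (tumor, normal) genotype pairs; constitutional genotypes are diploid
#' AA/AB/BB.  States 1-11 are copy-number alterations, 12-16 somatic LOH at
#' increasing copy number, and 17-21 germline-like LOH (the heterozygous
#' constitutional genotype is absent).
#'
#' @return A data frame of class `"state_table"` with one row per state:
#'   `state`, `copy_number`, `description`, and a list-column `pairs`; each
#'   element of `pairs` is a data frame with columns `tumor`, `normal`
#'   (strings), `z_t`, `x_t`, `z_n`, `x_n` (B-allele counts and copy
#'   numbers).
#' @examples
#' st <- build_state_table()
#' nrow(st)             # 21
#' st$pairs[[2]]$tumor  # "A" "A" "B" "B"
#' @export
build_state_table <- function() {
  defs <- state_defs()
  pairs <- lapply(defs, function(d) {
    parts <- strsplit(d[[4]], "/", fixed = TRUE)
    tum <- vapply(parts, `[`, "", 1L)
    nor <- vapply(parts, `[`, "", 2L)
    gt <- lapply(tum, parse_genotype_string)
    gn <- lapply(nor, parse_genotype_string)
    data.frame(
      tumor = tum, normal = nor,
      z_t = vapply(gt, `[[`, 0L, "b_count"),
      x_t = vapply(gt, `[[`, 0L, "copies"),
      z_n = vapply(gn, `[[`, 0L, "b_count"),
      x_n = vapply(gn, `[[`, 0L, "copies")
    )
  })
  st <- data.frame(
    state = vapply(defs, `[[`, 0L, 1L),
    copy_number = vapply(defs, `[[`, 0L, 2L),
    description = vapply(defs, `[[`, "", 3L)
  )
  st$pairs <- pairs
  class(st) <- c("state_table", class(st))
  st
}

#' Loss-of-heterozygosity flags for tumor states
#'
#' A state is LOH when every allowable pair with a heterozygous
#' constitutional genotype has a homozygous or null tumor genotype, or when
#' the heterozygous constitutional genotype is disallowed altogether
#' (germline-LOH states).  Deletion states 1-2 satisfy the predicate through
#' allele loss; [loh_class()] separates these as `"copy-loss-loh"` so
#' copy-neutral and copy-loss LOH can be reported in different columns.
#'
#' @param state Integer state id(s) in 1..21, or a `state_table` row subset.
#' @param state_table A table from [build_state_table()].
#' @return `is_loh`: logical vector; `loh_class`: character vector with
#'   values `"none"`, `"loh"` or `"copy-loss-loh"`.
#' @examples
#' is_loh(12)  # TRUE  (2n somatic LOH)
#' is_loh(4)   # FALSE (single copy duplication)
#' @export
is_loh <- function(state, state_table = build_state_table()) {
  if (is.data.frame(state)) state <- state$state
  vapply(as.integer(state), function(s) {
    p <- state_table$pairs[[match(s, state_table$state)]]
    het <- p$z_n == 1L
    if (!any(het)) return(TRUE)  # heterozygous normal genotype disallowed
    all(p$z_t[het] == 0L | p$z_t[het] == p$x_t[het])
  }, NA)
}

#' @rdname is_loh
#' @export
loh_class <- function(state, state_table = build_state_table()) {
  if (is.data.frame(state)) state <- state$state
  state <- as.integer(state)
  out <- rep("none", length(state))
  out[state %in% 12:21] <- "loh"
  out[state %in% 1:2] <- "copy-loss-loh"
  out
}

#' Export the state table as TSV
#'
#' Writes one row per state with columns `state`, `tumor_copy_number`,
#' `genotype_pairs` (comma-separated `tumor/normal` strings) and
#' `description`.
#'
#' @param state_table A table from [build_state_table()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_state_table <- function(state_table = build_state_table(), path) {
  out <- data.frame(
    state = state_table$state,
    tumor_copy_number = state_table$copy_number,
    genotype_pairs = vapply(state_table$pairs, function(p)
      paste(paste0(p$tumor, "/", p$normal), collapse = ","), ""),
    description = state_table$description
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
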
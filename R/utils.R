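#' @useDynLib cnahmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dgamma rbinom rexp rt runif setNames rmultinom
#' @importFrom utils read.delim write.table modifyList
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# karyotype ordering of chromosome labels: 1..22, X, Y, MT, then others
chrom_order <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[toupper(x) == "M"] <- "MT"
  num <- suppressWarnings(as.integer(x))
  rank <- ifelse(!is.na(num), num,
                 ifelse(toupper(x) == "X", 23L,
                        ifelse(toupper(x) == "Y", 24L,
                               ifelse(toupper(x) == "MT", 25L, 26L))))
  order(rank, x)
}

normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[toupper(x) == "M"] <- "MT"
  toupper(x)
}
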
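#' @useDynLib polyamp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rlnorm rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

RANKS <- c("superkingdom", "phylum", "class", "order", "family", "genus",
           "species", "strain")

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Reverse complement of a DNA string
#'
#' IUPAC-aware: degenerate codes map to the complement of their base set
#' (e.g. R -> Y). Case is preserved as upper case.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# 32-bit FNV-1a hash of a string, folded into [0, 2^31). Used to derive a
# per-read RNG seed from (seed, read_id) so classification does not depend on
# processing order. Arithmetic kept exact in doubles by splitting the 32-bit
# multiply into 16-bit halves.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
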
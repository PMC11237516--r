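# Shared fixtures and independent oracles, built in code.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

rnd_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                               collapse = "")

# Global (full-primer vs full-substring) edit distance with IUPAC matching,
# straightforward full-matrix DP. Independent of the package's aligner.
oracle_edit_row <- function(primer, text) {
  p <- strsplit(primer, "")[[1]]; s <- strsplit(text, "")[[1]]
  np <- length(p); ns <- length(s)
  D <- matrix(0L, np + 1L, ns + 1L)
  D[, 1] <- 0:np
  D[1, ] <- 0:ns
  for (i in seq_len(np)) {
    pset <- IUPAC_SETS[[p[i]]]
    for (j in seq_len(ns)) {
      cost <- if (s[j] %in% pset) 0L else 1L
      D[i + 1L, j + 1L] <- min(D[i, j] + cost, D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  D[np + 1L, ]  # distances of primer vs text[1..j] for all j
}

# Brute force over all (start, end) spans: for each start, one global DP over
# the suffix gives distances to every end. Tie-break: min distance, then min
# start, then min end.
oracle_match_primer <- function(read, primer, max_err) {
  n <- nchar(read)
  best <- NULL
  for (s in 0:n) {
    row <- oracle_edit_row(primer, substring(read, s + 1L, n))
    for (e in s:n) {
      d <- row[e - s + 1L]
      if (d > max_err) next
      if (is.null(best) || d < best[1] ||
          (d == best[1] && (s < best[2] || (s == best[2] && e < best[3]))))
        best <- c(d, s, e)
    }
  }
  best
}

# Tiny 3-taxon toy database with hand-enumerable k-mers (k = 4).
toy_db <- function() {
  lin <- lineage_table(
    c("T1", "T2", "T3"),
    superkingdom = rep("Bacteria", 3),
    phylum = c("P1", "P1", "P2"), class = c("C1", "C1", "C2"),
    order = c("O1", "O1", "O2"), family = c("F1", "F1", "F2"),
    genus = c("G1", "G1", "G2"),
    species = c("G1 s1", "G1 s2", "G2 s3"))
  # chosen so the three k-mer sets stay disjoint even with the reverse
  # complements indexed (T1's rc occupies the G/T runs)
  seqs <- list(T1 = "AAAACCCC", T2 = "ACGTACGT", T3 = "ACACACAC")
  list(lineages = lin, sequences = seqs)
}

write_fastq_plain <- function(path, ids, seqs, quals_chr) {
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", quals_chr))
  writeLines(lines, path)
  path
}

q_string <- function(q, len) strrep(intToUtf8(q + 33L), len)

# internal k-mer indexer of the installed package (0-based codes)
.polyamp_kmers <- function(s, k) polyamp:::.distinct_kmers(s, k)
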
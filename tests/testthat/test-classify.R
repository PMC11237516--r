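test_that("k-mer presence sets and smoothed conditionals match hand arithmetic", {
  lin <- lineage_table("solo", species = "s")
  m <- build_kmer_model(lin, list(solo = "ACGTACGTACGT"), k = 8, seed = 1)
  # 12-mer has 5 8-mer windows, of which the first and last coincide, so 4
  # distinct words; with the reverse complement indexed too the presence set
  # is the union of both strands' windows
  fwd <- .polyamp_kmers("ACGTACGTACGT", 8)
  rc <- .polyamp_kmers(revcomp("ACGTACGTACGT"), 8)
  expect_equal(length(fwd), 4L)
  # present words: P(w|t) = (1 + 0.75)/2 = 0.875; absent: 0.25/2 = 0.125
  expect_equal(sum(m$logp[1, ] > log(0.5)), length(union(fwd, rc)))

  # 3-taxon toy: P(w) = (n(w)+0.5)/(N+1), P(w|t) = (m(w)+P(w))/(M+1)
  db <- toy_db()
  m3 <- build_kmer_model(db$lineages, db$sequences, k = 4, seed = 1)
  w <- .polyamp_kmers("AAAA", 4) + 1L   # present only in T1
  expect_equal(exp(m3$logp[, w]),
               c((1 + 1.5 / 4) / 2, (0 + 1.5 / 4) / 2, (0 + 1.5 / 4) / 2),
               tolerance = 1e-12)
  # a word in no taxon: P(w) = 0.5/4, conditional (0 + 0.125)/2 for all taxa
  w0 <- .polyamp_kmers("AGAG", 4) + 1L
  expect_equal(exp(m3$logp[, w0]), rep(0.125 / 2, 3), tolerance = 1e-12)
  # two taxa sharing all k-mers get identical conditionals
  lin2 <- lineage_table(c("X1", "X2"), species = c("x1", "x2"))
  m2 <- build_kmer_model(lin2, list(X1 = "AAAACCCC", X2 = "AAAACCCC"), k = 4)
  expect_equal(m2$logp[1, ], m2$logp[2, ])
  expect_error(build_kmer_model(lin2[0, ], list()), "empty")
})

test_that("self-classification on disjoint taxa reaches species confidence 1", {
  db <- toy_db()
  m <- build_kmer_model(db$lineages, db$sequences, k = 4, seed = 5)
  for (tid in names(db$sequences)) {
    a <- classify_read(m, db$sequences[[tid]], read_id = tid)
    expect_equal(a$best_taxon, tid)
    expect_equal(unname(a$confidence["species"]), 1.0)
    expect_equal(a$assigned_rank, "species")
    expect_false(a$tied)
  }
})

test_that("reads with only unseen k-mers tie at the smoothing floor", {
  db <- toy_db()
  m <- build_kmer_model(db$lineages, db$sequences, k = 4, seed = 5)
  # AGAGAG... k-mers AGAG/GAGA absent from all three references & their rcs
  a <- classify_read(m, "AGAGAGAG", read_id = "degenerate")
  expect_true(a$tied)
  expect_true(all(abs(a$score - a$score[1]) < 1e-9))
  expect_error_free <- TRUE
  # too-short read is unassigned with a reason
  b <- classify_read(m, "ACG", read_id = "short")
  expect_equal(b$best_taxon, "unassigned")
  expect_equal(b$assigned_rank, "none")
})

test_that("bootstrap confidence matches exhaustive enumeration on tiny reads", {
  # two taxa, k=4; a read with V distinct k-mers, draw size ceil(V/8)=1:
  # the bootstrap winner distribution is exactly the per-k-mer winner
  # frequency, so species confidence -> (#k-mers favouring winner)/V
  lin <- lineage_table(c("A", "B"), genus = c("gA", "gB"),
                       species = c("a", "b"))
  m <- build_kmer_model(lin, list(A = "AAAAACCCCC", B = "ACGTACGTAC"),
                        k = 4, n_bootstrap = 4000, min_conf = 0.8, seed = 2)
  read <- "AAAAACGTAC"  # mixes A-words and B-words
  km <- .polyamp_kmers(read, 4)
  per_kmer_winner <- apply(m$logp[, km + 1L, drop = FALSE], 2, which.max)
  a <- classify_read(m, read, read_id = "mix")
  winner_row <- match(a$best_taxon, m$lineages$tax_id)
  p_exact <- mean(per_kmer_winner == winner_row)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(unname(a$confidence["species"]) - p_exact), 3 * se + 1e-9)
})

test_that("classification is deterministic given seed and order-independent", {
  db <- toy_db()
  m <- build_kmer_model(db$lineages, db$sequences, k = 4, seed = 5)
  r <- "AAAACCCCGGGG"
  a1 <- classify_read(m, r, read_id = "r1")
  a2 <- classify_read(m, r, read_id = "r1")
  expect_identical(a1$confidence, a2$confidence)
  # a different read in between must not change r1's result
  invisible(classify_read(m, "GGGGTTTT", read_id = "other"))
  a3 <- classify_read(m, r, read_id = "r1")
  expect_identical(a1$confidence, a3$confidence)
  # different seed changes the bootstrap stream
  a4 <- classify_read(m, r, read_id = "r1", seed = 99)
  expect_false(identical(a1$confidence, a4$confidence) &&
                 !all(a1$confidence %in% c(0, 1)))
})

test_that("bootstrap confidences are monotone non-increasing with depth", {
  set.seed(31)
  db <- make_reference_db(6, 4, seed = 13)
  m <- build_kmer_model(db$bacteria$lineages, db$bacteria$sequences, seed = 3)
  for (i in 1:12) {
    tid <- sample(names(db$bacteria$sequences), 1)
    ref <- db$bacteria$sequences[[tid]]
    frag <- substr(ref, 1, 80)
    noisy <- paste0(frag, rnd_dna(40))
    a <- classify_read(m, noisy, read_id = paste0("n", i))
    expect_true(all(diff(a$confidence) <= 1e-12))
  }
})

test_that("profiles conserve reads and roll ranks up correctly", {
  db <- toy_db()
  m <- build_kmer_model(db$lineages, db$sequences, k = 4, seed = 5)
  mk_assign <- function(id, row, rank) {
    list(read_id = id, best_taxon = m$lineages$tax_id[row], best_row = row,
         assigned_rank = rank)
  }
  # T1 and T2 share genus G1; one read only genus-confident
  asg <- list(mk_assign("r1", 1, "species"), mk_assign("r2", 2, "species"),
              mk_assign("r3", 1, "genus"),
              list(read_id = "r4", best_taxon = "unassigned",
                   best_row = NA_integer_, assigned_rank = "none"))
  p <- profile_sample(asg, m, sample_id = "s")
  expect_equal(sum(p$taxon_counts) + p$n_unassigned +
                 sum(p$rank_counts$species["unclassified-below-genus"]),
               4)
  expect_equal(unname(p$rank_counts$genus[["G1"]]), 3)
  expect_equal(unname(p$rank_counts$species[["unclassified-below-genus"]]), 1)
  expect_equal(sum(p$taxon_counts), 2)
  # rank-sum conservation on random assignment lists
  set.seed(8)
  ranks <- c(RANKS[1:7], "none")
  for (rep in 1:5) {
    n <- 30
    asg <- lapply(seq_len(n), function(i) {
      rk <- sample(ranks, 1)
      row <- sample(1:3, 1)
      if (rk == "none")
        list(read_id = paste0("r", i), best_taxon = "unassigned",
             best_row = NA_integer_, assigned_rank = "none")
      else mk_assign(paste0("r", i), row, rk)
    })
    p <- profile_sample(asg, m)
    depth <- vapply(asg, function(a)
      if (a$assigned_rank == "none") 0L else match(a$assigned_rank, RANKS), 0L)
    for (r in 1:7) {
      named <- p$rank_counts[[RANKS[r]]]
      real <- named[!startsWith(names(named), "unclassified-below-")]
      expect_equal(sum(real), sum(depth >= r))
    }
    expect_lte(sum(p$taxon_counts), sum(depth >= 7))
    expect_equal(p$n_unassigned, sum(depth == 0))
  }
})

test_that("external Emu-dialect profiles load, renormalise and round-trip", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "tax_id\tabundance\tspecies\tgenus\testimated_counts",
    "7\t0.6\tsp one\tgen1\t60",
    "9\t0.4\tsp two\tgen2\t40"), tf)
  p <- load_external_profile(tf, "fungi", sample_id = "S9")
  expect_equal(unname(p$rel), c(0.6, 0.4))
  expect_equal(unname(p$taxon_counts), c(60, 40))
  expect_equal(p$lineages$species, c("sp one", "sp two"))
  # abundances off by rounding are renormalised with a warning
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("tax_id\tabundance\tspecies", "7\t0.58\ts1", "9\t0.40\ts2"), tf2)
  expect_warning(p2 <- load_external_profile(tf2, "bacteria"), "renormalising")
  expect_equal(sum(p2$rel), 1)
  tf3 <- tempfile(fileext = ".tsv")
  writeLines(c("tax_id\tspecies", "7\ts1"), tf3)
  expect_error(load_external_profile(tf3, "fungi"), "abundance")
  # round-trip through the abundance-table writer
  out <- tempfile(fileext = ".tsv")
  write_abundance_table(list(p), out)
  back <- read_abundance_table(out)[[1]]
  expect_equal(back$taxon_counts[order(names(back$taxon_counts))],
               p$taxon_counts[order(names(p$taxon_counts))])
})
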
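bact_pc_profile <- function() {
  lin <- lineage_table(c("t1", "t2"),
                       species = c("Escherichia coli", "Mycobacterium smegmatis"),
                       genus = c("Escherichia", "Mycobacterium"))
  abundance_profile("PC", "bacteria", c(t1 = 34718, t2 = 10423), lin)
}

fungal_pc_profile <- function(with_genus_reads = TRUE) {
  ids <- c("f1", "f2", "f3", "f4")
  lin <- lineage_table(ids,
    species = c("Trichophyton interdigitale", "Rhizopus arrhizus",
                "Trichophyton sp.", "Rhizopus sp."),
    genus = c("Trichophyton", "Rhizopus", "Trichophyton", "Rhizopus"),
    kingdom = "fungi")
  counts <- c(f1 = 6145, f2 = 3327, f3 = 546, f4 = 59)
  if (!with_genus_reads) { counts <- counts[1:2]; lin <- lin[1:2, ] }
  abundance_profile("PC", "fungi", counts, lin)
}

test_that("two-strain control ratios reproduce the defined-mock arithmetic", {
  cc <- control_conformity(bact_pc_profile(),
                           c("Mycobacterium smegmatis" = 1,
                             "Escherichia coli" = 4))
  expect_equal(cc$ratio_species_str, "1:3.33")
  expect_equal(cc$ratio_species, 34718 / 10423, tolerance = 1e-12)
  expect_equal(cc$expected_str, "1:4")

  cf <- control_conformity(fungal_pc_profile(),
                           c("Trichophyton interdigitale" = 2.7,
                             "Rhizopus arrhizus" = 1))
  expect_equal(cf$ratio_species_str, "1.85:1")
  expect_equal(cf$ratio_rollup_str, "1.98:1")
  expect_equal(cf$ratio_rollup, (6145 + 546) / (3327 + 59), tolerance = 1e-12)
  # explicit roll-up mapping gives the same result as the genus heuristic
  cf2 <- control_conformity(fungal_pc_profile(),
                            c("Trichophyton interdigitale" = 2.7,
                              "Rhizopus arrhizus" = 1),
                            rollup_names = c("Trichophyton sp." = "Trichophyton interdigitale",
                                             "Rhizopus sp." = "Rhizopus arrhizus"))
  expect_equal(cf2$ratio_rollup_str, "1.98:1")
  expect_error(control_conformity(bact_pc_profile(),
                                  c(a = 1, b = 2, c = 3)), "two")
})

test_that("ratio orientation is consistent under swapping the two taxa", {
  p <- bact_pc_profile()
  a <- control_conformity(p, c("Mycobacterium smegmatis" = 1,
                               "Escherichia coli" = 4))
  b <- control_conformity(p, c("Escherichia coli" = 4,
                               "Mycobacterium smegmatis" = 1))
  expect_equal(a$ratio_species, b$ratio_species)
  expect_equal(a$ratio_species_str, "1:3.33")
  expect_equal(b$ratio_species_str, "3.33:1")
})

test_that("resource calculator reproduces the ensembling fractions", {
  r <- resource_calculator(A = 2, N = 12)
  expect_equal(r$ensembling_pct, 50)
  expect_equal(r$ensembling_fraction, 0.5)
  expect_equal(r$negative_control_pct, 17)
  expect_equal(r$negative_control_fraction, 2 / 12, tolerance = 1e-12)
  expect_equal(unname(r$spike_pct["ITS"]), 25)
  expect_equal(unname(r$spike_pct["16S"]), 75)
  # raw spike fractions sum to one before rounding
  expect_equal(sum(r$spike_fraction), 1)
  r2 <- resource_calculator(A = 3, N = 5, molar_amounts = c(a = 1, b = 1, c = 2))
  expect_equal(r2$ensembling_pct, 33)
  expect_equal(sum(r2$spike_fraction), 1)
})

test_that("top-taxa tables rank by cumulative reads with stable tie order", {
  lin <- lineage_table(c("a", "b", "c"), species = c("sa", "sb", "sc"),
                       genus = c("g", "g", "g"))
  p1 <- abundance_profile("s1", "bacteria", c(a = 60, b = 30, c = 10), lin)
  t1 <- top_taxa_table(list(p1), top_n = 2)
  expect_equal(rownames(t1$table), c("a", "b"))
  expect_equal(unname(t1$table[, "s1"]), c(0.6, 0.3))
  # tie on cumulative reads -> alphabetical
  p2 <- abundance_profile("s2", "bacteria", c(c = 50, b = 50), lin)
  t2 <- top_taxa_table(list(p2), top_n = 2)
  expect_equal(rownames(t2$table), c("b", "c"))
  # proportions are counts/total and sample order does not matter
  set.seed(21)
  profs <- lapply(1:4, function(i) {
    cts <- setNames(sample(0:40, 3), c("a", "b", "c"))
    cts <- cts[cts > 0]
    abundance_profile(paste0("s", i), "bacteria", cts, lin,
                      n_reads = sum(cts) + 5)
  })
  ta <- top_taxa_table(profs, top_n = 3)
  tb <- top_taxa_table(rev(profs), top_n = 3)
  expect_equal(ta$table, tb$table)
  expect_true(all(colSums(ta$table) <= 1 + 1e-9))
  for (i in seq_along(profs)) {
    p <- profs[[i]]
    for (t in names(p$taxon_counts))
      expect_equal(ta$table[t, p$sample_id],
                   unname(p$taxon_counts[t] / sum(p$taxon_counts)))
  }
  # the >= 0.01% lineage export excludes rare taxa
  p3 <- abundance_profile("s9", "bacteria", c(a = 99999, b = 1), lin)
  t3 <- top_taxa_table(list(p3), top_n = 2, min_prop = 1e-4)
  expect_true("a" %in% t3$lineage_export$tax_id)
  expect_false("b" %in% t3$lineage_export$tax_id)
})

test_that("contamination screen flags only taxa dominant in samples", {
  lin <- lineage_table(paste0("t", 1:5), species = paste0("sp", 1:5),
                       genus = rep("g", 5))
  nc <- abundance_profile("NC", "fungi",
                          c(t1 = 8, t2 = 3, t3 = 2, t4 = 1, t5 = 1), lin)
  # sample: t1 dominant (50%), t2 rare (0.5%)
  samp <- abundance_profile("S1", "fungi",
                            c(t1 = 500, t2 = 5, t9 = 495),
                            lineage_table(c("t1", "t2", "t9"),
                                          species = c("sp1", "sp2", "sp9"),
                                          genus = rep("g", 3)))
  scr <- contamination_screen(list(nc), list(samp), dominance_threshold = 0.01)
  expect_equal(sum(scr$overlap$flagged), 1L)
  expect_equal(scr$overlap$taxon[scr$overlap$flagged], "t1")
  expect_equal(unname(scr$total_nc_reads["fungi"]), 15)
  # NC with zero reads of a kingdom -> empty overlap, total 0
  nc0 <- abundance_profile("NC", "bacteria",
                           setNames(numeric(0), character(0)), lin[0, ],
                           n_reads = 0)
  scr0 <- contamination_screen(list(nc0), list(samp))
  expect_equal(nrow(scr0$overlap), 0L)
  expect_equal(unname(scr0$total_nc_reads["bacteria"]), 0)
  expect_error(contamination_screen(list(), list(samp)), "negative-control")
})
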
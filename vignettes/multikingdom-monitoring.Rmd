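---
title: "Multi-kingdom amplicon runs: segregation, classification and real-time saturation monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kingdom amplicon runs: segregation, classification and real-time saturation monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyamp)
```

## The problem

Pooling full-length 16S rRNA gene amplicons (bacteria, ~1.5 kb, primers
27F/1492R) and full-length ITS amplicons (fungi, ~0.6 kb, nested ITS1/ITS4)
into a single barcoded nanopore library halves library and flow-cell cost per
kingdom, but creates two dry-lab problems that this package addresses:

1. every read must be attributed to its kingdom and cleaned before any
   taxonomy is possible, because both marker types share one barcode; and
2. the sparse fungal fraction (a deliberate minority spike, 25% molar) risks
   being under-sequenced, so the run should be monitored live and stopped
   only when species discovery has saturated for both kingdoms in most
   samples -- and as soon as it has, to preserve the flow cell.

`polyamp` implements the full dry-lab loop: streaming FASTQ batch ingestion,
degenerate-primer kingdom segregation with QC filters, fast per-read k-mer
naive-Bayes classification, windowed rarefaction/Chao1 saturation tracking
with a run-stop rule, UNITE-style ITS database construction, and control,
abundance and resource reporting. A synthetic run generator with complete
ground truth makes the whole loop testable offline.

## Kingdom segregation

Each primer is aligned semi-globally (primer fully consumed, read end-points
free) inside a window at each read end, under unit-cost edit distance where an
IUPAC code matches any base of its set at no cost. Defaults:

* error budget `max_err_frac = 0.2` of the primer length (the same tolerance a
  standard demultiplexing/trimming tool uses by default; four edits on a 20-mer);
* search window 100 bases beyond the primer length at each end -- amplicon
  reads begin and end with primers, and restricting the search prevents
  spurious internal hits;
* a primer set "supports" a read if at least one of its four oriented
  primers hits; a unique supporter decides the kingdom, two supporters are
  resolved by hit count then total edit distance, and residual ties are
  reported as `conflict` rather than guessed.

Filters then run in a fixed order on the primer-trimmed insert: length bounds
200--3,500 nt, 3' tail truncation to 1,550 nt (the tail distal to the forward
primer, after orienting the read forward-primer-first), then a mean-quality
gate at arithmetic mean phred 20. The order matters: the length thresholds
describe insert biology, so they are applied after primer removal, and the
quality mean is computed on the bases actually retained. Exactly one of
{retained, too_short, too_long, low_quality} holds per verdicted read, and
segregation is orientation-invariant (a reverse-complemented read yields the
same verdict with a mirrored trim span, and the same canonical output read).

```{r segregation}
ps <- default_primer_sets()
insert <- paste(sample(c("A","C","G","T"), 400, replace = TRUE), collapse = "")
amplicon <- paste0(chartr("RYM", "ATA", ps$`16S`$forward), insert,
                   revcomp(ps$`16S`$reverse))
rd <- new_read("demo", amplicon, rep(30L, nchar(amplicon)))
call <- assign_kingdom(rd, ps)
call$verdict
trim_and_filter(rd, call)$read
```

## Per-read classification

Real-time monitoring needs speed more than finesse, so reads are classified
with the classic word-model naive Bayes on distinct 8-mers
(presence/absence, not counts). With `n(w)` of `N` taxa containing word `w`
and `M` reference sequences for a taxon:

* word prior `P(w) = (n(w) + 0.5) / (N + 1)`,
* taxon conditional `P(w | t) = (m(w) + P(w)) / (M + 1)`, `m(w)` in {0, 1},
* `score(t) = sum over the read's distinct words of log P(w | t)`.

Reverse-complement k-mers of every reference are indexed too, so occasional
orientation errors degrade scores gracefully instead of catastrophically.
Confidence comes from 100 bootstrap draws of one eighth of the read's
distinct words: the confidence at a rank is the fraction of draws whose
winner agrees with the full-data winner on the entire lineage prefix down to
that rank, which makes the confidence vector non-increasing with depth by
construction. The assignment is truncated at the deepest rank with
confidence at least 0.8 (k = 8, 100 bootstraps and the 0.8 cutoff are the
established defaults of this classifier family). Ties in the argmax go to
the lexicographically smallest taxon identifier and are flagged.

One deliberate design choice: the bootstrap RNG for a read is seeded from the
global seed and a 32-bit hash of the read identifier, not from the global RNG
stream. Classification of a read is therefore a pure function of (model,
read, seed), independent of processing order -- which is what makes online
(streamed) and offline (one-pass) monitoring bit-identical, and crashed-and-
restarted watchers exactly reproducible.

The high-accuracy end-of-run abundance re-estimation used for final
reporting is a different algorithm owned by a different tool; `polyamp`
consumes its output table via `load_external_profile()` and deliberately does
not reimplement it.

## Saturation monitoring and the stop rule

Per barcode and kingdom, species counts accumulate over arrival windows (one
window = one batch file; the emulated run writes 4,000 reads per file).
After each window the package records observed richness `S_obs` and the
bias-corrected Chao1 asymptote

```
S_hat = S_obs + f1 (f1 - 1) / (2 (f2 + 1))
```

with `f1` singletons and `f2` doubletons (the `f2 + 1` correction avoids the
division by zero of the classical form). Rarefaction curves use the analytic
hypergeometric expectation

```
E[S(m)] = S_obs - sum_i C(n - n_i, m) / C(n, m)
```

evaluated in log space (`lchoose`) for stability, and extrapolation beyond
the observed `n` follows the standard sample-size-based form anchored on
Chao1, `S(n + m*) = S_obs + f0 (1 - (1 - f1/(n f0 + f1))^{m*})`.

A barcode/kingdom is *saturated* when, over the last `W = 3` windows, at most
1 new species appeared **and** the Chao1 asymptote grew by at most 1%; below
500 cumulative reads it is `insufficient_reads`, otherwise `gaining`. The
run-level recommendation is to stop once at least half of the eligible
(subject) barcodes are saturated in **both** kingdoms -- the stricter of the
two possible readings, chosen because the minority fungal fraction is exactly
the signal the ensemble design risks losing. The window count (three
consecutive scans), and the requirement of a majority of samples, follow the
published monitoring practice for such runs; the numeric epsilons (1 species,
1%, 500 reads) are this package's defaults, all configurable and all logged.
Hill orders beyond richness (q = 0) are out of scope: the decision is about
species discovery, not evenness.

The decision is monotone-absorbing in practice: with a frozen community,
accumulating further windows cannot un-saturate a barcode (richness gains
stay zero and Chao1 declines toward `S_obs` as singletons fill in).

## The watcher

`watch_run()` polls a MinKNOW-style directory (`fastq_pass/barcodeNN/*.fastq.gz`;
a flat layout is supported). A file is processed once its size is unchanged
across two polls -- basecaller write behaviour is not standardized, so size
stability plus a persisted ledger of processed-file digests is the portable
contract. The ledger makes restarts safe (no batch is ever double-counted)
and the per-read seeding makes the streamed result bit-identical to
`process_run_offline()` on the same files. Unreadable files are logged,
skipped and retried on the next poll; the watcher itself never crashes on
them. Polling (not filesystem events) is the portable default contract.

## Database construction

`dereplicate_lineages()` reduces a UNITE-style taxonomy-annotated FASTA to
unique lineages, where lineage identity is the exact 7-rank tuple after
prefix stripping and underscore normalization -- no fuzzy synonym merging.
Placeholder names (`unidentified`, `*_sp`, `Incertae sedis`) are preserved
verbatim but flagged, since downstream reports legitimately show
uncertain-genus fractions. Taxon identifiers are assigned in sorted lineage
order, so they are a pure function of the lineage set (permutation-invariant
and idempotent). Up to 10 representative sequences per lineage (longest
first) feed the classifier; a k-mer presence model does not benefit from
more, and the cap bounds model memory. The exporter writes the consuming
tool's dialect bit-exactly (`taxonomy.tsv` with the species-first column
order, `species_taxid.fasta` with `tax_id:serial` headers); only the fungal
side is built here because a current stock bacterial database already exists
for the consuming tool.

## The synthetic run generator

`make_reference_db()` and `simulate_run()` emulate the study conditions the
rest of the package is tested under:

* two length regimes (bacterial ~1,450 nt, fungal ~550 nt, each +-10%
  uniform jitter) reproducing the bimodal read-length profile of a mixed
  run qualitatively -- not an empirical length distribution;
* references rejection-sampled until all pairwise 8-mer Jaccard similarities
  are below 0.5, so taxa are k-mer separable by construction;
* per-read error model: substitution/insertion/deletion rates summing to
  0.05 (~95% median read accuracy), with per-base qualities drawn around
  phred 24 for correct and phred 7 for erroneous bases so the mean-quality
  filter is meaningful (no signal-level artefacts are modelled);
* a 96-well plate layout (93 subjects, one two-strain bacterial positive
  control at 1:4 molar parts, a fungal two-strain control at 2.7:1, negative
  controls and a pooled-negative barcode), ITS molar fraction 0.25 (the 3:1
  ensemble mix), batch files of 4,000 reads;
* negative-control depth is not something the emulated study reports; it is
  set to 1% of subject depth as a realistic trace level;
* everything is bit-reproducible under a seed, and a manifest records each
  read's true taxon, kingdom and orientation.

What passing tests on this generator do **not** show: robustness to chimeras
and barcode hopping (removed upstream in the emulated workflow and not
simulated), PCR and copy-number bias, realistic homopolymer error structure,
or classification difficulty from closely related real taxa -- synthetic
references are far better separated than congeneric ITS sequences. The
end-to-end recovery results are therefore a correctness check of the
pipeline's plumbing and statistics, not a benchmark of classifier accuracy
on real communities.

## Numerical and edge-case choices

* Rarefaction pre-condition `1 <= m <= n` is enforced; beyond `n`,
  `extrapolate()` must be used. `E[S(m)]` is exact (log-space binomials), not
  simulated.
* `chao1` returns `S_obs` when there are no singletons; extrapolation is then
  flat by construction.
* Ratio formatting in control reports rounds half-up at 2 decimals and
  orients the ratio the way the expected parts were given (`1:x` when the
  minor strain is listed first), so swapping the strains inverts the string
  exactly.
* Genus roll-up in conformity reports adds reads from taxa sharing the
  expected strain's genus (e.g. a `Trichophyton sp.` bucket), or an explicit
  name mapping when provided.
* The contamination screen flags a negative-control taxon only when it is
  also dominant (>= 1% relative abundance) in at least one sample; trace
  overlap is listed but not flagged.
* Empty accumulation windows advance the window counter and repeat the last
  richness values, so wall-clock-quiet periods cannot fake saturation gains.
* Reads from the `unclassified` barcode are counted in run totals but join no
  per-sample statistic.
* `k` is limited to 4--12 and the dense model to `4^k x taxa` doubles; the
  default k = 8 keeps the model at ~0.5 MB per taxon per strand.

## Problem sizes used in the shipped checks

The package's own validation uses desk-scale runs chosen to exercise every
code path: a 12-barcode x 10,000-read end-to-end recovery (50 bacterial + 20
fungal taxa, 5% error) in the test suite, and a 6-barcode x 3,000-read run of
the same shape in the reproduction script, alongside exact worked-example
arithmetic (control ratios, resource fractions) and oracle comparisons
(Monte-Carlo rarefaction, brute-force primer alignment). Cohort-scale
results (millions of reads, hundreds of real species) are intentionally out
of scope for automated checks.

## Known limitations

* The fast classifier is a monitoring instrument; final abundance calls
  should come from a dedicated re-estimation tool whose output the reporting
  stage ingests directly.
* No signal-space (squiggle) handling, no basecalling, no sequencer API
  interaction -- the package consumes demultiplexed FASTQ only.
* Quality encoding is assumed phred+33 and is not auto-detected.
* Saturation monitoring tracks richness only; coverage-based stopping
  criteria are not offered.
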
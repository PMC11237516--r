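#' Lineage table constructor
#'
#' An 8-rank taxonomy path (superkingdom..species, plus an optional strain
#' slot) with a stable taxon identifier.
#'
#' @param tax_id character identifiers, unique.
#' @param ... named character vectors for the ranks `superkingdom`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species`, `strain` (missing ranks
#'   default to empty strings).
#' @param kingdom `"bacteria"` or `"fungi"` (recycled).
#' @param uncertain logical flag per record for placeholder lineages.
#' @return data frame with class `polyamp_lineages`.
#' @export
lineage_table <- function(tax_id, ..., kingdom = "bacteria", uncertain = FALSE) {
  args <- list(...)
  n <- length(tax_id)
  if (anyDuplicated(tax_id)) stop("tax_id values must be unique")
  df <- data.frame(tax_id = as.character(tax_id), stringsAsFactors = FALSE)
  for (r in RANKS) df[[r]] <- if (!is.null(args[[r]])) as.character(args[[r]]) else rep("", n)
  df$kingdom <- rep_len(kingdom, n)
  df$uncertain <- rep_len(uncertain, n)
  class(df) <- c("polyamp_lineages", "data.frame")
  df
}

#' Build a k-mer naive-Bayes classifier model
#'
#' RDP-style word model on distinct k-mers (presence/absence). The prior for
#' word w over N taxa with n(w) of them containing w is
#' `P(w) = (n(w) + 0.5) / (N + 1)`; the taxon conditional with m(w) in {0,1}
#' indicating presence among that taxon's references and M its reference count
#' is `P(w | taxon) = (m(w) + P(w)) / (M + 1)`. Reverse-complement k-mers of
#' every reference are indexed too, so reads in either orientation score
#' against the correct taxon.
#'
#' @param lineages a [lineage_table()] (one row per taxon).
#' @param sequences list (parallel to `lineages`, or named by `tax_id`) of
#'   character vectors of reference sequences per taxon.
#' @param k k-mer size (4--12).
#' @param n_bootstrap bootstrap draws per read.
#' @param min_conf confidence cutoff for the assigned rank.
#' @param seed base RNG seed mixed into per-read bootstrap seeds.
#' @return a `polyamp_model`.
#' @export
build_kmer_model <- function(lineages, sequences, k = 8L, n_bootstrap = 100L,
                             min_conf = 0.8, seed = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 4L, k <= 12L)
  n_taxa <- nrow(lineages)
  if (n_taxa == 0L || length(sequences) == 0L) stop("empty reference database")
  if (!is.null(names(sequences))) sequences <- sequences[lineages$tax_id]
  if (length(sequences) != n_taxa)
    stop("sequences must parallel the lineage table")
  nw_len <- 4^k
  if (nw_len * n_taxa > 2^31)
    stop("k too large for a dense model with this many taxa")
  # order taxa by tax_id so argmax ties resolve to the smallest tax_id
  ord <- order(lineages$tax_id, method = "radix")
  lineages <- lineages[ord, , drop = FALSE]
  sequences <- sequences[ord]
  # taxa in rows: a word's taxon vector is a contiguous column (fast gather)
  pres <- matrix(0, nrow = n_taxa, ncol = nw_len)
  m_refs <- integer(n_taxa)
  for (t in seq_len(n_taxa)) {
    refs <- sequences[[t]]
    if (length(refs) == 0L) stop("taxon without reference sequences: ",
                                 lineages$tax_id[t])
    refs <- toupper(refs)
    refs <- gsub("N", "", refs, fixed = TRUE)
    km <- unique(unlist(lapply(c(refs, revcomp(refs)),
                               function(s) .distinct_kmers(s, k))))
    pres[t, km + 1L] <- 1
    m_refs[t] <- length(refs)
  }
  nw <- colSums(pres)
  prior <- (nw + 0.5) / (n_taxa + 1)
  logp <- log(sweep(pres, 2, prior, `+`)) - log(m_refs + 1)
  structure(list(k = k, lineages = lineages, logp = logp, prior = prior,
                 n_bootstrap = as.integer(n_bootstrap), min_conf = min_conf,
                 seed = as.integer(seed)),
            class = "polyamp_model")
}

#' @export
print.polyamp_model <- function(x, ...) {
  cat(sprintf("<k-mer naive-Bayes model> k=%d, %d taxa, %d bootstraps, min_conf %.2f\n",
              x$k, nrow(x$lineages), x$n_bootstrap, x$min_conf))
  invisible(x)
}

#' Classify one read against a k-mer model
#'
#' Score(taxon) is the sum of `log P(w | taxon)` over the read's distinct
#' k-mers; the winner is the maximum (ties to the lexicographically smallest
#' `tax_id`, flagged). Confidence is bootstrapped: `n_bootstrap` draws of
#' `ceil(V / 8)` of the V distinct k-mers with replacement; the confidence at
#' a rank is the fraction of draws whose winner matches the best taxon's
#' lineage on all ranks down to that rank (hence non-increasing with depth).
#' The assignment is truncated at the deepest rank with confidence at least
#' `min_conf`.
#'
#' @param model a [build_kmer_model()] result.
#' @param bases read sequence (or a [new_read()]).
#' @param read_id identifier used to derive the per-read bootstrap seed; taken
#'   from the read when `bases` is a `polyamp_read`.
#' @param seed overrides the model's base seed when given.
#' @return a `polyamp_assignment`: `read_id`, `best_taxon` (tax_id or
#'   `"unassigned"`), `confidence` (named numeric over the 7 ranks),
#'   `assigned_rank` (rank name or `"none"`), `tied`.
#' @export
classify_read <- function(model, bases, read_id = "read", seed = NULL) {
  if (inherits(bases, "polyamp_read")) {
    read_id <- bases$read_id
    bases <- bases$bases
  }
  seed <- seed %||% model$seed
  km <- .distinct_kmers(toupper(bases), model$k)
  if (length(km) == 0L) {
    return(structure(list(read_id = read_id, best_taxon = "unassigned",
                          confidence = setNames(rep(NA_real_, 7L), RANKS[1:7]),
                          assigned_rank = "none", tied = FALSE,
                          reason = "shorter than k"),
                     class = "polyamp_assignment"))
  }
  # per-read deterministic seed: order-independent classification
  rseed <- (seed + fnv1a32(read_id)) %% 2147483647
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(rseed)
  res <- .nb_classify(model$logp, km, model$n_bootstrap)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  lin <- model$lineages
  best <- res$best
  conf <- rank_confidences(lin, best, res$winners)
  ranks_ok <- which(conf >= model$min_conf)
  assigned_rank <- if (length(ranks_ok)) RANKS[max(ranks_ok)] else "none"
  best_taxon <- if (assigned_rank == "none") "unassigned" else lin$tax_id[best]
  structure(list(read_id = read_id, best_taxon = best_taxon,
                 best_row = best,
                 confidence = conf, assigned_rank = assigned_rank,
                 tied = res$tied, score = res$score),
            class = "polyamp_assignment")
}

# fraction of bootstrap winners agreeing with taxon `best` on the full lineage
# prefix down to each of the 7 ranks; prefix agreement makes the vector
# non-increasing by construction
rank_confidences <- function(lin, best, winners) {
  conf <- numeric(7L)
  agree <- rep(TRUE, length(winners))
  for (r in seq_len(7L)) {
    agree <- agree & (lin[[RANKS[r]]][winners] == lin[[RANKS[r]]][best])
    conf[r] <- mean(agree)
  }
  setNames(conf, RANKS[1:7])
}

#' Classify a set of reads
#'
#' @param model a [build_kmer_model()].
#' @param reads list of `polyamp_read` / `polyamp_processed` objects or a
#'   character vector of sequences.
#' @param seed optional base seed override.
#' @return list of `polyamp_assignment`s.
#' @export
classify_reads <- function(model, reads, seed = NULL) {
  lapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    if (inherits(r, "polyamp_processed")) r <- r$read
    if (is.character(r)) {
      nm <- names(reads)[i] %||% paste0("read", i)
      classify_read(model, r, read_id = nm, seed = seed)
    } else classify_read(model, r, seed = seed)
  })
}

#' Abundance profile constructor
#'
#' Per-sample, per-kingdom taxon counts with rank-wise roll-ups.
#'
#' @param sample_id sample label.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param taxon_counts named numeric: reads per species-resolved tax_id.
#' @param lineages lineage rows for the taxa present.
#' @param n_reads total input reads (assigned + unassigned).
#' @param rank_counts optional list of named count vectors per rank.
#' @param n_unassigned reads with no assignment at all.
#' @return a `polyamp_profile`.
#' @export
abundance_profile <- function(sample_id, kingdom, taxon_counts, lineages,
                              n_reads = sum(taxon_counts),
                              rank_counts = NULL, n_unassigned = NULL) {
  structure(list(sample_id = sample_id, kingdom = kingdom,
                 taxon_counts = taxon_counts, lineages = lineages,
                 n_reads = n_reads, rank_counts = rank_counts,
                 n_unassigned = n_unassigned %||% (n_reads - sum(taxon_counts))),
            class = "polyamp_profile")
}

#' @export
print.polyamp_profile <- function(x, ...) {
  cat(sprintf("<abundance profile> %s / %s: %d taxa, %g of %g reads species-resolved\n",
              x$sample_id, x$kingdom, length(x$taxon_counts),
              sum(x$taxon_counts), x$n_reads))
  invisible(x)
}

#' Relative abundances of a profile
#' @param profile a `polyamp_profile`.
#' @param denominator `"assigned"` (species-resolved reads) or `"all"` (all
#'   input reads).
#' @return named numeric vector.
#' @export
rel_abundance <- function(profile, denominator = c("assigned", "all")) {
  denominator <- match.arg(denominator)
  total <- if (denominator == "assigned") sum(profile$taxon_counts) else profile$n_reads
  if (total == 0) return(profile$taxon_counts * 0)
  profile$taxon_counts / total
}

#' Aggregate read assignments into an abundance profile
#'
#' Counts are aggregated at every rank using each read's assigned rank: a read
#' confident only to genus counts toward genus and all shallower ranks, and
#' toward `"unclassified-below-genus"` at species rank. Reads with no rank at
#' `min_conf` are counted as unassigned.
#'
#' @param assignments list of [classify_read()] results.
#' @param model the model used (for lineages).
#' @param sample_id,kingdom profile labels.
#' @return a `polyamp_profile` with `rank_counts` filled.
#' @export
profile_sample <- function(assignments, model, sample_id = "sample",
                           kingdom = NULL) {
  lin <- model$lineages
  kingdom <- kingdom %||% (if (nrow(lin)) lin$kingdom[1] else "bacteria")
  n <- length(assignments)
  best <- vapply(assignments, `[[`, character(1), "best_taxon")
  arank <- vapply(assignments, `[[`, character(1), "assigned_rank")
  assigned <- best != "unassigned" & arank != "none"
  d <- match(arank, RANKS)           # NA for "none"
  row <- rep(NA_integer_, n)
  if (any(assigned))
    row[assigned] <- as.integer(
      vapply(assignments[assigned], function(a) as.numeric(a$best_row),
             numeric(1)))
  rank_counts <- setNames(vector("list", 7L), RANKS[1:7])
  for (r in seq_len(7L)) {
    rn <- RANKS[r]
    nm <- character(0)
    if (any(assigned)) {
      deep <- assigned & d >= r
      shallow <- assigned & d < r
      nm <- c(
        {v <- lin[[rn]][row[deep]]; v[is.na(v) | !nzchar(v)] <- "(blank)"; v},
        paste0("unclassified-below-", RANKS[d[shallow]])
      )
    }
    tb <- table(nm)
    rank_counts[[rn]] <- setNames(as.numeric(tb), names(tb))
  }
  sp <- assigned & d >= 7L
  tb <- table(lin$tax_id[row[sp]])
  taxon_counts <- setNames(as.numeric(tb), names(tb))
  used <- lin[lin$tax_id %in% names(taxon_counts), , drop = FALSE]
  abundance_profile(sample_id, kingdom, taxon_counts, used,
                    n_reads = n, rank_counts = rank_counts,
                    n_unassigned = sum(!assigned))
}

#' Load an externally produced abundance table (Emu dialect)
#'
#' Expects a tab-separated table with a `tax_id` column, an `abundance`
#' column, and rank columns (at least `species`). Abundances are renormalised
#' to sum to one over the assigned taxa (with a warning when they deviate by
#' more than 1e-6); read counts are reconstructed from an
#' `estimated counts` / `estimated_counts` column when present.
#'
#' @param tsv path to the table.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param sample_id label for the resulting profile.
#' @return a `polyamp_profile`.
#' @export
load_external_profile <- function(tsv, kingdom, sample_id = "sample") {
  df <- read.delim(tsv, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- sub("^estimated counts$", "estimated_counts", names(df))
  missing_cols <- setdiff(c("tax_id", "abundance"), names(df))
  if (length(missing_cols))
    stop("external profile missing column(s): ",
         paste(missing_cols, collapse = ", "))
  ab <- as.numeric(df$abundance)
  s <- sum(ab)
  if (s <= 0) stop("external profile has non-positive total abundance")
  if (abs(s - 1) > 1e-6) {
    warning(sprintf("abundances sum to %.6f; renormalising to 1", s))
  }
  ab <- ab / s
  counts <- if ("estimated_counts" %in% names(df)) as.numeric(df$estimated_counts) else ab
  lin <- lineage_table(as.character(df$tax_id), kingdom = kingdom)
  for (r in RANKS[1:7]) if (r %in% names(df)) lin[[r]] <- as.character(df[[r]])
  tc <- setNames(counts, as.character(df$tax_id))
  p <- abundance_profile(sample_id, kingdom, tc, lin, n_reads = sum(counts))
  p$rel <- setNames(ab, as.character(df$tax_id))
  p
}
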
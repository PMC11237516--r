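#' Top-taxa relative-abundance table
#'
#' Taxa are ranked by cumulative reads across samples; per-sample relative
#' proportions (both over species-resolved reads and over all reads) are
#' reported for the top `top_n`. Taxa below `min_prop` cumulative relative
#' proportion are excluded from the lineage export used as cladogram input.
#' Cumulative-read ties order alphabetically.
#'
#' @param profiles list of `polyamp_profile`s (one kingdom).
#' @param rank currently `"species"` (profile taxa) — roll-ups are available
#'   via each profile's `rank_counts`.
#' @param top_n number of taxa to report.
#' @param min_prop minimum cumulative relative proportion for the lineage
#'   export (default 1e-4, i.e. 0.01%).
#' @return list: `table` (data frame taxon x sample proportions),
#'   `cumulative_reads`, `lineage_export` (lineage rows of all taxa at or
#'   above `min_prop`).
#' @export
top_taxa_table <- function(profiles, rank = "species", top_n = 10L,
                           min_prop = 1e-4) {
  stopifnot(top_n >= 1)
  if (inherits(profiles, "polyamp_profile")) profiles <- list(profiles)
  profiles <- profiles[order(vapply(profiles, `[[`, character(1), "sample_id"))]
  all_counts <- lapply(profiles, function(p)
    if (rank == "species" || is.null(p$rank_counts)) p$taxon_counts
    else p$rank_counts[[rank]])
  taxa <- sort(unique(unlist(lapply(all_counts, names))))
  cum <- setNames(numeric(length(taxa)), taxa)
  for (cts in all_counts)
    if (length(cts)) cum[names(cts)] <- cum[names(cts)] + cts
  ord <- order(-cum, names(cum), method = "radix")
  cum <- cum[ord]
  top <- utils::head(names(cum), top_n)
  mat_assigned <- sapply(seq_along(profiles), function(i) {
    cts <- all_counts[[i]]
    tot <- sum(cts)
    vapply(top, function(t)
      if (tot > 0 && t %in% names(cts)) cts[[t]] / tot else 0, numeric(1))
  })
  mat_all <- sapply(seq_along(profiles), function(i) {
    cts <- all_counts[[i]]
    tot <- profiles[[i]]$n_reads
    vapply(top, function(t)
      if (tot > 0 && t %in% names(cts)) cts[[t]] / tot else 0, numeric(1))
  })
  if (is.null(dim(mat_assigned))) {
    mat_assigned <- matrix(mat_assigned, nrow = length(top))
    mat_all <- matrix(mat_all, nrow = length(top))
  }
  sample_ids <- vapply(profiles, `[[`, character(1), "sample_id")
  colnames(mat_assigned) <- colnames(mat_all) <- sample_ids
  rownames(mat_assigned) <- rownames(mat_all) <- top
  total_reads <- sum(cum)
  keep <- names(cum)[cum / max(total_reads, 1) >= min_prop]
  lineage_export <- do.call(rbind, lapply(profiles, function(p) p$lineages))
  if (!is.null(lineage_export)) {
    lineage_export <- lineage_export[!duplicated(lineage_export$tax_id), ,
                                     drop = FALSE]
    lineage_export <- lineage_export[lineage_export$tax_id %in% keep, ,
                                     drop = FALSE]
  }
  list(table = mat_assigned, table_all_reads = mat_all,
       cumulative_reads = cum, lineage_export = lineage_export)
}

# format a positive ratio as "x:1" or "1:x" at 2 decimals (half-up)
format_ratio <- function(major_over_minor, minor_first) {
  v <- round_half_up(major_over_minor, 2)
  if (minor_first) sprintf("1:%.2f", v) else sprintf("%.2f:1", v)
}

#' Positive-control conformity
#'
#' Compares observed read counts for a defined two-strain mock against its
#' expected molar parts. The species-level ratio divides the expected-major
#' strain's count by the expected-minor strain's; the roll-up ratio adds
#' genus-level assignments (e.g. `"Trichophyton sp."` reads for a
#' `Trichophyton` strain) to each side. Ratios are formatted at two decimals,
#' oriented as the expected parts are: `"1:x"` when the minor taxon is listed
#' first, `"x:1"` otherwise.
#'
#' @param profile a `polyamp_profile` for the control barcode; taxa are
#'   matched by species name.
#' @param expected named numeric of exactly two molar parts, e.g.
#'   `c("Mycobacterium smegmatis" = 1, "Escherichia coli" = 4)`.
#' @param rollup_names optional named character mapping extra taxon names
#'   (e.g. `"Trichophyton sp."`) to the expected taxon they roll into; when
#'   `NULL`, taxa sharing the expected strain's genus are rolled up using the
#'   profile lineages.
#' @return a `polyamp_conformity`: observed counts, expected parts, ratios
#'   (numeric) and formatted strings at species level and after roll-up.
#' @export
control_conformity <- function(profile, expected, rollup_names = NULL) {
  if (length(expected) != 2L) stop("expected must name exactly two taxa")
  counts_all <- profile$taxon_counts
  name_of <- function(tid) {
    i <- match(tid, profile$lineages$tax_id)
    if (!is.na(i) && nzchar(profile$lineages$species[i]))
      profile$lineages$species[i] else tid
  }
  by_name <- setNames(as.numeric(counts_all),
                      vapply(names(counts_all) %||% character(0), name_of,
                             character(1)))
  obs <- vapply(names(expected), function(nm)
    sum(by_name[names(by_name) == nm]), numeric(1))
  if (sum(obs) == 0) stop("no reads assigned to either expected control taxon")
  major <- which.max(expected)
  minor <- which.min(expected)
  minor_first <- (which(names(expected) == names(expected)[minor]) == 1L)
  ratio_species <- obs[major] / max(obs[minor], 1)
  # genus roll-up
  rolled <- obs
  genus_of <- function(nm) {
    i <- match(nm, profile$lineages$species)
    if (!is.na(i)) profile$lineages$genus[i] else strsplit(nm, " ")[[1]][1]
  }
  for (j in seq_along(expected)) {
    gj <- genus_of(names(expected)[j])
    extra <- 0
    for (i in seq_along(by_name)) {
      nm <- names(by_name)[i]
      if (nm %in% names(expected)) next
      target <- if (!is.null(rollup_names) && nm %in% names(rollup_names))
        rollup_names[[nm]] else NULL
      if (!is.null(target)) {
        if (target == names(expected)[j]) extra <- extra + by_name[i]
      } else if (identical(genus_of(nm), gj) && nzchar(gj)) {
        extra <- extra + by_name[i]
      }
    }
    rolled[j] <- rolled[j] + extra
  }
  ratio_rollup <- rolled[major] / max(rolled[minor], 1)
  structure(list(
    barcode = profile$sample_id, observed = obs, expected = expected,
    observed_rollup = rolled,
    ratio_species = unname(ratio_species),
    ratio_rollup = unname(ratio_rollup),
    ratio_species_str = format_ratio(ratio_species, minor_first),
    ratio_rollup_str = format_ratio(ratio_rollup, minor_first),
    expected_str = {
      v <- unname(expected)
      if (minor_first) sprintf("1:%g", v[major] / v[minor])
      else sprintf("%g:1", v[major] / v[minor])
    }), class = "polyamp_conformity")
}

#' @export
print.polyamp_conformity <- function(x, ...) {
  cat(sprintf("<control conformity %s> expected %s; species-level %s; with genus roll-up %s\n",
              x$barcode, x$expected_str, x$ratio_species_str, x$ratio_rollup_str))
  invisible(x)
}

#' Negative-control contamination screen
#'
#' Lists every taxon observed in the negative controls with its NC read
#' count, and flags those that are also dominant (relative abundance at least
#' `dominance_threshold` over species-resolved reads) in at least one sample —
#' the overlap that would indicate contamination bleeding into the biological
#' signal.
#'
#' @param nc_profiles list of negative-control `polyamp_profile`s.
#' @param sample_profiles list of subject `polyamp_profile`s.
#' @param dominance_threshold relative-abundance cutoff (default 0.01).
#' @return list: `overlap` (data frame taxon, nc_reads, flagged,
#'   max_sample_abundance), `total_nc_reads` per kingdom.
#' @export
contamination_screen <- function(nc_profiles, sample_profiles,
                                 dominance_threshold = 0.01) {
  if (length(nc_profiles) == 0L) stop("need at least one negative-control profile")
  nc_counts <- list()
  for (p in nc_profiles) {
    for (t in names(p$taxon_counts)) {
      key <- paste(p$kingdom, t, sep = "\r")
      nc_counts[[key]] <- (nc_counts[[key]] %||% 0) + p$taxon_counts[[t]]
    }
  }
  max_ab <- setNames(numeric(length(nc_counts)), names(nc_counts))
  for (p in sample_profiles) {
    ra <- rel_abundance(p, "assigned")
    for (key in names(nc_counts)) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      if (parts[1] == p$kingdom && parts[2] %in% names(ra))
        max_ab[key] <- max(max_ab[key], ra[[parts[2]]])
    }
  }
  overlap <- if (length(nc_counts)) data.frame(
    kingdom = vapply(strsplit(names(nc_counts), "\r", fixed = TRUE), `[`, "", 1L),
    taxon = vapply(strsplit(names(nc_counts), "\r", fixed = TRUE), `[`, "", 2L),
    nc_reads = as.numeric(unlist(nc_counts)),
    max_sample_abundance = unname(max_ab),
    flagged = unname(max_ab >= dominance_threshold),
    stringsAsFactors = FALSE
  ) else data.frame(kingdom = character(0), taxon = character(0),
                    nc_reads = numeric(0), max_sample_abundance = numeric(0),
                    flagged = logical(0))
  total_nc <- tapply(
    vapply(nc_profiles, function(p) sum(p$taxon_counts), numeric(1)),
    vapply(nc_profiles, `[[`, character(1), "kingdom"), sum)
  list(overlap = overlap, total_nc_reads = total_nc)
}

#' Resource-effectiveness calculator
#'
#' Quantifies the savings of ensembling `A` amplicon types into one library
#' and pooling negative controls: the per-amplicon resource fraction is
#' `1/A`, the negative-control fraction with `N` controls pooled into two
#' sequenced libraries is `2/N`, and each amplicon's spike percentage is its
#' molar amount over the pool total. Display percentages are rounded to the
#' nearest integer; raw fractions are kept unrounded.
#'
#' @param A number of amplicon types ensembled.
#' @param N number of negative controls maintained.
#' @param input_scale multi-kingdom input DNA relative to a single-amplicon
#'   library (carried through unrounded).
#' @param molar_amounts named numeric, fmol per amplicon type.
#' @return a `polyamp_resources` list with raw fractions and display
#'   percentages.
#' @export
resource_calculator <- function(A, N, input_scale = NULL,
                                molar_amounts = c(`16S` = 100, ITS = 33.3)) {
  stopifnot(A >= 1, N >= 1, all(molar_amounts > 0))
  spike_frac <- molar_amounts / sum(molar_amounts)
  structure(list(
    A = A, N = N,
    ensembling_fraction = 1 / A,
    ensembling_pct = round_half_up(100 / A, 0),
    negative_control_fraction = 2 / N,
    negative_control_pct = round_half_up(200 / N, 0),
    input_scale = input_scale,
    spike_fraction = spike_frac,
    spike_pct = round_half_up(100 * spike_frac, 0)
  ), class = "polyamp_resources")
}

#' @export
print.polyamp_resources <- function(x, ...) {
  cat(sprintf("<resource effectiveness> ensembling 1/A = %d%%; negative controls 2/N = %d%%\n",
              x$ensembling_pct, x$negative_control_pct))
  cat("  spike:", paste(sprintf("%s %d%%", names(x$spike_pct), x$spike_pct),
                        collapse = ", "), "\n")
  invisible(x)
}
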
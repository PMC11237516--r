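#' Parse a UNITE-style taxonomy header
#'
#' Headers carry a rank-prefixed lineage segment
#' `k__...;p__...;c__...;o__...;f__...;g__...;s__...`; the accession is the
#' first `|`- or whitespace-delimited token before it. Prefixes are stripped
#' and underscores become spaces. Placeholder names (`unidentified`,
#' `..._sp`, `Incertae sedis` variants) are kept verbatim but flag the record
#' as uncertain. Kingdom is fungi (the database side built here is the ITS
#' one).
#'
#' @param header FASTA header line (with or without the leading `>`).
#' @return list `(accession, lineage)` where `lineage` is a one-row
#'   [lineage_table()].
#' @export
parse_unite_header <- function(header) {
  h <- sub("^>", "", header)
  if (!grepl("k__", h, fixed = TRUE))
    stop("no rank-prefixed lineage segment in header: ", h)
  toks <- strsplit(h, "[|]")[[1]]
  lin_tok <- toks[grepl("k__", toks)][1]
  accession <- trimws(strsplit(toks[1], "[ \t]")[[1]][1])
  fields <- strsplit(lin_tok, ";", fixed = TRUE)[[1]]
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  vals <- setNames(rep("", 7L), prefixes)
  for (f in fields) {
    f <- trimws(f)
    p <- substr(f, 1, 3)
    if (p %in% prefixes) vals[p] <- substring(f, 4)
  }
  vals <- gsub("_", " ", vals)
  placeholder <- grepl("^unidentified$|\\bsp$|Incertae sedis", vals,
                       ignore.case = TRUE)
  lineage_table(
    tax_id = accession,
    superkingdom = vals[1], phylum = vals[2], class = vals[3],
    order = vals[4], family = vals[5], genus = vals[6], species = vals[7],
    kingdom = "fungi", uncertain = any(placeholder)
  ) -> lin
  list(accession = accession, lineage = lin)
}

# minimal FASTA reader (plain or gzipped); returns list(headers, sequences)
read_fasta_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx)) stop("no FASTA records in ", path)
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    if (hdr_idx[i] + 1L > ends[i]) return("")
    paste(lines[(hdr_idx[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  list(headers = sub("^>", "", lines[hdr_idx]), sequences = toupper(seqs))
}

#' Dereplicate UNITE entries to unique lineages
#'
#' Lineage identity is the exact 7-rank tuple after normalisation; `tax_id`s
#' are assigned deterministically in sorted lineage order (1-based), so the
#' assignment is a pure function of the lineage set. Up to `reps` representative
#' sequences are retained per lineage, longest first.
#'
#' @param fasta path to a UNITE-style FASTA (optionally gzipped), or a list
#'   with `headers` and `sequences`.
#' @param reps maximum representative sequences per lineage.
#' @return a `polyamp_db`: list with `lineages` ([lineage_table()] plus
#'   `tax_id`), `representatives` (named list of sequences per tax_id),
#'   `n_input`, `n_lineages`.
#' @export
dereplicate_lineages <- function(fasta, reps = 10L) {
  fa <- if (is.character(fasta)) read_fasta_lines(fasta) else fasta
  parsed <- lapply(fa$headers, parse_unite_header)
  keys <- vapply(parsed, function(p) {
    l <- p$lineage
    paste(vapply(RANKS[1:7], function(r) l[[r]], character(1)), collapse = ";")
  }, character(1))
  ord_keys <- sort(unique(keys), method = "radix")
  tax_ids <- as.character(seq_along(ord_keys))
  lin_rows <- lapply(seq_along(ord_keys), function(i) {
    j <- match(ord_keys[i], keys)
    l <- parsed[[j]]$lineage
    l$tax_id <- tax_ids[i]
    l
  })
  lineages <- do.call(rbind, lin_rows)
  class(lineages) <- c("polyamp_lineages", "data.frame")
  representatives <- setNames(vector("list", length(ord_keys)), tax_ids)
  for (i in seq_along(ord_keys)) {
    members <- which(keys == ord_keys[i])
    seqs <- fa$sequences[members]
    seqs <- seqs[order(-nchar(seqs), seqs)]  # longest first, ties lexicographic
    representatives[[i]] <- utils::head(seqs, reps)
  }
  structure(list(lineages = lineages, representatives = representatives,
                 n_input = length(keys), n_lineages = length(ord_keys)),
            class = "polyamp_db")
}

#' @export
print.polyamp_db <- function(x, ...) {
  cat(sprintf("<lineage database> %d input sequences -> %d unique lineages\n",
              x$n_input, x$n_lineages))
  invisible(x)
}

#' Export a dereplicated database in the Emu dialect
#'
#' Writes `taxonomy.tsv` (header exactly
#' `tax_id species genus family order class phylum superkingdom`,
#' tab-separated, one row per unique lineage, empty ranks preserved as empty
#' fields) and `species_taxid.fasta` (representatives with headers
#' `tax_id:serial`), plus `build_report.tsv` with input/lineage counts.
#'
#' @param db a [dereplicate_lineages()] result.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
export_emu_db <- function(db, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tax_path <- file.path(out_dir, "taxonomy.tsv")
  cols <- c("tax_id", "species", "genus", "family", "order", "class",
            "phylum", "superkingdom")
  tab <- db$lineages[, cols]
  write.table(tab, tax_path, sep = "\t", quote = FALSE, row.names = FALSE)
  fa_path <- file.path(out_dir, "species_taxid.fasta")
  con <- file(fa_path, "wt")
  for (tid in names(db$representatives)) {
    seqs <- db$representatives[[tid]]
    for (s in seq_along(seqs)) {
      writeLines(c(paste0(">", tid, ":", s), seqs[s]), con)
    }
  }
  close(con)
  rep_path <- file.path(out_dir, "build_report.tsv")
  write.table(
    data.frame(metric = c("input_sequences", "unique_lineages"),
               value = c(db$n_input, db$n_lineages)),
    rep_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(taxonomy = tax_path, fasta = fa_path, report = rep_path))
}

#' Load an exported Emu-dialect database
#'
#' Round-trip reader for [export_emu_db()] output.
#'
#' @param dir directory containing `taxonomy.tsv` and `species_taxid.fasta`.
#' @return a `polyamp_db`.
#' @export
load_emu_db <- function(dir) {
  tax <- read.delim(file.path(dir, "taxonomy.tsv"), sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  fa <- read_fasta_lines(file.path(dir, "species_taxid.fasta"))
  lineages <- lineage_table(
    tax$tax_id,
    superkingdom = tax$superkingdom, phylum = tax$phylum, class = tax$class,
    order = tax$order, family = tax$family, genus = tax$genus,
    species = tax$species, kingdom = "fungi")
  tids <- sub(":.*$", "", fa$headers)
  representatives <- split(fa$sequences, factor(tids, levels = tax$tax_id))
  structure(list(lineages = lineages,
                 representatives = as.list(representatives),
                 n_input = length(fa$sequences),
                 n_lineages = nrow(tax)),
            class = "polyamp_db")
}

#' Build a classifier model from a dereplicated database
#'
#' Convenience bridge: [dereplicate_lineages()] output straight into
#' [build_kmer_model()].
#'
#' @param db a `polyamp_db`.
#' @inheritParams build_kmer_model
#' @return a `polyamp_model`.
#' @export
model_from_db <- function(db, k = 8L, n_bootstrap = 100L, min_conf = 0.8,
                          seed = 1L) {
  build_kmer_model(db$lineages, db$representatives, k = k,
                   n_bootstrap = n_bootstrap, min_conf = min_conf, seed = seed)
}
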
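#' Streaming FASTQ batch reader
#'
#' Reads one or more FASTQ (optionally gzipped) files and yields reads in
#' fixed-size batches, emulating the fixed-size "pass" files a nanopore
#' basecaller writes. Memory use is proportional to `batch_size`: at most one
#' batch of reads is materialised at a time, so arbitrarily large runs can be
#' streamed. Records are validated as 4-line FASTQ with phred+33 qualities.
#'
#' @param paths character vector of FASTQ / FASTQ.gz paths, processed in order.
#' @param batch_size positive integer, reads per batch (the last batch of the
#'   stream may be shorter).
#' @param callback function called as `callback(batch)` for every
#'   [read_batch()]; if it returns `FALSE` streaming stops early.
#' @param barcode barcode label attached to the reads; by default parsed from
#'   each file's parent directory name when it looks like `barcodeNN` or
#'   `unclassified`, else from a `barcode=NN` token in the read header, else
#'   `"unclassified"`.
#' @return invisibly, the total number of reads streamed.
#' @export
read_fastq_batches <- function(paths, batch_size, callback, barcode = NULL) {
  stopifnot(length(paths) >= 1, batch_size >= 1, is.function(callback))
  batch_size <- as.integer(batch_size)
  pending <- list()     # reads carried into the next batch
  batch_index <- 0L
  total <- 0L
  flush <- function(reads, bc) {
    b <- read_batch(reads, batch_index, bc)
    batch_index <<- batch_index + 1L
    total <<- total + length(reads)
    !identical(callback(b), FALSE)
  }
  for (path in paths) {
    bc_file <- barcode %||% barcode_from_path(path)
    con <- open_fastq(path)
    rec_i <- 0L
    repeat {
      lines <- readLines(con, n = 4L * batch_size, warn = FALSE)
      if (length(lines) == 0L) break
      if (length(lines) %% 4L != 0L) {
        close(con)
        stop(sprintf("truncated FASTQ record at end of '%s' (record %d)",
                     path, rec_i + length(lines) %/% 4L + 1L))
      }
      n <- length(lines) %/% 4L
      for (r in seq_len(n)) {
        i <- 4L * (r - 1L)
        hdr <- lines[i + 1L]
        if (!startsWith(hdr, "@")) {
          close(con)
          stop(sprintf("malformed FASTQ record %d in '%s': header does not start with '@'",
                       rec_i + r, path))
        }
        if (!startsWith(lines[i + 3L], "+")) {
          close(con)
          stop(sprintf("malformed FASTQ record %d in '%s': separator line missing '+'",
                       rec_i + r, path))
        }
        bases <- toupper(lines[i + 2L])
        qual <- lines[i + 4L]
        if (nchar(bases) != nchar(qual)) {
          close(con)
          stop(sprintf("sequence/quality length mismatch at record %d in '%s'",
                       rec_i + r, path))
        }
        bc <- bc_file
        if (is.null(barcode) && !grepl("^(barcode[0-9]+|unclassified)$", bc_file)) {
          m <- regmatches(hdr, regexpr("barcode=[0-9A-Za-z]+", hdr))
          bc <- if (length(m)) paste0("barcode", sub("barcode=", "", m)) else "unclassified"
        }
        pending[[length(pending) + 1L]] <- new_read(
          read_id = sub("^@", "", strsplit(hdr, "[ \t]")[[1]][1]),
          bases = bases,
          quals = utf8ToInt(qual) - 33L,
          barcode = bc,
          batch_index = batch_index
        )
        if (length(pending) == batch_size) {
          ok <- flush(pending, bc)
          pending <- list()
          if (!ok) { close(con); return(invisible(total)) }
        }
      }
      rec_i <- rec_i + n
    }
    close(con)
  }
  if (length(pending) > 0L) flush(pending, pending[[1L]]$barcode)
  invisible(total)
}

open_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTQ file not found: '%s'", path))
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

barcode_from_path <- function(path) {
  dir <- basename(dirname(normalizePath(path, mustWork = FALSE)))
  if (grepl("^(barcode[0-9]+|unclassified)$", dir)) dir else basename(path)
}

#' Construct a single read
#'
#' @param read_id read identifier.
#' @param bases DNA string over `{A,C,G,T,N}`.
#' @param quals integer phred scores (0--93), one per base.
#' @param barcode barcode label (`"barcode01"`..`"barcode96"` or
#'   `"unclassified"`).
#' @param batch_index non-negative integer batch counter.
#' @return a `polyamp_read` object.
#' @export
new_read <- function(read_id, bases, quals, barcode = "unclassified",
                     batch_index = 0L) {
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals))
    stop("length(bases) must equal length(quals)")
  if (length(quals) && (min(quals) < 0L || max(quals) > 93L))
    stop("phred scores must lie in [0, 93]")
  structure(list(read_id = read_id, bases = bases, quals = quals,
                 barcode = barcode, batch_index = as.integer(batch_index)),
            class = "polyamp_read")
}

#' @export
print.polyamp_read <- function(x, ...) {
  cat(sprintf("<read %s> %d nt, barcode %s, mean Q %.1f\n", x$read_id,
              nchar(x$bases), x$barcode,
              if (length(x$quals)) mean(x$quals) else NA_real_))
  invisible(x)
}

#' Construct a batch of reads
#'
#' All reads in a batch share a barcode and batch index.
#'
#' @param reads list of [new_read()] objects.
#' @param batch_index integer batch counter.
#' @param barcode shared barcode label.
#' @return a `polyamp_batch` object.
#' @export
read_batch <- function(reads, batch_index, barcode) {
  structure(list(reads = reads, batch_index = as.integer(batch_index),
                 barcode = barcode),
            class = "polyamp_batch")
}

#' @export
print.polyamp_batch <- function(x, ...) {
  cat(sprintf("<batch %d> %d reads, barcode %s\n", x$batch_index,
              length(x$reads), x$barcode))
  invisible(x)
}

#' Parse a sample sheet
#'
#' Tab-separated with header columns `barcode`, `sample_id`, `role` and an
#' optional `expected_ratio`. Roles are one of `subject`, `positive_control`,
#' `negative_control`, `ncp` (pooled negative controls). Expected ratios for
#' control barcodes are written `"name:part,name:part"`, e.g. `"Msmeg:1,Ecoli:4"`
#' for a two-strain mock mixed in 1:4 molar proportion.
#'
#' @param file path to the TSV sheet.
#' @return a `polyamp_sheet`: data frame of entries plus an `expected_ratios`
#'   attribute (named list of named numeric vectors, keyed by barcode).
#' @export
parse_sample_sheet <- function(file) {
  df <- read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("barcode", "sample_id", "role")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$barcode))
    stop("duplicate barcode(s) in sample sheet: ",
         paste(unique(df$barcode[duplicated(df$barcode)]), collapse = ", "))
  if (nrow(df) > 96L) stop("sample sheet has more than 96 entries")
  roles <- c("subject", "positive_control", "negative_control", "ncp")
  bad <- setdiff(unique(df$role), roles)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(roles, collapse = ", "), ")")
  ratios <- list()
  if ("expected_ratio" %in% names(df)) {
    for (i in seq_len(nrow(df))) {
      s <- df$expected_ratio[i]
      if (!is.na(s) && nzchar(s)) {
        parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
        if (any(lengths(parts) != 2L))
          stop(sprintf("cannot parse expected_ratio '%s' for %s", s, df$barcode[i]))
        v <- as.numeric(vapply(parts, `[`, "", 2L))
        names(v) <- trimws(vapply(parts, `[`, "", 1L))
        if (anyNA(v)) stop(sprintf("non-numeric part in expected_ratio '%s'", s))
        ratios[[df$barcode[i]]] <- v
      }
    }
  }
  structure(df[need], expected_ratios = ratios, class = c("polyamp_sheet", "data.frame"))
}

#' Barcodes by role
#' @param sheet a [parse_sample_sheet()] result.
#' @param roles character vector of roles to keep.
#' @return character vector of barcodes.
#' @export
sheet_barcodes <- function(sheet, roles = "subject") {
  sheet$barcode[sheet$role %in% roles]
}

#' Write abundance profiles to a TSV table
#'
#' One row per (sample, kingdom, taxon): columns `sample_id, kingdom, tax_id,
#' superkingdom, phylum, class, order, family, genus, species, reads,
#' rel_abundance`. Relative abundances sum to 1 per (sample, kingdom) over the
#' assigned taxa plus a single `unassigned` row that absorbs unassigned reads
#' and reads not confidently resolved to species rank.
#'
#' @param profiles list of [abundance_profile()] objects.
#' @param out output path.
#' @return `out`, invisibly.
#' @export
write_abundance_table <- function(profiles, out) {
  if (length(profiles) == 0L) stop("profiles must be non-empty")
  if (inherits(profiles, "polyamp_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "polyamp_profile"))
    counts <- p$taxon_counts
    other <- p$n_reads - sum(counts)  # unassigned + sub-species-confidence
    total <- sum(counts) + other
    lin <- p$lineages
    df <- data.frame(
      sample_id = p$sample_id, kingdom = p$kingdom,
      tax_id = c(names(counts), "unassigned"),
      stringsAsFactors = FALSE
    )
    for (r in RANKS[1:7]) {
      df[[r]] <- c(vapply(names(counts), function(tid) {
        i <- match(tid, lin$tax_id)
        if (is.na(i)) "" else lin[[r]][i]
      }, character(1)), "")
    }
    df$reads <- c(as.numeric(counts), other)
    df$rel_abundance <- if (total > 0) df$reads / total else
      c(rep(0, length(counts)), 1)
    if (total == 0) df$rel_abundance <- c(rep(0, length(counts)), 1)
    df
  })
  tab <- do.call(rbind, rows)
  # fixed column order; species after genus, no strain column in the table
  tab <- tab[, c("sample_id", "kingdom", "tax_id", RANKS[1:7], "reads",
                 "rel_abundance")]
  tab$rel_abundance <- sprintf("%.6f", tab$rel_abundance)
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read back an abundance table written by [write_abundance_table()]
#'
#' @param file path to the TSV.
#' @return list of [abundance_profile()] objects, one per (sample, kingdom).
#' @export
read_abundance_table <- function(file) {
  tab <- read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  tab$reads <- as.numeric(tab$reads)
  keys <- unique(tab[, c("sample_id", "kingdom")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$sample_id == keys$sample_id[i] & tab$kingdom == keys$kingdom[i], ]
    assigned <- sub[sub$tax_id != "unassigned", ]
    counts <- setNames(assigned$reads, assigned$tax_id)
    lin <- assigned[, c("tax_id", RANKS[1:7])]
    lin$strain <- ""
    abundance_profile(
      sample_id = keys$sample_id[i], kingdom = keys$kingdom[i],
      taxon_counts = counts, lineages = lin,
      n_reads = sum(sub$reads)
    )
  })
}
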
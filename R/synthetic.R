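#' Error model for synthetic nanopore-like reads
#'
#' Per-base substitution / insertion / deletion rates (defaults summing to
#' 0.05, i.e. ~95% median read accuracy) and quality emission: correct bases
#' draw phred scores around `q_correct`, erroneous bases around `q_error`, so
#' the arithmetic-mean-phred filter is meaningful.
#'
#' @param sub,ins,del per-base error rates.
#' @param q_correct,q_error mean phred of correct / erroneous bases.
#' @param q_sd jitter (SD) of emitted phred scores.
#' @return a `polyamp_errmodel`.
#' @export
error_model <- function(sub = 0.03, ins = 0.01, del = 0.01,
                        q_correct = 24, q_error = 7, q_sd = 2) {
  stopifnot(sub >= 0, ins >= 0, del >= 0, sub + ins + del < 1)
  structure(list(sub = sub, ins = ins, del = del, q_correct = q_correct,
                 q_error = q_error, q_sd = q_sd),
            class = "polyamp_errmodel")
}

#' Community specification for a synthetic run
#'
#' Defaults emulate the study conditions of a 3:1 molar 16S:ITS multi-kingdom
#' pool: ITS molar fraction 0.25, log-normal taxon abundances, two-strain
#' positive controls at 1:4 (bacteria) and 2.7:1 (fungi), negligible
#' negative-control material (1% of subject depth).
#'
#' @param its_fraction molar fraction of ITS reads per subject barcode.
#' @param lognormal_sd sigma of the log-normal taxon abundance vectors.
#' @param pc_bacteria,pc_fungi two-element molar parts of the positive-control
#'   strains (taxa 1 and 2 of each kingdom's reference set).
#' @param nc_rate negative-control read depth as a fraction of subject depth.
#' @return a `polyamp_community`.
#' @export
community_spec <- function(its_fraction = 0.25, lognormal_sd = 1,
                           pc_bacteria = c(1, 4), pc_fungi = c(2.7, 1),
                           nc_rate = 0.01) {
  stopifnot(its_fraction >= 0, its_fraction <= 1,
            length(pc_bacteria) == 2, length(pc_fungi) == 2)
  structure(list(its_fraction = its_fraction, lognormal_sd = lognormal_sd,
                 pc_bacteria = pc_bacteria, pc_fungi = pc_fungi,
                 nc_rate = nc_rate),
            class = "polyamp_community")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Synthesize a reference database
#'
#' Random reference sequences in two length regimes (bacterial ~1,450 nt,
#' fungal ~550 nt, each with +-10% jitter), rejection-sampled until all
#' pairwise 8-mer Jaccard similarities are below 0.5 so taxa are k-mer
#' separable. Fungal lineages are also rendered as UNITE-style rank-prefixed
#' headers (optionally with `unidentified` placeholders or duplicated
#' lineages, for database-construction tests).
#'
#' @param n_bact,n_fungi taxa per kingdom.
#' @param len_bact,len_fungi base reference lengths (nt).
#' @param seed RNG seed (the generator is bit-reproducible under it).
#' @param unidentified_frac fraction of fungal lineages whose genus/species
#'   are `unidentified` placeholders.
#' @param duplicate_lineages number of extra fungal entries repeating an
#'   existing lineage (distinct sequence, same taxonomy).
#' @param max_tries rejection-sampling budget per sequence.
#' @return list with `bacteria` / `fungi` (each: `lineages`, `sequences`
#'   named by tax_id) and `unite_fasta` (`headers`, `sequences`) for the
#'   fungal side.
#' @export
make_reference_db <- function(n_bact, n_fungi, len_bact = 1450L,
                              len_fungi = 550L, seed = 1L,
                              unidentified_frac = 0, duplicate_lineages = 0L,
                              max_tries = 50L) {
  stopifnot(n_bact >= 1, n_fungi >= 1)
  set.seed(seed %% 2147483647)
  gen_kingdom <- function(n, len, prefix, superk, kingdom) {
    seqs <- character(n)
    kmer_sets <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        L <- round(len * runif(1, 0.9, 1.1))
        s <- random_dna(L)
        km <- .distinct_kmers(s, 8L)
        sep <- TRUE
        if (i > 1L) for (j in seq_len(i - 1L)) {
          jac <- length(intersect(km, kmer_sets[[j]])) /
            length(union(km, kmer_sets[[j]]))
          if (jac >= 0.5) { sep <- FALSE; break }
        }
        if (sep) { seqs[i] <- s; kmer_sets[[i]] <- km; ok <- TRUE; break }
      }
      if (!ok) stop("could not achieve k-mer divergence; use longer sequences")
    }
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    genus <- sprintf("%sgenus%02d", toupper(substr(kingdom, 1, 1)),
                     ((seq_len(n) - 1L) %/% 3L) + 1L)
    species <- sprintf("%s species%03d", genus, seq_len(n))
    lin <- lineage_table(
      ids,
      superkingdom = rep(superk, n),
      phylum = sprintf("%sphylum%02d", toupper(substr(kingdom, 1, 1)),
                       ((seq_len(n) - 1L) %/% 10L) + 1L),
      class = rep(paste0(superk, "classA"), n),
      order = rep(paste0(superk, "orderA"), n),
      family = sprintf("%sfam%02d", toupper(substr(kingdom, 1, 1)),
                       ((seq_len(n) - 1L) %/% 5L) + 1L),
      genus = genus, species = species, kingdom = kingdom)
    list(lineages = lin, sequences = setNames(as.list(seqs), ids))
  }
  bact <- gen_kingdom(n_bact, len_bact, "BTAX", "Bacteria", "bacteria")
  fung <- gen_kingdom(n_fungi, len_fungi, "FTAX", "Fungi", "fungi")
  n_unid <- round(unidentified_frac * n_fungi)
  if (n_unid > 0) {
    idx <- seq_len(n_unid)
    fung$lineages$genus[idx] <- "unidentified"
    fung$lineages$species[idx] <- "unidentified"
    fung$lineages$uncertain[idx] <- TRUE
  }
  headers <- vapply(seq_len(n_fungi), function(i) {
    l <- fung$lineages[i, ]
    und <- function(x) gsub(" ", "_", x)
    sprintf("%s|k__%s;p__%s;c__%s;o__%s;f__%s;g__%s;s__%s",
            fung$lineages$tax_id[i], und(l$superkingdom), und(l$phylum),
            und(l$class), und(l$order), und(l$family), und(l$genus),
            und(l$species))
  }, character(1))
  sequences <- unlist(fung$sequences, use.names = FALSE)
  if (duplicate_lineages > 0L) {
    for (d in seq_len(duplicate_lineages)) {
      src <- ((d - 1L) %% n_fungi) + 1L
      hdr <- sub("^[^|]+", sprintf("FDUP%03d", d), headers[src])
      headers <- c(headers, hdr)
      sequences <- c(sequences, random_dna(nchar(sequences[src])))
    }
  }
  list(bacteria = bact, fungi = fung,
       unite_fasta = list(headers = headers, sequences = sequences))
}

#' Write a UNITE-style FASTA
#' @param unite_fasta the `unite_fasta` element of [make_reference_db()].
#' @param path output path (plain or `.gz`).
#' @return `path`, invisibly.
#' @export
write_unite_fasta <- function(unite_fasta, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(rbind(paste0(">", unite_fasta$headers), unite_fasta$sequences),
             con)
  invisible(path)
}

#' Simulate one amplicon read
#'
#' The template is forward primer + insert + reverse-complement(reverse
#' primer); with probability 1/2 the whole read is flipped to the reverse
#' orientation. The template is then corrupted by the error model and per-base
#' qualities are emitted consistently with each base's error status (inserted
#' and substituted bases draw low scores).
#'
#' @param reference insert (marker) sequence.
#' @param primers a [primer_set()].
#' @param err an [error_model()].
#' @param read_id identifier for the read.
#' @param barcode barcode label.
#' @return list `(read, truth)`; `truth` records the true orientation and the
#'   error counts.
#' @export
simulate_read <- function(reference, primers, err = error_model(),
                          read_id = "read1", barcode = "unclassified") {
  template <- paste0(primers$forward, reference, revcomp(primers$reverse))
  flipped <- runif(1) < 0.5
  if (flipped) template <- revcomp(template)
  bases <- strsplit(template, "", fixed = TRUE)[[1]]
  # degenerate IUPAC positions in the primers are instantiated uniformly
  deg <- which(!(bases %in% c("A", "C", "G", "T")))
  for (i in deg) bases[i] <- sample(iupac_expand(bases[i]), 1L)
  n <- length(bases)
  u <- runif(n)
  ACGT <- c("A", "C", "G", "T")
  # substitutions always change the base (rotate by 1..3 in ACGT order)
  base_idx <- match(bases, ACGT)
  sub_to <- ACGT[((base_idx - 1L + sample(3L, n, replace = TRUE)) %% 4L) + 1L]
  ins_b <- sample(ACGT, n, replace = TRUE)
  p1 <- err$sub; p2 <- p1 + err$del; p3 <- p2 + err$ins
  is_sub <- u < p1
  is_del <- u >= p1 & u < p2
  is_ins <- u >= p2 & u < p3           # insertion before the base
  b <- bases
  b[is_sub] <- sub_to[is_sub]
  cnt <- rep(1L, n); cnt[is_del] <- 0L; cnt[is_ins] <- 2L
  idx <- rep(seq_len(n), cnt)
  ins_first <- !duplicated(idx) & is_ins[idx]   # first of an ins pair
  out_b <- b[idx]; out_b[ins_first] <- ins_b[idx][ins_first]
  out_err <- is_sub[idx]; out_err[ins_first] <- TRUE
  q <- rnorm(length(out_b), err$q_correct, err$q_sd)
  q[out_err] <- rnorm(sum(out_err), err$q_error, err$q_sd)
  q <- pmin(pmax(round(q), 2L), 41L)
  rd <- new_read(read_id, paste(out_b, collapse = ""), as.integer(q),
                 barcode = barcode)
  list(read = rd,
       truth = list(read_id = read_id, flipped = flipped,
                    n_sub = sum(is_sub), n_del = sum(is_del),
                    n_ins = sum(is_ins), template_len = n))
}

iupac_expand <- function(code) {
  map <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  map[[code]]
}

#' Default 96-well multi-kingdom sample sheet
#'
#' 93 subjects, one positive control, one negative control and one pooled
#' negative control (NCP), or a truncated plate with `n_subjects` subjects.
#'
#' @param n_subjects number of subject barcodes (<= 93).
#' @param path optional path; when given the sheet is written as TSV and the
#'   path returned.
#' @param db optional [make_reference_db()] result used to name the expected
#'   positive-control taxa; defaults to generic names.
#' @param spec a [community_spec()] for the expected ratio annotations.
#' @return a [parse_sample_sheet()]-compatible data frame (invisibly the path
#'   when `path` is given).
#' @export
default_sample_sheet <- function(n_subjects = 93L, path = NULL, db = NULL,
                                 spec = community_spec()) {
  stopifnot(n_subjects >= 1, n_subjects <= 93)
  n <- n_subjects + 3L
  bcs <- sprintf("barcode%02d", seq_len(n))
  roles <- c(rep("subject", n_subjects), "positive_control",
             "negative_control", "ncp")
  ids <- c(sprintf("S%02d", seq_len(n_subjects)), "PC", "NC", "NCP")
  pcb <- if (!is.null(db)) db$bacteria$lineages$species[1:2] else
    c("ControlBacteriumA", "ControlBacteriumB")
  pcf <- if (!is.null(db)) db$fungi$lineages$species[1:2] else
    c("ControlFungusA", "ControlFungusB")
  ratio <- paste0(
    pcb[1], ":", spec$pc_bacteria[1], ",", pcb[2], ":", spec$pc_bacteria[2],
    ",", pcf[1], ":", spec$pc_fungi[1], ",", pcf[2], ":", spec$pc_fungi[2])
  df <- data.frame(barcode = bcs, sample_id = ids, role = roles,
                   expected_ratio = c(rep("", n_subjects), ratio, "", ""),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  df
}

#' Simulate a full multi-kingdom run with ground truth
#'
#' Emulates a demultiplexed nanopore run: per-barcode gzipped FASTQ files of
#' `batch_size` reads each (last file short) in MinKNOW layout
#' `out_dir/fastq_pass/barcodeNN/`, with each read's kingdom drawn from the
#' ITS molar fraction and its taxon from a per-barcode log-normal abundance
#' vector (positive controls use the two-strain parts; negative controls get
#' `nc_rate` of the subject depth). A ground-truth manifest and true abundance
#' vectors are written alongside.
#'
#' @param sheet a [parse_sample_sheet()] result or data frame.
#' @param db a [make_reference_db()] result.
#' @param spec a [community_spec()].
#' @param reads_per_barcode reads per subject (and PC) barcode.
#' @param batch_size reads per written FASTQ file.
#' @param seed RNG seed.
#' @param out_dir run directory to create.
#' @param err an [error_model()].
#' @return list: `run_dir`, `manifest` (data frame read_id, barcode, kingdom,
#'   tax_id, flipped), `true_abundance` (per barcode/kingdom named vectors),
#'   `files`.
#' @export
simulate_run <- function(sheet, db, spec = community_spec(),
                         reads_per_barcode = 10000L, batch_size = 4000L,
                         seed = 1L, out_dir = tempfile("run"),
                         err = error_model()) {
  set.seed(seed %% 2147483647)
  primer_sets <- default_primer_sets()
  dir.create(file.path(out_dir, "fastq_pass"), showWarnings = FALSE,
             recursive = TRUE)
  m_id <- character(0); m_bc <- character(0); m_king <- character(0)
  m_tid <- character(0); m_flip <- logical(0)
  true_ab <- list(); files <- character(0)
  n_b <- nrow(db$bacteria$lineages); n_f <- nrow(db$fungi$lineages)
  for (i in seq_len(nrow(sheet))) {
    bc <- sheet$barcode[i]; role <- sheet$role[i]
    n_reads <- switch(role,
      subject = reads_per_barcode,
      positive_control = reads_per_barcode,
      round(spec$nc_rate * reads_per_barcode))
    ab_b <- switch(role,
      positive_control = c(spec$pc_bacteria / sum(spec$pc_bacteria),
                           rep(0, n_b - 2L)),
      {x <- rlnorm(n_b, 0, spec$lognormal_sd); x / sum(x)})
    ab_f <- switch(role,
      positive_control = c(spec$pc_fungi / sum(spec$pc_fungi),
                           rep(0, n_f - 2L)),
      {x <- rlnorm(n_f, 0, spec$lognormal_sd); x / sum(x)})
    true_ab[[bc]] <- list(bacteria = setNames(ab_b, db$bacteria$lineages$tax_id),
                          fungi = setNames(ab_f, db$fungi$lineages$tax_id))
    if (n_reads == 0L) next
    kingdoms <- ifelse(runif(n_reads) < spec$its_fraction, "fungi", "bacteria")
    bc_dir <- file.path(out_dir, "fastq_pass", bc)
    dir.create(bc_dir, showWarnings = FALSE)
    # taxon draws for the whole barcode up front
    tax_b <- sample.int(n_b, n_reads, replace = TRUE, prob = ab_b)
    tax_f <- sample.int(n_f, n_reads, replace = TRUE, prob = ab_f)
    b_id <- character(n_reads); b_king <- character(n_reads)
    b_tid <- character(n_reads); b_flip <- logical(n_reads)
    n_files <- ceiling(n_reads / batch_size)
    ridx <- 0L
    for (f in seq_len(n_files)) {
      n_this <- min(batch_size, n_reads - (f - 1L) * batch_size)
      lines <- character(4L * n_this)
      for (r in seq_len(n_this)) {
        ridx <- ridx + 1L
        king <- kingdoms[ridx]
        side <- if (king == "fungi") db$fungi else db$bacteria
        tid <- side$lineages$tax_id[
          if (king == "fungi") tax_f[ridx] else tax_b[ridx]]
        rid <- sprintf("%s_r%05d", bc, ridx)
        sim <- simulate_read(side$sequences[[tid]],
                             primer_sets[[if (king == "fungi") "ITS" else "16S"]],
                             err, read_id = rid, barcode = bc)
        b_id[ridx] <- rid; b_king[ridx] <- king; b_tid[ridx] <- tid
        b_flip[ridx] <- sim$truth$flipped
        j <- 4L * (r - 1L)
        lines[j + 1L] <- paste0("@", rid)
        lines[j + 2L] <- sim$read$bases
        lines[j + 3L] <- "+"
        lines[j + 4L] <- intToUtf8(sim$read$quals + 33L)
      }
      path <- file.path(bc_dir, sprintf("%s_batch%03d.fastq.gz", bc, f - 1L))
      con <- gzfile(path, "wt", compression = 1)
      writeLines(lines, con)
      close(con)
      files <- c(files, path)
    }
    m_id <- c(m_id, b_id); m_bc <- c(m_bc, rep(bc, n_reads))
    m_king <- c(m_king, b_king); m_tid <- c(m_tid, b_tid)
    m_flip <- c(m_flip, b_flip)
  }
  manifest <- data.frame(read_id = m_id, barcode = m_bc, kingdom = m_king,
                         tax_id = m_tid, flipped = m_flip,
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(run_dir = out_dir, manifest = manifest, true_abundance = true_ab,
       files = files)
}
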
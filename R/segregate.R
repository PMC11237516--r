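#' Primer sets for kingdom segregation
#'
#' A primer set names the amplicon (e.g. `"16S"`, `"ITS"`), its forward and
#' reverse primers (IUPAC codes allowed) and the kingdom it marks.
#'
#' @param name amplicon label.
#' @param forward,reverse IUPAC DNA strings.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @return a `polyamp_primerset`.
#' @export
primer_set <- function(name, forward, reverse, kingdom) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (!nzchar(p)) stop("primers must be non-empty")
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    bad <- setdiff(ch, IUPAC_CHARS)
    if (length(bad))
      stop("invalid IUPAC character(s) in primer: ", paste(bad, collapse = ", "))
  }
  kingdom <- match.arg(kingdom, c("bacteria", "fungi"))
  structure(list(name = name, forward = forward, reverse = reverse,
                 kingdom = kingdom), class = "polyamp_primerset")
}

#' Default primer sets
#'
#' Full-length 16S rRNA gene primers 27F/1492R for bacteria and the inner
#' nested pair ITS1/ITS4 for the fungal ITS region (the sequenced nested
#' amplicon carries the inner primers, so the outer ITS1F is not searched).
#'
#' @return list of two [primer_set()] objects named `16S` and `ITS`.
#' @export
default_primer_sets <- function() {
  list(
    `16S` = primer_set("16S", "AGRGTTYGATYMTGGCTCAG", "CGGYTACCTTGTTACGACTT",
                       "bacteria"),
    ITS = primer_set("ITS", "TCCGTAGGTGAACCTGCGG", "TCCTCCGCTTATTGATATGC",
                     "fungi")
  )
}

#' Read primer sets from a TSV
#' @param file TSV with columns `name, kingdom, forward, reverse`.
#' @return list of [primer_set()] objects.
#' @export
read_primer_sets <- function(file) {
  df <- read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "kingdom", "forward", "reverse")
  if (!all(need %in% names(df)))
    stop("primer TSV needs columns: ", paste(need, collapse = ", "))
  sets <- lapply(seq_len(nrow(df)), function(i)
    primer_set(df$name[i], df$forward[i], df$reverse[i], df$kingdom[i]))
  names(sets) <- df$name
  sets
}

#' Length/quality filter parameters
#'
#' Defaults follow standard full-length multi-kingdom amplicon QC: retain
#' inserts of 200--3,500 nt, truncate 3' tails to 1,550 nt, require an
#' arithmetic mean phred of at least 20. Primer matches may use up to
#' `max_err_frac` of the primer length in edit distance and are searched in
#' `search_window` bases from each read end.
#'
#' @param min_len,max_len retained insert length bounds (nt).
#' @param trunc_len 3' truncation length (nt).
#' @param min_mean_q minimum arithmetic mean phred score.
#' @param max_err_frac fraction of primer length allowed as edit distance.
#' @param search_window bases from each read end searched for primers.
#' @return a `polyamp_filter` list.
#' @export
filter_params <- function(min_len = 200L, max_len = 3500L, trunc_len = 1550L,
                          min_mean_q = 20, max_err_frac = 0.2,
                          search_window = 100L) {
  stopifnot(min_len > 0, min_len <= max_len, trunc_len > 0, min_mean_q >= 0,
            max_err_frac >= 0, max_err_frac < 0.5, search_window > 0)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 trunc_len = as.integer(trunc_len), min_mean_q = min_mean_q,
                 max_err_frac = max_err_frac,
                 search_window = as.integer(search_window)),
            class = "polyamp_filter")
}

#' Match a degenerate primer within a read window
#'
#' Semi-global alignment: the primer must be fully contained, read end-points
#' are free inside the window. Unit-cost edit distance; an IUPAC code in the
#' primer matches any base of its set at zero cost. The best hit minimises
#' edit distance, with ties broken by smaller start, then shorter span.
#'
#' @param bases read sequence (A/C/G/T/N).
#' @param primer IUPAC primer string.
#' @param max_err maximum edit distance accepted.
#' @param window integer `c(from, to)`: 0-based half-open interval of the read
#'   searched; defaults to the whole read.
#' @return a hit list `(primer_name, start, end, edit_distance)` in read
#'   coordinates (0-based half-open), or `NULL` when no alignment is within
#'   `max_err`.
#' @export
match_primer <- function(bases, primer, max_err, window = NULL) {
  bases <- toupper(bases); primer <- toupper(primer)
  n <- nchar(bases)
  if (is.null(window)) window <- c(0L, n)
  stopifnot(window[1] >= 0, window[2] <= n, window[1] <= window[2])
  sub <- substr(bases, window[1] + 1L, window[2])
  res <- .semi_global_match(sub, primer, as.integer(max_err))
  if (res[1] < 0) return(NULL)
  list(primer_name = NA_character_,
       start = as.integer(window[1] + res[2]),
       end = as.integer(window[1] + res[3]),
       edit_distance = as.integer(res[1]))
}

# search one primer in a 5' or 3' end window; returns hit or NULL.
# Calls the alignment core directly: `bases` is assumed upper-case (the FASTQ
# reader and the simulator both guarantee it).
search_end <- function(bases, primer, max_err, params, end3 = FALSE) {
  n <- nchar(bases)
  w <- min(params$search_window + nchar(primer), n)
  from <- if (end3) n - w else 0L
  res <- .semi_global_match(substr(bases, from + 1L, from + w), primer,
                            as.integer(max_err))
  if (res[1] < 0) return(NULL)
  list(primer_name = NA_character_, start = as.integer(from + res[2]),
       end = as.integer(from + res[3]), edit_distance = as.integer(res[1]))
}

# precompute per-set search specs (primer orientations, reverse complements,
# error budgets) once per batch instead of once per read
compile_primer_plan <- function(primer_sets, params) {
  lapply(primer_sets, function(ps) {
    specs <- list(
      list(p = ps$forward, name = paste0(ps$name, "_fwd"), end3 = FALSE, ori = "+"),
      list(p = revcomp(ps$reverse), name = paste0(ps$name, "_rev_rc"), end3 = TRUE, ori = "+"),
      list(p = ps$reverse, name = paste0(ps$name, "_rev"), end3 = FALSE, ori = "-"),
      list(p = revcomp(ps$forward), name = paste0(ps$name, "_fwd_rc"), end3 = TRUE, ori = "-")
    )
    for (i in seq_along(specs))
      specs[[i]]$max_err <- as.integer(ceiling(params$max_err_frac * nchar(specs[[i]]$p)))
    list(set = ps, specs = specs)
  })
}

#' Assign a read to a kingdom by primer evidence
#'
#' For each primer set, the forward primer is searched in the 5' window and
#' its reverse complement in the 3' window, and likewise the reverse primer
#' (covering both read orientations). A set supports the read if at least one
#' of its primers hits within `ceil(max_err_frac * primer length)` edits. A
#' unique supporting set gives the verdict; with several, the set with more
#' distinct primer hits wins, ties by lower total edit distance, remaining
#' ties are `unassigned` with reason `conflict`. The trim span excludes all
#' matched primer spans; `orientation` records whether the insert is in
#' forward (`"+"`) or reverse (`"-"`) orientation relative to the forward
#' primer.
#'
#' @param read a [new_read()] object.
#' @param primer_sets list of [primer_set()] objects.
#' @param params [filter_params()].
#' @param plan precompiled search plan (internal; [segregate_reads()] builds
#'   it once per batch).
#' @return a `polyamp_call`: list with `read_id`, `verdict`
#'   (`amplicon_16S` / `amplicon_ITS` / `unassigned`), `kingdom`, `hits`,
#'   `trim_span` (0-based half-open), `orientation`, `reject_reason`.
#' @export
assign_kingdom <- function(read, primer_sets, params = filter_params(),
                           plan = NULL) {
  stopifnot(length(primer_sets) >= 1)
  plan <- plan %||% compile_primer_plan(primer_sets, params)
  bases <- read$bases
  n <- nchar(bases)
  evidence <- lapply(plan, function(pl) {
    ps <- pl$set
    hits <- list()
    for (spec in pl$specs) {
      h <- search_end(bases, spec$p, spec$max_err, params, end3 = spec$end3)
      if (!is.null(h)) {
        h$primer_name <- spec$name
        h$end3 <- spec$end3
        h$orientation <- spec$ori
        hits[[length(hits) + 1L]] <- h
      }
    }
    # keep the better hit per end (one primer per end can be real)
    if (length(hits) > 1L) {
      for (e3 in c(FALSE, TRUE)) {
        idx <- which(vapply(hits, `[[`, logical(1), "end3") == e3)
        if (length(idx) > 1L) {
          d <- vapply(hits[idx], `[[`, integer(1), "edit_distance")
          drop <- idx[-which.min(d)]
          hits[drop] <- NULL
        }
      }
    }
    list(set = ps, hits = hits,
         n_hits = length(hits),
         total_err = sum(vapply(hits, `[[`, integer(1), "edit_distance")))
  })
  supporting <- Filter(function(e) e$n_hits >= 1L, evidence)
  unassigned <- function(reason) {
    structure(list(read_id = read$read_id, verdict = "unassigned",
                   kingdom = NA_character_, hits = list(),
                   trim_span = NULL, orientation = NA_character_,
                   reject_reason = reason), class = "polyamp_call")
  }
  if (length(supporting) == 0L) return(unassigned("no_primer"))
  if (length(supporting) > 1L) {
    nh <- vapply(supporting, `[[`, integer(1), "n_hits")
    supporting <- supporting[nh == max(nh)]
    if (length(supporting) > 1L) {
      te <- vapply(supporting, `[[`, numeric(1), "total_err")
      supporting <- supporting[te == min(te)]
    }
    if (length(supporting) > 1L) return(unassigned("conflict"))
  }
  ev <- supporting[[1L]]
  # orientation by majority of hit votes; ties resolved toward "+"
  oris <- vapply(ev$hits, `[[`, character(1), "orientation")
  orientation <- if (sum(oris == "-") > sum(oris == "+")) "-" else "+"
  from <- 0L; to <- n
  for (h in ev$hits) {
    if (h$end3) to <- min(to, h$start) else from <- max(from, h$end)
  }
  if (from > to) { from <- to <- min(from, n) }  # overlapping primers: empty insert
  structure(list(read_id = read$read_id,
                 verdict = paste0("amplicon_", ev$set$name),
                 kingdom = ev$set$kingdom, hits = ev$hits,
                 trim_span = c(from, to), orientation = orientation,
                 reject_reason = NULL), class = "polyamp_call")
}

#' Trim primers and apply length/quality filters
#'
#' Order of operations: (1) cut the read to the call's trim span; (2) reject
#' if the insert is shorter than `min_len` (`too_short`) or longer than
#' `max_len` (`too_long`); (3) truncate the 3' tail so the retained length is
#' at most `trunc_len` (reverse-orientation reads are reverse-complemented
#' first, so truncation always discards the end distal to the forward primer);
#' (4) reject if the arithmetic mean phred of the retained bases is below
#' `min_mean_q` (`low_quality`). Exactly one of retained / too_short /
#' too_long / low_quality holds.
#'
#' @param read a [new_read()].
#' @param call its [assign_kingdom()] verdict (must not be `unassigned`).
#' @param params [filter_params()].
#' @return a `polyamp_processed` list (`read`, `kingdom`, `verdict`,
#'   `mean_q`) when retained, or a `polyamp_reject` list with
#'   `reject_reason`.
#' @export
trim_and_filter <- function(read, call, params = filter_params()) {
  if (call$verdict == "unassigned") stop("cannot trim an unassigned read")
  span <- call$trim_span
  bases <- substr(read$bases, span[1] + 1L, span[2])
  quals <- read$quals[seq.int(span[1] + 1L, length.out = span[2] - span[1])]
  reject <- function(reason) {
    structure(list(read_id = read$read_id, reject_reason = reason,
                   kingdom = call$kingdom), class = "polyamp_reject")
  }
  len <- nchar(bases)
  if (len < params$min_len) return(reject("too_short"))
  if (len > params$max_len) return(reject("too_long"))
  if (identical(call$orientation, "-")) {
    bases <- revcomp(bases)
    quals <- rev(quals)
  }
  if (len > params$trunc_len) {
    bases <- substr(bases, 1L, params$trunc_len)
    quals <- quals[seq_len(params$trunc_len)]
  }
  mq <- mean(quals)
  if (mq < params$min_mean_q) return(reject("low_quality"))
  out <- new_read(read$read_id, bases, quals, read$barcode, read$batch_index)
  structure(list(read = out, kingdom = call$kingdom, verdict = call$verdict,
                 mean_q = mq), class = "polyamp_processed")
}

#' Segregate a batch of reads by kingdom
#'
#' Runs [assign_kingdom()] and [trim_and_filter()] over a list of reads and
#' splits the survivors by kingdom.
#'
#' @param reads list of [new_read()] objects.
#' @param primer_sets list of [primer_set()]s.
#' @param params [filter_params()].
#' @return list with `passed` (named list kingdom -> list of processed reads),
#'   `audit` (data frame: read_id, verdict, reason, trim_from, trim_to,
#'   orientation, total_edit_distance) and `reject_counts` (named integer).
#' @export
segregate_reads <- function(reads, primer_sets, params = filter_params()) {
  kingdoms <- unique(vapply(primer_sets, `[[`, character(1), "kingdom"))
  plan <- compile_primer_plan(primer_sets, params)
  n <- length(reads)
  passed <- setNames(vector("list", length(kingdoms)), kingdoms)
  for (k in kingdoms) passed[[k]] <- vector("list", n)
  npass <- setNames(integer(length(kingdoms)), kingdoms)
  a_id <- character(n); a_verdict <- character(n); a_reason <- character(n)
  a_from <- rep(NA_integer_, n); a_to <- rep(NA_integer_, n)
  a_ori <- rep(NA_character_, n); a_dist <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    rd <- reads[[i]]
    call <- assign_kingdom(rd, primer_sets, params, plan = plan)
    a_id[i] <- rd$read_id
    a_verdict[i] <- call$verdict
    if (call$verdict == "unassigned") {
      a_reason[i] <- call$reject_reason
    } else {
      a_from[i] <- call$trim_span[1]; a_to[i] <- call$trim_span[2]
      a_ori[i] <- call$orientation
      a_dist[i] <- sum(vapply(call$hits, `[[`, integer(1), "edit_distance"))
      pr <- trim_and_filter(rd, call, params)
      if (inherits(pr, "polyamp_reject")) {
        a_reason[i] <- pr$reject_reason
      } else {
        k <- call$kingdom
        npass[k] <- npass[k] + 1L
        passed[[k]][[npass[k]]] <- pr
      }
    }
  }
  for (k in kingdoms) passed[[k]] <- passed[[k]][seq_len(npass[k])]
  audit <- data.frame(read_id = a_id, verdict = a_verdict, reason = a_reason,
                      trim_from = a_from, trim_to = a_to, orientation = a_ori,
                      edit_distance = a_dist, stringsAsFactors = FALSE)
  rc <- table(audit$reason[nzchar(audit$reason)])
  list(passed = passed, audit = audit,
       reject_counts = setNames(as.integer(rc), names(rc)))
}
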
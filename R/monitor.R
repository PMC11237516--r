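#' Run-monitoring configuration
#'
#' Bundles everything the watcher needs to process a run directory.
#'
#' @param model a [build_kmer_model()] per kingdom: named list
#'   `list(bacteria = ..., fungi = ...)` (a single model is applied to its own
#'   kingdom only).
#' @param primer_sets list of [primer_set()]s.
#' @param sheet a [parse_sample_sheet()] result.
#' @param filter [filter_params()].
#' @param saturation [saturation_params()].
#' @param batch_size reads per processing batch.
#' @return a `polyamp_config`.
#' @export
monitor_config <- function(model, primer_sets = default_primer_sets(),
                           sheet = NULL, filter = filter_params(),
                           saturation = saturation_params(),
                           batch_size = 4000L) {
  if (inherits(model, "polyamp_model"))
    model <- setNames(list(model), model$lineages$kingdom[1])
  structure(list(model = model, primer_sets = primer_sets, sheet = sheet,
                 filter = filter, saturation = saturation,
                 batch_size = as.integer(batch_size)),
            class = "polyamp_config")
}

# fresh per-run mutable state
new_run_state <- function(config) {
  kingdoms <- unique(vapply(config$primer_sets, `[[`, character(1), "kingdom"))
  structure(list(config = config, accum = list(),
                 counts = list(),      # per-barcode seen/passed/per-kingdom
                 assignments = list(), # per-barcode, per-kingdom assignment lists
                 kingdoms = kingdoms, snapshot_index = 0L),
            class = "polyamp_runstate")
}

# process one batch of reads for one barcode through segregate -> classify ->
# accumulation; returns the updated state
process_batch <- function(state, batch) {
  config <- state$config
  bc <- batch$barcode
  if (is.null(state$counts[[bc]]))
    state$counts[[bc]] <- list(seen = 0, passed = 0,
                               kingdom = setNames(numeric(length(state$kingdoms)),
                                                  state$kingdoms))
  seg <- segregate_reads(batch$reads, config$primer_sets, config$filter)
  state$counts[[bc]]$seen <- state$counts[[bc]]$seen + length(batch$reads)
  for (k in state$kingdoms) {
    passed <- seg$passed[[k]] %||% list()
    state$counts[[bc]]$passed <- state$counts[[bc]]$passed + length(passed)
    state$counts[[bc]]$kingdom[k] <- state$counts[[bc]]$kingdom[k] + length(passed)
    key <- paste(bc, k, sep = "/")
    if (is.null(state$accum[[key]]))
      state$accum[[key]] <- accumulation_state(bc, k)
    model <- config$model[[k]]
    if (is.null(model)) next
    asg <- classify_reads(model, passed)
    # keep only what cumulative re-profiling needs (memory on large runs)
    slim <- lapply(asg, function(a)
      list(best_taxon = a$best_taxon, best_row = a$best_row %||% NA_integer_,
           assigned_rank = a$assigned_rank))
    state$assignments[[key]] <- c(state$assignments[[key]] %||% list(), slim)
    prof <- profile_sample(asg, model, sample_id = bc, kingdom = k)
    state$accum[[key]] <- update_accumulation(state$accum[[key]], prof)
  }
  state
}

#' Cumulative abundance profile of one barcode/kingdom
#'
#' Re-aggregates every assignment retained so far for a barcode and kingdom
#' into a single `polyamp_profile`.
#'
#' @param state a run state from [process_run_offline()] or [watch_run()].
#' @param barcode barcode label.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @return a `polyamp_profile`.
#' @export
state_profile <- function(state, barcode, kingdom) {
  key <- paste(barcode, kingdom, sep = "/")
  model <- state$config$model[[kingdom]]
  profile_sample(state$assignments[[key]] %||% list(), model,
                 sample_id = barcode, kingdom = kingdom)
}

#' Snapshot of a run state
#'
#' @param state internal run state (from [process_run_offline()] /
#'   [watch_run()]).
#' @param label snapshot label, e.g. `"T3"`.
#' @return a `polyamp_snapshot`: per-barcode table (reads seen/passed,
#'   per-kingdom reads and saturation status), global totals, fraction
#'   saturated, and the stop decision.
#' @export
run_snapshot <- function(state, label = NULL) {
  config <- state$config
  barcodes <- sort(names(state$counts))
  per_bc <- do.call(rbind, lapply(barcodes, function(bc) {
    row <- data.frame(barcode = bc, seen = state$counts[[bc]]$seen,
                      passed = state$counts[[bc]]$passed,
                      stringsAsFactors = FALSE)
    for (k in state$kingdoms) {
      row[[paste0("reads_", k)]] <- state$counts[[bc]]$kingdom[[k]]
      key <- paste(bc, k, sep = "/")
      row[[paste0("status_", k)]] <-
        if (!is.null(state$accum[[key]]))
          is_saturated(state$accum[[key]], config$saturation)
        else "insufficient_reads"
    }
    row
  }))
  eligible <- if (!is.null(config$sheet)) sheet_barcodes(config$sheet, "subject")
              else barcodes
  decision <- stop_recommendation(state$accum, config$saturation,
                                  eligible_barcodes = eligible)
  structure(list(label = label %||% paste0("T", state$snapshot_index),
                 index = state$snapshot_index,
                 per_barcode = per_bc,
                 total_reads = sum(vapply(state$counts, `[[`, numeric(1), "seen")),
                 fraction_saturated = decision$fraction_saturated,
                 stop = decision$stop, decision = decision),
            class = "polyamp_snapshot")
}

#' @export
print.polyamp_snapshot <- function(x, ...) {
  cat(sprintf("<snapshot %s> %g reads over %d barcodes; %.0f%% saturated; %s\n",
              x$label, x$total_reads,
              if (is.null(x$per_barcode)) 0L else nrow(x$per_barcode),
              100 * x$fraction_saturated,
              if (x$stop) "STOP recommended" else "continue"))
  invisible(x)
}

# list candidate FASTQ files of a run directory in deterministic order
list_run_fastq <- function(run_dir, layout = c("minknow", "flat")) {
  layout <- match.arg(layout)
  pats <- "\\.fastq(\\.gz)?$"
  files <- if (layout == "minknow") {
    base <- file.path(run_dir, "fastq_pass")
    if (!dir.exists(base)) base <- run_dir
    list.files(base, pattern = pats, recursive = TRUE, full.names = TRUE)
  } else {
    list.files(run_dir, pattern = pats, full.names = TRUE)
  }
  sort(files)
}

#' Offline (one-pass) processing of a run directory
#'
#' Processes every FASTQ batch file under `run_dir` once, in sorted order, and
#' returns the final state and snapshot. This is the reference the online
#' watcher must agree with bit-for-bit.
#'
#' @param run_dir run directory (MinKNOW layout `fastq_pass/barcodeNN/` or
#'   flat).
#' @param config a [monitor_config()].
#' @param layout `"minknow"` or `"flat"`.
#' @return list `(state, snapshot)`.
#' @export
process_run_offline <- function(run_dir, config, layout = "minknow") {
  state <- new_run_state(config)
  for (f in list_run_fastq(run_dir, layout)) {
    state <- process_file(state, f)
  }
  state$snapshot_index <- state$snapshot_index + 1L
  list(state = state, snapshot = run_snapshot(state))
}

process_file <- function(state, path) {
  env <- environment()
  read_fastq_batches(path, state$config$batch_size, function(batch) {
    env$state <- process_batch(env$state, batch)
    TRUE
  })
  state
}

#' Watch a run directory and process batches as they appear
#'
#' Polls `run_dir` every `poll_interval` seconds; a file is processed once it
#' is complete (size unchanged across two polls) and never reprocessed: a
#' ledger of processed file digests is persisted under `ledger_path`, so a
#' killed and restarted watcher never double-counts a batch. Unreadable files
#' are logged and retried on the next poll. A snapshot is emitted after every
#' poll that processed at least one file (and as a heartbeat otherwise when
#' `heartbeat = TRUE`).
#'
#' @param run_dir run directory.
#' @param config a [monitor_config()].
#' @param poll_interval seconds between polls.
#' @param max_polls stop after this many polls (keeps the watcher finite; use
#'   `Inf` for an open-ended run).
#' @param stop_on_decision end the watch once the run-stop rule fires.
#' @param ledger_path path of the persisted processed-file ledger.
#' @param on_snapshot callback applied to every emitted snapshot.
#' @param layout `"minknow"` or `"flat"`.
#' @param heartbeat emit snapshots on idle polls.
#' @param state resume from a previous state (restart support).
#' @return list `(state, snapshots)` with all emitted snapshots.
#' @export
watch_run <- function(run_dir, config, poll_interval = 1, max_polls = 10L,
                      stop_on_decision = FALSE,
                      ledger_path = file.path(run_dir, ".polyamp_ledger.tsv"),
                      on_snapshot = NULL, layout = "minknow",
                      heartbeat = FALSE, state = NULL) {
  state <- state %||% new_run_state(config)
  ledger <- read_ledger(ledger_path)
  sizes_prev <- NULL
  snapshots <- list()
  polls <- 0L
  while (polls < max_polls) {
    polls <- polls + 1L
    files <- list_run_fastq(run_dir, layout)
    info <- file.info(files)
    sizes <- setNames(info$size, files)
    stable <- files[!is.na(sizes) &
                      files %in% names(sizes_prev %||% numeric(0)) &
                      sizes == sizes_prev[files]]
    todo <- setdiff(stable, ledger$path)
    processed_any <- FALSE
    for (f in sort(todo)) {
      digest <- unname(tools::md5sum(f))
      if (digest %in% ledger$digest) next
      ok <- tryCatch({
        state <- process_file(state, f)
        TRUE
      }, error = function(e) {
        message(sprintf("skipping unreadable file '%s': %s (will retry)",
                        f, conditionMessage(e)))
        FALSE
      })
      if (ok) {
        ledger <- rbind(ledger, data.frame(path = f, digest = digest,
                                           stringsAsFactors = FALSE))
        write_ledger(ledger, ledger_path)
        processed_any <- TRUE
      }
    }
    sizes_prev <- sizes
    if (processed_any || heartbeat) {
      state$snapshot_index <- state$snapshot_index + 1L
      snap <- run_snapshot(state)
      snapshots[[length(snapshots) + 1L]] <- snap
      if (!is.null(on_snapshot)) on_snapshot(snap)
      if (stop_on_decision && snap$stop) break
    }
    if (polls < max_polls && poll_interval > 0) Sys.sleep(poll_interval)
  }
  list(state = state, snapshots = snapshots)
}

read_ledger <- function(path) {
  if (file.exists(path))
    read.delim(path, sep = "\t", stringsAsFactors = FALSE,
               colClasses = "character")
  else data.frame(path = character(0), digest = character(0),
                  stringsAsFactors = FALSE)
}

write_ledger <- function(ledger, path) {
  write.table(ledger, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write snapshot reports
#'
#' Writes a per-barcode status TSV and, per barcode/kingdom, a curve TSV of
#' the accumulation history (windows labelled `T0..Tk`) suitable for plotting
#' species-accumulation curves; appends a line to a run log with monotone
#' snapshot indices.
#'
#' @param snapshot a [run_snapshot()].
#' @param state the run state the snapshot came from.
#' @param out_dir output directory.
#' @return paths of the written files, invisibly.
#' @export
snapshot_report <- function(snapshot, state, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status_path <- file.path(out_dir,
                           sprintf("status_%s.tsv", snapshot$label))
  write.table(snapshot$per_barcode, status_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  curve_paths <- character(0)
  for (key in names(state$accum)) {
    a <- state$accum[[key]]
    if (a$windows_seen == 0L) next
    df <- data.frame(
      window = paste0("T", seq_len(a$windows_seen) - 1L),
      cumulative_reads = a$reads_history,
      S_obs = a$richness_history,
      chao1 = a$chao1_history)
    p <- file.path(out_dir, sprintf("curve_%s_%s.tsv", a$barcode, a$kingdom))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    curve_paths <- c(curve_paths, p)
  }
  log_path <- file.path(out_dir, "run_log.tsv")
  line <- sprintf("%d\t%s\t%g\t%.4f\t%s", snapshot$index, snapshot$label,
                  snapshot$total_reads, snapshot$fraction_saturated,
                  if (snapshot$stop) "stop" else "continue")
  if (!file.exists(log_path))
    cat("index\tlabel\ttotal_reads\tfraction_saturated\tdecision\n",
        file = log_path)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(c(status = status_path, curves = curve_paths, log = log_path))
}
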
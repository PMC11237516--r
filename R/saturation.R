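#' Species count vector
#'
#' Multiset of per-species read counts for one sample/kingdom; the unit of all
#' rarefaction and richness arithmetic.
#'
#' @param counts numeric vector of per-species counts, all > 0.
#' @return a `polyamp_counts` with fields `counts`, `n`, `S_obs`.
#' @export
count_vector <- function(counts) {
  counts <- as.numeric(counts[counts > 0])
  structure(list(counts = counts, n = sum(counts), S_obs = length(counts)),
            class = "polyamp_counts")
}

#' Analytic rarefaction
#'
#' Expected number of distinct species in a random subsample of `m` of the `n`
#' reads: `E[S(m)] = S_obs - sum_i C(n - n_i, m) / C(n, m)`, evaluated in
#' log-space (`lchoose`) for numerical stability.
#'
#' @param cv a [count_vector()].
#' @param m subsample size, `1 <= m <= n`.
#' @return expected richness (numeric scalar).
#' @export
rarefy <- function(cv, m) {
  stopifnot(inherits(cv, "polyamp_counts"))
  if (m < 1 || m > cv$n) stop("m must lie in [1, n]; use extrapolate() beyond n")
  cv$S_obs - sum(exp(lchoose(cv$n - cv$counts, m) - lchoose(cv$n, m)))
}

#' Bias-corrected Chao1 asymptotic richness
#'
#' With `f1` singletons and `f2` doubletons:
#' `S_hat = S_obs + f1 (f1 - 1) / (2 (f2 + 1))`; equals `S_obs` when `f1 = 0`.
#'
#' @param cv a [count_vector()].
#' @return estimated asymptotic richness.
#' @export
chao1 <- function(cv) {
  stopifnot(inherits(cv, "polyamp_counts"), cv$n >= 1)
  f1 <- sum(cv$counts == 1)
  f2 <- sum(cv$counts == 2)
  cv$S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Richness extrapolation beyond the observed sample
#'
#' Standard sample-size-based extrapolation anchored on Chao1:
#' `S(n + m*) = S_obs + f0 (1 - (1 - f1 / (n f0 + f1))^m*)` with
#' `f0 = chao1 - S_obs` and `m* = m - n`; returns `S_obs` when `f1 = 0`
#' (no unseen-species mass).
#'
#' @param cv a [count_vector()].
#' @param m target sample size, `m > n`.
#' @return expected richness at size `m`; bounded above by [chao1()].
#' @export
extrapolate <- function(cv, m) {
  stopifnot(inherits(cv, "polyamp_counts"))
  if (m <= cv$n) stop("m must exceed n; use rarefy() within the sample")
  f1 <- sum(cv$counts == 1)
  if (f1 == 0) return(cv$S_obs)
  f0 <- chao1(cv) - cv$S_obs
  if (f0 <= 0) return(cv$S_obs)
  mstar <- m - cv$n
  cv$S_obs + f0 * (1 - (1 - f1 / (cv$n * f0 + f1))^mstar)
}

#' Rarefaction/extrapolation curve over a size grid
#'
#' @param cv a [count_vector()].
#' @param grid increasing subsample sizes; defaults to 20 points up to `2n`.
#' @return data frame `m`, `E_S`, `extrapolated`.
#' @export
rarefaction_curve <- function(cv, grid = NULL) {
  if (is.null(grid))
    grid <- unique(round(seq(1, max(2 * cv$n, 2), length.out = 40)))
  grid <- sort(unique(grid[grid >= 1]))
  E_S <- vapply(grid, function(m)
    if (m <= cv$n) rarefy(cv, m) else extrapolate(cv, m), numeric(1))
  data.frame(m = grid, E_S = E_S, extrapolated = grid > cv$n)
}

#' Per-barcode, per-kingdom accumulation state
#'
#' Windowed history of observed richness and the Chao1 asymptote driving the
#' saturation decision; one arrival batch ("pore-scan") = one window.
#'
#' @param barcode barcode label.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @return a `polyamp_accum`.
#' @export
accumulation_state <- function(barcode, kingdom) {
  structure(list(barcode = barcode, kingdom = kingdom, windows_seen = 0L,
                 species_counts = numeric(0),
                 richness_history = numeric(0), chao1_history = numeric(0),
                 reads_history = numeric(0)),
            class = "polyamp_accum")
}

#' Fold one batch profile into an accumulation state
#'
#' Species counts are merged cumulatively; the cumulative observed richness,
#' Chao1 asymptote and read totals are appended as a new window. An empty
#' batch repeats the previous values (the window still advances).
#'
#' @param state a [accumulation_state()].
#' @param batch_profile a `polyamp_profile` for the new batch (kingdom must
#'   match), or a named count vector of species counts.
#' @return the updated state.
#' @export
update_accumulation <- function(state, batch_profile) {
  counts <- if (inherits(batch_profile, "polyamp_profile")) {
    if (!identical(batch_profile$kingdom, state$kingdom))
      stop("batch kingdom does not match accumulation state")
    batch_profile$taxon_counts
  } else batch_profile
  sc <- state$species_counts
  if (length(counts)) {
    nm <- names(counts)
    old <- match(nm, names(sc))
    hit <- !is.na(old)
    sc[old[hit]] <- sc[old[hit]] + counts[hit]
    if (any(!hit)) sc <- c(sc, counts[!hit])
  }
  state$species_counts <- sc
  cv <- count_vector(sc)
  state$windows_seen <- state$windows_seen + 1L
  state$richness_history <- c(state$richness_history, cv$S_obs)
  state$chao1_history <- c(state$chao1_history,
                           if (cv$n >= 1) chao1(cv) else 0)
  state$reads_history <- c(state$reads_history, cv$n)
  state
}

#' Saturation decision parameters
#'
#' @param window_span W consecutive windows ("pore-scans") over which gains
#'   are assessed.
#' @param min_reads minimum cumulative reads before a verdict.
#' @param epsilon_abs maximum new species over the last W windows.
#' @param epsilon_rel maximum relative Chao1 asymptote gain over the last W
#'   windows.
#' @param majority_frac fraction of eligible barcodes that must be saturated
#'   in both kingdoms before the run-stop recommendation fires.
#' @return a `polyamp_satparams`.
#' @export
saturation_params <- function(window_span = 3L, min_reads = 500L,
                              epsilon_abs = 1, epsilon_rel = 0.01,
                              majority_frac = 0.5) {
  stopifnot(window_span >= 2, majority_frac > 0, majority_frac <= 1)
  structure(list(window_span = as.integer(window_span),
                 min_reads = as.integer(min_reads),
                 epsilon_abs = epsilon_abs, epsilon_rel = epsilon_rel,
                 majority_frac = majority_frac),
            class = "polyamp_satparams")
}

#' Saturation status of one accumulation state
#'
#' `insufficient_reads` below `min_reads` cumulative reads; otherwise
#' `saturated` iff over the last `window_span` windows both the observed
#' richness gain is at most `epsilon_abs` and the relative Chao1 gain is at
#' most `epsilon_rel`; else `gaining`.
#'
#' @param state a [accumulation_state()].
#' @param params [saturation_params()].
#' @return one of `"saturated"`, `"gaining"`, `"insufficient_reads"`.
#' @export
is_saturated <- function(state, params = saturation_params()) {
  w <- state$windows_seen
  if (w == 0L || state$reads_history[w] < params$min_reads)
    return("insufficient_reads")
  if (w < params$window_span) return("gaining")
  i0 <- w - params$window_span + 1L
  dS <- state$richness_history[w] - state$richness_history[i0]
  c0 <- state$chao1_history[i0]
  dC_rel <- if (c0 > 0) (state$chao1_history[w] - c0) / c0 else 0
  if (dS <= params$epsilon_abs && dC_rel <= params$epsilon_rel)
    "saturated" else "gaining"
}

#' Run-level stop recommendation
#'
#' Eligible barcodes (controls excluded) vote: the run stops when the fraction
#' saturated in BOTH kingdoms reaches `majority_frac`. The report lists the
#' least-accumulated barcodes, the ones a run operator would watch before
#' stopping.
#'
#' @param states list of [accumulation_state()]s (both kingdoms per barcode).
#' @param params [saturation_params()].
#' @param eligible_barcodes barcodes that vote (typically subjects only).
#' @return list: `stop` (logical), `fraction_saturated`, `statuses`
#'   (data frame barcode/kingdom/status/reads), `least_accumulated` (up to 5
#'   barcodes by total reads).
#' @export
stop_recommendation <- function(states, params = saturation_params(),
                                eligible_barcodes = NULL) {
  statuses <- do.call(rbind, lapply(states, function(s) data.frame(
    barcode = s$barcode, kingdom = s$kingdom,
    status = is_saturated(s, params),
    reads = if (s$windows_seen) s$reads_history[s$windows_seen] else 0,
    stringsAsFactors = FALSE)))
  if (is.null(statuses))
    return(list(stop = FALSE, fraction_saturated = 0,
                statuses = data.frame(), least_accumulated = character(0)))
  eligible_barcodes <- eligible_barcodes %||% unique(statuses$barcode)
  el <- statuses[statuses$barcode %in% eligible_barcodes, , drop = FALSE]
  per_bc <- tapply(el$status == "saturated", el$barcode, all)
  frac <- if (length(per_bc)) mean(per_bc) else 0
  reads_bc <- tapply(el$reads, el$barcode, sum)
  least <- names(sort(reads_bc))[seq_len(min(5L, length(reads_bc)))]
  list(stop = frac >= params$majority_frac, fraction_saturated = frac,
       statuses = statuses, least_accumulated = least)
}
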
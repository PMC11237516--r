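test_that("analytic rarefaction matches closed-form and enumeration cases", {
  expect_equal(rarefy(count_vector(c(5, 3, 2)), 1), 1.0)
  # counts [2,2], m=2: enumerate all C(4,2)=6 subsamples of the 4 reads
  reads <- c("a", "a", "b", "b")
  pairs <- combn(4, 2)
  mean_distinct <- mean(apply(pairs, 2, function(ix) length(unique(reads[ix]))))
  expect_equal(rarefy(count_vector(c(2, 2)), 2), mean_distinct)
  expect_equal(mean_distinct, 5 / 3)
  cv <- count_vector(c(7, 3, 1, 1))
  expect_equal(rarefy(cv, cv$n), cv$S_obs)
  expect_error(rarefy(cv, cv$n + 1), "extrapolate")
})

test_that("rarefaction agrees with vegan and with Monte-Carlo subsampling", {
  skip_if_not_installed("vegan")
  set.seed(71)
  for (i in 1:20) {
    S <- sample(3:12, 1)
    counts <- sample(1:25, S, replace = TRUE)
    cv <- count_vector(counts)
    if (cv$n > 200) counts <- pmax(1, counts %/% 2)
    cv <- count_vector(counts)
    m <- sample(seq_len(cv$n), 1)
    # independent implementation oracle
    expect_equal(rarefy(cv, m),
                 as.numeric(suppressWarnings(vegan::rarefy(counts, m))),
                 tolerance = 1e-8)
    # Monte-Carlo oracle (epsilon absorbs float error when all draws agree)
    pool <- rep(seq_along(counts), counts)
    reps <- 10000L
    draws <- vapply(seq_len(reps), function(j)
      length(unique(sample(pool, m))), integer(1))
    se <- sd(draws) / sqrt(reps)
    expect_lt(abs(rarefy(cv, m) - mean(draws)), 3 * se + 1e-6)
  }
})

test_that("rarefaction curves are non-decreasing and concave in m", {
  set.seed(5)
  for (i in 1:10) {
    counts <- sample(1:20, sample(3:10, 1), replace = TRUE)
    cv <- count_vector(counts)
    es <- vapply(seq_len(cv$n), function(m) rarefy(cv, m), numeric(1))
    expect_true(all(diff(es) >= -1e-10))
    if (cv$n >= 3) expect_true(all(diff(diff(es)) <= 1e-10))
    expect_equal(es[1], 1.0)
  }
})

test_that("chao1 follows the bias-corrected singleton/doubleton formula", {
  expect_equal(chao1(count_vector(c(3, 3, 3))), 3)
  expect_equal(chao1(count_vector(c(1, 1, 2))), 3 + 2 * 1 / (2 * 2))
  expect_equal(chao1(count_vector(1)), 1)
  # direct arithmetic oracle on random vectors
  set.seed(9)
  for (i in 1:10) {
    counts <- sample(1:6, sample(3:20, 1), replace = TRUE)
    f1 <- sum(counts == 1); f2 <- sum(counts == 2)
    expect_equal(chao1(count_vector(counts)),
                 length(counts) + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
})

test_that("extrapolation is anchored at S_obs, bounded by chao1, and exact", {
  cv <- count_vector(c(1, 1, 2))
  # closed-form oracle at m = 2n
  f1 <- 2; f0 <- chao1(cv) - cv$S_obs
  want <- cv$S_obs + f0 * (1 - (1 - f1 / (cv$n * f0 + f1))^cv$n)
  expect_equal(extrapolate(cv, 2 * cv$n), want)
  # no singletons -> flat curve
  cv0 <- count_vector(c(2, 3, 4))
  expect_equal(extrapolate(cv0, 100), cv0$S_obs)
  # m -> infinity approaches the chao1 asymptote
  expect_equal(extrapolate(cv, 10^7), chao1(cv), tolerance = 1e-6)
  # continuity at m = n
  expect_lt(abs(extrapolate(cv, cv$n + 1) - cv$S_obs), f0 + 1e-9)
  set.seed(2)
  for (i in 1:10) {
    cvr <- count_vector(sample(1:5, 8, replace = TRUE))
    ms <- cvr$n + c(1, 10, 100)
    vals <- vapply(ms, function(m) extrapolate(cvr, m), numeric(1))
    expect_true(all(vals <= chao1(cvr) + 1e-9))
    expect_true(all(diff(vals) >= -1e-10))
    expect_error(extrapolate(cvr, cvr$n), "exceed")
  }
})

test_that("accumulation updates are cumulative and order-independent", {
  st <- accumulation_state("barcode01", "bacteria")
  st <- update_accumulation(st, c(spA = 2, spB = 1, spC = 4))
  st <- update_accumulation(st, c(spD = 1, spE = 2))
  expect_equal(st$richness_history, c(3, 5))
  expect_equal(st$reads_history, c(7, 10))
  # empty batch repeats the last values
  st <- update_accumulation(st, setNames(numeric(0), character(0)))
  expect_equal(st$windows_seen, 3L)
  expect_equal(st$richness_history[3], 5)
  expect_equal(st$reads_history[3], 10)
  # order independence of the final pooled state
  set.seed(14)
  batches <- lapply(1:6, function(i) {
    n <- sample(0:5, 1)
    if (n == 0) return(setNames(numeric(0), character(0)))
    setNames(sample(1:4, n, replace = TRUE), sample(letters[1:8], n))
  })
  pool_state <- function(bs) {
    s <- accumulation_state("x", "fungi")
    for (b in bs) s <- update_accumulation(s, b)
    sort_counts <- s$species_counts[order(names(s$species_counts))]
    list(counts = sort_counts, final_S = tail(s$richness_history, 1))
  }
  a <- pool_state(batches)
  b <- pool_state(rev(batches))
  expect_equal(a$counts, b$counts)
  expect_equal(a$final_S, b$final_S)
})

test_that("saturation statuses follow the windowed decision rule", {
  params <- saturation_params(window_span = 3, min_reads = 100,
                              epsilon_abs = 1, epsilon_rel = 0.01)
  mk_state <- function(S, reads, chao = S) {
    st <- accumulation_state("b", "bacteria")
    st$windows_seen <- length(S)
    st$richness_history <- S; st$chao1_history <- chao
    st$reads_history <- reads
    st
  }
  expect_equal(is_saturated(mk_state(c(40, 40, 40, 40), c(200, 400, 600, 800)),
                            params), "saturated")
  expect_equal(is_saturated(mk_state(c(10, 18, 30), c(200, 400, 600)), params),
               "gaining")
  expect_equal(is_saturated(mk_state(c(40, 40, 40), c(10, 50, 90)), params),
               "insufficient_reads")
  # fewer windows than the span cannot be judged saturated
  expect_equal(is_saturated(mk_state(c(40, 40), c(300, 600)), params), "gaining")
})

test_that("a frozen community saturates and never reverts as batches stream", {
  set.seed(50)
  S_true <- 50
  ab <- rlnorm(S_true, 0, 1); ab <- ab / sum(ab)
  st <- accumulation_state("barcode01", "bacteria")
  params <- saturation_params()
  statuses <- character(0)
  for (w in 1:12) {
    draws <- table(sample.int(S_true, 4000, replace = TRUE, prob = ab))
    st <- update_accumulation(st, setNames(as.numeric(draws),
                                           paste0("sp", names(draws))))
    statuses <- c(statuses, is_saturated(st, params))
  }
  expect_true("saturated" %in% statuses)
  first_sat <- min(which(statuses == "saturated"))
  expect_true(all(statuses[first_sat:length(statuses)] == "saturated"))
  expect_true(statuses[1] %in% c("gaining", "insufficient_reads"))
})

test_that("stop decision fires exactly at the majority fraction", {
  params <- saturation_params(majority_frac = 0.5, min_reads = 10)
  mk <- function(bc, kingdom, sat) {
    st <- accumulation_state(bc, kingdom)
    S <- if (sat) c(20, 20, 20) else c(5, 15, 25)
    st$windows_seen <- 3L
    st$richness_history <- S
    st$chao1_history <- S
    st$reads_history <- c(400, 800, 1200)
    st
  }
  # 93 subjects, 47 saturated in both kingdoms: 47/93 = 0.505 >= 0.5 -> stop
  bcs <- sprintf("barcode%02d", 1:93)
  states <- list()
  for (i in seq_along(bcs)) {
    sat <- i <= 47
    states[[length(states) + 1]] <- mk(bcs[i], "bacteria", sat)
    states[[length(states) + 1]] <- mk(bcs[i], "fungi", sat)
  }
  dec <- stop_recommendation(states, params, eligible_barcodes = bcs)
  expect_true(dec$stop)
  expect_equal(dec$fraction_saturated, 47 / 93)
  # 46/93 < 0.5 -> continue
  states2 <- states
  states2[[93]] <- mk(bcs[47], "bacteria", FALSE)  # barcode47 bacteria gaining
  dec2 <- stop_recommendation(states2, params, eligible_barcodes = bcs)
  expect_false(dec2$stop)
  # all insufficient -> continue
  st0 <- accumulation_state("barcode01", "bacteria")
  st0 <- update_accumulation(st0, c(a = 1))
  dec3 <- stop_recommendation(list(st0), params,
                              eligible_barcodes = "barcode01")
  expect_false(dec3$stop)
  # strict unanimity blocks on a single gaining barcode
  params4 <- saturation_params(majority_frac = 1, min_reads = 10)
  dec4 <- stop_recommendation(states2, params4, eligible_barcodes = bcs)
  expect_false(dec4$stop)
})
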
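test_that("tag binning places fragment midpoints in the right windows", {
  g <- genome_model(c(chrA = 1500L))
  cfg <- caller_config()
  # + tag at start 0: midpoint 100 -> window 0
  wc <- bin_reads(lib_at(0L), g, cfg)
  expect_equal(wc$counts$chrA, c(1L, rep(0L, 9L)))
  # + tag at start 60: midpoint 160 -> window 1
  wc <- bin_reads(lib_at(60L), g, cfg)
  expect_equal(wc$counts$chrA, c(0L, 1L, rep(0L, 8L)))
  # - tag ending at 160: shifted point 60 -> window 0
  gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(111L, 160L),
                               strand = "-")
  wc <- bin_reads(read_library(gr), g, cfg)
  expect_equal(which(wc$counts$chrA == 1L), 1L)
  # lambda definition
  expect_equal(wc$lambda, 1 * 150 / (0.793 * 1500))
})

test_that("window sums match a per-tag counting oracle on random tags", {
  set.seed(5)
  g <- genome_model(c(chrA = 60000L, chrB = 45000L))
  n <- 10000L
  chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
  start0 <- floor(runif(n, 0, ifelse(chrom == "chrA", 59000, 44000)))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  lib <- read_library(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start0 + 1L, start0 + 120L), strand = strand))
  cfg <- caller_config()
  wc <- bin_reads(lib, g, cfg)
  expect_equal(sum(unlist(wc$counts)), n)  # tag conservation
  # oracle: count per window by explicit per-tag arithmetic
  for (cn in c("chrA", "chrB")) {
    sel <- chrom == cn
    pos <- ifelse(strand[sel] == "+", start0[sel] + 100L,
                  start0[sel] + 120L - 100L)
    pos <- pmin(pmax(pos, 0), g$chrom_sizes[[cn]] - 1L)
    oracle <- tabulate(pos %/% 150L + 1L,
                       nbins = ceiling(g$chrom_sizes[[cn]] / 150))
    expect_equal(wc$counts[[cn]], oracle)
  }
})

test_that("eligibility threshold matches an exhaustive Poisson tail scan", {
  expect_equal(eligibility_threshold(1e-9, 0.2), 1L)  # any tag surprising
  expect_equal(eligibility_threshold(2, 1), 0L)       # all eligible
  for (lambda in c(0.1, 0.5, 1, 2, 5, 20)) {
    for (p in c(0.5, 0.2, 0.05, 0.001)) {
      expect_equal(eligibility_threshold(lambda, p),
                   eligibility_oracle(lambda, p),
                   info = sprintf("lambda=%g p=%g", lambda, p))
    }
  }
  expect_error(eligibility_threshold(0, 0.2), "positive")
})

test_that("island finding equals an independent linear-scan oracle", {
  make_wc <- function(counts, lambda, w = 150L) {
    structure(list(counts = list(chrA = counts), window_size = w,
                   total_tags = sum(counts),
                   effective_length = sum(counts) * w / lambda,
                   lambda = lambda),
              class = "WindowCounts")
  }
  lambda <- 1.2
  l0 <- eligibility_threshold(lambda, 0.2)

  # no eligible windows -> empty set
  wc <- make_wc(rep(0L, 20L), lambda)
  expect_length(find_islands(wc, caller_config()), 0L)

  # isolated eligible window: single-window identity
  counts <- rep(0L, 20L); counts[8L] <- 9L
  isl <- find_islands(make_wc(counts, lambda), caller_config())
  expect_length(isl, 1L)
  expect_equal(GenomicRanges::start(isl), 7L * 150L + 1L)
  expect_equal(GenomicRanges::end(isl), 8L * 150L)
  expect_equal(isl$score, -dpois(9L, lambda, log = TRUE))
  expect_equal(isl$tag_count, 9L)

  # random counts, gap 0 and gap 2, against the scan oracle
  set.seed(23)
  for (rep_i in 1:20) {
    counts <- rpois(80L, lambda) + rbinom(80L, 1L, 0.1) * rpois(80L, 6)
    for (gap in c(0L, 2L)) {
      cfg <- caller_config(gap_size = gap)
      isl <- find_islands(make_wc(counts, lambda), cfg)
      orc <- island_scan_oracle(counts, lambda, l0, gap)
      if (is.null(orc)) {
        expect_length(isl, 0L)
      } else {
        expect_equal(length(isl), nrow(orc))
        expect_equal(GenomicRanges::start(isl), (orc$first - 1L) * 150L + 1L)
        expect_equal(GenomicRanges::end(isl), orc$last * 150L)
        expect_equal(isl$score, orc$score)
        expect_equal(isl$tag_count, orc$tag_count)
      }
    }
  }
})

test_that("score threshold: trivial regimes and recursion/Monte-Carlo accord", {
  cfg_inf <- caller_config()
  cfg_inf$e_value <- Inf
  expect_equal(as.numeric(calibrate_score_threshold(cfg_inf, 1, 1000L)), 0)

  # no window ever eligible -> empty null -> threshold 0 (with a warning
  # that the threshold is vacuous)
  cfg0 <- caller_config(eligibility_p = 1e-300)
  expect_warning(s0 <- calibrate_score_threshold(cfg0, 1, 1000L),
                 "threshold is 0")
  expect_equal(as.numeric(s0), 0)

  # lambda = 1, 1e5 windows, E = 1: recursion vs 500-replicate Monte Carlo
  cfg_r <- caller_config(e_value = 1)
  cfg_m <- caller_config(e_value = 1, null_method = "monte_carlo",
                         mc_replicates = 500L, seed = 99L)
  s_rec <- calibrate_score_threshold(cfg_r, 1, 1e5)
  s_mc <- calibrate_score_threshold(cfg_m, 1, 1e5)
  ef <- attr(s_rec, "expected_fn")
  mc_scores <- attr(s_mc, "mc_scores")
  # the two nulls agree: Monte-Carlo island counts above either threshold
  # match the recursion's expected counts within sampling error
  for (s in c(as.numeric(s_rec), as.numeric(s_mc))) {
    mc_count <- sum(mc_scores >= s) / 500
    expect_lt(abs(mc_count - ef(s)), 0.25)
  }
  expect_lte(ef(as.numeric(s_rec)), 1)
})

test_that("no-input calling handles empty and extreme-signal libraries", {
  g <- genome_model(c(chrA = 150000L))
  empty <- read_library(GenomicRanges::GRanges())
  expect_length(call_islands_no_input(empty, g, caller_config()), 0L)

  # all tags in one window at ~50x lambda: exactly one island
  lib <- lib_at(1200L + 0:49, width = 10L)
  isl <- call_islands_no_input(lib, g, caller_config(e_value = 0.1))
  expect_length(isl, 1L)
  expect_equal(isl$tag_count, 50L)
})

test_that("with-input mode: null self-comparison and BH q-value ordering", {
  g <- genome_model(c(chrA = 300000L))
  expect_error(
    call_islands_with_input(lib_at(0L), read_library(GenomicRanges::GRanges()),
                            g, caller_config()),
    "non-empty input")

  # identical IP and input: nothing should reach q <= 0.05
  n_called <- vapply(1:8, function(seed) {
    set.seed(seed)
    start0 <- floor(runif(4000L, 0, 299000))
    lib <- read_library(GenomicRanges::GRanges(
      "chrA", IRanges::IRanges(start0 + 1L, start0 + 100L), strand = "+"))
    cfg <- caller_config(fdr = 0.05)
    length(call_islands_with_input(lib, lib, g, cfg))
  }, 0L)
  expect_true(mean(n_called == 0L) >= 0.95)

  # strong contrast: zero input tags in the island span, large IP count
  ip <- lib_at(c(1200L + 0:59, seq(10000L, 290000L, by = 500L)), width = 10L)
  input <- lib_at(seq(5L, 299000L, by = 150L), width = 10L)
  isl <- call_islands_with_input(ip, input, g, caller_config(fdr = 1e-5))
  expect_gte(length(isl), 1L)
  expect_true(any(isl$tag_count >= 50L))

  # BH: q-values sorted by ascending p are non-decreasing
  cand <- call_islands_with_input(ip, input, g, caller_config(fdr = 0.999))
  if (length(cand) > 1L) {
    ord <- order(cand$pvalue)
    expect_true(all(diff(cand$significance[ord]) >= -1e-12))
  }
})

test_that("adjacent islands merge at one-window gaps, idempotently", {
  mk <- function(s0, e0) {
    gr <- GenomicRanges::GRanges("chrA",
                                 IRanges::IRanges(s0 + 1L, e0))
    gr$score <- rep(1, length(gr))
    gr$tag_count <- rep(5L, length(gr))
    gr
  }
  # gap of exactly one window (150 bp) merges
  m <- merge_adjacent(mk(c(0L, 300L), c(150L, 450L)), caller_config())
  expect_length(m, 1L)
  expect_equal(GenomicRanges::start(m), 1L)
  expect_equal(GenomicRanges::end(m), 450L)
  expect_equal(m$score, 2)
  expect_equal(m$tag_count, 10L)

  # gap of two windows does not merge
  m2 <- merge_adjacent(mk(c(0L, 450L), c(150L, 600L)), caller_config())
  expect_length(m2, 2L)

  # idempotence on random island sets
  set.seed(77)
  for (i in 1:10) {
    s0 <- sort(sample.int(30000L, 40L)) * 10L
    gr <- mk(s0, s0 + sample(c(150L, 300L, 450L), 40L, replace = TRUE))
    m1 <- merge_adjacent(gr, caller_config())
    m2 <- merge_adjacent(m1, caller_config())
    expect_equal(GenomicRanges::start(m1), GenomicRanges::start(m2))
    expect_equal(GenomicRanges::end(m1), GenomicRanges::end(m2))
    expect_equal(m1$score, m2$score)
  }
})

test_that("relaxing the E-value never loses island coverage", {
  sim <- tiny_sim(seed = 19L)
  g <- generate_genome(sim)
  tr <- plant_origins(g, sim)
  libs <- simulate_libraries(g, tr, sim)
  strict <- call_islands_no_input(libs$IP_B, g, caller_config(e_value = 1e-5))
  relaxed <- call_islands_no_input(libs$IP_B, g, caller_config(e_value = 0.1))
  # every base called at the strict threshold is called at the relaxed one
  lost <- GenomicRanges::setdiff(oriscan:::granges_only(strict),
                                 oriscan:::granges_only(relaxed))
  expect_length(lost, 0L)
  expect_gte(length(relaxed), length(strict))
})
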
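test_that("genome generation is deterministic and honours degenerate configs", {
  sim <- tiny_sim(seed = 3L)
  g1 <- generate_genome(sim)
  g2 <- generate_genome(sim)
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))
  expect_identical(get_track(g1, "genes"), get_track(g2, "genes"))
  expect_identical(get_track(g1, "timing"), get_track(g2, "timing"))

  # byte-identical FASTA for the same seed
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  Biostrings::writeXStringSet(g1$sequence, p1)
  Biostrings::writeXStringSet(g2$sequence, p2)
  expect_identical(readLines(p1), readLines(p2))

  # no genes: empty gene track, timing still tiles every chromosome
  sim0 <- tiny_sim(seed = 3L, n_genes = 0L, n_origins = 0L)
  g0 <- generate_genome(sim0)
  expect_length(get_track(g0, "genes"), 0L)
  timing <- get_track(g0, "timing")
  for (cn in names(g0$chrom_sizes)) {
    cov <- GenomicRanges::reduce(timing[
      as.character(GenomicRanges::seqnames(timing)) == cn])
    expect_equal(sum(GenomicRanges::width(cov)), g0$chrom_sizes[[cn]])
  }

  # every gene has a TSS; exons exist
  expect_equal(length(get_track(g1, "tss")), length(get_track(g1, "genes")))
  expect_gt(length(get_track(g1, "exons")), 0L)
})

test_that("planted G4 motifs are recovered by the scanner", {
  sim <- tiny_sim(seed = 5L)
  g <- generate_genome(sim)
  planted <- get_track(g, "g4")
  expect_gt(length(planted), 0L)
  found <- scan_g4(g$sequence)
  hits <- IRanges::overlapsAny(planted, found, ignore.strand = TRUE)
  expect_true(all(hits))
  # every planted motif is fully covered by a reported motif (a planted
  # motif can be subsumed by a longer chain when nearby G runs extend it)
  within <- GenomicRanges::findOverlaps(planted, found, type = "within",
                                        ignore.strand = TRUE)
  expect_equal(length(unique(S4Vectors::queryHits(within))), length(planted))
})

test_that("origin planting respects boundary fractions and binomial targets", {
  # every origin within a TSS window
  sim1 <- tiny_sim(seed = 13L, frac_origins_at_tss = 1, n_origins = 25L)
  g1 <- generate_genome(sim1)
  t1 <- plant_origins(g1, sim1)
  expect_true(all(t1$origins$at_tss))
  tssw <- oriscan:::tss_window(get_track(g1, "tss"), sim1$tss_halfwidth)
  expect_true(all(IRanges::overlapsAny(t1$origins, tssw,
                                       ignore.strand = TRUE)))

  # no origin in S1/S2
  sim2 <- tiny_sim(seed = 13L, frac_origins_early = 0)
  g2 <- generate_genome(sim2)
  t2 <- plant_origins(g2, sim2)
  timing <- get_track(g2, "timing")
  early <- timing[names(timing) %in% c("S1", "S2")]
  expect_false(any(IRanges::overlapsAny(t2$origins, early,
                                        ignore.strand = TRUE)))

  # 1000 origins at frac 0.5: observed fraction within 3 binomial SD
  sim3 <- sim_config(n_chromosomes = 4L, chrom_length = 2e6,
                     n_genes = 1200L, n_origins = 1000L,
                     gene_length_range = c(1000L, 3000L),
                     frac_origins_at_tss = 0.5, with_sequence = FALSE,
                     timing_block = 150000L, timing_overlap = 7000L,
                     seed = 29L)
  g3 <- generate_genome(sim3)
  t3 <- plant_origins(g3, sim3)
  obs <- mean(t3$origins$at_tss)
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / 1000))
  obs_early <- mean(t3$origins$timing_class %in% c("S1", "S2"))
  expect_lt(abs(obs_early - 0.75), 3 * sqrt(0.75 * 0.25 / 1000) + 0.02)

  # germline origins all emit a positive jump at their position
  germ <- t3$origins[t3$origins$germline]
  expect_gt(length(germ), 0L)
  plus_jumps <- t3$jumps[GenomicRanges::strand(t3$jumps) == "+"]
  expect_true(all(GenomicRanges::start(germ) %in%
                  GenomicRanges::start(plus_jumps)))

  # clusters: some origin pairs closer than 5 kb
  d <- inter_origin_distances(oriscan:::granges_only(t3$origins), 5000L)
  expect_gt(fraction_short_distances(d), 0.05)

  # error when demanding more TSS origins than TSS exist
  sim_err <- tiny_sim(seed = 1L, n_genes = 5L, n_origins = 50L,
                      frac_origins_at_tss = 1, cluster_fraction = 0)
  g_err <- generate_genome(sim_err)
  expect_error(plant_origins(g_err, sim_err), "placement")
})

test_that("library simulation: empty-signal case and support bound", {
  # no firing, no background: empty IP libraries, input still uniform
  sim <- tiny_sim(seed = 17L, firing_probability = 0,
                  s_phase_background_fraction = 0)
  g <- generate_genome(sim)
  tr <- plant_origins(g, sim)
  libs <- simulate_libraries(g, tr, sim)
  expect_equal(total_tags(libs$IP_A), 0L)
  expect_equal(total_tags(libs$IP_B), 0L)
  expect_equal(total_tags(libs$input), sim$reads_input)

  # single certain origin, no background: every fragment midpoint within
  # labelling_time * (rate_mean + 4 sd) of the origin
  sim1 <- tiny_sim(seed = 21L, n_origins = 1L, firing_probability = 1,
                   s_phase_background_fraction = 0, cluster_fraction = 0,
                   reads_ip = 5000L)
  g1 <- generate_genome(sim1)
  t1 <- plant_origins(g1, sim1)
  libs1 <- simulate_libraries(g1, t1, sim1)
  reach <- sim1$labelling_time * (sim1$fork_rate_mean + 4 * sim1$fork_rate_sd)
  opos <- GenomicRanges::start(t1$origins)
  ochr <- as.character(GenomicRanges::seqnames(t1$origins))
  tags <- libs1$IP_B$tags
  same <- as.character(GenomicRanges::seqnames(tags)) == ochr
  expect_true(all(same))
  mids <- (GenomicRanges::start(tags) + GenomicRanges::end(tags)) / 2
  expect_true(all(abs(mids - opos) <= reach + sim1$fragment_max / 2 + 1))
})

test_that("fragment distances from the origin match a Monte-Carlo oracle", {
  sim <- sim_config(n_chromosomes = 1L, chrom_length = 2e6, n_genes = 10L,
                    n_origins = 1L, firing_probability = 1,
                    s_phase_background_fraction = 0, cluster_fraction = 0,
                    frac_origins_at_tss = 0, frac_origins_early = 1,
                    n_nuclei = 400L, reads_ip = 40000L,
                    reads_input = 100L, with_sequence = FALSE,
                    timing_block = 1000000L, seed = 31L)
  g <- generate_genome(sim)
  # one certain origin at the chromosome centre, so tracts never clip
  o <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 1e6))
  o$firing_probability <- 1
  tr <- oriscan:::new_truth(o, GenomicRanges::GRanges())
  libs <- simulate_libraries(g, tr, sim)
  tags <- libs$IP_B$tags
  mids <- (GenomicRanges::start(tags) + GenomicRanges::end(tags)) / 2
  emp <- mean(abs(mids - GenomicRanges::start(tr$origins)))

  # oracle: direct draws of (t, rate_left, rate_right); fragments sample
  # tracts proportionally to length, midpoint uniform within the tract
  set.seed(101)
  K <- 1e5
  t <- runif(K, 0, sim$max_lag)
  draw_rate <- function(n) {
    r <- rnorm(n, sim$fork_rate_mean, sim$fork_rate_sd)
    while (any(r < 1)) r[r < 1] <- rnorm(sum(r < 1), sim$fork_rate_mean,
                                         sim$fork_rate_sd)
    r
  }
  ll <- (sim$labelling_time - t) * draw_rate(K)
  lr <- (sim$labelling_time - t) * draw_rate(K)
  # E|mid - origin| for a uniform midpoint on [-ll, lr] is
  # (ll^2 + lr^2) / (2 (ll + lr)); weight tracts by total length
  oracle <- sum((ll^2 + lr^2) / 2) / sum(ll + lr)
  expect_lt(abs(emp - oracle) / oracle, 0.05)
})

test_that("replicate A receives the configured fraction of B's depth", {
  sim <- tiny_sim(seed = 37L)
  g <- generate_genome(sim)
  tr <- plant_origins(g, sim)
  libs <- simulate_libraries(g, tr, sim)
  expect_equal(total_tags(libs$IP_A) / total_tags(libs$IP_B), 0.5,
               tolerance = 0.01)
  # same seed twice: identical libraries
  libs2 <- simulate_libraries(g, tr, sim)
  expect_identical(GenomicRanges::start(libs$IP_B$tags),
                   GenomicRanges::start(libs2$IP_B$tags))
})

test_that("IP read density at efficient origins is strongly enriched", {
  sim <- tiny_sim(seed = 41L)
  g <- generate_genome(sim)
  tr <- plant_origins(g, sim)
  libs <- simulate_libraries(g, tr, sim)
  eff <- tr$origins[tr$origins$firing_probability >= 0.3]
  win <- oriscan:::tss_window(oriscan:::granges_only(eff), 1000L)
  n_near <- sum(IRanges::overlapsAny(libs$IP_B$tags, win,
                                     ignore.strand = TRUE))
  density_near <- n_near / sum(GenomicRanges::width(win))
  density_genome <- total_tags(libs$IP_B) / sum(g$chrom_sizes)
  expect_gte(density_near / density_genome, 5)
})

test_that("input library is uniform: chi-squared flat across 10 kb bins", {
  flat <- vapply(1:20, function(seed) {
    sim <- tiny_sim(seed = seed, reads_ip = 1000L, reads_input = 20000L)
    g <- generate_genome(sim)
    tr <- plant_origins(g, sim)
    libs <- simulate_libraries(g, tr, sim)
    tags <- libs$input$tags
    mids <- (GenomicRanges::start(tags) + GenomicRanges::end(tags)) %/% 2L
    bin <- paste(as.character(GenomicRanges::seqnames(tags)),
                 mids %/% 10000L)
    n_bins <- sum(g$chrom_sizes) / 10000
    counts <- tabulate(factor(bin, levels = unique(bin)))
    counts <- c(counts, rep(0L, n_bins - length(counts)))
    suppressWarnings(chisq.test(counts)$p.value) > 0.01
  }, NA)
  expect_gte(mean(flat), 0.95)
})

test_that("truth tables round-trip through BED", {
  sim <- tiny_sim(seed = 43L)
  g <- generate_genome(sim)
  tr <- plant_origins(g, sim)
  dir <- withr::local_tempdir()
  write_truth(tr, dir)
  back <- read_truth(dir, genome = g)
  orig <- oriscan:::sort_by_genome(tr$origins)
  expect_equal(GenomicRanges::start(back$origins),
               GenomicRanges::start(orig))
  expect_equal(back$origins$timing_class, orig$timing_class)
  expect_equal(back$origins$germline, orig$germline)
  expect_equal(GenomicRanges::start(back$jumps),
               GenomicRanges::start(oriscan:::sort_by_genome(tr$jumps)))
  expect_equal(as.character(GenomicRanges::strand(back$jumps)),
               as.character(GenomicRanges::strand(
                 oriscan:::sort_by_genome(tr$jumps))))

  # empty truth still writes valid (empty) files
  empty <- oriscan:::new_truth(GenomicRanges::GRanges(),
                               GenomicRanges::GRanges())
  dir2 <- withr::local_tempdir()
  write_truth(empty, dir2)
  expect_length(read_truth(dir2)$origins, 0L)

  # line-level re-parse: sorted, non-negative, within chromosome bounds
  lines <- readLines(file.path(dir, "origins.bed"))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ch <- vapply(f, `[[`, "", 1L)
  s0 <- as.numeric(vapply(f, `[[`, "", 2L))
  e0 <- as.numeric(vapply(f, `[[`, "", 3L))
  expect_true(all(s0 >= 0))
  expect_true(all(e0 <= g$chrom_sizes[ch]))
  expect_true(all(tapply(s0, ch, function(x) all(diff(x) >= 0))))
})
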
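## Broad-enrichment island calling against a Poisson background, in the
## SICER tradition: fixed non-overlapping windows, Poisson-eligible windows,
## islands as gap-tolerant runs of eligible windows, and a genome-wide
## E-value (expected background islands) or input-normalised FDR control.

#' Island caller configuration
#'
#' Defaults follow the published nascent-strand calling setup: 150 bp
#' windows, gap size 0, 200 bp fragment shift, effective genome fraction
#' 0.793, redundancy threshold 1, and E-value / FDR thresholds of 1e-5.
#'
#' @param window_size window width in bp.
#' @param gap_size maximum number of ineligible windows allowed inside an
#'   island.
#' @param fragment_size library fragment size in bp; each tag is shifted to
#'   its fragment midpoint before binning.
#' @param effective_genome_fraction mappable fraction of the genome, used to
#'   scale the Poisson background rate.
#' @param redundancy_threshold maximum retained tags per (chrom, start,
#'   strand).
#' @param e_value expected number of background islands tolerated genome-wide
#'   (no-input mode).
#' @param fdr Benjamini--Hochberg q-value threshold (with-input mode).
#' @param eligibility_p Poisson upper-tail probability below which a window
#'   count makes the window island-eligible.
#' @param null_method `"recursion"` (dynamic programming over the island
#'   score null) or `"monte_carlo"` (simulated background genomes).
#' @param mc_replicates number of simulated genomes for the Monte-Carlo null.
#' @param seed optional integer seed for the Monte-Carlo null.
#' @return A list of class `CallerConfig`.
#' @export
caller_config <- function(window_size = 150L, gap_size = 0L,
                          fragment_size = 200L,
                          effective_genome_fraction = 0.793,
                          redundancy_threshold = 1L,
                          e_value = 1e-5, fdr = 1e-5,
                          eligibility_p = 0.2,
                          null_method = c("recursion", "monte_carlo"),
                          mc_replicates = 500L, seed = NULL) {
  null_method <- match.arg(null_method)
  stopifnot(window_size > 0, gap_size >= 0, fragment_size >= 0,
            effective_genome_fraction > 0, effective_genome_fraction <= 1,
            redundancy_threshold >= 1, e_value > 0,
            fdr > 0, fdr < 1, eligibility_p > 0,
            mc_replicates >= 1)
  structure(list(window_size = as.integer(window_size),
                 gap_size = as.integer(gap_size),
                 fragment_size = as.integer(fragment_size),
                 effective_genome_fraction = effective_genome_fraction,
                 redundancy_threshold = as.integer(redundancy_threshold),
                 e_value = e_value, fdr = fdr,
                 eligibility_p = eligibility_p,
                 null_method = null_method,
                 mc_replicates = as.integer(mc_replicates),
                 seed = seed),
            class = "CallerConfig")
}

#' Bin read tags into fixed windows
#'
#' Each tag contributes one count to the window containing its inferred
#' fragment midpoint: `start + fragment_size/2` for + tags, `end -
#' fragment_size/2` for - tags, the tag midpoint for unstranded tags, all in
#' 0-based coordinates and clipped into the chromosome. Windows are anchored
#' at coordinate 0; the trailing partial window is kept.
#'
#' @param lib a deduplicated `ReadLibrary`.
#' @param genome a `GenomeModel`.
#' @param cfg a `CallerConfig`.
#' @return An object of class `WindowCounts`: per-chromosome count vectors,
#'   the total tag count, the effective genome length and the background
#'   rate `lambda` (expected tags per window).
#' @export
bin_reads <- function(lib, genome, cfg = caller_config()) {
  stopifnot(inherits(lib, "ReadLibrary"), inherits(genome, "GenomeModel"))
  w <- cfg$window_size
  shift <- cfg$fragment_size %/% 2L
  gr <- lib$tags
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  bed_start <- BiocGenerics::start(gr) - 1L
  bed_end <- BiocGenerics::end(gr)
  str <- as.character(BiocGenerics::strand(gr))
  pos <- ifelse(str == "-", bed_end - shift,
         ifelse(str == "+", bed_start + shift,
                (bed_start + bed_end) %/% 2L))
  counts <- lapply(names(genome$chrom_sizes), function(cn) {
    L <- genome$chrom_sizes[[cn]]
    nw <- as.integer(ceiling(L / w))
    p <- pos[chr == cn]
    p <- pmin(pmax(p, 0), L - 1L)
    tabulate(p %/% w + 1L, nbins = nw)
  })
  names(counts) <- names(genome$chrom_sizes)
  total <- length(gr)
  eff_len <- cfg$effective_genome_fraction * sum(genome$chrom_sizes)
  structure(list(counts = counts, window_size = w, total_tags = total,
                 effective_length = eff_len,
                 lambda = total * w / eff_len),
            class = "WindowCounts")
}

#' @export
print.WindowCounts <- function(x, ...) {
  cat(sprintf("WindowCounts: %d tags in %d bp windows, lambda = %.4g\n",
              x$total_tags, x$window_size, x$lambda))
  invisible(x)
}

#' Minimum eligible window count
#'
#' The smallest integer count whose Poisson upper-tail probability under the
#' background rate falls below `eligibility_p`; windows with at least this
#' many tags are island-eligible.
#'
#' @param lambda background rate (expected tags per window), > 0.
#' @param eligibility_p tail probability cut-off; `>= 1` makes every window
#'   eligible (returns 0).
#' @return Integer threshold `l0`.
#' @export
eligibility_threshold <- function(lambda, eligibility_p = 0.2) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  if (eligibility_p >= 1) return(0L)
  l0 <- 0L
  ## P(X >= l0) = 1 - ppois(l0 - 1, lambda)
  while (stats::ppois(l0 - 1L, lambda, lower.tail = FALSE) >= eligibility_p)
    l0 <- l0 + 1L
  l0
}

## Core run finder on a single chromosome's counts.  Returns a data.frame of
## islands (first/last window index, score, tag_count over eligible member
## windows).  Gaps of <= gap_size ineligible windows are internal.
island_runs <- function(counts, lambda, l0, gap_size = 0L) {
  eligible <- counts >= l0
  idx <- which(eligible)
  if (!length(idx))
    return(data.frame(first = integer(), last = integer(),
                      score = numeric(), tag_count = integer()))
  grp <- cumsum(c(TRUE, diff(idx) - 1L > gap_size))
  contrib <- -stats::dpois(counts[idx], lambda, log = TRUE)
  data.frame(
    first = tapply(idx, grp, min),
    last = tapply(idx, grp, max),
    score = as.numeric(tapply(contrib, grp, sum)),
    tag_count = as.integer(tapply(counts[idx], grp, sum)),
    row.names = NULL)
}

#' Find candidate islands
#'
#' Islands are maximal runs of eligible windows (counts at or above the
#' [eligibility_threshold()]) allowing up to `gap_size` consecutive
#' ineligible windows inside a run. The island score is the sum over its
#' eligible windows of the negative natural log Poisson probability of the
#' window count under the background rate; `tag_count` sums the eligible
#' member-window counts.
#'
#' @param counts a `WindowCounts`.
#' @param cfg a `CallerConfig`.
#' @return A `GRanges` of candidate islands (window-aligned, clipped to the
#'   chromosome end) with metadata columns `score` and `tag_count`.
#' @export
find_islands <- function(counts, cfg = caller_config()) {
  stopifnot(inherits(counts, "WindowCounts"))
  w <- counts$window_size
  lambda <- counts$lambda
  if (counts$total_tags == 0L) return(empty_islands())
  l0 <- eligibility_threshold(lambda, cfg$eligibility_p)
  per_chrom <- lapply(names(counts$counts), function(cn) {
    runs <- island_runs(counts$counts[[cn]], lambda, l0, cfg$gap_size)
    if (!nrow(runs)) return(NULL)
    runs$chrom <- cn
    runs
  })
  runs <- do.call(rbind, per_chrom)
  if (is.null(runs) || !nrow(runs)) return(empty_islands())
  chrom_len <- vapply(runs$chrom,
                      function(cn) counts_chrom_length(counts, cn), 0)
  start1 <- (runs$first - 1L) * w + 1L
  end1 <- pmin(runs$last * w, chrom_len)
  gr <- GenomicRanges::GRanges(runs$chrom,
                               IRanges::IRanges(start = start1, end = end1))
  gr$score <- runs$score
  gr$tag_count <- runs$tag_count
  sort_by_genome(gr)
}

counts_chrom_length <- function(counts, cn) {
  ## chromosome length is only needed to clip the trailing window; recover
  ## it from the stored window grid (full windows) -- callers that need the
  ## exact length pass a genome downstream.  We store n_windows * w as the
  ## upper bound, so provide exact lengths via attribute when available.
  len <- attr(counts, "chrom_lengths")
  if (!is.null(len) && cn %in% names(len)) return(len[[cn]])
  length(counts$counts[[cn]]) * counts$window_size
}

empty_islands <- function() {
  gr <- GenomicRanges::GRanges()
  gr$score <- numeric()
  gr$tag_count <- integer()
  gr
}

#' Calibrate the island score threshold
#'
#' Finds the smallest score `s*` such that the expected number of background
#' islands with score >= `s*` over `n_windows` independent Poisson windows
#' is at most `e_value`. With `null_method = "recursion"` the island-score
#' null distribution is computed by dynamic programming: run lengths are
#' geometric in the per-window eligibility probability, and the run score is
#' the corresponding convolution of the single-window score distribution on
#' a fine grid. With `null_method = "monte_carlo"` the null is estimated
#' from `mc_replicates` simulated background genomes.
#'
#' The recursion supports `gap_size = 0` (the calling default); for positive
#' gap sizes the Monte-Carlo null is used.
#'
#' @param cfg a `CallerConfig`.
#' @param lambda background rate per window.
#' @param n_windows number of genome windows.
#' @return Score threshold `s*` (0 when every candidate passes), with the
#'   expected-count function attached as attribute `expected_fn` when the
#'   recursion was used.
#' @export
calibrate_score_threshold <- function(cfg, lambda, n_windows) {
  stopifnot(lambda > 0, n_windows > 0)
  if (!is.finite(cfg$e_value)) return(0)
  l0 <- eligibility_threshold(lambda, cfg$eligibility_p)
  p_elig <- stats::ppois(l0 - 1L, lambda, lower.tail = FALSE)
  if (p_elig <= 0) return(0)   # no window can ever be eligible
  method <- cfg$null_method
  if (method == "recursion" && (cfg$gap_size > 0L || p_elig > 0.9))
    method <- "monte_carlo"
  if (method == "recursion")
    threshold_by_recursion(cfg, lambda, n_windows, l0, p_elig)
  else
    threshold_by_monte_carlo(cfg, lambda, n_windows, l0)
}

## Expected background islands with score >= s, computed exactly (up to
## score-grid discretisation) for gap size 0:
##   E(s) = n_windows * (1 - p) * p * sum_k p^(k-1) (1 - p) P(S_k >= s),
## where p is the per-window eligibility probability and S_k the sum of k
## iid single-window scores conditional on eligibility.
threshold_by_recursion <- function(cfg, lambda, n_windows, l0, p_elig,
                                   delta = 0.01) {
  cmax <- max(stats::qpois(1e-14, lambda, lower.tail = FALSE), l0 + 10L)
  cs <- l0:cmax
  pr <- stats::dpois(cs, lambda)
  w <- pr / sum(pr)                       # conditional count distribution
  s1 <- -stats::dpois(cs, lambda, log = TRUE)
  ## single-window score distribution on the grid
  k1 <- pmax(round(s1 / delta), 0) + 1L
  d <- numeric(max(k1))
  for (i in seq_along(k1)) d[k1[i]] <- d[k1[i]] + w[i]
  n_runs <- n_windows * (1 - p_elig) * p_elig
  tail_k <- function(q) rev(cumsum(rev(q)))  # tail mass per grid point
  ## accumulate tail of run-score distribution over run lengths
  acc <- numeric(length(d))
  qk <- d
  wk <- (1 - p_elig)
  k <- 1L
  repeat {
    if (length(qk) > length(acc)) acc <- c(acc, numeric(length(qk) - length(acc)))
    acc[seq_along(qk)] <- acc[seq_along(qk)] + wk * qk
    k <- k + 1L
    wk <- (1 - p_elig) * p_elig^(k - 1L)
    if (wk < 1e-13 || k > 2000L) break
    qk <- conv_grid(qk, d)
  }
  tails <- tail_k(acc)
  expected <- n_runs * tails
  grid_s <- (seq_along(expected) - 1L) * delta
  expected_fn <- function(s) {
    i <- pmax(ceiling(s / delta - 1e-9), 0) + 1L  # smallest grid point >= s
    ifelse(i > length(tails), 0, n_runs * tails[pmin(i, length(tails))])
  }
  ok <- which(expected <= cfg$e_value)
  s_star <- if (!length(ok)) {
    max(grid_s) + delta  # unreachable in practice: grid covers full support
  } else grid_s[ok[1L]]
  if (s_star == 0 && cfg$e_value >= n_runs)
    warning("e_value exceeds the expected number of background islands; ",
            "score threshold is 0")
  attr(s_star, "expected_fn") <- expected_fn
  s_star
}

## convolution of two probability vectors on the same grid (index 1 = 0);
## power-of-two zero padding keeps the FFT fast for awkward lengths
conv_grid <- function(a, b) {
  n <- length(a) + length(b) - 1L
  N <- 2^ceiling(log2(n))
  fa <- stats::fft(c(a, numeric(N - length(a))))
  fb <- stats::fft(c(b, numeric(N - length(b))))
  r <- Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n)] / N
  r[r < 0] <- 0
  ## drop numerically empty tail to bound growth
  nz <- which(r > 1e-17)
  if (length(nz)) r[seq_len(max(nz))] else r[1L]
}

threshold_by_monte_carlo <- function(cfg, lambda, n_windows, l0) {
  if (!is.null(cfg$seed)) {
    old <- get0(".Random.seed", envir = .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(cfg$seed)
  }
  reps <- cfg$mc_replicates
  scores <- vector("list", reps)
  for (r in seq_len(reps)) {
    counts <- stats::rpois(n_windows, lambda)
    runs <- island_runs(counts, lambda, l0, cfg$gap_size)
    scores[[r]] <- runs$score
  }
  all_scores <- sort(unlist(scores), decreasing = TRUE)
  m <- floor(cfg$e_value * reps)
  s_star <- if (length(all_scores) <= m) {
    if (cfg$e_value >= 1)
      warning("e_value exceeds the observed background island count; ",
              "score threshold is 0")
    0
  } else {
    all_scores[m + 1L] * (1 + 1e-12) + 1e-12
  }
  attr(s_star, "mc_scores") <- all_scores
  s_star
}

#' Call islands without an input library
#'
#' The sensitive calling mode: candidate islands from [find_islands()] are
#' retained when their score meets the genome-wide E-value threshold from
#' [calibrate_score_threshold()]. Tags are deduplicated at the configured
#' redundancy threshold first.
#'
#' @param lib IP `ReadLibrary`.
#' @param genome a `GenomeModel`.
#' @param cfg a `CallerConfig`.
#' @return A `GRanges` island set with `score`, `tag_count` and
#'   `significance` (rank by decreasing score). The calibrated threshold is
#'   stored in `metadata()$score_threshold`.
#' @export
call_islands_no_input <- function(lib, genome, cfg = caller_config()) {
  lib <- deduplicate_tags(lib, cfg$redundancy_threshold)
  counts <- bin_reads(lib, genome, cfg)
  attr(counts, "chrom_lengths") <- genome$chrom_sizes
  if (counts$total_tags == 0L) return(empty_islands())
  cand <- find_islands(counts, cfg)
  n_windows <- sum(vapply(counts$counts, length, 0L))
  s_star <- calibrate_score_threshold(cfg, counts$lambda, n_windows)
  out <- cand[cand$score >= as.numeric(s_star)]
  out$significance <- rank(-out$score, ties.method = "first")
  S4Vectors::metadata(out) <- list(score_threshold = as.numeric(s_star),
                                   lambda = counts$lambda,
                                   library = lib$name)
  out
}

#' Call islands against an input library
#'
#' Candidate islands are found in the IP library exactly as in the no-input
#' mode; each candidate is then tested against the input: the island's IP
#' tag count is compared to a Poisson mean equal to the input tag count over
#' the same window span (floored at a pseudocount of 1) scaled by the
#' IP/input library-size ratio. Benjamini--Hochberg correction is applied
#' over all candidates and islands with q-value at most `cfg$fdr` are
#' retained.
#'
#' @param lib IP `ReadLibrary`.
#' @param input_lib input (pre-IP) `ReadLibrary`; must be non-empty.
#' @param genome a `GenomeModel`.
#' @param cfg a `CallerConfig`.
#' @return A `GRanges` island set with `score`, `tag_count`, `input_count`,
#'   `pvalue` and `significance` (the BH q-value).
#' @export
call_islands_with_input <- function(lib, input_lib, genome,
                                    cfg = caller_config()) {
  if (total_tags(input_lib) == 0L)
    stop("with-input calling requires a non-empty input library")
  lib <- deduplicate_tags(lib, cfg$redundancy_threshold)
  input_lib <- deduplicate_tags(input_lib, cfg$redundancy_threshold)
  counts <- bin_reads(lib, genome, cfg)
  attr(counts, "chrom_lengths") <- genome$chrom_sizes
  if (counts$total_tags == 0L) return(empty_islands())
  cand <- find_islands(counts, cfg)
  if (!length(cand)) return(empty_islands())
  in_counts <- bin_reads(input_lib, genome, cfg)
  w <- cfg$window_size
  input_in_span <- vapply(seq_along(cand), function(i) {
    cn <- as.character(GenomeInfoDb::seqnames(cand))[i]
    first <- (BiocGenerics::start(cand)[i] - 1L) %/% w + 1L
    last <- (BiocGenerics::end(cand)[i] - 1L) %/% w + 1L
    sum(in_counts$counts[[cn]][first:last])
  }, 0)
  ratio <- counts$total_tags / in_counts$total_tags
  mu <- pmax(input_in_span, 1) * ratio
  p <- stats::ppois(cand$tag_count - 1L, mu, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  cand$input_count <- as.integer(input_in_span)
  cand$pvalue <- p
  cand$significance <- q
  out <- cand[q <= cfg$fdr]
  S4Vectors::metadata(out) <- list(lambda = counts$lambda,
                                   library = lib$name,
                                   input = input_lib$name)
  out
}

#' Merge nearly adjacent islands
#'
#' Joins same-chromosome islands separated by at most one window
#' (`window_size` bp) into single islands, summing scores and tag counts.
#' Idempotent.
#'
#' @param islands a `GRanges` island set.
#' @param cfg a `CallerConfig` (only `window_size` is used).
#' @return The merged `GRanges`.
#' @export
merge_adjacent <- function(islands, cfg = caller_config()) {
  if (length(islands) < 2L) return(islands)
  islands <- sort_by_genome(islands)
  red <- GenomicRanges::reduce(islands, min.gapwidth = cfg$window_size + 1L,
                               with.revmap = TRUE, ignore.strand = TRUE)
  revmap <- red$revmap
  red$revmap <- NULL
  if (!is.null(islands$score))
    red$score <- vapply(revmap, function(i) sum(islands$score[i]), 0)
  if (!is.null(islands$tag_count))
    red$tag_count <- vapply(revmap,
                            function(i) sum(islands$tag_count[i]), 0L)
  S4Vectors::metadata(red) <- S4Vectors::metadata(islands)
  red
}

#' Write an island set as BED6+2
#'
#' Name column carries an island id, the BED score column the island score
#' capped at 1000, and two extra columns `tag_count` and `significance`.
#'
#' @param islands a `GRanges` island set.
#' @param path output path.
#' @export
write_islands_bed <- function(islands, path) {
  gr <- islands
  names(gr) <- sprintf("island_%d", seq_along(gr))
  full_score <- if (is.null(gr$score)) rep(0, length(gr)) else gr$score
  gr$island_score <- full_score
  gr$score <- round(pmin(full_score, 1000), 3)
  if (is.null(gr$tag_count)) gr$tag_count <- NA_integer_
  if (is.null(gr$significance)) gr$significance <- NA_real_
  write_intervals_bed(gr, path,
                      extra_cols = c("tag_count", "significance"))
}
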
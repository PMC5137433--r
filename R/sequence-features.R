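## Sequence-level features: G-quadruplex motif scanning and nucleotide
## compositional skew profiles.

#' G4 scanning parameters
#'
#' A G-quadruplex motif is four (or more) runs of at least three
#' consecutive guanines separated by loops of 1--7 bases. Runs are maximal
#' guanine runs; a loop is the full stretch between two qualifying runs and
#' may contain shorter guanine runs but never `N`.
#'
#' @param min_run minimum guanines per run.
#' @param n_runs minimum number of runs per motif.
#' @param loop_min,loop_max loop length bounds in bp.
#' @param scan_both_strands also report the C-run equivalent (minus-strand
#'   motifs) at the same coordinates.
#' @return A list of class `G4Params`.
#' @export
g4_params <- function(min_run = 3L, n_runs = 4L, loop_min = 1L,
                      loop_max = 7L, scan_both_strands = TRUE) {
  stopifnot(min_run >= 2, n_runs >= 2, loop_min >= 0,
            loop_min <= loop_max)
  structure(list(min_run = as.integer(min_run), n_runs = as.integer(n_runs),
                 loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "G4Params")
}

#' Scan sequences for G-quadruplex motifs
#'
#' Maximal leftmost scanning: qualifying guanine runs (>= `min_run` G) are
#' chained while consecutive runs are separated by a legal loop
#' (`loop_min`..`loop_max` bases containing no `N`); every maximal chain of
#' at least `n_runs` runs is one motif spanning from the first run's start
#' to the last run's end. Motifs therefore never overlap on the same
#' strand. Minus-strand motifs are the same pattern on C runs, reported at
#' plus-strand coordinates with strand `-`.
#'
#' @param sequence a named character vector or [Biostrings::DNAStringSet].
#' @param params a `G4Params`.
#' @return A stranded `GRanges` of motif intervals.
#' @export
scan_g4 <- function(sequence, params = g4_params()) {
  seqs <- as_sequence_list(sequence)
  hits <- lapply(names(seqs), function(cn) {
    s <- seqs[[cn]]
    plus <- g4_chain_scan(s, "G", params)
    minus <- if (params$scan_both_strands) g4_chain_scan(s, "C", params)
             else NULL
    rows <- rbind(
      if (nrow(plus)) cbind(plus, strand = "+"),
      if (!is.null(minus) && nrow(minus)) cbind(minus, strand = "-"))
    if (is.null(rows) || !nrow(rows)) return(NULL)
    rows$chrom <- cn
    rows
  })
  rows <- do.call(rbind, hits)
  if (is.null(rows) || !nrow(rows)) {
    gr <- GenomicRanges::GRanges()
    return(gr)
  }
  gr <- GenomicRanges::GRanges(rows$chrom,
                               IRanges::IRanges(start = rows$start0 + 1L,
                                                end = rows$end0),
                               strand = rows$strand)
  sort_by_genome(gr)
}

## chain maximal base-runs of `base` into motifs; returns 0-based half-open
g4_chain_scan <- function(s, base, params) {
  empty <- data.frame(start0 = integer(), end0 = integer())
  m <- gregexpr(paste0(base, "{", params$min_run, ",}"), s)[[1L]]
  if (m[1L] == -1L) return(empty)
  run_start <- as.integer(m) - 1L            # 0-based
  run_len <- attr(m, "match.length")
  run_end <- run_start + run_len             # exclusive
  k <- length(run_start)
  if (k < params$n_runs) return(empty)
  gaps <- run_start[-1L] - run_end[-k]
  legal <- gaps >= params$loop_min & gaps <= params$loop_max
  if (any(legal)) {
    ## an N anywhere in the loop disqualifies it
    has_n <- vapply(which(legal), function(i)
      grepl("N", substr(s, run_end[i] + 1L, run_start[i + 1L]),
            fixed = TRUE), NA)
    legal[which(legal)[has_n]] <- FALSE
  }
  grp <- cumsum(c(TRUE, !legal))
  sizes <- tabulate(grp)
  keep <- which(sizes >= params$n_runs)
  if (!length(keep)) return(empty)
  data.frame(
    start0 = vapply(keep, function(g) run_start[grp == g][1L], 0L),
    end0 = vapply(keep, function(g) max(run_end[grp == g]), 0L))
}

as_sequence_list <- function(sequence) {
  if (methods::is(sequence, "DNAStringSet")) {
    out <- as.character(sequence)
  } else if (methods::is(sequence, "DNAString")) {
    out <- stats::setNames(as.character(sequence), "seq")
  } else {
    nm <- names(sequence)
    out <- toupper(as.character(sequence))   # toupper drops names
    names(out) <- if (!is.null(nm)) nm
                  else if (length(out) == 1L) "seq"
                  else paste0("seq", seq_along(out))
  }
  out
}

#' Nucleotide compositional skew profile
#'
#' Computes `S = (T - A)/(T + A) + (G - C)/(G + C)` from base counts in
#' non-overlapping windows anchored at the sequence start (1 kb by
#' default), on the given (+) strand. A term with zero denominator
#' contributes 0. The trailing partial window is computed on the remaining
#' bases and flagged.
#'
#' @param sequence a named character vector or [Biostrings::DNAStringSet].
#' @param window window size in bp.
#' @return An object of class `SkewProfile`: a data.frame per sequence with
#'   `chrom`, `start0`, `end0`, `S` and `partial`.
#' @export
skew_profile <- function(sequence, window = 1000L) {
  stopifnot(window > 0)
  seqs <- as_sequence_list(sequence)
  per <- lapply(names(seqs), function(cn) {
    s <- seqs[[cn]]
    len <- nchar(s)
    if (!len) return(NULL)
    starts0 <- seq.int(0L, len - 1L, by = window)
    ends0 <- pmin(starts0 + window, len)
    dna <- Biostrings::DNAStringSet(substring(s, starts0 + 1L, ends0))
    f <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T"))
    ta <- skew_term(f[, "T"], f[, "A"])
    gc <- skew_term(f[, "G"], f[, "C"])
    data.frame(chrom = cn, start0 = starts0, end0 = ends0,
               S = ta + gc, partial = (ends0 - starts0) < window)
  })
  structure(list(window = window, profile = do.call(rbind, per)),
            class = "SkewProfile")
}

skew_term <- function(x, y) ifelse(x + y == 0, 0, (x - y) / (x + y))

#' @export
print.SkewProfile <- function(x, ...) {
  cat(sprintf("SkewProfile: %d windows of %d bp\n",
              nrow(x$profile), x$window))
  invisible(x)
}

#' @rdname skew_profile
#' @param profile a `SkewProfile`.
#' @param path bedGraph output path.
#' @export
write_skew_bedgraph <- function(profile, path) {
  p <- profile$profile
  write_bedgraph(p$chrom, p$start0, p$end0, p$S, path)
}
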
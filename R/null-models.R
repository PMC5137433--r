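## Width-preserving randomised control distributions for the origin
## catalogue: full randomisation within each chromosome, and positional
## jitter that approximately preserves the replication-timing profile.

#' Null-model configuration
#'
#' @param mode `"chromosome"` (uniform start anywhere on the same
#'   chromosome) or `"timing_jitter"` (start shifted by a uniform offset in
#'   `[-jitter_halfwidth, +jitter_halfwidth]`, half the 480 kb average early
#'   replication-timing window by default).
#' @param jitter_halfwidth maximum absolute start shift in bp.
#' @param seed optional integer seed.
#' @param max_redraws redraw attempts for placements extending past the
#'   chromosome end.
#' @return A list of class `NullConfig`.
#' @export
null_config <- function(mode = c("chromosome", "timing_jitter"),
                        jitter_halfwidth = 240000L, seed = NULL,
                        max_redraws = 100L) {
  mode <- match.arg(mode)
  stopifnot(jitter_halfwidth >= 0, max_redraws >= 1)
  structure(list(mode = mode,
                 jitter_halfwidth = as.integer(jitter_halfwidth),
                 seed = seed, max_redraws = as.integer(max_redraws)),
            class = "NullConfig")
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(seed)
  }
  expr
}

#' Randomise origins within chromosomes
#'
#' Each origin keeps its chromosome and width; a new start is drawn
#' uniformly over the chromosome. Draws that would extend past the
#' chromosome end are redrawn (up to `max_redraws`), so every null origin
#' remains a valid genomic interval and the width multiset is preserved
#' exactly.
#'
#' @param origins a `GRanges` origin set.
#' @param genome a `GenomeModel`.
#' @param cfg a `NullConfig`.
#' @return A `GRanges` of randomised origins (same length and widths).
#' @export
randomize_within_chromosome <- function(origins, genome,
                                        cfg = null_config()) {
  if (!length(origins)) return(origins)
  chr <- as.character(GenomeInfoDb::seqnames(origins))
  if (!all(chr %in% names(genome$chrom_sizes)))
    stop("origin on a chromosome absent from the genome model")
  L <- genome$chrom_sizes[chr]
  w <- BiocGenerics::width(origins)
  too_wide <- w > L
  if (any(too_wide))
    stop("origin wider than its chromosome: ",
         paste0(chr[too_wide][1L], ":",
                BiocGenerics::start(origins)[too_wide][1L]))
  with_seed(cfg$seed, {
    start0 <- floor(stats::runif(length(origins), 0, L))  # 0-based start
    for (i in seq_len(cfg$max_redraws)) {
      bad <- start0 + w > L
      if (!any(bad)) break
      start0[bad] <- floor(stats::runif(sum(bad), 0, L[bad]))
    }
    bad <- start0 + w > L
    if (any(bad))
      stop("could not place origin ", chr[bad][1L], ":",
           BiocGenerics::start(origins)[bad][1L],
           " within its chromosome after max_redraws")
    rebuild_origins(origins, start0)
  })
}

#' Jitter origins within their timing neighbourhood
#'
#' Each origin's start is shifted by an integer offset drawn uniformly in
#' `[-jitter_halfwidth, +jitter_halfwidth]`; chromosome and width are
#' preserved and out-of-chromosome placements are redrawn. With the default
#' 240 kb half-width the shifted set approximately preserves the
#' replication-timing profile of the original catalogue while destroying
#' fine-scale positioning.
#'
#' @inheritParams randomize_within_chromosome
#' @return A `GRanges` of jittered origins.
#' @export
randomize_within_timing <- function(origins, genome, cfg = null_config()) {
  if (!length(origins)) return(origins)
  chr <- as.character(GenomeInfoDb::seqnames(origins))
  if (!all(chr %in% names(genome$chrom_sizes)))
    stop("origin on a chromosome absent from the genome model")
  L <- genome$chrom_sizes[chr]
  w <- BiocGenerics::width(origins)
  old0 <- BiocGenerics::start(origins) - 1L
  J <- cfg$jitter_halfwidth
  draw <- function(n) floor(stats::runif(n, -J, J + 1))
  with_seed(cfg$seed, {
    start0 <- old0 + draw(length(origins))
    for (i in seq_len(cfg$max_redraws)) {
      bad <- start0 < 0 | start0 + w > L
      if (!any(bad)) break
      start0[bad] <- old0[bad] + draw(sum(bad))
    }
    bad <- start0 < 0 | start0 + w > L
    if (any(bad))
      stop("origin ", chr[bad][1L], ":", old0[bad][1L] + 1L,
           " cannot be jittered onto its chromosome ",
           "(the full jitter window is off-chromosome)")
    rebuild_origins(origins, start0)
  })
}

rebuild_origins <- function(origins, start0) {
  out <- origins
  IRanges::ranges(out) <- IRanges::IRanges(
    start = as.integer(start0) + 1L,
    width = BiocGenerics::width(origins))
  out
}
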
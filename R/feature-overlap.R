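## Interval-vs-interval analytics for the origin catalogue: genic
## annotation, replication-timing profiles, inter-origin spacing and
## skew-jump overlap profiles.

#' Annotate origins by genic context
#'
#' Assigns each origin exactly one category with priority
#' TSS > exon > intron > intergenic. A TSS hit is any overlap with the
#' window `[tss - tss_halfwidth, tss + tss_halfwidth)` around a TSS
#' position (1 kb total by default).
#'
#' @param origins a `GRanges` origin set.
#' @param tss `GRanges` of TSS positions (1 bp intervals).
#' @param exons,introns `GRanges` of exon and intron intervals.
#' @param tss_halfwidth half-width of the TSS window in bp.
#' @return An object of class `AnnotationResult`: per-origin `category`
#'   factor plus counts and fractions.
#' @export
annotate_origins <- function(origins, tss, exons, introns,
                             tss_halfwidth = 500L) {
  tw <- tss_window(tss, tss_halfwidth)
  hit_tss <- IRanges::overlapsAny(origins, tw, ignore.strand = TRUE)
  hit_exon <- IRanges::overlapsAny(origins, exons, ignore.strand = TRUE)
  hit_intron <- IRanges::overlapsAny(origins, introns, ignore.strand = TRUE)
  category <- factor(ifelse(hit_tss, "TSS",
                     ifelse(hit_exon, "exon",
                     ifelse(hit_intron, "intron", "intergenic"))),
                     levels = c("TSS", "exon", "intron", "intergenic"))
  counts <- table(category)
  structure(list(category = category,
                 counts = counts,
                 fractions = if (length(origins)) counts / length(origins)
                             else counts * NA_real_,
                 n = length(origins)),
            class = "AnnotationResult")
}

## [p - hw, p + hw) around the TSS base, clipped at chromosome bounds
tss_window <- function(tss, halfwidth) {
  start1 <- pmax(BiocGenerics::start(tss) - halfwidth, 1L)
  end1 <- BiocGenerics::start(tss) + halfwidth - 1L
  sl <- GenomeInfoDb::seqlengths(tss)
  if (length(sl) && !all(is.na(sl))) {
    lim <- unname(sl[as.character(GenomeInfoDb::seqnames(tss))])
    end1 <- ifelse(is.na(lim), end1, pmin(end1, lim))
  }
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(tss),
                         IRanges::IRanges(start1, pmax(end1, start1)))
}

#' @export
print.AnnotationResult <- function(x, ...) {
  cat("Origin annotation (priority TSS > exon > intron > intergenic):\n")
  print(x$counts)
  invisible(x)
}

#' Replication-timing profile of an origin set
#'
#' For each timing class S1..S6, the count and percentage of origins
#' overlapping (>= 1 nt) any window of that class. Timing windows of
#' adjacent classes overlap, so an origin can count in several classes and
#' percentages may sum above 100.
#'
#' @param origins a `GRanges` origin set.
#' @param timing `GRanges` timing track with window names `S1`..`S6` (taken
#'   from `names()` or the `name`/`timing_class` metadata column).
#' @return An object of class `TimingProfile` with per-class `count` and
#'   `percent`, plus `n_unassigned` origins overlapping no class.
#' @export
timing_profile <- function(origins, timing) {
  labels <- timing_labels(timing)
  classes <- paste0("S", 1:6)
  ## origins on chromosomes absent from the timing track overlap nothing
  ## (reported via n_unassigned); silence the no-common-seqlevels notice
  hit <- suppressWarnings(sapply(classes, function(cl)
    IRanges::overlapsAny(origins, timing[labels == cl],
                         ignore.strand = TRUE)))
  hit <- matrix(hit, nrow = length(origins), ncol = length(classes),
                dimnames = list(NULL, classes))
  count <- colSums(hit)
  structure(list(count = count,
                 percent = if (length(origins))
                   100 * count / length(origins) else count * NA_real_,
                 n = length(origins),
                 n_unassigned = sum(rowSums(hit) == 0L)),
            class = "TimingProfile")
}

timing_labels <- function(timing) {
  if (!is.null(names(timing)) && any(nzchar(names(timing))))
    return(names(timing))
  for (col in c("name", "timing_class"))
    if (!is.null(S4Vectors::mcols(timing)[[col]]))
      return(as.character(S4Vectors::mcols(timing)[[col]]))
  stop("timing track carries no S1..S6 labels")
}

#' @export
print.TimingProfile <- function(x, ...) {
  cat("Timing profile (% of origins overlapping each class):\n")
  print(round(x$percent, 1))
  if (x$n_unassigned)
    cat(x$n_unassigned, "origin(s) overlap no timing window\n")
  invisible(x)
}

#' Histogram of inter-origin distances
#'
#' Per chromosome, origins are sorted by midpoint and successive midpoint
#' differences are binned into half-open bins `[k*bin, (k+1)*bin)` (5 kb by
#' default). Chromosomes with fewer than two origins contribute no
#' distances. Edge-to-edge distances are available via `measure`.
#'
#' @param origins a `GRanges` origin set.
#' @param bin bin width in bp.
#' @param measure `"midpoint"` (default) or `"edge"` (end-to-next-start
#'   gap, floored at 0).
#' @return An object of class `DistanceHistogram`: `breaks0` (bin starts),
#'   `counts`, `distances` and `n_distances`.
#' @export
inter_origin_distances <- function(origins, bin = 5000L,
                                   measure = c("midpoint", "edge")) {
  measure <- match.arg(measure)
  stopifnot(bin > 0)
  chr <- as.character(GenomeInfoDb::seqnames(origins))
  dists <- unlist(lapply(unique(chr), function(cn) {
    g <- origins[chr == cn]
    if (length(g) < 2L) return(numeric())
    if (measure == "midpoint") {
      mid <- (BiocGenerics::start(g) - 1L + BiocGenerics::end(g)) %/% 2L
      diff(sort(mid))
    } else {
      g <- sort_by_genome(g)
      pmax(BiocGenerics::start(g)[-1L] - BiocGenerics::end(g)[-length(g)] - 1L, 0L)
    }
  }), use.names = FALSE)
  if (!length(dists)) dists <- numeric()
  nb <- if (length(dists)) max(dists) %/% bin + 1L else 0L
  counts <- if (nb) tabulate(dists %/% bin + 1L, nbins = nb) else integer()
  structure(list(bin = bin,
                 breaks0 = if (nb) (seq_len(nb) - 1L) * bin else numeric(),
                 counts = counts,
                 distances = dists,
                 n_distances = length(dists)),
            class = "DistanceHistogram")
}

#' @export
print.DistanceHistogram <- function(x, ...) {
  cat(sprintf("DistanceHistogram: %d distances, %d bp bins\n",
              x$n_distances, x$bin))
  invisible(x)
}

#' Fraction of distances below a cut-off
#'
#' @param hist a `DistanceHistogram`.
#' @param cutoff distance in bp (default one bin).
#' @export
fraction_short_distances <- function(hist, cutoff = hist$bin) {
  if (!hist$n_distances) return(NA_real_)
  sum(hist$distances < cutoff) / hist$n_distances
}

#' Skew-jump overlap profile
#'
#' For a nested set of window sizes (up to 40 kb by default), computes the
#' fraction of compositional skew jumps whose centred window
#' `[p - W/2, p + W/2)` overlaps at least one origin, separately for
#' positive and negative jump polarity. Jump intervals wider than 1 bp are
#' collapsed to their midpoint. Fractions are non-decreasing in window
#' size.
#'
#' @param origins a `GRanges` origin set.
#' @param jumps a `GRanges` of jumps; strand encodes polarity (`+`/`-`).
#' @param window_sizes window sizes in bp.
#' @return An object of class `JumpOverlapProfile`: a matrix of fractions
#'   (rows = window sizes, columns = polarity) plus jump counts.
#' @export
jump_overlap_profile <- function(origins, jumps,
                                 window_sizes = c(2, 4, 6, 10, 20, 30, 40) * 1000) {
  stopifnot(all(window_sizes > 0))
  pol <- as.character(BiocGenerics::strand(jumps))
  mid0 <- (BiocGenerics::start(jumps) - 1L + BiocGenerics::end(jumps)) %/% 2L
  frac <- matrix(NA_real_, nrow = length(window_sizes), ncol = 2L,
                 dimnames = list(as.character(window_sizes), c("+", "-")))
  for (p in c("+", "-")) {
    sel <- pol == p
    if (!any(sel)) next
    for (i in seq_along(window_sizes)) {
      W <- window_sizes[i]
      half <- W %/% 2L
      win <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(jumps)[sel],
        IRanges::IRanges(start = pmax(mid0[sel] - half, 0L) + 1L,
                         end = mid0[sel] + half))
      frac[i, p] <- mean(IRanges::overlapsAny(win, origins,
                                              ignore.strand = TRUE))
    }
  }
  structure(list(window_sizes = window_sizes, fraction = frac,
                 n_jumps = c(`+` = sum(pol == "+"), `-` = sum(pol == "-"))),
            class = "JumpOverlapProfile")
}

#' @export
print.JumpOverlapProfile <- function(x, ...) {
  cat("Jump-overlap profile (fraction of jumps hitting an origin):\n")
  print(round(x$fraction, 3))
  invisible(x)
}
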
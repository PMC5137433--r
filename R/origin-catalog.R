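## Replicate-intersect origin catalogue and its summaries.

#' Intersect two replicate island sets
#'
#' The origin catalogue keeps only genomic bases called as enriched in both
#' biological replicates: the base-pair intersection of the two island sets
#' (minimum overlap one nucleotide), with book-ended or overlapping result
#' pieces merged. Every output interval is contained in at least one island
#' of each replicate.
#'
#' @param a,b `GRanges` island sets.
#' @return A `GRanges` origin set (non-overlapping, sorted); provenance is
#'   recorded in `metadata()`.
#' @export
intersect_replicates <- function(a, b) {
  out <- GenomicRanges::intersect(granges_only(a), granges_only(b),
                                  ignore.strand = TRUE)
  out <- sort_by_genome(out)
  S4Vectors::metadata(out) <- list(
    n_a = length(a), n_b = length(b),
    provenance = c(S4Vectors::metadata(a)$library,
                   S4Vectors::metadata(b)$library))
  out
}

granges_only <- function(gr) {
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                         IRanges::ranges(gr),
                         seqinfo = GenomeInfoDb::seqinfo(gr))
}

#' Reciprocal element-wise overlap counts
#'
#' Counts how many elements of each set overlap (by >= 1 nt) any element of
#' the other, the quantities behind pairwise Venn comparisons of origin
#' sets. Counts are element-wise, so the two directions are generally
#' asymmetric (one broad element can hit several narrow ones).
#'
#' @param a,b `GRanges` sets.
#' @return Named list: `n_a_hit`, `n_a_only`, `n_b_hit`, `n_b_only`.
#' @export
count_reciprocal <- function(a, b) {
  a_hit <- sum(IRanges::overlapsAny(a, b, ignore.strand = TRUE))
  b_hit <- sum(IRanges::overlapsAny(b, a, ignore.strand = TRUE))
  list(n_a_hit = a_hit, n_a_only = length(a) - a_hit,
       n_b_hit = b_hit, n_b_only = length(b) - b_hit)
}

#' Summarise an origin catalogue
#'
#' Per-chromosome origin counts (including zero-count chromosomes), width
#' quantiles (median/quartiles with linear interpolation) genome-wide and
#' per chromosome, and optionally tags-per-origin distributions recomputed
#' by re-binning each library over the final origin spans, so the summary is
#' caller-independent.
#'
#' @param origins a `GRanges` origin set.
#' @param genome a `GenomeModel`.
#' @param libraries optional named list of `ReadLibrary` objects.
#' @param cfg a `CallerConfig` supplying the fragment shift for re-binning.
#' @return An object of class `CatalogSummary`.
#' @export
summarize_catalog <- function(origins, genome, libraries = NULL,
                              cfg = caller_config()) {
  chroms <- names(genome$chrom_sizes)
  chr <- factor(as.character(GenomeInfoDb::seqnames(origins)),
                levels = chroms)
  per_chrom <- as.integer(table(chr))
  names(per_chrom) <- chroms
  widths <- BiocGenerics::width(origins)
  qs <- if (length(widths)) {
    stats::quantile(widths, c(0.25, 0.5, 0.75), names = FALSE)
  } else c(NA_real_, NA_real_, NA_real_)
  width_by_chrom <- lapply(chroms, function(cn) {
    wc <- widths[chr == cn]
    if (length(wc)) stats::quantile(wc, c(0.25, 0.5, 0.75), names = FALSE)
    else c(NA_real_, NA_real_, NA_real_)
  })
  names(width_by_chrom) <- chroms
  tags_per_origin <- NULL
  if (!is.null(libraries)) {
    tags_per_origin <- lapply(libraries, function(lib)
      count_tags_in_spans(lib, origins, genome, cfg))
  }
  structure(list(total = length(origins),
                 per_chromosome = per_chrom,
                 width_quartiles = stats::setNames(qs, c("q25", "median", "q75")),
                 width_by_chromosome = width_by_chrom,
                 tags_per_origin = tags_per_origin,
                 empty = length(origins) == 0L),
            class = "CatalogSummary")
}

## tags whose shifted fragment positions fall inside each span
count_tags_in_spans <- function(lib, spans, genome, cfg) {
  counts <- bin_point_positions(lib, genome, cfg)
  pts <- counts$points
  vapply(seq_along(spans), function(i) {
    cn <- as.character(GenomeInfoDb::seqnames(spans))[i]
    p <- pts[[cn]]
    sum(p >= BiocGenerics::start(spans)[i] - 1L &
        p < BiocGenerics::end(spans)[i])
  }, 0L)
}

## 0-based shifted tag point positions per chromosome
bin_point_positions <- function(lib, genome, cfg) {
  shift <- cfg$fragment_size %/% 2L
  gr <- lib$tags
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  bed_start <- BiocGenerics::start(gr) - 1L
  bed_end <- BiocGenerics::end(gr)
  str <- as.character(BiocGenerics::strand(gr))
  pos <- ifelse(str == "-", bed_end - shift,
         ifelse(str == "+", bed_start + shift,
                (bed_start + bed_end) %/% 2L))
  pts <- lapply(names(genome$chrom_sizes), function(cn) {
    L <- genome$chrom_sizes[[cn]]
    pmin(pmax(pos[chr == cn], 0), L - 1L)
  })
  names(pts) <- names(genome$chrom_sizes)
  list(points = pts)
}

#' @export
print.CatalogSummary <- function(x, ...) {
  cat(sprintf("Origin catalogue: %d origins on %d chromosome(s)\n",
              x$total, sum(x$per_chromosome > 0)))
  if (!x$empty)
    cat(sprintf("widths (bp): median %.0f, IQR [%.0f, %.0f]\n",
                x$width_quartiles["median"], x$width_quartiles["q25"],
                x$width_quartiles["q75"]))
  invisible(x)
}

#' Write a catalogue summary as TSV and JSON
#'
#' @param summary a `CatalogSummary`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @export
write_catalog_summary <- function(summary, tsv_path = NULL,
                                  json_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(chrom = names(summary$per_chromosome),
                     n_origins = as.integer(summary$per_chromosome),
                     median_width = vapply(summary$width_by_chromosome,
                                           `[[`, 0, 2L))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(total = summary$total,
           per_chromosome = as.list(summary$per_chromosome),
           width_quartiles = as.list(summary$width_quartiles)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
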
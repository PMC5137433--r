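## Readers/writers and interval primitives shared by all stages.
##
## On disk everything is BED-style 0-based half-open; in memory intervals are
## GRanges (1-based closed). read/write pairs are exact inverses.

#' Assemble a genome model
#'
#' A genome model bundles an ordered chromosome table, an optional genome
#' sequence and any number of named annotation tracks (genes, TSS, timing
#' windows, excluded regions, G4 motifs, skew jumps, external origin sets).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp), in
#'   the order chromosomes should be reported.
#' @param sequence optional [Biostrings::DNAStringSet] named by chromosome.
#' @param tracks named list of `GRanges` annotation tracks.
#' @return An object of class `GenomeModel`.
#' @export
genome_model <- function(chrom_sizes, sequence = NULL, tracks = list()) {
  if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)) ||
      any(names(chrom_sizes) == ""))
    stop("chromosome sizes must be named")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicate chromosome name: ",
         names(chrom_sizes)[duplicated(names(chrom_sizes))][1L])
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("chromosome lengths must be positive")
  chrom_sizes <- round(chrom_sizes)
  if (!is.null(sequence)) {
    if (!all(names(chrom_sizes) %in% names(sequence)))
      stop("sequence missing for some chromosomes")
    sequence <- sequence[names(chrom_sizes)]
    if (!all(Biostrings::width(sequence) == unname(chrom_sizes)))
      stop("sequence lengths disagree with chromosome table")
  }
  gm <- structure(
    list(chrom_sizes = chrom_sizes, sequence = sequence, tracks = list()),
    class = "GenomeModel")
  for (nm in names(tracks)) gm <- set_track(gm, nm, tracks[[nm]])
  gm
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf("GenomeModel: %d chromosome(s), %.3f Mb%s\n",
              length(x$chrom_sizes), sum(x$chrom_sizes) / 1e6,
              if (is.null(x$sequence)) "" else " (with sequence)"))
  if (length(x$tracks))
    cat("tracks:",
        paste(sprintf("%s[%d]", names(x$tracks),
                      vapply(x$tracks, length, 0L)), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname genome_model
#' @param genome a `GenomeModel`.
#' @export
genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome$chrom_sizes),
                        seqlengths = unname(as.integer(genome$chrom_sizes)))
}

#' Attach or fetch an annotation track
#'
#' @param genome a `GenomeModel`.
#' @param name track name.
#' @param gr a `GRanges`; every interval must lie within chromosome bounds.
#' @return `set_track` the updated model; `get_track` the `GRanges` (error if
#'   absent).
#' @export
set_track <- function(genome, name, gr) {
  stopifnot(inherits(genome, "GenomeModel"), methods::is(gr, "GRanges"))
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- !(chr %in% names(genome$chrom_sizes))
  if (any(unknown))
    stop("track '", name, "': unknown chromosome ", chr[unknown][1L])
  if (length(gr) &&
      any(BiocGenerics::end(gr) > genome$chrom_sizes[chr] |
          BiocGenerics::start(gr) < 1L))
    stop("track '", name, "': interval outside chromosome bounds")
  genome$tracks[[name]] <- gr
  genome
}

#' @rdname set_track
#' @export
get_track <- function(genome, name) {
  if (is.null(genome$tracks[[name]]))
    stop("genome model has no track '", name, "'")
  genome$tracks[[name]]
}

#' Read a chrom.sizes table
#'
#' Two tab-separated columns: chromosome name, length in bp. Ordering is
#' preserved; duplicate names and non-positive lengths are errors.
#'
#' @param path file path.
#' @return A `GenomeModel` skeleton (no sequence, no tracks).
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty chrom.sizes file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 0L) < 2L))
    stop("malformed chrom.sizes line: ",
         lines[vapply(parts, length, 0L) < 2L][1L])
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(len)) stop("non-numeric chromosome length in ", path)
  genome_model(stats::setNames(len, nm))
}

#' @rdname read_chrom_sizes
#' @param genome a `GenomeModel`.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(sprintf("%s\t%d", names(genome$chrom_sizes),
                     as.integer(genome$chrom_sizes)), path)
  invisible(path)
}

## 0-based half-open file coords -> 1-based closed GRanges, and back.
bed_to_granges <- function(df, seqinfo = NULL) {
  strand <- if (ncol(df) >= 6L) df[[6L]] else "*"
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1L]],
    ranges = IRanges::IRanges(start = df[[2L]] + 1L, end = df[[3L]]),
    strand = strand)
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
    suppressWarnings(GenomeInfoDb::seqinfo(gr) <- seqinfo)
  }
  if (ncol(df) >= 4L) names(gr) <- as.character(df[[4L]])
  if (ncol(df) >= 5L) gr$score <- df[[5L]]
  gr
}

#' Read genomic intervals from a BED file
#'
#' Accepts BED3--BED6 plus optional named extra columns. Coordinates are
#' validated (`start < end`); records on chromosomes absent from `genome` are
#' skipped with a warning, or rejected when `strict = TRUE`.
#'
#' @param path BED file path.
#' @param genome optional `GenomeModel` used for chromosome validation and
#'   seqinfo.
#' @param extra_cols character vector naming columns after the first six.
#' @param strict fail (instead of warn-and-skip) on unknown chromosomes.
#' @return A `GRanges`; BED columns 4/5/6 populate names, `score` and strand.
#' @export
read_intervals_bed <- function(path, genome = NULL, extra_cols = NULL,
                               strict = FALSE) {
  si <- if (!is.null(genome)) genome_seqinfo(genome) else NULL
  if (!file.exists(path)) stop("no such BED file: ", path)
  if (file.size(path) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(si)) suppressWarnings(GenomeInfoDb::seqinfo(gr) <- si)
    return(gr)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  if (!is.numeric(df[[2L]]) || !is.numeric(df[[3L]]))
    stop("non-numeric BED coordinates in ", path)
  if (any(df[[2L]] < 0L)) stop("negative start coordinate in ", path)
  if (any(df[[2L]] >= df[[3L]]))
    stop("BED record with start >= end in ", path)
  if (!is.null(genome)) {
    unknown <- !(df[[1L]] %in% names(genome$chrom_sizes))
    if (any(unknown)) {
      if (strict)
        stop("unknown chromosome in ", path, ": ", df[[1L]][unknown][1L])
      warning(sum(unknown), " record(s) on unknown chromosomes skipped")
      df <- df[!unknown, , drop = FALSE]
    }
    bad <- df[[3L]] > genome$chrom_sizes[df[[1L]]]
    if (any(bad)) stop("interval beyond chromosome end in ", path)
  }
  gr <- bed_to_granges(df, si)
  if (!is.null(extra_cols)) {
    for (i in seq_along(extra_cols)) {
      col <- 6L + i
      if (col <= ncol(df))
        S4Vectors::mcols(gr)[[extra_cols[i]]] <- df[[col]]
    }
  }
  gr
}

#' Write genomic intervals to a BED file
#'
#' Emits BED6 (name from `names(gr)` or ".", score from `gr$score` or 0,
#' strand "." for "*") plus any `extra_cols` from the metadata columns,
#' sorted by (chromosome order, start). Inverse of [read_intervals_bed()].
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @param extra_cols metadata column names appended after the strand column.
#' @export
write_intervals_bed <- function(gr, path, extra_cols = NULL) {
  gr <- sort_by_genome(gr)
  n <- length(gr)
  fmt_num <- function(x) {
    if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE,
                              digits = 15) else as.character(x)
  }
  cols <- list(
    as.character(GenomeInfoDb::seqnames(gr)),
    format(BiocGenerics::start(gr) - 1L, scientific = FALSE, trim = TRUE),
    format(BiocGenerics::end(gr), scientific = FALSE, trim = TRUE),
    if (is.null(names(gr))) rep(".", n) else names(gr),
    if (is.null(gr$score)) rep("0", n) else fmt_num(gr$score),
    sub("\\*", ".", as.character(BiocGenerics::strand(gr))))
  for (ec in extra_cols) cols <- c(cols, list(fmt_num(S4Vectors::mcols(gr)[[ec]])))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

## deterministic (chrom order, start, end) sort
sort_by_genome <- function(gr) {
  ord <- order(match(as.character(GenomeInfoDb::seqnames(gr)),
                     GenomeInfoDb::seqlevels(gr)),
               BiocGenerics::start(gr), BiocGenerics::end(gr))
  gr[ord]
}

#' Construct a read library
#'
#' A read library is a set of stranded read tags (one BED record per
#' sequenced fragment) with a library label.
#'
#' @param tags a `GRanges` of read tags, or a BED file path.
#' @param name library label (e.g. "IP-A").
#' @param genome optional `GenomeModel` for validation when reading a path.
#' @return An object of class `ReadLibrary`.
#' @export
read_library <- function(tags, name = "library", genome = NULL) {
  if (is.character(tags)) tags <- read_intervals_bed(tags, genome = genome)
  stopifnot(methods::is(tags, "GRanges"))
  structure(list(tags = tags, name = name), class = "ReadLibrary")
}

#' @export
print.ReadLibrary <- function(x, ...) {
  cat(sprintf("ReadLibrary '%s': %d tag(s)\n", x$name, total_tags(x)))
  invisible(x)
}

#' @rdname read_library
#' @param lib a `ReadLibrary`.
#' @export
total_tags <- function(lib) length(lib$tags)

#' Remove redundant read tags
#'
#' Retains at most `redundancy_threshold` tags per identical
#' (chromosome, start, strand) triple, keeping first occurrences in input
#' order. Mirrors the standard pre-calling redundancy filter (threshold 1
#' keeps one tag per position and strand).
#'
#' @param lib a `ReadLibrary`.
#' @param redundancy_threshold maximum retained copies per position (>= 1).
#' @return The filtered `ReadLibrary`.
#' @export
deduplicate_tags <- function(lib, redundancy_threshold = 1L) {
  stopifnot(inherits(lib, "ReadLibrary"), redundancy_threshold >= 1L)
  gr <- lib$tags
  if (!length(gr)) return(lib)
  key <- paste(as.character(GenomeInfoDb::seqnames(gr)),
               BiocGenerics::start(gr),
               as.character(BiocGenerics::strand(gr)), sep = "\r")
  if (redundancy_threshold == 1L) {
    lib$tags <- gr[!duplicated(key)]
  } else {
    copy <- stats::ave(seq_along(key), key, FUN = seq_along)
    lib$tags <- gr[copy <= redundancy_threshold]
  }
  lib
}

#' Drop tags overlapping excluded regions
#'
#' Removes every tag overlapping (by >= 1 bp) an interval of the excluded
#' track, e.g. a blacklist of regions unreliable for signal detection.
#'
#' @param lib a `ReadLibrary`.
#' @param excluded a `GRanges` of excluded intervals (may be empty).
#' @return The filtered `ReadLibrary`.
#' @export
filter_excluded <- function(lib, excluded) {
  stopifnot(inherits(lib, "ReadLibrary"))
  if (!length(excluded)) return(lib)
  hits <- IRanges::overlapsAny(lib$tags, excluded, ignore.strand = TRUE)
  lib$tags <- lib$tags[!hits]
  lib
}

#' Write a bedGraph profile
#'
#' @param chrom,start0,end0,value parallel vectors; coordinates 0-based
#'   half-open.
#' @param path output path.
#' @export
write_bedgraph <- function(chrom, start0, end0, value, path) {
  writeLines(paste(chrom,
                   format(start0, scientific = FALSE, trim = TRUE),
                   format(end0, scientific = FALSE, trim = TRUE),
                   format(value, scientific = FALSE, trim = TRUE,
                          digits = 10),
                   sep = "\t"), path)
  invisible(path)
}
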
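## Synthetic data generator: a toy genome with genes, timing domains and
## planted G4 motifs; planted origins with firing probabilities; and read
## libraries with the statistical structure of a cell-free origin-labelling
## experiment (bidirectional forks, firing lag, sonication fragments,
## elongation background, unequal IP efficiency, uniform input).

#' Simulation configuration
#'
#' Defaults reflect the experimental system the pipeline targets: fork
#' progression 300 +/- 200 bp/min (truncated at 1 bp/min), firing lag
#' uniform on 0--10 min within a 15 min labelling window, sonication
#' fragments 100--1000 bp, a 3.5% dispersed elongation background from
#' contaminating S-phase nuclei, and replicate A at half the per-origin
#' depth of replicate B. About half the origins sit at TSS and three
#' quarters in early (S1/S2) timing windows, mirroring the catalogue-level
#' structure the analysis is meant to recover. Per-nucleus origin firing
#' probability is a free parameter (mean 0.3); per-origin values are spread
#' uniformly around the mean so efficient and weak origins coexist.
#'
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes genes to place (non-overlapping).
#' @param n_origins origins to plant.
#' @param frac_origins_at_tss fraction of origins placed in TSS windows.
#' @param frac_origins_early fraction placed in S1 or S2 timing windows.
#' @param firing_probability mean per-nucleus firing probability.
#' @param n_nuclei simulated nuclei per library.
#' @param fork_rate_mean,fork_rate_sd fork speed distribution (bp/min),
#'   truncated at 1.
#' @param labelling_time labelling duration (min).
#' @param max_lag maximum firing lag (min), uniform.
#' @param s_phase_background_fraction fraction of IP fragments placed
#'   uniformly genome-wide.
#' @param fragment_min,fragment_max sonication fragment length bounds (bp).
#' @param ip_efficiency_A,ip_efficiency_B relative IP efficiencies; library
#'   A receives `ip_efficiency_A / ip_efficiency_B` times the per-origin
#'   read depth of B.
#' @param reads_ip IP-B fragment count (A is scaled by the efficiency
#'   ratio).
#' @param reads_input input-library fragment count.
#' @param cluster_fraction fraction of origins planted < 5 kb from another
#'   origin of the same kind, creating origin clusters.
#' @param frac_origins_germline fraction flagged germline, each emitting a
#'   positive skew jump at its position.
#' @param n_negative_jumps negative-polarity jumps planted far (>= 50 kb)
#'   from any origin.
#' @param frac_tss_with_g4 fraction of TSS carrying a planted G4 motif.
#' @param timing_block,timing_overlap timing-domain tile size and overlap
#'   between adjacent classes (bp).
#' @param tss_halfwidth TSS window half-width (bp).
#' @param gene_length_range gene length bounds (bp).
#' @param with_sequence generate a genome sequence (needed for G4/skew
#'   work).
#' @param seed integer seed; all generator stages derive their streams from
#'   it.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_chromosomes = 4L, chrom_length = 5e6,
                       n_genes = 400L, n_origins = 250L,
                       frac_origins_at_tss = 0.5,
                       frac_origins_early = 0.75,
                       firing_probability = 0.3, n_nuclei = 200L,
                       fork_rate_mean = 300, fork_rate_sd = 200,
                       labelling_time = 15, max_lag = 10,
                       s_phase_background_fraction = 0.035,
                       fragment_min = 100L, fragment_max = 1000L,
                       ip_efficiency_A = 0.5, ip_efficiency_B = 1,
                       reads_ip = 200000L, reads_input = 100000L,
                       cluster_fraction = 0.15,
                       frac_origins_germline = 0.1,
                       n_negative_jumps = 25L,
                       frac_tss_with_g4 = 0.3,
                       timing_block = 400000L, timing_overlap = 20000L,
                       tss_halfwidth = 500L,
                       gene_length_range = c(2000L, 20000L),
                       with_sequence = TRUE, seed = 1L) {
  fracs <- c(frac_origins_at_tss, frac_origins_early, firing_probability,
             s_phase_background_fraction, cluster_fraction,
             frac_origins_germline, frac_tss_with_g4)
  stopifnot(all(fracs >= 0), all(fracs <= 1),
            fragment_min <= fragment_max, fragment_min > 0,
            labelling_time > 0, max_lag >= 0, max_lag <= labelling_time,
            n_chromosomes >= 1, chrom_length > 0, n_genes >= 0,
            n_origins >= 0, n_nuclei >= 1, fork_rate_mean > 0,
            ip_efficiency_A > 0, ip_efficiency_B > 0,
            reads_ip >= 0, reads_input >= 0,
            timing_block > 0, timing_overlap >= 0,
            timing_overlap < timing_block)
  structure(mget(names(formals(sim_config))), class = "SimConfig")
}

## deterministic per-stage seed split so each generator stage has its own
## stream regardless of what ran before it
stage_seed <- function(seed, stage) {
  offs <- c(genome = 11L, origins = 23L, libraries = 37L)
  (as.integer(seed) + offs[[stage]] * 1000003L) %% .Machine$integer.max
}

#' Generate a toy genome
#'
#' Builds chromosomes fully tiled by S1--S6 timing domains (contiguous
#' blocks cycling through the classes, with a small overlap between
#' adjacent blocks), non-overlapping genes with one TSS, alternating
#' exon/intron structure, sparse excluded regions, and -- when
#' `with_sequence` -- a random genome sequence with canonical G4 motifs
#' (`GGGTGGGTGGGTGGG`, non-G flanked) written in at a recorded subset of
#' TSS. Deterministic for a fixed seed.
#'
#' @param config a `SimConfig`.
#' @return A `GenomeModel` with tracks `genes`, `exons`, `introns`, `tss`,
#'   `timing`, `excluded` and `g4`.
#' @export
generate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(stage_seed(config$seed, "genome"), generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  sizes <- stats::setNames(rep(L, config$n_chromosomes), chroms)
  genome <- genome_model(sizes)
  si <- genome_seqinfo(genome)

  ## timing domains: blocks cycling S1..S6, each extended by the overlap
  timing <- do.call(c, lapply(chroms, function(cn) {
    starts0 <- seq.int(0L, L - 1L, by = config$timing_block)
    ends0 <- pmin(starts0 + config$timing_block + config$timing_overlap, L)
    cls <- paste0("S", (seq_along(starts0) - 1L) %% 6L + 1L)
    gr <- GenomicRanges::GRanges(cn, IRanges::IRanges(starts0 + 1L, ends0),
                                 seqinfo = si)
    names(gr) <- cls
    gr$timing_class <- cls
    gr
  }))

  ## genes: non-overlapping intervals, random strand, alternating
  ## exon/intron structure with the first exon at the TSS
  n_genes <- config$n_genes
  genes <- exons <- introns <- tss <- GenomicRanges::GRanges(seqinfo = si)
  if (n_genes > 0L) {
    per_chrom <- tabulate(sample.int(config$n_chromosomes, n_genes,
                                     replace = TRUE),
                          nbins = config$n_chromosomes)
    glen <- round(stats::runif(n_genes, config$gene_length_range[1L],
                               config$gene_length_range[2L]))
    gene_rows <- list()
    gi <- 0L
    for (ci in seq_len(config$n_chromosomes)) {
      k <- per_chrom[ci]
      if (!k) next
      lens <- glen[gi + seq_len(k)]
      ## place k genes without overlap: distribute the slack uniformly
      slack <- L - sum(lens)
      if (slack <= k) stop("chromosome too short to host the requested genes")
      gaps <- sort(sample.int(slack - 1L, k))
      starts0 <- gaps + cumsum(c(0, lens[-k]))
      gene_rows[[ci]] <- data.frame(chrom = chroms[ci], start0 = starts0,
                                    len = lens)
      gi <- gi + k
    }
    gdf <- do.call(rbind, gene_rows)
    gdf$strand <- sample(c("+", "-"), nrow(gdf), replace = TRUE)
    genes <- GenomicRanges::GRanges(gdf$chrom,
                                    IRanges::IRanges(gdf$start0 + 1L,
                                                     gdf$start0 + gdf$len),
                                    strand = gdf$strand, seqinfo = si)
    names(genes) <- sprintf("gene_%d", seq_along(genes))
    ## TSS: 5' end of the gene
    tss0 <- ifelse(gdf$strand == "+", gdf$start0, gdf$start0 + gdf$len - 1L)
    tss <- GenomicRanges::GRanges(gdf$chrom,
                                  IRanges::IRanges(tss0 + 1L, tss0 + 1L),
                                  strand = gdf$strand, seqinfo = si)
    names(tss) <- names(genes)
    ## exon/intron structure: 1-4 exons of 150-500 bp anchored at the 5'
    ## end, introns fill the remainder
    ex_list <- in_list <- list()
    for (i in seq_len(nrow(gdf))) {
      n_ex <- sample.int(4L, 1L)
      ex_len <- round(stats::runif(n_ex, 150, 500))
      in_len <- if (n_ex > 1L) {
        rest <- gdf$len[i] - sum(ex_len)
        if (rest < n_ex) { n_ex <- 1L; ex_len <- ex_len[1L]; integer() }
        else round(rest * diff(sort(c(0, stats::runif(n_ex - 2L), 1))))
      } else integer()
      pieces <- c(rbind(ex_len, c(in_len, 0)))[seq_len(2L * n_ex - 1L)]
      offs <- cumsum(c(0, pieces[-length(pieces)]))
      is_exon <- seq_along(pieces) %% 2L == 1L
      p_start0 <- gdf$start0[i] + offs
      p_end0 <- pmin(p_start0 + pieces, gdf$start0[i] + gdf$len[i])
      keep <- p_end0 > p_start0
      ex_list[[i]] <- data.frame(chrom = gdf$chrom[i],
                                 start0 = p_start0[is_exon & keep],
                                 end0 = p_end0[is_exon & keep])
      if (any(!is_exon & keep))
        in_list[[i]] <- data.frame(chrom = gdf$chrom[i],
                                   start0 = p_start0[!is_exon & keep],
                                   end0 = p_end0[!is_exon & keep])
    }
    edf <- do.call(rbind, ex_list)
    exons <- GenomicRanges::GRanges(edf$chrom,
                                    IRanges::IRanges(edf$start0 + 1L,
                                                     edf$end0),
                                    seqinfo = si)
    idf <- do.call(rbind, in_list)
    introns <- if (!is.null(idf) && nrow(idf))
      GenomicRanges::GRanges(idf$chrom,
                             IRanges::IRanges(idf$start0 + 1L, idf$end0),
                             seqinfo = si)
    else GenomicRanges::GRanges(seqinfo = si)
  }

  ## sparse excluded regions: two 10 kb intervals per chromosome
  ex_start0 <- unlist(lapply(seq_len(config$n_chromosomes), function(ci)
    floor(stats::runif(2L, 0, L - 10000))))
  excluded <- GenomicRanges::GRanges(
    rep(chroms, each = 2L),
    IRanges::IRanges(ex_start0 + 1L, ex_start0 + 10000L), seqinfo = si)

  ## sequence with planted G4 motifs at a subset of TSS
  g4 <- GenomicRanges::GRanges(seqinfo = si)
  sequence <- NULL
  motif <- "GGGTGGGTGGGTGGG"
  if (config$with_sequence) {
    sequence <- Biostrings::DNAStringSet(vapply(chroms, function(cn)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c(0.295, 0.205, 0.205, 0.295)), collapse = ""),
      ""))
    names(sequence) <- chroms
    if (length(tss) && config$frac_tss_with_g4 > 0) {
      n_g4 <- round(config$frac_tss_with_g4 * length(tss))
      if (n_g4 > 0L) {
        pick <- sort(sample.int(length(tss), n_g4))
        g4_chrom <- as.character(GenomeInfoDb::seqnames(tss))[pick]
        ## 1-based start of the "A<motif>A" patch; non-G flanks keep the
        ## planted coordinates exact under maximal run extension
        patch <- paste0("A", motif, "A")
        patch1 <- pmin(pmax(BiocGenerics::start(tss)[pick] + 100L, 1L),
                       L - nchar(patch) + 1L)
        for (i in seq_len(n_g4)) {
          Biostrings::subseq(sequence[[g4_chrom[i]]],
                             start = patch1[i],
                             width = nchar(patch)) <- Biostrings::DNAString(patch)
        }
        g4 <- GenomicRanges::GRanges(
          g4_chrom,
          IRanges::IRanges(patch1 + 1L, patch1 + nchar(motif)),
          strand = "+", seqinfo = si)
      }
    }
  }

  genome$sequence <- sequence
  genome <- set_track(genome, "genes", genes)
  genome <- set_track(genome, "exons", exons)
  genome <- set_track(genome, "introns", introns)
  genome <- set_track(genome, "tss", tss)
  genome <- set_track(genome, "timing", timing)
  genome <- set_track(genome, "excluded", excluded)
  genome <- set_track(genome, "g4", g4)
  genome
}

#' Plant origins on a synthetic genome
#'
#' Each origin independently draws its TSS flag (`frac_origins_at_tss`) and
#' early-timing flag (`frac_origins_early`) and is placed in the matching
#' stratum: inside the +/-`tss_halfwidth` window of a TSS of the requested
#' timing, or at a uniform non-TSS position of the requested timing,
#' avoiding excluded regions. A `cluster_fraction` of origins is planted
#' < 5 kb from an earlier origin of the same kind, creating origin
#' clusters. A `frac_origins_germline` subset is flagged germline and emits
#' a positive skew jump at its position; negative jumps are planted far
#' from any origin. Deterministic for a fixed seed.
#'
#' @param genome a `GenomeModel` from [generate_genome()].
#' @param config a `SimConfig`.
#' @return An object of class `SimulationTruth`: `origins` (1 bp `GRanges`
#'   with `firing_probability`, `timing_class`, `at_tss`, `has_g4`,
#'   `germline`) and `jumps` (stranded `GRanges`, `+` at germline origins).
#' @export
plant_origins <- function(genome, config = sim_config()) {
  stopifnot(inherits(genome, "GenomeModel"), inherits(config, "SimConfig"))
  for (tr in c("tss", "timing", "excluded"))
    if (is.null(genome$tracks[[tr]]))
      stop("genome model lacks required track '", tr, "'")
  with_seed(stage_seed(config$seed, "origins"),
            plant_origins_impl(genome, config))
}

plant_origins_impl <- function(genome, config) {
  si <- genome_seqinfo(genome)
  n <- config$n_origins
  timing <- get_track(genome, "timing")
  tss <- get_track(genome, "tss")
  excluded <- get_track(genome, "excluded")
  labels <- timing_labels(timing)
  classes <- paste0("S", 1:6)
  ## origin density declines from earliest to latest windows within each
  ## stratum, so planted catalogues show the early-skewed profile the
  ## assay recovers
  class_weight <- c(S1 = 0.6, S2 = 0.4,
                    S3 = 0.4, S4 = 0.3, S5 = 0.2, S6 = 0.1)
  class_rgn <- lapply(classes, function(cl)
    GenomicRanges::reduce(granges_only(timing[labels == cl])))
  names(class_rgn) <- classes
  tssw <- if (length(tss)) tss_window(tss, config$tss_halfwidth)
          else GenomicRanges::GRanges(seqinfo = si)
  avoid <- GenomicRanges::reduce(c(granges_only(excluded),
                                   granges_only(tssw)))
  early_rgn <- GenomicRanges::reduce(c(class_rgn$S1, class_rgn$S2))

  if (n == 0L)
    return(new_truth(GenomicRanges::GRanges(seqinfo = si),
                     GenomicRanges::GRanges(seqinfo = si)))

  at_tss <- stats::runif(n) < config$frac_origins_at_tss
  early <- stats::runif(n) < config$frac_origins_early
  satellite <- stats::runif(n) < config$cluster_fraction
  satellite[1L:min(2L, n)] <- FALSE   # need anchors to cluster around

  ## TSS indices and non-TSS placement regions stratified by timing class
  tss_class <- if (length(tss)) assign_timing_class(tss, timing)
               else character()
  free_by_class <- lapply(classes, function(cl) {
    r <- GenomicRanges::setdiff(class_rgn[[cl]], avoid)
    ## late placements must not fall into S1/S2 overlap zones, so the
    ## early/late split is exact by construction
    if (!cl %in% c("S1", "S2")) r <- GenomicRanges::setdiff(r, early_rgn)
    r
  })
  names(free_by_class) <- classes
  tss_early_any <- IRanges::overlapsAny(tss, early_rgn,
                                        ignore.strand = TRUE)
  is_early_pos <- function(cn, p0)
    IRanges::overlapsAny(GenomicRanges::GRanges(
      cn, IRanges::IRanges(p0 + 1L, p0 + 1L)), early_rgn)
  in_tss_window <- function(cn, p0)
    IRanges::overlapsAny(GenomicRanges::GRanges(
      cn, IRanges::IRanges(p0 + 1L, p0 + 1L)), tssw)
  draw_class <- function(is_early) {
    pool <- if (is_early) c("S1", "S2") else c("S3", "S4", "S5", "S6")
    sample(pool, 1L, prob = class_weight[pool])
  }

  pos0 <- integer(n); chrom <- character(n)
  used_tss <- integer(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    if (satellite[i]) {
      anchors <- which(seq_len(n) < i & at_tss[seq_len(n)] == at_tss[i] &
                       early[seq_len(n)] == early[i] & nzchar(chrom))
      if (length(anchors)) {
        a <- if (length(anchors) == 1L) anchors else sample(anchors, 1L)
        if (at_tss[i]) {
          off <- sample(c(-1L, 1L), 1L) * sample.int(100L, 1L)
        } else {
          off <- sample(c(-1L, 1L), 1L) * (500L + sample.int(4000L, 1L))
        }
        cand <- pos0[a] + off
        Lc <- genome$chrom_sizes[[chrom[a]]]
        cand <- pmin(pmax(cand, 0L), Lc - 1L)
        ## satellites must not drift out of their placement stratum
        if (is_early_pos(chrom[a], cand) == early[i] &&
            in_tss_window(chrom[a], cand) == at_tss[i]) {
          chrom[i] <- chrom[a]; pos0[i] <- cand
          placed <- TRUE
        }
      }
    }
    if (!placed && at_tss[i]) {
      cl <- draw_class(early[i])
      pool <- setdiff(which(tss_class == cl & tss_early_any == early[i]),
                      used_tss)
      if (!length(pool)) {
        ## fall back to any TSS of the same stratum before failing, so the
        ## early/late split stays exact
        pool <- setdiff(which(tss_early_any == early[i]), used_tss)
      }
      if (!length(pool))
        stop("more origins requested than available TSS placement sites")
      j <- if (length(pool) == 1L) pool else sample(pool, 1L)
      used_tss <- c(used_tss, j)
      t0 <- BiocGenerics::start(tss)[j] - 1L
      chrom[i] <- as.character(GenomeInfoDb::seqnames(tss))[j]
      cand <- t0 + sample.int(2L * config$tss_halfwidth, 1L) -
        config$tss_halfwidth - 1L
      cand <- pmax(pmin(cand, t0 + config$tss_halfwidth - 1L),
                   t0 - config$tss_halfwidth + 1L)
      cand <- pmax(cand, 0L)
      ## the offset may leave the timing stratum near a block boundary;
      ## the TSS base itself never does
      pos0[i] <- if (is_early_pos(chrom[i], cand) == early[i]) cand else t0
      placed <- TRUE
    }
    if (!placed) {
      cl <- draw_class(early[i])
      rgn <- free_by_class[[cl]]
      if (!length(rgn)) {
        stratum <- if (early[i]) c("S1", "S2") else c("S3", "S4", "S5", "S6")
        rgn <- do.call(c, unname(free_by_class[stratum]))
      }
      if (!length(rgn) || sum(BiocGenerics::width(rgn)) == 0)
        stop("no placement region available for the requested timing stratum")
      p <- sample_uniform_position(rgn)
      chrom[i] <- p$chrom; pos0[i] <- p$pos0
    }
  }

  origins <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(pos0 + 1L, pos0 + 1L),
                                    seqinfo = si)
  names(origins) <- sprintf("origin_%d", seq_len(n))

  ## per-origin firing probability spread around the configured mean
  fp <- config$firing_probability
  origins$firing_probability <- if (fp >= 0.05 && fp <= 0.95) {
    lo <- max(0.05, 2 * fp - 0.95)
    stats::runif(n, lo, 2 * fp - lo)
  } else rep(fp, n)

  ## recompute flags from geometry
  origins$at_tss <- IRanges::overlapsAny(origins, tssw,
                                         ignore.strand = TRUE)
  origins$timing_class <- assign_timing_class(origins, timing)
  g4 <- genome$tracks$g4
  origins$has_g4 <- origins$at_tss &
    IRanges::overlapsAny(tss_window(origins, config$tss_halfwidth),
                         if (is.null(g4)) GenomicRanges::GRanges() else g4,
                         ignore.strand = TRUE)
  germ <- stats::runif(n) < config$frac_origins_germline
  origins$germline <- germ

  ## jumps: + at germline origins, - far from all origins
  pos_jumps <- granges_only(origins[germ])
  BiocGenerics::strand(pos_jumps) <- "+"
  neg <- sample_far_positions(genome, origins, config$n_negative_jumps,
                              min_dist = 50000L)
  jumps <- c(pos_jumps, neg)
  names(jumps) <- NULL
  new_truth(origins, jumps)
}

new_truth <- function(origins, jumps) {
  structure(list(origins = origins, jumps = jumps),
            class = "SimulationTruth")
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat(sprintf("SimulationTruth: %d origins (%d germline), %d jumps\n",
              length(x$origins),
              sum(x$origins$germline %||% logical()),
              length(x$jumps)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiles_whole_genome <- function(genome) {
  GenomicRanges::GRanges(names(genome$chrom_sizes),
                         IRanges::IRanges(1L, unname(genome$chrom_sizes)),
                         seqinfo = genome_seqinfo(genome))
}

## draw one position uniformly over the bases of a region set
sample_uniform_position <- function(rgn) {
  w <- BiocGenerics::width(rgn)
  i <- sample.int(length(rgn), 1L, prob = w)
  off <- sample.int(w[i], 1L) - 1L
  list(chrom = as.character(GenomeInfoDb::seqnames(rgn))[i],
       pos0 = BiocGenerics::start(rgn)[i] - 1L + off)
}

## timing class of the window containing each position (first match)
assign_timing_class <- function(origins, timing) {
  labels <- timing_labels(timing)
  hits <- GenomicRanges::findOverlaps(origins, timing,
                                      ignore.strand = TRUE,
                                      select = "first")
  ifelse(is.na(hits), NA_character_, labels[hits])
}

## uniform positions at least min_dist from every origin
sample_far_positions <- function(genome, origins, k, min_dist = 50000L) {
  si <- genome_seqinfo(genome)
  if (k <= 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = si)
    return(gr)
  }
  near <- GenomicRanges::reduce(
    tss_window(granges_only(origins), min_dist))
  free <- GenomicRanges::setdiff(tiles_whole_genome(genome), near)
  if (!length(free)) stop("no room to place distal jumps")
  out <- lapply(seq_len(k), function(i) sample_uniform_position(free))
  gr <- GenomicRanges::GRanges(
    vapply(out, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(out, `[[`, 0L, "pos0") + 1L,
                     vapply(out, `[[`, 0L, "pos0") + 1L),
    strand = "-", seqinfo = si)
  gr
}

#' Simulate sequencing libraries
#'
#' Per simulated nucleus each origin fires with its per-origin probability
#' at a time drawn uniformly on `[0, max_lag]`; two labelled tracts extend
#' bidirectionally for the remaining labelling time at independently drawn
#' truncated-normal fork rates, clipped at chromosome ends. IP fragments
#' are sampled uniformly from the labelled tracts (midpoint uniform within
#' a tract chosen proportionally to its length, fragment length uniform on
#' `[fragment_min, fragment_max]`); a `s_phase_background_fraction` of
#' fragments is placed uniformly genome-wide, emulating the elongation
#' background from contaminating S-phase nuclei. Library A receives
#' `ip_efficiency_A / ip_efficiency_B` times the per-origin depth of B; the
#' input library is uniform genome-wide. Deterministic per seed.
#'
#' @param genome a `GenomeModel`.
#' @param truth a `SimulationTruth` from [plant_origins()].
#' @param config a `SimConfig`.
#' @return Named list of three `ReadLibrary` objects: `IP_A`, `IP_B`,
#'   `input`.
#' @export
simulate_libraries <- function(genome, truth, config = sim_config()) {
  stopifnot(inherits(genome, "GenomeModel"),
            inherits(truth, "SimulationTruth"),
            inherits(config, "SimConfig"))
  with_seed(stage_seed(config$seed, "libraries"),
            simulate_libraries_impl(genome, truth, config))
}

simulate_libraries_impl <- function(genome, truth, config) {
  si <- genome_seqinfo(genome)
  origins <- truth$origins
  ochrom <- as.character(GenomeInfoDb::seqnames(origins))
  opos0 <- BiocGenerics::start(origins) - 1L
  fp <- origins$firing_probability %||% rep(config$firing_probability,
                                            length(origins))

  ## one shared set of firing events per simulated experiment: both IP
  ## libraries sample fragments from the same replicated chromatin
  n_fire <- stats::rbinom(length(origins), config$n_nuclei, fp)
  oi <- rep(seq_along(origins), n_fire)
  tracts <- if (length(oi)) {
    t_fire <- stats::runif(length(oi), 0, config$max_lag)
    ext_time <- pmax(config$labelling_time - t_fire, 0)
    rate_l <- truncated_normal(length(oi), config$fork_rate_mean,
                               config$fork_rate_sd, lower = 1)
    rate_r <- truncated_normal(length(oi), config$fork_rate_mean,
                               config$fork_rate_sd, lower = 1)
    L <- genome$chrom_sizes[ochrom[oi]]
    lo0 <- pmax(opos0[oi] - round(ext_time * rate_l), 0)
    hi0 <- pmin(opos0[oi] + round(ext_time * rate_r), L)
    data.frame(origin = oi, chrom = ochrom[oi], lo0 = lo0, hi0 = hi0,
               len = pmax(hi0 - lo0, 1))
  } else data.frame(origin = integer(), chrom = character(),
                    lo0 = numeric(), hi0 = numeric(), len = numeric())

  sample_signal <- function(n) {
    if (!n || !nrow(tracts))
      return(data.frame(chrom = character(), mid0 = numeric(),
                        origin = integer()))
    ti <- sample.int(nrow(tracts), n, replace = TRUE, prob = tracts$len)
    mid0 <- floor(stats::runif(n, tracts$lo0[ti], tracts$hi0[ti]))
    data.frame(chrom = tracts$chrom[ti], mid0 = mid0,
               origin = tracts$origin[ti])
  }
  sample_uniform <- function(n) {
    if (!n) return(data.frame(chrom = character(), mid0 = numeric()))
    ci <- sample.int(length(genome$chrom_sizes), n, replace = TRUE,
                     prob = genome$chrom_sizes)
    cn <- names(genome$chrom_sizes)[ci]
    data.frame(chrom = cn,
               mid0 = floor(stats::runif(n, 0, genome$chrom_sizes[ci])))
  }
  to_library <- function(mids, name) {
    n <- nrow(mids)
    if (!n) {
      return(read_library(GenomicRanges::GRanges(seqinfo = si), name))
    }
    len <- round(stats::runif(n, config$fragment_min, config$fragment_max))
    L <- genome$chrom_sizes[mids$chrom]
    s0 <- pmax(mids$mid0 - len %/% 2, 0)
    e0 <- pmin(s0 + len, L)
    s0 <- pmax(pmin(s0, e0 - 1), 0)
    gr <- GenomicRanges::GRanges(
      mids$chrom, IRanges::IRanges(s0 + 1, e0),
      strand = sample(c("+", "-"), n, replace = TRUE), seqinfo = si)
    read_library(gr, name)
  }

  eff_ratio <- config$ip_efficiency_A / config$ip_efficiency_B
  make_ip <- function(total, name) {
    n_bg <- round(total * config$s_phase_background_fraction)
    n_sig <- total - n_bg
    if (!nrow(tracts)) n_sig <- 0L   # no origin fired: signal part empty
    to_library(rbind(sample_signal(n_sig)[c("chrom", "mid0")],
                     sample_uniform(n_bg)), name)
  }
  ip_b <- make_ip(config$reads_ip, "IP-B")
  ip_a <- make_ip(round(config$reads_ip * eff_ratio), "IP-A")
  input <- to_library(sample_uniform(config$reads_input), "input")
  list(IP_A = ip_a, IP_B = ip_b, input = input)
}

truncated_normal <- function(n, mean, sd, lower = 1) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < lower
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, lower)
}

#' Write the simulation truth to BED files
#'
#' Origins go to `origins.bed` (BED6 plus `firing_probability`,
#' `timing_class`, `at_tss`, `has_g4`, `germline` columns) and jumps to
#' `jumps.bed` (BED6; strand encodes polarity). Files round-trip through
#' [read_intervals_bed()] unchanged.
#'
#' @param truth a `SimulationTruth`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the two paths.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  op <- file.path(dir, "origins.bed")
  jp <- file.path(dir, "jumps.bed")
  o <- truth$origins
  extra <- intersect(c("firing_probability", "timing_class", "at_tss",
                       "has_g4", "germline"),
                     names(S4Vectors::mcols(o)))
  write_intervals_bed(o, op, extra_cols = extra)
  write_intervals_bed(truth$jumps, jp)
  invisible(c(origins = op, jumps = jp))
}

#' Read a simulation truth written by [write_truth()]
#'
#' @param dir directory containing `origins.bed` and `jumps.bed`.
#' @param genome optional `GenomeModel` for validation.
#' @return A `SimulationTruth`.
#' @export
read_truth <- function(dir, genome = NULL) {
  o <- read_intervals_bed(file.path(dir, "origins.bed"), genome = genome,
                          extra_cols = c("firing_probability",
                                         "timing_class", "at_tss",
                                         "has_g4", "germline"))
  for (col in c("at_tss", "has_g4", "germline"))
    if (!is.null(S4Vectors::mcols(o)[[col]]))
      S4Vectors::mcols(o)[[col]] <- as.logical(S4Vectors::mcols(o)[[col]])
  j <- read_intervals_bed(file.path(dir, "jumps.bed"), genome = genome)
  new_truth(o, j)
}
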
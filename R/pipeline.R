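## End-to-end driver: post-process -> call -> intersect -> randomise ->
## overlap analytics, with a reproducibility manifest; plus a simulate-and-
## evaluate wrapper that scores the called catalogue against planted truth.

#' Pipeline run configuration
#'
#' @param genome a `GenomeModel` (chromosomes plus any annotation tracks
#'   the enabled analyses need: `excluded`, `tss`, `exons`, `introns`,
#'   `timing`, `jumps`).
#' @param ip_a,ip_b `ReadLibrary` replicates.
#' @param input optional input `ReadLibrary` (required for
#'   `mode = "with_input"`).
#' @param caller a `CallerConfig`.
#' @param mode calling mode: `"no_input"` (default, the more sensitive and
#'   specific mode for this assay) or `"with_input"`.
#' @param jitter_halfwidth timing-jitter null half-width (bp).
#' @param analyses character vector of analysis toggles, any of
#'   `"annotation"`, `"timing"`, `"distances"`, `"venn"`, `"jumps"`,
#'   `"g4"`, `"skew"`.
#' @param distance_bin inter-origin distance bin (bp).
#' @param tss_halfwidth TSS annotation window half-width (bp).
#' @param jump_window_sizes nested jump window sizes (bp).
#' @param out_dir output directory, or `NULL` for in-memory results only.
#' @param seed global seed, split deterministically per stage.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(genome, ip_a, ip_b, input = NULL,
                       caller = caller_config(),
                       mode = c("no_input", "with_input"),
                       jitter_halfwidth = 240000L,
                       analyses = c("annotation", "timing", "distances",
                                    "venn", "jumps", "g4", "skew"),
                       distance_bin = 5000L, tss_halfwidth = 500L,
                       jump_window_sizes = c(2, 4, 6, 10, 20, 30, 40) * 1000,
                       out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (mode == "with_input" && is.null(input))
    stop("with_input mode requires an input library")
  structure(list(genome = genome, ip_a = ip_a, ip_b = ip_b, input = input,
                 caller = caller, mode = mode,
                 jitter_halfwidth = as.integer(jitter_halfwidth),
                 analyses = analyses, distance_bin = as.integer(distance_bin),
                 tss_halfwidth = as.integer(tss_halfwidth),
                 jump_window_sizes = jump_window_sizes,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full origin-calling pipeline
#'
#' Deduplicates and blacklist-filters both IP libraries, calls enrichment
#' islands per replicate, applies the one-window merge rule, intersects the
#' replicates into the origin catalogue, generates both randomised null
#' catalogues, and runs the enabled analyses against catalogue and nulls.
#' With `out_dir` set, writes origin/null BEDs, analysis TSV/JSON, a log
#' and a manifest of output checksums; a rerun with the same configuration
#' and inputs is bit-identical.
#'
#' @param cfg a `RunConfig`.
#' @return A list of class `PipelineResult` with elements `islands_a`,
#'   `islands_b`, `origins`, `null_chromosome`, `null_timing`, `summary`,
#'   `analyses` and (if written) `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  genome <- cfg$genome
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log <<- c(log, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  excluded <- cfg$genome$tracks$excluded %||% GenomicRanges::GRanges()
  prep <- function(lib) {
    lib <- deduplicate_tags(lib, cfg$caller$redundancy_threshold)
    filter_excluded(lib, excluded)
  }
  say("post-process: dedup (threshold %d) + excluded-region filter",
      cfg$caller$redundancy_threshold)
  ip_a <- stage("post-process", prep(cfg$ip_a))
  ip_b <- stage("post-process", prep(cfg$ip_b))
  input <- if (!is.null(cfg$input)) stage("post-process", prep(cfg$input))

  call_one <- function(lib) {
    isl <- if (cfg$mode == "with_input")
      call_islands_with_input(lib, input, genome, cfg$caller)
    else call_islands_no_input(lib, genome, cfg$caller)
    merge_adjacent(isl, cfg$caller)
  }
  say("call islands (%s mode)", cfg$mode)
  islands_a <- stage("call", call_one(ip_a))
  islands_b <- stage("call", call_one(ip_b))
  say("islands: A=%d, B=%d", length(islands_a), length(islands_b))

  origins <- stage("intersect", intersect_replicates(islands_a, islands_b))
  say("replicate-intersect catalogue: %d origins", length(origins))
  summary <- summarize_catalog(origins, genome,
                               libraries = list(IP_A = ip_a, IP_B = ip_b),
                               cfg = cfg$caller)

  null_chrom <- stage("randomise", randomize_within_chromosome(
    origins, genome,
    null_config("chromosome", seed = stage_seed(cfg$seed, "genome"))))
  null_timing <- stage("randomise", randomize_within_timing(
    origins, genome,
    null_config("timing_jitter", jitter_halfwidth = cfg$jitter_halfwidth,
                seed = stage_seed(cfg$seed, "origins"))))

  analyses <- list()
  sets <- list(origins = origins, null_chromosome = null_chrom,
               null_timing = null_timing)
  if ("annotation" %in% cfg$analyses && !is.null(genome$tracks$tss))
    analyses$annotation <- stage("annotation", lapply(sets, function(s)
      annotate_origins(s, get_track(genome, "tss"),
                       genome$tracks$exons %||% GenomicRanges::GRanges(),
                       genome$tracks$introns %||% GenomicRanges::GRanges(),
                       cfg$tss_halfwidth)))
  if ("timing" %in% cfg$analyses && !is.null(genome$tracks$timing))
    analyses$timing <- stage("timing", lapply(sets, function(s)
      timing_profile(s, get_track(genome, "timing"))))
  if ("distances" %in% cfg$analyses)
    analyses$distances <- stage("distances", lapply(sets, function(s)
      inter_origin_distances(s, cfg$distance_bin)))
  if ("venn" %in% cfg$analyses)
    analyses$venn <- stage("venn",
                           count_reciprocal(islands_a, islands_b))
  if ("jumps" %in% cfg$analyses && !is.null(genome$tracks$jumps))
    analyses$jumps <- stage("jumps", lapply(sets, function(s)
      jump_overlap_profile(s, get_track(genome, "jumps"),
                           cfg$jump_window_sizes)))
  if ("g4" %in% cfg$analyses && !is.null(genome$sequence))
    analyses$g4 <- stage("g4", {
      motifs <- scan_g4(genome$sequence)
      list(motifs = motifs,
           origin_overlap = count_reciprocal(origins, motifs))
    })
  if ("skew" %in% cfg$analyses && !is.null(genome$sequence))
    analyses$skew <- stage("skew", skew_profile(genome$sequence))

  result <- structure(list(islands_a = islands_a, islands_b = islands_b,
                           origins = origins,
                           null_chromosome = null_chrom,
                           null_timing = null_timing,
                           summary = summary, analyses = analyses,
                           log = log, config_seed = cfg$seed),
                      class = "PipelineResult")
  if (!is.null(cfg$out_dir))
    result$paths <- stage("write", write_pipeline_outputs(result, cfg))
  result
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("PipelineResult: %d origins (islands A=%d, B=%d)\n",
              length(x$origins), length(x$islands_a), length(x$islands_b)))
  invisible(x)
}

write_pipeline_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  paths <- c(origins = p("origins.bed"),
             islands_a = p("islands_A.bed"), islands_b = p("islands_B.bed"),
             null_chromosome = p("null_chromosome.bed"),
             null_timing = p("null_timing.bed"),
             summary_tsv = p("catalog_summary.tsv"),
             summary_json = p("catalog_summary.json"),
             log = p("pipeline.log"), manifest = p("manifest.json"))
  write_islands_bed(result$islands_a, paths["islands_a"])
  write_islands_bed(result$islands_b, paths["islands_b"])
  write_intervals_bed(result$origins, paths["origins"])
  write_intervals_bed(result$null_chromosome, paths["null_chromosome"])
  write_intervals_bed(result$null_timing, paths["null_timing"])
  write_catalog_summary(result$summary, paths["summary_tsv"],
                        paths["summary_json"])
  if (!is.null(result$analyses$venn))
    jsonlite::write_json(result$analyses$venn, p("venn.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(result$analyses$timing)) {
    tp <- result$analyses$timing
    df <- data.frame(class = names(tp$origins$percent),
                     origins_pct = as.numeric(tp$origins$percent),
                     null_chromosome_pct = as.numeric(tp$null_chromosome$percent),
                     null_timing_pct = as.numeric(tp$null_timing$percent))
    utils::write.table(df, p("timing_profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$analyses$annotation)) {
    an <- result$analyses$annotation
    df <- data.frame(category = names(an$origins$counts),
                     origins = as.integer(an$origins$counts),
                     null_chromosome = as.integer(an$null_chromosome$counts),
                     null_timing = as.integer(an$null_timing$counts))
    utils::write.table(df, p("annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLines(result$log, paths["log"])
  checksums <- tools::md5sum(setdiff(unname(paths), paths["manifest"]))
  names(checksums) <- basename(names(checksums))
  jsonlite::write_json(list(seed = result$config_seed,
                            checksums = as.list(checksums)),
                       paths["manifest"], auto_unbox = TRUE, digits = NA)
  paths
}

#' Simulate an experiment and evaluate the pipeline on it
#'
#' Generates a synthetic genome, plants origins, simulates the three
#' libraries, runs the full pipeline, and scores the called catalogue
#' against the planted truth: recall (planted origins recovered within
#' `tolerance` bp by a called origin) overall and for efficient origins
#' (firing probability at or above `efficient_min`), a precision proxy
#' (called origins within labelled-tract reach of a planted origin), the
#' replicate overlap asymmetry, and timing/TSS recovery summaries.
#'
#' @param sim a `SimConfig`.
#' @param caller a `CallerConfig`.
#' @param analyses analysis toggles passed to [run_config()].
#' @param out_dir optional output directory.
#' @param efficient_min firing-probability cut-off defining efficient
#'   origins.
#' @param tolerance recovery distance in bp.
#' @return A list of class `SimEvaluation` with the pipeline result, truth
#'   and scores.
#' @export
simulate_and_run <- function(sim = sim_config(), caller = caller_config(),
                             analyses = c("annotation", "timing",
                                          "distances", "venn", "jumps"),
                             out_dir = NULL, efficient_min = 0.3,
                             tolerance = 500L) {
  genome <- generate_genome(sim)
  truth <- plant_origins(genome, sim)
  genome <- set_track(genome, "jumps", truth$jumps)
  libs <- simulate_libraries(genome, truth, sim)
  cfg <- run_config(genome, ip_a = libs$IP_A, ip_b = libs$IP_B,
                    input = libs$input, caller = caller,
                    analyses = analyses, out_dir = out_dir,
                    tss_halfwidth = sim$tss_halfwidth, seed = sim$seed)
  result <- run_pipeline(cfg)

  scores <- score_against_truth(result, truth, sim,
                                efficient_min = efficient_min,
                                tolerance = tolerance)
  structure(list(result = result, truth = truth, scores = scores,
                 genome = genome, libraries = libs),
            class = "SimEvaluation")
}

score_against_truth <- function(result, truth, sim, efficient_min = 0.3,
                                tolerance = 500L) {
  origins <- result$origins
  planted <- truth$origins
  fp <- planted$firing_probability %||% rep(sim$firing_probability,
                                            length(planted))
  near <- tss_window(granges_only(planted), tolerance)
  recovered <- IRanges::overlapsAny(near, origins, ignore.strand = TRUE)
  eff <- fp >= efficient_min
  ## precision proxy: a called origin within labelled-tract reach of any
  ## planted origin (labelling_time * (mean + 4 sd) fork travel)
  reach <- sim$labelling_time * (sim$fork_rate_mean + 4 * sim$fork_rate_sd)
  reach_win <- tss_window(granges_only(planted), reach)
  called_near <- IRanges::overlapsAny(origins, reach_win,
                                      ignore.strand = TRUE)
  venn <- count_reciprocal(result$islands_a, result$islands_b)
  list(
    n_called = length(origins),
    n_planted = length(planted),
    recall_all = mean(recovered),
    recall_efficient = if (any(eff)) mean(recovered[eff]) else NA_real_,
    n_efficient = sum(eff),
    precision_proxy = if (length(origins)) mean(called_near) else NA_real_,
    frac_a_hit = if (length(result$islands_a))
      venn$n_a_hit / length(result$islands_a) else NA_real_,
    frac_b_hit = if (length(result$islands_b))
      venn$n_b_hit / length(result$islands_b) else NA_real_,
    tss_fraction_planted = mean(planted$at_tss %||% NA),
    early_fraction_planted = mean((planted$timing_class %||% NA) %in%
                                    c("S1", "S2")))
}

#' @export
print.SimEvaluation <- function(x, ...) {
  s <- x$scores
  cat(sprintf(paste0(
    "SimEvaluation: %d called / %d planted origins\n",
    "recall (efficient) = %.3f, recall (all) = %.3f, precision proxy = %.3f\n",
    "replicate overlap: A->B %.3f, B->A %.3f\n"),
    s$n_called, s$n_planted, s$recall_efficient, s$recall_all,
    s$precision_proxy, s$frac_a_hit, s$frac_b_hit))
  invisible(x)
}
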
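# Shared small fixtures, generated in code.

tiny_sim <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2L, chrom_length = 6e5, n_genes = 80L,
         n_origins = 30L, reads_ip = 30000L, reads_input = 15000L,
         timing_block = 50000L, timing_overlap = 5000L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

two_chrom_genome <- function(L = 100000L) {
  genome_model(c(chrA = L, chrB = L))
}

# a read library with tags at given 0-based start positions on one chrom
lib_at <- function(starts0, chrom = "chrA", width = 50L, strand = "+",
                   name = "test") {
  read_library(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts0 + 1L, starts0 + width),
    strand = strand), name)
}
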
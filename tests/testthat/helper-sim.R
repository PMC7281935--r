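# Shared fixtures: one small synthetic study reused across test files
# (regenerated per R session, cached in this environment).

.fixtures <- new.env(parent = emptyenv())

tiny_cfg <- function(seed = 11L, ...) {
  defaults <- list(
    seed = seed, n_chromosomes = 1L, chrom_length = 300000L,
    n_genes = 10L, n_key_genes = 3L, flank = 10000L,
    base_mut_rate = 2e-4, n_samples = 6L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

tiny_study <- function() {
  if (is.null(.fixtures$study)) .fixtures$study <- simulate_study(tiny_cfg())
  .fixtures$study
}

table1_path <- function() {
  system.file("extdata", "table1_swegbm1.tsv", package = "nccmscan")
}

# Brute-force per-base oracle: label of a single base for one gene, scanning
# its annotation naively. Returns NA when the base is not in the territory.
oracle_base_label <- function(genome, gene_id, pos, flank_bp) {
  i <- match(gene_id, genome$genes$gene_id)
  ch_len <- GenomeInfoDb::seqlengths(genome$seqinfo)[[
    as.character(GenomicRanges::seqnames(genome$genes))[i]]]
  g_start <- GenomicRanges::start(genome$genes)[i]
  g_end <- GenomicRanges::end(genome$genes)[i]
  in_any <- function(gr) {
    any(pos >= GenomicRanges::start(gr) & pos <= GenomicRanges::end(gr))
  }
  if (pos >= g_start & pos <= g_end) {
    if (in_any(genome$utr5[[gene_id]])) return("utr5")
    if (in_any(genome$utr3[[gene_id]])) return("utr3")
    if (in_any(genome$exons[[gene_id]])) return(NA_character_)  # coding exon
    return("intron")
  }
  if ((pos >= max(1, g_start - flank_bp) && pos < g_start) ||
      (pos > g_end && pos <= min(ch_len, g_end + flank_bp))) {
    return("flank")
  }
  NA_character_
}

# Allele-specific site key (re-derived here so tests state the contract
# independently of the package internals).
variant_key_public <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

# Canonical call table from truth rows (for feeding downstream modules
# without running the filtration cascade).
truth_as_calls <- function(truth) {
  df <- truth
  df$provenance <- "truth"
  df$filter_trail <- ""
  df[, c("sample_id", "chrom", "pos", "ref", "alt", "vtype", "ref_reads",
         "alt_reads", "provenance", "filter_trail")]
}
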
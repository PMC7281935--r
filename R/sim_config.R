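#' Configuration for the synthetic study generator
#'
#' Bundles every generative knob of the toy study: genome geometry, the
#' constrained-element density, per-sample somatic mutation rate, the planted
#' enrichment of constrained non-coding mutations inside key-gene territories,
#' caller discordance and germline contamination.
#'
#' Defaults emulate the study conditions the pipeline is designed for: a
#' two-chromosome megabase-scale toy genome, \eqn{\pm}100 kbp intergenic
#' flanks, ~15% of bases inside constrained elements (the fraction of variants
#' with rejected-substitutions score \eqn{\ge} 2 reported for a real GBM
#' cohort), 39 tumor samples, tumor depth ~75x, and a 4-fold planted elevation
#' of the constrained non-coding mutation rate near the designated key genes.
#' The per-base somatic rate is scaled up relative to a real tumor genome so a
#' megabase toy genome yields cohort-level counts; see the package vignette.
#'
#' @param seed integer seed; all generator output is a pure function of the
#'   config (including this seed).
#' @param n_chromosomes,chrom_length genome geometry (bp per chromosome).
#' @param n_genes,n_key_genes protein-coding gene count and how many are
#'   designated "key" genes (carriers of the planted enrichment).
#' @param flank intergenic flank, bp, added on both sides of each gene span
#'   when building query territories. Default 100,000.
#' @param constrained_block_rate target fraction of bases inside constrained
#'   elements (per-base score \eqn{\ge} 2).
#' @param base_mut_rate somatic mutations per bp per sample outside enriched
#'   regions.
#' @param enrichment_factor multiplier (\eqn{\ge} 1) applied to
#'   `base_mut_rate` at constrained non-coding positions inside key-gene
#'   territories.
#' @param n_samples number of tumor/normal pairs.
#' @param germline_contamination_rate expected fraction of a sample's emitted
#'   tumor calls that are leaked germline variants.
#' @param discordance_rate fraction of true somatic calls private to a single
#'   caller (the rest appear in both callers' VCFs).
#' @param artifact_rate expected caller-private false-positive calls per
#'   sample, as a fraction of the expected somatic count (per caller). These
#'   are what the caller-concordance step exists to remove.
#' @param sim_fraction fraction of somatic calls simulated as indels (1-5 bp).
#' @param mean_depth mean tumor sequencing depth (Poisson).
#' @param germline_db_sensitivity probability that a germline pool site is
#'   present in each germline database.
#'
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 1000000L,
                       n_genes = 40L,
                       n_key_genes = 8L,
                       flank = 100000L,
                       constrained_block_rate = 0.15,
                       base_mut_rate = 5e-05,
                       enrichment_factor = 4,
                       n_samples = 39L,
                       germline_contamination_rate = 0.1,
                       discordance_rate = 0.1,
                       artifact_rate = 0.1,
                       sim_fraction = 0.04,
                       mean_depth = 75,
                       germline_db_sensitivity = 0.9) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    n_key_genes = as.integer(n_key_genes), flank = as.integer(flank),
    constrained_block_rate = constrained_block_rate,
    base_mut_rate = base_mut_rate, enrichment_factor = enrichment_factor,
    n_samples = as.integer(n_samples),
    germline_contamination_rate = germline_contamination_rate,
    discordance_rate = discordance_rate, artifact_rate = artifact_rate,
    sim_fraction = sim_fraction,
    mean_depth = mean_depth,
    germline_db_sensitivity = germline_db_sensitivity
  )
  for (f in c("constrained_block_rate", "germline_contamination_rate",
              "discordance_rate", "artifact_rate", "sim_fraction",
              "germline_db_sensitivity")) {
    if (!is_fraction(cfg[[f]])) stopf("'%s' must be a fraction in [0,1]", f)
  }
  if (!is.numeric(cfg$base_mut_rate) || cfg$base_mut_rate < 0 ||
      cfg$base_mut_rate > 1) {
    stopf("'base_mut_rate' must be in [0,1]")
  }
  if (cfg$enrichment_factor < 1) stopf("'enrichment_factor' must be >= 1")
  if (cfg$flank <= 0) stopf("'flank' must be > 0")
  if (cfg$chrom_length <= 2L * cfg$flank) {
    stopf("'chrom_length' must exceed 2*flank (%d)", 2L * cfg$flank)
  }
  if (cfg$n_key_genes > cfg$n_genes) stopf("more key genes than genes")
  if (cfg$n_chromosomes < 1L) stopf("need at least one chromosome")
  structure(cfg, class = "sim_config")
}
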
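#' Pipeline thresholds
#'
#' Collects every numeric threshold of the analysis in one validated list.
#'
#' @param gerp_min constraint threshold for NCCM calling.
#' @param flank intergenic flank bp for territories.
#' @param pon_min panel-of-normals removal threshold.
#' @param fmg_min frequently-mutated-gene sample threshold.
#' @param rate_thresholds NCCM-per-100kbp ranking thresholds.
#' @param window affinity-scan window length (odd).
#' @param hotspot_min recurrence threshold.
#' @return validated list.
#' @export
pipeline_config <- function(gerp_min = 2, flank = 100000L, pon_min = 2L,
                            fmg_min = 4L, rate_thresholds = c(1, 2, 3, 4),
                            window = 41L, hotspot_min = 2L) {
  cfg <- list(gerp_min = gerp_min, flank = as.integer(flank),
              pon_min = as.integer(pon_min), fmg_min = as.integer(fmg_min),
              rate_thresholds = rate_thresholds,
              window = as.integer(window),
              hotspot_min = as.integer(hotspot_min))
  if (any(unlist(cfg[c("flank", "pon_min", "fmg_min", "window",
                       "hotspot_min")]) <= 0)) {
    stopf("pipeline thresholds must be positive")
  }
  cfg
}

#' Run the full NCCM pipeline on a synthetic study
#'
#' End-to-end orchestration: simulate (or accept) a study, run the
#' filtration cascade per sample, build territories, call NCCMs, compute
#' per-gene rates and the key-vs-OPCG enrichment test with its
#' constraint-site-rate control, rank genes, tally frequently mutated genes
#' from coding calls, annotate NCCMs against the regulatory tracks,
#' compute affinity deltas for the top-supported NCCMs, detect recurrent
#' hotspot sites with mutual exclusivity, and refit mutational signatures
#' per stratum. Deterministic given `(sim_cfg, thresholds)`.
#'
#' @param sim_cfg a [sim_config()], or an existing `sim_study`.
#' @param thresholds a [pipeline_config()].
#' @param out_dir optional directory: stage tables (TSV) and
#'   `summary.json` are written there.
#' @param trap_top number of NCCM sites to scan for affinity deltas.
#' @return a `pipeline_result` list with all stage outputs and a `summary`
#'   list (what `summary.json` contains).
#' @export
run_pipeline <- function(sim_cfg = sim_config(),
                         thresholds = pipeline_config(),
                         out_dir = NULL, trap_top = 3L) {
  study <- if (inherits(sim_cfg, "sim_study")) sim_cfg else
    simulate_study(sim_cfg)
  genome <- study$genome
  co <- study$cohort

  pon <- build_pon(co$normals)
  filtered <- lapply(co$samples, function(s) {
    filter_cascade(co$caller_a[co$caller_a$sample_id == s, ],
                   co$caller_b[co$caller_b$sample_id == s, ],
                   pon, co$germline_dbs, co$whitelist,
                   min_normals = thresholds$pon_min)
  })
  names(filtered) <- co$samples
  calls <- do.call(rbind, lapply(filtered, `[[`, "post_germline"))
  rownames(calls) <- NULL
  stage_counts <- Reduce(`+`, lapply(filtered, `[[`, "counts"))

  terrs <- build_territories(genome, flank_bp = thresholds$flank)
  key_ids <- genome$genes$gene_id[genome$genes$is_key]
  nccms <- call_nccms(calls, terrs, study$constraint, genome,
                      gerp_min = thresholds$gerp_min)
  rates <- nccm_rate(nccms, terrs, key_genes = key_ids)
  cfs <- vapply(terrs, constrained_fraction, numeric(1),
                constraint_track = study$constraint,
                threshold = thresholds$gerp_min)
  enr <- compare_groups(rates, constrained_fractions = cfs)
  ranking <- rank_genes(rates, thresholds$rate_thresholds)

  # FMG from coding (CDS-overlapping) filtered calls
  cds_all <- GenomicRanges::reduce(unlist(genome$cds), ignore.strand = TRUE)
  cgr <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, calls$pos))
  genes_gr <- genome$genes
  hit <- GenomicRanges::findOverlaps(cgr, genes_gr, ignore.strand = TRUE)
  coding_hit <- IRanges::overlapsAny(cgr, cds_all)
  inc <- data.frame(
    gene_id = genes_gr$gene_id[S4Vectors::subjectHits(hit)],
    sample_id = calls$sample_id[S4Vectors::queryHits(hit)],
    coding = coding_hit[S4Vectors::queryHits(hit)]
  )
  fmg <- fmg_frequency(inc[inc$coding, c("gene_id", "sample_id")],
                       min_samples = thresholds$fmg_min)

  nccms_ann <- annotate_nccms(nccms, study$tracks, proximity = 20L)
  reg_sum <- if (nrow(nccms_ann) > 0) regulatory_summary(nccms_ann) else
    NULL

  hotspots <- find_recurrent(calls, min_samples = thresholds$hotspot_min)
  me <- if (nrow(hotspots) >= 1) {
    mutual_exclusivity(utils::head(hotspots, 5))
  } else NULL

  # affinity deltas for the most recurrent NCCM sites
  models <- pfm_models(study$pfms)
  trap_sites <- utils::head(dedupe_nccm_sites(nccms), trap_top)
  deltas <- lapply(seq_len(nrow(trap_sites)), function(i) {
    s <- trap_sites[i, ]
    win <- variant_windows(genome, s$chrom, s$pos, s$ref, s$alt,
                           window = thresholds$window)
    d <- affinity_delta(win$wt, win$mut, models)
    d$site <- sprintf("%s:%d:%s>%s", s$chrom, s$pos, s$ref, s$alt)
    d
  })
  deltas <- if (length(deltas)) do.call(rbind, deltas) else NULL

  # signatures: total, coding/non-coding, constraint/non-constraint
  cons <- GenomicRanges::reduce(
    study$constraint[study$constraint$score >= thresholds$gerp_min])
  is_coding <- coding_hit
  is_cons <- IRanges::overlapsAny(cgr, cons)
  catalog <- make_signature_catalog(seed = study$config$seed)
  strat <- list(total = rep(TRUE, nrow(calls)), coding = is_coding,
                noncoding = !is_coding, constraint = is_cons,
                nonconstraint = !is_cons)
  sig <- lapply(strat, function(keep) {
    v <- count_contexts(calls[keep, , drop = FALSE], genome,
                        by_sample = FALSE)
    if (sum(v) == 0) return(NULL)
    refit(v, catalog)
  })

  summary <- list(
    seed = study$config$seed,
    n_samples = length(co$samples),
    filtration = as.list(stage_counts),
    n_nccms = nrow(nccms),
    enrichment = list(mean_key = enr$mean_key, mean_opcg = enr$mean_opcg,
                      t = enr$t_stat, p = enr$p_value,
                      control_p = enr$control_p),
    genes_ge_1_per_100kbp = length(ranking[[1]]),
    fmg = fmg$gene_id,
    fraction_annotated = if (is.null(reg_sum)) NA else
      reg_sum$fraction_annotated,
    n_hotspots = nrow(hotspots),
    exposures = lapply(sig, function(s) if (is.null(s)) NULL else
      as.list(s$exposures))
  )

  res <- structure(list(
    study = study, filtered = filtered, calls = calls,
    territories = terrs, nccms = nccms_ann, rates = rates,
    enrichment = enr, ranking = ranking, fmg = fmg,
    regulatory = reg_sum, hotspots = hotspots,
    mutual_exclusivity = me, affinity_deltas = deltas,
    signatures = sig, summary = summary
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, nm) {
      write.table(df, file.path(out_dir, nm), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    wt(calls, "filtered_calls.tsv")
    wt(nccms_ann, "nccms.tsv")
    wt(rates, "gene_rates.tsv")
    wt(hotspots, "hotspots.tsv")
    if (!is.null(deltas)) wt(deltas, "affinity_deltas.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
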
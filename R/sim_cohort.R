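#' Generate a synthetic tumor cohort with planted NCCM enrichment
#'
#' Plants somatic mutations in two strata: constrained non-coding bases inside
#' key-gene territories mutate at `base_mut_rate * enrichment_factor` per bp
#' per sample, everything else at `base_mut_rate`. Each true somatic call is
#' concordant between the two simulated callers with probability
#' `1 - discordance_rate` (otherwise private to exactly one). Read counts
#' follow depth ~ Poisson(`mean_depth`), alt ~ Binomial(depth, true VAF).
#' Germline variants from a shared population pool leak into both callers'
#' tumor output, populate the per-sample normal VCFs (the panel-of-normals
#' substrate), and seed the germline databases with sensitivity < 1; a small
#' fraction of true somatic sites is injected into a germline database, most
#' of which are recorded in the somatic whitelist, so the whitelisting rule
#' has real work to do.
#'
#' @param genome a `genome_model` with sequence.
#' @param constraint constraint track GRanges (from
#'   [generate_constraint_track()]).
#' @param config a [sim_config()].
#' @param territories optional precomputed [build_territories()] output for
#'   all genes at `config$flank` (rebuilt when absent).
#' @return a `sim_cohort` list: `truth` (one row per planted variant with
#'   labels: somatic/germline, constrained, key-territory membership, caller
#'   membership, true VAF), `caller_a`/`caller_b` (canonical call tables),
#'   `normals` (per-sample germline call tables), `germline_dbs` (list of
#'   site tables), `whitelist` (site table), `strata` (widths in bp of the
#'   enriched and background strata), `samples` (ids).
#' @export
generate_cohort <- function(genome, constraint, config,
                            territories = NULL) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  samples <- sprintf("S%03d", seq_len(config$n_samples))

  whole <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(genome$seqinfo),
    IRanges::IRanges(1L, GenomeInfoDb::seqlengths(genome$seqinfo)),
    seqinfo = genome$seqinfo
  )
  constrained <- GenomicRanges::reduce(constraint[constraint$score >= 2])
  cds_all <- GenomicRanges::reduce(unlist(genome$cds), ignore.strand = TRUE)
  terrs <- if (is.null(territories)) {
    build_territories(genome, flank_bp = config$flank)
  } else territories
  key_ids <- genome$genes$gene_id[genome$genes$is_key]
  key_union <- GenomicRanges::reduce(
    unlist(GenomicRanges::GRangesList(
      lapply(terrs[key_ids], function(t) GenomicRanges::granges(t$regions))
    )), ignore.strand = TRUE)
  enriched <- GenomicRanges::setdiff(
    GenomicRanges::intersect(constrained, key_union, ignore.strand = TRUE),
    cds_all, ignore.strand = TRUE)
  background <- GenomicRanges::setdiff(whole, enriched, ignore.strand = TRUE)
  w_enr <- sum(GenomicRanges::width(enriched))
  w_bg <- sum(GenomicRanges::width(background))

  all_terr_gr <- territory_granges(terrs)

  somatic <- list()
  for (s in samples) {
    n_enr <- rpois(1, w_enr * config$base_mut_rate * config$enrichment_factor)
    n_bg <- rpois(1, w_bg * config$base_mut_rate)
    pos <- rbind(sample_positions(enriched, n_enr),
                 sample_positions(background, n_bg))
    if (nrow(pos) == 0) next
    pos$sample_id <- s
    somatic[[s]] <- pos
  }
  somatic <- if (length(somatic)) do.call(rbind, somatic) else
    data.frame(chrom = character(), pos = integer(), sample_id = character())

  truth <- allele_table(somatic, genome, config)
  if (nrow(truth) > 0) {
    truth$is_germline <- FALSE
    truth$is_artifact <- FALSE
    truth$vaf_true <- rbeta(nrow(truth), 2, 3)
    conc <- runif(nrow(truth)) >= config$discordance_rate
    a_only <- !conc & runif(nrow(truth)) < 0.5
    truth$in_caller_a <- conc | a_only
    truth$in_caller_b <- conc | (!conc & !a_only)
  } else {
    truth$is_germline <- logical()
    truth$is_artifact <- logical()
    truth$vaf_true <- numeric()
    truth$in_caller_a <- logical()
    truth$in_caller_b <- logical()
  }

  # germline population pool
  e_som <- w_enr * config$base_mut_rate * config$enrichment_factor +
    w_bg * config$base_mut_rate
  n_pool <- if (config$germline_contamination_rate == 0) 0L else
    max(5L, round(config$germline_contamination_rate * e_som / 0.275))
  pool_pos <- sample_positions(whole, n_pool)
  pool_pos$sample_id <- rep("pool", nrow(pool_pos))
  pool <- allele_table(pool_pos, genome, config, snv_only = TRUE)
  pool$carrier_freq <- runif(nrow(pool), 0.05, 0.5)

  germ <- list()
  for (s in samples) {
    carried <- runif(nrow(pool)) < pool$carrier_freq
    if (!any(carried)) next
    g <- pool[carried, c("chrom", "pos", "ref", "alt", "vtype")]
    g$sample_id <- s
    g$vaf_true <- ifelse(runif(nrow(g)) < 0.1, 1.0, 0.5)
    germ[[s]] <- g
  }
  germ <- if (length(germ)) do.call(rbind, germ) else NULL
  if (!is.null(germ)) {
    germ$is_germline <- TRUE
    germ$is_artifact <- FALSE
    germ$in_caller_a <- TRUE   # systematic leakage: both callers see it
    germ$in_caller_b <- TRUE
    truth <- rbind(truth[, names(germ)], germ)
  }

  # caller-private sequencing artifacts (what consensus calling removes)
  if (config$artifact_rate > 0) {
    arts <- list()
    for (s in samples) {
      n_art <- rpois(2, config$artifact_rate * e_som)  # per caller
      if (sum(n_art) == 0) next
      ap <- sample_positions(whole, sum(n_art))
      ap$sample_id <- s
      a <- allele_table(ap, genome, config, snv_only = TRUE)
      a$vaf_true <- runif(nrow(a), 0.02, 0.15)
      a$is_germline <- FALSE
      a$is_artifact <- TRUE
      a$in_caller_a <- seq_len(nrow(a)) <= n_art[1]
      a$in_caller_b <- !a$in_caller_a
      arts[[s]] <- a
    }
    if (length(arts)) {
      arts <- do.call(rbind, arts)
      truth <- rbind(truth[, names(arts)], arts)
    }
  }

  # labels against constraint and key territories (anchor base)
  tgr <- GenomicRanges::GRanges(truth$chrom, IRanges::IRanges(truth$pos,
                                                              truth$pos))
  truth$constrained <- IRanges::overlapsAny(tgr, constrained)
  truth$in_key_territory <- IRanges::overlapsAny(tgr, key_union) &
    !IRanges::overlapsAny(tgr, cds_all)
  hit <- GenomicRanges::findOverlaps(tgr, all_terr_gr)
  tg <- rep(NA_character_, nrow(truth))
  first <- !duplicated(S4Vectors::queryHits(hit))
  tg[S4Vectors::queryHits(hit)[first]] <-
    all_terr_gr$gene_id[S4Vectors::subjectHits(hit)[first]]
  truth$territory_gene <- tg

  # read counts and caller tables
  depth <- pmax(10L, rpois(nrow(truth), config$mean_depth))
  alt_reads <- pmin(depth, pmax(1L, rbinom(nrow(truth), depth,
                                           truth$vaf_true)))
  truth$ref_reads <- depth - alt_reads
  truth$alt_reads <- alt_reads

  mk_caller <- function(flag, caller) {
    df <- truth[truth[[flag]], c("sample_id", "chrom", "pos", "ref", "alt",
                                 "vtype", "ref_reads", "alt_reads")]
    df$provenance <- rep(caller, nrow(df))
    df$filter_trail <- rep("", nrow(df))
    rownames(df) <- NULL
    as_calls(df)
  }

  # per-sample normal calls (germline only), depth regime of a normal sample
  normals <- lapply(samples, function(s) {
    g <- truth[truth$is_germline & truth$sample_id == s, ]
    if (nrow(g) == 0) return(empty_calls())
    nd <- pmax(8L, rpois(nrow(g), 38))
    na <- pmin(nd, pmax(1L, rbinom(nrow(g), nd, g$vaf_true)))
    as_calls(data.frame(
      sample_id = s, chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
      vtype = g$vtype, ref_reads = nd - na, alt_reads = na,
      provenance = "haplotype_caller", filter_trail = "",
      stringsAsFactors = FALSE
    ))
  })
  names(normals) <- samples

  # germline databases: pool sites at < 1 sensitivity, plus a misfiled 5% of
  # somatic sites, 80% of which are whitelisted as known somatic
  site_cols <- c("chrom", "pos", "ref", "alt")
  db1 <- pool[runif(nrow(pool)) < config$germline_db_sensitivity, site_cols]
  db2 <- pool[runif(nrow(pool)) < config$germline_db_sensitivity, site_cols]
  som_sites <- unique(truth[!truth$is_germline, site_cols])
  mis <- som_sites[runif(nrow(som_sites)) < 0.05, , drop = FALSE]
  wl <- mis[runif(nrow(mis)) < 0.8, , drop = FALSE]
  db1 <- unique(rbind(db1, mis))
  rownames(truth) <- rownames(db1) <- rownames(db2) <- rownames(wl) <- NULL

  structure(list(
    truth = truth,
    caller_a = mk_caller("in_caller_a", "caller_a"),
    caller_b = mk_caller("in_caller_b", "caller_b"),
    normals = normals,
    germline_dbs = list(db1 = db1, db2 = db2),
    whitelist = wl,
    strata = c(enriched = w_enr, background = w_bg),
    samples = samples,
    config = config
  ), class = "sim_cohort")
}

# Assign ref/alt alleles at sampled positions from the genome sequence;
# a configured fraction becomes 1-5 bp indels (unless snv_only).
allele_table <- function(pos_df, genome, config, snv_only = FALSE) {
  n <- nrow(pos_df)
  out <- data.frame(
    sample_id = character(n), chrom = character(n), pos = integer(n),
    ref = character(n), alt = character(n), vtype = character(n),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(out)
  out$sample_id <- pos_df$sample_id
  out$chrom <- pos_df$chrom
  out$pos <- pos_df$pos
  bases <- c("A", "C", "G", "T")
  is_indel <- if (snv_only) rep(FALSE, n) else
    runif(n) < config$sim_fraction
  # plain character views of the chromosomes: far cheaper than per-row
  # XStringSet subsetting
  seq_str <- setNames(as.character(genome$sequence),
                      names(genome$sequence))
  chr_len <- GenomeInfoDb::seqlengths(genome$seqinfo)
  ref1 <- substring(seq_str[out$chrom], out$pos, out$pos)
  out$ref <- ref1
  # random non-reference base, vectorized
  others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  out$alt <- others[cbind(match(ref1, bases),
                          sample.int(3L, n, replace = TRUE))]
  out$vtype <- "SPM"
  for (i in which(is_indel)) {
    L <- sample(1:5, 1)
    if (runif(1) < 0.5 && out$pos[i] + L <= chr_len[[out$chrom[i]]]) {
      # deletion anchored at pos
      out$ref[i] <- substring(seq_str[[out$chrom[i]]], out$pos[i],
                              out$pos[i] + L)
      out$alt[i] <- ref1[i]
    } else {
      out$alt[i] <- paste0(ref1[i],
                           paste(sample(bases, L, replace = TRUE),
                                 collapse = ""))
    }
    out$vtype[i] <- "SIM"
  }
  out
}

#' Generate a toy JASPAR-style PFM set
#'
#' Six position frequency matrices of varying width (6-15), integer counts
#' with constant per-column depth. One designated matrix ("FOXA1_like")
#' carries a near-invariant position (counts 97/1/1/1) mimicking a highly
#' conserved nucleotide in a forkhead-type motif, for use in affinity-delta
#' demonstrations.
#'
#' @param config a [sim_config()] (only the seed is used).
#' @param depth per-column count depth.
#' @return named list of 4 x W count matrices; the designated matrix carries
#'   attributes `designated = TRUE` and `invariant_col`.
#' @export
generate_pfms <- function(config, depth = 100L) {
  set.seed(config$seed + 3L)
  bases <- c("A", "C", "G", "T")
  mk <- function(w, conc = 0.5) {
    m <- vapply(seq_len(w), function(j) {
      p <- rgamma(4, conc); p <- p / sum(p)
      as.integer(rmultinom(1, depth - 4L, p)) + 1L  # keep counts positive
    }, integer(4))
    rownames(m) <- bases
    m
  }
  pfms <- list(
    TFA_like = mk(sample(6:9, 1)),
    TFB_like = mk(sample(8:12, 1)),
    TFC_like = mk(sample(10:15, 1)),
    TFD_like = mk(sample(6:8, 1)),
    TFE_like = mk(sample(9:13, 1))
  )
  w <- 12L
  foxa <- mk(w, conc = 0.3)
  inv_col <- 6L
  foxa[, inv_col] <- c(1L, 1L, 1L, 1L)
  foxa["T", inv_col] <- depth - 3L
  attr(foxa, "designated") <- TRUE
  attr(foxa, "invariant_col") <- inv_col
  pfms$FOXA1_like <- foxa
  pfms
}

#' Generate and optionally write a complete synthetic study
#'
#' Runs every generator (genome, constraint track, regulatory tracks, PFMs,
#' cohort) under one config and, when `out_dir` is given, writes the full
#' file layout: `genome.fa`, `genes.gtf`, `lincrna.bed`, `gerp.bedGraph`,
#' `tracks/` (BED6 + manifest), `jaspar_pfms.txt`, per-sample
#' `<S>.caller_a.vcf` / `<S>.caller_b.vcf` / `<S>.normal.vcf`,
#' `germline_db1.vcf`, `germline_db2.vcf`, `whitelist.vcf`, and `truth.tsv`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return a `sim_study` list: `genome`, `constraint`, `tracks`, `pfms`,
#'   `cohort`, `config`, and (if written) `paths`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  genome <- generate_genome(config)
  constraint <- generate_constraint_track(genome, config)
  tracks <- generate_regulatory_tracks(genome, config)
  pfms <- generate_pfms(config)
  cohort <- generate_cohort(genome, constraint, config)
  study <- structure(list(genome = genome, constraint = constraint,
                          tracks = tracks, pfms = pfms, cohort = cohort,
                          config = config), class = "sim_study")
  if (!is.null(out_dir)) {
    study$paths <- write_study(study, out_dir)
  }
  study
}

#' @rdname simulate_study
#' @param study a `sim_study`.
#' @param dir output directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- as.list(write_genome_files(study$genome, dir))
  paths$gerp <- write_constraint_bedgraph(
    study$constraint, file.path(dir, "gerp.bedGraph"))
  paths$tracks_manifest <- write_regulatory_tracks(
    study$tracks, file.path(dir, "tracks"))
  paths$pfms <- write_jaspar_pfms(study$pfms,
                                  file.path(dir, "jaspar_pfms.txt"))
  co <- study$cohort
  si <- study$genome$seqinfo
  vdir <- file.path(dir, "vcf")
  dir.create(vdir, showWarnings = FALSE)
  for (s in co$samples) {
    write_variant_vcf(co$caller_a[co$caller_a$sample_id == s, ],
                      file.path(vdir, paste0(s, ".caller_a.vcf")), s, si)
    write_variant_vcf(co$caller_b[co$caller_b$sample_id == s, ],
                      file.path(vdir, paste0(s, ".caller_b.vcf")), s, si)
    write_variant_vcf(co$normals[[s]],
                      file.path(vdir, paste0(s, ".normal.vcf")),
                      paste0("N_", s), si)
  }
  paths$vcf_dir <- vdir
  write_site_vcf(co$germline_dbs$db1, file.path(dir, "germline_db1.vcf"), si)
  write_site_vcf(co$germline_dbs$db2, file.path(dir, "germline_db2.vcf"), si)
  write_site_vcf(co$whitelist, file.path(dir, "whitelist.vcf"), si)
  paths$germline_dbs <- file.path(dir, c("germline_db1.vcf",
                                         "germline_db2.vcf"))
  paths$whitelist <- file.path(dir, "whitelist.vcf")
  paths$truth <- file.path(dir, "truth.tsv")
  write.table(co$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

# Sites-only VCF (no samples) for germline databases and the whitelist.
write_site_vcf <- function(sites, path, seqinfo = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2", "##source=nccmscan-simulator"), con)
  if (!is.null(seqinfo)) {
    for (ch in GenomeInfoDb::seqnames(seqinfo)) {
      writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                         GenomeInfoDb::seqlengths(seqinfo)[[ch]]), con)
    }
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"), con)
  if (nrow(sites) > 0) {
    o <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
    sites <- sites[o, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", sites$chrom,
                       sites$pos, sites$ref, sites$alt), con)
  }
  invisible(path)
}
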
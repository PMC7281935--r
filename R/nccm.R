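#' Assign a variant position to gene territories
#'
#' Returns one assignment per territory containing the position: the
#' territory's gene and a non-coding category (`utr5`, `utr3`, `intronic`,
#' or `intergenic` for flank hits). Positions inside any gene's coding exons
#' receive no assignments. Overlap with a lincRNA interval is recorded as a
#' logical flag on each assignment (the position keeps its territory
#' category).
#'
#' Indels are assigned at their anchor (leftmost) base.
#'
#' @param chrom,pos variant anchor coordinate (1-based).
#' @param territories list of `gene_territory` (or the flattened GRanges
#'   from the internal representation).
#' @param genome a `genome_model` (for coding exons and lincRNAs).
#' @return data.frame with columns `gene_id, category, lincRNA`; zero rows
#'   when unassigned.
#' @export
classify_variant <- function(chrom, pos, territories, genome) {
  tgr <- if (inherits(territories, "GRanges")) territories else
    territory_granges(territories)
  p <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  cds_all <- GenomicRanges::reduce(unlist(genome$cds), ignore.strand = TRUE)
  empty <- data.frame(gene_id = character(), category = character(),
                      lincRNA = logical(), stringsAsFactors = FALSE)
  if (IRanges::overlapsAny(p, cds_all)) return(empty)
  hits <- GenomicRanges::findOverlaps(p, tgr, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  j <- S4Vectors::subjectHits(hits)
  in_linc <- length(genome$lincRNAs) > 0 &&
    IRanges::overlapsAny(p, genome$lincRNAs, ignore.strand = TRUE)
  cat_map <- c(utr5 = "utr5", utr3 = "utr3", intron = "intronic",
               flank = "intergenic")
  out <- data.frame(
    gene_id = tgr$gene_id[j],
    category = unname(cat_map[tgr$label[j]]),
    lincRNA = in_linc, stringsAsFactors = FALSE
  )
  unique(out)
}

#' Call non-coding constraint mutations
#'
#' An NCCM is a (variant occurrence, gene) pair: a filtered somatic variant
#' whose anchor position (i) lies in the gene's query territory (UTRs,
#' introns, or intergenic flanks), (ii) is outside every coding exon, and
#' (iii) carries a constraint score at or above `gerp_min` (inclusive;
#' score exactly at the threshold is constrained). A variant inside several
#' genes' territories yields one record per gene; a recurrent site yields
#' one record per sample occurrence.
#'
#' @param variants canonical call table (filtration output).
#' @param territories list of `gene_territory`.
#' @param constraint_track GRanges with `score`; uncovered positions count
#'   as score `-Inf` (unconstrained).
#' @param genome a `genome_model`.
#' @param gerp_min constraint threshold (default 2).
#' @return NCCM table: one row per (variant, gene) with `sample_id, chrom,
#'   pos, ref, alt, vtype, gene_id, category, lincRNA, gerp_rs, vaf,
#'   vaf_bin`.
#' @export
call_nccms <- function(variants, territories, constraint_track, genome,
                       gerp_min = 2.0) {
  tgr <- territory_granges(territories)
  cds_all <- GenomicRanges::reduce(unlist(genome$cds), ignore.strand = TRUE)
  nccm_cols <- c("sample_id", "chrom", "pos", "ref", "alt", "vtype",
                 "gene_id", "category", "lincRNA", "gerp_rs", "vaf",
                 "vaf_bin")
  empty <- data.frame(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), vtype = character(),
    gene_id = character(), category = character(), lincRNA = logical(),
    gerp_rs = numeric(), vaf = numeric(), vaf_bin = character(),
    stringsAsFactors = FALSE
  )
  if (nrow(variants) == 0) return(empty)

  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos,
                                                 variants$pos))
  # constraint score at the anchor base
  sc_hit <- GenomicRanges::findOverlaps(vgr, constraint_track)
  score <- rep(-Inf, nrow(variants))
  first <- !duplicated(S4Vectors::queryHits(sc_hit))
  score[S4Vectors::queryHits(sc_hit)[first]] <-
    constraint_track$score[S4Vectors::subjectHits(sc_hit)[first]]

  coding <- IRanges::overlapsAny(vgr, cds_all)
  in_linc <- if (length(genome$lincRNAs)) {
    IRanges::overlapsAny(vgr, genome$lincRNAs, ignore.strand = TRUE)
  } else rep(FALSE, nrow(variants))

  hits <- GenomicRanges::findOverlaps(vgr, tgr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  keep <- !coding[qi] & score[qi] >= gerp_min
  qi <- qi[keep]; si <- si[keep]
  if (length(qi) == 0) return(empty)
  cat_map <- c(utr5 = "utr5", utr3 = "utr3", intron = "intronic",
               flank = "intergenic")
  vaf <- compute_vaf(variants[qi, , drop = FALSE])
  out <- data.frame(
    sample_id = variants$sample_id[qi],
    chrom = variants$chrom[qi], pos = variants$pos[qi],
    ref = variants$ref[qi], alt = variants$alt[qi],
    vtype = variants$vtype[qi],
    gene_id = tgr$gene_id[si],
    category = unname(cat_map[tgr$label[si]]),
    lincRNA = in_linc[qi],
    gerp_rs = score[qi], vaf = vaf, vaf_bin = vaf_bin(vaf),
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  rownames(out) <- NULL
  out[, nccm_cols]
}

#' Bin a variant allele fraction
#'
#' Contiguous partition of \[0,1\]: `low` = \[0, 0.10\], `mid` =
#' (0.10, 0.45\], `high` = (0.45, 1\]. The mid/high boundary resolves the
#' two conventions seen in browser-figure legends ("11-45%" vs "> 46%")
#' into a gap-free partition.
#'
#' @param vaf numeric vector in \[0,1\].
#' @return character vector in `{low, mid, high}`.
#' @export
vaf_bin <- function(vaf) {
  if (any(is.na(vaf)) || any(vaf < 0 | vaf > 1)) {
    stopf("VAF outside [0,1]")
  }
  ifelse(vaf <= 0.10, "low", ifelse(vaf <= 0.45, "mid", "high"))
}

#' Collapse recurrent identical NCCMs to unique sites
#'
#' Optional site-level deduplication: keeps one record per
#' `(gene, chrom, pos, ref, alt)` and adds `n_samples` support.
#'
#' @param nccms NCCM table from [call_nccms()].
#' @return deduplicated table with an `n_samples` column.
#' @export
dedupe_nccm_sites <- function(nccms) {
  key <- paste(nccms$gene_id, nccms$chrom, nccms$pos, nccms$ref, nccms$alt,
               sep = ":")
  n_samples <- vapply(split(nccms$sample_id, key),
                      function(s) length(unique(s)), integer(1))
  out <- nccms[!duplicated(key), , drop = FALSE]
  out$n_samples <- as.integer(n_samples[paste(out$gene_id, out$chrom,
                                              out$pos, out$ref, out$alt,
                                              sep = ":")])
  rownames(out) <- NULL
  out
}
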
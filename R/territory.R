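#' Build the queried territory of one gene
#'
#' A gene's territory is the genomic region over which its non-coding
#' constraint mutations are counted: 5'/3' UTRs, introns (gene span minus
#' exons), and the two intergenic flanks of `flank_bp` on each side of the
#' gene span (TSS-to-TES extent), clipped to the chromosome. Coding exons are
#' never part of a territory. Territories of different genes are built
#' independently, so one position may belong to several genes' territories;
#' by default flank bases overlapping a neighboring gene's exons are retained
#' (the downstream variant classifier excludes coding positions).
#'
#' @param gene_id gene identifier present in `genome`.
#' @param genome a `genome_model`.
#' @param flank_bp intergenic flank in bp (default 100,000).
#' @param exclude_other_exons if TRUE, remove every gene's coding exons from
#'   the territory intervals themselves (default FALSE: retain).
#' @return a `gene_territory` list: `gene_id`, `regions` (GRanges with a
#'   `label` column in `{utr5, utr3, intron, flank}`, disjoint within the
#'   gene), `total_length` (bp).
#' @export
build_territory <- function(gene_id, genome, flank_bp = 100000L,
                            exclude_other_exons = FALSE) {
  idx <- match(gene_id, genome$genes$gene_id)
  if (is.na(idx)) stopf("gene '%s' not in genome", gene_id)
  ch <- as.character(GenomicRanges::seqnames(genome$genes))[idx]
  g_start <- GenomicRanges::start(genome$genes)[idx]
  g_end <- GenomicRanges::end(genome$genes)[idx]
  L <- GenomeInfoDb::seqlengths(genome$seqinfo)[[ch]]

  # all interval arithmetic on light IRanges (single chromosome per gene);
  # per-gene interval lists may be injected by build_territories to avoid
  # repeated S4 list extraction
  feats <- attr(genome, "feature_cache")
  if (is.null(feats)) feats <- feature_lists(genome)
  exons <- IRanges::reduce(feats$exons[[gene_id]])
  utr5 <- IRanges::reduce(feats$utr5[[gene_id]])
  utr3 <- IRanges::reduce(feats$utr3[[gene_id]])

  introns <- IRanges::setdiff(IRanges::IRanges(g_start, g_end), exons)
  # UTR annotations take precedence where they overlap putative introns
  if (length(utr5)) introns <- IRanges::setdiff(introns, utr5)
  if (length(utr3)) introns <- IRanges::setdiff(introns, utr3)

  flanks <- IRanges::IRanges()
  if (g_start > 1L) {
    flanks <- c(flanks, IRanges::IRanges(max(1L, g_start - flank_bp),
                                         g_start - 1L))
  }
  if (g_end < L) {
    flanks <- c(flanks, IRanges::IRanges(g_end + 1L,
                                         min(L, g_end + flank_bp)))
  }

  pieces <- list(utr5 = utr5, utr3 = utr3, intron = introns,
                 flank = flanks)
  if (exclude_other_exons) {
    cds_all <- unlist(genome$cds)
    all_cds <- IRanges::reduce(IRanges::ranges(cds_all[
      as.character(GenomicRanges::seqnames(cds_all)) == ch]))
    pieces <- lapply(pieces, IRanges::setdiff, y = all_cds)
  }
  lens <- vapply(pieces, length, integer(1))
  all_ir <- do.call(c, unname(pieces))
  o <- order(IRanges::start(all_ir))
  regions <- GenomicRanges::GRanges(ch, all_ir[o],
                                    seqinfo = genome$seqinfo)
  regions$label <- rep(names(pieces), lens)[o]
  structure(list(
    gene_id = gene_id, regions = regions,
    total_length = sum(GenomicRanges::width(regions))
  ), class = "gene_territory")
}

#' Build territories for many genes
#'
#' @param genome a `genome_model`.
#' @param gene_ids gene identifiers (default: all genes).
#' @inheritParams build_territory
#' @return named list of `gene_territory` objects.
#' @export
build_territories <- function(genome, gene_ids = genome$genes$gene_id,
                              flank_bp = 100000L,
                              exclude_other_exons = FALSE) {
  attr(genome, "feature_cache") <- feature_lists(genome)
  out <- lapply(gene_ids, build_territory, genome = genome,
                flank_bp = flank_bp,
                exclude_other_exons = exclude_other_exons)
  names(out) <- gene_ids
  out
}

# One-shot extraction of the per-gene IRanges lists from the GRangesLists
# (element-wise [[ on a CompressedGRangesList is slow in a loop).
feature_lists <- function(genome) {
  as_ir_list <- function(grl) {
    out <- as.list(IRanges::ranges(grl))
    names(out) <- names(grl)
    out
  }
  list(exons = as_ir_list(genome$exons), cds = as_ir_list(genome$cds),
       utr5 = as_ir_list(genome$utr5), utr3 = as_ir_list(genome$utr3))
}

# Flatten a territory list into one GRanges with gene_id + label columns.
territory_granges <- function(territories) {
  grl <- lapply(territories, function(t) {
    gr <- t$regions
    if (length(gr)) gr$gene_id <- t$gene_id else gr$gene_id <- character(0)
    gr
  })
  unname(unlist(GenomicRanges::GRangesList(grl)))
}

#' Pool two gene lists into a key-gene set
#'
#' Set union with per-gene provenance, e.g. pooling an external cohort's
#' significantly mutated genes with this cohort's SMGs/FMGs.
#'
#' @param list_a,list_b character vectors of gene ids.
#' @param source_a,source_b provenance tags.
#' @return a `key_gene_set` list: `gene_ids` (sorted unique union) and
#'   `sources` (named list of tags per gene).
#' @export
assemble_key_gene_set <- function(list_a, list_b,
                                  source_a = "external",
                                  source_b = "cohort") {
  ids <- sort(unique(c(list_a, list_b)))
  sources <- lapply(ids, function(g) {
    c(if (g %in% list_a) source_a, if (g %in% list_b) source_b)
  })
  names(sources) <- ids
  structure(list(gene_ids = ids, sources = sources),
            class = "key_gene_set")
}

#' Constrained-base fraction of a territory
#'
#' Fraction of territory bases whose constraint score is at or above the
#' threshold; bases not covered by the track count as unconstrained. This is
#' the per-gene quantity for the constraint-site-rate control test (do key
#' genes simply sit in more constrained sequence?).
#'
#' @param territory a `gene_territory`.
#' @param constraint_track GRanges with `score`.
#' @param threshold constrained iff score >= threshold (default 2).
#' @return fraction in \[0,1\].
#' @export
constrained_fraction <- function(territory, constraint_track,
                                 threshold = 2.0) {
  if (territory$total_length == 0) {
    stopf("territory of gene '%s' has zero length", territory$gene_id)
  }
  cons <- GenomicRanges::reduce(
    constraint_track[constraint_track$score >= threshold])
  ov <- GenomicRanges::intersect(
    GenomicRanges::reduce(GenomicRanges::granges(territory$regions),
                          ignore.strand = TRUE),
    cons, ignore.strand = TRUE)
  sum(GenomicRanges::width(ov)) / territory$total_length
}
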
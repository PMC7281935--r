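#' Recurrently mutated sites across a cohort
#'
#' Sites are `(chrom, pos, ref, alt)` — the same position with a different
#' alt allele is a different site. Recurrence counts distinct samples (a
#' sample contributes once per site regardless of caller multiplicity).
#'
#' @param variants canonical call table for the cohort (all samples).
#' @param min_samples recurrence threshold (default 2).
#' @return data.frame `chrom, pos, ref, alt, n_samples, sample_ids`
#'   (comma-joined), sorted by decreasing `n_samples` then position.
#' @export
find_recurrent <- function(variants, min_samples = 2L) {
  if (nrow(variants) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      n_samples = integer(), sample_ids = character(),
                      stringsAsFactors = FALSE))
  }
  key <- variant_key(variants)
  by_site <- split(variants$sample_id, key)
  samples <- lapply(by_site, function(s) sort(unique(s)))
  n <- lengths(samples)
  keep <- n >= min_samples
  sites <- variants[match(names(by_site)[keep], key),
                    c("chrom", "pos", "ref", "alt"), drop = FALSE]
  sites$n_samples <- as.integer(n[keep])
  sites$sample_ids <- vapply(samples[keep], paste, character(1),
                             collapse = ",")
  sites <- sites[order(-sites$n_samples, sites$chrom, sites$pos,
                       sites$alt), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Strand-aware offset relative to a gene's translation start
#'
#' Offset 0 is the first base of the start codon; bases immediately
#' upstream of it (promoter side) are negative. For a plus-strand gene the
#' ATG is the leftmost CDS base and `offset = pos - atg`; for a
#' minus-strand gene the ATG is the rightmost CDS base and
#' `offset = atg - pos` (positions numerically above the ATG are upstream
#' and come out negative). This reproduces the usual "-124 bp" style
#' promoter-hotspot notation for genes on either strand.
#'
#' @param pos 1-based position on the gene's chromosome.
#' @param gene one-element GRanges with strand, or a `gene_id`.
#' @param genome a `genome_model` (for CDS lookup when `gene` is an id).
#' @return signed integer offset in bp.
#' @export
promoter_offset <- function(pos, gene, genome = NULL) {
  if (is.character(gene)) {
    stopifnot(!is.null(genome))
    cds <- genome$cds[[gene]]
    if (is.null(cds) || length(cds) == 0) {
      stopf("gene '%s' lacks an annotated CDS", gene)
    }
    strand <- as.character(GenomicRanges::strand(
      genome$genes[match(gene, genome$genes$gene_id)]))
  } else {
    cds <- gene$cds
    strand <- gene$strand
    if (is.null(cds) || length(cds) == 0) stopf("gene lacks a CDS")
  }
  if (strand == "+") {
    atg <- min(GenomicRanges::start(cds))
    pos - atg
  } else {
    atg <- max(GenomicRanges::end(cds))
    atg - pos
  }
}

#' Mutual exclusivity of hotspot sites
#'
#' For every pair of sites, counts samples carrying both; a pair is flagged
#' mutually exclusive iff no sample carries both. A single site is
#' vacuously exclusive.
#'
#' @param hotspots data.frame from [find_recurrent()] (needs
#'   `sample_ids`), or a named list of per-site sample-id vectors.
#' @return list: `pairs` (data.frame `site_a, site_b, co_count,
#'   exclusive`), `all_exclusive` (logical).
#' @export
mutual_exclusivity <- function(hotspots) {
  carriers <- if (is.data.frame(hotspots)) {
    setNames(strsplit(hotspots$sample_ids, ","),
             paste0(hotspots$chrom, ":", hotspots$pos, ":", hotspots$ref,
                    ">", hotspots$alt))
  } else hotspots
  k <- length(carriers)
  if (k < 1) stopf("no hotspot sites")
  if (k == 1) {
    return(list(pairs = data.frame(site_a = character(),
                                   site_b = character(),
                                   co_count = integer(),
                                   exclusive = logical()),
                all_exclusive = TRUE))
  }
  idx <- utils::combn(k, 2)
  pairs <- data.frame(
    site_a = names(carriers)[idx[1, ]],
    site_b = names(carriers)[idx[2, ]],
    co_count = vapply(seq_len(ncol(idx)), function(i) {
      length(intersect(carriers[[idx[1, i]]], carriers[[idx[2, i]]]))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  pairs$exclusive <- pairs$co_count == 0L
  list(pairs = pairs, all_exclusive = all(pairs$exclusive))
}
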
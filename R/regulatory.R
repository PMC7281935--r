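#' Annotate NCCMs with regulatory tracks
#'
#' Point-in-interval overlap of each NCCM's anchor base against every
#' annotation track. Adds, per NCCM: the overlapped `(track, element)` pairs
#' (semicolon-joined), a `support` count (number of distinct tracks hit —
#' positions recurring across independently curated tracks carry increased
#' likelihood of regulatory function), and optionally a proximity column
#' listing TFBS elements within `proximity` bp of the variant.
#'
#' @param nccms NCCM table from [call_nccms()].
#' @param tracks named list of GRanges with `element_id` labels and a `kind`
#'   attribute (`tfbs, histone, dnase, methylation, curated, other`).
#' @param proximity if not `NULL`, report tfbs-kind elements within this
#'   many bp in a `tfbs_within` column.
#' @return `nccms` with `annotations`, `support`, per-kind logical columns
#'   (`hit_<kind>`), and optionally `tfbs_within`.
#' @export
annotate_nccms <- function(nccms, tracks, proximity = NULL) {
  n <- nrow(nccms)
  vgr <- GenomicRanges::GRanges(nccms$chrom,
                                IRanges::IRanges(nccms$pos, nccms$pos))
  ann <- rep("", n)
  support <- integer(n)
  kinds <- unique(vapply(tracks, function(t) {
    k <- attr(t, "kind"); if (is.null(k)) "other" else k
  }, character(1)))
  kind_hit <- matrix(FALSE, n, length(kinds),
                     dimnames = list(NULL, kinds))
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    kind <- attr(tr, "kind"); if (is.null(kind)) kind <- "other"
    hits <- GenomicRanges::findOverlaps(vgr, tr, ignore.strand = TRUE)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    lab <- paste0(nm, ":", tr$element_id[S4Vectors::subjectHits(hits)])
    lab_by_q <- vapply(split(lab, qi), paste, character(1),
                       collapse = ";")
    idx <- as.integer(names(lab_by_q))
    ann[idx] <- ifelse(nzchar(ann[idx]), paste(ann[idx], lab_by_q,
                                               sep = ";"), lab_by_q)
    support[idx] <- support[idx] + 1L
    kind_hit[idx, kind] <- TRUE
  }
  nccms$annotations <- ann
  nccms$support <- support
  for (k in kinds) nccms[[paste0("hit_", k)]] <- kind_hit[, k]
  if (!is.null(proximity)) {
    tfbs <- tracks[vapply(tracks, function(t)
      identical(attr(t, "kind"), "tfbs"), logical(1))]
    prox <- rep("", n)
    for (nm in names(tfbs)) {
      tr <- tfbs[[nm]]
      hits <- GenomicRanges::findOverlaps(
        vgr, tr, maxgap = proximity, ignore.strand = TRUE)
      if (length(hits) == 0) next
      qi <- S4Vectors::queryHits(hits)
      lab <- tr$element_id[S4Vectors::subjectHits(hits)]
      lab_by_q <- vapply(split(lab, qi), paste, character(1),
                         collapse = ";")
      idx <- as.integer(names(lab_by_q))
      prox[idx] <- ifelse(nzchar(prox[idx]),
                          paste(prox[idx], lab_by_q, sep = ";"), lab_by_q)
    }
    nccms$tfbs_within <- prox
  }
  nccms
}

#' Summarize regulatory support of annotated NCCMs
#'
#' @param nccms annotated NCCM table from [annotate_nccms()].
#' @return a list: `n` (NCCM count), `fraction_annotated` (share with at
#'   least one track hit), `support_histogram` (table over support counts,
#'   sums to `n`), `per_kind` (hit counts per track kind; one NCCM may hit
#'   several kinds).
#' @export
regulatory_summary <- function(nccms) {
  if (nrow(nccms) == 0) stopf("empty NCCM table")
  if (is.null(nccms$support)) stopf("NCCMs are not annotated yet")
  kind_cols <- grep("^hit_", names(nccms), value = TRUE)
  per_kind <- vapply(kind_cols, function(cl) sum(nccms[[cl]]), integer(1))
  names(per_kind) <- sub("^hit_", "", kind_cols)
  list(
    n = nrow(nccms),
    fraction_annotated = mean(nccms$support >= 1),
    support_histogram = table(factor(nccms$support,
                                     levels = 0:max(nccms$support))),
    per_kind = per_kind
  )
}
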
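#' Read somatic calls from a VCF
#'
#' Loads a (single-sample) caller VCF into the canonical call table.
#' Multi-allelic records are split into biallelic calls at load time;
#' read counts come from the AD field when present.
#'
#' @param path VCF file.
#' @param sample_id sample identifier to stamp on the calls.
#' @param caller caller name recorded as provenance.
#' @return canonical call data.frame (`sample_id, chrom, pos, ref, alt,
#'   vtype, ref_reads, alt_reads, provenance, filter_trail`).
#' @export
read_caller_vcf <- function(path, sample_id, caller = "caller") {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0) return(empty_calls())
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  ad <- tryCatch(VariantAnnotation::geno(vcf)$AD, error = function(e) NULL)
  ref_reads <- alt_reads <- rep(0L, n)
  if (!is.null(ad)) {
    if (length(dim(ad)) == 3) {
      # expanded biallelic records: variants x samples x (ref, alt)
      ref_reads <- as.integer(ad[, 1, 1])
      alt_reads <- as.integer(ad[, 1, 2])
    } else if (length(dim(ad)) == 2) {
      pick <- function(k) vapply(seq_len(n), function(i) {
        v <- ad[i, 1][[1]]
        if (length(v) < k || is.na(v[k])) 0L else as.integer(v[k])
      }, integer(1))
      ref_reads <- pick(1L)
      alt_reads <- pick(2L)
    }
    ref_reads[is.na(ref_reads)] <- 0L
    alt_reads[is.na(alt_reads)] <- 0L
  }
  as_calls(data.frame(
    sample_id = sample_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt, vtype = infer_vtype(ref, alt),
    ref_reads = ref_reads, alt_reads = alt_reads,
    provenance = caller, filter_trail = "",
    stringsAsFactors = FALSE
  ))
}

#' Read a sites-only VCF into a site table
#'
#' For germline databases and somatic whitelists: only `(chrom, pos, ref,
#' alt)` is kept. Multi-allelic records are split.
#'
#' @param path VCF file.
#' @return data.frame with columns `chrom, pos, ref, alt`.
#' @export
read_site_vcf <- function(path) {
  vcf <- VariantAnnotation::expand(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF), alt = as.character(rr$ALT),
    stringsAsFactors = FALSE
  )
}

#' Caller-concordant call set
#'
#' A call is concordant iff `(chrom, pos, ref, alt)` match exactly between
#' the two callers' call sets for the same sample. Read counts are taken
#' from the designated caller (A by default); provenance records both.
#'
#' @param calls_a,calls_b canonical call tables from the same sample.
#' @param counts_from `"a"` or `"b"`: whose read counts survive.
#' @return concordant canonical call table.
#' @export
intersect_callers <- function(calls_a, calls_b, counts_from = c("a", "b")) {
  counts_from <- match.arg(counts_from)
  sa <- unique(calls_a$sample_id); sb <- unique(calls_b$sample_id)
  if (length(sa) > 1 || length(sb) > 1 ||
      (length(sa) == 1 && length(sb) == 1 && sa != sb)) {
    stopf("caller call sets are not from one common sample")
  }
  primary <- if (counts_from == "a") calls_a else calls_b
  other <- if (counts_from == "a") calls_b else calls_a
  keep <- variant_key(primary) %in% variant_key(other)
  out <- primary[keep, , drop = FALSE]
  if (nrow(out) > 0) {
    prov <- sort(unique(c(calls_a$provenance, calls_b$provenance)))
    out$provenance <- paste(prov, collapse = "+")
    out$filter_trail <- trail_push(out$filter_trail, "concordant:PASS")
  }
  rownames(out) <- NULL
  out
}

trail_push <- function(trail, entry) {
  ifelse(nzchar(trail), paste(trail, entry, sep = ";"), entry)
}

#' Build a panel of normals
#'
#' Tallies, per germline site `(chrom, pos, ref, alt)`, the number of normal
#' samples carrying it. Different alt alleles at one position are distinct
#' sites (allele-specific panel); a position-specific panel can be built
#' with `allele_specific = FALSE`.
#'
#' @param normal_calls list of canonical call tables, one per normal sample
#'   (e.g. from [read_caller_vcf()]).
#' @param allele_specific match on allele (default) or position only.
#' @return a `panel_of_normals`: named integer vector of per-site sample
#'   counts, with the matching mode as an attribute.
#' @export
build_pon <- function(normal_calls, allele_specific = TRUE) {
  keys <- unlist(lapply(normal_calls, function(df) {
    unique(variant_key(df, allele_specific))
  }))
  counts <- table(keys)
  out <- setNames(as.integer(counts), names(counts))
  attr(out, "allele_specific") <- allele_specific
  class(out) <- "panel_of_normals"
  out
}

#' Filter calls against a panel of normals
#'
#' Removes a call iff its site is carried by at least `min_normals` normal
#' samples in the panel.
#'
#' @param calls canonical call table.
#' @param pon a `panel_of_normals` from [build_pon()].
#' @param min_normals removal threshold (default 2: a site seen in two or
#'   more normals is treated as germline/artifact).
#' @return surviving calls, with the panel outcome appended to
#'   `filter_trail`.
#' @export
filter_pon <- function(calls, pon, min_normals = 2L) {
  keys <- variant_key(calls, isTRUE(attr(pon, "allele_specific")))
  counts <- unclass(pon)[keys]
  counts[is.na(counts)] <- 0L
  removed <- counts >= min_normals
  out <- calls[!removed, , drop = FALSE]
  if (nrow(out) > 0) {
    out$filter_trail <- trail_push(out$filter_trail, "pon:PASS")
  }
  rownames(out) <- NULL
  out
}

#' Germline-database filter with somatic whitelisting
#'
#' A call is removed iff it is present in at least one germline database and
#' absent from the somatic whitelist; calls found in a germline resource but
#' also catalogued as somatic (the whitelist) are retained.
#'
#' @param calls canonical call table.
#' @param germline_dbs list of site tables (`chrom, pos, ref, alt`).
#' @param whitelist_db site table of known-somatic sites (may be empty).
#' @return surviving calls with updated `filter_trail`.
#' @export
filter_germline <- function(calls, germline_dbs, whitelist_db = NULL) {
  db_keys <- unique(unlist(lapply(germline_dbs, variant_key)))
  wl_keys <- if (is.null(whitelist_db) || nrow(whitelist_db) == 0) {
    character()
  } else {
    unique(variant_key(whitelist_db))
  }
  keys <- variant_key(calls)
  in_db <- keys %in% db_keys
  in_wl <- keys %in% wl_keys
  removed <- in_db & !in_wl
  out <- calls[!removed, , drop = FALSE]
  if (nrow(out) > 0) {
    tag <- ifelse(in_db[!removed] & in_wl[!removed],
                  "germline:WHITELISTED", "germline:PASS")
    out$filter_trail <- trail_push(out$filter_trail, tag)
  }
  rownames(out) <- NULL
  out
}

#' Variant allele fraction
#'
#' `alt_reads / (ref_reads + alt_reads)`; errors on zero depth.
#'
#' @param calls canonical call table (or any data.frame with `ref_reads`,
#'   `alt_reads`).
#' @return numeric vector of fractions in \[0,1\].
#' @export
compute_vaf <- function(calls) {
  depth <- calls$ref_reads + calls$alt_reads
  if (any(depth <= 0)) {
    stopf("zero read depth at %d call(s); VAF undefined", sum(depth <= 0))
  }
  calls$alt_reads / depth
}

#' Run the full filtration cascade for one sample
#'
#' Concordance -> panel of normals -> germline databases (with
#' whitelisting), in the fixed order; each step is a subset of the previous.
#'
#' @param calls_a,calls_b per-caller call tables for one sample.
#' @param pon a `panel_of_normals`.
#' @param germline_dbs list of site tables.
#' @param whitelist_db site table.
#' @param min_normals panel removal threshold.
#' @return list with per-stage call tables: `concordant`, `post_pon`,
#'   `post_germline` (the final set), and `counts` per stage.
#' @export
filter_cascade <- function(calls_a, calls_b, pon, germline_dbs,
                           whitelist_db = NULL, min_normals = 2L) {
  conc <- intersect_callers(calls_a, calls_b)
  post_pon <- filter_pon(conc, pon, min_normals)
  post_germ <- filter_germline(post_pon, germline_dbs, whitelist_db)
  list(
    concordant = conc, post_pon = post_pon, post_germline = post_germ,
    counts = c(caller_a = nrow(calls_a), caller_b = nrow(calls_b),
               concordant = nrow(conc), post_pon = nrow(post_pon),
               post_germline = nrow(post_germ))
  )
}
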
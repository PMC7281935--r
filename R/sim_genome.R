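#' Generate a toy genome with gene models
#'
#' Builds a deterministic toy genome: uniform-random chromosome sequences and
#' non-overlapping protein-coding gene models (multi-exon, stranded, with CDS
#' and both UTRs), plus a handful of intergenic lincRNA intervals. A random
#' subset of `n_key_genes` genes is flagged as the key-gene set that carries
#' the planted enrichment downstream.
#'
#' All coordinates are 1-based closed ([IRanges::IRanges]); file writers emit
#' the standard dialects (GTF/VCF 1-based, BED/bedGraph 0-based half-open).
#'
#' @param config a [sim_config()].
#' @return a `genome_model` list: `seqinfo` ([GenomeInfoDb::Seqinfo]),
#'   `sequence` ([Biostrings::DNAStringSet]), `genes` (GRanges of gene spans
#'   with `gene_id`, `is_key`), and per-gene [GenomicRanges::GRangesList]s
#'   `exons`, `cds`, `utr5`, `utr3`, plus `lincRNAs` (GRanges).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  lens <- setNames(rep(config$chrom_length, config$n_chromosomes), chroms)
  si <- GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = unname(lens))

  seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    rawToChar(as.raw(c(65L, 67L, 71L, 84L)[  # A C G T, uniform
      sample.int(4L, lens[[ch]], replace = TRUE)]))
  }, character(1)))

  # distribute genes round-robin over chromosomes, then place non-overlapping
  # spans per chromosome by allocating the free space between them
  gene_chrom <- chroms[(seq_len(config$n_genes) - 1L) %% length(chroms) + 1L]
  spans <- list()
  for (ch in chroms) {
    k <- sum(gene_chrom == ch)
    if (k == 0L) next
    glens <- sample(5000:30000, k, replace = TRUE)
    free <- lens[[ch]] - sum(glens)
    if (free < (k + 1L) * 100L) {
      stopf("chromosome %s too short for %d genes", ch, k)
    }
    gaps <- as.integer(rmultinom(1, free - (k + 1L) * 100L,
                                 rep(1, k + 1L))) + 100L
    starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0L, glens[-k]))
    spans[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = starts + 1L, width = glens),
      strand = sample(c("+", "-"), k, replace = TRUE), seqinfo = si
    )
  }
  genes <- if (length(spans)) {
    sort(do.call(c, unname(spans)), ignore.strand = TRUE)
  } else {
    GenomicRanges::GRanges(seqinfo = si)
  }
  genes$gene_id <- sprintf("G%03d", seq_along(genes))
  genes$is_key <- genes$gene_id %in%
    sample(genes$gene_id, config$n_key_genes)

  parts <- do.call(rbind, lapply(seq_along(genes), function(i) {
    df <- build_gene_parts(GenomicRanges::start(genes)[i],
                           GenomicRanges::end(genes)[i])
    strand <- as.character(GenomicRanges::strand(genes))[i]
    df$part[df$part == "utr_left"] <- if (strand == "+") "utr5" else "utr3"
    df$part[df$part == "utr_right"] <- if (strand == "+") "utr3" else "utr5"
    df$gene_id <- genes$gene_id[i]
    df$chrom <- as.character(GenomicRanges::seqnames(genes))[i]
    df$strand <- strand
    df
  }))
  if (is.null(parts)) {
    parts <- data.frame(part = character(), start = integer(),
                        end = integer(), gene_id = character(),
                        chrom = character(), strand = character())
  }
  grl <- function(field) {
    sub <- parts[parts$part == field, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(sub$start, sub$end),
      strand = sub$strand, seqinfo = si
    )
    GenomicRanges::split(gr, factor(sub$gene_id,
                                    levels = genes$gene_id))
  }

  # intergenic lincRNA intervals in the gaps between genes
  inter <- GenomicRanges::gaps(genes, ignore.strand = TRUE)
  inter <- inter[GenomicRanges::strand(inter) == "*" &
                   GenomicRanges::width(inter) > 6000]
  n_linc <- max(1L, config$n_genes %/% 10L)
  linc <- GenomicRanges::GRanges(seqinfo = si)
  if (length(inter) > 0) {
    pick <- inter[sample.int(length(inter), min(n_linc, length(inter)))]
    st <- GenomicRanges::start(pick) +
      floor(runif(length(pick)) * (GenomicRanges::width(pick) - 5000))
    linc <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(pick),
      IRanges::IRanges(st, width = sample(1000:5000, length(pick),
                                          replace = TRUE)),
      strand = sample(c("+", "-"), length(pick), replace = TRUE),
      seqinfo = si
    )
    linc$linc_id <- sprintf("LINC%02d", seq_along(linc))
  }

  structure(list(
    seqinfo = si, sequence = seqs, genes = genes,
    exons = grl("exon"), cds = grl("cds"),
    utr5 = grl("utr5"), utr3 = grl("utr3"), lincRNAs = linc
  ), class = "genome_model")
}

# Split one gene span into alternating exon/intron segments, then carve the
# exonic sequence into 5'UTR / CDS / 3'UTR in transcription order. Pure
# integer arithmetic; strand is applied by the caller when naming UTR sides.
# Returns a data.frame (part, start, end) with part in
# {exon, cds, utr_left, utr_right}, later relabeled utr5/utr3 by strand.
build_gene_parts <- function(g_start, g_end) {
  w <- g_end - g_start + 1L
  k <- sample(2:8, 1)
  wts <- runif(2L * k - 1L, 0.5, 1.5)
  wts[seq(2, 2L * k - 2L, by = 2)] <- wts[seq(2, 2L * k - 2L, by = 2)] * 2
  seg <- pmax(50L, as.integer(round(wts / sum(wts) * w)))
  seg[length(seg)] <- w - sum(seg[-length(seg)])
  stopifnot(seg[length(seg)] >= 50L)
  bnd <- cumsum(c(0L, seg))
  ex_i <- seq(1, 2L * k - 1L, by = 2)
  g0 <- g_start - 1L
  ex_st <- g0 + bnd[ex_i] + 1L
  ex_en <- g0 + bnd[ex_i + 1L]
  # exonic (spliced, left-to-right) coordinates of CDS start/end
  ew <- ex_en - ex_st + 1L
  E <- sum(ew)
  cs <- max(2L, as.integer(floor(E * runif(1, 0.10, 0.30))))
  ce <- min(E - 1L, as.integer(ceiling(E * runif(1, 0.70, 0.95))))
  map <- function(a, b) {
    cw <- cumsum(c(0L, ew))
    hits <- which(cw[-length(cw)] < b & cw[-1] >= a)
    data.frame(
      start = pmax(ex_st[hits], ex_st[hits] + (a - 1L - cw[hits])),
      end = pmin(ex_en[hits], ex_st[hits] + (b - 1L - cw[hits]))
    )
  }
  blocks <- list(
    exon = data.frame(start = ex_st, end = ex_en),
    cds = map(cs, ce),
    utr_left = if (cs > 1L) map(1L, cs - 1L) else NULL,
    utr_right = if (ce < E) map(ce + 1L, E) else NULL
  )
  out <- do.call(rbind, lapply(names(blocks), function(p) {
    b <- blocks[[p]]
    if (is.null(b) || nrow(b) == 0) return(NULL)
    cbind(part = p, b)
  }))
  out
}

#' Generate a block-structured per-base constraint track
#'
#' Emulates a rejected-substitutions (GERP-like) conservation track as a
#' two-component mixture: contiguous constrained elements whose per-base score
#' is \eqn{\ge} 2, embedded in background whose score is < 2. Element and gap
#' lengths are exponential, calibrated so the realized constrained fraction
#' matches `config$constrained_block_rate`.
#'
#' @param genome a `genome_model`.
#' @param config a [sim_config()].
#' @return GRanges with a numeric `score` column; contiguous non-overlapping
#'   blocks, constant score per block (a run-length encoding of the per-base
#'   track). Suitable for [rtracklayer::export()] as bedGraph.
#' @export
generate_constraint_track <- function(genome, config) {
  set.seed(config$seed + 1L)
  p <- config$constrained_block_rate
  mean_elem <- 200
  out <- list()
  for (ch in GenomeInfoDb::seqnames(genome$seqinfo)) {
    L <- GenomeInfoDb::seqlengths(genome$seqinfo)[[ch]]
    if (p <= 0) {
      st <- seq(1L, L, by = 1000L)
      out[[ch]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(st, pmin(st + 999L, L)),
        score = runif(length(st), -12, 1.9), seqinfo = genome$seqinfo
      )
      next
    }
    mean_gap <- mean_elem * (1 - p) / p
    n <- ceiling(L / (mean_elem + mean_gap) * 1.3) + 50L
    gaps <- pmax(1L, as.integer(round(rexp(n, 1 / mean_gap))))
    elems <- pmax(20L, as.integer(round(rexp(n, 1 / mean_elem))))
    # alternate gap, element, gap, element ... from base 1
    widths <- as.vector(rbind(gaps, elems))
    ends <- cumsum(as.numeric(widths))
    keep <- ends <= L
    widths <- widths[keep]
    starts <- c(1, ends[keep][-sum(keep)] + 1)
    is_elem <- (seq_along(widths) %% 2L) == 0L
    gr <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(as.integer(starts), width = widths),
      seqinfo = genome$seqinfo
    )
    gr$score <- ifelse(is_elem, runif(length(gr), 2, 7),
                       runif(length(gr), -12, 1.9))
    # trailing remainder is background
    if (max(ends[keep]) < L) {
      tail_gr <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(as.integer(max(ends[keep]) + 1), L),
        seqinfo = genome$seqinfo
      )
      tail_gr$score <- runif(1, -12, 1.9)
      gr <- c(gr, tail_gr)
    }
    out[[ch]] <- gr
  }
  do.call(c, unname(out))
}

#' Generate synthetic regulatory annotation tracks
#'
#' Four independent interval tracks (TFBS, histone mark, DNase, methylation)
#' each covering a configurable fraction of the genome, with per-element
#' labels. Stand-ins for curated browser tracks, used to exercise the
#' annotation and multi-track support summaries.
#'
#' @param genome a `genome_model`.
#' @param config a [sim_config()].
#' @param coverage named fractions of the genome covered per track.
#' @return named list of GRanges, each with `element_id` labels and a `kind`
#'   attribute in `{tfbs, histone, dnase, methylation}`.
#' @export
generate_regulatory_tracks <- function(genome, config,
                                       coverage = c(TFBS = 0.10,
                                                    H3K4Me3 = 0.15,
                                                    DNase = 0.12,
                                                    Methyl = 0.20)) {
  set.seed(config$seed + 4L)
  kinds <- c(TFBS = "tfbs", H3K4Me3 = "histone", DNase = "dnase",
             Methyl = "methylation")
  tracks <- list()
  for (nm in names(coverage)) {
    p <- coverage[[nm]]
    segs <- list()
    for (ch in GenomeInfoDb::seqnames(genome$seqinfo)) {
      L <- GenomeInfoDb::seqlengths(genome$seqinfo)[[ch]]
      mean_elem <- 300
      mean_gap <- mean_elem * (1 - p) / p
      n <- ceiling(L / (mean_elem + mean_gap) * 1.3) + 20L
      gaps <- pmax(1, round(rexp(n, 1 / mean_gap)))
      elems <- pmax(30, round(rexp(n, 1 / mean_elem)))
      ends <- cumsum(as.numeric(as.vector(rbind(gaps, elems))))
      st <- ends[seq(1, length(ends), by = 2)] + 1
      en <- ends[seq(2, length(ends), by = 2)]
      keep <- en <= L
      segs[[ch]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(as.integer(st[keep]), as.integer(en[keep])),
        seqinfo = genome$seqinfo
      )
    }
    gr <- do.call(c, unname(segs))
    gr$element_id <- sprintf("%s_%04d", nm, seq_along(gr))
    attr(gr, "kind") <- kinds[[nm]]
    tracks[[nm]] <- gr
  }
  tracks
}
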
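#' Write the toy genome to standard files
#'
#' Emits the reference FASTA, a GTF with gene/transcript/exon/CDS/UTR
#' features, and a BED6 of lincRNA intervals.
#'
#' @param genome a `genome_model`.
#' @param dir output directory (created if needed).
#' @return invisibly, named paths (`fasta`, `gtf`, `lincrna_bed`).
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome$sequence, fasta)
  gtf <- file.path(dir, "genes.gtf")
  write_gene_gtf(genome, gtf)
  bed <- file.path(dir, "lincrna.bed")
  linc <- genome$lincRNAs
  if (length(linc) > 0) {
    names(linc) <- linc$linc_id
    linc$score <- 0
  }
  rtracklayer::export(linc, bed, format = "BED")
  invisible(c(fasta = fasta, gtf = gtf, lincrna_bed = bed))
}

# GTF emitter. Feature rows are written per transcript (one transcript per
# gene in the toy genome); attribute column carries gene_id/transcript_id.
write_gene_gtf <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##description: synthetic toy genome gene models", con)
  fmt_row <- function(ch, feat, st, en, strand, attrs) {
    sprintf("%s\tnccmscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
            ch, feat, st, en, strand, attrs)
  }
  for (i in seq_along(genome$genes)) {
    g <- genome$genes[i]
    gid <- g$gene_id
    tid <- paste0(gid, ".t1")
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    ch <- as.character(GenomicRanges::seqnames(g))
    strand <- as.character(GenomicRanges::strand(g))
    writeLines(fmt_row(ch, "gene", GenomicRanges::start(g),
                       GenomicRanges::end(g), strand,
                       sprintf('gene_id "%s";', gid)), con)
    writeLines(fmt_row(ch, "transcript", GenomicRanges::start(g),
                       GenomicRanges::end(g), strand, attrs), con)
    emit <- function(gr, feat) {
      for (j in seq_along(gr)) {
        writeLines(fmt_row(ch, feat, GenomicRanges::start(gr)[j],
                           GenomicRanges::end(gr)[j], strand, attrs), con)
      }
    }
    emit(genome$exons[[gid]], "exon")
    emit(genome$cds[[gid]], "CDS")
    emit(genome$utr5[[gid]], "five_prime_utr")
    emit(genome$utr3[[gid]], "three_prime_utr")
  }
  invisible(path)
}

#' Read gene models from a GTF
#'
#' Rebuilds the `genome_model` interval components (no sequence) from a GTF
#' with gene/exon/CDS/five_prime_utr/three_prime_utr features, as written by
#' [write_genome_files()] or any annotation using those feature types.
#'
#' @param path GTF file.
#' @param key_genes optional character vector of gene ids to flag `is_key`.
#' @param seqlengths optional named chromosome lengths; inferred from the
#'   maximum annotated coordinate plus margin when absent.
#' @return a `genome_model` (with `sequence = NULL`).
#' @export
read_gene_models <- function(path, key_genes = character(),
                             seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(seqlengths)) {
    mx <- vapply(split(GenomicRanges::end(gr),
                       as.character(GenomicRanges::seqnames(gr))), max,
                 numeric(1))
    seqlengths <- mx + 200000
  }
  si <- GenomeInfoDb::Seqinfo(seqnames = names(seqlengths),
                              seqlengths = as.integer(unname(seqlengths)))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
  GenomeInfoDb::seqinfo(gr) <- si
  genes <- gr[gr$type == "gene"]
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = genes$gene_id,
    is_key = genes$gene_id %in% key_genes
  )
  genes <- sort(genes, ignore.strand = TRUE)
  per_gene <- function(type) {
    sub <- gr[gr$type == type]
    out <- GenomicRanges::split(
      GenomicRanges::granges(sub),
      factor(sub$gene_id, levels = genes$gene_id)
    )
    out
  }
  structure(list(
    seqinfo = si, sequence = NULL, genes = genes,
    exons = per_gene("exon"), cds = per_gene("CDS"),
    utr5 = per_gene("five_prime_utr"), utr3 = per_gene("three_prime_utr"),
    lincRNAs = GenomicRanges::GRanges(seqinfo = si)
  ), class = "genome_model")
}

#' Write / read a constraint track as bedGraph
#'
#' @param track GRanges with `score` (as from [generate_constraint_track()]).
#' @param path bedGraph file.
#' @return the path (write) or a GRanges with `score` (read).
#' @export
write_constraint_bedgraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_constraint_bedgraph
#' @export
read_constraint_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

# Minimal VCF 4.2 emitter for the simulator: one tumor (or normal) sample
# column with GT:AD:DP. Biallelic records only, which is what the generator
# plants; readers split multi-allelics anyway.
write_variant_vcf <- function(calls, path, sample_name, seqinfo = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=nccmscan-simulator", con)
  if (!is.null(seqinfo)) {
    for (ch in GenomeInfoDb::seqnames(seqinfo)) {
      writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                         GenomeInfoDb::seqlengths(seqinfo)[[ch]]), con)
    }
  }
  writeLines(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,',
           'Description="Allelic depths (ref,alt)">'),
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  ), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_name), collapse = "\t"), con)
  if (nrow(calls) > 0) {
    o <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
    calls <- calls[o, , drop = FALSE]
    gt <- sprintf("0/1:%d,%d:%d", calls$ref_reads, calls$alt_reads,
                  calls$ref_reads + calls$alt_reads)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t%s",
                       calls$chrom, calls$pos, calls$ref, calls$alt, gt), con)
  }
  invisible(path)
}

#' Write PFMs in JASPAR text format
#'
#' @param pfms named list of integer count matrices (rows A, C, G, T).
#' @param path output file.
#' @export
write_jaspar_pfms <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- names(pfms)
  for (i in seq_along(pfms)) {
    m <- pfms[[i]]
    writeLines(sprintf(">MA%04d.1 %s", i, ids[i]), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m[b, ], width = 5), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Parse a JASPAR text PFM file
#'
#' Accepts the 2016-style four-row `A [ ... ]` blocks (with or without
#' brackets). Returns matrices named by the motif name (falling back to the
#' matrix accession).
#'
#' @param path JASPAR text file.
#' @return named list of 4 x W integer matrices with rownames A,C,G,T.
#' @export
read_jaspar_pfms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stopf("no JASPAR records in '%s'", path)
  out <- list()
  for (i in seq_along(heads)) {
    h <- lines[heads[i]]
    block <- lines[(heads[i] + 1L):(if (i < length(heads))
      heads[i + 1L] - 1L else length(lines))]
    if (length(block) != 4L) {
      stopf("JASPAR record '%s' does not have 4 base rows", h)
    }
    rows <- lapply(block, function(l) {
      as.numeric(strsplit(trimws(gsub("^[ACGTacgt]|\\[|\\]", " ", l)),
                          "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stopf("ragged JASPAR record '%s'", h)
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    toks <- strsplit(sub("^>", "", h), "\\s+")[[1]]
    nm <- if (length(toks) >= 2) toks[2] else toks[1]
    out[[nm]] <- m
  }
  out
}

#' Write regulatory tracks as BED6 plus a manifest
#'
#' One BED6 per track (name column = element label) and a YAML manifest
#' mapping track name to file and kind.
#'
#' @param tracks named list of GRanges from [generate_regulatory_tracks()].
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_regulatory_tracks <- function(tracks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (nm in names(tracks)) {
    gr <- tracks[[nm]]
    names(gr) <- gr$element_id
    gr$score <- 0
    p <- file.path(dir, paste0(nm, ".bed"))
    rtracklayer::export(gr, p, format = "BED")
    manifest[[nm]] <- list(path = basename(p), kind = attr(tracks[[nm]],
                                                           "kind"))
  }
  mp <- file.path(dir, "tracks.yaml")
  writeLines(unlist(lapply(names(manifest), function(nm) {
    c(sprintf("%s:", nm),
      sprintf("  path: %s", manifest[[nm]]$path),
      sprintf("  kind: %s", manifest[[nm]]$kind))
  })), mp)
  invisible(mp)
}

#' Load regulatory tracks from a manifest
#'
#' @param manifest path to the YAML manifest written by
#'   [write_regulatory_tracks()].
#' @return named list of GRanges with `kind` attributes.
#' @export
read_regulatory_tracks <- function(manifest) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stopf("reading a track manifest requires the 'yaml' package")
  }
  m <- yaml::read_yaml(manifest)
  base <- dirname(manifest)
  out <- list()
  for (nm in names(m)) {
    gr <- rtracklayer::import(file.path(base, m[[nm]]$path), format = "BED")
    gr$element_id <- gr$name
    attr(gr, "kind") <- m[[nm]]$kind
    out[[nm]] <- gr
  }
  out
}
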
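#' The 96 trinucleotide substitution channels
#'
#' Pyrimidine-frame channel labels in the conventional order: substitution
#' class outermost (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3'
#' flank, each over A,C,G,T.
#'
#' @return character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
context_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  b <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(b, b, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))
  }))
}

#' Count 96-channel trinucleotide contexts
#'
#' Tallies somatic point mutations into the 96 pyrimidine-frame channels
#' using the reference sequence for the two flanking bases. Substitutions
#' with a purine reference (A/G) are reverse-complemented into the
#' pyrimidine frame. Indels are excluded; variants at a contig edge (no
#' flank on one side) are skipped with a warning.
#'
#' @param variants canonical call table (or any data.frame with
#'   `sample_id, chrom, pos, ref, alt, vtype`).
#' @param genome a `genome_model` with sequence (or a
#'   [Biostrings::DNAStringSet] named by chromosome).
#' @param by_sample return a 96 x n_samples matrix (default) or one pooled
#'   96-vector.
#' @return integer matrix (channels x samples) or named vector; column
#'   sums equal the number of counted SPMs.
#' @export
count_contexts <- function(variants, genome, by_sample = TRUE) {
  seqs <- if (inherits(genome, "genome_model")) genome$sequence else genome
  chan <- context_channels()
  spm <- variants[variants$vtype == "SPM" &
                    nchar(variants$ref) == 1 & nchar(variants$alt) == 1, ,
                  drop = FALSE]
  if (nrow(spm) > 0) {
    lens <- setNames(Biostrings::width(seqs), names(seqs))
    at_edge <- spm$pos <= 1L | spm$pos >= lens[spm$chrom]
    if (any(at_edge)) {
      warning(sprintf("%d variant(s) at a contig edge skipped",
                      sum(at_edge)), call. = FALSE)
      spm <- spm[!at_edge, , drop = FALSE]
    }
  }
  tally <- function(df) {
    v <- setNames(integer(96), chan)
    if (nrow(df) == 0) return(v)
    tri <- vapply(seq_len(nrow(df)), function(i) {
      as.character(Biostrings::subseq(seqs[[df$chrom[i]]],
                                      df$pos[i] - 1L, df$pos[i] + 1L))
    }, character(1))
    ref <- df$ref; alt <- df$alt
    flip <- ref %in% c("A", "G")
    rc <- function(x) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
        x)))
    }
    tri[flip] <- rc(tri[flip])
    ref[flip] <- rc(ref[flip])
    alt[flip] <- rc(alt[flip])
    lab <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                  substr(tri, 3, 3))
    tab <- table(factor(lab, levels = chan))
    v[] <- as.integer(tab)
    v
  }
  if (!by_sample) return(tally(spm))
  samples <- sort(unique(variants$sample_id))
  out <- vapply(samples, function(s) {
    tally(spm[spm$sample_id == s, , drop = FALSE])
  }, integer(96))
  if (is.null(dim(out))) out <- matrix(out, nrow = 96,
                                       dimnames = list(chan, samples))
  out
}

#' Refit a context vector against a signature catalog
#'
#' Non-negative least squares of the normalized 96-channel frequency vector
#' on the catalog columns, with exposures renormalized to the simplex and
#' the cosine similarity between the observed spectrum and its
#' reconstruction reported.
#'
#' @param context_vector 96 non-negative counts (sum > 0).
#' @param catalog 96 x K matrix, columns summing to 1.
#' @return a `signature_exposure` list: `exposures` (length K, on the
#'   simplex), `reconstruction_cosine`.
#' @export
refit <- function(context_vector, catalog) {
  y <- as.numeric(context_vector)
  if (length(y) != nrow(catalog)) {
    stopf("context vector length %d != catalog rows %d", length(y),
          nrow(catalog))
  }
  if (sum(y) <= 0) stopf("empty context vector; nothing to refit")
  cs <- colSums(catalog)
  if (any(abs(cs - 1) > 1e-6)) {
    stopf("catalog columns must each sum to 1")
  }
  f <- y / sum(y)
  fit <- pracma::lsqnonneg(as.matrix(catalog), f)
  x <- fit$x
  if (sum(x) <= 0) x <- rep(1 / ncol(catalog), ncol(catalog))
  expo <- x / sum(x)
  names(expo) <- colnames(catalog)
  recon <- as.numeric(as.matrix(catalog) %*% x)
  structure(list(
    exposures = expo,
    reconstruction_cosine = cosine_sim(f, recon)
  ), class = "signature_exposure")
}

#' Load a signature catalog from TSV
#'
#' 96 rows x K signature columns; an optional first column of channel
#' labels is matched against [context_channels()] and used to order rows.
#'
#' @param path TSV file.
#' @return 96 x K numeric matrix, columns normalized to sum 1.
#' @export
read_signature_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(df[[1]])) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
    m <- as.matrix(df)
    rownames(m) <- rn
    m <- m[context_channels(), , drop = FALSE]
  } else {
    m <- as.matrix(df)
    rownames(m) <- context_channels()
  }
  sweep(m, 2, colSums(m), "/")
}

#' Generate a synthetic, well-separated signature catalog
#'
#' K dissimilar signatures: each concentrates most of its mass on its own
#' block of channels (pairwise cosine similarity is low), so exposure
#' recovery is well conditioned. Clearly a stand-in for a real catalog, for
#' testing and demonstration.
#'
#' @param K number of signatures (default 5).
#' @param seed RNG seed.
#' @param concentration mass placed on a signature's own channel block.
#' @return 96 x K matrix, columns summing to 1, named `SYN1..SYNK`.
#' @export
make_signature_catalog <- function(K = 5L, seed = 1L,
                                   concentration = 0.85) {
  set.seed(seed)
  chan <- context_channels()
  blocks <- split(seq_len(96), cut(seq_len(96), K, labels = FALSE))
  m <- vapply(seq_len(K), function(k) {
    w <- rgamma(96, 0.3) + 1e-4
    w <- w / sum(w) * (1 - concentration)
    wb <- rgamma(length(blocks[[k]]), 1) + 1e-4
    w[blocks[[k]]] <- w[blocks[[k]]] +
      wb / sum(wb) * concentration
    w / sum(w)
  }, numeric(96))
  dimnames(m) <- list(chan, paste0("SYN", seq_len(K)))
  m
}
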
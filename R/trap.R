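#' Biophysical TF-binding model from a position frequency matrix
#'
#' Converts raw motif counts into a mismatch-energy matrix: per column j,
#' pseudocounted base probabilities p(b,j) are formed and the energy of base
#' b is E(b,j) = (1/lambda) * ln(p_max,j / p(b,j)), so the per-column
#' consensus base has energy exactly 0 and all energies are >= 0. Together
#' with the scaling constant R0 (default ln R0 = 0.584 W - 5.66) this
#' defines the expected-occupancy affinity model used by [trap_affinity()].
#'
#' @param counts 4 x W non-negative count matrix, rownames A,C,G,T.
#' @param tf_name factor name.
#' @param pseudocount added to every count (default 1).
#' @param lambda mismatch-energy scale (default 0.7).
#' @param R0 strand/offset-level scaling; default `exp(0.584 * W - 5.66)`.
#' @return a `pfm_model` list: `tf_name`, `counts`, `probs`, `energy`
#'   (4 x W), `col_mean_energy` (used for N bases), `width`, `lambda`,
#'   `R0`, `consensus`.
#' @export
pfm_model <- function(counts, tf_name = "TF", pseudocount = 1,
                      lambda = 0.7, R0 = NULL) {
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  W <- ncol(counts)
  if (W < 4) stopf("PFM '%s' narrower than 4 columns", tf_name)
  if (any(counts < 0)) stopf("negative counts in PFM '%s'", tf_name)
  depth <- colSums(counts)
  if (any(depth + 4 * pseudocount <= 0)) {
    stopf("all-zero column with zero pseudocount in PFM '%s'", tf_name)
  }
  probs <- sweep(counts + pseudocount, 2, depth + 4 * pseudocount, "/")
  pmaxs <- apply(probs, 2, max)
  energy <- sweep(-log(probs), 2, -log(pmaxs), "-") / lambda
  if (is.null(R0)) R0 <- exp(0.584 * W - 5.66)
  consensus <- rownames(probs)[apply(probs, 2, which.max)]
  structure(list(
    tf_name = tf_name, counts = counts, probs = probs, energy = energy,
    col_mean_energy = colMeans(energy), width = W, lambda = lambda,
    R0 = R0, consensus = paste(consensus, collapse = "")
  ), class = "pfm_model")
}

#' @rdname pfm_model
#' @param pfms named list of count matrices (e.g. from
#'   [read_jaspar_pfms()]).
#' @param ... passed to [pfm_model()].
#' @export
pfm_models <- function(pfms, ...) {
  out <- lapply(names(pfms), function(nm) pfm_model(pfms[[nm]], nm, ...))
  names(out) <- names(pfms)
  out
}

# Sum of per-column energies for every offset of one strand.
site_energies <- function(seq_chars, pfm) {
  W <- pfm$width
  n <- length(seq_chars) - W + 1L
  idx <- match(seq_chars, c("A", "C", "G", "T"))
  evals <- matrix(0, nrow = 4L + 1L, ncol = W)
  evals[1:4, ] <- pfm$energy
  evals[5L, ] <- pfm$col_mean_energy   # N base
  idx[is.na(idx)] <- 5L
  vapply(seq_len(n), function(i) {
    sum(evals[cbind(idx[i:(i + W - 1L)], seq_len(W))])
  }, numeric(1))
}

rev_comp_chars <- function(seq_chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[seq_chars]))
}

#' Expected TF occupancy of a sequence
#'
#' Affinity = sum over every offset i on both strands of
#' R0 exp(-E_i) / (1 + R0 exp(-E_i)), where E_i is the summed mismatch
#' energy of the W-mer starting at i. N bases contribute their column's
#' mean energy.
#'
#' @param sequence character string over `{A,C,G,T,N}` (case-insensitive),
#'   length >= motif width.
#' @param pfm a `pfm_model`.
#' @return non-negative affinity (dimensionless expected occupancy summed
#'   over binding sites).
#' @export
trap_affinity <- function(sequence, pfm) {
  stopifnot(inherits(pfm, "pfm_model"))
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stopf("sequence contains bases outside {A,C,G,T,N}")
  }
  if (length(chars) < pfm$width) {
    stopf("sequence (%d bp) shorter than motif width (%d)",
          length(chars), pfm$width)
  }
  e_fwd <- site_energies(chars, pfm)
  e_rev <- site_energies(rev_comp_chars(chars), pfm)
  occ <- function(E) {
    x <- pfm$R0 * exp(-E)
    x / (1 + x)
  }
  sum(occ(e_fwd)) + sum(occ(e_rev))
}

#' Wild-type vs mutant affinity deltas, ranked
#'
#' Computes, per TF, the affinity of the wild-type and the mutant window
#' (typically 41 bp with the variant allele centered) and their difference
#' `affinity_mut - affinity_wt`, ranked by decreasing absolute delta.
#'
#' @param wt_window,mut_window equal-purpose sequence windows (for an SNV,
#'   same length differing at the center base; indel windows may differ in
#'   length).
#' @param pfm_set named list of `pfm_model` (or raw count matrices, which
#'   are converted with defaults).
#' @param top_k rows to return (default 5); `Inf` for all.
#' @return data.frame `tf_name, affinity_wt, affinity_mut, delta,
#'   log_ratio, rank`, ranked by `abs(delta)` descending.
#' @export
affinity_delta <- function(wt_window, mut_window, pfm_set, top_k = 5) {
  if (!inherits(pfm_set[[1]], "pfm_model")) pfm_set <- pfm_models(pfm_set)
  rows <- lapply(pfm_set, function(pfm) {
    aw <- trap_affinity(wt_window, pfm)
    am <- trap_affinity(mut_window, pfm)
    data.frame(tf_name = pfm$tf_name, affinity_wt = aw, affinity_mut = am,
               delta = am - aw,
               log_ratio = log((am + 1e-12) / (aw + 1e-12)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$delta), out$tf_name), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  head(out, n = if (is.finite(top_k)) top_k else nrow(out))
}

#' Information content of one motif column
#'
#' IC = 2 + sum_b p(b) log2 p(b) bits, with pseudocounted probabilities;
#' 0 for a uniform column, approaching 2 for an invariant one.
#'
#' @param pfm a `pfm_model` or raw count matrix.
#' @param column_index 1-based column.
#' @param pseudocount used when `pfm` is a raw matrix.
#' @return bits in \[0, 2\].
#' @export
matrix_position_conservation <- function(pfm, column_index,
                                         pseudocount = 1) {
  probs <- if (inherits(pfm, "pfm_model")) pfm$probs else
    pfm_model(pfm, pseudocount = pseudocount)$probs
  if (column_index < 1 || column_index > ncol(probs)) {
    stopf("column %d outside motif width %d", column_index, ncol(probs))
  }
  p <- probs[, column_index]
  2 + sum(p * log2(p))
}

#' Extract the variant-centered window pair for an affinity scan
#'
#' Cuts the `window`-bp reference window centered on the variant anchor and
#' builds the mutant window by substituting the alt allele at the center
#' (SNV) or splicing the indel alleles in.
#'
#' @param genome a `genome_model` with sequence.
#' @param chrom,pos,ref,alt the variant.
#' @param window odd window length (default 41; variant at position
#'   `(window+1)/2`).
#' @return list `wt`, `mut` (character sequences).
#' @export
variant_windows <- function(genome, chrom, pos, ref, alt, window = 41L) {
  if (window %% 2L == 0L) stopf("window length must be odd")
  half <- (window - 1L) %/% 2L
  L <- GenomeInfoDb::seqlengths(genome$seqinfo)[[chrom]]
  st <- max(1L, pos - half)
  en <- min(L, pos + half + nchar(ref) - 1L)
  wt <- as.character(Biostrings::subseq(genome$sequence[[chrom]], st, en))
  center <- pos - st + 1L
  if (substr(wt, center, center + nchar(ref) - 1L) != ref) {
    stopf("reference allele mismatch at %s:%d", chrom, pos)
  }
  mut <- paste0(substr(wt, 1L, center - 1L), alt,
                substr(wt, center + nchar(ref), nchar(wt)))
  list(wt = wt, mut = mut)
}
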
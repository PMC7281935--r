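#' Per-gene NCCM rates per 100 kbp
#'
#' Rate = NCCM count / territory length x 100,000. Every gene with a
#' territory is reported; genes without NCCMs get rate 0. NCCMs are counted
#' at the variant-occurrence level (one per sample carrying the site).
#'
#' @param nccms NCCM table from [call_nccms()].
#' @param territories list of `gene_territory` covering every gene to
#'   report.
#' @param key_genes character vector of key gene ids (grouping).
#' @return data.frame `gene_id, nccm_count, territory_length, rate, group`
#'   with `group` in `{key, opcg}`.
#' @export
nccm_rate <- function(nccms, territories, key_genes = character()) {
  lens <- vapply(territories, `[[`, numeric(1), "total_length")
  if (any(lens == 0)) {
    stopf("zero-length territory for gene '%s'",
          names(territories)[which(lens == 0)[1]])
  }
  counts <- table(factor(nccms$gene_id, levels = names(territories)))
  data.frame(
    gene_id = names(territories),
    nccm_count = as.integer(counts),
    territory_length = unname(lens),
    rate = as.integer(counts) / unname(lens) * 1e5,
    group = ifelse(names(territories) %in% key_genes, "key", "opcg"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Key-gene vs other-protein-coding-gene enrichment test
#'
#' Welch two-sample t-test (two-sided) on per-gene NCCM rates, key genes
#' against all other protein-coding genes, plus the constraint-site-rate
#' control: the identical test applied to per-gene constrained-base
#' fractions, which should *not* differ if the enrichment is a mutational
#' signal rather than an excess of constrained sequence near key genes.
#'
#' @param rates data.frame from [nccm_rate()] (with `group`).
#' @param constrained_fractions optional named numeric vector (per gene) of
#'   constrained-base fractions for the control test.
#' @param zero_genes include genes with zero NCCMs in the distributions
#'   (default TRUE).
#' @return an `enrichment_result` list: `mean_key`, `mean_opcg`, `t_stat`,
#'   `p_value`, `control_t`, `control_p`, `n_key`, `n_opcg`.
#' @export
compare_groups <- function(rates, constrained_fractions = NULL,
                           zero_genes = TRUE) {
  if (!zero_genes) rates <- rates[rates$nccm_count > 0, , drop = FALSE]
  key <- rates$rate[rates$group == "key"]
  opcg <- rates$rate[rates$group == "opcg"]
  if (length(key) < 2 || length(opcg) < 2) {
    stopf("each group needs at least two genes (key=%d, opcg=%d)",
          length(key), length(opcg))
  }
  if (stats::sd(c(key, opcg)) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(key, opcg, var.equal = FALSE)
  }
  res <- list(
    mean_key = mean(key), mean_opcg = mean(opcg),
    t_stat = unname(tt$statistic), p_value = tt$p.value,
    control_t = NA_real_, control_p = NA_real_,
    n_key = length(key), n_opcg = length(opcg)
  )
  if (!is.null(constrained_fractions)) {
    cf <- constrained_fractions[rates$gene_id]
    ck <- cf[rates$group == "key"]; co <- cf[rates$group == "opcg"]
    ctt <- if (stats::sd(c(ck, co)) == 0) {
      list(statistic = c(t = 0), p.value = 1)
    } else t.test(ck, co, var.equal = FALSE)
    res$control_t <- unname(ctt$statistic)
    res$control_p <- ctt$p.value
  }
  structure(res, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "NCCM rate enrichment: key mean %.3f vs OPCG mean %.3f per 100 kbp\n",
    x$mean_key, x$mean_opcg))
  cat(sprintf("Welch t = %.3f, two-sided P = %.3g (n = %d vs %d)\n",
              x$t_stat, x$p_value, x$n_key, x$n_opcg))
  if (!is.na(x$control_p)) {
    cat(sprintf("Constraint-site-rate control: t = %.3f, P = %.3g\n",
                x$control_t, x$control_p))
  }
  invisible(x)
}

#' Rank genes by NCCM rate thresholds
#'
#' For each threshold, the genes whose rate is at or above it (inclusive),
#' sorted by decreasing rate with lexicographic gene-id tie-break. The
#' resulting lists are nested across increasing thresholds.
#'
#' @param rates data.frame from [nccm_rate()].
#' @param thresholds NCCMs per 100 kbp (default `c(1, 2, 3, 4)`).
#' @return named list (one element per threshold) of gene-id vectors.
#' @export
rank_genes <- function(rates, thresholds = c(1, 2, 3, 4)) {
  o <- order(-rates$rate, rates$gene_id)
  sorted <- rates[o, , drop = FALSE]
  out <- lapply(thresholds, function(th) {
    sorted$gene_id[sorted$rate >= th]
  })
  names(out) <- paste0("rate_ge_", thresholds)
  out
}

#' Frequently mutated genes by sample count
#'
#' Genes carrying non-silent mutations in at least `min_samples` tumor
#' samples.
#'
#' @param incidence binary gene x sample matrix (rownames = genes), or a
#'   data.frame with `gene_id` and `sample_id` columns (long form).
#' @param min_samples inclusion threshold (default 4, roughly 10% of a
#'   39-sample cohort).
#' @return data.frame `gene_id, n_samples, pct_cohort`, sorted by
#'   decreasing support.
#' @export
fmg_frequency <- function(incidence, min_samples = 4L) {
  if (is.data.frame(incidence)) {
    tab <- vapply(split(incidence$sample_id, incidence$gene_id),
                  function(s) length(unique(s)), integer(1))
    n_cohort <- length(unique(incidence$sample_id))
  } else {
    m <- (incidence > 0) * 1L
    tab <- rowSums(m)
    n_cohort <- ncol(m)
  }
  keep <- tab >= min_samples
  out <- data.frame(
    gene_id = names(tab)[keep],
    n_samples = as.integer(tab[keep]),
    pct_cohort = as.numeric(tab[keep]) / n_cohort * 100,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$n_samples, out$gene_id), , drop = FALSE]
}
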
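#' Load cohort metadata
#'
#' Reads the cohort table (one row per tumor sample: grade, age, sex,
#' survival, expression subtype, purity, depth of coverage, concordant
#' SPM/SIM counts, recurrence flag). The packaged fixture
#' `table1_swegbm1.tsv` transcribes a published 39-patient IDH-wild-type GBM
#' cohort summary.
#'
#' @param path TSV with columns `sample_id, grade, age, sex, survival_days,
#'   subtype, purity, depth, spm_count, sim_count, recurrent`.
#' @return data.frame, one row per sample.
#' @examples
#' meta <- load_metadata(system.file("extdata", "table1_swegbm1.tsv",
#'                                   package = "nccmscan"))
#' nrow(meta)  # 39
#' @export
load_metadata <- function(path) {
  need <- c("sample_id", "grade", "age", "sex", "survival_days", "subtype",
            "purity", "depth", "spm_count", "sim_count", "recurrent")
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character"))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stopf("metadata file lacks column(s): %s", paste(missing,
                                                     collapse = ", "))
  }
  df <- df[, need]
  if (nrow(df) == 0) return(df)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$age[i]) || !is.numeric(df$age[i]) || df$age[i] <= 0) {
      stopf("row %d ('%s'): unparsable or non-positive age", i,
            df$sample_id[i])
    }
  }
  bad_sub <- !df$subtype %in% c("CL", "MS", "PN", "n/a")
  if (any(bad_sub)) {
    stopf("row %d: subtype '%s' not in {CL, MS, PN, n/a}",
          which(bad_sub)[1], df$subtype[which(bad_sub)[1]])
  }
  if (any(df$spm_count < 0 | df$sim_count < 0)) {
    stopf("negative variant counts in metadata")
  }
  df$recurrent <- as.logical(df$recurrent)
  df
}

#' Summarize a cohort
#'
#' Cohort-level descriptive statistics plus SPM/SIM totals with and without
#' hyper-mutated samples. Hyper-mutated samples are either given explicitly
#' (`exclude_ids`) or flagged by the default rule: per-sample SPM+SIM total
#' exceeding `hyper_factor` times the cohort median total.
#'
#' @param metas data.frame from [load_metadata()].
#' @param exclude_ids sample ids to treat as hyper-mutated; `NULL` uses the
#'   median-multiple rule.
#' @param hyper_factor multiple of the median total that flags
#'   hyper-mutation under the default rule.
#' @return a `cohort_summary` list: `n`, `age` (median/min/max), `sex_counts`,
#'   `subtype_counts`, `recurrent_count`, `per_sample_totals`,
#'   `hyper_mutated` (ids), `totals` (SPM/SIM with all samples) and
#'   `totals_excl` (hyper-mutated excluded).
#' @export
cohort_summary <- function(metas, exclude_ids = NULL, hyper_factor = 10) {
  if (!is.data.frame(metas) || nrow(metas) == 0) {
    stopf("empty cohort metadata")
  }
  tot <- metas$spm_count + metas$sim_count
  hyper <- if (is.null(exclude_ids)) {
    metas$sample_id[tot > hyper_factor * median(tot)]
  } else {
    intersect(as.character(exclude_ids), metas$sample_id)
  }
  keep <- !metas$sample_id %in% hyper
  structure(list(
    n = nrow(metas),
    age = c(median = median(metas$age), min = min(metas$age),
            max = max(metas$age)),
    sex_counts = table(metas$sex),
    subtype_counts = table(metas$subtype),
    recurrent_count = sum(metas$recurrent),
    per_sample_totals = setNames(tot, metas$sample_id),
    hyper_mutated = hyper,
    totals = c(spm = sum(metas$spm_count), sim = sum(metas$sim_count)),
    totals_excl = c(spm = sum(metas$spm_count[keep]),
                    sim = sum(metas$sim_count[keep]))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d samples (%d recurrent)\n", x$n,
              x$recurrent_count))
  cat(sprintf("Age: median %g (range %g-%g)\n", x$age["median"],
              x$age["min"], x$age["max"]))
  cat("Sex:", paste(names(x$sex_counts), x$sex_counts, collapse = ", "),
      "\n")
  cat("Subtype:", paste(names(x$subtype_counts), x$subtype_counts,
                        collapse = ", "), "\n")
  if (length(x$hyper_mutated)) {
    cat("Hyper-mutated (excluded from adjusted totals):",
        paste(x$hyper_mutated, collapse = ", "), "\n")
  }
  cat(sprintf("SPM/SIM totals: %d / %d (all); %d / %d (excl.)\n",
              x$totals["spm"], x$totals["sim"], x$totals_excl["spm"],
              x$totals_excl["sim"]))
  invisible(x)
}
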
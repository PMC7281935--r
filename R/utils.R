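#' @importFrom methods is
#' @importFrom stats median rbeta rbinom rexp rgamma rmultinom rpois runif
#'   setNames t.test sd
#' @importFrom utils read.delim write.table head
NULL

# Canonical site key used by every set operation in the filtration cascade.
# Allele-specific by default: two alt alleles at one position are distinct
# sites (germline "SNPs" are alleles, not positions).
variant_key <- function(df, allele_specific = TRUE) {
  if (allele_specific) {
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  } else {
    paste(df$chrom, df$pos, sep = ":")
  }
}

# Empty canonical variant-call table (one row per somatic call).
empty_calls <- function() {
  data.frame(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), vtype = character(),
    ref_reads = integer(), alt_reads = integer(),
    provenance = character(), filter_trail = character(),
    stringsAsFactors = FALSE
  )
}

as_calls <- function(df) {
  need <- names(empty_calls())
  missing <- setdiff(need, names(df))
  for (m in missing) df[[m]] <- vector(class(empty_calls()[[m]]), nrow(df))
  df[, need, drop = FALSE]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)

is_fraction <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x <= 1

# Variants are classified as point mutations iff both alleles are single
# bases; everything else is an indel.
infer_vtype <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SPM", "SIM")
}

# Uniformly sample n integer positions (without replacement) from the bases
# covered by a GRanges. Used by the simulator to place mutations in a stratum.
sample_positions <- function(gr, n) {
  gr <- GenomicRanges::reduce(gr)
  w <- GenomicRanges::width(gr)
  total <- sum(w)
  if (n == 0L || total == 0L) {
    return(data.frame(chrom = character(), pos = integer()))
  }
  n <- min(n, total)
  offs <- sort(sample.int(total, n))
  cw <- cumsum(w)
  idx <- findInterval(offs - 1L, c(0L, cw), rightmost.closed = FALSE)
  within <- offs - c(0L, cw)[idx] - 1L
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr))[idx],
    pos = GenomicRanges::start(gr)[idx] + within
  )
}

# Cosine similarity between two non-negative vectors.
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
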
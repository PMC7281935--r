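# Independent reference implementation of the occupancy model: explicit
# per-offset loops, no shared code with the package internals.
oracle_affinity <- function(seq, counts, pseudocount = 1, lambda = 0.7,
                            R0 = exp(0.584 * ncol(counts) - 5.66)) {
  bases <- c("A", "C", "G", "T")
  W <- ncol(counts)
  p <- apply(counts + pseudocount, 2, function(cl) cl / sum(cl))
  rownames(p) <- bases
  E <- matrix(0, 4, W, dimnames = list(bases, NULL))
  for (j in seq_len(W)) {
    E[, j] <- log(max(p[, j]) / p[, j]) / lambda
  }
  one_strand <- function(s) {
    ch <- strsplit(s, "")[[1]]
    tot <- 0
    for (i in seq_len(length(ch) - W + 1)) {
      e <- 0
      for (j in seq_len(W)) {
        b <- ch[i + j - 1]
        e <- e + if (b == "N") mean(E[, j]) else E[b, j]
      }
      tot <- tot + R0 * exp(-e) / (1 + R0 * exp(-e))
    }
    tot
  }
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  unname(one_strand(seq) + one_strand(rc(seq)))
}

test_that("mismatch energies follow the pseudocounted log-ratio form", {
  # uniform column -> all energies 0
  m <- matrix(25L, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pm <- pfm_model(m)
  expect_true(all(pm$energy == 0))

  # (97,1,1,1) column: non-consensus energy = ln(98/2)/0.7
  m2 <- m
  m2[, 2] <- c(97L, 1L, 1L, 1L)
  pm2 <- pfm_model(m2)
  expect_equal(unname(pm2$energy["A", 2]), 0)
  expect_equal(unname(pm2$energy["C", 2]), log(98 / 2) / 0.7,
               tolerance = 1e-12)
  expect_true(all(pm2$energy >= 0))

  # consensus sequence scores zero total energy (occupancy R0/(1+R0)
  # from its matching forward offset)
  aff <- trap_affinity(pm2$consensus, pm2)
  expect_gte(aff, pm2$R0 / (1 + pm2$R0))

  expect_error(pfm_model(m[, 1:3]), "narrower")
  expect_error(pfm_model(matrix(0L, 4, 5), pseudocount = 0), "all-zero")
})

test_that("affinity equals the brute-force enumeration on both strands", {
  set.seed(5)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:5) {
    W <- sample(4:6, 1)
    counts <- matrix(sample(0:30, 4 * W, replace = TRUE), 4, W,
                     dimnames = list(bases, NULL))
    pm <- pfm_model(counts)
    seqs <- c(
      paste(sample(bases, 10, replace = TRUE), collapse = ""),
      paste(sample(c(bases, "N"), 12, replace = TRUE), collapse = "")
    )
    for (s in seqs) {
      expect_equal(trap_affinity(s, pm), oracle_affinity(s, counts),
                   tolerance = 1e-10)
    }
  }
  # exhaustive over all 4-mers for one W=4 matrix
  counts <- matrix(c(10L, 0L, 2L, 1L), 4, 4, dimnames = list(bases, NULL))
  pm <- pfm_model(counts)
  all4 <- apply(expand.grid(bases, bases, bases, bases), 1, paste,
                collapse = "")
  for (s in all4[seq(1, 256, by = 3)]) {
    expect_equal(trap_affinity(s, pm), oracle_affinity(s, counts),
                 tolerance = 1e-10)
  }
})

test_that("affinity is reverse-complement symmetric", {
  pm <- pfm_model(generate_pfms(sim_config(seed = 2))$TFB_like)
  rc <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  set.seed(8)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 41, replace = TRUE),
               collapse = "")
    expect_equal(trap_affinity(s, pm), trap_affinity(rc(s), pm),
                 tolerance = 1e-10)
  }
  expect_error(trap_affinity("ACGT", pm), "shorter")
  expect_error(trap_affinity(strrep("X", 50), pm), "outside")
})

test_that("a mutation in a near-invariant motif position lowers affinity", {
  # promoter-style oligo pair differing by one T>C at position 11
  wt <- "GCAACAGTGGTTTGCTCTGGAGAGGAAA"
  mut <- "GCAACAGTGGCTTGCTCTGGAGAGGAAA"
  # forkhead-like matrix requiring T at the column the variant hits:
  # motif matches wt positions 9..14 (GGTTTG), near-invariant T at col 3
  bases <- c("A", "C", "G", "T")
  counts <- matrix(5L, 4, 6, dimnames = list(bases, NULL))
  counts[, 1] <- c(2L, 2L, 90L, 2L)   # G
  counts[, 2] <- c(2L, 2L, 90L, 2L)   # G
  counts[, 3] <- c(1L, 1L, 1L, 97L)   # T  <- variant column
  counts[, 4] <- c(2L, 2L, 2L, 90L)   # T
  counts[, 5] <- c(2L, 2L, 2L, 90L)   # T
  counts[, 6] <- c(2L, 2L, 90L, 2L)   # G
  d <- affinity_delta(wt, mut, list(FOXA1_like = counts), top_k = 1)
  expect_lt(d$delta, 0)               # mutant binds worse
  expect_equal(d$tf_name, "FOXA1_like")
})

test_that("delta ranking matches independently sorted brute-force deltas", {
  pfms <- generate_pfms(sim_config(seed = 4))
  wt <- paste(rep("A", 41), collapse = "")
  mut <- paste0(strrep("A", 20), "G", strrep("A", 20))
  got <- affinity_delta(wt, mut, pfms, top_k = Inf)
  oracle <- vapply(pfms, function(m) {
    oracle_affinity(mut, m) - oracle_affinity(wt, m)
  }, numeric(1))
  oracle <- oracle[order(-abs(oracle), names(oracle))]
  expect_equal(got$tf_name, names(oracle))
  expect_equal(got$delta, unname(oracle), tolerance = 1e-10)
  # identical windows -> all deltas zero, not an error
  same <- affinity_delta(wt, wt, pfms, top_k = Inf)
  expect_true(all(same$delta == 0))
})

test_that("column information content matches the direct formula", {
  bases <- c("A", "C", "G", "T")
  uni <- matrix(25L, 4, 5, dimnames = list(bases, NULL))
  expect_equal(matrix_position_conservation(uni, 3), 0)
  m <- uni
  m[, 2] <- c(97L, 1L, 1L, 1L)
  p <- (c(97, 1, 1, 1) + 1) / 104
  expect_equal(matrix_position_conservation(m, 2),
               2 + sum(p * log2(p)), tolerance = 1e-12)
  expect_error(matrix_position_conservation(m, 9), "outside")
  # IC bounded in [0,2] for arbitrary columns
  set.seed(3)
  for (i in 1:10) {
    mm <- matrix(sample(0:50, 16, replace = TRUE), 4, 4,
                 dimnames = list(bases, NULL))
    ic <- matrix_position_conservation(mm, sample(4, 1))
    expect_gte(ic, 0); expect_lte(ic, 2)
  }
})

test_that("variant windows center the allele and splice indels", {
  st <- tiny_study()
  g <- st$genome
  tr <- st$cohort$truth
  snv <- tr[tr$vtype == "SPM", ][1, ]
  win <- variant_windows(g, snv$chrom, snv$pos, snv$ref, snv$alt)
  expect_equal(nchar(win$wt), 41L)
  expect_equal(substr(win$wt, 21, 21), snv$ref)
  expect_equal(substr(win$mut, 21, 21), snv$alt)
  expect_equal(substr(win$wt, 1, 20), substr(win$mut, 1, 20))
  sim <- tr[tr$vtype == "SIM" & nchar(tr$ref) > 1, ]
  if (nrow(sim) > 0) {
    wd <- variant_windows(g, sim$chrom[1], sim$pos[1], sim$ref[1],
                          sim$alt[1])
    expect_equal(nchar(wd$wt) - nchar(wd$mut),
                 nchar(sim$ref[1]) - nchar(sim$alt[1]))
  }
  expect_error(variant_windows(g, snv$chrom, snv$pos, snv$ref, snv$alt,
                               window = 40L), "odd")
})
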
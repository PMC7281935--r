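test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(constrained_block_rate = 1.2), "fraction")
  expect_error(sim_config(enrichment_factor = 0.5), ">= 1")
  expect_error(sim_config(flank = 0), "flank")
  expect_error(sim_config(chrom_length = 150000L, flank = 100000L),
               "2\\*flank")
  expect_error(sim_config(n_genes = 3, n_key_genes = 5), "key")
})

test_that("generation is deterministic: same config, same bytes", {
  cfg <- tiny_cfg(seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, out_dir = d1)
  simulate_study(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("gene placement yields pairwise-disjoint spans", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chrom_length = 2000000L,
                    n_genes = 20, n_key_genes = 4)
  g <- generate_genome(cfg)
  expect_length(g$genes, 20L)
  # brute-force pairwise overlap oracle
  st <- GenomicRanges::start(g$genes); en <- GenomicRanges::end(g$genes)
  ch <- as.character(GenomicRanges::seqnames(g$genes))
  for (i in 1:19) for (j in (i + 1):20) {
    if (ch[i] == ch[j]) {
      expect_true(en[i] < st[j] || en[j] < st[i])
    }
  }
  # too many genes for the chromosome is a configuration error
  expect_error(generate_genome(
    sim_config(seed = 1, n_chromosomes = 1, chrom_length = 250000L,
               n_genes = 30, n_key_genes = 2)), "too short")
})

test_that("an empty gene request writes a headered, gene-free GTF", {
  cfg <- sim_config(seed = 3, n_genes = 0L, n_key_genes = 0L,
                    n_chromosomes = 1, chrom_length = 210000L)
  g <- generate_genome(cfg)
  expect_length(g$genes, 0L)
  d <- withr::local_tempdir()
  paths <- write_genome_files(g, d)
  lines <- readLines(paths["gtf"])
  expect_match(lines[1], "^##")
  expect_equal(sum(!grepl("^#", lines)), 0L)
})

test_that("constraint track hits its target constrained fraction", {
  # zero rate: no base at or above the threshold
  cfg0 <- tiny_cfg(constrained_block_rate = 0)
  g0 <- generate_genome(cfg0)
  t0 <- generate_constraint_track(g0, cfg0)
  expect_true(all(t0$score < 2))

  # 15% target on 1 Mbp within +/- 2 points, by per-base accounting
  cfg <- sim_config(seed = 13, n_chromosomes = 1, chrom_length = 1000000L,
                    n_genes = 10, n_key_genes = 2,
                    constrained_block_rate = 0.15)
  g <- generate_genome(cfg)
  tr <- generate_constraint_track(g, cfg)
  frac <- sum(GenomicRanges::width(tr[tr$score >= 2])) / 1000000
  expect_gte(frac, 0.13); expect_lte(frac, 0.17)

  # blocks tile the chromosome without overlap (sweep oracle)
  o <- order(GenomicRanges::start(tr))
  expect_true(all(GenomicRanges::start(tr)[o][-1] >=
                    GenomicRanges::end(tr)[o][-length(tr)] + 1))
})

test_that("cohort generation honors its degenerate switches", {
  cfg <- tiny_cfg(base_mut_rate = 0, germline_contamination_rate = 0,
                  artifact_rate = 0)
  g <- generate_genome(cfg)
  tr <- generate_constraint_track(g, cfg)
  co <- generate_cohort(g, tr, cfg)
  expect_equal(nrow(co$caller_a), 0L)
  expect_equal(nrow(co$caller_b), 0L)

  cfg2 <- tiny_cfg(discordance_rate = 0, artifact_rate = 0,
                   germline_contamination_rate = 0)
  g2 <- generate_genome(cfg2)
  tr2 <- generate_constraint_track(g2, cfg2)
  co2 <- generate_cohort(g2, tr2, cfg2)
  expect_setequal(
    paste(co2$caller_a$sample_id, variant_key_public(co2$caller_a)),
    paste(co2$caller_b$sample_id, variant_key_public(co2$caller_b)))
})

test_that("truth table and caller VCF record sets are conserved", {
  st <- tiny_study()
  co <- st$cohort
  tr <- co$truth
  for (side in c("a", "b")) {
    calls <- co[[paste0("caller_", side)]]
    flagged <- tr[tr[[paste0("in_caller_", side)]], ]
    expect_setequal(paste(calls$sample_id, variant_key_public(calls)),
                    paste(flagged$sample_id, variant_key_public(flagged)))
  }
  # concordance bookkeeping: discordant somatic calls sit in exactly one
  som <- tr[!tr$is_germline & !tr$is_artifact, ]
  expect_true(all(som$in_caller_a | som$in_caller_b))
  expect_true(all(tr$in_caller_a[tr$is_germline] &
                    tr$in_caller_b[tr$is_germline]))
  expect_true(all(xor(tr$in_caller_a[tr$is_artifact],
                      tr$in_caller_b[tr$is_artifact])))
})

test_that("planted rates are recovered from the truth table", {
  cfg <- sim_config(seed = 31, n_chromosomes = 2, chrom_length = 1000000L,
                    n_genes = 40, n_key_genes = 10, flank = 20000L,
                    base_mut_rate = 2e-4, enrichment_factor = 4,
                    n_samples = 15, germline_contamination_rate = 0,
                    artifact_rate = 0)
  g <- generate_genome(cfg)
  ct <- generate_constraint_track(g, cfg)
  co <- generate_cohort(g, ct, cfg)
  tr <- co$truth[!co$truth$is_germline & !co$truth$is_artifact, ]
  n_enr <- sum(tr$constrained & tr$in_key_territory)
  n_bg <- nrow(tr) - n_enr
  expect_gt(n_enr, 500)  # enough planted events for a stable ratio
  rate_enr <- n_enr / co$strata["enriched"]
  rate_bg <- n_bg / co$strata["background"]
  ratio <- unname(rate_enr / rate_bg)
  expect_gte(ratio, 3); expect_lte(ratio, 5)

  # background rate within 3 binomial sigma of the configured per-sample
  # rate times the cohort size
  lam <- cfg$base_mut_rate * cfg$n_samples
  expect_lt(abs(rate_bg - lam), 3 * sqrt(lam / co$strata["background"]))
})

test_that("simulated read depths and discordance match their settings", {
  st <- tiny_study()
  tr <- st$cohort$truth
  depth <- tr$ref_reads + tr$alt_reads
  expect_gt(mean(depth), 70); expect_lt(mean(depth), 80)
  expect_true(all(tr$alt_reads >= 1))
  som <- tr[!tr$is_germline & !tr$is_artifact, ]
  disc <- mean(!(som$in_caller_a & som$in_caller_b))
  expect_lt(abs(disc - tiny_cfg()$discordance_rate),
            3 * sqrt(0.1 * 0.9 / nrow(som)) + 0.01)
})

test_that("GTF and site-VCF writers round-trip through their readers", {
  st <- tiny_study()
  d <- withr::local_tempdir()
  paths <- write_study(st, d)
  gm <- read_gene_models(paths$gtf,
                         key_genes = st$genome$genes$gene_id[
                           st$genome$genes$is_key],
                         seqlengths = c(chr1 = 300000L))
  expect_equal(gm$genes$gene_id, st$genome$genes$gene_id)
  expect_equal(sum(gm$genes$is_key), 3L)
  for (field in c("exons", "cds", "utr5", "utr3")) {
    expect_equal(
      unname(S4Vectors::elementNROWS(gm[[field]])),
      unname(S4Vectors::elementNROWS(st$genome[[field]])), label = field)
    expect_equal(
      GenomicRanges::start(unlist(gm[[field]])),
      GenomicRanges::start(unlist(st$genome[[field]])), label = field)
  }
  # territories built from the re-read models match the originals
  t1 <- build_territory(gm$genes$gene_id[1], gm, flank_bp = 5000L)
  t2 <- build_territory(gm$genes$gene_id[1], st$genome, flank_bp = 5000L)
  expect_equal(t1$total_length, t2$total_length)

  db <- read_site_vcf(file.path(d, "germline_db1.vcf"))
  orig <- st$cohort$germline_dbs$db1
  expect_setequal(variant_key_public(db), variant_key_public(orig))
})

test_that("generated PFMs satisfy the JASPAR contract", {
  pfms <- generate_pfms(sim_config(seed = 9))
  expect_gte(length(pfms), 5L)
  for (m in pfms) {
    expect_true(all(m >= 0))
    expect_true(all(m == floor(m)))
    expect_gte(ncol(m), 6L); expect_lte(ncol(m), 15L)
    # constant per-column depth within a matrix
    expect_length(unique(colSums(m)), 1L)
  }
  # the designated matrix carries a near-invariant, high-information column
  des <- pfms$FOXA1_like
  ic <- matrix_position_conservation(des, attr(des, "invariant_col"))
  expect_gte(ic, 1.5)
  # parse-then-write round trip is identity
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.txt")
  write_jaspar_pfms(pfms, p1)
  back <- read_jaspar_pfms(p1)
  p2 <- file.path(d, "b.txt")
  write_jaspar_pfms(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})
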
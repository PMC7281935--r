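mk_calls <- function(pos, sample_id = "s1", ref = "A", alt = "T",
                     caller = "caller_a", ref_reads = 50L,
                     alt_reads = 10L) {
  data.frame(
    sample_id = sample_id, chrom = "chr1", pos = as.integer(pos),
    ref = ref, alt = alt, vtype = "SPM", ref_reads = ref_reads,
    alt_reads = alt_reads, provenance = caller, filter_trail = "",
    stringsAsFactors = FALSE
  )
}

test_that("caller intersection keeps exactly the shared (site, allele) keys", {
  a <- mk_calls(1:10)
  expect_equal(nrow(intersect_callers(a, a)), 10L)
  b <- mk_calls(11:20, caller = "caller_b")
  expect_equal(nrow(intersect_callers(a, b)), 0L)

  # 5 shared + 3 private to A + 2 private to B, vs set-intersection oracle
  a2 <- mk_calls(c(1:5, 21:23))
  b2 <- mk_calls(c(1:5, 31:32), caller = "caller_b")
  got <- intersect_callers(a2, b2)
  oracle <- intersect(paste0("chr1:", a2$pos, ":A:T"),
                      paste0("chr1:", b2$pos, ":A:T"))
  expect_equal(sort(paste0("chr1:", got$pos, ":A:T")), sort(oracle))
  expect_true(all(grepl("caller_a\\+caller_b", got$provenance)))

  # same position, different allele is not concordant
  c1 <- mk_calls(5, alt = "G")
  expect_equal(nrow(intersect_callers(mk_calls(5), c1)), 0L)

  # read counts come from the designated caller
  a3 <- mk_calls(7, alt_reads = 33L)
  b3 <- mk_calls(7, caller = "caller_b", alt_reads = 99L)
  expect_equal(intersect_callers(a3, b3)$alt_reads, 33L)
  expect_equal(intersect_callers(a3, b3, counts_from = "b")$alt_reads, 99L)

  expect_error(intersect_callers(mk_calls(1, sample_id = "s1"),
                                 mk_calls(1, sample_id = "s2")),
               "common sample")
})

test_that("panel of normals tallies per-site sample counts", {
  n1 <- mk_calls(c(1, 2, 3), sample_id = "n1")
  n2 <- mk_calls(c(2, 3), sample_id = "n2")
  n3 <- mk_calls(c(3), sample_id = "n3")
  pon <- build_pon(list(n1, n2, n3))
  expect_equal(unname(unclass(pon)[c("chr1:1:A:T", "chr1:2:A:T",
                                     "chr1:3:A:T")]), c(1L, 2L, 3L))
  # single normal: every count is 1
  pon1 <- build_pon(list(n1))
  expect_true(all(unclass(pon1) == 1L))
  # no normals: empty panel retains everything
  pon0 <- build_pon(list(mk_calls(1)[0, ]))
  calls <- mk_calls(1:5)
  expect_equal(nrow(filter_pon(calls, pon0)), 5L)
})

test_that("panel filter removes sites at the 'at least two normals' rule", {
  pon <- build_pon(list(mk_calls(1:2, sample_id = "n1"),
                        mk_calls(2, sample_id = "n2")))
  calls <- mk_calls(1:3)
  surv <- filter_pon(calls, pon, min_normals = 2L)
  # count 2 -> removed; count 1 -> retained; count 0 -> retained
  expect_equal(surv$pos, c(1L, 3L))
  expect_true(all(grepl("pon:PASS", surv$filter_trail)))
})

test_that("germline filter honors the somatic whitelist", {
  db <- data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "T")
  wl <- data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "T")
  calls <- mk_calls(1:3)
  surv <- filter_germline(calls, list(db), wl)
  # pos 1: germline DB + whitelist -> retained; pos 2: DB only -> removed;
  # pos 3: in no database -> retained
  expect_equal(surv$pos, c(1L, 3L))
  expect_match(surv$filter_trail[1], "WHITELISTED")
  expect_match(surv$filter_trail[2], "germline:PASS")
})

test_that("VAF is alt over total depth, erroring on zero depth", {
  expect_equal(compute_vaf(mk_calls(1, ref_reads = 30L, alt_reads = 0L)), 0)
  expect_equal(compute_vaf(mk_calls(1, ref_reads = 73L, alt_reads = 27L)),
               0.27)
  expect_equal(compute_vaf(mk_calls(1, ref_reads = 0L, alt_reads = 40L)), 1)
  expect_error(compute_vaf(mk_calls(1, ref_reads = 0L, alt_reads = 0L)),
               "depth")
})

test_that("cascade stages are nested subsets with non-increasing counts", {
  st <- tiny_study()
  co <- st$cohort
  pon <- build_pon(co$normals)
  s <- co$samples[1]
  res <- filter_cascade(co$caller_a[co$caller_a$sample_id == s, ],
                        co$caller_b[co$caller_b$sample_id == s, ],
                        pon, co$germline_dbs, co$whitelist)
  n <- res$counts
  expect_true(n["concordant"] <= min(n["caller_a"], n["caller_b"]))
  expect_true(n["post_pon"] <= n["concordant"])
  expect_true(n["post_germline"] <= n["post_pon"])
  for (stage in c("post_pon", "post_germline")) {
    expect_true(all(variant_key_public(res[[stage]]) %in%
                      variant_key_public(res$concordant)))
  }
})

test_that("cascade precision against truth improves monotonically", {
  st <- tiny_study()
  co <- st$cohort
  truth <- co$truth
  som_keys <- paste(truth$sample_id,
                    variant_key_public(truth))[!truth$is_germline &
                                                 !truth$is_artifact]
  pon <- build_pon(co$normals)
  precision <- function(calls) {
    if (nrow(calls) == 0) return(NA_real_)
    k <- paste(calls$sample_id, variant_key_public(calls))
    mean(k %in% som_keys)
  }
  stages <- list(caller_a = co$caller_a)
  merged <- lapply(co$samples, function(s) {
    filter_cascade(co$caller_a[co$caller_a$sample_id == s, ],
                   co$caller_b[co$caller_b$sample_id == s, ],
                   pon, co$germline_dbs, co$whitelist)
  })
  for (stage in c("concordant", "post_pon", "post_germline")) {
    stages[[stage]] <- do.call(rbind, lapply(merged, `[[`, stage))
  }
  prec <- vapply(stages, precision, numeric(1))
  expect_true(all(diff(prec) >= 0))
  expect_gt(prec["post_germline"], prec["caller_a"])

  # germline removal recall, tracked separately: most leaked germline gone
  germ_keys <- paste(truth$sample_id,
                     variant_key_public(truth))[truth$is_germline]
  final_keys <- paste(stages$post_germline$sample_id,
                      variant_key_public(stages$post_germline))
  expect_gt(mean(!germ_keys %in% final_keys), 0.8)
})

test_that("caller VCFs round-trip through the VCF reader", {
  st <- tiny_study()
  dir <- withr::local_tempdir()
  write_study(st, dir)
  s <- st$cohort$samples[1]
  back <- read_caller_vcf(file.path(dir, "vcf",
                                    paste0(s, ".caller_a.vcf")),
                          s, "caller_a")
  orig <- st$cohort$caller_a[st$cohort$caller_a$sample_id == s, ]
  o1 <- order(back$pos, back$alt); o2 <- order(orig$pos, orig$alt)
  expect_equal(back$pos[o1], orig$pos[o2])
  expect_equal(back$alt[o1], orig$alt[o2])
  expect_equal(back$alt_reads[o1], orig$alt_reads[o2])
  expect_equal(back$vtype[o1], orig$vtype[o2])
})
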
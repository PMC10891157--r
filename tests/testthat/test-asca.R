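test_that("exact HWE test matches full enumeration", {
  expect_gt(hweExactTest(25, 50, 25), 0.5)   # perfect HWE
  for (g in list(c(40, 20, 40), c(10, 5, 10), c(3, 14, 3), c(20, 0, 10))) {
    expect_equal(hweExactTest(g[1], g[2], g[3]),
                 bruteHWE(g[1], g[2], g[3]), tolerance = 1e-12)
  }
  set.seed(1)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    g <- as.vector(stats::rmultinom(1, n, c(0.3, 0.4, 0.3)))
    expect_equal(hweExactTest(g[1], g[2], g[3]),
                 bruteHWE(g[1], g[2], g[3]), tolerance = 1e-12)
  }
  expect_error(hweExactTest(0, 0, 0), "zero-total")
})

test_that("SNP filter enforces MAF and HWE rules", {
  gt <- data.frame(snp_id = c("hwe_ok", "mono", "hwe_bad", "maf_edge"),
                   n_aa = c(25, 100, 40, 91),
                   n_ab = c(50, 0, 20, 8),
                   n_bb = c(25, 0, 40, 1))
  out <- snpFilter(gt)
  expect_true("hwe_ok" %in% out$snp_id)
  expect_false("mono" %in% out$snp_id)       # MAF 0
  expect_false("hwe_bad" %in% out$snp_id)    # HWE p ~ 1e-10
  # maf_edge: MAF = 10/200 = 0.05 exactly -> retained under inclusive rule
  expect_true("maf_edge" %in% out$snp_id)
  out_strict <- snpFilter(gt, maf_inclusive = FALSE)
  expect_false("maf_edge" %in% out_strict$snp_id)
  expect_warning(snpFilter(rbind(gt, data.frame(snp_id = "empty", n_aa = 0,
                                                n_ab = 0, n_bb = 0))),
                 "zero-total")
})

test_that("aggregation thresholds are inclusive at every boundary", {
  rec <- function(id, refs, alts) {
    data.frame(snp_id = id, ref_count = refs, alt_count = alts, het = TRUE)
  }
  records <- rbind(
    rec("keep_boundary", c(8, 8, 8, 8, 8), c(2, 2, 2, 2, 2)),  # 5 het, 50 tot, 10 alt
    rec("few_het", c(20, 20, 20, 20), c(10, 10, 10, 10)),      # 4 het
    rec("low_allele", c(9, 9, 9, 9, 9), c(1, 2, 2, 2, 2)))     # alt = 9
  out <- aggregateAlleleCounts(records)
  expect_identical(out$snp_id, "keep_boundary")
  expect_equal(out$ref_count, 40)
  expect_equal(out$alt_count, 10)
  expect_equal(out$n_het, 5)
})

test_that("binomial ASCA matches enumeration, caps and floors", {
  bal <- data.frame(snp_id = "s", ref_count = 25, alt_count = 25)
  out <- binomialASCA(bal)
  expect_equal(out$p_value, 1)
  expect_equal(out$aif, 0.5)
  ext <- binomialASCA(data.frame(snp_id = "s", ref_count = 50,
                                 alt_count = 0))
  expect_equal(ext$p_value, 2 * 0.5^50, tolerance = 1e-12)
  expect_equal(ext$aif, 1)
  mid <- binomialASCA(data.frame(snp_id = "s", ref_count = 35,
                                 alt_count = 15))
  expect_equal(mid$p_value, bruteBinom2sided(15, 50), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    x <- sample(0:n, 1)
    got <- binomialASCA(data.frame(snp_id = "s", ref_count = n - x,
                                   alt_count = x))$p_value
    expect_equal(got, bruteBinom2sided(x, n), tolerance = 1e-12)
  }
  expect_error(binomialASCA(data.frame(snp_id = "s", ref_count = 0,
                                       alt_count = 0)), "zero-total")
})

test_that("AIF stays in [0.5, 1] and equals 0.5 only at p = 1 extremes", {
  cfg <- alleleSimConfig(n_snps = 300, frac_imbalanced = 0.3, seed = 5)
  res <- binomialASCA(aggregateAlleleCounts(
    simulateAlleleCounts(cfg, aggregate = FALSE)))
  expect_true(all(res$aif >= 0.5 & res$aif <= 1))
  expect_true(all(res$p_value[res$aif == 0.5] == 1))
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("planted imbalance is detected with high power", {
  # pi = 0.7, per-individual depth 12 with ~8 hets (~100 reads aggregated)
  cfg <- alleleSimConfig(n_snps = 1000, frac_imbalanced = 0.1,
                         pi_alt = 0.7, depth_mean = 12, seed = 6)
  per <- simulateAlleleCounts(cfg, aggregate = FALSE)
  agg <- aggregateAlleleCounts(per)
  truth <- unique(per$snp_id[per$truth == "imbalanced"])
  res <- binomialASCA(agg)
  power <- mean(res$is_asca[res$snp_id %in% truth])
  fdr <- mean(!(res$snp_id[res$is_asca] %in% truth))
  expect_gt(power, 0.75)
  expect_lt(fdr, 0.15)
})

test_that("group AIF comparison: exact small-sample p matches enumeration", {
  res <- data.frame(snp_id = paste0("s", 1:6),
                    aif = c(0.9, 0.85, 0.8, 0.6, 0.55, 0.5),
                    is_asca = TRUE,
                    rnm = rep(c("hi", "lo"), each = 3))
  out <- groupAIFTest(res, "rnm")
  hi <- out[out$group == "hi", ]
  expect_equal(hi$u_statistic, 9)       # all greater -> U = n1 * n2
  expect_equal(hi$p_value,
               bruteMWUgreater(c(0.9, 0.85, 0.8), c(0.6, 0.55, 0.5)),
               tolerance = 1e-12)
  expect_equal(hi$p_value, 1 / 20)
  skip_grp <- rbind(res, data.frame(snp_id = "s7", aif = 0.7,
                                    is_asca = TRUE, rnm = "tiny"))
  expect_warning(groupAIFTest(skip_grp, "rnm"), "tiny")
})

test_that("group AIF test is calibrated under exchangeable groups", {
  set.seed(7)
  pv <- replicate(100, {
    res <- data.frame(snp_id = paste0("s", 1:60),
                      aif = 0.5 + abs(rnorm(60, 0, 0.1)),
                      is_asca = TRUE,
                      rnm = sample(rep(c("a", "b", "c"), 20)))
    groupAIFTest(res, "rnm")$p_value[1]
  })
  expect_lt(abs(mean(pv < 0.1) - 0.1), 3 * sqrt(0.1 * 0.9 / 100))
})

test_that("TFBS enrichment flags planted overlap and delegates", {
  pos <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(seq(100, 4000, by = 100),
                                                 width = 1))
  names(pos) <- paste0("s", seq_along(pos))
  res <- data.frame(snp_id = names(pos),
                    is_asca = rep(c(TRUE, FALSE), each = 20))
  # TF bound sites covering exactly the imbalanced SNPs
  tf <- list(planted = GenomicRanges::GRanges("chr1",
             IRanges::IRanges(99, 2001)),
             empty = GenomicRanges::GRanges("chr1",
             IRanges::IRanges(90000, 90001)))
  out <- ascaTFBSEnrichment(res, tf, pos)
  planted <- out[out$tf_group == "planted", ]
  expect_true(planted$enriched)
  expect_equal(planted$p_value, fisher2x2(20, 0, 0, 20)$p_value)
  expect_false(out$enriched[out$tf_group == "empty"])
  # shuffled labels are not enriched
  set.seed(8)
  res_s <- res
  res_s$is_asca <- sample(res$is_asca)
  out_s <- ascaTFBSEnrichment(res_s, tf["planted"], pos)
  expect_gt(out_s$p_value[1], 1e-4)
})
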
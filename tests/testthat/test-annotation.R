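gr <- function(chrom, start0, end0, ...) {
  # convenience constructor using BED 0-based half-open coordinates
  g <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start0 + 1, end0))
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(g)[[nm]] <- mc[[nm]]
  g
}

test_that("closest TSS within 100 kb wins, ties break by expression", {
  peaks <- gr("chr1", c(1000, 50000), c(2000, 50500))
  names(peaks) <- c("p1", "p2")
  tss <- gr("chr1", c(1500, 8000, 50100, 50200), c(1501, 8001, 50101, 50201),
            gene_id = c("gA", "gB", "gC", "gD"),
            expression = c(5, 9, 5, 9))
  out <- assignTargetGene(peaks, tss)
  # p1: gA inside the peak beats gB at distance
  expect_equal(out$gene_id[out$peak_id == "p1"], "gA")
  # p2: two TSSs inside -> higher expression (gD) wins
  expect_equal(out$gene_id[out$peak_id == "p2"], "gD")

  far <- gr("chr1", 500000, 500100)
  names(far) <- "pfar"
  tss_b <- gr("chr1", c(399999, 399998), c(400000, 399999),
              gene_id = c("near", "beyond"), expression = c(1, 1))
  out_b <- assignTargetGene(far, tss_b)
  # gap of exactly 100,000 is kept; 100,001 is not
  expect_equal(out_b$gene_id, "near")
})

test_that("chromatin states collapse by summit position", {
  peaks <- gr("chr1", c(100, 300, 700, 900), c(200, 400, 800, 1000),
              summit_offset = c(50, 50, 50, 50))
  names(peaks) <- paste0("p", 1:4)
  states <- gr("chr1", c(100, 300, 700), c(250, 420, 780),
               name = c("Enh", "TssBiv", "Quies"))
  out <- collapseChromatinState(peaks, states)
  expect_equal(out$collapsed_state,
               c("Enhancer", "Bivalent Chromatin", "unassigned",
                 "unassigned"))
  # the 12-state map is total onto the 5 collapsed states
  expect_equal(sort(unique(unname(chromatinStateMap()))),
               sort(c("Active Promoter", "Enhancer", "Bivalent Chromatin",
                      "Transcription", "Repressed Polycomb")))
  expect_length(chromatinStateMap(), 12)
  bad <- gr("chr1", 100, 200, summit_offset = 150)
  expect_error(collapseChromatinState(bad, states), "summit")
})

test_that("reciprocal overlap applies the inclusive boundary to both sides", {
  a <- gr("chr1", c(0, 0), c(100, 1000))
  b <- gr("chr1", c(75, 0), c(175, 100))
  m <- reciprocalOverlap(a, b, 0.25)
  # [0,100) vs [75,175): overlap 25 = 0.25 * 100 on both -> matched
  expect_true(any(m$idx_a == 1 & m$idx_b == 1))
  # [0,1000) vs [0,100): 100 < 0.25 * 1000 -> not matched
  expect_false(any(m$idx_a == 2 & m$idx_b == 2))
  # identity matches at any fraction; symmetry of the two tracks
  self <- reciprocalOverlap(a[1], a[1], 1)
  expect_equal(nrow(self), 1)
  m_swap <- reciprocalOverlap(b, a, 0.25)
  expect_equal(nrow(m), nrow(m_swap))
})

test_that("reference peak selection bins by score and spreads remainder", {
  set.seed(1)
  peaks <- gr("chr1", seq(0, 19 * 100, by = 100),
              seq(0, 19 * 100, by = 100) + 50,
              score = sample(20))
  names(peaks) <- paste0("p", 1:20)
  out <- selectReferencePeaks(peaks, n_quantiles = 20, keep_from = 8)
  expect_equal(length(out$peaks), 13)
  expect_equal(sort(out$peaks$score), 8:20)

  # blacklist removal happens before binning
  bl <- gr("chr1", 0, 60)
  out_bl <- selectReferencePeaks(peaks, excluded = list(bl),
                                 n_quantiles = 19, keep_from = 1)
  expect_equal(length(out_bl$peaks), 19)
  expect_false("p1" %in% names(out_bl$peaks))

  # remainder rule: 45 peaks into 20 bins -> sizes 2 except top 5 of 3
  peaks45 <- gr("chr1", seq(0, 44) * 10, seq(0, 44) * 10 + 5,
                score = seq_len(45))
  names(peaks45) <- paste0("q", 1:45)
  out45 <- selectReferencePeaks(peaks45, n_quantiles = 20, keep_from = 1)
  sizes <- table(out45$assignment$score_quantile)
  expect_true(all(sizes %in% c(2, 3)))
  expect_equal(sum(sizes == 3), 5)
  expect_true(all(diff(sizes[as.character(1:20)]) >= 0))
  expect_error(selectReferencePeaks(peaks[1:5], n_quantiles = 20), "fewer")
})

test_that("TF group collapsing partitions the motif set", {
  sites <- list(m1 = c("s1", "s2", "s3"), m2 = c("s1", "s2", "s3"),
                m3 = c("s4", "s5"), m4 = c("s6"), m5 = character(0))
  expect_warning(out <- collapseTFGroups(sites), "m5")
  expect_equal(sort(out$motif), sort(names(sites)))
  expect_equal(sum(out$group_size[!duplicated(out$group)]), 5)
  expect_equal(out$group[out$motif == "m1"], out$group[out$motif == "m2"])
  expect_false(out$group[out$motif == "m3"] == out$group[out$motif == "m4"])

  # planted: 3 clones of one set + 4 unrelated motifs -> one triple + 4 singles
  clones <- list(c1 = paste0("x", 1:10), c2 = paste0("x", 1:10),
                 c3 = paste0("x", 1:10),
                 u1 = paste0("y", 1:5), u2 = paste0("z", 1:5),
                 u3 = paste0("w", 1:5), u4 = paste0("v", 1:5))
  oc <- collapseTFGroups(clones)
  expect_equal(sort(as.integer(table(oc$group))), c(1L, 1L, 1L, 1L, 3L))
  trio <- oc$group[oc$motif == "c1"]
  expect_true(all(oc$group[oc$motif %in% c("c2", "c3")] == trio))
  expect_equal(oc$category[oc$motif == "u1"], "single")

  # all pairwise-disjoint sets -> all singletons
  disj <- list(d1 = "a", d2 = "b", d3 = "c")
  od <- collapseTFGroups(disj)
  expect_equal(length(unique(od$group)), 3)

  # family table drives the multi-member category
  fam <- c(c1 = "FOX", c2 = "FOX", c3 = "FOX")
  of <- collapseTFGroups(clones, families = fam)
  expect_equal(unique(of$category[of$motif %in% c("c1", "c2", "c3")]),
               "family")
})

test_that("base-pair Fisher table matches hand arithmetic", {
  a <- gr("chr1", 0, 100)
  b <- gr("chr1", 50, 150)
  res <- intervalFisherBP(a, b, c(chr1 = 1000))
  expect_equal(unlist(res[, c("a", "b", "c", "d")], use.names = FALSE),
               c(50, 50, 50, 850))
  expect_equal(res$p_value, bruteFisher2sided(50, 50, 50, 850),
               tolerance = 1e-12)
  # depletion direction for disjoint tracks covering 10% each
  a2 <- gr("chr1", 0, 1000)
  b2 <- gr("chr1", 5000, 6000)
  res2 <- intervalFisherBP(a2, b2, c(chr1 = 10000))
  expect_lt(res2$odds_ratio, 1)
  # degenerate whole-chromosome track is flagged
  whole <- gr("chr1", 0, 1000)
  res3 <- intervalFisherBP(whole, whole, c(chr1 = 1000))
  expect_true(res3$degenerate)
  expect_error(intervalFisherBP(a, b, c(chr1 = 120)), "beyond")
})

test_that("narrowPeak round-trips through BED text", {
  tmp <- tempfile(fileext = ".narrowPeak")
  df <- data.frame("chr1", c(100L, 500L), c(300L, 900L),
                   c("pk1", "pk2"), c(150L, 80L), ".", 1.5, 2.5, 3.5,
                   c(50L, 100L))
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  gr_in <- readNarrowPeak(tmp)
  expect_equal(GenomicRanges::start(gr_in), c(101L, 501L))
  expect_equal(gr_in$summit_offset, c(50L, 100L))
  out <- tempfile(fileext = ".bed")
  writeBed(gr_in, out)
  back <- readBed(out)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr_in))
  expect_equal(back$name, gr_in$name)
})
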
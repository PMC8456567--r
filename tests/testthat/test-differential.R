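test_that("paired t statistic matches the hand example and stats::t.test", {
  res <- paired_t_test(tiny_paired(c(2, 4, 6), c(1, 2, 3)))
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2L)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  expect_equal(res$direction, "up")

  # oracle sweep: per-gene equality with t.test on differences
  for (s in 1:50) {
    po <- random_paired(n_genes = 6, n_pairs = 5, seed = s)
    res <- paired_t_test(po)
    for (i in seq_len(nrow(po$values))) {
      d <- po$values[i, po$pairing$tumor] - po$values[i, po$pairing$normal]
      tt <- t.test(d)
      expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    }
  }
})

test_that("paired t is invariant to pair order and flags degenerate genes", {
  po <- random_paired(10, 6, seed = 1)
  shuffled <- paired_omics(po$values, po$pairing[sample(6), ], "expression")
  expect_equal(paired_t_test(po)$t, paired_t_test(shuffled)$t)

  same <- tiny_paired(c(3, 3, 3), c(3, 3, 3))
  res <- paired_t_test(same)
  expect_false(res$tested)
  expect_true(is.na(res$p))
  expect_false(add_fdr(res, 0.5)$significant)

  expect_error(paired_t_test(tiny_paired(2, 1)), "at least 2")
})

test_that("BH adjustment matches the hand example and its step-up properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(9)
  for (k in 1:10) {
    p <- runif(50)
    f <- bh_fdr(p)
    # monotone non-decreasing in p-rank
    expect_true(all(diff(f[order(p)]) >= -1e-15))
    # invariant under input permutation
    idx <- sample(50)
    expect_equal(bh_fdr(p[idx]), f[idx])
    expect_true(all(f <= 1))
  }
})

test_that("segment-to-gene mapping does overlap-weighted averaging", {
  ann <- data.frame(gene_id = "g1", chrom = "chr1", start = 100L, end = 200L,
                    strand = "+", tss = 100L)
  seg <- data.frame(sample = "s1", chrom = "chr1",
                    start = c(1L, 151L), end = c(150L, 300L),
                    seg_mean = c(0.5, -0.5))
  v <- segments_to_gene_matrix(seg, ann)
  expect_equal(v["g1", "s1"], (51 * 0.5 + 50 * -0.5) / 101, tolerance = 1e-12)
  expect_lt(abs(v["g1", "s1"] - 0.00495), 1e-5)

  # fully covered gene inherits the segment mean; uncovered gene is NA
  ann2 <- rbind(ann, data.frame(gene_id = "g2", chrom = "chr1", start = 5000L,
                                end = 5100L, strand = "+", tss = 5000L))
  seg2 <- data.frame(sample = "s1", chrom = "chr1", start = 50L, end = 400L,
                     seg_mean = 0.3)
  v2 <- segments_to_gene_matrix(seg2, ann2)
  expect_equal(v2["g1", "s1"], 0.3)
  expect_true(is.na(v2["g2", "s1"]))

  expect_warning(
    segments_to_gene_matrix(
      data.frame(sample = "s1", chrom = "chr9", start = 1L, end = 10L,
                 seg_mean = 1), ann),
    "ignored")
})

test_that("segment mapping agrees exactly with a per-bp brute-force oracle", {
  set.seed(11)
  for (rep in 1:5) {
    ann <- generate_annotation(8, 1, seed = rep)
    ann$end <- pmin(ann$end, ann$start + sample(50:400, 8))  # short genes
    ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
    # random segmentation of the chromosome
    len <- max(ann$end) + 500
    cuts <- sort(sample(seq_len(len - 1), 12))
    seg <- data.frame(sample = "s1", chrom = "chr1",
                      start = c(1L, cuts + 1L), end = c(cuts, len),
                      seg_mean = rnorm(13))
    keep <- seg$start <= seg$end
    seg <- seg[keep, ]
    v <- segments_to_gene_matrix(seg, ann)
    for (i in seq_len(nrow(ann))) {
      bp <- ann$start[i]:ann$end[i]
      means <- vapply(bp, function(p) {
        hit <- seg$seg_mean[seg$start <= p & seg$end >= p]
        if (length(hit)) hit[1] else NA_real_
      }, numeric(1))
      expect_equal(unname(v[ann$gene_id[i], "s1"]), mean(means, na.rm = TRUE),
                   tolerance = 1e-12)
    }
  }
})

test_that("promoter windows are strand-aware and clamped", {
  ann <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                    start = c(5000L, 4000L, 500L), end = c(6000L, 5000L, 900L),
                    strand = c("+", "-", "+"),
                    tss = c(5000L, 5000L, 500L))
  pr <- promoter_region(ann)
  expect_equal(unlist(pr[pr$gene_id == "a", c("lo", "hi")], use.names = FALSE),
               c(4000L, 5300L))
  expect_equal(unlist(pr[pr$gene_id == "b", c("lo", "hi")], use.names = FALSE),
               c(4700L, 6000L))
  expect_equal(unlist(pr[pr$gene_id == "c", c("lo", "hi")], use.names = FALSE),
               c(1L, 800L))
  ann$strand[1] <- "?"
  expect_error(promoter_region(ann), "strand")
})

test_that("promoter methylation aggregates probe means with closed boundaries", {
  ann <- data.frame(gene_id = "g1", chrom = "chr1", start = 5000L, end = 9000L,
                    strand = "+", tss = 5000L)
  # promoter window is [4000, 5300]
  probes <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                       chrom = "chr1",
                       position = c(4100L, 5200L, 4000L, 5301L),
                       s1 = c(0.2, 0.4, 0.6, 0.9))
  m <- aggregate_promoter_methylation(probes, ann)
  # boundary probe at 4000 included; 5301 excluded
  expect_equal(unname(m["g1", "s1"]), mean(c(0.2, 0.4, 0.6)))

  one <- aggregate_promoter_methylation(probes[2, ], ann)
  expect_equal(unname(one["g1", "s1"]), 0.4)

  # genes with no promoter probe are absent
  ann2 <- rbind(ann, data.frame(gene_id = "g2", chrom = "chr1", start = 50000L,
                                end = 51000L, strand = "+", tss = 50000L))
  m2 <- aggregate_promoter_methylation(probes, ann2)
  expect_equal(rownames(m2), "g1")

  probes$s1[1] <- 1.2
  expect_error(aggregate_promoter_methylation(probes, ann), "\\[0,1\\]")
})

test_that("mutation frequency counts each patient once", {
  pats <- sprintf("P%03d", 1:548)
  mut <- data.frame(patient = pats[1:28], gene = "TP99")
  r <- mutation_frequency(mut, pats)
  expect_equal(unname(r["TP99"]), 28 / 548, tolerance = 1e-12)
  expect_gte(unname(r["TP99"]), 0.05)

  dup <- rbind(mut, data.frame(patient = pats[1], gene = "TP99"))
  expect_equal(unname(mutation_frequency(dup, pats)["TP99"]), 28 / 548)

  none <- data.frame(patient = character(), gene = character())
  expect_equal(length(mutation_frequency(none, pats)), 0L)

  expect_error(mutation_frequency(
    data.frame(patient = "X9", gene = "A"), pats), "absent")
})

test_that("SGOL scores follow the thresholded sum rule and drop sex chromosomes", {
  ann <- data.frame(gene_id = c("g1", "gx"), chrom = c("chr1", "chrX"),
                    start = c(100L, 100L), end = c(200L, 200L),
                    strand = "+", tss = 100L)
  seg <- do.call(rbind, lapply(seq_along(c(0.3, 0.25, -0.1)), function(i) {
    data.frame(sample = paste0("s", i), chrom = c("chr1", "chrX"),
               start = 1L, end = 500L, seg_mean = c(0.3, 0.25, -0.1)[i])
  }))
  expect_warning(sg <- sgol_scores(seg, ann), "ignored")  # chrX segments dropped
  expect_equal(sg$gene_id, "g1")
  expect_equal(sg$gain_score, 0.55)
  expect_equal(sg$loss_score, 0)

  seg2 <- data.frame(sample = c("s1", "s2"), chrom = "chr1", start = 1L,
                     end = 500L, seg_mean = c(-0.3, -0.3))
  sg2 <- sgol_scores(seg2, ann[1, ])
  expect_equal(sg2$loss_score, -0.6)
  expect_equal(sg2$gain_score, 0)

  seg3 <- data.frame(sample = "s1", chrom = "chr1", start = 1L, end = 500L,
                     seg_mean = 0)
  sg3 <- sgol_scores(seg3, ann[1, ])
  expect_equal(sg3$gain_score, 0)
  expect_equal(sg3$loss_score, 0)

  expect_error(sgol_scores(seg3, ann, gain_thresh = -0.2, loss_thresh = 0.2),
               "exceed")
})
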
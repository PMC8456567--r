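test_that("annotation generation is deterministic, disjoint and strand-consistent", {
  one <- generate_annotation(1, 1, seed = 0)
  expect_equal(nrow(one), 1L)
  expect_equal(one$chrom, "chr1")
  expect_equal(one$tss, if (one$strand == "+") one$start else one$end)

  a <- generate_annotation(200, 4, seed = 7)
  b <- generate_annotation(200, 4, seed = 7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  big <- generate_annotation(200, 4, seed = 1)
  expect_equal(length(unique(big$gene_id)), 200L)
  # brute-force pairwise overlap check per chromosome
  for (chrom in unique(big$chrom)) {
    g <- big[big$chrom == chrom, ]
    for (i in seq_len(nrow(g) - 1)) {
      for (j in seq(i + 1, nrow(g))) {
        expect_true(g$end[i] < g$start[j] || g$end[j] < g$start[i])
      }
    }
  }
  expect_error(generate_annotation(0, 1, seed = 1), "positive")
  expect_error(generate_annotation(10, 23, seed = 1), "22")
})

test_that("cohort generation is bit-reproducible under a fixed seed", {
  a <- generate_cohort(cohort_config(n_genes = 60L, n_pairs_cnv = 5L, seed = 7L))
  b <- generate_cohort(cohort_config(n_genes = 60L, n_pairs_cnv = 5L, seed = 7L))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_cohort(cohort_config(n_genes = 60L, n_pairs_cnv = 5L, seed = 8L))
  expect_false(identical(serialize(a, NULL), serialize(c2, NULL)))
})

test_that("planted lesions follow the consistency directionality", {
  co <- default_cohort()
  tr <- co$truth
  dirs <- setNames(rep(0, nrow(co$annotation)), co$annotation$gene_id)
  dirs[tr$de_genes_up] <- 1
  dirs[tr$de_genes_down] <- -1

  # expression: every planted up-gene has positive mean tumor-normal shift
  d <- rowMeans(co$expression$values[, co$expression$pairing$tumor] -
                  co$expression$values[, co$expression$pairing$normal])
  expect_true(all(d[tr$de_genes_up] > 0))
  expect_true(all(d[tr$de_genes_down] < 0))

  # CNV: planted genes amplified with up, deleted with down
  cnv <- segments_to_gene_matrix(co$cnv_segments, co$annotation, co$cnv_pairing)
  dc <- rowMeans(cnv$values[, cnv$pairing$tumor] - cnv$values[, cnv$pairing$normal])
  expect_true(mean(sign(dc[tr$cnv_consistent]) == dirs[tr$cnv_consistent]) >= 0.95)

  # methylation: hypo with up, hyper with down
  meth <- aggregate_promoter_methylation(co$methylation_probes, co$annotation,
                                         pairing = co$meth_pairing)
  dm <- rowMeans(meth$values[, meth$pairing$tumor] - meth$values[, meth$pairing$normal])
  expect_true(mean(sign(dm[tr$meth_consistent]) == -dirs[tr$meth_consistent]) >= 0.95)

  # mutations: planted frequent genes above the screening threshold
  rates <- mutation_frequency(co$mutations, co$mut_patients)
  expect_true(all(rates[tr$mut_frequent] >= 0.05))

  # structural invariants
  beta <- as.matrix(co$methylation_probes[, -(1:3)])
  expect_true(all(beta >= 0 & beta <= 1))
  seg <- co$cnv_segments
  for (key in unique(paste(seg$sample, seg$chrom))[1:10]) {
    s <- seg[paste(seg$sample, seg$chrom) == key, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }
})

test_that("a zero-effect zero-noise config yields exactly zero paired differences", {
  co <- generate_cohort(cohort_config(n_genes = 40L, n_pairs_cnv = 4L,
                                      expr_delta = 0, expr_noise = 0, seed = 3L))
  d <- co$expression$values[, co$expression$pairing$tumor] -
    co$expression$values[, co$expression$pairing$normal]
  expect_true(all(d == 0))
})

test_that("an unplanted cohort produces significant calls at no more than twice the nominal FDR", {
  counts <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(n_genes = 150L, n_pairs_cnv = 4L,
                                        n_pairs_meth = 4L, frac_de = 0,
                                        seed = 500L + s))
    sum(add_fdr(paired_t_test(co$expression), 0.01)$significant)
  }, numeric(1))
  limit <- 2 * 0.01 * 150
  expect_gte(sum(counts <= limit), 18)
})

test_that("generated networks are clean, connected, and reject bad arguments", {
  ann <- generate_annotation(10, 1, seed = 3)
  net <- generate_network(ann, NULL, m_edges_per_node = 1, seed = 3)
  expect_gte(nrow(net), 9)
  expect_true(all(net$from != net$to))
  expect_false(any(duplicated(net)))
  g <- igraph::graph_from_data_frame(net, directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_error(generate_network(ann, NULL, m_edges_per_node = 0, seed = 1),
               "positive")

  co <- default_cohort()
  g2 <- igraph::graph_from_data_frame(co$network_edges, directed = FALSE)
  expect_true(igraph::is_connected(g2))
  expect_true(all(co$truth$hub_genes %in% igraph::V(g2)$name))
})

test_that("clinical generation honours censoring and the planted hazard", {
  cl0 <- generate_clinical(50, hazard_beta = 0.7, censor_rate = 0, seed = 2)
  expect_true(all(cl0$os_event == 1L))
  expect_error(generate_clinical(50, censor_rate = 1, seed = 1), "censor_rate")

  # planted log-hazard is recoverable at moderate n
  cl <- generate_clinical(400, hazard_beta = 0.7, censor_rate = 0.3, seed = 1)
  fit <- cox_univariate(cl$marker_high, cl$os_time, cl$os_event)
  expect_lt(abs(fit$beta_hat - 0.7), 0.25)

  # null covariate: log-rank p roughly uniform
  p <- vapply(1:200, function(s) {
    cl <- generate_clinical(80, hazard_beta = 0, censor_rate = 0.3, seed = s)
    logrank_test(cl$os_time, cl$os_event, cl$marker_high)$p
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.02)
  expect_lte(mean(p < 0.05), 0.09)
})
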
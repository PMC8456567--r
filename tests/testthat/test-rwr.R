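test_that("network merging deduplicates, drops self-loops and reports bad rows", {
  m <- merge_networks(data.frame(from = "A", to = "B"),
                      data.frame(from = "B", to = "A"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$from, "A")

  m2 <- merge_networks(data.frame(from = c("A", "A"), to = c("A", "B")))
  expect_equal(nrow(m2), 1L)

  d1 <- data.frame(from = c("A", "B"), to = c("B", "C"))
  d2 <- data.frame(from = c("X", "Y"), to = c("Y", "Z"))
  expect_equal(nrow(merge_networks(d1, d2)), 4L)

  bad <- data.frame(from = c("A", NA), to = c("B", "C"))
  expect_error(merge_networks(bad), "line 2")
})

test_that("the biggest connected component is selected with lexical tie-break", {
  edges <- data.frame(from = c("a", "b", "x"), to = c("b", "c", "y"))
  g <- induced_bcc(edges, c("a", "b", "c", "x", "y"))
  expect_setequal(g$nodes, c("a", "b", "c"))

  g2 <- induced_bcc(edges, c("a", "b", "c"))
  expect_setequal(g2$nodes, c("a", "b", "c"))

  # equal component sizes: take the one holding the smallest node id
  tie <- data.frame(from = c("d", "a"), to = c("e", "b"))
  g3 <- induced_bcc(tie, c("a", "b", "d", "e"))
  expect_setequal(g3$nodes, c("a", "b"))

  expect_error(induced_bcc(edges, "zz"), "isolated")
  expect_error(induced_bcc(edges, character()), "empty")
})

test_that("walk graphs are column-stochastic with positive degrees", {
  co <- default_cohort()
  g <- walk_graph(co$network_edges)
  expect_true(all(abs(Matrix::colSums(g$W) - 1) < 1e-12))
  expect_true(all(g$degree >= 1))
  expect_false(any(g$edges$from == g$edges$to))
})

test_that("the restart walk reproduces hand-solved fixed points", {
  g2 <- walk_graph(data.frame(from = "A", to = "B"))
  r <- rwr(g2, c(A = 1, B = 0))
  expect_equal(unname(r$p_infinity), c(0.76923, 0.23077), tolerance = 1e-5)
  expect_equal(sum(r$p_infinity), 1, tolerance = 1e-9)

  g3 <- walk_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
  r3 <- rwr(g3, c(A = 1, B = 0, C = 0))
  expect_equal(unname(r3$p_infinity), c(0.73462, 0.23077, 0.03462),
               tolerance = 1e-5)

  # restart-only limit returns the source distribution for any graph
  r1 <- rwr(g3, c(A = 0.2, B = 0.5, C = 0.3), rwr_config(restart = 1))
  expect_equal(unname(r1$p_infinity), c(0.2, 0.5, 0.3), tolerance = 1e-12)

  expect_error(rwr(g2, c(A = 0.6, B = 0.6)), "sum to 1")
  expect_error(rwr(g2, c(A = 1, B = 0), rwr_config(max_iter = 1)),
               "L1 gap")
})

test_that("iterative solutions match the direct linear solve on random graphs", {
  expect_equal(unname(rwr_closed_form(
    walk_graph(data.frame(from = "A", to = "B")), c(A = 1, B = 0), 0.7)),
    c(0.76923, 0.23077), tolerance = 1e-5)

  # symmetry: uniform restart on a cycle stays uniform
  cyc <- walk_graph(data.frame(from = c("a", "b", "c", "d"),
                               to = c("b", "c", "d", "a")))
  u <- rep(0.25, 4); names(u) <- cyc$nodes
  expect_equal(unname(rwr_closed_form(cyc, u, 0.7)), rep(0.25, 4),
               tolerance = 1e-12)

  for (s in 1:5) {
    ann <- generate_annotation(60, 2, seed = s)
    g <- walk_graph(generate_network(ann, NULL, 2, seed = s))
    set.seed(s)
    p0 <- runif(length(g$nodes)); p0 <- p0 / sum(p0); names(p0) <- g$nodes
    it <- rwr(g, p0)$p_infinity
    cf <- rwr_closed_form(g, p0)
    expect_lt(max(abs(it - cf)), 1e-8)
  }
})

test_that("the L1 gap contracts geometrically with factor 1 - r", {
  ann <- generate_annotation(40, 2, seed = 9)
  g <- walk_graph(generate_network(ann, NULL, 2, seed = 9))
  n <- length(g$nodes)
  p0 <- c(1, rep(0, n - 1)); names(p0) <- g$nodes
  r <- 0.7
  p <- p0; gaps <- numeric(0)
  for (t in 1:15) {
    pn <- as.numeric((1 - r) * (g$W %*% p)) + r * p0
    gaps <- c(gaps, sum(abs(pn - p)))
    p <- pn
  }
  ratios <- gaps[-1] / gaps[-length(gaps)]
  expect_true(all(ratios <= (1 - r) + 1e-9))
  # hence convergence to 1e-10 within ~20 iterations
  expect_lte(rwr(g, p0)$n_iter, 25)
})

test_that("permutation p-values match an independent closed-form recomputation", {
  ann <- generate_annotation(12, 1, seed = 4)
  g <- walk_graph(generate_network(ann, NULL, 2, seed = 4))
  n <- length(g$nodes)
  set.seed(21)
  scores <- sample(c(rep(0L, n - 4), 1L, 1L, 2L, 3L))
  names(scores) <- g$nodes
  cfg <- rwr_config(n_perm = 50L, seed = 77L)
  res <- permutation_significance(g, scores, cfg)

  obs <- rwr_closed_form(g, scores / sum(scores))
  exceed <- integer(n)
  omicwalk:::with_seed(cfg$seed, {
    for (k in 1:50) {
      s <- unname(scores[sample.int(n)])  # shuffled over node positions
      pk <- rwr_closed_form(g, stats::setNames(s / sum(s), g$nodes))
      exceed <- exceed + (pk >= obs - 1e-12)
    }
  })
  expect_equal(res$perm_p, unname((1 + exceed) / 51), tolerance = 1e-6)
  expect_true(all(res$perm_p >= 1 / 51))
  expect_equal(res$p_infinity, unname(obs), tolerance = 1e-8)
})

test_that("degenerate score vectors are handled per contract", {
  g <- walk_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
  flat <- c(A = 1L, B = 1L, C = 1L)
  res <- permutation_significance(g, flat, rwr_config(n_perm = 20L, seed = 1))
  expect_true(all(res$perm_p == 1))

  expect_error(permutation_significance(g, c(A = 0L, B = 0L, C = 0L),
                                        rwr_config(n_perm = 10L)),
               "zero")
})

test_that("significant-gene selection uses a strict threshold and stable order", {
  res <- data.frame(node = c("n1", "n2", "n3", "n4"),
                    score = 1L, p_infinity = 0.25,
                    perm_p = c(0.02, 0.001, 0.5, 0.001),
                    significant = FALSE)
  out <- select_significant(res, alpha = 0.02)
  expect_equal(out, c("n2", "n4"))  # 0.02 exactly is excluded; ties by node id

  res$perm_p <- rep(1, 4)
  expect_equal(length(select_significant(res)), 0L)

  res$perm_p <- c(0.001, 0.5, 1, 1)
  expect_equal(select_significant(res), "n1")
})
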
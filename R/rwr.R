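#' Merge interaction networks into one undirected edge set
#'
#' Takes one or more two-column edge tables (directed or undirected; e.g. a
#' protein-protein interaction list and a pathway-derived regulatory list),
#' drops edge direction, removes self-loops and collapses duplicate edges
#' under canonical (sorted) node ordering.
#'
#' @param ... two-column data.frames (or a single list of them); columns are
#'   taken as from/to node ids.
#' @return data.frame with columns `from`, `to` (`from < to` lexically), one
#'   row per undirected edge.
#' @export
merge_networks <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]]) && !is.data.frame(lists[[1]])) {
    lists <- lists[[1]]
  }
  if (!length(lists)) stop("no edge lists supplied", call. = FALSE)
  edges <- do.call(rbind, lapply(seq_along(lists), function(k) {
    el <- as.data.frame(lists[[k]], stringsAsFactors = FALSE)
    if (ncol(el) < 2L) stop(sprintf("edge list %d has fewer than 2 columns", k), call. = FALSE)
    u <- as.character(el[[1]]); v <- as.character(el[[2]])
    bad <- which(is.na(u) | is.na(v) | u == "" | v == "")
    if (length(bad)) {
      stop(sprintf("edge list %d: malformed row at line %d", k, bad[1]), call. = FALSE)
    }
    data.frame(from = u, to = v, stringsAsFactors = FALSE)
  }))
  keep <- edges$from != edges$to
  edges <- edges[keep, , drop = FALSE]
  lo <- pmin(edges$from, edges$to)
  hi <- pmax(edges$from, edges$to)
  canon <- data.frame(from = lo, to = hi, stringsAsFactors = FALSE)
  canon <- canon[!duplicated(canon), , drop = FALSE]
  canon <- canon[order(canon$from, canon$to), , drop = FALSE]
  rownames(canon) <- NULL
  canon
}

#' Build a walking graph (column-stochastic transition matrix)
#'
#' @param edges undirected edge data.frame (`from`, `to`), typically from
#'   [merge_networks()] or [induced_bcc()].
#' @return object of class `walk_graph`: ordered `nodes`, `edges`, and the
#'   sparse column-stochastic matrix `W` (column j spreads probability 1/deg(j)
#'   over the neighbors of node j). Every node must have degree >= 1.
#' @export
walk_graph <- function(edges) {
  edges <- merge_networks(edges)  # enforce canonical clean form
  if (!nrow(edges)) stop("empty edge set", call. = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  n <- length(nodes)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n), dimnames = list(nodes, nodes))
  deg <- Matrix::colSums(adj)
  W <- adj %*% Matrix::Diagonal(n, 1 / deg)
  cs <- Matrix::colSums(W)
  stopifnot(all(abs(cs - 1) < 1e-12))
  structure(list(nodes = nodes, edges = edges, W = W, degree = deg),
            class = "walk_graph")
}

#' @export
print.walk_graph <- function(x, ...) {
  cat(sprintf("walk_graph: %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Biggest connected component of an induced subgraph
#'
#' Projects a node subset (typically the differentially expressed genes) onto
#' the merged network, takes the induced subgraph, and returns its largest
#' connected component as a walking graph. Size ties are broken in favour of
#' the component containing the lexicographically smallest node.
#'
#' @param edges undirected edge data.frame.
#' @param node_subset character vector of nodes to project.
#' @return a [walk_graph()] on the biggest connected component.
#' @export
induced_bcc <- function(edges, node_subset) {
  if (!length(node_subset)) stop("`node_subset` is empty", call. = FALSE)
  edges <- merge_networks(edges)
  keep <- edges$from %in% node_subset & edges$to %in% node_subset
  sub <- edges[keep, , drop = FALSE]
  if (!nrow(sub)) {
    stop("induced subgraph has no edges (isolated nodes cannot be walked)", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(sub, directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component holding the lexicographically smallest member
    firsts <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)[1]]
  }
  members <- igraph::V(g)$name[comp$membership == best]
  walk_graph(sub[sub$from %in% members & sub$to %in% members, , drop = FALSE])
}

#' Random-walk-with-restart configuration
#'
#' @param restart restart probability r in (0,1]; at each step the walker
#'   returns to the source distribution with probability r (default 0.7).
#' @param tol L1 convergence tolerance on successive probability vectors
#'   (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @param n_perm number of node-label permutations for the empirical null
#'   (default 10000).
#' @param alpha permutation p-value significance threshold, strict
#'   (default 0.02).
#' @param seed integer seed for the permutation stream.
#' @return list of class `rwr_config`.
#' @export
rwr_config <- function(restart = 0.7, tol = 1e-10, max_iter = 10000L,
                       n_perm = 10000L, alpha = 0.02, seed = 1L) {
  if (!(restart > 0 && restart <= 1)) stop("`restart` must lie in (0,1]", call. = FALSE)
  if (!(tol > 0)) stop("`tol` must be positive", call. = FALSE)
  assert_positive_int(max_iter, "max_iter")
  assert_positive_int(n_perm, "n_perm")
  assert_prob(alpha, "alpha", open_left = TRUE)
  structure(list(restart = restart, tol = tol, max_iter = as.integer(max_iter),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed)),
            class = "rwr_config")
}

# batched power iteration: P0 is an n x m matrix of restart distributions;
# iterates every column until its own L1 gap drops below tol.
.rwr_iterate <- function(W, P0, restart, tol, max_iter) {
  P <- P0
  active <- rep(TRUE, ncol(P0))
  iters <- integer(ncol(P0))
  it <- 0L
  while (any(active)) {
    it <- it + 1L
    if (it > max_iter) {
      stop(sprintf("random walk failed to converge in %d iterations (last L1 gap %.3e)",
                   max_iter, max(last_gap)), call. = FALSE)
    }
    Pa <- P[, active, drop = FALSE]
    Pn <- (1 - restart) * as.matrix(W %*% Pa) + restart * P0[, active, drop = FALSE]
    # probability mass must be conserved at every step
    stopifnot(all(abs(colSums(Pn) - 1) < 1e-9))
    gap <- colSums(abs(Pn - Pa))
    last_gap <- gap
    P[, active] <- Pn
    done <- gap < tol
    iters[which(active)[done]] <- it
    active[active] <- !done
  }
  list(P = P, n_iter = iters)
}

#' Random walk with restart
#'
#' Iterates p_{t+1} = (1 - r) W p_t + r p_0 from p_0 until the L1 distance
#' between successive vectors falls below `tol`, returning the steady-state
#' probability vector. Probability mass (sum 1) is asserted at every step.
#'
#' @param graph a [walk_graph()].
#' @param p0 non-negative restart distribution over `graph$nodes` (named or
#'   in node order), summing to 1 within 1e-12.
#' @param config an [rwr_config()]; only `restart`, `tol`, `max_iter` are
#'   used here.
#' @return list with `p_infinity` (named, sums to 1) and `n_iter`.
#' @export
rwr <- function(graph, p0, config = rwr_config()) {
  stopifnot(inherits(graph, "walk_graph"))
  n <- length(graph$nodes)
  if (!is.null(names(p0))) p0 <- p0[graph$nodes]
  if (length(p0) != n || anyNA(p0)) {
    stop("`p0` must cover every graph node", call. = FALSE)
  }
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-12) {
    stop("`p0` must be non-negative and sum to 1", call. = FALSE)
  }
  res <- .rwr_iterate(graph$W, matrix(p0, ncol = 1), config$restart,
                      config$tol, config$max_iter)
  list(p_infinity = stats::setNames(res$P[, 1], graph$nodes),
       n_iter = res$n_iter[1])
}

#' Direct linear solve of the restart walk (oracle)
#'
#' Solves the fixed point p = r (I - (1 - r) W)^{-1} p_0 by a dense linear
#' solve; intended as an independent cross-check of [rwr()] on graphs small
#' enough to densify.
#'
#' @inheritParams rwr
#' @param restart restart probability r.
#' @return named steady-state vector.
#' @export
rwr_closed_form <- function(graph, p0, restart = 0.7) {
  stopifnot(inherits(graph, "walk_graph"))
  n <- length(graph$nodes)
  if (n > 2000L) stop("dense solve limited to graphs of <= 2000 nodes", call. = FALSE)
  if (!is.null(names(p0))) p0 <- p0[graph$nodes]
  A <- diag(n) - (1 - restart) * as.matrix(graph$W)
  stats::setNames(as.numeric(solve(A, restart * p0)), graph$nodes)
}

#' Permutation significance of steady-state probabilities
#'
#' Runs the restart walk with p_0 proportional to the integer source scores,
#' then permutes the score vector over the nodes (network topology fixed)
#' `n_perm` times, re-running the walk for each permutation. The per-node
#' empirical p-value is the upper-tail fraction with an add-one pseudo-count:
#' (1 + #\{permutations with permuted steady-state >= observed\}) /
#' (n_perm + 1), so it can never be exactly zero.
#'
#' @param graph a [walk_graph()].
#' @param scores non-negative integer scores named by node (0 allowed; at
#'   least one node must be positive). The permutation shuffles the full
#'   vector including zeros, preserving the score multiset.
#' @param config an [rwr_config()].
#' @param chunk_size permutations solved per batch (memory/speed trade-off).
#' @return data.frame of class `rwr_result`: `node`, `score`, `p_infinity`,
#'   `perm_p`, `significant` (perm_p < alpha, strict); attributes `n_iter`
#'   (observed run) and `config`.
#' @export
permutation_significance <- function(graph, scores, config = rwr_config(),
                                     chunk_size = 500L) {
  stopifnot(inherits(graph, "walk_graph"))
  if (is.null(names(scores))) stop("`scores` must be named by node", call. = FALSE)
  scores <- scores[graph$nodes]
  if (anyNA(scores)) stop("`scores` must cover every graph node", call. = FALSE)
  if (any(scores < 0)) stop("scores must be non-negative", call. = FALSE)
  if (sum(scores) == 0) stop("all scores are zero: no source nodes", call. = FALSE)
  n <- length(graph$nodes)
  p0 <- scores / sum(scores)
  obs <- rwr(graph, p0, config)

  exceed <- integer(n)
  with_seed(config$seed, {
    done <- 0L
    while (done < config$n_perm) {
      m <- min(chunk_size, config$n_perm - done)
      P0 <- vapply(seq_len(m), function(k) {
        s <- scores[sample.int(n)]
        s / sum(s)
      }, numeric(n))
      perm <- .rwr_iterate(graph$W, P0, config$restart, config$tol, config$max_iter)
      exceed <- exceed + rowSums(perm$P >= obs$p_infinity)
      done <- done + m
    }
  })
  perm_p <- (1 + exceed) / (config$n_perm + 1)
  out <- data.frame(
    node = graph$nodes,
    score = as.integer(scores),
    p_infinity = as.numeric(obs$p_infinity),
    perm_p = perm_p,
    significant = perm_p < config$alpha,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "n_iter") <- obs$n_iter
  attr(out, "config") <- config
  class(out) <- c("rwr_result", class(out))
  out
}

#' Select significantly afflicted genes
#'
#' @param result an `rwr_result` from [permutation_significance()].
#' @param alpha strict threshold on the permutation p-value (default 0.02).
#' @return character vector of nodes with `perm_p < alpha`, ordered by
#'   (perm_p, node id).
#' @export
select_significant <- function(result, alpha = 0.02) {
  hit <- result[result$perm_p < alpha, , drop = FALSE]
  hit <- hit[order(hit$perm_p, hit$node), , drop = FALSE]
  hit$node
}
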
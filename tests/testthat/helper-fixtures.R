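# Shared fixtures, built in code at test time.

# tiny paired matrix: genes x (tumor, normal) columns
tiny_paired <- function(tumor, normal, layer = "expression") {
  stopifnot(length(tumor) == length(normal))
  n <- length(tumor)
  vals <- rbind(g1 = c(tumor, normal))
  colnames(vals) <- c(paste0("t", seq_len(n)), paste0("n", seq_len(n)))
  paired_omics(vals, data.frame(tumor = paste0("t", seq_len(n)),
                                normal = paste0("n", seq_len(n))), layer)
}

# random small paired matrix for oracle sweeps
random_paired <- function(n_genes, n_pairs, seed) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * 2 * n_pairs), n_genes,
                 dimnames = list(paste0("g", seq_len(n_genes)),
                                 c(paste0("t", seq_len(n_pairs)),
                                   paste0("n", seq_len(n_pairs)))))
  paired_omics(vals, data.frame(tumor = paste0("t", seq_len(n_pairs)),
                                normal = paste0("n", seq_len(n_pairs))),
               "expression")
}

# default small cohort, generated once per test run
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 42L) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(cohort_config(seed = seed))
  }
  .cohort_cache[[key]]
}

# run the differential + grouping + walk stages on a cohort and return the
# pieces recovery tests need
run_recovery <- function(cohort, n_perm = 500L, perm_seed = 1L) {
  d <- add_fdr(paired_t_test(cohort$expression), 0.01)
  hits <- d$gene_id[d$significant]
  cnv <- paired_t_test(segments_to_gene_matrix(
    cohort$cnv_segments, cohort$annotation, cohort$cnv_pairing))
  meth <- paired_t_test(aggregate_promoter_methylation(
    cohort$methylation_probes, cohort$annotation, pairing = cohort$meth_pairing))
  asn <- classify_groups(d, cnv, meth,
                         mutation_frequency(cohort$mutations, cohort$mut_patients))
  graph <- induced_bcc(cohort$network_edges, hits)
  sc <- score_sources(asn)[graph$nodes]
  names(sc) <- graph$nodes
  sc[is.na(sc)] <- 0L
  res <- permutation_significance(graph, sc,
                                  rwr_config(n_perm = n_perm, seed = perm_seed))
  list(diff = d, hits = hits, assignment = asn, graph = graph, rwr = res)
}
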
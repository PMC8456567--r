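#' Combine omics layers into dysregulation groups and source scores
#'
#' Classifies differentially expressed genes (DEGs) by the consistency of
#' their upstream lesions:
#' * Group A: DEG with direction-consistent copy number change
#'   (up-regulated and amplified, or down-regulated and deleted);
#' * Group B: DEG with direction-consistent promoter methylation change
#'   (up-regulated and hypomethylated, or down-regulated and hypermethylated);
#' * Group C: DEG with somatic mutation frequency at or above `mut_rate`
#'   (no directional requirement).
#'
#' Membership always requires DEG status; a gene missing from a layer cannot
#' join that layer's group. The source score of a gene is the number of
#' groups it belongs to (0-3); genes scoring 0 act as information targets in
#' the network walk.
#'
#' @param expr,cnv,meth differential tables from [paired_t_test()] (FDR not
#'   yet required; it is computed here at the layer's threshold). `cnv` and
#'   `meth` may be NULL when a layer is unavailable.
#' @param mut_rates named rate vector from [mutation_frequency()] (or NULL).
#' @param fdr_expr,fdr_cnv,fdr_meth per-layer FDR thresholds
#'   (defaults 0.01, 1e-5, 0.01).
#' @param mut_rate mutation-frequency threshold (default 0.05, inclusive).
#' @return data.frame `gene_id`, `in_A`, `in_B`, `in_C`, `direction`
#'   (expression direction for DEGs, "none" otherwise), `score`. The gene
#'   universe is the expression table's genes.
#' @export
classify_groups <- function(expr, cnv = NULL, meth = NULL, mut_rates = NULL,
                            fdr_expr = 0.01, fdr_cnv = 1e-5, fdr_meth = 0.01,
                            mut_rate = 0.05) {
  if (anyDuplicated(expr$gene_id)) stop("duplicated gene ids in `expr`", call. = FALSE)
  expr <- add_fdr(expr, fdr_expr)
  deg <- expr$significant
  dir <- ifelse(deg, expr$direction, "none")

  layer_dir <- function(diff, level) {
    if (is.null(diff)) return(list(up = character(), down = character()))
    if (anyDuplicated(diff$gene_id)) stop("duplicated gene ids in a layer table", call. = FALSE)
    diff <- add_fdr(diff, level)
    sig <- diff[diff$significant, , drop = FALSE]
    list(up = sig$gene_id[sig$direction == "up"],
         down = sig$gene_id[sig$direction == "down"])
  }
  cn <- layer_dir(cnv, fdr_cnv)    # up = amplified, down = deleted
  me <- layer_dir(meth, fdr_meth)  # up = hypermethylated, down = hypomethylated

  g <- expr$gene_id
  in_A <- deg & ((dir == "up" & g %in% cn$up) | (dir == "down" & g %in% cn$down))
  in_B <- deg & ((dir == "up" & g %in% me$down) | (dir == "down" & g %in% me$up))
  mut_genes <- if (is.null(mut_rates)) character() else names(mut_rates)[mut_rates >= mut_rate]
  in_C <- deg & g %in% mut_genes

  data.frame(
    gene_id = g,
    in_A = in_A, in_B = in_B, in_C = in_C,
    direction = dir,
    score = as.integer(in_A) + as.integer(in_B) + as.integer(in_C),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Source score vector from a group assignment
#'
#' @param assignment output of [classify_groups()].
#' @return named integer vector of 0-3 scores over the gene universe.
#' @export
score_sources <- function(assignment) {
  stats::setNames(as.integer(assignment$score), assignment$gene_id)
}

#' Group sizes, direction splits, overlaps and score histogram
#'
#' @param assignment output of [classify_groups()].
#' @return list with elements `n_genes`, `groups` (sizes of A/B/C with
#'   up/down splits), `venn` (all seven intersection counts), `score_counts`
#'   (genes per score 0-3).
#' @export
group_summary <- function(assignment) {
  a <- assignment
  grp_split <- function(flag) {
    c(total = sum(flag),
      up = sum(flag & a$direction == "up"),
      down = sum(flag & a$direction == "down"))
  }
  venn <- c(
    A_only = sum(a$in_A & !a$in_B & !a$in_C),
    B_only = sum(!a$in_A & a$in_B & !a$in_C),
    C_only = sum(!a$in_A & !a$in_B & a$in_C),
    AB = sum(a$in_A & a$in_B & !a$in_C),
    AC = sum(a$in_A & !a$in_B & a$in_C),
    BC = sum(!a$in_A & a$in_B & a$in_C),
    ABC = sum(a$in_A & a$in_B & a$in_C)
  )
  list(
    n_genes = nrow(a),
    groups = list(A = grp_split(a$in_A), B = grp_split(a$in_B), C = grp_split(a$in_C)),
    venn = venn,
    score_counts = stats::setNames(
      vapply(0:3, function(k) sum(a$score == k), integer(1)),
      paste0("score_", 0:3))
  )
}
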
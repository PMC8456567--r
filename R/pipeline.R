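#' Pipeline configuration
#'
#' Collects the fixed analysis constants (per-layer FDR thresholds, mutation
#' rate cutoff, walk parameters, survival alpha) together with either a
#' synthetic-cohort block or a set of input file paths.
#'
#' @param synthetic a [cohort_config()] to simulate inputs, or NULL when
#'   `inputs` is given.
#' @param inputs named list of input file paths (see [validate_inputs()]);
#'   ignored when `synthetic` is non-NULL.
#' @param fdr_expr,fdr_cnv,fdr_meth,mut_rate per-layer significance
#'   thresholds (defaults 0.01, 1e-5, 0.01, 0.05).
#' @param rwr an [rwr_config()] block.
#' @param survival_alpha reporting threshold for the survival stage.
#' @param seed run seed (overrides the synthetic block's seed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = cohort_config(), inputs = NULL,
                            fdr_expr = 0.01, fdr_cnv = 1e-5, fdr_meth = 0.01,
                            mut_rate = 0.05,
                            rwr = rwr_config(n_perm = 1000L),
                            survival_alpha = 0.05, seed = 42L) {
  for (nm in c("fdr_expr", "fdr_cnv", "fdr_meth", "mut_rate", "survival_alpha")) {
    v <- get(nm)
    if (!(v > 0 && v < 1)) stop(sprintf("`%s` must lie in (0,1)", nm), call. = FALSE)
  }
  if (is.null(synthetic) && is.null(inputs)) {
    stop("either `synthetic` or `inputs` must be given", call. = FALSE)
  }
  if (!is.null(inputs)) {
    missing <- !vapply(inputs, file.exists, logical(1))
    if (any(missing)) {
      stop("input file missing: ", inputs[[which(missing)[1]]], call. = FALSE)
    }
  }
  if (!is.null(synthetic)) {
    synthetic$seed <- as.integer(seed)
  }
  rwr$seed <- as.integer(seed)
  structure(list(synthetic = synthetic, inputs = inputs,
                 fdr_expr = fdr_expr, fdr_cnv = fdr_cnv, fdr_meth = fdr_meth,
                 mut_rate = mut_rate, rwr = rwr,
                 survival_alpha = survival_alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with optional blocks `synthetic`, `inputs`,
#'   `thresholds` (fdr_expr/fdr_cnv/fdr_meth/mut_rate), `rwr`
#'   (restart/tol/max_iter/n_perm/alpha), `survival_alpha`, `seed`.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- y$thresholds %||% list()
  rw <- y$rwr %||% list()
  syn <- if (is.null(y$inputs)) do.call(cohort_config, y$synthetic %||% list()) else NULL
  pipeline_config(
    synthetic = syn,
    inputs = y$inputs,
    fdr_expr = th$fdr_expr %||% 0.01,
    fdr_cnv = th$fdr_cnv %||% 1e-5,
    fdr_meth = th$fdr_meth %||% 0.01,
    mut_rate = th$mut_rate %||% 0.05,
    rwr = rwr_config(restart = rw$restart %||% 0.7, tol = rw$tol %||% 1e-10,
                     max_iter = rw$max_iter %||% 10000L,
                     n_perm = rw$n_perm %||% 1000L,
                     alpha = rw$alpha %||% 0.02),
    survival_alpha = y$survival_alpha %||% 0.05,
    seed = y$seed %||% 42L
  )
}

.load_inputs <- function(config, outdir) {
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    write_cohort(cohort, file.path(outdir, "inputs"))
    list(
      annotation = cohort$annotation,
      expression = cohort$expression,
      cnv_segments = cohort$cnv_segments,
      cnv_pairing = cohort$cnv_pairing,
      methylation_probes = cohort$methylation_probes,
      meth_pairing = cohort$meth_pairing,
      mutations = cohort$mutations,
      mut_patients = cohort$mut_patients,
      network_edges = cohort$network_edges,
      clinical = cohort$clinical,
      truth = cohort$truth
    )
  } else {
    paths <- config$inputs
    expr_m <- read_omics_matrix(paths$expression)
    expr_pr <- .read_tsv(paths$expr_pairing)
    mut <- .read_tsv(paths$mutations)
    list(
      annotation = read_annotation(paths$annotation),
      expression = paired_omics(expr_m, expr_pr, "expression"),
      cnv_segments = read_segments(paths$cnv_segments),
      cnv_pairing = .read_tsv(paths$cnv_pairing),
      methylation_probes = .read_tsv(paths$methylation_probes),
      meth_pairing = .read_tsv(paths$meth_pairing),
      mutations = mut,
      mut_patients = .read_tsv(paths$mut_patients)$patient,
      network_edges = read_edges(paths$network_edges),
      clinical = .read_tsv(paths$clinical),
      truth = NULL
    )
  }
}

#' Run the integrative analysis end to end
#'
#' Stages, in order: (1) load or simulate inputs; (2) per-layer paired
#' differential tests plus mutation frequencies; (3) combination into
#' dysregulation groups and source scores; (4) projection of the
#' differentially expressed genes onto the network, biggest connected
#' component, random walk with restart and permutation significance;
#' (5) survival and association statistics on the clinical table. Every
#' stage writes its outputs as TSV/JSON under `outdir`, and a run manifest
#' (configuration echo, per-stage record counts, output file MD5 hashes,
#' package version) is written last. A failure in any stage aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return the manifest list, invisibly; all outputs are on disk.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  counts <- list()

  inp <- stage("inputs", .load_inputs(config, outdir))
  counts$genes <- nrow(inp$annotation)

  # -- differential stage -----------------------------------------------
  res <- stage("differential", {
    expr_diff <- add_fdr(paired_t_test(inp$expression), config$fdr_expr)
    cnv_mat <- segments_to_gene_matrix(inp$cnv_segments, inp$annotation,
                                       inp$cnv_pairing)
    cnv_diff <- add_fdr(paired_t_test(cnv_mat), config$fdr_cnv)
    meth_mat <- aggregate_promoter_methylation(inp$methylation_probes,
                                               inp$annotation,
                                               pairing = inp$meth_pairing)
    meth_diff <- add_fdr(paired_t_test(meth_mat), config$fdr_meth)
    mut_rates <- mutation_frequency(inp$mutations, inp$mut_patients)
    sgol <- sgol_scores(inp$cnv_segments, inp$annotation)
    list(expr = expr_diff, cnv = cnv_diff, meth = meth_diff,
         mut_rates = mut_rates, sgol = sgol)
  })
  for (nm in c("expr", "cnv", "meth")) {
    .write_tsv(res[[nm]], file.path(outdir, sprintf("diff_%s.tsv", nm)))
  }
  .write_tsv(data.frame(gene_id = names(res$mut_rates), rate = res$mut_rates),
             file.path(outdir, "mutation_rates.tsv"))
  .write_tsv(res$sgol, file.path(outdir, "sgol_scores.tsv"))
  counts$deg <- sum(res$expr$significant)

  # -- integration stage ------------------------------------------------
  assignment <- stage("groups", classify_groups(
    res$expr, res$cnv, res$meth, res$mut_rates,
    fdr_expr = config$fdr_expr, fdr_cnv = config$fdr_cnv,
    fdr_meth = config$fdr_meth, mut_rate = config$mut_rate))
  .write_tsv(assignment, file.path(outdir, "group_assignment.tsv"))
  summ <- group_summary(assignment)
  jsonlite::write_json(summ, file.path(outdir, "group_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  counts$sources <- sum(assignment$score > 0)

  # -- network stage ----------------------------------------------------
  rwr_res <- stage("network_rwr", {
    deg_genes <- res$expr$gene_id[res$expr$significant]
    graph <- induced_bcc(inp$network_edges, deg_genes)
    scores <- score_sources(assignment)
    scores <- scores[graph$nodes]
    names(scores) <- graph$nodes
    scores[is.na(scores)] <- 0L
    permutation_significance(graph, scores, config$rwr)
  })
  .write_tsv(as.data.frame(rwr_res), file.path(outdir, "rwr_result.tsv"))
  sig_genes <- select_significant(rwr_res, config$rwr$alpha)
  jsonlite::write_json(
    list(r = config$rwr$restart, tol = config$rwr$tol,
         n_perm = config$rwr$n_perm, alpha = config$rwr$alpha,
         seed = config$rwr$seed, n_iter = attr(rwr_res, "n_iter"),
         bcc_nodes = nrow(rwr_res), significant_genes = sig_genes),
    file.path(outdir, "rwr_manifest.json"), auto_unbox = TRUE, digits = NA)
  counts$bcc_nodes <- nrow(rwr_res)
  counts$significant_genes <- length(sig_genes)

  # -- survival stage ---------------------------------------------------
  surv <- stage("survival", {
    cl <- inp$clinical
    lr <- logrank_test(cl$os_time, cl$os_event, cl$marker_high)
    cox <- cox_univariate(cl$marker_high, cl$os_time, cl$os_event)
    km <- lapply(split(seq_len(nrow(cl)), cl$marker_high), function(idx) {
      km_estimate(cl$os_time[idx], cl$os_event[idx])
    })
    covars <- c("age_group", "pT", "pN", "stage", "grade", "adjctx",
                "adjrad", "er_status")
    assoc <- do.call(rbind, lapply(covars, function(cv) {
      tab <- table(cl[[cv]], cl$marker_high)
      ct <- tryCatch(chi_squared_association(as.matrix(tab)),
                     error = function(e) list(chi2 = NA, df = NA, p = NA))
      data.frame(covariate = cv, chi2 = ct$chi2, df = ct$df, p = ct$p)
    }))
    list(logrank = lr, cox = cox, km = km, assoc = assoc)
  })
  .write_tsv(data.frame(
    factor = "marker_high", hr = surv$cox$hr, ci_low = surv$cox$ci_low,
    ci_high = surv$cox$ci_high, p = surv$cox$p,
    logrank_chi2 = surv$logrank$chi2, logrank_p = surv$logrank$p),
    file.path(outdir, "survival_cox.tsv"))
  .write_tsv(surv$assoc, file.path(outdir, "survival_association.tsv"))
  for (g in names(surv$km)) {
    .write_tsv(surv$km[[g]], file.path(outdir, sprintf("km_marker_%s.tsv", g)))
  }
  counts$patients <- nrow(inp$clinical)

  # -- manifest ---------------------------------------------------------
  outputs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  hashes <- tools::md5sum(outputs)
  names(hashes) <- sub(paste0("^", outdir, "/?"), "", names(hashes))
  manifest <- list(
    package_version = as.character(utils::packageVersion("omicwalk")),
    seed = config$seed,
    thresholds = list(fdr_expr = config$fdr_expr, fdr_cnv = config$fdr_cnv,
                      fdr_meth = config$fdr_meth, mut_rate = config$mut_rate),
    rwr = config$rwr[c("restart", "tol", "max_iter", "n_perm", "alpha")],
    counts = counts,
    hashes = as.list(hashes)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
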
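#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping gene bodies on `n_chrom` chromosomes
#' (round-robin assignment, sequential placement with random inter-gene
#' gaps), random strands, and a strand-consistent transcription start site
#' (gene start on "+", gene end on "-").
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chrom number of chromosomes, 1..22.
#' @param seed integer seed; the table is deterministic given the arguments.
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (1-based closed),
#'   `strand`, `tss`.
#' @export
generate_annotation <- function(n_genes, n_chrom = 4L, seed = 1L) {
  assert_positive_int(n_genes, "n_genes")
  assert_positive_int(n_chrom, "n_chrom")
  if (n_chrom > 22L) stop("`n_chrom` must be <= 22", call. = FALSE)
  with_seed(seed, {
    chrom_of <- rep(paste0("chr", seq_len(n_chrom)), length.out = n_genes)
    ids <- sprintf("g%04d", seq_len(n_genes))
    out <- vector("list", n_chrom)
    for (c_i in seq_len(n_chrom)) {
      idx <- which(chrom_of == paste0("chr", c_i))
      if (!length(idx)) next
      gaps <- sample(2000:20000, length(idx), replace = TRUE)
      lens <- sample(200:5000, length(idx), replace = TRUE)
      start <- cumsum(gaps) + cumsum(c(0L, utils::head(lens, -1L)))
      end <- start + lens - 1L
      strand <- sample(c("+", "-"), length(idx), replace = TRUE)
      out[[c_i]] <- data.frame(
        gene_id = ids[idx], chrom = paste0("chr", c_i),
        start = as.integer(start), end = as.integer(end),
        strand = strand,
        tss = as.integer(ifelse(strand == "+", start, end)),
        stringsAsFactors = FALSE
      )
    }
    ann <- do.call(rbind, out)
    ann <- ann[order(match(ann$gene_id, ids)), , drop = FALSE]
    rownames(ann) <- NULL
    ann
  })
}

#' Synthetic cohort configuration
#'
#' Defaults emulate, at roughly one third scale, a paired tumor/normal
#' multi-omics cancer cohort with 51 expression pairs, 237 copy-number
#' pairs, 40 methylation pairs and 548 mutation patients: here 17 / 79 / 13
#' pairs and 183 patients over 300 genes on 4 chromosomes.
#'
#' @param n_genes,n_chrom annotation size.
#' @param n_pairs_expr,n_pairs_cnv,n_pairs_meth tumor/normal pair counts per
#'   layer (>= 2).
#' @param n_mut_patients mutation cohort size (>= 2).
#' @param frac_de fraction of genes planted as differentially expressed
#'   (half up, half down).
#' @param frac_cnv,frac_meth,frac_mut fractions of the planted DE genes that
#'   additionally carry, respectively, a direction-consistent copy-number
#'   lesion, a direction-consistent promoter-methylation lesion, or frequent
#'   somatic mutation.
#' @param expr_delta additive tumor-normal expression shift for planted DE
#'   genes (normalized-expression units); `expr_noise` its Gaussian SD.
#' @param cnv_delta log2-ratio shift of tumor segments over planted
#'   copy-number genes; `cnv_noise` per-segment SD.
#' @param meth_delta beta-value shift of planted promoter probes in tumors
#'   (hypomethylation for up-genes, hypermethylation for down-genes);
#'   `meth_noise` per-probe SD.
#' @param mut_rate_range range of planted per-gene mutation rates (both
#'   above the usual 5% screening threshold); `mut_background` rate of
#'   sporadic background mutation.
#' @param seg_break_prob probability of a segment breakpoint between
#'   adjacent genes (planted genes are always isolated in their own
#'   segment).
#' @param n_hubs number of planted network hub genes.
#' @param m_edges_per_node preferential-attachment edges per added node.
#' @param hazard_beta planted log hazard ratio of the binary clinical
#'   covariate; `censor_rate` expected censoring fraction.
#' @param n_patients clinical cohort size.
#' @param seed master seed; all per-layer randomness is derived from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 300L, n_chrom = 4L,
                          n_pairs_expr = 17L, n_pairs_cnv = 79L,
                          n_pairs_meth = 13L, n_mut_patients = 183L,
                          frac_de = 0.1, frac_cnv = 0.28, frac_meth = 0.2,
                          frac_mut = 0.045,
                          expr_delta = 10, expr_noise = 3,
                          cnv_delta = 0.5, cnv_noise = 0.05,
                          meth_delta = 0.25, meth_noise = 0.05,
                          mut_rate_range = c(0.08, 0.2), mut_background = 0.01,
                          seg_break_prob = 0.3,
                          n_hubs = 5L, m_edges_per_node = 2L,
                          hazard_beta = 0.7, censor_rate = 0.3,
                          n_patients = 200L,
                          seed = 42L) {
  for (nm in c("n_pairs_expr", "n_pairs_cnv", "n_pairs_meth",
               "n_mut_patients", "n_patients")) {
    v <- get(nm)
    if (v < 2L) stop(sprintf("`%s` must be >= 2", nm), call. = FALSE)
  }
  for (nm in c("frac_de", "frac_cnv", "frac_meth", "frac_mut")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(sprintf("`%s` must lie in [0,1]", nm), call. = FALSE)
  }
  for (nm in c("expr_delta", "expr_noise", "cnv_delta", "cnv_noise",
               "meth_delta", "meth_noise", "hazard_beta")) {
    if (!is.finite(get(nm))) stop(sprintf("`%s` must be finite", nm), call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("`censor_rate` must lie in [0,1)", call. = FALSE)
  }
  fields <- setdiff(names(formals(cohort_config)), "...")
  cfg <- mget(fields, envir = environment())
  cfg[c("n_genes", "n_chrom", "n_pairs_expr", "n_pairs_cnv", "n_pairs_meth",
        "n_mut_patients", "n_hubs", "m_edges_per_node", "n_patients", "seed")] <-
    lapply(cfg[c("n_genes", "n_chrom", "n_pairs_expr", "n_pairs_cnv",
                 "n_pairs_meth", "n_mut_patients", "n_hubs", "m_edges_per_node",
                 "n_patients", "seed")], as.integer)
  structure(cfg, class = "cohort_config")
}

# planted ground truth: which genes carry which lesions
.plant_truth <- function(annotation, cfg) {
  with_seed(child_seed(cfg$seed, 1L), {
    genes <- annotation$gene_id
    n_de <- round(cfg$frac_de * length(genes))
    de <- if (n_de > 0) sample(genes, n_de) else character()
    up <- de[seq_len(floor(n_de / 2))]
    down <- setdiff(de, up)
    # hubs are planted as high-score sources: lesions in both the CNV and
    # methylation layers, so the score multiset keeps high scores rare and
    # concentrated at the hubs (most sources carry a single lesion)
    hubs <- if (length(de) && cfg$n_hubs > 0) {
      sample(de, min(cfg$n_hubs, length(de)))
    } else {
      character()
    }
    pick <- function(frac, force = character()) {
      k <- max(0L, round(frac * length(de)) - length(force))
      pool <- setdiff(de, force)
      sort(union(force,
                 if (k > 0 && length(pool)) sample(pool, min(k, length(pool)))
                 else character()))
    }
    cnv <- pick(cfg$frac_cnv, force = hubs)
    meth <- pick(cfg$frac_meth, force = hubs)
    mut <- pick(cfg$frac_mut)
    list(de_genes_up = sort(up), de_genes_down = sort(down),
         cnv_consistent = sort(cnv), meth_consistent = sort(meth),
         mut_frequent = sort(mut), hub_genes = sort(hubs),
         hazard_beta = cfg$hazard_beta)
  })
}

.gene_direction <- function(genes, truth) {
  ifelse(genes %in% truth$de_genes_up, 1L,
         ifelse(genes %in% truth$de_genes_down, -1L, 0L))
}

.make_pairing <- function(prefix, n) {
  data.frame(tumor = sprintf("%s%02d_T", prefix, seq_len(n)),
             normal = sprintf("%s%02d_N", prefix, seq_len(n)),
             stringsAsFactors = FALSE)
}

# expression: log-normal per-gene baselines; tumors shifted by +/- delta
.gen_expression <- function(annotation, truth, cfg) {
  with_seed(child_seed(cfg$seed, 2L), {
    genes <- annotation$gene_id
    n <- cfg$n_pairs_expr
    pairing <- .make_pairing("E", n)
    base <- exp(stats::rnorm(length(genes), log(100), 0.5))
    normal <- base * exp(matrix(stats::rnorm(length(genes) * n, 0, 0.1),
                                length(genes), n))
    dir <- .gene_direction(genes, truth)
    shift <- dir * cfg$expr_delta +
      matrix(stats::rnorm(length(genes) * n, 0, cfg$expr_noise), length(genes), n)
    tumor <- normal + shift
    vals <- cbind(tumor, normal)
    dimnames(vals) <- list(genes, c(pairing$tumor, pairing$normal))
    list(matrix = paired_omics(vals, pairing, "expression"),
         counts = round(pmax(vals, 0)))
  })
}

# copy number: per-sample segment tables; planted genes isolated in their
# own tumor segment carrying the +/- delta
.gen_cnv_segments <- function(annotation, truth, cfg) {
  with_seed(child_seed(cfg$seed, 3L), {
    pairing <- .make_pairing("C", cfg$n_pairs_cnv)
    planted <- cfg$cnv_delta * .gene_direction(annotation$gene_id, truth) *
      as.integer(annotation$gene_id %in% truth$cnv_consistent)
    names(planted) <- annotation$gene_id
    rows <- list()
    for (chrom in unique(annotation$chrom)) {
      ann_c <- annotation[annotation$chrom == chrom, , drop = FALSE]
      ann_c <- ann_c[order(ann_c$start), , drop = FALSE]
      chrom_len <- max(ann_c$end) + 10000L
      k <- nrow(ann_c)
      mids <- if (k > 1) {
        floor((ann_c$end[-k] + ann_c$start[-1]) / 2)
      } else {
        integer()
      }
      # break always next to planted genes so their lesion is segment-pure
      is_planted <- planted[ann_c$gene_id] != 0
      forced <- logical(length(mids))
      if (k > 1) forced <- is_planted[-k] | is_planted[-1]
      for (s in seq_len(nrow(pairing))) {
        use <- forced | stats::runif(length(mids)) < cfg$seg_break_prob
        bounds <- c(1L, mids[use] + 1L, chrom_len + 1L)
        starts <- utils::head(bounds, -1L)
        ends <- utils::tail(bounds, -1L) - 1L
        seg_gene_effect <- vapply(seq_along(starts), function(i) {
          inside <- ann_c$start >= starts[i] & ann_c$end <= ends[i]
          eff <- planted[ann_c$gene_id[inside]]
          if (any(eff != 0)) eff[eff != 0][1] else 0
        }, numeric(1))
        base_t <- stats::rnorm(length(starts), 0, cfg$cnv_noise)
        base_n <- stats::rnorm(length(starts), 0, cfg$cnv_noise)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = pairing$tumor[s], chrom = chrom, start = starts, end = ends,
          seg_mean = base_t + seg_gene_effect, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = pairing$normal[s], chrom = chrom, start = starts, end = ends,
          seg_mean = base_n, stringsAsFactors = FALSE)
      }
    }
    list(segments = do.call(rbind, rows), pairing = pairing)
  })
}

# methylation: 0-6 probes per promoter (>= 1 for planted genes), background
# probes outside promoters; tumors shifted towards hypo (up-genes) or hyper
# (down-genes) at planted promoters
.gen_methylation <- function(annotation, truth, cfg) {
  with_seed(child_seed(cfg$seed, 4L), {
    pairing <- .make_pairing("M", cfg$n_pairs_meth)
    prom <- promoter_region(annotation)
    genes <- annotation$gene_id
    dir <- .gene_direction(genes, truth)
    is_meth <- genes %in% truth$meth_consistent
    n_probe <- sample(0:6, length(genes), replace = TRUE)
    n_probe[is_meth & n_probe == 0L] <- 1L
    probe_rows <- list()
    for (i in seq_along(genes)) {
      if (n_probe[i] == 0L) next
      pos <- sort(sample(prom$lo[i]:prom$hi[i], n_probe[i]))
      # planted effect: up-gene promoters lose methylation, down-gene gain
      eff <- if (is_meth[i]) -dir[i] * cfg$meth_delta else 0
      base <- if (is_meth[i]) stats::runif(n_probe[i], 0.3, 0.6) else
        stats::runif(n_probe[i], 0.2, 0.8)
      probe_rows[[length(probe_rows) + 1L]] <- data.frame(
        chrom = prom$chrom[i], position = pos, base = base, effect = eff,
        stringsAsFactors = FALSE)
    }
    # background probes in inter-genic space (never inside a promoter)
    for (chrom in unique(annotation$chrom)) {
      chrom_len <- max(annotation$end[annotation$chrom == chrom]) + 10000L
      pos <- sample.int(chrom_len, ceiling(cfg$n_genes / 8))
      pr <- prom[prom$chrom == chrom, , drop = FALSE]
      in_prom <- vapply(pos, function(p) any(p >= pr$lo & p <= pr$hi), logical(1))
      pos <- pos[!in_prom]
      if (length(pos)) {
        probe_rows[[length(probe_rows) + 1L]] <- data.frame(
          chrom = chrom, position = pos,
          base = stats::runif(length(pos), 0.2, 0.8), effect = 0,
          stringsAsFactors = FALSE)
      }
    }
    pr <- do.call(rbind, probe_rows)
    np <- nrow(pr)
    clamp <- function(x) pmin(1, pmax(0, x))
    tum <- vapply(seq_len(cfg$n_pairs_meth), function(s) {
      clamp(pr$base + pr$effect + stats::rnorm(np, 0, cfg$meth_noise))
    }, numeric(np))
    nor <- vapply(seq_len(cfg$n_pairs_meth), function(s) {
      clamp(pr$base + stats::rnorm(np, 0, cfg$meth_noise))
    }, numeric(np))
    beta <- cbind(tum, nor)
    colnames(beta) <- c(pairing$tumor, pairing$normal)
    probes <- cbind(
      data.frame(probe_id = sprintf("cg%05d", seq_len(np)),
                 chrom = pr$chrom, position = pr$position,
                 stringsAsFactors = FALSE),
      as.data.frame(beta))
    list(probes = probes, pairing = pairing)
  })
}

.gen_mutations <- function(annotation, truth, cfg) {
  with_seed(child_seed(cfg$seed, 5L), {
    patients <- sprintf("P%04d", seq_len(cfg$n_mut_patients))
    rows <- list()
    for (g in truth$mut_frequent) {
      rate <- stats::runif(1, cfg$mut_rate_range[1], cfg$mut_rate_range[2])
      k <- max(1L, ceiling(rate * cfg$n_mut_patients))
      rows[[length(rows) + 1L]] <- data.frame(
        patient = sample(patients, k), gene = g, stringsAsFactors = FALSE)
    }
    for (g in setdiff(annotation$gene_id, truth$mut_frequent)) {
      k <- stats::rbinom(1, cfg$n_mut_patients, cfg$mut_background)
      if (k > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient = sample(patients, k), gene = g, stringsAsFactors = FALSE)
      }
    }
    mut <- if (length(rows)) do.call(rbind, rows) else
      data.frame(patient = character(), gene = character(), stringsAsFactors = FALSE)
    rownames(mut) <- NULL
    list(mutations = mut, patients = patients)
  })
}

#' Generate a scale-free interaction network with planted hubs
#'
#' Preferential-attachment growth seeded on the planted hub genes; every
#' planted source gene (any consistent upstream lesion in `truth`) is then
#' preferentially wired to a hub, so information flow from sources
#' accumulates at hubs. No self-loops or duplicate undirected edges.
#'
#' @param annotation gene annotation (nodes are drawn from its `gene_id`s).
#' @param truth planted-truth list (from [generate_cohort()]); NULL for a
#'   plain unplanted network over all genes.
#' @param m_edges_per_node edges added per new node (>= 1).
#' @param seed integer seed.
#' @param hub_attach_prob probability a source gene gains an extra hub edge.
#' @return data.frame of canonical undirected edges (`from`, `to`).
#' @export
generate_network <- function(annotation, truth = NULL, m_edges_per_node = 2L,
                             seed = 1L, hub_attach_prob = 0.8) {
  if (!nrow(annotation)) stop("empty annotation", call. = FALSE)
  assert_positive_int(m_edges_per_node, "m_edges_per_node")
  with_seed(seed, {
    if (is.null(truth)) {
      nodes <- annotation$gene_id
      hubs <- character()
      sources <- character()
    } else {
      de <- c(truth$de_genes_up, truth$de_genes_down)
      others <- setdiff(annotation$gene_id, de)
      extra <- if (length(others)) sample(others, round(0.3 * length(others))) else character()
      nodes <- unique(c(de, extra))
      hubs <- intersect(truth$hub_genes, nodes)
      sources <- intersect(
        unique(c(truth$cnv_consistent, truth$meth_consistent, truth$mut_frequent)),
        nodes)
    }
    if (length(nodes) < 2L) stop("need at least 2 network nodes", call. = FALSE)
    seed_nodes <- if (length(hubs) >= 2L) hubs else
      utils::head(c(hubs, sample(setdiff(nodes, hubs))), max(2L, length(hubs)))
    grown <- seed_nodes
    deg <- stats::setNames(rep(1L, length(seed_nodes)), seed_nodes)
    from <- character(); to <- character()
    # connect the seed set as a path
    if (length(seed_nodes) > 1L) {
      from <- utils::head(seed_nodes, -1L)
      to <- utils::tail(seed_nodes, -1L)
      deg[] <- 2L
      deg[c(1L, length(deg))] <- 1L
    }
    rest <- sample(setdiff(nodes, seed_nodes))
    for (v in rest) {
      m <- min(m_edges_per_node, length(grown))
      targets <- sample(grown, m, prob = deg[grown] + 1)
      from <- c(from, rep(v, m)); to <- c(to, targets)
      deg[v] <- m
      deg[targets] <- deg[targets] + 1L
      grown <- c(grown, v)
    }
    # wire sources towards hubs so planted signal converges there
    for (v in setdiff(sources, hubs)) {
      if (length(hubs) && stats::runif(1) < hub_attach_prob) {
        h <- sample(hubs, 1L)
        from <- c(from, v); to <- c(to, h)
      }
    }
    merge_networks(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic clinical table
#'
#' Exponential event times whose hazard is multiplied by
#' `exp(hazard_beta * marker_high)` for a balanced binary covariate, with
#' independent exponential censoring calibrated so the expected censoring
#' fraction in the reference arm equals `censor_rate`. Decorative
#' categorical covariates mirror the usual baseline-characteristics fields.
#'
#' @param n_patients cohort size.
#' @param hazard_beta planted log hazard ratio of `marker_high`.
#' @param censor_rate expected censoring fraction in \[0,1).
#' @param seed integer seed.
#' @return data.frame `patient_id`, `os_time` / `os_event`, `dfs_time` /
#'   `dfs_event` (months), `marker_high` (0/1, the planted covariate) and
#'   categorical covariates (`age_group`, `pT`, `pN`, `stage`, `grade`,
#'   `adjctx`, `adjrad`, `er_status`).
#' @export
generate_clinical <- function(n_patients, hazard_beta = 0.7, censor_rate = 0.3,
                              seed = 1L) {
  assert_positive_int(n_patients, "n_patients")
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("`censor_rate` must lie in [0,1)", call. = FALSE)
  }
  with_seed(seed, {
    n <- n_patients
    x <- stats::rbinom(n, 1L, 0.5)
    lambda0 <- 1 / 40  # median OS ~ 28 months in the reference arm
    surv_pair <- function(scale_beta) {
      t_ev <- stats::rexp(n, rate = lambda0 * exp(scale_beta * x))
      if (censor_rate == 0) {
        list(time = t_ev, event = rep(1L, n))
      } else {
        lam_c <- lambda0 * censor_rate / (1 - censor_rate)
        t_c <- stats::rexp(n, rate = lam_c)
        list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
      }
    }
    os <- surv_pair(hazard_beta)
    dfs <- surv_pair(hazard_beta)
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      os_time = os$time, os_event = os$event,
      dfs_time = dfs$time, dfs_event = dfs$event,
      marker_high = x,
      age_group = sample(c("ge65", "lt65"), n, replace = TRUE, prob = c(0.3, 0.7)),
      pT = sample(paste0("T", 1:4), n, replace = TRUE, prob = c(0.35, 0.37, 0.17, 0.11)),
      pN = sample(c("N0", "N+"), n, replace = TRUE, prob = c(0.55, 0.45)),
      stage = sample(c("I", "II", "III"), n, replace = TRUE, prob = c(0.34, 0.35, 0.31)),
      grade = sample(c("G1_2", "G3"), n, replace = TRUE, prob = c(0.64, 0.36)),
      adjctx = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.66, 0.34)),
      adjrad = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.3, 0.7)),
      er_status = sample(c("positive", "negative"), n, replace = TRUE,
                         prob = c(0.23, 0.77)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a full synthetic multi-omics cohort
#'
#' Produces every input the pipeline consumes — annotation, paired
#' expression (normalized values and rounded raw counts), copy-number
#' segment tables, methylation probe table, per-patient mutation list,
#' interaction network and clinical table — together with the planted ground
#' truth used by recovery tests. Planted lesions follow the usual
#' directionality: up-regulated genes pair with amplification and promoter
#' hypomethylation, down-regulated genes with deletion and hypermethylation.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `annotation`,
#'   `expression` (paired_omics), `expression_counts`, `cnv_segments`,
#'   `cnv_pairing`, `methylation_probes`, `meth_pairing`, `mutations`,
#'   `mut_patients`, `network_edges`, `clinical`, `truth`, `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  annotation <- generate_annotation(config$n_genes, config$n_chrom,
                                    child_seed(config$seed, 0L))
  truth <- .plant_truth(annotation, config)
  expr <- .gen_expression(annotation, truth, config)
  cnv <- .gen_cnv_segments(annotation, truth, config)
  meth <- .gen_methylation(annotation, truth, config)
  mut <- .gen_mutations(annotation, truth, config)
  net <- generate_network(annotation, truth, config$m_edges_per_node,
                          child_seed(config$seed, 6L))
  clinical <- generate_clinical(config$n_patients, config$hazard_beta,
                                config$censor_rate, child_seed(config$seed, 7L))
  structure(list(
    annotation = annotation,
    expression = expr$matrix,
    expression_counts = expr$counts,
    cnv_segments = cnv$segments,
    cnv_pairing = cnv$pairing,
    methylation_probes = meth$probes,
    meth_pairing = meth$pairing,
    mutations = mut$mutations,
    mut_patients = mut$patients,
    network_edges = net,
    clinical = clinical,
    truth = truth,
    config = config,
    seed = config$seed
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_cohort (seed %d): %d genes, %d expr pairs, %d CNV pairs, ",
    "%d meth pairs, %d mutation patients, %d network edges\n"),
    x$seed, nrow(x$annotation), nrow(x$expression$pairing),
    nrow(x$cnv_pairing), nrow(x$meth_pairing), length(x$mut_patients),
    nrow(x$network_edges)))
  invisible(x)
}
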
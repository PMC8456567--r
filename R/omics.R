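#' Construct a paired tumor/normal omics matrix
#'
#' Container for one omics layer of a paired cohort design: a genes x samples
#' value matrix plus an explicit tumor/normal pairing map. Paired differential
#' tests ([paired_t_test()]) operate on the per-pair differences
#' tumor - normal.
#'
#' @param values numeric matrix, rows = genes (rownames required), columns =
#'   samples (colnames required).
#' @param pairing data.frame with columns `tumor` and `normal`, one row per
#'   patient pair; every sample named must be a column of `values` and no
#'   sample may appear in two pairs.
#' @param layer one of `"expression"`, `"cnv"`, `"methylation"`.
#' @return an object of class `paired_omics` (list with elements `values`,
#'   `pairing`, `layer`).
#' @examples
#' m <- matrix(rnorm(8), 2, 4,
#'   dimnames = list(c("g1", "g2"), c("t1", "t2", "n1", "n2")))
#' po <- paired_omics(m, data.frame(tumor = c("t1", "t2"),
#'                                  normal = c("n1", "n2")), "expression")
#' @export
paired_omics <- function(values, pairing, layer = c("expression", "cnv", "methylation")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids in `values`", call. = FALSE)
  pairing <- as.data.frame(pairing, stringsAsFactors = FALSE)
  if (!all(c("tumor", "normal") %in% names(pairing))) {
    stop("`pairing` needs columns `tumor` and `normal`", call. = FALSE)
  }
  samp <- c(pairing$tumor, pairing$normal)
  missing <- setdiff(samp, colnames(values))
  if (length(missing)) {
    stop("pairing references samples absent from `values`: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samp)) stop("a sample appears in more than one pair", call. = FALSE)
  if (layer == "methylation") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      stop("methylation beta values must lie in [0,1]", call. = FALSE)
    }
  }
  structure(list(values = values, pairing = pairing, layer = layer),
            class = "paired_omics")
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf("paired_omics [%s]: %d genes x %d samples (%d pairs)\n",
              x$layer, nrow(x$values), ncol(x$values), nrow(x$pairing)))
  invisible(x)
}

#' Paired t tests, one gene per row
#'
#' Per-gene two-sided paired t test of tumor vs normal: with paired
#' differences d = tumor - normal, t = mean(d) / (sd(d)/sqrt(n)) on n - 1
#' degrees of freedom. Genes whose differences have zero standard deviation
#' (or any missing value across the pairs) carry `tested = FALSE` and NA
#' statistics; they are never counted significant downstream.
#'
#' @param x a [paired_omics()] object with at least 2 pairs.
#' @return data.frame with columns `gene_id`, `mean_diff`, `t`, `df`, `p`,
#'   `direction` ("up" when mean tumor - normal difference is positive,
#'   "down" otherwise), `tested`. FDR is attached separately by [add_fdr()].
#' @export
paired_t_test <- function(x) {
  stopifnot(inherits(x, "paired_omics"))
  n <- nrow(x$pairing)
  if (n < 2L) stop("paired t test needs at least 2 pairs", call. = FALSE)
  d <- x$values[, x$pairing$tumor, drop = FALSE] -
    x$values[, x$pairing$normal, drop = FALSE]
  m <- rowMeans(d)
  s <- apply(d, 1L, stats::sd)
  complete <- rowSums(is.na(d)) == 0L
  tested <- complete & !is.na(s) & s > 0
  tval <- ifelse(tested, m / (s / sqrt(n)), NA_real_)
  p <- ifelse(tested, 2 * stats::pt(-abs(tval), df = n - 1L), NA_real_)
  data.frame(
    gene_id = rownames(x$values),
    mean_diff = m,
    t = tval,
    df = n - 1L,
    p = p,
    direction = ifelse(is.na(m) | m == 0, "none", ifelse(m > 0, "up", "down")),
    tested = tested,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; order of the input is preserved,
#' and the adjusted values are monotone non-decreasing in the p-value ranks.
#'
#' @param pvalues numeric vector of p-values in \[0,1\] (NA allowed and
#'   propagated).
#' @return numeric vector of BH-adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("`pvalues` must be numeric", call. = FALSE)
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Attach FDR and significance calls to a differential table
#'
#' @param diff output of [paired_t_test()].
#' @param level FDR threshold; a gene is significant when `tested` and
#'   `fdr < level` (strict).
#' @return `diff` with columns `fdr` and `significant` added.
#' @export
add_fdr <- function(diff, level = 0.01) {
  assert_prob(level, "level", open_left = TRUE)
  diff$fdr <- bh_fdr(diff$p)
  diff$significant <- !is.na(diff$fdr) & diff$tested & diff$fdr < level
  diff
}

#' Strand-aware promoter windows
#'
#' The promoter of a gene is the window from `upstream` bp upstream of the
#' transcription start site to `downstream` bp downstream of it, flipped for
#' minus-strand genes and clamped at position 1.
#'
#' @param annotation data.frame with columns `gene_id`, `chrom`, `strand`
#'   ("+" or "-"), `tss` (1-based).
#' @param upstream,downstream window extent in bp (defaults 1000 and 300).
#' @return data.frame `gene_id`, `chrom`, `lo`, `hi` (1-based closed).
#' @export
promoter_region <- function(annotation, upstream = 1000L, downstream = 300L) {
  if (!all(c("gene_id", "chrom", "strand", "tss") %in% names(annotation))) {
    stop("annotation needs columns gene_id, chrom, strand, tss", call. = FALSE)
  }
  if (!all(annotation$strand %in% c("+", "-"))) {
    stop("unknown strand value; expected '+' or '-'", call. = FALSE)
  }
  plus <- annotation$strand == "+"
  lo <- ifelse(plus, annotation$tss - upstream, annotation$tss - downstream)
  hi <- ifelse(plus, annotation$tss + downstream, annotation$tss + upstream)
  data.frame(
    gene_id = annotation$gene_id,
    chrom = annotation$chrom,
    lo = pmax(1L, as.integer(lo)),
    hi = as.integer(hi),
    stringsAsFactors = FALSE
  )
}

# shared overlap machinery: weighted mean of interval values over gene windows
.overlap_weighted_mean <- function(win, ival, values_by_sample) {
  # win: gene_id, chrom, lo, hi; ival: chrom, start, end + values_by_sample
  gr_g <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$lo, win$hi))
  gr_s <- GenomicRanges::GRanges(ival$chrom, IRanges::IRanges(ival$start, ival$end))
  hits <- GenomicRanges::findOverlaps(gr_g, gr_s)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_g)[qh], IRanges::ranges(gr_s)[sh]))
  list(gene = qh, seg = sh, w = as.numeric(w))
}

#' Map copy-number segments onto genes
#'
#' Converts a segmentation table (log2-ratio segment means) into a gene-level
#' matrix: each gene's value in a sample is the overlap-length-weighted mean
#' of the segment means of all segments overlapping the gene body, with
#' 1-based closed coordinates on both sides. Genes with no covered base in a
#' sample are NA. Segments on chromosomes absent from the annotation are
#' dropped with a warning.
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `seg_mean`.
#' @param annotation gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param pairing optional tumor/normal pairing data.frame; when supplied the
#'   result is a [paired_omics()] object of layer `"cnv"`, otherwise a bare
#'   matrix.
#' @return genes x samples matrix, or `paired_omics` when `pairing` is given.
#' @export
segments_to_gene_matrix <- function(segments, annotation, pairing = NULL) {
  need <- c("sample", "chrom", "start", "end", "seg_mean")
  if (!all(need %in% names(segments))) {
    stop("segments need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(segments$start > segments$end)) {
    stop("segment with start > end", call. = FALSE)
  }
  unknown <- !(segments$chrom %in% unique(annotation$chrom))
  if (any(unknown)) {
    warning(sum(unknown), " segment(s) on chromosomes absent from the annotation were ignored")
    segments <- segments[!unknown, , drop = FALSE]
  }
  samples <- unique(segments$sample)
  genes <- annotation$gene_id
  win <- data.frame(gene_id = genes, chrom = annotation$chrom,
                    lo = annotation$start, hi = annotation$end)
  ov <- .overlap_weighted_mean(win, segments, NULL)
  si <- match(segments$sample[ov$seg], samples)
  num <- Matrix::sparseMatrix(i = ov$gene, j = si,
                              x = ov$w * segments$seg_mean[ov$seg],
                              dims = c(length(genes), length(samples)))
  den <- Matrix::sparseMatrix(i = ov$gene, j = si, x = ov$w,
                              dims = c(length(genes), length(samples)))
  vals <- as.matrix(num) / as.matrix(den)
  vals[as.matrix(den) == 0] <- NA_real_
  dimnames(vals) <- list(genes, samples)
  if (is.null(pairing)) return(vals)
  paired_omics(vals, pairing, "cnv")
}

#' Promoter-mean methylation per gene
#'
#' For each gene, averages the beta values of all probes whose position lies
#' inside the gene's promoter window (closed interval, boundary probes
#' included; probe strand ignored). Genes whose promoter contains no probe
#' are absent from the output.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `position`,
#'   plus one numeric beta column per sample.
#' @param annotation gene annotation with `gene_id`, `chrom`, `strand`, `tss`.
#' @param upstream,downstream promoter extent passed to [promoter_region()].
#' @param pairing optional pairing; when given, returns [paired_omics()] of
#'   layer `"methylation"`.
#' @return genes x samples beta matrix (genes with >= 1 promoter probe only),
#'   or `paired_omics` when `pairing` is given.
#' @export
aggregate_promoter_methylation <- function(probes, annotation,
                                           upstream = 1000L, downstream = 300L,
                                           pairing = NULL) {
  need <- c("probe_id", "chrom", "position")
  if (!all(need %in% names(probes))) {
    stop("probe table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  samp_cols <- setdiff(names(probes), need)
  if (!length(samp_cols)) stop("probe table has no sample columns", call. = FALSE)
  beta <- as.matrix(probes[, samp_cols, drop = FALSE])
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0,1]", call. = FALSE)
  }
  prom <- promoter_region(annotation, upstream, downstream)
  ov <- .overlap_weighted_mean(
    prom,
    data.frame(chrom = probes$chrom, start = probes$position, end = probes$position),
    NULL)
  if (!length(ov$gene)) {
    stop("no probe falls inside any promoter window", call. = FALSE)
  }
  grp <- factor(ov$gene, levels = sort(unique(ov$gene)))
  agg <- apply(beta[ov$seg, , drop = FALSE], 2L,
               function(col) tapply(col, grp, mean))
  agg <- matrix(agg, nrow = nlevels(grp),
                dimnames = list(prom$gene_id[as.integer(levels(grp))], samp_cols))
  if (is.null(pairing)) return(agg)
  paired_omics(agg, pairing, "methylation")
}

#' Per-gene somatic mutation frequency
#'
#' Fraction of cohort patients carrying at least one somatic mutation in each
#' gene; repeated mutations of one gene in one patient count once.
#'
#' @param mutations data.frame with columns `patient`, `gene`.
#' @param patients character vector of all cohort patient ids (the
#'   denominator); every mutation's patient must belong to it.
#' @return named numeric vector of rates in \[0,1\], one entry per mutated
#'   gene.
#' @export
mutation_frequency <- function(mutations, patients) {
  if (!all(c("patient", "gene") %in% names(mutations))) {
    stop("mutations need columns `patient` and `gene`", call. = FALSE)
  }
  if (!length(patients)) stop("empty patient cohort", call. = FALSE)
  bad <- setdiff(unique(mutations$patient), patients)
  if (length(bad)) {
    stop("mutation patient id(s) absent from cohort: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  uniq <- unique(mutations[, c("patient", "gene")])
  tab <- table(uniq$gene)
  rates <- as.numeric(tab) / length(patients)
  names(rates) <- names(tab)
  rates
}

#' Segment Gain Or Loss (SGOL) scores
#'
#' Summarizes recurrent copy-number gain and loss per gene across samples:
#' the gain score is the sum over samples of gene-level values exceeding
#' `gain_thresh`, the loss score the sum of values below `loss_thresh`.
#' Sex chromosomes (chrX/chrY) are excluded so mixed-sex cohorts do not
#' inject artefactual dosage differences.
#'
#' @param segments segmentation table (see [segments_to_gene_matrix()]).
#' @param annotation gene annotation.
#' @param gain_thresh,loss_thresh log2-ratio thresholds (defaults +0.2/-0.2);
#'   `gain_thresh` must exceed `loss_thresh`.
#' @return data.frame `gene_id`, `chrom`, `gain_score` (>= 0), `loss_score`
#'   (<= 0).
#' @export
sgol_scores <- function(segments, annotation, gain_thresh = 0.2, loss_thresh = -0.2) {
  if (gain_thresh <= loss_thresh) {
    stop("`gain_thresh` must exceed `loss_thresh`", call. = FALSE)
  }
  autosomal <- !(annotation$chrom %in% c("chrX", "chrY", "X", "Y"))
  annotation <- annotation[autosomal, , drop = FALSE]
  vals <- segments_to_gene_matrix(segments, annotation)
  gain <- rowSums(vals * (vals > gain_thresh), na.rm = TRUE)
  loss <- rowSums(vals * (vals < loss_thresh), na.rm = TRUE)
  data.frame(
    gene_id = annotation$gene_id,
    chrom = annotation$chrom,
    gain_score = gain,
    loss_score = loss,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
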
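# Plain-text readers/writers for the pipeline's TSV dialects. Everything is
# tab-separated, unquoted, with a header row.

.write_tsv <- function(x, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    x <- cbind(stats::setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                               rownames_col),
               as.data.frame(x, stringsAsFactors = FALSE))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a genes x samples matrix from TSV
#'
#' First column = gene id, remaining columns = samples.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames.
#' @export
read_omics_matrix <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Read a SEG-dialect segmentation table
#'
#' Accepts either lower-case pipeline headers (`sample`, `chrom`, `start`,
#' `end`, `seg_mean`) or the conventional SEG headers (`Sample`,
#' `Chromosome`, `Start`, `End`, `Segment_Mean`); coordinates are taken as
#' 1-based inclusive.
#'
#' @param path TSV file path.
#' @return data.frame with pipeline column names.
#' @export
read_segments <- function(path) {
  df <- .read_tsv(path)
  map <- c(Sample = "sample", Chromosome = "chrom", Start = "start",
           End = "end", Segment_Mean = "seg_mean")
  hit <- names(df) %in% names(map)
  names(df)[hit] <- map[names(df)[hit]]
  need <- c("sample", "chrom", "start", "end", "seg_mean")
  if (!all(need %in% names(df))) {
    stop("segmentation file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df[, need]
}

#' Read a BED-like gene annotation with strand and TSS
#'
#' @param path TSV with columns gene_id, chrom, start, end, strand, tss.
#' @return annotation data.frame.
#' @export
read_annotation <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss")
  if (!all(need %in% names(df))) {
    stop("annotation lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df[, need]
}

#' Read a two-column edge list
#'
#' @param path TSV whose first two columns are node ids (header optional
#'   names `from`/`to` are conventional).
#' @return data.frame `from`, `to`.
#' @export
read_edges <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop("edge list needs two columns", call. = FALSE)
  stats::setNames(df[, 1:2], c("from", "to"))
}

#' Write all inputs of a synthetic cohort as plain TSV/JSON files
#'
#' Emits the dialects the pipeline reads back: expression and count
#' matrices, SEG-style segments, probe table, annotation, mutation pairs,
#' edge list, clinical table, pairing maps, and the planted truth as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  seg <- cohort$cnv_segments
  seg_out <- data.frame(Sample = seg$sample, Chromosome = seg$chrom,
                        Start = seg$start, End = seg$end,
                        Segment_Mean = seg$seg_mean)
  paths <- c(
    expression = .write_tsv(cohort$expression$values, p("expression.tsv"), "gene_id"),
    expression_counts = .write_tsv(cohort$expression_counts, p("expression_counts.tsv"), "gene_id"),
    expr_pairing = .write_tsv(cohort$expression$pairing, p("expr_pairing.tsv")),
    cnv_segments = .write_tsv(seg_out, p("cnv_segments.seg.tsv")),
    cnv_pairing = .write_tsv(cohort$cnv_pairing, p("cnv_pairing.tsv")),
    methylation_probes = .write_tsv(cohort$methylation_probes, p("methylation_probes.tsv")),
    meth_pairing = .write_tsv(cohort$meth_pairing, p("meth_pairing.tsv")),
    annotation = .write_tsv(cohort$annotation, p("annotation.tsv")),
    mutations = .write_tsv(cohort$mutations, p("mutations.tsv")),
    mut_patients = .write_tsv(
      data.frame(patient = cohort$mut_patients), p("mut_patients.tsv")),
    network_edges = .write_tsv(cohort$network_edges, p("network_edges.tsv")),
    clinical = .write_tsv(cohort$clinical, p("clinical.tsv"))
  )
  jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  c(paths, truth = p("truth.json"))
}

#' Validate pipeline input files
#'
#' Report-only schema and sanity checks: file existence, required columns,
#' beta values inside \[0,1\] (with the first offending row), segment
#' coordinate sanity, and tumor/normal pairing completeness against the
#' matrix columns.
#'
#' @param paths named list/vector of file paths; recognized names are
#'   `expression`, `expr_pairing`, `cnv_segments`, `methylation_probes`,
#'   `meth_pairing`, `annotation`, `mutations`, `network_edges`, `clinical`.
#' @return data.frame `file`, `ok`, `message` (one row per supplied path).
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  check_one <- function(name, path) {
    if (!file.exists(path)) return(sprintf("file not found: %s", path))
    out <- tryCatch({
      if (name == "expression") {
        m <- read_omics_matrix(path)
        if (!nrow(m)) return("no genes")
        if (anyDuplicated(rownames(m))) return("duplicated gene ids")
        "ok"
      } else if (name == "cnv_segments") {
        seg <- read_segments(path)
        bad <- which(seg$start > seg$end)
        if (length(bad)) return(sprintf("start > end at row %d", bad[1]))
        "ok"
      } else if (name == "methylation_probes") {
        df <- .read_tsv(path)
        beta <- as.matrix(df[, setdiff(names(df), c("probe_id", "chrom", "position")),
                             drop = FALSE])
        bad <- which(rowSums(beta < 0 | beta > 1, na.rm = TRUE) > 0)
        if (length(bad)) return(sprintf("beta outside [0,1] at row %d", bad[1]))
        "ok"
      } else if (name == "annotation") {
        ann <- read_annotation(path)
        bad <- which(ann$start > ann$end)
        if (length(bad)) return(sprintf("start > end at row %d", bad[1]))
        if (anyDuplicated(ann$gene_id)) return("duplicated gene ids")
        "ok"
      } else if (name == "network_edges") {
        read_edges(path); "ok"
      } else if (name %in% c("expr_pairing", "meth_pairing", "cnv_pairing")) {
        pr <- .read_tsv(path)
        if (!all(c("tumor", "normal") %in% names(pr))) return("needs tumor/normal columns")
        "ok"
      } else {
        .read_tsv(path); "ok"
      }
    }, error = function(e) conditionMessage(e))
    out
  }
  msgs <- vapply(names(paths), function(nm) check_one(nm, paths[[nm]]), character(1))
  # cross-file check: every pairing sample present in its matrix
  if (all(c("expression", "expr_pairing") %in% names(paths)) &&
      msgs[["expression"]] == "ok" && msgs[["expr_pairing"]] == "ok") {
    m <- read_omics_matrix(paths$expression)
    pr <- .read_tsv(paths$expr_pairing)
    missing <- setdiff(c(pr$tumor, pr$normal), colnames(m))
    if (length(missing)) {
      msgs[["expr_pairing"]] <- sprintf("sample without matrix column: %s", missing[1])
    }
  }
  data.frame(file = names(paths), ok = msgs == "ok", message = unname(msgs),
             stringsAsFactors = FALSE, row.names = NULL)
}
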
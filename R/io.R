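#' Read a cells x genes count matrix
#'
#' Supports the CellRanger triplet layout (Matrix Market `.mtx` storing
#' genes x cells plus single-column barcode and feature files; the 1-based
#' triplet indices follow the Matrix Market standard) and dense delimited
#' text (rows = cells, first column = cell id, header = gene ids).
#'
#' @param path `.mtx` file (or a directory containing `matrix.mtx`),
#'   or a dense delimited file
#' @param layout "mtx" or "dense"; `NULL` guesses from the file name
#' @param barcodes,features companion id files for the mtx layout;
#'   defaults are `barcodes.tsv` and `features.tsv`/`genes.tsv` next to
#'   the matrix
#' @param sep field separator for the dense layout (default tab)
#' @return cells x genes dgCMatrix with cell rownames and gene colnames
#' @export
readCounts <- function(path, layout = NULL, barcodes = NULL,
                       features = NULL, sep = "\t") {
  if (dir.exists(path)) path <- file.path(path, "matrix.mtx")
  if (is.null(layout))
    layout <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  if (layout == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("parse error: ", conditionMessage(e)))
    dirn <- dirname(path)
    if (is.null(barcodes)) barcodes <- file.path(dirn, "barcodes.tsv")
    if (is.null(features)) {
      features <- file.path(dirn, "features.tsv")
      if (!file.exists(features)) features <- file.path(dirn, "genes.tsv")
    }
    bc <- readLines(barcodes)
    ft <- utils::read.table(features, sep = "\t",
                            stringsAsFactors = FALSE)[, 1]
    if (nrow(m) != length(ft) || ncol(m) != length(bc))
      stop("inconsistent inputs: matrix dimensions do not match id files")
    m <- methods::as(Matrix::t(m), "CsparseMatrix") # cells x genes
    dimnames(m) <- list(bc, ft)
    m
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            row.names = 1, check.names = FALSE)
    methods::as(as.matrix(df), "CsparseMatrix")
  }
}

#' Write a count matrix in the CellRanger triplet layout
#'
#' @param counts cells x genes matrix
#' @param dir output directory (created if needed)
#' @param metadata optional named list recorded in `metadata.yaml`
#' @return the directory, invisibly
#' @export
writeCounts <- function(counts, dir, metadata = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
                               "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  bc <- rownames(counts)
  if (is.null(bc)) bc <- paste0("cell", seq_len(nrow(counts)))
  ft <- colnames(counts)
  if (is.null(ft)) ft <- paste0("gene", seq_len(ncol(counts)))
  writeLines(bc, file.path(dir, "barcodes.tsv"))
  writeLines(ft, file.path(dir, "features.tsv"))
  if (!is.null(metadata))
    yaml::write_yaml(metadata, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read an embedding from delimited text
#'
#' Rows are cells, the first column the cell id; a single header line is
#' detected automatically (non-numeric fields past the first column).
#'
#' @param path delimited file
#' @param sep field separator (default tab)
#' @return numeric matrix with cell-id rownames
#' @export
readEmbedding <- function(path, sep = "\t") {
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(first[-1]))))
  df <- utils::read.table(path, header = hasHeader, sep = sep,
                          row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' @describeIn readEmbedding write an embedding as delimited text
#' @param embedding numeric matrix with cell-id rownames
#' @export
writeEmbedding <- function(embedding, path, sep = "\t") {
  df <- data.frame(cell_id = rownames(embedding), embedding,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell labels
#'
#' @param path two-column delimited file: cell_id, label (header optional)
#' @param sep field separator (default tab)
#' @return named character vector
#' @export
readLabels <- function(path, sep = "\t") {
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  hasHeader <- identical(tolower(first[1]), "cell_id")
  df <- utils::read.table(path, header = hasHeader, sep = sep,
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[, 2]), df[, 1])
}

#' @describeIn readLabels write per-cell labels
#' @param labels named vector (names = cell ids)
#' @export
writeLabels <- function(labels, path, sep = "\t") {
  utils::write.table(data.frame(cell_id = names(labels),
                                label = as.vector(labels)),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a RareQResult to disk
#'
#' Emits `cells.tsv` (cell_id, cluster, q, is_rare), `clusters.tsv`
#' (cluster, n, mean_q, q_c, is_rare) and `run_metadata.yaml` (parameters,
#' package and R versions, optional input-file hashes).
#'
#' @param result a [RareQResult-class]
#' @param outdir output directory (created if needed)
#' @param inputFiles optional paths whose md5 hashes are recorded
#' @return the directory, invisibly
#' @export
writeResult <- function(result, outdir, inputFiles = NULL) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("io error: cannot create ", outdir)
  q <- qValues(result)
  lab <- clusterLabels(result)
  cells <- data.frame(cell_id = names(q), cluster = lab, q = q,
                      is_rare = lab %in% rareClusterIds(result))
  utils::write.table(cells, file.path(outdir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  st <- clusterStats(result)
  clusters <- data.frame(cluster = st$cluster, n = st$n, mean_q = st$meanQ,
                         q_c = st$qC, is_rare = st$isRare)
  utils::write.table(clusters, file.path(outdir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p <- result@params
  meta <- list(
    parameters = list(k = p@k, k_param = p@kParam,
                      q_threshold = p@qThreshold,
                      ratio_threshold = p@ratioThreshold, vote_k = p@voteK,
                      max_propagation_iters = p@maxPropagationIters,
                      max_vote_rounds = p@maxVoteRounds,
                      min_cluster_size = p@minClusterSize),
    n_cells = length(lab),
    n_clusters = nrow(st),
    rare_clusters = as.list(rareClusterIds(result)),
    versions = list(rareq = as.character(utils::packageVersion("rareq")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  if (!is.null(inputFiles))
    meta$input_hashes <- as.list(tools::md5sum(inputFiles))
  yaml::write_yaml(meta, file.path(outdir, "run_metadata.yaml"))
  invisible(outdir)
}

#' @describeIn writeResult write the per-cell Q table (cell_id, q)
#' @param q a [QScores-class]
#' @param path output file
#' @export
writeQScores <- function(q, path) {
  utils::write.table(data.frame(cell_id = names(qValues(q)),
                                q = as.vector(qValues(q))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an EvaluationReport
#'
#' @param report an [EvaluationReport-class]
#' @param outdir output directory
#' @return the directory, invisibly
#' @export
writeEvaluation <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report@perType, file.path(outdir, "per_type.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summaryLines <- c(sprintf("nmi\t%.6f", report@nmi),
                    sprintf("median_f1\t%.6f",
                            if (nrow(report@perType))
                              stats::median(report@perType$f1) else NA))
  writeLines(summaryLines, file.path(outdir, "summary.tsv"))
  invisible(outdir)
}
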
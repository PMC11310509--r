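#' Read a sparse count matrix from MatrixMarket with sidecar name files
#'
#' @param mtx_path Path to the .mtx file (genes x cells).
#' @param genes_path,cells_path One name per line, matching the matrix rows
#'   and columns respectively.
#' @return A sparse \code{dgCMatrix} with dimnames attached and count state
#'   \code{"raw"}.
#' @export
read_counts <- function(mtx_path, genes_path, cells_path) {
  for (p in c(mtx_path, genes_path, cells_path))
    if (!file.exists(p)) stop2(paste("file not found:", p), "missing_input")
  m <- as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- readLines(genes_path)
  cls <- readLines(cells_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cls))
    stop2(sprintf("dimension mismatch: matrix %d x %d vs %d genes, %d cells",
                  nrow(m), ncol(m), length(genes), length(cls)),
          "dimension_mismatch")
  if (any(m@x < 0) || any(m@x != floor(m@x)))
    stop2("raw counts must be non-negative integers", "non_integer_counts")
  dimnames(m) <- list(genes, cls)
  m <- as(m, "dMatrix")
  attr(m, "state") <- "raw"
  m
}

#' Write a count matrix as MatrixMarket plus gene/cell name sidecars
#'
#' @param m Sparse genes x cells matrix with dimnames.
#' @param mtx_path,genes_path,cells_path Output paths.
#' @return Invisibly, \code{mtx_path}.
#' @export
write_counts <- function(m, mtx_path, genes_path, cells_path) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  Matrix::writeMM(as(m, "CsparseMatrix"), mtx_path)
  writeLines(rownames(m), genes_path)
  writeLines(colnames(m), cells_path)
  invisible(mtx_path)
}

#' Normalization state of a count matrix
#' @param m A count matrix produced or normalized by this package.
#' @return One of \code{"raw"}, \code{"cpm"}, \code{"log1p_cpm"},
#'   \code{"scaled"} (or \code{NULL} if untracked).
#' @export
counts_state <- function(m) attr(m, "state")

#' Normalize raw counts to CPM or natural-log CPM
#'
#' CPM divides each column by its total count and scales to one million;
#' \code{log1p_cpm} applies \code{log(1 + cpm)} (natural log). All-zero
#' columns are left all-zero and flagged with a warning.
#'
#' @param m Raw count matrix (genes x cells).
#' @param target \code{"cpm"} or \code{"log1p_cpm"}.
#' @return Matrix of the same shape with updated count state.
#' @export
normalize_counts <- function(m, target = c("log1p_cpm", "cpm")) {
  target <- match.arg(target)
  state <- counts_state(m) %||% "raw"
  if (state != "raw")
    stop2(paste("normalize_counts expects raw counts, got state", state),
          "invalid_state")
  cs <- Matrix::colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero column(s) left unnormalized")
    cs[zero] <- 1
  }
  out <- m %*% Matrix::Diagonal(x = 1e6 / cs)
  dimnames(out) <- dimnames(m)
  if (target == "log1p_cpm") {
    if (is(out, "sparseMatrix")) out@x <- log1p(out@x) else out <- log1p(out)
  }
  attr(out, "state") <- target
  out
}

#' Read / write the per-cell metadata table
#'
#' Tab-separated with a header row; columns \code{cell_id}, \code{age_days},
#' \code{pcw_group}, \code{location}, \code{major_class} and optional
#' \code{subclass}, \code{latent_time}.
#'
#' @param path File path.
#' @return A validated data.frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop2(paste("file not found:", path), "missing_input")
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_cell_table(df)
}

#' @rdname read_cell_table
#' @param cells Cell table to write.
#' @export
write_cell_table <- function(cells, path) {
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_cell_table <- function(df) {
  need <- c("cell_id", "age_days", "location", "major_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2(paste("cell table missing columns:", paste(miss, collapse = ", ")),
          "malformed_table")
  if (anyDuplicated(df$cell_id)) stop2("duplicate cell_ids", "malformed_table")
  if (any(df$age_days <= 0)) stop2("age_days must be positive", "malformed_table")
  if (!all(df$location %in% c("macula", "periphery", "whole")))
    stop2("location must be macula, periphery or whole", "malformed_table")
  if (!is.null(df$latent_time)) {
    lt <- df$latent_time[!is.na(df$latent_time)]
    if (any(lt < 0 | lt > 1)) stop2("latent_time must lie in [0,1]", "malformed_table")
  }
  if (is.null(df$pcw_group)) df$pcw_group <- as.integer(floor(df$age_days / 7))
  df
}

#' Read / write peaks as BED6 (0-based, half-open)
#'
#' @param path File path.
#' @return Peak data.frame with columns \code{contig}, \code{start},
#'   \code{end}, \code{peak_id}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop2(paste("file not found:", path), "missing_input")
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop2("BED file needs at least 4 columns", "malformed_bed")
  df <- df[, 1:4]
  names(df) <- c("contig", "start", "end", "peak_id")
  validate_peaks(df)
}

#' @rdname read_bed
#' @param peaks Peak table to write.
#' @export
write_bed <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  out <- data.frame(peaks$contig, peaks$start, peaks$end, peaks$peak_id,
                    0L, ".")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_peaks <- function(peaks) {
  stopifnot(all(c("contig", "start", "end", "peak_id") %in% names(peaks)))
  if (any(peaks$start >= peaks$end))
    stop2("peak start must be < end (0-based, half-open)", "malformed_bed")
  if (anyDuplicated(peaks$peak_id))
    stop2("duplicate peak_ids", "malformed_bed")
  peaks
}

#' Write a generated atlas to a directory of plain-text files
#'
#' Counts as MatrixMarket + sidecars, cell metadata as TSV, peaks as BED6,
#' pseudobulk/peak accessibility and embeddings as TSV, ground truth as JSON,
#' configuration as YAML.
#'
#' @param atlas A \code{retina_atlas}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_counts(atlas$counts, fp("counts.mtx"), fp("genes.txt"), fp("cells.txt"))
  write_cell_table(atlas$cells, fp("cell_table.tsv"))
  write_bed(atlas$peaks, fp("peaks.bed"))
  wt <- function(x, f) write.table(x, fp(f), sep = "\t", quote = FALSE)
  wt(atlas$peak_acc, "peak_accessibility.tsv")
  wt(atlas$acc_gene, "gene_accessibility.tsv")
  wt(atlas$pseudobulk$expr, "pseudobulk_expr.tsv")
  write.table(atlas$pseudobulk$units, fp("pseudobulk_units.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(atlas$gene_anchors, fp("gene_anchors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  wt(atlas$embedding, "embedding.tsv")
  wt(atlas$velocities, "velocities.tsv")
  write_counts(atlas$adult$counts, fp("adult_counts.mtx"),
               fp("adult_genes.txt"), fp("adult_cells.txt"))
  writeLines(atlas$adult$classes, fp("adult_classes.txt"))
  jsonlite::write_json(atlas$truth, fp("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- atlas$config
  cfg$classes <- as.list(cfg$classes)
  yaml::write_yaml(unclass(cfg), fp("config.yaml"))
  invisible(dir)
}

#' Read an atlas directory written by [write_atlas()]
#'
#' @param dir Directory path.
#' @return A \code{retina_atlas} list (ground truth included when present).
#' @export
read_atlas <- function(dir) {
  fp <- function(f) file.path(dir, f)
  if (!dir.exists(dir)) stop2(paste("no such atlas directory:", dir),
                              "missing_input")
  rt <- function(f) as.matrix(read.delim(fp(f), check.names = FALSE))
  counts <- read_counts(fp("counts.mtx"), fp("genes.txt"), fp("cells.txt"))
  cells <- read_cell_table(fp("cell_table.tsv"))
  truth <- if (file.exists(fp("ground_truth.json")))
    jsonlite::read_json(fp("ground_truth.json"), simplifyVector = TRUE)
  else NULL
  structure(list(
    cells = cells,
    counts = counts,
    acc_gene = rt("gene_accessibility.tsv"),
    pseudobulk = list(
      units = read.delim(fp("pseudobulk_units.tsv"), stringsAsFactors = FALSE),
      expr = rt("pseudobulk_expr.tsv")),
    peak_acc = rt("peak_accessibility.tsv"),
    peaks = read_bed(fp("peaks.bed")),
    gene_anchors = read.delim(fp("gene_anchors.tsv"), stringsAsFactors = FALSE),
    embedding = rt("embedding.tsv"),
    velocities = rt("velocities.tsv"),
    adult = list(
      counts = read_counts(fp("adult_counts.mtx"), fp("adult_genes.txt"),
                           fp("adult_cells.txt")),
      classes = readLines(fp("adult_classes.txt"))),
    truth = truth
  ), class = "retina_atlas")
}
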
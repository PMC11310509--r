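#' Maturation scores against an adult reference
#'
#' For one major class, developmental and adult cells are pooled, a top-PCs
#' embedding is computed on the pooled expression matrix, embedding vectors
#' are averaged within the adult reference and within each developmental
#' (location, PCW group), and each group's maturation score is the Pearson
#' correlation between its average vector and the adult average vector. A
#' score of 1 means the group's mean embedding coincides with the adult
#' profile.
#'
#' Groups smaller than \code{min_cells} are reported with \code{NA} scores
#' rather than extrapolated.
#'
#' @param dev Developmental expression matrix (genes x cells), normalized to
#'   natural-log CPM (\code{log1p_cpm}).
#' @param dev_cells Cell table for \code{dev} columns (needs
#'   \code{major_class}, \code{location}, \code{pcw_group}).
#' @param adult Adult expression matrix (genes x cells), same genes,
#'   normalized to \code{log1p_cpm}.
#' @param adult_classes Class label per adult cell.
#' @param class Major class to score.
#' @param n_pcs Number of principal components (default 50).
#' @param n_hvg Highly variable genes kept before PCA (default 2000).
#' @param min_cells Minimum developmental group size (default 20).
#' @param scale. Variance-scale genes before PCA (default FALSE: centering
#'   only).
#' @return data.frame with \code{major_class}, \code{location},
#'   \code{pcw_group}, \code{score}, \code{n_cells}.
#' @export
maturation_scores <- function(dev, dev_cells, adult, adult_classes, class,
                              n_pcs = 50L, n_hvg = 2000L, min_cells = 20L,
                              scale. = FALSE) {
  for (m in list(dev, adult)) {
    st <- counts_state(m)
    if (!is.null(st) && st != "log1p_cpm")
      stop2("maturation_scores expects log1p_cpm-normalized matrices",
            "invalid_state")
  }
  if (!class %in% adult_classes)
    stop2(paste("class absent from adult reference:", class), "missing_class")
  di <- which(dev_cells$major_class == class)
  ai <- which(adult_classes == class)
  if (!length(di))
    stop2(paste("class absent from developmental data:", class), "missing_class")

  pooled <- cbind(as_dense(dev[, di, drop = FALSE]),
                  as_dense(adult[, ai, drop = FALSE]))
  v <- apply(pooled, 1L, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, sum(v > 0)))]
  x <- t(pooled[keep, , drop = FALSE])
  rank <- min(n_pcs, nrow(x) - 1L, ncol(x))
  if (rank < 2L)
    stop2("fewer than 2 informative components", "degenerate_embedding")
  emb <- prcomp(x, center = TRUE, scale. = scale., rank. = rank)$x

  n_dev <- length(di)
  adult_mean <- colMeans(emb[(n_dev + 1L):nrow(emb), , drop = FALSE])
  grp <- interaction(dev_cells$location[di], dev_cells$pcw_group[di], drop = TRUE)
  out <- lapply(levels(grp), function(g) {
    j <- which(grp == g)
    loc <- dev_cells$location[di][j[1]]
    pcw <- dev_cells$pcw_group[di][j[1]]
    score <- if (length(j) >= min_cells)
      cor(adult_mean, colMeans(emb[j, , drop = FALSE])) else NA_real_
    data.frame(major_class = class, location = loc, pcw_group = pcw,
               score = score, n_cells = length(j), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$location, out$pcw_group), , drop = FALSE]
}

#' Maturation scores for every adult-represented class of an atlas
#'
#' Convenience wrapper running [maturation_scores()] per class on a
#' synthetic or real atlas bundle.
#'
#' @param atlas A \code{retina_atlas}.
#' @param min_cells Minimum group size scored at atlas scale (default 60,
#'   about 1 percent of the demo atlas): per-group scores are meant to be
#'   computed over large cell groups, and a 50-dimensional correlation over a
#'   small group's mean embedding is shrunk toward zero by noise, which can
#'   scramble the developmental ordering.
#' @param ... Passed to [maturation_scores()].
#' @return Row-bound score table across classes.
#' @export
maturation_scores_atlas <- function(atlas, min_cells = 60L, ...) {
  dev <- normalize_counts(atlas$counts, "log1p_cpm")
  adult <- normalize_counts(atlas$adult$counts, "log1p_cpm")
  classes <- intersect(unique(atlas$cells$major_class),
                       unique(atlas$adult$classes))
  do.call(rbind, lapply(classes, function(cl)
    maturation_scores(dev, atlas$cells, adult, atlas$adult$classes, cl,
                      min_cells = min_cells, ...)))
}
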
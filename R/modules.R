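#' Detect genes correlated with latent time
#'
#' Per gene, the Pearson correlation of normalized expression with latent
#' time, its exact two-sided p-value from the t reference distribution, and
#' a Benjamini-Hochberg q-value. Genes are selected at \code{q < alpha}.
#' This is a linear-correlation stand-in for graph-autocorrelation gene
#' selection: it tests the same null (no expression trend along latent time)
#' against the same covariate. Constant genes have no defined correlation
#' and are excluded.
#'
#' @param expr Normalized genes x cells matrix.
#' @param latent_time Per-cell latent time in [0,1].
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with \code{gene}, \code{r}, \code{p}, \code{q},
#'   \code{selected}.
#' @export
detect_correlated_genes <- function(expr, latent_time, alpha = 0.05) {
  stopifnot(length(latent_time) == ncol(expr))
  if (anyNA(latent_time))
    stop2("latent_time must be present for all cells", "missing_latent_time")
  x <- as_dense(expr)
  n <- ncol(x)
  xc <- x - rowMeans(x)
  tc <- latent_time - mean(latent_time)
  sx <- sqrt(rowSums(xc^2))
  st <- sqrt(sum(tc^2))
  r <- as.numeric(xc %*% tc) / (sx * st)
  const <- sx == 0
  r[const] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  q <- rep(NA_real_, length(r))
  q[!const] <- p.adjust(p[!const], "BH")
  data.frame(gene = rownames(x), r = r, p = p, q = q,
             selected = !const & !is.na(q) & q < alpha,
             stringsAsFactors = FALSE)
}

#' Group selected genes into latent-time modules
#'
#' Average-linkage hierarchical clustering of the gene-gene correlation
#' matrix (distance 1 - r), cut into K groups. With \code{core_only}, genes
#' whose mean within-module correlation falls below \code{core_floor} stay
#' unassigned; modules with fewer than \code{min_gene_threshold} members are
#' not emitted (their genes become unassigned). When \code{latent_time} is
#' supplied, emitted modules are renumbered by the latent-time position of
#' their peak mean expression, so module 1 peaks earliest.
#'
#' @param expr Normalized genes x cells matrix.
#' @param genes Selected gene names (rows of \code{expr}).
#' @param K Number of modules to cut (default 3).
#' @param min_gene_threshold Minimum emitted module size (default 160, scale
#'   to the data at hand).
#' @param core_only Keep only core genes (default TRUE).
#' @param core_floor Mean within-module correlation floor (default 0.3 is
#'   suited to low-noise data; lower it for noisy counts).
#' @param latent_time Optional per-cell latent time used to order modules.
#' @return Object of class \code{module_result}: list with \code{genes}
#'   (gene, module, core_r), \code{K}, \code{sizes}.
#' @export
group_modules <- function(expr, genes, K = 3L, min_gene_threshold = 160L,
                          core_only = TRUE, core_floor = 0.3,
                          latent_time = NULL) {
  if (length(genes) < 2L * K) {
    warning("too few selected genes for ", K, " modules; reducing K")
    K <- max(1L, length(genes) %/% 2L)
  }
  x <- as_dense(expr[genes, , drop = FALSE])
  cc <- cor(t(x))
  hc <- hclust(as.dist(1 - cc), method = "average")
  ## Cut at the shallowest depth that yields K clusters of workable size:
  ## average linkage merges straggler genes near the top of the tree, so a
  ## plain K-cut can spend its budget peeling off singletons while two real
  ## modules stay merged.
  cl <- cutree(hc, k = K)
  for (k in K:length(genes)) {
    cand <- cutree(hc, k = k)
    sizes <- table(cand)
    big <- as.integer(names(sizes)[sizes >= min_gene_threshold])
    if (length(big) >= K) {
      keep_ids <- big[order(-sizes[as.character(big)])][seq_len(K)]
      cl <- ifelse(cand %in% keep_ids, cand, NA_integer_)
      break
    }
  }

  core_r <- vapply(seq_along(genes), function(i) {
    if (is.na(cl[i])) return(NA_real_)
    j <- setdiff(which(!is.na(cl) & cl == cl[i]), i)
    if (!length(j)) return(1)
    mean(cc[i, j])
  }, numeric(1))
  assigned <- cl
  if (core_only) assigned[!is.na(core_r) & core_r < core_floor] <- NA_integer_

  sizes <- table(assigned)
  drop <- as.integer(names(sizes)[sizes < min_gene_threshold])
  assigned[assigned %in% drop] <- NA_integer_

  kept <- sort(unique(assigned[!is.na(assigned)]))
  if (!is.null(latent_time) && length(kept)) {
    peaks <- vapply(kept, function(k) {
      mexpr <- colMeans(x[assigned %in% k, , drop = FALSE])
      lo <- stats::lowess(latent_time, mexpr, f = 0.4)
      lo$x[which.max(lo$y)]
    }, numeric(1))
    remap <- setNames(rank(peaks, ties.method = "first"), kept)
  } else {
    remap <- setNames(seq_along(kept), kept)
  }
  module <- ifelse(is.na(assigned), NA_integer_,
                   as.integer(remap[as.character(assigned)]))
  structure(list(
    genes = data.frame(gene = genes, module = module, core_r = core_r,
                       stringsAsFactors = FALSE),
    K = K, sizes = table(module)
  ), class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  cat("module_result:", sum(!is.na(x$genes$module)), "of", nrow(x$genes),
      "genes assigned to", length(x$sizes), "module(s)\n")
  print(x$sizes)
  invisible(x)
}

#' Smooth expression by averaging over nearest neighbors along latent time
#'
#' @param expr Genes x cells matrix.
#' @param latent_time Per-cell ordering covariate.
#' @param k Neighborhood size (default 30).
#' @return Smoothed dense matrix, same shape.
#' @export
smooth_expression <- function(expr, latent_time, k = 30L) {
  x <- as_dense(expr)
  n <- ncol(x)
  k <- min(k, n)
  o <- order(latent_time)
  xs <- x[, o, drop = FALSE]
  cs <- cbind(0, t(apply(xs, 1L, cumsum)))
  half <- k %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, lo + k - 1L)
  lo <- pmax(1L, hi - k + 1L)
  sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(x))
  out <- matrix(0, nrow(x), n, dimnames = dimnames(x))
  out[, o] <- sm
  out
}

#' Per-cell module score
#'
#' The cell loadings of a single-component PCA of the smoothed, centered
#' expression submatrix of a module's genes, standardized to unit variance
#' and with the sign oriented so the score correlates positively with mean
#' module expression. Standardization makes the score invariant to gene
#' duplication, and for a one-gene module it reduces to the standardized
#' smoothed expression of that gene.
#'
#' @param expr Normalized genes x cells matrix.
#' @param module_genes Gene names of one module.
#' @param latent_time Optional covariate for KNN smoothing (skipped if NULL).
#' @param k Smoothing neighborhood (default 30).
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, module_genes, latent_time = NULL, k = 30L) {
  if (ncol(expr) < 2L) stop2("need at least 2 cells", "invalid_argument")
  x <- as_dense(expr[module_genes, , drop = FALSE])
  if (!is.null(latent_time)) x <- smooth_expression(x, latent_time, k)
  xc <- x - rowMeans(x)
  sv <- svd(t(xc), nu = 1L, nv = 0L)
  score <- sv$u[, 1L] * sv$d[1L]
  if (sd(score) > 0) score <- (score - mean(score)) / sd(score)
  meanexpr <- colMeans(x)
  if (sd(meanexpr) > 0 && cor(score, meanexpr) < 0) score <- -score
  setNames(score, colnames(expr))
}

#' Expression-weighted developmental time of a gene
#'
#' Expression values are scaled to sum to one and used as weights on sample
#' age: \code{sum(w * age_days)}. A gene with zero total expression has no
#' defined weighted time and is reported as \code{NA}.
#'
#' @param expr_vec Non-negative expression vector over cells.
#' @param age_days Sample age (days) per cell.
#' @return Weighted time in days, or \code{NA}.
#' @export
expression_weighted_time <- function(expr_vec, age_days) {
  stopifnot(length(expr_vec) == length(age_days))
  s <- sum(expr_vec)
  if (s <= 0) {
    warning("gene has zero total expression; weighted time undefined")
    return(NA_real_)
  }
  sum((expr_vec / s) * age_days)
}

#' Latent-time consistency tests
#'
#' (1) Two-sided Pearson product-moment correlation between PCW group
#' (numeric) and latent time over all cells; (2) per PCW group, a two-sided
#' Welch two-sample t-test of macula vs periphery latent time, with
#' multiple-testing adjustment over the tested groups (Bonferroni by
#' default). PCW groups missing a location are skipped and reported.
#'
#' @param cells Cell table with \code{pcw_group}, \code{location},
#'   \code{latent_time}.
#' @param adjust Adjustment method for the per-PCW tests (default
#'   \code{"bonferroni"}).
#' @return List with \code{pearson} (estimate, p) and \code{welch}
#'   (data.frame: pcw_group, mean_macula, mean_periphery, t, p, p_adj,
#'   skipped).
#' @export
latent_time_tests <- function(cells, adjust = "bonferroni") {
  if (anyNA(cells$latent_time))
    stop2("latent_time must be present", "missing_latent_time")
  pcw_num <- as.numeric(cells$pcw_group)
  ct <- if (sd(pcw_num) == 0 || sd(cells$latent_time) == 0)
    list(estimate = NA_real_, p.value = NA_real_)
  else cor.test(pcw_num, cells$latent_time)
  pcws <- sort(unique(cells$pcw_group))
  rows <- lapply(pcws, function(w) {
    m <- cells$latent_time[cells$pcw_group == w & cells$location == "macula"]
    p <- cells$latent_time[cells$pcw_group == w & cells$location == "periphery"]
    if (length(m) < 2L || length(p) < 2L)
      return(data.frame(pcw_group = w, mean_macula = mean(m),
                        mean_periphery = mean(p), t = NA_real_, p = NA_real_,
                        skipped = TRUE))
    tt <- tryCatch(t.test(m, p), error = function(e) NULL)
    if (is.null(tt))           # e.g. both groups constant
      return(data.frame(pcw_group = w, mean_macula = mean(m),
                        mean_periphery = mean(p), t = NA_real_, p = NA_real_,
                        skipped = TRUE))
    data.frame(pcw_group = w, mean_macula = mean(m), mean_periphery = mean(p),
               t = unname(tt$statistic), p = tt$p.value, skipped = FALSE)
  })
  welch <- do.call(rbind, rows)
  welch$p_adj <- NA_real_
  tested <- !welch$skipped
  welch$p_adj[tested] <- p.adjust(welch$p[tested], adjust)
  list(pearson = list(estimate = unname(ct$estimate), p = ct$p.value),
       welch = welch)
}
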
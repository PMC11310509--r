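#' Differentially accessible regions per class
#'
#' For each focal class versus all other pseudobulk replicates, a one-sided
#' Wilcoxon rank-sum test (greater accessibility in the focal class) on
#' log2-normalized accessibility, Benjamini-Hochberg corrected across peaks
#' within the class. A peak is a DAR iff \code{q < q_thresh} and its log2
#' fold change exceeds \code{lfc_thresh} (strictly).
#'
#' @param acc Peaks x pseudobulk matrix of log2-normalized accessibility.
#' @param classes Class label per pseudobulk column; every class needs >= 2
#'   replicates.
#' @param q_thresh FDR threshold (default 0.01).
#' @param lfc_thresh log2 fold-change gate, exclusive (default 1).
#' @param focal Classes to test (default: all).
#' @return data.frame with \code{peak_id}, \code{class}, \code{log2_fc},
#'   \code{p}, \code{q}, \code{is_dar}.
#' @export
call_dars <- function(acc, classes, q_thresh = 0.01, lfc_thresh = 1,
                      focal = NULL) {
  stopifnot(length(classes) == ncol(acc))
  classes <- as.character(classes)
  focal <- focal %||% sort(unique(classes))
  out <- lapply(focal, function(cl) {
    j <- classes == cl
    if (sum(j) < 2L) stop2(paste("class", cl, "has fewer than 2 replicates"),
                           "invalid_argument")
    a <- acc[, j, drop = FALSE]; b <- acc[, !j, drop = FALSE]
    lfc <- rowMeans(a) - rowMeans(b)
    p <- vapply(seq_len(nrow(acc)), function(i)
      wilcox.test(a[i, ], b[i, ], alternative = "greater")$p.value,
      numeric(1))
    q <- p.adjust(p, "BH")
    data.frame(peak_id = rownames(acc), class = cl, log2_fc = lfc,
               p = p, q = q, is_dar = q < q_thresh & lfc > lfc_thresh,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.peaks_to_granges <- function(peaks) {
  peaks <- validate_peaks(peaks)
  GenomicRanges::GRanges(peaks$contig,
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end),
                         peak_id = peaks$peak_id)
}

#' Classify peaks by fractional overlap with a reference peak set
#'
#' A query peak is \code{overlapping} iff the number of its bases covered by
#' the union of reference peaks is at least \code{min_frac} of its length
#' (inclusive boundary: exactly 20 percent counts); otherwise it is
#' \code{specific} (e.g., developmental-specific relative to adult peaks).
#' Coordinates are 0-based, half-open.
#'
#' @param query,reference Peak tables (\code{contig}, \code{start},
#'   \code{end}, \code{peak_id}).
#' @param min_frac Minimum covered fraction (default 0.2).
#' @return data.frame with \code{peak_id}, \code{overlap_bases},
#'   \code{frac}, \code{status}.
#' @export
classify_overlap <- function(query, reference, min_frac = 0.2) {
  q <- .peaks_to_granges(query)
  r <- GenomicRanges::reduce(.peaks_to_granges(reference))
  ov <- GenomicRanges::findOverlaps(q, r)
  inter <- GenomicRanges::pintersect(q[S4Vectors::queryHits(ov)],
                                     r[S4Vectors::subjectHits(ov)])
  bases <- rep(0L, length(q))
  if (length(ov)) {
    agg <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
    bases[as.integer(names(agg))] <- as.integer(agg)
  }
  w <- GenomicRanges::width(q)
  frac <- bases / w
  data.frame(peak_id = query$peak_id, overlap_bases = bases, frac = frac,
             status = ifelse(frac >= min_frac, "overlapping", "specific"),
             stringsAsFactors = FALSE)
}

#' Peak-to-gene linkage by windowed correlation
#'
#' For each gene, candidate peaks are those within \code{max_bp} of the
#' gene's anchor (distance from the anchor position to the nearest base of
#' the half-open peak interval, 0 if the anchor falls inside); a candidate
#' is linked iff the Pearson correlation between its accessibility and the
#' gene's expression across matched pseudobulk units reaches \code{min_r}
#' (inclusive).
#'
#' @param acc Peaks x units accessibility matrix (rownames = peak ids).
#' @param expr Genes x units expression matrix over the same units.
#' @param peaks Peak table (contig, start, end, peak_id).
#' @param anchors data.frame with \code{gene}, \code{contig}, \code{anchor}
#'   (anchor = transcription start position).
#' @param max_bp Window (default 250000).
#' @param min_r Correlation floor, inclusive (default 0.45).
#' @return data.frame of links: \code{peak_id}, \code{gene},
#'   \code{distance_bp}, \code{pearson_r}.
#' @export
link_peaks_to_genes <- function(acc, expr, peaks, anchors,
                                max_bp = 250000L, min_r = 0.45) {
  peaks <- validate_peaks(peaks)
  genes <- rownames(expr)
  miss <- setdiff(genes, anchors$gene)
  if (length(miss))
    stop2(paste("gene(s) without anchor:", paste(head(miss, 5), collapse = ", ")),
          "missing_anchor")
  stopifnot(identical(colnames(acc), colnames(expr)))
  pk_row <- match(peaks$peak_id, rownames(acc))
  links <- list()
  for (g in genes) {
    ai <- match(g, anchors$gene)
    same <- peaks$contig == anchors$contig[ai]
    if (!any(same)) next
    a <- anchors$anchor[ai]
    dist <- pmax(0L, pmax(peaks$start[same] - a, a - peaks$end[same] + 1L))
    cand <- which(same)[dist <= max_bp]
    dist <- dist[dist <= max_bp]
    if (!length(cand)) next
    e <- as.numeric(expr[g, ])
    if (sd(e) == 0) next
    for (k in seq_along(cand)) {
      av <- as.numeric(acc[pk_row[cand[k]], ])
      if (sd(av) == 0) next
      r <- cor(av, e)
      if (r >= min_r)
        links[[length(links) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[cand[k]], gene = g,
          distance_bp = dist[k], pearson_r = r, stringsAsFactors = FALSE)
    }
  }
  if (!length(links))
    return(data.frame(peak_id = character(0), gene = character(0),
                      distance_bp = integer(0), pearson_r = numeric(0)))
  do.call(rbind, links)
}

# Pointwise phase classification shared by the segmenter and the generator's
# ground truth. Slopes are forward differences (last point reuses the
# previous slope). Primed takes precedence; a zero slope in both trajectories
# inherits the concordant class of the sign of the last nonzero change
# (flat-flat stretches are coupled in the direction they were moving).
classify_phase_pointwise <- function(c_, s, silence, open) {
  n <- length(c_)
  if (n < 3L) stop2("grid must have at least 3 points", "invalid_argument")
  dc <- c(diff(c_), NA); dc[n] <- dc[n - 1L]
  ds <- c(diff(s), NA); ds[n] <- ds[n - 1L]
  silent <- if (max(s) <= 0) rep(TRUE, n) else s < silence
  phase <- character(n)
  for (i in seq_len(n)) {
    if (c_[i] > open && silent[i]) { phase[i] <- "primed"; next }
    sc <- sign(dc[i]); ss <- sign(ds[i])
    if (sc == 0) sc <- ss
    if (ss == 0) ss <- sc
    phase[i] <- if (sc >= 0 && ss >= 0) "coupled_on"
    else if (sc < 0 && ss < 0) "coupled_off"
    else "decoupled"
  }
  factor(phase, levels = c("primed", "coupled_on", "coupled_off", "decoupled"))
}

#' Segment a gene's chromatin-expression relationship into phases
#'
#' On a shared gene-time grid, each point is classified as \code{primed}
#' (chromatin open above \code{open_frac} of its maximum while expression is
#' silent, below \code{silence_frac} of its maximum), \code{coupled_on}
#' (both increasing), \code{coupled_off} (both decreasing) or
#' \code{decoupled} (opposite slopes). Phase percentages are grid-point
#' shares and sum to 100.
#'
#' @param chromatin,expression Smoothed trajectories on a common grid.
#' @param grid Gene-time grid (default: equally spaced on [0,1]).
#' @param silence_frac Silence threshold as a fraction of max expression
#'   (default 0.05).
#' @param open_frac Open-chromatin threshold as a fraction of max
#'   accessibility (default 0.5).
#' @return Object of class \code{phase_segmentation}: list with \code{grid},
#'   \code{phase} (factor per grid point), \code{percentages} (named,
#'   summing to 100).
#' @export
segment_phases <- function(chromatin, expression, grid = NULL,
                           silence_frac = 0.05, open_frac = 0.5) {
  stopifnot(length(chromatin) == length(expression))
  n <- length(chromatin)
  if (n < 3L) stop2("grid must have at least 3 points", "invalid_argument")
  grid <- grid %||% seq(0, 1, length.out = n)
  phase <- classify_phase_pointwise(chromatin, expression,
                                    silence = silence_frac * max(expression),
                                    open = open_frac * max(chromatin))
  pct <- 100 * table(phase) / n
  structure(list(grid = grid, phase = phase,
                 percentages = setNames(as.numeric(pct), names(pct))),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("phase_segmentation over", length(x$grid), "grid points:\n")
  print(round(x$percentages, 1))
  invisible(x)
}

#' Average phase percentages per class, with an optional module comparison
#'
#' @param segmentations Named list of \code{phase_segmentation} objects (one
#'   per gene).
#' @param gene_class Class label per gene (same order); per class, phase
#'   percentages are averaged across genes.
#' @param compare Optional list of two gene-name vectors; a two-sided Welch
#'   t-test compares their coupled-on percentages (p BH-adjusted if several
#'   comparisons are supplied as a list of pairs).
#' @return List with \code{summary} (class x phase mean percentages) and
#'   \code{comparison} (Welch result or NULL).
#' @export
phase_summaries <- function(segmentations, gene_class, compare = NULL) {
  stopifnot(length(segmentations) == length(gene_class))
  if (!length(segmentations)) stop2("empty gene set", "invalid_argument")
  lev <- levels(segmentations[[1]]$phase)
  pcts <- t(vapply(segmentations, function(s) {
    p <- setNames(rep(0, length(lev)), lev)
    p[names(s$percentages)] <- s$percentages
    p
  }, numeric(length(lev))))
  summary <- aggregate(pcts, by = list(class = gene_class), FUN = mean)
  comparison <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2L)
    g1 <- pcts[names(segmentations) %in% compare[[1]], "coupled_on"]
    g2 <- pcts[names(segmentations) %in% compare[[2]], "coupled_on"]
    tt <- t.test(g1, g2)
    comparison <- data.frame(mean_1 = mean(g1), mean_2 = mean(g2),
                             t = unname(tt$statistic), p = tt$p.value,
                             p_adj = p.adjust(tt$p.value, "BH"))
  }
  list(summary = summary, comparison = comparison)
}

#' Bin values along latent time into a smoothed trajectory
#'
#' Utility to turn per-cell measurements into a gene-time trajectory: cells
#' are cut into \code{n_bins} equal-width latent-time bins and averaged.
#'
#' @param values Per-cell values.
#' @param latent_time Per-cell latent time.
#' @param n_bins Number of bins (default 25).
#' @return List with \code{grid} (bin midpoints) and \code{mean} (per-bin
#'   averages); empty bins are dropped.
#' @export
binned_trajectory <- function(values, latent_time, n_bins = 25L) {
  br <- seq(min(latent_time), max(latent_time), length.out = n_bins + 1L)
  bin <- cut(latent_time, br, include.lowest = TRUE, labels = FALSE)
  mids <- (br[-1] + br[-length(br)]) / 2
  m <- tapply(values, bin, mean)
  keep <- as.integer(names(m))
  list(grid = mids[keep], mean = as.numeric(m))
}
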
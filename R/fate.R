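## Cell-cell transition kernels and absorbing-chain fate probabilities.

.knn_index <- function(embedding, k, block = 1024L) {
  n <- nrow(embedding)
  if (k >= n) stop2("k must be < number of cells", "invalid_argument")
  sq <- rowSums(embedding^2)
  idx <- matrix(0L, n, k)
  for (s in seq(1L, n, by = block)) {
    rows <- s:min(s + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * embedding[rows, , drop = FALSE] %*% t(embedding)
    for (r in seq_along(rows)) {
      d <- d2[r, ]; d[rows[r]] <- Inf
      idx[rows[r], ] <- order(d)[seq_len(k)]
    }
  }
  idx
}

#' Velocity transition kernel
#'
#' For each cell i, transition mass over its k nearest embedding neighbors j
#' is proportional to \code{exp(cos(v_i, x_j - x_i) / tau)}: neighbors lying
#' in the direction of the cell's velocity vector receive more mass. Cells
#' with a zero-length velocity get a uniform row over their neighbors (their
#' count is reported in the \code{"n_zero_velocity"} attribute).
#'
#' @param embedding Cells x dims coordinate matrix.
#' @param velocities Cells x dims velocity matrix (same shape).
#' @param k Number of nearest neighbors (>= 2).
#' @param tau Softmax temperature (default 1; small tau concentrates mass on
#'   the best-aligned neighbor).
#' @return Row-stochastic sparse matrix (dgCMatrix).
#' @export
velocity_kernel <- function(embedding, velocities, k = 30L, tau = 1) {
  if (!all(dim(embedding) == dim(velocities)))
    stop2("embedding and velocities must have the same shape", "shape_mismatch")
  if (k < 2L) stop2("k must be >= 2", "invalid_argument")
  n <- nrow(embedding)
  idx <- .knn_index(embedding, k)
  vnorm <- sqrt(rowSums(velocities^2))
  n_zero <- sum(vnorm == 0)
  w <- matrix(0, n, k)
  for (i in seq_len(n)) {
    disp <- embedding[idx[i, ], , drop = FALSE] -
      matrix(embedding[i, ], k, ncol(embedding), byrow = TRUE)
    dn <- sqrt(rowSums(disp^2))
    cosv <- if (vnorm[i] == 0) rep(0, k) else {
      cs <- as.numeric(disp %*% velocities[i, ]) / (dn * vnorm[i])
      cs[dn == 0] <- 0
      cs
    }
    e <- exp((cosv - max(cosv)) / tau)
    w[i, ] <- e / sum(e)
  }
  T_ <- sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(idx)),
                     x = as.vector(t(w)), dims = c(n, n),
                     dimnames = list(rownames(embedding), rownames(embedding)))
  attr(T_, "n_zero_velocity") <- n_zero
  T_
}

#' Connectivity transition kernel
#'
#' Gaussian similarity over the k-nearest-neighbor graph: mass over neighbor
#' j is proportional to \code{exp(-d_ij^2 / sigma_i^2)} with a per-cell
#' bandwidth equal to the median neighbor distance. Deterministic given the
#' embedding.
#'
#' @inheritParams velocity_kernel
#' @return Row-stochastic sparse matrix.
#' @export
connectivity_kernel <- function(embedding, k = 30L) {
  if (k < 2L) stop2("k must be >= 2", "invalid_argument")
  n <- nrow(embedding)
  idx <- .knn_index(embedding, k)
  w <- matrix(0, n, k)
  for (i in seq_len(n)) {
    disp <- embedding[idx[i, ], , drop = FALSE] -
      matrix(embedding[i, ], k, ncol(embedding), byrow = TRUE)
    d2 <- rowSums(disp^2)
    s2 <- stats::median(d2)
    e <- if (s2 == 0) rep(1, k) else exp(-d2 / s2)
    w[i, ] <- e / sum(e)
  }
  sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(idx)),
               x = as.vector(t(w)), dims = c(n, n),
               dimnames = list(rownames(embedding), rownames(embedding)))
}

#' Convex combination of transition kernels
#'
#' \code{T = w_vel * T_vel + (1 - w_vel) * T_conn}; with both inputs
#' row-stochastic the result is row-stochastic. The default weighting (0.8
#' velocity, 0.2 connectivity) follows the combined-kernel construction used
#' for fate inference.
#'
#' @param T_vel,T_conn Row-stochastic matrices of identical shape.
#' @param w_vel Velocity weight in [0,1] (default 0.8).
#' @return Row-stochastic sparse matrix.
#' @export
combine_kernels <- function(T_vel, T_conn, w_vel = 0.8) {
  if (!all(dim(T_vel) == dim(T_conn)))
    stop2("kernel shapes differ", "shape_mismatch")
  if (w_vel < 0 || w_vel > 1) stop2("w_vel must be in [0,1]", "invalid_argument")
  for (m in list(T_vel, T_conn))
    if (max(abs(Matrix::rowSums(m) - 1)) > 1e-8)
      stop2("input kernels must be row-stochastic", "not_stochastic")
  w_vel * T_vel + (1 - w_vel) * T_conn
}

#' Transition model: kernel plus terminal fate sets
#'
#' @param T_ Row-stochastic cells x cells matrix.
#' @param terminal_sets Named list mapping fate name to cell indices (or cell
#'   ids matching the matrix dimnames); sets must be disjoint and non-empty.
#' @param w_vel Optional record of the kernel weighting.
#' @return An object of class \code{transition_model}.
#' @export
transition_model <- function(T_, terminal_sets, w_vel = NA_real_) {
  if (max(abs(Matrix::rowSums(T_) - 1)) > 1e-9)
    stop2("rows must sum to 1 within 1e-9", "not_stochastic")
  if (is.null(names(terminal_sets)) || any(names(terminal_sets) == ""))
    stop2("terminal_sets must be a named list", "invalid_argument")
  terminal_sets <- lapply(terminal_sets, function(s) {
    if (is.character(s)) s <- match(s, rownames(T_))
    if (anyNA(s) || !length(s)) stop2("empty or unknown terminal set", "invalid_argument")
    as.integer(s)
  })
  all_t <- unlist(terminal_sets)
  if (anyDuplicated(all_t)) stop2("terminal sets must be disjoint", "invalid_argument")
  structure(list(T = T_, terminal_sets = terminal_sets, w_vel = w_vel),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("transition_model:", nrow(x$T), "cells,", length(x$terminal_sets),
      "terminal fates (", paste(names(x$terminal_sets), collapse = ", "), ")\n")
  invisible(x)
}

#' Absorption probabilities of the fate-transition chain
#'
#' Terminal cells are made absorbing; with Q the transient-transient block
#' and R the transient-terminal block, the absorption probability matrix is
#' \code{B = solve(I - Q, R)} aggregated per fate. Every row of B sums to 1;
#' terminal cells receive probability 1 for their own fate. Transient cells
#' from which no terminal set is reachable are flagged (returned in the
#' \code{"unreachable"} attribute with NA rows), never silently zeroed.
#'
#' @param model A [transition_model()].
#' @return Object of class \code{fate_probs}: cells x fates matrix with
#'   attribute \code{"unreachable"}.
#' @export
absorption_probabilities <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  T_ <- model$T
  n <- nrow(T_)
  fates <- names(model$terminal_sets)
  term <- unlist(model$terminal_sets)
  trans <- setdiff(seq_len(n), term)

  ## reachability: a cell reaches a terminal set if it has an edge into the
  ## current reach set (fixed point of a reverse BFS, done by sparse multiply)
  adj <- as(T_ != 0, "CsparseMatrix")
  ind <- numeric(n); ind[term] <- 1
  repeat {
    new <- as.numeric(adj %*% ind) > 0
    grew <- new & !(ind > 0)
    if (!any(grew)) break
    ind[grew] <- 1
  }
  unreachable <- which(!(ind > 0))

  B <- matrix(NA_real_, n, length(fates),
              dimnames = list(rownames(T_), fates))
  for (f in fates) B[model$terminal_sets[[f]], ] <- 0
  for (f in fates) B[model$terminal_sets[[f]], f] <- 1

  ok <- setdiff(trans, unreachable)
  if (length(ok)) {
    Q <- T_[ok, ok, drop = FALSE]
    Ragg <- vapply(fates, function(f)
      as.numeric(Matrix::rowSums(T_[ok, model$terminal_sets[[f]], drop = FALSE])),
      numeric(length(ok)))
    if (length(ok) == 1L) Ragg <- matrix(Ragg, nrow = 1L)
    A <- Diagonal(length(ok)) - Q
    X <- as.matrix(Matrix::solve(A, Ragg))
    B[ok, ] <- X
  }
  if (length(unreachable))
    warning(length(unreachable),
            " cell(s) cannot reach any terminal set; rows flagged NA")
  structure(B, class = c("fate_probs", class(B)),
            unreachable = rownames(T_)[unreachable] %||% unreachable)
}

#' @export
print.fate_probs <- function(x, ...) {
  cat("fate_probs:", nrow(x), "cells x", ncol(x), "fates\n")
  print(head(unclass(x), 4L))
  invisible(x)
}

#' Cluster-level fate assignment
#'
#' The fate of a cluster is the argmax of its members' mean absorption
#' probabilities if that maximum reaches \code{threshold}; otherwise the
#' cluster is undetermined (\code{NA}). Members inherit the cluster fate.
#' Ties are broken lexicographically and flagged.
#'
#' @param B A \code{fate_probs} matrix (cells x fates).
#' @param clusters Cluster label per cell.
#' @param threshold Minimum mean probability to commit (default 0.5).
#' @return List with \code{clusters} (cluster, fate, max_prob, tie) and
#'   \code{cell_fate} (named per-cell vector).
#' @export
assign_cluster_fates <- function(B, clusters, threshold = 0.5) {
  stopifnot(length(clusters) == nrow(B))
  lev <- unique(as.character(clusters))
  rows <- lapply(lev, function(cl) {
    j <- which(clusters == cl)
    if (!length(j)) stop2(paste("empty cluster", cl), "invalid_argument")
    m <- colMeans(B[j, , drop = FALSE])
    if (anyNA(m)) return(data.frame(cluster = cl, fate = NA_character_,
                                    max_prob = NA_real_, tie = FALSE))
    top <- which(m == max(m))
    fate <- if (m[top[1]] >= threshold)
      sort(colnames(B)[top])[1] else NA_character_
    data.frame(cluster = cl, fate = fate, max_prob = max(m),
               tie = length(top) > 1L, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  cell_fate <- setNames(df$fate[match(as.character(clusters), df$cluster)],
                        rownames(B))
  list(clusters = df, cell_fate = cell_fate)
}

#' Terminal sets from a latent-time rule
#'
#' Cells of each fate class whose latent time exceeds the within-class
#' quantile are declared terminal, automating the manual terminal-state
#' choice.
#'
#' @param cells Cell table with \code{major_class} and \code{latent_time}.
#' @param fates Fate class names.
#' @param latent_quantile Within-class latent-time quantile (default 0.8).
#' @return Named list of cell indices per fate.
#' @export
terminal_sets_by_rule <- function(cells, fates, latent_quantile = 0.8) {
  out <- lapply(fates, function(f) {
    j <- which(cells$major_class == f)
    if (!length(j)) stop2(paste("no cells of fate class", f), "invalid_argument")
    q <- quantile(cells$latent_time[j], latent_quantile, na.rm = TRUE)
    j[cells$latent_time[j] >= q]
  })
  setNames(out, fates)
}
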
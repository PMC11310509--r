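#' Class-marker ranking with the overestimated-variance t-test
#'
#' For each focal group g versus the rest, the statistic is
#' \code{t = (m_g - m_rest) / sqrt(v_g/n_g + v_rest/n_g)} -- both variance
#' terms are divided by the focal group's size, deliberately overestimating
#' the rest-group variance term and making the test conservative. Two-sided
#' p-values use a Welch-Satterthwaite df built from the same two terms;
#' Benjamini-Hochberg correction is applied within each focal group.
#'
#' @param expr Normalized (log1p_cpm) genes x cells matrix.
#' @param groups Group label per cell (>= 2 groups, every group of size
#'   >= 2).
#' @return data.frame with \code{group}, \code{gene}, \code{mean_diff},
#'   \code{t}, \code{p}, \code{q}.
#' @export
rank_genes_overestim_t <- function(expr, groups) {
  stopifnot(length(groups) == ncol(expr))
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop2("need at least two groups", "invalid_argument")
  x <- as_dense(expr)
  out <- lapply(lev, function(g) {
    jg <- groups == g
    ng <- sum(jg); nr <- sum(!jg)
    if (ng < 2L || nr < 2L) stop2(paste("group", g, "has fewer than 2 cells"),
                                  "invalid_argument")
    mg <- rowMeans(x[, jg, drop = FALSE])
    mr <- rowMeans(x[, !jg, drop = FALSE])
    vg <- apply(x[, jg, drop = FALSE], 1L, var)
    vr <- apply(x[, !jg, drop = FALSE], 1L, var)
    a <- vg / ng; b <- vr / ng           # rest variance over focal n: overestimated
    se <- sqrt(a + b)
    tt <- ifelse(se == 0, 0, (mg - mr) / se)
    df <- ifelse(se == 0, ng - 1,
                 (a + b)^2 / (a^2 / (ng - 1) + b^2 / (nr - 1)))
    p <- ifelse(se == 0, 1, 2 * pt(abs(tt), df = df, lower.tail = FALSE))
    data.frame(group = g, gene = rownames(x), mean_diff = mg - mr,
               t = tt, p = p, q = p.adjust(p, "BH"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## ---- vectorized negative-binomial GLM across genes -------------------------

# Batched solve of p x p weighted normal equations via Cramer's rule
# (p = 2 or 3). S: list of crossproduct vectors over genes.
.batch_solve <- function(S, Tv, p) {
  if (p == 2L) {
    det <- S[["11"]] * S[["22"]] - S[["12"]]^2
    b1 <- (Tv[[1]] * S[["22"]] - Tv[[2]] * S[["12"]]) / det
    b2 <- (S[["11"]] * Tv[[2]] - S[["12"]] * Tv[[1]]) / det
    rbind(b1, b2)
  } else if (p == 3L) {
    a <- S[["11"]]; b <- S[["12"]]; c <- S[["13"]]
    d <- S[["22"]]; e <- S[["23"]]; f <- S[["33"]]
    det <- a * (d * f - e^2) - b * (b * f - c * e) + c * (b * e - c * d)
    i11 <- d * f - e^2; i12 <- c * e - b * f; i13 <- b * e - c * d
    i22 <- a * f - c^2; i23 <- b * c - a * e; i33 <- a * d - b^2
    b1 <- (i11 * Tv[[1]] + i12 * Tv[[2]] + i13 * Tv[[3]]) / det
    b2 <- (i12 * Tv[[1]] + i22 * Tv[[2]] + i23 * Tv[[3]]) / det
    b3 <- (i13 * Tv[[1]] + i23 * Tv[[2]] + i33 * Tv[[3]]) / det
    rbind(b1, b2, b3)
  } else stop2("batched solver supports p = 2 or 3", "invalid_argument")
}

# Diagonal of (X'WX)^{-1} for SEs, same Cramer quantities.
.batch_inv_diag <- function(S, p) {
  if (p == 2L) {
    det <- S[["11"]] * S[["22"]] - S[["12"]]^2
    rbind(S[["22"]] / det, S[["11"]] / det)
  } else {
    a <- S[["11"]]; b <- S[["12"]]; c <- S[["13"]]
    d <- S[["22"]]; e <- S[["23"]]; f <- S[["33"]]
    det <- a * (d * f - e^2) - b * (b * f - c * e) + c * (b * e - c * d)
    rbind((d * f - e^2) / det, (a * f - c^2) / det, (a * d - b^2) / det)
  }
}

# IRLS for log-link NB regression, vectorized across genes.
# Y: n x G dense counts; X: n x p design; offset: length n; theta: length G
# (Inf-like values give the Poisson limit). Returns coef (p x G), se,
# loglik, converged.
.nb_irls <- function(Y, X, offset, theta, max_iter = 50L, tol = 1e-8) {
  n <- nrow(Y); G <- ncol(Y); p <- ncol(X)
  pairs <- list(); nm <- character(0)
  for (a in seq_len(p)) for (b in a:p) {
    pairs[[length(pairs) + 1L]] <- X[, a] * X[, b]
    nm <- c(nm, paste0(a, b))
  }
  XP <- do.call(cbind, pairs); colnames(XP) <- nm

  mu <- (Y + colMeans(Y)[col(Y)]) / 2 + 0.1
  eta <- log(mu)
  B <- matrix(0, p, G)
  converged <- rep(FALSE, G)
  diverged <- rep(FALSE, G)
  th <- matrix(theta, n, G, byrow = TRUE)
  active <- seq_len(G)                       # genes still iterating
  for (it in seq_len(max_iter)) {
    full <- length(active) == G
    Ya <- if (full) Y else Y[, active, drop = FALSE]
    mua <- if (full) mu else mu[, active, drop = FALSE]
    tha <- if (full) th else th[, active, drop = FALSE]
    etaa <- if (full) eta else eta[, active, drop = FALSE]
    W <- mua / (1 + mua / tha)
    Z <- (etaa - offset) + (Ya - mua) / mua
    Sm <- crossprod(XP, W)                   # (p(p+1)/2) x G in one BLAS call
    S <- setNames(lapply(seq_len(nrow(Sm)), function(j) Sm[j, ]), nm)
    Tm <- crossprod(X, W * Z)
    Tv <- lapply(seq_len(p), function(a) Tm[a, ])
    B_new <- .batch_solve(S, Tv, p)
    bad <- !is.finite(colSums(B_new))
    if (any(bad)) B_new[, bad] <- B[, active[bad]]
    # coefficient-stability convergence (equivalent at the fitted optimum to
    # a deviance-change criterion, and far cheaper than a likelihood pass)
    done <- colSums(abs(B_new - B[, active, drop = FALSE])) <
      tol * (1 + colSums(abs(B[, active, drop = FALSE])))
    B[, active] <- B_new
    eta_new <- offset + X %*% B_new
    eta_new[eta_new > 30] <- 30               # guard against overflow
    eta[, active] <- eta_new
    mu[, active] <- exp(eta_new)
    converged[active[done]] <- TRUE
    diverged[active] <- bad
    active <- active[!(done | bad)]
    if (!length(active)) break
  }
  W <- mu / (1 + mu / th)
  Sm <- crossprod(XP, W)
  S <- setNames(lapply(seq_len(nrow(Sm)), function(j) Sm[j, ]), nm)
  se <- sqrt(.batch_inv_diag(S, p))
  list(coef = B, se = se, loglik = .nb_loglik(Y, mu, th), mu = mu,
       converged = converged & !diverged & is.finite(colSums(B)))
}

.nb_loglik <- function(Y, mu, th) {
  # mu > 0 always (log link), so Y * log(mu / (th + mu)) is 0 when Y = 0
  colSums(lgamma(Y + th) - lgamma(th) - lgamma(Y + 1) +
            th * log(th / (th + mu)) + Y * log(mu / (th + mu)))
}

# Method-of-moments dispersion from a Poisson-limit fit.
.mom_theta <- function(Y, mu) {
  num <- colSums(mu^2)
  den <- colSums((Y - mu)^2 - mu)
  th <- ifelse(den <= 0, 1e6, num / den)
  clamp(th, 0.01, 1e6)
}

#' Two-stage macula-vs-periphery differential expression
#'
#' Stage 1: per gene, a negative-binomial log-link regression with a
#' log-total-count offset and Location as the sole covariate; a two-sided
#' Wald test on the Location coefficient (the normalized effect, natural-log
#' scale). A gene passes if \code{q < q_thresh}, \code{|effect| >
#' effect_thresh}, and it is detected in more than \code{min_cells_detected}
#' cells. Stage 2: NB fits of the full (Location + Age) versus reduced (Age)
#' model compared by a 1-df likelihood ratio test, passing at \code{q <
#' q_thresh}. The final DEG set is the intersection of the two stages.
#' Dispersion is a per-gene method-of-moments estimate from a Poisson-limit
#' fit, shared by all models of that gene. Non-converged genes are flagged
#' and excluded from both stages. q-values are computed over the
#' abundance-passing, converged genes.
#'
#' @param counts Raw genes x cells counts (sparse or dense).
#' @param cells Cell table with \code{location} (macula/periphery) and
#'   \code{age_days}; single major class expected.
#' @param q_thresh,effect_thresh,min_cells_detected Thresholds (defaults
#'   0.01, 1, 2000 cells).
#' @return data.frame per gene: \code{gene}, \code{n_detected},
#'   \code{effect}, \code{p_wald}, \code{q_wald}, \code{p_lrt},
#'   \code{q_lrt}, \code{abundance_pass}, \code{wald_pass},
#'   \code{lrt_pass}, \code{converged}, \code{final_deg}; attribute
#'   \code{"n_nonconverged"}.
#' @export
location_deg <- function(counts, cells, q_thresh = 0.01, effect_thresh = 1,
                         min_cells_detected = 2000L) {
  stopifnot(nrow(cells) == ncol(counts))
  if (!all(c("macula", "periphery") %in% cells$location))
    stop2("both locations must be present", "invalid_argument")
  st <- counts_state(counts) %||% "raw"
  if (st != "raw") stop2("location_deg expects raw counts", "invalid_state")

  genes <- rownames(counts)
  n_detected <- as.integer(Matrix::rowSums(counts > 0))
  abundance_pass <- n_detected > min_cells_detected
  offset <- log(pmax(Matrix::colSums(counts), 1))
  loc <- as.numeric(cells$location == "macula")
  age <- as.numeric(cells$age_days)

  res <- data.frame(gene = genes, n_detected = n_detected,
                    effect = NA_real_, p_wald = NA_real_, q_wald = NA_real_,
                    p_lrt = NA_real_, q_lrt = NA_real_,
                    abundance_pass = abundance_pass,
                    wald_pass = FALSE, lrt_pass = FALSE,
                    converged = NA, stringsAsFactors = FALSE)

  fit_idx <- which(abundance_pass)
  n_noncv <- 0L
  if (length(fit_idx)) {
    block <- 400L
    X1 <- cbind(1, loc)
    Xf <- cbind(1, loc, scale(age, scale = FALSE))
    Xr <- cbind(1, scale(age, scale = FALSE))
    for (s in seq(1L, length(fit_idx), by = block)) {
      ii <- fit_idx[s:min(s + block - 1L, length(fit_idx))]
      Y <- t(as_dense(counts[ii, , drop = FALSE]))
      pois <- .nb_irls(Y, X1, offset, rep(1e6, length(ii)), max_iter = 10L,
                       tol = 1e-4)
      theta <- .mom_theta(Y, pois$mu)
      f1 <- .nb_irls(Y, X1, offset, theta)
      ff <- .nb_irls(Y, Xf, offset, theta)
      fr <- .nb_irls(Y, Xr, offset, theta)
      cv <- f1$converged & ff$converged & fr$converged
      res$converged[ii] <- cv
      res$effect[ii] <- f1$coef[2L, ]
      z <- f1$coef[2L, ] / f1$se[2L, ]
      res$p_wald[ii] <- 2 * pnorm(-abs(z))
      lr <- pmax(2 * (ff$loglik - fr$loglik), 0)
      res$p_lrt[ii] <- pchisq(lr, df = 1L, lower.tail = FALSE)
    }
    usable <- which(res$abundance_pass & res$converged %in% TRUE)
    n_noncv <- sum(res$abundance_pass & !(res$converged %in% TRUE))
    res$q_wald[usable] <- p.adjust(res$p_wald[usable], "BH")
    res$q_lrt[usable] <- p.adjust(res$p_lrt[usable], "BH")
    res$wald_pass <- !is.na(res$q_wald) & res$q_wald < q_thresh &
      abs(res$effect) > effect_thresh
    res$lrt_pass <- !is.na(res$q_lrt) & res$q_lrt < q_thresh
  }
  res$final_deg <- res$abundance_pass & res$wald_pass & res$lrt_pass
  attr(res, "n_nonconverged") <- n_noncv
  res
}
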
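#' Estimate per-group Gaussian birth-rate curves
#'
#' Fits, for each cell group (major class or inferred fate), a Gaussian over
#' age by method of moments -- \code{mu} and \code{sigma} are the mean and
#' standard deviation of the member cells' ages -- and scales the density by
#' the group's share of cells, so each curve's analytic integral equals the
#' group proportion and the curves integrate to 1 over groups. To counteract
#' sample-size variation, at most \code{n_downsample} cells are drawn without
#' replacement from every sample (a (location, age) collection unit); smaller
#' samples are used in full.
#'
#' @param cells Cell table with \code{age_days} and \code{location}.
#' @param groups Group label per cell (default \code{cells$major_class});
#'   cells with \code{NA} group are excluded entirely, including from the
#'   proportion denominator.
#' @param location Optional filter: keep only cells at this location.
#' @param n_downsample Per-sample cap (default 20000).
#' @param seed Optional seed for the downsampling draw.
#' @return Object of class \code{birth_curves}: a data.frame with
#'   \code{group}, \code{location}, \code{mu}, \code{sigma},
#'   \code{proportion}, \code{n_cells}. Groups with fewer than 2 cells are
#'   omitted with a warning (no defined sd).
#' @export
estimate_birth_curves <- function(cells, groups = cells$major_class,
                                  location = NULL, n_downsample = 20000L,
                                  seed = NULL) {
  stopifnot(length(groups) == nrow(cells))
  keep <- !is.na(groups)
  cells <- cells[keep, , drop = FALSE]
  groups <- as.character(groups[keep])
  if (!is.null(location)) {
    j <- cells$location == location
    if (!any(j)) stop2(paste("no cells at location", location), "empty_location")
    cells <- cells[j, , drop = FALSE]
    groups <- groups[j]
  }
  if (!is.null(seed)) set.seed(seed)
  sample_id <- paste(cells$location, cells$age_days, sep = "@")
  take <- unlist(lapply(split(seq_len(nrow(cells)), sample_id), function(ix) {
    if (length(ix) > n_downsample) sample(ix, n_downsample) else ix
  }), use.names = FALSE)
  age <- cells$age_days[take]
  grp <- groups[take]
  loc_lab <- location %||% "all"

  tab <- table(grp)
  res <- lapply(names(tab), function(g) {
    a <- age[grp == g]
    if (length(a) < 2L) {
      warning("group '", g, "' has fewer than 2 cells; curve omitted")
      return(NULL)
    }
    data.frame(group = g, location = loc_lab, mu = mean(a), sigma = sd(a),
               proportion = length(a) / length(age), n_cells = length(a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    stop2("no group with at least 2 cells", "degenerate_groups")
  structure(out, class = c("birth_curves", "data.frame"))
}

#' Birth-rate curves for inferred progenitor fates
#'
#' Applies the birth-curve estimator with cells grouped by inferred fate;
#' cells whose fate is undetermined (\code{NA}) are excluded from the fit and
#' from the proportion denominator.
#'
#' @param cells Cell table of the progenitor population.
#' @param fate Inferred fate per cell (\code{NA} = undetermined).
#' @inheritParams estimate_birth_curves
#' @return A \code{birth_curves} object.
#' @export
fate_birth_curves <- function(cells, fate, location = NULL,
                              n_downsample = 20000L, seed = NULL) {
  estimate_birth_curves(cells, groups = fate, location = location,
                        n_downsample = n_downsample, seed = seed)
}

#' Evaluate fitted birth curves on an age grid
#'
#' @param object A \code{birth_curves} fit.
#' @param t Ages (days) at which to evaluate.
#' @return Matrix (groups x ages) of \code{proportion * dnorm(t, mu, sigma)}.
#' @export
birth_curve_values <- function(object, t) {
  stopifnot(inherits(object, "birth_curves"))
  out <- t(vapply(seq_len(nrow(object)), function(i)
    object$proportion[i] * dnorm(t, object$mu[i], object$sigma[i]),
    numeric(length(t))))
  rownames(out) <- object$group
  out
}

#' @export
print.birth_curves <- function(x, ...) {
  cat("Gaussian birth curves (", nrow(x), " groups, location = ",
      x$location[1], "):\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.birth_curves <- function(x, t = NULL, ...) {
  if (is.null(t)) t <- seq(min(x$mu - 3 * x$sigma), max(x$mu + 3 * x$sigma),
                           length.out = 200)
  v <- birth_curve_values(x, t)
  graphics::matplot(t, t(v), type = "l", lty = 1, xlab = "age (days)",
                    ylab = "birth rate", ...)
  graphics::legend("topright", legend = x$group, col = seq_len(nrow(x)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
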
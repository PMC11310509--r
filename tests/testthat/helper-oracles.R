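# Independent oracles and shared fixtures for the test suite.

# Cache atlases across test files (generation is the expensive step).
.atlas_cache <- new.env(parent = emptyenv())

demo_atlas <- function(seed = 1L, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.atlas_cache[[key]]))
    .atlas_cache[[key]] <- generate_atlas(atlas_config(seed = seed, ...))
  .atlas_cache[[key]]
}

# Monte-Carlo absorption oracle: frequencies of random walks absorbed in each
# terminal set, independent of the linear-solve implementation.
mc_absorption <- function(T_, terminal_sets, start, n_walks = 1e5,
                          max_steps = 10000L) {
  T_ <- as.matrix(T_)
  n <- nrow(T_)
  term_fate <- integer(n)
  for (f in seq_along(terminal_sets)) term_fate[terminal_sets[[f]]] <- f
  state <- rep.int(start, n_walks)
  absorbed <- term_fate[state]
  for (step in seq_len(max_steps)) {
    live <- which(absorbed == 0L)
    if (!length(live)) break
    for (s in unique(state[live])) {
      idx <- live[state[live] == s]
      state[idx] <- sample.int(n, length(idx), replace = TRUE, prob = T_[s, ])
    }
    absorbed[live] <- term_fate[state[live]]
  }
  tab <- tabulate(absorbed, nbins = length(terminal_sets))
  tab / n_walks
}

# Random row-stochastic transition model on n cells with disjoint terminal
# sets; every state has positive mass everywhere, so terminals are reachable.
random_transition_model <- function(n, n_fates = 3L, seed = 1L) {
  set.seed(seed)
  T_ <- matrix(stats::runif(n * n), n, n)
  T_ <- T_ / rowSums(T_)
  sizes <- sample(2:4, n_fates, replace = TRUE)
  term <- split(seq_len(sum(sizes)), rep(seq_len(n_fates), sizes))
  names(term) <- paste0("fate", seq_len(n_fates))
  transition_model(as(T_, "CsparseMatrix"), term)
}

# Brute-force fractional-overlap oracle: count covered bases positionwise.
overlap_fraction_bruteforce <- function(q_start, q_end, r_starts, r_ends) {
  covered <- logical(q_end - q_start)
  for (i in seq_along(r_starts)) {
    lo <- max(q_start, r_starts[i]); hi <- min(q_end, r_ends[i])
    if (hi > lo) covered[(lo - q_start + 1):(hi - q_start)] <- TRUE
  }
  sum(covered) / (q_end - q_start)
}

# Build a vector with an exact Pearson correlation r against x.
vector_with_cor <- function(x, r, seed = 1L) {
  set.seed(seed)
  z <- stats::rnorm(length(x))
  z <- stats::residuals(stats::lm(z ~ x))
  xs <- (x - mean(x)) / stats::sd(x)
  zs <- (z - mean(z)) / stats::sd(z)
  r * xs + sqrt(1 - r^2) * zs
}

# Tiny MatrixMarket file writer for malformed/degenerate input tests.
write_mtx_text <- function(path, nrow, ncol, entries) {
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(nrow, ncol, nrow(entries)))
  if (nrow(entries))
    lines <- c(lines, apply(entries, 1L, paste, collapse = " "))
  writeLines(lines, path)
}
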
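test_that("latent-time correlation detection matches the exact Pearson test", {
  set.seed(3)
  n <- 1000
  t_ <- runif(n)
  x <- rbind(sig = t_ + rnorm(n, 0, 0.1),
             null = rnorm(n),
             const = rep(2, n))
  colnames(x) <- paste0("c", 1:n)
  res <- detect_correlated_genes(x, t_)
  expect_true(res$selected[res$gene == "sig"])
  expect_false(res$selected[res$gene == "const"])
  expect_true(is.na(res$r[res$gene == "const"]))
  # per-gene p equals cor.test's exact p
  for (g in c("sig", "null")) {
    ct <- cor.test(x[g, ], t_)
    expect_equal(res$p[res$gene == g], ct$p.value, tolerance = 1e-10)
    expect_equal(res$r[res$gene == g], unname(ct$estimate), tolerance = 1e-10)
  }
})

test_that("detection is calibrated under label permutation", {
  set.seed(11)
  n <- 300; g <- 200
  x <- matrix(rnorm(n * g), g, n, dimnames = list(paste0("g", 1:g), NULL))
  t_ <- runif(n)
  frac <- replicate(20, {
    res <- detect_correlated_genes(x, sample(t_))
    mean(res$selected)
  })
  expect_lte(mean(frac), 0.05)
})

test_that("planted modules are recovered and relabeled by trajectory peak", {
  at <- demo_atlas(seed = 4, n_cells = 3000)
  expr <- normalize_counts(at$counts, "log1p_cpm")
  lt <- at$cells$latent_time
  det <- detect_correlated_genes(expr, lt)
  expect_true(all(det$selected[match(
    names(at$truth$module)[at$truth$module != "none"], det$gene)]))
  sm <- smooth_expression(expr[det$gene[det$selected], ], lt, k = 50)
  mod <- group_modules(sm, det$gene[det$selected], K = 3,
                       min_gene_threshold = 10, latent_time = lt)
  g <- mod$genes
  tm <- at$truth$module[g$gene]
  planted <- tm != "none"
  # planted labels map one-to-one onto recovered labels, in temporal order
  expect_identical(unname(table(tm[planted], g$module[planted]) >= 29),
                   unname(diag(TRUE, 3)))
  # a gene uncorrelated with every module stays unassigned under core_only
  noise <- matrix(rnorm(ncol(sm)), 1, dimnames = list("noise", colnames(sm)))
  sm2 <- rbind(as.matrix(sm), noise)
  mod2 <- group_modules(sm2, c(g$gene, "noise"), K = 3, min_gene_threshold = 10,
                        latent_time = lt)
  expect_true(is.na(mod2$genes$module[mod2$genes$gene == "noise"]))
})

test_that("module grouping is deterministic and order-invariant", {
  at <- demo_atlas(seed = 4, n_cells = 3000)
  expr <- normalize_counts(at$counts, "log1p_cpm")
  lt <- at$cells$latent_time
  genes <- names(at$truth$module)[at$truth$module != "none"]
  sm <- smooth_expression(expr[genes, ], lt, k = 50)
  m1 <- group_modules(sm, genes, K = 3, min_gene_threshold = 5, latent_time = lt)
  m2 <- group_modules(sm, genes, K = 3, min_gene_threshold = 5, latent_time = lt)
  expect_identical(m1$genes, m2$genes)
  perm <- sample(length(genes))
  m3 <- group_modules(sm[perm, ], genes[perm], K = 3, min_gene_threshold = 5,
                      latent_time = lt)
  merged <- merge(m1$genes, m3$genes, by = "gene")
  expect_identical(merged$module.x, merged$module.y)
})

test_that("module scores equal first-PC loadings and are duplication-invariant", {
  set.seed(7)
  n <- 200
  x <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:n)))
  x[1:3, ] <- x[1:3, ] + rep(seq(0, 2, length.out = n), each = 3)
  s <- module_score(x, paste0("g", 1:5))
  # oracle: full PCA of the centered transpose
  pc1 <- prcomp(t(x - rowMeans(x)), center = FALSE)$x[, 1]
  expect_equal(abs(cor(s, pc1)), 1, tolerance = 1e-10)
  expect_equal(sd(s), 1, tolerance = 1e-10)

  # one-gene module: standardized expression of that gene (up to sign)
  s1 <- module_score(x, "g1")
  z <- as.numeric(scale(x["g1", ]))
  expect_equal(abs(cor(s1, z)), 1, tolerance = 1e-12)

  # duplicating the module genes leaves the score unchanged
  x2 <- rbind(x, x)
  rownames(x2) <- make.unique(rownames(x2))
  s2 <- module_score(x2, rownames(x2))
  expect_equal(as.numeric(s), as.numeric(s2), tolerance = 1e-10)

  # gene order invariance
  s3 <- module_score(x[5:1, ], paste0("g", 5:1))
  expect_equal(as.numeric(s), as.numeric(s3), tolerance = 1e-10)
})

test_that("expression-weighted time is the normalized-weight age average", {
  expect_equal(expression_weighted_time(c(0, 3, 0), c(80, 100, 120)), 100)
  expect_equal(expression_weighted_time(c(1, 1), c(80, 120)), 100)
  set.seed(2)
  e <- runif(10); a <- sample(50:150, 10)
  manual <- 0
  for (i in 1:10) manual <- manual + (e[i] / sum(e)) * a[i]
  expect_equal(expression_weighted_time(e, a), manual, tolerance = 1e-12)
  expect_warning(wt <- expression_weighted_time(c(0, 0), c(80, 120)), "zero")
  expect_true(is.na(wt))
})

test_that("latent-time tests detect a planted macular lead", {
  set.seed(13)
  n <- 2000
  cells <- data.frame(
    pcw_group = rep(c(10L, 15L, 20L), length.out = n),
    location = rep(c("macula", "periphery"), each = n / 2))
  base <- 0.04 * cells$pcw_group
  cells$latent_time <- pmin(pmax(
    base + ifelse(cells$location == "macula", 0.05, 0) + rnorm(n, 0, 0.05),
    0), 1)
  res <- latent_time_tests(cells)
  expect_gt(res$pearson$estimate, 0.5)
  expect_lt(res$pearson$p, 1e-10)
  expect_true(all(res$welch$mean_macula > res$welch$mean_periphery))
  expect_true(all(res$welch$p_adj < 0.05))

  # exact affine latent time gives correlation 1
  cells2 <- cells
  cells2$latent_time <- 0.03 * cells2$pcw_group
  res2 <- latent_time_tests(cells2)
  expect_equal(res2$pearson$estimate, 1, tolerance = 1e-12)
})

test_that("Welch p-values are uniform under the null", {
  set.seed(21)
  p <- replicate(100, {
    cells <- data.frame(pcw_group = 10L,
                        location = rep(c("macula", "periphery"), each = 40),
                        latent_time = runif(80, 0.3, 0.7))
    latent_time_tests(cells)$welch$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("groups missing a location are skipped and reported", {
  cells <- data.frame(pcw_group = rep(c(10L, 12L), each = 30),
                      location = c(rep("macula", 30), rep(c("macula", "periphery"), 15)),
                      latent_time = runif(60))
  res <- latent_time_tests(cells)
  expect_true(res$welch$skipped[res$welch$pcw_group == 10])
  expect_false(res$welch$skipped[res$welch$pcw_group == 12])
})
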
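test_that("velocity kernel matches a scalar cosine-softmax recomputation", {
  set.seed(10)
  n <- 50; d <- 4; k <- 6
  emb <- matrix(rnorm(n * d), n, d)
  vel <- matrix(rnorm(n * d), n, d)
  T_ <- velocity_kernel(emb, vel, k = k, tau = 1)
  expect_equal(max(abs(Matrix::rowSums(T_) - 1)), 0, tolerance = 1e-12)
  for (i in c(1, 17, 50)) {
    d2 <- colSums((t(emb) - emb[i, ])^2); d2[i] <- Inf
    nb <- order(d2)[1:k]
    cosv <- sapply(nb, function(j) {
      disp <- emb[j, ] - emb[i, ]
      sum(disp * vel[i, ]) / (sqrt(sum(disp^2)) * sqrt(sum(vel[i, ]^2)))
    })
    w <- exp(cosv); w <- w / sum(w)
    expect_equal(as.numeric(T_[i, nb]), as.numeric(w), tolerance = 1e-10)
    expect_equal(sum(T_[i, -nb]), 0)
  }
})

test_that("velocity kernel limits: aligned neighbor at small tau, zero velocity", {
  emb <- rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  vel <- rbind(c(1, 0), c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  T_ <- expect_silent(velocity_kernel(emb, vel, k = 4, tau = 0.01))
  expect_gt(T_[1, 2], 0.999)            # mass concentrates on the aligned neighbor
  expect_equal(as.numeric(T_[2, ])[-2], rep(0.25, 4))  # zero velocity -> uniform
  expect_identical(attr(T_, "n_zero_velocity"), 4L)
  # orthogonal velocity: symmetric neighbors get equal mass
  vel2 <- rbind(c(0, 1), vel[-1, ])
  T2 <- velocity_kernel(emb, vel2, k = 4, tau = 1)
  expect_equal(T2[1, 2], T2[1, 4], tolerance = 1e-12)
})

test_that("kernel combination is the stated convex mixture", {
  set.seed(2)
  emb <- matrix(rnorm(40), 20, 2)
  vel <- matrix(rnorm(40), 20, 2)
  Tv <- velocity_kernel(emb, vel, k = 5)
  Tc <- connectivity_kernel(emb, k = 5)
  expect_identical(as.matrix(combine_kernels(Tv, Tc, w_vel = 1)), as.matrix(Tv))
  Tm <- combine_kernels(Tv, Tc, w_vel = 0.8)
  expect_equal(as.matrix(Tm), 0.8 * as.matrix(Tv) + 0.2 * as.matrix(Tc),
               tolerance = 1e-12)
  expect_lt(max(abs(Matrix::rowSums(Tm) - 1)), 1e-9)
  expect_error(combine_kernels(Tv[1:10, 1:10], Tc), class = "shape_mismatch")
})

test_that("absorption probabilities: absorbing, symmetric, and MC-checked cases", {
  # terminal cells keep probability 1 for their own fate
  m <- random_transition_model(30, 2, seed = 5)
  B <- absorption_probabilities(m)
  for (f in names(m$terminal_sets)) {
    expect_true(all(B[m$terminal_sets[[f]], f] == 1))
  }
  expect_lt(max(abs(rowSums(B) - 1)), 1e-6)
  expect_true(all(B >= -1e-12 & B <= 1 + 1e-12))

  # symmetric 5-state chain equidistant between two fates -> 0.5 / 0.5
  T5 <- rbind(c(0, .5, 0, .5, 0),     # A: half back to middle, half to left
              c(.5, 0, .5, 0, 0),     # middle
              c(0, .5, 0, 0, .5),     # B: mirror of A
              c(0, 0, 0, 1, 0),
              c(0, 0, 0, 0, 1))
  mod5 <- transition_model(methods::as(T5, "CsparseMatrix"),
                           list(left = 4L, right = 5L))
  B5 <- absorption_probabilities(mod5)
  expect_equal(as.numeric(B5[2, ]), c(0.5, 0.5), tolerance = 1e-10)

  # Monte-Carlo oracle on the same toy chain
  mc <- mc_absorption(T5, mod5$terminal_sets, start = 2L, n_walks = 1e5)
  expect_lt(max(abs(as.numeric(B5[2, ]) - mc)), 0.01)
})

test_that("unreachable transient cells are flagged, not zeroed", {
  T_ <- rbind(c(0.5, 0.5, 0, 0),
              c(0.5, 0.5, 0, 0),
              c(0, 0, 0.2, 0.8),
              c(0, 0, 0, 1))
  mod <- transition_model(methods::as(T_, "CsparseMatrix"), list(f = 4L))
  expect_warning(B <- absorption_probabilities(mod), "unreachable|cannot reach")
  expect_true(all(is.na(B[1:2, ])))
  expect_equal(as.numeric(B[3, ]), 1)
  expect_identical(length(attr(B, "unreachable")), 2L)
})

test_that("cluster fate assignment follows the threshold rule and flags ties", {
  B <- rbind(c(0.9, 0.05, 0.05),
             c(0.34, 0.33, 0.33),
             c(0.5, 0.5, 0))
  colnames(B) <- c("Rod", "AC", "BC")
  rownames(B) <- paste0("c", 1:3)
  af <- assign_cluster_fates(B, clusters = c("k1", "k2", "k3"), threshold = 0.5)
  expect_identical(af$clusters$fate, c("Rod", NA, "AC"))  # tie -> lexicographic
  expect_identical(af$clusters$tie, c(FALSE, FALSE, TRUE))
  expect_identical(unname(af$cell_fate), c("Rod", NA, "AC"))
})

test_that("planted progenitor fates are recovered through the full kernel chain", {
  at <- demo_atlas(seed = 2, n_cells = 2500)
  fates <- sort(unique(stats::na.omit(at$truth$fate)))
  ts <- terminal_sets_by_rule(at$cells, fates)
  Tm <- combine_kernels(velocity_kernel(at$embedding, at$velocities, k = 30),
                        connectivity_kernel(at$embedding, k = 30), 0.8)
  B <- absorption_probabilities(transition_model(Tm, ts, 0.8))
  expect_lt(max(abs(rowSums(B) - 1)), 1e-6)
  nrpc <- which(at$cells$major_class == "NRPC")
  truth <- at$truth$fate[nrpc]
  af <- assign_cluster_fates(B[nrpc, ], truth, threshold = 0.5)
  expect_gt(mean(!is.na(af$cell_fate) & af$cell_fate == truth), 0.95)
  # fate assignment is invariant to uniform scaling of the embedding
  Tm2 <- combine_kernels(velocity_kernel(3 * at$embedding, at$velocities, k = 30),
                         connectivity_kernel(3 * at$embedding, k = 30), 0.8)
  expect_equal(as.matrix(Tm2), as.matrix(Tm), tolerance = 1e-9)
})

test_that("TF specification prediction recovers the planted map and flags edge cases", {
  at <- demo_atlas(seed = 2, n_cells = 2500)
  nrpc <- which(at$cells$major_class == "NRPC")
  expr <- normalize_counts(at$counts, "log1p_cpm")[, nrpc]
  tfs <- names(at$truth$tf_map)
  pred <- predict_tf_specification(expr, at$truth$fate[nrpc], tfs)
  expect_identical(pred$predicted_class, unname(unlist(at$truth$tf_map)[pred$tf]))

  zero <- expr; zero[tfs[1], ] <- 0
  p0 <- predict_tf_specification(zero, at$truth$fate[nrpc], tfs[1])
  expect_true(p0$all_zero)
  expect_true(is.na(p0$predicted_class))
  expect_error(predict_tf_specification(expr, at$truth$fate[nrpc], "NOPE"),
               class = "missing_gene")
})

test_that("prediction validation counts matches as the published table does", {
  v <- validate_tf_predictions(annotation = table1_fixture())
  expect_identical(v$n_matched, 22L)
  expect_identical(v$n_unmatched, 10L)
  expect_identical(v$n_unknown, 63L)
  expect_equal(v$match_rate, 68.75)

  ann <- data.frame(tf = c("A", "B"), predicted_class = c("Rod", "AC"),
                    literature_classes = c(NA, NA))
  expect_true(is.na(validate_tf_predictions(annotation = ann)$match_rate))
  ann2 <- data.frame(tf = c("A", "B"), predicted_class = c("Rod", "AC"),
                     literature_classes = c("Rod", "BC"))
  expect_equal(validate_tf_predictions(annotation = ann2)$match_rate, 50)
})
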
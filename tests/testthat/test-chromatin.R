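test_that("DAR calls recover planted class-specific peaks at the stated gates", {
  set.seed(4)
  classes <- rep(c("Rod", "BC", "AC"), each = 5)
  acc <- matrix(rnorm(30 * 15, 2, 0.3), 30, 15,
                dimnames = list(sprintf("p%02d", 1:30), NULL))
  acc[1:5, classes == "Rod"] <- acc[1:5, classes == "Rod"] + 2   # 4x accessibility
  res <- call_dars(acc, classes)
  rod <- res[res$class == "Rod", ]
  expect_true(all(rod$is_dar[1:5]))
  expect_false(any(res$is_dar[!(res$class == "Rod" & res$peak_id %in%
                                  sprintf("p%02d", 1:5))]))
  # exact small-n enumeration oracle for one planted peak
  a <- acc[1, classes == "Rod"]; b <- acc[1, classes != "Rod"]
  ranks <- rank(c(a, b)); w <- sum(ranks[1:5]) - 5 * 6 / 2
  combos <- utils::combn(15, 5)
  null_w <- apply(combos, 2, function(ix) sum(rank(c(a, b))[ix]) - 15)
  p_manual <- mean(null_w >= w)
  expect_equal(rod$p[1], p_manual, tolerance = 1e-10)

  # identical accessibility yields no DARs
  flat <- matrix(2, 10, 15, dimnames = list(sprintf("f%02d", 1:10), NULL))
  expect_true(all(!suppressWarnings(call_dars(flat, classes))$is_dar))

  # fold-change gate: strong p but log2FC 0.5 is not a DAR
  acc2 <- matrix(rnorm(2 * 40, 2, 0.05), 2, 40,
                 dimnames = list(c("x1", "x2"), NULL))
  cls2 <- rep(c("A", "B"), each = 20)
  acc2[1, cls2 == "A"] <- acc2[1, cls2 == "A"] + 0.5
  r2 <- call_dars(acc2, cls2, focal = "A")
  expect_lt(r2$p[1], 1e-6)
  expect_false(r2$is_dar[1])
})

test_that("overlap classification agrees with brute-force base counting", {
  # identical, disjoint, and the inclusive 20% boundary
  q <- data.frame(contig = "c1", start = c(0L, 200L, 400L),
                  end = c(100L, 300L, 500L),
                  peak_id = c("same", "apart", "edge"))
  r <- data.frame(contig = "c1", start = c(0L, 1000L, 480L),
                  end = c(100L, 1100L, 600L),
                  peak_id = c("r1", "r2", "r3"))
  res <- classify_overlap(q, r)
  expect_identical(res$status, c("overlapping", "specific", "overlapping"))
  expect_identical(res$overlap_bases[3], 20L)   # exactly 20% of 100 bp

  set.seed(12)
  n <- 1000
  qs <- sample(0:5000, n, TRUE); qw <- sample(20:200, n, TRUE)
  rs <- sample(0:5000, 300, TRUE); rw <- sample(20:200, 300, TRUE)
  query <- data.frame(contig = "c1", start = qs, end = qs + qw,
                      peak_id = sprintf("q%04d", 1:n))
  ref <- data.frame(contig = "c1", start = rs, end = rs + rw,
                    peak_id = sprintf("r%04d", 1:300))
  res <- classify_overlap(query, ref)
  frac_bf <- vapply(seq_len(n), function(i)
    overlap_fraction_bruteforce(qs[i], qs[i] + qw[i], rs, rs + rw), numeric(1))
  expect_equal(res$frac, frac_bf, tolerance = 1e-12)
  expect_identical(res$status, ifelse(frac_bf >= 0.2, "overlapping", "specific"))
})

test_that("peak-gene links respect the window and the inclusive r floor", {
  set.seed(6)
  units <- 30
  expr <- matrix(rnorm(2 * units, 3, 1), 2, units,
                 dimnames = list(c("gNear", "gFar"), paste0("u", 1:units)))
  anchors <- data.frame(gene = c("gNear", "gFar"), contig = "c1",
                        anchor = c(1000000L, 5000000L))
  e <- expr["gNear", ]
  acc <- rbind(
    at_floor   = vector_with_cor(e, 0.45, seed = 1),
    below      = vector_with_cor(e, 0.449, seed = 2),
    strong_far = as.numeric(scale(expr["gFar", ])))
  peaks <- data.frame(
    contig = "c1",
    start = c(1100000L, 1150000L, 5300001L),
    end = c(1100500L, 1150500L, 5300501L),
    peak_id = rownames(acc))
  colnames(acc) <- paste0("u", 1:units)
  links <- link_peaks_to_genes(acc, expr, peaks, anchors)
  expect_true(any(links$peak_id == "at_floor" & links$gene == "gNear"))
  expect_false("below" %in% links$peak_id)
  expect_false("strong_far" %in% links$peak_id)  # r ~ 1 but 300 kb away
  expect_true(all(links$distance_bp <= 250000))
  expect_true(all(links$pearson_r >= 0.45))
  expect_error(link_peaks_to_genes(acc, expr, peaks, anchors[1, ]),
               class = "missing_anchor")
})

test_that("atlas peak-gene links recover the planted pairs and only those", {
  at <- demo_atlas(seed = 5, n_cells = 3000)
  links <- link_peaks_to_genes(at$peak_acc, at$pseudobulk$expr, at$peaks,
                               at$gene_anchors)
  planted <- paste(names(at$truth$peak_link), unlist(at$truth$peak_link))
  found <- paste(links$peak_id, links$gene)
  expect_true(all(planted %in% found))
  expect_true(all(links$distance_bp <= 250000))
  expect_true(all(links$pearson_r >= 0.45))
})

test_that("phase segmentation handles the canonical trajectories", {
  grid <- seq(0, 1, length.out = 41)
  seg_up <- segment_phases(0.2 + 0.7 * grid, 0.3 + 0.6 * grid, grid)
  expect_equal(unname(seg_up$percentages["coupled_on"]), 100)
  expect_equal(sum(seg_up$percentages), 100)

  seg_primed <- segment_phases(0.8 + 0.2 * grid, rep(0, 41), grid)
  expect_equal(unname(seg_primed$percentages["primed"]), 100)

  seg_dec <- segment_phases(1 - 0.5 * grid, 0.9 - 0.5 * grid, grid)
  expect_equal(unname(seg_dec$percentages["coupled_off"]), 100)

  expect_error(segment_phases(c(1, 2), c(1, 2)), class = "invalid_argument")
})

test_that("planted piecewise phase boundaries are recovered within one step", {
  n <- 41
  grid <- seq(0, 1, length.out = n)
  # chromatin opens early (primed), both rise (coupled_on), chromatin falls
  # while expression still rises (decoupled), then both fall (coupled_off)
  q1 <- 11; q2 <- 21; q3 <- 31
  c_ <- c(seq(0.75, 1, length.out = q1),
          seq(1, 1.4, length.out = q2 - q1),
          seq(1.4, 1.0, length.out = q3 - q2),
          seq(1.0, 0.4, length.out = n - q3))
  s <- c(rep(0, q1),
         seq(0.05, 0.6, length.out = q2 - q1),
         seq(0.6, 0.9, length.out = q3 - q2),
         seq(0.9, 0.2, length.out = n - q3))
  seg <- segment_phases(c_, s, grid)
  phase <- as.character(seg$phase)
  boundary <- function(ph) min(which(phase == ph))
  expect_lte(abs(boundary("coupled_on") - (q1 + 1)), 1)
  expect_lte(abs(boundary("decoupled") - (q2 + 1)), 1)
  expect_lte(abs(boundary("coupled_off") - (q3 + 1)), 1)
  expect_true(all(phase[1:(q1 - 1)] == "primed"))
  expect_equal(sum(seg$percentages), 100)

  # percentages are invariant to uniform rescaling of either trajectory
  seg_scaled <- segment_phases(10 * c_, 0.2 * s, grid)
  expect_identical(seg$phase, seg_scaled$phase)
})

test_that("phase summaries average per class and compare gene sets", {
  grid <- seq(0, 1, length.out = 21)
  up <- segment_phases(0.2 + 0.7 * grid, 0.3 + 0.6 * grid, grid)
  segs <- list(g1 = up, g2 = up)
  ps <- phase_summaries(segs, c("Rod", "Rod"))
  expect_equal(unname(unlist(ps$summary[1, c("primed", "coupled_on",
                                             "coupled_off", "decoupled")])),
               c(0, 100, 0, 0))
  one <- phase_summaries(segs[1], "Rod")
  expect_equal(unname(unlist(one$summary[1, -1])), unname(up$percentages))

  # planted 30% vs 70% coupled-on shares across 100 genes each
  set.seed(8)
  mk <- function(share) {
    k <- round(20 * share)
    c_ <- c(seq(0.1, 0.6, length.out = k + 1), seq(0.6, 0.1, length.out = 20 - k))
    s <- c(seq(0.1, 0.6, length.out = k + 1), seq(0.6, 0.1, length.out = 20 - k))
    segment_phases(c_, s, seq(0, 1, length.out = 21))
  }
  g30 <- lapply(1:100, function(i) mk(stats::rbeta(1, 30, 70)))
  g70 <- lapply(1:100, function(i) mk(stats::rbeta(1, 70, 30)))
  segs <- c(g30, g70)
  names(segs) <- paste0("g", seq_along(segs))
  ps2 <- phase_summaries(segs, rep(c("m1", "m3"), each = 100),
                         compare = list(paste0("g", 1:100), paste0("g", 101:200)))
  expect_lt(ps2$comparison$p, 1e-6)
  expect_lt(ps2$comparison$mean_1, ps2$comparison$mean_2)
})
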
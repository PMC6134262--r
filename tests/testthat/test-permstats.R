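test_that("pseudo-F on 1-D Euclidean data equals the classical ANOVA F", {
  x <- c(0, 1, 10, 11)
  g <- c("A", "A", "B", "B")
  D <- as.matrix(dist(x))
  r <- permanova(D, g)
  # hand ANOVA: SS_A = 100, SS_W = 1, df = (1, 2) -> F = 200
  expect_equal(r$F, 200, tolerance = 1e-10)
  expect_equal(r$r2, 100 / 101, tolerance = 1e-12)
  F_aov <- summary(stats::aov(x ~ factor(g)))[[1]]$`F value`[1]
  expect_equal(r$F, F_aov, tolerance = 1e-10)
  expect_identical(r$method, "exact")
})

test_that("exact enumeration agrees with a brute-force oracle over assignments", {
  x <- c(0, 1, 10, 11)
  g <- c("A", "A", "B", "B")
  D <- as.matrix(dist(x))
  oracle <- bruteforce_permanova(D, g)
  expect_equal(oracle$n_assignments, 6)
  r <- permanova(D, g, method = "exact")
  expect_equal(r$F, oracle$F, tolerance = 1e-12)
  expect_equal(r$p, oracle$p) # = 1/3: label-swapped assignment reaches F too

  # a second, asymmetric instance (groups 2 + 3)
  set.seed(11)
  y <- rnorm(5)
  g2 <- c("A", "A", "B", "B", "B")
  D2 <- as.matrix(dist(y))
  o2 <- bruteforce_permanova(D2, g2)
  r2 <- permanova(D2, g2, method = "exact")
  expect_equal(r2$F, o2$F, tolerance = 1e-12)
  expect_equal(r2$p, o2$p)
})

test_that("permanova matches vegan::adonis2 on F and r2", {
  set.seed(5)
  X <- matrix(rexp(12 * 30), 12, 30)
  g <- rep(c("a", "b", "c"), each = 4)
  D <- canberra_matrix(X)
  ours <- permanova(D, g, n_perm = 99)
  ref <- vegan::adonis2(as_dist(D) ~ g, permutations = 19)
  expect_equal(ours$F, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$r2, ref$R2[1], tolerance = 1e-10)
  expect_equal(ours$df_between, ref$Df[1])
})

test_that("permutation p-values are reproducible bit-for-bit given seed", {
  set.seed(8)
  X <- matrix(rexp(30 * 40), 30, 40)
  g <- rep(c("a", "b"), 15)
  D <- canberra_matrix(X)
  r1 <- permanova(D, g, n_perm = 199, seed = 7)
  r2 <- permanova(D, g, n_perm = 199, seed = 7)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$observed_ge_count, r2$observed_ge_count)
  expect_identical(r1$method, "monte_carlo")
  # +1/+1 convention: p never 0, consistent with the count
  expect_equal(r1$p, (r1$observed_ge_count + 1) / (199 + 1))
  expect_gt(r1$p, 0)
})

test_that("strata-restricted permutations preserve per-stratum label multisets", {
  strata <- rep(c("s1", "s2", "s3"), times = c(4, 3, 5))
  idx <- split(seq_along(strata), strata)
  set.seed(123)
  for (i in 1:200) {
    p <- psmtools:::.perm_within_strata(length(strata), idx)
    expect_identical(strata[p], strata) # every draw stays inside its stratum
    expect_identical(sort(p), seq_along(strata))
  }
})

test_that("exhaustive and Monte-Carlo modes agree within binomial error", {
  set.seed(31)
  y <- rnorm(7)
  g <- c("A", "A", "A", "B", "B", "B", "B")
  D <- as.matrix(dist(y))
  pe <- permanova(D, g, method = "exact")$p
  npm <- 4999
  pm <- permanova(D, g, n_perm = npm, seed = 2, method = "monte_carlo")$p
  se <- sqrt(pe * (1 - pe) / npm)
  expect_lt(abs(pm - pe), 4 * se + 1 / npm)
})

test_that("degenerate within-group geometry reports infinite F with a flag", {
  # two groups of coincident points, groups apart
  D <- as.matrix(dist(c(0, 0, 5, 5)))
  r <- permanova(D, c("A", "A", "B", "B"))
  expect_true(r$degenerate)
  expect_identical(r$F, Inf)
  expect_gt(r$p, 0)
  expect_error(permanova(D, rep("A", 4)), "2 groups")
})

test_that("strata restriction changes the permutation distribution", {
  # block-confounded signal: within-block shuffles only
  set.seed(13)
  blocks <- rep(paste0("b", 1:4), each = 4)
  g <- rep(c("t1", "t1", "t2", "t2"), 4)
  X <- matrix(rnorm(16 * 10), 16, 10) +
    matrix(rnorm(4 * 10, sd = 3)[rep(1:4, each = 4)], 16, 10)
  D <- as.matrix(dist(X))
  r_str <- permanova(D, g, strata = blocks, n_perm = 499, seed = 3)
  r_free <- permanova(D, g, n_perm = 499, seed = 3)
  expect_equal(r_str$F, r_free$F) # observed statistic identical
  expect_false(identical(r_str$p, r_free$p)) # null distribution differs
})

test_that("equal dispersions give F = 0 and the Euclidean no-op holds", {
  # group A = {(0,0),(2,0)}, B = {(10,0),(12,0)}: all distances to centroid 1
  P <- rbind(c(0, 0), c(2, 0), c(10, 0), c(12, 0))
  D <- as.matrix(dist(P))
  r <- permdisp(D, c("A", "A", "B", "B"), center_type = "centroid",
                n_perm = 99)
  expect_equal(unname(r$distances_to_center), rep(1, 4), tolerance = 1e-10)
  expect_equal(r$F, 0)
  # truly Euclidean D: z equals the plain distance to the group centroid
  set.seed(19)
  Q <- matrix(rnorm(16), 8, 2)
  gq <- rep(c("a", "b"), each = 4)
  rq <- permdisp(as.matrix(dist(Q)), gq, center_type = "centroid",
                 n_perm = 49)
  zdirect <- unlist(lapply(split(seq_len(8), gq), function(idx) {
    ctr <- colMeans(Q[idx, , drop = FALSE])
    sqrt(rowSums(sweep(Q[idx, , drop = FALSE], 2, ctr)^2))
  }))
  expect_equal(sort(unname(rq$distances_to_center)), sort(unname(zdirect)),
               tolerance = 1e-8)
})

test_that("clearly different dispersions are detected", {
  # points on a line: group A spread 1, group B spread 5
  x <- c(-1, -0.5, 0.5, 1, -5, -2.5, 2.5, 5)
  g <- rep(c("A", "B"), each = 4)
  D <- as.matrix(dist(x))
  r <- permdisp(D, g, center_type = "centroid", n_perm = 999, seed = 4)
  # hand ANOVA on known distances to centroid
  z <- abs(x)
  zm <- tapply(z, g, mean)
  ssb <- sum(4 * (zm - mean(z))^2)
  ssw <- sum((z - zm[g])^2)
  expect_equal(r$F, (ssb / 1) / (ssw / 6), tolerance = 1e-10)
  expect_gt(r$F, 0)
  expect_lt(r$p, 0.05)
})

test_that("permdisp agrees with vegan::betadisper", {
  set.seed(6)
  X <- matrix(rexp(14 * 20), 14, 20)
  g <- rep(c("a", "b"), each = 7)
  D <- canberra_matrix(X)
  bd <- vegan::betadisper(as_dist(D), g, type = "centroid")
  ours <- permdisp(D, g, center_type = "centroid", n_perm = 49)
  expect_equal(unname(ours$distances_to_center), unname(bd$distances),
               tolerance = 1e-8)
  expect_equal(ours$F, stats::anova(bd)$`F value`[1], tolerance = 1e-8)
  # spatial-median flavor: same geometry, different optimizer -> loose check
  bdm <- vegan::betadisper(as_dist(D), g, type = "median")
  ourm <- permdisp(D, g, center_type = "spatial_median", n_perm = 49)
  expect_equal(unname(ourm$distances_to_center), unname(bdm$distances),
               tolerance = 1e-4)
})

test_that("permdisp validates its preconditions", {
  D <- as.matrix(dist(1:5))
  expect_error(permdisp(D, c("a", "a", "a", "a", "b")), ">= 2 samples")
})

test_that("mean dissimilarity decomposition handles all documented cases", {
  # two singleton groups
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  md <- meandist_groups(D, c("g1", "g2"))
  expect_equal(md$m["g1", "g2"], 0.4)
  expect_true(all(is.na(diag(md$m))))
  expect_true(all(md$singleton))

  # identical points split into two labels: between = within = 0
  D0 <- matrix(0, 4, 4)
  md0 <- meandist_groups(D0, c("a", "a", "b", "b"))
  expect_equal(unname(md0$m), matrix(0, 2, 2))
  expect_false(any(md0$centroid_separation))

  # generator data with a pure centroid shift: between exceeds both withins
  des <- make_design(design_spec(list(cond = c("ref", "trt")), 8, blocks = 2))
  tr <- ground_truth(seed = 15, n_features_total = 400, shared_fraction = 0,
                     effects = list(trt = list(n_features = 80, delta = 4)),
                     block_sd = 0)
  sim <- simulate_tables(des, tr)
  D2 <- canberra_matrix(sim$positive)
  md2 <- meandist_groups(D2, sim$positive$samples$condition)
  expect_true(md2$centroid_separation["ref", "trt"])

  # cross-check against vegan::meandist
  ref <- vegan::meandist(as_dist(D2), sim$positive$samples$condition)
  ref_m <- matrix(as.numeric(ref), nrow(ref))
  expect_equal(unname(md2$m), ref_m, tolerance = 1e-12)
})
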
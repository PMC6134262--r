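test_that("shift classification uses inclusive +/- thresholds on group means", {
  # ref mean 100; condition means 180 (up), 24 (down), 150 (neither), 175 (up)
  X <- rbind(c(100, 100, 100, 100),
             c(100, 100, 100, 100),
             c(180, 24, 150, 175),
             c(180, 24, 150, 175))
  tbl <- make_table(X, c("ref", "ref", "trt", "trt"))
  sr <- shift_report(tbl, "ref")
  expect_equal(unname(sr$relative_change[, "trt"]), c(80, -76, 50, 75))
  expect_setequal(sr$up_sets$trt, c("f001", "f004")) # +75 inclusive
  expect_setequal(sr$down_sets$trt, "f002")
  expect_length(intersect(sr$up_sets$trt, sr$down_sets$trt), 0)
})

test_that("features undetected in the reference are routed aside", {
  X <- rbind(c(0, 10), c(0, 10), c(5, 30), c(7, 30))
  tbl <- make_table(X, c("ref", "ref", "trt", "trt"))
  sr <- shift_report(tbl, "ref")
  expect_equal(sr$undetected, "f001")
  expect_true(is.na(sr$relative_change["f001", "trt"]))
  expect_false("f001" %in% sr$up_sets$trt)
  expect_error(shift_report(tbl, "nope"), "unknown reference")
})

test_that("a single-condition table yields an empty report", {
  tbl <- make_table(matrix(5, 3, 2), rep("ref", 3))
  sr <- shift_report(tbl, "ref")
  expect_length(sr$conditions, 0)
  expect_null(sr$venn_up)
})

test_that("identical condition and reference distributions give zero change", {
  X <- rbind(c(10, 20), c(10, 20), c(10, 20), c(10, 20))
  tbl <- make_table(X, c("ref", "ref", "same", "same"))
  sr <- shift_report(tbl, "ref")
  expect_equal(unname(sr$relative_change[, "same"]), c(0, 0))
  expect_length(sr$up_sets$same, 0)
  expect_length(sr$down_sets$same, 0)
})

test_that("generator effect features land in the up set and means re-check", {
  des <- make_design(design_spec(list(cond = c("ref", "temp")), 10,
                                 blocks = 2))
  tr <- ground_truth(seed = 61, n_features_total = 200, shared_fraction = 1,
                     effects = list(temp = list(n_features = 40, delta = 2)),
                     noise_cv = 0.02, block_sd = 0, dropout_rate = 0)
  sim <- simulate_tables(des, tr)
  tb <- sim$positive
  sr <- shift_report(tb, "ref")
  eff <- paste0(sim$truth$effect_features$temp, "_P")
  expect_true(all(eff %in% sr$up_sets$temp)) # delta 2 = +100% >> +75%
  # independent recount of per-feature means
  is_t <- tb$samples$condition == "temp"
  rc_brute <- 100 * (colMeans(tb$intensities[is_t, ]) /
                       colMeans(tb$intensities[!is_t, ]) - 1)
  expect_equal(unname(sr$relative_change[, "temp"]), unname(rc_brute),
               tolerance = 1e-12)
})

test_that("venn regions agree with brute-force set algebra over 3 conditions", {
  set.seed(91)
  universe <- sprintf("m%03d", 1:60)
  sets <- list(a = sample(universe, 25), b = sample(universe, 20),
               c = sample(universe, 15))
  vr <- venn_regions(sets)
  expect_length(vr$counts, 7)
  expect_equal(sum(vr$counts), length(unique(unlist(sets))))
  # brute force every region
  inall <- function(x, inn, outn) {
    keep <- x
    for (s in inn) keep <- intersect(keep, sets[[s]])
    for (s in outn) keep <- setdiff(keep, sets[[s]])
    keep
  }
  nm <- names(sets)
  for (r in 1:7) {
    inn <- nm[as.logical(bitwAnd(r, c(1, 2, 4)))]
    expect_equal(unname(vr$counts[paste(inn, collapse = "&")]),
                 length(inall(universe, inn, setdiff(nm, inn))),
                 label = paste("region", paste(inn, collapse = "&")))
  }
})

test_that("degenerate and absent bootstrap cases follow the contract", {
  # zero-variance groups: CI collapses to the point estimate
  X <- matrix(c(rep(10, 3), rep(15, 3)), 6, 1)
  tbl <- make_table(X, rep(c("ref", "trt"), each = 3))
  bc <- bootstrap_contrast(tbl, "f001", "trt", "ref", n_boot = 200, seed = 5)
  expect_equal(bc$relative_change, 50)
  expect_equal(c(bc$ci_low, bc$ci_high), c(50, 50))
  expect_true(bc$significant)

  # condition group all zeros: the completely-absent case
  X2 <- matrix(c(rep(10, 3), rep(0, 3)), 6, 1)
  tbl2 <- make_table(X2, rep(c("ref", "trt"), each = 3))
  bc2 <- bootstrap_contrast(tbl2, "f001", "trt", "ref", n_boot = 200)
  expect_true(bc2$absent_flag)
  expect_equal(bc2$relative_change, -100)
  expect_equal(c(bc2$ci_low, bc2$ci_high), c(-100, -100))

  expect_error(bootstrap_contrast(tbl2, "zzz", "trt", "ref"), "not found")
  # reference undetected is a contract error
  X3 <- matrix(c(rep(0, 3), rep(5, 3)), 6, 1)
  tbl3 <- make_table(X3, rep(c("ref", "trt"), each = 3))
  expect_error(bootstrap_contrast(tbl3, "f001", "trt", "ref"), "undetected")
})

test_that("bootstrap CIs are seeded, ordered, and shrink with group size", {
  mk <- function(n, seed) {
    set.seed(seed)
    X <- matrix(c(rlnorm(n, 2, 0.4), rlnorm(n, 2 + log(2), 0.4)), 2 * n, 1)
    make_table(X, rep(c("ref", "trt"), each = n))
  }
  widths <- vapply(c(4, 16, 64), function(n) {
    bc <- bootstrap_contrast(mk(n, 7), "f001", "trt", "ref",
                             n_boot = 1000, seed = 3)
    expect_lte(bc$ci_low, bc$relative_change)
    expect_gte(bc$ci_high, bc$relative_change)
    bc$ci_high - bc$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # reproducible given the seed
  b1 <- bootstrap_contrast(mk(8, 7), "f001", "trt", "ref", n_boot = 500,
                           seed = 11)
  b2 <- bootstrap_contrast(mk(8, 7), "f001", "trt", "ref", n_boot = 500,
                           seed = 11)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
})
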
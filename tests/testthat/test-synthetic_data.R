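test_that("design expansion obeys the plot-count invariant and block balance", {
  ds <- design_spec(list(overstory = c("open", "closed"),
                         warming = c("ambient", "mod", "high"),
                         precip = c("ambient", "reduced")),
                    replicates_per_cell = 6, blocks = 3)
  d <- make_design(ds)
  expect_equal(length(unique(d$plot)), 72)
  expect_equal(nrow(d), 72) # one plant per plot by default
  # every plot in exactly one block; blocks balanced within each cell
  expect_true(all(tapply(d$block, d$plot, function(b) length(unique(b))) == 1))
  per_cell <- table(d$condition, d$block)
  expect_true(all(per_cell == 2)) # 6 replicates over 3 blocks

  # degenerate design: single factor, one level, one replicate
  d1 <- make_design(design_spec(list(f = "only"), 1))
  expect_equal(nrow(d1), 1)

  expect_error(design_spec(list(f = character(0)), 1), "zero levels")
})

test_that("plants_per_plot multiplies samples, not plots", {
  ds <- design_spec(list(cond = c("a", "b")), 2, blocks = 2,
                    plants_per_plot = 3)
  d <- make_design(ds)
  expect_equal(length(unique(d$plot)), 4)
  expect_equal(nrow(d), 12)
  expect_false(any(duplicated(d$sample_id)))
})

test_that("shared-fraction extremes produce the constructed overlap", {
  des <- make_design(design_spec(list(cond = c("x", "y")), 3, blocks = 3))

  sim0 <- simulate_tables(des, ground_truth(seed = 5, n_features_total = 60,
                                            shared_fraction = 0))
  m0 <- match_features(sim0$positive, sim0$negative)
  expect_equal(nrow(m0$pairs), 0)

  sim1 <- simulate_tables(des, ground_truth(seed = 5, n_features_total = 60,
                                            shared_fraction = 1,
                                            rt_jitter = 0))
  # every positive feature has exactly one negative partner at exactly
  # the polarity offset
  expect_equal(nrow(sim1$truth$shared_pairs), 60)
  dmass <- sim1$positive$features$mass - sim1$negative$features$mass
  expect_equal(dmass, rep(2.014552, 60), tolerance = 1e-12)
  m1 <- match_features(sim1$positive, sim1$negative)
  expect_equal(nrow(m1$pairs), 60)
  expect_equal(max(m1$pairs$mass_delta), 0, tolerance = 1e-9)
})

test_that("condition effect delta is recovered in group mean intensity ratios", {
  # delta = 3 on 100 of 2000 features; ratio of group means ~ 3 at n = 12/group
  des <- make_design(design_spec(list(cond = c("ref", "temp")), 12,
                                 blocks = 3))
  is_temp <- des$condition == "temp"
  ratios <- vapply(1:200, function(s) {
    tr <- ground_truth(seed = s, n_features_total = 2000, shared_fraction = 0,
                       effects = list(temp = list(n_features = 100, delta = 3)),
                       dropout_rate = 0)
    sim <- simulate_tables(des, tr)
    tb <- sim$positive
    fid <- intersect(paste0(sim$truth$effect_features$temp, "_P"),
                     tb$features$feature_id)
    fi <- match(fid, tb$features$feature_id)
    mean(colMeans(tb$intensities[is_temp, fi, drop = FALSE]) /
           colMeans(tb$intensities[!is_temp, fi, drop = FALSE]))
  }, numeric(1))
  expect_equal(mean(ratios), 3, tolerance = 0.02)
})

test_that("turnover toggles equal the requested presence changes absent dropout", {
  des <- make_design(design_spec(list(cond = c("ref", "trt")), 6, blocks = 3))
  tr <- ground_truth(seed = 9, n_features_total = 200, shared_fraction = 1,
                     turnover = list(trt = list(n_features = 40)),
                     dropout_rate = 0)
  sim <- simulate_tables(des, tr)
  tb <- sim$positive
  in_trt <- tb$samples$condition == "trt"
  B <- binarize(tb)
  loss <- match(paste0(sim$truth$turnover_features$trt$loss, "_P"),
                tb$features$feature_id)
  gain <- match(paste0(sim$truth$turnover_features$trt$gain, "_P"),
                tb$features$feature_id)
  expect_equal(length(loss), 20)
  expect_true(all(B[in_trt, loss] == 0))
  expect_true(all(B[!in_trt, loss] == 1))
  expect_true(all(B[in_trt, gain] == 1))
  expect_true(all(B[!in_trt, gain] == 0))
})

test_that("identical seed gives byte-identical output files", {
  des <- make_design(design_spec(list(cond = c("x", "y")), 2, blocks = 2))
  tr <- ground_truth(seed = 31, n_features_total = 40)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_tables(des, tr), d1)
  write_simulation(simulate_tables(des, tr), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("effect and turnover sets are disjoint within a condition", {
  des <- make_design(design_spec(list(cond = c("ref", "trt")), 4, blocks = 2))
  tr <- ground_truth(seed = 3, n_features_total = 100, shared_fraction = 0.5,
                     effects = list(trt = list(n_features = 30, delta = 2)),
                     turnover = list(trt = list(n_features = 30)))
  sim <- simulate_tables(des, tr)
  eff <- sim$truth$effect_features$trt
  tov <- unlist(sim$truth$turnover_features$trt)
  expect_length(intersect(eff, tov), 0)
  expect_length(eff, 30)
  expect_length(tov, 30)
})
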
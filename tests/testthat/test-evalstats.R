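test_that("pooled Dice over slices is a single global ratio", {
  # slices with (|A ∩ B|, |A|, |B|) = (2, 4, 2) and (3, 3, 3)
  a1 <- matrix(0L, 3, 3); a1[c(1, 2, 3, 4)] <- 1L
  b1 <- matrix(0L, 3, 3); b1[c(1, 2)] <- 1L
  a2 <- matrix(0L, 3, 3); a2[c(5, 6, 7)] <- 1L
  b2 <- a2
  expect_equal(dice_score(list(a1, a2), list(b1, b2)), 2 * 5 / (7 + 5))
})

test_that("the threshold baseline sweeps 101 candidates and maximizes training Dice", {
  v <- matrix(0L, 16, 16); v[4:9, 4:9] <- 1L
  img <- array(10, c(16, 16, 1)); img[4:9, 4:9, 1] <- 200
  ds <- annotated_dataset(list(img), list(v), provenance = "high_quality",
                          intensity_max = 255)
  bl <- threshold_baseline(ds, ds)
  expect_length(bl$grid, 101)
  expect_equal(bl$grid, seq(0, 255, length.out = 101))
  expect_equal(bl$train_dice, 1)        # separable intensities
  expect_equal(bl$test_dice, 1)
  # the chosen threshold achieves the maximum of a full re-evaluation
  recheck <- vapply(bl$grid, function(t)
    dice_score((img[, , 1] > t) + 0L, v), numeric(1))
  expect_equal(bl$train_dice, max(recheck))
  expect_equal(bl$threshold, bl$grid[which.max(recheck)])  # lowest tie wins
})

test_that("threshold baseline handles degenerate inputs", {
  flat <- annotated_dataset(list(array(7, c(8, 8, 1))),
                            list(matrix(0L, 8, 8)),
                            provenance = "high_quality", intensity_max = 255)
  expect_warning(bl <- threshold_baseline(flat), "degenerate")
  # all-background labels: the empty prediction is perfect by convention
  expect_equal(bl$train_dice, 1)
})

test_that("annotation cost is the linear equivalent-low-quality count", {
  expect_equal(annotation_cost(10, 90, 5), 140)
  expect_equal(annotation_cost(0, 37, 5), 37)
  expect_equal(annotation_cost(12, 0, 5), 60)
  expect_error(annotation_cost(-1, 5), "non-negative")
  set.seed(1)
  for (i in 1:25) {
    nh <- sample(0:50, 1); nl <- sample(0:500, 1); k <- sample(1:9, 1)
    expect_equal(annotation_cost(nh, nl, k), k * nh + nl)
    expect_equal(annotation_cost(2 * nh, 2 * nl, k),
                 2 * annotation_cost(nh, nl, k))
  }
})

# exhaustive sign-flip enumeration oracle for the paired signed-rank test
enum_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

test_that("wilcoxon_compare matches exhaustive enumeration", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    expect_equal(wilcoxon_compare(a, b), enum_signed_rank_p(a - b),
                 tolerance = 1e-12, info = paste("case", i))
  }
})

test_that("wilcoxon_compare conventions", {
  x <- c(0.8, 0.82, 0.85, 0.9, 0.91)
  expect_equal(wilcoxon_compare(x, x + 0.05), 0.0625)  # n = 5, one-sided tail
  a <- stats::rnorm(6); b <- stats::rnorm(6)
  expect_equal(wilcoxon_compare(a, b), wilcoxon_compare(b, a))
  expect_warning(p <- wilcoxon_compare(x, x), "zero")
  expect_equal(p, 1)
})

test_that("make_low_quality freezes one corruption per sample", {
  vols <- generate_volumes(synthetic_config(n_volumes = 1,
                                            slices_per_volume = 6, seed = 15))
  ds <- volumes_to_dataset(vols)
  spec <- perturbation_spec(omission_rate = 0.7, seed = 4)
  lq1 <- make_low_quality(ds, spec)
  lq2 <- make_low_quality(ds, spec)
  expect_identical(lapply(lq1$labels, `[[`, "values"),
                   lapply(lq2$labels, `[[`, "values"))
  expect_true(all(lq1$provenance == "low_quality"))
  expect_identical(lq1$truth, mask_list(ds))
  pre <- dice_score(mask_list(lq1), lq1$truth)
  expect_lt(pre, 1)
})

test_that("experiment drivers return the promised bookkeeping", {
  vols <- generate_volumes(synthetic_config(n_volumes = 2,
                                            slices_per_volume = 8, seed = 16))
  hq <- volumes_to_dataset(vols[[1]])
  clean2 <- volumes_to_dataset(vols[[2]])
  spec <- perturbation_spec(omission_rate = 0.7, seed = 5)
  lq_eval <- make_low_quality(clean2, spec)
  cfg <- desk_cfg(9); cfg$max_epochs <- 1L; cfg$min_steps <- 0L
  nc <- tiny_net()

  # capacity: a 1-cell grid gives a single scalar row
  grid <- run_capacity_grid(vols, slice_counts = 4, volume_counts = 1,
                            spec = spec, cfg = cfg, eval_lq = lq_eval,
                            net_config = nc)
  expect_equal(nrow(grid), 1)
  expect_true(all(c("dice", "pre_dice") %in% names(grid)))

  # mismatch: table has one row per training spec, diagonal included
  specs <- list(matched = spec,
                stronger = perturbation_spec(omission_rate = 0.9, seed = 5))
  mm <- run_mismatch_grid(hq, clean2, spec, specs, cfg, net_config = nc)
  expect_equal(nrow(mm), 2)
  expect_true("matched" %in% mm$spec)

  # degradation: one row per level; level 0 reproduces the clean result
  levels <- list(clean = perturbation_spec(seed = 1),
                 degraded = perturbation_spec(omission_rate = 0.3, seed = 1))
  dg <- run_hq_degradation(hq, levels, spec, cfg, lq_eval, n_runs = 1,
                           net_config = nc)
  expect_equal(nrow(dg), 2)
  dg2 <- run_hq_degradation(hq, levels["clean"], spec, cfg, lq_eval,
                            n_runs = 1, net_config = nc)
  expect_equal(dg$dice[dg$level == "clean"], dg2$dice)

  # cost trade-off: fraction 0 costs n, fraction 1 costs k * n
  test_ds <- clean2; test_ds$truth <- mask_list(clean2)
  ct <- run_cost_tradeoff(hq, hq_fractions = c(0, 1), spec = spec, cfg = cfg,
                          test = test_ds, k = 5, net_config = nc)
  n <- length(hq)
  expect_equal(ct$cost[ct$fraction == 0], n)
  expect_equal(ct$cost[ct$fraction == 1], 5 * n)
})

test_that("scenario comparison with a perfect upgrade equals HQ + LQ-truth training", {
  # substituting the upgraded set by the LQ truth makes the HQ + upgraded
  # scenario coincide with training on HQ plus clean LQ labels
  vols <- generate_volumes(synthetic_config(n_volumes = 1,
                                            slices_per_volume = 8, seed = 17))
  ds <- volumes_to_dataset(vols)
  hq <- ds[1:4]
  clean_lq <- ds[5:8]
  perfect_upgrade <- annotated_dataset(clean_lq$images, mask_list(clean_lq),
                                       provenance = "upgraded",
                                       intensity_max = clean_lq$intensity_max)
  cfg <- desk_cfg(10); cfg$max_epochs <- 2L; cfg$min_steps <- 0L
  f1 <- train_segmentation(c(hq, perfect_upgrade), cfg, tiny_net())
  f2 <- train_segmentation(c(hq, clean_lq), cfg, tiny_net())
  expect_equal(f1$params, f2$params)
})

test_that("run_scenarios reports one value per scenario per run", {
  vols <- generate_volumes(synthetic_config(n_volumes = 2,
                                            slices_per_volume = 6, seed = 18))
  hq <- volumes_to_dataset(vols[[1]])
  clean2 <- volumes_to_dataset(vols[[2]], "high_quality")
  spec <- perturbation_spec(omission_rate = 0.7, seed = 6)
  lq <- make_low_quality(clean2, spec)
  test_ds <- clean2; test_ds$truth <- mask_list(clean2)
  cfg <- desk_cfg(11); cfg$max_epochs <- 1L; cfg$min_steps <- 0L
  rep <- run_scenarios(hq, lq, spec, cfg, test_ds, n_runs = 2,
                       net_config = tiny_net())
  expect_equal(nrow(rep$runs), 2)
  expect_true(all(c("lq_only", "hq_only", "hq_lq", "hq_upgraded",
                    "threshold") %in% names(rep$runs)))
  expect_true(all(rep$runs[-1] >= 0 & rep$runs[-1] <= 1))
  expect_equal(nrow(rep$annotation_quality), 2)
})
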
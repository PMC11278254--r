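make_tiny_data <- function(n = 8, seed = 21) {
  vols <- generate_volumes(synthetic_config(n_volumes = 1,
                                            slices_per_volume = n, seed = seed))
  volumes_to_dataset(vols)
}

test_that("annotated datasets validate, subset and concatenate", {
  ds <- make_tiny_data(6)
  expect_equal(length(ds), length(ds$images))
  sub <- ds[2:3]
  expect_equal(length(sub), 2)
  expect_equal(sub$ids, ds$ids[2:3])
  lq <- ds; lq$provenance <- rep("low_quality", length(ds))
  both <- c(ds, lq)
  expect_equal(length(both), 2 * length(ds))
  expect_setequal(unique(both$provenance), c("high_quality", "low_quality"))
  expect_error(annotated_dataset(ds$images, ds$labels[-1]), "length")
})

test_that("zero-epoch training returns the seeded initialization unchanged", {
  ds <- make_tiny_data(6)
  cfg <- desk_cfg(4); cfg$max_epochs <- 0L
  f <- train_segmentation(ds, cfg, tiny_net())
  expect_identical(f$params, build_network(tiny_net(), seed = 4)$params)
  P <- compose_perturbation(perturbation_spec(omission_rate = 0.5,
                                              resample_policy = "per_draw",
                                              seed = 1))
  u <- train_upgrade(ds, P, cfg, tiny_net())
  expect_identical(u$params, build_network(tiny_net(2L), seed = 4)$params)
})

test_that("training inputs are validated", {
  ds <- make_tiny_data(6)
  lq <- ds; lq$provenance <- rep("low_quality", length(ds))
  P_once <- compose_perturbation(perturbation_spec(omission_rate = 0.5,
                                                   resample_policy = "once"))
  P_draw <- compose_perturbation(perturbation_spec(omission_rate = 0.5,
                                                   resample_policy = "per_draw"))
  expect_error(train_upgrade(lq, P_draw, desk_cfg(1)), "high_quality")
  expect_error(train_upgrade(ds, P_once, desk_cfg(1)), "per_draw")
  expect_error(train_segmentation(ds[integer()], desk_cfg(1)), "empty")
})

test_that("early stopping keeps the best validation score", {
  ds <- make_tiny_data(10)
  cfg <- desk_cfg(2, max_epochs = 40L); cfg$patience <- 3L
  cfg$min_steps <- 0L  # this test checks the epoch-denominated contract
  f <- train_segmentation(ds, cfg, tiny_net())
  h <- f$history
  expect_lte(nrow(h), 40)
  # stopped no more than patience + 1 epochs after the best epoch
  expect_lte(nrow(h) - which.max(h$val_dice), cfg$patience + 1)
  # returned parameters reproduce the best validation score
  val <- ds[f$val_ids]
  preds <- lapply(seq_len(length(val)), function(i)
    predict_mask(f, val$images[[i]], intensity_max = val$intensity_max))
  truths <- mask_list(val)
  expect_equal(dice_score(preds, truths), max(h$val_dice), tolerance = 1e-8)
})

test_that("the validation split comes from training data only", {
  ds <- make_tiny_data(10)
  cfg <- desk_cfg(3); cfg$max_epochs <- 1L; cfg$min_steps <- 0L
  f <- train_segmentation(ds, cfg, tiny_net())
  expect_true(all(f$val_ids %in% seq_len(length(ds))))
  expect_equal(length(f$val_ids), round(0.2 * length(ds)))
  # same seed -> same split
  f2 <- train_segmentation(ds, cfg, tiny_net())
  expect_identical(f$val_ids, f2$val_ids)
})

test_that("per-draw perturbation yields distinct corruptions within an epoch", {
  ds <- make_tiny_data(6)
  P <- compose_perturbation(perturbation_spec(omission_rate = 0.5,
                                              resample_policy = "per_draw",
                                              seed = 8))
  lab <- ds$labels[[1]]
  draws <- replicate(8, sum(P(lab)$values > 0))
  expect_gt(length(unique(draws)), 1)
})

test_that("an identity perturbation lets the upgrade network copy its input", {
  # with P = identity the perturbed-label channel equals the target; the
  # network only has to learn a passthrough
  post <- vapply(1:3, function(s) {
    ds <- make_tiny_data(10, seed = 30 + s)
    P <- compose_perturbation(perturbation_spec(resample_policy = "per_draw",
                                                seed = s))
    cfg_id <- desk_cfg(s, max_epochs = 20L); cfg_id$min_steps <- 0L
    u <- train_upgrade(ds, P, cfg_id, tiny_net())
    up <- upgrade_labels(u, {
      lq <- ds; lq$provenance <- rep("low_quality", length(ds)); lq
    })
    dice_score(mask_list(up), mask_list(ds))
  }, numeric(1))
  expect_gte(mean(post), 0.95)
})

test_that("upgrade_labels preserves cardinality, shape and binary range", {
  ds <- make_tiny_data(5)
  lq <- ds; lq$provenance <- rep("low_quality", length(ds))
  cfg <- desk_cfg(1); cfg$max_epochs <- 0L
  P <- compose_perturbation(perturbation_spec(omission_rate = 0.5,
                                              resample_policy = "per_draw"))
  u <- train_upgrade(ds, P, cfg, tiny_net())
  up <- upgrade_labels(u, lq)
  expect_equal(length(up), length(lq))
  expect_true(all(up$provenance == "upgraded"))
  for (i in seq_len(length(up))) {
    expect_equal(dim(up$labels[[i]]), dim(lq$images[[i]])[1:2])
    expect_true(all(up$labels[[i]] %in% c(0L, 1L)))
  }
  rgb <- annotated_dataset(list(array(0, c(16, 16, 3))),
                           list(matrix(0L, 16, 16)),
                           provenance = "low_quality")
  expect_error(upgrade_labels(u, rgb), "channel mismatch")
})

test_that("training on upgraded copies of clean masks equals training on the originals", {
  ds <- make_tiny_data(8)
  lq <- ds; lq$provenance <- rep("low_quality", length(ds))
  as_upgraded <- annotated_dataset(lq$images, mask_list(lq),
                                   provenance = "upgraded", ids = lq$ids,
                                   intensity_max = lq$intensity_max)
  cfg <- desk_cfg(6); cfg$max_epochs <- 2L; cfg$min_steps <- 0L
  f1 <- train_segmentation(c(ds, as_upgraded), cfg, tiny_net())
  f2 <- train_segmentation(c(ds, lq), cfg, tiny_net())
  expect_equal(f1$params, f2$params)
})

test_that("the pipeline runs end to end and records its seeds", {
  vols <- generate_volumes(synthetic_config(n_volumes = 2,
                                            slices_per_volume = 8, seed = 44))
  hq <- volumes_to_dataset(vols[[1]])
  lq <- make_low_quality(volumes_to_dataset(vols[[2]], "high_quality"),
                         perturbation_spec(omission_rate = 0.7, seed = 3))
  lq$provenance <- rep("low_quality", length(lq))
  test <- volumes_to_dataset(vols[[2]])
  test$truth <- mask_list(test)
  cfg <- desk_cfg(5); cfg$max_epochs <- 2L; cfg$min_steps <- 0L
  res <- run_pipeline(hq, lq, perturbation_spec(omission_rate = 0.7, seed = 3),
                      cfg, test = test, net_config = tiny_net())
  expect_s3_class(res$upgrade_net, "network_handle")
  expect_s3_class(res$segmentation_net, "network_handle")
  expect_equal(length(res$upgraded), length(lq))
  expect_true(all(c("pre_upgrade_dice", "post_upgrade_dice", "test_dice") %in%
                    names(res$report)))
  prov <- res$report$provenance
  expect_equal(prov$train_seed, cfg$seed)
  expect_equal(prov$perturbation_seed, 3L)
  expect_true(length(prov$val_ids_upgrade) > 0)
})

test_that("skipping the upgrade step leaves pseudo-labels untouched", {
  ds <- make_tiny_data(8)
  hq <- ds[1:5]
  unl <- ds$images[6:8]
  truth <- mask_list(ds[6:8])
  cfg <- desk_cfg(7); cfg$max_epochs <- 2L; cfg$min_steps <- 0L
  spec <- perturbation_spec(omission_rate = 0.5, salt_pepper_rate = 0.1,
                            bias_qmax = 2, seed = 2)
  res <- run_case_study(hq, unl, spec, cfg, truth = truth,
                        net_config = tiny_net(), upgrade = FALSE)
  expect_equal(res$report$post_upgrade_dice, res$report$pre_upgrade_dice)
  expect_equal(length(res$upgraded), 3)
})
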
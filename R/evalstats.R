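#' Evaluate a segmentation network on a test set
#'
#' Pooled evaluation computes one global Dice coefficient over all test
#' pixels (a Dice computed over the entire test set); the per-slice mean is
#' attached as attribute `"per_slice_mean"` either way.
#'
#' @param model Trained `network_handle`.
#' @param test [annotated_dataset()] with ground-truth masks as labels (or
#'   a `truth` slot).
#' @param pooled If `FALSE` the per-slice mean Dice is returned instead.
#' @return Scalar Dice with attribute `per_slice_mean`.
#' @export
evaluate_model <- function(model, test, pooled = TRUE) {
  stopifnot(inherits(model, "network_handle"),
            inherits(test, "annotated_dataset"))
  if (length(test) == 0) stop("empty test set")
  truths <- if (!is.null(test$truth)) test$truth
  else lapply(seq_len(length(test)), function(i) dataset_mask(test, i))
  preds <- batched_predict(model, lapply(seq_len(length(test)), function(i)
    norm_image(test, i)))
  pooled_dice <- dice_score(preds, truths)
  per_slice <- mean(mapply(dice_score, preds, truths))
  out <- if (pooled) pooled_dice else per_slice
  attr(out, "per_slice_mean") <- per_slice
  out
}

image_luminance <- function(im) {
  if (is.matrix(im)) return(im)
  if (dim(im)[3] == 1L) im[, , 1] else apply(im, c(1, 2), mean)
}

#' Intensity-thresholding baseline
#'
#' Sweeps 101 candidate thresholds `{0, 0.01 I_max, ..., I_max}` (a grid
#' with a step of 1% of the maximum pixel intensity), classifies pixels
#' with intensity strictly above the threshold as foreground, picks the
#' threshold with the highest pooled training Dice (lowest threshold on
#' ties), and reports the test Dice at that threshold. RGB images are
#' reduced to their channel mean.
#'
#' @param train,test [annotated_dataset()] objects with ground-truth masks.
#' @return List with `threshold`, `train_dice`, `test_dice`, and the full
#'   sweep (`grid`, `grid_dice`).
#' @export
threshold_baseline <- function(train, test = NULL) {
  stopifnot(inherits(train, "annotated_dataset"))
  imax <- train$intensity_max
  grid <- seq(0, imax, length.out = 101L)
  tr_imgs <- lapply(train$images, image_luminance)
  tr_masks <- if (!is.null(train$truth)) train$truth
  else lapply(seq_len(length(train)), function(i) dataset_mask(train, i))
  if (all(vapply(tr_imgs, function(im) max(im) == min(im), logical(1))))
    warning("constant-intensity images: threshold is degenerate")
  sweep_dice <- vapply(grid, function(t) {
    dice_score(lapply(tr_imgs, function(im) (im > t) + 0L), tr_masks)
  }, numeric(1))
  best <- which.max(sweep_dice)  # first max = lowest threshold on ties
  out <- list(threshold = grid[best], train_dice = sweep_dice[best],
              grid = grid, grid_dice = sweep_dice)
  if (!is.null(test)) {
    te_imgs <- lapply(test$images, image_luminance)
    te_masks <- if (!is.null(test$truth)) test$truth
    else lapply(seq_len(length(test)), function(i) dataset_mask(test, i))
    out$test_dice <- dice_score(
      lapply(te_imgs, function(im) (im > grid[best]) + 0L), te_masks)
  }
  out
}

#' Annotation cost in equivalent low-quality annotations
#'
#' One high-quality annotation costs `k` low-quality annotations (default
#' 5, for illustration purposes); a low-quality annotation costs 1, so the
#' total effort for `n_hq` high-quality plus `n_lq` low-quality labels is
#' `k * n_hq + n_lq`.
#'
#' @param n_hq,n_lq Non-negative annotation counts.
#' @param k Cost factor of a high-quality annotation.
#' @return Numeric cost.
#' @export
annotation_cost <- function(n_hq, n_lq, k = 5) {
  if (any(c(n_hq, n_lq) < 0)) stop("annotation counts must be non-negative")
  k * n_hq + n_lq
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided paired signed-rank test between matched run scores, exact for
#' tie-free samples of up to 25 pairs (and, by full sign-flip enumeration
#' with average ranks, for tied samples of up to 15). All-zero differences
#' return p = 1 with a warning.
#'
#' @param runs_a,runs_b Equal-length numeric vectors of paired scores.
#' @return Two-sided p-value.
#' @export
wilcoxon_compare <- function(runs_a, runs_b) {
  stopifnot(length(runs_a) == length(runs_b))
  d <- runs_a - runs_b
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1")
    return(1)
  }
  nz <- d[d != 0]
  n <- length(nz)
  if (n <= 25 && !anyDuplicated(abs(nz))) {
    # tie-free: exact signed-rank distribution
    res <- suppressWarnings(stats::wilcox.test(runs_a, runs_b, paired = TRUE,
                                               exact = TRUE))
    return(res$p.value)
  }
  if (n <= 15) {
    # tied absolute differences: exact by full sign-flip enumeration with
    # average ranks
    r <- rank(abs(nz))
    w_obs <- sum(r[nz > 0])
    w_all <- as.matrix(expand.grid(rep(list(c(0, 1)), n))) %*% r
    return(min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))))
  }
  suppressWarnings(stats::wilcox.test(runs_a, runs_b, paired = TRUE,
                                      exact = FALSE, correct = TRUE))$p.value
}

#' Compare training scenarios
#'
#' Trains and evaluates the competing uses of a high-quality and a
#' low-quality set over repeated runs with fresh seeds: LQ only, HQ only,
#' HQ + LQ, HQ + upgraded, plus the deterministic thresholding baseline,
#' and reports the annotation quality of the low-quality labels before and
#' after the upgrade.
#'
#' @param hq,lq,test [annotated_dataset()] objects; `lq` and `test` should
#'   carry ground truth in their `truth` slot (or clean labels).
#' @param spec [perturbation_spec()] for the upgrade training.
#' @param cfg [train_config()]; run `r` uses seed `cfg$seed + r`.
#' @param n_runs Number of repeated runs.
#' @param scenarios Subset of scenarios to run.
#' @param net_config Optional [model_config()].
#' @return A `scenario_report`: list with `runs` (data frame of per-run
#'   Dice per scenario), `means`, and `annotation_quality`.
#' @export
run_scenarios <- function(hq, lq, spec, cfg, test, n_runs = 5L,
                          scenarios = c("lq_only", "hq_only", "hq_lq",
                                        "hq_upgraded", "threshold"),
                          net_config = NULL) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  thr <- if ("threshold" %in% scenarios) {
    # the baseline sweeps against the true training masks: clean HQ labels
    # plus the LQ set's ground truth (it is annotation-scenario independent)
    thr_train <- annotated_dataset(
      c(hq$images, lq$images),
      c(lapply(seq_len(length(hq)), function(i) dataset_mask(hq, i)),
        lq$truth %||% lapply(seq_len(length(lq)), function(i) dataset_mask(lq, i))),
      provenance = "high_quality", intensity_max = hq$intensity_max)
    threshold_baseline(thr_train, test)$test_dice
  }
  rows <- list(); aq <- list()
  for (r in seq_len(n_runs)) {
    cfg_r <- cfg; cfg_r$seed <- cfg$seed + r
    spec_r <- spec; spec_r$seed <- spec$seed + r
    row <- list(run = r)
    if ("lq_only" %in% scenarios)
      row$lq_only <- as.numeric(evaluate_model(
        train_segmentation(lq, cfg_r, net_config), test))
    if ("hq_only" %in% scenarios)
      row$hq_only <- as.numeric(evaluate_model(
        train_segmentation(hq, cfg_r, net_config), test))
    if ("hq_lq" %in% scenarios)
      row$hq_lq <- as.numeric(evaluate_model(
        train_segmentation(c(hq, lq), cfg_r, net_config), test))
    if ("hq_upgraded" %in% scenarios) {
      pl <- run_pipeline(hq, lq, spec_r, cfg_r, test = test,
                         net_config = net_config)
      row$hq_upgraded <- as.numeric(pl$report$test_dice)
      aq[[r]] <- c(pre = pl$report$pre_upgrade_dice %||% NA_real_,
                   post = pl$report$post_upgrade_dice %||% NA_real_)
    }
    if ("threshold" %in% scenarios) row$threshold <- thr
    rows[[r]] <- as.data.frame(row)
  }
  runs <- do.call(rbind, rows)
  means <- colMeans(runs[, setdiff(names(runs), "run"), drop = FALSE])
  structure(list(runs = runs, means = means,
                 annotation_quality = if (length(aq)) do.call(rbind, aq)),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("scenario_report (mean test Dice over", nrow(x$runs), "runs):\n")
  print(round(x$means, 4))
  if (!is.null(x$annotation_quality)) {
    cat("annotation quality (mean pre/post upgrade):\n")
    print(round(colMeans(x$annotation_quality), 4))
  }
  invisible(x)
}

#' Upgrade-network capacity study
#'
#' For each combination of total annotated slices and number of source
#' volumes, samples a high-quality training set with the equidistant
#' circular sampler, trains an upgrade network, and measures the Dice of
#' the upgraded annotations on a fixed held-out perturbed set.
#'
#' @param volumes Volumes from [generate_volumes()].
#' @param slice_counts,volume_counts Grid axes.
#' @param spec [perturbation_spec()] (also used to corrupt the evaluation
#'   set, frozen once).
#' @param cfg [train_config()].
#' @param eval_lq Held-out low-quality [annotated_dataset()] with `truth`.
#' @param net_config Optional [model_config()].
#' @return A data frame (n_slices, n_volumes, dice, pre_dice) with a
#'   `trend` attribute (Spearman correlation of Dice with slice count).
#' @export
run_capacity_grid <- function(volumes, slice_counts, volume_counts, spec,
                              cfg, eval_lq, net_config = NULL) {
  pre <- dice_score(lapply(seq_len(length(eval_lq)), function(i)
    dataset_mask(eval_lq, i)), eval_lq$truth)
  rows <- list()
  for (nv in volume_counts) for (ns in slice_counts) {
    plan <- tryCatch(sample_slices(volumes, ns, nv), error = function(e) NULL)
    if (is.null(plan)) {
      warning(sprintf("skipping infeasible cell (%d slices, %d volumes)", ns, nv))
      next
    }
    hq <- volumes_to_dataset(volumes, "high_quality", plan = plan)
    spec_t <- spec; spec_t$resample_policy <- "per_draw"
    u <- train_upgrade(hq, compose_perturbation(spec_t), cfg, net_config)
    up <- upgrade_labels(u, eval_lq)
    d <- dice_score(lapply(seq_len(length(up)), function(i) dataset_mask(up, i)),
                    eval_lq$truth)
    rows[[length(rows) + 1L]] <- data.frame(n_slices = ns, n_volumes = nv,
                                            dice = d, pre_dice = pre)
  }
  out <- do.call(rbind, rows)
  if (nrow(out) > 1 && length(unique(out$n_slices)) > 1)
    attr(out, "trend") <- stats::cor(out$n_slices, out$dice,
                                     method = "spearman")
  out
}

#' Perturbation-mismatch study
#'
#' Fixes a low-quality set corrupted once with `lq_spec` and trains upgrade
#' networks under each candidate training perturbation, reporting the Dice
#' of the upgraded annotations for every training spec.
#'
#' @param hq High-quality [annotated_dataset()].
#' @param lq_clean Clean dataset standing in for the low-quality pool
#'   (instance labels; its corruption is derived here).
#' @param lq_spec [perturbation_spec()] generating the fixed low-quality
#'   set (applied once per sample).
#' @param train_specs Named list of [perturbation_spec()] candidates.
#' @param cfg [train_config()].
#' @param net_config Optional [model_config()].
#' @return Data frame (spec name, dice, pre_dice).
#' @export
run_mismatch_grid <- function(hq, lq_clean, lq_spec, train_specs, cfg,
                              net_config = NULL) {
  lq <- make_low_quality(lq_clean, lq_spec)
  pre <- dice_score(lapply(seq_len(length(lq)), function(i) dataset_mask(lq, i)),
                    lq$truth)
  rows <- lapply(seq_along(train_specs), function(j) {
    sp <- train_specs[[j]]; sp$resample_policy <- "per_draw"
    u <- train_upgrade(hq, compose_perturbation(sp), cfg, net_config)
    up <- upgrade_labels(u, lq)
    data.frame(spec = names(train_specs)[j] %||% as.character(j),
               dice = dice_score(lapply(seq_len(length(up)), function(i)
                 dataset_mask(up, i)), lq$truth),
               pre_dice = pre)
  })
  do.call(rbind, rows)
}

#' Degraded-reference study
#'
#' Perturbs the high-quality training annotations themselves at each
#' degradation level (a list of perturbation specs; an all-zero spec is the
#' clean reference), retrains the upgrade network, and reports the upgraded
#' Dice per level.
#'
#' @param hq High-quality [annotated_dataset()].
#' @param degradation_specs Named list of [perturbation_spec()]; include an
#'   all-zero spec as level 0.
#' @param spec [perturbation_spec()] the upgrade network trains against.
#' @param cfg [train_config()].
#' @param eval_lq Held-out low-quality [annotated_dataset()] with `truth`.
#' @param n_runs Repeats per level (standard deviation reported when > 1).
#' @param net_config Optional [model_config()].
#' @return Data frame (level, dice, sd).
#' @export
run_hq_degradation <- function(hq, degradation_specs, spec, cfg, eval_lq,
                               n_runs = 1L, net_config = NULL) {
  rows <- lapply(seq_along(degradation_specs), function(j) {
    dspec <- degradation_specs[[j]]
    vals <- vapply(seq_len(n_runs), function(r) {
      cfg_r <- cfg; cfg_r$seed <- cfg$seed + r - 1L
      hq_r <- degrade_hq(hq, dspec, seed_shift = r - 1L)
      sp <- spec; sp$resample_policy <- "per_draw"; sp$seed <- spec$seed + r - 1L
      u <- train_upgrade(hq_r, compose_perturbation(sp), cfg_r, net_config)
      up <- upgrade_labels(u, eval_lq)
      dice_score(lapply(seq_len(length(up)), function(i) dataset_mask(up, i)),
                 eval_lq$truth)
    }, numeric(1))
    data.frame(level = names(degradation_specs)[j] %||% as.character(j),
               dice = mean(vals),
               sd = if (n_runs > 1) stats::sd(vals) else NA_real_)
  })
  do.call(rbind, rows)
}

degrade_hq <- function(hq, dspec, seed_shift = 0L) {
  zero <- dspec$omission_rate == 0 && dspec$inclusion_rate == 0 &&
    dspec$bias_qmax == 0 && dspec$salt_pepper_rate == 0 &&
    dspec$segment_inclusion_rate == 0
  if (zero) return(hq)
  sp <- dspec; sp$seed <- dspec$seed + seed_shift
  P <- compose_perturbation(sp)
  hq$labels <- lapply(seq_len(length(hq)), function(i)
    P(hq$labels[[i]], image = norm_image(hq, i)))
  hq
}

#' Corrupt a clean dataset into a frozen low-quality set
#'
#' Applies the perturbation once per sample (the corruption of a
#' low-quality annotation process is fixed, not resampled) and stores the
#' clean binarized labels as `truth`.
#'
#' @param clean [annotated_dataset()] with clean instance labels.
#' @param spec [perturbation_spec()].
#' @return Low-quality `annotated_dataset` with `truth`.
#' @export
make_low_quality <- function(clean, spec) {
  sp <- spec; sp$resample_policy <- "once"
  P <- compose_perturbation(sp)
  truth <- lapply(seq_len(length(clean)), function(i) dataset_mask(clean, i))
  labels <- lapply(seq_len(length(clean)), function(i)
    P(clean$labels[[i]], image = norm_image(clean, i)))
  annotated_dataset(clean$images, labels, provenance = "low_quality",
                    ids = clean$ids, intensity_max = clean$intensity_max,
                    truth = truth)
}

#' Annotation-cost trade-off study
#'
#' For each fraction of slices given high-quality annotations, builds the
#' corresponding HQ/LQ mix from a fixed slice budget, runs the matching
#' scenario (LQ-only at fraction 0, HQ-only at fraction 1, the upgrade
#' framework in between), and reports cost in equivalent low-quality
#' annotations together with the achieved test Dice.
#'
#' @param slices Clean [annotated_dataset()] (the annotation budget).
#' @param hq_fractions Fractions in `[0, 1]`.
#' @param spec [perturbation_spec()] corrupting the LQ part.
#' @param cfg [train_config()].
#' @param test Test [annotated_dataset()].
#' @param k High-quality cost factor.
#' @param net_config Optional [model_config()].
#' @return Data frame (fraction, n_hq, n_lq, cost, dice).
#' @export
run_cost_tradeoff <- function(slices, hq_fractions = c(0, 0.1, 1),
                              spec, cfg, test, k = 5, net_config = NULL) {
  stopifnot(all(hq_fractions >= 0 & hq_fractions <= 1))
  n <- length(slices)
  rows <- lapply(hq_fractions, function(f) {
    n_hq <- round_half_up(f * n)
    hq_idx <- if (n_hq > 0) round(seq(1, n, length.out = n_hq)) else integer()
    lq_idx <- setdiff(seq_len(n), hq_idx)
    dice <- if (n_hq == 0) {
      lq <- make_low_quality(slices[lq_idx], spec)
      as.numeric(evaluate_model(train_segmentation(lq, cfg, net_config), test))
    } else if (length(lq_idx) == 0) {
      as.numeric(evaluate_model(
        train_segmentation(slices[hq_idx], cfg, net_config), test))
    } else {
      lq <- make_low_quality(slices[lq_idx], spec)
      pl <- run_pipeline(slices[hq_idx], lq, spec, cfg, test = test,
                         net_config = net_config)
      as.numeric(pl$report$test_dice)
    }
    data.frame(fraction = f, n_hq = n_hq, n_lq = length(lq_idx),
               cost = annotation_cost(n_hq, length(lq_idx), k), dice = dice)
  })
  do.call(rbind, rows)
}
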
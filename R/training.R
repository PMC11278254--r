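#' Annotated dataset
#'
#' Images paired with labels plus a provenance tag. Labels may be
#' [instance_label_map()] objects (high-quality sets, perturbable) or plain
#' binary masks (upgraded sets, pseudo-labels). An optional `truth` list of
#' clean masks supports evaluating annotation quality when the ground truth
#' is known (synthetic data).
#'
#' @param images List of `H x W x C` arrays (matrices are treated as C = 1).
#' @param labels List of [instance_label_map()] or binary matrices, same
#'   length as `images`.
#' @param provenance One of `"high_quality"`, `"low_quality"`, `"upgraded"`.
#' @param ids Optional character sample ids (defaults to `s001, ...`).
#' @param intensity_max Dtype maximum used to scale intensities to
#'   `[0, 1]`; inferred from the data if omitted (65535, 255 or 1).
#' @param truth Optional list of ground-truth binary masks.
#' @return An `annotated_dataset`.
#' @export
annotated_dataset <- function(images, labels,
                              provenance = c("high_quality", "low_quality",
                                             "upgraded"),
                              ids = NULL, intensity_max = NULL,
                              truth = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(length(images) == length(labels))
  images <- lapply(images, function(im) {
    if (is.matrix(im)) dim(im) <- c(dim(im), 1L)
    im
  })
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(images))
  if (is.null(intensity_max)) {
    mx <- max(vapply(images, max, numeric(1)), 0)
    intensity_max <- if (mx > 255) 65535 else if (mx > 1) 255 else 1
  }
  if (!is.null(truth)) stopifnot(length(truth) == length(images))
  structure(list(images = images, labels = labels,
                 provenance = rep(provenance, length(images)),
                 ids = ids, intensity_max = intensity_max, truth = truth),
            class = "annotated_dataset")
}

#' @export
length.annotated_dataset <- function(x) length(x$images)

#' @export
print.annotated_dataset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("annotated_dataset: %d samples of %d x %d x %d (%s)\n",
              length(x), d[1], d[2], d[3],
              paste(unique(x$provenance), collapse = " + ")))
  invisible(x)
}

#' @export
`[.annotated_dataset` <- function(x, i) {
  structure(list(images = x$images[i], labels = x$labels[i],
                 provenance = x$provenance[i], ids = x$ids[i],
                 intensity_max = x$intensity_max,
                 truth = if (!is.null(x$truth)) x$truth[i]),
            class = "annotated_dataset")
}

#' Concatenate annotated datasets
#'
#' Plain concatenation: samples from each set are weighted equally during
#' training, matching an additive training objective over the combined set.
#'
#' @param ... `annotated_dataset` objects.
#' @return A combined `annotated_dataset` with per-sample provenance.
#' @export
c.annotated_dataset <- function(...) {
  ds <- list(...)
  stopifnot(all(vapply(ds, inherits, logical(1), "annotated_dataset")))
  truths <- lapply(ds, function(d) {
    if (is.null(d$truth)) rep(list(NULL), length(d)) else d$truth
  })
  has_truth <- any(vapply(ds, function(d) !is.null(d$truth), logical(1)))
  structure(list(images = do.call(c, lapply(ds, `[[`, "images")),
                 labels = do.call(c, lapply(ds, `[[`, "labels")),
                 provenance = do.call(c, lapply(ds, `[[`, "provenance")),
                 ids = make.unique(do.call(c, lapply(ds, `[[`, "ids"))),
                 intensity_max = ds[[1]]$intensity_max,
                 truth = if (has_truth) do.call(c, truths)),
            class = "annotated_dataset")
}

dataset_mask <- function(ds, i) binarize(ds$labels[[i]])

dataset_channels <- function(ds) dim(ds$images[[1]])[3]

norm_image <- function(ds, i) ds$images[[i]] / ds$intensity_max

#' Training configuration
#'
#' Defaults follow the reference protocol: ADAM with learning rate `1e-5`,
#' batch size 4, an 80/20 training/validation split of the training data,
#' and early stopping once the validation Dice score has not improved for
#' `patience` consecutive epochs (the best-scoring parameters are kept).
#' Desk-scale experiments typically raise the learning rate and cap
#' `max_epochs`.
#'
#' @param learning_rate ADAM step size.
#' @param batch_size Samples per gradient step.
#' @param patience Epochs without validation improvement before stopping.
#' @param max_epochs Hard cap on epochs.
#' @param val_fraction Fraction of the training data held out for
#'   validation, in (0, 1).
#' @param min_steps Floor on the total number of gradient steps: when an
#'   epoch holds few batches (tiny training sets), the epoch cap and the
#'   patience are raised so at least this many steps can be taken. 0
#'   disables the floor. Epoch-denominated budgets degenerate when one
#'   epoch is a single batch; a step floor keeps the optimisation budget
#'   comparable across training-set sizes.
#' @param max_steps Cap on the total number of gradient steps (0 = none);
#'   the epoch cap is lowered so a large training set does not receive a
#'   disproportionate optimisation budget. Whole epochs are kept: the cap
#'   rounds up to the next full pass.
#' @param seed Seed for the split, shuffling, perturbation draws, and
#'   parameter initialization.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 4L,
                         patience = 10L, max_epochs = 500L,
                         val_fraction = 0.2, min_steps = 0L,
                         max_steps = 0L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, patience >= 0,
            max_epochs >= 0, val_fraction > 0, val_fraction < 1,
            min_steps >= 0, max_steps >= 0,
            max_steps == 0 || max_steps >= min_steps)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction,
                 min_steps = as.integer(min_steps),
                 max_steps = as.integer(max_steps),
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) { p[] <- 0; p }),
       v = lapply(params, function(p) { p[] <- 0; p }),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

stack_batch <- function(xs) {
  d <- dim(xs[[1]])
  out <- array(0, c(d, length(xs)))
  for (i in seq_along(xs)) out[, , , i] <- xs[[i]]
  out
}

# chunked evaluation-mode inference over a list of (H, W, C) inputs
batched_predict <- function(net, xs, chunk = 8L) {
  masks <- vector("list", length(xs))
  for (start in seq(1, length(xs), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(xs))
    p <- unet_forward(net, stack_batch(xs[sel]), training = FALSE)$p
    for (j in seq_along(sel))
      masks[[sel[j]]] <- (p[, , 2, j] > 0.5) + 0L
  }
  masks
}

# shared trainer. input_fn(i, draw) -> (H, W, Cin) array; target_fn(i) ->
# binary H x W mask. Validation inputs are built once with draw = 0 (frozen
# corruption) so the early-stopping score is stable across epochs.
fit_network <- function(net, n, input_fn, target_fn, cfg,
                        redraw_inputs = FALSE) {
  if (n < 1) stop("empty training set")
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed + 7L)
  n_val <- max(1L, round(cfg$val_fraction * n))
  if (n_val >= n) n_val <- n - 1L
  val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer()
  train_idx <- setdiff(seq_len(n), val_idx)
  val_x <- lapply(val_idx, function(i) input_fn(i, 0L))
  val_t <- lapply(val_idx, target_fn)
  train_x0 <- if (!redraw_inputs) lapply(train_idx, function(i) input_fn(i, 0L))
  train_t <- lapply(train_idx, target_fn)

  val_dice <- function() {
    if (length(val_idx) == 0) return(NA_real_)
    p <- unet_forward(net, stack_batch(val_x), training = FALSE)$p
    preds <- lapply(seq_along(val_x), function(i) (p[, , 2, i] > 0.5) + 0L)
    dice_score(preds, val_t)
  }

  best_params <- net$params; best_state <- net$state
  best_score <- -Inf; since_best <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dice = numeric())
  steps_per_epoch <- ceiling(length(train_idx) / cfg$batch_size)
  max_epochs <- cfg$max_epochs
  patience <- cfg$patience
  min_steps <- cfg$min_steps %||% 0L
  if (min_steps > 0L) {
    floor_epochs <- ceiling(min_steps / steps_per_epoch)
    if (floor_epochs > max_epochs) {
      patience <- max(patience, ceiling(floor_epochs / 4))
      max_epochs <- floor_epochs
    }
  }
  max_steps <- cfg$max_steps %||% 0L
  if (max_steps > 0L) {
    cap_epochs <- max(1L, ceiling(max_steps / steps_per_epoch))
    if (cap_epochs < max_epochs) max_epochs <- cap_epochs
  }
  draw <- 0L
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    perm <- sample(seq_along(train_idx))
    losses <- c()
    for (start in seq(1, length(perm), by = cfg$batch_size)) {
      sel <- perm[start:min(start + cfg$batch_size - 1L, length(perm))]
      xs <- lapply(sel, function(j) {
        if (redraw_inputs) {
          draw <<- draw + 1L
          input_fn(train_idx[j], draw)
        } else train_x0[[j]]
      })
      x <- stack_batch(xs)
      t_arr <- array(0, c(dim(x)[1:2], length(sel)))
      for (j in seq_along(sel)) t_arr[, , j] <- train_t[[sel[j]]]
      fw <- unet_forward(net, x, training = TRUE, want_cache = TRUE)
      net$state <- fw$state
      # pad target to the network's padded size for the loss gradient
      ph <- fw$padded_hw
      tp <- array(0, c(ph[1], ph[2], length(sel)))
      tp[seq_len(dim(x)[1]), seq_len(dim(x)[2]), ] <- t_arr
      pfull <- softmax2(fw$z)
      losses <- c(losses, dice_loss(pfull, tp))
      gz <- dice_softmax_grad(pfull, tp)
      grads <- unet_backward(net, fw, gz)
      st <- adam_step(net$params, grads, net$opt %||% adam_init(net$params),
                      cfg$learning_rate)
      net$params <- st$params
      net$opt <- st$opt
    }
    vd <- val_dice()
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_dice = vd))
    if (!is.na(vd) && vd > best_score + 1e-6) {
      best_score <- vd; best_params <- net$params; best_state <- net$state
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > patience) break
    }
  }
  net$params <- best_params
  net$state <- best_state
  net$opt <- NULL
  net$history <- history
  net$val_ids <- val_idx
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

upgrade_input <- function(ds, i, lab) {
  img <- norm_image(ds, i)
  d <- dim(img)
  x <- array(0, c(d[1], d[2], d[3] + 1L))
  x[, , seq_len(d[3])] <- img
  x[, , d[3] + 1L] <- binarize(lab)
  x
}

#' Train the upgrade network
#'
#' Trains a network `u` that maps (image, perturbed label) to the clean
#' label: every drawn training sample presents the image with a freshly
#' perturbed version of its high-quality annotation concatenated as an
#' extra input channel, while the target is the unperturbed binarized
#' label. Minimizes the Dice loss with ADAM; early stopping keeps the
#' parameters with the best validation Dice.
#'
#' @param hq High-quality [annotated_dataset()] with instance labels.
#' @param P Perturbation function from [compose_perturbation()] with
#'   `resample_policy = "per_draw"`.
#' @param cfg A [train_config()].
#' @param net_config Optional [model_config()]; `in_channels` is forced to
#'   C + 1.
#' @return A trained `network_handle`.
#' @export
train_upgrade <- function(hq, P, cfg = train_config(), net_config = NULL) {
  stopifnot(inherits(hq, "annotated_dataset"))
  if (length(hq) == 0) stop("empty high-quality set")
  if (!all(hq$provenance == "high_quality"))
    stop("train_upgrade expects a high_quality dataset")
  spec <- attr(P, "spec")
  if (!is.null(spec) && spec$resample_policy != "per_draw")
    stop("train_upgrade requires a perturbation with resample_policy = 'per_draw'")
  C <- dataset_channels(hq)
  if (is.null(net_config)) net_config <- model_config(in_channels = C + 1L)
  net_config$in_channels <- C + 1L
  net <- build_network(net_config, seed = cfg$seed)
  if (cfg$max_epochs == 0L) return(net)
  input_fn <- function(i, draw) {
    upgrade_input(hq, i, P(hq$labels[[i]], image = norm_image(hq, i)))
  }
  target_fn <- function(i) dataset_mask(hq, i)
  fit_network(net, length(hq), input_fn, target_fn, cfg,
              redraw_inputs = TRUE)
}

#' Upgrade the labels of a low-quality set
#'
#' Applies a trained upgrade network to every sample: the image and the
#' binarized low-quality label enter as channels, and the arg-max channel
#' of the output becomes the upgraded mask. Images are unchanged.
#'
#' @param u Trained upgrade `network_handle`.
#' @param lq Low-quality [annotated_dataset()].
#' @return An `annotated_dataset` with provenance `"upgraded"` and binary
#'   masks as labels.
#' @export
upgrade_labels <- function(u, lq) {
  stopifnot(inherits(u, "network_handle"), inherits(lq, "annotated_dataset"))
  C <- dataset_channels(lq)
  if (u$config$in_channels != C + 1L)
    stop(sprintf("channel mismatch: network expects %d input channels, data provides %d + 1",
                 u$config$in_channels, C))
  masks <- batched_predict(u, lapply(seq_len(length(lq)), function(i)
    upgrade_input(lq, i, lq$labels[[i]])))
  annotated_dataset(lq$images, masks, provenance = "upgraded", ids = lq$ids,
                    intensity_max = lq$intensity_max, truth = lq$truth)
}

#' Train a segmentation network
#'
#' Standard supervised training on (image, binary mask) pairs from one or
#' more datasets (concatenated with equal sample weight), with the same
#' optimizer and early-stopping contract as [train_upgrade()].
#'
#' @param train An [annotated_dataset()] or list of them.
#' @param cfg A [train_config()].
#' @param net_config Optional [model_config()].
#' @return A trained `network_handle`.
#' @export
train_segmentation <- function(train, cfg = train_config(), net_config = NULL) {
  if (is.list(train) && !inherits(train, "annotated_dataset"))
    train <- do.call(c, train)
  stopifnot(inherits(train, "annotated_dataset"))
  if (length(train) == 0) stop("empty training set")
  C <- dataset_channels(train)
  if (is.null(net_config)) net_config <- model_config(in_channels = C)
  net_config$in_channels <- C
  net <- build_network(net_config, seed = cfg$seed)
  if (cfg$max_epochs == 0L) return(net)
  input_fn <- function(i, draw) norm_image(train, i)
  target_fn <- function(i) dataset_mask(train, i)
  fit_network(net, length(train), input_fn, target_fn, cfg)
}

#' Predict a segmentation mask for one image
#'
#' @param net Trained segmentation `network_handle`.
#' @param image `H x W x C` array or matrix in raw intensity counts.
#' @param intensity_max Dtype maximum used for input scaling.
#' @return Binary `H x W` mask.
#' @export
predict_mask <- function(net, image, intensity_max = 65535) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  p <- network_forward(net, image / intensity_max)
  (p[, , 2, 1] > 0.5) + 0L
}

#' Run the full upgrade pipeline
#'
#' End-to-end: train the upgrade network on the perturbed high-quality set,
#' upgrade the low-quality set, and train the final segmentation network on
#' the union of the high-quality and upgraded sets.
#'
#' @param hq High-quality [annotated_dataset()].
#' @param lq Low-quality [annotated_dataset()] (disjoint from `hq`).
#' @param spec A [perturbation_spec()] describing the corruption the
#'   upgrade network trains against.
#' @param cfg A [train_config()].
#' @param test Optional test [annotated_dataset()] for evaluation.
#' @param net_config Optional [model_config()] shared by both networks.
#' @return List with `upgrade_net`, `segmentation_net`, `upgraded` (the
#'   upgraded dataset) and `report` (annotation quality before/after the
#'   upgrade when `lq` carries truth, test Dice when `test` is given, and a
#'   provenance record of every seed used).
#' @export
run_pipeline <- function(hq, lq, spec, cfg = train_config(), test = NULL,
                         net_config = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  spec$resample_policy <- "per_draw"
  P <- compose_perturbation(spec)
  u <- train_upgrade(hq, P, cfg, net_config)
  upgraded <- upgrade_labels(u, lq)
  f <- train_segmentation(c(hq, upgraded), cfg, net_config)
  report <- list(provenance = list(train_seed = cfg$seed,
                                   perturbation_seed = spec$seed,
                                   net_seed = cfg$seed,
                                   val_ids_upgrade = u$val_ids,
                                   val_ids_segmentation = f$val_ids))
  if (!is.null(lq$truth)) {
    pre <- lapply(seq_len(length(lq)), function(i) dataset_mask(lq, i))
    post <- lapply(seq_len(length(upgraded)), function(i) dataset_mask(upgraded, i))
    report$pre_upgrade_dice <- dice_score(pre, lq$truth)
    report$post_upgrade_dice <- dice_score(post, lq$truth)
  }
  if (!is.null(test)) report$test_dice <- evaluate_model(f, test)
  list(upgrade_net = u, segmentation_net = f, upgraded = upgraded,
       report = report)
}

#' Self-training case study: upgrading low-quality predictions
#'
#' Emulates a pipeline with no manual low-quality annotation cost: a
#' segmentation network trained on a small well-annotated set produces
#' pseudo-labels for unlabeled images; an upgrade network trained on the
#' same small set with a composite perturbation (omission, segment
#' inclusion, salt-and-pepper, bias) then refines those pseudo-labels.
#'
#' @param hq Small high-quality [annotated_dataset()].
#' @param unlabeled_images List of images without annotations.
#' @param spec Composite [perturbation_spec()].
#' @param cfg A [train_config()].
#' @param truth Optional list of ground-truth masks for the unlabeled
#'   images (evaluation only).
#' @param net_config Optional [model_config()].
#' @param upgrade If `FALSE` the upgrade step is bypassed and the report's
#'   post-upgrade quality equals the pre-upgrade quality.
#' @return List with `pseudo` (pseudo-labelled dataset), `upgraded`, and
#'   `report` (pre-/post-upgrade Dice against `truth` when available).
#' @export
run_case_study <- function(hq, unlabeled_images, spec, cfg = train_config(),
                           truth = NULL, net_config = NULL, upgrade = TRUE) {
  stopifnot(inherits(hq, "annotated_dataset"))
  f0 <- train_segmentation(hq, cfg, net_config)
  imgs <- lapply(unlabeled_images, function(im) {
    if (is.matrix(im)) dim(im) <- c(dim(im), 1L)
    im
  })
  pseudo_masks <- lapply(imgs, function(im)
    predict_mask(f0, im, intensity_max = hq$intensity_max))
  pseudo <- annotated_dataset(imgs, pseudo_masks, provenance = "low_quality",
                              intensity_max = hq$intensity_max, truth = truth)
  if (upgrade) {
    spec$resample_policy <- "per_draw"
    P <- compose_perturbation(spec)
    u <- train_upgrade(hq, P, cfg, net_config)
    upgraded <- upgrade_labels(u, pseudo)
  } else {
    u <- NULL
    upgraded <- annotated_dataset(imgs, pseudo_masks, provenance = "upgraded",
                                  intensity_max = hq$intensity_max,
                                  truth = truth)
  }
  report <- list()
  if (!is.null(truth)) {
    report$pre_upgrade_dice <- dice_score(pseudo_masks, truth)
    report$post_upgrade_dice <- dice_score(
      lapply(seq_len(length(upgraded)), function(i) dataset_mask(upgraded, i)),
      truth)
  }
  list(segmentation_net = f0, upgrade_net = u, pseudo = pseudo,
       upgraded = upgraded, report = report)
}
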
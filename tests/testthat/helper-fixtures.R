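# shared fixtures, built in code

# a 20x20 map with 4 square target cells and 2 known distractor shapes
toy_map <- function() {
  v <- matrix(0L, 20, 20)
  v[2:4, 2:4] <- 1L; v[2:4, 10:12] <- 2L
  v[10:12, 2:4] <- 3L; v[10:14, 10:14] <- 4L
  fp <- matrix(0L, 20, 20)
  fp[17:18, 2:3] <- 1001L; fp[17:18, 10:11] <- 1002L
  instance_label_map(v, distractor_ids = c(1001L, 1002L),
                     distractor_footprints = fp)
}

# a 32x32 map with n square cells laid out on a grid (cells 3x3)
grid_map <- function(n_cells, n_distractors = 0L, size = 32L) {
  v <- matrix(0L, size, size)
  fp <- matrix(0L, size, size)
  pos <- expand.grid(r = seq(2L, size - 4L, by = 6L),
                     c = seq(2L, size - 4L, by = 6L))
  stopifnot(nrow(pos) >= n_cells + n_distractors)
  for (i in seq_len(n_cells))
    v[pos$r[i] + 0:2, pos$c[i] + 0:2] <- i
  for (j in seq_len(n_distractors)) {
    k <- n_cells + j
    fp[pos$r[k] + 0:1, pos$c[k] + 0:1] <- 1000L + j
  }
  instance_label_map(v, distractor_ids = if (n_distractors > 0)
    1000L + seq_len(n_distractors) else integer(),
    distractor_footprints = fp)
}

# independent brute-force morphology oracle: direct 3x3 neighbourhood sweep
# over every pixel, zero outside the image
sweep_morph <- function(mask, op, q) {
  m <- mask > 0
  h <- nrow(m); w <- ncol(m)
  for (it in seq_len(q)) {
    out <- matrix(FALSE, h, w)
    for (r in seq_len(h)) for (cc in seq_len(w)) {
      vals <- logical(0)
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        vals <- c(vals, if (rr >= 1 && rr <= h && ccc >= 1 && ccc <= w)
          m[rr, ccc] else FALSE)
      }
      out[r, cc] <- if (op == "erode") all(vals) else any(vals)
    }
    m <- out
  }
  m + 0L
}

# desk-scale training protocol used throughout the suite
desk_cfg <- function(seed, max_epochs = 25L) {
  train_config(learning_rate = 2e-3, batch_size = 4L, patience = 6L,
               max_epochs = max_epochs, val_fraction = 0.2,
               min_steps = 120L, max_steps = 160L, seed = seed)
}

tiny_net <- function(in_channels = 1L) {
  model_config(in_channels = in_channels, preset = "tiny")
}

# the desk-scale benchmark: 3 volumes; volumes 1-2 provide 20 HQ slices
# (equidistant circular sampling) and 16 LQ slices corrupted once with 70%
# omission; volume 3 is the held-out test volume. Memoised per session.
.bench_env <- new.env(parent = emptyenv())
toy_benchmark <- function() {
  if (!is.null(.bench_env$b)) return(.bench_env$b)
  vols <- generate_volumes(synthetic_config(n_volumes = 3, seed = 42))
  pool <- volumes_to_dataset(vols[1:2])
  plan <- sample_slices(vols[1:2], 20, 2)
  hq_idx <- match(sprintf("v%02d_s%03d", plan$volume, plan$slice), pool$ids)
  hq <- pool[hq_idx]
  rest <- setdiff(seq_len(length(pool)), hq_idx)
  lq_idx <- rest[round(seq(1, length(rest), length.out = 16))]
  spec <- perturbation_spec(omission_rate = 0.7, seed = 9)
  lq <- make_low_quality(pool[lq_idx], spec)
  test <- volumes_to_dataset(vols[[3]])
  test$truth <- lapply(seq_len(length(test)), function(i)
    binarize(test$labels[[i]]))
  lq_eval <- make_low_quality(test, spec)
  .bench_env$b <- list(vols = vols, hq = hq, lq = lq, test = test,
                       lq_eval = lq_eval, spec = spec)
  .bench_env$b
}

mask_list <- function(ds) lapply(seq_len(length(ds)), function(i)
  binarize(ds$labels[[i]]))
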
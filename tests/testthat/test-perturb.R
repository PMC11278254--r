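test_that("omission removes exactly round(rate * E) cells at every rate", {
  lab <- grid_map(10)
  for (rate in seq(0, 1, by = 0.1)) {
    set.seed(17)
    out <- perturb_omission(lab, rate)
    expect_equal(length(present_target_ids(out)), 10L - round(rate * 10),
                 info = paste("rate", rate))
    # monotone: foreground shrinks, untouched cells keep their footprint
    expect_true(all(out$values[out$values > 0] ==
                      lab$values[out$values > 0]))
    expect_true(all(binarize(out) <= binarize(lab)))
  }
  expect_identical(perturb_omission(lab, 0), lab)
})

test_that("omission survivors keep their exact footprints", {
  lab <- toy_map()
  set.seed(5)
  out <- perturb_omission(lab, 0.5)
  kept <- present_target_ids(out)
  expect_length(kept, 2L)
  # brute-force pixel recount against the original footprints
  expect_equal(sum(out$values > 0),
               sum(lab$values %in% kept))
  for (id in kept)
    expect_identical(which(out$values == id), which(lab$values == id))
})

test_that("inclusion adds exactly round(rate * F) shapes at every rate", {
  lab <- grid_map(3, n_distractors = 10)
  for (rate in seq(0, 1, by = 0.1)) {
    set.seed(23)
    out <- perturb_inclusion(lab, rate)
    added <- intersect(unique(as.vector(out$values)), lab$distractor_ids)
    expect_length(added, round(rate * 10))
    expect_true(all(binarize(out) >= binarize(lab)))
  }
  expect_identical(perturb_inclusion(lab, 0), lab)
})

test_that("binarized inclusion equals the union with included footprints", {
  lab <- grid_map(3, n_distractors = 4)
  set.seed(31)
  out <- perturb_inclusion(lab, 0.5)
  added <- intersect(unique(as.vector(out$values)), lab$distractor_ids)
  expected <- binarize(lab) | (lab$distractor_footprints %in% added)
  dim(expected) <- dim(lab$values)
  expect_equal(binarize(out), expected + 0L)
})

bias_with <- function(lab, qmax, want_op = NULL, want_q = NULL) {
  # draw until the logged per-cell operation matches the requested one
  for (s in 1:500) {
    set.seed(s)
    out <- perturb_bias(lab, qmax)
    log <- attr(out, "bias_log")
    if ((is.null(want_op) || all(log$op == want_op)) &&
        (is.null(want_q) || all(log$q == want_q)))
      return(out)
  }
  stop("no seed produced the requested operation")
}

test_that("bias erosion and dilation match closed forms on squares", {
  v <- matrix(0L, 11, 11); v[4:8, 4:8] <- 1L  # 5x5 interior square
  lab <- instance_label_map(v)
  out <- bias_with(lab, 2, "erode", 2)
  expect_equal(sum(out$values == 1L), 1)      # 5x5 eroded twice -> 1x1
  out <- bias_with(lab, 2, "dilate", 2)
  expect_equal(sum(out$values == 1L), 81)     # (5 + 2*2)^2
  # dilation clipped at the image border
  vb <- matrix(0L, 6, 6); vb[1:3, 1:3] <- 1L
  out <- bias_with(instance_label_map(vb), 1, "dilate", 1)
  expect_equal(sum(out$values == 1L), 16)     # 4x4 clipped corner
})

test_that("bias on a plus-shaped cell equals the brute-force sweep", {
  v <- matrix(0L, 9, 9)
  v[5, 4:6] <- 1L; v[4:6, 5] <- 1L           # 7-pixel plus (5 unique rows)
  lab <- instance_label_map(v)
  out <- bias_with(lab, 1, "dilate", 1)
  expect_equal((out$values > 0) + 0L, sweep_morph(v, "dilate", 1))
})

test_that("per-cell bias equals an independent structuring-element sweep", {
  for (case in 1:100) {
    set.seed(case)
    h <- sample(8:32, 1); w <- sample(8:32, 1)
    v <- matrix(0L, h, w)
    r0 <- sample(h - 3, 1); c0 <- sample(w - 3, 1)
    blob <- matrix(stats::runif(16) < 0.6, 4, 4)
    blob[2, 2] <- TRUE
    v[r0 + 0:3, c0 + 0:3][blob] <- 1L
    lab <- instance_label_map(v)
    set.seed(1000 + case)
    out <- perturb_bias(lab, 3)
    log <- attr(out, "bias_log")
    expect_equal((out$values > 0) + 0L, sweep_morph(v, log$op, log$q),
                 info = paste("case", case))
  }
})

test_that("bias never lets a dilating cell claim another instance", {
  v <- matrix(0L, 12, 12)
  v[3:5, 3:5] <- 1L; v[3:5, 8:10] <- 2L  # two cells 2 px apart
  lab <- instance_label_map(v)
  for (s in 1:30) {
    set.seed(s)
    out <- perturb_bias(lab, 3)
    log <- attr(out, "bias_log")
    # the second cell is processed after the first: its pixels never land on
    # the first cell's final footprint, and erosion-only cells never grow
    expect_equal(sum(out$values == 1L & v == 2L), 0)
    for (i in 1:2) {
      if (log$op[i] == "erode")
        expect_true(all(which(out$values == i) %in% which(v == i)))
    }
  }
  expect_identical(perturb_bias(lab, 0), lab)
})

test_that("a cell eroded to emptiness disappears and is logged", {
  v <- matrix(0L, 7, 7); v[3:4, 3:4] <- 1L  # 2x2 cell dies after one erosion
  lab <- instance_label_map(v)
  out <- bias_with(lab, 2, "erode", 2)
  expect_equal(sum(out$values), 0)
  expect_false(attr(out, "bias_log")$survived)
})

test_that("salt-and-pepper respects its selection rate", {
  m <- matrix(0L, 16, 16)
  expect_identical(perturb_salt_pepper(m, 0), m)
  set.seed(2)
  full <- perturb_salt_pepper(m, 1)
  # every pixel redrawn fair-coin: foreground fraction near 0.5
  expect_lt(abs(mean(full) - 0.5), 4 * sqrt(0.25 / length(m)) + 0.05)
  # at rate 0.1 the changed fraction of a blank mask is Binomial(n, 0.05)
  for (s in 1:10) {
    set.seed(s)
    big <- matrix(0L, 256, 256)
    out <- perturb_salt_pepper(big, 0.1)
    frac <- mean(out != big)
    expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / length(big)))
  }
})

test_that("felzenszwalb recovers piecewise-constant regions", {
  img <- matrix(0, 20, 20); img[, 11:20] <- 100
  seg <- felzenszwalb(img, scale = 50, sigma = 0, min_size = 5)
  expect_equal(max(seg), 2)
  expect_equal(length(unique(as.vector(seg[, 1:10]))), 1)
  expect_equal(length(unique(as.vector(seg[, 11:20]))), 1)
  expect_false(seg[1, 1] == seg[1, 20])
  uni <- felzenszwalb(matrix(5, 16, 16), scale = 50, sigma = 0, min_size = 5)
  expect_equal(max(uni), 1)
})

test_that("segment inclusion adds whole segments under fresh ids", {
  lab <- grid_map(2)
  img <- matrix(0, 32, 32); img[, 17:32] <- 200
  expect_identical(perturb_segment_inclusion(img, lab, 0), lab)
  # uniform image: one segment, round(0.1 * 1) = 0 additions
  set.seed(4)
  expect_warning(out <- perturb_segment_inclusion(matrix(7, 32, 32), lab, 0.1),
                 "degenerate")
  expect_identical(out$values, lab$values)
  # two regions: including 1 of 2 adds exactly that region's background px
  set.seed(4)
  out <- perturb_segment_inclusion(img, lab, 0.5,
                                   felz = list(scale = 50, sigma = 0,
                                               min_size = 5))
  seg <- felzenszwalb(img, scale = 50, sigma = 0, min_size = 5)
  new_ids <- setdiff(unique(as.vector(out$values)),
                     c(0L, unique(as.vector(lab$values))))
  expect_length(new_ids, 1)
  added_px <- sum(out$values %in% new_ids)
  region_sizes <- vapply(1:2, function(s) sum(seg == s & lab$values == 0L),
                         numeric(1))
  expect_true(added_px %in% region_sizes)
  expect_error(perturb_segment_inclusion(matrix(0, 5, 5), lab, 0.1),
               "same height")
})

test_that("composition applies the enabled stages and is seed-deterministic", {
  lab <- toy_map()
  img <- matrix(stats::runif(400) * 100, 20, 20)
  # all-zero spec is the identity
  P0 <- compose_perturbation(perturbation_spec(seed = 1))
  expect_identical(P0(lab, img), lab)
  # a single-stage spec behaves exactly like pure omission
  P1 <- compose_perturbation(perturbation_spec(omission_rate = 0.5, seed = 6))
  out <- P1(lab)
  expect_length(present_target_ids(out), 2L)
  kept <- present_target_ids(out)
  expect_identical(out$values[out$values > 0], lab$values[out$values > 0])
  expect_identical(out$distractor_footprints, lab$distractor_footprints)
  # same spec + seed -> identical draw sequence
  Pa <- compose_perturbation(perturbation_spec(omission_rate = 0.5,
                                               bias_qmax = 2, seed = 6))
  Pb <- compose_perturbation(perturbation_spec(omission_rate = 0.5,
                                               bias_qmax = 2, seed = 6))
  expect_identical(Pa(lab)$values, Pb(lab)$values)
  expect_identical(Pa(lab)$values, Pb(lab)$values)  # second draws agree too
  # successive draws differ (stochastic corruption)
  Pc <- compose_perturbation(perturbation_spec(omission_rate = 0.5, seed = 6))
  draws <- replicate(6, sum(Pc(lab)$values > 0))
  expect_gt(length(unique(draws)), 1)
})

test_that("a heavy composite corruption degrades the Dice below 1", {
  lab <- grid_map(10, n_distractors = 10)
  P <- compose_perturbation(perturbation_spec(omission_rate = 0.7,
                                              inclusion_rate = 0.7,
                                              bias_qmax = 6, seed = 2))
  out <- P(lab)
  expect_lt(dice_score(binarize(out), binarize(lab)), 1)
})

test_that("binarized omission output is a subset of the input foreground", {
  lab <- grid_map(8, n_distractors = 3)
  for (s in 1:20) {
    set.seed(s)
    out <- perturb_omission(lab, stats::runif(1))
    expect_true(all(binarize(out) <= binarize(lab)))
  }
})
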
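#' Configuration for the synthetic cell-volume generator
#'
#' The generator emulates virtual-microscope volumes containing a large-cell
#' target population (HL60-like nuclei) and a small-cell distractor
#' population (granulocyte-like objects). Cells are random axis-aligned
#' ellipsoids in (row, col, depth); successive slices of one volume cut the
#' same ellipsoids at successive depths, so adjacent slices are spatially
#' correlated. Intensities are built from a background level plus per-cell
#' levels, modulated by a multiplicative low-frequency texture, blurred, and
#' degraded with additive Gaussian noise, so that plain intensity
#' thresholding cannot segment the target class perfectly (soft boundary
#' ramps and bright distractors both defeat a single global threshold).
#'
#' Intensity units are raw counts of the configured bit depth (16-bit for
#' grayscale, 8-bit for RGB); radii and sigmas are in pixels.
#'
#' @param n_volumes Number of volumes.
#' @param slices_per_volume Slices generated per volume before empty-label
#'   slices are dropped.
#' @param height,width Slice size in pixels.
#' @param n_target_cells,n_distractor_cells Cells per volume.
#' @param target_radius_range,distractor_radius_range In-plane semi-axis
#'   ranges (pixels); must keep targets strictly larger on average.
#' @param target_depth_range,distractor_depth_range Depth semi-axis ranges
#'   (slices).
#' @param background_level,cell_level,distractor_level Mean intensities.
#' @param cell_level_sd Per-cell intensity spread.
#' @param texture_amplitude Relative amplitude of the multiplicative
#'   low-frequency texture field.
#' @param texture_scale Correlation length of the texture (pixels).
#' @param blur_sigma Gaussian blur applied to the clean image (pixels).
#' @param noise_sigma Additive Gaussian noise (intensity counts).
#' @param channels 1 for 16-bit grayscale, 3 for an 8-bit histology-like
#'   RGB rendering.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_volumes = 2L,
                             slices_per_volume = 24L,
                             height = 64L, width = 64L,
                             n_target_cells = 4L,
                             n_distractor_cells = 6L,
                             target_radius_range = c(6, 9),
                             distractor_radius_range = c(2, 3),
                             target_depth_range = c(8, 14),
                             distractor_depth_range = c(2, 5),
                             background_level = 8000,
                             cell_level = 30000,
                             distractor_level = 26000,
                             cell_level_sd = 4000,
                             texture_amplitude = 0.25,
                             texture_scale = 8,
                             blur_sigma = 1.2,
                             noise_sigma = 2500,
                             channels = 1L,
                             seed = 1L) {
  cfg <- list(n_volumes = as.integer(n_volumes),
              slices_per_volume = as.integer(slices_per_volume),
              height = as.integer(height), width = as.integer(width),
              n_target_cells = as.integer(n_target_cells),
              n_distractor_cells = as.integer(n_distractor_cells),
              target_radius_range = as.numeric(target_radius_range),
              distractor_radius_range = as.numeric(distractor_radius_range),
              target_depth_range = as.numeric(target_depth_range),
              distractor_depth_range = as.numeric(distractor_depth_range),
              background_level = background_level,
              cell_level = cell_level,
              distractor_level = distractor_level,
              cell_level_sd = cell_level_sd,
              texture_amplitude = texture_amplitude,
              texture_scale = texture_scale,
              blur_sigma = blur_sigma,
              noise_sigma = noise_sigma,
              channels = as.integer(channels),
              seed = as.integer(seed))
  cfg$bit_depth <- if (cfg$channels == 3L) 8L else 16L
  stopifnot(cfg$n_volumes > 0, cfg$slices_per_volume > 0,
            cfg$height > 0, cfg$width > 0, cfg$n_target_cells > 0,
            cfg$n_distractor_cells >= 0, cfg$channels %in% c(1L, 3L))
  if (mean(cfg$target_radius_range) <= mean(cfg$distractor_radius_range))
    stop("target cells must be strictly larger on average than distractors")
  if (2 * max(cfg$target_radius_range) >= min(cfg$height, cfg$width))
    stop("target radius range does not fit inside the image")
  class(cfg) <- "synthetic_config"
  cfg
}

DISTRACTOR_ID_OFFSET <- 1000L

# low-frequency texture field: coarse white noise interpolated bilinearly
smooth_noise_field <- function(h, w, scale) {
  gh <- max(2L, ceiling(h / scale) + 1L)
  gw <- max(2L, ceiling(w / scale) + 1L)
  g <- matrix(stats::rnorm(gh * gw), gh, gw)
  ry <- seq(1, gh, length.out = h)
  rx <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ry), gh - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), gw - 1L); fx <- rx - x0
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  cc <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fym <- rep(fy, w); fxm <- rep(fx, each = h)
  v <- (1 - fym) * (1 - fxm) * a + fym * (1 - fxm) * b +
    (1 - fym) * fxm * cc + fym * fxm * d
  f <- matrix(v, h, w)
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
  mp <- out[, pad_idx(ncol(m)), drop = FALSE]
  out2 <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out2 <- out2 + k[i] * mp[, i:(i + ncol(m) - 1L), drop = FALSE]
  out2
}

place_cells <- function(n, radius_range, depth_range, h, w, s, placed,
                        stratify_z, what) {
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(100L)) {
      ry <- stats::runif(1, radius_range[1], radius_range[2])
      rx <- stats::runif(1, radius_range[1], radius_range[2])
      rz <- stats::runif(1, depth_range[1], depth_range[2])
      cz <- if (stratify_z) {
        (i - 0.5) / n * s + stats::runif(1, -s / (2 * n), s / (2 * n))
      } else stats::runif(1, 1, s)
      rmax <- max(ry, rx)
      cy <- stats::runif(1, rmax + 1, h - rmax)
      cx <- stats::runif(1, rmax + 1, w - rmax)
      cand <- list(cy = cy, cx = cx, cz = cz, ry = ry, rx = rx, rz = rz)
      clash <- any(vapply(placed, function(p) {
        inplane <- sqrt((p$cy - cy)^2 + (p$cx - cx)^2) <
          (max(p$ry, p$rx) + rmax + 2)
        depth <- abs(p$cz - cz) < (p$rz + rz + 1)
        inplane && depth
      }, logical(1)))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("infeasible packing: could not place %s cell %d after 100 retries",
                   what, i))
    cells[[i]] <- cand
    placed <- c(placed, list(cand))
  }
  list(cells = cells, placed = placed)
}

# footprint of an ellipsoid cut at depth z, painted into `mat` with `id`
paint_slice <- function(mat, cell, z, id) {
  dz <- (z - cell$cz) / cell$rz
  if (abs(dz) >= 1) return(mat)
  sc <- sqrt(1 - dz^2)
  a <- cell$ry * sc; b <- cell$rx * sc
  if (a < 0.5 || b < 0.5) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  ys <- max(1L, floor(cell$cy - a)):min(h, ceiling(cell$cy + a))
  xs <- max(1L, floor(cell$cx - b)):min(w, ceiling(cell$cx + b))
  yy <- (ys - cell$cy) / a
  xx <- (xs - cell$cx) / b
  inside <- outer(yy^2, xx^2, "+") <= 1
  sub <- mat[ys, xs, drop = FALSE]
  sub[inside] <- id
  mat[ys, xs] <- sub
  mat
}

#' Generate seeded synthetic cell volumes
#'
#' Produces volumes of image slices paired with instance label maps. Target
#' and distractor ids come from disjoint ranges (targets from 1, distractors
#' from `1000 + 1`), all footprints in a slice are pairwise disjoint
#' (rejection sampling with 100 retries per cell), and slices without any
#' target cell are dropped. The noise-free intermediate image is kept in
#' each slice as `clean` for diagnostics.
#'
#' @param config A [synthetic_config()].
#' @return List of volumes; each volume is a list with `volume_id` and
#'   `slices`, a list of `list(image, label, clean)` where `image` is an
#'   H x W x C integer-valued array and `label` an [instance_label_map()].
#' @export
generate_volumes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  lapply(seq_len(config$n_volumes), function(v) generate_one_volume(config, v))
}

generate_one_volume <- function(cfg, volume_id) {
  h <- cfg$height; w <- cfg$width; s <- cfg$slices_per_volume
  tg <- place_cells(cfg$n_target_cells, cfg$target_radius_range,
                    cfg$target_depth_range, h, w, s, list(),
                    stratify_z = TRUE, what = "target")
  ds <- if (cfg$n_distractor_cells > 0) {
    place_cells(cfg$n_distractor_cells, cfg$distractor_radius_range,
                cfg$distractor_depth_range, h, w, s, tg$placed,
                stratify_z = FALSE, what = "distractor")
  } else list(cells = list())
  t_levels <- stats::rnorm(cfg$n_target_cells, cfg$cell_level, cfg$cell_level_sd)
  d_levels <- stats::rnorm(max(1L, cfg$n_distractor_cells),
                           cfg$distractor_level, cfg$cell_level_sd)
  imax <- 2^cfg$bit_depth - 1
  slices <- vector("list", s)
  for (z in seq_len(s)) {
    lab <- matrix(0L, h, w)
    fp <- matrix(0L, h, w)
    clean <- matrix(cfg$background_level, h, w)
    for (i in seq_along(tg$cells)) {
      lab <- paint_slice(lab, tg$cells[[i]], z, i)
      clean[lab == i] <- t_levels[i]
    }
    for (i in seq_along(ds$cells)) {
      id <- DISTRACTOR_ID_OFFSET + i
      fp <- paint_slice(fp, ds$cells[[i]], z, id)
      clean[fp == id] <- d_levels[i]
    }
    tex <- 1 + cfg$texture_amplitude * smooth_noise_field(h, w, cfg$texture_scale)
    img <- gaussian_blur(clean * tex, cfg$blur_sigma)
    img <- img + stats::rnorm(h * w, 0, cfg$noise_sigma)
    if (cfg$channels == 1L) {
      img <- array(pmin(pmax(round(img), 0), imax), c(h, w, 1L))
    } else {
      g <- pmin(pmax(img / (2^16 - 1), 0), 1)  # internal gray in [0,1]
      # histology-like rendering: pale pink background, purple objects
      bgc <- c(0.93, 0.82, 0.88) + stats::rnorm(3, 0, 0.01)
      fgc <- c(0.45, 0.20, 0.55) + stats::rnorm(3, 0, 0.02)
      img <- array(0, c(h, w, 3L))
      for (ch in 1:3) img[, , ch] <- bgc[ch] + (fgc[ch] - bgc[ch]) * g
      img <- pmin(pmax(round(img * imax), 0), imax)
    }
    label <- instance_label_map(
      lab,
      target_ids = sort(intersect(seq_along(tg$cells), unique(as.vector(lab)))),
      distractor_ids = sort(setdiff(unique(as.vector(fp)), 0L)),
      distractor_footprints = fp)
    slices[[z]] <- list(image = img, label = label, clean = clean,
                        slice_index = z)
  }
  keep <- vapply(slices, function(sl) any(sl$label$values > 0), logical(1))
  slices <- slices[keep]
  for (i in seq_along(slices)) slices[[i]]$slice_index <- i
  structure(list(volume_id = volume_id, slices = slices,
                 bit_depth = cfg$bit_depth, channels = cfg$channels),
            class = "cell_volume")
}

#' @export
print.cell_volume <- function(x, ...) {
  cat(sprintf("cell_volume %d: %d slices of %d x %d x %d (%d-bit)\n",
              x$volume_id, length(x$slices),
              dim(x$slices[[1]]$image)[1], dim(x$slices[[1]]$image)[2],
              x$channels, x$bit_depth))
  invisible(x)
}

#' Flatten volumes into an annotated dataset
#'
#' @param volumes List of volumes from [generate_volumes()], or a single
#'   volume.
#' @param provenance Provenance tag for the resulting dataset.
#' @param plan Optional [sample_slices()] plan restricting which slices are
#'   taken; by default all slices of all volumes are used.
#' @return An [annotated_dataset()].
#' @export
volumes_to_dataset <- function(volumes, provenance = "high_quality",
                               plan = NULL) {
  if (inherits(volumes, "cell_volume")) volumes <- list(volumes)
  sel <- if (is.null(plan)) {
    do.call(rbind, lapply(seq_along(volumes), function(v)
      data.frame(volume = v, slice = seq_along(volumes[[v]]$slices))))
  } else as.data.frame(plan)
  images <- vector("list", nrow(sel)); labels <- vector("list", nrow(sel))
  ids <- character(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    sl <- volumes[[sel$volume[i]]]$slices[[sel$slice[i]]]
    images[[i]] <- sl$image
    labels[[i]] <- sl$label
    ids[i] <- sprintf("v%02d_s%03d", sel$volume[i], sel$slice[i])
  }
  annotated_dataset(images, labels, provenance = provenance, ids = ids,
                    intensity_max = 2^volumes[[1]]$bit_depth - 1)
}
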
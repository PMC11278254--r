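#' Declarative description of a stochastic annotation corruption
#'
#' Bundles the three formal annotation perturbations — omission (a fraction
#' `r_omega` of target cells deleted), inclusion (a fraction `r_phi` of
#' distractor shapes added as false foreground), and bias (per-cell
#' morphological erosion/dilation with up to `qmax` iterations of a 3x3
#' all-ones structuring element) — together with the composite corruption
#' stages (Felzenszwalb segment inclusion and salt-and-pepper noise) used to
#' emulate the errors of an undertrained segmentation network.
#'
#' `resample_policy` distinguishes the two ways a perturbation is used:
#' `"once"` freezes one corruption per annotated image (how a fixed
#' low-quality set is manufactured), `"per_draw"` redraws the corruption at
#' every request (how upgrade-network training pairs are generated).
#'
#' @param omission_rate,inclusion_rate Rates in `[0, 1]`.
#' @param bias_qmax Non-negative integer; 0 disables the bias stage.
#' @param salt_pepper_rate Probability in `[0, 1]` that a pixel of the
#'   binarized label is re-drawn uniformly as foreground/background.
#' @param segment_inclusion_rate Fraction of Felzenszwalb segments of the
#'   image added as false foreground.
#' @param resample_policy `"once"` or `"per_draw"`.
#' @param felz Parameters for [felzenszwalb()].
#' @param seed Integer; drives all randomness of [compose_perturbation()].
#' @return A `perturbation_spec`.
#' @export
perturbation_spec <- function(omission_rate = 0, inclusion_rate = 0,
                              bias_qmax = 0, salt_pepper_rate = 0,
                              segment_inclusion_rate = 0,
                              resample_policy = c("once", "per_draw"),
                              felz = list(scale = 100, sigma = 0.8,
                                          min_size = 20),
                              seed = 1L) {
  resample_policy <- match.arg(resample_policy)
  rates <- c(omission_rate, inclusion_rate, salt_pepper_rate,
             segment_inclusion_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (bias_qmax < 0 || bias_qmax != round(bias_qmax))
    stop("bias_qmax must be a non-negative integer")
  structure(list(omission_rate = omission_rate,
                 inclusion_rate = inclusion_rate,
                 bias_qmax = as.integer(bias_qmax),
                 salt_pepper_rate = salt_pepper_rate,
                 segment_inclusion_rate = segment_inclusion_rate,
                 resample_policy = resample_policy,
                 felz = felz, seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Omission perturbation
#'
#' Deletes a uniformly chosen subset of the target cells: exactly
#' `round(rate * E)` of the `E` present target cells (rounding half away
#' from zero) have all their pixels set to background. Distractor
#' bookkeeping and all other pixels are untouched. Uses the current RNG
#' stream.
#'
#' @param label An [instance_label_map()].
#' @param rate Omission rate `r_omega` in `[0, 1]`.
#' @return The perturbed `instance_label_map`.
#' @export
perturb_omission <- function(label, rate) {
  stopifnot(is_label_map(label), rate >= 0, rate <= 1)
  ids <- present_target_ids(label)
  if (length(ids) == 0L || rate == 0) return(label)
  n_drop <- round_half_up(rate * length(ids))
  if (n_drop == 0L) return(label)
  drop <- sample(ids, n_drop)
  v <- label$values
  v[v %in% drop] <- 0L
  label$values <- v
  label
}

#' Inclusion perturbation
#'
#' Adds a uniformly chosen subset of the distractor shapes as false
#' foreground: exactly `round(rate * F)` of the `F` known distractor
#' footprints are written into the label with their own ids (so they become
#' foreground after [binarize()]).
#'
#' @param label An [instance_label_map()] whose metadata carries distractor
#'   footprints.
#' @param rate Inclusion rate `r_phi` in `[0, 1]`.
#' @return The perturbed `instance_label_map`.
#' @export
perturb_inclusion <- function(label, rate) {
  stopifnot(is_label_map(label), rate >= 0, rate <= 1)
  ids <- present_distractor_ids(label)
  if (length(ids) == 0L || rate == 0) return(label)
  n_add <- round_half_up(rate * length(ids))
  if (n_add == 0L) return(label)
  add <- sample(ids, n_add)
  v <- label$values
  fp <- label$distractor_footprints
  sel <- fp %in% add
  v[sel] <- fp[sel]
  label$values <- v
  label
}

# binary 3x3 all-ones morphology on a zero-padded window; EBImage's border
# handling is replicate-style, so each footprint is processed inside its own
# zero-padded window to get the zero-outside semantics the perturbation
# assumes
morph_iter <- function(mask, op, q) {
  kern <- EBImage::makeBrush(3L, shape = "box")
  m <- mask
  for (i in seq_len(q)) {
    m <- if (op == "erode") EBImage::erode(m, kern) else EBImage::dilate(m, kern)
  }
  m
}

#' Bias perturbation
#'
#' Models sloppy boundary delineation: for each present target cell
#' independently, an operation (erosion or dilation) is drawn uniformly and
#' a severity `q ~ Uniform{1..qmax}`; the cell's binary footprint then
#' undergoes `q` iterations of that operation with the fixed 3x3 all-ones
#' structuring element. Dilation only claims background pixels (cells are
#' processed in ascending id order, so the first-processed cell wins
#' simultaneous claims), and a cell eroded to emptiness disappears; such
#' events are recorded in the `"bias_log"` attribute of the result.
#'
#' @param label An [instance_label_map()].
#' @param qmax Maximum number of iterations; 0 returns the input unchanged.
#' @return The perturbed `instance_label_map` with a `"bias_log"` attribute
#'   (data frame: id, op, q, survived).
#' @export
perturb_bias <- function(label, qmax) {
  stopifnot(is_label_map(label), qmax >= 0, qmax == round(qmax))
  if (qmax == 0) return(label)
  ids <- present_target_ids(label)
  v <- label$values
  h <- nrow(v); w <- ncol(v)
  log <- data.frame(id = integer(), op = character(), q = integer(),
                    survived = logical())
  for (id in ids) {
    op <- sample(c("erode", "dilate"), 1L)
    q <- sample.int(qmax, 1L)
    px <- which(v == id, arr.ind = TRUE)
    pad <- q + 1L
    r0 <- min(px[, 1]) - pad; r1 <- max(px[, 1]) + pad
    c0 <- min(px[, 2]) - pad; c1 <- max(px[, 2]) + pad
    win <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    win[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- 1
    out <- morph_iter(win, op, q)
    # map window coordinates back, clipping at the image border
    v[v == id] <- 0L
    wpx <- which(out > 0.5, arr.ind = TRUE)
    if (nrow(wpx) > 0) {
      rr <- wpx[, 1] + r0 - 1L; cc <- wpx[, 2] + c0 - 1L
      keep <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      rr <- rr[keep]; cc <- cc[keep]
      lin <- cbind(rr, cc)
      free <- v[lin] == 0L  # dilation never overwrites other instances
      v[lin[free, , drop = FALSE]] <- id
    }
    survived <- any(v == id)
    log <- rbind(log, data.frame(id = id, op = op, q = q, survived = survived))
  }
  label$values <- v
  attr(label, "bias_log") <- log
  label
}

#' Salt-and-pepper corruption of a binary mask
#'
#' Each pixel is independently selected with probability `rate`; selected
#' pixels are set to foreground or background with equal chance.
#'
#' @param mask Binary (0/1) matrix.
#' @param rate Selection probability in `[0, 1]`.
#' @return Corrupted 0/1 integer matrix.
#' @export
perturb_salt_pepper <- function(mask, rate) {
  stopifnot(is.matrix(mask), rate >= 0, rate <= 1)
  m <- (mask > 0) + 0L
  if (rate == 0) return(m)
  sel <- stats::runif(length(m)) < rate
  m[sel] <- stats::rbinom(sum(sel), 1L, 0.5)
  dim(m) <- dim(mask)
  m
}

#' Felzenszwalb graph-based segmentation
#'
#' Efficient graph segmentation on the 8-connected pixel grid: edges are
#' sorted by intensity difference (Euclidean over channels after a Gaussian
#' pre-blur) and merged greedily when the edge weight does not exceed the
#' internal difference of either component plus its adaptive threshold
#' `scale / |C|`; components smaller than `min_size` are then merged with
#' their nearest neighbour.
#'
#' @param image Numeric matrix or H x W x C array.
#' @param scale Larger values favour larger segments.
#' @param sigma Pre-blur standard deviation in pixels.
#' @param min_size Minimum component size (pixels).
#' @return Integer matrix of segment labels `1..K`.
#' @export
felzenszwalb <- function(image, scale = 100, sigma = 0.8, min_size = 20) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  h <- dim(image)[1]; w <- dim(image)[2]; nc <- dim(image)[3]
  sm <- array(0, dim(image))
  for (ch in seq_len(nc)) sm[, , ch] <- gaussian_blur(image[, , ch], sigma)
  idx <- matrix(seq_len(h * w), h, w)
  edge_set <- function(dr, dc) {
    a <- idx[seq_len(h - abs(dr)) + max(-dr, 0), seq_len(w - abs(dc)) + max(-dc, 0), drop = FALSE]
    b <- idx[seq_len(h - abs(dr)) + max(dr, 0), seq_len(w - abs(dc)) + max(dc, 0), drop = FALSE]
    d2 <- 0
    for (ch in seq_len(nc)) {
      s <- sm[, , ch]
      d2 <- d2 + (s[a] - s[b])^2
    }
    cbind(as.vector(a), as.vector(b), sqrt(d2))
  }
  ed <- rbind(edge_set(1, 0), edge_set(0, 1), edge_set(1, 1), edge_set(-1, 1))
  ed <- ed[order(ed[, 3]), , drop = FALSE]
  n <- h * w
  parent <- seq_len(n); csize <- rep(1L, n); internal <- rep(0, n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
    root
  }
  for (e in seq_len(nrow(ed))) {
    a <- find(ed[e, 1]); b <- find(ed[e, 2])
    if (a == b) next
    wgt <- ed[e, 3]
    if (wgt <= min(internal[a] + scale / csize[a],
                   internal[b] + scale / csize[b])) {
      parent[b] <- a
      csize[a] <- csize[a] + csize[b]
      internal[a] <- wgt
    }
  }
  for (e in seq_len(nrow(ed))) {
    a <- find(ed[e, 1]); b <- find(ed[e, 2])
    if (a != b && (csize[a] < min_size || csize[b] < min_size)) {
      parent[b] <- a
      csize[a] <- csize[a] + csize[b]
    }
  }
  roots <- vapply(seq_len(n), function(i) as.integer(find(i)), integer(1))
  matrix(match(roots, unique(roots)), h, w)
}

#' Segment-inclusion perturbation
#'
#' Partitions the image with [felzenszwalb()] and adds `round(rate * K)` of
#' the `K` segments, chosen uniformly, as false foreground under fresh
#' instance ids outside both the target and distractor id sets. Only
#' background pixels are claimed, so existing instances are preserved.
#'
#' @param image Image matrix or H x W x C array matching the label size.
#' @param label An [instance_label_map()].
#' @param rate Fraction of segments to include.
#' @param felz Parameter list for [felzenszwalb()].
#' @return The perturbed `instance_label_map`.
#' @export
perturb_segment_inclusion <- function(image, label, rate,
                                      felz = list(scale = 100, sigma = 0.8,
                                                  min_size = 20)) {
  stopifnot(is_label_map(label), rate >= 0, rate <= 1)
  d <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  if (!all(d == dim(label$values)))
    stop("image and label must have the same height and width")
  if (rate == 0) return(label)
  seg <- felzenszwalb(image, scale = felz$scale, sigma = felz$sigma,
                      min_size = felz$min_size)
  k <- max(seg)
  if (k == 1L) warning("degenerate single-segment partition")
  n_add <- round_half_up(rate * k)
  if (n_add == 0L) return(label)
  chosen <- sample.int(k, n_add)
  fresh <- max(c(label$target_ids, label$distractor_ids,
                 as.vector(label$values), 0L))
  v <- label$values
  for (s in chosen) {
    fresh <- fresh + 1L
    v[seg == s & v == 0L] <- fresh
  }
  label$values <- v
  label
}

#' Compose a perturbation function from a spec
#'
#' Returns a callable `P(label, image = NULL)` applying the enabled stages
#' in the composite order: omission, then segment inclusion (needs the
#' image), then salt-and-pepper on the binarized label (connected components
#' are re-labelled as instances afterwards so the bias stage can act
#' per cell), then bias. Each invocation advances an internal deterministic
#' seed stream derived from `spec$seed`, so a fixed spec yields a
#' reproducible sequence of corruptions; with `resample_policy = "once"`
#' callers apply `P` a single time per sample and freeze the result, with
#' `"per_draw"` they re-apply it at every training iteration.
#'
#' @param spec A [perturbation_spec()].
#' @return A function of `(label, image = NULL)` returning an
#'   [instance_label_map()]; it carries the spec as attribute `"spec"`.
#' @export
compose_perturbation <- function(spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  counter <- 0L
  base <- spec$seed %% 10000L
  P <- function(label, image = NULL) {
    counter <<- counter + 1L
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(base * 100000L + counter)
    if (spec$omission_rate > 0) label <- perturb_omission(label, spec$omission_rate)
    if (spec$segment_inclusion_rate > 0) {
      if (is.null(image))
        stop("segment inclusion requires the image alongside the label")
      label <- perturb_segment_inclusion(image, label,
                                         spec$segment_inclusion_rate, spec$felz)
    }
    if (spec$inclusion_rate > 0) label <- perturb_inclusion(label, spec$inclusion_rate)
    if (spec$salt_pepper_rate > 0) {
      m <- perturb_salt_pepper(binarize(label), spec$salt_pepper_rate)
      comp <- EBImage::bwlabel(m)
      storage.mode(comp) <- "integer"
      label <- instance_label_map(comp,
                                  distractor_ids = label$distractor_ids,
                                  distractor_footprints = label$distractor_footprints)
    }
    if (spec$bias_qmax > 0) label <- perturb_bias(label, spec$bias_qmax)
    label
  }
  attr(P, "spec") <- spec
  P
}
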
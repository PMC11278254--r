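#' Network configuration
#'
#' Describes the encoder-decoder segmentation/upgrade network: `depth`
#' encoder blocks (each two 3x3 convolutions with batch normalisation and
#' ReLU) followed by 2x2 max pooling, a bottleneck block, and a mirrored
#' decoder with 2x2 transposed-convolution upsampling and skip connections
#' at equal spatial resolution. The output is a two-channel image processed
#' by a soft-max, channel 1 encoding background and channel 2 foreground.
#' Spatial sizes not divisible by `2^depth` are zero-padded internally and
#' cropped on output.
#'
#' @param in_channels Input channels: C for segmentation, C + 1 for the
#'   upgrade network (image plus the binarized low-quality label).
#' @param depth Number of encoder blocks (default 4).
#' @param base_channels Channels of the first block (default 64); doubled at
#'   each level.
#' @param preset `"tiny"` selects a desk-scale variant (depth 3, base 8)
#'   suitable for CPU-bound experiments and the test suite.
#' @return A `model_config`.
#' @export
model_config <- function(in_channels = 1L, depth = 4L, base_channels = 64L,
                         preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "tiny")
    depth <- 3L; base_channels <- 8L
  }
  stopifnot(in_channels >= 1, depth >= 1, base_channels >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 output_channels = 2L),
            class = "model_config")
}

# architecture as an ordered op sequence; skip bookkeeping by level index
unet_ops <- function(cfg) {
  d <- cfg$depth; base <- cfg$base_channels
  ch <- base * 2^(0:d)   # ch[i] = channels of level i; ch[d+1] = bottleneck
  ops <- list()
  add <- function(...) ops[[length(ops) + 1L]] <<- list(...)
  cin <- cfg$in_channels
  block <- function(nm, cin, cout) {
    add(op = "conv", nm = paste0(nm, ".conv1"), cin = cin, cout = cout)
    add(op = "bn", nm = paste0(nm, ".bn1"), c = cout)
    add(op = "relu")
    add(op = "conv", nm = paste0(nm, ".conv2"), cin = cout, cout = cout)
    add(op = "bn", nm = paste0(nm, ".bn2"), c = cout)
    add(op = "relu")
  }
  for (i in seq_len(d)) {
    block(paste0("enc", i), cin, ch[i])
    add(op = "save_skip", level = i)
    add(op = "pool")
    cin <- ch[i]
  }
  block("bot", cin, ch[d + 1])
  cin <- ch[d + 1]
  for (i in rev(seq_len(d))) {
    add(op = "up", nm = paste0("dec", i, ".up"), cin = cin, cout = ch[i])
    add(op = "concat", level = i, skip_c = ch[i])
    block(paste0("dec", i), 2L * ch[i], ch[i])
    cin <- ch[i]
  }
  add(op = "conv", nm = "out.conv", cin = cin, cout = cfg$output_channels)
  ops
}

#' Build an initialized network
#'
#' He-initialized convolution weights, unit-gamma/zero-beta batch
#' normalisation; deterministic for a fixed seed.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the parameter draw.
#' @return A `network_handle` with fields `config`, `params`, `state`
#'   (batch-norm running statistics), and `history`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  ops <- unet_ops(config)
  params <- list(); state <- list()
  for (o in ops) {
    if (o$op == "conv") {
      sd <- sqrt(2 / (9 * o$cin))
      params[[paste0(o$nm, ".W")]] <- matrix(stats::rnorm(9 * o$cin * o$cout, 0, sd),
                                             9 * o$cin, o$cout)
      params[[paste0(o$nm, ".b")]] <- numeric(o$cout)
    } else if (o$op == "up") {
      sd <- sqrt(2 / o$cin)
      params[[paste0(o$nm, ".W")]] <- matrix(stats::rnorm(o$cin * 4 * o$cout, 0, sd),
                                             o$cin, 4 * o$cout)
      params[[paste0(o$nm, ".b")]] <- numeric(o$cout)
    } else if (o$op == "bn") {
      params[[paste0(o$nm, ".g")]] <- rep(1, o$c)
      params[[paste0(o$nm, ".be")]] <- rep(0, o$c)
      state[[paste0(o$nm, ".rm")]] <- rep(0, o$c)
      state[[paste0(o$nm, ".rv")]] <- rep(1, o$c)
    }
  }
  structure(list(config = config, ops = ops, params = params, state = state,
                 history = NULL),
            class = "network_handle")
}

#' @export
print.network_handle <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("network_handle: depth %d, base %d, %d input channels, %s parameters\n",
              x$config$depth, x$config$base_channels, x$config$in_channels,
              format(np, big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, best validation Dice %.4f\n",
                nrow(x$history), max(x$history$val_dice)))
  invisible(x)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# batch normalisation primitives live in src/convops.cpp
bn_fw <- function(x, g, be, rm, rv, training) {
  cpp_bn_fw(x, g, be, rm, rv, training)
}

bn_bw <- function(gy, cache, g) {
  cpp_bn_bw(gy, cache$xhat, cache$isd, g)
}

up_fw <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  Cout <- length(b)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  ym <- xm %*% W
  y <- array(0, c(2L * H, 2L * Wd, Cout, N))
  offs <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (p in 1:4) {
    sl <- ym[, ((p - 1L) * Cout + 1L):(p * Cout), drop = FALSE]
    y[seq(offs[[p]][1], 2L * H, 2L), seq(offs[[p]][2], 2L * Wd, 2L), , ] <-
      aperm(array(sl, c(H, Wd, N, Cout)), c(1, 2, 4, 3))
  }
  sweep(y, 3, b, "+")
}

up_bw <- function(x, W, gy) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  Cout <- ncol(W) / 4L
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  gW <- matrix(0, nrow(W), ncol(W))
  gxm <- matrix(0, nrow(xm), C)
  gb <- numeric(Cout)
  offs <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (p in 1:4) {
    cols <- ((p - 1L) * Cout + 1L):(p * Cout)
    gp <- gy[seq(offs[[p]][1], 2L * H, 2L), seq(offs[[p]][2], 2L * Wd, 2L), , ,
             drop = FALSE]
    gpm <- matrix(aperm(gp, c(1, 2, 4, 3)), ncol = Cout)
    gW[, cols] <- crossprod(xm, gpm)
    gxm <- gxm + tcrossprod(gpm, W[, cols, drop = FALSE])
    gb <- gb + colSums(gpm)
  }
  gx <- aperm(array(gxm, c(H, Wd, N, C)), c(1, 2, 4, 3))
  list(gx = gx, gW = gW, gb = gb)
}

softmax2 <- function(z) {
  m <- pmax(z[, , 1, , drop = FALSE], z[, , 2, , drop = FALSE])
  e1 <- exp(z[, , 1, , drop = FALSE] - m)
  e2 <- exp(z[, , 2, , drop = FALSE] - m)
  s <- e1 + e2
  p <- z
  p[, , 1, ] <- e1 / s
  p[, , 2, ] <- e2 / s
  p
}

pad_to_multiple <- function(x, mult) {
  d <- dim(x)
  H2 <- ceiling(d[1] / mult) * mult
  W2 <- ceiling(d[2] / mult) * mult
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, H = d[1], W = d[2]))
  xp <- array(0, c(H2, W2, d[3], d[4]))
  xp[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(x = xp, H = d[1], W = d[2])
}

# forward pass; x is (H, W, Cin, N). Returns probabilities, logits, and (if
# requested) the cache needed by unet_backward.
unet_forward <- function(net, x, training = FALSE, want_cache = FALSE) {
  stopifnot(length(dim(x)) == 4L, dim(x)[3] == net$config$in_channels)
  pd <- pad_to_multiple(x, 2L^net$config$depth)
  cur <- pd$x
  caches <- vector("list", length(net$ops))
  skips <- list()
  new_state <- net$state
  for (k in seq_along(net$ops)) {
    o <- net$ops[[k]]
    if (o$op == "conv") {
      W <- net$params[[paste0(o$nm, ".W")]]
      b <- net$params[[paste0(o$nm, ".b")]]
      if (want_cache) caches[[k]] <- list(x = cur)
      cur <- cpp_conv_fw(cur, W, b)
    } else if (o$op == "bn") {
      r <- bn_fw(cur, net$params[[paste0(o$nm, ".g")]],
                 net$params[[paste0(o$nm, ".be")]],
                 net$state[[paste0(o$nm, ".rm")]],
                 net$state[[paste0(o$nm, ".rv")]], training)
      if (training) {
        new_state[[paste0(o$nm, ".rm")]] <-
          (1 - BN_MOMENTUM) * new_state[[paste0(o$nm, ".rm")]] + BN_MOMENTUM * r$mu
        new_state[[paste0(o$nm, ".rv")]] <-
          (1 - BN_MOMENTUM) * new_state[[paste0(o$nm, ".rv")]] + BN_MOMENTUM * r$va
      }
      if (want_cache) caches[[k]] <- r[c("xhat", "isd")]
      cur <- r$y
    } else if (o$op == "relu") {
      mask <- cur > 0
      if (want_cache) caches[[k]] <- list(mask = mask)
      cur <- cur * mask
    } else if (o$op == "pool") {
      r <- cpp_maxpool_fw(cur)
      if (want_cache) caches[[k]] <- list(idx = r$idx, xdim = dim(cur))
      cur <- r$y
    } else if (o$op == "save_skip") {
      skips[[o$level]] <- cur
    } else if (o$op == "up") {
      W <- net$params[[paste0(o$nm, ".W")]]
      b <- net$params[[paste0(o$nm, ".b")]]
      if (want_cache) caches[[k]] <- list(x = cur)
      cur <- up_fw(cur, W, b)
    } else if (o$op == "concat") {
      sk <- skips[[o$level]]
      if (want_cache) caches[[k]] <- list(up_c = dim(cur)[3])
      d <- dim(cur)
      both <- array(0, c(d[1], d[2], d[3] + dim(sk)[3], d[4]))
      both[, , seq_len(d[3]), ] <- cur
      both[, , d[3] + seq_len(dim(sk)[3]), ] <- sk
      cur <- both
    }
  }
  z <- cur
  p <- softmax2(z)
  crop <- function(a) a[seq_len(pd$H), seq_len(pd$W), , , drop = FALSE]
  list(p = crop(p), z = z, caches = caches, state = new_state,
       orig_hw = c(pd$H, pd$W), padded_hw = dim(z)[1:2])
}

# backward pass from gradient at the logits (padded size); returns flat
# gradient list aligned with net$params
unet_backward <- function(net, fw, gz) {
  grads <- lapply(net$params, function(p) { p[] <- 0; p })
  cur <- gz
  skip_grads <- list()
  for (k in rev(seq_along(net$ops))) {
    o <- net$ops[[k]]
    if (o$op == "conv") {
      r <- cpp_conv_bw(fw$caches[[k]]$x, net$params[[paste0(o$nm, ".W")]], cur,
                       k > 1L)  # the input gradient of the first layer is unused
      grads[[paste0(o$nm, ".W")]] <- r$gW
      grads[[paste0(o$nm, ".b")]] <- r$gb
      cur <- r$gx
    } else if (o$op == "bn") {
      r <- bn_bw(cur, fw$caches[[k]], net$params[[paste0(o$nm, ".g")]])
      grads[[paste0(o$nm, ".g")]] <- r$dg
      grads[[paste0(o$nm, ".be")]] <- r$dbe
      cur <- r$gx
    } else if (o$op == "relu") {
      cur <- cur * fw$caches[[k]]$mask
    } else if (o$op == "pool") {
      cur <- cpp_maxpool_bw(fw$caches[[k]]$idx, cur, fw$caches[[k]]$xdim)
    } else if (o$op == "save_skip") {
      sg <- skip_grads[[as.character(o$level)]]
      if (!is.null(sg)) cur <- cur + sg
    } else if (o$op == "up") {
      r <- up_bw(fw$caches[[k]]$x, net$params[[paste0(o$nm, ".W")]], cur)
      grads[[paste0(o$nm, ".W")]] <- r$gW
      grads[[paste0(o$nm, ".b")]] <- r$gb
      cur <- r$gx
    } else if (o$op == "concat") {
      uc <- fw$caches[[k]]$up_c
      skip_grads[[as.character(o$level)]] <-
        cur[, , (uc + 1L):dim(cur)[3], , drop = FALSE]
      cur <- cur[, , seq_len(uc), , drop = FALSE]
    }
  }
  grads
}

#' Forward pass returning per-pixel class probabilities
#'
#' Runs the network in evaluation mode (batch-norm running statistics).
#'
#' @param net A trained or initialized `network_handle`.
#' @param x Input array `(H, W, C)` for one sample or `(H, W, C, N)` for a
#'   batch; `C` must match the network's `in_channels`.
#' @return Array `(H, W, 2, N)` of probabilities; the two channels sum to 1
#'   at every pixel (channel 1 background, channel 2 foreground).
#' @export
network_forward <- function(net, x) {
  stopifnot(inherits(net, "network_handle"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  unet_forward(net, x, training = FALSE, want_cache = FALSE)$p
}

DICE_EPS <- 1e-6

#' Soft Dice loss
#'
#' `1 - soft-Dice` averaged over the two one-hot channels, with smoothing
#' `1e-6` guarding empty masks; 0 exactly when the prediction equals the
#' one-hot target.
#'
#' @param pred Probability array `(H, W, 2)` or `(H, W, 2, N)`; the two
#'   channels must sum to 1 per pixel.
#' @param target Binary foreground mask `(H, W)` or `(H, W, N)`.
#' @return Scalar loss, non-negative.
#' @export
dice_loss <- function(pred, target) {
  if (length(dim(pred)) == 3L) dim(pred) <- c(dim(pred), 1L)
  if (is.null(dim(target)) || length(dim(target)) == 2L)
    dim(target) <- c(dim(target), 1L)
  t_fg <- as.numeric(target > 0)
  dim(t_fg) <- dim(target)
  loss_chan <- function(p, t) {
    # p is (H, W, 1, N), t is (H, W, N); identical flattening order
    i <- sum(as.vector(p) * as.vector(t)); s <- sum(p) + sum(t)
    1 - (2 * i + DICE_EPS) / (s + DICE_EPS)
  }
  (loss_chan(pred[, , 1, , drop = FALSE], 1 - t_fg) +
     loss_chan(pred[, , 2, , drop = FALSE], t_fg)) / 2
}

# gradient of dice_loss at the logits (through the 2-channel soft-max)
dice_softmax_grad <- function(p, target) {
  d <- dim(p)
  t_fg <- as.numeric(target > 0); dim(t_fg) <- d[c(1, 2, 4)]
  gp <- p
  for (ch in 1:2) {
    t <- if (ch == 1) 1 - t_fg else t_fg
    pc <- p[, , ch, , drop = FALSE]; dim(pc) <- d[c(1, 2, 4)]
    i <- sum(pc * t); s <- sum(pc) + sum(t)
    gp[, , ch, ] <- -0.5 * (2 * t * (s + DICE_EPS) - (2 * i + DICE_EPS)) /
      (s + DICE_EPS)^2
  }
  dot <- gp[, , 1, , drop = FALSE] * p[, , 1, , drop = FALSE] +
    gp[, , 2, , drop = FALSE] * p[, , 2, , drop = FALSE]
  gz <- p
  for (ch in 1:2)
    gz[, , ch, ] <- p[, , ch, , drop = FALSE] *
      (gp[, , ch, , drop = FALSE] - dot)
  gz
}

#' Sørensen–Dice coefficient of two binary masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; two empty masks score 1 by convention. Lists of
#' masks are pooled into a single global ratio over all pixels, matching a
#' Dice coefficient computed over an entire test set.
#'
#' @param a,b Binary matrices (or lists of equally shaped binary matrices).
#' @return Scalar in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  if (!is.list(a)) { a <- list(a); b <- list(b) }
  stopifnot(length(a) == length(b))
  inter <- 0; total <- 0
  for (i in seq_along(a)) {
    ma <- a[[i]] > 0; mb <- b[[i]] > 0
    stopifnot(all(dim(ma) == dim(mb)))
    inter <- inter + sum(ma & mb)
    total <- total + sum(ma) + sum(mb)
  }
  if (total == 0) return(1)
  2 * inter / total
}

#' Save / load a network checkpoint
#'
#' Single-file, self-describing archive (RDS) embedding the configuration,
#' parameters, batch-norm state, and training history.
#'
#' @param net A `network_handle`.
#' @param path File path.
#' @return `save_network` returns `path` invisibly; `load_network` the
#'   restored `network_handle`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "network_handle"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "network_handle")) stop("not a network checkpoint: ", path)
  net
}
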
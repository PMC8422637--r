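#' Synthetic four-modality phantoms
#'
#' Generates everything the pipeline needs without clinical data: a
#' four-channel volume (emulating the flair/t1/t2/t1ce MRI modalities) with
#' spherical "tumor" blobs of smooth intensity falloff over a noisy "brain"
#' background, surrounded by a contiguous exactly-zero outer shell (air).
#' The zero shell covers a requested fraction of the background voxels -
#' realized exactly via a radius quantile - which is what makes whole
#' computation blocks skippable, as in real brain MRI where roughly 70% of
#' voxels are empty background. The ground-truth label volume marks blob
#' voxels with class 1.
#'
#' @param shape spatial shape (depth, height, width); axes should be
#'   divisible by the target network's pooling factor.
#' @param n_blobs number of tumor blobs (0 allowed).
#' @param radius_range blob radius range in voxels.
#' @param tumor_mean,background_mean per-modality intensity means (length 4
#'   or recycled).
#' @param noise_sd additive Gaussian noise s.d. for both compartments.
#' @param zero_frac target fraction of background voxels set exactly to 0,
#'   in \[0, 1).
#' @param n_modalities number of channels (default 4).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return List with `volume` (real `quantseg_volume`) and `labels`
#'   (single-channel label volume).
#' @examples
#' ph <- make_phantom(shape = c(16, 16, 16), seed = 1)
#' mean(vol_chw(ph$labels) == 1)
#' @export
make_phantom <- function(shape = c(16L, 16L, 16L), n_blobs = 2L,
                         radius_range = c(3, 5),
                         tumor_mean = c(0.85, 0.7, 0.75, 0.9),
                         background_mean = c(0.3, 0.25, 0.28, 0.32),
                         noise_sd = 0.04, zero_frac = 0.7,
                         n_modalities = 4L, seed = 1L) {
  stopifnot(length(shape) == 3L, zero_frac >= 0, zero_frac < 1)
  shape <- as.integer(shape)
  tumor_mean <- rep_len(tumor_mean, n_modalities)
  background_mean <- rep_len(background_mean, n_modalities)
  withr::with_seed(as.integer(seed), {
    ctr <- (shape + 1) / 2
    idx <- as.matrix(expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]),
                                 x = seq_len(shape[3])))
    # blob geometry: centers kept near the middle so blobs stay inside the
    # brain compartment, away from the zero shell
    rmax <- max(radius_range)
    if (n_blobs > 0 && any(2 * rmax + 2 > shape)) {
      stop("blobs of the requested radius cannot fit the volume shape", call. = FALSE)
    }
    label <- rep(FALSE, nrow(idx))
    falloff <- rep(0, nrow(idx))
    for (b in seq_len(n_blobs)) {
      rad <- stats::runif(1, radius_range[1], radius_range[2])
      cb <- vapply(1:3, function(a) stats::runif(1, ctr[a] - shape[a] / 6,
                                                 ctr[a] + shape[a] / 6), numeric(1))
      d2 <- (idx[, 1] - cb[1])^2 + (idx[, 2] - cb[2])^2 + (idx[, 3] - cb[3])^2
      inside <- d2 <= rad^2
      label <- label | inside
      falloff <- pmax(falloff, exp(-d2 / (2 * rad^2)))
    }
    # contiguous zero shell: the zero_frac quantile of background radius
    dc <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2)
    bg <- !label
    zero_mask <- rep(FALSE, nrow(idx))
    if (zero_frac > 0 && any(bg)) {
      # zero exactly the requested fraction of background voxels, outermost
      # first (rank on radius, deterministic tie-break), so the zero region
      # is a contiguous shell as in real brain MRI
      bg_idx <- which(bg)
      n_zero <- round(zero_frac * length(bg_idx))
      zero_mask[bg_idx[order(-dc[bg_idx])][seq_len(n_zero)]] <- TRUE
    }
    vol <- array(0, c(n_modalities, shape))
    for (m in seq_len(n_modalities)) {
      base <- ifelse(label,
                     tumor_mean[m] * (0.6 + 0.4 * falloff),
                     background_mean[m])
      vals <- base + stats::rnorm(length(base), sd = noise_sd)
      vals[zero_mask] <- 0
      vol[m, , , ] <- array(vals, shape)
    }
    list(volume = chw_to_vol(vol),
         labels = chw_to_vol(array(as.numeric(array(label, shape)), c(1L, shape))))
  })
}

#' Seeded random network with bounded activations
#'
#' Builds the U-Net topology of [build_unet3d()] and fills it with
#' reproducible random parameters. Convolution weights use a
#' delta-orthogonal-style initialization: a centre-tap delta kernel that
#' passes channel `i` through (modulo the channel count) plus Gaussian noise
#' scaled by fan-in, so the frozen backbone mixes but does not destroy the
#' input intensities and activations stay bounded. Biases are zero (the
#' exactly-zero background of a phantom stays zero through the encoder, as
#' in a network trained on zero-background MRI); BN statistics have variance
#' in \[0.5, 1.5\]. Two calls with the same seed are identical.
#'
#' @param channels_base,depth_levels,in_channels,out_classes as in
#'   [build_unet3d()].
#' @param seed integer seed.
#' @return A `unet_graph`.
#' @export
make_random_network <- function(channels_base, depth_levels, seed,
                                in_channels = 4L, out_classes = 2L) {
  g <- build_unet3d(channels_base, depth_levels, in_channels, out_classes)
  withr::with_seed(as.integer(seed), {
    for (i in seq_along(g$layers)) {
      ly <- g$layers[[i]]
      if (ly$type %in% c("conv", "deconv")) {
        d <- dim(ly$params$weights)
        fan_in <- prod(d[-1])
        w <- array(stats::rnorm(prod(d), sd = 0.3 / sqrt(fan_in)), d)
        ctr <- pmax((d[3:5] + 1L) %/% 2L, 1L)
        for (o in seq_len(d[1])) {     # identity-passing centre tap
          w[o, (o - 1L) %% d[2] + 1L, ctr[1], ctr[2], ctr[3]] <-
            w[o, (o - 1L) %% d[2] + 1L, ctr[1], ctr[2], ctr[3]] + 1
        }
        g$layers[[i]]$params$weights <- w
        g$layers[[i]]$params$bias <- rep(0, d[1])
      } else if (ly$type == "bn") {
        ch <- ly$out_ch
        g$layers[[i]]$params <- bn_params(
          mean = stats::rnorm(ch, sd = 0.05),
          variance = stats::runif(ch, 0.5, 1.5),
          gamma = stats::runif(ch, 0.8, 1.2),
          beta = stats::rnorm(ch, sd = 0.05))
      }
    }
  })
  g
}

# classifier-input feature maps of a network (activations entering the final
# 1x1x1 classifier convolution)
infer_features <- function(net, v) {
  n <- length(net$layers)
  feats <- NULL
  rec <- function(ly, x, y) if (ly$id == n) feats <<- x
  infer_float(net, v, record = rec)
  feats
}

#' Toy fitting helper
#'
#' Stand-in for full-scale training, used only to obtain a network that
#' actually segments the synthetic phantoms: the randomly initialized
#' backbone is kept frozen and the 1x1x1 classifier head is fitted by
#' full-batch gradient descent on a voxelwise class-weighted softmax
#' cross-entropy over standardized backbone features (a convex problem, so
#' the outcome does not depend on a lucky initialization). The
#' standardization is folded back into the classifier weights, so the
#' returned object is an ordinary `unet_graph`. With `steps = 0` the network
#' is returned unchanged.
#'
#' @param net a `unet_graph` (random weights; see [make_random_network()]).
#' @param phantoms list of `make_phantom()` results used for fitting.
#' @param steps gradient steps (default 300).
#' @param seed integer seed (kept for interface symmetry; the fit itself is
#'   deterministic).
#' @param lr learning rate on standardized features.
#' @param holdout optional list of phantoms; when supplied, the fitted
#'   network's mean foreground Dice on them must reach `dsc_floor`,
#'   otherwise an error is raised (the fixture contract failed).
#' @param dsc_floor Dice floor checked on `holdout` (default 0.8).
#' @return The fitted `unet_graph`.
#' @export
fit_toy <- function(net, phantoms, steps = 300L, seed = 1L, lr = 0.5,
                    holdout = NULL, dsc_floor = 0.8) {
  stopifnot(inherits(net, "unet_graph"), length(phantoms) >= 1L)
  if (steps > 0L) {
    nc <- net$out_classes
    feats <- lapply(phantoms, function(ph) {
      f <- infer_features(net, ph$volume)
      dim(f) <- c(dim(f)[1], prod(dim(f)[2:4]))
      f
    })
    X <- do.call(cbind, feats)                       # features x voxels
    yv <- unlist(lapply(phantoms, function(ph) as.vector(vol_chw(ph$labels))))
    mu <- rowMeans(X)
    sdv <- pmax(sqrt(rowMeans((X - mu)^2)), 1e-6)
    Xs <- (X - mu) / sdv
    Y <- matrix(0, nc, length(yv))                   # one-hot classes x voxels
    Y[cbind(yv + 1L, seq_along(yv))] <- 1
    wcls <- as.numeric(table(factor(yv, levels = 0:(nc - 1))))
    wvox <- (length(yv) / (nc * pmax(wcls, 1)))[yv + 1L]
    wvox <- wvox / mean(wvox)
    W <- matrix(0, nc, nrow(Xs)); b <- rep(0, nc)
    nvox <- length(yv)
    for (s in seq_len(steps)) {
      Z <- W %*% Xs + b
      Z <- Z - rep(apply(Z, 2, max), each = nc)
      P <- exp(Z); P <- P / rep(colSums(P), each = nc)
      G <- (P - Y) * rep(wvox, each = nc)            # d(loss)/dZ, weighted
      W <- W - lr * (G %*% t(Xs)) / nvox
      b <- b - lr * rowSums(G) / nvox
    }
    # fold standardization into the classifier convolution
    Wf <- W / rep(sdv, each = nc)
    bf <- b - as.numeric(Wf %*% mu)
    cls <- length(net$layers)
    d <- dim(net$layers[[cls]]$params$weights)
    net$layers[[cls]]$params$weights <- array(Wf, d)
    net$layers[[cls]]$params$bias <- bf
  }
  if (!is.null(holdout)) {
    ds <- vapply(holdout, function(ph) {
      lab <- argmax_labels(infer_float(net, ph$volume))
      seg_metrics(lab, ph$labels, n_classes = net$out_classes)$mean_dice_fg
    }, numeric(1))
    if (mean(ds) < dsc_floor) {
      stop(sprintf("toy fit failed its contract: held-out Dice %.3f < floor %.2f",
                   mean(ds), dsc_floor), call. = FALSE)
    }
  }
  net
}
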
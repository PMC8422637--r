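#' Float reference inference
#'
#' Runs a `unet_graph` on a real-valued volume in plain double precision.
#' This path defines the ground truth that BN folding, int8 quantization and
#' the decomposed/partitioned execution paths are all tested against.
#'
#' @param net a `unet_graph`.
#' @param v a real-valued `quantseg_volume` whose channel count equals the
#'   network's input channels and whose spatial axes are divisible by
#'   `2^(depth_levels - 1)`.
#' @param record optional function called as `record(layer, x, y)` with each
#'   layer's input and output arrays (used by activation calibration).
#' @return A real-valued `quantseg_volume` of per-class scores with the same
#'   spatial shape as the input.
#' @export
infer_float <- function(net, v, record = NULL) {
  stopifnot(inherits(net, "unet_graph"), inherits(v, "quantseg_volume"))
  if (v$value_kind != "real") stop("infer_float needs a real-valued volume", call. = FALSE)
  if (vol_channels(v) != net$in_channels) {
    stop(sprintf("volume has %d channels, network expects %d",
                 vol_channels(v), net$in_channels), call. = FALSE)
  }
  pool <- 2L^(net$depth_levels - 1L)
  if (any(vol_spatial(v) %% pool != 0L)) {
    stop(sprintf("spatial axes (%s) must be divisible by %d for %d pooling levels",
                 paste(vol_spatial(v), collapse = "x"), pool, net$depth_levels),
         call. = FALSE)
  }
  outs <- vector("list", length(net$layers) + 1L)
  outs[[1L]] <- vol_chw(v)   # slot i+1 holds output of layer id i
  for (ly in net$layers) {
    xs <- lapply(ly$inputs, function(i) outs[[i + 1L]])
    x <- if (length(xs) == 1L) xs[[1L]] else concat_channels(xs, ly)
    y <- layer_forward_float(ly, x)
    if (!is.null(record)) record(ly, x, y)
    outs[[ly$id + 1L]] <- y
  }
  chw_to_vol(outs[[length(outs)]])
}

concat_channels <- function(xs, ly) {
  sh <- dim(xs[[1L]])[2:4]
  for (x in xs) {
    if (!identical(dim(x)[2:4], sh)) {
      stop(sprintf("concat layer %d ('%s'): predecessor spatial shapes differ (%s vs %s)",
                   ly$id, ly$name, paste(sh, collapse = "x"),
                   paste(dim(x)[2:4], collapse = "x")), call. = FALSE)
    }
  }
  chs <- vapply(xs, function(x) dim(x)[1], integer(1))
  out <- array(0, c(sum(chs), sh))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

layer_forward_float <- function(ly, x) {
  if (dim(x)[1] != ly$in_ch) {
    stop(sprintf("layer %d ('%s') expected %d input channels, got %d",
                 ly$id, ly$name, ly$in_ch, dim(x)[1]), call. = FALSE)
  }
  switch(ly$type,
    conv = {
      p <- ly$params
      y <- tryCatch(
        conv3d_forward(x, p$weights, stride = p$stride, padding = p$padding),
        error = function(e) stop(sprintf("layer %d ('%s'): %s", ly$id, ly$name,
                                         conditionMessage(e)), call. = FALSE))
      y + ly$params$bias
    },
    deconv = {
      p <- ly$params
      deconv3d_forward(x, p$weights, stride = p$stride, padding = p$padding) +
        p$bias
    },
    bn = bn_forward(ly$params, x),
    relu = pmax(x, 0),
    maxpool = maxpool_forward(x, ly$pool),
    concat = x,   # concatenation happened when gathering inputs
    stop(sprintf("unknown layer type '%s'", ly$type), call. = FALSE)
  )
}

bn_forward <- function(bn, x) {
  scale <- bn$gamma / sqrt(bn$variance + bn$epsilon)
  shift <- bn$beta - bn$mean * scale
  x * scale + shift   # channel axis is first: R recycles per channel
}

maxpool_forward <- function(x, pool = c(2L, 2L, 2L)) {
  d <- dim(x)
  if (any(d[2:4] %% pool != 0L)) {
    stop("maxpool input axes must be divisible by the pool size", call. = FALSE)
  }
  osz <- d[2:4] %/% pool
  iz <- seq(1L, by = pool[1], length.out = osz[1])
  iy <- seq(1L, by = pool[2], length.out = osz[2])
  ix <- seq(1L, by = pool[3], length.out = osz[3])
  out <- NULL
  for (a in seq_len(pool[1]) - 1L) {
    for (b in seq_len(pool[2]) - 1L) {
      for (cc in seq_len(pool[3]) - 1L) {
        s <- x[, iz + a, iy + b, ix + cc, drop = FALSE]
        out <- if (is.null(out)) s else pmax(out, s)
      }
    }
  }
  dim(out) <- c(d[1], osz)
  out
}

#' Per-voxel argmax labels
#'
#' Collapses a multi-channel score volume to a single-channel integer label
#' volume. Labels are 0-based channel indices; ties break toward the lowest
#' class index. Works identically for real scores and int8 codes (argmax is
#' monotone, so a softmax is redundant for labeling).
#'
#' @param scores a `quantseg_volume` with >= 1 channel.
#' @return A single-channel real `quantseg_volume` of integer labels.
#' @export
argmax_labels <- function(scores) {
  stopifnot(inherits(scores, "quantseg_volume"))
  x <- vol_chw(scores)
  d <- dim(x)
  m <- matrix(x, nrow = d[1])           # classes x voxels
  lab <- max.col(t(m), ties.method = "first") - 1L
  chw_to_vol(array(as.numeric(lab), c(1L, d[2:4])))
}
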
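#' Layer graphs for 3D U-Net-style networks
#'
#' A `unet_graph` is an ordered, acyclic list of typed layer records.
#' Supported layer types: `conv` (3-D convolution, also the 1x1x1 classifier
#' head), `deconv` (transposed convolution), `bn` (batch normalization),
#' `relu`, `maxpool` (2x2x2, stride 2) and `concat` (channel concatenation of
#' exactly two predecessors with equal spatial shape). Each layer lists the
#' ids of its predecessors in `inputs`; id 0 denotes the network input. The
#' layer list is in topological order.
#'
#' @name unet_graph
NULL

new_layer <- function(id, name, type, inputs, in_ch, out_ch, ...) {
  c(list(id = as.integer(id), name = name, type = type,
         inputs = as.integer(inputs), in_ch = as.integer(in_ch),
         out_ch = as.integer(out_ch)),
    list(...))
}

#' Convolution / deconvolution parameters
#'
#' @param weights 5-axis tensor (out_ch, in_ch, kd, kh, kw).
#' @param bias numeric vector of length out_ch.
#' @param stride,padding positive / non-negative integer triples.
#' @param transposed logical; `TRUE` marks a transposed (deconvolution) layer.
#' @return A `conv_params` list.
#' @export
conv_params <- function(weights, bias, stride = c(1L, 1L, 1L),
                        padding = c(0L, 0L, 0L), transposed = FALSE) {
  d <- dim(weights)
  if (length(d) != 5L) stop("weights must be 5-axis (out, in, kd, kh, kw)", call. = FALSE)
  if (any(d[3:5] < 1L)) stop("kernel extents must be >= 1", call. = FALSE)
  if (length(bias) != d[1]) stop("bias length must equal out_ch", call. = FALSE)
  stride <- rep_len(as.integer(stride), 3L)
  if (any(stride < 1L)) stop("stride components must be >= 1", call. = FALSE)
  padding <- rep_len(as.integer(padding), 3L)
  if (any(padding < 0L)) stop("padding components must be >= 0", call. = FALSE)
  list(weights = weights, bias = as.numeric(bias), stride = stride,
       padding = padding, transposed = isTRUE(transposed))
}

#' Batch-normalization parameters
#'
#' Per-channel statistics and affine terms of a BN layer: input mean `mu`,
#' input variance `sigma2`, scale `gamma`, offset `beta`, and the small
#' `epsilon` that keeps the denominator away from zero.
#'
#' @param mean,variance,gamma,beta numeric vectors of equal length (channels).
#' @param epsilon small positive real; default `1e-5`.
#' @return A `bn_params` list.
#' @export
bn_params <- function(mean, variance, gamma, beta, epsilon = 1e-5) {
  n <- length(mean)
  if (length(variance) != n || length(gamma) != n || length(beta) != n) {
    stop("BN parameter vectors must share one length", call. = FALSE)
  }
  if (any(variance < 0)) stop("BN variance must be >= 0 elementwise", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0) stop("BN epsilon must be > 0", call. = FALSE)
  list(mean = as.numeric(mean), variance = as.numeric(variance),
       gamma = as.numeric(gamma), beta = as.numeric(beta),
       epsilon = as.numeric(epsilon))
}

new_unet_graph <- function(layers, in_channels, out_classes, depth_levels,
                           channels_base) {
  g <- structure(
    list(layers = layers, in_channels = as.integer(in_channels),
         out_classes = as.integer(out_classes),
         depth_levels = as.integer(depth_levels),
         channels_base = as.integer(channels_base)),
    class = "unet_graph")
  validate_unet_graph(g)
  g
}

validate_unet_graph <- function(g) {
  seen <- 0L
  for (ly in g$layers) {
    if (any(!ly$inputs %in% seen)) {
      stop(sprintf("layer %d ('%s') references a later or unknown layer (graph must be acyclic, topologically ordered)",
                   ly$id, ly$name), call. = FALSE)
    }
    if (ly$type == "concat" && length(ly$inputs) != 2L) {
      stop(sprintf("concat layer %d must have exactly two predecessors", ly$id),
           call. = FALSE)
    }
    in_ch <- sum(vapply(ly$inputs, function(i) layer_out_ch(g, i), integer(1)))
    if (in_ch != ly$in_ch) {
      stop(sprintf("channel mismatch at layer %d ('%s'): predecessors provide %d, layer expects %d",
                   ly$id, ly$name, in_ch, ly$in_ch), call. = FALSE)
    }
    seen <- c(seen, ly$id)
  }
  invisible(g)
}

layer_out_ch <- function(g, id) {
  if (id == 0L) return(g$in_channels)
  g$layers[[id]]$out_ch
}

#' @export
print.unet_graph <- function(x, ...) {
  cat(sprintf("<unet_graph> %d layers, in=%d channels, %d classes, %d levels (base %d)\n",
              length(x$layers), x$in_channels, x$out_classes, x$depth_levels,
              x$channels_base))
  invisible(x)
}

#' Summarize a layer graph as a tibble
#'
#' One row per layer: id, name, type, predecessor ids, channel counts.
#'
#' @param g a `unet_graph`.
#' @return A tibble.
#' @export
layer_table <- function(g) {
  tibble::tibble(
    id = vapply(g$layers, `[[`, integer(1), "id"),
    name = vapply(g$layers, `[[`, character(1), "name"),
    type = vapply(g$layers, `[[`, character(1), "type"),
    inputs = vapply(g$layers, function(l) paste(l$inputs, collapse = ","), character(1)),
    in_ch = vapply(g$layers, `[[`, integer(1), "in_ch"),
    out_ch = vapply(g$layers, `[[`, integer(1), "out_ch")
  )
}

#' Build a 3D U-Net layer graph
#'
#' Constructs the standard encoder--decoder topology: an analysis path of
#' conv--BN--ReLU pairs with 2x2x2 max pooling between resolution levels, and
#' a synthesis path of stride-2 deconvolution upsampling, skip-connection
#' concatenation (skip channels first) and further conv--BN--ReLU pairs,
#' ending in a 1x1x1 classifier convolution. Channel widths double per level:
#' level `l` uses `channels_base * 2^(l-1)` channels, so with
#' `channels_base = 32` and 4 input modalities the first two convolutions map
#' 4 -> 32 -> 32 and level 2 maps 32 -> 64 -> 64. All 3x3x3 convolutions use
#' "same" zero padding 1 so skip shapes agree; deconvolutions use kernel 2,
#' stride 2, padding 0 (exact doubling).
#'
#' Weights are zero-initialized; see [make_random_network()] for a seeded
#' random network.
#'
#' @param channels_base channel width of the first level (>= 1).
#' @param depth_levels number of resolution levels (>= 1).
#' @param in_channels input channels (4 for flair/t1/t2/t1ce MRI).
#' @param out_classes classifier output channels.
#' @return A `unet_graph`.
#' @examples
#' g <- build_unet3d(2, 2, in_channels = 4, out_classes = 3)
#' layer_table(g)
#' @export
build_unet3d <- function(channels_base, depth_levels, in_channels = 4L,
                         out_classes = 3L) {
  stopifnot(channels_base >= 1, depth_levels >= 1, in_channels >= 1,
            out_classes >= 1)
  layers <- list()
  nid <- 0L
  add <- function(name, type, inputs, in_ch, out_ch, ...) {
    nid <<- nid + 1L
    layers[[nid]] <<- new_layer(nid, name, type, inputs, in_ch, out_ch, ...)
    nid
  }
  zero_conv <- function(in_ch, out_ch, k = c(3L, 3L, 3L), pad = c(1L, 1L, 1L),
                        stride = c(1L, 1L, 1L), transposed = FALSE) {
    conv_params(array(0, c(out_ch, in_ch, k)), rep(0, out_ch),
                stride = stride, padding = pad, transposed = transposed)
  }
  ident_bn <- function(ch) bn_params(rep(0, ch), rep(1, ch), rep(1, ch), rep(0, ch))
  add_conv_block <- function(tag, from, in_ch, out_ch) {
    cid <- add(paste0(tag, "_conv"), "conv", from, in_ch, out_ch,
               params = zero_conv(in_ch, out_ch))
    bid <- add(paste0(tag, "_bn"), "bn", cid, out_ch, out_ch,
               params = ident_bn(out_ch))
    add(paste0(tag, "_relu"), "relu", bid, out_ch, out_ch)
  }
  width <- function(lev) channels_base * 2L^(lev - 1L)

  prev <- 0L
  prev_ch <- in_channels
  skips <- integer(depth_levels)
  for (lev in seq_len(depth_levels)) {
    w <- width(lev)
    prev <- add_conv_block(sprintf("enc%d_a", lev), prev, prev_ch, w)
    prev <- add_conv_block(sprintf("enc%d_b", lev), prev, w, w)
    skips[lev] <- prev
    prev_ch <- w
    if (lev < depth_levels) {
      prev <- add(sprintf("pool%d", lev), "maxpool", prev, w, w,
                  pool = c(2L, 2L, 2L))
    }
  }
  if (depth_levels > 1L) {
    for (lev in seq(depth_levels - 1L, 1L)) {
      w_lo <- width(lev + 1L)
      w <- width(lev)
      did <- add(sprintf("up%d_deconv", lev), "deconv", prev, w_lo, w,
                 params = zero_conv(w_lo, w, k = c(2L, 2L, 2L), pad = c(0L, 0L, 0L),
                                    stride = c(2L, 2L, 2L), transposed = TRUE))
      bid <- add(sprintf("up%d_bn", lev), "bn", did, w, w, params = ident_bn(w))
      rid <- add(sprintf("up%d_relu", lev), "relu", bid, w, w)
      # skip-connection channels first, upsampled channels second
      cid <- add(sprintf("up%d_concat", lev), "concat", c(skips[lev], rid),
                 2L * w, 2L * w)
      prev <- add_conv_block(sprintf("dec%d_a", lev), cid, 2L * w, w)
      prev <- add_conv_block(sprintf("dec%d_b", lev), prev, w, w)
      prev_ch <- w
    }
  }
  add("classifier", "conv", prev, prev_ch, out_classes,
      params = zero_conv(prev_ch, out_classes, k = c(1L, 1L, 1L),
                         pad = c(0L, 0L, 0L)))
  new_unet_graph(layers, in_channels, out_classes, depth_levels, channels_base)
}

count_layers <- function(g, type) {
  sum(vapply(g$layers, function(l) l$type == type, logical(1)))
}
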
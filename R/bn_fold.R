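#' Fold a batch-normalization layer into the preceding convolution
#'
#' Inference does not need BN as a separate layer: for a convolution
#' `Y = W * X + B` followed by BN with statistics `mu`, `sigma2`, scale
#' `gamma`, offset `beta` and stabilizer `eps`, the two compose into a single
#' convolution with
#' \deqn{W' = W \cdot \gamma / \sqrt{\sigma^2 + \epsilon}}
#' \deqn{B' = (B - \mu) \cdot \gamma / \sqrt{\sigma^2 + \epsilon} + \beta}
#' so that `W' * X + B'` reproduces BN(conv(X)) exactly. The same identity
#' holds for deconvolution, whose core computation is the same
#' multiply-accumulate.
#'
#' @param conv a `conv_params`.
#' @param bn a `bn_params` whose vectors have length `out_ch`.
#' @return A `conv_params` with merged weights and bias (same shapes,
#'   stride/padding/transposed unchanged).
#' @examples
#' cp <- conv_params(array(2, c(1, 1, 1, 1, 1)), 0)
#' bp <- bn_params(0, 3, 2, 0, epsilon = 1)
#' fold_bn(cp, bp)$weights[1]   # 2 * 2 / sqrt(4) = 2
#' @export
fold_bn <- function(conv, bn) {
  oc <- dim(conv$weights)[1]
  if (length(bn$mean) != oc) {
    stop(sprintf("BN has %d channels but convolution has %d output channels",
                 length(bn$mean), oc), call. = FALSE)
  }
  scale <- bn$gamma / sqrt(bn$variance + bn$epsilon)
  w <- conv$weights
  d <- dim(w)
  dim(w) <- c(oc, prod(d[-1]))
  w <- w * scale          # recycles per output channel (first axis)
  dim(w) <- d
  conv_params(w, (conv$bias - bn$mean) * scale + bn$beta,
              stride = conv$stride, padding = conv$padding,
              transposed = conv$transposed)
}

#' Remove every BN layer from a graph by folding
#'
#' Traverses the graph, merges each BN layer into its (single, immediately
#' preceding) convolutional or deconvolutional layer with [fold_bn()], and
#' rewires the BN layer's consumers to the merged convolution. Float
#' inference on the folded graph matches the original within rounding error.
#' A BN layer whose predecessor is not a conv/deconv is a structural error,
#' never silently skipped. The operation is idempotent: a graph without BN
#' layers is returned unchanged.
#'
#' @param net a `unet_graph`.
#' @return A `unet_graph` with no `bn` layers.
#' @export
fold_network <- function(net) {
  stopifnot(inherits(net, "unet_graph"))
  layers <- net$layers
  for (ly in layers) {
    if (ly$type != "bn") next
    if (length(ly$inputs) != 1L || ly$inputs == 0L) {
      stop(sprintf("BN layer %d ('%s') has no single preceding layer to fold into",
                   ly$id, ly$name), call. = FALSE)
    }
    pred <- layers[[ly$inputs]]
    if (!pred$type %in% c("conv", "deconv")) {
      stop(sprintf("BN layer %d ('%s') follows a '%s' layer; folding requires an adjacent conv or deconv",
                   ly$id, ly$name, pred$type), call. = FALSE)
    }
    layers[[pred$id]]$params <- fold_bn(pred$params, ly$params)
  }
  # drop BN layers, rewiring consumers and renumbering ids
  keep <- vapply(layers, function(l) l$type != "bn", logical(1))
  remap <- integer(length(layers) + 1L)      # old id -> surviving producer id
  remap[1L] <- 0L
  for (ly in layers) {
    remap[ly$id + 1L] <- if (ly$type == "bn") remap[ly$inputs + 1L] else ly$id
  }
  kept <- layers[keep]
  newid <- integer(length(layers) + 1L)      # surviving old id -> new id
  newid[1L] <- 0L
  for (i in seq_along(kept)) newid[kept[[i]]$id + 1L] <- i
  for (i in seq_along(kept)) {
    kept[[i]]$inputs <- newid[remap[kept[[i]]$inputs + 1L] + 1L]
    kept[[i]]$id <- i
  }
  new_unet_graph(kept, net$in_channels, net$out_classes, net$depth_levels,
                 net$channels_base)
}
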
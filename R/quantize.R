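#' Power-of-two shift bits for dynamic fixed-point quantization
#'
#' The scale factor of every quantized tensor is constrained to a power of
#' two so that scaling is a bit shift on hardware. For a tensor with maximum
#' absolute value `m`, the shift-bit count is
#' `b_s = b_w - 1 - ceil(log2(m))` with bit width `b_w` (8 by default), so
#' codes are `round(x * 2^b_s)`. `b_s` may be negative (tensors with
#' `m > 2^(b_w-1)`) or exceed `b_w - 1` (tensors with `m < 1`). An all-zero
#' tensor (`max_abs = 0`) is represented exactly at any scale; `b_w - 1` is
#' returned by convention.
#'
#' @param max_abs non-negative finite real: the tensor's max absolute value.
#' @param b_w bit width (default 8).
#' @return Integer shift-bit count.
#' @examples
#' shift_bits(1.0)    # 7
#' shift_bits(3.7)    # 5
#' shift_bits(0.25)   # 9
#' @export
shift_bits <- function(max_abs, b_w = 8L) {
  stopifnot(is.finite(max_abs), max_abs >= 0)
  if (max_abs == 0) return(as.integer(b_w - 1L))
  as.integer(b_w - 1L - ceiling(log2(max_abs)))
}

# round half away from zero (ties move outward), elementwise
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# arithmetic shift of integer-valued doubles: left for s >= 0, rounding right
# shift (round half away from zero) for s < 0
shift_scale <- function(v, s) {
  if (s >= 0) return(v * 2^s)
  step <- 2^(-s)
  sign(v) * ((abs(v) + step / 2) %/% step)
}

clamp_codes <- function(v, b_w = 8L) {
  lim <- 2^(b_w - 1)
  pmin(pmax(v, -lim), lim - 1)
}

#' Quantize a real tensor to signed fixed-point codes
#'
#' Maps every element to `clamp(round(x * 2^b_s), -2^(b_w-1), 2^(b_w-1)-1)`
#' with round-half-away-from-zero. With `b_s` from [shift_bits()] only
#' elements at the max absolute value can saturate (and do, when `max_abs`
#' is an exact power of two: `1.0 * 2^7 = 128` clamps to 127); every other
#' element's dequantized error is at most half a step, `2^(-b_s-1)`.
#'
#' @param x numeric array/vector; all elements must be finite.
#' @param b_s shift-bit count (scale is `2^b_s`).
#' @param b_w bit width (default 8).
#' @param name tensor name used in error messages.
#' @return Array of integer-valued codes (stored as doubles), same shape.
#' @export
quantize_tensor <- function(x, b_s, b_w = 8L, name = "tensor") {
  if (any(!is.finite(x))) {
    stop(sprintf("non-finite values in '%s'; cannot quantize", name), call. = FALSE)
  }
  q <- clamp_codes(round_half_away(x * 2^b_s), b_w)
  if (!is.null(dim(x))) dim(q) <- dim(x)
  q
}

#' @rdname quantize_tensor
#' @param q codes produced by `quantize_tensor()`.
#' @return `dequantize_tensor()`: the represented real values `q * 2^-b_s`.
#' @export
dequantize_tensor <- function(q, b_s) q * 2^(-b_s)

#' Quantize a real volume to int8 codes
#'
#' @param v real `quantseg_volume`.
#' @param b_s shift-bit count.
#' @param b_w bit width (default 8).
#' @return An int8-code `quantseg_volume` at scale `2^b_s`.
#' @export
quantize_volume <- function(v, b_s, b_w = 8L) {
  stopifnot(inherits(v, "quantseg_volume"), v$value_kind == "real")
  as_volume(quantize_tensor(v$data, b_s, b_w, name = "volume"),
            value_kind = "int8", shift_bits = b_s, bit_width = b_w)
}

#' Record activation ranges on calibration volumes
#'
#' Runs the folded float network forward on a small set of representative
#' volumes ("training mode") and records, per layer, the running maximum
#' absolute value of its input and output tensors. These ranges determine the
#' input/output shift bits of each layer via [shift_bits()]. The full-scale
#' workflow uses two patient volumes as calibration input.
#'
#' @param net a folded `unet_graph` (no BN layers).
#' @param calib non-empty list of real `quantseg_volume`s.
#' @return A tibble with columns `id`, `name`, `type`, `max_abs_in`,
#'   `max_abs_out`.
#' @export
calibrate <- function(net, calib) {
  stopifnot(inherits(net, "unet_graph"))
  if (!is.list(calib) || length(calib) == 0L) {
    stop("calibration set must be a non-empty list of volumes", call. = FALSE)
  }
  n <- length(net$layers)
  max_in <- numeric(n); max_out <- numeric(n)
  rec <- function(ly, x, y) {
    max_in[ly$id]  <<- max(max_in[ly$id],  max(abs(x)))
    max_out[ly$id] <<- max(max_out[ly$id], max(abs(y)))
  }
  for (v in calib) infer_float(net, v, record = rec)
  dplyr::mutate(layer_table(net)[, c("id", "name", "type")],
                max_abs_in = max_in, max_abs_out = max_out)
}

#' Quantize a folded network to int8
#'
#' Converts every convolutional/deconvolutional layer of a BN-free graph to
#' 8-bit signed fixed-point: weight and bias scale factors are computed
#' separately per layer from their own max absolute values (power-of-two shift
#' bits), and input/output scale factors come from the calibration record.
#' ReLU and max-pooling pass their incoming scheme through unchanged; a
#' concatenation requantizes both branches to the coarser (smaller `b_s`)
#' scheme. Wherever a producer's output scheme differs from a consumer's
#' input scheme an explicit requantization shift is recorded on the edge.
#'
#' @param net folded `unet_graph`; a remaining BN layer is an error (fold
#'   first with [fold_network()]).
#' @param record calibration tibble from [calibrate()].
#' @param b_w bit width (default 8; wider widths supported for precision
#'   studies).
#' @return A `quantized_network`: layer list with int8 codes and per-layer
#'   `QuantScheme`s (`b_s` for weights, biases, input, output), plus the
#'   requantization records.
#' @export
quantize_network <- function(net, record, b_w = 8L) {
  stopifnot(inherits(net, "unet_graph"))
  if (count_layers(net, "bn") > 0L) {
    stop("graph still contains BN layers; run fold_network() first", call. = FALSE)
  }
  b_w <- as.integer(b_w)
  if (!net$layers[[1L]]$type %in% c("conv", "deconv")) {
    stop("the first layer must be a conv/deconv (it defines the input scheme)",
         call. = FALSE)
  }
  n <- length(net$layers)
  if (!all(c("id", "max_abs_in", "max_abs_out") %in% names(record)) ||
      nrow(record) != n) {
    stop("calibration record does not match this network", call. = FALSE)
  }
  qlayers <- vector("list", n)
  out_bs <- integer(n + 1L)   # scheme leaving each producer (index id + 1)
  for (ly in net$layers) {
    mi <- record$max_abs_in[record$id == ly$id]
    mo <- record$max_abs_out[record$id == ly$id]
    ql <- ly
    if (ly$type %in% c("conv", "deconv")) {
      p <- ly$params
      bs_w <- shift_bits(max(abs(p$weights)), b_w)
      bs_b <- shift_bits(max(abs(p$bias)), b_w)
      bs_in <- shift_bits(mi, b_w)
      bs_out <- shift_bits(mo, b_w)
      ql$q <- list(
        weights = quantize_tensor(p$weights, bs_w, b_w, name = paste0(ly$name, ".weights")),
        bias = quantize_tensor(p$bias, bs_b, b_w, name = paste0(ly$name, ".bias")),
        bs_weight = bs_w, bs_bias = bs_b, bs_in = bs_in, bs_out = bs_out)
      # float parameters do not travel with the quantized network
      ql$params <- p[c("stride", "padding", "transposed")]
      out_bs[ly$id + 1L] <- bs_out
    } else if (ly$type == "concat") {
      bs <- min(out_bs[ly$inputs + 1L])
      ql$q <- list(bs_in = bs, bs_out = bs)
      out_bs[ly$id + 1L] <- bs
    } else {  # relu, maxpool: scheme passes through
      bs <- out_bs[ly$inputs + 1L]
      ql$q <- list(bs_in = bs, bs_out = bs)
      out_bs[ly$id + 1L] <- bs
    }
    qlayers[[ly$id]] <- ql
  }
  # requantization shifts per (producer -> consumer) edge where schemes differ
  first_in <- qlayers[[1L]]$q$bs_in
  out_bs[1L] <- first_in       # network input arrives at layer 1's scheme
  requant <- list()
  for (ql in qlayers) {
    for (src in ql$inputs) {
      shift <- ql$q$bs_in - out_bs[src + 1L]
      if (shift != 0L) {
        requant[[length(requant) + 1L]] <-
          list(from = src, to = ql$id, shift = as.integer(shift))
      }
    }
  }
  structure(
    list(layers = qlayers, in_channels = net$in_channels,
         out_classes = net$out_classes, depth_levels = net$depth_levels,
         channels_base = net$channels_base, bit_width = b_w,
         input_bs = first_in, requant = requant),
    class = "quantized_network")
}

#' @export
print.quantized_network <- function(x, ...) {
  cat(sprintf("<quantized_network> %d layers, b_w=%d, input scheme b_s=%d, %d requantization edges\n",
              length(x$layers), x$bit_width, x$input_bs, length(x$requant)))
  invisible(x)
}

#' Scheme manifest of a quantized network
#'
#' @param x a `quantized_network`.
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per layer and the shift-bit
#'   schemes (`bs_weight`/`bs_bias` are `NA` for non-parametric layers).
#' @export
tidy.quantized_network <- function(x, ...) {
  tibble::tibble(
    id = vapply(x$layers, `[[`, integer(1), "id"),
    name = vapply(x$layers, `[[`, character(1), "name"),
    type = vapply(x$layers, `[[`, character(1), "type"),
    bs_weight = vapply(x$layers, function(l) l$q$bs_weight %||% NA_integer_, integer(1)),
    bs_bias = vapply(x$layers, function(l) l$q$bs_bias %||% NA_integer_, integer(1)),
    bs_in = vapply(x$layers, function(l) l$q$bs_in, integer(1)),
    bs_out = vapply(x$layers, function(l) l$q$bs_out, integer(1))
  )
}

#' @rdname tidy.quantized_network
#' @return `glance()`: a one-row tibble (layer counts, bit width, code range
#'   actually used).
#' @export
glance.quantized_network <- function(x, ...) {
  codes <- unlist(lapply(x$layers, function(l) c(l$q$weights, l$q$bias)))
  tibble::tibble(
    n_layers = length(x$layers),
    n_conv = sum(vapply(x$layers, function(l) l$type %in% c("conv", "deconv"), logical(1))),
    bit_width = x$bit_width,
    code_min = min(codes), code_max = max(codes),
    n_requant_edges = length(x$requant)
  )
}
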
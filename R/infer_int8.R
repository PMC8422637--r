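#' Bit-exact integer inference
#'
#' Emulates the accelerator's fixed-point pipeline in pure integer
#' arithmetic: int8 x int8 products are accumulated in a 32-bit-wide signed
#' accumulator at scale `2^(bs_in + bs_weight)`; the int8 bias is aligned to
#' the accumulator scale by an arithmetic shift; the accumulator is rescaled
#' to the layer's output scheme by an arithmetic right shift with
#' round-half-away-from-zero, then clamped to the code range. ReLU is
#' `max(0, code)`, max pooling an integer maximum, and every requantization
#' edge applies its recorded shift. The result is bit-reproducible across
#' runs and platforms; exceeding the 32-bit accumulator raises an error
#' rather than wrapping.
#'
#' All integer values are carried in doubles, which represent integers
#' exactly far beyond the 32-bit range checked here.
#'
#' @param qnet a `quantized_network`.
#' @param v an int8-code `quantseg_volume` whose `shift_bits` equals the
#'   network's input scheme (`qnet$input_bs`); see [quantize_volume()].
#' @return An int8-code `quantseg_volume` of per-class score codes at the
#'   classifier's output scheme.
#' @export
infer_int8 <- function(qnet, v) {
  stopifnot(inherits(qnet, "quantized_network"), inherits(v, "quantseg_volume"))
  if (v$value_kind != "int8") {
    stop("infer_int8 needs an int8-code volume; quantize first with quantize_volume()",
         call. = FALSE)
  }
  if (v$shift_bits != qnet$input_bs) {
    stop(sprintf("volume scheme b_s=%d does not match the network input scheme b_s=%d and no requantization record covers the network input",
                 v$shift_bits, qnet$input_bs), call. = FALSE)
  }
  outs <- vector("list", length(qnet$layers) + 1L)
  outs[[1L]] <- vol_chw(v)
  for (ql in qnet$layers) {
    xs <- lapply(ql$inputs, function(i) {
      requant_edge(qnet, outs[[i + 1L]], i, ql$id)
    })
    x <- if (length(xs) == 1L) xs[[1L]] else concat_channels(xs, ql)
    outs[[ql$id + 1L]] <- int8_layer_forward(ql, x, qnet$bit_width)
  }
  y <- outs[[length(outs)]]
  chw_to_vol(y, value_kind = "int8",
             shift_bits = qnet$layers[[length(qnet$layers)]]$q$bs_out,
             bit_width = qnet$bit_width)
}

requant_edge <- function(qnet, x, from, to) {
  for (r in qnet$requant) {
    if (r$from == from && r$to == to) {
      return(clamp_codes(shift_scale(x, r$shift), qnet$bit_width))
    }
  }
  x
}

ACC_LIMIT <- 2^31

int8_layer_forward <- function(ql, x, b_w) {
  switch(ql$type,
    conv = ,
    deconv = {
      p <- ql$params
      acc <- if (ql$type == "conv") {
        conv3d_forward(x, ql$q$weights, stride = p$stride, padding = p$padding)
      } else {
        deconv3d_forward(x, ql$q$weights, stride = p$stride, padding = p$padding)
      }
      acc_bs <- ql$q$bs_in + ql$q$bs_weight
      acc <- acc + shift_scale(ql$q$bias, acc_bs - ql$q$bs_bias)
      if (max(abs(acc)) >= ACC_LIMIT) {
        stop(sprintf("32-bit accumulator overflow in layer %d ('%s')",
                     ql$id, ql$name), call. = FALSE)
      }
      clamp_codes(shift_scale(acc, ql$q$bs_out - acc_bs), b_w)
    },
    relu = pmax(x, 0),
    maxpool = maxpool_forward(x, ql$pool),
    concat = x,
    stop(sprintf("unknown quantized layer type '%s'", ql$type), call. = FALSE)
  )
}

#' Compare float and int8 inference on evaluation volumes
#'
#' Runs both paths on each volume, derives label maps by [argmax_labels()],
#' and reports Dice (per evaluated class, mean over classes > 0) and pixel
#' accuracy for each path against the reference labels, plus the
#' float-to-int8 deltas. The observed drop is the software analogue of the
#' near-lossless degradation reported for the quantized segmentation network.
#'
#' @param net float `unet_graph` (folded or not).
#' @param qnet matching `quantized_network`.
#' @param volumes list of real `quantseg_volume`s.
#' @param refs list of reference label volumes (`quantseg_volume`s), same
#'   length as `volumes`.
#' @return A `quant_comparison`: tibble with one row per volume
#'   (`dsc_float`, `dsc_int8`, `dsc_delta`, `acc_float`, `acc_int8`,
#'   `acc_delta`, `label_agreement` between the two paths).
#' @export
compare_float_int8 <- function(net, qnet, volumes, refs) {
  stopifnot(length(volumes) == length(refs))
  rows <- purrr::map2(volumes, refs, function(v, ref) {
    lf <- argmax_labels(infer_float(net, v))
    li <- argmax_labels(infer_int8(qnet, quantize_volume(v, qnet$input_bs,
                                                         qnet$bit_width)))
    mf <- seg_metrics(lf, ref, n_classes = qnet$out_classes)
    mi <- seg_metrics(li, ref, n_classes = qnet$out_classes)
    tibble::tibble(
      dsc_float = mf$mean_dice_fg, dsc_int8 = mi$mean_dice_fg,
      dsc_delta = mi$mean_dice_fg - mf$mean_dice_fg,
      acc_float = mf$accuracy, acc_int8 = mi$accuracy,
      acc_delta = mi$accuracy - mf$accuracy,
      label_agreement = mean(vol_chw(lf) == vol_chw(li)))
  })
  out <- dplyr::bind_rows(rows, .id = "volume")
  out$volume <- as.integer(out$volume)
  class(out) <- c("quant_comparison", class(out))
  out
}

#' @export
tidy.quant_comparison <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.quant_comparison <- function(x, ...) {
  tibble::tibble(
    n_volumes = nrow(x),
    mean_dsc_float = mean(x$dsc_float), mean_dsc_int8 = mean(x$dsc_int8),
    mean_dsc_delta = mean(x$dsc_delta),
    mean_acc_float = mean(x$acc_float), mean_acc_int8 = mean(x$acc_int8),
    mean_label_agreement = mean(x$label_agreement)
  )
}
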
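#' 3D convolution by accumulation of 2D depth slices
#'
#' The accelerator's PE array is a 2-D convolution engine: a `kd x kh x kw`
#' 3-D kernel is split along depth into `kd` 2-D kernels, each applied to the
#' matching input depth slice, and the `kd` partial results are accumulated.
#' For integer inputs this is *exactly* equal to direct 3-D convolution
#' (integer addition is associative); for floats it agrees to rounding error.
#' `decompose_kernel()` performs the split, `conv3d_via_2d()` the
#' slice-accumulated convolution. All kernels are stored as
#' (out_ch, in_ch, kd, kh, kw).
#'
#' @param k3d 5-axis kernel tensor (out_ch, in_ch, kd, kh, kw).
#' @return `decompose_kernel()`: an object of class `slice_kernel_set`: a list
#'   with `slices` (list of (out_ch, in_ch, kh, kw) arrays), `depth_offset`
#'   (0-based offset of each slice) and the original kernel dimensions.
#' @examples
#' k <- array(seq_len(2 * 1 * 3 * 3 * 3), c(2, 1, 3, 3, 3))
#' ks <- decompose_kernel(k)
#' length(ks$slices)
#' identical(reassemble_kernel(ks), k)
#' @export
decompose_kernel <- function(k3d) {
  d <- dim(k3d)
  if (length(d) != 5L) stop("kernel must be 5-axis (out, in, kd, kh, kw)", call. = FALSE)
  slices <- lapply(seq_len(d[3]), function(a) {
    s <- k3d[, , a, , , drop = FALSE]
    dim(s) <- d[c(1, 2, 4, 5)]
    s
  })
  structure(list(slices = slices, depth_offset = seq_len(d[3]) - 1L, kdim = d),
            class = "slice_kernel_set")
}

#' @rdname decompose_kernel
#' @param ks a `slice_kernel_set`.
#' @return `reassemble_kernel()`: the original 5-axis kernel, bit-exactly.
#' @export
reassemble_kernel <- function(ks) {
  d <- ks$kdim
  out <- array(0, d)
  for (a in seq_len(d[3])) out[, , a, , ] <- ks$slices[[a]]
  out
}

#' @rdname decompose_kernel
#' @param x input array (in_ch, depth, height, width).
#' @param stride,padding integer length-3 vectors (depth, height, width).
#' @return `conv3d_via_2d()`: the convolved (out_ch, d', h', w') array.
#' @export
conv3d_via_2d <- function(x, ks, stride = c(1L, 1L, 1L), padding = c(0L, 0L, 0L)) {
  stride <- rep_len(as.integer(stride), 3L)
  padding <- rep_len(as.integer(padding), 3L)
  kd <- ks$kdim[3]; kh <- ks$kdim[4]; kw <- ks$kdim[5]
  oc <- ks$kdim[1]; ic <- ks$kdim[2]
  if (dim(x)[1] != ic) {
    stop(sprintf("input has %d channels but kernel expects %d", dim(x)[1], ic),
         call. = FALSE)
  }
  xp <- pad_spatial(x, padding)
  dp <- dim(xp)[2:4]
  osz <- (dp - c(kd, kh, kw)) %/% stride + 1L
  if (any(osz < 1L)) {
    stop("kernel larger than (padded) input; output axis would drop below 1",
         call. = FALSE)
  }
  nvox <- prod(osz)
  acc <- matrix(0, nrow = oc, ncol = nvox)
  iz <- seq(1L, by = stride[1], length.out = osz[1])
  iy <- seq(1L, by = stride[2], length.out = osz[2])
  ix <- seq(1L, by = stride[3], length.out = osz[3])
  # depth-slice major: each 2-D kernel is fully accumulated before the next
  for (a in seq_len(kd)) {
    wa <- ks$slices[[a]]
    for (b in seq_len(kh)) {
      for (cc in seq_len(kw)) {
        xs <- xp[, iz + (a - 1L), iy + (b - 1L), ix + (cc - 1L), drop = FALSE]
        dim(xs) <- c(ic, nvox)
        wm <- wa[, , b, cc, drop = FALSE]
        dim(wm) <- c(oc, ic)
        acc <- acc + wm %*% xs
      }
    }
  }
  dim(acc) <- c(oc, osz)
  acc
}

# direct entry point used by the inference engines
conv3d_forward <- function(x, w, stride = c(1L, 1L, 1L), padding = c(0L, 0L, 0L)) {
  conv3d_via_2d(x, decompose_kernel(w), stride = stride, padding = padding)
}

#' Transposed 3D convolution by zero insertion
#'
#' Deconvolution (transposed convolution) is realized exactly as the hardware
#' does: `stride - 1` zeros are inserted between input voxels, the result is
#' zero-padded by `kernel - 1 - padding`, and an ordinary convolution with the
#' spatially flipped kernel is applied. With kernel 2, stride 2, padding 0
#' each spatial axis exactly doubles. The inserted zeros are the origin of the
#' high sparsity seen by the layer that follows a deconvolution.
#'
#' @param x input array (in_ch, depth, height, width).
#' @param w kernel (out_ch, in_ch, kd, kh, kw).
#' @param stride,padding integer length-3 vectors of the *transposed*
#'   convolution.
#' @return (out_ch, d', h', w') array with
#'   `d' = (d - 1) * stride - 2 * padding + kd`.
#' @export
deconv3d_forward <- function(x, w, stride = c(2L, 2L, 2L), padding = c(0L, 0L, 0L)) {
  stride <- rep_len(as.integer(stride), 3L)
  padding <- rep_len(as.integer(padding), 3L)
  k <- dim(w)[3:5]
  if (any(k - 1L - padding < 0L)) {
    stop("transposed-conv padding may not exceed kernel - 1", call. = FALSE)
  }
  u <- zero_insert(x, stride)
  conv3d_forward(u, flip_kernel(w), stride = c(1L, 1L, 1L),
                 padding = k - 1L - padding)
}
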
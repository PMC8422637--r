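#' Five-axis volumes
#'
#' All voxel data in quantseg travels as a `quantseg_volume`: a 5-axis array
#' with fixed axis order (batch, channel, depth, height, width). A volume is
#' either real-valued (`value_kind = "real"`) or holds signed fixed-point
#' integer codes (`value_kind = "int8"`), in which case `shift_bits` records
#' the exponent of its power-of-two scale factor: the represented value of a
#' code `q` is `q * 2^-shift_bits`.
#'
#' @param data numeric array with 3, 4 or 5 dimensions. 3-D input is taken as
#'   (depth, height, width) of a single-channel, single-batch volume; 4-D as
#'   (channel, depth, height, width).
#' @param value_kind `"real"` or `"int8"`.
#' @param shift_bits integer scale exponent; required when
#'   `value_kind = "int8"`, must be absent otherwise.
#' @param bit_width code bit width for `"int8"` volumes (default 8; wider
#'   widths are supported for precision experiments).
#' @return A `quantseg_volume`.
#' @examples
#' v <- as_volume(array(rnorm(64), c(4, 4, 4)))
#' dim(v$data)
#' @export
as_volume <- function(data, value_kind = c("real", "int8"), shift_bits = NULL,
                      bit_width = 8L) {
  value_kind <- match.arg(value_kind)
  d <- dim(data)
  if (is.null(d)) stop("volume data must be an array", call. = FALSE)
  if (length(d) == 3L) dim(data) <- c(1L, 1L, d)
  if (length(d) == 4L) dim(data) <- c(1L, d)
  if (length(dim(data)) != 5L) {
    stop("volume data must have 3, 4 or 5 axes (batch, channel, depth, height, width)",
         call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all volume axes must be >= 1", call. = FALSE)
  if (value_kind == "int8") {
    if (is.null(shift_bits)) stop("int8 volumes need shift_bits", call. = FALSE)
    lim <- 2^(bit_width - 1)
    if (any(data < -lim | data > lim - 1)) {
      stop(sprintf("int8-code values out of range [%d, %d]", -lim, lim - 1),
           call. = FALSE)
    }
  } else if (!is.null(shift_bits)) {
    stop("shift_bits is only meaningful for int8 volumes", call. = FALSE)
  }
  structure(
    list(data = data, value_kind = value_kind,
         shift_bits = if (value_kind == "int8") as.integer(shift_bits) else NULL,
         bit_width = as.integer(bit_width)),
    class = "quantseg_volume"
  )
}

#' @export
print.quantseg_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<quantseg_volume> %s  batch=%d channel=%d spatial=%dx%dx%d",
              x$value_kind, d[1], d[2], d[3], d[4], d[5]))
  if (identical(x$value_kind, "int8")) {
    cat(sprintf("  shift_bits=%d (scale 2^%d)", x$shift_bits, x$shift_bits))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.quantseg_volume <- function(x) dim(x$data)

vol_channels <- function(v) dim(v$data)[2]
vol_spatial  <- function(v) dim(v$data)[3:5]

# drop batch axis -> (channel, depth, height, width); batch size 1 assumed
vol_chw <- function(v, batch = 1L) {
  d <- dim(v$data)
  x <- v$data[batch, , , , , drop = FALSE]
  dim(x) <- d[2:5]
  x
}

chw_to_vol <- function(x, value_kind = "real", shift_bits = NULL, bit_width = 8L) {
  dim(x) <- c(1L, dim(x))
  as_volume(x, value_kind = value_kind, shift_bits = shift_bits,
            bit_width = bit_width)
}

#' Stack single-modality arrays into a multi-channel volume
#'
#' @param ... 3-D arrays of identical shape, in channel order.
#' @return A real-valued `quantseg_volume` with one channel per argument.
#' @export
stack_modalities <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && is.null(dim(mods[[1]]))) {
    mods <- mods[[1]]
  }
  sh <- dim(mods[[1]])
  if (length(sh) != 3L) stop("each modality must be a 3-D array", call. = FALSE)
  for (m in mods) {
    if (!identical(dim(m), sh)) stop("modality shapes differ", call. = FALSE)
  }
  x <- array(0, c(length(mods), sh))
  for (i in seq_along(mods)) x[i, , , ] <- mods[[i]]
  chw_to_vol(x)
}

# zero-pad the three spatial axes of a (channel, d, h, w) array
pad_spatial <- function(x, pad) {
  if (all(pad == 0L)) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * pad[1], d[3] + 2 * pad[2], d[4] + 2 * pad[3]))
  out[, pad[1] + seq_len(d[2]), pad[2] + seq_len(d[3]), pad[3] + seq_len(d[4])] <- x
  out
}

# insert (stride - 1) zeros between neighbouring voxels along each spatial axis
zero_insert <- function(x, stride) {
  d <- dim(x)
  nd <- (d[2:4] - 1L) * stride + 1L
  out <- array(0, c(d[1], nd))
  out[, seq(1L, nd[1], by = stride[1]),
        seq(1L, nd[2], by = stride[2]),
        seq(1L, nd[3], by = stride[3])] <- x
  out
}

# reverse a 5-axis kernel along its three spatial axes
flip_kernel <- function(w) {
  d <- dim(w)
  w[, , rev(seq_len(d[3])), rev(seq_len(d[4])), rev(seq_len(d[5])), drop = FALSE]
}
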
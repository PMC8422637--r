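#' Segmentation evaluation metrics
#'
#' Dice similarity coefficient `2|A n B| / (|A| + |B|)` of one class and
#' overall pixel (voxel) accuracy. When both masks are empty the Dice score
#' is defined as 1 (standard convention, avoids 0/0).
#'
#' @param pred,ref label volumes (`quantseg_volume`s or arrays) of identical
#'   shape with non-negative integer labels.
#' @param class_id label under evaluation (default 1).
#' @return `dice()`: a real in \[0, 1\].
#' @examples
#' a <- array(c(1, 1, 1, 0, 0, 0, 1, 1), c(2, 2, 2))
#' b <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
#' dice(a, b)            # overlap 3 of |A|=5, |B|=4
#' pixel_accuracy(a, b)
#' @export
dice <- function(pred, ref, class_id = 1) {
  p <- label_array(pred); r <- label_array(ref)
  check_same_shape(p, r)
  a <- p == class_id; b <- r == class_id
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' @rdname dice
#' @return `pixel_accuracy()`: fraction of voxels with equal labels.
#' @export
pixel_accuracy <- function(pred, ref) {
  p <- label_array(pred); r <- label_array(ref)
  check_same_shape(p, r)
  mean(p == r)
}

label_array <- function(x) {
  if (inherits(x, "quantseg_volume")) x <- x$data
  if (any(x < 0) || any(x != floor(x))) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  x
}

check_same_shape <- function(p, r) {
  if (!identical(dim(p), dim(r)) && length(p) != length(r)) {
    stop(sprintf("label shapes differ: %s vs %s",
                 paste(dim(p), collapse = "x"), paste(dim(r), collapse = "x")),
         call. = FALSE)
  }
  if (!is.null(dim(p)) && !is.null(dim(r)) && !identical(dim(p), dim(r))) {
    stop(sprintf("label shapes differ: %s vs %s",
                 paste(dim(p), collapse = "x"), paste(dim(r), collapse = "x")),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Per-class segmentation report
#'
#' Dice per class plus the unweighted mean over foreground classes (positive
#' labels) and voxel accuracy. The mean-over-foreground aggregation is reported
#' alongside the per-class values because a single printed DSC does not fix
#' the aggregation.
#'
#' @param pred,ref label volumes of identical shape.
#' @param n_classes number of classes (labels `0 .. n_classes - 1`).
#' @return A list: `per_class` tibble (`class`, `dice`), `mean_dice_fg`,
#'   `accuracy`.
#' @export
seg_metrics <- function(pred, ref, n_classes = 2L) {
  per <- tibble::tibble(
    class = seq_len(n_classes) - 1L,
    dice = vapply(seq_len(n_classes) - 1L, function(k) dice(pred, ref, k),
                  numeric(1)))
  fg <- per$dice[per$class > 0]
  list(per_class = per,
       mean_dice_fg = if (length(fg)) mean(fg) else per$dice[1],
       accuracy = pixel_accuracy(pred, ref))
}
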
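#' NIfTI volume input/output
#'
#' A multi-modality case is stored as one single-modality NIfTI file per
#' channel, merged on the channel axis in the documented order flair, t1,
#' t2, t1ce. Headers/affines are passed through unmodified from a template
#' when writing; synthetic fixtures use the identity affine. No resampling
#' is performed.
#'
#' @param paths character vector of NIfTI files (.nii / .nii.gz), one per
#'   modality, in channel order.
#' @return `read_nifti_volume()`: a real `quantseg_volume` with one channel
#'   per file.
#' @export
read_nifti_volume <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("input file not found: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  mods <- lapply(paths, function(p) {
    a <- RNifti::readNifti(p)
    arr <- as.array(a)
    if (length(dim(arr)) != 3L) {
      stop(sprintf("%s: expected a 3-D single-modality image", p), call. = FALSE)
    }
    arr
  })
  stack_modalities(mods)
}

#' @rdname read_nifti_volume
#' @param v a `quantseg_volume` (labels or a single-channel image; for
#'   multi-channel volumes one file per channel is written with the channel
#'   index appended).
#' @param path output file (.nii or .nii.gz).
#' @param template optional NIfTI file whose header/affine is reused.
#' @return `write_nifti_volume()`: the written path(s), invisibly.
#' @export
write_nifti_volume <- function(v, path, template = NULL) {
  stopifnot(inherits(v, "quantseg_volume"))
  x <- vol_chw(v)
  nch <- dim(x)[1]
  tpl <- if (!is.null(template)) RNifti::readNifti(template) else NULL
  write_one <- function(arr, p) {
    img <- if (is.null(tpl)) RNifti::asNifti(arr)
           else RNifti::asNifti(arr, reference = tpl)
    RNifti::writeNifti(img, p)
    p
  }
  if (nch == 1L) {
    a <- x[1L, , , ]
    dim(a) <- dim(x)[2:4]
    return(invisible(write_one(a, path)))
  }
  paths <- vapply(seq_len(nch), function(ch) {
    a <- x[ch, , , ]
    dim(a) <- dim(x)[2:4]
    write_one(a, sub("(\\.nii(\\.gz)?)$", sprintf("_ch%d\\1", ch), path))
  }, character(1))
  invisible(paths)
}

#' @rdname read_nifti_volume
#' @param dir directory to write a phantom into.
#' @param phantom result of [make_phantom()].
#' @param prefix file-name prefix.
#' @return `write_phantom_nifti()`: named character vector of the written
#'   files (flair, t1, t2, t1ce, labels).
#' @export
write_phantom_nifti <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- vol_chw(phantom$volume)
  mods <- c("flair", "t1", "t2", "t1ce")[seq_len(dim(x)[1])]
  files <- vapply(seq_along(mods), function(ch) {
    a <- x[ch, , , ]; dim(a) <- dim(x)[2:4]
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, mods[ch]))
    RNifti::writeNifti(RNifti::asNifti(a), p)
    p
  }, character(1))
  lab <- vol_chw(phantom$labels)[1L, , , ]
  dim(lab) <- vol_spatial(phantom$labels)
  lp <- file.path(dir, sprintf("%s_labels.nii.gz", prefix))
  RNifti::writeNifti(RNifti::asNifti(lab), lp)
  stats::setNames(c(files, lp), c(mods, "labels"))
}
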
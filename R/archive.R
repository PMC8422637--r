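#' Network archives
#'
#' Float and quantized networks are stored on disk as a directory archive: a
#' `manifest.json` listing layer order, types, hyper-parameters and (for
#' quantized networks) the complete shift-bit scheme manifest, plus one
#' little-endian binary file per parameter tensor (`float64` for real
#' parameters, `int32` for int8 codes). Every array file carries an md5
#' digest in the manifest; a mismatch on read raises a corruption error.
#' The round trip read -> write -> read is bit-exact.
#'
#' @param x a `unet_graph` or `quantized_network`.
#' @param path directory to create/overwrite.
#' @return `write_network_archive()`: `path`, invisibly.
#' @export
write_network_archive <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrays <- list()
  put <- function(id, slot, a, dtype) {
    file <- sprintf("L%03d_%s.bin", id, slot)
    con <- file(file.path(path, file), "wb")
    if (dtype == "float64") {
      writeBin(as.numeric(a), con, size = 8, endian = "little")
    } else {
      writeBin(as.integer(a), con, size = 4, endian = "little")
    }
    close(con)
    list(file = file, dim = as.integer(if (is.null(dim(a))) length(a) else dim(a)),
         dtype = dtype,
         md5 = unname(tools::md5sum(file.path(path, file))))
  }
  quantized <- inherits(x, "quantized_network")
  layers <- lapply(x$layers, function(ly) {
    rec <- list(id = ly$id, name = ly$name, type = ly$type,
                inputs = I(ly$inputs), in_ch = ly$in_ch, out_ch = ly$out_ch)
    arr <- list()
    if (ly$type %in% c("conv", "deconv")) {
      p <- ly$params
      kern <- if (quantized) dim(ly$q$weights)[3:5] else dim(p$weights)[3:5]
      rec$conv <- list(stride = I(p$stride), padding = I(p$padding),
                       transposed = p$transposed,
                       kernel = I(as.integer(kern)))
      if (quantized) {
        rec$scheme <- ly$q[c("bs_weight", "bs_bias", "bs_in", "bs_out")]
        arr$weights <- put(ly$id, "weights", ly$q$weights, "int32")
        arr$bias <- put(ly$id, "bias", ly$q$bias, "int32")
      } else {
        arr$weights <- put(ly$id, "weights", p$weights, "float64")
        arr$bias <- put(ly$id, "bias", p$bias, "float64")
      }
    } else if (ly$type == "bn") {
      arr$mean <- put(ly$id, "mean", ly$params$mean, "float64")
      arr$variance <- put(ly$id, "variance", ly$params$variance, "float64")
      arr$gamma <- put(ly$id, "gamma", ly$params$gamma, "float64")
      arr$beta <- put(ly$id, "beta", ly$params$beta, "float64")
      rec$bn <- list(epsilon = ly$params$epsilon)
    } else if (ly$type == "maxpool") {
      rec$pool <- I(ly$pool)
    }
    if (quantized && !ly$type %in% c("conv", "deconv")) {
      rec$scheme <- ly$q[c("bs_in", "bs_out")]
    }
    rec$arrays <- arr
    rec
  })
  manifest <- list(
    format = "quantseg-archive", version = 1L,
    kind = if (quantized) "quantized" else "float",
    in_channels = x$in_channels, out_classes = x$out_classes,
    depth_levels = x$depth_levels, channels_base = x$channels_base,
    layers = layers)
  if (quantized) {
    manifest$bit_width <- x$bit_width
    manifest$input_bs <- x$input_bs
    manifest$requant <- x$requant
  }
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "manifest.json"))
  invisible(path)
}

#' @rdname write_network_archive
#' @return `read_network_archive()`: the reconstructed `unet_graph` or
#'   `quantized_network`.
#' @export
read_network_archive <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop(sprintf("not a network archive (no manifest.json): %s", path), call. = FALSE)
  }
  mf <- jsonlite::fromJSON(mf_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(mf$format, "quantseg-archive")) {
    stop("unrecognized archive format", call. = FALSE)
  }
  get <- function(a) {
    f <- file.path(path, a$file)
    if (!file.exists(f)) stop(sprintf("archive corruption: missing %s", a$file), call. = FALSE)
    if (!identical(unname(tools::md5sum(f)), a$md5)) {
      stop(sprintf("archive corruption: digest mismatch for %s", a$file), call. = FALSE)
    }
    n <- prod(a$dim)
    con <- file(f, "rb")
    v <- if (a$dtype == "float64") {
      readBin(con, "numeric", n, size = 8, endian = "little")
    } else {
      as.numeric(readBin(con, "integer", n, size = 4, endian = "little"))
    }
    close(con)
    if (length(v) != n) stop(sprintf("archive corruption: %s truncated", a$file), call. = FALSE)
    if (length(a$dim) > 1L) dim(v) <- a$dim
    v
  }
  quantized <- identical(mf$kind, "quantized")
  layers <- lapply(mf$layers, function(rec) {
    ly <- new_layer(rec$id, rec$name, rec$type, unlist(rec$inputs),
                    rec$in_ch, rec$out_ch)
    if (rec$type %in% c("conv", "deconv")) {
      w_dim <- c(rec$out_ch, rec$in_ch, unlist(rec$conv$kernel))
      if (quantized) {
        w <- get(rec$arrays$weights); dim(w) <- w_dim
        ly$params <- list(stride = as.integer(unlist(rec$conv$stride)),
                          padding = as.integer(unlist(rec$conv$padding)),
                          transposed = isTRUE(rec$conv$transposed))
        ly$q <- list(weights = w, bias = get(rec$arrays$bias),
                     bs_weight = as.integer(rec$scheme$bs_weight),
                     bs_bias = as.integer(rec$scheme$bs_bias),
                     bs_in = as.integer(rec$scheme$bs_in),
                     bs_out = as.integer(rec$scheme$bs_out))
      } else {
        w <- get(rec$arrays$weights); dim(w) <- w_dim
        ly$params <- conv_params(w, get(rec$arrays$bias),
                                 stride = unlist(rec$conv$stride),
                                 padding = unlist(rec$conv$padding),
                                 transposed = isTRUE(rec$conv$transposed))
      }
    } else if (rec$type == "bn") {
      eps <- rec$bn$epsilon
      if (is.null(eps)) eps <- 1e-5   # common default when a stored record omits it
      ly$params <- bn_params(get(rec$arrays$mean), get(rec$arrays$variance),
                             get(rec$arrays$gamma), get(rec$arrays$beta),
                             epsilon = eps)
    } else if (rec$type == "maxpool") {
      ly$pool <- as.integer(unlist(rec$pool))
    }
    if (quantized && !rec$type %in% c("conv", "deconv")) {
      ly$q <- list(bs_in = as.integer(rec$scheme$bs_in),
                   bs_out = as.integer(rec$scheme$bs_out))
    }
    ly
  })
  if (quantized) {
    structure(
      list(layers = layers, in_channels = as.integer(mf$in_channels),
           out_classes = as.integer(mf$out_classes),
           depth_levels = as.integer(mf$depth_levels),
           channels_base = as.integer(mf$channels_base),
           bit_width = as.integer(mf$bit_width),
           input_bs = as.integer(mf$input_bs),
           requant = lapply(mf$requant, function(r)
             list(from = as.integer(r$from), to = as.integer(r$to),
                  shift = as.integer(r$shift)))),
      class = "quantized_network")
  } else {
    new_unet_graph(layers, mf$in_channels, mf$out_classes, mf$depth_levels,
                   mf$channels_base)
  }
}

#' Check that an archive round-trips bit-exactly
#'
#' Reads `path`, writes the object to a scratch directory, reads it back and
#' compares: `TRUE` when all parameter arrays, schemes and manifest-level
#' metadata are identical.
#'
#' @param path an existing archive directory.
#' @return Logical.
#' @export
roundtrip_archive <- function(path) {
  a <- read_network_archive(path)
  tmp <- tempfile("qseg_rt_")
  on.exit(unlink(tmp, recursive = TRUE))
  write_network_archive(a, tmp)
  b <- read_network_archive(tmp)
  identical(a, b)
}
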
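#' Accelerator resource configuration
#'
#' Parametric description of the modelled chip: on-chip capacities of the
#' input, parameter and intermediate/output memories (bytes; int8 data is one
#' byte per element), the number of PE multipliers, load and write-back
#' bandwidths (bytes per cycle) and the configuration cost per instruction
#' (cycles). The model is cycle-approximate: stage costs are linear in bytes
#' and MACs with these coefficients, and all of them are configuration, not
#' measured silicon.
#'
#' @param input_mem,param_mem,output_mem capacities in bytes.
#' @param pe_multipliers multiply-accumulate units available per cycle.
#' @param load_bw,wb_bw bytes per cycle.
#' @param cf_cycles configuration stage cost per instruction.
#' @return A `resource_config` list.
#' @export
resource_config <- function(input_mem = 65536, param_mem = 65536,
                            output_mem = 65536, pe_multipliers = 2048,
                            load_bw = 64, wb_bw = 64, cf_cycles = 8) {
  rc <- list(input_mem = input_mem, param_mem = param_mem,
             output_mem = output_mem, pe_multipliers = pe_multipliers,
             load_bw = load_bw, wb_bw = wb_bw, cf_cycles = cf_cycles)
  if (any(vapply(rc, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1)))) {
    stop("all resource-config fields must be positive scalars", call. = FALSE)
  }
  structure(rc, class = "resource_config")
}

#' @rdname resource_config
#' @param path YAML file with any of the fields above.
#' @export
read_resource_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("resource config not found: %s", path), call. = FALSE)
  do.call(resource_config, yaml::read_yaml(path))
}

halve_caps <- function(rc) {
  rc$input_mem <- rc$input_mem %/% 2
  rc$param_mem <- rc$param_mem %/% 2
  rc$output_mem <- rc$output_mem %/% 2
  rc
}

# The three hardware PE configurations: input lanes x output lanes x pixels
# computed per issue.
pe_mode_table <- function() {
  tibble::tibble(
    mode = c("4-32", "32-32", "32-64"),
    in_ch = c(4L, 32L, 32L),
    out_ch = c(32L, 32L, 64L),
    pixels = c(4L, 2L, 1L))
}

#' Select the PE computing mode for a layer shape
#'
#' Layers with at most 4 input channels run in 4-32 mode (4 pixels per
#' issue); 32-in/32-out layers in 32-32 mode (2 pixels per issue); layers
#' with more than 32 output channels in 32-64 mode (1 pixel per issue).
#' Other shapes are mapped to the nearest mode by zero-padding channels;
#' padded lanes count as idle in the utilization report.
#'
#' @param in_ch,out_ch layer channel counts.
#' @return One row of the PE-mode table (`mode`, `in_ch`, `out_ch`,
#'   `pixels`).
#' @export
select_pe_mode <- function(in_ch, out_ch) {
  tab <- pe_mode_table()
  name <- if (in_ch <= 4L) "4-32" else if (out_ch > 32L) "32-64" else "32-32"
  tab[tab$mode == name, ]
}

# conv and deconv are both executed on a "lowered" grid: deconvolution first
# zero-inserts its input (stride becomes 1, padding kernel-1-padding, kernel
# flipped), after which block partitioning, zero detection and execution are
# identical for both layer types.
lower_layer <- function(ql, in_spatial) {
  p <- ql$params
  k <- dim(ql$q$weights)[3:5]
  if (p$transposed || ql$type == "deconv") {
    list(kernel = k, stride = c(1L, 1L, 1L), padding = k - 1L - p$padding,
         in_spatial = (in_spatial - 1L) * p$stride + 1L,
         out_spatial = (in_spatial - 1L) * p$stride - 2L * p$padding + k,
         transposed = TRUE)
  } else {
    list(kernel = k, stride = p$stride, padding = p$padding,
         in_spatial = in_spatial,
         out_spatial = (in_spatial + 2L * p$padding - k) %/% p$stride + 1L,
         transposed = FALSE)
  }
}

block_in_extent <- function(t, lw) (t - 1L) * lw$stride + lw$kernel

#' Partition a layer into computation blocks
#'
#' One layer rarely fits on chip, so its output is tiled into computation
#' blocks: output channels in groups of the PE mode's output width, and the
#' spatial box halved along its largest axis (ties broken depth, height,
#' width) until the block's input region, parameters and output region all
#' fit their memories. Blocks tile the output exactly, without overlap, in a
#' deterministic order: channel-group major, then z, y, x ascending.
#'
#' @param ql a conv/deconv layer record of a `quantized_network`.
#' @param in_spatial input spatial shape (depth, height, width).
#' @param rc a [resource_config()].
#' @return A tibble of blocks: channel range, output box (in lowered/output
#'   coordinates), PE mode, real and channel-padded MAC counts, byte counts.
#' @export
partition_layer <- function(ql, in_spatial, rc) {
  stopifnot(ql$type %in% c("conv", "deconv"))
  lw <- lower_layer(ql, as.integer(in_spatial))
  ic <- ql$in_ch; oc <- ql$out_ch
  mode <- select_pe_mode(ic, oc)
  g <- min(mode$out_ch, oc)     # channel-group size (real channels stored)
  out_pad <- mode$out_ch        # lanes issued, padded with zero channels
  kvol <- prod(lw$kernel)
  fits <- function(t) {
    in_b <- ic * prod(block_in_extent(t, lw))
    par_b <- g * ic * kvol + g
    out_b <- g * prod(t)
    in_b <= rc$input_mem && par_b <= rc$param_mem && out_b <= rc$output_mem
  }
  t <- lw$out_spatial
  if (any(t < 1L)) stop(sprintf("layer %d ('%s') has empty output", ql$id, ql$name), call. = FALSE)
  while (!fits(t)) {
    if (all(t == 1L)) {
      stop(sprintf("infeasible partition: a single minimal block of layer %d ('%s') exceeds on-chip capacity",
                   ql$id, ql$name), call. = FALSE)
    }
    i <- which.max(t)      # ties break toward depth, then height, then width
    t[i] <- as.integer(ceiling(t[i] / 2))
  }
  starts <- function(n, tt) seq.int(1L, n, by = tt)
  ch0 <- starts(oc, g)
  z0 <- starts(lw$out_spatial[1], t[1])
  y0 <- starts(lw$out_spatial[2], t[2])
  x0 <- starts(lw$out_spatial[3], t[3])
  grid <- expand.grid(x0 = x0, y0 = y0, z0 = z0, ch0 = ch0,
                      KEEP.OUT.ATTRS = FALSE)   # ch-major, then z, y, x
  grid <- grid[, c("ch0", "z0", "y0", "x0")]
  ic_pad <- as.integer(ceiling(ic / mode$in_ch) * mode$in_ch)
  blk <- tibble::as_tibble(grid)
  blk$ch1 <- pmin(blk$ch0 + g - 1L, oc)
  blk$z1 <- pmin(blk$z0 + t[1] - 1L, lw$out_spatial[1])
  blk$y1 <- pmin(blk$y0 + t[2] - 1L, lw$out_spatial[2])
  blk$x1 <- pmin(blk$x0 + t[3] - 1L, lw$out_spatial[3])
  nch <- blk$ch1 - blk$ch0 + 1L
  vox <- (blk$z1 - blk$z0 + 1L) * (blk$y1 - blk$y0 + 1L) * (blk$x1 - blk$x0 + 1L)
  # input region in lowered, unpadded coordinates (clamped at the borders)
  reg <- function(b0, b1, ax) {
    r0 <- pmax((b0 - 1L) * lw$stride[ax] + 1L - lw$padding[ax], 1L)
    r1 <- pmin((b1 - 1L) * lw$stride[ax] + lw$kernel[ax] - lw$padding[ax],
               lw$in_spatial[ax])
    cbind(r0, r1)
  }
  rz <- reg(blk$z0, blk$z1, 1L); ry <- reg(blk$y0, blk$y1, 2L); rx <- reg(blk$x0, blk$x1, 3L)
  blk$iz0 <- rz[, 1]; blk$iz1 <- rz[, 2]
  blk$iy0 <- ry[, 1]; blk$iy1 <- ry[, 2]
  blk$ix0 <- rx[, 1]; blk$ix1 <- rx[, 2]
  tibble::tibble(
    layer_id = ql$id, layer_name = ql$name, mode = mode$mode,
    block = seq_len(nrow(blk)), blk,
    macs_real = nch * ic * kvol * vox,
    macs_padded = out_pad * ic_pad * kvol * vox,
    in_bytes = ic * (blk$iz1 - blk$iz0 + 1L) * (blk$iy1 - blk$iy0 + 1L) *
      (blk$ix1 - blk$ix0 + 1L),
    param_bytes = nch * ic * kvol + nch,
    out_bytes = nch * vox,
    zero_input = FALSE)
}

#' Allocate on-chip addresses for a block sequence
#'
#' Each memory space (input, parameter, output) is either one region at
#' offset 0 (serial execution) or two disjoint ping-pong banks of half the
#' capacity (double buffering), with consecutive instructions alternating
#' banks so one instruction's load can overlap another's execution.
#'
#' @param blocks tibble from [partition_layer()] (possibly several layers,
#'   in execution order).
#' @param rc a [resource_config()].
#' @param double_buffered logical.
#' @return `blocks` with `addr_in`, `addr_param`, `addr_out` columns.
#' @export
allocate_addresses <- function(blocks, rc, double_buffered = TRUE) {
  nb <- nrow(blocks)
  bank <- if (double_buffered) (seq_len(nb) - 1L) %% 2L else rep(0L, nb)
  place <- function(bytes, cap, space) {
    bank_size <- if (double_buffered) cap %/% 2 else cap
    if (any(bytes > bank_size)) {
      stop(sprintf("%s buffer overflow: a block needs %d bytes but the %s bank holds %d",
                   space, max(bytes),
                   if (double_buffered) "ping-pong" else "single", bank_size),
           call. = FALSE)
    }
    bank * bank_size
  }
  blocks$addr_in <- place(blocks$in_bytes, rc$input_mem, "input")
  blocks$addr_param <- place(blocks$param_bytes, rc$param_mem, "parameter")
  blocks$addr_out <- place(blocks$out_bytes, rc$output_mem, "output")
  blocks
}

#' Generate one instruction per computation block
#'
#' Stage costs follow the linear cycle model: `CF` is the fixed
#' configuration cost; `LD = ceil((input + parameter bytes) / load
#' bandwidth)`; `EX = ceil(padded MACs / active multipliers)` where the
#' active multipliers are the PE mode's lanes capped by the configured
#' multiplier count; `WB = ceil(output bytes / write-back bandwidth)`.
#'
#' @param blocks address-allocated block tibble.
#' @param rc a [resource_config()].
#' @param sched_layer integer vector assigning each block to a scheduling
#'   layer (defaults to dense ranks of `layer_id`).
#' @return An instruction tibble (opcode, mode, stage costs, addresses).
#' @export
generate_instructions <- function(blocks, rc,
                                  sched_layer = dplyr::dense_rank(blocks$layer_id)) {
  modes <- pe_mode_table()
  lanes <- vapply(blocks$mode, function(m) {
    r <- modes[modes$mode == m, ]
    min(r$in_ch * r$out_ch * r$pixels, rc$pe_multipliers)
  }, numeric(1))
  tibble::tibble(
    instr = seq_len(nrow(blocks)),
    opcode = 1L,
    layer_id = blocks$layer_id,
    sched_layer = as.integer(sched_layer),
    mode = blocks$mode,
    block = blocks$block,
    cf = as.integer(rc$cf_cycles),
    ld = as.integer(ceiling((blocks$in_bytes + blocks$param_bytes) / rc$load_bw)),
    ex = as.integer(ceiling(blocks$macs_padded / lanes)),
    wb = as.integer(ceiling(blocks$out_bytes / rc$wb_bw)),
    macs_real = blocks$macs_real,
    macs_padded = blocks$macs_padded,
    addr_in = as.integer(blocks$addr_in),
    addr_param = as.integer(blocks$addr_param),
    addr_out = as.integer(blocks$addr_out))
}

#' Binary instruction stream
#'
#' Fixed-width little-endian format with a versioned header: magic `"QSEG"`,
#' version byte, instruction count (uint32); then per instruction: opcode
#' (uint8), PE-mode index (uint8), scheduling layer (uint16), four stage-cost
#' fields and four address fields (uint32 each; the fourth address is
#' reserved). `decode_instructions(encode_instructions(x))` reproduces every
#' encoded field exactly.
#'
#' @param instrs instruction tibble from [generate_instructions()].
#' @return `encode_instructions()`: a raw vector.
#' @export
encode_instructions <- function(instrs) {
  modes <- pe_mode_table()$mode
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("QSEG"), con)
  writeBin(as.raw(1L), con)
  writeBin(as.integer(nrow(instrs)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(instrs))) {
    writeBin(as.raw(instrs$opcode[i]), con)
    writeBin(as.raw(match(instrs$mode[i], modes) - 1L), con)
    writeBin(as.integer(instrs$sched_layer[i]), con, size = 2, endian = "little")
    writeBin(as.integer(c(instrs$cf[i], instrs$ld[i], instrs$ex[i], instrs$wb[i],
                          instrs$addr_in[i], instrs$addr_param[i],
                          instrs$addr_out[i], 0L)),
             con, size = 4, endian = "little")
  }
  rawConnectionValue(con)
}

#' @rdname encode_instructions
#' @param bytes raw vector from `encode_instructions()`.
#' @export
decode_instructions <- function(bytes) {
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  if (!identical(rawToChar(readBin(con, "raw", 4)), "QSEG")) {
    stop("not a QSEG instruction stream", call. = FALSE)
  }
  ver <- as.integer(readBin(con, "raw", 1))
  if (ver != 1L) stop(sprintf("unsupported instruction format version %d", ver), call. = FALSE)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  modes <- pe_mode_table()$mode
  rows <- lapply(seq_len(n), function(i) {
    op <- as.integer(readBin(con, "raw", 1))
    md <- as.integer(readBin(con, "raw", 1))
    sl <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
    f <- readBin(con, "integer", 8, size = 4, endian = "little")
    tibble::tibble(instr = i, opcode = op, sched_layer = sl,
                   mode = modes[md + 1L], cf = f[1], ld = f[2], ex = f[3],
                   wb = f[4], addr_in = f[5], addr_param = f[6],
                   addr_out = f[7])
  })
  dplyr::bind_rows(rows)
}

#' Mark and drop computation blocks with all-zero input
#'
#' The zero-filling of the deconvolution layers (and the empty background of
#' brain MRI volumes) leaves large all-zero regions in feature maps. A block
#' whose entire required input region is zero is skipped: its output is the
#' bias-only value (the convolution of a zero region is the aligned,
#' requantized bias, not zero), so the final layer output is bit-identical
#' to the unskipped computation. Detection is per computation block.
#'
#' @param blocks block tibble from [partition_layer()].
#' @param x_lowered the layer's lowered input array (`in_ch`, d, h, w) of
#'   int8 codes (zero-inserted for deconvolution).
#' @return List: `blocks` (flagged tibble), `kept`, `skipped`,
#'   `skipped_fraction`.
#' @export
zero_skip <- function(blocks, x_lowered) {
  flag <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    all(x_lowered[, b$iz0:b$iz1, b$iy0:b$iy1, b$ix0:b$ix1] == 0)
  }, logical(1))
  blocks$zero_input <- flag
  list(blocks = blocks, kept = blocks[!flag, ], skipped = blocks[flag, ],
       skipped_fraction = mean(flag))
}

# run the int8 computation of one conv/deconv layer block by block,
# writing bias-only outputs for skipped blocks; bit-identical to
# int8_layer_forward on the whole layer
execute_blocks <- function(ql, blocks, x, b_w) {
  lw <- lower_layer(ql, dim(x)[2:4])
  w <- ql$q$weights
  if (lw$transposed) {
    x <- zero_insert(x, ql$params$stride)
    w <- flip_kernel(w)
  }
  xp <- pad_spatial(x, lw$padding)
  acc_bs <- ql$q$bs_in + ql$q$bs_weight
  bias_acc <- shift_scale(ql$q$bias, acc_bs - ql$q$bs_bias)
  bias_only <- clamp_codes(shift_scale(bias_acc, ql$q$bs_out - acc_bs), b_w)
  out <- array(0, c(ql$out_ch, lw$out_spatial))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    ch <- b$ch0:b$ch1
    if (isTRUE(b$zero_input)) {
      out[ch, b$z0:b$z1, b$y0:b$y1, b$x0:b$x1] <- bias_only[ch]
      next
    }
    slab <- xp[, ((b$z0 - 1L) * lw$stride[1] + 1L):((b$z1 - 1L) * lw$stride[1] + lw$kernel[1]),
                 ((b$y0 - 1L) * lw$stride[2] + 1L):((b$y1 - 1L) * lw$stride[2] + lw$kernel[2]),
                 ((b$x0 - 1L) * lw$stride[3] + 1L):((b$x1 - 1L) * lw$stride[3] + lw$kernel[3]),
               drop = FALSE]
    acc <- conv3d_forward(slab, w[ch, , , , , drop = FALSE],
                          stride = lw$stride, padding = c(0L, 0L, 0L))
    acc <- acc + bias_acc[ch]
    if (max(abs(acc)) >= ACC_LIMIT) {
      stop(sprintf("32-bit accumulator overflow in layer %d ('%s')", ql$id, ql$name),
           call. = FALSE)
    }
    out[ch, b$z0:b$z1, b$y0:b$y1, b$x0:b$x1] <-
      clamp_codes(shift_scale(acc, ql$q$bs_out - acc_bs), b_w)
  }
  out
}

#' Simulate the accelerator on a quantized network
#'
#' Behavioural + timing model of one inference: every conv/deconv layer is
#' partitioned into computation blocks (against the per-bank capacity when
#' double buffering), optionally zero-skipped, executed block by block with
#' the bit-exact integer engine, and turned into a four-stage instruction;
#' the whole stream is then scheduled layer by layer. ReLU, max pooling and
#' concatenation are computed exactly but treated as fused (not timed).
#' The simulated label volume is always bit-identical to [infer_int8()]
#' followed by [argmax_labels()] - partitioning and skipping change the
#' schedule, never the values.
#'
#' @param qnet a `quantized_network`.
#' @param v int8-code input volume at the network's input scheme.
#' @param rc a [resource_config()].
#' @param double_buffer,zero_skip logical switches.
#' @return An `accel_sim` object: `scores` (int8 volume), `labels`
#'   (label volume), `blocks`, `instructions`, `trace` (a
#'   `schedule_trace`), `utilization`, `skipped_fraction`.
#' @export
simulate_accelerator <- function(qnet, v, rc, double_buffer = TRUE,
                                 zero_skip = TRUE) {
  stopifnot(inherits(qnet, "quantized_network"), inherits(rc, "resource_config"))
  if (v$value_kind != "int8" || v$shift_bits != qnet$input_bs) {
    stop("input volume must be int8 codes at the network input scheme", call. = FALSE)
  }
  rc_part <- if (double_buffer) halve_caps(rc) else rc
  outs <- vector("list", length(qnet$layers) + 1L)
  outs[[1L]] <- vol_chw(v)
  all_blocks <- list()
  sched_layer <- 0L
  for (ql in qnet$layers) {
    xs <- lapply(ql$inputs, function(i) requant_edge(qnet, outs[[i + 1L]], i, ql$id))
    x <- if (length(xs) == 1L) xs[[1L]] else concat_channels(xs, ql)
    if (ql$type %in% c("conv", "deconv")) {
      sched_layer <- sched_layer + 1L
      blocks <- partition_layer(ql, dim(x)[2:4], rc_part)
      if (zero_skip) {
        lw <- lower_layer(ql, dim(x)[2:4])
        xl <- if (lw$transposed) zero_insert(x, ql$params$stride) else x
        blocks <- zero_skip(blocks, xl)$blocks
      }
      outs[[ql$id + 1L]] <- execute_blocks(ql, blocks, x, qnet$bit_width)
      blocks$sched_layer <- sched_layer
      all_blocks[[length(all_blocks) + 1L]] <- blocks
    } else {
      outs[[ql$id + 1L]] <- int8_layer_forward(ql, x, qnet$bit_width)
    }
  }
  blocks <- dplyr::bind_rows(all_blocks)
  live <- blocks[!blocks$zero_input, ]            # skipped blocks issue no instruction
  live <- allocate_addresses(live, rc, double_buffered = double_buffer)
  instrs <- generate_instructions(live, rc, sched_layer = live$sched_layer)
  trace <- schedule(instrs, double_buffered = double_buffer)
  scores <- chw_to_vol(outs[[length(outs)]], value_kind = "int8",
                       shift_bits = qnet$layers[[length(qnet$layers)]]$q$bs_out,
                       bit_width = qnet$bit_width)
  structure(
    list(scores = scores, labels = argmax_labels(scores), blocks = blocks,
         instructions = instrs, trace = trace,
         utilization = utilization_report(trace, rc),
         skipped_fraction = mean(blocks$zero_input)),
    class = "accel_sim")
}

#' @export
print.accel_sim <- function(x, ...) {
  cat(sprintf("<accel_sim> %d blocks (%.1f%% zero-skipped), makespan %d cycles\n",
              nrow(x$blocks), 100 * x$skipped_fraction, x$trace$makespan))
  invisible(x)
}
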
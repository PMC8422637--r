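qnet_fixture <- function(seed = 71, base = 2L, levels = 2L, size = 8L) {
  net <- fold_network(make_random_network(base, levels, seed = seed))
  withr::with_seed(seed + 1, {
    v <- as_volume(array(rnorm(4 * size^3), c(1, 4, size, size, size)))
  })
  qn <- quantize_network(net, calibrate(net, list(v)))
  list(qnet = qn, v8 = quantize_volume(v, qn$input_bs))
}

test_that("PE mode selection follows the layer channel shape", {
  expect_equal(select_pe_mode(4, 32)$mode, "4-32")
  expect_equal(select_pe_mode(4, 32)$pixels, 4L)
  expect_equal(select_pe_mode(32, 32)$mode, "32-32")
  expect_equal(select_pe_mode(32, 32)$pixels, 2L)
  expect_equal(select_pe_mode(32, 64)$mode, "32-64")
  expect_equal(select_pe_mode(32, 64)$pixels, 1L)
  expect_equal(select_pe_mode(3, 16)$mode, "4-32")    # padded to 4 lanes
})

test_that("partition tiles the layer output exactly and fits capacities", {
  fx <- qnet_fixture()
  ql <- fx$qnet$layers[[1]]
  big <- resource_config()       # large enough for a single block
  b1 <- partition_layer(ql, c(8, 8, 8), big)
  expect_equal(nrow(b1), 1)
  rc <- resource_config(input_mem = 600, param_mem = 4096, output_mem = 512)
  b <- partition_layer(ql, c(8, 8, 8), rc)
  expect_gt(nrow(b), 1)
  # exact disjoint cover of the output voxel/channel grid
  cover <- array(0L, c(ql$out_ch, 8, 8, 8))
  for (i in seq_len(nrow(b))) {
    cover[b$ch0[i]:b$ch1[i], b$z0[i]:b$z1[i], b$y0[i]:b$y1[i], b$x0[i]:b$x1[i]] <-
      cover[b$ch0[i]:b$ch1[i], b$z0[i]:b$z1[i], b$y0[i]:b$y1[i], b$x0[i]:b$x1[i]] + 1L
    expect_lte(b$in_bytes[i], rc$input_mem)
    expect_lte(b$param_bytes[i], rc$param_mem)
    expect_lte(b$out_bytes[i], rc$output_mem)
  }
  expect_true(all(cover == 1L))
})

test_that("shrinking any capacity never decreases the block count", {
  fx <- qnet_fixture()
  ql <- fx$qnet$layers[[3]]      # a mid-network conv
  for (axis in c("input_mem", "output_mem")) {
    caps <- c(16384, 4096, 1024, 512, 256)
    counts <- vapply(caps, function(cp) {
      args <- list(input_mem = 16384, param_mem = 16384, output_mem = 16384)
      args[[axis]] <- cp
      nrow(partition_layer(ql, c(8, 8, 8), do.call(resource_config, args)))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("an oversized minimal block is an infeasible-partition error", {
  fx <- qnet_fixture()
  rc <- resource_config(input_mem = 4, param_mem = 4, output_mem = 4)
  expect_error(partition_layer(fx$qnet$layers[[1]], c(8, 8, 8), rc),
               "infeasible partition.*enc1_a_conv")
})

test_that("address allocation is disjoint per ping-pong bank and in range", {
  fx <- qnet_fixture()
  rc <- resource_config(input_mem = 2048, param_mem = 2048, output_mem = 2048)
  b <- partition_layer(fx$qnet$layers[[1]], c(8, 8, 8),
                       quantseg:::halve_caps(rc))
  ab <- allocate_addresses(b, rc, double_buffered = TRUE)
  # consecutive blocks alternate banks; intervals within a step never overlap
  for (i in seq_len(nrow(ab) - 1)) {
    expect_true(ab$addr_in[i] + ab$in_bytes[i] <= rc$input_mem)
    iv1 <- c(ab$addr_in[i], ab$addr_in[i] + ab$in_bytes[i])
    iv2 <- c(ab$addr_in[i + 1], ab$addr_in[i + 1] + ab$in_bytes[i + 1])
    expect_true(iv1[2] <= iv2[1] || iv2[2] <= iv1[1])
  }
  one <- allocate_addresses(b[1, ], rc, double_buffered = FALSE)
  expect_equal(one$addr_in, 0)
  small <- resource_config(input_mem = 8, param_mem = 2048, output_mem = 2048)
  expect_error(allocate_addresses(b, small, double_buffered = TRUE),
               "input buffer overflow")
})

test_that("instruction costs follow the ceiling-division cycle model", {
  blocks <- tibble::tibble(
    layer_id = 1L, layer_name = "L", mode = "32-64", block = 1:2,
    ch0 = 1L, ch1 = 64L, z0 = 1L, z1 = 1L, y0 = 1L, y1 = 1L, x0 = 1L, x1 = 1L,
    iz0 = 1L, iz1 = 1L, iy0 = 1L, iy1 = 1L, ix0 = 1L, ix1 = 1L,
    macs_real = c(1024, 0), macs_padded = c(1024, 0),
    in_bytes = c(100, 0), param_bytes = c(28, 0), out_bytes = c(64, 0),
    zero_input = FALSE, addr_in = 0, addr_param = 0, addr_out = 0)
  rc <- resource_config(pe_multipliers = 256, load_bw = 64, wb_bw = 32,
                        cf_cycles = 5)
  ins <- generate_instructions(blocks, rc)
  expect_equal(ins$ex, c(4L, 0L))          # ceil(1024 / 256); zero-MAC block
  expect_equal(ins$ld[1], 2L)              # ceil(128 / 64)
  expect_equal(ins$wb[1], 2L)              # ceil(64 / 32)
  expect_equal(ins$cf, c(5L, 5L))
})

test_that("instruction streams round-trip through the binary format", {
  fx <- qnet_fixture()
  rc <- resource_config(input_mem = 2048, param_mem = 8192, output_mem = 2048)
  sim <- simulate_accelerator(fx$qnet, fx$v8, rc)
  ins <- sim$instructions
  dec <- decode_instructions(encode_instructions(ins))
  for (col in c("opcode", "sched_layer", "mode", "cf", "ld", "ex", "wb",
                "addr_in", "addr_param", "addr_out")) {
    expect_equal(dec[[col]], ins[[col]], ignore_attr = TRUE)
  }
  expect_error(decode_instructions(as.raw(1:10)), "not a QSEG")
})

test_that("zero-skip removes exactly the all-zero blocks and preserves outputs", {
  ph <- make_phantom(shape = c(32, 32, 32), seed = 91)
  net <- fold_network(make_random_network(2, 2, seed = 92))
  qn <- quantize_network(net, calibrate(net, list(ph$volume)))
  v8 <- quantize_volume(ph$volume, qn$input_bs)
  rc <- resource_config(input_mem = 1024, param_mem = 8192, output_mem = 2048)
  skip <- simulate_accelerator(qn, v8, rc, zero_skip = TRUE)
  full <- simulate_accelerator(qn, v8, rc, zero_skip = FALSE)
  expect_identical(skip$scores$data, full$scores$data)
  expect_gt(skip$skipped_fraction, 0)
  expect_equal(full$skipped_fraction, 0)
  # dense input: nothing to skip
  withr::with_seed(93, {
    dense <- as_volume(array(rnorm(4 * 8^3, mean = 3), c(1, 4, 8, 8, 8)))
  })
  qd <- quantize_network(net, calibrate(net, list(dense)))
  simd <- simulate_accelerator(qd, quantize_volume(dense, qd$input_bs),
                               resource_config(input_mem = 512,
                                               param_mem = 8192,
                                               output_mem = 2048))
  expect_equal(simd$skipped_fraction, 0)
})

test_that("all-zero input volume skips every first-layer block, bias-only output", {
  fx <- qnet_fixture(seed = 95)
  qn <- fx$qnet
  z <- as_volume(array(0, dim(fx$v8$data)), value_kind = "int8",
                 shift_bits = qn$input_bs)
  rc <- resource_config(input_mem = 512, param_mem = 8192, output_mem = 2048)
  sim <- simulate_accelerator(qn, z, rc)
  l1 <- sim$blocks[sim$blocks$layer_id == 1, ]
  expect_true(all(l1$zero_input))
  expect_identical(sim$scores$data, infer_int8(qn, z)$data)
})

test_that("block execution reproduces infer_int8 bit-exactly for any partition", {
  fx <- qnet_fixture(seed = 97)
  want <- infer_int8(fx$qnet, fx$v8)$data
  for (seed in 1:5) {
    withr::with_seed(seed, {
      rc <- resource_config(
        input_mem = sample(c(400, 1024, 4096), 1),
        param_mem = sample(c(4096, 16384), 1),
        output_mem = sample(c(256, 2048, 8192), 1),
        load_bw = sample(c(16, 64), 1), wb_bw = sample(c(16, 64), 1))
    })
    for (db in c(TRUE, FALSE)) {
      sim <- simulate_accelerator(fx$qnet, fx$v8, rc, double_buffer = db)
      expect_identical(sim$scores$data, want)
    }
  }
})

test_that("utilization reflects real versus padded multiplier lanes", {
  # a 32-64 block exactly filling the PE: occupancy 1 during EX
  blocks <- tibble::tibble(
    layer_id = 1L, layer_name = "L", mode = "32-64", block = 1L,
    ch0 = 1L, ch1 = 64L, z0 = 1L, z1 = 1L, y0 = 1L, y1 = 1L, x0 = 1L, x1 = 1L,
    iz0 = 1L, iz1 = 1L, iy0 = 1L, iy1 = 1L, ix0 = 1L, ix1 = 1L,
    macs_real = 2048 * 4, macs_padded = 2048 * 4,
    in_bytes = 10, param_bytes = 10, out_bytes = 10,
    zero_input = FALSE, addr_in = 0, addr_param = 0, addr_out = 0)
  rc <- resource_config(pe_multipliers = 2048)
  tr <- schedule(generate_instructions(blocks, rc))
  u <- utilization_report(tr, rc)
  expect_equal(u$per_mode$occupancy, 1.0)

  # 3 real input channels padded to the 4 lanes of 4-32 mode: occupancy 3/4
  rc2 <- resource_config(pe_multipliers = 4 * 32 * 4)
  b2 <- blocks
  b2$mode <- "4-32"
  b2$macs_real <- 3 * 32 * 512; b2$macs_padded <- 4 * 32 * 512
  tr2 <- schedule(generate_instructions(b2, rc2))
  expect_equal(utilization_report(tr2, rc2)$per_mode$occupancy, 3 / 4)

  # double buffering raises (or matches) the EX busy fraction
  fx <- qnet_fixture(seed = 98)
  rc3 <- resource_config(input_mem = 2048, param_mem = 8192, output_mem = 2048)
  sim <- simulate_accelerator(fx$qnet, fx$v8, rc3)
  ser <- schedule(sim$instructions, double_buffered = FALSE)
  expect_gte(glance(sim$trace)$ex_busy_fraction, glance(ser)$ex_busy_fraction)
})
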
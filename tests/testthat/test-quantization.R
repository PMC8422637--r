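test_that("shift_bits follows b_w - 1 - ceil(log2(max_abs))", {
  expect_equal(shift_bits(1.0), 7L)
  expect_equal(shift_bits(3.7), 5L)     # ceil(log2 3.7) = 2
  expect_equal(shift_bits(0.25), 9L)    # ceil(log2 0.25) = -2
  expect_equal(shift_bits(0), 7L)       # all-zero tensor convention
  expect_equal(shift_bits(1.0, b_w = 16L), 15L)
})

test_that("quantize_tensor clamps, rounds half away from zero, and is exact on the grid", {
  expect_equal(quantize_tensor(0, b_s = 5L), 0)
  # positive-edge saturation: 1.0 at b_s = 7 rounds to 128, clamps to 127
  expect_equal(quantize_tensor(1.0, b_s = 7L), 127)
  expect_equal(quantize_tensor(-1.0, b_s = 7L), -128)
  # ties away from zero
  expect_equal(quantize_tensor(c(0.5, -0.5, 1.5, -1.5), b_s = 0L),
               c(1, -1, 2, -2))
  # values already on the grid are reproduced exactly
  q0 <- c(-128, -37, 0, 64, 127)
  expect_equal(quantize_tensor(q0 * 2^-4, b_s = 4L), q0)
  expect_error(quantize_tensor(c(1, NaN), b_s = 0L, name = "w"), "'w'")
})

test_that("quantization error is at most half a step for non-saturated elements", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      x <- rnorm(500, sd = 10^runif(1, -3, 2))
    })
    bs <- shift_bits(max(abs(x)))
    q <- quantize_tensor(x, bs)
    ns <- q > -128 & q < 127
    expect_true(all(abs(x[ns] - dequantize_tensor(q[ns], bs)) <= 2^(-bs - 1) + 1e-12))
    # scale bound: only elements at the max can saturate
    sat <- which(!ns)
    if (length(sat)) expect_equal(abs(x[sat]), rep(max(abs(x)), length(sat)))
  }
})

test_that("calibration records running max-abs per layer", {
  net <- fold_network(make_random_network(2, 2, seed = 3))
  withr::with_seed(4, {
    v1 <- as_volume(array(rnorm(4 * 8^3), c(1, 4, 8, 8, 8)))
    v2 <- as_volume(array(rnorm(4 * 8^3), c(1, 4, 8, 8, 8)))
  })
  r1 <- calibrate(net, list(v1))
  # oracle: instrumented float pass on layer 1's input
  expect_equal(r1$max_abs_in[1], max(abs(v1$data)))
  zero <- as_volume(array(0, c(1, 4, 8, 8, 8)))
  rz <- calibrate(net, list(zero))
  expect_equal(rz$max_abs_in[1], 0)
  # two volumes give the elementwise max of the single-volume records
  r2 <- calibrate(net, list(v2))
  r12 <- calibrate(net, list(v1, v2))
  expect_equal(r12$max_abs_in, pmax(r1$max_abs_in, r2$max_abs_in))
  expect_equal(r12$max_abs_out, pmax(r1$max_abs_out, r2$max_abs_out))
  expect_error(calibrate(net, list()), "non-empty")
})

test_that("quantize_network assigns schemes per layer and stays in code range", {
  net <- fold_network(make_random_network(2, 2, seed = 5))
  # force a known weight max on the first layer
  net$layers[[1]]$params$weights[1] <- 1.0
  net$layers[[1]]$params$weights <- net$layers[[1]]$params$weights /
    max(abs(net$layers[[1]]$params$weights))
  withr::with_seed(6, {
    v <- as_volume(array(rnorm(4 * 8^3), c(1, 4, 8, 8, 8)))
  })
  qn <- quantize_network(net, calibrate(net, list(v)))
  expect_equal(qn$layers[[1]]$q$bs_weight, 7L)   # max|W| = 1.0
  for (ql in qn$layers) {
    if (!is.null(ql$q$weights)) {
      expect_true(all(ql$q$weights >= -128 & ql$q$weights <= 127))
      expect_true(all(ql$q$bias >= -128 & ql$q$bias <= 127))
    }
  }
  sch <- tidy(qn)
  expect_true(all(!is.na(sch$bs_in)))
  expect_error(quantize_network(make_random_network(2, 2, seed = 5),
                                calibrate(net, list(v))),
               "fold_network")
})

test_that("weight and bias scale factors are computed separately per layer", {
  net <- fold_network(make_random_network(2, 2, seed = 8))
  withr::with_seed(9, {
    v <- as_volume(array(rnorm(4 * 8^3), c(1, 4, 8, 8, 8)))
  })
  qn <- quantize_network(net, calibrate(net, list(v)))
  for (ql in qn$layers) {
    if (ql$type %in% c("conv", "deconv")) {
      p <- net$layers[[ql$id]]$params
      expect_equal(ql$q$bs_weight, shift_bits(max(abs(p$weights))))
      expect_equal(ql$q$bs_bias, shift_bits(max(abs(p$bias))))
    }
  }
})
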
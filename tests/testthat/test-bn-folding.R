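random_conv_bn <- function(seed, transposed = FALSE) {
  withr::with_seed(seed, {
    ic <- sample(1:4, 1); oc <- sample(1:4, 1); k <- sample(1:3, 1)
    conv <- if (transposed) {
      conv_params(array(rnorm(oc * ic * 8), c(oc, ic, 2, 2, 2)), rnorm(oc),
                  stride = c(2, 2, 2), transposed = TRUE)
    } else {
      conv_params(array(rnorm(oc * ic * k^3), c(oc, ic, k, k, k)), rnorm(oc),
                  padding = rep((k - 1) %/% 2, 3))
    }
    bn <- bn_params(rnorm(oc), runif(oc, 0.1, 2), runif(oc, 0.5, 1.5),
                    rnorm(oc), epsilon = 10^runif(1, -6, -3))
    x <- array(rnorm(ic * 6^3), c(ic, 6, 6, 6))
    list(conv = conv, bn = bn, x = x)
  })
}

test_that("identity BN leaves a convolution unchanged", {
  cp <- conv_params(array(rnorm(2 * 3 * 27), c(2, 3, 3, 3, 3)), rnorm(2))
  # gamma=1, beta=0, mu=0, sigma2=1, and a tiny epsilon (zero is not allowed)
  bp <- bn_params(c(0, 0), c(1, 1), c(1, 1), c(0, 0), epsilon = 1e-12)
  f <- fold_bn(cp, bp)
  expect_equal(f$weights, cp$weights, tolerance = 1e-10)
  expect_equal(f$bias, cp$bias, tolerance = 1e-10)
})

test_that("hand-evaluated fold: W=2, gamma=2, sigma2=3, eps=1 gives W'=2, B'=0", {
  f <- fold_bn(conv_params(array(2, c(1, 1, 1, 1, 1)), 0),
               bn_params(0, 3, 2, 0, epsilon = 1))
  expect_equal(f$weights[1], 2)
  expect_equal(f$bias, 0)
})

test_that("folded layer reproduces conv-then-BN, including nonzero beta", {
  for (seed in 1:15) {
    for (transposed in c(FALSE, TRUE)) {
      cs <- random_conv_bn(seed + 100 * transposed, transposed)
      direct <- if (transposed) {
        naive_deconv3d(cs$x, cs$conv$weights, cs$conv$stride, cs$conv$padding)
      } else {
        naive_conv3d(cs$x, cs$conv$weights, cs$conv$stride, cs$conv$padding)
      }
      want <- naive_bn(cs$bn, direct + cs$conv$bias)
      f <- fold_bn(cs$conv, cs$bn)
      got <- if (transposed) {
        deconv3d_forward(cs$x, f$weights, f$stride, f$padding)
      } else {
        quantseg:::conv3d_forward(cs$x, f$weights, f$stride, f$padding)
      }
      got <- got + f$bias
      expect_lt(max(abs(got - want)) / max(abs(want)), 1e-5)
    }
  }
})

test_that("fold_network removes exactly the BN layers and preserves outputs", {
  g <- make_random_network(2, 2, seed = 11)
  n_bn <- quantseg:::count_layers(g, "bn")
  expect_gt(n_bn, 0)
  fg <- fold_network(g)
  expect_equal(quantseg:::count_layers(fg, "bn"), 0)
  expect_equal(length(fg$layers), length(g$layers) - n_bn)
  withr::with_seed(12, {
    v <- as_volume(array(rnorm(4 * 16^3), c(1, 4, 16, 16, 16)))
  })
  a <- infer_float(g, v)$data
  b <- infer_float(fg, v)$data
  expect_lt(max(abs(a - b)), 1e-5 * diff(range(a)))
})

test_that("folding is idempotent and BN-free graphs pass through unchanged", {
  g <- make_random_network(2, 2, seed = 13)
  f1 <- fold_network(g)
  f2 <- fold_network(f1)
  expect_identical(f1, f2)
})

test_that("a BN layer without an eligible predecessor is a structural error", {
  layers <- list(
    quantseg:::new_layer(1, "r", "relu", 0, 2, 2),
    quantseg:::new_layer(2, "b", "bn", 1, 2, 2,
                         params = bn_params(c(0, 0), c(1, 1), c(1, 1), c(0, 0))))
  g <- quantseg:::new_unet_graph(layers, 2, 2, 1, 2)
  expect_error(fold_network(g), "folding requires an adjacent conv or deconv")
})

test_that("channel mismatch between conv and BN is rejected", {
  cp <- conv_params(array(0, c(2, 1, 1, 1, 1)), c(0, 0))
  bp <- bn_params(0, 1, 1, 0)
  expect_error(fold_bn(cp, bp), "channels")
})
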
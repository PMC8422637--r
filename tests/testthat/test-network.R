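test_that("build_unet3d reproduces the expected topology", {
  g <- build_unet3d(32, 3, in_channels = 4, out_classes = 3)
  tab <- layer_table(g)
  first_conv <- tab[tab$type == "conv", ][1, ]
  expect_equal(first_conv$in_ch, 4L)
  expect_equal(first_conv$out_ch, 32L)
  # all three hardware channel patterns occur: 4->32, 32->32, 32->64
  convs <- tab[tab$type %in% c("conv", "deconv"), ]
  expect_true(any(convs$in_ch == 4 & convs$out_ch == 32))
  expect_true(any(convs$in_ch == 32 & convs$out_ch == 32))
  expect_true(any(convs$in_ch == 32 & convs$out_ch == 64))
})

test_that("hand-enumerated two-level topology matches the builder", {
  g <- build_unet3d(2, 2, in_channels = 4, out_classes = 3)
  expected <- c(
    "enc1_a_conv:conv", "enc1_a_bn:bn", "enc1_a_relu:relu",
    "enc1_b_conv:conv", "enc1_b_bn:bn", "enc1_b_relu:relu",
    "pool1:maxpool",
    "enc2_a_conv:conv", "enc2_a_bn:bn", "enc2_a_relu:relu",
    "enc2_b_conv:conv", "enc2_b_bn:bn", "enc2_b_relu:relu",
    "up1_deconv:deconv", "up1_bn:bn", "up1_relu:relu", "up1_concat:concat",
    "dec1_a_conv:conv", "dec1_a_bn:bn", "dec1_a_relu:relu",
    "dec1_b_conv:conv", "dec1_b_bn:bn", "dec1_b_relu:relu",
    "classifier:conv")
  tab <- layer_table(g)
  expect_equal(paste(tab$name, tab$type, sep = ":"), expected)
  # skip-connection channels come first in the concat
  concat <- g$layers[[17]]
  expect_equal(concat$inputs, c(6L, 16L))
  # channel widths double per level
  expect_equal(tab$out_ch[tab$name == "enc2_b_conv"], 4L)
})

test_that("minimal one-level configuration runs end to end", {
  g <- build_unet3d(1, 1, in_channels = 1, out_classes = 1)
  g$layers[[1]]$params$weights[] <- 1 / 27
  v <- as_volume(array(rnorm(512), c(8, 8, 8)))
  out <- infer_float(g, v)
  expect_equal(dim(out), c(1, 1, 8, 8, 8))
})

test_that("identity and all-ones kernels give hand-computable outputs", {
  # identity 1x1x1 conv: output equals input
  ly <- quantseg:::new_layer(1, "id", "conv", 0, 1, 1,
    params = conv_params(array(1, c(1, 1, 1, 1, 1)), 0))
  g <- quantseg:::new_unet_graph(list(ly), 1, 1, 1, 1)
  v <- as_volume(array(rnorm(64), c(4, 4, 4)))
  expect_equal(infer_float(g, v)$data, v$data)

  # 3x3x3 all-ones kernel on all-ones 3^3 input, no padding: single value 27
  ly2 <- quantseg:::new_layer(1, "sum", "conv", 0, 1, 1,
    params = conv_params(array(1, c(1, 1, 3, 3, 3)), 0))
  g2 <- quantseg:::new_unet_graph(list(ly2), 1, 1, 1, 1)
  out <- infer_float(g2, as_volume(array(1, c(3, 3, 3))))
  expect_equal(dim(out), c(1, 1, 1, 1, 1))
  expect_equal(out$data[1], 27)
})

test_that("float inference matches the direct-loop oracle on random tiny nets", {
  for (seed in 1:5) {
    net <- make_tiny_net(seed)
    withr::with_seed(seed + 50, {
      v <- as_volume(array(rnorm(net$in_channels * 16^3),
                           c(1, net$in_channels, 16, 16, 16)))
    })
    got <- infer_float(net, v)
    x <- quantseg:::vol_chw(v)
    for (ly in net$layers) {
      x <- switch(ly$type,
        conv = naive_conv3d(x, ly$params$weights, ly$params$stride,
                            ly$params$padding) + ly$params$bias,
        deconv = naive_deconv3d(x, ly$params$weights, ly$params$stride,
                                ly$params$padding) + ly$params$bias,
        relu = pmax(x, 0))
    }
    expect_lt(max(abs(quantseg:::vol_chw(got) - x)) / max(abs(x)), 1e-6)
  }
})

test_that("maxpool/deconv path restores spatial shape at every concat", {
  for (levels in 2:3) {
    g <- build_unet3d(2, levels, in_channels = 2, out_classes = 2)
    sz <- 8L * 2L^(levels - 2L)
    v <- as_volume(array(rnorm(2 * sz^3), c(1, 2, sz, sz, sz)))
    expect_equal(dim(infer_float(g, v))[3:5], c(sz, sz, sz))
  }
  # stride-2 kernel-2 deconvolution exactly doubles each axis
  x <- array(rnorm(2 * 3 * 4 * 5), c(2, 3, 4, 5))
  w <- array(rnorm(2 * 2 * 8), c(2, 2, 2, 2, 2))
  expect_equal(dim(deconv3d_forward(x, w))[2:4], c(6, 8, 10))
})

test_that("shape errors name the offending layer", {
  g <- build_unet3d(2, 2, in_channels = 4, out_classes = 2)
  bad <- as_volume(array(0, c(1, 3, 8, 8, 8)))
  expect_error(infer_float(g, bad), "3 channels.*expects 4")
  odd <- as_volume(array(0, c(1, 4, 7, 7, 7)))
  expect_error(infer_float(g, odd), "divisible")
})

test_that("argmax labeling is 0-based with ties toward the lowest class", {
  sc <- array(0, c(1, 3, 1, 1, 1))
  sc[1, , 1, 1, 1] <- c(0.2, 0.9, 0.1)
  expect_equal(quantseg:::vol_chw(argmax_labels(as_volume(sc)))[1, 1, 1, 1], 1)
  tie <- array(0.5, c(1, 2, 2, 2, 2))
  expect_true(all(quantseg:::vol_chw(argmax_labels(as_volume(tie))) == 0))
  withr::with_seed(9, {
    sc <- array(rnorm(4 * 5^3), c(1, 4, 5, 5, 5))
  })
  got <- quantseg:::vol_chw(argmax_labels(as_volume(sc)))
  want <- apply(sc[1, , , , ], c(2, 3, 4), which.max) - 1
  expect_equal(got[1, , , ], want)
})
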
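# Independent oracles used throughout the suite. These are deliberately
# written as direct (slow) loops, separate from the package's vectorized
# slice-decomposed implementation.

naive_conv3d <- function(x, w, stride = c(1, 1, 1), padding = c(0, 0, 0)) {
  xp <- quantseg:::pad_spatial(x, padding)
  d <- dim(xp); k <- dim(w)[3:5]; oc <- dim(w)[1]
  osz <- (d[2:4] - k) %/% stride + 1
  out <- array(0, c(oc, osz))
  for (o in seq_len(oc)) {
    wo <- as.vector(w[o, , , , , drop = FALSE])
    for (z in seq_len(osz[1])) for (y in seq_len(osz[2])) for (xx in seq_len(osz[3])) {
      patch <- xp[, (z - 1) * stride[1] + seq_len(k[1]),
                    (y - 1) * stride[2] + seq_len(k[2]),
                    (xx - 1) * stride[3] + seq_len(k[3]), drop = FALSE]
      out[o, z, y, xx] <- sum(wo * as.vector(patch))
    }
  }
  out
}

# scatter-form transposed convolution: y[s*z + j] += w[j] * x[z]
naive_deconv3d <- function(x, w, stride = c(2, 2, 2), padding = c(0, 0, 0)) {
  d <- dim(x); k <- dim(w)[3:5]; oc <- dim(w)[1]
  osz <- (d[2:4] - 1) * stride - 2 * padding + k
  out <- array(0, c(oc, osz))
  for (o in seq_len(oc)) for (i in seq_len(d[1])) {
    for (z in seq_len(d[2])) for (y in seq_len(d[3])) for (xx in seq_len(d[4])) {
      v <- x[i, z, y, xx]
      if (v == 0) next
      for (a in seq_len(k[1])) for (b in seq_len(k[2])) for (cc in seq_len(k[3])) {
        oz <- (z - 1) * stride[1] + a - padding[1]
        oy <- (y - 1) * stride[2] + b - padding[2]
        ox <- (xx - 1) * stride[3] + cc - padding[3]
        if (oz >= 1 && oz <= osz[1] && oy >= 1 && oy <= osz[2] &&
            ox >= 1 && ox <= osz[3]) {
          out[o, oz, oy, ox] <- out[o, oz, oy, ox] + w[o, i, a, b, cc] * v
        }
      }
    }
  }
  out
}

naive_bn <- function(bn, x) {
  out <- x
  for (ch in seq_len(dim(x)[1])) {
    xh <- (x[ch, , , ] - bn$mean[ch]) / sqrt(bn$variance[ch] + bn$epsilon)
    out[ch, , , ] <- bn$gamma[ch] * xh + bn$beta[ch]
  }
  out
}

# round-half-away-from-zero right shift written independently of the
# package's modulo-based version (exact: v / 2^s is a binary-exact division)
oracle_rshift <- function(v, s) {
  if (s <= 0) return(v * 2^(-s))
  sign(v) * floor(abs(v) / 2^s + 0.5)
}

oracle_clamp <- function(v, b_w) pmin(pmax(v, -2^(b_w - 1)), 2^(b_w - 1) - 1)

# unbounded-precision re-implementation of the integer pipeline (loop-based
# convolutions, 2^53 exactness guard instead of the 32-bit accumulator)
oracle_infer_int8 <- function(qnet, v) {
  outs <- vector("list", length(qnet$layers) + 1L)
  outs[[1L]] <- quantseg:::vol_chw(v)
  b_w <- qnet$bit_width
  for (ql in qnet$layers) {
    xs <- lapply(ql$inputs, function(i) {
      x <- outs[[i + 1L]]
      for (r in qnet$requant) {
        if (r$from == i && r$to == ql$id) {
          x <- oracle_clamp(oracle_rshift(x, -r$shift), b_w)
        }
      }
      x
    })
    x <- if (length(xs) == 1L) xs[[1L]] else {
      sh <- dim(xs[[1]])[2:4]
      out <- array(0, c(sum(vapply(xs, function(q) dim(q)[1], integer(1))), sh))
      at <- 0L
      for (q in xs) { out[at + seq_len(dim(q)[1]), , , ] <- q; at <- at + dim(q)[1] }
      out
    }
    y <- switch(ql$type,
      conv = ,
      deconv = {
        p <- ql$params
        acc <- if (ql$type == "conv") {
          naive_conv3d(x, ql$q$weights, p$stride, p$padding)
        } else {
          naive_deconv3d(x, ql$q$weights, p$stride, p$padding)
        }
        acc_bs <- ql$q$bs_in + ql$q$bs_weight
        acc <- acc + oracle_rshift(ql$q$bias, ql$q$bs_bias - acc_bs)
        stopifnot(max(abs(acc)) < 2^53)
        oracle_clamp(oracle_rshift(acc, acc_bs - ql$q$bs_out), b_w)
      },
      relu = pmax(x, 0),
      maxpool = quantseg:::maxpool_forward(x, ql$pool),
      concat = x)
    outs[[ql$id + 1L]] <- y
  }
  outs[[length(outs)]]
}

# independent event-driven scheduler: advances time event by event, starting
# any stage whose predecessor stage is done, whose resource is free (FIFO by
# instruction), and whose gating constraints hold
event_sim <- function(instrs, double_buffered = TRUE) {
  n <- nrow(instrs)
  if (n == 0) return(list(makespan = 0))
  layer <- if ("sched_layer" %in% names(instrs)) instrs$sched_layer else rep(1L, n)
  cost <- cbind(instrs$cf, instrs$ld, instrs$ex, instrs$wb)
  stage <- rep(1L, n)        # next stage to start (1..4; 5 = retired)
  s <- matrix(NA_real_, n, 4); e <- matrix(NA_real_, n, 4)
  res_free <- numeric(4)
  t <- 0
  repeat {
    progressed <- FALSE
    for (i in seq_len(n)) {
      k <- stage[i]
      if (k > 4L) next
      ready_at <- if (k == 1L) {
        gate <- if (double_buffered) {
          if (i > 2) e[i - 2, 4] else 0
        } else {
          if (i > 1) e[i - 1, 4] else 0
        }
        if (is.na(gate)) Inf else gate
      } else {
        e[i, k - 1]
      }
      if (k == 3L) {           # EX waits for all earlier layers' WBs
        earlier <- which(layer < layer[i])
        if (length(earlier)) {
          wbs <- e[earlier, 4]
          ready_at <- max(ready_at, if (any(is.na(wbs))) Inf else max(wbs))
        }
      }
      # FIFO per resource: an earlier instruction waiting for this stage wins
      if (any(stage[seq_len(i - 1)] == k)) next
      start <- max(ready_at, res_free[k])
      if (start <= t) {
        s[i, k] <- start; e[i, k] <- start + cost[i, k]
        res_free[k] <- e[i, k]
        stage[i] <- k + 1L
        progressed <- TRUE
      }
    }
    if (all(stage > 4L)) break
    if (!progressed) {
      # advance time to the earliest moment any non-FIFO-blocked stage could start
      cand <- c()
      for (i in seq_len(n)) {
        k <- stage[i]
        if (k > 4L) next
        if (any(stage[seq_len(i - 1)] == k)) next   # FIFO-blocked; its turn comes later
        base <- if (k == 1L) {
          g <- if (double_buffered) { if (i > 2) e[i - 2, 4] else 0 }
               else { if (i > 1) e[i - 1, 4] else 0 }
          if (is.na(g)) Inf else g
        } else {
          if (is.na(e[i, k - 1])) Inf else e[i, k - 1]
        }
        if (k == 3L) {
          earlier <- which(layer < layer[i])
          if (length(earlier)) {
            wbs <- e[earlier, 4]
            base <- max(base, if (any(is.na(wbs))) Inf else max(wbs))
          }
        }
        cand <- c(cand, max(base, res_free[k]))
      }
      nxt <- suppressWarnings(min(cand[cand > t & is.finite(cand)]))
      if (!is.finite(nxt)) stop("event simulator deadlock")
      t <- nxt
    }
  }
  list(makespan = max(e[, 4]), start = s, end = e)
}

# tiny sequential networks for integer-soundness checks
make_tiny_net <- function(seed) {
  withr::with_seed(seed, {
    in_ch <- sample(1:3, 1)
    chs <- c(in_ch, sample(1:4, 2, replace = TRUE))
    layers <- list()
    nid <- 0L
    add <- function(name, type, inputs, in_ch, out_ch, ...) {
      nid <<- nid + 1L
      layers[[nid]] <<- quantseg:::new_layer(nid, name, type, inputs, in_ch, out_ch, ...)
      nid
    }
    prev <- 0L
    for (j in 1:2) {
      k <- sample(1:3, 1)
      w <- array(rnorm(chs[j + 1] * chs[j] * k^3, sd = 0.5), c(chs[j + 1], chs[j], k, k, k))
      prev <- add(sprintf("c%d", j), "conv", prev, chs[j], chs[j + 1],
                  params = quantseg::conv_params(w, rnorm(chs[j + 1], sd = 0.2),
                                                 padding = rep((k - 1) %/% 2, 3)))
      prev <- add(sprintf("r%d", j), "relu", prev, chs[j + 1], chs[j + 1])
    }
    if (runif(1) < 0.5) {
      w <- array(rnorm(chs[3] * chs[3] * 8, sd = 0.5), c(chs[3], chs[3], 2, 2, 2))
      prev <- add("up", "deconv", prev, chs[3], chs[3],
                  params = quantseg::conv_params(w, rnorm(chs[3], sd = 0.2),
                                                 stride = c(2, 2, 2), transposed = TRUE))
    }
    quantseg:::new_unet_graph(layers, in_ch, chs[3], 1L, chs[2])
  })
}

make_tiny_qnet <- function(seed, size = 6L, b_w = 8L) {
  net <- make_tiny_net(seed)
  withr::with_seed(seed + 1000L, {
    v <- as_volume(array(rnorm(net$in_channels * size^3),
                         c(1, net$in_channels, size, size, size)))
  })
  qnet <- quantize_network(net, calibrate(net, list(v)), b_w = b_w)
  list(net = net, qnet = qnet, volume = v)
}

random_phantom_pair <- function(seed, shape = c(16, 16, 16)) {
  make_phantom(shape = shape, seed = seed)
}

# random four-stage instruction programs for scheduling checks
rand_program <- function(seed, n = NULL, layers = NULL) {
  withr::with_seed(seed, {
    if (is.null(n)) n <- sample(1:12, 1)
    if (is.null(layers)) layers <- sort(sample(1:3, n, replace = TRUE))
    tibble::tibble(
      cf = sample(0:10, n, replace = TRUE),
      ld = sample(0:20, n, replace = TRUE),
      ex = sample(0:40, n, replace = TRUE),
      wb = sample(0:15, n, replace = TRUE),
      sched_layer = layers)
  })
}
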
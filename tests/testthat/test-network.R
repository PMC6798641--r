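test_that("convolution matches hand computation and the loop oracle", {
  # single one-hot motif detector (k = 1) reads off the G positions
  x <- encode_sequence("AGGCUG")$mat
  w <- array(0, c(1, 4, 1))
  w[1, 3, 1] <- 1
  expect_equal(as.numeric(conv_forward(x, w, 0)), c(0, 1, 1, 0, 0, 1))

  set.seed(51)
  for (rep in 1:20) {
    L <- sample(6:20, 1)
    C <- sample(2:4, 1)
    k <- sample(1:min(5, L), 1)
    nf <- sample(1:6, 1)
    x <- matrix(rnorm(L * C), L, C)
    w <- array(rnorm(nf * C * k), c(nf, C, k))
    b <- rnorm(nf)
    expect_equal(conv_forward(x, w, b), conv_oracle(x, w, b),
                 tolerance = 1e-12)
  }
  # output width and degenerate kernel
  expect_equal(ncol(conv_forward(matrix(0, 100, 4),
                                 array(0, c(1, 4, 5)), 0)), 96)
  expect_error(conv_forward(matrix(0, 3, 4), array(0, c(1, 4, 5)), 0),
               class = "premir_shape_error")
})

test_that("relu clamps negatives and is idempotent", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  z <- matrix(rnorm(20), 4)
  expect_equal(relu(relu(z)), relu(z))
  expect_equal(relu(abs(z)), abs(z))
})

test_that("maxpool matches the brute-force window maximum", {
  expect_equal(as.numeric(maxpool(matrix(c(1, 3, 2, 0), 1), 2)), c(3, 2))
  z <- matrix(rnorm(36), 4)
  expect_equal(maxpool(z, 1), z)
  set.seed(52)
  z9 <- matrix(rnorm(36), 4, 9)
  p <- maxpool(z9, 2)
  expect_equal(dim(p), c(4, 4))
  expect_equal(p, maxpool_oracle(z9, 2))
  expect_error(maxpool(matrix(0, 2, 3), 4), class = "premir_shape_error")
})

test_that("lstm_step closed forms and bounds hold", {
  hdim <- 5
  zero_par <- list(Wx = matrix(0, 3, 4 * hdim), Wh = matrix(0, hdim, 4 * hdim),
                   b = numeric(4 * hdim), peep = matrix(0, hdim, 3))
  st <- lstm_step(numeric(3), list(h = numeric(hdim), c = numeric(hdim)),
                  zero_par)
  expect_equal(st$c, rep(0, hdim))
  expect_equal(st$h, rep(0, hdim))

  # a saturated forget gate retains memory almost exactly
  par <- zero_par
  par$b[(hdim + 1):(2 * hdim)] <- 10
  c_prev <- runif(hdim, -1, 1)
  st2 <- lstm_step(numeric(3), list(h = numeric(hdim), c = c_prev), par)
  expect_equal(st2$c, c_prev, tolerance = 1e-4)

  set.seed(53)
  for (rep in 1:10) {
    par <- list(Wx = matrix(rnorm(12 * hdim), 3), Wh = matrix(rnorm(4 * hdim^2), hdim),
                b = rnorm(4 * hdim), peep = matrix(rnorm(3 * hdim), hdim))
    st <- lstm_step(rnorm(3), list(h = runif(hdim, -1, 1), c = rnorm(hdim)),
                    par)
    expect_true(all(abs(st$h) < 1))
  }
})

random_lstm_par <- function(d, hdim) {
  list(Wx = matrix(rnorm(d * 4 * hdim), d) * 0.3,
       Wh = matrix(rnorm(hdim * 4 * hdim), hdim) * 0.3,
       b = rnorm(4 * hdim) * 0.1,
       peep = matrix(rnorm(3 * hdim), hdim) * 0.1)
}

test_that("the compiled batched BLSTM agrees with the stepwise reference", {
  set.seed(54)
  d <- 3
  hdim <- 4
  par <- list(fw = random_lstm_par(d, hdim), bw = random_lstm_par(d, hdim))
  for (rep in 1:8) {
    tlen <- sample(3:9, 1)
    nvalid <- sample(2:tlen, 1)
    xs <- matrix(rnorm(tlen * d), tlen, d)
    mask <- c(rep(1, nvalid), rep(0, tlen - nvalid))
    ref <- bilstm_forward(xs, mask, par)

    xp_fw <- xs %*% par$fw$Wx
    xp_bw <- xs %*% par$bw$Wx
    m <- matrix(mask, 1)
    hf <- premirnet:::lstm_forward_cpp(xp_fw, par$fw$b, par$fw$Wh,
                                       par$fw$peep, m, FALSE)$h_final
    hb <- premirnet:::lstm_forward_cpp(xp_bw, par$bw$b, par$bw$Wh,
                                       par$bw$peep, m, TRUE)$h_final
    expect_equal(c(as.numeric(hf), as.numeric(hb)), ref, tolerance = 1e-12)
  }
})

test_that("BLSTM output has dimension 2 x lstm_hidden and honours masks", {
  set.seed(55)
  par <- list(fw = random_lstm_par(2, 20), bw = random_lstm_par(2, 20))
  xs <- matrix(rnorm(12 * 2), 12, 2)
  out <- bilstm_forward(xs, rep(1, 12), par)
  expect_length(out, 40)

  # trailing padding changes nothing
  xs_pad <- rbind(xs, matrix(rnorm(8), 4, 2))
  out_pad <- bilstm_forward(xs_pad, c(rep(1, 12), rep(0, 4)), par)
  expect_equal(out_pad, out, tolerance = 1e-14)
  expect_error(bilstm_forward(xs, rep(0, 12), par),
               class = "premir_shape_error")

  # palindromic input with tied directional weights gives equal halves
  par$bw <- par$fw
  pal <- rbind(xs[1:6, ], xs[6:1, ])
  res <- bilstm_forward(pal, rep(1, 12), par)
  expect_equal(res[1:20], res[21:40], tolerance = 1e-12)
})

test_that("batch norm standardises in train mode and is stateless in eval", {
  bn <- batchnorm(matrix(c(1, 2, 3), 3, 1), "train")
  expect_equal(mean(bn$y), 0, tolerance = 1e-12)
  expect_equal(sd(bn$y), 1, tolerance = 1e-3)  # eps-stabilised

  # constant batch collapses to zeros rather than NaN
  cb <- batchnorm(matrix(5, 4, 2), "train")
  expect_equal(cb$y, matrix(0, 4, 2))

  run <- list(mean = c(1, 2), var = c(4, 9))
  x <- matrix(rnorm(10), 5, 2)
  e1 <- batchnorm(x, "eval", running = run)
  e2 <- batchnorm(x, "eval", running = run)
  expect_identical(e1$y, e2$y)
  expect_identical(e1$running, run)
  expect_error(batchnorm(matrix(1, 1, 2), "train"),
               class = "premir_shape_error")
})

test_that("network forward is a probability and eval mode is deterministic", {
  enc <- tiny_encoded(n_pos = 6, seed = 7)
  set.seed(1)
  model <- premirnet:::init_model(tiny_model_config(), enc$L)
  p1 <- network_forward(model, enc, mode = "eval")
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, network_forward(model, enc, mode = "eval"))

  # a duplicated example gets an identical score in eval mode
  dup <- enc[c(1, 1, 2, 3)]
  pd <- network_forward(model, dup, mode = "eval")
  expect_identical(pd[1], pd[2])
})

test_that("eval-mode scores are invariant to extra right padding", {
  ds <- simulate_hairpins(synthetic_params(n_pos = 4, imbalance_ratio = 1,
                                           seed = 8))
  enc1 <- encode_dataset(ds)
  enc2 <- encode_dataset(ds, L = enc1$L + 13)
  set.seed(2)
  model <- premirnet:::init_model(tiny_model_config(), enc1$L)
  expect_equal(network_forward(model, enc1, mode = "eval"),
               network_forward(model, enc2, mode = "eval"),
               tolerance = 1e-12)
})

test_that("with dropout off, two forward/backward passes agree bitwise", {
  enc <- tiny_encoded(n_pos = 6, seed = 9)
  set.seed(3)
  model <- premirnet:::init_model(tiny_model_config(dropout_p = 0), enc$L)
  r1 <- premirnet:::batch_loss_grads(model, enc, loss_config())
  r2 <- premirnet:::batch_loss_grads(model, enc, loss_config())
  expect_identical(r1$loss, r2$loss)
  expect_identical(premirnet:::flatten_params(r1$grads),
                   premirnet:::flatten_params(r2$grads))
})

test_that("parameter flattening round-trips exactly", {
  set.seed(4)
  model <- premirnet:::init_model(tiny_model_config(), 60)
  theta <- premirnet:::flatten_params(model$params)
  back <- premirnet:::unflatten_params(theta, model$params)
  expect_equal(back, model$params)
})
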
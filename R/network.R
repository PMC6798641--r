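#' Network architecture configuration
#'
#' Hyperparameters of the cascaded network: two convolutional branches
#' (sequence and structure) with ReLU and max-pooling, position-wise
#' channel concatenation, a bidirectional peephole LSTM, and a
#' batch-normalised fully connected head ending in a sigmoid unit.
#'
#' @param n_filters Convolution filters per branch (default 16).
#' @param kernel_len Convolution window length `k` (default 5, stride 1).
#' @param pool_size Non-overlapping max-pool width `m` (default 2).
#' @param lstm_hidden Hidden units per LSTM direction (default 20).
#' @param fc_hidden Dense layer width (default 256).
#' @param dropout_p Dropout probability on the max-pool, BLSTM and FC
#'   outputs, train mode only (default 0.5).
#' @param l2_lambda L2 penalty coefficient on the FC weight matrices
#'   (default 1e-4).
#' @param bn_momentum Exponential-moving-average momentum for the batch
#'   norm running statistics (default 0.99).
#' @param bn_eps Batch norm variance stabiliser (default 1e-5).
#' @param peephole Use the peephole gate terms (default TRUE); FALSE gives
#'   a plain LSTM for comparison.
#' @return A `model_config` list.
#' @export
model_config <- function(n_filters = 16, kernel_len = 5, pool_size = 2,
                         lstm_hidden = 20, fc_hidden = 256,
                         dropout_p = 0.5, l2_lambda = 1e-4,
                         bn_momentum = 0.99, bn_eps = 1e-5,
                         peephole = TRUE) {
  stopifnot(n_filters >= 1, kernel_len >= 1, pool_size >= 1,
            lstm_hidden >= 1, fc_hidden >= 1,
            dropout_p >= 0, dropout_p < 1, l2_lambda >= 0)
  structure(list(n_filters = n_filters, kernel_len = kernel_len,
                 pool_size = pool_size, lstm_hidden = lstm_hidden,
                 fc_hidden = fc_hidden, dropout_p = dropout_p,
                 l2_lambda = l2_lambda, bn_momentum = bn_momentum,
                 bn_eps = bn_eps, peephole = peephole),
            class = "model_config")
}

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

orthogonal <- function(n) {
  q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  q
}

# Initialise all trainable parameters and batch-norm running statistics.
# Consumes the current R RNG stream, so results are reproducible under
# set.seed(). Gate order in every 4H-wide LSTM matrix is [i | f | g | o];
# forget-gate biases start at 1 so early training retains memory.
init_model <- function(cfg, L) {
  k <- cfg$kernel_len
  f <- cfg$n_filters
  h <- cfg$lstm_hidden
  fc <- cfg$fc_hidden
  lstm_in <- 2 * f
  lstm_dir <- function() {
    b <- numeric(4 * h)
    b[(h + 1):(2 * h)] <- 1
    list(Wx = glorot(lstm_in, 4 * h),
         Wh = do.call(cbind, lapply(1:4, function(g) orthogonal(h))),
         b = b,
         peep = matrix(0, h, 3))
  }
  params <- list(
    Wc_seq = glorot(k * 4, f), bc_seq = numeric(f),
    Wc_str = glorot(k * 3, f), bc_str = numeric(f),
    g1 = rep(1, 2 * f), be1 = numeric(2 * f),
    fw = lstm_dir(), bw = lstm_dir(),
    g2 = rep(1, 2 * h), be2 = numeric(2 * h),
    W1 = glorot(2 * h, fc), b1 = numeric(fc),
    g3 = rep(1, fc), be3 = numeric(fc),
    W2 = glorot(fc, 1), b2 = numeric(1))
  running <- list(
    m1 = numeric(2 * f), v1 = rep(1, 2 * f),
    m2 = numeric(2 * h), v2 = rep(1, 2 * h),
    m3 = numeric(fc), v3 = rep(1, fc))
  structure(list(params = params, running = running, cfg = cfg, L = L),
            class = "premir_model")
}

# ---- elementary ops (public module surface; also the reference path) ----

#' Convolution forward pass (single example)
#'
#' Valid cross-correlation with stride 1: output entry `(i, s)` is the dot
#' product of filter `i` with the window of `k` consecutive input columns
#' starting at `s`, plus the filter bias.
#'
#' @param x Input matrix, `L x C` (positions by channels).
#' @param w Filter bank array, `n_filters x C x k`.
#' @param b Bias vector, length `n_filters`.
#' @return Feature map, `n_filters x (L - k + 1)`.
#' @export
conv_forward <- function(x, w, b) {
  L <- nrow(x)
  C <- ncol(x)
  stopifnot(dim(w)[2] == C, length(b) == dim(w)[1])
  k <- dim(w)[3]
  if (k > L) abort("kernel longer than input", class = "premir_shape_error")
  nf <- dim(w)[1]
  # pack into (k*C) x nf so the windows can be matrix-multiplied
  wmat <- matrix(0, k * C, nf)
  for (r in seq_len(k)) {
    wmat[(r - 1) * C + seq_len(C), ] <- t(matrix(w[, , r], nf, C))
  }
  m <- im2col(array(x, c(1, L, C)), k)
  t(m %*% wmat + rep(b, each = nrow(m)))
}

#' Rectified linear unit
#'
#' @param z Numeric vector/matrix/array.
#' @return `pmax(z, 0)` elementwise.
#' @export
relu <- function(z) pmax(z, 0)

#' Non-overlapping max-pooling along the position axis
#'
#' @param z Feature map, `n_filters x s`.
#' @param m Pool width; windows are non-overlapping, a trailing remainder
#'   narrower than `m` is dropped.
#' @return Pooled map, `n_filters x floor(s/m)`.
#' @export
maxpool <- function(z, m) {
  s <- ncol(z)
  if (m > s) abort("pool size exceeds map width", class = "premir_shape_error")
  p <- s %/% m
  out <- matrix(-Inf, nrow(z), p)
  for (r in seq_len(m)) {
    out <- pmax(out, z[, (seq_len(p) - 1) * m + r, drop = FALSE])
  }
  out
}

#' One LSTM cell step (reference implementation)
#'
#' Applies the gate equations in order — input gate, forget gate (both with
#' peephole terms reading the previous cell state), candidate update,
#' output gate (peephole on the new cell state) — and returns the new
#' state. Gate order in the stacked weight matrices is
#' `[input | forget | candidate | output]`.
#'
#' @param x Input vector (length `d`).
#' @param state List with `h` and `c` vectors (length `H`).
#' @param par List with `Wx` (`d x 4H`), `Wh` (`H x 4H`), `b` (length
#'   `4H`) and `peep` (`H x 3`, columns for the input/forget/output
#'   peepholes; zeros give a plain LSTM).
#' @return List with the new `h` and `c`; every element of `h` lies in
#'   (-1, 1).
#' @export
lstm_step <- function(x, state, par) {
  hdim <- length(state$h)
  a <- as.numeric(x %*% par$Wx) + as.numeric(state$h %*% par$Wh) + par$b
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(a[1:hdim] + par$peep[, 1] * state$c)
  f <- sig(a[(hdim + 1):(2 * hdim)] + par$peep[, 2] * state$c)
  g <- tanh(a[(2 * hdim + 1):(3 * hdim)])
  c_new <- f * state$c + i * g
  o <- sig(a[(3 * hdim + 1):(4 * hdim)] + par$peep[, 3] * c_new)
  list(h = o * tanh(c_new), c = c_new)
}

#' Bidirectional LSTM over one sequence (reference implementation)
#'
#' Runs a forward and a backward pass over the valid positions and
#' concatenates the two final hidden states. The training fast path is a
#' compiled batched implementation; the test suite asserts both agree.
#'
#' @param xs Input matrix, `T x d` (time steps by features).
#' @param mask 0/1 vector of length `T`; only positions with `mask == 1`
#'   are scanned.
#' @param par List with elements `fw` and `bw`, each as in [lstm_step()].
#' @return Numeric vector of length `2H` (forward then backward final
#'   hidden state).
#' @export
bilstm_forward <- function(xs, mask, par) {
  valid <- which(mask == 1)
  if (length(valid) == 0) {
    abort("empty valid region", class = "premir_shape_error")
  }
  run <- function(steps, p) {
    hdim <- ncol(p$Wh) / 4
    st <- list(h = numeric(hdim), c = numeric(hdim))
    for (t in steps) st <- lstm_step(xs[t, ], st, p)
    st$h
  }
  c(run(valid, par$fw), run(rev(valid), par$bw))
}

#' Batch normalisation (standalone)
#'
#' Train mode standardises each column by the batch mean and sample
#' standard deviation (`n - 1` denominator, epsilon-stabilised) and
#' updates the running statistics; eval mode uses the running statistics,
#' making repeated calls stateless.
#'
#' @param x Numeric matrix, rows = batch examples, columns = neurons.
#' @param mode `"train"` or `"eval"`.
#' @param gamma,beta Scale and shift vectors (defaults 1 and 0).
#' @param running List with `mean` and `var` vectors; required in eval
#'   mode.
#' @param momentum EMA momentum for the running statistics.
#' @param eps Variance stabiliser.
#' @return List with `y` (normalised matrix) and updated `running`.
#' @export
batchnorm <- function(x, mode = c("train", "eval"), gamma = NULL,
                      beta = NULL, running = NULL, momentum = 0.99,
                      eps = 1e-5) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  cdim <- ncol(x)
  if (is.null(gamma)) gamma <- rep(1, cdim)
  if (is.null(beta)) beta <- rep(0, cdim)
  if (is.null(running)) running <- list(mean = numeric(cdim), var = rep(1, cdim))
  if (mode == "train") {
    if (nrow(x) < 2) abort("train-mode batch norm needs batch size >= 2",
                           class = "premir_shape_error")
    fw <- bn_forward(x, gamma, beta, eps)
    running$mean <- momentum * running$mean + (1 - momentum) * fw$mu
    running$var <- momentum * running$var + (1 - momentum) * fw$var
    list(y = fw$y, running = running)
  } else {
    xhat <- colop(colop(x, running$mean, "-"), sqrt(running$var + eps), "/")
    list(y = colop(colop(xhat, gamma, "*"), beta, "+"),
         running = running)
  }
}

# ---- internal batched forward/backward --------------------------------

# im2col: (B, L, C) array -> (B*S) x (k*C) matrix, rows ordered batch-
# fastest then window start, columns grouped by window offset then channel.
im2col <- function(x, k) {
  b <- dim(x)[1]
  L <- dim(x)[2]
  C <- dim(x)[3]
  s <- L - k + 1
  if (s < 1) abort("kernel longer than input", class = "premir_shape_error")
  out <- matrix(0, b * s, k * C)
  for (r in seq_len(k)) {
    block <- x[, r:(r + s - 1), , drop = FALSE]
    out[, (r - 1) * C + seq_len(C)] <- matrix(block, b * s, C)
  }
  out
}


# Fast column-wise broadcast ops (sweep() pays an aperm() tax per call).
colop <- function(x, v, op) {
  v <- rep(v, each = nrow(x))
  switch(op, "+" = x + v, "-" = x - v, "*" = x * v, "/" = x / v)
}

# Weighted batch norm core (weights are 0/1 row validity indicators);
# compiled, see src/netops.cpp.
bn_forward <- function(x, gamma, beta, eps, w = NULL) {
  out <- bn_forward_cpp(x, gamma, beta, eps, if (is.null(w)) numeric(0) else w)
  out$mu <- as.numeric(out$mu)
  out$var <- as.numeric(out$var)
  out$w <- w
  out
}

bn_backward <- function(dy, cache, gamma) {
  bn_backward_cpp(dy, cache$xhat, cache$s, cache$n, gamma,
                  if (is.null(cache$w)) numeric(0) else cache$w)
}

bn_eval <- function(x, gamma, beta, rmean, rvar, eps) {
  xhat <- colop(colop(x, rmean, "-"), sqrt(rvar + eps), "/")
  colop(colop(xhat, gamma, "*"), beta, "+")
}

# Full network forward pass over an encoded batch. In train mode batch
# statistics are used (and returned for the running-stat update) and
# dropout masks are drawn from the R RNG; eval mode is deterministic.
nn_forward <- function(model, enc, train = FALSE, use_dropout = train) {
  pr <- model$params
  cfg <- model$cfg
  k <- cfg$kernel_len
  m <- cfg$pool_size
  hdim <- cfg$lstm_hidden
  b <- dim(enc$xseq)[1]
  len_pool <- pmax(enc$length - k + 1, 0) %/% m
  if (any(len_pool < 1)) {
    abort("record(s) too short for this kernel/pool configuration",
      class = "premir_shape_error")
  }
  bs <- branch_forward_cpp(enc$xseq, pr$Wc_seq, pr$bc_seq, k, m)
  bt <- branch_forward_cpp(enc$xstr, pr$Wc_str, pr$bc_str, k, m)
  p <- as.integer(bs$p)
  f <- cfg$n_filters
  mp <- outer(len_pool, seq_len(p), ">=") * 1
  uf <- matrix(0, b * p, 2 * f)
  uf[, 1:f] <- bs$v
  uf[, (f + 1):(2 * f)] <- bt$v
  wvec <- as.vector(mp)

  if (train) {
    bn1 <- bn_forward(uf, pr$g1, pr$be1, cfg$bn_eps, w = wvec)
    y1 <- bn1$y
  } else {
    bn1 <- NULL
    y1 <- bn_eval(uf, pr$g1, pr$be1, model$running$m1, model$running$v1,
                  cfg$bn_eps) * wvec
  }
  if (use_dropout && cfg$dropout_p > 0) {
    d1m <- matrix((runif(length(y1)) >= cfg$dropout_p) /
                    (1 - cfg$dropout_p), nrow(y1), ncol(y1))
    d1 <- y1 * d1m
  } else {
    d1m <- NULL
    d1 <- y1
  }

  run_dir <- function(dir, reverse) {
    pp <- pr[[dir]]
    lstm_forward_cpp(d1 %*% pp$Wx, pp$b, pp$Wh, pp$peep, mp, reverse)
  }
  fw <- run_dir("fw", FALSE)
  bw <- run_dir("bw", TRUE)
  rcat <- cbind(fw$h_final, bw$h_final)

  if (train) {
    bn2 <- bn_forward(rcat, pr$g2, pr$be2, cfg$bn_eps)
    y2 <- bn2$y
  } else {
    bn2 <- NULL
    y2 <- bn_eval(rcat, pr$g2, pr$be2, model$running$m2, model$running$v2,
                  cfg$bn_eps)
  }
  if (use_dropout && cfg$dropout_p > 0) {
    d2m <- matrix((runif(length(y2)) >= cfg$dropout_p) /
                    (1 - cfg$dropout_p), nrow(y2), ncol(y2))
    d2 <- y2 * d2m
  } else {
    d2m <- NULL
    d2 <- y2
  }

  z1 <- colop(d2 %*% pr$W1, pr$b1, "+")
  a1 <- pmax(z1, 0)
  if (train) {
    bn3 <- bn_forward(a1, pr$g3, pr$be3, cfg$bn_eps)
    y3 <- bn3$y
  } else {
    bn3 <- NULL
    y3 <- bn_eval(a1, pr$g3, pr$be3, model$running$m3, model$running$v3,
                  cfg$bn_eps)
  }
  if (use_dropout && cfg$dropout_p > 0) {
    d3m <- matrix((runif(length(y3)) >= cfg$dropout_p) /
                    (1 - cfg$dropout_p), nrow(y3), ncol(y3))
    d3 <- y3 * d3m
  } else {
    d3m <- NULL
    d3 <- y3
  }
  z2 <- as.numeric(d3 %*% pr$W2) + pr$b2
  prob <- 1 / (1 + exp(-z2))

  list(prob = prob,
       cache = list(bs = bs, bt = bt, uf = uf, mp = mp, wvec = wvec,
                    p = p, b = b, bn1 = bn1, d1m = d1m, d1 = d1,
                    fw = fw, bw = bw, rcat = rcat, bn2 = bn2, d2m = d2m,
                    d2 = d2, z1 = z1, bn3 = bn3, d3m = d3m, d3 = d3,
                    prob = prob))
}

# Backward pass: dlp is d(loss)/d(prob) per example (already including the
# 1/B of mean reduction). Returns gradients named like the parameters,
# with the L2 terms on the FC weight matrices included.
nn_backward <- function(model, cache, dlp) {
  pr <- model$params
  cfg <- model$cfg
  hdim <- cfg$lstm_hidden
  b <- cache$b
  p <- cache$p
  lam <- cfg$l2_lambda

  dz2 <- matrix(dlp * cache$prob * (1 - cache$prob), ncol = 1)
  gW2 <- t(cache$d3) %*% dz2 + 2 * lam * pr$W2
  gb2 <- sum(dz2)
  dd3 <- dz2 %*% t(pr$W2)
  dy3 <- if (is.null(cache$d3m)) dd3 else dd3 * cache$d3m
  bn3b <- bn_backward(dy3, cache$bn3, pr$g3)
  dz1 <- bn3b$dx * (cache$z1 > 0)
  gW1 <- t(cache$d2) %*% dz1 + 2 * lam * pr$W1
  gb1 <- colSums(dz1)
  dd2 <- dz1 %*% t(pr$W1)
  dy2 <- if (is.null(cache$d2m)) dd2 else dd2 * cache$d2m
  bn2b <- bn_backward(dy2, cache$bn2, pr$g2)
  drcat <- bn2b$dx

  back_dir <- function(dir, run, dh, reverse) {
    pp <- pr[[dir]]
    res <- lstm_backward_cpp(run$g, run$c, run$h, run$tc, pp$Wh, pp$peep,
                             cache$mp, dh, reverse)
    list(dxp = res$dx, dWh = res$dWh, dpeep = res$dpeep)
  }
  bfw <- back_dir("fw", cache$fw, drcat[, 1:hdim, drop = FALSE], FALSE)
  bbw <- back_dir("bw", cache$bw, drcat[, (hdim + 1):(2 * hdim), drop = FALSE],
                  TRUE)
  gfw <- list(Wx = t(cache$d1) %*% bfw$dxp, Wh = bfw$dWh,
              b = colSums(bfw$dxp), peep = bfw$dpeep)
  gbw <- list(Wx = t(cache$d1) %*% bbw$dxp, Wh = bbw$dWh,
              b = colSums(bbw$dxp), peep = bbw$dpeep)
  dd1 <- bfw$dxp %*% t(pr$fw$Wx) + bbw$dxp %*% t(pr$bw$Wx)
  dy1 <- if (is.null(cache$d1m)) dd1 else dd1 * cache$d1m
  bn1b <- bn_backward(dy1, cache$bn1, pr$g1)
  du <- bn1b$dx
  f <- cfg$n_filters
  gseq <- branch_backward_cpp(du[, 1:f, drop = FALSE], cache$bs$argr,
                              cache$bs$z, cache$bs$m, cfg$pool_size, b)
  gstr <- branch_backward_cpp(du[, (f + 1):(2 * f), drop = FALSE],
                              cache$bt$argr, cache$bt$z, cache$bt$m,
                              cfg$pool_size, b)

  list(Wc_seq = gseq$dWc, bc_seq = gseq$dbc,
       Wc_str = gstr$dWc, bc_str = gstr$dbc,
       g1 = bn1b$dgamma, be1 = bn1b$dbeta,
       fw = gfw, bw = gbw,
       g2 = bn2b$dgamma, be2 = bn2b$dbeta,
       W1 = gW1, b1 = gb1,
       g3 = bn3b$dgamma, be3 = bn3b$dbeta,
       W2 = gW2, b2 = gb2)
}

# Update batch-norm running statistics from a train-mode forward cache.
update_running <- function(model, cache) {
  mom <- model$cfg$bn_momentum
  r <- model$running
  r$m1 <- mom * r$m1 + (1 - mom) * cache$bn1$mu
  r$v1 <- mom * r$v1 + (1 - mom) * cache$bn1$var
  r$m2 <- mom * r$m2 + (1 - mom) * cache$bn2$mu
  r$v2 <- mom * r$v2 + (1 - mom) * cache$bn2$var
  r$m3 <- mom * r$m3 + (1 - mom) * cache$bn3$mu
  r$v3 <- mom * r$v3 + (1 - mom) * cache$bn3$var
  model$running <- r
  model
}

#' Network forward pass over encoded examples
#'
#' Scores encoded examples with a model. In `"eval"` mode (the default for
#' prediction) dropout is off and the aggregated batch-norm statistics are
#' used, so repeated calls are deterministic; `"train"` mode uses batch
#' statistics and draws dropout masks from the R RNG.
#'
#' @param model A `premir_model` (or the model inside a fitted object).
#' @param enc An `encoded_hairpins` object with the model's pad length.
#' @param mode `"eval"` or `"train"`.
#' @return Numeric vector of probabilities in (0, 1), one per example.
#' @export
network_forward <- function(model, enc, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  nn_forward(model, enc, train = mode == "train")$prob
}

# Flatten/inject parameters; used by Adam and the finite-difference checks.
flatten_params <- function(pl) {
  unlist(pl, use.names = TRUE)
}

unflatten_params <- function(vec, template) {
  offset <- 0L
  take <- function(tpl) {
    if (is.list(tpl)) return(lapply(tpl, take))
    n <- length(tpl)
    out <- unname(vec[(offset + 1L):(offset + n)])
    offset <<- offset + n
    dim(out) <- dim(tpl)
    out
  }
  take(template)
}
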
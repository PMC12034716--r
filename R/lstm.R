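# Minimal LSTM with hand-written backpropagation through time.
# Gate layout in the stacked weight matrices: input, forget, candidate,
# output (rows 1..H, H+1..2H, 2H+1..3H, 3H+1..4H).

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(input_dim, hidden, init_sd = 0.02) {
  list(
    Wx = matrix(stats::rnorm(4 * hidden * input_dim, sd = init_sd),
                4 * hidden, input_dim),
    Wh = matrix(stats::rnorm(4 * hidden * hidden, sd = init_sd),
                4 * hidden, hidden),
    b  = numeric(4 * hidden)
  )
}

# X: n x input_dim. Returns hidden states H (n x hidden) and the caches
# needed for the backward pass.
lstm_forward <- function(p, X) {
  n <- nrow(X)
  hd <- length(p$b) / 4L
  H <- matrix(0, n, hd)
  cache <- vector("list", n)
  h <- numeric(hd)
  cc <- numeric(hd)
  for (t in seq_len(n)) {
    a <- as.vector(p$Wx %*% X[t, ]) + as.vector(p$Wh %*% h) + p$b
    i <- sigmoid(a[1:hd])
    f <- sigmoid(a[(hd + 1):(2 * hd)])
    g <- tanh(a[(2 * hd + 1):(3 * hd)])
    o <- sigmoid(a[(3 * hd + 1):(4 * hd)])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- if (t == 1L) numeric(hd) else H[t - 1L, ]
    h <- o * tc
    H[t, ] <- h
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, c_prev = c_prev,
                       tc = tc, h_prev = h_prev)
  }
  list(H = H, cache = cache)
}

# dH: n x hidden gradients on the hidden states. Returns parameter
# gradients and dX (n x input_dim).
lstm_backward <- function(p, X, fw, dH) {
  n <- nrow(X)
  hd <- ncol(fw$H)
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  db <- numeric(4 * hd)
  dX <- matrix(0, n, ncol(X))
  dh_next <- numeric(hd)
  dc_next <- numeric(hd)
  for (t in rev(seq_len(n))) {
    cc <- fw$cache[[t]]
    dh <- dH[t, ] + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc * cc$tc)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    da <- c(di * cc$i * (1 - cc$i),
            df * cc$f * (1 - cc$f),
            dg * (1 - cc$g * cc$g),
            do_ * cc$o * (1 - cc$o))
    dWx <- dWx + outer(da, X[t, ])
    dWh <- dWh + outer(da, cc$h_prev)
    db <- db + da
    dX[t, ] <- as.vector(crossprod(p$Wx, da))
    dh_next <- as.vector(crossprod(p$Wh, da))
    dc_next <- dc * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}
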
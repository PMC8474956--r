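# Bidirectional LSTM layer for the hybrid convolutional-recurrent
# architecture. Input layout (D*T) x B with feature index fastest; output
# (2H*T) x B where at each time step the first H channels are the forward
# pass and the last H the backward pass. Gate order within the stacked
# weight matrices is input, forget, cell, output.

layer_lstm_bi <- function(name, D, H, T) {
  u <- function(nr, nc) matrix(runif(nr * nc, -1, 1) / sqrt(H), nrow = nr)
  list(type = "lstm_bi", name = name, D = D, H = H, T = T,
       params = list(
         fwd_Wx = u(4 * H, D), fwd_Wh = u(4 * H, H), fwd_b = numeric(4 * H),
         bwd_Wx = u(4 * H, D), bwd_Wh = u(4 * H, H), bwd_b = numeric(4 * H)))
}

lstm_dir_forward <- function(Wx, Wh, b, xs, ord, H, B) {
  h <- matrix(0, H, B)
  cc <- matrix(0, H, B)
  hs <- vector("list", length(ord))
  cache <- vector("list", length(ord))
  for (s in seq_along(ord)) {
    t <- ord[s]
    A <- Wx %*% xs[[t]] + Wh %*% h + b
    i <- sigmoid(A[1:H, , drop = FALSE])
    f <- sigmoid(A[(H + 1):(2 * H), , drop = FALSE])
    g <- tanh(A[(2 * H + 1):(3 * H), , drop = FALSE])
    o <- sigmoid(A[(3 * H + 1):(4 * H), , drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    cache[[s]] <- list(i = i, f = f, g = g, o = o, c_prev = cc,
                       tanhc = tc, h_prev = h, t = t)
    cc <- c_new
    h <- o * tc
    hs[[s]] <- h
  }
  list(hs = hs, cache = cache)
}

lstm_dir_backward <- function(Wx, Wh, xs, dhs, cache, H, B) {
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4 * H)
  dh_next <- matrix(0, H, B)
  dc_next <- matrix(0, H, B)
  dxs <- vector("list", length(xs))
  for (s in seq(length(cache), 1)) {
    cs <- cache[[s]]
    dh <- dhs[[s]] + dh_next
    dtc <- dh * cs$o
    dc <- dc_next + dtc * (1 - cs$tanhc^2)
    do_ <- dh * cs$tanhc
    di <- dc * cs$g
    dg <- dc * cs$i
    df <- dc * cs$c_prev
    dc_next <- dc * cs$f
    dA <- rbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                dg * (1 - cs$g^2),
                do_ * cs$o * (1 - cs$o))
    dWx <- dWx + tcrossprod(dA, xs[[cs$t]])
    dWh <- dWh + tcrossprod(dA, cs$h_prev)
    db <- db + rowSums(dA)
    dh_next <- crossprod(Wh, dA)
    dxs[[cs$t]] <- crossprod(Wx, dA)
  }
  list(dWx = dWx, dWh = dWh, db = db, dxs = dxs)
}

lstm_bi_forward <- function(layer, x, training = FALSE) {
  D <- layer$D; H <- layer$H; T <- layer$T; B <- ncol(x)
  xs <- lapply(seq_len(T), function(t)
    x[((t - 1) * D + 1):(t * D), , drop = FALSE])
  p <- layer$params
  fw <- lstm_dir_forward(p$fwd_Wx, p$fwd_Wh, p$fwd_b, xs, seq_len(T), H, B)
  bw <- lstm_dir_forward(p$bwd_Wx, p$bwd_Wh, p$bwd_b, xs, rev(seq_len(T)), H, B)
  out <- matrix(0, 2 * H * T, B)
  for (s in seq_len(T)) {
    t_f <- s
    out[((t_f - 1) * 2 * H + 1):((t_f - 1) * 2 * H + H), ] <- fw$hs[[s]]
    t_b <- T - s + 1
    out[((t_b - 1) * 2 * H + H + 1):(t_b * 2 * H), ] <- bw$hs[[s]]
  }
  list(out = out, cache = list(xs = xs, fw = fw$cache, bw = bw$cache))
}

lstm_bi_backward <- function(layer, cache, dout) {
  D <- layer$D; H <- layer$H; T <- layer$T; B <- ncol(dout)
  dh_f <- vector("list", T)
  dh_b <- vector("list", T)
  for (s in seq_len(T)) {
    t_f <- s
    dh_f[[s]] <- dout[((t_f - 1) * 2 * H + 1):((t_f - 1) * 2 * H + H), ,
                      drop = FALSE]
    t_b <- T - s + 1
    dh_b[[s]] <- dout[((t_b - 1) * 2 * H + H + 1):(t_b * 2 * H), ,
                      drop = FALSE]
  }
  p <- layer$params
  gf <- lstm_dir_backward(p$fwd_Wx, p$fwd_Wh, cache$xs, dh_f, cache$fw, H, B)
  gb <- lstm_dir_backward(p$bwd_Wx, p$bwd_Wh, cache$xs, dh_b, cache$bw, H, B)
  dx <- matrix(0, D * T, B)
  for (t in seq_len(T)) {
    dx[((t - 1) * D + 1):(t * D), ] <- gf$dxs[[t]] + gb$dxs[[t]]
  }
  list(dx = dx,
       grads = list(fwd_Wx = gf$dWx, fwd_Wh = gf$dWh, fwd_b = gf$db,
                    bwd_Wx = gb$dWx, bwd_Wh = gb$dWh, bwd_b = gb$db))
}
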
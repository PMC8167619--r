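# Batched Bi-LSTM -> additive attention -> softmax engine, in plain matrix
# algebra with hand-derived gradients. Batches are (B x T) index matrices
# into a row-table of frozen token vectors (row 1 of the table is the pad /
# all-zero vector). Masked (pad) steps freeze the recurrent state, get zero
# attention, and receive no gradient, which gives exact pad invariance.

.sigm <- function(x) 1 / (1 + exp(-x))

.init_params <- function(input_dim, hidden, att_dim, n_classes = 3L,
                         seed = 1L) {
  with_seed(seed, {
    u01 <- function(nr, nc, fan) {
      matrix(runif(nr * nc, -1, 1) / sqrt(fan), nr, nc)
    }
    gate_b <- function(h) {
      b <- numeric(4 * h)
      b[(h + 1):(2 * h)] <- 1  # forget-gate bias starts open
      b
    }
    h <- hidden
    list(
      Wx_f = u01(input_dim, 4 * h, input_dim), Wh_f = u01(h, 4 * h, h),
      b_f = gate_b(h),
      Wx_b = u01(input_dim, 4 * h, input_dim), Wh_b = u01(h, 4 * h, h),
      b_b = gate_b(h),
      Wa = u01(2 * h, att_dim, 2 * h),
      We = u01(input_dim, att_dim, input_dim),  # token-identity term
      ba = numeric(att_dim),
      u = drop(u01(att_dim, 1, att_dim)),
      # the output layer reads both the attended recurrent states and the
      # attended input vectors; the x-channel can only carry a token's
      # identity if attention actually selects that token
      Wo = u01(2 * h + input_dim, n_classes, 2 * h + input_dim),
      bo = numeric(n_classes)
    )
  })
}

# one LSTM direction over the batch; steps is the processing order.
# rec_drop > 0 applies variational (same mask every step) dropout to the
# recurrent h- and c-inputs during training: it limits how reliably class
# evidence can be carried along the sequence, which pushes the attention
# layer to read evidence where it occurs instead of from a diffuse summary.
.lstm_dir <- function(par, X, mask, steps, prefix, rec_drop = 0,
                      train = FALSE) {
  Wx <- par[[paste0("Wx_", prefix)]]
  Wh <- par[[paste0("Wh_", prefix)]]
  b <- par[[paste0("b_", prefix)]]
  h <- nrow(Wh)
  B <- nrow(mask)
  H <- C <- matrix(0, B, h)
  if (train && rec_drop > 0) {
    rmh <- matrix((runif(B * h) >= rec_drop) / (1 - rec_drop), B, h)
    rmc <- matrix((runif(B * h) >= rec_drop) / (1 - rec_drop), B, h)
  } else {
    rmh <- rmc <- NULL
  }
  cache <- vector("list", length(steps))
  out <- vector("list", ncol(mask))
  for (s in seq_along(steps)) {
    t <- steps[s]
    m <- mask[, t]
    Hu <- if (is.null(rmh)) H else H * rmh
    Cu <- if (is.null(rmc)) C else C * rmc
    Z <- X[[t]] %*% Wx + Hu %*% Wh
    Z <- sweep(Z, 2, b, "+")
    i <- .sigm(Z[, 1:h, drop = FALSE])
    f <- .sigm(Z[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(Z[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- .sigm(Z[, (3 * h + 1):(4 * h), drop = FALSE])
    Cn <- f * Cu + i * g
    tc <- tanh(Cn)
    Hn <- o * tc
    cache[[s]] <- list(t = t, m = m, i = i, f = f, g = g, o = o,
                       c_prev = Cu, h_prev = Hu, c = Cn, tc = tc)
    C <- m * Cn + (1 - m) * C
    H <- m * Hn + (1 - m) * H
    out[[t]] <- H
  }
  structure(list(out = out, cache = cache), rmh = rmh, rmc = rmc)
}

.lstm_dir_backward <- function(par, cache, dH_ext, prefix, need_dx = FALSE,
                               rmh = NULL, rmc = NULL) {
  Wx <- par[[paste0("Wx_", prefix)]]
  Wh <- par[[paste0("Wh_", prefix)]]
  h <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, h, 4 * h)
  db <- numeric(4 * h)
  B <- nrow(cache[[1]]$h_prev)
  dh <- dc <- matrix(0, B, h)
  dX <- if (need_dx) vector("list", length(dH_ext)) else NULL
  for (s in rev(seq_along(cache))) {
    cc <- cache[[s]]
    m <- cc$m
    dh <- dh + dH_ext[[cc$t]]
    # unmasked rows: h_t = o * tanh(c_t)
    do_ <- m * dh * cc$tc
    dct <- m * dh * cc$o * (1 - cc$tc^2) + m * dc
    di <- dct * cc$g
    dg <- dct * cc$i
    df <- dct * cc$c_prev
    dzi <- di * cc$i * (1 - cc$i)
    dzf <- df * cc$f * (1 - cc$f)
    dzg <- dg * (1 - cc$g^2)
    dzo <- do_ * cc$o * (1 - cc$o)
    dZ <- cbind(dzi, dzf, dzg, dzo)
    dWx <- dWx + crossprod(attr(cache, "X")[[cc$t]], dZ)
    dWh <- dWh + crossprod(cc$h_prev, dZ)
    db <- db + colSums(dZ)
    if (need_dx) dX[[cc$t]] <- dZ %*% t(Wx)
    dh_gate <- dZ %*% t(Wh)
    if (!is.null(rmh)) dh_gate <- dh_gate * rmh
    dc_gate <- dct * cc$f
    if (!is.null(rmc)) dc_gate <- dc_gate * rmc
    dh <- (1 - m) * dh + dh_gate
    dc <- m * dc_gate + (1 - m) * dc
  }
  out <- list(dWx = dWx, dWh = dWh, db = db)
  if (need_dx) out$dX <- dX
  out
}

# full forward pass; returns probs, attention weights, and caches for
# backprop. X is a list over time of B x d matrices; mask is B x T (0/1).
.forward_batch <- function(par, X, mask, dropout = 0, train = FALSE,
                           rec_drop = 0) {
  Tn <- ncol(mask)
  B <- nrow(mask)
  h <- nrow(par$Wh_f)
  fw <- .lstm_dir(par, X, mask, seq_len(Tn), "f", rec_drop, train)
  bw <- .lstm_dir(par, X, mask, rev(seq_len(Tn)), "b", rec_drop, train)
  Hcat <- lapply(seq_len(Tn), function(t) cbind(fw$out[[t]], bw$out[[t]]))
  A <- vector("list", Tn)
  scores <- matrix(-1e30, B, Tn)
  for (t in seq_len(Tn)) {
    # additive attention over the recurrent state plus the token embedding
    # itself, so token identity can drive the weights directly
    A[[t]] <- tanh(sweep(Hcat[[t]] %*% par$Wa + X[[t]] %*% par$We, 2,
                         par$ba, "+"))
    sc <- drop(A[[t]] %*% par$u)
    scores[, t] <- ifelse(mask[, t] > 0, sc, -1e30)
  }
  if (any(rowSums(mask) == 0)) stop("fully-masked input sequence")
  mx <- apply(scores, 1, max)
  e <- exp(scores - mx) * mask
  alpha <- e / rowSums(e)
  d_in <- ncol(X[[1]])
  context <- matrix(0, B, 2 * h + d_in)
  for (t in seq_len(Tn)) {
    context <- context + alpha[, t] * cbind(Hcat[[t]], X[[t]])
  }
  dm <- NULL
  ctx_d <- context
  if (train && dropout > 0) {
    dm <- matrix((runif(B * (2 * h + d_in)) >= dropout) / (1 - dropout),
                 B, 2 * h + d_in)
    ctx_d <- context * dm
  }
  logits <- sweep(ctx_d %*% par$Wo, 2, par$bo, "+")
  lmx <- apply(logits, 1, max)
  el <- exp(logits - lmx)
  probs <- el / rowSums(el)
  list(probs = probs, alpha = alpha, fw = fw, bw = bw, Hcat = Hcat, A = A,
       context = context, ctx_d = ctx_d, dm = dm, mask = mask)
}

.backward_batch <- function(par, X, fwd, y, need_dx = FALSE,
                            entropy_beta = 0, class_w = c(1, 1, 1)) {
  B <- nrow(fwd$probs)
  Tn <- ncol(fwd$mask)
  h <- nrow(par$Wh_f)
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- (class_w[y] / B) * dlogits
  g <- list()
  g$Wo <- crossprod(fwd$ctx_d, dlogits)
  g$bo <- colSums(dlogits)
  dctx <- dlogits %*% t(par$Wo)
  if (!is.null(fwd$dm)) dctx <- dctx * fwd$dm
  dctx_h <- dctx[, seq_len(2 * h), drop = FALSE]
  dctx_x <- dctx[, -seq_len(2 * h), drop = FALSE]
  dalpha <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    dalpha[, t] <- rowSums(dctx_h * fwd$Hcat[[t]]) + rowSums(dctx_x * X[[t]])
  }
  if (entropy_beta > 0) {
    # d/dalpha of beta * mean_b sum_t -alpha log alpha
    dent <- -(log(pmax(fwd$alpha, 1e-12)) + 1) * (entropy_beta / B)
    dent[fwd$mask == 0] <- 0
    dalpha <- dalpha + dent
  }
  dscore <- fwd$alpha * (dalpha - rowSums(dalpha * fwd$alpha))
  g$Wa <- matrix(0, nrow(par$Wa), ncol(par$Wa))
  g$We <- matrix(0, nrow(par$We), ncol(par$We))
  g$ba <- numeric(length(par$ba))
  g$u <- numeric(length(par$u))
  dH_f <- dH_b <- vector("list", Tn)
  dX_att <- if (need_dx) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    dHcat <- fwd$alpha[, t] * dctx_h
    dA <- (dscore[, t] %o% par$u) * (1 - fwd$A[[t]]^2)
    g$Wa <- g$Wa + crossprod(fwd$Hcat[[t]], dA)
    g$We <- g$We + crossprod(X[[t]], dA)
    g$ba <- g$ba + colSums(dA)
    g$u <- g$u + colSums(fwd$A[[t]] * dscore[, t])
    if (need_dx) {
      dX_att[[t]] <- dA %*% t(par$We) + fwd$alpha[, t] * dctx_x
    }
    dHcat <- dHcat + dA %*% t(par$Wa)
    dH_f[[t]] <- dHcat[, 1:h, drop = FALSE]
    dH_b[[t]] <- dHcat[, (h + 1):(2 * h), drop = FALSE]
  }
  attr(fwd$fw$cache, "X") <- X
  attr(fwd$bw$cache, "X") <- X
  gf <- .lstm_dir_backward(par, fwd$fw$cache, dH_f, "f", need_dx,
                           attr(fwd$fw, "rmh"), attr(fwd$fw, "rmc"))
  gb <- .lstm_dir_backward(par, fwd$bw$cache, dH_b, "b", need_dx,
                           attr(fwd$bw, "rmh"), attr(fwd$bw, "rmc"))
  g$Wx_f <- gf$dWx; g$Wh_f <- gf$dWh; g$b_f <- gf$db
  g$Wx_b <- gb$dWx; g$Wh_b <- gb$dWh; g$b_b <- gb$db
  if (need_dx) {
    g$dX <- lapply(seq_len(Tn), function(t) {
      m <- fwd$mask[, t]
      m * (gf$dX[[t]] + gb$dX[[t]] + dX_att[[t]])
    })
  }
  g
}

.ce_loss <- function(probs, y, class_w = c(1, 1, 1)) {
  -mean(class_w[y] * log(pmax(probs[cbind(seq_len(nrow(probs)), y)], 1e-12)))
}

# mean per-example attention entropy (pads contribute zero)
.attention_entropy <- function(alpha) {
  mean(rowSums(-alpha * log(pmax(alpha, 1e-12))))
}

.adam_state <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(par)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, state = state)
}
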
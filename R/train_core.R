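# Hand-derived gradients for the encoder and heads, plus the AdamW optimizer
# and a small generic MLP trainer reused by the downstream harness.
# Correctness is pinned by finite-difference gradient checks in the tests.

.zeros_like <- function(x) {
  if (is.list(x)) lapply(x, .zeros_like)
  else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
  else numeric(length(x))
}

.tree_add <- function(a, b) {
  if (is.list(a)) Map(.tree_add, a, b) else a + b
}

.layernorm_bwd <- function(dY, ln, g) {
  d <- ncol(dY)
  dG <- colSums(dY * ln$xhat)
  dB <- colSums(dY)
  dXh <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dXh)
  m2 <- rowMeans(dXh * ln$xhat)
  dX <- (dXh - m1 - ln$xhat * m2) * ln$inv
  list(dX = dX, dG = dG, dB = dB)
}

.softmax_bwd <- function(dA, A) {
  (dA - rowSums(dA * A)) * A
}

.silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

# Backward pass for one sequence.  dfinal: gradient wrt the final
# post-layer-norm hidden states (L x d).  Returns a gradient tree matching
# params (mtr gradients handled by the caller).
.encoder_bwd <- function(params, cfg, cache, dfinal) {
  g <- .zeros_like(params)
  nh <- cfg$n_heads; dh <- cfg$d_head
  scal <- 1 / sqrt(dh)
  tab <- cache$tab
  lb <- .layernorm_bwd(dfinal, cache$lnf, params$lnf_g)
  g$lnf_g <- lb$dG; g$lnf_b <- lb$dB
  dX <- lb$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    p <- params$layers[[l]]
    cc <- cache$layers[[l]]
    # FFN block: X_next = mid + (silu(G) * U) %*% Wd
    dH <- dX %*% t(p$Wd)
    g$layers[[l]]$Wd <- crossprod(cc$H, dX)
    sG <- .silu(cc$G)
    dU <- dH * sG
    dG <- dH * cc$U * .silu_grad(cc$G)
    g$layers[[l]]$Wg <- crossprod(cc$ln2$out, dG)
    g$layers[[l]]$Wu <- crossprod(cc$ln2$out, dU)
    dln2 <- dG %*% t(p$Wg) + dU %*% t(p$Wu)
    lb2 <- .layernorm_bwd(dln2, cc$ln2, p$ln2_g)
    g$layers[[l]]$ln2_g <- lb2$dG; g$layers[[l]]$ln2_b <- lb2$dB
    dmid <- dX + lb2$dX
    # attention block: mid = X + (concat_h A_h V_h) %*% Wo
    dattn <- dmid  # gradient into attn_out
    g$layers[[l]]$Wo <- crossprod(cc$O, dattn)
    dO <- dattn %*% t(p$Wo)
    dQ <- matrix(0, nrow(dX), cfg$d_model)
    dK <- matrix(0, nrow(dX), cfg$d_model)
    dV <- matrix(0, nrow(dX), cfg$d_model)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      hc <- cc$heads[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, hc$Vh)
      dV[, cols] <- crossprod(hc$A, dOh)
      dS <- .softmax_bwd(dA, hc$A)
      dQr <- (dS %*% hc$Kr) * scal
      dKr <- (crossprod(dS, hc$Qr)) * scal
      dQ[, cols] <- .rope_unapply(dQr, tab)
      dK[, cols] <- .rope_unapply(dKr, tab)
    }
    g$layers[[l]]$Wq <- crossprod(cc$ln1$out, dQ)
    g$layers[[l]]$Wk <- crossprod(cc$ln1$out, dK)
    g$layers[[l]]$Wv <- crossprod(cc$ln1$out, dV)
    dln1 <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    lb1 <- .layernorm_bwd(dln1, cc$ln1, p$ln1_g)
    g$layers[[l]]$ln1_g <- lb1$dG; g$layers[[l]]$ln1_b <- lb1$dB
    dX <- dmid + lb1$dX
  }
  # embedding lookup
  for (i in seq_along(cache$ids)) {
    r <- cache$ids[i] + 1L
    g$E[r, ] <- g$E[r, ] + dX[i, ]
  }
  g
}

# MLM loss and gradient wrt final hidden states (and tied embedding/bias).
# labels: 0-based original ids at masked positions; masked_pos: 1-based.
.mlm_loss_grad <- function(params, final, masked_pos, labels) {
  if (length(masked_pos) == 0L) {
    return(list(loss = 0, dfinal = matrix(0, nrow(final), ncol(final)),
                dE = NULL, db = NULL))
  }
  Hm <- final[masked_pos, , drop = FALSE]
  logits <- sweep(tcrossprod(Hm, params$E), 2L, params$mlm_b, "+")
  m <- apply(logits, 1L, max)
  Z <- exp(logits - m)
  P <- Z / rowSums(Z)
  n <- length(masked_pos)
  ll <- log(P[cbind(seq_len(n), labels + 1L)])
  loss <- -mean(ll)
  dlog <- P
  dlog[cbind(seq_len(n), labels + 1L)] <-
    dlog[cbind(seq_len(n), labels + 1L)] - 1
  dlog <- dlog / n
  dHm <- dlog %*% params$E
  dE <- crossprod(dlog, Hm)     # V x d
  db <- colSums(dlog)
  dfinal <- matrix(0, nrow(final), ncol(final))
  dfinal[masked_pos, ] <- dHm
  list(loss = loss, dfinal = dfinal, dE = dE, db = db)
}

# MTR loss (mean squared error over the 99 normalized targets) and gradients
# wrt the pooled vector and head parameters.
.mtr_loss_grad <- function(mtr, pooled, target) {
  z1 <- drop(pooled %*% mtr$W1) + mtr$b1
  h1 <- .silu(z1)
  yhat <- drop(h1 %*% mtr$W2) + mtr$b2
  diff <- yhat - target
  loss <- mean(diff^2)
  dy <- 2 * diff / length(diff)
  dW2 <- outer(h1, dy)
  db2 <- dy
  dh1 <- drop(mtr$W2 %*% dy)
  dz1 <- dh1 * .silu_grad(z1)
  dW1 <- outer(pooled, dz1)
  db1 <- dz1
  dpooled <- drop(mtr$W1 %*% dz1)
  list(loss = loss, dpooled = dpooled,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# --- AdamW ----------------------------------------------------------------

adamw_state <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

# One decoupled-weight-decay Adam step over a parameter tree.  Weight decay
# applies to matrices only (projections/embeddings), not LN gains or biases.
adamw_step <- function(params, grads, state, lr, betas = c(0.9, 0.98),
                       weight_decay = 0.01, eps = 1e-8) {
  b1 <- betas[1L]; b2 <- betas[2L]
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    if (is.matrix(p) && weight_decay > 0) upd <- upd + weight_decay * p
    list(p = p - lr * upd, m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

# --- generic MLP (task heads) --------------------------------------------

.gelu <- function(x) 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
.gelu_grad <- function(x) {
  u <- sqrt(2 / pi) * (x + 0.044715 * x^3)
  t <- tanh(u)
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * sqrt(2 / pi) * (1 + 3 * 0.044715 * x^2)
}

mlp_init <- function(sizes, seed = 1L) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (i in seq_len(length(sizes) - 1L)) {
      W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1L], 0,
                                    sqrt(2 / sizes[i])),
                       sizes[i], sizes[i + 1L])
      b[[i]] <- rep(0, sizes[i + 1L])
    }
    list(W = W, b = b, sizes = sizes)
  })
}

# Forward through the MLP head.  Hidden layers use GeLU; inverted dropout on
# hidden activations when `dropout > 0` and `train = TRUE` (draws from the
# current RNG stream).
mlp_forward <- function(net, X, dropout = 0, train = FALSE) {
  nl <- length(net$W)
  Z <- list(); A <- list(); Dm <- list()
  a <- X
  for (i in seq_len(nl)) {
    z <- sweep(a %*% net$W[[i]], 2L, net$b[[i]], "+")
    if (i < nl) {
      h <- .gelu(z)
      if (train && dropout > 0) {
        keep <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h))
        h <- h * keep / (1 - dropout)
        Dm[[i]] <- keep
      }
    } else h <- z
    Z[[i]] <- z; A[[i]] <- h
    a <- h
  }
  list(out = a, Z = Z, A = A, Dm = Dm, X = X)
}

# Backward given dOut; returns gradient lists matching net$W / net$b.
mlp_backward <- function(net, fwd, dOut, dropout = 0) {
  nl <- length(net$W)
  dW <- vector("list", nl); db <- vector("list", nl)
  da <- dOut
  for (i in rev(seq_len(nl))) {
    dz <- if (i == nl) da else {
      h <- da
      if (dropout > 0 && length(fwd$Dm) >= i && !is.null(fwd$Dm[[i]])) {
        h <- h * fwd$Dm[[i]] / (1 - dropout)
      }
      h * .gelu_grad(fwd$Z[[i]])
    }
    ain <- if (i == 1L) fwd$X else fwd$A[[i - 1L]]
    dW[[i]] <- crossprod(ain, dz)
    db[[i]] <- colSums(dz)
    if (i > 1L) da <- dz %*% t(net$W[[i]])
  }
  list(W = dW, b = db)
}
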
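# BERT-style transformer encoder with rotary position embeddings (RoPE),
# SwiGLU feed-forward blocks and pre-layer normalization, implemented in
# plain matrix algebra.  Forward passes are deterministic; training-time
# gradients live in train_core.R.

.LN_EPS <- 1e-5

#' Named encoder scale configurations
#'
#' The three named scales fix (layers, hidden dimension, heads) at
#' small = (6, 384, 6), base = (12, 768, 12), large = (24, 1024, 16), all
#' with a per-head dimension of 64.  The feed-forward width defaults to
#' 4 x d_model with three projection matrices (gated unit).  `"custom"`
#' requires explicit dimensions.
#'
#' @param scale One of `"small"`, `"base"`, `"large"`, `"custom"`.
#' @param n_layers,d_model,n_heads,d_ffn Explicit dimensions for `"custom"`
#'   (or overrides; `d_ffn` defaults to `4 * d_model`).
#' @param vocab_size Vocabulary size (default 405).
#' @param max_len Maximum sequence length in tokens (default 512).
#' @param dropout Dropout probability field (default 0; desk-scale presets
#'   train without dropout in the encoder).
#' @return An `encoder_config`.
#' @export
encoder_config <- function(scale = c("small", "base", "large", "custom"),
                           n_layers = NULL, d_model = NULL, n_heads = NULL,
                           d_ffn = NULL, vocab_size = 405L, max_len = 512L,
                           dropout = 0) {
  scale <- match.arg(scale)
  dims <- switch(scale,
    small = c(6L, 384L, 6L),
    base  = c(12L, 768L, 12L),
    large = c(24L, 1024L, 16L),
    custom = NULL)
  if (is.null(dims)) {
    if (is.null(n_layers) || is.null(d_model) || is.null(n_heads)) {
      stop_smiclm("custom scale requires n_layers, d_model and n_heads",
                  "smiclm_badarg")
    }
    dims <- c(as.integer(n_layers), as.integer(d_model), as.integer(n_heads))
  } else {
    if (!is.null(n_layers) || !is.null(d_model) || !is.null(n_heads)) {
      stop_smiclm("named scales fix n_layers/d_model/n_heads; use scale='custom'",
                  "smiclm_badarg")
    }
  }
  if (dims[2L] %% dims[3L] != 0L) {
    stop_smiclm("d_model must be divisible by n_heads", "smiclm_badarg")
  }
  d_head <- dims[2L] %/% dims[3L]
  if (scale != "custom" && d_head != 64L) {
    stop_smiclm("named scales must have per-head dimension 64", "smiclm_badarg")
  }
  if (d_head %% 2L != 0L) {
    stop_smiclm("per-head dimension must be even for rotary embeddings",
                "smiclm_badarg")
  }
  structure(list(
    name = scale, n_layers = dims[1L], d_model = dims[2L],
    n_heads = dims[3L], d_head = d_head,
    d_ffn = as.integer(d_ffn %||% (4L * dims[2L])),
    vocab_size = as.integer(vocab_size), max_len = as.integer(max_len),
    dropout = dropout
  ), class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf(
    "<encoder_config:%s> %d layers, d_model %d, %d heads (d_head %d), d_ffn %d, vocab %d\n",
    x$name, x$n_layers, x$d_model, x$n_heads, x$d_head, x$d_ffn, x$vocab_size))
  invisible(x)
}

#' Count trainable parameters of an encoder configuration
#'
#' Exact closed-form sum under the shipped layout (tied MLM head; gated
#' feed-forward with three projections; 99-descriptor regression head with
#' one hidden layer of width d_model).
#'
#' @param cfg An `encoder_config`.
#' @return List with per-component counts and `total`.
#' @export
count_parameters <- function(cfg) {
  d <- cfg$d_model; f <- cfg$d_ffn; V <- cfg$vocab_size; L <- cfg$n_layers
  emb <- V * d
  attn <- 4L * d * d
  ffn <- 3L * d * f
  ln <- 4L * d
  per_layer <- attn + ffn + ln
  heads <- V +                       # mlm bias (embedding is tied)
    (d * d + d) + (d * 99L + 99L)    # mtr two-layer head
  final_ln <- 2L * d
  total <- emb + L * per_layer + final_ln + heads
  list(embeddings = emb, attention = L * attn, ffn = L * ffn,
       layernorm = L * ln + final_ln, heads = heads, total = total)
}

# Gaussian init N(0, 0.02^2) for projections/embeddings; LN at identity.
init_encoder <- function(cfg, seed = 1L) {
  with_seed(seed, {
    d <- cfg$d_model; f <- cfg$d_ffn; V <- cfg$vocab_size
    rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
    layers <- lapply(seq_len(cfg$n_layers), function(l) list(
      ln1_g = rep(1, d), ln1_b = rep(0, d),
      Wq = rn(d, d), Wk = rn(d, d), Wv = rn(d, d), Wo = rn(d, d),
      ln2_g = rep(1, d), ln2_b = rep(0, d),
      Wg = rn(d, f), Wu = rn(d, f), Wd = rn(f, d)
    ))
    params <- list(
      E = rn(V, d), mlm_b = rep(0, V),
      lnf_g = rep(1, d), lnf_b = rep(0, d),
      layers = layers,
      mtr = list(W1 = rn(d, d), b1 = rep(0, d),
                 W2 = rn(d, 99L), b2 = rep(0, 99L))
    )
    structure(list(cfg = cfg, params = params), class = "clm_encoder")
  })
}

#' @export
print.clm_encoder <- function(x, ...) {
  cat("<clm_encoder> "); print(x$cfg)
  cat("  total parameters:", count_parameters(x$cfg)$total, "\n")
  invisible(x)
}

# --- numerics -------------------------------------------------------------

.layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + .LN_EPS)
  Xh <- Xc * inv
  list(out = sweep(Xh, 2L, g, "*") + rep(b, each = nrow(X)),
       xhat = Xh, inv = inv)
}

.softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

.silu <- function(x) x / (1 + exp(-x))

# Rotary cos/sin tables for positions 1..L, half-dimension dh/2, base 10000.
.rope_tables <- local({
  memo <- new.env(parent = emptyenv())
  function(L, dh) {
    key <- paste(L, dh)
    hit <- get0(key, envir = memo)
    if (!is.null(hit)) return(hit)
    half <- dh %/% 2L
    theta <- 10000^(-(2 * (seq_len(half) - 1L)) / dh)
    ang <- outer(0:(L - 1L), theta)        # L x half
    val <- list(cos = cos(ang), sin = sin(ang))
    assign(key, val, envir = memo)
    val
  }
})

# Rotate a per-head matrix (L x dh) by position.  Pairs are (1,2),(3,4),...
.rope_apply <- function(M, tab) {
  dh <- ncol(M)
  odd <- seq(1L, dh, by = 2L); even <- odd + 1L
  x1 <- M[, odd, drop = FALSE]; x2 <- M[, even, drop = FALSE]
  out <- M
  out[, odd] <- x1 * tab$cos - x2 * tab$sin
  out[, even] <- x1 * tab$sin + x2 * tab$cos
  out
}

# Inverse rotation (transpose), used in the backward pass.
.rope_unapply <- function(M, tab) {
  dh <- ncol(M)
  odd <- seq(1L, dh, by = 2L); even <- odd + 1L
  x1 <- M[, odd, drop = FALSE]; x2 <- M[, even, drop = FALSE]
  out <- M
  out[, odd] <- x1 * tab$cos + x2 * tab$sin
  out[, even] <- -x1 * tab$sin + x2 * tab$cos
  out
}

# Forward pass for one sequence.  ids: 0-based token ids; mask: logical
# (TRUE = real token).  Returns all hidden states (layer 0 = embedding
# output) and, when keep_cache, the intermediates needed for backward.
.encoder_fwd <- function(params, cfg, ids, mask = NULL, keep_cache = FALSE) {
  L <- length(ids)
  if (any(ids < 0L | ids >= cfg$vocab_size)) {
    stop_smiclm("token id out of vocabulary range", "smiclm_badid")
  }
  mask <- mask %||% rep(TRUE, L)
  X <- params$E[ids + 1L, , drop = FALSE]
  tab <- .rope_tables(L, cfg$d_head)
  bias <- ifelse(mask, 0, -Inf)   # additive column bias for attention
  states <- vector("list", cfg$n_layers + 1L)
  states[[1L]] <- X
  cache <- if (keep_cache) list(layers = vector("list", cfg$n_layers)) else NULL
  nh <- cfg$n_heads; dh <- cfg$d_head
  scal <- 1 / sqrt(dh)
  for (l in seq_len(cfg$n_layers)) {
    p <- params$layers[[l]]
    ln1 <- .layernorm_fwd(X, p$ln1_g, p$ln1_b)
    Q <- ln1$out %*% p$Wq; K <- ln1$out %*% p$Wk; V <- ln1$out %*% p$Wv
    O <- matrix(0, L, cfg$d_model)
    hc <- if (keep_cache) vector("list", nh) else NULL
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qr <- .rope_apply(Q[, cols, drop = FALSE], tab)
      Kr <- .rope_apply(K[, cols, drop = FALSE], tab)
      Vh <- V[, cols, drop = FALSE]
      S <- tcrossprod(Qr, Kr) * scal
      S <- sweep(S, 2L, bias, "+")
      A <- .softmax_rows(S)
      O[, cols] <- A %*% Vh
      if (keep_cache) hc[[h]] <- list(Qr = Qr, Kr = Kr, Vh = Vh, A = A)
    }
    attn_out <- O %*% p$Wo
    mid <- X + attn_out
    ln2 <- .layernorm_fwd(mid, p$ln2_g, p$ln2_b)
    G <- ln2$out %*% p$Wg
    U <- ln2$out %*% p$Wu
    H <- .silu(G) * U
    X_next <- mid + H %*% p$Wd
    if (keep_cache) {
      cache$layers[[l]] <- list(X = X, ln1 = ln1, Q = Q, K = K, V = V,
                                heads = hc, O = O, mid = mid, ln2 = ln2,
                                G = G, U = U, H = H)
    }
    X <- X_next
    states[[l + 1L]] <- X
  }
  lnf <- .layernorm_fwd(X, params$lnf_g, params$lnf_b)
  if (keep_cache) {
    cache$lnf <- lnf
    cache$ids <- ids
    cache$mask <- mask
    cache$tab <- tab
  }
  list(states = states, final = lnf$out, cache = cache)
}

#' Run the encoder over token sequences
#'
#' Deterministic (evaluation-mode) forward pass.  Positions enter only
#' through rotation of the query/key projections; there is no absolute
#' position embedding table.  Padded positions (mask FALSE) are excluded from
#' attention and from pooled outputs.
#'
#' @param model A `clm_encoder` (or checkpoint as loaded by
#'   [load_checkpoint()]).
#' @param ids List of 0-based integer id vectors (or a single vector).
#' @param mask Optional list of logical vectors, TRUE for real tokens.
#' @return A `hidden_states` object: per-sequence list of `n_layers + 1`
#'   matrices (layer 0 is the embedding output) plus the final
#'   post-layer-norm states and masks.
#' @export
encode_tokens <- function(model, ids, mask = NULL) {
  if (!is.list(ids)) ids <- list(ids)
  if (!is.null(mask) && !is.list(mask)) mask <- list(mask)
  out <- lapply(seq_along(ids), function(i) {
    .encoder_fwd(model$params, model$cfg, as.integer(ids[[i]]),
                 mask = mask[[i]] %||% NULL)
  })
  structure(list(
    states = lapply(out, `[[`, "states"),
    final = lapply(out, `[[`, "final"),
    mask = lapply(seq_along(ids), function(i) {
      mask[[i]] %||% rep(TRUE, length(ids[[i]]))
    }),
    n_layers = model$cfg$n_layers
  ), class = "hidden_states")
}

#' Mask-weighted mean pooling of a hidden layer
#'
#' @param states A `hidden_states` object from [encode_tokens()].
#' @param layer Layer index, 0 (embedding output) .. n_layers; `"final"` for
#'   the post-layer-norm output.
#' @return Matrix n_sequences x d_model.
#' @export
mean_pool <- function(states, layer = "final") {
  t(vapply(seq_along(states$states), function(i) {
    m <- states$mask[[i]]
    if (!any(m)) stop_smiclm("all-pad sequence cannot be pooled", "smiclm_badarg")
    M <- if (identical(layer, "final")) states$final[[i]] else {
      stopifnot(layer >= 0L, layer <= states$n_layers)
      states$states[[i]][[layer + 1L]]
    }
    colMeans(M[m, , drop = FALSE])
  }, numeric(ncol(states$final[[1L]]))))
}

#' Multi-task regression head
#'
#' Two affine layers with a SiLU activation between, mapping a pooled
#' d_model-dimensional embedding to the 99 physicochemical descriptors.
#'
#' @param model A `clm_encoder`.
#' @param pooled Matrix n x d_model (rows are pooled sequence embeddings).
#' @return Matrix n x 99 of descriptor predictions (normalized scale).
#' @export
mtr_head <- function(model, pooled) {
  if (is.null(dim(pooled))) pooled <- matrix(pooled, 1L)
  if (ncol(pooled) != model$cfg$d_model) {
    stop_smiclm("pooled width does not match d_model", "smiclm_badarg")
  }
  p <- model$params$mtr
  H <- .silu(sweep(pooled %*% p$W1, 2L, p$b1, "+"))
  sweep(H %*% p$W2, 2L, p$b2, "+")
}

#' Masked-language-model logits
#'
#' Tied head: logits are the final hidden states projected on the transpose
#' of the input embedding table, plus a per-token bias.
#'
#' @param model A `clm_encoder`.
#' @param final Final hidden-state matrix (L x d_model) for one sequence.
#' @return L x vocab_size logit matrix.
#' @export
mlm_logits <- function(model, final) {
  sweep(tcrossprod(final, model$params$E), 2L, model$params$mlm_b, "+")
}

#' Save a checkpoint (tensor archive + JSON config sidecar)
#'
#' @param model A `clm_encoder`.
#' @param path Output path for the archive; `<path>.json` gets the config.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model$params, path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path Path given to [save_checkpoint()].
#' @return A `clm_encoder`.
#' @export
load_checkpoint <- function(path) {
  cfgl <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- structure(cfgl, class = "encoder_config")
  cfg[c("n_layers", "d_model", "n_heads", "d_head", "d_ffn", "vocab_size",
        "max_len")] <-
    lapply(cfg[c("n_layers", "d_model", "n_heads", "d_head", "d_ffn",
                 "vocab_size", "max_len")], as.integer)
  structure(list(cfg = cfg, params = readRDS(path)), class = "clm_encoder")
}
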
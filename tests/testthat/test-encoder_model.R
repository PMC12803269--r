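test_that("named scales carry the printed dimensions and per-head width 64", {
  expect_identical(unlist(encoder_config("small")[c("n_layers", "d_model",
                                                    "n_heads")]),
                   c(n_layers = 6L, d_model = 384L, n_heads = 6L))
  expect_identical(unlist(encoder_config("base")[c("n_layers", "d_model",
                                                   "n_heads")]),
                   c(n_layers = 12L, d_model = 768L, n_heads = 12L))
  lg <- encoder_config("large")
  expect_identical(unlist(lg[c("n_layers", "d_model", "n_heads")]),
                   c(n_layers = 24L, d_model = 1024L, n_heads = 16L))
  for (s in c("small", "base", "large")) {
    cfg <- encoder_config(s)
    expect_identical(cfg$d_model %/% cfg$n_heads, 64L)
    expect_identical(cfg$d_head, 64L)
  }
  expect_error(encoder_config("custom"), class = "smiclm_badarg")
  expect_error(encoder_config("small", n_layers = 3L), class = "smiclm_badarg")
})

test_that("parameter counting is exact for a bare embedding and additive", {
  cfg0 <- encoder_config("custom", n_layers = 0L, d_model = 8L, n_heads = 2L,
                         d_ffn = 16L, vocab_size = 405L)
  expect_identical(count_parameters(cfg0)$embeddings, 405L * 8L)
  c2 <- encoder_config("custom", n_layers = 2L, d_model = 32L, n_heads = 2L,
                       vocab_size = 50L)
  c4 <- encoder_config("custom", n_layers = 4L, d_model = 32L, n_heads = 2L,
                       vocab_size = 50L)
  per2 <- count_parameters(c2)
  per4 <- count_parameters(c4)
  expect_identical(per4$attention, 2L * per2$attention)
  expect_identical(per4$ffn, 2L * per2$ffn)
  # counted total equals the number of entries actually allocated
  m <- smiclm:::init_encoder(c2, seed = 1)
  alloc <- sum(unlist(rapply(m$params, length, how = "unlist")))
  expect_identical(alloc, per2$total)
})

test_that("base-scale parameter total approximates the published 114M", {
  tot <- count_parameters(encoder_config("base"))$total
  expect_lt(abs(tot - 114e6) / 114e6, 0.15)
})

test_that("forward pass is deterministic and position-sensitive", {
  m <- tiny_model()
  ids <- kmer_encode("CC(=O)O", tiny_vocab(), add_special = TRUE)
  hs <- encode_tokens(m, list(ids, ids))
  expect_identical(hs$final[[1]], hs$final[[2]])
  expect_length(hs$states[[1]], m$cfg$n_layers + 1L)
  # prepending BOS shifts positions and changes outputs (RoPE is positional)
  shifted <- c(tiny_vocab()$specials[["[BOS]"]], ids)
  hs2 <- encode_tokens(m, list(shifted))
  expect_gt(max(abs(hs2$final[[1]][-1, ] - hs$final[[1]])), 1e-6)
  expect_error(encode_tokens(m, list(c(0L, 9999L))), class = "smiclm_badid")
})

test_that("padding with a mask leaves real-token outputs unchanged", {
  m <- tiny_model()
  ids <- kmer_encode("CC(=O)O", tiny_vocab(), add_special = TRUE)
  plain <- encode_tokens(m, list(ids))
  pad <- tiny_vocab()$specials[["[PAD]"]]
  padded_ids <- c(ids, rep(pad, 4L))
  msk <- c(rep(TRUE, length(ids)), rep(FALSE, 4L))
  padded <- encode_tokens(m, list(padded_ids), mask = list(msk))
  expect_lt(max(abs(padded$final[[1]][seq_along(ids), ] - plain$final[[1]])),
            1e-10)
  expect_equal(mean_pool(padded, "final")[1, ],
               mean_pool(plain, "final")[1, ], tolerance = 1e-10)
})

test_that("there is no absolute position embedding table", {
  m <- tiny_model()
  nm <- names(m$params)
  expect_false(any(grepl("pos", nm, ignore.case = TRUE)))
  # positions enter only via rotation: zeroing the rotary tables would make
  # two tokens with equal embeddings interchangeable, checked indirectly by
  # the position-sensitivity test above; here we assert the parameter set.
  expect_setequal(nm, c("E", "mlm_b", "lnf_g", "lnf_b", "layers", "mtr"))
})

test_that("mean pooling averages only unmasked positions", {
  m <- tiny_model()
  ids <- c(6L, 8L, 9L)
  hs <- encode_tokens(m, list(ids), mask = list(c(TRUE, FALSE, FALSE)))
  expect_equal(mean_pool(hs, 0)[1, ], hs$states[[1]][[1]][1, ],
               tolerance = 1e-12)
  hs_all <- encode_tokens(m, list(ids))
  expect_error(
    suppressWarnings(mean_pool(encode_tokens(m, list(ids),
                                             mask = list(rep(FALSE, 3L))),
                               0)),
    class = "smiclm_badarg")
  expect_error(mean_pool(hs_all, 99L))
})

test_that("the regression head emits 99 finite outputs and trains", {
  m <- tiny_model()
  pooled <- matrix(0, 1L, m$cfg$d_model)
  out <- mtr_head(m, pooled)
  expect_identical(dim(out), c(1L, 99L))
  expect_true(all(is.finite(out)))
  expect_identical(mtr_head(m, pooled), out)   # deterministic
  expect_error(mtr_head(m, matrix(0, 1L, 7L)), class = "smiclm_badarg")
  # gradient flows to both layers under a dummy squared loss
  gr <- smiclm:::.mtr_loss_grad(m$params$mtr, rnorm(m$cfg$d_model), rnorm(99))
  expect_gt(max(abs(gr$grads$W1)), 0)
  expect_gt(max(abs(gr$grads$W2)), 0)
})

test_that("checkpoints round-trip to bit-identical evaluation outputs", {
  m <- tiny_model()
  p <- file.path(tempdir(), "ckpt.bin")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(m2$cfg$d_model, m$cfg$d_model)
  ids <- kmer_encode("CC(=O)O", tiny_vocab(), add_special = TRUE)
  expect_identical(encode_tokens(m2, list(ids))$final,
                   encode_tokens(m, list(ids))$final)
})

test_that("all three named scales instantiate and run a short forward pass", {
  ids <- list(0:31)
  for (s in c("small", "base")) {
    m <- smiclm:::init_encoder(encoder_config(s, vocab_size = 405L), seed = 2)
    hs <- encode_tokens(m, ids)
    expect_identical(dim(hs$final[[1]]), c(32L, m$cfg$d_model))
    rm(m, hs); gc(FALSE)
  }
  m <- smiclm:::init_encoder(encoder_config("large", vocab_size = 405L),
                             seed = 2)
  hs <- encode_tokens(m, ids)
  expect_identical(dim(hs$final[[1]]), c(32L, 1024L))
  rm(m, hs); gc(FALSE)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- encoder_config("custom", n_layers = 2L, d_model = 8L, n_heads = 2L,
                        d_ffn = 16L, vocab_size = 11L, max_len = 32L)
  enc <- smiclm:::init_encoder(cfg, seed = 3)
  params <- enc$params
  ids <- c(3L, 5L, 7L, 2L, 9L, 3L)
  mpos <- c(2L, 5L); labels <- c(5L, 9L)
  set.seed(42); target <- rnorm(99)
  loss_fn <- function(params) {
    fwd <- smiclm:::.encoder_fwd(params, cfg, ids, keep_cache = TRUE)
    ml <- smiclm:::.mlm_loss_grad(params, fwd$final, mpos, labels)
    mt <- smiclm:::.mtr_loss_grad(params$mtr, colMeans(fwd$final), target)
    list(loss = 0.6 * ml$loss + 0.4 * mt$loss, fwd = fwd, ml = ml, mt = mt)
  }
  r <- loss_fn(params)
  L <- length(ids)
  dfinal <- 0.6 * r$ml$dfinal +
    matrix(0.4 * r$mt$dpooled / L, L, cfg$d_model, byrow = TRUE)
  g <- smiclm:::.encoder_bwd(params, cfg, r$fwd$cache, dfinal)
  g$E <- g$E + 0.6 * r$ml$dE
  g$mlm_b <- g$mlm_b + 0.6 * r$ml$db
  g$mtr <- lapply(r$mt$grads, function(x) 0.4 * x)
  eps <- 1e-6
  check <- function(getter, setter, gval) {
    v <- getter(params)
    for (j in sample(length(v), min(4L, length(v)))) {
      p2 <- params; v2 <- v; v2[j] <- v2[j] + eps; p2 <- setter(p2, v2)
      p3 <- params; v3 <- v; v3[j] <- v3[j] - eps; p3 <- setter(p3, v3)
      num <- (loss_fn(p2)$loss - loss_fn(p3)$loss) / (2 * eps)
      expect_lt(abs(num - gval[j]), 1e-5 * max(1, abs(num)))
    }
  }
  set.seed(7)
  check(function(p) p$E, function(p, v) { p$E[] <- v; p }, g$E)
  check(function(p) p$lnf_g, function(p, v) { p$lnf_g <- v; p }, g$lnf_g)
  for (nm in c("Wq", "Wk", "Wo", "Wg", "Wu", "Wd", "ln1_g", "ln2_b")) {
    check(function(p) p$layers[[1]][[nm]],
          function(p, v) { p$layers[[1]][[nm]][] <- v; p },
          g$layers[[1]][[nm]])
  }
  for (nm in c("W1", "b1", "W2", "b2")) {
    check(function(p) p$mtr[[nm]],
          function(p, v) { p$mtr[[nm]][] <- v; p }, g$mtr[[nm]])
  }
})
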
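# Span-masked language modeling, the hybrid MLM + multi-task-regression
# objective, the AdamW learning-rate schedule, and the pretraining loop.

#' Pretraining configuration
#'
#' Defaults are the shipped protocol constants: 25% masking rate, span
#' lengths from a Gaussian (mu 3.5, sigma 1.0, minimum 1 token), hybrid loss
#' weights lambda_mlm = 0.6 / lambda_mtr = 0.4, AdamW with betas (0.9, 0.98)
#' and weight decay 0.01, linear warmup over 5,000 steps to a peak learning
#' rate of 3e-4, then cosine annealing to 10% of the peak.  Toy runs override
#' `steps`, `warmup_steps` and `batch_size`.
#'
#' @param rate Masking rate in (0, 1].
#' @param span_mu,span_sigma Span-length Gaussian parameters.
#' @param lambda_mlm,lambda_mtr Hybrid loss weights.
#' @param peak_lr Peak learning rate.
#' @param warmup_steps Linear warmup duration in steps.
#' @param final_lr_fraction Fraction of peak reached at the final step.
#' @param betas AdamW (beta1, beta2).
#' @param weight_decay Decoupled weight decay.
#' @param batch_size,steps,seed Loop controls.
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(rate = 0.25, span_mu = 3.5, span_sigma = 1.0,
                            lambda_mlm = 0.6, lambda_mtr = 0.4,
                            peak_lr = 3e-4, warmup_steps = 5000L,
                            final_lr_fraction = 0.1, betas = c(0.9, 0.98),
                            weight_decay = 0.01, batch_size = 512L,
                            steps = 100000L, seed = 1L) {
  structure(list(rate = rate, span_mu = span_mu, span_sigma = span_sigma,
                 lambda_mlm = lambda_mlm, lambda_mtr = lambda_mtr,
                 peak_lr = peak_lr, warmup_steps = as.integer(warmup_steps),
                 final_lr_fraction = final_lr_fraction, betas = betas,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), seed = as.integer(seed)),
            class = "pretrain_config")
}

#' Sample span lengths for span masking
#'
#' Draws from Normal(mu, sigma), rounds to the nearest integer, and clamps to
#' a minimum of one token.  Draws come from the current RNG stream; wrap in a
#' seeded context for reproducibility.
#'
#' @param n Number of draws.
#' @param mu,sigma Distribution parameters (defaults 3.5, 1.0).
#' @return Integer vector of span lengths, all >= 1.
#' @export
sample_span_length <- function(n = 1L, mu = 3.5, sigma = 1.0) {
  pmax(1L, as.integer(round(stats::rnorm(n, mu, sigma))))
}

#' Build a span-masking plan for one sequence
#'
#' The masking budget is round(rate x maskable positions) (round half up),
#' where maskable excludes `protected` positions (e.g. BOS/EOS).  Spans with
#' lengths from [sample_span_length()] are placed at random starts among the
#' still-unmasked maskable positions; each span extends over consecutive
#' available positions and is truncated at sequence boundaries, previously
#' masked regions, protected positions, and the remaining budget, so spans
#' never overlap and the budget is met exactly.
#'
#' @param length Sequence length (tokens).
#' @param rate Masking rate in (0, 1].
#' @param protected Integer vector of 1-based positions never masked.
#' @param span_mu,span_sigma Span-length distribution parameters.
#' @return A `masking_plan`: list with `sequence_length`, `masked_positions`
#'   (sorted), `spans` (data.frame start, length), `budget`.
#' @export
build_masking_plan <- function(length, rate = 0.25, protected = integer(0),
                               span_mu = 3.5, span_sigma = 1.0) {
  length <- as.integer(length)
  if (!(rate > 0 && rate <= 1)) {
    stop_smiclm("rate must be in (0, 1]", "smiclm_badarg")
  }
  protected <- as.integer(protected)
  maskable <- setdiff(seq_len(length), protected)
  if (length(maskable) == 0L) {
    stop_smiclm("no maskable positions", "smiclm_badarg")
  }
  budget <- round_half_up(rate * length(maskable))
  available <- rep(FALSE, length)
  available[maskable] <- TRUE
  masked <- integer(0)
  spans <- list()
  while (length(masked) < budget) {
    remaining <- budget - length(masked)
    len <- min(sample_span_length(1L, span_mu, span_sigma), remaining)
    open <- which(available)
    start <- open[sample.int(length(open), 1L)]
    pos <- start
    run <- start
    while (length(run) < len && pos + 1L <= length && available[pos + 1L]) {
      pos <- pos + 1L
      run <- c(run, pos)
    }
    available[run] <- FALSE
    masked <- c(masked, run)
    spans[[length(spans) + 1L]] <- c(start = start, length = length(run))
  }
  spans <- if (length(spans)) {
    as.data.frame(do.call(rbind, spans))
  } else data.frame(start = integer(0), length = integer(0))
  structure(list(sequence_length = length,
                 masked_positions = sort(masked),
                 spans = spans, budget = budget),
            class = "masking_plan")
}

#' Apply a masking plan to a token sequence
#'
#' Replaces every masked position with `mask_id` (pure-mask replacement; no
#' random-token or keep-original mixing) and records the original ids as
#' reconstruction labels.
#'
#' @param ids Integer vector of 0-based token ids.
#' @param plan A `masking_plan` for this sequence length.
#' @param mask_id Id of the `[MASK]` token.
#' @return List with `ids` (masked sequence) and `labels` (original ids at
#'   `plan$masked_positions`).
#' @export
apply_mask <- function(ids, plan, mask_id) {
  stopifnot(length(ids) == plan$sequence_length)
  labels <- ids[plan$masked_positions]
  ids[plan$masked_positions] <- mask_id
  list(ids = ids, labels = labels)
}

#' Combined pretraining loss
#'
#' The hybrid objective is the weighted sum
#' `lambda_mlm * l_mlm + lambda_mtr * l_mtr` with shipped weights 0.6 / 0.4.
#'
#' @param l_mlm,l_mtr Component losses.
#' @param cfg A `pretrain_config`.
#' @return Numeric scalar.
#' @export
combined_loss <- function(l_mlm, l_mtr, cfg = pretrain_config()) {
  cfg$lambda_mlm * l_mlm + cfg$lambda_mtr * l_mtr
}

#' Learning rate at a given step
#'
#' Linear warmup from 0 to `peak_lr` over `warmup_steps`, then half-cosine
#' annealing down to `final_lr_fraction * peak_lr` at `total_steps`.
#'
#' @param step Step index, 0..total_steps.
#' @param cfg A `pretrain_config`.
#' @param total_steps Total training steps (defaults to `cfg$steps`).
#' @return Learning rate.
#' @export
lr_at_step <- function(step, cfg = pretrain_config(), total_steps = cfg$steps) {
  if (total_steps < cfg$warmup_steps) {
    stop_smiclm("total_steps smaller than warmup_steps", "smiclm_badarg")
  }
  if (step < 0 || step > total_steps) {
    stop_smiclm("step outside 0..total_steps", "smiclm_badarg")
  }
  if (step <= cfg$warmup_steps) {
    return(cfg$peak_lr * step / cfg$warmup_steps)
  }
  frac <- (step - cfg$warmup_steps) / (total_steps - cfg$warmup_steps)
  floor_ <- cfg$final_lr_fraction
  cfg$peak_lr * (floor_ + (1 - floor_) * 0.5 * (1 + cos(pi * frac)))
}

#' Pretrain an encoder on a SMILES corpus
#'
#' Runs span-masked language modeling (`objective = "mlm"`), multi-task
#' descriptor regression (`"mtr"`), or the hybrid objective (`"hybrid"`,
#' weights from `pcfg`).  Sequences are k-mer encoded with BOS/EOS; BOS/EOS
#' are protected from masking.  With `randomize = TRUE` the corpus is
#' re-randomized (alternative SMILES spellings) at the start of every
#' pseudo-epoch.  A fixed seed reproduces the loss trace exactly on one
#' device.
#'
#' @param corpus Character vector of valid SMILES strings.
#' @param vocab A `kmer_vocab`.
#' @param encoder_cfg An `encoder_config` (its vocab_size must match).
#' @param pcfg A `pretrain_config`; `pcfg$steps`, `pcfg$batch_size`,
#'   `pcfg$warmup_steps` and `pcfg$seed` control the loop.
#' @param objective `"mlm"`, `"mtr"`, or `"hybrid"`.
#' @param descriptors Optional precomputed raw descriptor matrix for the
#'   corpus (computed internally when absent and the objective needs it).
#' @param randomize Dynamic SMILES randomization per pseudo-epoch (default
#'   TRUE).
#' @param max_len Truncate encoded sequences to this many tokens.
#' @return List with `model` (a `clm_encoder`), `trace` (data.frame step, lr,
#'   mlm_loss, mtr_loss, total), `descriptor_stats` (the
#'   `descriptor_matrix` used for target normalization, or NULL).
#' @export
pretrain <- function(corpus, vocab, encoder_cfg, pcfg, objective =
                       c("hybrid", "mlm", "mtr"), descriptors = NULL,
                     randomize = TRUE, max_len = encoder_cfg$max_len) {
  objective <- match.arg(objective)
  stopifnot(encoder_cfg$vocab_size == length(vocab$tokens))
  n <- length(corpus)
  use_mtr <- objective != "mlm"
  use_mlm <- objective != "mtr"
  dm <- NULL
  targets <- NULL
  if (use_mtr) {
    raw <- descriptors %||% compute_descriptors(corpus)
    failed <- attr(raw, "failed") %||% rep(FALSE, nrow(raw))
    dm <- normalize_descriptors(raw)
    targets <- dm$values
    targets[failed, ] <- NA_real_
  }
  model <- init_encoder(encoder_cfg, seed = pcfg$seed)
  opt <- adamw_state(model$params)
  map <- .vocab_map(vocab)
  mask_id <- vocab$specials[["[MASK]"]]
  bos <- vocab$specials[["[BOS]"]]; eos <- vocab$specials[["[EOS]"]]
  trace <- vector("list", pcfg$steps)
  prim_list <- .pretokenize_all(corpus)
  encode_all <- function(smls) {
    lapply(smls, function(s) {
      ids <- kmer_encode(s, vocab, add_special = TRUE, unk = "silent",
                         map = map)
      if (length(ids) > max_len) ids <- c(ids[seq_len(max_len - 1L)], eos)
      ids
    })
  }
  if (pcfg$steps == 0L) {
    empty <- data.frame(step = integer(0), lr = numeric(0),
                        mlm_loss = numeric(0), mtr_loss = numeric(0),
                        total = numeric(0))
    return(list(model = model, trace = empty, descriptor_stats = dm))
  }
  with_seed(pcfg$seed, {
    current <- corpus
    enc <- encode_all(current)
    order_idx <- sample.int(n)
    ptr <- 1L
    for (step in seq_len(pcfg$steps)) {
      lr <- lr_at_step(step, pcfg, total_steps = pcfg$steps)
      grads <- NULL
      mlm_sum <- 0; mtr_sum <- 0; nb_mlm <- 0L; nb_mtr <- 0L
      for (b in seq_len(pcfg$batch_size)) {
        if (ptr > n) {
          # new pseudo-epoch: reshuffle and re-randomize spellings
          if (randomize) {
            current <- .randomize_corpus(corpus, prim_list)
            enc <- encode_all(current)
          }
          order_idx <- sample.int(n)
          ptr <- 1L
        }
        i <- order_idx[ptr]; ptr <- ptr + 1L
        ids <- enc[[i]]
        L <- length(ids)
        w_mlm <- if (objective == "hybrid") pcfg$lambda_mlm else 1
        w_mtr <- if (objective == "hybrid") pcfg$lambda_mtr else 1
        gseq <- NULL
        if (use_mlm) {
          plan <- build_masking_plan(L, pcfg$rate,
                                     protected = c(1L, L),
                                     span_mu = pcfg$span_mu,
                                     span_sigma = pcfg$span_sigma)
          am <- apply_mask(ids, plan, mask_id)
          fwd <- .encoder_fwd(model$params, encoder_cfg, am$ids,
                              keep_cache = TRUE)
          ml <- .mlm_loss_grad(model$params, fwd$final,
                               plan$masked_positions, am$labels)
          mlm_sum <- mlm_sum + ml$loss; nb_mlm <- nb_mlm + 1L
          gseq <- .encoder_bwd(model$params, encoder_cfg, fwd$cache,
                               w_mlm * ml$dfinal)
          if (length(plan$masked_positions)) {
            gseq$E <- gseq$E + w_mlm * ml$dE
            gseq$mlm_b <- gseq$mlm_b + w_mlm * ml$db
          }
        }
        # the regression head reads the uncorrupted molecule: a separate
        # clean forward pass, so descriptor targets are never predicted
        # from masked inputs
        if (use_mtr && !all(is.na(targets[i, ]))) {
          fwd_c <- .encoder_fwd(model$params, encoder_cfg, ids,
                                keep_cache = TRUE)
          pooled <- colMeans(fwd_c$final)
          mt <- .mtr_loss_grad(model$params$mtr, pooled, targets[i, ])
          mtr_sum <- mtr_sum + mt$loss; nb_mtr <- nb_mtr + 1L
          dfinal_c <- matrix(w_mtr * mt$dpooled / L, L,
                             encoder_cfg$d_model, byrow = TRUE)
          g2 <- .encoder_bwd(model$params, encoder_cfg, fwd_c$cache,
                             dfinal_c)
          g2$mtr <- .tree_add(g2$mtr,
                              lapply(mt$grads, function(x) w_mtr * x))
          gseq <- if (is.null(gseq)) g2 else .tree_add(gseq, g2)
        }
        grads <- if (is.null(grads)) gseq else .tree_add(grads, gseq)
      }
      grads <- rapply(grads, function(x) x / pcfg$batch_size, how = "replace")
      upd <- adamw_step(model$params, grads, opt, lr = lr,
                        betas = pcfg$betas, weight_decay = pcfg$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      l_mlm <- if (nb_mlm) mlm_sum / nb_mlm else NA_real_
      l_mtr <- if (nb_mtr) mtr_sum / nb_mtr else NA_real_
      total <- switch(objective,
        mlm = l_mlm, mtr = l_mtr,
        hybrid = pcfg$lambda_mlm * l_mlm + pcfg$lambda_mtr *
          (if (is.na(l_mtr)) 0 else l_mtr))
      if (!is.finite(total)) {
        stop_smiclm(sprintf("non-finite loss at step %d (mlm=%g, mtr=%g)",
                            step, l_mlm, l_mtr), "smiclm_nan")
      }
      trace[[step]] <- data.frame(step = step, lr = lr, mlm_loss = l_mlm,
                                  mtr_loss = l_mtr, total = total)
    }
  })
  list(model = model, trace = do.call(rbind, trace), descriptor_stats = dm)
}

#' Predict descriptors for new molecules with a pretrained encoder
#'
#' Mean-pools the final hidden states and applies the regression head;
#' outputs are on the normalized descriptor scale defined by `dstats`.
#'
#' @param model A `clm_encoder`.
#' @param vocab The `kmer_vocab` used at pretraining time.
#' @param smiles Character vector of molecules.
#' @return Matrix n x 99 of normalized descriptor predictions.
#' @export
predict_descriptors <- function(model, vocab, smiles) {
  map <- .vocab_map(vocab)
  ids <- lapply(smiles, kmer_encode, vocab = vocab, add_special = TRUE,
                unk = "silent", map = map)
  hs <- encode_tokens(model, ids)
  pooled <- mean_pool(hs, "final")
  mtr_head(model, pooled)
}

#' Write a loss trace to CSV
#' @param trace Data frame from [pretrain()].
#' @param path Output path.
#' @export
write_loss_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
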
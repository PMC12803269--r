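# Downstream evaluation harness: task datasets, metrics, topological path
# fingerprints + random-forest baseline, head finetuning on frozen pooled
# embeddings with nested cross-validation and early stopping, and layer-wise
# linear probing.

#' Construct a task dataset
#'
#' @param smiles Character vector.
#' @param labels Numeric (regression) or 0/1 (binary) vector.
#' @param condition Optional numeric condition column (e.g. pH).
#' @param task_type `"regression"` or `"binary"`.
#' @param split_spec Optional integer fold assignment per row.
#' @return A `task_dataset`.
#' @export
task_dataset <- function(smiles, labels, condition = NULL,
                         task_type = c("regression", "binary"),
                         split_spec = NULL) {
  task_type <- match.arg(task_type)
  stopifnot(length(smiles) == length(labels),
            is.null(condition) || length(condition) == length(labels),
            is.null(split_spec) || length(split_spec) == length(labels))
  if (task_type == "binary" && !all(labels %in% c(0, 1))) {
    stop_smiclm("binary labels must be 0/1", "smiclm_badarg")
  }
  structure(list(smiles = smiles, labels = labels, condition = condition,
                 task_type = task_type, split_spec = split_spec),
            class = "task_dataset")
}

#' Read a task table from CSV
#'
#' Columns `smiles`, `label`, and optional `condition`, `fold`.
#'
#' @param path CSV path.
#' @param task_type `"regression"` or `"binary"` (inferred from labels when
#'   missing).
#' @return A `task_dataset`.
#' @export
read_task_csv <- function(path, task_type = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("smiles", "label") %in% names(df)))
  if (is.null(task_type)) {
    task_type <- if (all(df$label %in% c(0, 1))) "binary" else "regression"
  }
  task_dataset(df$smiles, df$label, condition = df[["condition"]],
               task_type = task_type, split_spec = df[["fold"]])
}

# --- metrics --------------------------------------------------------------

#' Evaluation metrics
#'
#' Binary tasks report the Matthews correlation coefficient (class threshold
#' 0.5 on scores) and AUROC (rank/Wilcoxon form); regression tasks report
#' R-squared against the mean of the truth.  A degenerate single-class
#' prediction has MCC defined as 0.
#'
#' @param pred Predicted scores (binary: probabilities or classes).
#' @param truth Observed labels.
#' @param task_type `"binary"` or `"regression"`.
#' @return Named list of metric values.
#' @export
metrics <- function(pred, truth, task_type = c("binary", "regression")) {
  task_type <- match.arg(task_type)
  if (length(pred) == 0L || length(pred) != length(truth)) {
    stop_smiclm("pred and truth must be equal-length and non-empty",
                "smiclm_badarg")
  }
  if (task_type == "regression") {
    return(list(r2 = r_squared(pred, truth)))
  }
  cls <- as.integer(pred >= 0.5)
  list(mcc = mcc(cls, truth), auroc = auroc(pred, truth))
}

#' Matthews correlation coefficient
#' @param pred Predicted classes (0/1).
#' @param truth True classes (0/1).
#' @return MCC in [-1, 1]; 0 when a denominator term vanishes (degenerate
#'   single-class predictions or truths).
#' @export
mcc <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
}

#' Area under the ROC curve (rank form)
#' @param scores Predicted scores.
#' @param truth True classes (0/1).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' R-squared against the truth mean
#' @param pred Predictions.
#' @param truth Observations.
#' @return 1 - SS_res / SS_tot.
#' @export
r_squared <- function(pred, truth) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

# --- topological path fingerprints ---------------------------------------

.fp_hash <- function(s, mult, mod) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * mult + c) %% mod
  h
}

# Enumerate canonical labels of all simple linear paths with 1..max_path
# bonds from the molecular graph.
.fp_paths <- function(graph, max_path = 7L) {
  n <- nrow(graph$atoms)
  if (n == 0L || nrow(graph$bonds) == 0L) return(character(0))
  ad <- .adjacency(graph)
  acode <- paste0(graph$atoms$symbol, ifelse(graph$atoms$aromatic, "a", ""))
  bcode <- c("1", "2", "3")
  bond_label <- function(o) if (o == 1.5) "4" else bcode[o]
  labels <- new.env(parent = emptyenv())
  walk <- function(v, visited, fwd, bonds_used) {
    if (bonds_used > 0L) {
      rev_ <- rev(fwd)
      lab <- paste0(fwd, collapse = "")
      labr <- paste0(rev_, collapse = "")
      assign(min(lab, labr), TRUE, envir = labels)
    }
    if (bonds_used == max_path) return()
    nb <- ad$adj[[v]]; os <- ad$ord[[v]]
    for (j in seq_along(nb)) {
      w <- nb[j]
      if (w %in% visited) next
      walk(w, c(visited, w),
           c(fwd, bond_label(os[j]), acode[w]), bonds_used + 1L)
    }
  }
  for (v in seq_len(n)) walk(v, v, acode[v], 0L)
  ls(labels)
}

#' Topological path fingerprints
#'
#' Hashed linear-path fingerprints over the heavy-atom graph: all simple
#' paths of 1-7 bonds, labeled by element/aromaticity and bond order, each
#' setting `bits_per_hash` bits (two independent hashes) in a 2048-bit
#' vector.
#'
#' @param smiles Character vector.
#' @param nbits Fingerprint length (default 2048).
#' @param max_path Maximum path length in bonds (default 7).
#' @param bits_per_hash Bits set per path (default 2).
#' @return Binary matrix n x nbits; rows of unparseable molecules are NA and
#'   flagged in the `failed` attribute.
#' @export
fp_topological <- function(smiles, nbits = 2048L, max_path = 7L,
                           bits_per_hash = 2L) {
  n <- length(smiles)
  M <- matrix(0L, n, nbits)
  failed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    g <- tryCatch(smiles_graph(smiles[i]), error = function(e) NULL)
    if (is.null(g)) { M[i, ] <- NA_integer_; failed[i] <- TRUE; next }
    for (p in .fp_paths(g, max_path)) {
      M[i, (.fp_hash(p, 31, 1048573) %% nbits) + 1L] <- 1L
      if (bits_per_hash >= 2L) {
        M[i, (.fp_hash(p, 37, 2097143) %% nbits) + 1L] <- 1L
      }
    }
  }
  attr(M, "failed") <- failed
  M
}

# --- folds ----------------------------------------------------------------

# Stratified (binary) or plain k-fold assignment, deterministic in the
# current RNG stream.
.make_folds <- function(labels, k, stratify = FALSE) {
  n <- length(labels)
  fold <- integer(n)
  if (stratify) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

# --- head finetuning ------------------------------------------------------

#' Default head configuration for desk-scale finetuning
#'
#' The task head is a two-hidden-layer feed-forward network with GeLU
#' activation and dropout 0.1, trained with AdamW at batch size 16,
#' validating every half epoch with early-stopping patience of 5 epochs.
#' The head-only trainer defaults to lr 1e-3 (a fresh MLP head under Adam);
#' `finetune_protocol_preset()` carries the full-model protocol constant
#' lr 1e-5.
#'
#' @param hidden Hidden widths (default c(64, 64)).
#' @param dropout Dropout probability (default 0.1).
#' @param lr Learning rate (default 1e-3).
#' @param batch_size Batch size (default 16).
#' @param max_epochs Epoch budget (default 80).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param val_every Validation interval in epochs (default 0.5).
#' @return A list of head hyperparameters.
#' @export
head_config <- function(hidden = c(64L, 64L), dropout = 0.1, lr = 1e-3,
                        batch_size = 16L, max_epochs = 80L, patience = 5L,
                        val_every = 0.5) {
  list(hidden = hidden, dropout = dropout, lr = lr, batch_size = batch_size,
       max_epochs = max_epochs, patience = patience, val_every = val_every)
}

#' @rdname head_config
#' @export
finetune_protocol_preset <- function() head_config(lr = 1e-5)

# Train one MLP head with early stopping.  X/y train, Xv/yv validation.
# Returns the best-validation network.
.train_head <- function(X, y, Xv, yv, binary, hcfg) {
  sizes <- c(ncol(X), hcfg$hidden, 1L)
  net <- mlp_init(sizes, seed = sample.int(1e6, 1L))
  state <- adamw_state(net[c("W", "b")])
  n <- nrow(X)
  nb <- max(1L, ceiling(n / hcfg$batch_size))
  check_every <- max(1L, round(nb * hcfg$val_every))
  best <- list(loss = Inf, net = net)
  bad_checks <- 0L
  max_bad <- ceiling(hcfg$patience / hcfg$val_every)
  val_loss <- function(net) {
    out <- drop(mlp_forward(net, Xv)$out)
    if (binary) {
      p <- 1 / (1 + exp(-out))
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      -mean(yv * log(p) + (1 - yv) * log(1 - p))
    } else mean((out - yv)^2)
  }
  if (hcfg$max_epochs == 0L) {
    return(list(net = net, flagged_untrained = TRUE))
  }
  done <- FALSE
  batch_count <- 0L
  for (epoch in seq_len(hcfg$max_epochs)) {
    ord <- sample.int(n)
    for (bi in seq_len(nb)) {
      idx <- ord[(((bi - 1L) * hcfg$batch_size) + 1L):min(bi * hcfg$batch_size, n)]
      fwd <- mlp_forward(net, X[idx, , drop = FALSE],
                         dropout = hcfg$dropout, train = TRUE)
      out <- drop(fwd$out)
      if (binary) {
        p <- 1 / (1 + exp(-out))
        dout <- matrix((p - y[idx]) / length(idx), ncol = 1L)
      } else {
        dout <- matrix(2 * (out - y[idx]) / length(idx), ncol = 1L)
      }
      gr <- mlp_backward(net, fwd, dout, dropout = hcfg$dropout)
      upd <- adamw_step(net[c("W", "b")], gr, state, lr = hcfg$lr,
                        betas = c(0.9, 0.999), weight_decay = 0.01)
      net$W <- upd$params$W; net$b <- upd$params$b
      state <- upd$state
      batch_count <- batch_count + 1L
      if (batch_count %% check_every == 0L) {
        vl <- val_loss(net)
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, net = net)
          bad_checks <- 0L
        } else {
          bad_checks <- bad_checks + 1L
          if (bad_checks >= max_bad) { done <- TRUE; break }
        }
      }
    }
    if (done) break
  }
  list(net = best$net, flagged_untrained = FALSE)
}

.head_predict <- function(net, X, binary) {
  out <- drop(mlp_forward(net, X)$out)
  if (binary) 1 / (1 + exp(-out)) else out
}

# Column standardization by training statistics.
.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
.standardize_apply <- function(st, X) {
  sweep(sweep(X, 2L, st$mu, "-"), 2L, st$sd, "/")
}

#' Finetune a task head on frozen encoder embeddings
#'
#' Desk-scale finetuning protocol: the pretrained encoder is frozen, final
#' hidden states are mean-pooled, and a two-hidden-layer GeLU head (dropout
#' 0.1) is trained with nested cross-validation — `outer_folds` outer test
#' folds; within each outer training set, `inner_folds` inner folds each
#' train one head with early stopping on the held-in inner validation fold.
#' Outer-test predictions are the ensemble mean over the inner-fold models.
#' Feature and condition standardization uses outer-training statistics
#' only.  When a condition column is present it is standardized and appended
#' to the pooled embedding before the head.
#'
#' @param model A `clm_encoder` (pretrained checkpoint).
#' @param vocab The `kmer_vocab` used at pretraining time.
#' @param data A `task_dataset`.
#' @param head_cfg A [head_config()] list.
#' @param outer_folds,inner_folds Fold counts (defaults 5, 4).
#' @param seed Integer seed.
#' @param embeddings Optional precomputed pooled-embedding matrix (rows
#'   aligned with `data$smiles`), to avoid re-encoding.
#' @return List with `predictions` (data.frame: row, fold, ensemble and
#'   per-inner-model columns), `score` (metrics on pooled outer-test
#'   predictions), `flagged_untrained`, and `fold_details` (standardization
#'   statistics per outer fold).
#' @export
finetune <- function(model, vocab, data, head_cfg = head_config(),
                     outer_folds = 5L, inner_folds = 4L, seed = 1L,
                     embeddings = NULL) {
  binary <- data$task_type == "binary"
  if (binary && length(unique(data$labels)) < 2L) {
    stop_smiclm("binary task needs both classes present", "smiclm_badarg")
  }
  X <- embeddings %||% {
    map <- .vocab_map(vocab)
    ids <- lapply(data$smiles, kmer_encode, vocab = vocab,
                  add_special = TRUE, unk = "silent", map = map)
    mean_pool(encode_tokens(model, ids), "final")
  }
  y <- data$labels
  n <- length(y)
  with_seed(seed, {
    fold <- data$split_spec %||% .make_folds(y, outer_folds,
                                             stratify = binary)
    preds <- rep(NA_real_, n)
    per_inner <- matrix(NA_real_, n, inner_folds)
    flagged <- FALSE
    fold_details <- list()
    for (k in sort(unique(fold))) {
      tr <- which(fold != k); te <- which(fold == k)
      st <- .standardize_fit(X[tr, , drop = FALSE])
      Xtr <- .standardize_apply(st, X[tr, , drop = FALSE])
      Xte <- .standardize_apply(st, X[te, , drop = FALSE])
      cst <- NULL
      if (!is.null(data$condition)) {
        cm <- matrix(data$condition, ncol = 1L)
        cst <- .standardize_fit(cm[tr, , drop = FALSE])
        Xtr <- cbind(Xtr, .standardize_apply(cst, cm[tr, , drop = FALSE]))
        Xte <- cbind(Xte, .standardize_apply(cst, cm[te, , drop = FALSE]))
      }
      ifold <- .make_folds(y[tr], inner_folds, stratify = binary)
      for (j in seq_len(inner_folds)) {
        itr <- which(ifold != j); iva <- which(ifold == j)
        if (binary && length(unique(y[tr][itr])) < 2L) {
          stop_smiclm("single-class inner training fold", "smiclm_badarg")
        }
        fit <- .train_head(Xtr[itr, , drop = FALSE], y[tr][itr],
                           Xtr[iva, , drop = FALSE], y[tr][iva],
                           binary, head_cfg)
        flagged <- flagged || fit$flagged_untrained
        per_inner[te, j] <- .head_predict(fit$net, Xte, binary)
      }
      preds[te] <- rowMeans(per_inner[te, , drop = FALSE])
      fold_details[[as.character(k)]] <- list(embed_stats = st,
                                              condition_stats = cst)
    }
    score <- metrics(preds, y, data$task_type)
    list(predictions = data.frame(row = seq_len(n), fold = fold,
                                  ensemble = preds, per_inner),
         score = score, flagged_untrained = flagged,
         fold_details = fold_details)
  })
}

# --- layer-wise linear probing -------------------------------------------

#' Layer-wise linear probe of a frozen encoder
#'
#' For each layer (0 = embedding output through n_layers), mean-pools the
#' frozen hidden states and fits an L1-penalized linear regression whose
#' penalty is selected by 5-fold cross-validation over a 100-value path
#' (iteration cap 10,000).  The reported score is held-out R-squared pooled
#' over `outer_folds` outer folds.
#'
#' @param model A `clm_encoder`.
#' @param vocab The matching `kmer_vocab`.
#' @param data A regression `task_dataset` with at least 10 rows.
#' @param outer_folds Outer fold count (default 5).
#' @param seed Integer seed.
#' @return A `probe_result` data.frame with columns `layer`, `r2`,
#'   `lambda` (median selected penalty across folds).
#' @export
layer_probe <- function(model, vocab, data, outer_folds = 5L, seed = 1L) {
  if (data$task_type != "regression") {
    stop_smiclm("layer probing is defined for regression tasks",
                "smiclm_badarg")
  }
  n <- length(data$smiles)
  if (n < 10L) stop_smiclm("need at least 10 observations", "smiclm_badarg")
  map <- .vocab_map(vocab)
  ids <- lapply(data$smiles, kmer_encode, vocab = vocab, add_special = TRUE,
                unk = "silent", map = map)
  hs <- encode_tokens(model, ids)
  y <- data$labels
  res <- lapply(0:hs$n_layers, function(l) {
    X <- mean_pool(hs, l)
    with_seed(seed + l, {
      fold <- .make_folds(y, outer_folds)
      pred <- rep(NA_real_, n)
      lambdas <- numeric(0)
      for (k in seq_len(outer_folds)) {
        tr <- which(fold != k); te <- which(fold == k)
        cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = 1,
                                nfolds = 5L, nlambda = 100L,
                                maxit = 10000L)
        pred[te] <- as.numeric(stats::predict(cv, X[te, , drop = FALSE],
                                              s = "lambda.min"))
        lambdas <- c(lambdas, cv$lambda.min)
      }
      data.frame(layer = l, r2 = r_squared(pred, y),
                 lambda = stats::median(lambdas))
    })
  })
  structure(do.call(rbind, res), class = c("probe_result", "data.frame"))
}

# --- fingerprint + random-forest baseline --------------------------------

#' Fingerprint random-forest baseline
#'
#' The classical baseline: 2048-bit topological path fingerprints (paths 1-7
#' bonds, 2 bits per hash) and a random forest with 100 trees (Gini impurity
#' for classification, unlimited depth).  Evaluated with the same fold
#' structure as [finetune()]; rows whose SMILES cannot be parsed are dropped
#' with a warning.
#'
#' @param data A `task_dataset`.
#' @param seed Integer seed.
#' @param folds Fold count when `data$split_spec` is absent (default 5).
#' @return List with `predictions` (scores aligned to kept rows), `kept`
#'   (row indices), `score` (metrics).
#' @export
fingerprint_baseline <- function(data, seed = 1L, folds = 5L) {
  FP <- fp_topological(data$smiles)
  failed <- attr(FP, "failed")
  if (any(failed)) {
    warning(sprintf("%d molecules could not be parsed; dropped", sum(failed)))
  }
  keep <- which(!failed)
  X <- FP[keep, , drop = FALSE]
  y <- data$labels[keep]
  binary <- data$task_type == "binary"
  with_seed(seed, {
    fold <- (data$split_spec %||% .make_folds(y, folds,
                                              stratify = binary))[keep]
    pred <- rep(NA_real_, length(keep))
    for (k in sort(unique(fold))) {
      tr <- which(fold != k); te <- which(fold == k)
      # drop constant columns to keep the forest honest and fast
      keepcol <- which(matrixStats_colSds(X[tr, , drop = FALSE]) > 0)
      if (length(keepcol) == 0L) keepcol <- 1L
      if (binary) {
        rf <- randomForest::randomForest(
          x = X[tr, keepcol, drop = FALSE], y = factor(y[tr], levels = c(0, 1)),
          ntree = 100L)
        pred[te] <- stats::predict(rf, X[te, keepcol, drop = FALSE],
                                   type = "prob")[, "1"]
      } else {
        rf <- randomForest::randomForest(
          x = X[tr, keepcol, drop = FALSE], y = y[tr], ntree = 100L)
        pred[te] <- stats::predict(rf, X[te, keepcol, drop = FALSE])
      }
    }
    list(predictions = pred, kept = keep,
         score = metrics(pred, y, data$task_type))
  })
}

# column standard deviations without extra dependencies
matrixStats_colSds <- function(X) {
  mu <- colMeans(X)
  sqrt(pmax(0, colMeans(X * X) - mu * mu))
}
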
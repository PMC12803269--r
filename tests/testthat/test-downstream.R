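test_that("metrics match closed-form values", {
  expect_identical(metrics(c(1, 0, 1, 0), c(1, 0, 1, 0), "binary")$mcc, 1)
  # contingency table TP=40 FP=10 FN=10 TN=40 -> MCC 0.6
  truth <- c(rep(1, 50), rep(0, 50))
  pred <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  expect_equal(mcc(pred, truth), 0.6, tolerance = 1e-12)
  expect_identical(mcc(rep(1, 10), c(rep(1, 5), rep(0, 5))), 0)  # degenerate
  set.seed(1)
  scores <- runif(400)
  truth2 <- rbinom(400, 1, 0.5)
  expect_lt(abs(metrics(scores, truth2, "binary")$auroc - 0.5), 0.1)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(rep(2, 3), c(1, 2, 3)), 0)
  expect_error(metrics(numeric(0), numeric(0)), class = "smiclm_badarg")
})

test_that("path fingerprints detect a literally hashed substructure", {
  # label = carries a terminal iodophenyl group (iodine is absent from the
  # generator grammar); every path inside the appended ring that reaches the
  # iodine hashes to the same fingerprint bits in all positives and none of
  # the negatives, giving the forest a dozen clean features
  with_pattern <- paste0(gen_small_molecules(60L, seed = 61), "c1ccc(I)cc1")
  without <- gen_small_molecules(60L, seed = 62)
  smiles <- c(with_pattern, without)
  labels <- rep(c(1L, 0L), each = 60L)
  task <- task_dataset(smiles, labels, task_type = "binary")
  res <- with_seed(1, fingerprint_baseline(task, seed = 5, folds = 3L))
  expect_gt(res$score$mcc, 0.85)
  expect_identical(
    with_seed(2, fingerprint_baseline(task, seed = 5, folds = 3L))$predictions,
    res$predictions)   # deterministic given its own seed
})

test_that("fingerprints give near-zero MCC on random labels", {
  smiles <- gen_small_molecules(80L, seed = 63)
  labels <- with_seed(9, rbinom(80L, 1L, 0.5))
  task <- task_dataset(smiles, labels, task_type = "binary")
  res <- fingerprint_baseline(task, seed = 5, folds = 4L)
  expect_lt(abs(res$score$mcc), 0.3)
})

test_that("fingerprint matrix has the documented shape and flags failures", {
  M <- fp_topological(c("CCO", "c1ccccc1"), nbits = 128L, max_path = 3L)
  expect_identical(dim(M), c(2L, 128L))
  expect_true(all(M %in% c(0L, 1L)))
  expect_gt(sum(M[1, ]), 0L)
  # ethanol with paths<=3: C-C, C-O, C-C-O -> at most 6 bits at 2 bits/hash
  expect_lte(sum(M[1, ]), 6L)
})

test_that("finetune ensembles inner-fold models and appends conditions", {
  task <- gen_labeled_task("condition_dependent_binary", n = 120L, seed = 71,
                           noise = 0)
  m <- tiny_model()
  ft <- finetune(m, tiny_vocab(), task,
                 head_cfg = head_config(max_epochs = 2L),
                 outer_folds = 3L, inner_folds = 2L, seed = 8L)
  pi <- as.matrix(ft$predictions[, c("X1", "X2")])
  expect_equal(ft$predictions$ensemble, rowMeans(pi), tolerance = 1e-12)
  # condition column standardized with training-fold statistics
  cs <- ft$fold_details[["1"]]$condition_stats
  expect_false(is.null(cs))
  expect_gt(cs$sd, 0)
})

test_that("zero-epoch budget returns untrained predictions, flagged", {
  task <- gen_labeled_task("descriptor_threshold_binary", n = 60L, seed = 72)
  ft <- finetune(tiny_model(), tiny_vocab(), task,
                 head_cfg = head_config(max_epochs = 0L),
                 outer_folds = 2L, inner_folds = 2L, seed = 8L)
  expect_true(ft$flagged_untrained)
  expect_true(all(is.finite(ft$predictions$ensemble)))
})

test_that("single-class folds are rejected", {
  task <- task_dataset(gen_small_molecules(20L, seed = 73),
                       rep(1L, 20L), task_type = "binary")
  expect_error(finetune(tiny_model(), tiny_vocab(), task),
               class = "smiclm_badarg")
})

test_that("test-fold rows cannot influence training statistics (canary)", {
  task <- gen_labeled_task("descriptor_threshold_binary", n = 80L, seed = 74)
  n <- length(task$smiles)
  split <- rep_len(1:4, n)
  base_task <- task_dataset(task$smiles, task$labels, task_type = "binary",
                            split_spec = split)
  m <- tiny_model()
  map <- smiclm:::.vocab_map(tiny_vocab())
  ids <- lapply(task$smiles, kmer_encode, vocab = tiny_vocab(),
                add_special = TRUE, unk = "silent", map = map)
  X <- mean_pool(encode_tokens(m, ids), "final")
  # canary: blow up one row that sits in test fold 1
  canary <- which(split == 1L)[1L]
  X2 <- X; X2[canary, ] <- X2[canary, ] + 1000
  hc <- head_config(max_epochs = 1L)
  f1 <- finetune(m, tiny_vocab(), base_task, head_cfg = hc, inner_folds = 2L,
                 seed = 4L, embeddings = X)
  f2 <- finetune(m, tiny_vocab(), base_task, head_cfg = hc, inner_folds = 2L,
                 seed = 4L, embeddings = X2)
  # fold 1 trains on folds 2-4, which the canary is not part of
  expect_identical(f1$fold_details[["1"]]$embed_stats,
                   f2$fold_details[["1"]]$embed_stats)
  non_canary <- setdiff(which(split == 1L), canary)
  expect_equal(f1$predictions$ensemble[non_canary],
               f2$predictions$ensemble[non_canary], tolerance = 1e-9)
})

test_that("layer probe recovers a realizable linear target and rejects nulls", {
  run <- toy_run()
  sm <- toy_corpus()[1:120]
  map <- smiclm:::.vocab_map(toy_vocab())
  ids <- lapply(sm, kmer_encode, vocab = toy_vocab(), add_special = TRUE,
                unk = "silent", map = map)
  hs <- encode_tokens(run$model, ids)
  X1 <- mean_pool(hs, 1L)
  w <- with_seed(9, rnorm(ncol(X1)))
  y <- drop(X1 %*% w)
  task <- task_dataset(sm, y, task_type = "regression")
  pr <- suppressWarnings(layer_probe(run$model, toy_vocab(), task, seed = 5))
  expect_identical(nrow(pr), run$model$cfg$n_layers + 1L)
  expect_gt(pr$r2[pr$layer == 1L], 0.9)
  yp <- with_seed(10, sample(y))
  pr0 <- suppressWarnings(layer_probe(run$model, toy_vocab(),
                                      task_dataset(sm, yp,
                                                   task_type = "regression"),
                                      seed = 5))
  expect_true(all(pr0$r2 <= 0.1))
  expect_error(layer_probe(run$model, toy_vocab(),
                           task_dataset("CC", 1, task_type = "regression")),
               class = "smiclm_badarg")
  bin <- task_dataset(sm, rep_len(c(0, 1), length(sm)), task_type = "binary")
  expect_error(layer_probe(run$model, toy_vocab(), bin),
               class = "smiclm_badarg")
})
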
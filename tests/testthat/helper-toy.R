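# Shared lazily-built objects for the test suite.  The toy study conditions
# are fixed here once: a 2,000-molecule synthetic corpus (1,600 train / 400
# held out), a k-mer vocabulary mined on the training split, a 2-layer
# d_model-64 encoder, and a 300-step hybrid pretraining run at batch size 16
# (three pseudo-epochs over the training split, mirroring the full
# protocol's three).

.cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .cache)) assign(key, fn(), envir = .cache)
  get(key, envir = .cache)
}

toy_corpus <- function() memo("corpus", function() {
  gen_small_molecules(2000L, seed = 21)
})

toy_split <- function() list(train = 1:1600, test = 1601:2000)

toy_vocab <- function() memo("vocab", function() {
  tr <- toy_corpus()[toy_split()$train]
  prims <- lapply(tr, function(s) smi_pretokenize(s)$primitives)
  tab <- mine_kmer_counts(prims, max_k = 6)
  kmer_vocabulary(tab, unique(unlist(prims)), target_size = 405L,
                  min_count = 5L)
})

toy_descriptors <- function() memo("descriptors", function() {
  compute_descriptors(toy_corpus())
})

toy_encoder_cfg <- function() {
  encoder_config("custom", n_layers = 2L, d_model = 64L, n_heads = 4L,
                 d_ffn = 128L, vocab_size = length(toy_vocab()$tokens),
                 max_len = 96L)
}

toy_pretrain_cfg <- function(steps = 300L) {
  pretrain_config(warmup_steps = 30L, steps = steps, batch_size = 16L,
                  peak_lr = 1e-3, seed = 7L)
}

# The 300-step hybrid run used by the pretraining-sanity and
# scaling-ordering tests.
toy_run <- function() memo("run", function() {
  sp <- toy_split()
  pretrain(toy_corpus()[sp$train], toy_vocab(), toy_encoder_cfg(),
           toy_pretrain_cfg(), objective = "hybrid",
           descriptors = toy_descriptors()[sp$train, ], randomize = TRUE)
})

# A tiny untrained encoder + vocabulary for plumbing tests that do not need
# learned representations.
tiny_vocab <- function() memo("tiny_vocab", function() {
  corpus <- c("CCO", "CCN", "CC(=O)O", "c1ccccc1", "CC(C)C")
  prims <- lapply(corpus, function(s) smi_pretokenize(s)$primitives)
  tab <- mine_kmer_counts(prims, max_k = 4)
  kmer_vocabulary(tab, unique(unlist(prims)), target_size = 40L,
                  min_count = 1L)
})

tiny_model <- function() memo("tiny_model", function() {
  cfg <- encoder_config("custom", n_layers = 2L, d_model = 16L,
                        n_heads = 2L, d_ffn = 32L,
                        vocab_size = length(tiny_vocab()$tokens),
                        max_len = 64L)
  smiclm:::init_encoder(cfg, seed = 11)
})

toy_task <- function() memo("task", function() {
  gen_labeled_task("descriptor_threshold_binary", n = 500L, seed = 31,
                   noise = 0.05)
})
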
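# Brute-force oracle: count contiguous windows by direct enumeration.
brute_counts <- function(seqs, max_k) {
  out <- list()
  for (p in seqs) {
    for (k in 2:max_k) {
      if (length(p) < k) next
      for (i in 1:(length(p) - k + 1)) {
        key <- paste(p[i:(i + k - 1)], collapse = "\x1f")
        out[[key]] <- (out[[key]] %||% 0L) + 1L
      }
    }
  }
  unlist(out)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("k-mer mining matches brute-force window enumeration", {
  corpus <- list(c("C", "C", "O"), c("C", "C", "O"))
  tab <- mine_kmer_counts(corpus, max_k = 3)
  expect_identical(sort(names(tab$counts)),
                   sort(c("C\x1fC", "C\x1fO", "C\x1fC\x1fO")))
  expect_true(all(tab$counts == 2L))
  # random corpora against the oracle
  corpus2 <- lapply(gen_small_molecules(30L, seed = 3), function(s) {
    smi_pretokenize(s)$primitives
  })
  tab2 <- mine_kmer_counts(corpus2, max_k = 4)
  oracle <- brute_counts(corpus2, 4)
  expect_identical(sort(names(tab2$counts)), sort(names(oracle)))
  expect_identical(unname(tab2$counts[names(oracle)]),
                   unname(as.integer(oracle)))
})

test_that("mining respects the length bound and the empty corpus", {
  tab <- mine_kmer_counts(list(c("C", "C", "O")), max_k = 2)
  expect_true(all(lengths(strsplit(names(tab$counts), "\x1f")) == 2L))
  expect_length(mine_kmer_counts(list(), max_k = 6)$counts, 0L)
  expect_error(mine_kmer_counts(list(), max_k = 1), class = "smiclm_badarg")
})

test_that("vocabulary construction ranks by frequency within the size budget", {
  tab <- structure(list(counts = c("C\x1fC" = 5L, "C\x1fO" = 3L,
                                   "C\x1fC\x1fO" = 2L),
                        max_k = 3L, corpus_size = 2L), class = "kmer_table")
  v <- kmer_vocabulary(tab, c("C", "O"), target_size = 9L, min_count = 1L)
  expect_identical(v$tokens[8:9], c("CC", "CO"))
  expect_identical(v$n_kmer, 2L)
  # no room for k-mers
  v0 <- kmer_vocabulary(tab, c("C", "O"), target_size = 7L, min_count = 1L)
  expect_identical(v0$n_kmer, 0L)
  expect_error(kmer_vocabulary(tab, c("C", "O"), target_size = 5L),
               class = "smiclm_badarg")
})

test_that("strict validity filter drops candidates closing unopened branches", {
  tab <- structure(list(counts = c(")\x1fC" = 50L, "C\x1f(" = 40L,
                                   "C\x1f(\x1fC\x1f)" = 30L),
                        max_k = 4L, corpus_size = 1L), class = "kmer_table")
  v <- kmer_vocabulary(tab, c("C", "(", ")"), target_size = 20L,
                       min_count = 1L)
  expect_false(")C" %in% v$tokens)
  expect_true("C(" %in% v$tokens)      # net-open surplus is allowed
  expect_true("C(C)" %in% v$tokens)
  vp <- kmer_vocabulary(tab, c("C", "(", ")"), target_size = 20L,
                        min_count = 1L, validity = "permissive")
  expect_true(")C" %in% vp$tokens)
})

test_that("greedy encoding is longest-match and decodes back exactly", {
  tab <- structure(list(counts = c("C\x1fC" = 9L, "C\x1fO" = 8L,
                                   "C\x1fC\x1fO" = 7L),
                        max_k = 3L, corpus_size = 1L), class = "kmer_table")
  v_all <- kmer_vocabulary(tab, c("C", "O"), target_size = 10L, min_count = 1L)
  expect_identical(kmer_decode(kmer_encode("CCO", v_all), v_all), "CCO")
  expect_length(kmer_encode("CCO", v_all), 1L)  # whole-string k-mer wins
  # only 2-mers available: greedy takes CC then O
  tab2 <- structure(list(counts = c("C\x1fC" = 9L, "C\x1fO" = 8L),
                         max_k = 3L, corpus_size = 1L), class = "kmer_table")
  v2 <- kmer_vocabulary(tab2, c("C", "O"), target_size = 9L, min_count = 1L)
  ids <- kmer_encode("CCO", v2)
  expect_identical(v2$tokens[ids + 1L], c("CC", "O"))
  # no k-mers: token count equals primitive count
  v1 <- kmer_vocabulary(tab2, c("C", "O"), target_size = 7L, min_count = 1L)
  expect_length(kmer_encode("CCO", v1), 3L)
})

test_that("decode drops specials, handles empty input, rejects bad ids", {
  v <- tiny_vocab()
  ids <- kmer_encode("CC(=O)O", v, add_special = TRUE)
  expect_identical(ids[1], unname(v$specials[["[BOS]"]]))
  expect_identical(kmer_decode(ids, v), "CC(=O)O")
  expect_identical(kmer_decode(integer(0), v), "")
  expect_identical(kmer_decode(c(v$specials[["[PAD]"]],
                                 kmer_encode("CCO", v)), v), "CCO")
  expect_error(kmer_decode(999L, v), class = "smiclm_badid")
})

test_that("unknown primitives map to UNK with a warning, or error on demand", {
  v <- tiny_vocab()   # mined on C/N/O molecules only
  expect_warning(ids <- kmer_encode("CSC", v), "UNK")
  expect_true(v$specials[["[UNK]"]] %in% ids)
  expect_error(kmer_encode("CSC", v, unk = "error"), class = "smiclm_unk")
  expect_silent(kmer_encode("CSC", v, unk = "silent"))
})

test_that("specials are never produced from raw bracket text", {
  v <- tiny_vocab()
  ids <- kmer_encode("[PAD]", v, unk = "silent")
  expect_false(v$specials[["[PAD]"]] %in% ids)
  expect_identical(ids, as.integer(unname(v$specials[["[UNK]"]])))
})

test_that("emitted tokens re-pretokenize to contiguous primitive slices", {
  v <- toy_vocab()
  corpus <- toy_corpus()[seq(1, 400, by = 7)]
  for (s in corpus) {
    prims <- smi_pretokenize(s)$primitives
    ids <- kmer_encode(s, v, unk = "silent")
    toks <- v$tokens[ids + 1L]
    toks <- toks[!(toks %in% names(v$specials))]
    pos <- 1L
    for (tk in toks) {
      if (tk == v$tokens[v$specials[["[UNK]"]] + 1L]) { pos <- pos + 1L; next }
      seg <- smi_pretokenize(tk)$primitives
      expect_identical(prims[pos:(pos + length(seg) - 1L)], seg)
      pos <- pos + length(seg)
    }
    expect_identical(pos - 1L, length(prims))
  }
})

test_that("greedy stays close to the optimal DP segmentation", {
  # greedy can overshoot the minimum token count; the gap is measured
  # against the DP oracle and bounded.  On the small-molecule fixture
  # corpus the measured worst case is 6 tokens (under 6% of a sequence)
  # with a mean near 1.5; on peptide corpora, whose vocabularies align
  # with the repeating backbone, the gap is near zero.
  v <- toy_vocab()
  corpus <- toy_corpus()[seq(2, 400, by = 2)]
  gap <- vapply(corpus, function(s) {
    length(kmer_encode(s, v, unk = "silent")) -
      length(kmer_encode(s, v, method = "dp", unk = "silent"))
  }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(gap >= 0))     # DP is a true lower bound
  expect_lte(max(gap), 8)
  expect_lt(mean(gap), 3)
})

test_that("adding a k-mer never lengthens encodings under the DP oracle", {
  base_tab <- mine_kmer_counts(lapply(toy_corpus()[1:100], function(s) {
    smi_pretokenize(s)$primitives
  }), max_k = 6)
  prims <- unique(unlist(lapply(toy_corpus()[1:100], function(s) {
    smi_pretokenize(s)$primitives
  })))
  small <- kmer_vocabulary(base_tab, prims, target_size = length(prims) + 25L,
                           min_count = 2L)
  bigger <- kmer_vocabulary(base_tab, prims, target_size = length(prims) + 45L,
                            min_count = 2L)
  for (s in toy_corpus()[1:100]) {
    expect_lte(length(kmer_encode(s, bigger, method = "dp", unk = "silent")),
               length(kmer_encode(s, small, method = "dp", unk = "silent")))
  }
})

test_that("vocabulary JSON serialization round-trips ids, order and counts", {
  v <- toy_vocab()
  p <- tempfile(fileext = ".json")
  write_vocab(v, p)
  v2 <- read_vocab(p)
  expect_identical(v2$tokens, v$tokens)
  expect_identical(v2$is_kmer, v$is_kmer)
  expect_identical(v2$count, v$count)
  expect_identical(v2$max_k, v$max_k)
  expect_identical(unname(v2$specials), unname(v$specials))
  s <- toy_corpus()[5]
  expect_identical(kmer_encode(s, v2, unk = "silent"),
                   kmer_encode(s, v, unk = "silent"))
})

test_that("compression stats match the hand-computed single-molecule case", {
  tab <- structure(list(counts = c("C\x1fC\x1fO" = 7L, "C\x1fC" = 9L),
                        max_k = 3L, corpus_size = 1L), class = "kmer_table")
  v <- kmer_vocabulary(tab, c("C", "O"), target_size = 10L, min_count = 1L)
  cs <- compression_stats("CCO", v)
  expect_equal(cs$mean_reduction_percent, 100 * (1 - 1 / 3), tolerance = 1e-9)
  # a vocabulary with no k-mers compresses nothing
  v0 <- kmer_vocabulary(tab, c("C", "O"), target_size = 7L, min_count = 99L)
  expect_identical(v0$n_kmer, 0L)
  expect_equal(compression_stats(c("CCO", "COC"), v0)$per_molecule, c(0, 0))
})
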
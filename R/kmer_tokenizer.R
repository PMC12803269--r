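# Frequency-mined k-mer tokenizer over atom-level primitives: candidate
# mining, vocabulary construction, greedy longest-match encoding (with an
# optimal dynamic-programming mode used as an oracle), and JSON serialization.

.SPECIALS <- c("[PAD]", "[MASK]", "[UNK]", "[BOS]", "[EOS]")
.KSEP <- "\x1f"  # internal key separator; never occurs in SMILES

# Normalize corpus input to a list of primitive character vectors.
.as_primitive_corpus <- function(corpus) {
  if (is.character(corpus)) return(.pretokenize_all(corpus))
  lapply(corpus, function(x) {
    if (inherits(x, "primitive_seq")) x$primitives else as.character(x)
  })
}

#' Mine contiguous k-mer counts from a primitive corpus
#'
#' Counts every contiguous window of 2..`max_k` primitives across the corpus
#' (overlapping windows all count).  The resulting table is the raw material
#' for [kmer_vocabulary()].
#'
#' @param corpus Character vector of SMILES strings, or a list of
#'   `primitive_seq` objects / primitive character vectors.
#' @param max_k Maximum k-mer length in primitives (default 6).
#' @return A `kmer_table`: list with `counts` (named integer vector, names are
#'   primitive tuples joined by an internal separator), `max_k`,
#'   `corpus_size`.
#' @export
mine_kmer_counts <- function(corpus, max_k = 6L) {
  max_k <- as.integer(max_k)
  if (max_k < 2L) stop_smiclm("max_k must be >= 2", "smiclm_badarg")
  prim <- .as_primitive_corpus(corpus)
  keys <- vector("list", max_k - 1L)
  for (k in 2:max_k) {
    kk <- lapply(prim, function(p) {
      L <- length(p)
      if (L < k) return(character(0))
      cols <- lapply(0:(k - 1L), function(j) p[(1L + j):(L - k + 1L + j)])
      do.call(paste, c(cols, sep = .KSEP))
    })
    keys[[k - 1L]] <- unlist(kk, use.names = FALSE)
  }
  keys <- unlist(keys, use.names = FALSE)
  if (length(keys) == 0L) {
    counts <- integer(0)
  } else {
    r <- rle(sort(keys, method = "radix"))
    counts <- r$lengths
    names(counts) <- r$values
  }
  structure(list(counts = counts, max_k = max_k, corpus_size = length(prim)),
            class = "kmer_table")
}

# Chemical-validity filter for k-mer candidates.  strict: reading the tuple
# left to right, branch parentheses never close more than they opened (a net
# surplus of opens is allowed, so motifs like "N[C@@H](" survive).
# permissive: no structural constraint.
.kmer_valid <- function(tuples, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (mode == "permissive") return(rep(TRUE, length(tuples)))
  vapply(tuples, function(tp) {
    bal <- 0L
    for (p in tp) {
      if (p == "(") bal <- bal + 1L
      else if (p == ")") { bal <- bal - 1L; if (bal < 0L) return(FALSE) }
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Build a k-mer vocabulary from mined counts
#'
#' The vocabulary is the union of the five special tokens, every observed
#' single primitive, and the highest-count k-mer candidates that pass the
#' validity filter and the `min_count` threshold, truncated so the total size
#' equals `target_size` (or less if candidates run out).  The default target
#' of 405 tokens mirrors the compact vocabulary size this tokenizer family is
#' typically run at.
#'
#' @param table A `kmer_table` from [mine_kmer_counts()].
#' @param primitives Character vector of all single primitives to include.
#' @param target_size Total vocabulary size including specials (default 405).
#' @param min_count Minimum corpus count for a k-mer candidate (default 10).
#' @param validity `"strict"` (default) or `"permissive"` candidate filter.
#' @return A `kmer_vocab` object.
#' @export
kmer_vocabulary <- function(table, primitives, target_size = 405L,
                            min_count = 10L,
                            validity = c("strict", "permissive")) {
  validity <- match.arg(validity)
  stopifnot(inherits(table, "kmer_table"))
  singles <- sort(unique(as.character(primitives)))
  floor_size <- length(.SPECIALS) + length(singles)
  if (target_size < floor_size) {
    stop_smiclm(sprintf(
      "target_size %d below specials + single primitives (%d)",
      target_size, floor_size), "smiclm_badarg")
  }
  cnt <- table$counts
  cnt <- cnt[cnt >= min_count]
  tuples <- strsplit(names(cnt), .KSEP, fixed = TRUE)
  keep <- .kmer_valid(tuples, validity)
  cnt <- cnt[keep]; tuples <- tuples[keep]
  text <- vapply(tuples, paste0, character(1), collapse = "")
  # deterministic ranking: count desc, then token text
  ord <- order(-cnt, text, method = "radix")
  cnt <- cnt[ord]; text <- text[ord]
  dup <- duplicated(text) | text %in% singles | text %in% .SPECIALS
  cnt <- cnt[!dup]; text <- text[!dup]
  room <- target_size - floor_size
  n_kmer <- min(room, length(text))
  kmers <- text[seq_len(n_kmer)]
  kcounts <- unname(cnt[seq_len(n_kmer)])
  tokens <- c(.SPECIALS, singles, kmers)
  vocab <- structure(list(
    tokens = tokens,
    is_kmer = c(rep(FALSE, length(.SPECIALS) + length(singles)),
                rep(TRUE, n_kmer)),
    count = c(rep(NA_integer_, length(.SPECIALS) + length(singles)), kcounts),
    specials = stats::setNames(0:(length(.SPECIALS) - 1L), .SPECIALS),
    n_single = length(singles),
    n_kmer = n_kmer,
    max_k = table$max_k,
    version = 1L
  ), class = "kmer_vocab")
  vocab
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf(
    "<kmer_vocab> %d tokens (%d specials, %d single-primitive, %d k-mer), max_k=%d\n",
    length(x$tokens), length(x$specials), x$n_single, x$n_kmer, x$max_k))
  invisible(x)
}

# token -> 0-based id environment, cached on the vocab's own environment-free
# structure via an attribute-less memo table keyed by identity is not possible
# for plain lists, so we just rebuild cheaply when not supplied.
.vocab_map <- function(vocab) {
  env <- new.env(parent = emptyenv(), size = length(vocab$tokens) * 2L)
  for (i in seq_along(vocab$tokens)) {
    assign(vocab$tokens[i], i - 1L, envir = env)
  }
  env
}

#' Encode a SMILES string to token ids
#'
#' Pretokenizes the string into primitives and segments them with greedy
#' longest-match, left to right, against the vocabulary (`method = "greedy"`,
#' the default inference rule), or with an optimal dynamic program minimizing
#' the token count (`method = "dp"`, used as a segmentation oracle).  A
#' primitive absent from the vocabulary maps to `[UNK]` with a warning
#' (`unk = "warn"`) or an error (`unk = "error"`).
#'
#' @param smiles A single SMILES string.
#' @param vocab A `kmer_vocab`.
#' @param add_special Wrap the ids in `[BOS]`/`[EOS]` (default FALSE).
#' @param method `"greedy"` or `"dp"`.
#' @param unk `"warn"` (default), `"error"`, or `"silent"`.
#' @param map Optional precomputed lookup from `.vocab_map()` (internal).
#' @return Integer vector of 0-based token ids.
#' @export
kmer_encode <- function(smiles, vocab, add_special = FALSE,
                        method = c("greedy", "dp"), unk = c("warn", "error", "silent"),
                        map = NULL) {
  method <- match.arg(method)
  unk <- match.arg(unk)
  prims <- if (inherits(smiles, "primitive_seq")) smiles$primitives else
    .pretokenize1(smiles)
  if (is.null(map)) map <- .vocab_map(vocab)
  ids <- if (method == "greedy") {
    .segment_greedy(prims, map, vocab$max_k, unk, vocab)
  } else {
    .segment_dp(prims, map, vocab$max_k, unk, vocab)
  }
  if (add_special) {
    ids <- c(vocab$specials[["[BOS]"]], ids, vocab$specials[["[EOS]"]])
  }
  as.integer(ids)
}

.unk_id <- function(vocab) vocab$specials[["[UNK]"]]

.segment_greedy <- function(prims, map, max_k, unk, vocab) {
  nspec <- length(vocab$specials)
  L <- length(prims)
  ids <- integer(0)
  i <- 1L
  while (i <= L) {
    hit <- NA_integer_
    for (k in min(max_k, L - i + 1L):1L) {
      key <- paste0(prims[i:(i + k - 1L)], collapse = "")
      id <- get0(key, envir = map, inherits = FALSE)
      # special tokens are never produced from raw text
      if (!is.null(id) && id < nspec) id <- NULL
      if (!is.null(id)) { hit <- id; i <- i + k; break }
    }
    if (is.na(hit)) {
      if (unk == "error") {
        stop_smiclm(sprintf("primitive '%s' not in vocabulary", prims[i]),
                    "smiclm_unk")
      }
      if (unk == "warn") {
        warning(sprintf("primitive '%s' not in vocabulary; mapped to [UNK]",
                        prims[i]))
      }
      hit <- .unk_id(vocab)
      i <- i + 1L
    }
    ids <- c(ids, hit)
  }
  ids
}

# Minimal-token-count segmentation (ties broken toward longer first piece),
# the oracle against which greedy is compared in the property suite.
.segment_dp <- function(prims, map, max_k, unk, vocab) {
  nspec <- length(vocab$specials)
  L <- length(prims)
  if (L == 0L) return(integer(0))
  best <- rep(Inf, L + 1L); best[L + 1L] <- 0
  choice <- integer(L)
  for (i in L:1L) {
    for (k in 1:min(max_k, L - i + 1L)) {
      key <- paste0(prims[i:(i + k - 1L)], collapse = "")
      id <- get0(key, envir = map, inherits = FALSE)
      if (!is.null(id) && id < nspec) id <- NULL
      cost <- if (!is.null(id)) 1 else if (k == 1L) 1 else Inf
      if (is.finite(cost) && cost + best[i + k + 0L] < best[i]) {
        best[i] <- cost + best[i + k]
        choice[i] <- k
      }
    }
  }
  ids <- integer(0)
  i <- 1L
  while (i <= L) {
    k <- choice[i]
    key <- paste0(prims[i:(i + k - 1L)], collapse = "")
    id <- get0(key, envir = map, inherits = FALSE)
    if (!is.null(id) && id < nspec) id <- NULL
    if (is.null(id)) {
      if (unk == "error") {
        stop_smiclm(sprintf("primitive '%s' not in vocabulary", prims[i]),
                    "smiclm_unk")
      }
      if (unk == "warn") {
        warning(sprintf("primitive '%s' not in vocabulary; mapped to [UNK]",
                        prims[i]))
      }
      id <- .unk_id(vocab)
    }
    ids <- c(ids, id)
    i <- i + k
  }
  ids
}

#' Decode token ids back to a SMILES string
#'
#' Concatenates the token strings, dropping special tokens.  For any string
#' whose primitives are all in the vocabulary,
#' `kmer_decode(kmer_encode(s, v), v) == s`.
#'
#' @param ids Integer vector of 0-based token ids.
#' @param vocab A `kmer_vocab`.
#' @return A SMILES string.
#' @export
kmer_decode <- function(ids, vocab) {
  if (length(ids) == 0L) return("")
  ids <- as.integer(ids)
  if (any(ids < 0L | ids >= length(vocab$tokens))) {
    stop_smiclm("token id out of range", "smiclm_badid")
  }
  toks <- vocab$tokens[ids + 1L]
  paste0(toks[!(toks %in% .SPECIALS)], collapse = "")
}

#' Token-count compression statistics
#'
#' For each molecule, the percent reduction in sequence length of the k-mer
#' encoding relative to atom-level primitive tokenization,
#' `100 * (1 - n_tokens / n_primitives)` (special tokens excluded), plus the
#' corpus mean.
#'
#' @param corpus Character vector of SMILES strings.
#' @param vocab A `kmer_vocab`.
#' @return List with `mean_reduction_percent` and `per_molecule` (numeric
#'   vector).
#' @export
compression_stats <- function(corpus, vocab) {
  if (length(corpus) == 0L) stop_smiclm("empty corpus", "smiclm_badarg")
  map <- .vocab_map(vocab)
  per <- vapply(corpus, function(s) {
    prims <- .pretokenize1(s)
    ids <- kmer_encode(prims_seq(prims, s), vocab, map = map)
    100 * (1 - length(ids) / length(prims))
  }, numeric(1), USE.NAMES = FALSE)
  list(mean_reduction_percent = mean(per), per_molecule = per)
}

# internal constructor avoiding re-tokenization
prims_seq <- function(prims, src) {
  structure(list(primitives = prims, source = src), class = "primitive_seq")
}

#' Write a vocabulary to JSON
#'
#' @param vocab A `kmer_vocab`.
#' @param path Output path.
#' @export
write_vocab <- function(vocab, path) {
  obj <- list(
    version = vocab$version,
    max_k = vocab$max_k,
    specials = as.list(vocab$specials),
    tokens = data.frame(
      text = vocab$tokens,
      id = seq_along(vocab$tokens) - 1L,
      is_kmer = vocab$is_kmer,
      count = vocab$count,
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a vocabulary from JSON
#'
#' @param path Path to a vocabulary JSON file written by [write_vocab()].
#' @return A `kmer_vocab`.
#' @export
read_vocab <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tok <- obj$tokens
  ord <- order(tok$id)
  tok <- tok[ord, , drop = FALSE]
  structure(list(
    tokens = tok$text,
    is_kmer = as.logical(tok$is_kmer),
    count = suppressWarnings(as.integer(tok$count)),
    specials = unlist(obj$specials),
    n_single = sum(!tok$is_kmer) - length(obj$specials),
    n_kmer = sum(tok$is_kmer),
    max_k = as.integer(obj$max_k),
    version = as.integer(obj$version)
  ), class = "kmer_vocab")
}
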
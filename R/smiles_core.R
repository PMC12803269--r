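# SMILES string services: the atom-level pre-tokenizer, lexical validation,
# canonicalization and atom-order randomization through the OpenBabel backend,
# and .smi line-file I/O.

# Primitive grammar: a bracket expression "[...]", a two-letter halogen, a
# %nn ring closure, or any single character (organic-subset atoms, bonds,
# branch parentheses, ring digits, dots).
.PRIM_RE <- "\\[[^]]*\\]|Cl|Br|%[0-9][0-9]|."

# Organic-subset / aromatic single-letter atom symbols (Cl, Br and bracket
# atoms are matched before single characters).
.ORGANIC_ATOMS <- c("B", "C", "N", "O", "P", "S", "F", "I",
                    "b", "c", "n", "o", "p", "s")

#' Split a SMILES string into atom-level primitives
#'
#' Segments a SMILES string into the smallest indivisible lexical units:
#' bracket atom expressions (`[C@@H]`, `[N+]`, ...), the two-letter halogens
#' `Cl` and `Br`, `%nn` ring closures, and single characters for everything
#' else (organic-subset atoms, bond symbols, branch parentheses, ring digits,
#' dots).  The concatenation of the primitives always equals the input.
#'
#' The input need not be chemically valid; validity is only checked at
#' [smi_canonicalize()].  Lexically malformed input (an unterminated `[`, or
#' a `%` not followed by two digits) raises an error naming the byte offset.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `primitive_seq`: a list with elements
#'   `primitives` (character vector) and `source` (the input string).
#' @examples
#' smi_pretokenize("C[C@@H](N)C(=O)O")$primitives
#' @export
smi_pretokenize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop_smiclm("smiles must be a single non-empty string", "smiclm_malformed")
  }
  prims <- .pretokenize1(smiles)
  structure(list(primitives = prims, source = smiles), class = "primitive_seq")
}

.pretokenize1 <- function(s) {
  m <- gregexpr(.PRIM_RE, s, perl = TRUE)[[1L]]
  prims <- regmatches(s, list(m))[[1L]]
  bad <- which(prims == "[" | prims == "%")
  if (length(bad)) {
    off <- m[bad[1L]]
    what <- if (prims[bad[1L]] == "[") "unterminated bracket '['" else
      "'%' ring closure without two digits"
    stop_smiclm(sprintf("malformed SMILES: %s at offset %d", what, off),
                "smiclm_malformed")
  }
  prims
}

# Fast path used internally: list of primitive vectors, no class wrapper.
.pretokenize_all <- function(smiles) lapply(smiles, .pretokenize1)

#' @export
print.primitive_seq <- function(x, ...) {
  cat("<primitive_seq> ", length(x$primitives), " primitives: ",
      paste(x$primitives, collapse = " | "), "\n", sep = "")
  invisible(x)
}

# TRUE for primitives that denote an atom (bracket expression, halogen,
# organic-subset letter).  Vectorized over a primitive character vector.
is_atom_primitive <- function(prims) {
  startsWith(prims, "[") | prims %in% c("Cl", "Br") | prims %in% .ORGANIC_ATOMS
}

# Lexical structure checks that the lenient backend parser does not enforce:
# branch parentheses balanced and never negative, no empty "()" branches,
# every ring-closure label opened an even number of times, brackets
# well-formed (guaranteed by pretokenization), string does not end on an
# opening bond.  Returns NULL if OK, otherwise a reason string.
.lexical_problem <- function(smiles) {
  prims <- tryCatch(.pretokenize1(smiles), error = function(e) NULL)
  if (is.null(prims)) return("malformed")
  depth <- 0L
  prev <- ""
  ring <- integer(0)
  for (p in prims) {
    if (p == "(") {
      depth <- depth + 1L
    } else if (p == ")") {
      if (prev == "(") return("empty_branch")
      depth <- depth - 1L
      if (depth < 0L) return("unbalanced_parens")
    } else if (grepl("^[0-9]$|^%[0-9][0-9]$", p)) {
      lab <- sub("^%", "", p)
      ring[lab] <- (if (is.na(ring[lab])) 0L else ring[lab]) + 1L
    }
    prev <- p
  }
  if (depth != 0L) return("unbalanced_parens")
  if (length(ring) && any(ring %% 2L != 0L)) return("unpaired_ring_closure")
  if (prims[length(prims)] %in% c("=", "#", "-", "/", "\\", ".", "(")) {
    return("dangling_symbol")
  }
  NULL
}

# One batched OpenBabel format conversion with index-based realignment, so a
# molecule the backend drops cannot shift later records.  Returns a character
# vector aligned with `smiles`, NA where conversion failed.
.ob_convert <- function(smiles, to = "CAN") {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  src <- paste0(smiles, " smiclm", seq_len(n), collapse = "\n")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", to, source = src),
    error = function(e) ""
  )
  res <- rep(NA_character_, n)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(parts) >= 2L && grepl("^smiclm[0-9]+$", parts[2L])) {
      idx <- as.integer(sub("^smiclm", "", parts[2L]))
      if (nzchar(parts[1L])) res[idx] <- parts[1L]
    }
  }
  res
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the backend's unique canonical form, used throughout for
#' molecule identity, deduplication and equality.  Canonicalization is
#' idempotent: `smi_canonicalize(smi_canonicalize(s)) == smi_canonicalize(s)`.
#'
#' A string is rejected (returned as `NA`) when it is lexically malformed
#' (unterminated bracket, unbalanced branch parentheses, unpaired ring
#' closures) or when the chemistry backend cannot parse it.  Rejection
#' reasons are attached as the `"reason"` attribute (`"invalid_smiles"` or
#' `NA` for kept entries).
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where rejected, with a
#'   `"reason"` attribute.
#' @examples
#' smi_canonicalize(c("OCC", "CCO", "C("))
#' @export
smi_canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  res <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(smiles)
  ok[ok] <- vapply(smiles[ok], function(s) is.null(.lexical_problem(s)),
                   logical(1))
  if (any(ok)) res[ok] <- .ob_convert(smiles[ok], "CAN")
  attr(res, "reason") <- ifelse(is.na(res), "invalid_smiles", NA_character_)
  res
}

# Rooted SMILES rewriting via the obabel CLI: re-emit each molecule with the
# given 1-based input atom as the first atom of the output string.  Molecules
# the tool cannot re-root keep their input string.
.ob_rooted <- function(smiles, roots) {
  stopifnot(length(smiles) == length(roots))
  res <- smiles
  for (r in unique(roots)) {
    idx <- which(roots == r)
    fin <- tempfile(fileext = ".smi")
    fout <- tempfile(fileext = ".smi")
    writeLines(paste0(smiles[idx], " smiclm", idx), fin)
    status <- suppressWarnings(system2(
      "obabel", c(fin, "-osmi", "-xf", as.character(r), "-O", fout),
      stdout = FALSE, stderr = FALSE
    ))
    if (identical(status, 0L) && file.exists(fout)) {
      lines <- readLines(fout, warn = FALSE)
      for (ln in lines) {
        parts <- strsplit(trimws(ln), "[ \t]+")[[1L]]
        if (length(parts) >= 2L && grepl("^smiclm[0-9]+$", parts[2L]) &&
            nzchar(parts[1L])) {
          res[as.integer(sub("^smiclm", "", parts[2L]))] <- parts[1L]
        }
      }
    }
    unlink(c(fin, fout))
  }
  res
}

#' Randomize the atom order of a SMILES string
#'
#' Rewrites a valid SMILES string starting from a randomly selected root atom,
#' producing an alternative string representation of the same molecule (the
#' canonical forms are equal).  Used as dynamic data augmentation during
#' pretraining so the model sees many valid spellings of each molecule.
#' The same `(smiles, seed)` pair always yields the same output.
#'
#' @param smiles A single valid SMILES string.
#' @param seed Integer seed for root-atom selection.
#' @return A SMILES string describing the same molecule.
#' @export
smi_randomize <- function(smiles, seed) {
  can <- smi_canonicalize(smiles)
  if (is.na(can[1L])) {
    stop_smiclm("cannot randomize an invalid SMILES string", "smiclm_invalid")
  }
  root <- with_seed(seed, .sample_root(.pretokenize1(smiles)))
  if (root <= 1L) return(smiles)
  out <- .ob_rooted(smiles, root)
  # the backend occasionally cannot re-root without information loss
  # (e.g. stereo on the would-be first atom); fall back to the input
  if (is.na(out) || !identical(unname(smi_canonicalize(out)[1L]), unname(can[1L]))) {
    return(smiles)
  }
  out
}

# Draw a root-atom index for re-rooting: a random atom, excluding atoms with
# stereo marks (the backend drops chirality written on the first atom).
# Returns 1 when there is no usable alternative root.
.sample_root <- function(prims) {
  atom_idx <- which(is_atom_primitive(prims))
  usable <- which(!grepl("@", prims[atom_idx], fixed = TRUE))
  usable <- usable[usable <= 12L]  # cap root depth; keeps batching cheap
  if (length(usable) <= 1L) return(1L)
  usable[sample.int(length(usable), 1L)]
}

#' Randomize a whole corpus of SMILES strings
#'
#' Batched variant of [smi_randomize()]: one root draw per molecule under a
#' single seed, with a canonical-equivalence check (molecules that cannot be
#' safely re-rooted keep their input spelling).
#'
#' @param smiles Character vector of valid SMILES strings.
#' @param seed Integer seed.
#' @return Character vector of alternative spellings, same molecules.
#' @export
smi_randomize_all <- function(smiles, seed) {
  with_seed(seed, .randomize_corpus(smiles))
}

# Vectorized corpus randomization used by the pretraining loop: one root draw
# per molecule from the current RNG stream, batched per distinct root, with a
# batched canonical-equivalence check and fallback to the input string.
.randomize_corpus <- function(smiles, prim_list = NULL) {
  if (is.null(prim_list)) prim_list <- .pretokenize_all(smiles)
  roots <- vapply(prim_list, .sample_root, integer(1))
  out <- .ob_rooted(smiles, roots)
  changed <- which(out != smiles)
  if (length(changed)) {
    ok <- smi_canonicalize(out[changed]) == smi_canonicalize(smiles[changed])
    revert <- changed[is.na(ok) | !ok]
    out[revert] <- smiles[revert]
  }
  out
}

#' Read a .smi line file
#'
#' One record per line, `SMILES[<tab or space>ID]`; lines starting with `#`
#' and blank lines are ignored.
#'
#' @param path Path to a .smi file.
#' @return A data.frame with columns `smiles` and `id` (`NA` when absent).
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a .smi line file
#'
#' @param smiles Character vector of SMILES strings.
#' @param path Output path.
#' @param id Optional character vector of identifiers.
#' @export
write_smi <- function(smiles, path, id = NULL) {
  lines <- if (is.null(id)) smiles else paste(smiles, id, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
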
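# Corpus curation: the small-molecule filter cascade, peptide confidence
# filters and cluster-representative selection, and balanced epoch sampling.

.SALT_FRAGMENTS <- c("Br", "Cl", "[Br-]", "[Cl-]", "[Br]", "[Cl]")

# String-level silicon patterns (configurable): a "silicon chain" is two Si
# atoms bonded directly or through one bridging O; the "silicon oxide
# polymer" is the repeating [Si](=O)[Si](=O) motif.
.SI_CHAIN_PATTERNS <- c(
  "\\[Si[^]]*\\]\\[Si",        # Si-Si
  "\\[Si[^]]*\\]O\\[Si"        # Si-O-Si
)
.SI_OXIDE_PATTERN <- "\\[Si[^]]*\\]\\(=O\\)\\[Si[^]]*\\]\\(=O\\)"

#' Apply the small-molecule filter cascade to one raw SMILES record
#'
#' Rules are applied in a fixed order: (1) reject strings shorter than 20
#' characters; (2) reject silicon chains (Si-Si or Si-O-Si); (3) reject
#' repeating silicon-oxide polymer motifs (`[Si](=O)[Si](=O)`); (4) strip
#' leading/trailing dot-separated fragments that are bare Br/Cl salts (neutral
#' or bracket/ionic spellings); (5) split the remaining dot-separated
#' components into independent entries; (6) canonicalize each, dropping
#' failures.  The length threshold applies to the raw string, before
#' stripping.
#'
#' @param raw A single raw SMILES string.
#' @param si_chain_patterns,si_oxide_pattern Regular expressions for the
#'   silicon rules (overridable).
#' @return A `curation_decision`: list with `kept` (logical), `reason` (one of
#'   `too_short`, `silicon_chain`, `silicon_oxide_polymer`, `invalid_smiles`,
#'   `kept`), and `emitted` (character vector of canonical SMILES, empty
#'   unless kept).
#' @export
filter_small_molecule <- function(raw,
                                  si_chain_patterns = .SI_CHAIN_PATTERNS,
                                  si_oxide_pattern = .SI_OXIDE_PATTERN) {
  stopifnot(is.character(raw), length(raw) == 1L)
  decision <- function(kept, reason, emitted = character(0)) {
    structure(list(kept = kept, reason = reason, emitted = emitted),
              class = "curation_decision")
  }
  if (is.na(raw) || nchar(raw) < 20L) return(decision(FALSE, "too_short"))
  if (any(vapply(si_chain_patterns, grepl, logical(1), x = raw))) {
    return(decision(FALSE, "silicon_chain"))
  }
  if (grepl(si_oxide_pattern, raw)) {
    return(decision(FALSE, "silicon_oxide_polymer"))
  }
  frags <- strsplit(raw, ".", fixed = TRUE)[[1L]]
  while (length(frags) && frags[1L] %in% .SALT_FRAGMENTS) {
    frags <- frags[-1L]
  }
  while (length(frags) && frags[length(frags)] %in% .SALT_FRAGMENTS) {
    frags <- frags[-length(frags)]
  }
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) return(decision(FALSE, "invalid_smiles"))
  can <- smi_canonicalize(frags)
  can <- can[!is.na(can)]
  if (length(can) == 0L) return(decision(FALSE, "invalid_smiles"))
  decision(TRUE, "kept", unname(can))
}

#' @export
print.curation_decision <- function(x, ...) {
  cat(sprintf("<curation_decision> %s (%s)%s\n",
              if (x$kept) "kept" else "rejected", x$reason,
              if (length(x$emitted)) paste0(": ", paste(x$emitted, collapse = " , "))
              else ""))
  invisible(x)
}

#' Curate a stream of raw small-molecule SMILES
#'
#' Runs [filter_small_molecule()] over every record, pools the emitted
#' entries, and deduplicates on canonical SMILES.  The stats histogram counts
#' every rejection reason plus duplicates removed.
#'
#' @param records Character vector of raw SMILES strings.
#' @return List with `kept` (character vector of unique canonical SMILES) and
#'   `stats` (named integer vector: too_short, silicon_chain,
#'   silicon_oxide_polymer, invalid_smiles, kept, duplicate).
#' @export
curate_small_molecules <- function(records) {
  reasons <- c("too_short", "silicon_chain", "silicon_oxide_polymer",
               "invalid_smiles", "kept")
  stats <- stats::setNames(integer(length(reasons) + 1L),
                           c(reasons, "duplicate"))
  emitted <- vector("list", length(records))
  for (i in seq_along(records)) {
    d <- filter_small_molecule(records[i])
    stats[d$reason] <- stats[d$reason] + 1L
    emitted[[i]] <- d$emitted
  }
  all_emitted <- unlist(emitted, use.names = FALSE)
  kept <- unique(all_emitted)
  stats["duplicate"] <- length(all_emitted) - length(kept)
  list(kept = kept, stats = stats)
}

#' Peptide confidence filter
#'
#' Keeps records with pTM > 0.7, pLDDT > 0.7 (both strict) and sequence
#' length at most 100 residues (inclusive).
#'
#' @param records Data frame with columns `sequence`, `pTM`, `pLDDT`.
#' @return Logical vector, TRUE for records passing the filter.
#' @export
filter_peptide_records <- function(records) {
  stopifnot(all(c("sequence", "pTM", "pLDDT") %in% names(records)))
  records$pTM > 0.7 & records$pLDDT > 0.7 & nchar(records$sequence) <= 100L
}

#' Select a cluster representative
#'
#' Returns the member with the highest product of pTM and pLDDT; exact ties
#' are broken by earliest input position.
#'
#' @param members Data frame of peptide records (columns `pTM`, `pLDDT`).
#' @return The selected row (single-row data frame).
#' @export
select_representative <- function(members) {
  if (is.null(members) || nrow(members) == 0L) {
    stop_smiclm("cannot select a representative from an empty cluster",
                "smiclm_badarg")
  }
  score <- members$pTM * members$pLDDT
  members[which.max(score), , drop = FALSE]
}

#' Build a balanced epoch sample
#'
#' Deterministically assembles one training epoch from per-source pools:
#' lipid-like entries are repeated `lipid_upsample` times, peptides are
#' included in full, and small molecules are downsampled without replacement
#' to `sizes[["small_molecule"]]`.  The combined list is shuffled with the
#' seeded generator; the same seed always reproduces the same sample.
#'
#' @param pools Named list of character vectors (`small_molecule`, `peptide`,
#'   `lipid`; any subset).
#' @param sizes Named integer vector; currently only `small_molecule` is
#'   consulted (defaults to the full pool).
#' @param lipid_upsample Upsampling factor for the lipid pool (default 5).
#' @param seed Integer seed.
#' @return An `epoch_sample`: list with `entries` (data.frame smiles, source),
#'   `composition` (named counts), `seed`.
#' @export
build_epoch_sample <- function(pools, sizes = NULL, lipid_upsample = 5L,
                               seed = 1L) {
  with_seed(seed, {
    parts <- list()
    for (src in names(pools)) {
      pool <- pools[[src]]
      take <- if (src == "lipid") {
        rep(pool, times = lipid_upsample)
      } else if (!is.null(sizes) && src %in% names(sizes) &&
                 !is.na(sizes[[src]])) {
        sz <- as.integer(sizes[[src]])
        if (sz > length(pool)) {
          stop_smiclm(sprintf(
            "requested %d entries from source '%s' but pool has %d",
            sz, src, length(pool)), "smiclm_badarg")
        }
        pool[sample.int(length(pool), sz)]
      } else {
        pool
      }
      if (length(take)) {
        parts[[src]] <- data.frame(smiles = take, source = src,
                                   stringsAsFactors = FALSE)
      }
    }
    entries <- do.call(rbind, unname(parts))
    entries <- entries[sample.int(nrow(entries)), , drop = FALSE]
    rownames(entries) <- NULL
    structure(list(entries = entries,
                   composition = table(entries$source),
                   seed = seed),
              class = "epoch_sample")
  })
}

#' Read peptide sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return Data frame with columns `id` and `sequence`.
#' @export
read_peptide_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_smiclm("the Biostrings package is required to read FASTA files",
                "smiclm_dependency")
  }
  aa <- Biostrings::readAAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(aa)),
             sequence = as.character(aa),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a peptide score table
#'
#' Tab-separated columns `id`, `pTM`, `pLDDT` and optional `cluster_id`, as
#' produced by an external clustering tool.
#'
#' @param path Path to a TSV file with a header row.
#' @return Data frame.
#' @export
read_peptide_scores <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
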
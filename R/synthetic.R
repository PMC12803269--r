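# Synthetic data generation: drug-like small-molecule SMILES from a fragment
# grammar, peptide corpora with light modifications, a curation fixture with
# hand-verified expected outcomes, and labeled tasks whose signal is a known
# function of computable descriptors.  Every generator is deterministic in
# its seed.

# Fragment grammar.  Units are string fragments that keep the growing chain
# lexically and chemically valid: starters begin a molecule, chain units
# extend it, terminals may end it.  Rings are closed within a unit (labels
# 1/2) or wrap the whole backbone (%10).
.SM_STARTERS <- c("C", "CC", "CO", "CN", "c1ccccc1", "C1CCCCC1")
.SM_CHAIN <- c("C", "C", "CC", "CCC", "CO", "CN", "C(C)", "C(C)C", "C(=O)",
               "CS", "C=C", "C(F)", "C(Cl)", "C(Br)", "c1ccccc1", "c1ccncc1",
               "C1CCCCC1", "C1CCNCC1", "c1ccc2ccccc2c1", "[C@@H](C)C",
               "[C@H](O)C", "/C=C/C", "OC(=O)", "N(C)", "OC", "C#C")
.SM_TERMINALS <- c("", "", "O", "N", "C#N", "C(=O)O", "C(=O)N", "F", "Cl",
                   "Br", "C(=O)OC", "S(=O)(=O)N", "[N+](C)(C)C", "C(=O)[O-]")

#' Generate synthetic drug-like small-molecule SMILES
#'
#' Grammar-based assembly from a curated fragment set, guaranteeing lexical
#' and chemical validity without a rejection loop.  A small fraction of
#' molecules are wrapped into `%10` macrocycles.  Output is deduplicated and
#' deterministic in the seed.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param length_range Target character-length range, default c(20, 80).
#' @return Character vector of `n` unique valid SMILES strings.
#' @export
gen_small_molecules <- function(n, seed = 1L, length_range = c(20L, 80L)) {
  if (n == 0L) return(character(0))
  with_seed(seed, {
    out <- character(0)
    guard <- 0L
    while (length(out) < n && guard < 50L * n) {
      guard <- guard + 1L
      target <- stats::runif(1, length_range[1L], length_range[2L])
      macro <- stats::runif(1) < 0.08
      s <- sample(.SM_STARTERS, 1L)
      while (nchar(s) < target - 6L) {
        s <- paste0(s, sample(.SM_CHAIN, 1L))
      }
      s <- if (macro) paste0("C%10", s, "C%10") else
        paste0(s, sample(.SM_TERMINALS, 1L))
      if (!(s %in% out)) out <- c(out, s)
    }
    out[seq_len(min(n, length(out)))]
  })
}

#' Generate a synthetic peptide corpus
#'
#' Random sequences over the 20 canonical residues converted with
#' [peptide_to_smiles()]; a fraction `mod_rate` receive a modification
#' (head-to-tail cyclization or backbone N-methylation, split evenly).
#' Synthetic structure-confidence scores pTM and pLDDT are drawn
#' Uniform(0.4, 1.0), independently — they exercise the confidence filters,
#' not structural realism.
#'
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @param len_range Residue-length range within [2, 100] (default c(5, 50)).
#' @param mod_rate Fraction modified (default 0).
#' @return Data frame with columns `sequence`, `smiles`, `length`,
#'   `modification` (none/cyclic/n_methyl), `pTM`, `pLDDT`.
#' @export
gen_peptide_corpus <- function(n, seed = 1L, len_range = c(5L, 50L),
                               mod_rate = 0) {
  stopifnot(len_range[1L] >= 2L, len_range[2L] <= 100L)
  with_seed(seed, {
    lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste0(sample(residue_alphabet(), L, replace = TRUE), collapse = "")
    }, character(1))
    mod <- rep("none", n)
    midx <- which(stats::runif(n) < mod_rate)
    if (length(midx)) {
      mod[midx] <- sample(c("cyclic", "n_methyl"), length(midx),
                          replace = TRUE)
    }
    smiles <- character(n)
    for (i in seq_len(n)) {
      smiles[i] <- switch(mod[i],
        none = peptide_to_smiles(seqs[i], validate = FALSE),
        cyclic = peptide_to_smiles(seqs[i], cyclic = TRUE, validate = FALSE),
        n_methyl = {
          # avoid proline and position 1 (keep the free N-terminus)
          ok <- which(strsplit(seqs[i], "")[[1L]] != "P")
          ok <- ok[ok > 1L]
          pos <- if (length(ok)) ok[sample.int(length(ok), 1L)] else integer(0)
          peptide_to_smiles(seqs[i], n_methyl_positions = pos,
                            validate = FALSE)
        })
    }
    data.frame(sequence = seqs, smiles = smiles, length = lens,
               modification = mod,
               pTM = stats::runif(n, 0.4, 1.0),
               pLDDT = stats::runif(n, 0.4, 1.0),
               stringsAsFactors = FALSE)
  })
}

#' Curation fixture with hand-verified expected outcomes
#'
#' A fixed set of raw small-molecule records exercising every rule of the
#' filter cascade — short strings, silicon chains, silicon-oxide polymer
#' motifs, lexically invalid strings, salt stripping, component splitting,
#' and duplicates (including duplicates under different spellings) — together
#' with the expected per-record reasons, the expected survivor set (as the
#' hand-stripped fragments), and the expected reason histogram.
#'
#' @param seed Unused (the fixture is fully deterministic); kept for
#'   generator-interface uniformity.
#' @return List with `records`, `expected_reasons`, `expected_survivors`
#'   (pre-canonicalization spellings), `expected_stats`.
#' @export
gen_curation_fixture <- function(seed = 1L) {
  c18acid <- paste0("N", strrep("C", 17), "C(=O)O")          # 18-C amino acid
  c18acid_alt <- paste0("OC(=O)", strrep("C", 17), "N")      # same molecule
  c12acid <- paste0("N", strrep("C", 11), "C(=O)O")
  icosanol <- paste0("O", strrep("C", 20))
  thiol <- paste0(strrep("C", 20), "S")
  quat <- paste0(strrep("C", 16), "[N+](C)(C)C")
  amide <- "CCCCCCCCCC(=O)NCCCCCCCCC"
  records <- c(
    "CCO",                                           # too_short
    "c1ccccc1",                                      # too_short
    "CCCCCCCCCC[Si][Si]CCC",                         # silicon_chain (Si-Si)
    "CCCCCCCC[Si]O[Si]CCCC",                         # silicon_chain (Si-O-Si)
    "CCCCCCCCC[Si](=O)[Si](=O)CCCC",                 # silicon_oxide_polymer
    "CCCC[Si](=O)[Si](=O)CCCCCCCCC",                 # silicon_oxide_polymer
    "C(C(C(C(C(C(C(C(C(C(",                          # invalid (parens)
    "CCCCCCCCCCC1CCCCCCCCC",                         # invalid (ring closure)
    paste0("Cl.", c18acid),                          # salt strip -> kept
    paste0("[Br-].", quat),                          # ionic salt strip
    paste0(c12acid, ".", icosanol),                  # split -> 2 entries
    c18acid,                                         # duplicate of record 9
    c18acid_alt,                                     # duplicate, respelled
    thiol,                                           # kept
    thiol,                                           # duplicate
    amide                                            # kept
  )
  expected_reasons <- c("too_short", "too_short", "silicon_chain",
                        "silicon_chain", "silicon_oxide_polymer",
                        "silicon_oxide_polymer", "invalid_smiles",
                        "invalid_smiles", rep("kept", 8L))
  expected_survivors <- c(c18acid, quat, c12acid, icosanol, thiol, amide)
  expected_stats <- c(too_short = 2L, silicon_chain = 2L,
                      silicon_oxide_polymer = 2L, invalid_smiles = 2L,
                      kept = 8L, duplicate = 3L)
  list(records = records, expected_reasons = expected_reasons,
       expected_survivors = expected_survivors,
       expected_stats = expected_stats)
}

#' Generate a labeled synthetic task
#'
#' Labels are a stated function of a computable descriptor (logP), so the
#' achievable score is controlled by construction:
#' `descriptor_threshold_binary` labels molecules by logP above the corpus
#' median, flipping each label with probability `noise`;
#' `descriptor_regression` uses logP plus Gaussian noise
#' (`noise` x sd(logP)); `condition_dependent_binary` makes the threshold a
#' linear function of a synthetic pH column, so the condition carries real
#' information.
#'
#' @param kind Task kind (see above).
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param noise Noise level (default 0.05).
#' @return A `task_dataset`: list with `smiles`, `labels`, `condition`,
#'   `task_type`, `split_spec` (NULL), and an `oracle` element holding the
#'   generating descriptor values and threshold.
#' @export
gen_labeled_task <- function(kind = c("descriptor_threshold_binary",
                                      "descriptor_regression",
                                      "condition_dependent_binary"),
                             n = 500L, seed = 1L, noise = 0.05) {
  kind <- match.arg(kind)
  smiles <- gen_small_molecules(ceiling(n * 1.15), seed = seed)
  desc <- compute_descriptors(smiles)
  logp <- desc[, "logP"]
  ok <- which(is.finite(logp))
  if (length(ok) < n) {
    stop_smiclm("descriptor computation failed for too many molecules",
                "smiclm_internal")
  }
  idx <- ok[seq_len(n)]
  smiles <- smiles[idx]; logp <- unname(logp[idx])
  with_seed(seed + 1L, {
    if (kind == "descriptor_regression") {
      labels <- logp + stats::rnorm(n, 0, noise * stats::sd(logp))
      task <- list(smiles = smiles, labels = labels, condition = NULL,
                   task_type = "regression", split_spec = NULL,
                   oracle = list(descriptor = "logP", values = logp))
    } else if (kind == "descriptor_threshold_binary") {
      thr <- stats::median(logp)
      labels <- as.integer(logp > thr)
      flip <- stats::runif(n) < noise
      labels[flip] <- 1L - labels[flip]
      task <- list(smiles = smiles, labels = labels, condition = NULL,
                   task_type = "binary", split_spec = NULL,
                   oracle = list(descriptor = "logP", values = logp,
                                 threshold = thr, flipped = flip))
    } else {
      ph <- stats::runif(n, 5, 9)
      beta <- 0.6 * stats::sd(logp)
      thr <- stats::median(logp) + beta * (ph - 7)
      labels <- as.integer(logp > thr)
      flip <- stats::runif(n) < noise
      labels[flip] <- 1L - labels[flip]
      task <- list(smiles = smiles, labels = labels, condition = ph,
                   task_type = "binary", split_spec = NULL,
                   oracle = list(descriptor = "logP", values = logp,
                                 threshold = thr, beta = beta,
                                 flipped = flip))
    }
    structure(task, class = "task_dataset")
  })
}

#' @export
print.task_dataset <- function(x, ...) {
  cat(sprintf("<task_dataset> %s, n=%d%s\n", x$task_type, length(x$smiles),
              if (!is.null(x$condition)) ", with condition column" else ""))
  invisible(x)
}

#' Write synthetic fixtures to a directory
#'
#' Writes a small-molecule .smi file, a peptide FASTA plus confidence-score
#' TSV, a labeled task CSV, and the curation fixture with its expected
#' outcomes as JSON.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- gen_small_molecules(50L, seed = seed)
  write_smi(sm, file.path(dir, "small_molecules.smi"),
            id = paste0("SM", seq_along(sm)))
  pep <- gen_peptide_corpus(20L, seed = seed, len_range = c(5L, 30L),
                            mod_rate = 0.2)
  writeLines(paste0(">PEP", seq_len(nrow(pep)), "\n", pep$sequence),
             file.path(dir, "peptides.fasta"))
  utils::write.table(
    data.frame(id = paste0("PEP", seq_len(nrow(pep))),
               pTM = pep$pTM, pLDDT = pep$pLDDT,
               cluster_id = rep_len(1:5, nrow(pep))),
    file.path(dir, "peptide_scores.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  task <- gen_labeled_task("descriptor_threshold_binary", n = 100L,
                           seed = seed)
  utils::write.csv(data.frame(smiles = task$smiles, label = task$labels),
                   file.path(dir, "task.csv"), row.names = FALSE)
  fx <- gen_curation_fixture(seed)
  jsonlite::write_json(fx, file.path(dir, "curation_fixture.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list.files(dir, full.names = TRUE))
}
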
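# Internal peptide -> SMILES builder: condenses residue fragments into linear
# or head-to-tail cyclic peptide SMILES, with optional backbone N-methylation.
# All canonical residues are built in the L configuration
# (backbone N[C@@H](R)C(=O); glycine has no stereocenter).

# Side chains written as a branch off the alpha carbon.
.AA_SIDE <- c(
  A = "C",
  R = "CCCN=C(N)N",
  N = "CC(N)=O",
  D = "CC(=O)O",
  C = "CS",
  E = "CCC(=O)O",
  Q = "CCC(N)=O",
  H = "Cc1cnc[nH]1",
  I = "[C@@H](C)CC",
  L = "CC(C)C",
  K = "CCCCN",
  M = "CCSC",
  F = "Cc1ccccc1",
  S = "CO",
  T = "[C@H](O)C",
  W = "Cc1c[nH]c2ccccc12",
  Y = "Cc1ccc(O)cc1",
  V = "C(C)C"
)
# G (no side chain, achiral) and P (cyclic backbone) are handled specially.

#' Residue letters known to the peptide builder
#' @return Character vector of one-letter codes.
#' @export
residue_alphabet <- function() sort(c(names(.AA_SIDE), "G", "P"))

# One residue fragment ending in its carbonyl "C(=O)".  `nme` adds a backbone
# N-methyl; `ring` is a ring-closure label string spliced onto the backbone N
# (used for head-to-tail cyclization of the first residue).
.residue_fragment <- function(letter, nme = FALSE, ring = "") {
  if (letter == "P") {
    if (nme) {
      stop_smiclm("cannot N-methylate proline (tertiary backbone nitrogen)",
                  "smiclm_residue")
    }
    return(paste0("N", ring, "3CCC[C@H]3C(=O)"))
  }
  npart <- if (nme) paste0("N", ring, "(C)") else paste0("N", ring)
  if (letter == "G") return(paste0(npart, "CC(=O)"))
  side <- .AA_SIDE[[letter]]
  paste0(npart, "[C@@H](", side, ")C(=O)")
}

#' Convert an amino-acid sequence to a peptide SMILES string
#'
#' Joins residues by amide condensation.  Linear peptides carry a free
#' N-terminal amine and a C-terminal carboxylic acid; `cyclic = TRUE` builds
#' the head-to-tail macrocycle instead (backbone amide between the first
#' nitrogen and the last carbonyl).  Positions listed in
#' `n_methyl_positions` get a backbone N-methyl group.  All residues are
#' L-configured.
#'
#' @param sequence One-letter amino-acid string (20 canonical residues).
#' @param cyclic Head-to-tail cyclization (default FALSE).
#' @param n_methyl_positions Optional integer vector of residue positions
#'   (1-based) to N-methylate.  Proline cannot be N-methylated.
#' @param validate Verify that the output canonicalizes (default TRUE; batch
#'   generators turn this off and verify in bulk).
#' @return A SMILES string; guaranteed to canonicalize.
#' @examples
#' peptide_to_smiles("GG")
#' @export
peptide_to_smiles <- function(sequence, cyclic = FALSE,
                              n_methyl_positions = NULL, validate = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  letters_ <- strsplit(sequence, "")[[1L]]
  known <- letters_ %in% residue_alphabet()
  if (!all(known)) {
    bad <- which(!known)[1L]
    stop_smiclm(sprintf("unknown residue letter '%s' at position %d",
                        letters_[bad], bad), "smiclm_residue")
  }
  n <- length(letters_)
  if (cyclic && n < 2L) {
    stop_smiclm("head-to-tail cyclization needs at least 2 residues",
                "smiclm_residue")
  }
  nme <- seq_len(n) %in% (n_methyl_positions %||% integer(0))
  frags <- vapply(seq_len(n), function(i) {
    .residue_fragment(letters_[i], nme = nme[i],
                      ring = if (cyclic && i == 1L) "%99" else "")
  }, character(1))
  if (cyclic) {
    # last carbonyl closes the macrocycle on the first nitrogen
    last <- frags[n]
    frags[n] <- sub("C\\(=O\\)$", "C%99=O", last)
    smi <- paste0(frags, collapse = "")
  } else {
    smi <- paste0(paste0(frags, collapse = ""), "O")
  }
  if (!validate) return(smi)
  can <- smi_canonicalize(smi)
  if (is.na(can[1L])) {
    stop_smiclm(sprintf("internal builder produced non-canonicalizable SMILES for '%s'",
                        sequence), "smiclm_residue")
  }
  smi
}
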
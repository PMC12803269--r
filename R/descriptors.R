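# The physicochemical descriptor set used as multi-task regression targets:
# 99 two-dimensional descriptors combining OpenBabel molecular properties with
# graph- and text-derived quantities computed from the package's own SMILES
# parser.  The list is frozen: order and names are part of the model contract.

.DESC_OB <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")

.DESC_GRAPH <- c(
  # atom composition
  "n_heavy", "n_C", "n_N", "n_O", "n_S", "n_P", "n_F", "n_Cl", "n_Br", "n_I",
  "n_B", "n_heteroatoms", "n_halogens",
  "frac_C", "frac_N", "frac_O", "frac_S", "frac_halogen", "frac_hetero",
  "avg_atomic_mass",
  # aromaticity
  "n_aromatic_atoms", "frac_aromatic", "n_aromatic_C", "n_aromatic_N",
  # charge and stereo
  "n_pos_charge", "n_neg_charge", "net_charge", "n_charged",
  "n_stereocenters", "n_stereo_bond_marks", "n_explicit_H",
  # bonds
  "n_bonds", "n_single_bonds", "n_double_bonds", "n_triple_bonds",
  "n_aromatic_bonds", "frac_double_bonds", "n_rotatable_bonds", "frac_sp3_C",
  # rings
  "n_rings", "n_ring_atoms", "n_ring_bonds", "frac_ring_atoms",
  "n_components",
  # degree distribution
  "n_deg1", "n_deg2", "n_deg3", "n_deg4", "mean_degree", "max_degree",
  # topological indices
  "wiener_index", "wiener_per_atom", "diameter", "radius", "avg_path_length",
  "zagreb_m1", "zagreb_m2", "randic_index", "platt_index",
  # functional-group motifs
  "n_carbonyl", "n_amide", "n_carboxyl", "n_ester", "n_hydroxyl",
  "n_ether_O", "n_amine_N", "n_thiol_S", "n_sulfide_S", "n_nitrile",
  # text / primitive statistics
  "n_primitives", "n_chars", "n_branches", "max_branch_depth",
  "n_ring_closures", "n_percent_closures", "n_dots", "n_bracket_atoms",
  "n_bond_symbols",
  # bonded element pairs
  "pair_C_C", "pair_C_N", "pair_C_O", "pair_C_S", "pair_C_F", "pair_C_Cl",
  "pair_C_Br", "pair_N_N", "pair_N_O", "pair_C_P", "pair_O_P",
  "pair_O_S", "pair_N_S"
)

#' Names of the 99 physicochemical descriptors
#'
#' The frozen, ordered descriptor manifest used as multi-task regression
#' targets during pretraining: 8 OpenBabel molecular properties (molecular
#' weight, logP, topological polar surface area, molar refractivity, two
#' hydrogen-bond-acceptor counts, hydrogen-bond donors, fluorine count)
#' followed by 91 graph- and text-derived 2D descriptors.
#'
#' @return Character vector of length 99.
#' @export
descriptor_names <- function() c(.DESC_OB, .DESC_GRAPH)

# Graph/text descriptors for one molecule.  Returns a named numeric vector
# following .DESC_GRAPH.
.graph_descriptors <- function(smiles) {
  prims <- .pretokenize1(smiles)
  g <- smiles_graph(prims_seq(prims, smiles))
  a <- g$atoms; b <- g$bonds
  n <- nrow(a); nb <- nrow(b)
  out <- stats::setNames(numeric(length(.DESC_GRAPH)), .DESC_GRAPH)
  cnt <- function(s) sum(a$symbol == s)
  out["n_heavy"] <- n
  for (el in c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")) {
    out[paste0("n_", el)] <- cnt(el)
  }
  halo <- sum(a$symbol %in% c("F", "Cl", "Br", "I"))
  het <- n - cnt("C")
  out["n_heteroatoms"] <- het
  out["n_halogens"] <- halo
  if (n > 0) {
    out["frac_C"] <- cnt("C") / n
    out["frac_N"] <- cnt("N") / n
    out["frac_O"] <- cnt("O") / n
    out["frac_S"] <- cnt("S") / n
    out["frac_halogen"] <- halo / n
    out["frac_hetero"] <- het / n
    mass <- .ATOMIC_MASS[a$symbol]
    mass[is.na(mass)] <- 12
    out["avg_atomic_mass"] <- mean(mass)
  }
  out["n_aromatic_atoms"] <- sum(a$aromatic)
  out["frac_aromatic"] <- if (n > 0) sum(a$aromatic) / n else 0
  out["n_aromatic_C"] <- sum(a$aromatic & a$symbol == "C")
  out["n_aromatic_N"] <- sum(a$aromatic & a$symbol == "N")
  out["n_pos_charge"] <- sum(a$charge > 0)
  out["n_neg_charge"] <- sum(a$charge < 0)
  out["net_charge"] <- sum(a$charge)
  out["n_charged"] <- sum(a$charge != 0)
  out["n_stereocenters"] <- sum(a$stereo)
  out["n_stereo_bond_marks"] <- sum(prims %in% c("/", "\\"))
  out["n_explicit_H"] <- sum(a$hcount, na.rm = TRUE)
  deg <- tabulate(c(b$from, b$to), nbins = n)
  out["n_bonds"] <- nb
  out["n_single_bonds"] <- sum(b$order == 1)
  out["n_double_bonds"] <- sum(b$order == 2)
  out["n_triple_bonds"] <- sum(b$order == 3)
  out["n_aromatic_bonds"] <- sum(b$order == 1.5)
  out["frac_double_bonds"] <- if (nb > 0) sum(b$order == 2) / nb else 0
  cyc <- .cycle_membership(g)
  out["n_ring_atoms"] <- sum(cyc$atoms)
  out["n_ring_bonds"] <- sum(cyc$bonds)
  out["frac_ring_atoms"] <- if (n > 0) sum(cyc$atoms) / n else 0
  # rotatable: acyclic single bonds whose both ends have degree > 1
  if (nb > 0) {
    rot <- b$order == 1 & !cyc$bonds & deg[b$from] > 1L & deg[b$to] > 1L
    out["n_rotatable_bonds"] <- sum(rot)
  }
  isC <- a$symbol == "C" & !a$aromatic
  if (any(isC) && nb > 0) {
    hasmult <- rep(FALSE, n)
    mult <- b$order > 1
    hasmult[b$from[mult]] <- TRUE
    hasmult[b$to[mult]] <- TRUE
    out["frac_sp3_C"] <- sum(isC & !hasmult) / max(1, cnt("C"))
  }
  # components and cyclomatic ring count
  ad <- .adjacency(g)$adj
  comp <- rep(NA_integer_, n)
  ncomp <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      ncomp <- ncomp + 1L
      d <- .bfs_dist(ad, i, n)
      comp[!is.na(d)] <- ncomp
    }
  }
  out["n_components"] <- ncomp
  out["n_rings"] <- nb - n + ncomp
  out["n_deg1"] <- sum(deg == 1L)
  out["n_deg2"] <- sum(deg == 2L)
  out["n_deg3"] <- sum(deg == 3L)
  out["n_deg4"] <- sum(deg >= 4L)
  out["mean_degree"] <- if (n > 0) mean(deg) else 0
  out["max_degree"] <- if (n > 0) max(deg) else 0
  # distance-based indices (per component; capped for very large graphs)
  if (n > 1 && n <= 400) {
    wien <- 0; diam <- 0; ecc <- rep(NA_real_, n); spsum <- 0; spn <- 0
    for (i in seq_len(n)) {
      d <- .bfs_dist(ad, i, n)
      dr <- d[!is.na(d) & d > 0L]
      wien <- wien + sum(dr)
      if (length(dr)) {
        ecc[i] <- max(dr)
        spsum <- spsum + sum(dr); spn <- spn + length(dr)
      }
    }
    out["wiener_index"] <- wien / 2
    out["wiener_per_atom"] <- wien / 2 / n
    out["diameter"] <- max(c(0, ecc), na.rm = TRUE)
    out["radius"] <- if (all(is.na(ecc))) 0 else min(ecc, na.rm = TRUE)
    out["avg_path_length"] <- if (spn > 0) spsum / spn else 0
  }
  out["zagreb_m1"] <- sum(deg^2)
  if (nb > 0) {
    df <- deg[b$from]; dt <- deg[b$to]
    out["zagreb_m2"] <- sum(df * dt)
    out["randic_index"] <- sum(1 / sqrt(df * dt))
    out["platt_index"] <- sum(df + dt - 2)
  }
  # functional-group motifs
  if (nb > 0) {
    nbs <- .adjacency(g)
    carbonylC <- rep(FALSE, n)
    for (e in seq_len(nb)) {
      if (b$order[e] == 2) {
        f <- b$from[e]; t <- b$to[e]
        if (a$symbol[f] == "C" && a$symbol[t] == "O") carbonylC[f] <- TRUE
        if (a$symbol[t] == "C" && a$symbol[f] == "O") carbonylC[t] <- TRUE
      }
    }
    out["n_carbonyl"] <- sum(carbonylC)
    n_amide <- 0L; n_carboxyl <- 0L; n_ester <- 0L
    for (c_idx in which(carbonylC)) {
      nbrs <- nbs$adj[[c_idx]]
      ords <- nbs$ord[[c_idx]]
      if (any(a$symbol[nbrs] == "N" & ords == 1)) n_amide <- n_amide + 1L
      singO <- nbrs[a$symbol[nbrs] == "O" & ords == 1]
      for (o in singO) {
        if (deg[o] == 1L) n_carboxyl <- n_carboxyl + 1L
        else n_ester <- n_ester + 1L
      }
    }
    out["n_amide"] <- n_amide
    out["n_carboxyl"] <- n_carboxyl
    out["n_ester"] <- n_ester
    n_hydroxyl <- 0L; n_ether <- 0L
    for (o in which(a$symbol == "O" & !a$aromatic)) {
      nbrs <- nbs$adj[[o]]
      ords <- nbs$ord[[o]]
      if (any(ords > 1)) next
      ncarbonyl <- any(carbonylC[nbrs])
      if (deg[o] == 1L && !ncarbonyl) n_hydroxyl <- n_hydroxyl + 1L
      if (deg[o] == 2L && all(a$symbol[nbrs] == "C") && !ncarbonyl) {
        n_ether <- n_ether + 1L
      }
    }
    out["n_hydroxyl"] <- n_hydroxyl
    out["n_ether_O"] <- n_ether
    n_amine <- 0L
    for (nn in which(a$symbol == "N" & !a$aromatic)) {
      nbrs <- nbs$adj[[nn]]
      if (!any(carbonylC[nbrs]) && all(nbs$ord[[nn]] == 1)) {
        n_amine <- n_amine + 1L
      }
    }
    out["n_amine_N"] <- n_amine
    out["n_thiol_S"] <- sum(a$symbol == "S" & deg == 1L)
    out["n_sulfide_S"] <- sum(a$symbol == "S" & deg == 2L & !a$aromatic)
    n_nitrile <- 0L
    for (e in seq_len(nb)) {
      if (b$order[e] == 3 &&
          ((a$symbol[b$from[e]] == "C" && a$symbol[b$to[e]] == "N") ||
           (a$symbol[b$to[e]] == "C" && a$symbol[b$from[e]] == "N"))) {
        n_nitrile <- n_nitrile + 1L
      }
    }
    out["n_nitrile"] <- n_nitrile
  }
  # text statistics
  out["n_primitives"] <- length(prims)
  out["n_chars"] <- nchar(smiles)
  out["n_branches"] <- sum(prims == "(")
  depth <- 0L; maxd <- 0L
  for (p in prims) {
    if (p == "(") { depth <- depth + 1L; maxd <- max(maxd, depth) }
    else if (p == ")") depth <- depth - 1L
  }
  out["max_branch_depth"] <- maxd
  out["n_ring_closures"] <- sum(grepl("^[0-9]$", prims))
  out["n_percent_closures"] <- sum(grepl("^%[0-9][0-9]$", prims))
  out["n_dots"] <- sum(prims == ".")
  out["n_bracket_atoms"] <- sum(startsWith(prims, "["))
  out["n_bond_symbols"] <- sum(prims %in% c("-", "=", "#", "/", "\\"))
  # bonded element pairs
  if (nb > 0) {
    s1 <- a$symbol[b$from]; s2 <- a$symbol[b$to]
    lo <- pmin(s1, s2); hi <- pmax(s1, s2)
    pk <- paste(lo, hi, sep = "_")
    for (pr in c("C_C", "C_N", "C_O", "C_S", "C_F", "C_Cl", "C_Br", "N_N",
                 "N_O", "C_P", "O_P", "O_S", "N_S")) {
      parts <- strsplit(pr, "_")[[1L]]
      key <- paste(sort(parts)[1L], sort(parts)[2L], sep = "_")
      out[paste0("pair_", pr)] <- sum(pk == key)
    }
  }
  out
}

#' Compute the 99-descriptor matrix for a set of molecules
#'
#' Deterministic per molecule; duplicate SMILES give identical rows.
#' Molecules the backend cannot parse are flagged in the `failed` attribute
#' (their rows are NA and are excluded from the regression loss downstream).
#'
#' @param smiles Character vector of valid SMILES strings.
#' @return Numeric matrix `length(smiles) x 99` with `descriptor_names()`
#'   columns and a logical `failed` attribute.
#' @export
compute_descriptors <- function(smiles) {
  n <- length(smiles)
  out <- matrix(NA_real_, n, 99L,
                dimnames = list(NULL, descriptor_names()))
  failed <- rep(FALSE, n)
  # OpenBabel properties, batched through SDF conversion
  ob <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(smiles, paste0("m", seq_len(n)))))
    p <- suppressWarnings(ChemmineR::propOB(sdf))
    idx <- as.integer(sub("^m", "", rownames(p)))
    list(p = p, idx = idx)
  }, error = function(e) NULL)
  if (!is.null(ob)) {
    for (col in .DESC_OB) {
      if (col %in% colnames(ob$p)) {
        out[ob$idx, col] <- suppressWarnings(as.numeric(ob$p[[col]]))
      }
    }
  }
  for (i in seq_len(n)) {
    gi <- tryCatch(.graph_descriptors(smiles[i]), error = function(e) NULL)
    if (is.null(gi)) { failed[i] <- TRUE; next }
    out[i, .DESC_GRAPH] <- gi
  }
  failed <- failed | apply(is.na(out[, .DESC_OB, drop = FALSE]), 1L, all)
  attr(out, "failed") <- failed
  out
}

#' Normalize a descriptor matrix to zero mean and unit variance
#'
#' Column statistics are computed from the supplied (training) rows only;
#' constant columns map to zero.  The returned object carries the statistics
#' so new data can be normalized consistently and predictions de-normalized.
#'
#' @param values Numeric matrix of raw descriptor values.
#' @return A `descriptor_matrix`: list with `values` (normalized), `names`,
#'   `mean`, `sd` (raw-scale column statistics; `sd` 1 for constant columns,
#'   flagged in `constant`).
#' @export
normalize_descriptors <- function(values) {
  mu <- colMeans(values, na.rm = TRUE)
  # population variance so the normalized training column has variance
  # exactly 1 under the denominator used here (sample sd, checked with var())
  sd <- apply(values, 2L, stats::sd, na.rm = TRUE)
  constant <- !is.finite(sd) | sd < 1e-12
  sd[constant] <- 1
  mu[!is.finite(mu)] <- 0
  norm <- sweep(sweep(values, 2L, mu, "-"), 2L, sd, "/")
  norm[, constant] <- 0
  structure(list(values = norm, names = colnames(values), mean = mu, sd = sd,
                 constant = constant), class = "descriptor_matrix")
}

#' Apply stored normalization statistics to new raw descriptor rows
#' @param dm A `descriptor_matrix` (for its statistics).
#' @param values Raw descriptor matrix with the same columns.
#' @return Normalized matrix.
#' @export
apply_normalization <- function(dm, values) {
  norm <- sweep(sweep(values, 2L, dm$mean, "-"), 2L, dm$sd, "/")
  norm[, dm$constant] <- 0
  norm
}

#' Invert descriptor normalization
#' @param dm A `descriptor_matrix`.
#' @param values Normalized matrix (defaults to `dm$values`).
#' @return Raw-scale matrix.
#' @export
denormalize_descriptors <- function(dm, values = dm$values) {
  out <- sweep(sweep(values, 2L, dm$sd, "*"), 2L, dm$mean, "+")
  out[, dm$constant] <- matrix(dm$mean[dm$constant], nrow(out),
                               sum(dm$constant), byrow = TRUE)
  out
}
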
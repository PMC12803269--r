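# Lightweight SMILES -> molecular graph parser over the primitive grammar.
# Used for 2D descriptor computation and path fingerprints.  Hydrogens are
# implicit (bracket H counts are recorded but not expanded); stereo marks are
# counted, not interpreted.

.BOND_CHARS <- c("-", "=", "#", ":", "/", "\\")
.BOND_ORDER <- c("-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1)

.ATOMIC_MASS <- c(B = 10.81, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                  S = 32.06, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.90,
                  Si = 28.085, Se = 78.971, As = 74.922, H = 1.008)

# Parse one bracket-atom primitive "[...]": returns list(symbol, aromatic,
# charge, hcount, stereo).
.parse_bracket <- function(p) {
  inner <- substr(p, 2L, nchar(p) - 1L)
  m <- regexec("^([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?(:[0-9]+)?$",
               inner)
  g <- regmatches(inner, m)[[1L]]
  if (length(g) == 0L) {
    return(list(symbol = "*", aromatic = FALSE, charge = 0L, hcount = 0L,
                stereo = FALSE))
  }
  sym <- g[3L]
  aromatic <- sym == tolower(sym) && sym != "*"
  symbol <- paste0(toupper(substr(sym, 1L, 1L)), substring(sym, 2L))
  hc <- g[5L]
  hcount <- if (!nzchar(hc)) 0L else if (hc == "H") 1L else
    as.integer(substring(hc, 2L))
  ch <- g[6L]
  charge <- if (!nzchar(ch)) 0L else if (ch %in% c("+", "-")) {
    if (ch == "+") 1L else -1L
  } else if (grepl("^[+]+$", ch)) nchar(ch) else if (grepl("^[-]+$", ch)) {
    -nchar(ch)
  } else {
    as.integer(paste0(substr(ch, 1L, 1L), "1")) * as.integer(substring(ch, 2L))
  }
  list(symbol = symbol, aromatic = aromatic, charge = charge, hcount = hcount,
       stereo = nzchar(g[4L]))
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds the heavy-atom graph: atoms with element symbol, aromaticity flag,
#' formal charge, explicit-H count and stereo mark; bonds with order (1, 2, 3,
#' or 1.5 for aromatic).  A bond written between two aromatic atoms with no
#' explicit symbol is aromatic.  Dots start new connected components.
#'
#' @param smiles A single SMILES string (lexically valid).
#' @return List with data.frames `atoms` (symbol, aromatic, charge, hcount,
#'   stereo, bracket) and `bonds` (from, to, order).
#' @export
smiles_graph <- function(smiles) {
  prims <- if (inherits(smiles, "primitive_seq")) smiles$primitives else
    .pretokenize1(smiles)
  sym <- character(0); arom <- logical(0); chg <- integer(0)
  hct <- integer(0); ste <- logical(0); brk <- logical(0)
  b_from <- integer(0); b_to <- integer(0); b_ord <- numeric(0)
  stack <- integer(0)
  prev <- 0L                 # last atom written; 0 = none (start/after dot)
  bond <- NA_character_      # pending explicit bond symbol
  ring_open <- list()        # label -> c(atom, bond_code_or_NA)
  add_bond <- function(a, b, bsym) {
    ord <- if (is.na(bsym)) {
      if (arom[a] && arom[b]) 1.5 else 1
    } else .BOND_ORDER[[bsym]]
    b_from <<- c(b_from, a); b_to <<- c(b_to, b); b_ord <<- c(b_ord, ord)
  }
  for (p in prims) {
    if (is_atom_primitive(p)) {
      if (startsWith(p, "[")) {
        at <- .parse_bracket(p)
      } else {
        at <- list(symbol = paste0(toupper(substr(p, 1L, 1L)), substring(p, 2L)),
                   aromatic = p == tolower(p) && !(p %in% c("Cl", "Br", "F", "I")),
                   charge = 0L, hcount = NA_integer_, stereo = FALSE)
      }
      sym <- c(sym, at$symbol); arom <- c(arom, at$aromatic)
      chg <- c(chg, at$charge); hct <- c(hct, at$hcount)
      ste <- c(ste, at$stereo); brk <- c(brk, startsWith(p, "["))
      idx <- length(sym)
      if (prev > 0L) add_bond(prev, idx, bond)
      prev <- idx; bond <- NA_character_
    } else if (p %in% .BOND_CHARS) {
      bond <- p
    } else if (p == "(") {
      stack <- c(stack, prev)
    } else if (p == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (p == ".") {
      prev <- 0L; bond <- NA_character_
    } else if (grepl("^[0-9]$|^%[0-9][0-9]$", p)) {
      lab <- sub("^%", "", p)
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        bsym <- if (!is.na(op[[2L]])) op[[2L]] else bond
        add_bond(op[[1L]], prev, if (is.null(bsym)) NA_character_ else bsym)
        ring_open[[lab]] <- NULL
      } else {
        ring_open[[lab]] <- list(prev, bond)
      }
      bond <- NA_character_
    }
    # anything else (rare symbols) is ignored
  }
  list(
    atoms = data.frame(symbol = sym, aromatic = arom, charge = chg,
                       hcount = hct, stereo = ste, bracket = brk,
                       stringsAsFactors = FALSE),
    bonds = data.frame(from = b_from, to = b_to, order = b_ord)
  )
}

# Adjacency list (atom index -> integer vector of neighbors) plus parallel
# bond-order lists.
.adjacency <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- vector("list", n)
  bord <- vector("list", n)
  if (n == 0L) return(list(adj = adj, ord = bord))
  for (i in seq_len(n)) { adj[[i]] <- integer(0); bord[[i]] <- numeric(0) }
  for (e in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$from[e]; b <- graph$bonds$to[e]; o <- graph$bonds$order[e]
    adj[[a]] <- c(adj[[a]], b); bord[[a]] <- c(bord[[a]], o)
    adj[[b]] <- c(adj[[b]], a); bord[[b]] <- c(bord[[b]], o)
  }
  list(adj = adj, ord = bord)
}

# BFS distances from one source over an adjacency list; unreachable = NA.
.bfs_dist <- function(adj, src, n) {
  d <- rep(NA_integer_, n)
  d[src] <- 0L
  q <- src; head <- 1L
  while (head <= length(q)) {
    v <- q[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
    }
  }
  d
}

# Atoms/bonds lying on at least one cycle, found by iteratively pruning
# degree-1 vertices.
.cycle_membership <- function(graph) {
  n <- nrow(graph$atoms)
  nb <- nrow(graph$bonds)
  alive_a <- rep(TRUE, n)
  alive_b <- rep(TRUE, nb)
  deg <- tabulate(c(graph$bonds$from, graph$bonds$to), nbins = n)
  repeat {
    leaves <- which(alive_a & deg == 1L)
    if (length(leaves) == 0L) break
    for (v in leaves) {
      alive_a[v] <- FALSE
      es <- which(alive_b & (graph$bonds$from == v | graph$bonds$to == v))
      for (e in es) {
        alive_b[e] <- FALSE
        other <- if (graph$bonds$from[e] == v) graph$bonds$to[e] else
          graph$bonds$from[e]
        deg[other] <- deg[other] - 1L
      }
      deg[v] <- 0L
    }
  }
  # isolated leftover atoms that never had bonds are not cycle atoms
  alive_a[deg == 0L] <- FALSE
  list(atoms = alive_a, bonds = alive_b)
}
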
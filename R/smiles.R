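# A compact SMILES reader for the organic subset.
#
# Scope: aliphatic/aromatic organic-subset atoms (B C N O P S F Cl Br I,
# b c n o p s), bracket atoms with charge/explicit H/isotope, branches,
# ring-bond closures (including %nn), bond orders - = # : and directional
# bonds / \ (read as single; stereochemistry is ignored), and dot-separated
# components.  Implicit hydrogen counts follow the standard valence model
# with charge adjustment.  This covers drug-like molecules written in
# ordinary SMILES; exotic chemistry (radicals, isotope-dependent properties,
# stereo descriptors) is out of scope and @/@@ marks are skipped.

SMILES_ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
SMILES_VALENCE <- list(B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L),
                       S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles SMILES string.
#' @return A list with `n_atoms`, per-atom vectors `element`, `aromatic`,
#'   `charge`, `n_h` (implicit+explicit hydrogens), `degree`, `in_ring`, and
#'   a `bonds` data.frame (1-based `i`, `j`, numeric `order`; aromatic bonds
#'   have order 1.5).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop("invalid SMILES: empty input")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elem <- character(0); arom <- logical(0); chg <- integer(0); exh <- integer(0)
  bi <- integer(0); bj <- integer(0); bo <- numeric(0)
  prev <- NA_integer_      # atom awaiting the next bond
  stack <- integer(0)      # branch return points
  pend <- NA_real_         # pending explicit bond order
  ring <- list()           # open ring-closure labels -> c(atom, order)
  i <- 1L
  add_atom <- function(el, ar, charge = 0L, nh = NA_integer_) {
    elem[[length(elem) + 1L]] <<- el
    arom[[length(arom) + 1L]] <<- ar
    chg[[length(chg) + 1L]] <<- charge
    exh[[length(exh) + 1L]] <<- nh
    a <- length(elem)
    if (!is.na(prev)) {
      o <- if (!is.na(pend)) pend else if (ar && arom[prev]) 1.5 else 1
      bi[[length(bi) + 1L]] <<- prev; bj[[length(bj) + 1L]] <<- a; bo[[length(bo) + 1L]] <<- o
    }
    prev <<- a
    pend <<- NA_real_
  }
  close_ring <- function(lab) {
    if (is.na(prev)) stop("invalid SMILES '", smiles, "': ring bond before any atom")
    if (!is.null(ring[[lab]])) {
      op <- ring[[lab]]
      a <- op[[1]]
      o <- if (!is.na(pend)) pend else if (!is.na(op[[2]])) op[[2]]
           else if (arom[a] && arom[prev]) 1.5 else 1
      if (a == prev) stop("invalid SMILES '", smiles, "': ring bond to self")
      bi[[length(bi) + 1L]] <<- a; bj[[length(bj) + 1L]] <<- prev; bo[[length(bo) + 1L]] <<- o
      ring[[lab]] <<- NULL
    } else {
      ring[[lab]] <<- list(prev, pend)
    }
    pend <<- NA_real_
  }
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) { add_atom(two, FALSE); i <- i + 2L; next }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) { add_atom(ch, FALSE); i <- i + 1L; next }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) { add_atom(toupper(ch), TRUE); i <- i + 1L; next }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("invalid SMILES '", smiles, "': unclosed bracket")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      add_atom(at$element, at$aromatic, at$charge, at$n_h)
      i <- j + 1L; next
    }
    if (ch %in% c("-", "/", "\\")) { pend <- 1; i <- i + 1L; next }
    if (ch == "=") { pend <- 2; i <- i + 1L; next }
    if (ch == "#") { pend <- 3; i <- i + 1L; next }
    if (ch == ":") { pend <- 1.5; i <- i + 1L; next }
    if (ch == "(") {
      if (is.na(prev)) stop("invalid SMILES '", smiles, "': branch before any atom")
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (!length(stack)) stop("invalid SMILES '", smiles, "': unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (grepl("^[0-9]$", ch)) { close_ring(ch); i <- i + 1L; next }
    if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        stop("invalid SMILES '", smiles, "': bad %nn ring label")
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L; next
    }
    if (ch == ".") { prev <- NA_integer_; pend <- NA_real_; i <- i + 1L; next }
    stop("invalid SMILES '", smiles, "': unexpected character '", ch, "' at position ", i)
  }
  if (length(stack)) stop("invalid SMILES '", smiles, "': unmatched '('")
  if (length(ring)) stop("invalid SMILES '", smiles, "': unclosed ring bond(s)")
  n_atoms <- length(elem)
  if (n_atoms == 0L) stop("invalid SMILES '", smiles, "': no atoms")
  deg <- tabulate(c(bi, bj), nbins = n_atoms)
  nh <- implicit_h(elem, arom, chg, exh, bi, bj, bo, n_atoms, smiles)
  list(n_atoms = n_atoms, element = elem, aromatic = arom, charge = chg,
       n_h = nh, degree = deg, in_ring = ring_membership(n_atoms, bi, bj),
       bonds = data.frame(i = bi, j = bj, order = bo))
}

parse_bracket_atom <- function(body, smiles) {
  m <- regmatches(body, regexec(
    "^([0-9]*)(se|as|[A-Z][a-z]?|[bcnops])((?:@{1,2})?)(H?)([0-9]*)((?:\\+{1,3}|-{1,3})?)([0-9]*)(?::[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0L) stop("invalid SMILES '", smiles, "': bad bracket atom [", body, "]")
  sym <- m[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  el <- if (aromatic) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
  nh <- if (m[5] == "H") { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
  charge <- 0L
  if (nzchar(m[7])) {
    sgn <- if (substr(m[7], 1, 1) == "+") 1L else -1L
    charge <- if (nzchar(m[8])) sgn * as.integer(m[8]) else sgn * nchar(m[7])
  }
  list(element = el, aromatic = aromatic, charge = charge, n_h = nh)
}

implicit_h <- function(elem, arom, chg, exh, bi, bj, bo, n_atoms, smiles) {
  bsum <- numeric(n_atoms)
  for (b in seq_along(bi)) {
    bsum[bi[b]] <- bsum[bi[b]] + bo[b]
    bsum[bj[b]] <- bsum[bj[b]] + bo[b]
  }
  nh <- integer(n_atoms)
  for (a in seq_len(n_atoms)) {
    if (!is.na(exh[a])) { nh[a] <- exh[a]; next }   # bracket atom: explicit
    vs <- SMILES_VALENCE[[elem[a]]]
    if (is.null(vs)) { nh[a] <- 0L; next }
    used <- as.integer(ceiling(bsum[a]))
    targets <- vs + chg[a]
    ok <- targets[targets >= used]
    nh[a] <- if (length(ok)) min(ok) - used else 0L
  }
  nh
}

ring_membership <- function(n_atoms, bi, bj) {
  inring <- logical(n_atoms)
  if (length(bi) == 0L) return(inring)
  g <- igraph::graph_from_edgelist(cbind(bi, bj), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  br <- igraph::bridges(g)
  cyc <- igraph::E(g)[setdiff(seq_len(igraph::ecount(g)), as.integer(br))]
  if (length(cyc)) {
    ends <- igraph::ends(g, cyc)
    inring[unique(as.integer(ends))] <- TRUE
  }
  inring
}

#' Dense adjacency matrix of a parsed molecule
#'
#' Binary atom-atom bond matrix with a unit diagonal on real atoms, zero
#' rows/columns beyond `n_atoms` when padded to `L_D`.
#'
#' @param mol result of [parse_smiles()].
#' @param L_D padded size (default: number of heavy atoms).
#' @return `L_D x L_D` 0/1 matrix.
#' @export
mol_adjacency <- function(mol, L_D = mol$n_atoms) {
  n <- min(mol$n_atoms, L_D)
  A <- matrix(0, L_D, L_D)
  if (n > 0L) A[cbind(seq_len(n), seq_len(n))] <- 1
  bd <- mol$bonds
  for (b in seq_len(nrow(bd))) {
    i <- bd$i[b]; j <- bd$j[b]
    if (i <= n && j <= n) { A[i, j] <- 1; A[j, i] <- 1 }
  }
  A
}
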
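# Raw input representations: protein amino-acid and k-mer token indices,
# drug functional-class circular fingerprints and molecular graphs.
#
# Index conventions: token indices are 0-based so they are portable across
# serialization; 0 is always the padding index.  For amino-acid encoding the
# vocabulary is the 20 canonical residues (indices 1..20), 'X' (21) and pad
# (0).  For k-mer encoding index 1 is the out-of-vocabulary token.

AA_INDEX <- stats::setNames(seq_along(c(AA_ALPHABET, "X")), c(AA_ALPHABET, "X"))

#' Amino-acid (per-residue) token encoding
#'
#' @param sequence protein sequence; characters outside the alphabet are
#'   first mapped to 'X'.
#' @param L_P padded length; longer sequences are truncated.
#' @return List with `idx` (integer vector of length `L_P`, 0 = pad) and
#'   `mask` (TRUE on real residues).
#' @export
encode_protein_aae <- function(sequence, L_P) {
  sequence <- canonical_aa(sequence)
  if (nchar(sequence) < 1L) stop("encode_protein_aae: empty sequence")
  ch <- strsplit(substr(sequence, 1L, L_P), "", fixed = TRUE)[[1]]
  idx <- integer(L_P)
  idx[seq_along(ch)] <- unname(AA_INDEX[ch])
  list(idx = idx, mask = seq_len(L_P) <= length(ch))
}

#' Decode amino-acid token indices back to a sequence
#' @param idx integer vector from [encode_protein_aae()].
#' @return Character string of the real (non-pad) positions.
#' @export
decode_protein_aae <- function(idx) {
  idx <- idx[idx > 0L]
  paste(c(AA_ALPHABET, "X")[idx], collapse = "")
}

#' Build a k-mer vocabulary from training sequences
#'
#' Keeps the `max_size` most frequent overlapping k-mers (stride 1), with
#' deterministic lexicographic tie-breaking; indices 0 (pad) and 1 (out of
#' vocabulary) are reserved.
#'
#' @param sequences character vector of training sequences.
#' @param k k-mer length (>= 1).
#' @param max_size maximum number of k-mer tokens kept.
#' @return An object of class `we_vocab`.
#' @export
build_we_vocab <- function(sequences, k = 3L, max_size = 8192L) {
  if (length(sequences) < 1L) stop("build_we_vocab: need at least one sequence")
  if (k < 1L) stop("build_we_vocab: k must be >= 1")
  toks <- unlist(lapply(canonical_aa(sequences), function(s) {
    n <- nchar(s)
    if (n < k) character(0)
    else substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }))
  tab <- table(toks)
  ord <- order(-as.integer(tab), names(tab))  # frequency desc, then lexicographic
  keep <- names(tab)[ord][seq_len(min(max_size, length(tab)))]
  structure(list(k = as.integer(k), tokens = keep,
                 index = stats::setNames(seq_along(keep) + 1L, keep)),
            class = "we_vocab")
}

#' @export
print.we_vocab <- function(x, ...) {
  cat("<we_vocab> k =", x$k, ",", length(x$tokens), "tokens (+ pad, OOV)\n")
  invisible(x)
}

#' Overlapping k-mer (word) token encoding
#'
#' @param sequence protein sequence.
#' @param vocab vocabulary from [build_we_vocab()] (carries `k`).
#' @param L_P padded length.
#' @return List with `idx` (0 = pad, 1 = out-of-vocabulary) and `mask`.
#' @export
encode_protein_we <- function(sequence, vocab, L_P) {
  stopifnot(inherits(vocab, "we_vocab"))
  sequence <- canonical_aa(sequence)
  n <- nchar(sequence)
  idx <- integer(L_P)
  if (n < vocab$k) {
    warning("sequence shorter than k = ", vocab$k, "; all-pad word encoding")
    return(list(idx = idx, mask = rep(FALSE, L_P)))
  }
  starts <- seq_len(min(n - vocab$k + 1L, L_P))
  toks <- substring(sequence, starts, starts + vocab$k - 1L)
  hit <- vocab$index[toks]
  hit[is.na(hit)] <- 1L  # OOV
  idx[seq_along(hit)] <- unname(hit)
  list(idx = idx, mask = seq_len(L_P) <= length(hit))
}

# ---- drug featurization ----------------------------------------------------

# Functional-class bits per atom (the FCFP initial invariant): hydrogen-bond
# donor, acceptor, aromatic, halogen, positive, negative.
fcfp_atom_classes <- function(mol) {
  don <- mol$element %in% c("N", "O") & mol$n_h >= 1L
  acc <- mol$element %in% c("N", "O") & mol$charge <= 0L
  hal <- mol$element %in% c("F", "Cl", "Br", "I")
  pos <- mol$charge > 0L
  neg <- mol$charge < 0L
  don * 1L + acc * 2L + mol$aromatic * 4L + hal * 8L + pos * 16L + neg * 32L
}

# deterministic polynomial hash of an integer vector into [0, 2^31 - 2]
hash_int_vec <- function(v) {
  m <- 2147483647
  h <- 17
  for (x in v) h <- (h * 31 + (x %% m)) %% m
  h
}

#' Functional-class circular fingerprint (FCFP-style)
#'
#' Morgan-style iterated neighborhood hashing seeded with per-atom
#' pharmacophoric class bits (donor, acceptor, aromatic, halogen, charge
#' signs) rather than element identities, folded to `n_bits` and presented
#' as a 0/1 vector.  Deterministic for a given SMILES.
#'
#' @param smiles SMILES string.
#' @param radius neighborhood radius (default 2, i.e. FCFP4-like).
#' @param n_bits folded length (default 1024).
#' @return Numeric 0/1 vector of length `n_bits`.
#' @export
encode_drug_fcfp <- function(smiles, radius = 2L, n_bits = 1024L) {
  mol <- parse_smiles(smiles)
  inv <- as.numeric(fcfp_atom_classes(mol))
  nb <- lapply(seq_len(mol$n_atoms), function(a) integer(0))
  bond_code <- function(o) if (o == 1.5) 4L else as.integer(o)
  bd <- mol$bonds
  for (b in seq_len(nrow(bd))) {
    nb[[bd$i[b]]] <- rbind(nb[[bd$i[b]]], c(bond_code(bd$order[b]), bd$j[b]))
    nb[[bd$j[b]]] <- rbind(nb[[bd$j[b]]], c(bond_code(bd$order[b]), bd$i[b]))
  }
  feats <- inv
  for (r in seq_len(radius)) {
    nxt <- numeric(mol$n_atoms)
    for (a in seq_len(mol$n_atoms)) {
      pairs <- nb[[a]]
      if (is.null(nrow(pairs)) || nrow(pairs) == 0L) {
        nxt[a] <- hash_int_vec(c(r, inv[a]))
      } else {
        pv <- cbind(pairs[, 1L], inv[pairs[, 2L]])
        pv <- pv[order(pv[, 1L], pv[, 2L]), , drop = FALSE]
        nxt[a] <- hash_int_vec(c(r, inv[a], as.numeric(t(pv))))
      }
    }
    inv <- nxt
    feats <- c(feats, inv)
  }
  fp <- numeric(n_bits)
  fp[(feats %% n_bits) + 1L] <- 1
  fp
}

FEAT_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")

#' Molecular graph features
#'
#' Per-atom feature rows (element one-hot over common drug elements plus an
#' "other" slot, scaled degree, aromaticity, formal charge, in-ring flag)
#' and the padded adjacency matrix with unit diagonal on real atoms.
#'
#' @param smiles SMILES string.
#' @param L_D padded atom count; molecules with more heavy atoms are
#'   truncated with a warning.
#' @return List with `atom_features` (`L_D x 14`), `adj` (`L_D x L_D`) and
#'   `n_atoms` (after truncation).
#' @export
smiles_to_graph <- function(smiles, L_D) {
  mol <- parse_smiles(smiles)
  n <- mol$n_atoms
  if (n > L_D) {
    warning("molecule has ", n, " heavy atoms; truncated to L_D = ", L_D)
    n <- L_D
  }
  f_atom <- length(FEAT_ELEMENTS) + 5L
  X <- matrix(0, L_D, f_atom)
  for (a in seq_len(n)) {
    e <- match(mol$element[a], FEAT_ELEMENTS)
    X[a, if (is.na(e)) length(FEAT_ELEMENTS) + 1L else e] <- 1
    X[a, f_atom - 3L] <- mol$degree[a] / 4
    X[a, f_atom - 2L] <- as.numeric(mol$aromatic[a])
    X[a, f_atom - 1L] <- mol$charge[a]
    X[a, f_atom] <- as.numeric(mol$in_ring[a])
  }
  mol_trunc <- mol
  mol_trunc$n_atoms <- n
  list(atom_features = X, adj = mol_adjacency(mol_trunc, L_D), n_atoms = n)
}
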
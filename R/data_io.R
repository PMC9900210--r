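# Readers/writers for the external formats, the pKd transform and
# cross-validation splitting.
#
# Conventions: protein residue coordinates are 0-based half-open (BED-like)
# throughout; tables are tab-delimited UTF-8 with a header row.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Protein record
#'
#' @param id identifier string.
#' @param sequence amino-acid sequence over the 20 canonical residues plus
#'   'X'; other characters are mapped to 'X'.
#' @param sites optional matrix/list of 0-based half-open residue intervals
#'   (binding-site annotations); normalized (sorted, merged) on construction.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, sites = NULL) {
  sequence <- canonical_aa(sequence)
  if (nchar(sequence) < 1L) stop("protein record '", id, "' has an empty sequence")
  iv <- as_interval_matrix(sites)
  if (nrow(iv) > 0L) {
    if (any(iv[, 1L] < 0L) || any(iv[, 2L] > nchar(sequence)))
      stop("protein record '", id, "': site interval outside [0, ", nchar(sequence), ")")
    iv <- merge_intervals(iv)
  }
  structure(list(id = id, sequence = sequence, sites = iv),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, "-", nchar(x$sequence), "aa,",
      nrow(x$sites), "site interval(s)\n")
  invisible(x)
}

#' Drug record
#'
#' @param id identifier string.
#' @param smiles SMILES string; must parse to a molecule with at least one
#'   heavy atom.
#' @return An object of class `drug_record`.
#' @export
drug_record <- function(id, smiles) {
  mol <- parse_smiles(smiles)  # errors on invalid input
  structure(list(id = id, smiles = smiles, n_atoms = mol$n_atoms),
            class = "drug_record")
}

canonical_aa <- function(x) {
  x <- toupper(x)
  gsub(sprintf("[^%s]", paste(c(AA_ALPHABET, "X"), collapse = "")), "X", x)
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  ir <- IRanges::reduce(IRanges::IRanges(start = iv[, 1L] + 1L, end = iv[, 2L]))
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and characters outside the 20-residue alphabet
#' (plus 'X') are mapped to 'X'.
#'
#' @param path FASTA file.
#' @return List of [protein_record()] objects (empty sites).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    id <- sub("\\s.*$", "", names(set)[i])
    if (is.na(id) || !nzchar(id)) stop("FASTA record ", i, " in ", path, " has an empty header")
    sq <- as.character(set[[i]])
    if (!nzchar(sq)) stop("FASTA record '", id, "' in ", path, " has an empty sequence")
    out[[i]] <- protein_record(id, sq)
  }
  out
}

#' Write protein records to a FASTA file
#'
#' @param proteins list of [protein_record()] objects.
#' @param path output file.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- Biostrings::BStringSet(vapply(proteins, `[[`, "", "sequence"))
  names(seqs) <- vapply(proteins, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a drug table (TSV: drug_id, smiles)
#'
#' @param path tab-delimited file with header columns `drug_id` and `smiles`.
#' @return List of [drug_record()] objects in file order.
#' @export
read_smiles_table <- function(path) {
  tb <- read_tsv_checked(path, c("drug_id", "smiles"))
  if (anyDuplicated(tb$drug_id))
    stop("duplicate drug_id in ", path, ": ",
         paste(unique(tb$drug_id[duplicated(tb$drug_id)]), collapse = ", "))
  out <- vector("list", nrow(tb))
  for (i in seq_len(nrow(tb))) {
    out[[i]] <- tryCatch(drug_record(tb$drug_id[i], tb$smiles[i]),
                         error = function(e) stop("row ", i, " of ", path, " ('",
                                                  tb$drug_id[i], "'): ",
                                                  conditionMessage(e), call. = FALSE))
  }
  out
}

#' Write a drug table
#' @param drugs list of [drug_record()] objects.
#' @param path output TSV.
#' @export
write_smiles_table <- function(drugs, path) {
  data.table::fwrite(data.table::data.table(
    drug_id = vapply(drugs, `[[`, "", "id"),
    smiles = vapply(drugs, `[[`, "", "smiles")), path, sep = "\t")
  invisible(path)
}

#' Read binding-site annotations (BED-like TSV)
#'
#' Three header columns: `protein_id`, `start`, `end`, with 0-based half-open
#' residue intervals.  Intervals are sorted and merged per protein.
#'
#' @param path input TSV.
#' @return Named list mapping protein_id to an interval matrix
#'   (columns start, end).
#' @export
read_sites <- function(path) {
  tb <- read_tsv_checked(path, c("protein_id", "start", "end"))
  st <- as.integer(tb$start); en <- as.integer(tb$end)
  bad <- which(is.na(st) | is.na(en) | st < 0L | st >= en)
  if (length(bad))
    stop("invalid site interval(s) in ", path, " at row(s) ",
         paste(bad, collapse = ", "), " (need 0 <= start < end)")
  split_iv <- split(seq_len(nrow(tb)), tb$protein_id)
  lapply(split_iv, function(idx)
    merge_intervals(cbind(start = st[idx], end = en[idx])))
}

#' Write binding-site annotations
#' @param sites named list of interval matrices (as from [read_sites()]).
#' @param path output TSV.
#' @export
write_sites <- function(sites, path) {
  rows <- lapply(names(sites), function(id) {
    iv <- as_interval_matrix(sites[[id]])
    if (nrow(iv) == 0L) return(NULL)
    data.table::data.table(protein_id = id, start = iv[, 1L], end = iv[, 2L])
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' Read an affinity table (TSV: drug_id, protein_id, affinity)
#'
#' Affinity semantics (pKd for Davis-style data, KIBA score for KIBA-style)
#' are set by the dataset mode of the caller, never auto-detected.  Duplicate
#' (drug, protein) pairs are rejected: their label would be ambiguous.
#'
#' @param path input TSV.
#' @param drugs,proteins optional record lists; when given, every id in the
#'   table must resolve against them.
#' @return data.frame with columns drug_id, protein_id, affinity.
#' @export
read_affinities <- function(path, drugs = NULL, proteins = NULL) {
  tb <- read_tsv_checked(path, c("drug_id", "protein_id", "affinity"))
  aff <- as.numeric(tb$affinity)
  if (any(!is.finite(aff)))
    stop("non-finite affinity value(s) in ", path, " at row(s) ",
         paste(which(!is.finite(aff)), collapse = ", "))
  key <- paste(tb$drug_id, tb$protein_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (drug, protein) pair(s) in ", path, " at row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  if (!is.null(drugs)) {
    known <- vapply(drugs, `[[`, "", "id")
    miss <- setdiff(unique(tb$drug_id), known)
    if (length(miss)) stop("unknown drug_id(s): ", paste(miss, collapse = ", "))
  }
  if (!is.null(proteins)) {
    known <- vapply(proteins, `[[`, "", "id")
    miss <- setdiff(unique(tb$protein_id), known)
    if (length(miss)) stop("unknown protein_id(s): ", paste(miss, collapse = ", "))
  }
  data.frame(drug_id = tb$drug_id, protein_id = tb$protein_id,
             affinity = aff, stringsAsFactors = FALSE)
}

#' Write an affinity table
#' @param affinities data.frame with columns drug_id, protein_id, affinity.
#' @param path output TSV.
#' @export
write_affinities <- function(affinities, path) {
  data.table::fwrite(data.table::as.data.table(
    affinities[, c("drug_id", "protein_id", "affinity")]), path, sep = "\t")
  invisible(path)
}

read_tsv_checked <- function(path, cols) {
  if (!file.exists(path)) stop("no such file: ", path)
  tb <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  miss <- setdiff(cols, names(tb))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  tb
}

#' Transform a dissociation constant (nM) to pKd
#'
#' `pKd = -log10(Kd / 1e9)`, i.e. the negative decadic logarithm of the
#' molar dissociation constant with Kd given in nanomolar units.
#'
#' @param kd_nM positive dissociation constant(s) in nM.
#' @return pKd value(s).
#' @export
#' @examples
#' kd_to_pkd(c(1e9, 100, 10000))  # 0, 7, 5
kd_to_pkd <- function(kd_nM) {
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0))
    stop("kd_to_pkd: Kd must be finite and positive")
  -log10(kd_nM / 1e9)
}

#' Build 5-fold cross-validation splits over a fixed held-out test set
#'
#' A single test set of `round(n_samples * test_fraction)` indices is drawn
#' once and shared by all folds; the remaining pool is partitioned into five
#' validation folds of as-equal-as-possible size.  Deterministic given
#' `seed`; the session RNG state is left untouched.
#'
#' @param n_samples total number of samples (>= 5 in the pool).
#' @param test_fraction fraction held out for testing (default ~1/6).
#' @param seed integer seed.
#' @return List of 5 splits, each a list with `train_indices`,
#'   `valid_indices`, `test_indices`, `fold` (0-based) and `seed`.
#' @export
make_cv_splits <- function(n_samples, test_fraction = 1 / 6, seed = 1L) {
  if (test_fraction < 0 || test_fraction >= 1) stop("test_fraction must be in [0, 1)")
  n_test <- round(n_samples * test_fraction)
  n_pool <- n_samples - n_test
  if (n_pool < 5L) stop("need at least 5 samples in the training pool, got ", n_pool)
  with_seed(seed, {
    perm <- sample.int(n_samples)
    test_idx <- sort(perm[seq_len(n_test)])
    pool <- if (n_test > 0L) perm[-seq_len(n_test)] else perm
    fold_of <- rep(seq_len(5L), length.out = n_pool)  # pool already shuffled
    lapply(0:4, function(f) {
      vi <- sort(pool[fold_of == f + 1L])
      list(train_indices = sort(setdiff(pool, vi)), valid_indices = vi,
           test_indices = test_idx, fold = f, seed = seed)
    })
  })
}

# evaluate expr under a temporary RNG seed, restoring the prior state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
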
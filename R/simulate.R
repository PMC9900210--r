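# Synthetic-data generator: random protein sequences with one planted motif
# (the annotated binding site) per protein, template drugs with a motif-class
# affinity profile, and affinities driven by drug-motif compatibility plus
# Gaussian noise.  Everything the training pipeline and all metrics need can
# be exercised on these data without external downloads.

# small pool of valid drug-like template molecules, cycled with substituent
# variation when more drugs are requested
SIM_SMILES_POOL <- c(
  "CCO", "CC(=O)O", "c1ccccc1", "c1ccncc1", "CC(=O)Nc1ccc(O)cc1",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "c1ccc2c(c1)cccc2", "CCN(CC)CC",
  "CC(=O)Oc1ccccc1C(=O)O", "C1CCNCC1", "c1ccsc1", "c1cc[nH]c1",
  "CC(N)C(=O)O", "NCCc1ccc(O)c(O)c1", "CN1CCC(CC1)c1ccccc1",
  "OCC1OC(O)C(O)C(O)C1O", "CC1=CC(=O)CC(C)(C)C1", "N#Cc1ccccc1",
  "COc1ccc(CC(N)C(=O)O)cc1", "Clc1ccc(Cl)cc1")
SIM_SUBSTITUENTS <- c("", "C", "CC", "O", "N", "CO", "CN", "F")

#' Simulation configuration
#'
#' Defaults state the simulated world: 50 proteins x 10 drugs with 200
#' sampled pairs, protein lengths 150-200 residues, one planted 8-residue
#' motif per protein drawn from one of 4 motif classes, and affinities
#' `base + gain * compat(drug class, motif class) + N(0, noise_sd)` clipped
#' to the plausible pKd range [4, 10].  The base of 5 mirrors the
#' concentration of Davis-style labels around pKd 5.
#'
#' @param n_proteins,n_drugs,n_pairs dataset sizes
#'   (`n_pairs <= n_proteins * n_drugs`).
#' @param protein_length_range inclusive length range of the random
#'   sequences.
#' @param motif_length planted motif (site) length.
#' @param n_motif_classes number of motif/drug classes.
#' @param affinity_base,affinity_gain,noise_sd affinity model parameters.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 50L, n_drugs = 10L, n_pairs = 200L,
                       protein_length_range = c(150L, 200L), motif_length = 8L,
                       n_motif_classes = 4L, affinity_base = 5, affinity_gain = 2,
                       noise_sd = 0.2, seed = 0L) {
  cfg <- list(n_proteins = as.integer(n_proteins), n_drugs = as.integer(n_drugs),
              n_pairs = as.integer(n_pairs),
              protein_length_range = as.integer(protein_length_range),
              motif_length = as.integer(motif_length),
              n_motif_classes = as.integer(n_motif_classes),
              affinity_base = affinity_base, affinity_gain = affinity_gain,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$motif_length > min(cfg$protein_length_range))
    stop("motif_length must not exceed the minimum protein length")
  if (cfg$n_pairs > cfg$n_proteins * cfg$n_drugs)
    stop("n_pairs exceeds the number of distinct (drug, protein) pairs")
  if (cfg$n_proteins < 1L || cfg$n_drugs < 1L || cfg$n_pairs < 1L)
    stop("dataset sizes must be positive")
  structure(cfg, class = "sim_config")
}

# deterministic class motifs: each class draws its motif from a distinct
# reduced residue alphabet, so classes are separable by sequence content
sim_motifs <- function(cfg) {
  pools <- split(AA_ALPHABET, rep(seq_len(cfg$n_motif_classes),
                                  length.out = length(AA_ALPHABET)))
  vapply(seq_len(cfg$n_motif_classes), function(cl)
    paste(sample(pools[[cl]], cfg$motif_length, replace = TRUE), collapse = ""),
    "")
}

# drug-motif compatibility: 1 when the classes match, else 0
sim_compat <- function(drug_class, motif_class) as.numeric(drug_class == motif_class)

#' Noiseless planted affinity for a class pair
#'
#' @param drug_class,motif_class 1-based class indices.
#' @param cfg a [sim_config()].
#' @return `affinity_base + affinity_gain * compat`, before noise/clipping.
#' @export
oracle_affinity <- function(drug_class, motif_class, cfg) {
  cfg$affinity_base + cfg$affinity_gain * sim_compat(drug_class, motif_class)
}

#' Generate a synthetic drug-target dataset with planted binding sites
#'
#' Proteins are i.i.d. uniform residue sequences with one class-specific
#' motif inserted at a recorded interval (the annotated site).  Drugs cycle
#' through a pool of valid template molecules with substituent variation and
#' carry a motif-class affinity profile.  Affinities follow
#' [oracle_affinity()] plus Gaussian noise, clipped to [4, 10].
#'
#' @param cfg a [sim_config()].
#' @return List with `proteins` (records incl. sites), `drugs` (records),
#'   `affinities` (data.frame), `protein_classes`, `drug_classes` and
#'   `motifs`.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    motifs <- sim_motifs(cfg)
    p_class <- sample.int(cfg$n_motif_classes, cfg$n_proteins, replace = TRUE)
    proteins <- lapply(seq_len(cfg$n_proteins), function(i) {
      len <- sample(seq(cfg$protein_length_range[1], cfg$protein_length_range[2]), 1L)
      sq <- paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
      start <- sample.int(len - cfg$motif_length + 1L, 1L) - 1L  # 0-based
      substr(sq, start + 1L, start + cfg$motif_length) <- motifs[p_class[i]]
      protein_record(sprintf("P%03d", i), sq,
                     sites = cbind(start = start, end = start + cfg$motif_length))
    })
    d_class <- rep(seq_len(cfg$n_motif_classes), length.out = cfg$n_drugs)
    smiles <- vapply(seq_len(cfg$n_drugs), function(i) {
      base <- SIM_SMILES_POOL[(i - 1L) %% length(SIM_SMILES_POOL) + 1L]
      sub <- SIM_SUBSTITUENTS[((i - 1L) %/% length(SIM_SMILES_POOL)) %%
                                length(SIM_SUBSTITUENTS) + 1L]
      paste0(sub, base)
    }, "")
    drugs <- lapply(seq_len(cfg$n_drugs), function(i)
      drug_record(sprintf("D%03d", i), smiles[i]))
    all_pairs <- expand.grid(d = seq_len(cfg$n_drugs), p = seq_len(cfg$n_proteins))
    pick <- all_pairs[sample.int(nrow(all_pairs), cfg$n_pairs), ]
    aff <- cfg$affinity_base +
      cfg$affinity_gain * sim_compat(d_class[pick$d], p_class[pick$p]) +
      stats::rnorm(cfg$n_pairs, sd = cfg$noise_sd)
    affinities <- data.frame(
      drug_id = sprintf("D%03d", pick$d), protein_id = sprintf("P%03d", pick$p),
      affinity = pmin(pmax(aff, 4), 10), stringsAsFactors = FALSE)
    list(proteins = proteins, drugs = drugs, affinities = affinities,
         protein_classes = p_class, drug_classes = d_class, motifs = motifs,
         config = cfg)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA (proteins), drugs TSV, affinities TSV, sites TSV and a JSON
#' manifest recording the configuration.
#'
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$proteins, file.path(dir, "proteins.fasta"))
  write_smiles_table(ds$drugs, file.path(dir, "drugs.tsv"))
  write_affinities(ds$affinities, file.path(dir, "affinities.tsv"))
  sites <- lapply(ds$proteins, `[[`, "sites")
  names(sites) <- vapply(ds$proteins, `[[`, "", "id")
  write_sites(sites, file.path(dir, "sites.tsv"))
  jsonlite::write_json(unclass(ds$config), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
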
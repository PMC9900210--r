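# Shared fixtures built in code.

ns <- asNamespace("dtamix")

# tiny end-to-end configuration that keeps full forward/backward passes fast
tiny_cfg <- function(...) {
  dta_config("tiny", L_P = 24L, L_D = 8L, C_P = 6L, C_D = 6L, C_S = 6L,
             kernel_lk = c(3L, 3L, 5L), kernel_2d = 3L, groups = 2L,
             fp_bits = 32L, head_hidden = c(8L, 4L), we_vocab_size = 64L, ...)
}

random_protein <- function(id, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  protein_record(id, paste(sample(dtamix:::AA_ALPHABET, len, TRUE), collapse = ""),
                 sites = {
                   s <- sample.int(len - 4L, 1L) - 1L
                   cbind(start = s, end = s + 4L)
                 })
}

# tiny featurized dataset: 3 proteins x 2 drugs
tiny_world <- function(seed = 11L) {
  set.seed(seed)
  cfg <- tiny_cfg()
  proteins <- lapply(1:3, function(i) random_protein(paste0("P", i), 20L + i))
  drugs <- list(drug_record("D1", "CCO"), drug_record("D2", "c1ccncc1"))
  store <- featurize_dataset(proteins, drugs, cfg)
  affinities <- data.frame(
    drug_id = c("D1", "D2", "D1", "D2", "D1", "D2"),
    protein_id = c("P1", "P1", "P2", "P2", "P3", "P3"),
    affinity = c(5.1, 6.8, 7.2, 5.0, 6.1, 5.6), stringsAsFactors = FALSE)
  list(cfg = cfg, proteins = proteins, drugs = drugs, store = store,
       affinities = affinities)
}
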
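# Full model: two encoder branches per entity, gated fusion, mix-decoder,
# affinity head; joint loss on affinity (MSE) and response vector
# (rectified Wing against interval-coded site labels).

#' Initialize all model parameters
#'
#' @param cfg a [dta_config()].
#' @param we_vocab_n number of k-mer tokens in the word-embedding vocabulary
#'   (pad and OOV rows are added internally).
#' @return Nested parameter list (leaves are autodiff parameter nodes).
#' @export
init_model_params <- function(cfg, we_vocab_n) {
  emb <- function(V, C, name)
    ag_param(matrix(stats::rnorm(V * C, sd = 0.1), V, C), name = name)
  prot <- list(
    aae_emb = emb(22L, cfg$C_P, "prot.aae_emb"),
    we_emb = emb(we_vocab_n + 2L, cfg$C_P, "prot.we_emb"),
    enc_aae = init_bio_blocks("cnn", cfg$Pn, cfg$L_P, cfg$C_P, cfg, "prot.aae"),
    enc_we = init_bio_blocks("cnn", cfg$Pn, cfg$L_P, cfg$C_P, cfg, "prot.we"),
    fuse = make_fusion(cfg$C_P, cfg$C_P, cfg$C_S, cfg$kernel_2d, cfg$share_fc1, "prot.fuse"))
  drug <- list(
    fp_fc1 = make_fc(cfg$fp_bits, cfg$C_D, "drug.fp_fc1"),
    fp_fc2 = make_fc(cfg$C_D, cfg$L_D * cfg$C_D, "drug.fp_fc2"),
    atom_fc = make_fc(cfg$f_atom, cfg$C_D, "drug.atom_fc"),
    enc_fp = init_bio_blocks("mlp", cfg$Dn, cfg$L_D, cfg$C_D, cfg, "drug.fp"),
    enc_graph = init_bio_blocks("mlp", cfg$Dn, cfg$L_D, cfg$C_D, cfg, "drug.graph"),
    fuse = make_fusion(cfg$C_D, cfg$C_D, cfg$C_S, cfg$kernel_2d, cfg$share_fc1, "drug.fuse"))
  N <- cfg$L_P + cfg$L_D
  mix <- list(
    Ws = ag_param(glorot(cfg$L_D, cfg$C_S), name = "mix.Ws"),
    se_p = list(W1 = ag_param(glorot(cfg$C_S, cfg$C_S), name = "mix.se_p.W1"),
                Wm = ag_param(glorot(cfg$C_S, cfg$C_S), name = "mix.se_p.Wm")),
    se_d = list(W1 = ag_param(glorot(cfg$C_S, cfg$C_S), name = "mix.se_d.W1"),
                Wm = ag_param(glorot(cfg$C_S, cfg$C_S), name = "mix.se_d.Wm")),
    ca = list(Wm1 = ag_param(glorot(cfg$C_S, cfg$C_S), name = "mix.ca.Wm1"),
              Wm2 = ag_param(glorot(N, N), name = "mix.ca.Wm2")),
    head = {
      dims <- c(N + cfg$C_S, cfg$head_hidden, 1L)
      lapply(seq_len(length(dims) - 1L), function(i)
        make_fc(dims[i], dims[i + 1L], paste0("mix.head", i)))
    })
  list(prot = prot, drug = drug, mix = mix)
}

# one full forward pass for a (protein, drug) input pair; returns the
# affinity node (1 x 1) and the response-vector node (L_P x 1)
fwd_model <- function(tp, params, cfg, pin, din, training = FALSE) {
  Fa <- fwd_bio_stack(tp, ag_embed(tp, params$prot$aae_emb, pin$aae$idx, pin$aae$mask),
                      params$prot$enc_aae, cfg$use_norm)
  Fw <- fwd_bio_stack(tp, ag_embed(tp, params$prot$we_emb, pin$we$idx, pin$we$mask),
                      params$prot$enc_we, cfg$use_norm)
  Fp <- fwd_fuse(tp, Fa, Fw, params$prot$fuse)

  hfp <- ag_relu(tp, fwd_fc(tp, ag_const(matrix(din$fp, nrow = 1L)), params$drug$fp_fc1))
  Xfp <- ag_reshape(tp, fwd_fc(tp, hfp, params$drug$fp_fc2), cfg$L_D, cfg$C_D)
  Xgr <- fwd_fc(tp, ag_const(din$graph$atom_features), params$drug$atom_fc)
  Fd <- fwd_fuse(tp, fwd_bio_stack(tp, Xfp, params$drug$enc_fp, cfg$use_norm),
                 fwd_bio_stack(tp, Xgr, params$drug$enc_graph, cfg$use_norm),
                 params$drug$fuse)

  K <- ag_matmul(tp, params$mix$Ws, Fd, ta = TRUE)
  s <- ag_response(tp, Fp, K)
  Fp2 <- ag_scale_rows(tp, Fp, s)
  Xd2 <- ag_scale_rows(tp, Fd, ag_const(matrix(rowMeans(din$graph$adj), ncol = 1L)))
  Xp3 <- fwd_self_enhance(tp, Fp2, params$mix$se_p)
  Xd3 <- fwd_self_enhance(tp, Xd2, params$mix$se_d)
  Y <- fwd_cross_attend(tp, Xp3, Xd3, params$mix$ca, cfg$C_S)
  v <- ag_vcat(tp, list(ag_rowmeans(tp, Y), ag_colmeans(tp, Y)))
  aff <- fwd_head(tp, v, params$mix$head, cfg$dropout, training)
  list(aff = aff, s = s)
}

# per-sample joint loss node; y_site NULL => affinity term only
fwd_loss <- function(tp, out, y_aff, y_site, cfg) {
  l <- ag_mse(tp, out$aff, y_aff)
  if (!is.null(y_site) && cfg$lambda_br != 0) {
    l <- ag_add(tp, l, ag_scale(tp, ag_rwing_mean(tp, out$s, y_site, cfg$loss_w,
                                                  cfg$loss_r, cfg$loss_epsilon),
                                cfg$lambda_br))
  }
  l
}

#' Featurize a dataset once for training/prediction
#'
#' Encodes every protein (amino-acid and k-mer indices) and drug
#' (fingerprint, atom features, adjacency) under a configuration, building
#' the k-mer vocabulary from the given proteins when none is supplied.
#'
#' @param proteins list of [protein_record()] objects.
#' @param drugs list of [drug_record()] objects.
#' @param cfg a [dta_config()].
#' @param vocab optional [build_we_vocab()] result (reuse the training
#'   vocabulary when featurizing new data).
#' @return An object of class `dta_store` with per-id encoded inputs,
#'   per-protein site label intervals and the vocabulary.
#' @export
featurize_dataset <- function(proteins, drugs, cfg, vocab = NULL) {
  if (is.null(vocab))
    vocab <- build_we_vocab(vapply(proteins, `[[`, "", "sequence"),
                            k = cfg$we_k, max_size = cfg$we_vocab_size)
  pins <- lapply(proteins, function(p) {
    list(aae = encode_protein_aae(p$sequence, cfg$L_P),
         we = encode_protein_we(p$sequence, vocab, cfg$L_P),
         sites = p$sites)
  })
  names(pins) <- vapply(proteins, `[[`, "", "id")
  dins <- lapply(drugs, function(d) {
    list(fp = encode_drug_fcfp(d$smiles, cfg$fp_radius, cfg$fp_bits),
         graph = smiles_to_graph(d$smiles, cfg$L_D))
  })
  names(dins) <- vapply(drugs, `[[`, "", "id")
  structure(list(proteins = pins, drugs = dins, vocab = vocab, cfg = cfg),
            class = "dta_store")
}

#' @export
print.dta_store <- function(x, ...) {
  cat("<dta_store>", length(x$proteins), "proteins,", length(x$drugs),
      "drugs, k-mer vocab", length(x$vocab$tokens), "\n")
  invisible(x)
}

# site label vector for one (protein, affinity) pair, NULL when unannotated
site_label_vector <- function(pin, affinity, L_P) {
  iv <- as_interval_matrix(pin$sites)
  if (nrow(iv) == 0L) return(NULL)
  suppressWarnings(embed_site_labels(iv, affinity, L_P))
}
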
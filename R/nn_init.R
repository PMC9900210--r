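# Parameter constructors and initialization.
#
# All draws come from the session RNG, so a single set.seed() before
# init_model_params() pins the whole initialization.

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

make_fc <- function(nin, nout, name = "fc") {
  list(W = ag_param(glorot(nin, nout), name = paste0(name, ".W")),
       b = ag_param(numeric(nout), name = paste0(name, ".b"), decay = FALSE))
}

# trainable per-channel scale/shift (the affine block)
make_affine <- function(C, name = "af") {
  list(alpha = ag_param(rep(1, C), name = paste0(name, ".alpha"), decay = FALSE),
       beta = ag_param(numeric(C), name = paste0(name, ".beta"), decay = FALSE))
}

# spatial-attention gate: k x k kernel + scalar bias
make_att <- function(k, name = "att") {
  list(W = ag_param(glorot(k, k), name = paste0(name, ".W")),
       b = ag_param(0, name = paste0(name, ".b"), decay = FALSE))
}

make_conv1d <- function(k, C, groups, name = "conv") {
  Cg <- C %/% groups
  list(W = ag_param(glorot(k * Cg, C), name = paste0(name, ".W")),
       b = ag_param(numeric(C), name = paste0(name, ".b"), decay = FALSE),
       k = k, groups = groups, cache = new.env(parent = emptyenv()))
}

make_biomlp_block <- function(L, C, name = "biomlp") {
  list(type = "mlp",
       global = list(af1 = make_affine(C, paste0(name, ".g.af1")),
                     fc = lapply(1:3, function(i) make_fc(L, L, paste0(name, ".g.fc", i))),
                     af2 = make_affine(C, paste0(name, ".g.af2"))),
       af3 = make_affine(C, paste0(name, ".af3")),
       fc2 = lapply(1:2, function(i) make_fc(C, C, paste0(name, ".fc2.", i))),
       af4 = make_affine(C, paste0(name, ".af4")),
       att = NULL,  # filled by caller (kernel size)
       fc_out = make_fc(C, C, paste0(name, ".out")))
}

make_biocnn_block <- function(L, C, kernel_lk, groups, name = "biocnn") {
  list(type = "cnn",
       global = list(af1 = make_affine(C, paste0(name, ".g.af1")),
                     fc = lapply(1:3, function(i) make_fc(L, L, paste0(name, ".g.fc", i))),
                     af2 = make_affine(C, paste0(name, ".g.af2"))),
       af3 = make_affine(C, paste0(name, ".af3")),
       convs = lapply(seq_along(kernel_lk), function(i)
         make_conv1d(kernel_lk[i], C, groups, paste0(name, ".conv", i))),
       norm = lapply(seq_along(kernel_lk), function(i) make_affine(C, paste0(name, ".bn", i))),
       af4 = make_affine(C, paste0(name, ".af4")),
       att = NULL,
       fc_out = make_fc(C, C, paste0(name, ".out")))
}

make_fusion <- function(C_in1, C_in2, C_S, kernel_2d, share_fc1, name = "fuse") {
  p <- list(
    align1 = if (C_in1 != C_S) make_fc(C_in1, C_S, paste0(name, ".align1")) else NULL,
    align2 = if (C_in2 != C_S) make_fc(C_in2, C_S, paste0(name, ".align2")) else NULL,
    fc1_a = make_fc(C_S, C_S, paste0(name, ".fc1a")),
    gate = list(W1 = ag_param(glorot(kernel_2d, kernel_2d), name = paste0(name, ".gate.W1")),
                W2 = ag_param(glorot(kernel_2d, kernel_2d), name = paste0(name, ".gate.W2")),
                b = ag_param(0, name = paste0(name, ".gate.b"), decay = FALSE)))
  p$fc1_b <- if (share_fc1) p$fc1_a else make_fc(C_S, C_S, paste0(name, ".fc1b"))
  p
}

# recursively collect unique parameter nodes from a nested params list
collect_params <- function(p) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x) && isTRUE(x$param)) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(p)
  out[!duplicated(vapply(out, data.table::address, ""))]
}

# wrap plain-numeric weight leaves of a params list as constant nodes so the
# ag forwards can run outside training; structural fields (k, groups, type)
# are kept as-is
wrap_params <- function(p) {
  weight_names <- c("W", "b", "W1", "W2", "alpha", "beta")
  if (is.environment(p) || is.null(p)) return(p)
  if (!is.list(p)) return(p)
  out <- p
  for (nm in seq_along(p)) {
    el <- p[[nm]]
    lab <- if (is.null(names(p))) "" else names(p)[nm]
    if (is.numeric(el) && lab %in% weight_names) out[[nm]] <- ag_const(el)
    else if (is.list(el)) out[[nm]] <- wrap_params(el)
  }
  out
}

# deep copy of parameter values (for checkpoints / best-model tracking)
snapshot_params <- function(params) lapply(collect_params(params), function(p) p$v)

restore_params <- function(params, snap) {
  ps <- collect_params(params)
  stopifnot(length(ps) == length(snap))
  for (i in seq_along(ps)) ps[[i]]$v <- snap[[i]]
  invisible(params)
}
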
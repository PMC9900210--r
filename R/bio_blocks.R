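# Token-mixing encoder blocks.
#
# Each block is a global feature extractor (a residual 3-layer FC stack that
# acts along the LENGTH axis, mixing positions per channel) followed by an
# individual feature extractor (per-element refinement: a channel-axis FC
# stack for drugs, a large-kernel grouped 1D convolution stack for
# proteins), gated by spatial attention and residual-added.
#
# Every forward here is written against the autodiff engine; the exported
# functions wrap plain-matrix parameters as constant nodes and return plain
# matrices, so the same math serves training and the user-facing API.

# ---- ag forwards -----------------------------------------------------------

fwd_affine <- function(tp, X, af) ag_affine_ch(tp, X, af$alpha, af$beta)

fwd_fc <- function(tp, X, fc) ag_add_bias(tp, ag_matmul(tp, X, fc$W), fc$b)

# Xout = Xin + AF2( FC3( AF1(Xin)^T )^T ): token mixing along the length
# axis.  Computed transpose-free: (X^T W + b)^T == W^T X + b(row-wise), see
# ag_lenfc.
fwd_global <- function(tp, X, p) {
  h <- fwd_affine(tp, X, p$af1)
  h <- ag_relu(tp, ag_lenfc(tp, h, p$fc[[1]]$W, p$fc[[1]]$b))
  h <- ag_relu(tp, ag_lenfc(tp, h, p$fc[[2]]$W, p$fc[[2]]$b))
  h <- ag_lenfc(tp, h, p$fc[[3]]$W, p$fc[[3]]$b)
  h <- fwd_affine(tp, h, p$af2)
  ag_add(tp, X, h)
}

# Att(X) = X * sigmoid(CNN2D(X)): per-position-per-channel gate
fwd_att <- function(tp, X, att) {
  ag_mul(tp, X, ag_sigmoid(tp, ag_conv2d(tp, X, att$W, att$b)))
}

# XMLP = FC( Xout + Att( AF( FC2( AF(Xout) ) ) ) )
fwd_mlp_individual <- function(tp, X, p) {
  h <- fwd_affine(tp, X, p$af3)
  h <- ag_relu(tp, fwd_fc(tp, h, p$fc2[[1]]))
  h <- fwd_fc(tp, h, p$fc2[[2]])
  h <- fwd_affine(tp, h, p$af4)
  h <- fwd_att(tp, h, p$att)
  fwd_fc(tp, ag_add(tp, X, h), p$fc_out)
}

# XCNN = FC( Xout + Att( AF( CNNLK( AF(Xout) ) ) ) ), CNNLK = 3 x
# {grouped 1D conv, per-channel length-axis normalization, ReLU}
fwd_cnn_individual <- function(tp, X, p, use_norm = TRUE) {
  h <- fwd_affine(tp, X, p$af3)
  for (i in seq_along(p$convs)) {
    cv <- p$convs[[i]]
    h <- ag_conv1d_group(tp, h, cv$W, cv$b, cv$k, cv$groups, cv$cache)
    if (use_norm) h <- fwd_affine(tp, ag_norm_len(tp, h), p$norm[[i]])
    h <- ag_relu(tp, h)
  }
  h <- fwd_affine(tp, h, p$af4)
  h <- fwd_att(tp, h, p$att)
  fwd_fc(tp, ag_add(tp, X, h), p$fc_out)
}

fwd_bio_block <- function(tp, X, p, use_norm = TRUE) {
  X <- fwd_global(tp, X, p$global)
  if (p$type == "mlp") fwd_mlp_individual(tp, X, p)
  else fwd_cnn_individual(tp, X, p, use_norm)
}

fwd_bio_stack <- function(tp, X, blocks, use_norm = TRUE) {
  for (p in blocks) X <- fwd_bio_block(tp, X, p, use_norm)
  X
}

# ---- parameter initializers ------------------------------------------------

#' Initialize a stack of encoder blocks
#'
#' @param type `"mlp"` (channel-axis individual extractor, drugs) or
#'   `"cnn"` (large-kernel grouped convolutions, proteins).
#' @param n number of stacked blocks (Dn or Pn).
#' @param L,C length and channel size of the feature map.
#' @param cfg a [dta_config()] supplying kernel sizes and group count.
#' @param name parameter name prefix.
#' @return Nested parameter list usable by [encode_with_blocks()].
#' @export
init_bio_blocks <- function(type = c("mlp", "cnn"), n, L, C, cfg, name = type) {
  type <- match.arg(type)
  lapply(seq_len(n), function(i) {
    p <- if (type == "mlp") make_biomlp_block(L, C, paste0(name, i))
    else make_biocnn_block(L, C, cfg$kernel_lk, cfg$groups, paste0(name, i))
    p$att <- make_att(cfg$kernel_2d, paste0(name, i, ".att"))
    p
  })
}

# ---- exported pure surface -------------------------------------------------

#' Affine (per-channel scale and shift) transform
#'
#' `AF(X) = Diag(alpha) applied channel-wise: each channel c of `X` is
#' scaled by `alpha[c]` and shifted by `beta[c]`.
#'
#' @param X `L x C` matrix.
#' @param alpha,beta numeric vectors of length `C`.
#' @return `L x C` matrix.
#' @export
affine_transform <- function(X, alpha, beta) {
  if (length(alpha) != ncol(X) || length(beta) != ncol(X))
    stop("affine_transform: alpha/beta length must equal ncol(X)")
  sweep(sweep(X, 2L, alpha, "*"), 2L, beta, "+")
}

#' Global feature extractor (token mixing along the length axis)
#'
#' `Xout = Xin + AF2(FC3(AF1(Xin)^T)^T)`: a residual three-layer fully
#' connected stack (two rectifier layers) acting on the length axis.
#'
#' @param X `L x C` matrix.
#' @param params parameter list with `af1`, `fc` (list of 3 `W`/`b` pairs,
#'   each `L x L`), `af2`; plain matrices accepted.
#' @return `L x C` matrix.
#' @export
global_feature_extractor <- function(X, params) {
  run_pure(function(tp) fwd_global(tp, ag_const(X), wrap_params(params)))
}

#' Spatial attention gate
#'
#' `Att(X) = X * sigmoid(CNN2D(X))` with a single-channel `k x k` 'same'
#' convolution over the `L x C` map.
#'
#' @param X `L x C` matrix.
#' @param W `k x k` kernel (odd k).
#' @param b scalar bias.
#' @return Gated `L x C` matrix.
#' @export
spatial_attention <- function(X, W, b = 0) {
  X * stats::plogis(cpp_conv2d_same(X, W, b))
}

#' Individual feature extractor of the drug encoder
#'
#' Channel-axis two-layer FC stack wrapped in affines, gated by spatial
#' attention, residual-added, then a final FC.
#'
#' @param X `L x C` output of [global_feature_extractor()].
#' @param params parameter list (`af3`, `fc2`, `af4`, `att`, `fc_out`).
#' @return `L x C_out` matrix.
#' @export
biomlp_individual <- function(X, params) {
  run_pure(function(tp) fwd_mlp_individual(tp, ag_const(X), wrap_params(params)))
}

#' Individual feature extractor of the protein encoder
#'
#' Three large-kernel grouped 1D convolution blocks (with optional
#' per-channel normalization and rectifiers) wrapped in affines, gated by
#' spatial attention, residual-added, then a final FC.
#'
#' @param X `L x C` output of [global_feature_extractor()].
#' @param params parameter list (`af3`, `convs`, `norm`, `af4`, `att`,
#'   `fc_out`).
#' @param use_norm enable the normalization layers.
#' @return `L x C_out` matrix.
#' @export
biocnn_individual <- function(X, params, use_norm = TRUE) {
  run_pure(function(tp) fwd_cnn_individual(tp, ag_const(X), wrap_params(params), use_norm))
}

#' Run a stack of encoder blocks on an embedded feature map
#'
#' @param X `L x C` matrix (already embedded).
#' @param blocks parameter list from [init_bio_blocks()].
#' @param use_norm enable normalization inside convolution blocks.
#' @return Encoded `L x C` matrix.
#' @export
encode_with_blocks <- function(X, blocks, use_norm = TRUE) {
  run_pure(function(tp) fwd_bio_stack(tp, ag_const(X), wrap_params(blocks), use_norm))
}

run_pure <- function(f) {
  tp <- ag_tape()
  f(tp)$v
}
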
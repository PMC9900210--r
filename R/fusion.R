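# Gated element-feature fusion of the two representations of an entity
# (amino-acid + k-mer embeddings for proteins; fingerprint + graph features
# for drugs) into one L x C_S matrix:
#
#   Watt = sigmoid(CNN2D(Concat(X1, X2)))
#   Xf   = FC1(X1) * Watt + X1 + FC1(X2) * (1 - Watt) + X2
#
# The concatenation feeds the gate convolution as two aligned input
# channels (one per representation), so the k x k gate kernel pair maps the
# stacked L x C_S maps back to a single L x C_S attention matrix.

fwd_align <- function(tp, X, align) if (is.null(align)) X else fwd_fc(tp, X, align)

fwd_fuse <- function(tp, X1, X2, p) {
  X1 <- fwd_align(tp, X1, p$align1)
  X2 <- fwd_align(tp, X2, p$align2)
  gate <- ag_add(tp, ag_conv2d(tp, X1, p$gate$W1, p$gate$b),
                 ag_conv2d(tp, X2, p$gate$W2, ag_const(0)))
  Watt <- ag_sigmoid(tp, gate)
  b1 <- ag_relu(tp, fwd_fc(tp, X1, p$fc1_a))
  b2 <- ag_relu(tp, fwd_fc(tp, X2, p$fc1_b))
  ag_add(tp, ag_add(tp, ag_mul(tp, b1, Watt), X1),
         ag_add(tp, ag_mul(tp, b2, ag_one_minus(tp, Watt)), X2))
}

#' Project a feature matrix to the shared channel width
#'
#' Learned linear map reconciling encoder channels (e.g. 100 protein
#' channels) with the shared fusion width `C_S`; the identity when the
#' widths already agree.
#'
#' @param X `L x C` matrix.
#' @param W,b projection parameters (`C x C_S`, length `C_S`); may be
#'   omitted when `C == C_S`.
#' @return `L x C_S` matrix.
#' @export
align_channels <- function(X, W = NULL, b = NULL) {
  if (is.null(W)) return(X)
  if (is.null(b)) b <- numeric(ncol(W))
  sweep(X %*% W, 2L, b, "+")
}

#' Gated fusion of two representations of one entity
#'
#' @param X1,X2 `L x C_S` matrices (already channel-aligned).
#' @param params parameter list: `fc1_a`, `fc1_b` (each `W` `C_S x C_S`,
#'   `b`), and `gate` (`W1`, `W2` `k x k` kernels, scalar `b`).  The two
#'   branch projections share weights when `fc1_b` is the same object as
#'   `fc1_a`.
#' @return Fused `L x C_S` matrix.
#' @export
elem_feature_fuse <- function(X1, X2, params) {
  if (!all(dim(X1) == dim(X2))) stop("elem_feature_fuse: X1/X2 shape mismatch")
  params$align1 <- NULL; params$align2 <- NULL
  run_pure(function(tp) fwd_fuse(tp, ag_const(X1), ag_const(X2), wrap_params(params)))
}
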
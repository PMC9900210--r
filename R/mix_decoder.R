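# The mix-decoder: drug-kernel sampling, the per-residue drug-target
# response vector, binding-region / adjacency information injection,
# self-enhancement and cross-attention, and pooling to the interaction
# vector feeding the affinity head.

# ---- pure exported operations ---------------------------------------------

#' Sample the drug kernel from the drug feature matrix
#'
#' `K = Ws^T Fd`: a learned linear layer collapses the drug length axis,
#' yielding a `C_S x C_S` kernel.
#'
#' @param Fd `L_D x C_S` drug feature matrix.
#' @param Ws `L_D x C_S` sampling weights.
#' @return `C_S x C_S` kernel.
#' @export
sample_drug_kernel <- function(Fd, Ws) {
  if (!all(dim(Fd) == dim(Ws))) stop("sample_drug_kernel: Ws must match Fd in shape")
  crossprod(Ws, Fd)
}

#' Per-residue drug-target response vector
#'
#' Slides the drug kernel along the protein feature map as a full-channel
#' window of height `C_S` centred at each residue ('same' zero padding):
#' `s_i = sum_{m,n} K(m,n) * Fp(i + m - floor(C_S/2), n)`.  The residues
#' with the highest response are the predicted binding region.
#'
#' @param Fp `L_P x C_S` protein feature matrix.
#' @param K kernel with `C_S` columns (typically `C_S x C_S`).
#' @return Numeric response vector of length `L_P`.
#' @export
compute_response_vector <- function(Fp, K) {
  as.numeric(cpp_response_vector(Fp, K))
}

#' Predicted binding region at scale S
#'
#' The region midpoint is the argmax of the response vector (smallest index
#' on ties); the interval `[c - floor(S/2), c + ceiling(S/2))` is clipped to
#' `[0, L_P)`.
#'
#' @param s response vector.
#' @param S region length in residues (>= 1).
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
predict_binding_region <- function(s, S) {
  if (S < 1) stop("predict_binding_region: S must be >= 1")
  L <- length(s)
  cen <- which.max(s) - 1L  # 0-based; which.max takes the first maximum
  c(start = max(0L, cen - S %/% 2L), end = min(L, cen + as.integer(ceiling(S / 2))))
}

#' Inject binding-region information into the protein features
#'
#' The response vector is column-replicated to an `L_P x C_S` matrix and
#' applied element-wise: row i of `Fp` is scaled by `s_i`.
#'
#' @param Fp `L_P x C_S` protein features.
#' @param s response vector of length `L_P`.
#' @return Weighted `L_P x C_S` matrix.
#' @export
inject_region_info <- function(Fp, s) {
  if (length(s) != nrow(Fp)) stop("inject_region_info: length(s) != nrow(Fp)")
  Fp * as.numeric(s)
}

#' Inject adjacency (connectivity) information into the drug features
#'
#' The adjacency matrix is down-sampled to an atom connectivity vector by
#' global average pooling over rows (`c_i = mean_j adj(i, j)`), replicated
#' across channels, and applied element-wise.
#'
#' @param Xd `L_D x C_S` drug features.
#' @param adj `L_D x L_D` adjacency matrix (unit diagonal on real atoms).
#' @return Weighted `L_D x C_S` matrix.
#' @export
inject_adj_info <- function(Xd, adj) {
  if (nrow(adj) != nrow(Xd) || ncol(adj) != nrow(Xd))
    stop("inject_adj_info: adj must be L_D x L_D")
  Xd * rowMeans(adj)
}

#' Self-enhancement block
#'
#' `Xout = (Xin W1) * fa(Xin)` with `fa(X) = softmax((X Wm) / C_S)` taken
#' over the length axis per channel, so positions compete for enhancement.
#'
#' @param X `L x C_S` feature matrix.
#' @param W1,Wm `C_S x C_S` parameter matrices.
#' @return Enhanced `L x C_S` matrix.
#' @export
self_enhance <- function(X, W1, Wm) {
  run_pure(function(tp) {
    Xn <- ag_const(X)
    fa <- ag_softmax_len(tp, ag_scale(tp, ag_matmul(tp, Xn, ag_const(Wm)), 1 / ncol(X)))
    ag_mul(tp, ag_matmul(tp, Xn, ag_const(W1)), fa)
  })
}

#' Cross-attention block
#'
#' Concatenates the protein and drug feature matrices along the length axis
#' (`Xm`, `(L_P + L_D) x C_S`) and computes
#' `Yout = Xm + ((Xm Wm1)^T Wm2)^T * fa(Xm)`; the token-mixing product is
#' transposed back so the element-wise product is shape-consistent.
#'
#' @param Xp `L_P x C_S` protein features.
#' @param Xd `L_D x C_S` drug features.
#' @param Wm1 `C_S x C_S` parameter matrix.
#' @param Wm2 `(L_P + L_D) x (L_P + L_D)` parameter matrix.
#' @return `(L_P + L_D) x C_S` matrix.
#' @export
cross_attend <- function(Xp, Xd, Wm1, Wm2) {
  run_pure(function(tp)
    fwd_cross_attend(tp, ag_const(Xp), ag_const(Xd),
                     list(Wm1 = ag_const(Wm1), Wm2 = ag_const(Wm2)), ncol(Xp)))
}

#' Pool the interaction matrix to the interaction vector
#'
#' Global average pooling over both axes: row means (length `L_P + L_D`)
#' concatenated with column means (length `C_S`).
#'
#' @param Y `(L_P + L_D) x C_S` matrix.
#' @return Numeric vector of length `L_P + L_D + C_S`.
#' @export
pool_interaction <- function(Y) {
  c(rowMeans(Y), colMeans(Y))
}

#' Affinity head
#'
#' Three fully connected layers with rectifiers (and dropout during
#' training) mapping the interaction vector to a scalar affinity.
#'
#' @param v interaction vector.
#' @param params list of three `W`/`b` layer parameter pairs.
#' @return Predicted affinity (scalar).
#' @export
affinity_head <- function(v, params) {
  run_pure(function(tp)
    fwd_head(tp, ag_const(matrix(v, ncol = 1L)), wrap_params(params),
             dropout = 0, training = FALSE))
}

# ---- ag forwards -----------------------------------------------------------

fwd_self_enhance <- function(tp, X, p) {
  fa <- ag_softmax_len(tp, ag_scale(tp, ag_matmul(tp, X, p$Wm), 1 / ncol(X$v)))
  ag_mul(tp, ag_matmul(tp, X, p$W1), fa)
}

fwd_cross_attend <- function(tp, Xp, Xd, p, C_S) {
  Xm <- ag_rbind(tp, Xp, Xd)
  fa <- ag_softmax_len(tp, ag_scale(tp, ag_matmul(tp, Xm, p$Wm1), 1 / C_S))
  mixed <- ag_transpose(tp, ag_matmul(tp, ag_matmul(tp, Xm, p$Wm1), p$Wm2, ta = TRUE))
  ag_add(tp, Xm, ag_mul(tp, mixed, fa))
}

fwd_head <- function(tp, v, p, dropout, training) {
  h <- v
  n <- length(p)
  for (i in seq_len(n)) {
    # h is a column vector; the bias parameter is stored n x 1, so a plain
    # elementwise add applies it
    h <- ag_add(tp, ag_matmul(tp, p[[i]]$W, h, ta = TRUE), p[[i]]$b)
    if (i < n) {
      h <- ag_relu(tp, h)
      h <- ag_dropout(tp, h, dropout, training)
    }
  }
  h
}
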
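# Loss functions for the joint affinity + binding-region objective.

#' Rectified Wing loss parameters
#'
#' Builds and validates the parameter set of the rectified Wing loss: a dead
#' zone of half-width `r` around zero, a logarithmic segment on
#' `r <= |x| < w`, and linear tails beyond `w`.  `epsilon` controls the
#' curvature of the logarithmic segment.
#'
#' The defaults are `w = 3, r = 1, epsilon = 0.15`.  The branch structure of
#' the loss requires `r < w`; parameter sets violating that ordering (which
#' would empty the logarithmic branch) are rejected.
#'
#' @param w positive width of the non-linear region.
#' @param r non-negative half-width of the rectified (zero) region; must be
#'   smaller than `w`.
#' @param epsilon positive curvature limit of the logarithmic segment.
#' @return A list with elements `w`, `r`, `epsilon` and the continuity
#'   constant `C = w - w * log(1 + (w - r) / epsilon)` that joins the
#'   logarithmic and linear branches.
#' @export
#' @examples
#' p <- rwing_params()
#' rwing(c(-0.5, 0.5, 2, 5), w = p$w, r = p$r, epsilon = p$epsilon)
rwing_params <- function(w = 3, r = 1, epsilon = 0.15) {
  stopifnot(is.numeric(w), is.numeric(r), is.numeric(epsilon))
  if (w <= 0) stop("w must be positive")
  if (r < 0) stop("r must be non-negative")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (r >= w) stop("rwing requires r < w (got r = ", r, ", w = ", w, ")")
  list(w = w, r = r, epsilon = epsilon,
       C = w - w * log(1 + (w - r) / epsilon))
}

#' Rectified Wing loss
#'
#' Piecewise robust loss used to supervise the per-residue response vector
#' against sparse interval-coded site labels: residuals inside `(-r, r)` cost
#' nothing (annotation noise is ignored), mid-range residuals are penalized
#' logarithmically, and large residuals linearly.  The constant
#' `C = w - w*log(1 + (w - r)/epsilon)` makes the function continuous at
#' `|x| = w`.
#'
#' @param x numeric vector of residuals.
#' @inheritParams rwing_params
#' @return Numeric vector of losses, same length as `x`.
#' @export
rwing <- function(x, w = 3, r = 1, epsilon = 0.15) {
  p <- rwing_params(w, r, epsilon)
  ax <- abs(x)
  out <- numeric(length(x))
  mid <- ax >= p$r & ax < p$w
  out[mid] <- p$w * log(1 + (ax[mid] - p$r) / p$epsilon)
  lin <- ax >= p$w
  out[lin] <- ax[lin] - p$C
  out
}

# derivative of rwing wrt x (subgradient 0 taken at the branch corners)
rwing_grad <- function(x, w = 3, r = 1, epsilon = 0.15) {
  p <- rwing_params(w, r, epsilon)
  ax <- abs(x)
  g <- numeric(length(x))
  mid <- ax >= p$r & ax < p$w
  g[mid] <- sign(x[mid]) * p$w / (p$epsilon + ax[mid] - p$r)
  lin <- ax >= p$w
  g[lin] <- sign(x[lin])
  g
}

#' Mean squared error
#'
#' @param pred,obs numeric vectors of equal, positive length.
#' @return Mean of squared residuals.
#' @export
mse_loss <- function(pred, obs) {
  if (length(pred) == 0L) stop("mse_loss: empty input")
  if (length(pred) != length(obs)) stop("mse_loss: length mismatch")
  mean((pred - obs)^2)
}

#' Embed binding-site intervals as a per-residue label vector
#'
#' Builds the supervision target for the response vector: zero off-site and
#' the pair's affinity value on every annotated site residue.  Intervals are
#' 0-based half-open on residue coordinates; parts beyond `L_P` (a truncated
#' sequence) are clipped, and intervals falling entirely outside are dropped
#' with a warning.
#'
#' @param sites matrix or list of 0-based half-open intervals
#'   (columns/elements: start, end), possibly overlapping.
#' @param affinity the pair's affinity label.
#' @param L_P padded protein length.
#' @return Numeric vector of length `L_P`.
#' @export
embed_site_labels <- function(sites, affinity, L_P) {
  y <- numeric(L_P)
  iv <- as_interval_matrix(sites)
  if (nrow(iv) == 0L) return(y)
  dropped <- iv[, 1L] >= L_P
  if (any(dropped)) {
    warning(sum(dropped), " site interval(s) beyond padded length ", L_P, " dropped")
    iv <- iv[!dropped, , drop = FALSE]
  }
  for (i in seq_len(nrow(iv))) {
    s <- max(0L, iv[i, 1L]); e <- min(L_P, iv[i, 2L])
    if (e > s) y[(s + 1L):e] <- affinity
  }
  y
}

#' Joint multi-task loss
#'
#' `MSE(pred_aff, true_aff) + lambda_br * mean_i RWing(s_i - y_i)`.  The
#' region term is averaged over residues; pairs without site annotations
#' should be passed with `y = NULL` so that only the affinity term
#' contributes.
#'
#' @param pred_aff,true_aff predicted and observed affinities (equal-length
#'   vectors, typically length 1 per pair).
#' @param s response vector (length `L_P`).
#' @param y binding label vector from [embed_site_labels()], or `NULL` when
#'   the pair carries no annotation.
#' @param lambda_br weight of the region term.
#' @param w,r,epsilon rectified Wing parameters (see [rwing_params()]).
#' @return Scalar loss.
#' @export
joint_loss <- function(pred_aff, true_aff, s, y, lambda_br = 1,
                       w = 3, r = 1, epsilon = 0.15) {
  l <- mse_loss(pred_aff, true_aff)
  if (!is.null(y) && lambda_br != 0) {
    if (length(s) != length(y)) stop("joint_loss: s and y lengths differ")
    l <- l + lambda_br * mean(rwing(s - y, w = w, r = r, epsilon = epsilon))
  }
  l
}

# coerce list-of-pairs or 2-column matrix to an integer interval matrix
as_interval_matrix <- function(sites) {
  if (is.null(sites)) return(matrix(integer(0), 0L, 2L))
  if (is.list(sites)) {
    if (length(sites) == 0L) return(matrix(integer(0), 0L, 2L))
    sites <- do.call(rbind, lapply(sites, function(p) as.integer(p[1:2])))
  }
  m <- matrix(as.integer(sites), ncol = 2L)
  colnames(m) <- c("start", "end")
  m
}
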
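# Minimal tape-based reverse-mode autodiff on dense matrices.
#
# There is no deep-learning framework in the supported dependency set, so the
# model runs on this engine: each operation records a node (an environment
# holding the forward value and a backward closure) on a tape; ag_backward
# replays the tape in reverse, accumulating gradients into parent nodes.
# Parameters are long-lived nodes created by ag_param(); their $g fields
# accumulate across samples until ag_zero_grad() is called, which is how
# minibatches are formed from per-sample graphs.
#
# Values are base-R numeric matrices throughout; vectors travel as n x 1
# matrices.  Convolution forward/backward kernels live in src/conv_ops.cpp.

#' Create a fresh autodiff tape
#'
#' @return An environment holding the recorded nodes of one forward pass.
#' @keywords internal
ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_push <- function(tp, node) {
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- node
  tp$n <- n
  node
}

new_node <- function(v) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  nd$bk <- NULL
  nd
}

#' Wrap a constant value (no gradient tracked)
#' @keywords internal
ag_const <- function(v) new_node(as.matrix(v))

#' Create a trainable parameter node
#'
#' @param v initial value (matrix or vector; vectors become n x 1).
#' @param name label used in optimizer diagnostics.
#' @param decay whether AdamW weight decay applies (FALSE for biases,
#'   affine shifts and normalization offsets).
#' @keywords internal
ag_param <- function(v, name = "", decay = TRUE) {
  nd <- new_node(as.matrix(v))
  nd$param <- TRUE
  nd$name <- name
  nd$decay <- decay
  nd
}

ag_acc <- function(node, d) {
  if (is.null(node$g)) node$g <- d else node$g <- node$g + d
  invisible(NULL)
}

#' Run the backward pass of a tape
#'
#' @param tp tape produced while building `loss`.
#' @param loss terminal scalar node.
#' @param seed gradient seeded at the loss (use 1/B to average a minibatch
#'   of per-sample graphs).
#' @keywords internal
ag_backward <- function(tp, loss, seed = 1) {
  loss$g <- matrix(seed, nrow(loss$v), ncol(loss$v))
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$bk)) nd$bk(nd$g)
  }
  invisible(NULL)
}

# ---- elementary ops --------------------------------------------------------

ag_matmul <- function(tp, a, b, ta = FALSE, tb = FALSE) {
  av <- a$v; bv <- b$v
  v <- if (!ta && !tb) av %*% bv
  else if (ta && !tb) crossprod(av, bv)
  else if (!ta && tb) tcrossprod(av, bv)
  else t(bv %*% av)
  nd <- new_node(v)
  nd$bk <- function(g) {
    if (!ta && !tb) { ag_acc(a, tcrossprod(g, bv)); ag_acc(b, crossprod(av, g)) }
    else if (ta && !tb) { ag_acc(a, tcrossprod(bv, g)); ag_acc(b, av %*% g) }
    else if (!ta && tb) { ag_acc(a, g %*% bv); ag_acc(b, crossprod(g, av)) }
    else { ag_acc(a, t(g %*% bv)); ag_acc(b, t(av %*% g)) }
  }
  ag_push(tp, nd)
}

ag_add <- function(tp, a, b) {
  nd <- new_node(a$v + b$v)
  nd$bk <- function(g) { ag_acc(a, g); ag_acc(b, g) }
  ag_push(tp, nd)
}

# add a length-C bias vector to every row of an L x C matrix
ag_add_bias <- function(tp, X, b) {
  nd <- new_node(X$v + rep(as.numeric(b$v), each = nrow(X$v)))
  nd$bk <- function(g) { ag_acc(X, g); ag_acc(b, matrix(colSums(g), ncol = 1L)) }
  ag_push(tp, nd)
}

# scale each column c by alpha[c] (the Diag(alpha) X part of an affine block)
ag_scale_cols <- function(tp, X, a) {
  L <- nrow(X$v)
  av <- rep(as.numeric(a$v), each = L)
  nd <- new_node(X$v * av)
  nd$bk <- function(g) {
    ag_acc(X, g * av)
    ag_acc(a, matrix(colSums(g * X$v), ncol = 1L))
  }
  ag_push(tp, nd)
}

# fused per-channel affine: X * alpha + beta in one node
ag_affine_ch <- function(tp, X, alpha, beta) {
  L <- nrow(X$v)
  av <- rep(as.numeric(alpha$v), each = L)
  nd <- new_node(X$v * av + rep(as.numeric(beta$v), each = L))
  nd$bk <- function(g) {
    ag_acc(X, g * av)
    ag_acc(alpha, matrix(colSums(g * X$v), ncol = 1L))
    ag_acc(beta, matrix(colSums(g), ncol = 1L))
  }
  ag_push(tp, nd)
}

# fully connected layer along the LENGTH axis without explicit transposes:
# V = W^T X + b (b length L, added per row), the un-transposed form of
# (X^T W + b)^T used by the token-mixing global extractor
ag_lenfc <- function(tp, X, W, b) {
  nd <- new_node(crossprod(W$v, X$v) + as.numeric(b$v))
  nd$bk <- function(g) {
    ag_acc(W, tcrossprod(X$v, g))
    ag_acc(X, W$v %*% g)
    ag_acc(b, matrix(rowSums(g), ncol = 1L))
  }
  ag_push(tp, nd)
}

# scale each row i by s[i]; s is an L x 1 node
ag_scale_rows <- function(tp, X, s) {
  sv <- as.numeric(s$v)
  nd <- new_node(X$v * sv)
  nd$bk <- function(g) {
    ag_acc(X, g * sv)
    ag_acc(s, matrix(rowSums(g * X$v), ncol = 1L))
  }
  ag_push(tp, nd)
}

ag_mul <- function(tp, a, b) {
  nd <- new_node(a$v * b$v)
  nd$bk <- function(g) { ag_acc(a, g * b$v); ag_acc(b, g * a$v) }
  ag_push(tp, nd)
}

ag_scale <- function(tp, a, k) {
  nd <- new_node(a$v * k)
  nd$bk <- function(g) ag_acc(a, g * k)
  ag_push(tp, nd)
}

ag_relu <- function(tp, a) {
  m <- a$v > 0
  nd <- new_node(a$v * m)
  nd$bk <- function(g) ag_acc(a, g * m)
  ag_push(tp, nd)
}

ag_sigmoid <- function(tp, a) {
  y <- 1 / (1 + exp(-a$v))
  nd <- new_node(y)
  nd$bk <- function(g) ag_acc(a, g * y * (1 - y))
  ag_push(tp, nd)
}

ag_one_minus <- function(tp, a) {
  nd <- new_node(1 - a$v)
  nd$bk <- function(g) ag_acc(a, -g)
  ag_push(tp, nd)
}

# column-major reshape (R matrix() semantics both ways)
ag_reshape <- function(tp, a, nr, nc) {
  dr <- nrow(a$v); dc <- ncol(a$v)
  nd <- new_node(matrix(a$v, nr, nc))
  nd$bk <- function(g) ag_acc(a, matrix(g, dr, dc))
  ag_push(tp, nd)
}

ag_transpose <- function(tp, a) {
  nd <- new_node(t(a$v))
  nd$bk <- function(g) ag_acc(a, t(g))
  ag_push(tp, nd)
}

# softmax over the length axis (rows), independently per column
ag_softmax_len <- function(tp, a) {
  L <- nrow(a$v)
  e <- exp(a$v - max(a$v))
  y <- e / rep(colSums(e), each = L)
  nd <- new_node(y)
  nd$bk <- function(g) {
    dot <- rep(colSums(g * y), each = L)
    ag_acc(a, y * (g - dot))
  }
  ag_push(tp, nd)
}

ag_rbind <- function(tp, a, b) {
  na <- nrow(a$v)
  nd <- new_node(rbind(a$v, b$v))
  nd$bk <- function(g) {
    ag_acc(a, g[seq_len(na), , drop = FALSE])
    ag_acc(b, g[-seq_len(na), , drop = FALSE])
  }
  ag_push(tp, nd)
}

ag_rowmeans <- function(tp, a) {
  C <- ncol(a$v)
  nd <- new_node(matrix(rowMeans(a$v), ncol = 1L))
  nd$bk <- function(g) ag_acc(a, matrix(g, nrow(a$v), C) / C)
  ag_push(tp, nd)
}

ag_colmeans <- function(tp, a) {
  L <- nrow(a$v)
  nd <- new_node(matrix(colMeans(a$v), ncol = 1L))
  nd$bk <- function(g) ag_acc(a, matrix(rep(as.numeric(g), each = L), L, ncol(a$v)) / L)
  ag_push(tp, nd)
}

# concatenate a list of column-vector nodes into one column vector
ag_vcat <- function(tp, parts) {
  lens <- vapply(parts, function(p) nrow(p$v), integer(1))
  nd <- new_node(matrix(unlist(lapply(parts, function(p) as.numeric(p$v))), ncol = 1L))
  nd$bk <- function(g) {
    off <- 0L
    for (j in seq_along(parts)) {
      ag_acc(parts[[j]], g[off + seq_len(lens[j]), , drop = FALSE])
      off <- off + lens[j]
    }
  }
  ag_push(tp, nd)
}

# ---- table lookup ----------------------------------------------------------

# Embed 0-based token indices via a table whose row (i + 1) holds symbol i.
# Positions with mask == FALSE embed to zero rows and receive no gradient.
ag_embed <- function(tp, table, idx, mask = NULL) {
  rows <- idx + 1L
  v <- table$v[rows, , drop = FALSE]
  if (!is.null(mask) && !all(mask)) v[!mask, ] <- 0
  nd <- new_node(v)
  nd$bk <- function(g) {
    if (!is.null(mask) && !all(mask)) g[!mask, ] <- 0
    d <- matrix(0, nrow(table$v), ncol(table$v))
    agg <- rowsum(g, rows)
    d[as.integer(rownames(agg)), ] <- agg
    ag_acc(table, d)
  }
  ag_push(tp, nd)
}

# ---- convolutions ----------------------------------------------------------

# Grouped 1D convolution along the length axis ('same' zero padding).
# W has dim (k * C/groups) x C with column block g holding the filters of
# group g; rows are ordered (window offset, within-group channel).  b is a
# length-C bias.
ag_conv1d_group <- function(tp, X, W, b, k, groups, cache = NULL) {
  L <- nrow(X$v); C <- ncol(X$v)
  if (C %% groups != 0L) stop("channels (", C, ") not divisible by groups (", groups, ")")
  Cg <- C %/% groups
  Xcol <- cpp_im2col_len(X$v, k)
  incols <- if (!is.null(cache) && !is.null(cache$incols)) cache$incols
  else {
    ic <- lapply(seq_len(groups), function(g) {
      ch <- (g - 1L) * Cg + seq_len(Cg)
      as.integer(outer(ch, (seq_len(k) - 1L) * C, "+"))
    })
    if (!is.null(cache)) cache$incols <- ic
    ic
  }
  out <- matrix(0, L, C)
  for (g in seq_len(groups)) {
    cols <- (g - 1L) * Cg + seq_len(Cg)
    out[, cols] <- Xcol[, incols[[g]], drop = FALSE] %*% W$v[, cols, drop = FALSE]
  }
  out <- sweep(out, 2L, as.numeric(b$v), "+")
  nd <- new_node(out)
  nd$bk <- function(gr) {
    dW <- matrix(0, nrow(W$v), ncol(W$v))
    dXcol <- matrix(0, L, k * C)
    for (g in seq_len(groups)) {
      cols <- (g - 1L) * Cg + seq_len(Cg)
      Xg <- Xcol[, incols[[g]], drop = FALSE]
      Gg <- gr[, cols, drop = FALSE]
      dW[, cols] <- crossprod(Xg, Gg)
      dXcol[, incols[[g]]] <- tcrossprod(Gg, W$v[, cols, drop = FALSE])
    }
    ag_acc(W, dW)
    ag_acc(b, matrix(colSums(gr), ncol = 1L))
    ag_acc(X, cpp_col2im_len(dXcol, k, L, C))
  }
  ag_push(tp, nd)
}

# Single-channel 'same' 2D convolution of an L x C map with a k x k kernel
# and scalar bias (the gate inside spatial attention and the fusion block).
ag_conv2d <- function(tp, X, W, b) {
  nd <- new_node(cpp_conv2d_same(X$v, W$v, as.numeric(b$v)))
  nd$bk <- function(g) {
    bw <- cpp_conv2d_same_bwd(X$v, W$v, g)
    ag_acc(X, bw$dX)
    ag_acc(W, bw$dW)
    ag_acc(b, matrix(bw$db, 1L, 1L))
  }
  ag_push(tp, nd)
}

# Full-channel sliding correlation of the protein map with the drug kernel
# (the response vector); returns an L x 1 node.
ag_response <- function(tp, Fp, K) {
  nd <- new_node(matrix(cpp_response_vector(Fp$v, K$v), ncol = 1L))
  nd$bk <- function(g) {
    bw <- cpp_response_vector_bwd(Fp$v, K$v, as.numeric(g))
    ag_acc(Fp, bw$dFp)
    ag_acc(K, bw$dK)
  }
  ag_push(tp, nd)
}

# ---- normalization / regularization ---------------------------------------

# Per-channel standardization over the length axis (population variance).
# Used in place of batch normalization inside the convolution blocks: the
# trainer works on per-sample graphs, where batch statistics would couple
# samples; see the methods vignette.
ag_norm_len <- function(tp, X, eps = 1e-5) {
  L <- nrow(X$v)
  mu <- rep(colMeans(X$v), each = L)
  xc <- X$v - mu
  sdv <- rep(sqrt(colMeans(xc^2) + eps), each = L)
  xh <- xc / sdv
  nd <- new_node(xh)
  nd$bk <- function(g) {
    m1 <- rep(colMeans(g), each = L)
    m2 <- rep(colMeans(g * xh), each = L)
    ag_acc(X, (g - m1 - xh * m2) / sdv)
  }
  ag_push(tp, nd)
}

# Inverted dropout; identity when not training.  Draws from the session RNG
# so seeding the trainer fixes the masks.
ag_dropout <- function(tp, X, rate, training) {
  if (!training || rate <= 0) return(X)
  keep <- (matrix(stats::runif(length(X$v)), nrow(X$v)) >= rate) / (1 - rate)
  nd <- new_node(X$v * keep)
  nd$bk <- function(g) ag_acc(X, g * keep)
  ag_push(tp, nd)
}

# ---- loss nodes ------------------------------------------------------------

# mean squared error between a prediction node (n x 1) and a constant target
ag_mse <- function(tp, pred, target) {
  r <- as.numeric(pred$v) - as.numeric(target)
  n <- length(r)
  nd <- new_node(matrix(mean(r^2), 1L, 1L))
  nd$bk <- function(g) ag_acc(pred, matrix(2 * r / n, ncol = 1L) * as.numeric(g))
  ag_push(tp, nd)
}

# mean rectified-Wing loss of (s - y); y is a constant label vector
ag_rwing_mean <- function(tp, s, y, w, r, epsilon) {
  x <- as.numeric(s$v) - as.numeric(y)
  n <- length(x)
  nd <- new_node(matrix(mean(rwing(x, w = w, r = r, epsilon = epsilon)), 1L, 1L))
  nd$bk <- function(g) {
    ag_acc(s, matrix(rwing_grad(x, w = w, r = r, epsilon = epsilon) / n, ncol = 1L) * as.numeric(g))
  }
  ag_push(tp, nd)
}
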
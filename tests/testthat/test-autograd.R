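# Gradient correctness of the autodiff engine: per-op finite-difference
# checks on smooth inputs, and a directional-derivative check through the
# full model.

fd_check <- function(build, params, eps = 1e-6) {
  # build(tp) must return a scalar node; params is a list of ag_param nodes
  # (gradients accumulate across backward passes, so zero them first)
  for (p in params) p$g <- NULL
  tp <- ns$ag_tape()
  loss <- build(tp)
  ns$ag_backward(tp, loss)
  for (p in params) {
    for (j in seq_len(min(4L, length(p$v)))) {
      v0 <- p$v[j]
      p$v[j] <- v0 + eps
      lp <- build(ns$ag_tape())$v[1]
      p$v[j] <- v0 - eps
      lm <- build(ns$ag_tape())$v[1]
      p$v[j] <- v0
      fd <- (lp - lm) / (2 * eps)
      an <- if (is.null(p$g)) 0 else p$g[j]
      expect_lt(abs(an - fd), 1e-6 + 2e-3 * (abs(an) + abs(fd)),
                label = paste0("|grad - fd| for ", p$name, "[", j, "]"))
    }
  }
}

sum_node <- function(tp, X) {
  # reduce to a scalar via mean of sigmoid (smooth everywhere)
  ns$ag_mse(tp, ns$ag_reshape(tp, ns$ag_sigmoid(tp, X), length(X$v), 1L),
            rep(0.3, length(X$v)))
}

test_that("matmul variants, affine, lenfc and elementwise ops differentiate", {
  set.seed(50)
  A <- ns$ag_param(rmat(4, 3), "A"); B <- ns$ag_param(rmat(3, 5), "B")
  fd_check(function(tp) sum_node(tp, ns$ag_matmul(tp, A, B)), list(A, B))
  At <- ns$ag_param(rmat(3, 4), "At")
  fd_check(function(tp) sum_node(tp, ns$ag_matmul(tp, At, B, ta = TRUE)), list(At, B))
  Bt <- ns$ag_param(rmat(5, 3), "Bt")
  fd_check(function(tp) sum_node(tp, ns$ag_matmul(tp, A, Bt, tb = TRUE)), list(A, Bt))
  fd_check(function(tp) sum_node(tp, ns$ag_matmul(tp, At, Bt, ta = TRUE, tb = TRUE)),
           list(At, Bt))

  X <- ns$ag_param(rmat(6, 4), "X")
  al <- ns$ag_param(rnorm(4), "alpha"); be <- ns$ag_param(rnorm(4), "beta")
  fd_check(function(tp) sum_node(tp, ns$ag_affine_ch(tp, X, al, be)), list(X, al, be))

  W <- ns$ag_param(rmat(6, 6), "W"); b <- ns$ag_param(rnorm(6), "b")
  fd_check(function(tp) sum_node(tp, ns$ag_lenfc(tp, X, W, b)), list(X, W, b))

  S <- ns$ag_param(rnorm(6), "S")
  fd_check(function(tp) sum_node(tp, ns$ag_scale_rows(tp, X, S)), list(X, S))
  fd_check(function(tp) sum_node(tp, ns$ag_softmax_len(tp, X)), list(X))
  fd_check(function(tp) sum_node(tp, ns$ag_norm_len(tp, X)), list(X))
  fd_check(function(tp) sum_node(tp, ns$ag_one_minus(tp, ns$ag_sigmoid(tp, X))),
           list(X))
})

test_that("convolutions, response correlation and embedding differentiate", {
  set.seed(51)
  X <- ns$ag_param(rmat(10, 4), "X")
  Wc <- ns$ag_param(rmat(3, 3), "Wc"); bc <- ns$ag_param(0.2, "bc")
  fd_check(function(tp) sum_node(tp, ns$ag_conv2d(tp, X, Wc, bc)), list(X, Wc, bc))

  Wg <- ns$ag_param(rmat(3 * 2, 4), "Wg"); bg <- ns$ag_param(rnorm(4), "bg")
  fd_check(function(tp) sum_node(tp, ns$ag_conv1d_group(tp, X, Wg, bg, 3L, 2L)),
           list(X, Wg, bg))

  K <- ns$ag_param(rmat(4, 4), "K")
  fd_check(function(tp) sum_node(tp, ns$ag_response(tp, X, K)), list(X, K))

  Tb <- ns$ag_param(rmat(7, 3), "table")
  idx <- c(0L, 3L, 3L, 6L, 1L)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  fd_check(function(tp) sum_node(tp, ns$ag_embed(tp, Tb, idx, mask)), list(Tb))
  # masked position embeds to zero
  tp <- ns$ag_tape()
  e <- ns$ag_embed(tp, Tb, idx, mask)
  expect_equal(e$v[5, ], rep(0, 3))
  expect_equal(e$v[2, ], Tb$v[4, ])
})

test_that("reductions and concatenation differentiate", {
  set.seed(52)
  X <- ns$ag_param(rmat(5, 3), "X"); Y <- ns$ag_param(rmat(2, 3), "Y")
  fd_check(function(tp) sum_node(tp, ns$ag_rbind(tp, X, Y)), list(X, Y))
  fd_check(function(tp) {
    Z <- ns$ag_rbind(tp, X, Y)
    sum_node(tp, ns$ag_vcat(tp, list(ns$ag_rowmeans(tp, Z), ns$ag_colmeans(tp, Z))))
  }, list(X, Y))
})

test_that("the full model's gradient matches a directional derivative", {
  ww <- tiny_world()
  set.seed(53)
  params <- init_model_params(ww$cfg, length(ww$store$vocab$tokens))
  pin <- ww$store$proteins[[1]]; din <- ww$store$drugs[[2]]
  y <- ns$site_label_vector(pin, 6.8, ww$cfg$L_P)
  lossval <- function() {
    tp <- ns$ag_tape()
    out <- ns$fwd_model(tp, params, ww$cfg, pin, din, FALSE)
    ns$fwd_loss(tp, out, 6.8, y, ww$cfg)$v[1]
  }
  tp <- ns$ag_tape()
  out <- ns$fwd_model(tp, params, ww$cfg, pin, din, FALSE)
  l <- ns$fwd_loss(tp, out, 6.8, y, ww$cfg)
  ns$ag_backward(tp, l)
  ps <- ns$collect_params(params)
  dirs <- lapply(ps, function(p) matrix(rnorm(length(p$v), sd = 1), nrow(p$v)))
  an <- sum(mapply(function(p, d) sum((if (is.null(p$g)) 0 else p$g) * d), ps, dirs))
  eps <- 1e-6
  for (i in seq_along(ps)) ps[[i]]$v <- ps[[i]]$v + eps * dirs[[i]]
  lp <- lossval()
  for (i in seq_along(ps)) ps[[i]]$v <- ps[[i]]$v - 2 * eps * dirs[[i]]
  lm <- lossval()
  for (i in seq_along(ps)) ps[[i]]$v <- ps[[i]]$v + eps * dirs[[i]]
  fd <- (lp - lm) / (2 * eps)
  expect_equal(an, fd, tolerance = 1e-3)
})

test_that("dropout is seeded, rescaled and off at evaluation", {
  X <- ns$ag_const(matrix(1, 50, 20))
  set.seed(99)
  tp <- ns$ag_tape()
  d1 <- ns$ag_dropout(tp, X, 0.4, training = TRUE)$v
  set.seed(99)
  d2 <- ns$ag_dropout(ns$ag_tape(), X, 0.4, training = TRUE)$v
  expect_identical(d1, d2)                      # same seed, same mask
  expect_setequal(unique(as.numeric(d1)), c(0, 1 / 0.6))
  expect_identical(ns$ag_dropout(ns$ag_tape(), X, 0.4, training = FALSE)$v, X$v)
})
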
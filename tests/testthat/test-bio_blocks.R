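# Closed forms with hand-set parameters, explicit-composition oracles, and
# shape/gradient-flow contracts for the encoder blocks.

id_affine <- function(C) list(alpha = rep(1, C), beta = rep(0, C))
zero_fc <- function(nin, nout) list(W = matrix(0, nin, nout), b = rep(0, nout))
id_fc <- function(n) list(W = diag(n), b = rep(0, n))

global_params <- function(L, C, fc) list(af1 = id_affine(C), fc = fc, af2 = id_affine(C))

test_that("global extractor closed forms: zero stack and identity doubling", {
  L <- 5L; C <- 3L
  X0 <- matrix(0, L, C)
  pz <- global_params(L, C, lapply(1:3, function(i) zero_fc(L, L)))
  expect_equal(global_feature_extractor(X0, pz), X0)
  # FC stack as identity on a non-negative map (rectifiers pass) -> 2 * X
  set.seed(20)
  Xp <- abs(rmat(L, C))
  pi_ <- global_params(L, C, lapply(1:3, function(i) id_fc(L)))
  expect_equal(global_feature_extractor(Xp, pi_), 2 * Xp)
})

test_that("global extractor equals the explicit transpose-composition oracle", {
  set.seed(21)
  for (rep in 1:20) {
    L <- 4L; C <- 3L
    X <- rmat(L, C)
    prm <- list(af1 = list(alpha = rnorm(C), beta = rnorm(C)),
                fc = lapply(1:3, function(i) list(W = rmat(L, L), b = rnorm(L))),
                af2 = list(alpha = rnorm(C), beta = rnorm(C)))
    H <- t(affine_transform(X, prm$af1$alpha, prm$af1$beta))      # C x L
    f <- function(H, p) sweep(H %*% p$W, 2, p$b, "+")
    H <- f(H, prm$fc[[1]]); H <- H * (H > 0)
    H <- f(H, prm$fc[[2]]); H <- H * (H > 0)
    H <- f(H, prm$fc[[3]])
    expected <- X + affine_transform(t(H), prm$af2$alpha, prm$af2$beta)
    expect_equal(global_feature_extractor(X, prm), expected, tolerance = 1e-10)
  }
})

test_that("spatial attention closed forms and loop oracle", {
  set.seed(22)
  X <- rmat(5, 4)
  # zero kernel, zero bias -> sigmoid(0) = 0.5 gate
  expect_equal(spatial_attention(X, matrix(0, 3, 3), 0), 0.5 * X)
  expect_equal(spatial_attention(matrix(0, 5, 4), rmat(3, 3), 0.3),
               matrix(0, 5, 4))
  for (rep in 1:20) {
    W <- rmat(3, 3); b <- rnorm(1)
    expect_equal(spatial_attention(X, W, b),
                 X * plogis(oracle_conv2d(X, W, b)), tolerance = 1e-10)
  }
})

test_that("drug-side individual extractor: zero case and composition oracle", {
  L <- 6L; C <- 4L
  zero_prm <- list(af3 = id_affine(C), fc2 = lapply(1:2, function(i) zero_fc(C, C)),
                   af4 = id_affine(C), att = list(W = matrix(0, 3, 3), b = 0),
                   fc_out = zero_fc(C, C))
  expect_equal(biomlp_individual(matrix(0, L, C), zero_prm), matrix(0, L, C))
  set.seed(23)
  for (rep in 1:15) {
    X <- rmat(L, C)
    prm <- list(af3 = list(alpha = rnorm(C), beta = rnorm(C)),
                fc2 = lapply(1:2, function(i) list(W = rmat(C, C), b = rnorm(C))),
                af4 = list(alpha = rnorm(C), beta = rnorm(C)),
                att = list(W = rmat(3, 3), b = rnorm(1)),
                fc_out = list(W = rmat(C, C), b = rnorm(C)))
    h <- affine_transform(X, prm$af3$alpha, prm$af3$beta)
    h <- sweep(h %*% prm$fc2[[1]]$W, 2, prm$fc2[[1]]$b, "+")
    h <- h * (h > 0)
    h <- sweep(h %*% prm$fc2[[2]]$W, 2, prm$fc2[[2]]$b, "+")
    h <- affine_transform(h, prm$af4$alpha, prm$af4$beta)
    h <- h * plogis(oracle_conv2d(h, prm$att$W, prm$att$b))
    expected <- sweep((X + h) %*% prm$fc_out$W, 2, prm$fc_out$b, "+")
    expect_equal(biomlp_individual(X, prm), expected, tolerance = 1e-10)
  }
})

test_that("protein-side extractor: delta kernels give identity through CNNLK", {
  L <- 10L; C <- 4L; groups <- 2L; Cg <- C / groups
  delta_conv <- function(k) {
    W <- matrix(0, k * Cg, C)
    j0 <- (k + 1L) / 2L
    for (co in seq_len(C)) {
      cg <- (co - 1L) %% Cg + 1L
      W[(j0 - 1L) * Cg + cg, co] <- 1
    }
    list(W = W, b = rep(0, C), k = k, groups = groups)
  }
  prm <- list(af3 = id_affine(C),
              convs = list(delta_conv(3L), delta_conv(5L), delta_conv(3L)),
              norm = lapply(1:3, function(i) id_affine(C)),
              af4 = id_affine(C), att = list(W = matrix(0, 3, 3), b = 0),
              fc_out = id_fc(C))
  set.seed(24)
  Xp <- abs(rmat(L, C))  # positive so the rectifiers pass
  # CNNLK(X) = X, gate = 0.5 -> output = X + 0.5 X
  expect_equal(biocnn_individual(Xp, prm, use_norm = FALSE), 1.5 * Xp,
               tolerance = 1e-10)
})

test_that("grouped convolution matches the naive loop oracle (incl. groups=1)", {
  set.seed(25)
  for (rep in 1:15) {
    L <- 16L; C <- 8L
    groups <- sample(c(1L, 2L, 4L), 1)
    k <- sample(c(3L, 5L, 7L), 1)
    X <- rmat(L, C)
    W <- rmat(k * C / groups, C)
    b <- rnorm(C)
    tp <- ns$ag_tape()
    got <- ns$ag_conv1d_group(tp, ns$ag_const(X), ns$ag_const(W), ns$ag_const(b),
                              k, groups)$v
    expect_equal(got, oracle_conv1d_group(X, W, b, k, groups), tolerance = 1e-10)
  }
})

test_that("block stacks preserve shapes, including the benchmark-scale config", {
  cfg <- tiny_cfg()
  set.seed(26)
  for (depth in 1:2) {
    blocks <- init_bio_blocks("cnn", depth, 20L, 8L,
                              dta_config("tiny", groups = 2L, C_P = 8L))
    out <- encode_with_blocks(rmat(20, 8), blocks)
    expect_equal(dim(out), c(20L, 8L))
  }
  # Davis-scale: Pn = 3 protein blocks on a 1200 x 100 map
  cfg_d <- dta_config("davis")
  blocks_d <- init_bio_blocks("cnn", cfg_d$Pn, cfg_d$L_P, cfg_d$C_P, cfg_d)
  out_d <- encode_with_blocks(rmat(cfg_d$L_P, cfg_d$C_P, sd = 0.1), blocks_d)
  expect_equal(dim(out_d), c(1200L, 100L))
  expect_true(all(is.finite(out_d)))
})

test_that("gradient reaches every parameter of the full model", {
  ww <- tiny_world()
  set.seed(27)
  params <- init_model_params(ww$cfg, length(ww$store$vocab$tokens))
  pin <- ww$store$proteins[[1]]
  din <- ww$store$drugs[[1]]
  y <- ns$site_label_vector(pin, 6.5, ww$cfg$L_P)
  tp <- ns$ag_tape()
  out <- ns$fwd_model(tp, params, ww$cfg, pin, din, training = FALSE)
  l <- ns$fwd_loss(tp, out, 6.5, y, ww$cfg)
  ns$ag_backward(tp, l)
  for (p in ns$collect_params(params)) {
    expect_false(is.null(p$g), info = p$name)
    expect_gt(max(abs(p$g)), 0, label = paste("grad of", p$name))
  }
})
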
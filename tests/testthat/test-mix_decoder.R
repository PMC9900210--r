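test_that("drug-kernel sampling is the stated linear collapse", {
  set.seed(40)
  Fd <- rmat(5, 3)
  expect_equal(sample_drug_kernel(Fd, matrix(0, 5, 3)), matrix(0, 3, 3))
  # L_D = C_S with identity weights returns Fd itself
  Fd_sq <- rmat(3, 3)
  expect_equal(sample_drug_kernel(Fd_sq, diag(3)), Fd_sq)
  for (rep in 1:20) {
    Ws <- rmat(5, 3)
    K <- sample_drug_kernel(Fd, Ws)
    expect_equal(K, t(Ws) %*% Fd, tolerance = 1e-12)
    expect_equal(dim(K), c(3L, 3L))
  }
  expect_error(sample_drug_kernel(Fd, rmat(4, 3)), "shape")
})

test_that("response vector: zero kernel, delta kernel and the loop oracle", {
  set.seed(41)
  Fp <- rmat(8, 3)
  expect_equal(compute_response_vector(Fp, matrix(0, 3, 3)), rep(0, 8))
  # single 1 at the kernel's centre row picks out one protein channel
  K <- matrix(0, 3, 3); K[2, 2] <- 1   # m0 = floor(3/2) (0-based) -> row 2
  expect_equal(compute_response_vector(Fp, K), Fp[, 2])
  for (rep in 1:100) {
    L <- sample(5:12, 1); C <- sample(2:5, 1); k <- sample(2:6, 1)
    Fp <- rmat(L, C); K <- rmat(k, C)
    expect_equal(compute_response_vector(Fp, K), oracle_response(Fp, K),
                 tolerance = 1e-10)
  }
})

test_that("predicted regions are centred on the argmax and clipped", {
  s <- rep(0, 20); s[8] <- 1   # 0-based position 7
  expect_equal(unname(predict_binding_region(s, 5L)), c(5L, 10L))
  s0 <- rep(0, 20); s0[1] <- 1
  expect_equal(unname(predict_binding_region(s0, 15L)), c(0L, 8L))
  # ties resolve to the smallest index
  expect_equal(unname(predict_binding_region(c(0, 3, 3, 0), 1L)), c(1L, 2L))
  set.seed(42)
  for (rep in 1:100) {
    s <- rnorm(30)
    reg <- predict_binding_region(s, 10L)
    am <- which.max(s) - 1L
    expect_true(reg[1] <= am && am < reg[2])
    expect_lte(reg[2] - reg[1], 10L)
    expect_gte(reg[1], 0L)
    expect_lte(reg[2], 30L)
  }
})

test_that("region and adjacency injection are row scalings", {
  set.seed(43)
  Fp <- rmat(6, 4)
  expect_equal(inject_region_info(Fp, rep(1, 6)), Fp)
  expect_equal(inject_region_info(Fp, rep(0, 6)), matrix(0, 6, 4))
  s <- rnorm(6)
  got <- inject_region_info(Fp, s)
  for (i in 1:6) expect_equal(got[i, ], Fp[i, ] * s[i])

  Xd <- rmat(3, 4)
  expect_equal(inject_adj_info(Xd, diag(3)), Xd / 3)
  expect_equal(inject_adj_info(Xd, matrix(1, 3, 3)), Xd)
  # ethanol graph with unit diagonal: connectivity row means (2/3, 1, 2/3)
  adj <- smiles_to_graph("CCO", 3L)$adj
  expect_equal(rowMeans(adj), c(2 / 3, 1, 2 / 3))
  expect_equal(inject_adj_info(Xd, adj), Xd * c(2 / 3, 1, 2 / 3))
})

test_that("self-enhancement matches the softmax formula oracle", {
  set.seed(44)
  C <- 3L
  # constant-over-length input gives the uniform softmax
  Xc <- matrix(rep(rnorm(C), each = 5), 5, C)
  W1 <- rmat(C, C); Wm <- rmat(C, C)
  fa_c <- oracle_softmax_len((Xc %*% Wm) / C)
  expect_equal(fa_c, matrix(1 / 5, 5, C))
  # W1 = identity, Wm = 0 -> X / L
  X <- rmat(4, C)
  expect_equal(self_enhance(X, diag(C), matrix(0, C, C)), X / 4)
  for (rep in 1:100) {
    X <- rmat(4, C); W1 <- rmat(C, C); Wm <- rmat(C, C)
    expect_equal(self_enhance(X, W1, Wm), oracle_self_enhance(X, W1, Wm),
                 tolerance = 1e-10)
  }
  # fa columns sum to one
  fa <- oracle_softmax_len((X %*% Wm) / C)
  expect_equal(colSums(fa), rep(1, C), tolerance = 1e-6)
})

test_that("cross-attention matches the transposed token-mixing oracle", {
  set.seed(45)
  C <- 3L; Lp <- 4L; Ld <- 2L
  Xp <- rmat(Lp, C); Xd <- rmat(Ld, C)
  # zero mixing matrix leaves the pure residual
  expect_equal(cross_attend(Xp, Xd, matrix(0, C, C), rmat(Lp + Ld, Lp + Ld)),
               rbind(Xp, Xd))
  for (rep in 1:100) {
    Xp <- rmat(Lp, C); Xd <- rmat(Ld, C)
    Wm1 <- rmat(C, C); Wm2 <- rmat(Lp + Ld, Lp + Ld)
    expect_equal(cross_attend(Xp, Xd, Wm1, Wm2),
                 oracle_cross_attend(Xp, Xd, Wm1, Wm2), tolerance = 1e-10)
  }
})

test_that("interaction pooling concatenates the two mean profiles", {
  Y1 <- matrix(1, 7, 3)
  expect_equal(pool_interaction(Y1), rep(1, 10))
  set.seed(46)
  Y <- rmat(9, 4)
  v <- pool_interaction(Y)
  expect_length(v, 13L)
  for (i in 1:9) expect_equal(v[i], mean(Y[i, ]))
  for (c in 1:4) expect_equal(v[9 + c], mean(Y[, c]))
  # Davis-scale interaction vector length: 1200 + 51 + 75
  expect_length(pool_interaction(matrix(0, 1200 + 51, 75)), 1326L)
})

test_that("affinity head is zero under zero weights and eval-deterministic", {
  prm <- list(list(W = matrix(0, 10, 4), b = rep(0, 4)),
              list(W = matrix(0, 4, 2), b = rep(0, 2)),
              list(W = matrix(0, 2, 1), b = 0))
  expect_equal(affinity_head(rnorm(10), prm), matrix(0, 1, 1))
  set.seed(47)
  prm2 <- list(list(W = rmat(10, 4), b = rnorm(4)),
               list(W = rmat(4, 2), b = rnorm(2)),
               list(W = rmat(2, 1), b = rnorm(1)))
  v <- rnorm(10)
  expect_identical(affinity_head(v, prm2), affinity_head(v, prm2))
})

test_that("end-to-end forward pass stays finite across 100 random inputs", {
  ww <- tiny_world()
  set.seed(48)
  params <- init_model_params(ww$cfg, length(ww$store$vocab$tokens))
  for (seed in 1:100) {
    set.seed(seed)
    pin <- ww$store$proteins[[sample.int(3, 1)]]
    din <- ww$store$drugs[[sample.int(2, 1)]]
    # jitter a couple of parameter tensors to explore the parameter space
    ps <- ns$collect_params(params)
    p <- ps[[sample.int(length(ps), 1)]]
    old <- p$v
    p$v <- p$v + matrix(rnorm(length(p$v), sd = 0.05), nrow(p$v))
    tp <- ns$ag_tape()
    out <- ns$fwd_model(tp, params, ww$cfg, pin, din, training = FALSE)
    expect_true(all(is.finite(out$aff$v)) && all(is.finite(out$s$v)))
    p$v <- old
  }
})
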
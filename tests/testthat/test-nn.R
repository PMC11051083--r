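test_that("co-attention equals an explicit-loop attention oracle", {
  set.seed(101)
  for (rep in 1:100) {
    k <- sample(c(4, 8, 16), 1)
    Tq <- sample(1:8, 1); Tc <- sample(1:8, 1)
    Xq <- matrix(rnorm(Tq * k), Tq, k)
    Xc <- matrix(rnorm(Tc * k), Tc, k)
    p <- tricoat:::init_coattn(k, project = TRUE)
    out <- tricoat:::coattn_fwd(Xq, Xc, p, S = 1L, Tq = Tq, Tc = Tc,
                                project = TRUE)
    Q <- Xq %*% p$q$W + matrix(p$q$b, Tq, k, byrow = TRUE)
    K <- Xc %*% p$k$W + matrix(p$k$b, Tc, k, byrow = TRUE)
    V <- Xc %*% p$v$W + matrix(p$v$b, Tc, k, byrow = TRUE)
    ref <- oracle_attention(Q, K, V, d_scale = k)
    expect_lt(max(abs(out$O - ref$O)), 1e-5)
    expect_lt(max(abs(out$A[, , 1] - ref$W)), 1e-5)
    # weight rows are probability vectors
    expect_true(all(out$A >= 0))
    expect_lt(max(abs(apply(out$A[, , 1, drop = FALSE], 1, sum) - 1)), 1e-6)
  }
})

test_that("a single clinical token receives all attention; equal logits give uniform weights", {
  set.seed(5)
  k <- 8
  Xq <- matrix(rnorm(3 * k), 3, k)
  # B = 1: softmax over a singleton
  Xc1 <- matrix(rnorm(k), 1, k)
  out1 <- tricoat:::coattn_fwd(Xq, Xc1, list(), 1L, 3L, 1L, project = FALSE)
  expect_equal(as.vector(out1$A), rep(1, 3))
  for (i in 1:3) expect_equal(out1$O[i, ], Xc1[1, ])
  # identical clinical tokens -> identical logits -> uniform weights
  Xc <- matrix(rep(rnorm(k), each = 4), 4, k)
  out2 <- tricoat:::coattn_fwd(Xq, Xc, list(), 1L, 3L, 4L, project = FALSE)
  expect_equal(as.vector(out2$A), rep(0.25, 12), tolerance = 1e-12)
  expect_equal(out2$O[1, ], colMeans(Xc))
})

test_that("encoder layer matches a loop-based pre-LN reference", {
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(c(8, 16), 1)
    h <- sample(c(2, 4), 1)
    Tn <- sample(2:5, 1)
    X <- matrix(rnorm(Tn * k), Tn, k)
    p <- tricoat:::init_encoder_layer(k)
    got <- tricoat:::encoder_layer_fwd(X, p, S = 1L, Tn = Tn, h = h)$Y
    ref <- oracle_encoder_layer(X, p, h)
    expect_lt(max(abs(got - ref)), 1e-5)
  }
})

test_that("encoders are token-permutation equivariant (no positional encoding)", {
  set.seed(23)
  k <- 8; Tn <- 6
  X <- matrix(rnorm(Tn * k), Tn, k)
  p <- tricoat:::init_encoder_layer(k)
  perm <- sample(Tn)
  Y <- tricoat:::encoder_layer_fwd(X, p, 1L, Tn, 2L)$Y
  Yp <- tricoat:::encoder_layer_fwd(X[perm, ], p, 1L, Tn, 2L)$Y
  expect_equal(Yp, Y[perm, ], tolerance = 1e-10)
  # co-attention: outputs permute with query order, weights with both axes
  Xc <- matrix(rnorm(4 * k), 4, k)
  pc <- tricoat:::init_coattn(k, TRUE)
  a <- tricoat:::coattn_fwd(X, Xc, pc, 1L, Tn, 4L)
  b <- tricoat:::coattn_fwd(X[perm, ], Xc, pc, 1L, Tn, 4L)
  expect_equal(b$O, a$O[perm, ], tolerance = 1e-10)
  cperm <- c(3, 1, 4, 2)
  d <- tricoat:::coattn_fwd(X, Xc[cperm, ], pc, 1L, Tn, 4L)
  expect_equal(d$A[, , 1], a$A[, cperm, 1], tolerance = 1e-10)
})

test_that("self-attention weight rows sum to 1 at every layer and head", {
  set.seed(29)
  X <- matrix(rnorm(2 * 5 * 8), 10, 8)  # 2 subjects x 5 tokens
  p <- tricoat:::init_mha(8)
  out <- tricoat:::mha_fwd(X, p, S = 2L, Tn = 5L, h = 4L)
  sums <- apply(out$cache$A, c(1, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("analytic gradients match finite differences for all model families", {
  sim <- tiny_sim()
  inp <- scaled_inputs(sim)
  dims <- tricoat:::cohort_dims(inp)
  cfg <- tiny_config()
  rows <- 1:4
  y <- tricoat:::label_vector(sim$truth, inp$subjects[rows])

  # full tri-modal co-attention model
  set.seed(5)
  params <- tricoat:::init_tricoat_params(cfg, dims)
  fw <- tricoat:::tricoat_fwd(params, inp, rows, cfg)
  g <- tricoat:::tricoat_bwd(tricoat:::ce_loss(fw$logits, y)$dlogits, fw, params, cfg)
  lf <- function(p) {
    tricoat:::ce_loss(tricoat:::tricoat_fwd(p, inp, rows, cfg)$logits, y)$loss
  }
  set.seed(99)
  expect_lt(max_grad_error(params, lf, g), 1e-4)

  # token classifier (early fusion realization)
  set.seed(5)
  params <- tricoat:::init_tokclf_params(cfg, dims, "all")
  fw <- tricoat:::tokclf_fwd(params, inp, rows, cfg, "all")
  g <- tricoat:::tokclf_bwd(tricoat:::ce_loss(fw$logits, y)$dlogits, fw, params, cfg)
  lf <- function(p) {
    tricoat:::ce_loss(tricoat:::tokclf_fwd(p, inp, rows, cfg, "all")$logits, y)$loss
  }
  set.seed(98)
  expect_lt(max_grad_error(params, lf, g), 1e-4)

  # stage-wise MLP (parameters jittered off exact ReLU kinks)
  scfg <- stagewise_config()
  blocks <- tricoat:::flat_blocks(inp)
  Xb <- lapply(blocks, function(b) b[rows, , drop = FALSE])
  set.seed(5)
  params <- tricoat:::init_stagewise_params(scfg, lapply(blocks, ncol), "all")
  params <- tricoat:::tree_map(function(x) x + rnorm(length(x), 0, 0.05), params)
  fw <- tricoat:::stagewise_fwd(params, Xb, "all")
  g <- tricoat:::stagewise_bwd(tricoat:::ce_loss(fw$logits, y)$dlogits, fw, params, "all")
  lf <- function(p) {
    tricoat:::ce_loss(tricoat:::stagewise_fwd(p, Xb, "all")$logits, y)$loss
  }
  set.seed(97)
  expect_lt(max_grad_error(params, lf, g), 1e-4)
})
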
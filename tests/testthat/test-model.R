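test_that("tokenizers produce the reference shapes at full dimensions", {
  sim <- tiny_sim(n = c(2, 2, 2), n_roi = 72, n_snp = 70,
                  inform = c(imaging = 5, genetics = 5, clinical = 2))
  inp <- scaled_inputs(sim)
  k <- 256L
  set.seed(1)
  ti <- tricoat:::tokenize_fwd("imaging", inp, 1L,
                               tricoat:::init_tokenizer("imaging", k))
  expect_equal(dim(ti$Tok), c(72L, 256L))
  tg <- tricoat:::tokenize_fwd("genetics", inp, 1L,
                               tricoat:::init_tokenizer("genetics", k))
  expect_equal(dim(tg$Tok), c(70L, 256L))
  tc <- tricoat:::tokenize_fwd("clinical", inp, 1L,
                               tricoat:::init_tokenizer("clinical", k, B = 7L))
  expect_equal(dim(tc$Tok), c(7L, 256L))
  # genetics halves: SNPs on the same chromosome share the embedding half
  chrom <- inp$chrom
  same <- which(chrom == chrom[1])
  if (length(same) > 1) {
    expect_equal(tg$Tok[same[1], 129:256], tg$Tok[same[2], 129:256])
  }
  # differing dosages only change the projected half
  expect_true(any(tg$Tok[same[1], 1:128] != tg$Tok[same[2], 1:128]) ||
                all(inp$dos[1, same[1]] == inp$dos[1, same[2]]))
})

test_that("tokenizer linearity and locality", {
  sim <- tiny_sim()
  inp <- scaled_inputs(sim)
  k <- 8L
  # zero input with zero bias -> zero imaging tokens
  p_img <- tricoat:::init_tokenizer("imaging", k)
  inp0 <- inp
  inp0$img[] <- 0
  tok0 <- tricoat:::tokenize_fwd("imaging", inp0, 1L, p_img)
  expect_equal(max(abs(tok0$Tok)), 0)
  # permuting ROI order permutes token rows identically (shared affine map)
  t1 <- tricoat:::tokenize_fwd("imaging", inp, 1L, p_img)
  M <- ncol(inp$img) / 4L
  perm <- sample(M)
  inp_p <- inp
  cols <- as.vector(vapply(perm, function(r) (r - 1L) * 4L + 1:4, integer(4)))
  inp_p$img <- inp$img[, cols, drop = FALSE]
  t2 <- tricoat:::tokenize_fwd("imaging", inp_p, 1L, p_img)
  expect_equal(t2$Tok, t1$Tok[perm, ], tolerance = 1e-12)
  # clinical: doubling one score changes only its own token row
  p_cli <- tricoat:::init_tokenizer("clinical", k, B = 7L)
  c1 <- tricoat:::tokenize_fwd("clinical", inp, 2L, p_cli)
  inp2 <- inp
  inp2$cli[2, 3] <- 2 * inp2$cli[2, 3] + 1
  c2 <- tricoat:::tokenize_fwd("clinical", inp2, 2L, p_cli)
  changed <- which(rowSums(abs(c2$Tok - c1$Tok)) > 1e-12)
  expect_equal(changed, 3L)
})

test_that("forward pass honors the shape contract and is deterministic", {
  sim <- tiny_sim(n = c(5, 5, 5), n_roi = 6, n_snp = 5)
  scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, sim$cohort$subjects))
  cfg <- tiny_config(epochs = 1)
  fit <- fit_tricoat(scaled, sim$truth, sim$cohort$subjects, NULL, cfg)
  out <- predict(fit, scaled, sim$cohort$subjects[1:3], attention = TRUE)
  expect_equal(dim(out$prob), c(3L, 4L))
  expect_equal(rowSums(as.matrix(out$prob[, 2:4])), rep(1, 3), tolerance = 1e-9)
  # attention: (M+1) x (B+1) and (N+1) x (B+1) per subject, rows sum to 1
  expect_equal(dim(out$attention$imaging), c(7L, 8L, 3L))
  expect_equal(dim(out$attention$genetics), c(6L, 8L, 3L))
  expect_lt(max(abs(apply(out$attention$imaging, c(1, 3), sum) - 1)), 1e-6)
  expect_equal(dimnames(out$attention$imaging)[[2]][1], "<cls>")
  # identical training runs produce identical models and predictions
  fit2 <- fit_tricoat(scaled, sim$truth, sim$cohort$subjects, NULL, cfg)
  out2 <- predict(fit2, scaled, sim$cohort$subjects[1:3])
  expect_identical(out$prob, out2)
  # two subjects with identical inputs get identical logits
  co2 <- sim$cohort
  dup_src <- co2$subjects[1]; dup_dst <- co2$subjects[2]
  for (tbl in c("imaging", "dosages", "clinical", "mmse")) {
    src_rows <- co2[[tbl]]$subject_id == dup_src
    dst_rows <- co2[[tbl]]$subject_id == dup_dst
    vals <- co2[[tbl]][src_rows, setdiff(names(co2[[tbl]]), "subject_id")]
    co2[[tbl]][dst_rows, setdiff(names(co2[[tbl]]), "subject_id")] <- vals
  }
  scaled2 <- apply_scaler(co2, fit_scaler(co2, co2$subjects))
  pd <- predict(fit, scaled2, c(dup_src, dup_dst))
  expect_equal(as.numeric(pd[1, 2:4]), as.numeric(pd[2, 2:4]), tolerance = 1e-12)
})

test_that("training loss decreases on a learnable cohort", {
  sim <- tiny_sim(n = c(10, 10, 10), effect = 2, seed = 19, n_roi = 6, n_snp = 5,
                  inform = c(imaging = 3, genetics = 2, clinical = 3))
  scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, sim$cohort$subjects))
  cfg <- tiny_config(k = 16, hidden = 16, epochs = 10, batch = 10, seed = 2)
  fit <- fit_tricoat(scaled, sim$truth, sim$cohort$subjects, NULL, cfg)
  h <- tidy(fit)
  expect_equal(nrow(h), 10L)
  expect_lt(mean(tail(h$train_loss, 3)), mean(head(h$train_loss, 3)))
})

test_that("checkpoint selection tracks the best validation epoch", {
  sim <- tiny_sim(n = c(10, 10, 10), effect = 2, seed = 23, n_roi = 6, n_snp = 5,
                  inform = c(imaging = 3, genetics = 2, clinical = 3))
  sp <- strat_split(sim$truth, 0.7, seed = 3)
  scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, sp$train))
  cfg <- tiny_config(k = 16, hidden = 16, epochs = 6, batch = 8, seed = 2)
  fit <- fit_tricoat(scaled, sim$truth, sp$train, sp$test, cfg)
  h <- tidy(fit)
  expect_equal(fit$best_val_auroc, max(h$val_score))
  expect_equal(fit$best_epoch, which.max(h$val_score))
})

test_that("config invariants are enforced before any compute", {
  expect_error(tricoat_config(k = 255), "even")
  expect_error(tricoat_config(k = 256, n_heads = 5), "divide")
  expect_error(tricoat_config(dropout = 1.2))
})

test_that("flatten joint-representation variant runs and differs from cls", {
  sim <- tiny_sim(n = c(4, 4, 4), n_roi = 4, n_snp = 3)
  scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, sim$cohort$subjects))
  cfg_f <- tiny_config(epochs = 1, joint = "flatten")
  fit_f <- fit_tricoat(scaled, sim$truth, sim$cohort$subjects, NULL, cfg_f)
  pf <- predict(fit_f, scaled)
  expect_equal(rowSums(as.matrix(pf[, 2:4])), rep(1, 12), tolerance = 1e-9)
  cfg_c <- tiny_config(epochs = 1, include_clinical_cls = TRUE)
  fit_c <- fit_tricoat(scaled, sim$truth, sim$cohort$subjects, NULL, cfg_c)
  pc <- predict(fit_c, scaled)
  expect_false(identical(pf, pc))
})
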
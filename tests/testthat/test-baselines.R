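test_that("flattened feature blocks have the expected widths", {
  sim <- tiny_sim(n = c(2, 2, 2), n_roi = 72, n_snp = 70,
                  inform = c(imaging = 5, genetics = 5, clinical = 2))
  inp <- scaled_inputs(sim)
  expect_equal(ncol(tricoat:::flat_features(inp, "imaging")), 72L * 4L)
  expect_equal(ncol(tricoat:::flat_features(inp, "genetics")), 70L)
  expect_equal(ncol(tricoat:::flat_features(inp, "clinical")), 7L)
  expect_equal(ncol(tricoat:::flat_features(inp, "all")), 288L + 70L + 7L)
})

test_that("stage-wise parameter counts follow the declared 64/32/16 topology", {
  sim <- tiny_sim()
  inp <- scaled_inputs(sim)
  blocks <- tricoat:::flat_blocks(inp)
  cfg <- stagewise_config()
  set.seed(1)
  p <- tricoat:::init_stagewise_params(cfg, lapply(blocks, ncol), "all")
  d_im <- ncol(blocks$imaging); d_g <- ncol(blocks$genetics); d_c <- ncol(blocks$clinical)
  count <- sum(unlist(tricoat:::tree_map(length, p)))
  want <- (d_im + 1) * 64 + (d_g + 1) * 64 + (d_c + 1) * 64 +
    (3 * 64 + 1) * 32 + (32 + 1) * 16 + (16 + 1) * 3
  expect_equal(count, want)
  # single-modality adaptation: first (64) plus last (16) stages only
  p1 <- tricoat:::init_stagewise_params(cfg, list(d_c), "clinical")
  count1 <- sum(unlist(tricoat:::tree_map(length, p1)))
  expect_equal(count1, (d_c + 1) * 64 + (64 + 1) * 16 + (16 + 1) * 3)
})

test_that("late fusion is the mean of branch probabilities", {
  sim <- tiny_sim(n = c(4, 4, 4), n_roi = 4, n_snp = 3, seed = 5)
  scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, sim$cohort$subjects))
  m <- tc_method("late", config = tiny_config(epochs = 1))
  fit <- fit_method(m, scaled, sim$truth, sim$cohort$subjects, seed = 3)
  P <- predict_method(fit, scaled)
  expect_equal(unname(rowSums(P)), rep(1, 12), tolerance = 1e-6)
  branch_probs <- lapply(fit$fit, tricoat:::predict_tokclf, cohort = scaled)
  expect_equal(P, Reduce(`+`, branch_probs) / 3, tolerance = 1e-12)
  # if all branches agreed exactly, the fused output would equal them
  same <- Reduce(`+`, list(branch_probs[[1]], branch_probs[[1]], branch_probs[[1]])) / 3
  expect_equal(same, branch_probs[[1]])
})

test_that("svm and rf adapters honor the declared hyperparameters", {
  sim <- tiny_sim(n = c(8, 8, 8), effect = 2, seed = 9)
  scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, sim$cohort$subjects))
  fit_s <- fit_method(tc_method("svm"), scaled, sim$truth, sim$cohort$subjects, seed = 1)
  expect_equal(fit_s$fit$cost, 1)
  expect_equal(as.character(fit_s$fit$call$kernel), "radial")
  fit_r <- fit_method(tc_method("rf"), scaled, sim$truth, sim$cohort$subjects, seed = 1)
  expect_equal(fit_r$fit$ntree, 100L)
  Ps <- predict_method(fit_s, scaled)
  Pr <- predict_method(fit_r, scaled)
  expect_equal(unname(rowSums(Ps)), rep(1, 24), tolerance = 1e-6)
  expect_equal(colnames(Pr), c("slow", "intermediate", "fast"))
  # determinism given the seed
  fit_r2 <- fit_method(tc_method("rf"), scaled, sim$truth, sim$cohort$subjects, seed = 1)
  expect_equal(predict_method(fit_r2, scaled), Pr)
})

test_that("null cohorts give chance-level AUROC for every flat-feature model", {
  sim <- tiny_sim(n = c(30, 30, 30), effect = 0, seed = 31)
  sp <- strat_split(sim$truth, 2 / 3, seed = 4)
  scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, sp$train))
  y_te <- truth_of(sim, sp$test)
  se <- null_auroc_se(y_te)
  for (nm in c("svm", "rf")) {
    for (mod in c("all", "imaging", "clinical")) {
      fit <- fit_method(tc_method(nm, mod), scaled, sim$truth, sp$train, seed = 11)
      auc <- auroc_ovo(y_te, predict_method(fit, scaled, sp$test))
      expect_lt(abs(auc - 0.5), 3 * se,
                label = sprintf("%s/%s null AUROC", nm, mod))
    }
  }
})

test_that("early fusion classifier trains and is deterministic", {
  sim <- tiny_sim(n = c(4, 4, 4), n_roi = 4, n_snp = 3, seed = 6)
  scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, sim$cohort$subjects))
  m <- tc_method("early", config = tiny_config(epochs = 2))
  f1 <- fit_method(m, scaled, sim$truth, sim$cohort$subjects, seed = 8)
  f2 <- fit_method(m, scaled, sim$truth, sim$cohort$subjects, seed = 8)
  expect_equal(predict_method(f1, scaled), predict_method(f2, scaled))
  # one shared class token over M + N + B tokens
  expect_equal(f1$fit$cfg$k, 8L)
  expect_length(f1$fit$params$cls, 8L)
  expect_named(f1$fit$params$tok, c("imaging", "genetics", "clinical"))
})
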
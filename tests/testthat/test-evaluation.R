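test_that("exact divisibility gives one subject per class per fold", {
  labels <- tibble(subject_id = sprintf("S%02d", 1:30),
                   subtype = rep(c("slow", "intermediate", "fast"), 10))
  plan <- make_fold_plan(labels, n_outer = 10, n_inner = 5, seed = 3)
  for (o in plan$outer) {
    y <- labels$subtype[match(o$test_ids, labels$subject_id)]
    expect_equal(sort(as.character(y)), c("fast", "intermediate", "slow"))
  }
})

test_that("outer folds partition the cohort; inner folds partition outer-train", {
  sim <- tiny_sim(n = c(25, 40, 12), seed = 17)
  labels <- sim$truth
  plan <- make_fold_plan(labels, seed = 5)
  test_sets <- lapply(plan$outer, `[[`, "test_ids")
  expect_setequal(unlist(test_sets), labels$subject_id)
  expect_equal(sum(lengths(test_sets)), nrow(labels))  # disjoint + exhaustive
  for (o in plan$outer) {
    expect_length(intersect(o$test_ids, o$train_ids), 0)
    vals <- lapply(o$inner, `[[`, "val_ids")
    expect_setequal(unlist(vals), o$train_ids)
    expect_equal(sum(lengths(vals)), length(o$train_ids))
    for (i in o$inner) {
      expect_length(intersect(i$val_ids, o$test_ids), 0)
    }
  }
  # deterministic given seed
  plan2 <- make_fold_plan(labels, seed = 5)
  expect_identical(tidy(plan), tidy(plan2))
  # a class smaller than the fold count warns
  expect_warning(make_fold_plan(tibble(subject_id = sprintf("A%02d", 1:25),
                                       subtype = c(rep("slow", 10),
                                                   rep("intermediate", 10),
                                                   rep("fast", 5))),
                                seed = 1),
                 "fewer members")
})

test_that("fold label distributions are chance-compatible on a 494-subject cohort", {
  set.seed(41)
  labels <- tibble(subject_id = sprintf("S%03d", 1:494),
                   subtype = sample(rep(c("slow", "intermediate", "fast"),
                                        c(177, 302, 15))))
  plan <- suppressWarnings(make_fold_plan(labels, seed = 7))
  pooled <- table(labels$subtype)
  for (o in plan$outer) {
    y <- labels$subtype[match(o$test_ids, labels$subject_id)]
    tab <- table(factor(y, levels = names(pooled)))
    p <- suppressWarnings(stats::chisq.test(tab, p = pooled / sum(pooled))$p.value)
    expect_gt(p, 0.05)
  }
})

test_that("cross-testing emits exactly n_outer x n_repeats rows per method", {
  sim <- tiny_sim(n = c(20, 20, 20), effect = 1.5, seed = 8)
  labels <- sim$truth
  plan <- make_fold_plan(labels, n_outer = 10, n_inner = 5, seed = 2)
  methods <- list(svm = tc_method("svm"), rf = tc_method("rf"))
  report <- run_cross_testing(sim$cohort, labels, methods, plan, seed = 9)
  expect_s3_class(report, "evaluation_report")
  expect_equal(nrow(report), 2L * 50L)
  counts <- tidy(report) |> dplyr::count(method)
  expect_equal(counts$n, c(50L, 50L))
  g <- glance(report)
  expect_equal(g$n_runs, c(50L, 50L))
  expect_true(all(g$mean_auroc > 0 & g$mean_auroc <= 1))
  # sample SD convention
  svm_rows <- tidy(report) |> dplyr::filter(method == "svm")
  expect_equal(g$sd_auroc[g$method == "svm"], stats::sd(svm_rows$auroc))
})

test_that("perturbing test-fold rows changes nothing upstream (leakage probe)", {
  sim <- tiny_sim(n = c(12, 12, 12), effect = 1, seed = 14)
  labels <- sim$truth
  plan <- make_fold_plan(labels, n_outer = 3, n_inner = 2, seed = 4)
  o <- plan$outer[[1]]
  # scaler purity
  sc1 <- fit_scaler(sim$cohort, o$train_ids)
  co2 <- sim$cohort
  tr <- co2$clinical$subject_id %in% o$test_ids
  co2$clinical[tr, clinical_features()] <- co2$clinical[tr, clinical_features()] * 5 + 7
  sc2 <- fit_scaler(co2, o$train_ids)
  expect_identical(tidy(sc1), tidy(sc2))
  # hyperparameter selection purity: settings chosen on perturbed-test data match
  methods <- list(svm = tc_method("svm"))
  grid <- list(svm = list(cost = c(0.1, 1)))
  r1 <- run_cross_testing(sim$cohort, labels, methods, plan, grid = grid,
                          n_repeats = 2, seed = 6)
  r2 <- run_cross_testing(co2, labels, methods, plan, grid = grid,
                          n_repeats = 2, seed = 6)
  # fold 1 is the fold whose test rows were perturbed: its scaler, inner-CV
  # selections and training are pure functions of its outer-training data
  # (in other folds the perturbed subjects legitimately become training data)
  f1 <- function(r) tidy(r) |> dplyr::filter(fold == 1)
  expect_identical(f1(r1)$setting, f1(r2)$setting)
})

test_that("paired t-test conventions and null calibration", {
  sim_report <- function(a, b) {
    df <- bind_rows(tibble(method = "A", fold = rep(1:10, each = 5),
                           rep = rep(1:5, 10), auroc = a, n_test = 10,
                           setting = "default"),
                    tibble(method = "B", fold = rep(1:10, each = 5),
                           rep = rep(1:5, 10), auroc = b, n_test = 10,
                           setting = "default"))
    class(df) <- c("evaluation_report", class(df))
    df
  }
  x <- runif(50, 0.6, 0.8)
  expect_equal(paired_ttest(sim_report(x, x), "A", "B")$p_value, 1)
  expect_equal(paired_ttest(sim_report(x + 0.05, x), "A", "B")$p_value, 0)
  set.seed(50)
  r <- sim_report(x, x + rnorm(50, 0, 0.02))
  tt <- paired_ttest(r, "A", "B")
  a_rows <- tidy(r) |> dplyr::filter(method == "A")
  b_rows <- tidy(r) |> dplyr::filter(method == "B")
  ref <- stats::t.test(a_rows$auroc, b_rows$auroc, paired = TRUE)
  expect_equal(tt$p_value, ref$p.value)
  expect_equal(tt$t, unname(ref$statistic))
  expect_error(paired_ttest(r, "A", "C"), "not present")
  # null calibration: p-values approximately uniform under no difference
  set.seed(55)
  ps <- replicate(400, {
    base <- runif(50, 0.5, 0.9)
    a <- base + rnorm(50, 0, 0.03)
    b <- base + rnorm(50, 0, 0.03)
    paired_ttest(sim_report(a, b), "A", "B")$p_value
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})
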
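#' Build a nested stratified cross-testing fold plan
#'
#' Partitions the cohort into `n_outer` stratified test folds; for each
#' outer fold, the remaining training subjects are further partitioned into
#' `n_inner` stratified validation folds used solely for hyperparameter /
#' checkpoint selection.  Stratification assigns each class's shuffled
#' members round-robin, so per-fold class counts are within one subject of
#' exact proportionality; a class with fewer members than folds triggers a
#' warning and best-effort placement (some folds then lack that class in
#' their validation split, never in the outer test folds while members
#' remain).
#'
#' @param labels Tibble `subject_id`, `subtype` (or any label column named
#'   `subtype`).
#' @param n_outer,n_inner Number of outer test folds and inner validation
#'   folds.
#' @param seed Integer seed; the plan is deterministic given
#'   `(labels, seed)`.
#' @return A `fold_plan`: list with `outer` (per fold: `test_ids`,
#'   `train_ids`, and `inner`, a list of `val_ids`/`train_ids` pairs).
#' @export
make_fold_plan <- function(labels, n_outer = 10L, n_inner = 5L, seed = 1L) {
  labels <- as_tibble(labels)
  check_columns(labels, c("subject_id", "subtype"), "labels")
  labels <- labels |> arrange(.data$subject_id)
  y <- as_subtype(labels$subtype)
  ids <- as.character(labels$subject_id)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  small <- levels(y)[table(y) > 0 & table(y) < n_outer]
  if (length(small) > 0) {
    warn(sprintf("class(es) with fewer members than the %d outer folds: %s; using best-effort stratification",
                 n_outer, paste(small, collapse = ", ")))
  }
  assign_folds <- function(ids, y, k) {
    fold <- integer(length(ids))
    for (cl in levels(y)) {
      members <- which(y == cl)
      if (length(members) == 0) next
      members <- members[sample.int(length(members))]
      start <- sample.int(k, 1L)
      fold[members] <- ((start + seq_along(members) - 2L) %% k) + 1L
    }
    fold
  }

  outer_fold <- assign_folds(ids, y, n_outer)
  outer <- lapply(seq_len(n_outer), function(f) {
    test_ids <- ids[outer_fold == f]
    train_ids <- ids[outer_fold != f]
    ytr <- y[outer_fold != f]
    inner_fold <- assign_folds(train_ids, ytr, n_inner)
    inner <- lapply(seq_len(n_inner), function(g) {
      list(val_ids = train_ids[inner_fold == g],
           train_ids = train_ids[inner_fold != g])
    })
    list(fold = f, test_ids = test_ids, train_ids = train_ids, inner = inner)
  })
  structure(list(outer = outer, n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner), seed = as.integer(seed),
                 subjects = ids),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d outer test folds x %d inner validation folds over %d subjects (seed %d)\n",
              x$n_outer, x$n_inner, length(x$subjects), x$seed))
  invisible(x)
}

#' Fold membership as a tibble
#' @param x A `fold_plan`.
#' @param ... Unused.
#' @return Tibble `subject_id`, `outer_fold` (the fold whose test set holds
#'   the subject).
#' @method tidy fold_plan
#' @export
tidy.fold_plan <- function(x, ...) {
  bind_rows(lapply(x$outer, function(o) {
    tibble(subject_id = o$test_ids, outer_fold = o$fold)
  })) |> arrange(.data$subject_id)
}

#' Write / read a fold plan as JSON
#'
#' Explicit subject-ID lists per outer fold and inner split, so a plan can
#' be shared across languages and runs.
#'
#' @param plan A `fold_plan`.
#' @param path JSON file path.
#' @return `path` (write) or a `fold_plan` (read).
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(
    list(n_outer = plan$n_outer, n_inner = plan$n_inner, seed = plan$seed,
         subjects = plan$subjects, outer = plan$outer),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  outer <- lapply(raw$outer, function(o) {
    list(fold = o$fold, test_ids = unlist(o$test_ids),
         train_ids = unlist(o$train_ids),
         inner = lapply(o$inner, function(i) {
           list(val_ids = unlist(i$val_ids), train_ids = unlist(i$train_ids))
         }))
  })
  structure(list(outer = outer, n_outer = raw$n_outer, n_inner = raw$n_inner,
                 seed = raw$seed, subjects = unlist(raw$subjects)),
            class = "fold_plan")
}

grid_settings <- function(grid) {
  if (is.null(grid) || length(grid) == 0) return(list(NULL))
  df <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

setting_id <- function(setting) {
  if (is.null(setting)) return("default")
  paste(sprintf("%s=%s", names(setting), vapply(setting, format, character(1))),
        collapse = ",")
}

derive_seed <- function(seed, fold, rep) {
  as.integer((as.numeric(seed) * 7919 + fold * 131 + rep * 17) %% 2147483647)
}

#' Run the nested cross-testing protocol
#'
#' For every outer fold: a feature scaler is fit on the outer-training
#' subjects only and applied to the whole cohort; for each method, each of
#' the `n_inner` validation splits selects the best hyperparameter setting
#' from `grid` by validation OvO AUROC; the model is then retrained on the
#' full outer-training set under that setting (the matching validation
#' split drives epoch checkpointing) and scored once on the untouched test
#' fold.  With the default 10 outer folds and 5 inner repeats this yields
#' 50 test evaluations per method.  Test-fold rows influence nothing
#' upstream of their own scoring: scaler statistics, hyperparameter
#' selection and checkpoint choice are functions of outer-training data
#' only.
#'
#' @param cohort An unscaled `tricoat_cohort`.
#' @param labels Tibble `subject_id`, `subtype`.
#' @param methods Named list of [tc_method()] objects.
#' @param plan A [make_fold_plan()] plan.
#' @param grid Optional named list of per-method tuning grids (each a named
#'   list of value vectors, e.g. `list(lr = c(1e-3, 1e-4))`); methods
#'   absent from `grid` are trained at their declared configuration.
#' @param n_repeats Test evaluations per outer fold (one per inner split;
#'   default `plan$n_inner`).
#' @param seed Master seed; per-(fold, repeat) training seeds are derived
#'   from it.
#' @param verbose Report progress.
#' @return An `evaluation_report` tibble: method, fold, rep, auroc, n_test,
#'   setting.
#' @export
run_cross_testing <- function(cohort, labels, methods, plan, grid = NULL,
                              n_repeats = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(plan, "fold_plan"), is.list(methods), length(methods) > 0)
  if (is.null(names(methods)) || any(names(methods) == "")) {
    abort("methods must be a named list")
  }
  n_repeats <- as.integer(n_repeats %||% plan$n_inner)
  stopifnot(n_repeats <= plan$n_inner)
  labels <- as_tibble(labels)
  rows <- list()
  for (o in plan$outer) {
    scaler <- fit_scaler(cohort, o$train_ids)
    scaled <- apply_scaler(cohort, scaler)
    y_test <- subtype_levels()[label_vector(labels, o$test_ids)]
    for (mname in names(methods)) {
      method <- methods[[mname]]
      settings <- grid_settings(grid[[mname]])
      for (r in seq_len(n_repeats)) {
        inner <- o$inner[[r]]
        rseed <- derive_seed(seed, o$fold, r)
        chosen <- settings[[1]]
        if (length(settings) > 1) {
          val_scores <- vapply(settings, function(s) {
            mth <- update_method(method, s)
            fit <- fit_method(mth, scaled, labels, inner$train_ids,
                              inner$val_ids, seed = rseed)
            P <- predict_method(fit, scaled, inner$val_ids)
            yv <- subtype_levels()[label_vector(labels, inner$val_ids)]
            tryCatch(auroc_ovo(yv, P), error = function(e) NA_real_)
          }, numeric(1))
          chosen <- settings[[which.max(val_scores)]]
        }
        fit <- fit_method(update_method(method, chosen), scaled, labels,
                          o$train_ids, inner$val_ids, seed = rseed)
        P <- predict_method(fit, scaled, o$test_ids)
        auc <- tryCatch(auroc_ovo(y_test, P), error = function(e) {
          warn(sprintf("AUROC undefined for method %s, fold %d, repeat %d: %s",
                       mname, o$fold, r, conditionMessage(e)))
          NA_real_
        })
        rows[[length(rows) + 1L]] <-
          tibble(method = mname, fold = o$fold, rep = r, auroc = auc,
                 n_test = length(o$test_ids), setting = setting_id(chosen))
        if (verbose) {
          message(sprintf("fold %2d rep %d  %-10s AUROC %.3f",
                          o$fold, r, mname, auc))
        }
      }
    }
  }
  report <- bind_rows(rows)
  class(report) <- c("evaluation_report", class(report))
  attr(report, "seed") <- seed
  report
}

#' Per-run evaluation rows
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "evaluation_report")
  out
}

#' Aggregate mean +/- SD per method
#'
#' The SD is the sample standard deviation (denominator n - 1) over all
#' fold-and-repeat evaluations of a method.
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Tibble method, n_runs, mean_auroc, sd_auroc.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  missing <- sum(is.na(x$auroc))
  if (missing > 0) {
    warn(sprintf("%d evaluation(s) with undefined AUROC excluded from summaries", missing))
  }
  tidy.evaluation_report(x) |>
    filter(!is.na(.data$auroc)) |>
    group_by(method = .data$method) |>
    summarise(n_runs = dplyr::n(), mean_auroc = mean(.data$auroc),
              sd_auroc = stats::sd(.data$auroc), .groups = "drop")
}

#' AUROC distributions per method
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot boxplot of per-run test AUROCs by method.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- tidy.evaluation_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$auroc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "Test OvO AUROC") +
    ggplot2::theme_minimal()
}

#' Paired t-test between two methods' matched evaluations
#'
#' Two-sided paired t-test on the fold-and-repeat-matched AUROC
#' differences.  Degenerate conventions (documented, deterministic): if
#' every matched difference is exactly zero the p-value is 1; if the
#' differences are constant but nonzero (zero variance) the p-value is 0.
#'
#' @param report An `evaluation_report`.
#' @param method_a,method_b Method names present in the report.
#' @return Tibble with mean difference (a - b), t statistic and p-value.
#' @export
paired_ttest <- function(report, method_a, method_b) {
  df <- tidy.evaluation_report(report)
  a <- df |> filter(.data$method == method_a) |> arrange(.data$fold, .data$rep)
  b <- df |> filter(.data$method == method_b) |> arrange(.data$fold, .data$rep)
  if (nrow(a) == 0 || nrow(b) == 0) abort("method not present in report")
  if (nrow(a) != nrow(b) ||
      !identical(a[c("fold", "rep")], b[c("fold", "rep")])) {
    abort("methods have unmatched (fold, rep) entries")
  }
  d <- a$auroc - b$auroc
  if (anyNA(d)) abort("cannot pair evaluations with undefined AUROC")
  if (all(d == 0)) {
    return(tibble(method_a = method_a, method_b = method_b,
                  mean_diff = 0, t = NA_real_, p_value = 1))
  }
  if (stats::sd(d) == 0) {
    return(tibble(method_a = method_a, method_b = method_b,
                  mean_diff = mean(d), t = sign(mean(d)) * Inf, p_value = 0))
  }
  tt <- stats::t.test(a$auroc, b$auroc, paired = TRUE)
  tibble(method_a = method_a, method_b = method_b,
         mean_diff = unname(tt$estimate), t = unname(tt$statistic),
         p_value = tt$p.value)
}

#' All pairwise paired t-tests in a report
#' @param report An `evaluation_report`.
#' @return Tibble of pairwise comparisons.
#' @export
pairwise_ttests <- function(report) {
  ms <- unique(report$method)
  if (length(ms) < 2) return(tibble())
  bind_rows(utils::combn(ms, 2, function(pr) {
    paired_ttest(report, pr[1], pr[2])
  }, simplify = FALSE))
}
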
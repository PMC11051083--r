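#' Fit a leakage-safe feature scaler on a training subset
#'
#' Learns z-score parameters (mean and population SD, denominator `n`) for
#' every imaging ROI-trait column and every clinical score, using only the
#' rows of `train_ids`.  Genotype dosages and the per-SNP GWAS attributes
#' are deliberately left unscaled: they enter the genetic tokenizer raw.
#' Constant features receive scale 1 with a warning so that applying the
#' scaler never divides by zero.
#'
#' The fitted statistics are a pure function of the training rows, which is
#' what makes per-fold normalization leakage-safe: rows outside `train_ids`
#' cannot influence the transform.
#'
#' @param cohort A `tricoat_cohort`.
#' @param train_ids Character vector of training subject IDs (subset of
#'   `cohort$subjects`).
#' @return A `tricoat_scaler`: tibble of (table, feature, center, scale)
#'   wrapped with the modalities it applies to.
#' @export
fit_scaler <- function(cohort, train_ids) {
  stopifnot(inherits(cohort, "tricoat_cohort"))
  train_ids <- as.character(train_ids)
  if (length(train_ids) == 0) abort("train_ids must be non-empty")
  extra <- setdiff(train_ids, cohort$subjects)
  if (length(extra) > 0) {
    abort(sprintf("train_ids not in cohort: %s", paste(utils::head(extra, 5), collapse = ", ")))
  }

  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  stats_for <- function(m, table) {
    mt <- m[rownames(m) %in% train_ids, , drop = FALSE]
    mu <- colMeans(mt)
    sd <- apply(mt, 2, pop_sd)
    const <- sd <= 0
    if (any(const)) {
      warn(sprintf("%d constant feature(s) in '%s' (e.g. %s): scale set to 1",
                   sum(const), table, colnames(mt)[which(const)[1]]))
      sd[const] <- 1
    }
    tibble(table = table, feature = colnames(mt), center = unname(mu), scale = unname(sd))
  }

  params <- bind_rows(stats_for(imaging_matrix(cohort), "imaging"),
                      stats_for(clinical_matrix(cohort), "clinical"))
  structure(list(params = params, modalities = c("imaging", "clinical"),
                 n_train = length(train_ids)),
            class = "tricoat_scaler")
}

#' @export
print.tricoat_scaler <- function(x, ...) {
  cat(sprintf("<tricoat_scaler> %d features (%s), fit on %d subjects\n",
              nrow(x$params), paste(x$modalities, collapse = " + "), x$n_train))
  invisible(x)
}

#' Broom-style view of scaler parameters
#' @param x A `tricoat_scaler`.
#' @param ... Unused.
#' @return Tibble with columns table, feature, center, scale.
#' @method tidy tricoat_scaler
#' @export
tidy.tricoat_scaler <- function(x, ...) x$params

scale_table <- function(params, m, table, invert = FALSE) {
  p <- params[params$table == table, ]
  unmatched <- setdiff(p$feature, colnames(m))
  if (length(unmatched) > 0) {
    abort(sprintf("scaler features not present in cohort '%s' table: %s",
                  table, paste(utils::head(unmatched, 5), collapse = ", ")))
  }
  idx <- match(p$feature, colnames(m))
  if (invert) {
    m[, idx] <- sweep(sweep(m[, idx, drop = FALSE], 2, p$scale, "*"), 2, p$center, "+")
  } else {
    m[, idx] <- sweep(sweep(m[, idx, drop = FALSE], 2, p$center, "-"), 2, p$scale, "/")
  }
  m
}

rebuild_imaging <- function(cohort, m) {
  rois <- sort(unique(cohort$imaging$roi_id))
  traits <- imaging_traits()
  long <- tidyr::expand_grid(subject_id = rownames(m), roi_id = rois)
  for (tr in traits) {
    cols <- paste0(rois, "::", tr)
    long[[tr]] <- as.vector(t(m[, cols, drop = FALSE]))
  }
  long |> arrange(.data$subject_id, .data$roi_id)
}

rebuild_clinical <- function(m) {
  out <- as_tibble(m)
  out <- bind_cols(tibble(subject_id = rownames(m)), out)
  out |> arrange(.data$subject_id)
}

#' Apply (or invert) a fitted scaler
#'
#' Returns a transformed copy of the cohort in which the imaging and
#' clinical features covered by the scaler are z-scored with the training
#' statistics.  Genotype and MMSE tables are untouched.  With
#' `invert = TRUE` the transform is undone, recovering the original values
#' to numerical tolerance.
#'
#' @param cohort A `tricoat_cohort`.
#' @param scaler A `tricoat_scaler` from [fit_scaler()].
#' @param invert Undo rather than apply the transform.
#' @return A transformed `tricoat_cohort`.
#' @export
apply_scaler <- function(cohort, scaler, invert = FALSE) {
  stopifnot(inherits(cohort, "tricoat_cohort"), inherits(scaler, "tricoat_scaler"))
  im <- scale_table(scaler$params, imaging_matrix(cohort), "imaging", invert)
  cl <- scale_table(scaler$params, clinical_matrix(cohort), "clinical", invert)
  out <- cohort
  out$imaging <- rebuild_imaging(cohort, im)
  out$clinical <- rebuild_clinical(cl)
  out
}
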
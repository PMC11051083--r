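#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

#' Canonical clinical score names
#'
#' The seven baseline cognitive scores used by the clinical modality:
#' Logical Memory delayed recall, Digit Symbol substitution, Trail Making
#' Test B, and the four RAVLT summaries (immediate, learning, forgetting,
#' percent forgetting).
#'
#' @return Character vector of length 7.
#' @export
clinical_features <- function() {
  c("LDELTOTAL", "DIGITSCOR", "TRABSCOR",
    "RAVLT_immediate", "RAVLT_learning", "RAVLT_forgetting",
    "RAVLT_perc_forgetting")
}

#' MMSE visit schedule (months)
#' @return Integer vector `c(0, 6, 12, 24)`.
#' @export
mmse_visits <- function() c(0L, 6L, 12L, 24L)

check_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("table '%s' is missing required column(s): %s",
                  table, paste(missing, collapse = ", ")),
          class = "tricoat_schema_error")
  }
  invisible(df)
}

check_no_dup <- function(df, keys, table) {
  dup <- df |> count(across(all_of(keys))) |> filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    ex <- dup[1, keys, drop = FALSE]
    abort(sprintf("table '%s' has %d duplicated (%s) row(s), e.g. (%s)",
                  table, nrow(dup), paste(keys, collapse = ", "),
                  paste(unlist(ex), collapse = ", ")),
          class = "tricoat_integrity_error")
  }
  invisible(df)
}

check_finite <- function(df, cols, table) {
  for (cl in cols) {
    bad <- !is.finite(df[[cl]])
    if (any(bad)) {
      abort(sprintf(
        "table '%s', column '%s': %d missing/non-finite value(s); imputation is not supported",
        table, cl, sum(bad)), class = "tricoat_integrity_error")
    }
  }
  invisible(df)
}

#' Assemble an aligned multimodal cohort
#'
#' Bundles the four per-subject tables (imaging ROIs, genotype dosages with
#' their per-SNP attributes, clinical scores, MMSE panel) into a single
#' validated container.  Subjects are aligned on the intersection of the
#' subject IDs across tables; subjects absent from any table are dropped with
#' a message.  Subject order is lexicographic by ID so that every downstream
#' step (fold assignment, training batches) is reproducible.
#'
#' @param imaging Long tibble: `subject_id`, `roi_id`, `thickness_avg`,
#'   `thickness_sd`, `surface_area`, `volume` (one row per subject x ROI).
#' @param dosages Tibble: `subject_id`, `snp_id`, `dosage` with dosage in
#'   \{0, 1, 2\} (minor-allele count).
#' @param snps Per-SNP static attributes: `snp_id`, `chromosome` (1-22, or
#'   23/"X" for the X chromosome), `odds_ratio`, `rare_allele_freq`,
#'   `intergenic` (0/1).
#' @param clinical Tibble: `subject_id` plus the seven [clinical_features()]
#'   columns.
#' @param mmse Tibble: `subject_id`, `visit_month` in \{0, 6, 12, 24\},
#'   `mmse` (integer 0-30).  Baseline (month 0) is mandatory; follow-up
#'   visits may be missing.
#' @param labels Optional tibble `subject_id`, `subtype` with subtype in
#'   slow/intermediate/fast, covering all subjects.
#'
#' @return An object of class `tricoat_cohort`: a named list of the aligned
#'   tibbles plus the ordered `subjects` vector.
#' @export
cohort <- function(imaging, dosages, snps, clinical, mmse, labels = NULL) {
  imaging  <- as_tibble(imaging)
  dosages  <- as_tibble(dosages)
  snps     <- as_tibble(snps)
  clinical <- as_tibble(clinical)
  mmse     <- as_tibble(mmse)

  check_columns(imaging, c("subject_id", "roi_id", imaging_traits()), "imaging")
  check_columns(dosages, c("subject_id", "snp_id", "dosage"), "genotype_dosages")
  check_columns(snps, c("snp_id", "chromosome", "odds_ratio",
                        "rare_allele_freq", "intergenic"), "genotype_snps")
  check_columns(clinical, c("subject_id", clinical_features()), "clinical")
  check_columns(mmse, c("subject_id", "visit_month", "mmse"), "mmse")

  sets <- list(imaging = unique(imaging$subject_id),
               genotype = unique(dosages$subject_id),
               clinical = unique(clinical$subject_id),
               mmse = unique(mmse$subject_id))
  common <- sort(Reduce(intersect, sets))
  if (length(common) == 0) {
    abort("no subject is present in all four tables", class = "tricoat_fatal_error")
  }
  dropped <- sort(unique(unlist(lapply(sets, setdiff, y = common))))
  if (length(dropped) > 0) {
    inform(sprintf("dropping %d subject(s) absent from at least one table: %s",
                   length(dropped), paste(utils::head(dropped, 10), collapse = ", ")))
  }

  imaging  <- imaging  |> filter(.data$subject_id %in% common) |>
    arrange(.data$subject_id, .data$roi_id)
  dosages  <- dosages  |> filter(.data$subject_id %in% common) |>
    arrange(.data$subject_id, .data$snp_id)
  clinical <- clinical |> filter(.data$subject_id %in% common) |>
    arrange(.data$subject_id)
  mmse     <- mmse     |> filter(.data$subject_id %in% common) |>
    arrange(.data$subject_id, .data$visit_month)
  snps <- snps |> arrange(.data$snp_id)
  snps$chromosome <- chromosome_code(snps$chromosome)

  check_no_dup(imaging, c("subject_id", "roi_id"), "imaging")
  check_no_dup(dosages, c("subject_id", "snp_id"), "genotype_dosages")
  check_no_dup(snps, "snp_id", "genotype_snps")
  check_no_dup(clinical, "subject_id", "clinical")
  check_no_dup(mmse, c("subject_id", "visit_month"), "mmse")

  check_finite(imaging, imaging_traits(), "imaging")
  check_finite(clinical, clinical_features(), "clinical")
  check_finite(snps, c("chromosome", "odds_ratio", "rare_allele_freq", "intergenic"),
               "genotype_snps")

  bad <- !(dosages$dosage %in% c(0, 1, 2))
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "invalid allele dosage %s for snp '%s', subject '%s' (must be 0, 1 or 2)",
      format(dosages$dosage[i]), dosages$snp_id[i], dosages$subject_id[i]),
      class = "tricoat_integrity_error")
  }
  orphan <- setdiff(unique(dosages$snp_id), snps$snp_id)
  if (length(orphan) > 0) {
    abort(sprintf("dosages reference SNP(s) with no static record: %s",
                  paste(utils::head(orphan, 5), collapse = ", ")),
          class = "tricoat_integrity_error")
  }

  # identical ROI set for every subject
  roi_tab <- imaging |> count(.data$subject_id)
  rois <- sort(unique(imaging$roi_id))
  if (any(roi_tab$n != length(rois))) {
    abort("imaging ROI set differs across subjects", class = "tricoat_integrity_error")
  }
  snp_tab <- dosages |> count(.data$subject_id)
  snp_ids <- sort(unique(dosages$snp_id))
  if (any(snp_tab$n != length(snp_ids))) {
    abort("genotype SNP set differs across subjects", class = "tricoat_integrity_error")
  }
  if (!all(mmse$visit_month %in% mmse_visits())) {
    abort("mmse visit_month values must be in {0, 6, 12, 24}",
          class = "tricoat_integrity_error")
  }
  base_ids <- mmse$subject_id[mmse$visit_month == 0L]
  if (!all(common %in% base_ids)) {
    abort("every subject needs a baseline (month 0) MMSE measurement",
          class = "tricoat_integrity_error")
  }

  if (!is.null(labels)) {
    labels <- as_tibble(labels)
    check_columns(labels, c("subject_id", "subtype"), "labels")
    labels <- labels |> filter(.data$subject_id %in% common) |>
      arrange(.data$subject_id)
    if (!setequal(labels$subject_id, common)) {
      abort("labels must cover every aligned subject", class = "tricoat_integrity_error")
    }
    labels$subtype <- as_subtype(labels$subtype)
  }

  structure(
    list(imaging = imaging, dosages = dosages, snps = snps,
         clinical = clinical, mmse = mmse, labels = labels,
         subjects = common),
    class = "tricoat_cohort")
}

imaging_traits <- function() c("thickness_avg", "thickness_sd", "surface_area", "volume")

subtype_levels <- function() c("slow", "intermediate", "fast")

as_subtype <- function(x) {
  f <- factor(as.character(x), levels = subtype_levels())
  if (anyNA(f)) {
    abort("subtype labels must be 'slow', 'intermediate' or 'fast'",
          class = "tricoat_integrity_error")
  }
  f
}

chromosome_code <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    x[toupper(x) == "X"] <- "23"
    x <- suppressWarnings(as.numeric(x))
  }
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 1 | x > 23 | x != round(x))) {
    abort("chromosome must be an integer 1-22 or 23/'X'", class = "tricoat_integrity_error")
  }
  as.integer(x)
}

#' @export
print.tricoat_cohort <- function(x, ...) {
  cat("<tricoat_cohort>\n")
  cat(sprintf("  subjects: %d\n", length(x$subjects)))
  cat(sprintf("  imaging:  %d ROIs x 4 traits\n", length(unique(x$imaging$roi_id))))
  cat(sprintf("  genotype: %d SNPs\n", nrow(x$snps)))
  cat(sprintf("  clinical: %d scores\n", length(clinical_features())))
  cat(sprintf("  mmse:     %d visit records\n", nrow(x$mmse)))
  if (!is.null(x$labels)) {
    cat("  labels:  ", paste(sprintf("%s=%d", levels(x$labels$subtype),
                                     tabulate(x$labels$subtype, 3)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `tricoat_cohort`.
#' @return Integer.
#' @export
n_subjects <- function(cohort) length(cohort$subjects)

#' Read a cohort from CSV files
#'
#' Reads the five fixed-schema CSV tables (see `write_cohort()` for the
#' schemas) and assembles them with [cohort()], aligning subjects on the
#' intersection of IDs.  An optional `labels.csv` is attached when present.
#'
#' @param dir Directory containing `imaging.csv`, `genotype_dosages.csv`,
#'   `genotype_snps.csv`, `clinical.csv`, `mmse.csv` and optionally
#'   `labels.csv`; ignored when `paths` is given.
#' @param paths Optional named list/vector overriding individual file paths
#'   (names `imaging`, `dosages`, `snps`, `clinical`, `mmse`, `labels`).
#' @return A `tricoat_cohort`.
#' @export
read_cohort <- function(dir = NULL, paths = NULL) {
  default <- c(imaging = "imaging.csv", dosages = "genotype_dosages.csv",
               snps = "genotype_snps.csv", clinical = "clinical.csv",
               mmse = "mmse.csv", labels = "labels.csv")
  p <- as.list(if (is.null(dir)) character(0) else file.path(dir, default))
  names(p) <- names(default)
  for (nm in names(paths %||% list())) p[[nm]] <- paths[[nm]]
  rd <- function(path) readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  labels <- NULL
  if (!is.null(p$labels) && file.exists(p$labels)) labels <- rd(p$labels)
  cohort(imaging = rd(p$imaging), dosages = rd(p$dosages), snps = rd(p$snps),
         clinical = rd(p$clinical), mmse = rd(p$mmse), labels = labels)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: writes `imaging.csv`, `genotype_dosages.csv`,
#' `genotype_snps.csv`, `clinical.csv`, `mmse.csv` (and `labels.csv` when
#' labels are attached) into `dir` as UTF-8, comma-separated CSV with a
#' header row and `.` decimal separator.  Values round-trip through
#' [read_cohort()] to within float-formatting tolerance.
#'
#' @param cohort A `tricoat_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tricoat_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, file) readr::write_csv(df, file.path(dir, file), progress = FALSE)
  wr(cohort$imaging, "imaging.csv")
  wr(cohort$dosages, "genotype_dosages.csv")
  wr(cohort$snps, "genotype_snps.csv")
  wr(cohort$clinical, "clinical.csv")
  wr(cohort$mmse, "mmse.csv")
  if (!is.null(cohort$labels)) wr(cohort$labels, "labels.csv")
  invisible(dir)
}

#' Read a PLINK additive-dosage export
#'
#' Maps a PLINK 1.9 `.raw` file (`--recode A`) into the
#' `genotype_dosages.csv` schema.  Column headers of the form
#' `rs12345_A` are stripped of the counted-allele suffix; the IID column
#' becomes `subject_id`.
#'
#' @param path Path to a `.raw` file (whitespace-separated, header row).
#' @return Tibble with columns `subject_id`, `snp_id`, `dosage`.
#' @export
read_plink_raw <- function(path) {
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  snp_cols <- setdiff(names(raw), meta)
  out <- tibble(subject_id = as.character(raw$IID)) |>
    bind_cols(as_tibble(raw[snp_cols])) |>
    tidyr::pivot_longer(-"subject_id", names_to = "snp_id", values_to = "dosage") |>
    mutate(snp_id = sub("_[ACGT]$", "", .data$snp_id),
           dosage = as.numeric(.data$dosage)) |>
    arrange(.data$subject_id, .data$snp_id)
  out
}

# ---- internal dense views -------------------------------------------------

# S x (M*4) imaging matrix; columns ordered roi-major then trait, named
# "<roi>::<trait>" so scaler features and tokenizer reshapes agree.
imaging_matrix <- function(cohort) {
  traits <- imaging_traits()
  wide <- cohort$imaging |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "roi_id",
                       values_from = all_of(traits), names_glue = "{roi_id}::{.value}") |>
    arrange(.data$subject_id)
  rois <- sort(unique(cohort$imaging$roi_id))
  cols <- as.vector(t(outer(rois, traits, function(r, tr) paste0(r, "::", tr))))
  m <- as.matrix(wide[, cols])
  rownames(m) <- wide$subject_id
  m
}

# S x N dosage matrix, SNPs in lexicographic order
dosage_matrix <- function(cohort) {
  wide <- cohort$dosages |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "snp_id",
                       values_from = "dosage") |>
    arrange(.data$subject_id)
  snp_ids <- sort(cohort$snps$snp_id)
  m <- as.matrix(wide[, snp_ids])
  rownames(m) <- wide$subject_id
  m
}

# S x B clinical score matrix
clinical_matrix <- function(cohort) {
  cl <- cohort$clinical |> arrange(.data$subject_id)
  m <- as.matrix(cl[, clinical_features()])
  rownames(m) <- cl$subject_id
  m
}
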
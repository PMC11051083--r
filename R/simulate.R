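#' Specification of a synthetic cohort
#'
#' Defines the generative model used to emulate a baseline multimodal
#' cohort with planted, tunable cross-modal class structure.  Defaults are
#' calibrated to the real-cohort summary statistics the method was designed
#' around: class sizes 177/302/15 (slow/intermediate/fast), a baseline MMSE
#' around 27 +/- 2, and 24-month MMSE changes of roughly +0.8, -3.8 and
#' -9.0 points for the slow, intermediate and fast decliners; the 6- and
#' 12-month class means are taken proportional to elapsed time.
#'
#' `effect_size` is the standardized mean shift per class step on
#' informative features: class scores are -1 (slow), 0 (intermediate) and
#' +1 (fast), so adjacent classes differ by `effect_size` within-class SDs
#' and the extreme classes by twice that.  For informative SNPs the shift
#' is applied on the allele-frequency scale so that the dosage mean moves
#' by the same standardized amount.  Setting `effect_size = 0` produces a
#' null cohort in which baseline features carry no class information.
#'
#' @param n_per_class Named or positional integer vector (slow,
#'   intermediate, fast).
#' @param traj_mean 3x3 matrix of class mean MMSE deltas (rows slow /
#'   intermediate / fast, columns months 6 / 12 / 24).
#' @param traj_noise_sd SD (points) of the Gaussian noise added to each
#'   follow-up delta.
#' @param n_roi,n_snp,n_clinical Modality dimensions (ROIs, SNPs, scores).
#' @param n_informative Named vector: how many ROIs / SNPs / clinical
#'   scores carry class signal (default 12 / 10 / 3, clamped to the
#'   modality dimensions).
#' @param effect_size Standardized per-class-step shift on informative
#'   features; either a scalar or a named vector
#'   `c(imaging=, genetics=, clinical=)`.
#' @param mmse_baseline_mean,mmse_baseline_sd Baseline MMSE distribution
#'   (rounded, clipped to 0-30).
#' @param seed Default seed used by [simulate_cohort()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_class = c(slow = 177, intermediate = 302, fast = 15),
                        traj_mean = default_traj_mean(),
                        traj_noise_sd = 1.5,
                        n_roi = 72, n_snp = 70, n_clinical = 7,
                        n_informative = NULL,
                        effect_size = 1,
                        mmse_baseline_mean = 27, mmse_baseline_sd = 2,
                        seed = 1L) {
  n_per_class <- as.integer(unlist(n_per_class))
  stopifnot(length(n_per_class) == 3, all(n_per_class >= 0), sum(n_per_class) > 0)
  traj_mean <- matrix(as.numeric(unlist(traj_mean)), nrow = 3, ncol = 3,
                      dimnames = list(subtype_levels(), c("m6", "m12", "m24")))
  per_modality <- function(x) {
    mods <- c("imaging", "genetics", "clinical")
    x <- unlist(x)
    if (length(x) == 1) x <- rep(x, 3)
    stopifnot(length(x) == 3)
    if (all(mods %in% names(x))) x <- x[mods] else names(x) <- mods
    x
  }
  if (is.null(n_informative)) {
    n_informative <- pmin(c(imaging = 12, genetics = 10, clinical = 3),
                          c(imaging = n_roi, genetics = n_snp,
                            clinical = n_clinical))
  }
  effect_size <- per_modality(effect_size)
  n_informative <- per_modality(n_informative)
  stopifnot(!anyNA(effect_size), all(effect_size >= 0),
            traj_noise_sd >= 0, n_clinical <= length(clinical_features()),
            n_informative[1] <= n_roi, n_informative[2] <= n_snp,
            n_informative[3] <= n_clinical)
  structure(list(n_per_class = stats::setNames(n_per_class, subtype_levels()),
                 traj_mean = traj_mean, traj_noise_sd = traj_noise_sd,
                 n_roi = n_roi, n_snp = n_snp, n_clinical = n_clinical,
                 n_informative = n_informative, effect_size = effect_size,
                 mmse_baseline_mean = mmse_baseline_mean,
                 mmse_baseline_sd = mmse_baseline_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default class trajectory means (MMSE points at 6/12/24 months)
#' @return 3x3 matrix, rows slow/intermediate/fast.
#' @export
default_traj_mean <- function() {
  d24 <- c(slow = 0.8, intermediate = -3.8, fast = -9.0)
  t(vapply(d24, function(d) d * c(6, 12, 24) / 24, numeric(3)))
}

# per-trait base scales: mean and within-subject SD on plausible
# FreeSurfer-output scales (mm, mm, mm^2, mm^3)
trait_base <- function() {
  list(thickness_avg = c(2.5, 0.25), thickness_sd = c(0.6, 0.1),
       surface_area = c(2500, 400), volume = c(6000, 900))
}

clinical_base <- function() {
  # plausible baseline cognitive score scales (mean, SD)
  m <- rbind(LDELTOTAL = c(8, 4), DIGITSCOR = c(38, 10), TRABSCOR = c(110, 50),
             RAVLT_immediate = c(35, 10), RAVLT_learning = c(4, 2),
             RAVLT_forgetting = c(4, 2.5), RAVLT_perc_forgetting = c(55, 30))
  m
}

#' Simulate a multimodal cohort with planted class structure
#'
#' Draws a cohort under a [cohort_spec()].  Subjects get a true subtype;
#' informative imaging ROIs shift all four morphometric traits coherently
#' by `effect_size` SDs per class step, informative SNP dosages are drawn
#' `Binomial(2, p)` with a class-tilted allele frequency, informative
#' clinical scores shift like imaging, and MMSE follow-ups are the baseline
#' plus the class trajectory mean plus Gaussian noise (rounded, clipped to
#' 0-30).  SNP static attributes are drawn once per SNP: log-normal odds
#' ratio around 1, rare-allele frequency Uniform(0.01, 0.5), intergenic
#' Bernoulli(0.5), chromosome uniform on 1-22.  The draw is fully
#' deterministic given `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A list of class `cohort_sim` with elements `cohort` (a
#'   `tricoat_cohort`) and `truth` (tibble `subject_id`, `subtype`).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n <- sum(spec$n_per_class)
  subtype <- rep(subtype_levels(), times = spec$n_per_class)
  ids <- sprintf("S%05d", seq_len(n))
  u <- rep(c(-1, 0, 1), times = spec$n_per_class)  # class score per subject

  rois <- sprintf("ROI%03d", seq_len(spec$n_roi))
  snp_ids <- sprintf("rs%06d", seq_len(spec$n_snp))
  feats <- clinical_features()[seq_len(spec$n_clinical)]
  inf_roi <- rois[seq_len(spec$n_informative[["imaging"]])]
  inf_snp <- snp_ids[seq_len(spec$n_informative[["genetics"]])]
  inf_cl <- feats[seq_len(spec$n_informative[["clinical"]])]

  # imaging: per-ROI Gaussian traits; informative ROIs shift all 4 traits
  # coherently (atrophy direction: fast decliners lower)
  tb <- trait_base()
  imaging <- tidyr::expand_grid(subject_id = ids, roi_id = rois)
  for (tr in imaging_traits()) {
    base <- tb[[tr]]
    roi_mu <- stats::setNames(stats::rnorm(spec$n_roi, base[1], base[2] / 2), rois)
    x <- stats::rnorm(n * spec$n_roi, mean = roi_mu[imaging$roi_id], sd = base[2])
    shift <- ifelse(imaging$roi_id %in% inf_roi,
                    -rep(u, each = spec$n_roi) * spec$effect_size[["imaging"]] * base[2], 0)
    imaging[[tr]] <- x + shift
  }

  # genotype: class-tilted binomial dosages for informative SNPs; the tilt
  # moves the dosage mean by effect_size * sd(dosage) per class step
  p0 <- stats::setNames(stats::runif(spec$n_snp, 0.05, 0.5), snp_ids)
  dos <- tidyr::expand_grid(subject_id = ids, snp_id = snp_ids)
  pj <- p0[dos$snp_id]
  tilt <- ifelse(dos$snp_id %in% inf_snp,
                 rep(u, each = spec$n_snp) * spec$effect_size[["genetics"]] *
                   sqrt(2 * pj * (1 - pj)) / 2, 0)
  pfull <- pmin(pmax(pj + tilt, 0.02), 0.98)
  dos$dosage <- stats::rbinom(nrow(dos), 2L, pfull)

  snps <- tibble(snp_id = snp_ids,
                 chromosome = sample(1:22, spec$n_snp, replace = TRUE),
                 odds_ratio = exp(stats::rnorm(spec$n_snp, 0, 0.15)),
                 rare_allele_freq = stats::runif(spec$n_snp, 0.01, 0.5),
                 intergenic = stats::rbinom(spec$n_snp, 1L, 0.5))

  # clinical scores; informative ones shift like imaging (worse for fast)
  cb <- clinical_base()
  clinical <- tibble(subject_id = ids)
  for (f in feats) {
    base <- cb[f, ]
    shift <- if (f %in% inf_cl) -u * spec$effect_size[["clinical"]] * base[2] else 0
    clinical[[f]] <- stats::rnorm(n, base[1], base[2]) + shift
  }
  for (f in setdiff(clinical_features(), feats)) {
    clinical[[f]] <- stats::rnorm(n, cb[f, 1], cb[f, 2])
  }

  # MMSE panel: baseline plus class trajectory mean plus noise
  clip_mmse <- function(x) pmin(pmax(round(x), 0), 30)
  base_mmse <- clip_mmse(stats::rnorm(n, spec$mmse_baseline_mean, spec$mmse_baseline_sd))
  cls_idx <- rep(1:3, times = spec$n_per_class)
  mmse <- tibble(subject_id = rep(ids, each = 4),
                 visit_month = rep(mmse_visits(), n))
  follow <- vapply(1:3, function(v) {
    clip_mmse(base_mmse + spec$traj_mean[cbind(cls_idx, v)] +
                stats::rnorm(n, 0, spec$traj_noise_sd))
  }, numeric(n))
  score <- cbind(base_mmse, follow)  # n x 4, visit-major after transpose
  mmse$mmse <- as.integer(as.vector(t(score)))

  truth <- tibble(subject_id = ids, subtype = as_subtype(subtype)) |>
    arrange(.data$subject_id)
  co <- cohort(imaging = imaging, dosages = dos, snps = snps,
               clinical = clinical, mmse = mmse)
  structure(list(cohort = co, truth = truth, spec = spec, seed = as.integer(seed)),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> seed %d, effect sizes [%s]\n", x$seed,
              paste(sprintf("%s=%.2g", names(x$spec$effect_size), x$spec$effect_size),
                    collapse = ", ")))
  print(x$cohort)
  invisible(x)
}

# preserve caller RNG state around seeded simulation
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
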
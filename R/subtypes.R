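#' Baseline-anchored MMSE trajectory deltas
#'
#' Subtracts the baseline MMSE from each follow-up visit so every subject
#' starts at 0; the three deltas (6, 12, 24 months) are the feature vector
#' used for subtype clustering.  Subjects missing any follow-up visit are
#' excluded (and reported via a message): the labelling stage requires
#' complete two-year trajectories.
#'
#' @param mmse Tibble `subject_id`, `visit_month` (0/6/12/24), `mmse`, or a
#'   `tricoat_cohort` whose `$mmse` table is used.
#' @return Tibble `subject_id`, `d6`, `d12`, `d24` with attribute
#'   `excluded` listing dropped subjects.
#' @export
compute_deltas <- function(mmse) {
  if (inherits(mmse, "tricoat_cohort")) mmse <- mmse$mmse
  mmse <- as_tibble(mmse)
  check_columns(mmse, c("subject_id", "visit_month", "mmse"), "mmse")
  base <- mmse |> filter(.data$visit_month == 0L) |>
    select("subject_id", baseline = "mmse")
  no_base <- setdiff(unique(mmse$subject_id), base$subject_id)
  if (length(no_base) > 0) {
    abort(sprintf("%d subject(s) have no baseline MMSE", length(no_base)),
          class = "tricoat_integrity_error")
  }
  wide <- mmse |> filter(.data$visit_month > 0L) |>
    left_join(base, by = "subject_id") |>
    mutate(delta = .data$mmse - .data$baseline) |>
    select("subject_id", "visit_month", "delta") |>
    tidyr::pivot_wider(names_from = "visit_month", values_from = "delta",
                       names_prefix = "d")
  need <- paste0("d", mmse_visits()[-1])
  for (cl in setdiff(need, names(wide))) wide[[cl]] <- NA_real_
  complete <- stats::complete.cases(wide[, need])
  excluded <- wide$subject_id[!complete]
  if (length(excluded) > 0) {
    inform(sprintf("excluding %d subject(s) with incomplete MMSE follow-up",
                   length(excluded)))
  }
  out <- wide[complete, c("subject_id", need)] |> arrange(.data$subject_id)
  if (nrow(out) == 0) {
    abort("no subject has complete MMSE follow-up", class = "tricoat_fatal_error")
  }
  attr(out, "excluded") <- as.character(excluded)
  out
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center sampled with probability proportional to squared
# distance to the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j, ] <- X[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- X[sample.int(n, 1L, prob = d2), ]
    }
    dj <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

#' Cluster subjects into slow / intermediate / fast decline subtypes
#'
#' Runs k-means with k = 3 on the raw trajectory deltas (equal weights,
#' no further scaling): k-means++ seeding, Lloyd iterations, and 10
#' restarts of which the solution with the lowest total within-cluster sum
#' of squares is kept.  Clusters are then mapped to semantic labels by
#' sorting the 24-month centroid delta in decreasing order: least decline
#' becomes `slow`, most becomes `fast`.
#'
#' @param traj Output of [compute_deltas()] (or an MMSE table /
#'   `tricoat_cohort`, which is passed through [compute_deltas()] first).
#' @param seed Integer seed controlling seeding and restarts.
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @return A `subtype_labeling`: labels tibble, centroid table (in delta
#'   space), cluster-to-label mapping and total within-SS.
#' @export
cluster_subtypes <- function(traj, seed = 1L, n_restarts = 10L) {
  if (!is.data.frame(traj) || !all(c("d6", "d12", "d24") %in% names(traj))) {
    traj <- compute_deltas(traj)
  }
  X <- as.matrix(traj[, c("d6", "d12", "d24")])
  if (nrow(unique(X)) < 3L) {
    abort("need at least 3 distinct trajectory vectors for k = 3 clustering")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(X, 3L)
    km <- tryCatch(
      stats::kmeans(X, centers = centers, iter.max = 100L, algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 3L) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) {
    abort("k-means failed to produce 3 non-empty clusters in any restart")
  }
  ord <- order(best$centers[, "d24"], decreasing = TRUE)  # slow first
  mapping <- integer(3L)
  mapping[ord] <- 1:3
  labels <- tibble(subject_id = traj$subject_id,
                   subtype = factor(subtype_levels()[mapping[best$cluster]],
                                    levels = subtype_levels())) |>
    arrange(.data$subject_id)
  centroids <- as_tibble(best$centers[ord, , drop = FALSE]) |>
    mutate(subtype = factor(subtype_levels(), levels = subtype_levels()),
           size = as.integer(best$size[ord]), .before = 1)
  structure(list(labels = labels, centroids = centroids,
                 mapping = stats::setNames(mapping, paste0("cluster", 1:3)),
                 tot_withinss = best$tot.withinss, seed = as.integer(seed),
                 traj = traj),
            class = "subtype_labeling")
}

#' @export
print.subtype_labeling <- function(x, ...) {
  cat("<subtype_labeling> k-means (k = 3) on MMSE deltas\n")
  print(x$centroids)
  invisible(x)
}

#' Per-subject subtype labels
#' @param x A `subtype_labeling`.
#' @param ... Unused.
#' @return Tibble `subject_id`, `subtype`.
#' @method tidy subtype_labeling
#' @export
tidy.subtype_labeling <- function(x, ...) x$labels

#' One-row clustering summary
#' @param x A `subtype_labeling`.
#' @param ... Unused.
#' @return Tibble with cluster sizes, centroid 24-month deltas and
#'   total within-cluster sum of squares.
#' @method glance subtype_labeling
#' @export
glance.subtype_labeling <- function(x, ...) {
  sz <- stats::setNames(x$centroids$size, paste0("n_", x$centroids$subtype))
  d24 <- stats::setNames(x$centroids$d24, paste0("d24_", x$centroids$subtype))
  bind_cols(as_tibble(as.list(sz)), as_tibble(as.list(d24)),
            tibble(tot_withinss = x$tot_withinss))
}

#' Plot mean subtype trajectories
#'
#' Draws the baseline-anchored mean MMSE delta trajectory of each subtype,
#' with one translucent line per subject behind the cluster means.
#'
#' @param object A `subtype_labeling`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subtype_labeling
#' @export
autoplot.subtype_labeling <- function(object, ...) {
  long <- object$traj |>
    left_join(object$labels, by = "subject_id") |>
    tidyr::pivot_longer(c("d6", "d12", "d24"), names_to = "visit",
                        values_to = "delta") |>
    mutate(month = as.integer(sub("^d", "", .data$visit))) |>
    bind_rows(tibble(subject_id = object$labels$subject_id,
                     subtype = object$labels$subtype, visit = "d0",
                     delta = 0, month = 0L))
  cent <- long |>
    group_by(.data$subtype, .data$month) |>
    summarise(delta = mean(.data$delta), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$month, y = .data$delta,
                                     colour = .data$subtype)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id), alpha = 0.12) +
    ggplot2::geom_line(data = cent, linewidth = 1.2) +
    ggplot2::geom_point(data = cent, size = 2) +
    ggplot2::labs(x = "Months from baseline", y = "MMSE change from baseline",
                  colour = "Subtype") +
    ggplot2::theme_minimal()
}
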
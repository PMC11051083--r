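#' Average co-attention weights into an association table
#'
#' Takes the per-subject co-attention records of a trained model (see
#' `predict(..., attention = TRUE)`) and averages them over a subject set.
#' Class-token rows and columns are excluded — they aggregate sequence
#' information rather than associate named features — and each remaining
#' query-token row is renormalized to sum to 1 before averaging, so the
#' table holds the mean of row-normalized weights.
#'
#' @param attention Attention records: a list with elements `imaging` and
#'   `genetics`, each a 3-d array (query tokens x clinical tokens x
#'   subjects) with named dimensions, as returned by
#'   [predict.tricoat_model()].
#' @param subjects Optional subject IDs to average over (default: all in
#'   the records).
#' @return An `association_table` tibble: `query` (ROI or SNP), `clinical`
#'   (score name), `modality`, `weight`; for each query token the weights
#'   over clinical features sum to 1.
#' @export
average_attention <- function(attention, subjects = NULL) {
  stopifnot(is.list(attention), all(c("imaging", "genetics") %in% names(attention)))
  out <- lapply(c("imaging", "genetics"), function(m) {
    A <- attention[[m]]
    subj <- subjects %||% dimnames(A)[[3]]
    if (length(subj) == 0) abort("empty subject set")
    miss <- setdiff(subj, dimnames(A)[[3]])
    if (length(miss) > 0) {
      abort(sprintf("no attention record for subject(s): %s",
                    paste(utils::head(miss, 5), collapse = ", ")))
    }
    A <- A[, , subj, drop = FALSE]
    qn <- setdiff(dimnames(A)[[1]], "<cls>")
    cn <- setdiff(dimnames(A)[[2]], "<cls>")
    A <- A[qn, cn, , drop = FALSE]
    # renormalize each query row within each subject, then average
    sums <- apply(A, c(1, 3), sum)
    for (s in seq_len(dim(A)[3])) A[, , s] <- A[, , s] / sums[, s]
    W <- apply(A, c(1, 2), mean)
    as_tibble(as.data.frame.table(W, responseName = "weight",
                                  stringsAsFactors = FALSE)) |>
      rename(query = "Var1", clinical = "Var2") |>
      mutate(modality = m)
  })
  tbl <- bind_rows(out) |>
    select("query", "clinical", "modality", "weight") |>
    arrange(.data$modality, .data$query, .data$clinical)
  class(tbl) <- c("association_table", class(tbl))
  tbl
}

#' Export top cross-modal associations as a chord-plot edge list
#'
#' Selects the `top_k` strongest edges (by mean attention weight) per query
#' modality and writes them as a `from,to,value` CSV directly consumable by
#' circular chord-diagram tools.  Ties are broken deterministically by
#' (weight descending, from ascending, to ascending).
#'
#' @param table An `association_table` from [average_attention()].
#' @param top_k Edges to keep per query modality (clamped, with a warning,
#'   to the table size).
#' @param path Optional output CSV path; when `NULL` the edge tibble is
#'   returned without writing.
#' @return Tibble `from`, `to`, `value` (invisibly when written to disk).
#' @export
export_chord_edges <- function(table, top_k, path = NULL) {
  stopifnot(top_k >= 1)
  edges <- as_tibble(table) |>
    group_by(.data$modality) |>
    arrange(desc(.data$weight), .data$query, .data$clinical, .by_group = TRUE) |>
    group_modify(function(df, key) {
      if (top_k > nrow(df)) {
        warn(sprintf("top_k = %d exceeds %d available edges; clamping", top_k, nrow(df)))
      }
      utils::head(df, top_k)
    }) |>
    ungroup() |>
    transmute(from = .data$query, to = .data$clinical, value = .data$weight)
  if (is.null(path)) return(edges)
  readr::write_csv(edges, path, progress = FALSE)
  invisible(edges)
}

#' Heatmap of mean cross-modal attention
#'
#' @param object An `association_table`.
#' @param top_k Show only the `top_k` strongest query tokens per modality
#'   (by their maximum weight); default all.
#' @param ... Unused.
#' @return A ggplot object, faceted by query modality.
#' @method autoplot association_table
#' @export
autoplot.association_table <- function(object, top_k = Inf, ...) {
  df <- as_tibble(object)
  keep <- df |>
    group_by(.data$modality, .data$query) |>
    summarise(mx = max(.data$weight), .groups = "drop_last") |>
    slice_max(.data$mx, n = top_k, with_ties = FALSE) |>
    ungroup()
  df <- df |> semi_join(keep, by = c("modality", "query"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clinical, y = .data$query,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~modality, scales = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "mean attention") +
    ggplot2::labs(x = "Clinical feature", y = "Query token") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
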
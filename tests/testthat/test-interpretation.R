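fake_records <- function(n_sub = 2, M = 3, N = 2, B = 2, seed = 1) {
  set.seed(seed)
  mk <- function(q, qnames) {
    A <- array(stats::rexp((q + 1) * (B + 1) * n_sub), c(q + 1, B + 1, n_sub))
    for (s in 1:n_sub) A[, , s] <- A[, , s] / rowSums(A[, , s])
    dimnames(A) <- list(c("<cls>", qnames),
                        c("<cls>", paste0("SCORE", seq_len(B))),
                        paste0("P", seq_len(n_sub)))
    A
  }
  list(imaging = mk(M, paste0("ROI", 1:M)), genetics = mk(N, paste0("rs", 1:N)))
}

renorm_slice <- function(A, s) {
  W <- A[-1, -1, s]
  W / rowSums(W)
}

test_that("averaging one subject returns that subject's (renormalized) weights", {
  rec <- fake_records(n_sub = 2)
  tbl <- average_attention(rec, subjects = "P1")
  W <- renorm_slice(rec$imaging, 1)
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      got <- tbl$weight[tbl$modality == "imaging" &
                          tbl$query == rownames(W)[i] &
                          tbl$clinical == colnames(W)[j]]
      expect_equal(got, W[i, j])
    }
  }
})

test_that("two-subject average is the exact elementwise mean", {
  rec <- fake_records(n_sub = 2)
  tbl <- average_attention(rec)
  W <- (renorm_slice(rec$genetics, 1) + renorm_slice(rec$genetics, 2)) / 2
  got <- tbl |>
    dplyr::filter(.data$modality == "genetics") |>
    tidyr::pivot_wider(id_cols = "query", names_from = "clinical",
                       values_from = "weight")
  gm <- as.matrix(got[match(rownames(W), got$query), colnames(W)])
  expect_equal(unname(gm), unname(W), tolerance = 1e-12)
  # per-query weights over clinical features sum to 1
  sums <- tbl |>
    dplyr::group_by(.data$modality, .data$query) |>
    dplyr::summarise(s = sum(.data$weight), .groups = "drop")
  expect_lt(max(abs(sums$s - 1)), 1e-6)
})

test_that("averaging commutes with disjoint subject-set union weighting", {
  rec <- fake_records(n_sub = 5, seed = 9)
  t_all <- average_attention(rec)
  t_a <- average_attention(rec, subjects = c("P1", "P2"))
  t_b <- average_attention(rec, subjects = c("P3", "P4", "P5"))
  merged <- dplyr::inner_join(t_a, t_b, by = c("query", "clinical", "modality"))
  combined <- (2 * merged$weight.x + 3 * merged$weight.y) / 5
  full <- dplyr::inner_join(merged, t_all, by = c("query", "clinical", "modality"))
  expect_equal(combined, full$weight, tolerance = 1e-12)
  expect_error(average_attention(rec, subjects = character(0)), "empty")
})

test_that("chord edge export selects top-k deterministically and round-trips", {
  tbl <- tibble(query = c("ROI1", "ROI2", "ROI3", "rs1", "rs2"),
                clinical = c("S1", "S1", "S2", "S1", "S2"),
                modality = c("imaging", "imaging", "imaging", "genetics", "genetics"),
                weight = c(0.5, 0.3, 0.3, 0.9, 0.1))
  class(tbl) <- c("association_table", class(tbl))
  edges <- export_chord_edges(tbl, top_k = 2)
  # imaging: 0.5 first, then the 0.3 tie broken by query name (ROI2 < ROI3)
  img <- edges[edges$from %in% c("ROI1", "ROI2", "ROI3"), ]
  expect_equal(img$from, c("ROI1", "ROI2"))
  expect_equal(nrow(edges), 4L)
  # clamped with warning when top_k exceeds the table
  expect_warning(big <- export_chord_edges(tbl, top_k = 10), "clamping")
  expect_equal(nrow(big), 5L)
  # CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  export_chord_edges(tbl, top_k = 2, path = path)
  rt <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(rt), as.data.frame(edges), tolerance = 1e-12)
})

test_that("trained-model attention records feed the association pipeline", {
  sim <- tiny_sim(n = c(5, 5, 5), n_roi = 4, n_snp = 3, seed = 12)
  scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, sim$cohort$subjects))
  fit <- fit_tricoat(scaled, sim$truth, sim$cohort$subjects, NULL,
                     tiny_config(epochs = 1))
  out <- predict(fit, scaled, attention = TRUE)
  tbl <- average_attention(out$attention)
  expect_equal(sort(unique(as.character(tbl$query))),
               sort(c(unique(sim$cohort$imaging$roi_id), sim$cohort$snps$snp_id)))
  expect_false(any(tbl$query == "<cls>"))
  expect_true(all(tbl$weight >= 0))
})
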
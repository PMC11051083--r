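#' One-vs-one multiclass AUROC (Hand-Till)
#'
#' For every unordered pair of classes \{i, j\} present in `truth`, the
#' subjects of those two classes are retained and the two directed AUCs are
#' computed: `A(i|j)` ranks class-i subjects above class-j subjects by the
#' class-i probability column, and `A(j|i)` the reverse using the class-j
#' column.  The pair score is their average, and the returned value is the
#' unweighted mean over all pairs (the Hand-Till M measure).  Ties in the
#' scores contribute 1/2 via midranks.
#'
#' @param truth Vector of true class labels (factor or character).
#' @param prob Numeric matrix or data frame of class probabilities, one
#'   column per class, column names matching the label levels; rows should
#'   sum to 1.
#' @return A single number in \[0, 1\].
#' @export
auroc_ovo <- function(truth, prob) {
  prob <- as.matrix(as.data.frame(prob))
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  if (length(classes) < 2L) abort("need at least 2 classes present to compute AUROC")
  missing_cols <- setdiff(classes, colnames(prob))
  if (length(missing_cols) > 0) {
    abort(sprintf("probability columns missing for class(es): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(prob) != length(truth)) abort("truth and prob must have matching rows")
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  vals <- vapply(pairs, function(pr) {
    keep <- truth %in% pr
    a1 <- binary_auc(prob[keep, pr[1]], truth[keep] == pr[1])
    a2 <- binary_auc(prob[keep, pr[2]], truth[keep] == pr[2])
    (a1 + a2) / 2
  }, numeric(1))
  mean(vals)
}

# Mann-Whitney AUC with midrank tie handling
binary_auc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    abort("AUROC undefined: one class has no subjects in this pair")
  }
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
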
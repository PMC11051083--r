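# Per-modality tokenizers.  Each maps one subject's raw (scaled) features to
# a sequence of k-dimensional tokens:
#   imaging  - one token per ROI from its 4 morphometric traits, via one
#              affine map shared across ROIs (4 -> k);
#   genetics - one token per SNP: (dosage, odds ratio, rare-allele
#              frequency, intergenic flag) -> k/2 via a shared affine map,
#              concatenated with a learned chromosome embedding (k/2);
#   clinical - one token per score, each scalar expanded by its own
#              per-feature affine map (1 -> k) so feature identity is kept
#              without positional encodings.
# Batched layout: (S * n_tokens) x k, subject-major.

N_CHROMOSOMES <- 23L

# dense per-cohort views consumed by the models
model_inputs <- function(cohort) {
  list(img = imaging_matrix(cohort),
       dos = dosage_matrix(cohort),
       snp_static = as.matrix(cohort$snps[, c("odds_ratio", "rare_allele_freq",
                                              "intergenic")]),
       chrom = cohort$snps$chromosome,
       cli = clinical_matrix(cohort),
       roi_ids = sort(unique(cohort$imaging$roi_id)),
       snp_ids = cohort$snps$snp_id,
       cli_names = clinical_features(),
       subjects = cohort$subjects)
}

init_tokenizer <- function(modality, k, B = 7L) {
  switch(modality,
    imaging = init_linear(4L, k),
    genetics = {
      p <- init_linear(4L, k %/% 2L)
      p$E <- matrix(stats::rnorm(N_CHROMOSOMES * (k %/% 2L), 0, 0.02),
                    N_CHROMOSOMES, k %/% 2L)
      p
    },
    clinical = list(W = matrix(stats::rnorm(B * k, 0, sqrt(2 / (1 + k))), B, k),
                    b = matrix(0, B, k)),
    abort(sprintf("unknown modality '%s'", modality)))
}

# imaging rows for a batch: inp$img[rows, ] is Sb x (4M) roi-major
tokenize_imaging_fwd <- function(inp, rows, p) {
  mb <- inp$img[rows, , drop = FALSE]
  Xi <- matrix(t(mb), ncol = 4L, byrow = TRUE)  # (Sb*M) x 4, subject-major
  list(Tok = linear_fwd(Xi, p), X = Xi, Tn = ncol(mb) %/% 4L)
}

tokenize_imaging_bwd <- function(dTok, cache, p) {
  b <- linear_bwd(dTok, cache$X, p)
  list(W = b$dW, b = b$db)
}

tokenize_genetics_fwd <- function(inp, rows, p) {
  Sb <- length(rows)
  N <- ncol(inp$dos)
  dcol <- as.vector(t(inp$dos[rows, , drop = FALSE]))
  Xg <- cbind(dcol, inp$snp_static[rep(seq_len(N), Sb), , drop = FALSE])
  chrom_rep <- rep(inp$chrom, Sb)
  Tok <- cbind(linear_fwd(Xg, p), p$E[chrom_rep, , drop = FALSE])
  list(Tok = Tok, X = Xg, chrom_rep = chrom_rep, Tn = N)
}

tokenize_genetics_bwd <- function(dTok, cache, p) {
  k2 <- ncol(p$W)
  b <- linear_bwd(dTok[, seq_len(k2), drop = FALSE], cache$X, p)
  dEflat <- rowsum(dTok[, -seq_len(k2), drop = FALSE], cache$chrom_rep)
  dE <- matrix(0, nrow(p$E), k2)
  dE[as.integer(rownames(dEflat)), ] <- dEflat
  list(W = b$dW, b = b$db, E = dE)
}

tokenize_clinical_fwd <- function(inp, rows, p) {
  cb <- inp$cli[rows, , drop = FALSE]
  B <- ncol(cb)
  xvec <- as.vector(t(cb))
  ridx <- rep(seq_len(B), length(rows))
  Tok <- xvec * p$W[ridx, , drop = FALSE] + p$b[ridx, , drop = FALSE]
  list(Tok = Tok, xvec = xvec, ridx = ridx, Tn = B)
}

tokenize_clinical_bwd <- function(dTok, cache, p) {
  list(W = rowsum(dTok * cache$xvec, cache$ridx),
       b = rowsum(dTok, cache$ridx))
}

tokenize_fwd <- function(modality, inp, rows, p) {
  switch(modality,
    imaging = tokenize_imaging_fwd(inp, rows, p),
    genetics = tokenize_genetics_fwd(inp, rows, p),
    clinical = tokenize_clinical_fwd(inp, rows, p))
}

tokenize_bwd <- function(modality, dTok, cache, p) {
  switch(modality,
    imaging = tokenize_imaging_bwd(dTok, cache, p),
    genetics = tokenize_genetics_bwd(dTok, cache, p),
    clinical = tokenize_clinical_bwd(dTok, cache, p))
}

token_names <- function(modality, inp) {
  switch(modality,
    imaging = inp$roi_ids,
    genetics = inp$snp_ids,
    clinical = inp$cli_names)
}
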
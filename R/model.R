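#' Model configuration for the tri-modal co-attention classifier
#'
#' Holds the architecture and optimization settings.  Shipped defaults are
#' the reference configuration of the method: embedding dimension `k = 256`,
#' four pre-LN transformer layers per single-modality encoder with four
#' self-attention heads, a single-head co-attention block, a one-hidden-layer
#' MLP head with 256 units, Adam with learning rate 1e-4, cross-entropy
#' loss, and 100 training epochs.  Feed-forward width (`4k`), GELU
#' nonlinearity, dropout 0.1 and batch size 32 are package defaults where
#' the reference leaves them open.
#'
#' @param k Embedding dimension (even; the genetic tokenizer uses `k/2`).
#' @param n_layers Encoder depth.
#' @param n_heads Self-attention heads per layer (must divide `k`).
#' @param mlp_hidden Hidden units of the classification head.
#' @param n_classes Number of output classes.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param dropout Dropout rate on sublayer outputs and the MLP hidden layer.
#' @param ff_mult Feed-forward expansion factor.
#' @param joint How the two co-attended sequences are turned into the joint
#'   representation: `"cls"` (concatenate the two co-attended class-token
#'   rows, 2k) or `"flatten"` (concatenate all co-attended token rows).
#' @param coattn_project Learn Q/K/V projections in the co-attention block;
#'   `FALSE` uses the encoder outputs directly as Q, K and V.
#' @param include_clinical_cls Also feed the clinical encoder's class token
#'   into the MLP head.
#' @param seed Seed for parameter initialization, batch order and dropout.
#' @return A `tricoat_config` list.
#' @export
tricoat_config <- function(k = 256L, n_layers = 4L, n_heads = 4L,
                           mlp_hidden = 256L, n_classes = 3L,
                           lr = 1e-4, epochs = 100L, batch_size = 32L,
                           dropout = 0.1, ff_mult = 4L,
                           joint = c("cls", "flatten"),
                           coattn_project = TRUE,
                           include_clinical_cls = FALSE,
                           seed = 1L) {
  joint <- match.arg(joint)
  k <- as.integer(k)
  if (k %% 2L != 0L) abort("embedding dimension k must be even (genetic tokenizer uses k/2)")
  if (k %% as.integer(n_heads) != 0L) abort("n_heads must divide k")
  stopifnot(n_layers >= 1, mlp_hidden >= 1, lr > 0, epochs >= 1,
            batch_size >= 1, dropout >= 0, dropout < 1)
  structure(list(k = k, n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 mlp_hidden = as.integer(mlp_hidden),
                 n_classes = as.integer(n_classes), lr = lr,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 dropout = dropout, ff_mult = as.integer(ff_mult),
                 joint = joint, coattn_project = coattn_project,
                 include_clinical_cls = include_clinical_cls,
                 seed = as.integer(seed)),
            class = "tricoat_config")
}

MODALITIES <- c("imaging", "genetics", "clinical")

init_tricoat_params <- function(cfg, dims) {
  k <- cfg$k
  tok <- list(imaging = init_tokenizer("imaging", k),
              genetics = init_tokenizer("genetics", k),
              clinical = init_tokenizer("clinical", k, B = dims$B))
  cls <- lapply(stats::setNames(MODALITIES, MODALITIES),
                function(m) stats::rnorm(k, 0, 0.02))
  enc <- lapply(stats::setNames(MODALITIES, MODALITIES),
                function(m) init_encoder(k, cfg$n_layers, cfg$ff_mult))
  coat <- list(imaging = init_coattn(k, cfg$coattn_project),
               genetics = init_coattn(k, cfg$coattn_project))
  d_joint <- switch(cfg$joint,
    cls = 2L * k,
    flatten = ((dims$M + 1L) + (dims$N + 1L)) * k)
  if (cfg$include_clinical_cls) d_joint <- d_joint + k
  head <- list(l1 = init_linear(d_joint, cfg$mlp_hidden),
               l2 = init_linear(cfg$mlp_hidden, cfg$n_classes))
  list(tok = tok, cls = cls, enc = enc, coattn = coat, head = head)
}

# flatten subject-major token blocks into one row per subject
rows_per_subject <- function(X, S) matrix(t(X), nrow = S, byrow = TRUE)
rows_per_subject_bwd <- function(dZ, k) matrix(t(dZ), ncol = k, byrow = TRUE)

tricoat_fwd <- function(params, inp, rows, cfg, train = FALSE) {
  S <- length(rows)
  k <- cfg$k
  enc_out <- list(); caches <- list(Tn = list())
  for (m in MODALITIES) {
    tk <- tokenize_fwd(m, inp, rows, params$tok[[m]])
    Tn <- tk$Tn
    X0 <- prepend_cls(tk$Tok, params$cls[[m]], S, Tn)
    eo <- encoder_fwd(X0, params$enc[[m]], S, Tn + 1L, cfg$n_heads,
                      cfg$dropout, train)
    enc_out[[m]] <- eo$Y
    caches[[m]] <- list(tok = tk, enc = eo$caches)
    caches$Tn[[m]] <- Tn + 1L
  }
  co <- list()
  for (m in c("imaging", "genetics")) {
    co[[m]] <- coattn_fwd(enc_out[[m]], enc_out$clinical, params$coattn[[m]],
                          S, caches$Tn[[m]], caches$Tn$clinical,
                          cfg$coattn_project)
  }
  joint_parts <- lapply(c("imaging", "genetics"), function(m) {
    if (cfg$joint == "cls") {
      co[[m]]$O[cls_positions(S, caches$Tn[[m]] - 1L), , drop = FALSE]
    } else {
      rows_per_subject(co[[m]]$O, S)
    }
  })
  Z <- do.call(cbind, joint_parts)
  if (cfg$include_clinical_cls) {
    Z <- cbind(Z, enc_out$clinical[cls_positions(S, caches$Tn$clinical - 1L), ,
                                   drop = FALSE])
  }
  H <- linear_fwd(Z, params$head$l1)
  G <- gelu(H)
  dh <- dropout_fwd(G, cfg$dropout, train)
  logits <- linear_fwd(dh$Y, params$head$l2)
  list(logits = logits,
       attention = list(imaging = co$imaging$A, genetics = co$genetics$A),
       cache = list(S = S, caches = caches, enc_out = enc_out, co = co,
                    Z = Z, H = H, G = G, dh = dh))
}

tricoat_bwd <- function(dlogits, fw, params, cfg) {
  S <- fw$cache$S
  k <- cfg$k
  ch <- fw$cache
  b2 <- linear_bwd(dlogits, ch$dh$Y, params$head$l2)
  dG <- dropout_bwd(b2$dX, ch$dh$mask)
  dH <- dG * gelu_grad(ch$H)
  b1 <- linear_bwd(dH, ch$Z, params$head$l1)
  dZ <- b1$dX
  g_head <- list(l1 = list(W = b1$dW, b = b1$db), l2 = list(W = b2$dW, b = b2$db))

  # split dZ back into the query-modality parts (+ optional clinical cls)
  widths <- vapply(c("imaging", "genetics"), function(m) {
    if (cfg$joint == "cls") k else ch$caches$Tn[[m]] * k
  }, numeric(1))
  offs <- cumsum(c(0, widths))
  dEnc <- list()  # gradients flowing into encoder outputs
  for (m in MODALITIES) dEnc[[m]] <- matrix(0, S * ch$caches$Tn[[m]], k)

  g_coat <- list()
  for (i in 1:2) {
    m <- c("imaging", "genetics")[i]
    Tq <- ch$caches$Tn[[m]]
    dZm <- dZ[, (offs[i] + 1L):offs[i + 1L], drop = FALSE]
    dO <- matrix(0, S * Tq, k)
    if (cfg$joint == "cls") {
      dO[cls_positions(S, Tq - 1L), ] <- dZm
    } else {
      dO <- rows_per_subject_bwd(dZm, k)
    }
    bc <- coattn_bwd(dO, ch$co[[m]]$cache, params$coattn[[m]])
    dEnc[[m]] <- dEnc[[m]] + bc$dXq
    dEnc$clinical <- dEnc$clinical + bc$dXc
    g_coat[[m]] <- bc$grads
  }
  if (cfg$include_clinical_cls) {
    dZc <- dZ[, (offs[3] + 1L):(offs[3] + k), drop = FALSE]
    pos <- cls_positions(S, ch$caches$Tn$clinical - 1L)
    dEnc$clinical[pos, ] <- dEnc$clinical[pos, ] + dZc
  }

  g_tok <- list(); g_cls <- list(); g_enc <- list()
  for (m in MODALITIES) {
    be <- encoder_bwd(dEnc[[m]], ch$caches[[m]]$enc, params$enc[[m]])
    g_enc[[m]] <- be$grads
    pc <- prepend_cls_bwd(be$dX, S, ch$caches$Tn[[m]] - 1L)
    g_cls[[m]] <- pc$dcls
    g_tok[[m]] <- tokenize_bwd(m, pc$dTok, ch$caches[[m]]$tok, params$tok[[m]])
  }
  list(tok = g_tok, cls = g_cls, enc = g_enc, coattn = g_coat, head = g_head)
}

cohort_dims <- function(inp) {
  list(M = ncol(inp$img) %/% 4L, N = ncol(inp$dos), B = ncol(inp$cli))
}

label_vector <- function(labels, ids) {
  labels <- as_tibble(labels)
  y <- labels$subtype[match(ids, labels$subject_id)]
  if (anyNA(y)) abort("labels missing for some requested subjects")
  as.integer(as_subtype(y))
}

#' Fit the tri-modal co-attention classifier
#'
#' Trains the full network (per-modality tokenizers, class tokens, pre-LN
#' transformer encoders, imaging->clinical and genetics->clinical
#' co-attention, joint MLP head) with Adam on softmax cross-entropy.
#' When `val_ids` is supplied, the one-vs-one validation AUROC is computed
#' after every epoch and the best-scoring checkpoint is retained
#' (epoch-level checkpoint selection); otherwise the final parameters are
#' kept.  Training is deterministic given `(cfg$seed, cfg, data)`.
#'
#' @param cohort A scaled `tricoat_cohort` (see [fit_scaler()]).
#' @param labels Tibble `subject_id`, `subtype`.
#' @param train_ids,val_ids Subject IDs used for optimization and for
#'   checkpoint selection.
#' @param cfg A [tricoat_config()].
#' @param verbose Print per-epoch loss.
#' @return A `tricoat_model` with parameters, config and training history.
#' @export
fit_tricoat <- function(cohort, labels, train_ids, val_ids = NULL,
                        cfg = tricoat_config(), verbose = FALSE) {
  stopifnot(inherits(cohort, "tricoat_cohort"), inherits(cfg, "tricoat_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  inp <- model_inputs(cohort)
  dims <- cohort_dims(inp)
  params <- init_tricoat_params(cfg, dims)
  tr_rows <- match(as.character(train_ids), inp$subjects)
  if (anyNA(tr_rows)) abort("train_ids not present in cohort")
  y_tr <- label_vector(labels, train_ids)

  step_fn <- function(p, brows, train) {
    fw <- tricoat_fwd(p, inp, tr_rows[brows], cfg, train = train)
    l <- ce_loss(fw$logits, y_tr[brows])
    list(loss = l$loss, grads = tricoat_bwd(l$dlogits, fw, p, cfg))
  }
  eval_fn <- NULL
  if (!is.null(val_ids) && length(val_ids) > 0) {
    va_rows <- match(as.character(val_ids), inp$subjects)
    y_va <- label_vector(labels, val_ids)
    eval_fn <- function(p) {
      P <- softmax_rows(tricoat_fwd(p, inp, va_rows, cfg, train = FALSE)$logits)
      colnames(P) <- subtype_levels()
      tryCatch(auroc_ovo(subtype_levels()[y_va], P), error = function(e) NA_real_)
    }
  }
  fit <- sgd_train(params, step_fn, length(tr_rows), cfg$epochs, cfg$batch_size,
                   cfg$lr, eval_fn, verbose)
  structure(list(params = fit$params, cfg = cfg, dims = dims,
                 history = fit$history, best_epoch = fit$best_epoch,
                 best_val_auroc = fit$best_score,
                 train_ids = as.character(train_ids)),
            class = "tricoat_model")
}

#' @export
print.tricoat_model <- function(x, ...) {
  cat(sprintf("<tricoat_model> k=%d, %d layers, %d heads; trained on %d subjects\n",
              x$cfg$k, x$cfg$n_layers, x$cfg$n_heads, length(x$train_ids)))
  if (is.finite(x$best_val_auroc)) {
    cat(sprintf("  best checkpoint: epoch %d (val OvO AUROC %.3f)\n",
                x$best_epoch, x$best_val_auroc))
  }
  invisible(x)
}

#' Predict subtype probabilities (and optionally attention) for subjects
#'
#' @param object A fitted `tricoat_model`.
#' @param cohort A `tricoat_cohort` scaled with the same scaler used in
#'   training.
#' @param ids Subject IDs to score (default: all subjects in the cohort).
#' @param attention Also return the per-subject co-attention weight
#'   matrices (query tokens x clinical tokens, rows summing to 1), named
#'   by ROI/SNP/clinical-feature with the class token as `<cls>`.
#' @param ... Unused.
#' @return Tibble `subject_id`, `slow`, `intermediate`, `fast` (class
#'   probabilities); with `attention = TRUE`, a list with elements `prob`
#'   and `attention`.
#' @export
predict.tricoat_model <- function(object, cohort, ids = NULL, attention = FALSE, ...) {
  inp <- model_inputs(cohort)
  ids <- as.character(ids %||% inp$subjects)
  rows <- match(ids, inp$subjects)
  if (anyNA(rows)) abort("requested subjects not present in cohort")
  fw <- tricoat_fwd(object$params, inp, rows, object$cfg, train = FALSE)
  P <- softmax_rows(fw$logits)
  colnames(P) <- subtype_levels()
  prob <- bind_cols(tibble(subject_id = ids), as_tibble(P))
  if (!attention) return(prob)
  att <- attention_records(fw$attention, inp, ids)
  list(prob = prob, attention = att)
}

attention_records <- function(att, inp, ids) {
  name_axes <- function(A, qnames, cnames) {
    dimnames(A) <- list(c("<cls>", qnames), c("<cls>", cnames), ids)
    A
  }
  list(imaging = name_axes(att$imaging, inp$roi_ids, inp$cli_names),
       genetics = name_axes(att$genetics, inp$snp_ids, inp$cli_names))
}

#' Training history of a fitted model
#' @param x A `tricoat_model` (or baseline fit with a history).
#' @param ... Unused.
#' @return Tibble with epoch, train_loss, val_score.
#' @method tidy tricoat_model
#' @export
tidy.tricoat_model <- function(x, ...) x$history

#' One-row model summary
#' @param x A `tricoat_model`.
#' @param ... Unused.
#' @return Tibble with architecture, parameter count and checkpoint info.
#' @method glance tricoat_model
#' @export
glance.tricoat_model <- function(x, ...) {
  n_par <- sum(unlist(tree_map(length, x$params)))
  tibble(k = x$cfg$k, n_layers = x$cfg$n_layers, n_heads = x$cfg$n_heads,
         n_parameters = n_par, epochs = x$cfg$epochs,
         best_epoch = x$best_epoch, best_val_auroc = x$best_val_auroc,
         final_train_loss = utils::tail(x$history$train_loss, 1))
}
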
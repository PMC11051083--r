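# Comparison models.  The transformer-backbone ablations (single-modality
# encoders, early fusion) share one "token classifier": token sequence ->
# learned class token -> pre-LN encoder stack -> class-token row -> MLP
# head.  Early fusion concatenates all three modality token sequences into
# a single sequence with one shared class token ("fusion at the input");
# late fusion trains the three single-modality classifiers independently
# and averages their predicted class probabilities; the stage-wise
# intermediate-fusion baseline is an MLP with per-modality 64-unit stages,
# a 32-unit joint stage and a 16-unit final stage.  SVM (RBF, C = 1) and
# random forest (gini, 100 trees, unlimited depth) consume flattened scaled
# features; their genetics block uses allele dosages only, since the
# per-SNP GWAS attributes are subject-invariant.

tokclf_modalities <- function(modality) {
  if (modality == "all") MODALITIES else modality
}

init_tokclf_params <- function(cfg, dims, modality) {
  mods <- tokclf_modalities(modality)
  tok <- lapply(stats::setNames(mods, mods), function(m) {
    init_tokenizer(m, cfg$k, B = dims$B)
  })
  list(tok = tok, cls = stats::rnorm(cfg$k, 0, 0.02),
       enc = init_encoder(cfg$k, cfg$n_layers, cfg$ff_mult),
       head = list(l1 = init_linear(cfg$k, cfg$mlp_hidden),
                   l2 = init_linear(cfg$mlp_hidden, cfg$n_classes)))
}

# row indices of modality m's tokens inside the combined subject-major blocks
combined_rows <- function(Tns, S) {
  Ttot <- sum(Tns)
  offs <- cumsum(c(0L, Tns[-length(Tns)]))
  lapply(seq_along(Tns), function(i) {
    as.vector(outer(seq_len(Tns[i]) + offs[i], (0:(S - 1L)) * Ttot, `+`))
  })
}

tokclf_fwd <- function(params, inp, rows, cfg, modality, train = FALSE) {
  S <- length(rows)
  mods <- tokclf_modalities(modality)
  tks <- lapply(stats::setNames(mods, mods), function(m) {
    tokenize_fwd(m, inp, rows, params$tok[[m]])
  })
  Tns <- vapply(tks, `[[`, integer(1), "Tn")
  Ttot <- sum(Tns)
  if (length(mods) == 1L) {
    Tok <- tks[[1]]$Tok
    ridx <- NULL
  } else {
    Tok <- matrix(0, S * Ttot, cfg$k)
    ridx <- combined_rows(Tns, S)
    for (i in seq_along(mods)) Tok[ridx[[i]], ] <- tks[[i]]$Tok
  }
  X0 <- prepend_cls(Tok, params$cls, S, Ttot)
  eo <- encoder_fwd(X0, params$enc, S, Ttot + 1L, cfg$n_heads, cfg$dropout, train)
  Z <- eo$Y[cls_positions(S, Ttot), , drop = FALSE]
  H <- linear_fwd(Z, params$head$l1)
  G <- gelu(H)
  dh <- dropout_fwd(G, cfg$dropout, train)
  logits <- linear_fwd(dh$Y, params$head$l2)
  list(logits = logits,
       cache = list(S = S, mods = mods, tks = tks, Tns = Tns, Ttot = Ttot,
                    ridx = ridx, enc = eo$caches, Z = Z, H = H, G = G, dh = dh))
}

tokclf_bwd <- function(dlogits, fw, params, cfg) {
  ch <- fw$cache
  S <- ch$S
  b2 <- linear_bwd(dlogits, ch$dh$Y, params$head$l2)
  dH <- dropout_bwd(b2$dX, ch$dh$mask) * gelu_grad(ch$H)
  b1 <- linear_bwd(dH, ch$Z, params$head$l1)
  dY <- matrix(0, S * (ch$Ttot + 1L), cfg$k)
  dY[cls_positions(S, ch$Ttot), ] <- b1$dX
  be <- encoder_bwd(dY, ch$enc, params$enc)
  pc <- prepend_cls_bwd(be$dX, S, ch$Ttot)
  g_tok <- list()
  for (i in seq_along(ch$mods)) {
    m <- ch$mods[i]
    dTm <- if (is.null(ch$ridx)) pc$dTok else pc$dTok[ch$ridx[[i]], , drop = FALSE]
    g_tok[[m]] <- tokenize_bwd(m, dTm, ch$tks[[m]], params$tok[[m]])
  }
  list(tok = g_tok, cls = pc$dcls, enc = be$grads,
       head = list(l1 = list(W = b1$dW, b = b1$db), l2 = list(W = b2$dW, b = b2$db)))
}

fit_token_classifier <- function(cohort, labels, train_ids, val_ids = NULL,
                                 cfg = tricoat_config(), modality = "all",
                                 verbose = FALSE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  inp <- model_inputs(cohort)
  dims <- cohort_dims(inp)
  params <- init_tokclf_params(cfg, dims, modality)
  tr_rows <- match(as.character(train_ids), inp$subjects)
  y_tr <- label_vector(labels, train_ids)
  step_fn <- function(p, brows, train) {
    fw <- tokclf_fwd(p, inp, tr_rows[brows], cfg, modality, train)
    l <- ce_loss(fw$logits, y_tr[brows])
    list(loss = l$loss, grads = tokclf_bwd(l$dlogits, fw, p, cfg))
  }
  eval_fn <- make_auroc_eval(inp, labels, val_ids, function(p, rows) {
    tokclf_fwd(p, inp, rows, cfg, modality, FALSE)$logits
  })
  fit <- sgd_train(params, step_fn, length(tr_rows), cfg$epochs, cfg$batch_size,
                   cfg$lr, eval_fn, verbose)
  structure(list(params = fit$params, cfg = cfg, modality = modality,
                 dims = dims, history = fit$history, best_epoch = fit$best_epoch,
                 best_val_auroc = fit$best_score),
            class = "tokclf_model")
}

make_auroc_eval <- function(inp, labels, val_ids, logits_fn) {
  if (is.null(val_ids) || length(val_ids) == 0) return(NULL)
  va_rows <- match(as.character(val_ids), inp$subjects)
  y_va <- label_vector(labels, val_ids)
  function(p) {
    P <- softmax_rows(logits_fn(p, va_rows))
    colnames(P) <- subtype_levels()
    tryCatch(auroc_ovo(subtype_levels()[y_va], P), error = function(e) NA_real_)
  }
}

predict_tokclf <- function(model, cohort, ids = NULL) {
  inp <- model_inputs(cohort)
  ids <- as.character(ids %||% inp$subjects)
  rows <- match(ids, inp$subjects)
  P <- softmax_rows(tokclf_fwd(model$params, inp, rows, model$cfg,
                               model$modality, FALSE)$logits)
  colnames(P) <- subtype_levels()
  rownames(P) <- ids
  P
}

# ---- stage-wise fusion MLP -----------------------------------------------

#' Configuration for the stage-wise intermediate-fusion MLP baseline
#'
#' Defaults follow the reference topology: 64 units per single-modality
#' stage, 32 units for the joint second stage, 16 for the final stage,
#' Adam with learning rate 1e-4, cross-entropy loss, 100 epochs.  The
#' single-modality adaptation keeps the first (64) and last (16) stages.
#'
#' @param dims Stage widths (single-modality, joint, final).
#' @param lr,epochs,batch_size,seed Optimization settings.
#' @return A `stagewise_config` list.
#' @export
stagewise_config <- function(dims = c(64L, 32L, 16L), lr = 1e-4, epochs = 100L,
                             batch_size = 32L, seed = 1L) {
  structure(list(dims = as.integer(dims), lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), n_classes = 3L,
                 seed = as.integer(seed)),
            class = "stagewise_config")
}

relu <- function(x) pmax(x, 0)

# flattened per-modality feature blocks used by stagewise / SVM / RF
flat_features <- function(inp, modality) {
  blocks <- list(imaging = inp$img, genetics = inp$dos, clinical = inp$cli)
  if (modality == "all") do.call(cbind, blocks) else blocks[[modality]]
}

flat_blocks <- function(inp) list(imaging = inp$img, genetics = inp$dos,
                                  clinical = inp$cli)

init_stagewise_params <- function(cfg, d_in, modality) {
  d <- cfg$dims
  if (modality == "all") {
    stage1 <- lapply(d_in, function(dm) init_linear(dm, d[1]))
    list(stage1 = stage1,
         joint = init_linear(length(d_in) * d[1], d[2]),
         final = init_linear(d[2], d[3]),
         out = init_linear(d[3], cfg$n_classes))
  } else {
    list(stage1 = list(init_linear(d_in[[1]], d[1])),
         final = init_linear(d[1], d[3]),
         out = init_linear(d[3], cfg$n_classes))
  }
}

stagewise_fwd <- function(params, Xb, modality) {
  H1 <- lapply(seq_along(Xb), function(i) linear_fwd(Xb[[i]], params$stage1[[i]]))
  A1 <- lapply(H1, relu)
  if (modality == "all") {
    C <- do.call(cbind, A1)
    H2 <- linear_fwd(C, params$joint); A2 <- relu(H2)
    H3 <- linear_fwd(A2, params$final); A3 <- relu(H3)
  } else {
    C <- A1[[1]]
    H2 <- NULL; A2 <- C
    H3 <- linear_fwd(A2, params$final); A3 <- relu(H3)
  }
  logits <- linear_fwd(A3, params$out)
  list(logits = logits, cache = list(Xb = Xb, H1 = H1, A1 = A1, C = C,
                                     H2 = H2, A2 = A2, H3 = H3, A3 = A3))
}

stagewise_bwd <- function(dlogits, fw, params, modality) {
  ch <- fw$cache
  bo <- linear_bwd(dlogits, ch$A3, params$out)
  dH3 <- bo$dX * (ch$H3 > 0)
  bf <- linear_bwd(dH3, ch$A2, params$final)
  g_joint <- NULL
  if (modality == "all") {
    dH2 <- bf$dX * (ch$H2 > 0)
    bj <- linear_bwd(dH2, ch$C, params$joint)
    g_joint <- list(W = bj$dW, b = bj$db)
    dC <- bj$dX
  } else {
    dC <- bf$dX
  }
  widths <- vapply(ch$A1, ncol, integer(1))
  offs <- cumsum(c(0L, widths))
  g_stage1 <- lapply(seq_along(ch$A1), function(i) {
    dA <- dC[, (offs[i] + 1L):offs[i + 1L], drop = FALSE]
    dH <- dA * (ch$H1[[i]] > 0)
    b <- linear_bwd(dH, ch$Xb[[i]], params$stage1[[i]])
    list(W = b$dW, b = b$db)
  })
  # element order must mirror init_stagewise_params (tree updates are positional)
  if (modality == "all") {
    list(stage1 = g_stage1, joint = g_joint,
         final = list(W = bf$dW, b = bf$db), out = list(W = bo$dW, b = bo$db))
  } else {
    list(stage1 = g_stage1,
         final = list(W = bf$dW, b = bf$db), out = list(W = bo$dW, b = bo$db))
  }
}

fit_stagewise <- function(cohort, labels, train_ids, val_ids = NULL,
                          cfg = stagewise_config(), modality = "all",
                          verbose = FALSE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  inp <- model_inputs(cohort)
  blocks <- if (modality == "all") flat_blocks(inp) else
    flat_blocks(inp)[modality]
  tr_rows <- match(as.character(train_ids), inp$subjects)
  y_tr <- label_vector(labels, train_ids)
  params <- init_stagewise_params(cfg, lapply(blocks, ncol), modality)
  get_batch <- function(rows) lapply(blocks, function(b) b[rows, , drop = FALSE])
  step_fn <- function(p, brows, train) {
    fw <- stagewise_fwd(p, get_batch(tr_rows[brows]), modality)
    l <- ce_loss(fw$logits, y_tr[brows])
    list(loss = l$loss, grads = stagewise_bwd(l$dlogits, fw, p, modality))
  }
  eval_fn <- make_auroc_eval(inp, labels, val_ids, function(p, rows) {
    stagewise_fwd(p, get_batch(rows), modality)$logits
  })
  fit <- sgd_train(params, step_fn, length(tr_rows), cfg$epochs, cfg$batch_size,
                   cfg$lr, eval_fn, verbose)
  structure(list(params = fit$params, cfg = cfg, modality = modality,
                 history = fit$history, best_epoch = fit$best_epoch,
                 best_val_auroc = fit$best_score),
            class = "stagewise_model")
}

predict_stagewise <- function(model, cohort, ids = NULL) {
  inp <- model_inputs(cohort)
  ids <- as.character(ids %||% inp$subjects)
  rows <- match(ids, inp$subjects)
  blocks <- if (model$modality == "all") flat_blocks(inp) else
    flat_blocks(inp)[model$modality]
  Xb <- lapply(blocks, function(b) b[rows, , drop = FALSE])
  P <- softmax_rows(stagewise_fwd(model$params, Xb, model$modality)$logits)
  colnames(P) <- subtype_levels()
  rownames(P) <- ids
  P
}

# ---- method interface for the evaluation harness --------------------------

#' Declare a model for the cross-testing harness
#'
#' Wraps one of the comparison methods behind a common fit/predict
#' interface so every method is trained and evaluated under the identical
#' fold plan and scaler pipeline.
#'
#' @param name One of `"tricoat"`, `"early"`, `"late"`, `"stagewise"`,
#'   `"svm"`, `"rf"`.
#' @param modality `"all"` or a single modality (`"imaging"`, `"genetics"`,
#'   `"clinical"`) for single-modality ablations.  A single-modality
#'   `"tricoat"` uses that modality's tokenizer, encoder and class-token
#'   MLP head (no co-attention).
#' @param config Optional configuration object ([tricoat_config()] /
#'   [stagewise_config()]) or, for svm/rf, a list of hyperparameter
#'   overrides (`cost`, `ntree`).
#' @return A `tc_method` object.
#' @export
tc_method <- function(name = c("tricoat", "early", "late", "stagewise", "svm", "rf"),
                      modality = "all", config = NULL) {
  name <- match.arg(name)
  stopifnot(modality %in% c("all", MODALITIES))
  if (name %in% c("early", "late") && modality != "all") {
    abort("fusion variants are multimodal; use modality = 'all'")
  }
  structure(list(name = name, modality = modality, config = config),
            class = c(paste0("tc_", name), "tc_method"))
}

#' @export
print.tc_method <- function(x, ...) {
  cat(sprintf("<tc_method> %s (%s)\n", x$name, x$modality))
  invisible(x)
}

method_nn_config <- function(method, seed) {
  cfg <- method$config %||% tricoat_config()
  cfg$seed <- as.integer(seed)
  cfg
}

# apply a named hyperparameter setting (e.g. from a tuning grid)
update_method <- function(method, setting) {
  if (is.null(setting) || length(setting) == 0) return(method)
  if (method$name %in% c("svm", "rf")) {
    method$config <- utils::modifyList(method$config %||% list(), as.list(setting))
  } else {
    cfg <- method$config %||%
      if (method$name == "stagewise") stagewise_config() else tricoat_config()
    for (nm in names(setting)) cfg[[nm]] <- setting[[nm]]
    method$config <- cfg
  }
  method
}

#' Train a declared method
#'
#' @param method A [tc_method()].
#' @param cohort A scaled `tricoat_cohort`.
#' @param labels Tibble `subject_id`, `subtype`.
#' @param train_ids,val_ids Training and validation subject IDs (the
#'   validation set drives epoch checkpoint selection for the deep models).
#' @param seed Seed overriding the config seed, so harness repeats differ.
#' @return A `tc_fit` whose `predict_method()` output is a probability
#'   matrix.
#' @export
fit_method <- function(method, cohort, labels, train_ids, val_ids = NULL,
                       seed = 1L) {
  UseMethod("fit_method")
}

#' @export
fit_method.tc_tricoat <- function(method, cohort, labels, train_ids,
                                  val_ids = NULL, seed = 1L) {
  cfg <- method_nn_config(method, seed)
  fit <- if (method$modality == "all") {
    fit_tricoat(cohort, labels, train_ids, val_ids, cfg)
  } else {
    fit_token_classifier(cohort, labels, train_ids, val_ids, cfg, method$modality)
  }
  new_tc_fit(method, fit)
}

#' @export
fit_method.tc_early <- function(method, cohort, labels, train_ids,
                                val_ids = NULL, seed = 1L) {
  cfg <- method_nn_config(method, seed)
  new_tc_fit(method, fit_token_classifier(cohort, labels, train_ids, val_ids,
                                          cfg, "all"))
}

#' @export
fit_method.tc_late <- function(method, cohort, labels, train_ids,
                               val_ids = NULL, seed = 1L) {
  cfg <- method_nn_config(method, seed)
  branches <- lapply(stats::setNames(MODALITIES, MODALITIES), function(m) {
    fit_token_classifier(cohort, labels, train_ids, val_ids, cfg, m)
  })
  new_tc_fit(method, branches)
}

#' @export
fit_method.tc_stagewise <- function(method, cohort, labels, train_ids,
                                    val_ids = NULL, seed = 1L) {
  cfg <- method$config %||% stagewise_config()
  cfg$seed <- as.integer(seed)
  new_tc_fit(method, fit_stagewise(cohort, labels, train_ids, val_ids, cfg,
                                   method$modality))
}

#' @export
fit_method.tc_svm <- function(method, cohort, labels, train_ids,
                              val_ids = NULL, seed = 1L) {
  inp <- model_inputs(cohort)
  X <- flat_features(inp, method$modality)
  rows <- match(as.character(train_ids), inp$subjects)
  y <- factor(subtype_levels()[label_vector(labels, train_ids)],
              levels = subtype_levels())
  cost <- (method$config %||% list())$cost %||% 1
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fit <- e1071::svm(x = X[rows, , drop = FALSE], y = y, kernel = "radial",
                    cost = cost, probability = TRUE)
  new_tc_fit(method, fit)
}

#' @export
fit_method.tc_rf <- function(method, cohort, labels, train_ids,
                             val_ids = NULL, seed = 1L) {
  inp <- model_inputs(cohort)
  X <- flat_features(inp, method$modality)
  rows <- match(as.character(train_ids), inp$subjects)
  y <- factor(subtype_levels()[label_vector(labels, train_ids)],
              levels = subtype_levels())
  ntree <- (method$config %||% list())$ntree %||% 100L
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = X[rows, , drop = FALSE], y = y,
                                    ntree = ntree)
  new_tc_fit(method, fit)
}

new_tc_fit <- function(method, fit) {
  structure(list(method = method, fit = fit),
            class = c(paste0("tc_fit_", method$name), "tc_fit"))
}

#' Predict class probabilities from a harness fit
#'
#' @param fit A `tc_fit` from [fit_method()].
#' @param cohort A scaled `tricoat_cohort`.
#' @param ids Subject IDs to score.
#' @return Numeric matrix, rows = subjects, columns = slow / intermediate /
#'   fast probabilities (rows sum to 1).
#' @export
predict_method <- function(fit, cohort, ids = NULL) {
  UseMethod("predict_method")
}

#' @export
predict_method.tc_fit_tricoat <- function(fit, cohort, ids = NULL) {
  if (fit$method$modality == "all") {
    prob <- predict.tricoat_model(fit$fit, cohort, ids)
    P <- as.matrix(prob[, subtype_levels()])
    rownames(P) <- prob$subject_id
    P
  } else {
    predict_tokclf(fit$fit, cohort, ids)
  }
}

#' @export
predict_method.tc_fit_early <- function(fit, cohort, ids = NULL) {
  predict_tokclf(fit$fit, cohort, ids)
}

#' @export
predict_method.tc_fit_late <- function(fit, cohort, ids = NULL) {
  probs <- lapply(fit$fit, predict_tokclf, cohort = cohort, ids = ids)
  Reduce(`+`, probs) / length(probs)
}

#' @export
predict_method.tc_fit_stagewise <- function(fit, cohort, ids = NULL) {
  predict_stagewise(fit$fit, cohort, ids)
}

#' @export
predict_method.tc_fit_svm <- function(fit, cohort, ids = NULL) {
  inp <- model_inputs(cohort)
  ids <- as.character(ids %||% inp$subjects)
  X <- flat_features(inp, fit$method$modality)
  rows <- match(ids, inp$subjects)
  pr <- stats::predict(fit$fit, X[rows, , drop = FALSE], probability = TRUE)
  P <- attr(pr, "probabilities")[, subtype_levels(), drop = FALSE]
  rownames(P) <- ids
  P
}

#' @export
predict_method.tc_fit_rf <- function(fit, cohort, ids = NULL) {
  inp <- model_inputs(cohort)
  ids <- as.character(ids %||% inp$subjects)
  X <- flat_features(inp, fit$method$modality)
  rows <- match(ids, inp$subjects)
  P <- stats::predict(fit$fit, X[rows, , drop = FALSE], type = "prob")
  P <- P[, subtype_levels(), drop = FALSE]
  rownames(P) <- ids
  P
}
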
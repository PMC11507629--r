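#' Run configuration for the training/prediction pipeline
#'
#' Collects task, optimization settings, ablation toggles and the backbone
#' configuration. The `"desk"` profile (default) is sized for CPU-scale
#' experiments on synthetic corpora; the `"paper"` profile records the
#' published full-scale settings (100 epochs, feature size 512, 6 Transformer
#' layers, 8 heads, 3 convolutional layers, 256 BiLSTM hidden units).
#'
#' @param task `"ss3"` or `"ss8"`.
#' @param profile `"desk"` or `"paper"`; sets epoch and backbone defaults.
#' @param epochs training epochs (>= 0).
#' @param batch_size sequences per optimizer step.
#' @param learning_rate step size for the optimizer; defaults to 5e-3 for the
#'   desk profile and 1e-3 for the paper profile.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed master seed for initialization, shuffling and dropout.
#' @param use_plm,use_seqenc feature ablation toggles (at least one `TRUE`).
#' @param use_transformer,use_cnn,use_bilstm backbone stage ablation toggles.
#' @param use_crf when `FALSE`, training uses per-position cross-entropy and
#'   prediction is the per-position argmax of the emissions.
#' @param crf_boundary train start/stop boundary scores (`FALSE` pins them at
#'   zero).
#' @param crf_lr_multiplier learning-rate multiplier for the CRF parameter
#'   group. The transition table is a handful of parameters competing with a
#'   whole encoder that can absorb context into the emissions; as in common
#'   encoder-CRF practice, the CRF layer gets a much larger step size so the
#'   label grammar is actually learned within the training budget.
#' @param backbone a [backbone_config()]; defaults to the profile's.
#' @param feature_dim width of the PLM-side feature block.
#' @param validation_fraction held-out fraction when no validation corpus is
#'   supplied.
#' @return list of class `run_config`.
#' @export
run_config <- function(task = c("ss3", "ss8"),
                       profile = c("desk", "paper"),
                       epochs = NULL, batch_size = 8L, learning_rate = NULL,
                       optimizer = c("adam", "sgd"), seed = 1L,
                       use_plm = TRUE, use_seqenc = TRUE,
                       use_transformer = TRUE, use_cnn = TRUE,
                       use_bilstm = TRUE, use_crf = TRUE,
                       crf_boundary = TRUE, crf_lr_multiplier = 50,
                       backbone = NULL, feature_dim = 64L,
                       validation_fraction = 0.1) {
  task <- match.arg(task)
  profile <- match.arg(profile)
  optimizer <- match.arg(optimizer)
  if (!use_plm && !use_seqenc)
    stop("at least one of use_plm / use_seqenc must be TRUE", call. = FALSE)
  K <- if (task == "ss3") 3L else 8L
  backbone <- backbone %||% backbone_config(profile = profile, emission_dim = K)
  if (backbone$emission_dim != K)
    stop("backbone emission_dim must match the task's state count", call. = FALSE)
  epochs <- epochs %||% (if (profile == "paper") 100L else 30L)
  # Desk-scale runs take only a few hundred optimizer steps; a larger step
  # size is needed there so slow-moving parameter groups (notably the CRF
  # transition table under Adam's per-coordinate normalization) actually
  # train within the budget.
  learning_rate <- learning_rate %||% (if (profile == "paper") 1e-3 else 5e-3)
  structure(list(task = task, profile = profile, K = K,
                 alphabet = ss_alphabet(if (task == "ss3") "SS3" else "SS8"),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed),
                 use_plm = use_plm, use_seqenc = use_seqenc,
                 use_transformer = use_transformer, use_cnn = use_cnn,
                 use_bilstm = use_bilstm, use_crf = use_crf,
                 crf_boundary = crf_boundary,
                 crf_lr_multiplier = crf_lr_multiplier,
                 backbone = backbone, feature_dim = as.integer(feature_dim),
                 validation_fraction = validation_fraction),
            class = "run_config")
}

# Initialize the full model parameter tree: optional token table, backbone,
# optional CRF. Order of elements is the flattening skeleton used by the
# optimizer and must stay stable.
model_init <- function(config, seed = config$seed) {
  d <- config$backbone$d_model
  in_dim <- (if (config$use_plm) config$feature_dim else 0L) +
    (if (config$use_seqenc) d else 0L)
  params <- list()
  if (config$use_seqenc) params$token <- token_table_init(d, seed = seed + 101L)
  params$backbone <- backbone_init(config$backbone, in_dim, seed = seed,
                                   use_transformer = config$use_transformer,
                                   use_cnn = config$use_cnn,
                                   use_bilstm = config$use_bilstm)
  if (config$use_crf) params$crf <- crf_params(config$K)
  params
}

# Fused input features for one sequence.
model_inputs <- function(params, config, feats, residues) {
  seqenc <- NULL
  if (config$use_seqenc) {
    idx <- residues_to_idx(residues)
    seqenc <- params$token[idx, , drop = FALSE] +
      positional_encoding(length(idx), config$backbone$d_model)
  }
  fuse_features(feats, seqenc, use_plm = config$use_plm,
                use_seqenc = config$use_seqenc)
}

# Emission scores for one sequence.
model_emissions <- function(params, config, feats, residues, train = FALSE,
                            keep_cache = FALSE) {
  x <- model_inputs(params, config, feats, residues)
  backbone_forward(params$backbone, x, config$backbone, train = train,
                   keep_cache = keep_cache)
}

# Loss and exact gradients for one labeled sequence. Returns the gradient
# tree in the same skeleton as the parameter tree.
model_seq_grad <- function(params, config, feats, residues, y_idx,
                           train = TRUE) {
  fw <- model_emissions(params, config, feats, residues, train = train,
                        keep_cache = TRUE)
  em <- fw$emissions
  L <- nrow(em)
  if (config$use_crf) {
    cg <- crf_nll_grad(em, y_idx, params$crf)
    loss <- cg$nll
    d_em <- cg$d_emissions
    crf_grads <- list(transitions = cg$d_transitions,
                      start = if (config$crf_boundary) cg$d_start else numeric(config$K),
                      stop = if (config$crf_boundary) cg$d_stop else numeric(config$K))
  } else {
    P <- softmax_rows(em)
    loss <- -sum(log(pmax(P[cbind(seq_len(L), y_idx)], 1e-300)))
    d_em <- P
    d_em[cbind(seq_len(L), y_idx)] <- d_em[cbind(seq_len(L), y_idx)] - 1
    crf_grads <- NULL
  }
  bb <- backbone_backward(d_em, fw$cache, params$backbone, config$backbone)
  grads <- list()
  if (config$use_seqenc) {
    d <- config$backbone$d_model
    off <- if (config$use_plm) config$feature_dim else 0L
    dseq <- bb$dx[, off + seq_len(d), drop = FALSE]
    idx <- residues_to_idx(residues)
    dT <- matrix(0, 21L, d)
    acc <- rowsum(dseq, group = idx)
    dT[as.integer(rownames(acc)), ] <- acc
    grads$token <- dT
  }
  grads$backbone <- bb$grads
  if (config$use_crf) grads$crf <- crf_grads
  list(loss = loss, grads = grads, L = L)
}

# Mean per-sequence loss over a corpus (no gradients, no dropout).
model_corpus_loss <- function(params, config, corpus, ids) {
  tot <- 0; n <- 0L
  for (id in ids) {
    em <- model_emissions(params, config, corpus$features[[id]],
                          corpus$residues[[id]])
    y <- labels_to_idx(corpus$labels[[id]], config$alphabet)
    tot <- tot + if (config$use_crf) {
      crf_nll(em, y, params$crf)
    } else {
      P <- softmax_rows(em)
      -sum(log(pmax(P[cbind(seq_along(y), y)], 1e-300)))
    }
    n <- n + 1L
  }
  tot / n
}

#' Train the labeling model
#'
#' Minimizes the mean per-sequence negative log-likelihood of the CRF (or
#' per-position cross-entropy when `use_crf` is off) with a first-order
#' optimizer (Adam by default). Training is fully seeded: initialization,
#' shuffling, dropout and the validation split all derive from
#' `config$seed`, so identical config and corpus give identical checkpoints.
#' The checkpoint keeps the parameters of the best validation-accuracy epoch.
#'
#' @param config a [run_config()].
#' @param corpus a labeled `ss_corpus` (from [generate_corpus()] or
#'   [load_corpus()]).
#' @param val optional validation corpus; when `NULL`, a seeded
#'   `validation_fraction` split by sequence is taken from `corpus`.
#' @param verbose print per-epoch train/validation loss and accuracy.
#' @return list of class `ss_checkpoint` with `params` (best epoch),
#'   `config`, and a per-epoch `history` data frame.
#' @export
ss_train <- function(config, corpus, val = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"), inherits(corpus, "ss_corpus"))
  if (length(corpus$ids) == 0L) stop("training corpus is empty", call. = FALSE)
  if (is.null(corpus$labels)) stop("training corpus has no labels", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)

  if (is.null(val)) {
    n <- length(corpus$ids)
    n_val <- max(1L, round(config$validation_fraction * n))
    if (n_val >= n) stop("corpus too small to split for validation", call. = FALSE)
    val_ids <- sample(corpus$ids, n_val)
    train_ids <- setdiff(corpus$ids, val_ids)
    val <- corpus
    val$ids <- val_ids
  } else {
    stopifnot(inherits(val, "ss_corpus"))
    train_ids <- corpus$ids
    val_ids <- val$ids
  }

  params <- model_init(config)
  skeleton <- params
  pvec <- flatten_tree(params)
  state <- adam_state_init(length(pvec))
  step_fn <- if (config$optimizer == "adam") adam_step else sgd_step
  lr <- rep(config$learning_rate, length(pvec))
  if (config$use_crf && config$crf_lr_multiplier != 1) {
    n_crf <- length(flatten_tree(params$crf))
    lr[(length(pvec) - n_crf + 1L):length(pvec)] <-
      config$learning_rate * config$crf_lr_multiplier
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_q = numeric(0))
  best <- list(q = -Inf, pvec = pvec)

  eval_val <- function(params) {
    preds <- ss_predict_params(params, config, val, val_ids)
    truth <- vapply(val_ids, function(id) val$labels[[id]], "")
    q <- 100 * sum(mapply(function(a, b) sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]),
                          truth, preds)) / sum(nchar(truth))
    loss <- model_corpus_loss(params, config, val, val_ids)
    list(q = q, loss = loss)
  }

  if (config$epochs == 0L) {
    ev <- eval_val(params)
    best$q <- ev$q
  }

  for (epoch in seq_len(config$epochs)) {
    order <- sample(train_ids)
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    ep_loss <- 0; ep_n <- 0L
    for (batch in batches) {
      gacc <- NULL
      for (id in batch) {
        sg <- model_seq_grad(params, config, corpus$features[[id]],
                             corpus$residues[[id]],
                             labels_to_idx(corpus$labels[[id]], config$alphabet))
        if (!is.finite(sg$loss))
          stop(sprintf("non-finite loss at epoch %d on sequence '%s'; aborting",
                       epoch, id), call. = FALSE)
        gv <- flatten_tree(sg$grads)
        gacc <- if (is.null(gacc)) gv else gacc + gv
        ep_loss <- ep_loss + sg$loss; ep_n <- ep_n + 1L
      }
      upd <- step_fn(pvec, gacc / length(batch), state, lr)
      pvec <- upd$pvec
      state <- upd$state
      params <- unflatten_tree(pvec, skeleton)
    }
    ev <- eval_val(params)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / ep_n,
                                         val_loss = ev$loss, val_q = ev$q))
    if (verbose)
      message(sprintf("epoch %3d  train_nll %8.4f  val_nll %8.4f  val_Q %6.2f",
                      epoch, ep_loss / ep_n, ev$loss, ev$q))
    if (ev$q > best$q) best <- list(q = ev$q, pvec = pvec)
  }

  structure(list(params = unflatten_tree(best$pvec, skeleton),
                 config = config, history = history,
                 best_val_q = best$q, val_ids = val_ids),
            class = "ss_checkpoint")
}

# Decode a set of corpus sequences with an explicit parameter tree.
ss_predict_params <- function(params, config, corpus, ids) {
  out <- vapply(ids, function(id) {
    em <- model_emissions(params, config, corpus$features[[id]],
                          corpus$residues[[id]])
    idx <- if (config$use_crf) {
      crf_viterbi(em, params$crf)$path
    } else {
      apply(em, 1L, which.max)
    }
    idx_to_labels(idx, config$alphabet)
  }, "")
  names(out) <- ids
  out
}

#' Predict secondary-structure labels
#'
#' Viterbi-decodes every sequence of the corpus with the checkpoint's
#' parameters (per-position argmax when the checkpoint was trained without
#' the CRF). Sequences are decoded independently, so predictions do not
#' depend on batch composition; input order is preserved.
#'
#' @param checkpoint an `ss_checkpoint` from [ss_train()].
#' @param corpus an `ss_corpus` (labels not required).
#' @return data.frame with columns `id`, `residues`, `labels`.
#' @export
ss_predict <- function(checkpoint, corpus) {
  stopifnot(inherits(checkpoint, "ss_checkpoint"), inherits(corpus, "ss_corpus"))
  ids <- corpus$ids
  if (length(ids) == 0L) {
    return(data.frame(id = character(0), residues = character(0),
                      labels = character(0), stringsAsFactors = FALSE))
  }
  labels <- ss_predict_params(checkpoint$params, checkpoint$config, corpus, ids)
  data.frame(id = ids, residues = unname(corpus$residues[ids]),
             labels = unname(labels), stringsAsFactors = FALSE)
}

#' Evaluate predictions against truth
#'
#' Per-protein Q accuracy and Sov, plus a TOTAL row with the micro-averaged
#' dataset scores (total correct residues / total residues; summed Sov
#' numerators / summed normalizers). Ids present in only one of the two sets
#' are reported with a warning and skipped.
#'
#' @param pred named character vector of predicted label strings, or the
#'   data.frame returned by [ss_predict()].
#' @param truth named character vector of true label strings.
#' @param sov_variant passed to [sov()].
#' @param path optional output path for a TSV report (columns id, L, Q, Sov).
#' @return data.frame with one row per protein plus a TOTAL row.
#' @export
ss_evaluate <- function(pred, truth, sov_variant = "literal", path = NULL) {
  if (is.data.frame(pred)) pred <- stats::setNames(pred$labels, pred$id)
  common <- intersect(names(pred), names(truth))
  missing <- union(setdiff(names(pred), names(truth)),
                   setdiff(names(truth), names(pred)))
  if (length(missing) > 0L)
    warning(sprintf("ids present in only one of prediction/truth skipped: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
  if (length(common) == 0L) stop("no common ids to evaluate", call. = FALSE)
  rows <- lapply(common, function(id) {
    data.frame(id = id, L = nchar(truth[[id]]),
               Q = q_accuracy(truth[[id]], pred[[id]]),
               Sov = sov(truth[[id]], pred[[id]], variant = sov_variant),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  n_correct <- sum(mapply(function(a, b) sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]),
                          truth[common], pred[common]))
  total <- data.frame(id = "TOTAL", L = sum(rep$L),
                      Q = 100 * n_correct / sum(rep$L),
                      Sov = sov_dataset(unname(truth[common]), unname(pred[common]),
                                        variant = sov_variant),
                      stringsAsFactors = FALSE)
  rep <- rbind(rep, total)
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep
}

#' Save / load a checkpoint
#'
#' Checkpoints hold the trained parameter tree plus the full run
#' configuration (including the alphabet), so `predict` can verify that a
#' checkpoint matches the requested task.
#'
#' @param checkpoint an `ss_checkpoint`.
#' @param path file path.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "ss_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "ss_checkpoint"))
  ck
}

#' Count directed label adjacencies
#'
#' Number of positions where state `from` is immediately followed by state
#' `to`, summed over all label strings. Used to check that CRF decoding
#' respects forbidden transitions of the generating grammar.
#'
#' @param labels character vector of label strings.
#' @param from,to single state symbols.
#' @return integer count.
#' @export
count_adjacencies <- function(labels, from, to) {
  sum(vapply(labels, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (length(ch) < 2L) return(0L)
    sum(ch[-length(ch)] == from & ch[-1] == to)
  }, integer(1)))
}
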
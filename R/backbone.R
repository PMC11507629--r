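#' Backbone configuration
#'
#' Hyperparameters of the emission-score backbone. The default profile is the
#' published full-scale configuration (feature size 512, six Transformer
#' layers with eight attention heads, three convolutional layers, 256 BiLSTM
#' hidden units per direction); the `"desk"` profile is a small configuration
#' of the same architecture sized so the complete train/predict loop runs in
#' minutes on one CPU core.
#'
#' @param profile `"paper"` (full-scale defaults) or `"desk"` (small).
#' @param d_model width of the sequence-encoding / Transformer stream.
#' @param transformer_layers number of encoder blocks.
#' @param attention_heads heads per block; must divide `d_model`.
#' @param ffn_dim inner width of the position-wise feed-forward network.
#' @param conv_layers number of stacked 1-D convolutional layers.
#' @param conv_kernel convolution width; must be odd (same-length output).
#' @param lstm_hidden BiLSTM hidden units per direction.
#' @param dropout dropout rate applied inside encoder blocks during training.
#' @param emission_dim number of label states K (3 or 8).
#' @return list of class `backbone_config`.
#' @export
backbone_config <- function(profile = c("paper", "desk"),
                            d_model = NULL, transformer_layers = NULL,
                            attention_heads = NULL, ffn_dim = NULL,
                            conv_layers = NULL, conv_kernel = 3L,
                            lstm_hidden = NULL, dropout = 0.1,
                            emission_dim = 3L) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") {
    list(d_model = 512L, transformer_layers = 6L, attention_heads = 8L,
         ffn_dim = 1024L, conv_layers = 3L, lstm_hidden = 256L)
  } else {
    list(d_model = 32L, transformer_layers = 1L, attention_heads = 2L,
         ffn_dim = 64L, conv_layers = 1L, lstm_hidden = 24L)
  }
  cfg <- list(
    profile = profile,
    d_model = as.integer(d_model %||% def$d_model),
    transformer_layers = as.integer(transformer_layers %||% def$transformer_layers),
    attention_heads = as.integer(attention_heads %||% def$attention_heads),
    ffn_dim = as.integer(ffn_dim %||% def$ffn_dim),
    conv_layers = as.integer(conv_layers %||% def$conv_layers),
    conv_kernel = as.integer(conv_kernel),
    lstm_hidden = as.integer(lstm_hidden %||% def$lstm_hidden),
    dropout = dropout,
    emission_dim = as.integer(emission_dim))
  if (cfg$d_model %% cfg$attention_heads != 0L)
    stop("d_model must be divisible by attention_heads", call. = FALSE)
  if (cfg$conv_kernel %% 2L == 0L)
    stop("conv_kernel must be odd for same-length output", call. = FALSE)
  if (any(unlist(cfg[c("d_model", "transformer_layers", "attention_heads",
                       "ffn_dim", "conv_layers", "lstm_hidden")]) < 1L))
    stop("all backbone size parameters must be >= 1", call. = FALSE)
  if (!cfg$emission_dim %in% c(3L, 8L))
    stop("emission_dim must be 3 or 8", call. = FALSE)
  structure(cfg, class = "backbone_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize backbone parameters
#'
#' Builds the trainable parameter tree for the configured stages. The fused
#' input (`in_dim` wide) is first projected to `d_model`; ablation flags
#' select which stages exist. The emission head is initialized small so the
#' initial per-residue negative log-likelihood is close to `log K`.
#'
#' @param cfg a [backbone_config()].
#' @param in_dim width of the fused input features.
#' @param seed integer seed for the initialization.
#' @param use_transformer,use_cnn,use_bilstm stage ablation toggles.
#' @return named list (parameter tree) understood by [backbone_forward()].
#' @export
backbone_init <- function(cfg, in_dim, seed = 1L,
                          use_transformer = TRUE, use_cnn = TRUE,
                          use_bilstm = TRUE) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  d <- cfg$d_model
  p <- list(proj = list(W = glorot_init(in_dim, d), b = numeric(d)))
  if (use_transformer) {
    p$transformer <- lapply(seq_len(cfg$transformer_layers),
                            function(i) tblock_init(d, cfg$ffn_dim))
  }
  if (use_cnn) {
    p$conv <- lapply(seq_len(cfg$conv_layers),
                     function(i) conv_init(cfg$conv_kernel, d, d))
  }
  cur <- d
  if (use_bilstm) {
    p$lstm <- list(fwd = lstm_init(cur, cfg$lstm_hidden),
                   bwd = lstm_init(cur, cfg$lstm_hidden))
    cur <- 2L * cfg$lstm_hidden
  }
  p$head <- list(W = glorot_init(cur, cfg$emission_dim) * 0.1,
                 b = numeric(cfg$emission_dim))
  p
}

#' Transformer encoder stack (forward)
#'
#' Applies the configured number of post-norm encoder blocks (multi-head
#' self-attention, residual + layer norm, position-wise feed-forward,
#' residual + layer norm). Shape-preserving; key positions beyond
#' `valid_len` are masked out of every attention softmax.
#'
#' @param x `L x d_model` input matrix.
#' @param params the `transformer` component of a [backbone_init()] tree.
#' @param cfg a [backbone_config()].
#' @param valid_len number of non-padded rows.
#' @return `L x d_model` matrix.
#' @export
transformer_encode <- function(x, params, cfg, valid_len = nrow(x)) {
  for (blk in params) {
    x <- tblock_fwd(x, blk, cfg$attention_heads, valid_len)$out
  }
  x
}

#' Stacked 1-D convolutional feature extraction (forward)
#'
#' @param x `L x d` input matrix.
#' @param params the `conv` component of a [backbone_init()] tree.
#' @param cfg a [backbone_config()].
#' @return `L x d` matrix (length-preserving via symmetric zero padding).
#' @export
conv_extract <- function(x, params, cfg) {
  for (layer in params) x <- conv1d_fwd(x, layer, cfg$conv_kernel)$out
  x
}

#' Bidirectional LSTM feature extraction (forward)
#'
#' Concatenates, per position, the hidden state of a forward LSTM run in
#' natural order with that of a backward LSTM run on the reversed sequence.
#'
#' @param x `L x d` input matrix.
#' @param params the `lstm` component of a [backbone_init()] tree
#'   (elements `fwd` and `bwd`).
#' @return `L x (2 * lstm_hidden)` matrix.
#' @export
bilstm_extract <- function(x, params) {
  Hf <- lstm_fwd(x, params$fwd)$out
  L <- nrow(x)
  Hb <- lstm_fwd(x[rev(seq_len(L)), , drop = FALSE], params$bwd)$out
  cbind(Hf, Hb[rev(seq_len(L)), , drop = FALSE])
}

#' Linear emission head
#'
#' Per-position affine map from backbone features to K unnormalized state
#' scores (the "firing scores"). No softmax is applied: the CRF consumes raw
#' scores.
#'
#' @param x `L x d` feature matrix.
#' @param W `d x K` weight matrix.
#' @param b length-K bias.
#' @return `L x K` emission-score matrix.
#' @export
emission_head <- function(x, W, b) {
  add_bias(x %*% W, b)
}

#' Full backbone forward pass
#'
#' Maps fused input features to per-residue emission scores through the
#' configured stages (input projection, Transformer encoder, CNN stack,
#' BiLSTM, linear head). Every stage is length-preserving. Rows beyond
#' `valid_len` are treated as padding: they are masked out of attention,
#' zeroed before the convolution, and excluded from the recurrence, so the
#' emission scores of real positions do not depend on padding.
#'
#' @param params parameter tree from [backbone_init()].
#' @param x fused input features, `L x in_dim`.
#' @param cfg a [backbone_config()].
#' @param valid_len number of real (non-padded) rows.
#' @param train logical; enables dropout.
#' @param keep_cache logical; retain intermediate caches for
#'   [backbone_backward()].
#' @return with `keep_cache = FALSE`, the `L x K` emission matrix; otherwise
#'   `list(emissions, cache)`.
#' @export
backbone_forward <- function(params, x, cfg, valid_len = nrow(x),
                             train = FALSE, keep_cache = FALSE) {
  L <- nrow(x)
  Lv <- valid_len
  caches <- list()
  pr <- linear_fwd(x, params$proj$W, params$proj$b)
  caches$proj <- pr$cache
  h <- pr$out
  if (!is.null(params$transformer)) {
    caches$transformer <- vector("list", length(params$transformer))
    for (i in seq_along(params$transformer)) {
      tb <- tblock_fwd(h, params$transformer[[i]], cfg$attention_heads,
                       valid = Lv, dropout = cfg$dropout, train = train)
      caches$transformer[[i]] <- tb$cache
      h <- tb$out
    }
  }
  if (Lv < L) h[(Lv + 1L):L, ] <- 0
  if (!is.null(params$conv)) {
    caches$conv <- vector("list", length(params$conv))
    for (i in seq_along(params$conv)) {
      cv <- conv1d_fwd(h, params$conv[[i]], cfg$conv_kernel)
      caches$conv[[i]] <- cv$cache
      h <- cv$out
      if (Lv < L) h[(Lv + 1L):L, ] <- 0
    }
  }
  if (!is.null(params$lstm)) {
    hr <- h[seq_len(Lv), , drop = FALSE]
    f <- lstm_fwd(hr, params$lstm$fwd)
    b <- lstm_fwd(hr[rev(seq_len(Lv)), , drop = FALSE], params$lstm$bwd)
    Hb <- b$out[rev(seq_len(Lv)), , drop = FALSE]
    h2 <- cbind(f$out, Hb)
    if (Lv < L) h2 <- rbind(h2, matrix(0, L - Lv, ncol(h2)))
    caches$lstm <- list(f = f$cache, b = b$cache, Lv = Lv)
    h <- h2
  }
  hd <- linear_fwd(h, params$head$W, params$head$b)
  caches$head <- hd$cache
  emissions <- hd$out
  if (!keep_cache) return(emissions)
  list(emissions = emissions, cache = caches)
}

# Reverse-mode pass through the whole backbone. Assumes the forward pass was
# run without padding (valid_len == nrow(x)), which is how training uses it.
# Returns gradients in the same tree shape as `params` plus the gradient with
# respect to the fused input (needed for the token-embedding table).
backbone_backward <- function(d_emissions, cache, params, cfg) {
  grads <- list()
  hb <- linear_bwd(d_emissions, cache$head, params$head$W)
  grads$head <- list(W = hb$dW, b = hb$db)
  dh <- hb$dx
  if (!is.null(params$lstm)) {
    hdim <- ncol(dh) %/% 2L
    L <- nrow(dh)
    dHf <- dh[, seq_len(hdim), drop = FALSE]
    dHb <- dh[, hdim + seq_len(hdim), drop = FALSE]
    fb <- lstm_bwd(dHf, cache$lstm$f, params$lstm$fwd)
    bb <- lstm_bwd(dHb[rev(seq_len(L)), , drop = FALSE], cache$lstm$b,
                   params$lstm$bwd)
    grads$lstm <- list(fwd = fb$grads, bwd = bb$grads)
    dh <- fb$dx + bb$dx[rev(seq_len(L)), , drop = FALSE]
  }
  if (!is.null(params$conv)) {
    grads$conv <- vector("list", length(params$conv))
    for (i in rev(seq_along(params$conv))) {
      cb <- conv1d_bwd(dh, cache$conv[[i]], params$conv[[i]])
      grads$conv[[i]] <- cb$grads
      dh <- cb$dx
    }
  }
  if (!is.null(params$transformer)) {
    grads$transformer <- vector("list", length(params$transformer))
    for (i in rev(seq_along(params$transformer))) {
      tb <- tblock_bwd(dh, cache$transformer[[i]], params$transformer[[i]])
      grads$transformer[[i]] <- tb$grads
      dh <- tb$dx
    }
  }
  pb <- linear_bwd(dh, cache$proj, params$proj$W)
  grads$proj <- list(W = pb$dW, b = pb$db)
  # order grads to match the params skeleton exactly
  grads <- grads[names(params)]
  list(grads = grads, dx = pb$dx)
}
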
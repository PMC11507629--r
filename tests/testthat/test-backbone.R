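test_that("scaled dot-product attention matches hand evaluation", {
  # single position: softmax of a scalar is 1, output is the V row
  expect_equal(scaled_dot_attention(matrix(2, 1, 2), matrix(1, 1, 2),
                                    matrix(c(3, 7), 1, 2)),
               matrix(c(3, 7), 1, 2))

  # identical keys: uniform weights, every output row is the V column mean
  set.seed(1)
  Q <- matrix(rnorm(8), 4, 2)
  K <- matrix(rep(c(1, 2), each = 4), 4, 2)
  V <- matrix(rnorm(12), 4, 3)
  out <- scaled_dot_attention(Q, K, V)
  for (r in 1:4) expect_equal(out[r, ], colMeans(V), tolerance = 1e-12)

  # two-key instance, weights computed by explicit arithmetic
  Q <- matrix(c(1, 0), 1, 2)
  Km <- rbind(c(1, 0), c(0, 1))
  Vm <- rbind(c(1, 0), c(0, 1))
  w1 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + exp(0))
  expect_equal(scaled_dot_attention(Q, Km, Vm, d_k = 2),
               matrix(c(w1, 1 - w1), 1, 2), tolerance = 1e-12)

  expect_error(scaled_dot_attention(Q, Km, Vm, d_k = 0), "positive")
})

test_that("a zeroed encoder block reduces to normalization of its input", {
  cfg <- tiny_backbone()
  set.seed(2)
  blk <- tblock_init(cfg$d_model, cfg$ffn_dim)
  blk$mha$Wo[] <- 0; blk$mha$bo[] <- 0
  blk$ffn$W2[] <- 0; blk$ffn$b2[] <- 0
  x <- matrix(rnorm(6 * cfg$d_model), 6, cfg$d_model)
  out <- tblock_fwd(x, blk, cfg$attention_heads)$out
  ref <- layernorm_fwd(layernorm_fwd(x, blk$ln1_g, blk$ln1_b)$out,
                       blk$ln2_g, blk$ln2_b)$out
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("the transformer stack preserves shape at full-scale settings", {
  cfg <- backbone_config(profile = "paper")
  expect_identical(cfg$transformer_layers, 6L)
  expect_identical(cfg$attention_heads, 8L)
  set.seed(3)
  params <- lapply(1:cfg$transformer_layers,
                   function(i) tblock_init(cfg$d_model, 64L))
  x <- matrix(rnorm(10 * 512), 10, 512)
  expect_identical(dim(transformer_encode(x, params, cfg)), c(10L, 512L))
})

test_that("convolution layers behave as specified", {
  # kernel 1, identity weights, no bias, no activation: identity map
  x <- matrix(rnorm(20), 5, 4)
  p <- list(W = diag(4), b = numeric(4))
  expect_equal(conv1d_fwd(x, p, 1L, activation = FALSE)$out, x)

  # length preservation: 9 rows in, 9 rows out for kernel 3
  set.seed(4)
  cfg <- tiny_backbone()
  layers <- lapply(1:3, function(i) conv_init(3L, 4L, 4L))
  x9 <- matrix(rnorm(36), 9, 4)
  cfg3 <- backbone_config(profile = "desk", d_model = 4L, attention_heads = 2L,
                          conv_layers = 3L, emission_dim = 3L, lstm_hidden = 2L)
  expect_identical(nrow(conv_extract(x9, layers, cfg3)), 9L)

  # receptive field: impulse at row 8 of 15; after 3 layers of kernel 3 the
  # response is confined to rows 8 +/- 3 (biases zero, so zero input stays zero)
  layers0 <- lapply(layers, function(l) { l$W <- abs(l$W); l$b[] <- 0; l })
  imp <- matrix(0, 15, 4); imp[8, ] <- 1
  out <- conv_extract(imp, layers0, cfg3)
  nz <- which(rowSums(abs(out)) > 0)
  expect_true(all(nz >= 5 & nz <= 11))
  expect_true(8 %in% nz)

  expect_error(backbone_config(profile = "desk", conv_kernel = 4L), "odd")
})

test_that("the BiLSTM concatenates direction-symmetric recurrent features", {
  set.seed(5)
  p <- list(fwd = lstm_init(6L, 4L), bwd = lstm_init(6L, 4L))
  x <- matrix(rnorm(7 * 6), 7, 6)
  out <- bilstm_extract(x, p)
  expect_identical(dim(out), c(7L, 8L))

  # with tied directions, reversing the input reverses rows and swaps halves
  p_tied <- list(fwd = p$fwd, bwd = p$fwd)
  a <- bilstm_extract(x, p_tied)
  b <- bilstm_extract(x[7:1, ], p_tied)
  expect_equal(a, b[7:1, c(5:8, 1:4)], tolerance = 1e-12)

  # L = 1 works and matches a single recurrence step
  out1 <- bilstm_extract(x[1, , drop = FALSE], p)
  expect_identical(dim(out1), c(1L, 8L))
  expect_equal(out1[1, 1:4], lstm_fwd(x[1, , drop = FALSE], p$fwd)$out[1, ])

  # published width: hidden 256 per direction gives 512 features
  set.seed(6)
  p256 <- list(fwd = lstm_init(512L, 256L), bwd = lstm_init(512L, 256L))
  expect_identical(dim(bilstm_extract(matrix(rnorm(5 * 512), 5, 512), p256)),
                   c(5L, 512L))
})

test_that("the emission head is a per-position affine map without softmax", {
  x <- matrix(rnorm(12), 4, 3)
  b <- c(1.5, -2, 0.25)
  out <- emission_head(x, matrix(0, 3, 3), b)
  for (r in 1:4) expect_equal(out[r, ], b)
  expect_identical(dim(emission_head(x, matrix(rnorm(9), 3, 3), numeric(3))),
                   c(4L, 3L))
  expect_identical(ncol(emission_head(x, matrix(rnorm(24), 3, 8), numeric(8))), 8L)
  # raw scores: no normalization applied
  expect_false(isTRUE(all.equal(rowSums(exp(out)), rep(1, 4))))
})

test_that("the full backbone is length-preserving, deterministic, and padding-invariant", {
  cfg <- tiny_backbone()
  set.seed(7)
  params <- backbone_init(cfg, in_dim = 10L, seed = 11L)
  x <- matrix(rnorm(7 * 10), 7, 10)
  e1 <- backbone_forward(params, x, cfg)
  expect_identical(dim(e1), c(7L, 3L))
  expect_true(all(is.finite(e1)))
  # frozen parameters: bitwise deterministic
  expect_identical(e1, backbone_forward(params, x, cfg))
  # right-padding with masking leaves real positions' emissions unchanged
  xp <- rbind(x, matrix(rnorm(3 * 10), 3, 10))
  ep <- backbone_forward(params, xp, cfg, valid_len = 7L)
  expect_equal(ep[1:7, ], e1, tolerance = 1e-5)
})

test_that("analytic gradients of the full model match central finite differences", {
  set.seed(8)
  feats <- matrix(rnorm(5 * 6), 5, 6)
  res <- "MKVAY"
  y <- c(1L, 2L, 3L, 3L, 1L)
  for (use_crf in c(TRUE, FALSE)) {
    config <- tiny_config(seed = 5L, use_crf = use_crf)
    params <- model_init(config)
    pv <- flatten_tree(params)
    loss_fn <- function(v) {
      p <- unflatten_tree(v, params)
      em <- model_emissions(p, config, feats, res)
      if (use_crf) {
        crf_nll(em, y, p$crf)
      } else {
        P <- softmax_rows(em)
        -sum(log(P[cbind(1:5, y)]))
      }
    }
    sg <- model_seq_grad(params, config, feats, res, y, train = FALSE)
    gv <- flatten_tree(sg$grads)
    expect_equal(sg$loss, loss_fn(pv), tolerance = 1e-10)
    idx <- sample(length(pv), 60L)
    h <- 1e-5
    fd <- vapply(idx, function(i) {
      p1 <- pv; p1[i] <- p1[i] + h
      p2 <- pv; p2[i] <- p2[i] - h
      (loss_fn(p1) - loss_fn(p2)) / (2 * h)
    }, numeric(1))
    denom <- pmax(abs(fd) + abs(gv[idx]), 1e-6)
    expect_lt(max(abs(fd - gv[idx]) / denom), 1e-4)
  }
})
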
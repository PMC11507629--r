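test_that("synthetic specs validate their stochastic structure", {
  expect_error(synthetic_spec(label_transition = matrix(1, 3, 3)), "sum to 1")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(synthetic_spec(class_means = matrix(1, 3, 64)), "distinct")
  expect_equal(rowSums(default_ss3_transitions()), c(H = 1, E = 1, C = 1))
  expect_equal(unname(rowSums(default_ss8_transitions())), rep(1, 8),
               tolerance = 1e-12)
  # the default grammars forbid direct helix-to-sheet transitions
  expect_identical(default_ss3_transitions()["H", "E"], 0)
  expect_identical(default_ss8_transitions()["H", "E"], 0)
})

test_that("label sampling is reproducible and respects the transition kernel", {
  spec <- synthetic_spec(n_sequences = 10L, seed = 5L)
  expect_identical(sample_labels(spec), sample_labels(spec))

  # identity kernel: constant-label sequences
  spec_id <- synthetic_spec(label_transition = diag(3), n_sequences = 8L,
                            seed = 2L)
  for (lab in sample_labels(spec_id)) {
    expect_identical(length(unique(strsplit(lab, "")[[1]])), 1L)
  }

  # forbidden transitions never occur in the generated corpus
  labs <- sample_labels(synthetic_spec(n_sequences = 100L, seed = 3L))
  expect_identical(count_adjacencies(labs, "H", "E"), 0L)
})

test_that("diagonal mass 0.9 gives geometric runs of mean length 10", {
  P <- matrix(0.05, 3, 3); diag(P) <- 0.9
  spec <- synthetic_spec(label_transition = P, n_sequences = 200L,
                         length_range = c(500L, 500L), seed = 9L)
  labs <- sample_labels(spec)
  runs <- unlist(lapply(labs, function(s) rle(strsplit(s, "")[[1]])$lengths))
  expect_gt(length(runs), 1e4)
  # geometric closed form 1 / (1 - 0.9) = 10, within 5% (end truncation
  # biases the empirical mean slightly low)
  expect_equal(mean(runs), 10, tolerance = 0.05)
})

test_that("features are label-coupled Gaussians with the spec geometry", {
  spec <- synthetic_spec(n_sequences = 6L, seed = 4L)
  labs <- sample_labels(spec)
  feats <- sample_features(labs, spec)
  expect_identical(names(feats), names(labs))
  for (id in names(labs)) {
    expect_identical(nrow(feats[[id]]), nchar(labs[[id]]))
    expect_identical(ncol(feats[[id]]), spec$feature_dim)
  }
  # vanishing noise: rows collapse onto the class means
  spec0 <- synthetic_spec(n_sequences = 3L, noise_sd = 1e-9, seed = 4L)
  labs0 <- sample_labels(spec0)
  f0 <- sample_features(labs0, spec0)
  idx <- labels_to_idx(labs0[[1]], spec0$alphabet)
  expect_equal(f0[[1]], spec0$class_means[idx, ], tolerance = 1e-6)
  # smoothing: interior rows are local averages
  specS <- synthetic_spec(n_sequences = 2L, seed = 4L, smooth = TRUE)
  fS <- sample_features(sample_labels(specS), specS)
  expect_identical(nrow(fS[[1]]), nchar(sample_labels(specS)[[1]]))
})

test_that("two-class Gaussian emissions hit the closed-form Bayes ceiling", {
  # restrict the chain to H/E, one feature dimension, means +1/-1, unit noise:
  # the optimal position-independent classifier has accuracy pnorm(1)
  P <- rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0), c(0, 0, 1))
  spec <- synthetic_spec(label_transition = P, label_init = c(0.5, 0.5, 0),
                         feature_dim = 1L,
                         class_means = matrix(c(1, -1, 0), 3, 1),
                         n_sequences = 100L, length_range = c(100L, 100L),
                         seed = 6L)
  labs <- sample_labels(spec)
  feats <- sample_features(labs, spec)
  y <- unlist(lapply(labs, function(s) labels_to_idx(s, spec$alphabet)))
  x <- do.call(rbind, feats)[, 1]
  acc <- mean(ifelse(x > 0, 1L, 2L) == y)
  expect_equal(acc, stats::pnorm(1), tolerance = 0.02)
})

test_that("corpus regeneration is bit-identical and file I/O round-trips", {
  spec <- synthetic_spec(n_sequences = 5L, seed = 12L)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1, c2)

  dir <- withr::local_tempdir()
  c3 <- generate_corpus(spec, dir = dir)
  expect_true(all(file.exists(unlist(c3$paths))))
  # the written corpus reloads through the standard I/O + cache provider
  re <- load_corpus(c3$paths$fasta, c3$paths$labels, alphabet = spec$alphabet,
                    provider = "cache", cache_path = c3$paths$cache)
  expect_identical(re$residues, c3$residues)
  expect_identical(re$labels, c3$labels)
  expect_equal(re$features, c3$features)
})

test_that("the Markov structure is exploitable by transition-aware decoding", {
  # with true-model emissions, Viterbi with the generating transitions must
  # beat per-position decoding of the same emissions: the corpus's context
  # signal is real and a CRF can capture it
  spec <- synthetic_spec(n_sequences = 60L, seed = 13L)
  labs <- sample_labels(spec)
  feats <- sample_features(labs, spec)
  p_true <- crf_params(3L)
  p_true$transitions <- log(spec$label_transition + 1e-10)
  p_zero <- crf_params(3L)
  n_vit <- n_arg <- n_tot <- 0L
  for (id in names(labs)) {
    y <- labels_to_idx(labs[[id]], spec$alphabet)
    X <- feats[[id]]
    em <- sapply(1:3, function(k) {
      mu <- spec$class_means[k, ]
      -colSums((t(X) - mu)^2) / (2 * spec$noise_sd^2)
    })
    n_vit <- n_vit + sum(crf_viterbi(em, p_true)$path == y)
    n_arg <- n_arg + sum(crf_viterbi(em, p_zero)$path == y)
    n_tot <- n_tot + length(y)
  }
  expect_gt(n_vit / n_tot, n_arg / n_tot + 0.05)
  expect_gt(n_vit / n_tot, 0.95)
})
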
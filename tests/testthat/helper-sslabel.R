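# Shared fixtures, built in code.

# Random label string over an alphabet.
random_labels <- function(L, alphabet = ss_alphabet("SS3")) {
  paste(sample(alphabet$states, L, replace = TRUE), collapse = "")
}

# Random CRF instance (emissions + parameters) for oracle comparisons.
random_crf_instance <- function(L, K, scale = 1) {
  p <- crf_params(K)
  p$transitions <- matrix(rnorm(K * K, sd = scale), K, K)
  p$start <- rnorm(K, sd = scale)
  p$stop <- rnorm(K, sd = scale)
  list(emissions = matrix(rnorm(L * K, sd = scale), L, K), params = p)
}

# A deliberately small backbone for fast structural tests.
tiny_backbone <- function(K = 3L) {
  backbone_config(profile = "desk", d_model = 8L, transformer_layers = 1L,
                  attention_heads = 2L, ffn_dim = 12L, conv_layers = 1L,
                  lstm_hidden = 4L, dropout = 0, emission_dim = K)
}

tiny_config <- function(...) {
  run_config(profile = "desk", backbone = tiny_backbone(), feature_dim = 6L,
             batch_size = 4L, ...)
}

# A small, quickly separable synthetic corpus for pipeline tests.
tiny_spec <- function(n = 24L, seed = 7L) {
  synthetic_spec(feature_dim = 6L, n_sequences = n, length_range = c(15L, 25L),
                 class_means = default_class_means(3L, 6L, separation = 3),
                 seed = seed)
}
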
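#' Sinusoidal positional encoding
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/d_model))` and entry
#' `(pos, 2i+1)` is `cos(pos / 10000^(2i/d_model))`, with `pos` 0-based, so
#' the first row is the canonical `(0, 1, 0, 1, ...)` vector. Columns of the
#' returned matrix are 1-based: column `2i+1` holds the sine component and
#' column `2i+2` the cosine component of pair `i`.
#'
#' @param L sequence length (>= 1).
#' @param d_model encoding dimension; must be even and >= 2.
#' @return `L x d_model` matrix with entries in `[-1, 1]`.
#' @examples
#' pe <- positional_encoding(4, 8)
#' pe[1, ]  # 0 1 0 1 0 1 0 1
#' @export
positional_encoding <- function(L, d_model) {
  if (d_model < 2 || d_model %% 2 != 0)
    stop("d_model must be even and >= 2", call. = FALSE)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  pos <- 0:(L - 1)
  two_i <- seq(0L, d_model - 2L, by = 2L)
  freq <- 1 / 10000^(two_i / d_model)
  ang <- outer(pos, freq)                      # L x d_model/2
  pe <- matrix(0, L, d_model)
  pe[, two_i + 1L] <- sin(ang)
  pe[, two_i + 2L] <- cos(ang)
  pe
}

#' Initialize a trainable token-embedding table
#'
#' One row per residue letter (20 standard amino acids plus X), in the order
#' of `AA_ALPHABET`. Unknown residues map to the X row rather than being
#' dropped, so sequence and label lengths never diverge.
#'
#' @param d_model embedding width.
#' @param seed integer seed for the Gaussian initialization.
#' @param sd standard deviation of the initial entries.
#' @return `21 x d_model` matrix with residue-letter rownames.
#' @export
token_table_init <- function(d_model, seed = 1L, sd = 0.5) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  tab <- matrix(stats::rnorm(21L * d_model, sd = sd), 21L, d_model)
  rownames(tab) <- AA_ALPHABET
  tab
}

# Residue string -> 1-based row indices into the token table (unknown -> X).
residues_to_idx <- function(residues) {
  chars <- strsplit(toupper(residues), "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  idx[is.na(idx)] <- match("X", AA_ALPHABET)
  idx
}

#' Token embedding of a residue sequence
#'
#' Row `t` of the result is the table row of residue `t`; identical residues
#' get identical rows. Deterministic given the table.
#'
#' @param residues residue string (length-L).
#' @param table token table from [token_table_init()] (or any `21 x d` matrix
#'   with `AA_ALPHABET` rownames).
#' @return `L x d` matrix (a `0 x d` matrix for the empty sequence).
#' @export
token_embed <- function(residues, table) {
  stopifnot(is.matrix(table), nrow(table) == 21L)
  if (!nzchar(residues)) return(matrix(0, 0L, ncol(table)))
  out <- table[residues_to_idx(residues), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Sequence encoding: token embedding plus positional encoding
#'
#' Elementwise sum of the token embedding and the sinusoidal positional
#' encoding, shape `L x d_model`.
#'
#' @inheritParams token_embed
#' @return `L x d_model` matrix.
#' @export
sequence_encoding <- function(residues, table) {
  tok <- token_embed(residues, table)
  if (nrow(tok) == 0L) return(tok)
  if (ncol(tok) %% 2 != 0)
    stop("token table width must be even to match the positional encoding",
         call. = FALSE)
  tok + positional_encoding(nrow(tok), ncol(tok))
}

# Deterministic 31-adic string hash modulo 2^31 - 1, used to seed the mock
# embedding provider per sequence (per-sequence purity: independent of batch).
string_hash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Per-residue protein language model embeddings
#'
#' Returns an `L x dim` matrix of per-residue embedding vectors. Three
#' providers are supported:
#'
#' * `"mock"` — a pure deterministic function of the sequence string and
#'   `seed`: rows are unit-variance pseudo-random Gaussians seeded from a hash
#'   of the sequence, so the embedding of a sequence never depends on what
#'   else is in the batch, and no model weights or network are needed.
#' * `"cache"` — looks the sequence id up in a precomputed embedding cache
#'   (see [write_embedding_cache()]).
#' * `"prott5"` — the adapter slot for a real PLM encoder; the encoder itself
#'   is not bundled, and selecting it raises an error directing to the mock
#'   provider.
#'
#' @param residues residue string.
#' @param provider one of `"mock"`, `"cache"`, `"prott5"`.
#' @param dim embedding width (1024 for the standard PLM contract).
#' @param seed integer seed mixed into the mock provider's hash.
#' @param cache named list of matrices from [read_embedding_cache()]
#'   (required for `provider = "cache"`).
#' @param id sequence id used for cache lookup.
#' @return `L x dim` numeric matrix.
#' @export
plm_embed <- function(residues, provider = c("mock", "cache", "prott5"),
                      dim = 1024L, seed = 1L, cache = NULL, id = NULL) {
  provider <- match.arg(provider)
  L <- nchar(residues)
  switch(provider,
    mock = {
      old <- get_rng_state(); on.exit(restore_rng_state(old))
      h <- string_hash(residues)
      set.seed(as.integer((h + (seed %% 65536) * 7919) %% 2147483647))
      matrix(stats::rnorm(L * dim), L, dim)
    },
    cache = {
      if (is.null(cache) || is.null(id))
        stop("provider 'cache' needs a cache list and a sequence id", call. = FALSE)
      m <- cache[[id]]
      if (is.null(m))
        stop(sprintf("id '%s' not found in the embedding cache", id), call. = FALSE)
      if (nrow(m) != L)
        stop(sprintf("cached embedding for '%s' has %d rows, sequence has %d residues",
                     id, nrow(m), L), call. = FALSE)
      m
    },
    prott5 = stop(paste("provider 'prott5' is an adapter slot only; the encoder",
                        "weights are not bundled with this package.",
                        "Use provider = 'mock' (always available) or a",
                        "precomputed embedding cache."), call. = FALSE)
  )
}

#' Write / read an embedding cache
#'
#' The cache is a serialized named list of `L x D` matrices keyed by sequence
#' id, produced once (e.g. by [generate_corpus()] or an external PLM run) and
#' consumed by the `"cache"` embedding provider.
#'
#' @param matrices named list of per-sequence embedding matrices.
#' @param path cache file path.
#' @return `write_embedding_cache` invisibly returns `path`;
#'   `read_embedding_cache` returns the named list.
#' @export
write_embedding_cache <- function(matrices, path) {
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  saveRDS(matrices, path)
  invisible(path)
}

#' @rdname write_embedding_cache
#' @export
read_embedding_cache <- function(path) {
  readRDS(path)
}

#' Fuse PLM embeddings with the sequence encoding
#'
#' Rowwise concatenation of the two feature blocks, shape
#' `L x (ncol(plm) + ncol(seqenc))`. Under ablation either side can be
#' omitted, in which case the remaining side is returned unchanged.
#'
#' @param plm `L x D` PLM embedding matrix (or `NULL`).
#' @param seqenc `L x d_model` sequence-encoding matrix (or `NULL`).
#' @param use_plm,use_seqenc ablation toggles; at least one must be `TRUE`.
#' @return fused feature matrix.
#' @export
fuse_features <- function(plm, seqenc, use_plm = TRUE, use_seqenc = TRUE) {
  if (!use_plm && !use_seqenc)
    stop("at least one of use_plm / use_seqenc must be TRUE", call. = FALSE)
  if (!use_plm) return(seqenc)
  if (!use_seqenc) return(plm)
  if (nrow(plm) != nrow(seqenc))
    stop(sprintf("length mismatch: PLM block has %d rows, sequence encoding %d",
                 nrow(plm), nrow(seqenc)), call. = FALSE)
  cbind(plm, seqenc)
}

# Save/restore the caller's RNG state so seeded helpers are side-effect free.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
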
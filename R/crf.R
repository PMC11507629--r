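# Linear-chain CRF over secondary-structure labels. All computations are in
# log space (logsumexp with max subtraction): the literal exponential form of
# the partition function overflows for chains longer than ~100 residues.

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Create linear-chain CRF parameters
#'
#' Transition scores (score of state a followed by state b), plus learnable
#' start/stop boundary score vectors — standard linear-chain practice; set
#' `boundary = FALSE` to pin them at zero, which reduces path scores to
#' emissions plus transitions only. Transitions initialize to zero (uniform),
#' so an untrained CRF behaves like an independent per-position softmax.
#'
#' @param K number of label states.
#' @param boundary include trainable start/stop scores (they are created
#'   either way, but callers that pass `boundary = FALSE` should keep them at
#'   zero; [ss_train()] freezes them when the run config disables boundaries).
#' @return list with `transitions` (K x K), `start`, `stop` (length K).
#' @export
crf_params <- function(K, boundary = TRUE) {
  list(transitions = matrix(0, K, K), start = numeric(K), stop = numeric(K))
}

check_crf_instance <- function(emissions, params, y = NULL) {
  stopifnot(is.matrix(emissions))
  L <- nrow(emissions); K <- ncol(emissions)
  if (L < 1L) stop("empty sequence: the CRF needs at least one position", call. = FALSE)
  stopifnot(nrow(params$transitions) == K, ncol(params$transitions) == K,
            length(params$start) == K, length(params$stop) == K)
  if (!is.null(y)) {
    if (length(y) != L)
      stop("label path length must equal the number of positions", call. = FALSE)
    if (any(y < 1L | y > K))
      stop("label index outside the alphabet", call. = FALSE)
  }
  invisible(list(L = L, K = K))
}

#' Score of one label path
#'
#' `start[y_1] + sum_t emissions[t, y_t] + sum_t transitions[y_{t-1}, y_t] +
#' stop[y_L]` — the unnormalized log-score whose exponential appears in the
#' CRF path probability.
#'
#' @param emissions `L x K` emission-score matrix.
#' @param y integer label path (1-based state indices), length L.
#' @param params CRF parameters from [crf_params()].
#' @return numeric scalar.
#' @export
crf_score_path <- function(emissions, y, params) {
  check_crf_instance(emissions, params, y)
  L <- nrow(emissions)
  s <- params$start[y[1]] + sum(emissions[cbind(seq_len(L), y)]) + params$stop[y[L]]
  if (L > 1L) s <- s + sum(params$transitions[cbind(y[-L], y[-1])])
  s
}

#' Log-partition function of the chain
#'
#' `log` of the sum over all `K^L` label paths of the exponentiated path
#' score, computed by the forward recursion in log space in `O(L K^2)`. This
#' is the normalizer that makes the path probabilities sum to one.
#'
#' @inheritParams crf_score_path
#' @return numeric scalar.
#' @export
crf_log_partition <- function(emissions, params) {
  check_crf_instance(emissions, params)
  L <- nrow(emissions); K <- ncol(emissions)
  alpha <- params$start + emissions[1, ]
  if (L > 1L) {
    for (t in 2:L) {
      # alpha_new[k] = logsumexp_j(alpha[j] + trans[j, k]) + em[t, k]
      M <- alpha + params$transitions          # K x K, column k = candidate sums
      mx <- apply(M, 2L, max)
      alpha <- mx + log(colSums(exp(M - matrix(mx, K, K, byrow = TRUE)))) +
        emissions[t, ]
    }
  }
  logsumexp(alpha + params$stop)
}

#' Negative log-likelihood of a label path
#'
#' `log Z - score(y)`; non-negative, and zero only when the true path carries
#' all probability mass. This is the training loss of the CRF layer.
#'
#' @inheritParams crf_score_path
#' @return numeric scalar.
#' @export
crf_nll <- function(emissions, y, params) {
  crf_log_partition(emissions, params) - crf_score_path(emissions, y, params)
}

# Forward/backward messages in log space; alpha[t, k] includes emissions up
# to and including t (and the start score); beta[t, k] scores completions
# after t (including the stop score).
crf_messages <- function(emissions, params) {
  L <- nrow(emissions); K <- ncol(emissions)
  alpha <- matrix(0, L, K); beta <- matrix(0, L, K)
  alpha[1, ] <- params$start + emissions[1, ]
  if (L > 1L) {
    for (t in 2:L) {
      M <- alpha[t - 1L, ] + params$transitions
      mx <- apply(M, 2L, max)
      alpha[t, ] <- mx + log(colSums(exp(M - matrix(mx, K, K, byrow = TRUE)))) +
        emissions[t, ]
    }
  }
  beta[L, ] <- params$stop
  if (L > 1L) {
    for (t in (L - 1L):1L) {
      # beta[t, j] = logsumexp_k(trans[j, k] + em[t+1, k] + beta[t+1, k])
      M <- t(params$transitions) + emissions[t + 1L, ] + beta[t + 1L, ]  # K x K, col j
      mx <- apply(M, 2L, max)
      beta[t, ] <- mx + log(colSums(exp(M - matrix(mx, K, K, byrow = TRUE))))
    }
  }
  logZ <- logsumexp(alpha[L, ] + params$stop)
  list(alpha = alpha, beta = beta, logZ = logZ)
}

#' Exact gradient of the CRF negative log-likelihood
#'
#' Computed from the forward-backward marginals: the emission gradient is the
#' per-position state marginals minus the one-hot truth; the transition
#' gradient is the expected adjacent-pair counts minus the observed counts;
#' similarly for the boundary scores.
#'
#' @inheritParams crf_score_path
#' @return list with `nll`, `d_emissions` (L x K), `d_transitions` (K x K),
#'   `d_start`, `d_stop` (length K), and `marginals` (L x K per-position
#'   posterior state probabilities).
#' @export
crf_nll_grad <- function(emissions, y, params) {
  check_crf_instance(emissions, params, y)
  L <- nrow(emissions); K <- ncol(emissions)
  msg <- crf_messages(emissions, params)
  marg <- exp(msg$alpha + msg$beta - msg$logZ)
  d_em <- marg
  d_em[cbind(seq_len(L), y)] <- d_em[cbind(seq_len(L), y)] - 1
  d_tr <- matrix(0, K, K)
  if (L > 1L) {
    for (t in seq_len(L - 1L)) {
      # pair marginal p(y_t = a, y_{t+1} = b)
      P <- exp(outer(msg$alpha[t, ], emissions[t + 1L, ] + msg$beta[t + 1L, ], "+") +
                 params$transitions - msg$logZ)
      d_tr <- d_tr + P
      d_tr[y[t], y[t + 1L]] <- d_tr[y[t], y[t + 1L]] - 1
    }
  }
  d_start <- marg[1, ]; d_start[y[1]] <- d_start[y[1]] - 1
  d_stop <- marg[L, ]; d_stop[y[L]] <- d_stop[y[L]] - 1
  nll <- msg$logZ - crf_score_path(emissions, y, params)
  list(nll = nll, d_emissions = d_em, d_transitions = d_tr,
       d_start = d_start, d_stop = d_stop, marginals = marg)
}

#' Viterbi decoding
#'
#' Dynamic-programming search for a maximum-scoring label path with
#' backtracking. Ties are broken deterministically toward the lowest state
#' index at every maximization, so the all-zero instance decodes to the
#' all-first-state path.
#'
#' @inheritParams crf_score_path
#' @return list with `path` (integer vector, 1-based state indices) and
#'   `score` (equal to `crf_score_path(emissions, path, params)`).
#' @export
crf_viterbi <- function(emissions, params) {
  check_crf_instance(emissions, params)
  L <- nrow(emissions); K <- ncol(emissions)
  delta <- matrix(-Inf, L, K)
  back <- matrix(0L, L, K)
  delta[1, ] <- params$start + emissions[1, ]
  if (L > 1L) {
    for (t in 2:L) {
      M <- delta[t - 1L, ] + params$transitions   # K x K, column k
      back[t, ] <- apply(M, 2L, which.max)        # first max: lowest index wins
      delta[t, ] <- M[cbind(back[t, ], seq_len(K))] + emissions[t, ]
    }
  }
  final <- delta[L, ] + params$stop
  path <- integer(L)
  path[L] <- which.max(final)
  if (L > 1L) {
    for (t in (L - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  }
  list(path = path, score = final[path[L]])
}

#' Exhaustive-enumeration oracle
#'
#' Enumerates all `K^L` label paths and scores each with [crf_score_path()].
#' Deliberately the naive method the dynamic programs replace; intended for
#' testing the forward recursion and Viterbi on small instances.
#'
#' @inheritParams crf_score_path
#' @param max_paths guard on `K^L`.
#' @return list with `scores` (length `K^L`), `paths` (matrix, one row per
#'   path), `best_path`, `best_score`, and `log_partition`.
#' @export
crf_brute_force <- function(emissions, params, max_paths = 1e6) {
  info <- check_crf_instance(emissions, params)
  L <- info$L; K <- info$K
  n <- K^L
  if (n > max_paths) stop("instance too large for exhaustive enumeration", call. = FALSE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  colnames(paths) <- NULL
  # vectorized scoring over all paths (identical by definition to
  # crf_score_path row by row, which the tests cross-check)
  scores <- params$start[paths[, 1L]] + params$stop[paths[, L]]
  for (t in seq_len(L)) scores <- scores + emissions[t, paths[, t]]
  if (L > 1L) {
    for (t in 2:L) {
      scores <- scores + params$transitions[cbind(paths[, t - 1L], paths[, t])]
    }
  }
  best <- which.max(scores)
  list(scores = scores, paths = paths,
       best_path = paths[best, ], best_score = scores[best],
       log_partition = logsumexp(scores))
}

#' Export a transition matrix as labeled CSV
#'
#' Writes the K x K transition-score matrix with state symbols as row and
#' column headers, for inspection of the learned label grammar (e.g. strongly
#' negative helix-to-sheet scores).
#'
#' @param params CRF parameters (or a checkpoint's `params$crf`).
#' @param path output CSV path.
#' @param states character vector of state symbols in index order.
#' @return invisibly `path`.
#' @export
export_transitions <- function(params, path, states) {
  m <- params$transitions
  stopifnot(length(states) == nrow(m))
  dimnames(m) <- list(states, states)
  utils::write.csv(m, path)
  invisible(path)
}
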
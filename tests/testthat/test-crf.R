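# The hand-checkable two-state, three-position instance used throughout:
# emissions favor state 1 at positions 1 and 3, state 2 at position 2;
# staying in the same state scores +2.
k2l3_instance <- function() {
  p <- crf_params(2L)
  p$transitions <- rbind(c(2, 0), c(0, 2))
  list(emissions = rbind(c(1, 0), c(0, 1), c(1, 0)), params = p)
}

test_that("path scores sum start, emission, transition and stop terms", {
  inst <- k2l3_instance()
  # hand sum for path (1,1,1): 1 + 0 + 1 (emissions) + 2 + 2 (transitions)
  expect_equal(crf_score_path(inst$emissions, c(1L, 1L, 1L), inst$params), 6)

  # L = 1 with zero boundaries reduces to the single emission
  p1 <- crf_params(3L)
  em1 <- matrix(c(0.3, -1, 2), 1, 3)
  expect_equal(crf_score_path(em1, 2L, p1), -1)

  # all-zero model scores every path zero
  p0 <- crf_params(2L)
  em0 <- matrix(0, 3, 2)
  for (y1 in 1:2) expect_equal(crf_score_path(em0, c(y1, 1L, 2L), p0), 0)

  # boundary scores enter at the ends
  pb <- crf_params(2L)
  pb$start <- c(5, 0); pb$stop <- c(0, 7)
  expect_equal(crf_score_path(em0, c(1L, 1L, 2L), pb), 12)

  expect_error(crf_score_path(matrix(0, 0, 2), integer(0), p0), "empty")
  expect_error(crf_score_path(em0, c(1L, 3L, 1L), p0), "outside")
})

test_that("the log-partition matches enumeration and the shift identity", {
  # uniform single position: log K
  expect_equal(crf_log_partition(matrix(0, 1, 3), crf_params(3L)), log(3),
               tolerance = 1e-12)

  inst <- k2l3_instance()
  bf <- crf_brute_force(inst$emissions, inst$params)
  expect_equal(crf_log_partition(inst$emissions, inst$params),
               bf$log_partition, tolerance = 1e-10)

  # adding c to every emission row adds L*c
  em2 <- inst$emissions + 1.7
  expect_equal(crf_log_partition(em2, inst$params),
               crf_log_partition(inst$emissions, inst$params) + 3 * 1.7,
               tolerance = 1e-10)
})

test_that("log-space recursion survives chain lengths that overflow exp", {
  set.seed(10)
  em <- matrix(rnorm(400 * 3, sd = 5), 400, 3)
  p <- crf_params(3L)
  p$transitions <- matrix(rnorm(9), 3, 3)
  lz <- crf_log_partition(em, p)
  expect_true(is.finite(lz))
  expect_gte(crf_nll(em, rep(1L, 400), p), 0)
})

test_that("the NLL is the log-partition minus the path score, with the right limits", {
  # uniform model: L * log K
  expect_equal(crf_nll(matrix(0, 5, 3), rep(2L, 5), crf_params(3L)), 5 * log(3),
               tolerance = 1e-12)

  inst <- k2l3_instance()
  expect_equal(crf_nll(inst$emissions, c(1L, 1L, 1L), inst$params),
               crf_log_partition(inst$emissions, inst$params) - 6,
               tolerance = 1e-12)

  # dominant true-path emissions drive the loss to zero
  em <- matrix(0, 4, 3)
  y <- c(1L, 3L, 2L, 2L)
  em[cbind(1:4, y)] <- 50
  expect_lt(crf_nll(em, y, crf_params(3L)), 1e-10)

  # non-negativity on random instances
  set.seed(11)
  for (i in 1:25) {
    inst <- random_crf_instance(sample(1:7, 1), sample(2:4, 1))
    y <- sample.int(ncol(inst$emissions), nrow(inst$emissions), replace = TRUE)
    expect_gte(crf_nll(inst$emissions, y, inst$params), 0)
  }
})

test_that("Viterbi decodes the enumerated argmax path with deterministic ties", {
  # zero transitions: per-position argmax
  set.seed(12)
  em <- matrix(rnorm(15), 5, 3)
  v <- crf_viterbi(em, crf_params(3L))
  expect_identical(v$path, apply(em, 1L, which.max))

  inst <- k2l3_instance()
  v <- crf_viterbi(inst$emissions, inst$params)
  expect_identical(v$path, c(1L, 1L, 1L))
  expect_equal(v$score, 6)
  bf <- crf_brute_force(inst$emissions, inst$params)
  expect_equal(v$score, bf$best_score)

  # L = 1: argmax of start + emission + stop
  p <- crf_params(3L)
  p$start <- c(0, 0, 10); p$stop <- c(0, 1, 0)
  expect_identical(crf_viterbi(matrix(c(5, 5, 0), 1, 3), p)$path, 3L)

  # all-zero instance: lowest state index wins every tie
  expect_identical(crf_viterbi(matrix(0, 4, 3), crf_params(3L))$path,
                   rep(1L, 4))
})

test_that("forward recursion, Viterbi and path probabilities agree with the oracle", {
  set.seed(13)
  for (i in 1:40) {
    K <- sample(c(2L, 3L), 1)
    L <- sample(1:6, 1)
    inst <- random_crf_instance(L, K)
    bf <- crf_brute_force(inst$emissions, inst$params)
    # the vectorized oracle scores match the scalar path scorer
    for (r in sample(nrow(bf$paths), min(3, nrow(bf$paths)))) {
      expect_equal(bf$scores[r],
                   crf_score_path(inst$emissions, bf$paths[r, ], inst$params),
                   tolerance = 1e-10)
    }
    expect_equal(crf_log_partition(inst$emissions, inst$params),
                 bf$log_partition, tolerance = 1e-8)
    v <- crf_viterbi(inst$emissions, inst$params)
    expect_equal(v$score, bf$best_score, tolerance = 1e-8)
    expect_equal(v$score, crf_score_path(inst$emissions, v$path, inst$params),
                 tolerance = 1e-10)
    # all-path probabilities sum to one
    expect_equal(sum(exp(bf$scores - bf$log_partition)), 1, tolerance = 1e-8)
  }
  # K = 1: a single path carries everything
  inst1 <- random_crf_instance(4L, 1L)
  bf1 <- crf_brute_force(inst1$emissions, inst1$params)
  expect_identical(nrow(bf1$paths), 1L)
  expect_equal(bf1$log_partition,
               crf_score_path(inst1$emissions, rep(1L, 4), inst1$params))
  expect_error(crf_brute_force(matrix(0, 25, 3), crf_params(3L)), "too large")
})

test_that("NLL gradients equal marginals minus observations and match finite differences", {
  set.seed(14)
  for (i in 1:6) {
    K <- sample(2:4, 1); L <- sample(2:6, 1)
    inst <- random_crf_instance(L, K)
    y <- sample.int(K, L, replace = TRUE)
    g <- crf_nll_grad(inst$emissions, y, inst$params)
    # marginals are a distribution per position
    expect_equal(rowSums(g$marginals), rep(1, L), tolerance = 1e-10)
    h <- 1e-5
    fd_em <- matrix(0, L, K)
    for (a in seq_len(L)) for (b in seq_len(K)) {
      e1 <- inst$emissions; e1[a, b] <- e1[a, b] + h
      e2 <- inst$emissions; e2[a, b] <- e2[a, b] - h
      fd_em[a, b] <- (crf_nll(e1, y, inst$params) - crf_nll(e2, y, inst$params)) / (2 * h)
    }
    expect_equal(g$d_emissions, fd_em, tolerance = 1e-6)
    fd_tr <- matrix(0, K, K)
    for (a in seq_len(K)) for (b in seq_len(K)) {
      p1 <- inst$params; p1$transitions[a, b] <- p1$transitions[a, b] + h
      p2 <- inst$params; p2$transitions[a, b] <- p2$transitions[a, b] - h
      fd_tr[a, b] <- (crf_nll(inst$emissions, y, p1) - crf_nll(inst$emissions, y, p2)) / (2 * h)
    }
    expect_equal(g$d_transitions, fd_tr, tolerance = 1e-6)
  }
})

test_that("transition matrices export as labeled CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  p <- crf_params(3L)
  p$transitions <- matrix(1:9 / 10, 3, 3)
  export_transitions(p, path, ss_alphabet("SS3")$states)
  m <- as.matrix(utils::read.csv(path, row.names = 1))
  expect_identical(rownames(m), c("H", "E", "C"))
  expect_equal(unname(m), unname(p$transitions))
})
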
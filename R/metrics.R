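#' Q accuracy (Q3 / Q8)
#'
#' Percentage of residues whose predicted state matches the true state:
#' `100 * sum_i A_i / N`, where `A_i` counts correct predictions in class i
#' and N is the total residue count.
#'
#' @param y_true,y_pred label strings of equal length.
#' @return numeric percentage in `[0, 100]`.
#' @examples
#' q_accuracy("HEC", "HEE")  # 66.667
#' @export
q_accuracy <- function(y_true, y_pred) {
  a <- strsplit(y_true, "")[[1]]
  b <- strsplit(y_pred, "")[[1]]
  if (length(a) != length(b))
    stop(sprintf("length mismatch: truth has %d residues, prediction %d",
                 length(a), length(b)), call. = FALSE)
  if (length(a) == 0L) return(NA_real_)
  100 * sum(a == b) / length(a)
}

#' Per-class recall
#'
#' For each state of the alphabet, the fraction of residues truly in that
#' state that were predicted correctly (`A_i / N_i`), as a percentage.
#' States absent from the truth get `NA`.
#'
#' @inheritParams q_accuracy
#' @param alphabet an [ss_alphabet()].
#' @return named numeric vector over the alphabet's states.
#' @export
q_class_recall <- function(y_true, y_pred, alphabet) {
  a <- strsplit(y_true, "")[[1]]
  b <- strsplit(y_pred, "")[[1]]
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  vapply(alphabet$states, function(s) {
    n <- sum(a == s)
    if (n == 0L) NA_real_ else 100 * sum(a == s & b == s) / n
  }, numeric(1))
}

#' Extract maximal same-state segments
#'
#' Splits a label string into its maximal runs: ordered segments covering all
#' positions exactly once, where the residues immediately before and after
#' each segment (if any) carry a different state.
#'
#' @param y label string.
#' @return data.frame with columns `state`, `start`, `end` (1-based
#'   inclusive) and `length`; zero rows for the empty string.
#' @examples
#' extract_segments("HHHEEC")
#' @export
extract_segments <- function(y) {
  if (!nzchar(y)) {
    return(data.frame(state = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  r <- rle(strsplit(y, "")[[1]])
  end <- cumsum(r$lengths)
  data.frame(state = r$values,
             start = end - r$lengths + 1L,
             end = end,
             length = r$lengths,
             stringsAsFactors = FALSE)
}

# Per-pair Sov terms for one protein. Returns the summed numerator
# (sum over overlapping same-state pairs of (minov + sigma)/maxov * len(S1))
# and the normalizer N for the requested variant.
sov_terms <- function(y_true, y_pred, variant = c("literal", "sov99")) {
  variant <- match.arg(variant)
  n1 <- nchar(y_true)
  if (n1 != nchar(y_pred))
    stop(sprintf("length mismatch: truth has %d residues, prediction %d",
                 n1, nchar(y_pred)), call. = FALSE)
  s1 <- extract_segments(y_true)
  s2 <- extract_segments(y_pred)
  numer <- 0
  n99 <- 0
  for (i in seq_len(nrow(s1))) {
    partners <- which(s2$state == s1$state[i] &
                        s2$start <= s1$end[i] & s2$end >= s1$start[i])
    if (length(partners) == 0L) {
      n99 <- n99 + s1$length[i]
      next
    }
    for (j in partners) {
      minov <- min(s1$end[i], s2$end[j]) - max(s1$start[i], s2$start[j]) + 1L
      maxov <- max(s1$end[i], s2$end[j]) - min(s1$start[i], s2$start[j]) + 1L
      sigma <- min(maxov - minov, minov,
                   s1$length[i] %/% 2L, s2$length[j] %/% 2L)
      numer <- numer + (minov + sigma) / maxov * s1$length[i]
      n99 <- n99 + s1$length[i]
    }
  }
  N <- if (variant == "literal") n1 else n99
  list(numer = numer, N = N)
}

#' Segment-overlap (Sov) score
#'
#' `Sov = 100 / N * sum over overlapping same-state segment pairs (S1 true,
#' S2 predicted) of (minov + sigma) / maxov * length(S1)`, where `minov` is
#' the length of the overlap, `maxov` the total extent spanned by the pair,
#' and the allowance `sigma = min(maxov - minov, minov, int(len(S1)/2),
#' int(len(S2)/2))`.
#'
#' Two normalizations are available. The default (`"literal"`) takes N as the
#' total number of residues in the sequence; true segments with no
#' overlapping partner then cost credit through the numerator only, which can
#' underscore relative to published SOV values. `"sov99"` uses the 1999
#' normalizer, which counts `length(S1)` once per overlapping pair and adds
#' true segments without a partner.
#'
#' @inheritParams q_accuracy
#' @param variant `"literal"` or `"sov99"`.
#' @return numeric percentage in `[0, 100]` (`NA` for empty input).
#' @examples
#' sov("HHHHHCCC", "HHHCCCCC")  # 80
#' @export
sov <- function(y_true, y_pred, variant = c("literal", "sov99")) {
  tm <- sov_terms(y_true, y_pred, variant)
  if (tm$N == 0) return(NA_real_)
  100 * tm$numer / tm$N
}

#' Dataset-level Sov
#'
#' Micro average: concatenates the per-protein numerators and normalizers
#' (N = total residues across proteins for the literal variant). Macro
#' average: unweighted mean of per-protein Sov scores.
#'
#' @param y_true,y_pred character vectors of label strings (matched order).
#' @param variant `"literal"` or `"sov99"`.
#' @param average `"micro"` or `"macro"`.
#' @return numeric percentage.
#' @export
sov_dataset <- function(y_true, y_pred, variant = c("literal", "sov99"),
                        average = c("micro", "macro")) {
  variant <- match.arg(variant)
  average <- match.arg(average)
  stopifnot(length(y_true) == length(y_pred))
  if (average == "macro") {
    return(mean(mapply(sov, y_true, y_pred, MoreArgs = list(variant = variant)),
                na.rm = TRUE))
  }
  terms <- mapply(function(a, b) unlist(sov_terms(a, b, variant)), y_true, y_pred)
  100 * sum(terms["numer", ]) / sum(terms["N", ])
}
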
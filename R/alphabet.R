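#' Secondary-structure label alphabets
#'
#' The eight-state alphabet follows the DSSP state set: H (alpha-helix),
#' T (beta-turn), S (bend), I (pi-helix), G (3-10 helix), E (beta-strand),
#' B (beta-bridge) and C (other/coil). The three-state alphabet collapses
#' these to H (helix), E (sheet) and C (coil). State order is fixed:
#' the index <-> symbol bijection used everywhere in the package is the
#' order returned in `$states`.
#'
#' @param name `"SS8"` or `"SS3"`.
#' @return A list of class `ss_alphabet` with elements `name`, `states`
#'   (ordered character vector) and `K` (alphabet size).
#' @examples
#' ss_alphabet("SS3")$states  # "H" "E" "C"
#' @export
ss_alphabet <- function(name = c("SS3", "SS8")) {
  name <- match.arg(name)
  states <- switch(name,
    SS8 = c("H", "T", "S", "I", "G", "E", "B", "C"),
    SS3 = c("H", "E", "C"))
  structure(list(name = name, states = states, K = length(states)),
            class = "ss_alphabet")
}

#' @export
print.ss_alphabet <- function(x, ...) {
  cat(sprintf("<ss_alphabet %s: %s>\n", x$name, paste(x$states, collapse = "")))
  invisible(x)
}

#' Validate a label string against an alphabet
#'
#' @param labels character scalar of state symbols.
#' @param alphabet an [ss_alphabet()].
#' @param id record identifier used in error messages.
#' @return invisibly `TRUE`; errors with the record id and 1-based position of
#'   the first offending symbol otherwise.
#' @export
check_labels <- function(labels, alphabet, id = "<labels>") {
  stopifnot(inherits(alphabet, "ss_alphabet"), is.character(labels),
            length(labels) == 1L)
  chars <- strsplit(labels, "")[[1]]
  bad <- which(!(chars %in% alphabet$states))
  if (length(bad) > 0L) {
    stop(sprintf("record '%s': symbol '%s' at position %d is not in alphabet %s",
                 id, chars[bad[1]], bad[1], alphabet$name), call. = FALSE)
  }
  invisible(TRUE)
}

#' The default eight-to-three state reduction table
#'
#' The three-state grouping follows the common DSSP convention:
#' H, G, I -> Helix; E, B -> Sheet; T, S, C -> Coil. The table is exposed so
#' that alternative conventions can be passed to [reduce_ss8_to_ss3()].
#'
#' @return named character vector mapping each SS8 symbol to an SS3 symbol.
#' @export
ss8_to_ss3_map <- function() {
  c(H = "H", G = "H", I = "H", E = "E", B = "E", T = "C", S = "C", C = "C")
}

#' Reduce eight-state labels to three states
#'
#' Positionwise reduction of an SS8 label string to SS3; length is preserved.
#'
#' @param labels character vector of SS8 label strings.
#' @param mapping named character vector over the SS8 states (default
#'   [ss8_to_ss3_map()]); values must lie in the SS3 state set.
#' @return character vector of SS3 label strings, names preserved.
#' @examples
#' reduce_ss8_to_ss3("HGIEBTSC")  # "HHHEECCC"
#' @export
reduce_ss8_to_ss3 <- function(labels, mapping = ss8_to_ss3_map()) {
  ss8 <- ss_alphabet("SS8")
  ss3 <- ss_alphabet("SS3")
  if (!setequal(names(mapping), ss8$states))
    stop("mapping must be named by the eight SS8 states", call. = FALSE)
  if (!all(mapping %in% ss3$states))
    stop("mapping values must be SS3 states (H, E, C)", call. = FALSE)
  for (lab in labels) if (nzchar(lab)) check_labels(lab, ss8)
  from <- paste(names(mapping), collapse = "")
  to <- paste(unname(mapping), collapse = "")
  out <- chartr(from, to, labels)
  names(out) <- names(labels)
  out
}

# Map label strings to integer index vectors (1-based) under an alphabet.
labels_to_idx <- function(labels, alphabet) {
  match(strsplit(labels, "")[[1]], alphabet$states)
}

idx_to_labels <- function(idx, alphabet) {
  paste(alphabet$states[idx], collapse = "")
}
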
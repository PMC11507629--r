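#' @keywords internal
# The 20 standard amino-acid letters plus X for unknowns. Token rows in the
# trainable embedding table follow this order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

# Nonstandard one-letter codes that are mapped to X on input.
NONSTANDARD_AA <- c("B", "Z", "U", "O", "J")

# Cheap structural pre-scan shared by the FASTA readers: the first non-empty
# line must start a record, otherwise report the offending line number.
check_fasta_lines <- function(lines, path) {
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(invisible(TRUE))
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA in '%s': expected a '>' header at line %d",
                 path, first), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read amino-acid sequences from a FASTA file
#'
#' Records are returned in file order as a named character vector (names are
#' the first whitespace-delimited token of each header). Residues are
#' uppercased; the nonstandard letters B, Z, U, O and J — and any other
#' character outside the 20 standard amino acids — are mapped to X with a
#' warning, so sequence and label lengths never diverge.
#'
#' @param path path to a FASTA file.
#' @return named character vector of residue strings (possibly empty).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  check_fasta_lines(lines, path)
  if (!any(nzchar(trimws(lines)))) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- vapply(names(set), function(h) strsplit(trimws(h), "\\s+")[[1]][1], "")
  names(seqs) <- ids
  cleaned <- gsub(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), "X", seqs)
  changed <- which(cleaned != seqs)
  if (length(changed) > 0L) {
    warning(sprintf("nonstandard residue letters mapped to X in %d record(s): %s",
                    length(changed), paste(ids[changed], collapse = ", ")),
            call. = FALSE)
  }
  names(cleaned) <- ids
  cleaned
}

#' Write amino-acid sequences to a FASTA file
#'
#' @param seqs named character vector of residue strings.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read per-residue secondary-structure labels
#'
#' The label file dialect is FASTA-like: a `>` header with the record id,
#' followed by one or more lines of state symbols which are concatenated.
#' Ids must match the paired sequence file exactly (case-sensitive); matching
#' is the caller's responsibility, equal lengths are checked by
#' [load_corpus()].
#'
#' @param path path to a label file.
#' @param alphabet an [ss_alphabet()] the symbols are validated against.
#' @return named character vector of label strings, file order preserved.
#'   A symbol outside the alphabet is an error naming the record and the
#'   1-based position.
#' @export
read_labels <- function(path, alphabet) {
  stopifnot(inherits(alphabet, "ss_alphabet"))
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  check_fasta_lines(lines, path)
  recs <- parse_fasta_like(lines)
  for (i in seq_along(recs)) check_labels(recs[[i]], alphabet, id = names(recs)[i])
  unlist_chr(recs)
}

# Minimal FASTA-like record splitter for the package's own label dialect.
parse_fasta_like <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(list(), character(0)))
  starts <- startsWith(trimws(lines), ">")
  rec_id <- cumsum(starts)
  ids <- vapply(trimws(lines[starts]), function(h)
    strsplit(sub("^>", "", h), "\\s+")[[1]][1], "", USE.NAMES = FALSE)
  bodies <- split(trimws(lines[!starts]), rec_id[!starts])
  out <- stats::setNames(rep(list(""), length(ids)), ids)
  for (j in names(bodies)) out[[as.integer(j)]] <- paste(bodies[[j]], collapse = "")
  out
}

unlist_chr <- function(x) {
  if (length(x) == 0L) return(stats::setNames(character(0), character(0)))
  stats::setNames(unlist(x, use.names = FALSE), names(x))
}

#' Write per-residue labels in the paired FASTA-like dialect
#'
#' @param labels named character vector of label strings.
#' @param path output path.
#' @param width line-wrap width.
#' @return invisibly `path`.
#' @export
write_labels <- function(labels, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(labels)) {
    writeLines(paste0(">", names(labels)[i]), con)
    s <- labels[[i]]
    if (nzchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}
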
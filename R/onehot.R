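#' One-hot encode a DNA sequence
#'
#' Maps a DNA string to a 4 x L matrix with rows A, C, G, T. Columns for
#' unambiguous bases are exact indicators; `N` (unknown base) encodes as
#' 0.25 in every row so that every column sums to one and the encoding
#' carries no spurious base preference.
#'
#' @param seq a character scalar or [Biostrings::DNAString]; alphabet
#'   `A,C,G,T,N`, case-insensitive.
#' @return numeric matrix, 4 rows named `A,C,G,T`, one column per base.
#' @examples
#' one_hot_encode("ACGT")
#' one_hot_encode("AN")
#' @export
one_hot_encode <- function(seq) {
  if (inherits(seq, "DNAString") || inherits(seq, "XString")) {
    seq <- as.character(seq)
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    stop("invalid character '", chars[bad], "' at position ", bad,
         " (alphabet is A,C,G,T,N)")
  }
  L <- length(chars)
  m <- matrix(0, nrow = 4L, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  is_n <- code == 5L
  if (any(!is_n)) {
    m[cbind(code[!is_n], which(!is_n))] <- 1
  }
  if (any(is_n)) m[, is_n] <- 0.25
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot_encode()] for unambiguous columns; columns without a
#' strict maximum row (e.g. the uniform 0.25 encoding of `N`) decode to `N`.
#'
#' @param m 4 x L one-hot matrix.
#' @return character scalar of length-L DNA.
#' @export
one_hot_decode <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 4L)
  if (ncol(m) == 0L) return("")
  top <- apply(m, 2L, max)
  idx <- apply(m, 2L, which.max)
  base <- c("A", "C", "G", "T")[idx]
  # a column that does not dominate (ties, soft values) is unknown
  base[top < 0.5 | colSums(m == matrix(top, 4, ncol(m), byrow = TRUE)) > 1L] <- "N"
  paste(base, collapse = "")
}

#' Encode a set of equal-length sequences into a 4 x L x N array
#'
#' @param seqs character vector or [Biostrings::DNAStringSet] of sequences,
#'   all the same length.
#' @return numeric array with dimensions `c(4, L, length(seqs))`.
#' @export
encode_sequences <- function(seqs) {
  if (inherits(seqs, "DNAStringSet") || inherits(seqs, "XStringSet")) {
    seqs <- as.character(seqs)
  }
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  seqs <- unname(seqs)
  L <- nchar(seqs[1])
  if (!all(nchar(seqs) == L)) stop("sequences must all have the same length")
  x <- array(0, dim = c(4L, L, length(seqs)),
             dimnames = list(c("A", "C", "G", "T"), NULL, NULL))
  for (i in seq_along(seqs)) x[, , i] <- one_hot_encode(seqs[i])
  x
}

#' Reverse complement a position weight matrix
#'
#' @param pwm W x 4 matrix with columns A, C, G, T (rows are motif
#'   positions).
#' @return W x 4 matrix of the motif read on the opposite strand.
#' @export
reverse_complement_pwm <- function(pwm) {
  stopifnot(is.matrix(pwm), ncol(pwm) == 4L)
  out <- pwm[rev(seq_len(nrow(pwm))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- c("A", "C", "G", "T")
  out
}

#' Consensus string of a position weight matrix
#'
#' @param pwm W x 4 matrix with columns A, C, G, T.
#' @return character scalar of the per-position most probable bases.
#' @export
pwm_consensus <- function(pwm) {
  stopifnot(is.matrix(pwm), ncol(pwm) == 4L)
  paste(c("A", "C", "G", "T")[apply(pwm, 1L, which.max)], collapse = "")
}
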
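#' Braid words over the Artin generators
#'
#' A braid word on `n` strands is an ordered sequence of signed generator
#' indices: the letter `k` with `1 <= |k| <= n - 1` denotes the Artin
#' generator `sigma_|k|` when positive (strand `|k|`, counted from the left,
#' passes over strand `|k| + 1`) and its inverse when negative.  The empty
#' sequence is the identity braid.
#'
#' @param letters integer vector of nonzero signed generator indices
#'   (possibly empty).
#' @param n braid index (number of strands), at least 1.
#'
#' @return An object of class `braid_word`: an integer vector with attribute
#'   `n`.
#' @examples
#' b <- braid_word(c(2, -1, -3, 1, 1, 2, -2), n = 4)
#' writhe(b)
#' @seealso [writhe()], [reduce_braid()], [braid_complexity()],
#'   [tn_classify()]
#' @export
braid_word <- function(letters = integer(0), n) {
  if (length(letters)) {
    letters <- as.integer(letters)
    if (anyNA(letters) || any(letters == 0L))
      stop("braid word letters must be nonzero integers")
    if (any(abs(letters) > n - 1L))
      stop("letter index exceeds n - 1 = ", n - 1L)
  } else {
    letters <- integer(0)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("braid index n must be a positive integer")
  structure(letters, n = n, class = "braid_word")
}

#' @export
print.braid_word <- function(x, ...) {
  n <- attr(x, "n")
  if (!length(x)) {
    cat("<braid_word> identity on", n, "strands\n")
  } else {
    cat("<braid_word> n =", n, ":", format_braid(x), "\n")
  }
  invisible(x)
}

#' @rdname braid_word
#' @param x object to test or coerce.
#' @export
is_braid_word <- function(x) inherits(x, "braid_word")

#' @export
`[.braid_word` <- function(x, i) {
  braid_word(unclass(x)[i], n = attr(x, "n"))
}

#' Serialize and parse braid words
#'
#' Braid words are serialized as whitespace-separated signed integers, e.g.
#' `"2 -1 -3 1 1 2 -2"`.
#'
#' @param word a [braid_word()].
#' @return `format_braid()` returns a character scalar; `parse_braid()`
#'   returns a [braid_word()].
#' @examples
#' parse_braid("2 -1 -3 1 1 2 -2", n = 4)
#' @export
format_braid <- function(word) {
  paste(unclass(word), collapse = " ")
}

#' @rdname format_braid
#' @param text character scalar of whitespace-separated signed integers.
#' @param n braid index; defaults to `max(|letter|) + 1`.
#' @export
parse_braid <- function(text, n = NULL) {
  text <- trimws(text)
  letters <- if (nzchar(text)) as.integer(strsplit(text, "\\s+")[[1]]) else integer(0)
  if (is.null(n)) n <- if (length(letters)) max(abs(letters)) + 1L else 2L
  braid_word(letters, n = n)
}

#' Writhe of a braid word
#'
#' The writhe is the sum of the exponents of the generators in the word,
#' i.e. the signed crossing count.  It is invariant under the three braid
#' moves (commutation of distant generators, the braid relation, and
#' cancellation of inverse pairs), and characterises the net twist of the
#' braid.
#'
#' @param word a [braid_word()].
#' @return integer writhe.
#' @examples
#' writhe(braid_word(c(2, -1, -3, 1, 1, 2, -2), n = 4))  # 1
#' @export
writhe <- function(word) {
  sum(sign(unclass(word)))
}

#' Permutation induced by a braid word
#'
#' Returns the permutation of strand start positions to end positions.
#'
#' @param word a [braid_word()].
#' @return integer vector `p` with `p[i]` the final position of the strand
#'   starting at position `i`.
#' @export
braid_permutation <- function(word) {
  n <- attr(word, "n")
  p <- seq_len(n)
  for (l in unclass(word)) {
    i <- abs(l)
    p[c(i, i + 1L)] <- p[c(i + 1L, i)]
  }
  order(p)  # end position of the strand starting at each position
}
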
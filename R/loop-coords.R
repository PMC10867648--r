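#' Dynnikov loop coordinates on the punctured disk
#'
#' An (isotopy class of an) essential closed multicurve in a disk with `n`
#' punctures on the real axis is encoded by `2n - 4` integers
#' `(a_1, ..., a_{n-2}, b_1, ..., b_{n-2})`.  The `a_i` measure the
#' above/below imbalance of strands passing the interior puncture `i + 1`;
#' the `b_i` are half-differences of the crossing numbers of the vertical
#' lines between consecutive punctures.  Braid generators act on these
#' coordinates by an exact piecewise-linear update, which is how all braid
#' invariants in this package are computed.
#'
#' Coordinates are stored as integer-valued doubles; entries grow
#' exponentially under pseudo-Anosov braids, so every update checks against
#' an overflow guard (2^49) beyond which exact integer arithmetic in doubles
#' is no longer certain.
#'
#' @param n puncture count (>= 3 for a nonempty coordinate vector).
#' @param a,b integer vectors of length `n - 2`.
#' @return An object of class `loop_coords` with fields `n`, `a`, `b`.
#' @examples
#' E <- canonical_loop(4)
#' apply_generator(apply_generator(E, 1), -1)  # round-trips to E
#' @export
loop_coords <- function(n, a = numeric(n - 2), b = numeric(n - 2)) {
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 punctures")
  if (length(a) != n - 2L || length(b) != n - 2L)
    stop("a and b must have length n - 2")
  if (any(a != round(a)) || any(b != round(b)))
    stop("loop coordinates must be integers")
  structure(list(n = n, a = as.numeric(a), b = as.numeric(b)),
            class = "loop_coords")
}

#' @export
print.loop_coords <- function(x, ...) {
  cat("<loop_coords> n =", x$n, "\n  a:", x$a, "\n  b:", x$b, "\n")
  invisible(x)
}

# Guard: coordinates beyond 2^49 lose guaranteed integer exactness in doubles.
.loop_overflow_guard <- 2^49

.check_overflow <- function(a, b) {
  if (max(abs(a), abs(b), 0) > .loop_overflow_guard)
    stop("loop coordinates exceeded the exact-integer guard (2^49); ",
         "use the renormalized growth iteration for long products")
  invisible(NULL)
}

# Left-end cap count: the number of strands wrapping the first puncture is
# -b_0 with b_0 = -max_i(|a_i| + b_i^+ + sum_{j<i} b_j).
.b0 <- function(a, b) {
  cb <- c(0, cumsum(b))[seq_along(a)]
  -max(abs(a) + pmax(b, 0) + cb)
}

# Interior update for sigma_j (2 <= j <= n-2) acting on (a,b) of an
# n-punctured disk; s = +1 for the generator, -1 for its inverse.  The
# inverse is the reflection conjugate (a -> -a) of the direct rule.
.upd_interior <- function(a, b, j, s) {
  i1 <- j - 1L; i2 <- j
  if (s < 0) { a[i1] <- -a[i1]; a[i2] <- -a[i2] }
  A1 <- a[i1]; B1 <- b[i1]; A2 <- a[i2]; B2 <- b[i2]
  z <- A1 - A2 + max(B2, 0) + max(-B1, 0)
  a[i1] <- A1 + max(B1, 0) + max(max(B2, 0) - z, 0)
  b[i1] <- B2 - max(z, 0)
  a[i2] <- A2 + min(B2, 0) + min(min(B1, 0) + z, 0)
  b[i2] <- B1 + max(z, 0)
  if (s < 0) { a[i1] <- -a[i1]; a[i2] <- -a[i2] }
  list(a = a, b = b)
}

# Boundary generators are handled by embedding into a disk with one extra
# phantom puncture on each side, where every generator is interior.  The
# embedded outer coordinates are (0, b_0) on the left and (0, b_{n-1}) on
# the right, both determined by the closed-multicurve constraints.
.apply_letter_raw <- function(a, b, l) {
  n <- length(a) + 2L
  if (abs(l) > n - 1L) stop("letter index out of range for ", n, " punctures")
  b0 <- .b0(a, b)
  ae <- c(0, a, 0)
  be <- c(b0, b, -b0 - sum(b))
  r <- .upd_interior(ae, be, abs(l) + 1L, sign(l))
  a <- r$a[2:(n - 1)]
  b <- r$b[2:(n - 1)]
  .check_overflow(a, b)
  list(a = a, b = b)
}

#' Act on loop coordinates with a braid generator or word
#'
#' `apply_generator()` applies a single signed Artin generator to a
#' multicurve given in loop coordinates; `apply_braid()` applies a whole
#' word letter by letter (first letter first).  The update is exact integer
#' arithmetic and each generator is inverted exactly by its negative.
#'
#' @param coords a [loop_coords()] object.
#' @param letter signed generator index with `1 <= |letter| <= n - 1`.
#' @return New `loop_coords`.
#' @export
apply_generator <- function(coords, letter) {
  r <- .apply_letter_raw(coords$a, coords$b, letter)
  loop_coords(coords$n, r$a, r$b)
}

#' @rdname apply_generator
#' @param word a [braid_word()] or plain integer vector of letters acting on
#'   punctures `1..n` of the coordinate disk.
#' @export
apply_braid <- function(coords, word) {
  a <- coords$a; b <- coords$b
  for (l in as.integer(unclass(word))) {
    r <- .apply_letter_raw(a, b, l)
    a <- r$a; b <- r$b
  }
  loop_coords(coords$n, a, b)
}

#' Geometric intersection number with the real axis
#'
#' Reconstructs, from the coordinates alone, the taut (minimal-position)
#' number of transversal intersections of the multicurve with the real axis
#' through the punctures.  The reconstruction recovers, for every interior
#' puncture, the numbers of strands passing above and below and the number
#' of strands capping around it, and adds the side-switching crossings gap
#' by gap.
#'
#' @param coords a [loop_coords()] object.
#' @return Nonnegative integer intersection count.
#' @export
intersections_with_axis <- function(coords) {
  sum(.gap_crossings(coords$a, coords$b))
}

# Per-gap taut crossing counts; returns a vector of length n + 1:
# outer-left gap, the n - 1 interior gaps, outer-right gap.
.gap_crossings <- function(a, b) {
  n <- length(a) + 2L
  b0 <- .b0(a, b)
  bext <- c(b0, b, -b0 - sum(b))
  nu <- -2 * cumsum(bext)[1:(n - 1)]    # vertical-line crossing numbers
  if (any(nu < 0)) stop("invalid loop coordinates (negative line crossings)")
  Au <- lcap <- rcap <- numeric(n)
  rcap[1] <- nu[1] / 2
  lcap[n] <- nu[n - 1] / 2
  if (n > 2) for (k in 2:(n - 1)) {
    bi <- bext[k]
    lcap[k] <- max(bi, 0)
    rcap[k] <- max(-bi, 0)
    base <- nu[k - 1] / 2 - max(bi, 0)
    Au[k] <- base - a[k - 1]
    if (Au[k] < 0 || base + a[k - 1] < 0)
      stop("invalid loop coordinates (negative strand counts)")
  }
  cg <- numeric(n + 1)
  cg[1] <- rcap[1]
  cg[n + 1] <- lcap[n]
  for (k in 1:(n - 1))
    cg[k + 1] <- abs(Au[k] + rcap[k] - Au[k + 1] - lcap[k + 1]) +
      lcap[k] + rcap[k + 1]
  cg
}

#' Canonical multiloop used as a total braid invariant
#'
#' The canonical comparison multicurve lives in a disk with `n + 1`
#' punctures: the `n` braid strands plus one basepoint puncture to their
#' right, which records the framing of the fixed disk boundary.  Its
#' coordinates are `a = 0`, `b = (-1, ..., -1)`: the nested family of loops
#' each enclosing the basepoint together with a right-end block of strands.
#' Two braid words are equal in the braid group if and only if they act
#' identically on this multiloop.
#'
#' @param n braid index.
#' @return A [loop_coords()] object on `n + 1` punctures.
#' @export
canonical_loop <- function(n) {
  loop_coords(n + 1L, a = numeric(n - 1L), b = rep(-1, n - 1L))
}

#' Total invariant of a braid word: action on the canonical multiloop
#'
#' @param word a [braid_word()].
#' @return Numeric vector `c(a, b)` of the image coordinates; equal vectors
#'   (for equal `n`) characterise equal braids.
#' @export
braid_loop_invariant <- function(word) {
  img <- apply_braid(canonical_loop(attr(word, "n")), word)
  c(img$a, img$b)
}

#' Test two braid words for equality in the braid group
#'
#' @param w1,w2 [braid_word()] objects with the same braid index.
#' @return logical.
#' @examples
#' braid_equivalent(parse_braid("1 2 1", 3), parse_braid("2 1 2", 3))
#' @export
braid_equivalent <- function(w1, w2) {
  if (attr(w1, "n") != attr(w2, "n")) return(FALSE)
  identical(braid_loop_invariant(w1), braid_loop_invariant(w2))
}

#' @rdname braid_equivalent
#' @param word a [braid_word()].
#' @export
is_trivial_braid <- function(word) {
  n <- attr(word, "n")
  identical(braid_loop_invariant(word),
            c(numeric(n - 1L), rep(-1, n - 1L)))
}
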
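#' Projection frame for braid extraction
#'
#' Constructs the pair of parallel planes and the orthonormal axes used to
#' reshape a multichain conformation into braid strands with a common
#' height coordinate.  Following the endpoint-plane algorithm: a seed
#' endpoint (1) is chosen; the nearest other-chain endpoint, excluding the
#' seed chain's far end (1'), becomes endpoint 2 and defines the vector
#' r12; the endpoint nearest to the line through 1 and 2 (excluding 1',
#' 2') becomes endpoint 3; the plane through 1, 2, 3 is the base plane and
#' the remaining endpoint farthest from it fixes the parallel top plane.
#' The axes are `z' = n` (plane normal, pointing at the top plane),
#' `x' = r12` normalized, and `y' = z' x x'` (Gram-Schmidt completion,
#' right-handed).
#'
#' Degenerate seeds (collinear endpoints 1, 2, 3) fall back
#' deterministically to the endpoint with the largest distance from the
#' 1-2 line.
#'
#' @param system a [chain_system()] with at least 2 chains.
#' @param seed_endpoint which endpoint seeds the construction: a pair
#'   `(chain, end)` with end 1 (first bead) or 2 (last bead).  The frame,
#'   and hence projection-sensitive quantities such as the isotopy class,
#'   can depend on this choice.
#' @return An object of class `projection_frame`: list with `origin`
#'   (point on the base plane), `axes` (3x3 matrix with columns x', y',
#'   z'), `offset` (plane separation), and `plane_of_chain` (+1 if the
#'   chain's first bead projects to the base plane, -1 otherwise).
#' @export
find_projection_frame <- function(system, seed_endpoint = c(1L, 1L)) {
  M <- n_chains(system)
  if (M < 2L) stop("need at least two chains")
  sys <- unwrap_system(system)
  ends <- do.call(rbind, lapply(sys$chains, function(ch)
    rbind(ch[1, ], ch[nrow(ch), ])))          # rows: (c1 start, c1 end, c2 start, ...)
  echain <- rep(seq_len(M), each = 2L)
  eend <- rep(1:2, M)
  id1 <- which(echain == seed_endpoint[1] & eend == seed_endpoint[2])
  id1p <- which(echain == seed_endpoint[1] & eend != seed_endpoint[2])
  p1 <- ends[id1, ]
  cand <- setdiff(seq_len(2 * M), c(id1, id1p))
  d2 <- rowSums(sweep(ends[cand, , drop = FALSE], 2, p1)^2)
  id2 <- cand[which.min(d2)]
  p2 <- ends[id2, ]
  id2p <- which(echain == echain[id2] & seq_len(2 * M) != id2)
  r12 <- p2 - p1
  cand3 <- setdiff(seq_len(2 * M), c(id1, id1p, id2, id2p))
  if (!length(cand3)) cand3 <- c(id2p, id1p)   # two-chain systems
  u <- r12 / sqrt(sum(r12^2))
  dl <- vapply(cand3, function(k) {
    v <- ends[k, ] - p1
    sqrt(max(0, sum(v^2) - sum(v * u)^2))     # distance to the 1-2 line
  }, numeric(1))
  if (max(dl) < 1e-9) stop("all endpoints collinear; projection plane undefined")
  # nearest endpoint strictly off the 1-2 line (collinear ones define no plane)
  id3 <- cand3[which.min(replace(dl, dl < 1e-9, Inf))]
  p3 <- ends[id3, ]
  nrm <- .cross3(r12, p3 - p1)
  nrm <- nrm / sqrt(sum(nrm^2))
  rest <- setdiff(seq_len(2 * M), c(id1, id2, id3))
  dists <- vapply(rest, function(k) sum((ends[k, ] - p1) * nrm), numeric(1))
  far <- rest[which.max(abs(dists))]
  offset <- dists[which.max(abs(dists))]
  if (offset < 0) { nrm <- -nrm; offset <- -offset }
  xax <- u
  zax <- nrm
  yax <- .cross3(zax, xax)
  axes <- cbind(xax, yax, zax)
  # assign each chain's ends to the nearer plane
  z_of <- as.numeric((ends - matrix(p1, 2 * M, 3, byrow = TRUE)) %*% zax)
  plane_of_chain <- vapply(seq_len(M), function(c) {
    zs <- z_of[echain == c]
    if (abs(zs[1] - 0) + abs(zs[2] - offset) <=
        abs(zs[1] - offset) + abs(zs[2] - 0)) 1 else -1
  }, numeric(1))
  structure(list(origin = p1, axes = axes, offset = offset,
                 plane_of_chain = plane_of_chain),
            class = "projection_frame")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.projection_frame <- function(x, ...) {
  cat("<projection_frame> offset", signif(x$offset, 5), "\n")
  print(signif(x$axes, 4))
  invisible(x)
}

#' Extract a braid word from a multichain conformation
#'
#' Transforms the conformation into the projection frame, orients every
#' chain from the base plane to the top plane, resamples each strand's
#' lateral position at equally spaced heights (linear interpolation along
#' the piecewise-linear path), and records a generator whenever two
#' laterally adjacent strands exchange order in x' between consecutive
#' heights.  Within a height interval the strand paths are linear, so all
#' exchange events are located exactly and emitted in height order; the
#' sign of each generator is read from the front/back (y') order of the
#' two strands at the exchange: the strand arriving from the left passing
#' in front gives a positive generator.  Exact lateral ties are broken by
#' a deterministic 1e-9 sigma perturbation.
#'
#' Chains whose height coordinate backtracks are monotonized with a
#' running maximum before resampling; frames where backtracking exceeds 5%
#' of a chain's contour are flagged in the `backtrack` attribute.
#'
#' @param system a [chain_system()].
#' @param frame a [find_projection_frame()] result; computed when `NULL`.
#' @param n_slices number of height slices; default 10 beads-per-chain.
#' @return A [braid_word()] on `n_chains(system)` strands with attribute
#'   `strand_order` (chains left to right at the base plane) and
#'   `backtrack` (fraction of non-monotone height per chain).
#' @examples
#' sys <- make_braided_bundle(parse_braid("1 2", 4), N = 40, seed = 1)
#' extract_braid(sys)
#' @export
extract_braid <- function(system, frame = NULL, n_slices = NULL) {
  M <- n_chains(system)
  if (is.null(frame)) frame <- find_projection_frame(system)
  ev <- .extract_events(system, frame, n_slices)
  out <- braid_word(ev$letters, n = M)
  attr(out, "strand_order") <- ev$strand_order
  attr(out, "backtrack") <- ev$backtrack
  if (any(ev$backtrack > 0.05)) attr(out, "backtrack_flag") <- TRUE
  out
}
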
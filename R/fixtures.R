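#' Ideal freely-jointed random-walk chains
#'
#' Generates `M` independent random walks of `N` beads with fixed bond
#' length `b` and uniformly random bond directions; chain starting points
#' are spread far apart so the chains do not overlap systematically.
#' Deterministic for a fixed seed.
#'
#' @param M number of chains.
#' @param N beads per chain.
#' @param b bond length (sigma).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A [chain_system()].
#' @examples
#' make_random_walks(2, 10, seed = 1)
#' @export
make_random_walks <- function(M, N, b = 0.965, seed = NULL) {
  if (b <= 0) stop("b must be positive")
  if (!is.null(seed)) set.seed(seed)
  chains <- lapply(seq_len(M), function(c) {
    z <- stats::runif(N - 1, -1, 1)
    phi <- stats::runif(N - 1, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    steps <- b * cbind(r * cos(phi), r * sin(phi), z)
    start <- c(10 * c, 0, 0)
    cs <- apply(steps, 2, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, nrow = 1)
    rbind(start, sweep(cs, 2, start, "+"))
  })
  chain_system(chains)
}

#' Hand-built conformations realizing each circuit topology motif
#'
#' Builds a bead arrangement whose contact detection (at the default
#' cutoffs) yields exactly two contacts, classified as the requested motif.
#' Beads sit on a sparse grid (spacing 2 sigma along chains, 3 sigma
#' between chains) except the four contact sites, which are moved to
#' isolated contact zones at distance 1 sigma.
#'
#' @param label one of [motif_classes].
#' @return list with `system` (a [chain_system()]) and `expected_contacts`
#'   (data.frame of the two designed contacts in canonical order).
#' @examples
#' fx <- make_motif_system("T2")
#' classify_pair(fx$expected_contacts[1, ], fx$expected_contacts[2, ])
#' @export
make_motif_system <- function(label) {
  label <- match.arg(label, motif_classes)
  spec <- switch(label,
    S  = list(M = 1, A = c(1, 1, 1, 4),  B = c(1, 7, 1, 10)),
    P  = list(M = 1, A = c(1, 1, 1, 10), B = c(1, 4, 1, 7)),
    X  = list(M = 1, A = c(1, 1, 1, 7),  B = c(1, 4, 1, 10)),
    I2 = list(M = 2, A = c(1, 1, 1, 4),  B = c(2, 1, 2, 4)),
    L2 = list(M = 2, A = c(1, 1, 2, 1),  B = c(1, 4, 2, 4)),
    T2 = list(M = 2, A = c(1, 1, 1, 5),  B = c(1, 3, 2, 1)),
    I3 = list(M = 3, A = c(1, 1, 1, 4),  B = c(2, 1, 3, 1)),
    T3 = list(M = 3, A = c(1, 1, 2, 1),  B = c(1, 4, 3, 1)),
    I4 = list(M = 4, A = c(1, 1, 2, 1),  B = c(3, 1, 4, 1)))
  N <- 10L
  chains <- lapply(seq_len(spec$M), function(c)
    cbind(2 * (seq_len(N) - 1), 30 * c, 0))
  place <- function(chains, site, where) {
    chains[[site[1]]][site[2], ] <- where
    chains
  }
  for (k in 1:2) {
    ct <- if (k == 1) spec$A else spec$B
    zone <- c(-10, -10 * k, 0)
    chains <- place(chains, ct[1:2], zone)
    chains <- place(chains, ct[3:4], zone + c(1, 0, 0))
  }
  sys <- chain_system(chains)
  exp_ct <- data.frame(chain1 = c(spec$A[1], spec$B[1]),
                       bead1 = c(spec$A[2], spec$B[2]),
                       chain2 = c(spec$A[3], spec$B[3]),
                       bead2 = c(spec$A[4], spec$B[4]))
  list(system = sys, expected_contacts = exp_ct, label = label)
}

#' Braided bundle conformations with a prescribed braid word
#'
#' Builds `M` chains running between two parallel planes and realizing the
#' crossings of `word` in order: in the band assigned to each letter the
#' two strands at the affected adjacent positions exchange laterally with
#' smooth cubic easing, the strand coming from the left passing in front
#' (+y) for a positive generator and behind for a negative one.  Chains
#' are resampled to `N` beads by arclength.
#'
#' @param word a [braid_word()]; its braid index must equal `M`.
#' @param M number of chains.
#' @param N beads per chain.
#' @param pitch height of each crossing band (sigma).
#' @param sep lateral strand spacing (sigma).
#' @param jitter small random lateral perturbation (sigma) breaking exact
#'   degeneracies; seeded.
#' @param seed integer seed for the jitter.
#' @return A [chain_system()] whose braid content is `word`.
#' @examples
#' sys <- make_braided_bundle(parse_braid("1 2", 4), M = 4, N = 40)
#' @export
make_braided_bundle <- function(word, M = attr(word, "n"), N = 30L,
                                pitch = 2, sep = 2, jitter = 0.02,
                                seed = NULL) {
  if (attr(word, "n") != M) stop("braid index of word must equal M")
  if (!is.null(seed)) set.seed(seed)
  letters <- as.integer(unclass(word))
  nb <- length(letters) + 2L           # margin band top and bottom
  res <- 24L                           # polyline points per band
  pos <- seq_len(M)                    # pos[strand] = current position
  paths <- lapply(seq_len(M), function(s)
    matrix(c(sep * (pos[s] - 1), 0, 0), ncol = 3))
  zband <- function(k, t) (k - 1 + t) * pitch
  tgrid <- seq(0, 1, length.out = res + 1L)[-1]
  band <- 1L
  add_straight <- function(paths, band) {
    for (s in seq_len(M)) {
      seg <- cbind(sep * (pos[s] - 1), 0, zband(band, tgrid))
      paths[[s]] <- rbind(paths[[s]], seg)
    }
    paths
  }
  paths <- add_straight(paths, band); band <- band + 1L
  for (l in letters) {
    q <- abs(l)
    s_left <- which(pos == q)       # strand currently at position q
    s_right <- which(pos == q + 1L)
    ease <- 3 * tgrid^2 - 2 * tgrid^3
    for (s in seq_len(M)) {
      if (s == s_left) {
        x <- sep * (q - 1 + ease)
        y <- sign(l) * 0.5 * sin(pi * tgrid)
      } else if (s == s_right) {
        x <- sep * (q - ease)
        y <- -sign(l) * 0.5 * sin(pi * tgrid)
      } else {
        x <- rep(sep * (pos[s] - 1), res)
        y <- rep(0, res)
      }
      paths[[s]] <- rbind(paths[[s]], cbind(x, y, zband(band, tgrid)))
    }
    pos[c(s_left, s_right)] <- c(q + 1L, q)
    band <- band + 1L
  }
  paths <- add_straight(paths, band)
  chains <- lapply(paths, function(p) {
    p <- .resample_arclength(p, N)
    p[, 1] <- p[, 1] + jitter * stats::rnorm(N)
    p[, 2] <- p[, 2] + jitter * stats::rnorm(N)
    p
  })
  chain_system(chains)
}

# resample a polyline to exactly N points equally spaced in arclength
.resample_arclength <- function(p, N) {
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 1e-12)
  p <- p[keep, , drop = FALSE]; s <- s[keep]
  tgt <- seq(0, s[length(s)], length.out = N)
  apply(p, 2, function(col) stats::approx(s, col, xout = tgt)$y)
}
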
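# Independent oracles used across the suite.
#
# 1. A geometric polyline oracle for the punctured disk: multicurves are
#    polylines, braid generators act as radially tapered half-twist
#    homeomorphisms, and taut intersection counts are obtained by removing
#    puncture-free bigons.  Everything is computed from coordinates-free
#    geometry, independent of the loop-coordinate code it checks.
# 2. A breadth-first-search oracle over the braid rewriting system
#    (commutation, braid relation, insertion/cancellation of inverse pairs)
#    for minimal word length.
# 3. A brute-force all-pairs distance scan for contact detection.

oracle_resample <- function(pts, closed, h = 0.02) {
  if (closed) pts <- rbind(pts, pts[1, ])
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  out <- vector("list", nrow(pts) - 1)
  for (k in seq_len(nrow(pts) - 1)) {
    m <- max(1L, ceiling(d[k] / h))
    t <- seq(0, 1, length.out = m + 1)[-(m + 1)]
    out[[k]] <- cbind(pts[k, 1] + t * (pts[k + 1, 1] - pts[k, 1]),
                      pts[k, 2] + t * (pts[k + 1, 2] - pts[k, 2]))
  }
  res <- do.call(rbind, out)
  if (!closed) res <- rbind(res, pts[nrow(pts), ])
  res
}

oracle_twist <- function(pts, center_x, sgn, r0 = 0.55, r1 = 1.5) {
  dx <- pts[, 1] - center_x
  dy <- pts[, 2]
  r <- sqrt(dx^2 + dy^2)
  th <- sgn * ifelse(r <= r0, pi, pmax(0, pi * (r1 - r) / (r1 - r0)))
  cbind(center_x + dx * cos(th) - dy * sin(th),
        dx * sin(th) + dy * cos(th))
}

oracle_apply_word <- function(curve, word, n, h = 0.015) {
  for (l in word) {
    stopifnot(abs(l) >= 1, abs(l) <= n - 1)
    curve <- lapply(curve, function(cp) {
      cp$pts <- oracle_twist(oracle_resample(cp$pts, cp$closed, h),
                             abs(l) + 0.5, sign(l))
      cp
    })
  }
  curve
}

.oracle_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (poly[j, 1] - poly[i, 1]) * (py - yi) / (yj - yi) + poly[i, 1]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

.oracle_min_crossings_comp <- function(pts, closed, line, punct) {
  np <- nrow(pts)
  f <- switch(line$type, h = pts[, 2], v = pts[, 1] - line$x,
              vh = pts[, 1] - line$x)
  f[f == 0] <- 1e-12
  crossings <- list()
  idx_last <- if (closed) np else np - 1L
  for (k in seq_len(idx_last)) {
    k2 <- if (k == np) 1L else k + 1L
    if (f[k] * f[k2] < 0) {
      t <- f[k] / (f[k] - f[k2])
      x <- pts[k, 1] + t * (pts[k2, 1] - pts[k, 1])
      y <- pts[k, 2] + t * (pts[k2, 2] - pts[k, 2])
      if (line$type == "vh" && sign(y) != line$side) next
      crossings[[length(crossings) + 1]] <- list(k = k, x = x, y = y)
    }
  }
  if (length(crossings) < 2) return(length(crossings))
  arc_pts <- function(u, v) {
    cu <- crossings[[u]]; cv <- crossings[[v]]
    if (u < v) ks <- if (cu$k + 1 <= cv$k) (cu$k + 1):cv$k else integer(0)
    else ks <- c(if (cu$k + 1 <= np) (cu$k + 1):np else integer(0),
                 if (cv$k >= 1) 1:cv$k else integer(0))
    rbind(c(cu$x, cu$y), pts[ks, , drop = FALSE], c(cv$x, cv$y))
  }
  removable <- function(u, v) {
    cu <- crossings[[u]]; cv <- crossings[[v]]
    if (line$type == "h") {
      x1 <- min(cu$x, cv$x); x2 <- max(cu$x, cv$x)
      if (any(punct[, 1] > x1 + 1e-9 & punct[, 1] < x2 - 1e-9)) return(FALSE)
    }
    poly <- arc_pts(u, v)
    for (q in seq_len(nrow(punct))) {
      if (.oracle_point_in_poly(punct[q, 1], punct[q, 2] + 1e-9, poly) ||
          .oracle_point_in_poly(punct[q, 1], punct[q, 2] - 1e-9, poly))
        return(FALSE)
    }
    TRUE
  }
  alive <- rep(TRUE, length(crossings))
  repeat {
    ids <- which(alive)
    m <- length(ids)
    if (m < 2) break
    pairs <- cbind(seq_len(m - 1), 2:m)
    if (closed) pairs <- rbind(pairs, c(m, 1))
    hit <- FALSE
    for (pr in seq_len(nrow(pairs))) {
      u <- ids[pairs[pr, 1]]; v <- ids[pairs[pr, 2]]
      if (removable(u, v)) { alive[c(u, v)] <- FALSE; hit <- TRUE; break }
    }
    if (!hit) break
  }
  sum(alive)
}

oracle_min_crossings <- function(curve, line, punct) {
  sum(vapply(curve, function(cp)
    .oracle_min_crossings_comp(cp$pts, cp$closed, line, punct), numeric(1)))
}

# Dynnikov-style coordinate measurement from geometry
oracle_measure <- function(curve, n) {
  punct <- cbind(1:n, 0)
  nu <- vapply(1:(n - 1), function(i)
    oracle_min_crossings(curve, list(type = "v", x = i + 0.5), punct), numeric(1))
  a <- vapply(1:(n - 2), function(i) {
    ab <- oracle_min_crossings(curve, list(type = "vh", x = i + 1, side = 1), punct)
    be <- oracle_min_crossings(curve, list(type = "vh", x = i + 1, side = -1), punct)
    (be - ab) / 2
  }, numeric(1))
  b <- (nu[1:(n - 2)] - nu[2:(n - 1)]) / 2
  list(a = a, b = b, nu = nu,
       axis = oracle_min_crossings(curve, list(type = "h"), punct))
}

oracle_round_loop <- function(i, j, ry = 0.35) {
  cx <- (i + j) / 2; rx <- (j - i) / 2 + 0.35
  t <- seq(0, 2 * pi, length.out = 200)[-200]
  list(pts = cbind(cx + rx * cos(t), ry * sin(t)), closed = TRUE)
}

# taut crossing count of the image of the central wall (boundary-anchored
# transversal arc through the middle gap), the geometric ground truth for
# the complexity count
oracle_wall_count <- function(word, n) {
  cg <- ceiling((n - 1) / 2)
  wall <- list(list(pts = cbind(rep(cg + 0.5, 2), c(2.2, -2.2)), closed = FALSE))
  img <- oracle_apply_word(wall, word, n, h = 0.01)
  oracle_min_crossings(img, list(type = "h"), cbind(1:n, 0))
}

## ---- BFS rewriting oracle for minimal braid length ----

bfs_min_length <- function(letters, n, visit_cap = 60000L) {
  key <- function(w) paste0("w", paste(w, collapse = " "))
  neighbours <- function(w) {
    out <- list()
    L <- length(w)
    if (L >= 2) for (i in seq_len(L - 1)) {
      if (w[i] == -w[i + 1]) out[[length(out) + 1]] <- w[-c(i, i + 1)]
      if (abs(abs(w[i]) - abs(w[i + 1])) >= 2)
        out[[length(out) + 1]] <- replace(w, c(i, i + 1), w[c(i + 1, i)])
    }
    if (L >= 3) for (i in seq_len(L - 2)) {
      tri <- w[i:(i + 2)]
      s <- sign(tri[1])
      if (all(sign(tri) == s)) {
        ii <- abs(tri)
        if (ii[1] == ii[3] && abs(ii[2] - ii[1]) == 1)
          out[[length(out) + 1]] <- replace(w, i:(i + 2), s * ii[c(2, 1, 2)])
      }
    }
    cap <- length(letters) + 2L
    if (L + 2 <= cap) for (i in 0:L) for (g in c(seq_len(n - 1), -seq_len(n - 1))) {
      out[[length(out) + 1]] <- append(w, c(g, -g), after = i)
    }
    out
  }
  seen <- new.env(hash = TRUE)
  queue <- vector("list", 1024L)
  queue[[1]] <- as.integer(letters)
  qhead <- 1L; qtail <- 1L
  assign(key(letters), TRUE, envir = seen)
  best <- length(letters)
  count <- 0L
  while (qhead <= qtail && count < visit_cap) {
    w <- queue[[qhead]]
    qhead <- qhead + 1L
    count <- count + 1L
    best <- min(best, length(w))
    if (best == 0L) break
    for (nb in neighbours(w)) {
      k <- key(nb)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        qtail <- qtail + 1L
        queue[[qtail]] <- nb
      }
    }
  }
  best
}

## ---- random legal rewriting moves (word equivalence generator) ----

random_rewrite <- function(word, moves = 100L) {
  n <- attr(word, "n")
  w <- as.integer(unclass(word))
  for (k in seq_len(moves)) {
    L <- length(w)
    choices <- list()
    if (L >= 2) for (i in seq_len(L - 1)) {
      if (abs(abs(w[i]) - abs(w[i + 1])) >= 2)
        choices[[length(choices) + 1]] <- list("swap", i)
      if (w[i] == -w[i + 1])
        choices[[length(choices) + 1]] <- list("del", i)
    }
    if (L >= 3) for (i in seq_len(L - 2)) {
      tri <- w[i:(i + 2)]
      s <- sign(tri[1])
      if (all(sign(tri) == s) && abs(tri)[1] == abs(tri)[3] &&
          abs(abs(tri)[2] - abs(tri)[1]) == 1)
        choices[[length(choices) + 1]] <- list("braid", i)
    }
    for (i in 0:L) choices[[length(choices) + 1]] <- list("ins", i)
    ch <- choices[[sample.int(length(choices), 1)]]
    i <- ch[[2]]
    w <- switch(ch[[1]],
      swap = replace(w, c(i, i + 1), w[c(i + 1, i)]),
      del = w[-c(i, i + 1)],
      braid = replace(w, i:(i + 2), sign(w[i]) * abs(w[c(i + 1, i, i + 1)])),
      ins = { g <- sample(c(seq_len(n - 1), -seq_len(n - 1)), 1)
              append(w, c(g, -g), after = i) })
  }
  braid_word(w, n)
}

## ---- brute-force contact oracle ----

brute_contacts <- function(system, rc = 1.4, min_sep = 3L) {
  fl <- braidct:::.flatten(system)
  out <- NULL
  nb <- nrow(fl$xyz)
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    d <- fl$xyz[i, ] - fl$xyz[j, ]
    if (!is.null(system$box)) d <- d - system$box * round(d / system$box)
    dist <- sqrt(sum(d^2))
    same <- fl$chain[i] == fl$chain[j]
    ok <- if (same) dist <= rc && abs(fl$bead[i] - fl$bead[j]) >= min_sep
          else dist <= rc
    if (ok) out <- rbind(out, data.frame(chain1 = fl$chain[i], bead1 = fl$bead[i],
                                         chain2 = fl$chain[j], bead2 = fl$bead[j]))
  }
  if (is.null(out)) return(data.frame(chain1 = integer(0), bead1 = integer(0),
                                      chain2 = integer(0), bead2 = integer(0)))
  out[order(out$chain1, out$bead1, out$chain2, out$bead2), , drop = FALSE]
}
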
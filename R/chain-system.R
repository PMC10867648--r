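#' Multichain bead conformations
#'
#' A `chain_system` holds the ordered 3D bead positions of one or more
#' polymer chains, per-bead masses, and an optional periodic cubic box.
#' Chains are oriented from their first to their last bead; all geometric
#' routines in the package respect this convention.
#'
#' @param chains list of numeric matrices, one per chain, each with 3
#'   columns (x, y, z) and at least 2 rows.
#' @param masses per-bead masses: either a single number, or a list of
#'   vectors parallel to `chains`.  Defaults to unit mass.
#' @param box optional periodic box: a single side length (cubic) or a
#'   3-vector.
#' @return An object of class `chain_system`.
#' @examples
#' sys <- chain_system(list(cbind(0:3, 0, 0), cbind(0:3, 1, 0)))
#' n_beads(sys)
#' @export
chain_system <- function(chains, masses = 1, box = NULL) {
  if (!is.list(chains) || !length(chains)) stop("chains must be a nonempty list")
  chains <- lapply(chains, function(ch) {
    ch <- as.matrix(ch)
    if (ncol(ch) != 3L) stop("each chain needs 3 coordinate columns")
    if (nrow(ch) < 2L) stop("each chain needs at least 2 beads")
    if (!all(is.finite(ch))) stop("bead positions must be finite")
    storage.mode(ch) <- "double"
    dimnames(ch) <- NULL
    ch
  })
  if (!is.list(masses)) {
    masses <- lapply(chains, function(ch) rep(as.numeric(masses[1]), nrow(ch)))
  } else if (length(masses) != length(chains)) {
    stop("masses list must parallel chains")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) == 1L) box <- rep(box, 3L)
    if (length(box) != 3L || any(box <= 0)) stop("box must be positive lengths")
  }
  structure(list(chains = chains, masses = masses, box = box),
            class = "chain_system")
}

#' @export
print.chain_system <- function(x, ...) {
  cat("<chain_system>", n_chains(x), "chains,",
      paste(vapply(x$chains, nrow, integer(1)), collapse = "+"), "beads",
      if (!is.null(x$box)) paste0("(periodic box ",
                                  paste(signif(x$box, 4), collapse = " x "), ")"),
      "\n")
  invisible(x)
}

#' @rdname chain_system
#' @param system a `chain_system`.
#' @export
n_chains <- function(system) length(system$chains)

#' @rdname chain_system
#' @export
n_beads <- function(system) sum(vapply(system$chains, nrow, integer(1)))

# flatten to a bead matrix with chain/bead bookkeeping
.flatten <- function(system) {
  nb <- vapply(system$chains, nrow, integer(1))
  list(xyz = do.call(rbind, system$chains),
       chain = rep(seq_along(nb), nb),
       bead = unlist(lapply(nb, seq_len)),
       mass = unlist(system$masses))
}

#' Apply a rigid-body transform to a chain system
#'
#' @param system a [chain_system()].
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation length-3 shift (default zero).
#' @return The transformed `chain_system` (box dropped, since an arbitrary
#'   rotation is incompatible with an axis-aligned periodic box).
#' @export
transform_system <- function(system, rotation = diag(3), translation = c(0, 0, 0)) {
  chains <- lapply(system$chains, function(ch)
    sweep(ch %*% t(rotation), 2, translation, "+"))
  chain_system(chains, system$masses, box = NULL)
}

#' Unwrap periodic images along each chain
#'
#' Rebuilds each chain from its bond vectors under the minimum-image
#' convention, so that bonded beads are geometrically adjacent; the first
#' bead of each chain is kept in place.  A no-op for systems without a box.
#'
#' @param system a [chain_system()].
#' @return An unwrapped `chain_system` (box retained for reference).
#' @export
unwrap_system <- function(system) {
  if (is.null(system$box)) return(system)
  L <- system$box
  chains <- lapply(system$chains, function(ch) {
    d <- diff(ch)
    d <- d - sweep(round(sweep(d, 2, L, "/")), 2, L, "*")
    rbind(ch[1, , drop = FALSE],
          sweep(apply(d, 2, cumsum), 2, ch[1, ], "+"))
  })
  chain_system(chains, system$masses, box = system$box)
}

#' Read and write trajectory frames in the LAMMPS dump text dialect
#'
#' Frames are stored in the plain-text dump layout
#' (`ITEM: TIMESTEP` / `ITEM: NUMBER OF ATOMS` / `ITEM: BOX BOUNDS` /
#' `ITEM: ATOMS id mol x y z`), so externally produced dumps with those
#' columns can be read back.
#'
#' @param trajectory a list of [chain_system()] frames, a single
#'   `chain_system`, or a `trajectory` object with `frames` and `times`.
#' @param path file path.
#' @return `write_dump()` returns `path` invisibly; `read_dump()` returns a
#'   `trajectory` object (list with `frames` and `times`).
#' @export
write_dump <- function(trajectory, path) {
  frames <- .as_frames(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames$frames)) {
    sys <- frames$frames[[k]]
    fl <- .flatten(sys)
    box <- if (is.null(sys$box)) rep(max(abs(fl$xyz)) + 1, 3) else sys$box
    writeLines(c("ITEM: TIMESTEP", format(frames$times[k]),
                 "ITEM: NUMBER OF ATOMS", format(nrow(fl$xyz)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 paste(0, box[1]), paste(0, box[2]), paste(0, box[3]),
                 "ITEM: ATOMS id mol x y z"), con)
    writeLines(sprintf("%d %d %.10g %.10g %.10g", seq_len(nrow(fl$xyz)),
                       fl$chain, fl$xyz[, 1], fl$xyz[, 2], fl$xyz[, 3]), con)
  }
  invisible(path)
}

.as_frames <- function(trajectory) {
  if (inherits(trajectory, "chain_system"))
    return(list(frames = list(trajectory), times = 0))
  if (inherits(trajectory, "trajectory")) return(trajectory)
  list(frames = trajectory, times = seq_along(trajectory) - 1)
}

#' @rdname write_dump
#' @param periodic logical: attach the box read from the dump to the frames.
#' @export
read_dump <- function(path, periodic = TRUE) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP")) stop("malformed dump at line ", i)
    tm <- as.numeric(lines[i + 1L])
    natoms <- as.integer(lines[i + 3L])
    box <- vapply(lines[(i + 5L):(i + 7L)], function(l) {
      v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
      v[2] - v[1]
    }, numeric(1))
    hdr <- lines[i + 8L]
    cols <- strsplit(sub("^ITEM: ATOMS ", "", hdr), "\\s+")[[1]]
    need <- match(c("id", "mol", "x", "y", "z"), cols)
    if (anyNA(need)) stop("dump must carry columns: id mol x y z")
    rows <- lines[(i + 9L):(i + 8L + natoms)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(rows), "\\s+"))),
                nrow = natoms, byrow = TRUE)
    m <- m[order(m[, need[1]]), , drop = FALSE]
    mol <- m[, need[2]]
    chains <- unname(lapply(split(seq_len(natoms), mol), function(idx)
      m[idx, need[3:5], drop = FALSE]))
    frames[[length(frames) + 1L]] <-
      chain_system(unname(chains), box = if (periodic) box else NULL)
    times <- c(times, tm)
    i <- i + 9L + natoms
  }
  structure(list(frames = frames, times = times), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$frames), "frames, time",
      signif(min(x$times), 4), "..", signif(max(x$times), 4), "\n")
  invisible(x)
}
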
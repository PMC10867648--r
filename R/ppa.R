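#' Primitive path analysis
#'
#' Contracts the contour of every chain while holding its two endpoints
#' fixed in space, exposing the entanglement skeleton of the multichain
#' system.  During the contraction all intrachain interactions are
#' disabled except the backbone FENE bonds, which pull each contour taut,
#' while a purely repulsive (truncated, shifted) pair term acts between
#' beads of different chains so that strands cannot pass through one
#' another.  The energy is minimized by damped steepest descent with the
#' per-bead displacement capped at `step_cap` per iteration; the cap is
#' far below the excluded-volume core and is what guarantees that no
#' strand passage can occur between iterations.
#'
#' The result is a set of contiguous straight segments linked by sharp
#' kinks where chains press on each other.  Isolated chains contract to
#' the straight segment joining their endpoints.
#'
#' @param system a [chain_system()].
#' @param config a [sim_config()] supplying the FENE constants.
#' @param tol convergence threshold on the maximum residual force
#'   (epsilon/sigma).
#' @param max_iter iteration cap; on hitting it the best iterate is
#'   returned with `converged = FALSE` and a warning.
#' @param step_cap maximum per-bead displacement per iteration (sigma).
#' @return The contracted [chain_system()] with attributes `converged`,
#'   `iterations` and `max_force`.
#' @examples
#' sys <- make_random_walks(1, 10, seed = 2)
#' pp <- primitive_paths(sys)
#' @export
primitive_paths <- function(system, config = sim_config(), tol = 1e-4,
                            max_iter = 100000L, step_cap = 0.01) {
  system <- unwrap_system(system)
  sa <- .sys_args(system)
  r <- kg_ppa(sa$x, sa$chain, sa$box, config$fene_K, config$fene_R0,
              tol, as.integer(max_iter), step_cap)
  if (!r$converged)
    warning("primitive path contraction stopped at max_iter with residual ",
            signif(r$max_force, 3))
  nb <- vapply(system$chains, nrow, integer(1))
  split_idx <- rep(seq_along(nb), nb)
  out <- chain_system(unname(lapply(split(seq_len(nrow(r$x)),
                                          factor(split_idx, levels = seq_along(nb))),
                                    function(ii) r$x[ii, , drop = FALSE])),
                      system$masses, box = system$box)
  attr(out, "converged") <- r$converged
  attr(out, "iterations") <- r$iterations
  attr(out, "max_force") <- r$max_force
  out
}

#' Contour length of each chain
#'
#' @param system a [chain_system()].
#' @return Numeric vector of per-chain contour lengths (after unwrapping).
#' @export
contour_lengths <- function(system) {
  sys <- unwrap_system(system)
  vapply(sys$chains, function(ch) sum(sqrt(rowSums(diff(ch)^2))), numeric(1))
}
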
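#' Radius of gyration of the full multichain system
#'
#' Mass-weighted root mean square distance of all beads from the centre of
#' mass of the whole system,
#' `Rg^2 = (1/M) * sum_i m_i |r_i - r_CM|^2` with `M` the total mass.
#' Periodic systems are unwrapped chain by chain before the computation.
#'
#' @param system a [chain_system()].
#' @return Nonnegative length in sigma units.
#' @examples
#' radius_of_gyration(chain_system(list(cbind(c(0, 1), 0, 0))))  # 0.5
#' @export
radius_of_gyration <- function(system) {
  fl <- .flatten(unwrap_system(system))
  m <- fl$mass
  cm <- colSums(fl$xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(fl$xyz, 2, cm)^2)) / sum(m))
}

#' Normalize Rg by the ideal-chain reference
#'
#' Divides the radius of gyration by `Rg_theta = b * sqrt((N - 1) / 6)`,
#' the entropic radius of gyration of a three-dimensional random walk of
#' `N` beads with bond length `b`.
#'
#' @param rg radius of gyration.
#' @param N beads per chain (>= 2).
#' @param b equilibrium bond length in sigma; defaults to 0.965, the mean
#'   backbone bond length of the bead-spring model at unit temperature.
#' @return Dimensionless normalized radius of gyration.
#' @export
rg_normalized <- function(rg, N, b = 0.965) {
  if (N < 2) stop("N must be at least 2")
  if (b <= 0) stop("b must be positive")
  rg / (b * sqrt((N - 1) / 6))
}

#' End-to-end correlation parameter
#'
#' Mean squared cosine between the end-to-end unit vectors of all chain
#' pairs: `CR = 2/(M(M-1)) * sum_{i<j} (u_i . u_j)^2`.  Equal to 1 for a
#' perfectly aligned bundle (the squared dot ignores chain orientation) and
#' 1/3 on average for independent random orientations, so it acts like a
#' nematic order parameter.  Chains with zero end-to-end vector are
#' excluded with a warning.
#'
#' @param system a [chain_system()] with at least 2 chains.
#' @return Value in `[0, 1]`.
#' @export
end_to_end_correlation <- function(system) {
  if (n_chains(system) < 2L) stop("need at least two chains")
  sys <- unwrap_system(system)
  ee <- t(vapply(sys$chains, function(ch) ch[nrow(ch), ] - ch[1, ], numeric(3)))
  len <- sqrt(rowSums(ee^2))
  if (any(len == 0)) {
    warning(sum(len == 0), " chain(s) with zero end-to-end vector excluded")
    ee <- ee[len > 0, , drop = FALSE]
    len <- len[len > 0]
  }
  M <- nrow(ee)
  if (M < 2L) return(NA_real_)
  u <- ee / len
  g <- (u %*% t(u))^2
  (sum(g) - M) / (M * (M - 1))
}

#' Structural observables of a frame
#'
#' @param system a [chain_system()].
#' @param b equilibrium bond length used in the normalization.
#' @return One-row `data.frame` with `Rg`, `Rg_tilde`, `CR`.
#' @export
observables_record <- function(system, b = 0.965) {
  N <- nrow(system$chains[[1]])
  rg <- radius_of_gyration(system)
  data.frame(Rg = rg,
             Rg_tilde = rg_normalized(rg, N, b),
             CR = if (n_chains(system) >= 2) end_to_end_correlation(system)
                  else NA_real_)
}

#' Mean backbone bond length of a system
#'
#' @param system a [chain_system()].
#' @return Mean Euclidean bond length over all backbone bonds (after
#'   unwrapping).
#' @export
mean_bond_length <- function(system) {
  sys <- unwrap_system(system)
  mean(unlist(lapply(sys$chains, function(ch) sqrt(rowSums(diff(ch)^2)))))
}
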
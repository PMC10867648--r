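#' Kremer-Grest simulation configuration
#'
#' Parameters of the bead-spring model in reduced Lennard-Jones units
#' (`sigma = epsilon = m = kB = 1`): chains are strings of beads joined by
#' FENE springs, all bead pairs interact through a truncated, shifted
#' 12-6 Lennard-Jones potential (cohesive: cutoff 2.5 sigma), and
#' successive bonds pay a bending energy `kappa * kB T * (1 - cos theta)`.
#' Dynamics are NVT via a Langevin thermostat (BAOAB splitting).
#'
#' @param M chains.
#' @param N beads per chain.
#' @param temp temperature in epsilon/kB.
#' @param rho bead number density in sigma^-3; sets the cubic box side
#'   `(M N / rho)^(1/3)`.
#' @param kappa bending stiffness (dimensionless).
#' @param dt timestep in tau (default 0.01).
#' @param steps number of integration steps.
#' @param stride steps between recorded frames.
#' @param seed integer seed for initial placement, velocities and thermostat
#'   noise.
#' @param lj_cutoff pair cutoff (sigma).
#' @param fene_K,fene_R0 FENE spring constant (epsilon/sigma^2) and maximum
#'   extension (sigma); defaults 30 and 1.5, the standard bead-spring
#'   choice consistent with a mean bond length of 0.965 sigma.
#' @param langevin_damping thermostat damping time (tau); `Inf` disables
#'   the thermostat (NVE).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(M = 4L, N = 10L, temp = 1, rho = 0.01, kappa = 0,
                       dt = 0.01, steps = 10000L, stride = 100L,
                       seed = NULL, lj_cutoff = 2.5, fene_K = 30,
                       fene_R0 = 1.5, langevin_damping = 1) {
  stopifnot(dt > 0, rho > 0, kappa >= 0, temp > 0, M >= 1, N >= 2)
  structure(list(M = as.integer(M), N = as.integer(N), temp = temp,
                 rho = rho, kappa = kappa, dt = dt,
                 steps = as.integer(steps), stride = as.integer(stride),
                 seed = seed, lj_cutoff = lj_cutoff, fene_K = fene_K,
                 fene_R0 = fene_R0, langevin_damping = langevin_damping),
            class = "sim_config")
}

#' Initial multichain configuration
#'
#' Places `M` self-avoiding random-walk chains with bond length 0.97 sigma
#' in the cubic periodic box set by the density, rejecting any bead closer
#' than 0.9 sigma (minimum image) to previously placed beads.  Seeded and
#' reproducible; independent of the bending stiffness.
#'
#' @param config a [sim_config()].
#' @param max_retries placement attempts per bead before restarting the
#'   chain, and chain restarts before giving up.
#' @return A [chain_system()] with the periodic box attached.
#' @export
init_system <- function(config, max_retries = 200L) {
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- (config$M * config$N / config$rho)^(1 / 3)
  box <- rep(L, 3)
  bond <- 0.97
  placed <- matrix(numeric(0), ncol = 3)
  mind2 <- 0.9^2
  clash <- function(p) {
    if (!nrow(placed)) return(FALSE)
    d <- sweep(placed, 2, p)
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    any(rowSums(d^2) < mind2)
  }
  chains <- vector("list", config$M)
  for (c in seq_len(config$M)) {
    for (attempt in seq_len(max_retries)) {
      ch <- matrix(NA_real_, config$N, 3)
      ch[1, ] <- stats::runif(3, 0, L)
      if (clash(ch[1, ])) next
      ok <- TRUE
      for (b in 2:config$N) {
        good <- FALSE
        for (try in seq_len(max_retries)) {
          z <- stats::runif(1, -1, 1); phi <- stats::runif(1, 0, 2 * pi)
          r <- sqrt(1 - z^2)
          cand <- ch[b - 1, ] + bond * c(r * cos(phi), r * sin(phi), z)
          self_ok <- b < 3 ||
            all(rowSums(sweep(ch[1:(b - 2), , drop = FALSE], 2, cand)^2) >= mind2)
          if (self_ok && !clash(cand)) {
            ch[b, ] <- cand; good <- TRUE; break
          }
        }
        if (!good) { ok <- FALSE; break }
      }
      if (ok) { chains[[c]] <- ch; placed <- rbind(placed, ch); break }
      if (attempt == max_retries)
        stop("chain placement failed; density too high")
    }
  }
  chain_system(chains, box = box)
}

.sys_args <- function(system) {
  fl <- .flatten(system)
  list(x = fl$xyz, chain = as.integer(fl$chain), box = system$box)
}

#' Potential energy components of a conformation
#'
#' @param system a [chain_system()].
#' @param config a [sim_config()].
#' @return list with `lj`, `fene`, `bend` energies (epsilon units).
#' @export
potential_energy <- function(system, config = sim_config()) {
  sa <- .sys_args(system)
  r <- kg_energy_forces(sa$x, sa$chain, sa$box, config$lj_cutoff,
                        config$fene_K, config$fene_R0, config$kappa,
                        config$temp)
  list(lj = r$pair, fene = r$fene, bend = r$bend)
}

#' Forces on every bead
#'
#' @inheritParams potential_energy
#' @return Matrix of forces (beads x 3), in flattened bead order.
#' @export
system_forces <- function(system, config = sim_config()) {
  sa <- .sys_args(system)
  kg_energy_forces(sa$x, sa$chain, sa$box, config$lj_cutoff,
                   config$fene_K, config$fene_R0, config$kappa,
                   config$temp)$forces
}

#' Run NVT (or NVE) bead-spring dynamics
#'
#' Integrates the Langevin equations with the BAOAB velocity-Verlet
#' splitting.  Velocities are drawn from the Maxwell distribution at the
#' start unless supplied.  Frames are recorded every `config$stride`
#' steps with unwrapped coordinates (the minimum-image convention is
#' applied inside the force loop only).
#'
#' @param system starting [chain_system()]; defaults to [init_system()].
#' @param config a [sim_config()].
#' @param velocities optional starting velocity matrix.
#' @return A `trajectory` object: `frames` (list of `chain_system`),
#'   `times` (tau), per-frame `kinetic`, `pair`, `fene`, `bend` energies,
#'   and `final` (list with `x`, `v`) for continuation runs.
#' @examples
#' \donttest{
#' cfg <- sim_config(M = 2, N = 5, steps = 200, stride = 50, seed = 1)
#' tr <- run_nvt(config = cfg)
#' }
#' @export
run_nvt <- function(system = NULL, config = sim_config(), velocities = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(system)) system <- init_system_noseed(config)
  sa <- .sys_args(system)
  n <- nrow(sa$x)
  if (is.null(velocities))
    velocities <- matrix(stats::rnorm(3 * n, sd = sqrt(config$temp)), n, 3)
  gamma <- if (is.finite(config$langevin_damping) && config$langevin_damping > 0)
    1 / config$langevin_damping else 0
  r <- kg_run(sa$x, velocities, sa$chain, sa$box, config$lj_cutoff,
              config$fene_K, config$fene_R0, config$kappa, config$temp,
              gamma, config$dt, config$steps, config$stride)
  nb <- vapply(system$chains, nrow, integer(1))
  split_idx <- rep(seq_along(nb), nb)
  frames <- lapply(seq_len(dim(r$frames)[3]), function(k) {
    xyz <- t(r$frames[, , k])
    chain_system(unname(lapply(split(seq_len(n),
                                     factor(split_idx, levels = seq_along(nb))),
                               function(ii) xyz[ii, , drop = FALSE])),
                 box = system$box)
  })
  structure(list(frames = frames, times = r$times, kinetic = r$kinetic,
                 pair = r$pair, fene = r$fene, bend = r$bend,
                 final = list(x = r$x, v = r$v), config = config),
            class = "trajectory")
}

# init_system without touching the RNG seed again (run_nvt already set it)
init_system_noseed <- function(config) {
  cfg <- config
  cfg$seed <- NULL
  init_system(cfg)
}
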
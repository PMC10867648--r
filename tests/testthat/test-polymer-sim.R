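test_that("initial placement is seeded, boxed, and stiffness-independent", {
  cfg <- sim_config(M = 4, N = 10, rho = 0.01, seed = 81)
  sys <- init_system(cfg)
  expect_equal(n_beads(sys), 40L)
  expect_equal(sys$box, rep((4000)^(1 / 3), 3), tolerance = 1e-9)
  # no pair closer than 0.9 sigma (minimum image), bonds at 0.97
  fl <- braidct:::.flatten(sys)
  d2 <- braidct:::.pair_dist2(fl$xyz, sys$box)
  expect_gte(min(sqrt(d2[upper.tri(d2)])), 0.9)
  expect_equal(mean(unlist(lapply(sys$chains, function(ch)
    sqrt(rowSums(diff(ch)^2))))), 0.97, tolerance = 1e-9)
  # same seed twice: identical; kappa plays no role at initialization
  sys2 <- init_system(cfg)
  expect_identical(sys$chains, sys2$chains)
  cfgk <- cfg; cfgk$kappa <- 12
  expect_identical(init_system(cfgk)$chains, sys$chains)
})

test_that("bending energy matches the angular formula", {
  cfg <- sim_config(M = 1, N = 3, kappa = 2, temp = 1, rho = 1e-6)
  collin <- chain_system(list(cbind(c(0, 0.97, 1.94), 0, 0)))
  expect_equal(potential_energy(collin, cfg)$bend, 0, tolerance = 1e-12)
  right <- chain_system(list(rbind(c(0, 0, 0), c(0.97, 0, 0), c(0.97, 0.97, 0))))
  expect_equal(potential_energy(right, cfg)$bend, 2 * (1 - cos(pi / 2)),
               tolerance = 1e-12)
  # scales linearly in kappa and temperature
  cfg2 <- cfg; cfg2$kappa <- 5; cfg2$temp <- 0.5
  expect_equal(potential_energy(right, cfg2)$bend, 5 * 0.5, tolerance = 1e-12)
})

test_that("analytic forces match numerical gradients of the energy", {
  set.seed(82)
  cfg <- sim_config(M = 2, N = 5, kappa = 3, rho = 0.001)
  tr <- run_nvt(config = sim_config(M = 2, N = 5, kappa = 3, rho = 0.001,
                                    steps = 500, stride = 500, seed = 82))
  sys <- tr$frames[[1]]
  f <- system_forces(sys, cfg)
  fl <- braidct:::.flatten(sys)
  pe <- function(xyz) {
    chains <- list(xyz[1:5, ], xyz[6:10, ])
    e <- potential_energy(chain_system(chains, box = sys$box), cfg)
    e$lj + e$fene + e$bend
  }
  h <- 1e-6
  for (pick in list(c(1, 1), c(3, 2), c(7, 3), c(10, 1))) {
    i <- pick[1]; k <- pick[2]
    xp <- fl$xyz; xp[i, k] <- xp[i, k] + h
    xm <- fl$xyz; xm[i, k] <- xm[i, k] - h
    num <- -(pe(xp) - pe(xm)) / (2 * h)
    expect_equal(f[i, k], num, tolerance = 1e-5)
  }
})

test_that("NVE dynamics conserve total energy", {
  cfg <- sim_config(M = 2, N = 6, temp = 0.5, rho = 0.005, kappa = 1,
                    dt = 0.002, steps = 10000, stride = 100, seed = 83,
                    langevin_damping = Inf)
  tr <- run_nvt(config = cfg)
  etot <- tr$kinetic + tr$pair + tr$fene + tr$bend
  drift <- (max(etot) - min(etot)) / abs(mean(etot))
  expect_lt(drift, 1e-3)
})

test_that("the thermostat equipartitions kinetic energy", {
  cfg <- sim_config(M = 2, N = 10, temp = 1, rho = 0.005, steps = 40000,
                    stride = 100, seed = 84)
  tr <- run_nvt(config = cfg)
  ke_per_bead <- mean(tr$kinetic[-(1:100)]) / n_beads(tr$frames[[1]])
  expect_equal(ke_per_bead, 1.5, tolerance = 0.05)
})

test_that("equilibrated bond lengths sit near 0.965 sigma at T = 1", {
  cfg <- sim_config(M = 2, N = 10, temp = 1, rho = 0.005, steps = 30000,
                    stride = 500, seed = 85)
  tr <- run_nvt(config = cfg)
  bl <- mean(vapply(tr$frames[-(1:20)], mean_bond_length, numeric(1)))
  expect_equal(bl, 0.965, tolerance = 0.02)
})

test_that("identical seeds reproduce trajectories bitwise", {
  cfg <- sim_config(M = 2, N = 5, steps = 1000, stride = 200, seed = 86)
  t1 <- run_nvt(config = cfg)
  t2 <- run_nvt(config = cfg)
  expect_identical(t1$frames[[5]]$chains, t2$frames[[5]]$chains)
})

test_that("overstretched FENE bonds abort with a diagnostic", {
  cfg <- sim_config(M = 1, N = 2, rho = 1e-6)
  bad <- chain_system(list(rbind(c(0, 0, 0), c(1.6, 0, 0))))
  expect_error(potential_energy(bad, cfg), "beyond R0")
})
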
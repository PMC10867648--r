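test_that("radius of gyration matches hand-computed geometries", {
  one <- chain_system(list(rbind(c(1, 2, 3), c(1, 2, 3) + 1e-12)))
  expect_equal(radius_of_gyration(one), 0, tolerance = 1e-9)
  two <- chain_system(list(rbind(c(0, 0, 0), c(3, 0, 0))))
  expect_equal(radius_of_gyration(two), 1.5)
  sq <- chain_system(list(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))))
  expect_equal(radius_of_gyration(sq), sqrt(0.5))
  # mass weighting: doubling one bead's mass moves the centre of mass
  wsys <- chain_system(list(rbind(c(0, 0, 0), c(3, 0, 0))),
                       masses = list(c(2, 1)))
  expect_equal(radius_of_gyration(wsys), sqrt((2 * 1^2 + 1 * 2^2) / 3))
})

test_that("the ideal-chain normalization divides by b sqrt((N-1)/6)", {
  b <- 0.965
  expect_equal(rg_normalized(b * sqrt((10 - 1) / 6), 10, b), 1)
  expect_equal(rg_normalized(1, 10, 0.965), 1 / (0.965 * sqrt(1.5)))
  expect_error(rg_normalized(1, 1), "at least 2")
})

test_that("ensembles of ideal random walks have unit normalized Rg", {
  set.seed(71)
  b <- 1
  N <- 100
  vals <- replicate(150, {
    sys <- make_random_walks(1, N, b = b)
    radius_of_gyration(sys) / (b * sqrt((N - 1) / 6))
  })
  # mean squared ratio -> (N+1)/N for a discrete random walk
  expect_equal(mean(vals^2), 1, tolerance = 0.1)
})

test_that("end-to-end correlation hits its reference values", {
  aligned <- chain_system(lapply(1:4, function(k) cbind(c(0, 1, 2), 3 * k, 0)))
  expect_equal(end_to_end_correlation(aligned), 1)
  ortho <- chain_system(list(cbind(c(0, 1), 0, 0), cbind(0, c(0, 1), 5)))
  expect_equal(end_to_end_correlation(ortho), 0)
  # flipping a chain's orientation leaves CR unchanged (squared cosine)
  flipped <- chain_system(list(cbind(c(1, 0), 0, 0), cbind(0, c(0, 1), 5)))
  expect_equal(end_to_end_correlation(flipped), 0)
})

test_that("uncorrelated orientation pairs average to CR = 1/3", {
  set.seed(72)
  npair <- 1e5
  z <- matrix(stats::runif(2 * npair, -1, 1), ncol = 2)
  phi <- matrix(stats::runif(2 * npair, 0, 2 * pi), ncol = 2)
  r <- sqrt(1 - z^2)
  dot <- r[, 1] * r[, 2] * cos(phi[, 1] - phi[, 2]) + z[, 1] * z[, 2]
  cr <- dot^2
  se <- stats::sd(cr) / sqrt(npair)
  expect_lt(abs(mean(cr) - 1 / 3), 3 * se + 1e-3)
  # and through the package function on random two-chain systems
  vals <- replicate(300, end_to_end_correlation(make_random_walks(2, 2, b = 1)))
  expect_equal(mean(vals), 1 / 3, tolerance = 0.1)
})

test_that("observables are invariant under rigid-body transforms", {
  sys <- make_random_walks(4, 10, seed = 73)
  th <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  sys2 <- transform_system(sys, R, c(-1, 2, 7))
  expect_equal(radius_of_gyration(sys2), radius_of_gyration(sys),
               tolerance = 1e-9)
  expect_equal(end_to_end_correlation(sys2), end_to_end_correlation(sys),
               tolerance = 1e-9)
  expect_true(end_to_end_correlation(sys) >= 0 &&
              end_to_end_correlation(sys) <= 1)
})
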
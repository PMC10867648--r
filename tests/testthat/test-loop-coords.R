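test_that("generator action round-trips exactly through its inverse", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(3:6, 1)
    co <- loop_coords(n, sample(-5:5, n - 2, TRUE), sample(-5:5, n - 2, TRUE))
    l <- sample(c(-(n - 1)):(n - 1), 1)
    if (l == 0) l <- 1
    back <- apply_generator(apply_generator(co, l), -l)
    expect_identical(back$a, co$a)
    expect_identical(back$b, co$b)
  }
})

test_that("the coordinate action satisfies the braid group relations", {
  set.seed(22)
  for (rep in 1:30) {
    n <- 6
    co <- loop_coords(n, sample(-4:4, n - 2, TRUE), sample(-4:4, n - 2, TRUE))
    j <- sample(1:(n - 2), 1)
    r1 <- apply_braid(co, c(j, j + 1, j))
    r2 <- apply_braid(co, c(j + 1, j, j + 1))
    expect_identical(c(r1$a, r1$b), c(r2$a, r2$b))
    # distant generators commute
    r3 <- apply_braid(co, c(1, n - 2))
    r4 <- apply_braid(co, c(n - 2, 1))
    expect_identical(c(r3$a, r3$b), c(r4$a, r4$b))
  }
})

test_that("coordinate updates agree with the geometric polyline oracle", {
  set.seed(23)
  for (rep in 1:12) {
    n <- sample(4:5, 1)
    i <- sample(1:(n - 1), 1)
    j <- min(i + sample(1:2, 1), n)
    if (i == 1 && j == n) j <- n - 1
    curve <- list(oracle_round_loop(i, j))
    w0 <- sample(c(-(1:(n - 1)), 1:(n - 1)), sample(0:2, 1), TRUE)
    curve <- oracle_apply_word(curve, w0, n)
    mc <- oracle_measure(curve, n)
    co <- loop_coords(n, mc$a, mc$b)
    l <- sample(c(-(1:(n - 1)), 1:(n - 1)), 1)
    curve2 <- oracle_apply_word(curve, l, n)
    mc2 <- oracle_measure(curve2, n)
    r <- apply_generator(co, l)
    expect_identical(r$a, mc2$a)
    expect_identical(r$b, mc2$b)
  }
})

test_that("axis intersection counts match the oracle's taut counts", {
  set.seed(24)
  for (rep in 1:12) {
    n <- sample(4:5, 1)
    i <- sample(1:(n - 1), 1)
    j <- min(i + 1, n)
    if (i == 1 && j == n) i <- 2
    curve <- list(oracle_round_loop(min(i, j), max(i, j)))
    w0 <- sample(c(-(1:(n - 1)), 1:(n - 1)), sample(0:3, 1), TRUE)
    curve <- oracle_apply_word(curve, w0, n)
    mc <- oracle_measure(curve, n)
    co <- loop_coords(n, mc$a, mc$b)
    expect_equal(intersections_with_axis(co), mc$axis)
  }
})

test_that("the canonical multiloop distinguishes braids incl. full twists", {
  # full twist is central but must not be confused with the identity
  n <- 3
  delta2 <- braid_word(rep(c(1, 2), 3), n)   # (sigma1 sigma2)^3
  expect_false(is_trivial_braid(delta2))
  expect_true(is_trivial_braid(braid_word(n = 3)))
  # trivial words constructed by conjugation reduce to the identity
  set.seed(25)
  for (rep in 1:10) {
    n <- 4
    g <- sample(c(-3:-1, 1:3), 4, TRUE)
    w <- braid_word(c(g, rev(-g)), n)
    expect_true(is_trivial_braid(w))
  }
})
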
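test_that("the endpoint-plane frame recovers an axis-aligned bundle", {
  ybase <- c(0, 0.3, 0.1, 0.4)
  sys <- chain_system(lapply(1:4, function(k)
    cbind(2 * k, ybase[k], seq(0, 12, length.out = 10))))
  fr <- find_projection_frame(sys)
  expect_equal(unname(abs(fr$axes[, 3])), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$offset, 12, tolerance = 1e-9)
})

test_that("frame axes are orthonormal and right-handed on random systems", {
  set.seed(101)
  for (rep in 1:60) {
    sys <- make_random_walks(4, 8, seed = 100 + rep)
    fr <- find_projection_frame(sys)
    G <- unname(t(fr$axes) %*% fr$axes)
    expect_equal(G, diag(3), tolerance = 1e-10)
    expect_equal(det(fr$axes), 1, tolerance = 1e-10)
  }
})

test_that("rigid rotations transport the frame with the system", {
  sys <- make_random_walks(4, 8, seed = 102)
  th <- 0.9
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  fr1 <- find_projection_frame(sys)
  fr2 <- find_projection_frame(transform_system(sys, R, c(1, 2, 3)))
  expect_equal(unname(fr2$axes), unname(R %*% fr1$axes), tolerance = 1e-9)
  expect_equal(fr2$offset, fr1$offset, tolerance = 1e-9)
})

test_that("straight parallel chains extract the empty word", {
  sys <- make_braided_bundle(braid_word(n = 4), N = 30, seed = 103)
  w <- extract_braid(sys)
  expect_equal(length(reduce_braid(w)), 0L)
})

test_that("a double helix of two chains gives writhe +/- k", {
  for (k in c(1, 3)) {
    word <- braid_word(rep(1L, k), 4)
    sys <- make_braided_bundle(word, N = 50, seed = 104)
    w <- extract_braid(sys)
    expect_equal(writhe(w), k)
    expect_equal(minimal_length(w), k)
  }
  # and the mirrored helix has the opposite handedness
  wneg <- extract_braid(make_braided_bundle(braid_word(c(-1L, -1L), 4),
                                            N = 50, seed = 105))
  expect_equal(writhe(wneg), -2)
})

test_that("extraction round-trips the invariants of random fixture words", {
  set.seed(106)
  ok <- 0
  total <- 40
  for (rep in seq_len(total)) {
    L <- sample(1:4, 1)
    letters <- sample(c(-3:-1, 1:3), L, TRUE)
    word <- braid_word(letters, 4)
    sys <- make_braided_bundle(word, N = 40, seed = 1000 + rep)
    got <- extract_braid(sys)
    same <- writhe(got) == writhe(word) &&
      minimal_length(got) == minimal_length(word) &&
      isTRUE(all.equal(braid_complexity(got, 3), braid_complexity(word, 3)))
    ok <- ok + as.integer(same)
  }
  expect_gte(ok / total, 0.95)
})

test_that("doubling the slice count leaves extracted invariants unchanged", {
  set.seed(107)
  for (rep in 1:5) {
    letters <- sample(c(-3:-1, 1:3), 3, TRUE)
    word <- braid_word(letters, 4)
    sys <- make_braided_bundle(word, N = 40, seed = 2000 + rep)
    w1 <- extract_braid(sys, n_slices = 400L)
    w2 <- extract_braid(sys, n_slices = 800L)
    expect_equal(writhe(w1), writhe(w2))
    expect_equal(minimal_length(w1), minimal_length(w2))
  }
})

test_that("projection-induced inverse pairs vanish under reduction", {
  # a zigzag strand that crosses its neighbour and immediately crosses back
  word <- braid_word(c(1L, -1L), 4)
  sys <- make_braided_bundle(word, N = 50, seed = 108)
  w <- extract_braid(sys)
  expect_equal(length(reduce_braid(w)), 0L)
  expect_true(is_trivial_braid(w))
})
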
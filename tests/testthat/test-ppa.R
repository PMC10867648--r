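test_that("straight parallel chains are a fixed point with frozen endpoints", {
  sp <- chain_system(lapply(1:4, function(k) cbind(0:9 * 0.97, 2 * k, 0)))
  pp <- primitive_paths(sp)
  expect_true(attr(pp, "converged"))
  expect_equal(pp$chains, sp$chains, tolerance = 1e-12)
})

test_that("an isolated coil contracts to the segment joining its endpoints", {
  set.seed(91)
  for (s in 1:3) {
    rw <- make_random_walks(1, 10, seed = 90 + s)
    pp <- primitive_paths(rw)
    expect_true(attr(pp, "converged"))
    # endpoints bitwise unchanged
    expect_identical(pp$chains[[1]][1, ], rw$chains[[1]][1, ])
    expect_identical(pp$chains[[1]][10, ], rw$chains[[1]][10, ])
    e2e <- sqrt(sum((rw$chains[[1]][10, ] - rw$chains[[1]][1, ])^2))
    expect_equal(contour_lengths(pp), e2e, tolerance = 0.01 * e2e,
                 ignore_attr = TRUE)
  }
})

test_that("contour length never increases and separable chains straighten", {
  set.seed(92)
  rw <- make_random_walks(2, 12, seed = 92)   # far apart, separable
  pp <- primitive_paths(rw)
  expect_true(all(contour_lengths(pp) <= contour_lengths(rw) + 1e-9))
  ee <- vapply(rw$chains, function(ch)
    sqrt(sum((ch[nrow(ch), ] - ch[1, ])^2)), numeric(1))
  expect_equal(contour_lengths(pp), ee, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("interlocked hooks survive contraction and yield a nonempty braid", {
  # two U-shaped chains linked like chain links: chain A is a U in the
  # y = 0 plane closed at x = 0; chain B threads through its aperture and
  # around the closing segment, so no isotopy with fixed ends can separate
  # them.  After contraction the primitive paths must still cross.
  chainA <- rbind(c(-4, 0, 0), c(0, 0, 0), c(0, 0, 2), c(-4, 0, 2))
  chainB <- rbind(c(-2, -4, 1), c(-2, 1, 1), c(1, 1, 1), c(1, -4, 1))
  resp <- function(p) braidct:::.resample_arclength(p, 24)
  sys <- chain_system(list(resp(chainA), resp(chainB)))
  pp <- suppressWarnings(primitive_paths(sys, max_iter = 40000))
  # the link cannot fully straighten: contour stays above end-to-end
  ee <- vapply(pp$chains, function(ch)
    sqrt(sum((ch[nrow(ch), ] - ch[1, ])^2)), numeric(1))
  expect_true(any(contour_lengths(pp) > ee * 1.02))
  # and the projected strands still cross
  word <- extract_braid(pp)
  expect_gt(length(word), 0)
})
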
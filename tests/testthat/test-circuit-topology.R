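test_that("contact detection applies the cutoff and the backbone exclusion", {
  # two beads on different chains at 1.3 sigma: one contact
  sys <- chain_system(list(cbind(c(0, 2), 0, 0), cbind(c(0, 2), 1.3, 0)))
  ct <- detect_contacts(sys, contact_config())
  expect_equal(nrow(ct), 2L)   # both bead columns are 1.3 apart
  # bonded neighbours at 0.965 sigma on one chain never form a contact
  ch <- cbind(seq(0, 0.965 * 4, by = 0.965), 0, 0)
  expect_equal(nrow(detect_contacts(chain_system(list(ch)))), 0L)
  # backbone separation 3 at close distance does count
  loop <- rbind(c(0, 0, 0), c(1, 0.4, 0), c(2, 0, 0), c(1, -0.4, 0))
  ct2 <- detect_contacts(chain_system(list(loop)))
  expect_equal(nrow(ct2), 1L)
  expect_equal(unlist(ct2[1, 1:4]), c(chain1 = 1, bead1 = 1, chain2 = 1, bead2 = 4))
})

test_that("contact sets equal the brute-force all-pairs scan", {
  set.seed(61)
  for (rep in 1:5) {
    sys <- make_random_walks(4, 10, b = 1, seed = 60 + rep)
    # compress the system so contacts actually occur
    sys <- chain_system(lapply(sys$chains, function(ch)
      sweep(ch, 2, colMeans(ch)) * 0.8))
    got <- detect_contacts(sys, contact_config())
    want <- brute_contacts(sys)
    expect_equal(got[, 1:4], want[, 1:4], ignore_attr = TRUE)
  }
})

test_that("every hand-built motif fixture classifies as designed", {
  for (lab in motif_classes) {
    fx <- make_motif_system(lab)
    ct <- detect_contacts(fx$system)
    expect_equal(nrow(ct), 2L, info = lab)
    expect_equal(ct[, 1:4], fx$expected_contacts, ignore_attr = TRUE)
    r <- classify_pair(ct[1, ], ct[2, ])
    expect_equal(r$label, lab)
    r_swapped <- classify_pair(ct[2, ], ct[1, ])
    expect_equal(r_swapped$label, lab)
  }
})

test_that("exhaustive two-contact placements partition into exactly 9 classes", {
  # enumerate all chain assignments of the 4 sites and all backbone
  # orderings within shared chains; positions are spaced >= 3 apart
  seen <- character(0)
  grid <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  for (g in seq_len(nrow(grid))) {
    chains <- grid[g, ]
    # positions: permute the sites on each chain
    per_chain <- split(seq_len(4), chains)
    perms_of <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
      out
    }
    combos <- lapply(per_chain, perms_of)
    idx <- lapply(combos, seq_along)
    pick_grid <- as.matrix(expand.grid(idx))
    for (p in seq_len(nrow(pick_grid))) {
      beads <- integer(4)
      for (ci in seq_along(combos)) {
        ordering <- combos[[ci]][[pick_grid[p, ci]]]
        beads[ordering] <- 3 * seq_along(ordering)   # separation >= 3
      }
      c1 <- c(chains[1], beads[1], chains[2], beads[2])
      c2 <- c(chains[3], beads[3], chains[4], beads[4])
      # skip degenerate same-site placements
      sites <- rbind(c1[1:2], c1[3:4], c2[1:2], c2[3:4])
      if (anyDuplicated(paste(sites[, 1], sites[, 2]))) next
      r1 <- classify_pair(c1, c2)
      r2 <- classify_pair(c2, c1)
      expect_equal(r1$label, r2$label)
      seen <- union(seen, r1$label)
    }
  }
  expect_setequal(seen, motif_classes)
})

test_that("string notation reproduces the ghost-contact examples", {
  # tandem umbrella: chain 1 carries A,B,A; chain 2 carries one B site
  s <- string_notation(c(1, 1, 1, 5), c(1, 3, 2, 4))
  expect_equal(s$text, "ABBOAO")
  expect_equal(s$n_chains, 2L)
  # series motif on a single chain
  expect_equal(string_notation(c(1, 1, 1, 4), c(1, 7, 1, 10))$text, "AABB")
  # two A's, two B's, length divisible by chain count
  set.seed(62)
  for (rep in 1:10) {
    lab <- sample(motif_classes, 1)
    fx <- make_motif_system(lab)
    ct <- detect_contacts(fx$system)
    s <- string_notation(ct[1, ], ct[2, ])
    chars <- strsplit(s$text, "")[[1]]
    expect_equal(sum(chars == "A"), 2)
    expect_equal(sum(chars == "B"), 2)
    expect_equal(length(chars) %% s$n_chains, 0)
  }
})

test_that("motif class can be recovered from the string notation", {
  # decode: rebuild per-chain site sequences from the string and reclassify
  decode_label <- function(text, n_chains) {
    chars <- matrix(strsplit(text, "")[[1]], ncol = n_chains, byrow = TRUE)
    sites <- NULL
    for (ch in seq_len(n_chains)) {
      col <- chars[, ch]
      for (lv in seq_along(col)) if (col[lv] != "O")
        sites <- rbind(sites, data.frame(chain = ch, bead = 3 * lv, lab = col[lv]))
    }
    A <- sites[sites$lab == "A", ]
    B <- sites[sites$lab == "B", ]
    classify_pair(c(A$chain[1], A$bead[1], A$chain[2], A$bead[2]),
                  c(B$chain[1], B$bead[1], B$chain[2], B$bead[2]))$label
  }
  for (lab in motif_classes) {
    fx <- make_motif_system(lab)
    ct <- detect_contacts(fx$system)
    s <- string_notation(ct[1, ], ct[2, ])
    expect_equal(decode_label(s$text, s$n_chains), lab, info = lab)
  }
})

test_that("motif fractions are a probability vector and match a pair census", {
  sys <- make_random_walks(4, 10, b = 1, seed = 63)
  sys <- chain_system(lapply(sys$chains, function(ch)
    sweep(ch, 2, colMeans(ch)) * 0.75))
  mf <- motif_fractions(sys)
  if (mf$n_pairs > 0) {
    expect_equal(sum(mf[, motif_classes]), 1, tolerance = 1e-12)
    expect_true(all(mf[, motif_classes] >= 0))
  }
  # census oracle: classify all pairs by hand
  ct <- detect_contacts(sys)
  if (nrow(ct) >= 2) {
    labs <- character(0)
    skip <- 0
    for (i in 1:(nrow(ct) - 1)) for (j in (i + 1):nrow(ct)) {
      r <- tryCatch(classify_pair(ct[i, ], ct[j, ]), error = function(e) NULL)
      if (is.null(r)) skip <- skip + 1 else labs <- c(labs, r$label)
    }
    expect_equal(mf$n_pairs, length(labs))
    expect_equal(mf$n_pairs_skipped, skip)
    for (cl in motif_classes)
      expect_equal(mf[[cl]], mean(labs == cl), tolerance = 1e-12)
  }
})

test_that("interchain-only systems have motif fractions summing on L2/T3/I4", {
  # four straight parallel chains at contact distance: no intrachain loops
  sys <- chain_system(lapply(1:4, function(k) cbind(0:9 * 0.97, 1.1 * k, 0)))
  mf <- motif_fractions(sys)
  expect_gt(mf$n_pairs, 0)
  expect_equal(mf$L2 + mf$T3 + mf$I4, 1, tolerance = 1e-12)
})

test_that("fewer than two contacts yields a flagged empty result", {
  sys <- chain_system(list(cbind(c(0, 5), 0, 0), cbind(c(0, 5), 50, 0)))
  mf <- motif_fractions(sys)
  expect_equal(mf$n_pairs, 0)
  expect_true(all(is.na(mf[, motif_classes])))
})

test_that("contacts and fractions are invariant under rigid-body transforms", {
  sys <- make_random_walks(3, 8, b = 1, seed = 64)
  sys <- chain_system(lapply(sys$chains, function(ch)
    sweep(ch, 2, colMeans(ch)) * 0.8))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sys2 <- transform_system(sys, R, c(3, -2, 5))
  mf1 <- motif_fractions(sys)
  mf2 <- motif_fractions(sys2)
  expect_equal(mf1, mf2, tolerance = 1e-9)
})
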
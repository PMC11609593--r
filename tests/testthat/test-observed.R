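test_that("interaction weight matches the contact polynomial", {
  expect_equal(interactionWeight(0, 9), 1)
  expect_equal(interactionWeight(9, 9), 0)   # 7 - 9 + 5 - 1 = 2; 1 - 2/2
  expect_equal(interactionWeight(4.5, 9),
               1 - 0.5 * (7 / 4 - 9 / 16 + 5 / 64 - 1 / 256))
  expect_equal(interactionWeight(4.5, 9), 0.369140625)
  expect_equal(interactionWeight(c(10, 100), 9), c(0, 0))
  expect_error(interactionWeight(-1, 9), "non-negative")
  expect_error(interactionWeight(1, 0), "positive")

  r <- seq(0, 9, length.out = 200)
  expect_true(all(diff(interactionWeight(r, 9)) <= 1e-12))
  expect_true(all(interactionWeight(r, 9) >= 0 & interactionWeight(r, 9) <= 1))
})

test_that("observed profile matches a brute-force pairwise sum", {
  set.seed(11)
  X <- matrix(stats::rnorm(3 * 12, sd = 4), ncol = 3)
  H <- stats::runif(12)
  s <- effectiveStructureFromPoints(X, hydro = H)
  o <- profileValues(oProfile(s, cutoff = 9))

  raw <- numeric(12)
  for (i in 1:12) for (j in 1:12) {
    if (i == j) next
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (r <= 9) raw[i] <- raw[i] + (H[i] + H[j]) * interactionWeight(r, 9)
  }
  expect_equal(o, raw / sum(raw), tolerance = 1e-12)
})

test_that("symmetric configurations give symmetric observed profiles", {
  pair <- effectiveStructureFromPoints(rbind(c(0, 0, 0), c(4, 0, 0)), hydro = 1)
  expect_equal(unname(profileValues(oProfile(pair))), c(0.5, 0.5))

  # regular tetrahedron, equal H, all pairs equidistant and within cutoff
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 2
  s <- effectiveStructureFromPoints(tet, hydro = 0.7)
  expect_equal(unname(profileValues(oProfile(s))), rep(0.25, 4))
})

test_that("units with no interacting pair are rejected as degenerate", {
  far <- effectiveStructureFromPoints(rbind(c(0, 0, 0), c(50, 0, 0)), hydro = 1)
  expect_error(oProfile(far), "degenerate observed profile")
})

test_that("observed profile is rigid-motion invariant and permutation equivariant", {
  set.seed(23)
  s <- makeMicelle(40, seed = 6)
  a <- profileValues(oProfile(s))
  moved <- transformStructure(s, random_rotation(), stats::rnorm(3, sd = 50))
  expect_equal(profileValues(oProfile(moved)), a, tolerance = 1e-9)

  perm <- sample(40)
  res <- residueTable(s)[perm, ]
  res$seq_id <- seq_len(40)
  rownames(res) <- NULL
  s2 <- new("EffectiveStructure", residues = res, unitLabel = "perm")
  expect_equal(profileValues(oProfile(s2)), a[perm], tolerance = 1e-12)
})

test_that("collinear chain at half-cutoff spacing matches hand enumeration", {
  c_ <- 9
  X <- cbind(c(0, c_ / 2, c_), 0, 0)
  s <- effectiveStructureFromPoints(X, hydro = 1)
  o <- profileValues(oProfile(s, cutoff = c_))
  wHalf <- interactionWeight(c_ / 2, c_)
  # ends interact only with the middle (end-to-end is exactly c, weight 0)
  raw <- c(2 * wHalf, 4 * wHalf, 2 * wHalf)
  expect_equal(unname(o), raw / sum(raw), tolerance = 1e-12)
})
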
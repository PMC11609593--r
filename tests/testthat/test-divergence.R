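test_that("KL divergence matches closed forms and a term-by-term oracle", {
  expect_equal(klDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), 1)  # exactly one bit

  set.seed(31)
  for (i in 1:20) {
    p <- random_simplex(10)
    q <- random_simplex(10)
    oracle <- 0
    for (k in 1:10) if (p[k] > 0) oracle <- oracle + p[k] * log2(p[k] / q[k])
    expect_equal(klDivergence(p, q), oracle, tolerance = 1e-12)
    expect_gte(klDivergence(p, q), 0)  # Gibbs inequality
  }

  expect_error(klDivergence(c(0.5, 0.5), c(1, 0)), "undefined")
  expect_error(klDivergence(c(0.5, 0.5), c(0.5, 0.5, 0)), "lengths")
  expect_error(klDivergence(c(2, 1), c(0.5, 0.5)), "normalised")
})

test_that("uniform reference profile is 1/n everywhere", {
  expect_equal(profileValues(rProfile(4)), rep(0.25, 4))
  expect_equal(profileValues(rProfile(2)), c(0.5, 0.5))
  for (n in c(3, 7, 50)) expect_equal(sum(profileValues(rProfile(n))), 1)
  expect_error(rProfile(1), "n >= 2")
})

test_that("RD is 0 at O = T, 1 at O = R, and matches the divergence ratio between", {
  t <- c(0.5, 0.3, 0.15, 0.05)
  expect_equal(relativeDistance(t, t), 0)
  expect_equal(relativeDistance(rep(0.25, 4), t), 1)

  o <- 0.5 * t + 0.5 * rep(0.25, 4)   # midpoint mixture
  rd <- relativeDistance(o, t)
  expect_gt(rd, 0); expect_lt(rd, 1)
  oracle <- klDivergence(o, t) /
    (klDivergence(o, t) + klDivergence(o, rep(0.25, 4)))
  expect_equal(rd, oracle, tolerance = 1e-12)

  expect_warning(rd0 <- relativeDistance(c(0.5, 0.5), c(0.5, 0.5)),
                 "RD defined as 0")
  expect_equal(rd0, 0)
})

test_that("RD is scale-free in the raw hydrophobicity units", {
  set.seed(17)
  raw_o <- stats::runif(12); raw_t <- stats::runif(12) + 0.1
  rd1 <- relativeDistance(raw_o / sum(raw_o), raw_t / sum(raw_t))
  rd2 <- relativeDistance(7.3 * raw_o / sum(7.3 * raw_o),
                          0.2 * raw_t / sum(0.2 * raw_t))
  expect_equal(rd1, rd2, tolerance = 1e-12)
})

test_that("residue status classifies excess and deficiency with zero-sum magnitudes", {
  t <- c(0.5, 0.5)
  same <- residueStatus(t, t)
  expect_true(all(same$status == "matched"))

  st <- residueStatus(c(0.6, 0.4), c(0.5, 0.5))
  expect_equal(st$status, c("excess", "deficiency"))
  expect_equal(st$delta, c(0.1, -0.1))
  expect_equal(sum(st$delta), 0)

  set.seed(3)
  o <- random_simplex(30); tt <- random_simplex(30)
  expect_equal(sum(residueStatus(o, tt)$delta), 0, tolerance = 1e-12)

  tau <- residueStatus(c(0.52, 0.48), c(0.5, 0.5), tau = 0.05)
  expect_true(all(tau$status == "matched"))
})

test_that("re-assessment after elimination recomputes the unit from scratch", {
  s <- makeMicelle(60, seed = 8)
  full <- fodStatus(s)
  expect_equal(rdValue(rdExcluding(s, NULL)), rdValue(full))
  expect_equal(rdValue(rdExcluding(s, integer(0))), rdValue(full))

  # dropping the most excessive residue must not worsen the micelle match
  for (seed in c(1, 2, 5)) {
    m <- makeMicelle(100, seed = seed)
    tb <- profileTable(m)
    worst <- which.max(tb$delta)
    expect_lte(rdValue(rdExcluding(m, worst)), rdValue(fodStatus(m)))
  }

  # selection-based exclusion drops a numbered range on a chain
  red <- rdExcluding(s, "A:1-10")
  expect_equal(nResidues(red), 50L)

  expect_error(rdExcluding(s, seq_len(59)), "fewer than 2")
})
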
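test_that("assessing a single-chain selection equals the plain assessment of that unit", {
  sp <- makeSwappedPair(80, seed = 2)
  st1 <- assessUnit(sp$structure, sp$host)
  st2 <- fodStatus(subsetUnit(sp$structure, sp$host))
  expect_equal(rdValue(st1), rdValue(st2))
  expect_equal(kValue(st1), kValue(st2))
})

test_that("fragment listing order does not change RD or K", {
  sp <- makeSwappedPair(100, seed = 3)
  ab <- assessUnit(sp$structure, parseSelection("A+B"))
  ba <- assessUnit(sp$structure, parseSelection("B+A"))
  expect_equal(rdValue(ab), rdValue(ba), tolerance = 1e-12)
  expect_equal(kValue(ab), kValue(ba))
})

test_that("a PDB path and the in-memory structure give the same assessment", {
  s <- makeMicelle(40, seed = 12)
  f <- tempfile(fileext = ".pdb")
  writeCaPdb(s, f)
  fromFile <- assessUnit(f, "A")
  # the PDB round trip re-derives H from residue codes (quantised scale),
  # so compare against the same quantised structure, not the raw one
  quantised <- effectiveAtoms(readStructure(f))
  expect_equal(rdValue(fromFile), rdValue(fodStatus(quantised)))
})

test_that("guest contribution requires disjoint, non-empty guest fragments", {
  sp <- makeSwappedPair(80, seed = 4)
  expect_error(guestContribution(sp$structure, sp$host, "A:1-5"), "overlap")
  expect_error(guestContribution(sp$structure, sp$host, "B:900-901"),
               "zero residues")
})

test_that("a core-completing guest lowers RD; an inverted guest does not", {
  for (seed in 1:3) {
    good <- makeSwappedPair(120, seed = seed, complete = TRUE)
    ga <- guestContribution(good$structure, good$host, good$guest)
    expect_lt(ga@deltaRd, 0)
    expect_lt(rdValue(ga@combinedStatus), rdValue(ga@hostStatus))

    bad <- makeSwappedPair(120, seed = seed, complete = FALSE)
    gb <- guestContribution(bad$structure, bad$host, bad$guest)
    expect_gte(gb@deltaRd, 0)
  }
})

test_that("batch tables report one row per unit and flag failures without aborting", {
  expect_error(batchTable(data.frame()), "empty manifest")

  s <- makeMicelle(30, seed = 21)
  f <- tempfile(fileext = ".pdb")
  writeCaPdb(s, f)
  manifest <- data.frame(
    source = c(f, f, "missing_file.pdb"),
    selection = c("A", "A:1-10", "A"),
    label = c("full", "head", "broken"),
    stringsAsFactors = FALSE)
  tb <- batchTable(manifest)
  expect_equal(nrow(tb), 3L)
  expect_true(all(is.na(tb$error[1:2])))
  expect_false(is.na(tb$error[3]))
  expect_true(is.na(tb$RD[3]))
  expect_equal(tb$N[2], 10L)

  # runs are reproducible
  tb2 <- batchTable(manifest)
  expect_equal(tb$RD, tb2$RD)

  out <- tempfile(fileext = ".csv")
  writeBatchTable(tb, out)
  written <- utils::read.csv(out, colClasses = "character")
  expect_match(written$RD[1], "^0\\.[0-9]{3}$")   # 3 decimals
  expect_match(written$K[1], "^[0-9]+\\.[0-9]$")  # 1 decimal

  one <- batchTable(data.frame(source = f, selection = "A", label = "u",
                               stringsAsFactors = FALSE))
  expect_equal(nrow(one), 1L)
})

test_that("profile averaging aligns on shared numbering and reports mean, sd and K", {
  s <- makeMicelle(40, seed = 30)
  tb <- profileTable(s)
  avg <- averageProfiles(list(tb, tb))
  expect_equal(avg$profiles$T_mean, tb$T)
  expect_true(all(avg$profiles$T_sd == 0))
  expect_equal(avg$k, attr(tb, "k"))
  expect_equal(avg$nUnits, 2L)

  tb2 <- tb
  tb2$O[5] <- tb2$O[5] + 0.01
  avg2 <- averageProfiles(list(tb, tb2))
  expect_equal(which(avg2$profiles$O_sd > 0), 5L)
  expect_equal(avg2$profiles$O_sd[5], 0.005)   # population sd of two values

  # positions absent from one unit are dropped with a warning
  tb3 <- tb[-(1:3), ]
  expect_warning(avg3 <- averageProfiles(list(tb, tb3)), "dropped")
  expect_equal(nrow(avg3$profiles), 37L)

  # mean and population sd match the direct formulas on a random family
  set.seed(9)
  fam <- lapply(1:4, function(i) {
    x <- tb
    x$T <- random_simplex(40); x$O <- random_simplex(40)
    x$M <- random_simplex(40)
    x
  })
  avg4 <- averageProfiles(fam)
  m <- sapply(fam, `[[`, "O")
  expect_equal(avg4$profiles$O_mean, rowMeans(m), tolerance = 1e-12)
  expect_equal(avg4$profiles$O_sd,
               apply(m, 1, function(v) sqrt(mean((v - mean(v))^2))),
               tolerance = 1e-12)
})
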
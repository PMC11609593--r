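test_that("PDB reading returns residues in file order with waters and ligands excluded", {
  path <- tiny_pdb()
  atoms <- readStructure(path)
  expect_equal(unique(atoms$seq_id), c(1L, 2L, 3L))
  expect_equal(atoms$aa_code[!duplicated(atoms$seq_id)],
               c("GLY", "ALA", "LYS"))

  path2 <- write_pdb(c(
    pdb_atom(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom(2, "O", "HOH", "A", 90, 9, 9, 9, record = "HETATM",
             element = "O"),
    pdb_atom(3, "ZN", "ZN ", "A", 91, 5, 5, 5, record = "HETATM",
             element = "ZN"),
    pdb_atom(4, "CA", "ALA", "A", 2, 3, 0, 0)))
  atoms2 <- readStructure(path2)
  expect_equal(nrow(atoms2), 2L)
  expect_setequal(atoms2$aa_code, c("GLY", "ALA"))
})

test_that("modified residues are kept and mapped to their parent for scale lookup", {
  path <- write_pdb(c(
    pdb_atom(1, "CA", "MSE", "A", 1, 0, 0, 0, record = "HETATM"),
    pdb_atom(2, "CA", "ALA", "A", 2, 3, 0, 0)))
  atoms <- readStructure(path)
  expect_equal(nrow(atoms), 2L)
  es <- effectiveAtoms(atoms)
  expect_equal(hydrophobicity(es)[1], scaleValue(defaultScale(), "MET"))
})

test_that("altloc conformers resolve to highest occupancy, ties by letter", {
  path <- write_pdb(c(
    pdb_atom(1, "CA", "GLY", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom(2, "CA", "GLY", "A", 1, 2, 0, 0, occ = 0.6, alt = "B"),
    pdb_atom(3, "CA", "ALA", "A", 2, 5, 0, 0, occ = 0.5, alt = "A"),
    pdb_atom(4, "CA", "ALA", "A", 2, 7, 0, 0, occ = 0.5, alt = "B")))
  atoms <- readStructure(path)
  expect_equal(nrow(atoms), 2L)
  expect_equal(atoms$x, c(2, 5))
})

test_that("selectUnit resolves ranges, orders fragments as listed, and flags empty fragments", {
  path <- write_pdb(c(
    pdb_atom(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom(2, "CA", "ALA", "A", 2, 3, 0, 0),
    pdb_atom(3, "CA", "LEU", "A", 3, 6, 0, 0),
    pdb_atom(4, "CA", "VAL", "A", 4, 9, 0, 0),
    pdb_atom(5, "CA", "SER", "A", 5, 12, 0, 0),
    pdb_atom(6, "CA", "TRP", "C", 10, 0, 5, 0),
    pdb_atom(7, "CA", "TYR", "C", 11, 3, 5, 0)))
  atoms <- readStructure(path)

  u <- selectUnit(atoms, "A:1-3")
  expect_equal(u$seq_id, 1:3)

  swapped <- selectUnit(atoms, parseSelection("C:10-11+A:2-4"))
  expect_equal(swapped$chain, c("C", "C", "A", "A", "A"))
  expect_equal(swapped$seq_id, c(10L, 11L, 2L, 3L, 4L))

  expect_error(selectUnit(atoms, "A:90-95"), "zero residues")
  expect_error(selectUnit(atoms, "Z:1-5"), "chain not present")
  expect_warning(selectUnit(atoms, "A:1-8"), "skipped")

  # idempotence: re-selecting the returned range returns the same residues
  again <- selectUnit(u, "A:1-3")
  expect_equal(again, u)
})

test_that("effective atoms are unweighted means, invariant to atom order, preserving residue order", {
  path <- tiny_pdb()
  atoms <- readStructure(path)
  es <- effectiveAtoms(atoms)
  expect_equal(nResidues(es), 3L)
  expect_equal(unname(coords(es)[1, ]), c(1, 0, 0))  # midpoint of (0,0,0),(2,0,0)
  expect_equal(residueTable(es)$aa_code, c("GLY", "ALA", "LYS"))

  shuffled <- atoms[c(2, 1, 4, 3, 6, 5), ]
  es2 <- effectiveAtoms(shuffled)
  expect_equal(coords(es2), coords(es))

  single <- effectiveAtoms(atoms[c(1, 3), ])
  expect_equal(unname(coords(single)[1, ]), c(0, 0, 0))
})

test_that("unknown residue types are excluded from the unit with a warning", {
  path <- write_pdb(c(
    pdb_atom(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom(2, "CA", "ALA", "A", 2, 3, 0, 0),
    pdb_atom(3, "CA", "UNK", "A", 3, 6, 0, 0)))
  atoms <- readStructure(path)
  expect_warning(es <- effectiveAtoms(atoms), "UNK")
  expect_equal(nResidues(es), 2L)
})

test_that("selection grammar parses fragments and round-trips through selectionString", {
  sel <- parseSelection("A:198-221+C:224-298")
  expect_equal(nrow(sel@fragments), 2L)
  expect_equal(sel@fragments$chain, c("A", "C"))
  expect_equal(sel@fragments$first, c(198L, 224L))
  expect_equal(selectionString(sel), "A:198-221+C:224-298")
  expect_equal(selectionString(parseSelection("B")), "B")
  expect_error(parseSelection("A:xx-yy"), "cannot parse")
  expect_error(unitSelection("A", 10, 5), "first <= last")
})

test_that("fixture files round-trip losslessly and reject malformed lines", {
  s <- makeMicelle(30, seed = 4)
  f <- tempfile(fileext = ".tsv")
  writeFixture(s, f)
  s2 <- readFixture(f)
  expect_equal(residueTable(s2)$chain, residueTable(s)$chain)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-6)       # 6-decimal text
  expect_lt(max(abs(hydrophobicity(s2) - hydrophobicity(s))), 1e-6)

  # another trip is exact: 6-decimal text is a fixed point
  f2 <- tempfile(fileext = ".tsv")
  writeFixture(s2, f2)
  expect_identical(readLines(f), readLines(f2))

  bad <- tempfile()
  writeLines(c("chain seq_id aa_code x y z hydro",
               "A 1 ALA 0 0 0 0.5",
               "A 2 ALA 1 oops 0 0.5"), bad)
  expect_error(readFixture(bad), "line 3")

  one <- data.frame(chain = "A", seq_id = 1L, aa_code = "ALA",
                    x = 0, y = 0, z = 0, hydro = 1)
  expect_error(new("EffectiveStructure", residues = one, unitLabel = "x"),
               "at least 2")
})

test_that("CA-only PDB export is readable and preserves coordinates", {
  s <- makeMicelle(25, seed = 9)
  f <- tempfile(fileext = ".pdb")
  writeCaPdb(s, f)
  es <- effectiveAtoms(readStructure(f))
  expect_equal(nResidues(es), 25L)
  expect_equal(coords(es), coords(s), tolerance = 1e-3)
})

test_that("the bundled scale covers the standard residues with documented values", {
  sc <- defaultScale()
  expect_equal(scaleCutoff(sc), 9.0)
  expect_equal(scaleValue(sc, "GLY"), 0.4556)
  expect_equal(scaleValue(sc, "ILE"), 1.0)
  expect_equal(scaleValue(sc, "ARG"), 0.0)
  expect_error(scaleValue(sc, "XXX"), "absent from scale")

  shipped <- system.file("extdata", "kyte_doolittle_normalized.tsv",
                         package = "fodm")
  lines <- sub("^# cutoff=.*$", "# cutoff=7.5", readLines(shipped))
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  expect_equal(scaleCutoff(loadScale(f)), 7.5)

  incomplete <- tempfile(fileext = ".tsv")
  writeLines(c("# cutoff=9.0", "ALA 0.3"), incomplete)
  expect_error(loadScale(incomplete), "lacks standard residues")
})
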
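# Coordinate input and residue reduction. Readers are thin wrappers over
# bio3d; everything downstream of them works on a plain atom table so that
# synthetic fixtures and deposited structures flow through the same code.

#' Read a PDB or mmCIF coordinate file
#'
#' Returns an atom table: one row per atom with author residue numbering
#' preserved. Waters and unrecognised heteroatom residues are excluded;
#' common modified residues with a standard parent (MSE and friends) are
#' kept. For multi-model (NMR) files only one model is used, the first by
#' default. When several alternate-location conformers of an atom are
#' present, the highest-occupancy one is kept, ties broken by altloc letter
#' order.
#'
#' @param source path to a coordinate file, or a 4-character PDB accession
#'   (fetched with [bio3d::get.pdb()], which requires network access).
#' @param format `"auto"` (by file extension), `"pdb"` or `"cif"`.
#' @param model 1-based model index for multi-model files.
#' @return a data.frame with columns `chain`, `seq_id`, `insert`,
#'   `aa_code`, `atom`, `x`, `y`, `z`, `occ`, `hetero`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      3  CA  ALA A   2       2.000   0.000   0.000  1.00  0.00           C",
#'   "END"), pdb)
#' atoms <- readStructure(pdb)
#' @export
readStructure <- function(source, format = c("auto", "pdb", "cif"),
                          model = 1L) {
  format <- match.arg(format)
  path <- source
  if (!file.exists(path)) {
    if (grepl("^[0-9][A-Za-z0-9]{3}$", source)) {
      path <- bio3d::get.pdb(source, path = tempdir(), verbose = FALSE)
    } else {
      stop("file not found and not a PDB accession: ", source)
    }
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  multi <- model > 1L
  obj <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, multi = multi, rm.alt = FALSE)
    else bio3d::read.pdb(path, multi = multi, rm.alt = FALSE),
    error = function(e) stop("cannot parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  atom <- obj$atom
  if (multi) {
    xyz <- obj$xyz
    if (model > nrow(xyz))
      stop("model index ", model, " exceeds ", nrow(xyz), " models")
    m <- matrix(xyz[model, ], ncol = 3L, byrow = TRUE)
    atom$x <- m[, 1]; atom$y <- m[, 2]; atom$z <- m[, 3]
  }
  resid <- toupper(atom$resid)
  water <- resid %in% c("HOH", "WAT", "DOD", "H2O")
  mapped <- resid %in% STANDARD_AA | resid %in% names(NONSTANDARD_PARENT)
  # polymer ATOM records stay (unknown codes are flagged downstream);
  # heteroatom records stay only for mapped modified residues
  keep <- !water & (atom$type == "ATOM" | mapped)
  atom <- atom[keep, , drop = FALSE]
  if (nrow(atom) == 0L)
    stop("no amino-acid residues found in '", path, "'")
  out <- data.frame(
    chain = as.character(atom$chain),
    seq_id = as.integer(atom$resno),
    insert = ifelse(is.na(atom$insert), "", as.character(atom$insert)),
    aa_code = toupper(as.character(atom$resid)),
    atom = as.character(atom$elety),
    x = atom$x, y = atom$y, z = atom$z,
    occ = ifelse(is.na(atom$o), 1, atom$o),
    hetero = atom$type != "ATOM",
    stringsAsFactors = FALSE)
  out$alt <- ifelse(is.na(atom$alt), "", as.character(atom$alt))
  dropAltlocs(out)
}

# keep the highest-occupancy conformer per atom; ties -> altloc letter order
dropAltlocs <- function(atoms) {
  if (!"alt" %in% names(atoms) || all(atoms$alt == ""))
    return(atoms[setdiff(names(atoms), "alt")])
  key <- paste(atoms$chain, atoms$seq_id, atoms$insert, atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms[setdiff(names(atoms), "alt")]
}

#' Resolve a unit selection against an atom table
#'
#' Concatenates the selected fragments in the order listed; within a
#' fragment, residues are sorted by ascending author number (insertion-coded
#' residues stay in file order at their shared number). Residue numbers
#' inside a range but absent from the structure are skipped with a warning.
#'
#' @param atoms atom table from [readStructure()].
#' @param selection a [UnitSelection-class] or selection string.
#' @return the subset of `atoms` for the unit, in unit order.
#' @export
selectUnit <- function(atoms, selection) {
  selection <- as_selection(selection)
  fr <- selection@fragments
  pieces <- vector("list", nrow(fr))
  for (i in seq_len(nrow(fr))) {
    if (!fr$chain[i] %in% atoms$chain)
      stop("selection fragment ", i, " (", fr$chain[i],
           "): chain not present in structure")
    sel <- atoms$chain == fr$chain[i]
    if (!is.na(fr$first[i]))
      sel <- sel & atoms$seq_id >= fr$first[i] & atoms$seq_id <= fr$last[i]
    piece <- atoms[sel, , drop = FALSE]
    if (nrow(piece) == 0L)
      stop("selection fragment '", fr$chain[i], ":", fr$first[i], "-",
           fr$last[i], "' resolves to zero residues")
    piece <- piece[order(piece$seq_id), , drop = FALSE]
    if (!is.na(fr$first[i])) {
      want <- fr$first[i]:fr$last[i]
      missing <- setdiff(want, unique(piece$seq_id))
      if (length(missing))
        warning("fragment ", fr$chain[i], ":", fr$first[i], "-", fr$last[i],
                ": ", length(missing),
                " residue number(s) in range have no coordinates and were skipped")
    }
    pieces[[i]] <- piece
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Reduce residues to effective atoms
#'
#' Each residue is represented by one effective atom at the unweighted
#' arithmetic mean of all its atom coordinates (hydrogens included when
#' present) and assigned the intrinsic hydrophobicity of its amino-acid
#' type from the scale. Residues whose code is neither in the scale nor
#' mappable to a standard parent are excluded with a warning.
#'
#' @param atoms atom table (typically the output of [selectUnit()]).
#' @param scale a [ScaleTable-class]; default [defaultScale()].
#' @param label unit label for the resulting structure.
#' @return an [EffectiveStructure-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  GLY A   1       2.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      3  CA  ALA A   2       2.000   3.000   0.000  1.00  0.00           C",
#'   "END"), pdb)
#' es <- effectiveAtoms(readStructure(pdb))
#' coords(es)   # GLY reduced to (1, 0, 0)
#' @export
effectiveAtoms <- function(atoms, scale = defaultScale(), label = "unit") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  key <- paste(atoms$chain, atoms$seq_id, atoms$insert, sep = "\r")
  key <- factor(key, levels = unique(key))   # preserve input residue order
  first <- !duplicated(key)
  aa <- atoms$aa_code[first]
  hv <- scaleValue(scale, aa, strict = FALSE)
  if (anyNA(hv)) {
    bad <- unique(aa[is.na(hv)])
    warning("excluding residue type(s) absent from scale '", scale@name,
            "': ", paste(bad, collapse = ", "))
  }
  res <- data.frame(
    chain = atoms$chain[first],
    seq_id = atoms$seq_id[first],
    aa_code = aa,
    x = as.numeric(tapply(atoms$x, key, mean)),
    y = as.numeric(tapply(atoms$y, key, mean)),
    z = as.numeric(tapply(atoms$z, key, mean)),
    hydro = hv,
    stringsAsFactors = FALSE)
  res <- res[!is.na(res$hydro), , drop = FALSE]
  rownames(res) <- NULL
  new("EffectiveStructure", residues = res, unitLabel = label)
}

#' Plain-text effective-structure fixtures
#'
#' Lossless round trip of an [EffectiveStructure-class] through a
#' whitespace-delimited text table, one residue per line:
#' `chain seq_id aa_code x y z hydro`, coordinates and hydrophobicities
#' written with six decimals, preceded by a one-line header.
#'
#' @param structure an [EffectiveStructure-class].
#' @param path file path.
#' @return `readFixture()` returns an [EffectiveStructure-class];
#'   `writeFixture()` returns `path` invisibly.
#' @examples
#' s <- makeMicelle(n = 20, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeFixture(s, f)
#' s2 <- readFixture(f)
#' all.equal(residueTable(s2), residueTable(s), tolerance = 1e-6)
#' @export
writeFixture <- function(structure, path) {
  stopifnot(is(structure, "EffectiveStructure"))
  res <- structure@residues
  lines <- c("chain seq_id aa_code x y z hydro",
             sprintf("%s %d %s %.6f %.6f %.6f %.6f",
                     res$chain, res$seq_id, res$aa_code,
                     res$x, res$y, res$z, res$hydro))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeFixture
#' @param label unit label; defaults to the file name.
#' @export
readFixture <- function(path, label = basename(path)) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("fixture '", path, "' has no residue lines")
  body <- lines[-1L]
  keep <- nzchar(trimws(body))
  parts <- strsplit(trimws(body[keep]), "\\s+")
  lineno <- which(keep) + 1L
  nf <- vapply(parts, length, 0L)
  if (any(nf != 7L))
    stop("malformed fixture line ", lineno[which(nf != 7L)[1]],
         " in '", path, "' (expected 7 fields)")
  num <- function(k)
    suppressWarnings(as.numeric(vapply(parts, `[`, "", k)))
  res <- data.frame(
    chain = vapply(parts, `[`, "", 1L),
    seq_id = as.integer(num(2L)),
    aa_code = vapply(parts, `[`, "", 3L),
    x = num(4L), y = num(5L), z = num(6L), hydro = num(7L),
    stringsAsFactors = FALSE)
  bad <- which(!stats::complete.cases(res))
  if (length(bad))
    stop("malformed fixture line ", lineno[bad[1]], " in '", path,
         "' (non-numeric field)")
  new("EffectiveStructure", residues = res, unitLabel = label)
}

#' Write an effective structure as a CA-only PDB file
#'
#' One `ATOM` record per residue, placing a CA atom at the effective
#' position. Used to exercise the PDB reader with synthetic fixtures;
#' intrinsic hydrophobicities are not stored in the PDB and are re-derived
#' from the residue codes on reading.
#'
#' @param structure an [EffectiveStructure-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCaPdb <- function(structure, path) {
  stopifnot(is(structure, "EffectiveStructure"))
  res <- structure@residues
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(res)), res$aa_code, substr(res$chain, 1, 1), res$seq_id,
    res$x, res$y, res$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Subset an effective structure with a unit selection
#'
#' Resolves a [UnitSelection-class] directly against the residues of an
#' existing [EffectiveStructure-class], keeping the hydrophobicities that
#' were already assigned. Fragments are concatenated in the order listed.
#'
#' @param structure an [EffectiveStructure-class].
#' @param selection a [UnitSelection-class] or selection string.
#' @return an [EffectiveStructure-class] for the selected residues.
#' @export
subsetUnit <- function(structure, selection) {
  stopifnot(is(structure, "EffectiveStructure"))
  selection <- as_selection(selection)
  res <- structure@residues
  fr <- selection@fragments
  pieces <- vector("list", nrow(fr))
  for (i in seq_len(nrow(fr))) {
    sel <- res$chain == fr$chain[i]
    if (!is.na(fr$first[i]))
      sel <- sel & res$seq_id >= fr$first[i] & res$seq_id <= fr$last[i]
    if (!any(sel))
      stop("selection fragment '", fr$chain[i], ":", fr$first[i], "-",
           fr$last[i], "' resolves to zero residues")
    piece <- res[sel, , drop = FALSE]
    pieces[[i]] <- piece[order(piece$seq_id), , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  new("EffectiveStructure", residues = out, unitLabel = selection@label)
}
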
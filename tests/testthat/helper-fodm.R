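# shared helpers: hand-written PDB fixtures and small random generators

pdb_atom <- function(serial, name, resn, chain, resno, x, y, z,
                     occ = 1, alt = " ", icode = " ", element = "C",
                     record = "ATOM  ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, sprintf(" %-3s", name), alt, resn, chain,
          resno, icode, x, y, z, occ, 0, element)
}

write_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a 3-residue single-chain PDB, 2 atoms per residue
tiny_pdb <- function() {
  write_pdb(c(
    pdb_atom(1, "N",  "GLY", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom(2, "CA", "GLY", "A", 1, 2, 0, 0),
    pdb_atom(3, "N",  "ALA", "A", 2, 0, 4, 0, element = "N"),
    pdb_atom(4, "CA", "ALA", "A", 2, 2, 4, 0),
    pdb_atom(5, "N",  "LYS", "A", 3, 0, 8, 0, element = "N"),
    pdb_atom(6, "CA", "LYS", "A", 3, 2, 8, 0)))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_simplex <- function(n, positive = TRUE) {
  v <- stats::runif(n, min = if (positive) 0.05 else 0)
  v / sum(v)
}
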
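#!/usr/bin/env Rscript
# Thin command-line front end over the fodm package.
#
#   Rscript scripts/fod.R status --structure FILE --selection "A:198-221+C:224-298" [--json OUT] [--profiles OUT.csv]
#   Rscript scripts/fod.R batch  --manifest FILE.csv --out TABLE.csv
#   Rscript scripts/fod.R synth  --kind micelle|uniform|modified|swapped \
#                                --n 100 --seed 1 [--ktrue 1.0] --out FIXTURE.tsv

suppressPackageStartupMessages({
  library(optparse)
  library(fodm)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: fod.R <status|batch|synth> [options]", call. = FALSE)
cmd <- args[1L]
rest <- args[-1L]

common <- list(
  make_option("--scale", type = "character", default = NULL,
              help = "TSV hydrophobicity scale (default: bundled)"),
  make_option("--cutoff", type = "double", default = NULL),
  make_option("--model", type = "integer", default = 1L))

config_from <- function(o) {
  scale <- if (is.null(o$scale)) defaultScale() else loadScale(o$scale)
  fodConfig(scale = scale, cutoff = o$cutoff, model = o$model)
}

if (cmd == "status") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--structure", type = "character"),
    make_option("--selection", type = "character", default = NULL),
    make_option("--label", type = "character", default = NULL),
    make_option("--json", type = "character", default = NULL),
    make_option("--profiles", type = "character", default = NULL)))),
    args = rest)
  cfg <- config_from(o)
  atoms <- readStructure(o$structure, model = cfg$model)
  sel <- if (is.null(o$selection)) {
    unitSelection(unique(atoms$chain),
                  label = if (is.null(o$label)) basename(o$structure)
                          else o$label)
  } else {
    parseSelection(o$selection,
                   label = if (is.null(o$label)) o$selection else o$label)
  }
  unit <- effectiveAtoms(selectUnit(atoms, sel), scale = cfg$scale,
                         label = sel@label)
  st <- fodStatus(unit, cfg)
  show(st)
  if (!is.null(o$json)) exportStatusJson(st, o$json)
  if (!is.null(o$profiles))
    write.csv(profileTable(unit, cfg), o$profiles, row.names = FALSE)
} else if (cmd == "batch") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--manifest", type = "character"),
    make_option("--out", type = "character", default = "batch.csv")))),
    args = rest)
  tb <- batchTable(o$manifest, config_from(o))
  writeBatchTable(tb, o$out)
  cat("wrote", o$out, "(", nrow(tb), "units )\n")
} else if (cmd == "synth") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--kind", type = "character", default = "micelle"),
    make_option("--n", type = "integer", default = 100L),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--ktrue", type = "double", default = 1.0),
    make_option("--pdb", action = "store_true", default = FALSE,
                help = "write a CA-only PDB instead of the fixture table"),
    make_option("--out", type = "character", default = "fixture.tsv"))),
    args = rest)
  s <- switch(o$kind,
    micelle = makeMicelle(o$n, o$seed),
    uniform = makeUniform(o$n, o$seed),
    modified = makeModified(o$n, o$seed, o$ktrue)$structure,
    swapped = makeSwappedPair(o$n, o$seed)$structure,
    stop("unknown --kind: ", o$kind))
  if (o$pdb) writeCaPdb(s, o$out) else writeFixture(s, o$out)
  cat("wrote", o$out, "\n")
} else {
  stop("unknown command '", cmd, "' (expected status, batch or synth)",
       call. = FALSE)
}
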
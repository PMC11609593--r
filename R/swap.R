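# Domain-swapping workflows: composed multi-chain units, guest-fragment
# contributions, batch tables, and profile averaging across homologues.

unit_from_source <- function(x, selection, config) {
  selection <- as_selection(selection)
  if (is(x, "EffectiveStructure"))
    return(subsetUnit(x, selection))
  atoms <- if (is.character(x))
    readStructure(x, model = config$model) else x
  stopifnot(is.data.frame(atoms))
  effectiveAtoms(selectUnit(atoms, selection), scale = config$scale,
                 label = selection@label)
}

#' @describeIn assessUnit from a PDB/mmCIF file path (or accession).
#' @export
setMethod("assessUnit", "character", function(x, selection, config) {
  fodStatus(unit_from_source(x, selection, config), config)
})

#' @describeIn assessUnit from an atom table ([readStructure()] output).
#' @export
setMethod("assessUnit", "data.frame", function(x, selection, config) {
  fodStatus(unit_from_source(x, selection, config), config)
})

#' @describeIn assessUnit from an [EffectiveStructure-class] (keeps the
#'   hydrophobicities already assigned, e.g. on synthetic fixtures).
#' @export
setMethod("assessUnit", "EffectiveStructure", function(x, selection, config) {
  fodStatus(unit_from_source(x, selection, config), config)
})

#' Contribution of a guest fragment to a host unit
#'
#' Assesses the host unit twice with identical configuration: alone, and
#' composed with the guest fragment donated by another chain. Both
#' assessments span their own Gaussian envelope over exactly the selected
#' residues, so "without guest" is a fresh unit, not a projection of the
#' combined one. A negative RD delta means the guest completes the common
#' hydrophobic core.
#'
#' @param x coordinate source: file path, atom table, or
#'   [EffectiveStructure-class].
#' @param host,guest disjoint [UnitSelection-class] objects (or selection
#'   strings).
#' @param config a [fodConfig()] list.
#' @return a [SwapAssessment-class].
#' @name guestContribution
NULL

guest_contribution_impl <- function(x, host, guest, config) {
  host <- as_selection(host); guest <- as_selection(guest)
  hostUnit <- unit_from_source(x, host, config)
  combinedSel <- new("UnitSelection",
                     fragments = rbind(host@fragments, guest@fragments),
                     label = paste0(host@label, "+", guest@label))
  combinedUnit <- unit_from_source(x, combinedSel, config)
  hkey <- with(hostUnit@residues, paste(chain, seq_id))
  ckey <- with(combinedUnit@residues, paste(chain, seq_id))
  if (length(ckey) <= length(hkey))
    stop("guest fragment resolves to zero residues beyond the host")
  if (anyDuplicated(ckey))
    stop("host and guest selections overlap")
  hs <- fodStatus(hostUnit, config)
  cs <- fodStatus(combinedUnit, config)
  new("SwapAssessment", hostStatus = hs, combinedStatus = cs,
      guestFragment = guest, deltaRd = cs@rd - hs@rd, deltaK = cs@k - hs@k)
}

#' @rdname guestContribution
#' @export
setMethod("guestContribution", "character", guest_contribution_impl)
#' @rdname guestContribution
#' @export
setMethod("guestContribution", "data.frame", guest_contribution_impl)
#' @rdname guestContribution
#' @export
setMethod("guestContribution", "EffectiveStructure", guest_contribution_impl)

#' Batch assessment of many structural units
#'
#' Runs [assessUnit()] over a manifest and collects one row per unit. A
#' failing unit is reported as a row with its error message instead of
#' aborting the batch.
#'
#' @param manifest a data.frame with columns `source` (file path or
#'   accession), `selection` (selection string, e.g. `"A:198-221+C:224-298"`;
#'   empty or `NA` selects all chains), `label`; or a path to a CSV (or
#'   YAML, if the yaml package is installed) file with those columns.
#' @param config a [fodConfig()] list.
#' @return data.frame with columns `source`, `label`, `fragments`, `N`,
#'   `RD`, `K`, `error` (NA when the unit succeeded). RD and K carry full
#'   precision; [writeBatchTable()] applies the conventional rounding.
#' @export
batchTable <- function(manifest, config = fodConfig()) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- if (grepl("\\.ya?ml$", manifest, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML manifests needs the yaml package")
      do.call(rbind, lapply(yaml::read_yaml(manifest), as.data.frame))
    } else {
      utils::read.csv(manifest, stringsAsFactors = FALSE)
    }
  }
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) == 0L) stop("empty manifest")
  need <- c("source", "selection", "label")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  atom_cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    src <- manifest$source[i]
    selstr <- manifest$selection[i]
    lab <- manifest$label[i]
    tryCatch({
      if (!is(src, "EffectiveStructure") && is.character(src)) {
        if (!exists(src, envir = atom_cache))
          assign(src, readStructure(src, model = config$model),
                 envir = atom_cache)
        obj <- get(src, envir = atom_cache)
      } else obj <- src
      sel <- if (is.na(selstr) || !nzchar(selstr)) {
        chains <- unique(if (is.data.frame(obj)) obj$chain
                         else obj@residues$chain)
        unitSelection(chains, label = lab)
      } else parseSelection(selstr, label = lab)
      st <- assessUnit(obj, sel, config)
      data.frame(source = if (is.character(src)) src else "<structure>",
                 label = lab, fragments = selectionString(sel),
                 N = st@N, RD = st@rd, K = st@k, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(source = if (is.character(src)) src else "<structure>",
                 label = lab,
                 fragments = if (is.na(selstr)) "" else selstr,
                 N = NA_integer_, RD = NA_real_, K = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname batchTable
#' @param table a [batchTable()] result.
#' @param path output CSV path.
#' @export
writeBatchTable <- function(table, path) {
  out <- table
  out$RD <- ifelse(is.na(out$RD), "", sprintf("%.3f", out$RD))
  out$K <- ifelse(is.na(out$K), "", sprintf("%.1f", out$K))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Average T/O/M profiles across homologous units
#'
#' Aligns per-residue profile tables by shared author numbering (the
#' chain + residue-number intersection across all units; no sequence
#' alignment), drops positions missing from any unit with a warning, and
#' returns the per-position arithmetic mean and population standard
#' deviation for each role, together with the average fitted K.
#'
#' @param tables list (length >= 2) of [profileTable()] outputs.
#' @param roles which profile columns to average.
#' @return list with `profiles` (data.frame: `chain`, `seq_id`, then
#'   `<role>_mean` and `<role>_sd` per role), `k` (mean fitted K) and
#'   `nUnits`.
#' @export
averageProfiles <- function(tables, roles = c("T", "O", "M")) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  keys <- lapply(tables, function(tb) paste(tb$chain, tb$seq_id, sep = "\r"))
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0L) stop("units share no residue numbering")
  dropped <- sum(vapply(keys, function(k) sum(!k %in% shared), 0L))
  if (dropped > 0L)
    warning(dropped, " position(s) missing from some units were dropped")
  aligned <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    tb[match(shared, keys[[i]]), , drop = FALSE]
  })
  base <- aligned[[1L]][, c("chain", "seq_id")]
  out <- base
  for (role in roles) {
    m <- vapply(aligned, function(tb) tb[[role]],
                numeric(length(shared)))
    m <- matrix(m, nrow = length(shared))
    out[[paste0(role, "_mean")]] <- rowMeans(m)
    out[[paste0(role, "_sd")]] <- sqrt(pmax(rowMeans(m^2) - rowMeans(m)^2, 0))
  }
  rownames(out) <- NULL
  ks <- vapply(tables, function(tb) {
    k <- attr(tb, "k"); if (is.null(k)) NA_real_ else k
  }, numeric(1))
  list(profiles = out, k = mean(ks), nUnits = length(tables))
}
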
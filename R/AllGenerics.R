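#' Accessors for fuzzy-oil-drop objects
#'
#' Small accessor generics used across the package in place of direct slot
#' access: residue counts, coordinates, hydrophobicities, profile values and
#' the components of a [FodStatus].
#'
#' @param x an object of the documented classes.
#' @return `nResidues()` an integer; `coords()` an N x 3 numeric matrix;
#'   `hydrophobicity()` a numeric vector; `residueTable()` a data.frame;
#'   `profileValues()` a numeric vector; `profileRole()` a character;
#'   `rdValue()`, `kValue()`, `klOT()`, `klOR()`, `klOM()` numerics;
#'   `unitLabel()` a character.
#'
#' @examples
#' s <- makeMicelle(n = 20, seed = 1)
#' nResidues(s)
#' head(coords(s))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("hydrophobicity", function(x) standardGeneric("hydrophobicity"))
#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("profileRole", function(x) standardGeneric("profileRole"))
#' @rdname accessors
#' @export
setGeneric("unitLabel", function(x) standardGeneric("unitLabel"))
#' @rdname accessors
#' @export
setGeneric("rdValue", function(x) standardGeneric("rdValue"))
#' @rdname accessors
#' @export
setGeneric("kValue", function(x) standardGeneric("kValue"))
#' @rdname accessors
#' @export
setGeneric("klOT", function(x) standardGeneric("klOT"))
#' @rdname accessors
#' @export
setGeneric("klOR", function(x) standardGeneric("klOR"))
#' @rdname accessors
#' @export
setGeneric("klOM", function(x) standardGeneric("klOM"))

#' @rdname accessors
#' @export
setMethod("nResidues", "EffectiveStructure",
          function(x) nrow(x@residues))
#' @rdname accessors
#' @export
setMethod("coords", "EffectiveStructure",
          function(x) as.matrix(x@residues[, c("x", "y", "z")]))
#' @rdname accessors
#' @export
setMethod("hydrophobicity", "EffectiveStructure",
          function(x) x@residues$hydro)
#' @rdname accessors
#' @export
setMethod("residueTable", "EffectiveStructure", function(x) x@residues)
#' @rdname accessors
#' @export
setMethod("profileValues", "HydroProfile", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("profileRole", "HydroProfile", function(x) x@role)
#' @rdname accessors
#' @export
setMethod("unitLabel", "EffectiveStructure", function(x) x@unitLabel)
#' @rdname accessors
#' @export
setMethod("unitLabel", "HydroProfile", function(x) x@unitLabel)
#' @rdname accessors
#' @export
setMethod("unitLabel", "FodStatus", function(x) x@unitLabel)
#' @rdname accessors
#' @export
setMethod("nResidues", "FodStatus", function(x) x@N)
#' @rdname accessors
#' @export
setMethod("rdValue", "FodStatus", function(x) x@rd)
#' @rdname accessors
#' @export
setMethod("kValue", "FodStatus", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("klOT", "FodStatus", function(x) x@dklOT)
#' @rdname accessors
#' @export
setMethod("klOR", "FodStatus", function(x) x@dklOR)
#' @rdname accessors
#' @export
setMethod("klOM", "FodStatus", function(x) x@dklOM)
#' @rdname accessors
#' @export
setMethod("rdValue", "SwapAssessment", function(x) x@deltaRd)

#' Assess a structural unit from a coordinate source
#'
#' Generic over the source of coordinates: a file path (PDB/mmCIF), an atom
#' table as returned by [readStructure()], or an [EffectiveStructure] whose
#' hydrophobicities are already assigned (synthetic fixtures). See
#' [assessUnit()] methods in the swap-analysis documentation.
#'
#' @param x coordinate source.
#' @param selection a [UnitSelection] or selection string.
#' @param config a [fodConfig()] list.
#' @export
setGeneric("assessUnit",
           function(x, selection, config = fodConfig())
             standardGeneric("assessUnit"))

#' @rdname guestContribution
#' @export
setGeneric("guestContribution",
           function(x, host, guest, config = fodConfig())
             standardGeneric("guestContribution"))
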
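#' @import methods
NULL

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Intrinsic hydrophobicity scale
#'
#' A `ScaleTable` maps three-letter amino-acid codes to intrinsic
#' hydrophobicity values \eqn{H^r} and carries the interaction cutoff
#' distance \eqn{c} used when summing pairwise hydrophobic contacts.
#' All twenty standard residues must be covered and values must be
#' non-negative; the package convention is a scale normalised to
#' \eqn{[0, 1]}.
#'
#' @slot values named numeric vector of \eqn{H^r}, names are 3-letter codes.
#' @slot name short identifier of the scale.
#' @slot cutoff interaction cutoff \eqn{c} in Angstroms.
#'
#' @seealso [loadScale()], [defaultScale()]
#' @export
setClass("ScaleTable",
         representation(values = "numeric", name = "character",
                        cutoff = "numeric"))

setValidity("ScaleTable", function(object) {
  msg <- character()
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff) ||
      object@cutoff <= 0)
    msg <- c(msg, "cutoff must be a single positive number")
  missing <- setdiff(STANDARD_AA, names(object@values))
  if (length(missing))
    msg <- c(msg, paste("scale lacks standard residues:",
                        paste(missing, collapse = ", ")))
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "scale values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Multi-fragment residue selection
#'
#' A `UnitSelection` defines a structural unit as an ordered list of
#' inclusive residue ranges, each on a named chain. Fragments may come from
#' different chains, which is how swapped domains such as
#' `A:198-221+C:224-298` are composed. Ranges use author (PDB) numbering
#' and are inclusive on both ends. A fragment whose bounds are `NA` selects
#' the whole chain.
#'
#' @slot fragments data.frame with columns `chain`, `first`, `last`.
#' @slot label unit label used in reports.
#'
#' @seealso [parseSelection()]
#' @export
setClass("UnitSelection",
         representation(fragments = "data.frame", label = "character"))

setValidity("UnitSelection", function(object) {
  fr <- object@fragments
  if (!all(c("chain", "first", "last") %in% names(fr)))
    return("fragments must have columns chain, first, last")
  if (nrow(fr) == 0L)
    return("selection must contain at least one fragment")
  bad <- !is.na(fr$first) & !is.na(fr$last) & fr$first > fr$last
  if (any(bad))
    return("each fragment must satisfy first <= last")
  TRUE
})

#' Effective-atom representation of a structural unit
#'
#' The unit of all profile computation: each residue is reduced to a single
#' effective atom (the unweighted mean of its atom coordinates) carrying an
#' intrinsic hydrophobicity \eqn{H^r}. Residue order follows fragment order,
#' then ascending author numbering within a fragment.
#'
#' @slot residues data.frame with columns `chain`, `seq_id`, `aa_code`,
#'   `x`, `y`, `z`, `hydro`.
#' @slot unitLabel label of the structural unit.
#'
#' @seealso [effectiveAtoms()], [fodStatus()]
#' @export
setClass("EffectiveStructure",
         representation(residues = "data.frame", unitLabel = "character"))

setValidity("EffectiveStructure", function(object) {
  res <- object@residues
  need <- c("chain", "seq_id", "aa_code", "x", "y", "z", "hydro")
  if (!all(need %in% names(res)))
    return(paste("residues must have columns:", paste(need, collapse = ", ")))
  if (nrow(res) < 2L)
    return("a structural unit needs at least 2 residues")
  xyz <- as.matrix(res[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    return("all effective coordinates must be finite")
  if (any(!is.finite(res$hydro)) || any(res$hydro < 0))
    return("intrinsic hydrophobicities must be finite and >= 0")
  TRUE
})

#' Fitted 3D Gaussian envelope
#'
#' The Gaussian capsule spanned over a structural unit: its centre, the
#' per-axis standard deviations adjusted to the size and shape of the unit,
#' and the orthonormal principal-axis frame in which the axis-wise Gaussian
#' factors are evaluated.
#'
#' @slot center numeric(3), centre of the envelope in Angstroms.
#' @slot sigmas numeric(3), per-axis sigma in Angstroms, all positive.
#' @slot rotation 3x3 orthonormal matrix (determinant +1) whose columns map
#'   molecule coordinates into the envelope frame.
#'
#' @seealso [fitEnvelope()], [tProfile()]
#' @export
setClass("GaussianEnvelope",
         representation(center = "numeric", sigmas = "numeric",
                        rotation = "matrix"))

setValidity("GaussianEnvelope", function(object) {
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    return("center must be numeric(3)")
  if (length(object@sigmas) != 3L || any(!is.finite(object@sigmas)) ||
      any(object@sigmas <= 0))
    return("sigmas must be three positive numbers")
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)))
    return("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal")
  if (det(R) < 0)
    return("rotation must have determinant +1")
  TRUE
})

#' Per-residue hydrophobicity distribution
#'
#' A normalised per-residue distribution tagged with its role: `T`
#' (theoretical, from the Gaussian envelope), `O` (observed, from pairwise
#' interactions), `R` (uniform reference) or `M` (environment-modified).
#' Values are non-negative and sum to one; `T`-role values are strictly
#' positive by construction.
#'
#' @slot values numeric vector of per-residue probabilities.
#' @slot role one of `"T"`, `"O"`, `"R"`, `"M"`.
#' @slot unitLabel label of the unit the profile describes.
#'
#' @export
setClass("HydroProfile",
         representation(values = "numeric", role = "character",
                        unitLabel = "character"))

setValidity("HydroProfile", function(object) {
  if (length(object@role) != 1L || !object@role %in% c("T", "O", "R", "M"))
    return("role must be one of T, O, R, M")
  v <- object@values
  if (length(v) < 2L)
    return("a profile needs at least 2 positions")
  if (any(!is.finite(v)) || any(v < 0))
    return("profile values must be finite and >= 0")
  if (abs(sum(v) - 1) > 1e-6)
    return("profile values must sum to 1")
  if (object@role == "T" && any(v <= 0))
    return("T-role profiles must be strictly positive")
  TRUE
})

#' Fuzzy-oil-drop status of a structural unit
#'
#' The summary statistics of one assessment: the two divergences against the
#' theoretical and uniform references, the relative distance RD, and the
#' fitted environment parameter K with its residual divergence. RD below 0.5
#' indicates the presence of a centric hydrophobic core; K = 0 means the
#' unit matches the pattern preferred by a polar aqueous environment.
#'
#' @slot unitLabel unit label.
#' @slot N residue count.
#' @slot dklOT Kullback-Leibler divergence of O from T, in bits.
#' @slot dklOR Kullback-Leibler divergence of O from the uniform R, in bits.
#' @slot rd relative distance, `dklOT / (dklOT + dklOR)`.
#' @slot k fitted environment parameter, >= 0.
#' @slot dklOM divergence of O from M at the fitted K, in bits.
#'
#' @seealso [fodStatus()], [assessUnit()]
#' @export
setClass("FodStatus",
         representation(unitLabel = "character", N = "integer",
                        dklOT = "numeric", dklOR = "numeric", rd = "numeric",
                        k = "numeric", dklOM = "numeric"))

setValidity("FodStatus", function(object) {
  if (object@dklOT < 0 || object@dklOR < 0 || object@dklOM < 0)
    return("divergences must be >= 0")
  if (object@k < 0)
    return("K must be >= 0")
  tot <- object@dklOT + object@dklOR
  expect <- if (tot == 0) 0 else object@dklOT / tot
  if (abs(object@rd - expect) > 1e-9)
    return("RD must equal dklOT / (dklOT + dklOR)")
  TRUE
})

#' Guest-fragment contribution assessment
#'
#' Pairs the status of a host unit assessed alone with the status of the
#' host plus a guest fragment donated by another chain, both computed with
#' identical configuration. Negative `deltaRd` means the guest improves the
#' common hydrophobic core.
#'
#' @slot hostStatus [FodStatus] of the host unit without the guest.
#' @slot combinedStatus [FodStatus] of host plus guest.
#' @slot guestFragment the guest [UnitSelection].
#' @slot deltaRd combined RD minus host RD.
#' @slot deltaK combined K minus host K.
#'
#' @seealso [guestContribution()]
#' @export
setClass("SwapAssessment",
         representation(hostStatus = "FodStatus",
                        combinedStatus = "FodStatus",
                        guestFragment = "UnitSelection",
                        deltaRd = "numeric", deltaK = "numeric"))

## show methods ---------------------------------------------------------

setMethod("show", "ScaleTable", function(object) {
  cat("ScaleTable '", object@name, "': ", length(object@values),
      " residues, cutoff ", object@cutoff, " A\n", sep = "")
})

setMethod("show", "UnitSelection", function(object) {
  cat("UnitSelection '", object@label, "': ",
      selectionString(object), "\n", sep = "")
})

setMethod("show", "EffectiveStructure", function(object) {
  res <- object@residues
  cat("EffectiveStructure '", object@unitLabel, "': ", nrow(res),
      " residues on chain(s) ",
      paste(unique(res$chain), collapse = ", "), "\n", sep = "")
})

setMethod("show", "GaussianEnvelope", function(object) {
  cat(sprintf("GaussianEnvelope: center (%.2f, %.2f, %.2f) A, sigmas (%.2f, %.2f, %.2f) A\n",
              object@center[1], object@center[2], object@center[3],
              object@sigmas[1], object@sigmas[2], object@sigmas[3]))
})

setMethod("show", "HydroProfile", function(object) {
  cat("HydroProfile role=", object@role, " ('", object@unitLabel, "'), N=",
      length(object@values), "\n", sep = "")
})

setMethod("show", "FodStatus", function(object) {
  core <- if (object@rd < 0.5) "hydrophobic core present"
          else "no centric hydrophobic core"
  cat("FodStatus '", object@unitLabel, "' (N=", object@N, ")\n",
      sprintf("  RD = %.3f (%s)\n", object@rd, core),
      sprintf("  K  = %.1f\n", object@k),
      sprintf("  D_KL(O|T) = %.4f bits, D_KL(O|R) = %.4f bits, D_KL(O|M) = %.4f bits\n",
              object@dklOT, object@dklOR, object@dklOM),
      sep = "")
})

setMethod("show", "SwapAssessment", function(object) {
  cat("SwapAssessment (guest '", object@guestFragment@label, "')\n", sep = "")
  cat(sprintf("  host:     RD = %.3f, K = %.1f\n",
              object@hostStatus@rd, object@hostStatus@k))
  cat(sprintf("  combined: RD = %.3f, K = %.1f\n",
              object@combinedStatus@rd, object@combinedStatus@k))
  cat(sprintf("  delta RD = %+.3f, delta K = %+.2f\n",
              object@deltaRd, object@deltaK))
})

setMethod("length", "HydroProfile", function(x) length(x@values))
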
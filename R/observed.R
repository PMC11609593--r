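# Observed hydrophobicity: distance-weighted pairwise hydrophobic
# interactions between effective atoms.

#' Hydrophobic interaction weight
#'
#' The polynomial contact function of the inter-residue distance `r` and
#' cutoff `c`:
#' \deqn{w(r) = 1 - \tfrac12\left(7(r/c)^2 - 9(r/c)^4 + 5(r/c)^6 -
#'   (r/c)^8\right)} for \eqn{r \le c} and 0 beyond the cutoff. It decays
#' smoothly from 1 at contact to exactly 0 at `r = c`.
#'
#' @param r distance(s) in Angstroms, >= 0.
#' @param c cutoff in Angstroms, > 0.
#' @return weights in `[0, 1]`, same length as `r`.
#' @examples
#' interactionWeight(c(0, 4.5, 9), c = 9)
#' @export
interactionWeight <- function(r, c = 9) {
  if (any(r < 0)) stop("distances must be non-negative")
  if (length(c) != 1L || c <= 0) stop("cutoff must be a single positive number")
  x2 <- (r / c)^2
  w <- 1 - 0.5 * (7 * x2 - 9 * x2^2 + 5 * x2^3 - x2^4)
  w[r > c] <- 0
  w
}

#' Observed hydrophobicity profile O
#'
#' For each residue the unnormalised observed level collects its hydrophobic
#' interactions with every other residue within the cutoff:
#' \deqn{\tilde O_i = \sum_{j \ne i} (H^r_i + H^r_j)\, w(r_{ij}, c),}
#' where \eqn{H^r} are the intrinsic hydrophobicities carried by the
#' structure and \eqn{r_{ij}} are distances between effective atoms. The
#' profile is normalised to sum to one. A unit in which no pair interacts
#' (all weights zero) has no observed distribution and raises an error.
#'
#' @param structure an [EffectiveStructure-class].
#' @param cutoff interaction cutoff in Angstroms; default 9.0, the package
#'   convention carried by [defaultScale()].
#' @param includeSelf also add the self term `2 H^r_i w(0) = 2 H^r_i`
#'   (off by default: O expresses inter-residue interaction).
#' @return a [HydroProfile-class] with role `"O"`.
#' @export
oProfile <- function(structure, cutoff = 9, includeSelf = FALSE) {
  stopifnot(is(structure, "EffectiveStructure"))
  H <- hydrophobicity(structure)
  D <- as.matrix(stats::dist(coords(structure)))
  W <- interactionWeight(D, cutoff)
  diag(W) <- if (includeSelf) 1 else 0
  raw <- unname(H * rowSums(W)) + as.vector(W %*% H)
  if (sum(raw) <= 0)
    stop("degenerate observed profile: no hydrophobic interactions within ",
         cutoff, " A in unit '", structure@unitLabel, "'")
  new("HydroProfile", values = raw / sum(raw), role = "O",
      unitLabel = structure@unitLabel)
}
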
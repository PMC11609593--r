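# The 3D Gaussian envelope and the theoretical hydrophobicity profile T.

#' Fit the 3D Gaussian envelope of a structural unit
#'
#' The envelope centre is the mean of the effective-atom positions and its
#' axes are the principal axes of their covariance, so the fit is
#' independent of the deposited coordinate frame. Along each principal
#' axis the sigma is set by the 3-sigma bounding rule: the largest absolute
#' coordinate after centring and rotation, divided by `sigmaFactor`
#' (default 3), so the whole unit lies within three sigmas of the centre.
#' Degenerate directions (near-collinear or coincident points) are floored
#' at `sigmaFloor` with a warning.
#'
#' @param structure an [EffectiveStructure-class].
#' @param sigmaFactor divisor of the maximal extent per axis; default 3.
#' @param sigmaFloor minimal admissible sigma in Angstroms; default 1.0.
#' @return a [GaussianEnvelope-class].
#' @examples
#' pts <- rbind(c(3,0,0), c(-3,0,0), c(0,3,0), c(0,-3,0), c(0,0,3), c(0,0,-3))
#' s <- effectiveStructureFromPoints(pts, hydro = rep(1, 6))
#' fitEnvelope(s)   # center (0,0,0), sigmas (1,1,1)
#' @export
fitEnvelope <- function(structure, sigmaFactor = 3, sigmaFloor = 1.0) {
  stopifnot(is(structure, "EffectiveStructure"),
            sigmaFactor > 0, sigmaFloor > 0)
  X <- coords(structure)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  V <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)$vectors
  if (det(V) < 0) V[, 3L] <- -V[, 3L]
  Y <- Xc %*% V
  sig <- apply(abs(Y), 2L, max) / sigmaFactor
  if (any(sig < sigmaFloor)) {
    warning("degenerate geometry: sigma floored at ", sigmaFloor,
            " A on ", sum(sig < sigmaFloor), " axis/axes")
    sig <- pmax(sig, sigmaFloor)
  }
  new("GaussianEnvelope", center = center, sigmas = sig, rotation = V)
}

#' Theoretical hydrophobicity profile T
#'
#' Evaluates the fitted 3D Gaussian at each residue's effective position:
#' the unnormalised value is the product of the three axis-wise Gaussian
#' factors in the envelope frame,
#' \deqn{\tilde T_i = e^{-x_i^2 / 2\sigma_x^2} e^{-y_i^2 / 2\sigma_y^2}
#'   e^{-z_i^2 / 2\sigma_z^2},}
#' and the profile is the distribution \eqn{T_i = \tilde T_i / \sum_j
#' \tilde T_j}. All values are strictly positive.
#'
#' @param envelope a [GaussianEnvelope-class]; fitted from `structure` when
#'   omitted.
#' @param structure an [EffectiveStructure-class].
#' @return a [HydroProfile-class] with role `"T"`.
#' @export
tProfile <- function(structure, envelope = fitEnvelope(structure)) {
  stopifnot(is(structure, "EffectiveStructure"),
            is(envelope, "GaussianEnvelope"))
  Y <- sweep(coords(structure), 2L, envelope@center) %*% envelope@rotation
  g <- exp(-rowSums(sweep(Y^2, 2L, 2 * envelope@sigmas^2, "/")))
  new("HydroProfile", values = g / sum(g), role = "T",
      unitLabel = structure@unitLabel)
}

#' Build an effective structure from bare points
#'
#' Convenience constructor for tests and geometric experiments: wraps an
#' N x 3 coordinate matrix and per-point hydrophobicities into an
#' [EffectiveStructure-class] on a single synthetic chain.
#'
#' @param points numeric N x 3 matrix of positions in Angstroms.
#' @param hydro numeric vector of intrinsic hydrophobicities (recycled).
#' @param chain chain identifier.
#' @param label unit label.
#' @param aa residue codes (recycled); cosmetic for synthetic units.
#' @return an [EffectiveStructure-class].
#' @export
effectiveStructureFromPoints <- function(points, hydro = 1, chain = "A",
                                         label = "points", aa = "ALA") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  n <- nrow(points)
  res <- data.frame(chain = rep_len(chain, n), seq_id = seq_len(n),
                    aa_code = rep_len(aa, n),
                    x = points[, 1], y = points[, 2], z = points[, 3],
                    hydro = rep_len(hydro, n), stringsAsFactors = FALSE)
  new("EffectiveStructure", residues = res, unitLabel = label)
}

#' Apply a rigid-body motion to an effective structure
#'
#' Rotates and translates all effective positions; hydrophobicities and
#' identities are untouched. Used to check frame invariance of the model.
#'
#' @param structure an [EffectiveStructure-class].
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric(3) shift in Angstroms.
#' @return the transformed [EffectiveStructure-class].
#' @export
transformStructure <- function(structure, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  stopifnot(is(structure, "EffectiveStructure"))
  X <- coords(structure) %*% t(rotation)
  X <- sweep(X, 2L, translation, "+")
  res <- structure@residues
  res$x <- X[, 1]; res$y <- X[, 2]; res$z <- X[, 3]
  new("EffectiveStructure", residues = res, unitLabel = structure@unitLabel)
}
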
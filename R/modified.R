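# Environment-modified distribution M and the environment parameter K.

#' Environment-modified distribution M
#'
#' Blends the theoretical distribution with its "membrane-like" complement:
#' \deqn{\tilde M_i = T_i + K (T_{MAX} - T_i),} normalised to a
#' distribution, where \eqn{T_{MAX}} is the maximum of the unit's
#' normalised T values (not the analytic Gaussian peak). `K = 0`
#' reproduces T exactly (pure aqueous, micelle-like); `K = 1` lifts every
#' residue to \eqn{T_{MAX}}, i.e. the uniform distribution; larger K
#' inverts the pattern towards hydrophobicity exposed at the surface.
#'
#' @param T_ theoretical profile ([HydroProfile-class] or normalised
#'   numeric vector).
#' @param K environment parameter, >= 0.
#' @return a [HydroProfile-class] with role `"M"`.
#' @examples
#' mProfile(c(0.5, 0.3, 0.2), K = 1)   # uniform
#' @export
mProfile <- function(T_, K) {
  if (length(K) != 1L || !is.finite(K) || K < 0)
    stop("K must be a single number >= 0")
  t <- profile_values(T_)
  lab <- if (is(T_, "HydroProfile")) T_@unitLabel else "unit"
  m <- t + K * (max(t) - t)
  new("HydroProfile", values = m / sum(m), role = "M", unitLabel = lab)
}

#' Fit the environment parameter K
#'
#' Finds the K >= 0 whose modified distribution best fits the observed one,
#' by minimising \eqn{D_{KL}(O\,|\,M(T, K))} over a grid: a coarse pass of
#' step `kStep` on `[0, kMax]`, refined at step `kFine` around the coarse
#' minimum. Ties are broken towards smaller K.
#'
#' @param O,T_ observed and theoretical profiles of equal length.
#' @param kMax upper bound of the search grid (default 10, safely above
#'   reported K values which stay below ~2.5).
#' @param kStep coarse grid step (default 0.1).
#' @param kFine refinement step (default 0.01).
#' @return list with elements `k` (fitted K) and `dkl` (divergence of O
#'   from M at the fitted K, in bits).
#' @export
fitK <- function(O, T_, kMax = 10, kStep = 0.1, kFine = 0.01) {
  o <- profile_values(O); t <- profile_values(T_)
  stopifnot(length(o) == length(t), kMax > 0, kStep > 0, kFine > 0)
  obj <- function(k) klDivergence(o, profile_values(mProfile(t, k)))
  ks <- seq(0, kMax, by = kStep)
  d <- vapply(ks, obj, numeric(1))
  k0 <- ks[which.min(d)]
  ks2 <- seq(max(0, k0 - kStep), min(kMax, k0 + kStep), by = kFine)
  d2 <- vapply(ks2, obj, numeric(1))
  best <- which.min(d2)
  list(k = ks2[best], dkl = d2[best])
}
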
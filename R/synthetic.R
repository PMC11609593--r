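# Synthetic effective-atom generators with controlled statistics: fixtures
# whose observed distribution follows T (RD near 0), follows the uniform R
# (RD near 1), or follows M(K) for a chosen K (parameter-recovery tests).
# All generators are deterministic given (parameters, seed). They make no
# attempt at realistic protein geometry.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# cosmetic residue codes: the standard residue whose scale value is
# nearest the assigned hydrophobicity
nearest_aa <- function(h, scale = defaultScale()) {
  v <- scale@values[STANDARD_AA]
  STANDARD_AA[apply(abs(outer(h, v, "-")), 1L, which.min)]
}

#' Synthetic micelle-like unit
#'
#' Samples `n` effective atoms from a 3D Gaussian cloud and assigns each
#' point an intrinsic hydrophobicity proportional to its own theoretical
#' level, rescaled to `[0, 1]` -- core points hydrophobic, shell points
#' polar. Assessed with the default configuration, the observed
#' distribution tracks T: RD stays well below 0.5 and the fitted K is ~0.
#'
#' @param n number of residues, >= 10.
#' @param seed RNG seed; the generator is deterministic given
#'   `(n, seed, sigmas)`.
#' @param sigmas per-axis standard deviations of the generating Gaussian in
#'   Angstroms. The default, 6 A isotropic, gives the ~35 A diameter of a
#'   compact ~100-residue domain.
#' @return an [EffectiveStructure-class] on synthetic chain A.
#' @examples
#' rdValue(fodStatus(makeMicelle(n = 100, seed = 1)))
#' @export
makeMicelle <- function(n, seed = 1L, sigmas = c(6, 6, 6)) {
  stopifnot(n >= 10, length(sigmas) == 3L, all(sigmas > 0))
  X <- with_seed(seed, matrix(stats::rnorm(3L * n, 0, rep(sigmas, each = n)),
                              nrow = n))
  s <- effectiveStructureFromPoints(X, hydro = 1,
                                    label = sprintf("micelle_n%d_s%d", n, seed))
  t <- tProfile(s)@values
  h <- (t - min(t)) / (max(t) - min(t))
  s@residues$hydro <- h
  s@residues$aa_code <- nearest_aa(h)
  s
}

#' Synthetic uniform-hydrophobicity unit
#'
#' Places `n` points on a compact cubic lattice (tiny seeded jitter breaks
#' exact ties) with one constant intrinsic hydrophobicity, so the observed
#' distribution is nearly featureless while the Gaussian envelope still
#' assigns a strongly peaked T: assessed RD approaches 1. The default
#' spacing keeps every pair well inside the interaction cutoff so that all
#' contact weights are close and the observed spread stays below
#' `0.1 / n`.
#'
#' @param n number of residues, >= 8 (lattice side is `ceiling(n^(1/3))`).
#' @param seed RNG seed for the jitter.
#' @param spacing lattice spacing in Angstroms.
#' @param hydro the constant intrinsic hydrophobicity.
#' @return an [EffectiveStructure-class].
#' @examples
#' rdValue(fodStatus(makeUniform(n = 125, seed = 1)))
#' @export
makeUniform <- function(n, seed = 1L, spacing = 0.3, hydro = 0.5) {
  stopifnot(n >= 8, spacing > 0, hydro > 0)
  side <- ceiling(n^(1 / 3))
  g <- seq(0, by = spacing, length.out = side)
  g <- g - mean(g)
  X <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(n), , drop = FALSE]
  X <- X + with_seed(seed, matrix(stats::rnorm(3L * n, 0, spacing * 0.01),
                                  nrow = n))
  s <- effectiveStructureFromPoints(X, hydro = hydro,
                                    label = sprintf("uniform_n%d_s%d", n, seed))
  s@residues$aa_code <- nearest_aa(rep(hydro, n))
  s
}

#' Synthetic unit whose observed profile follows M(T, K)
#'
#' Generates the same Gaussian geometry as [makeMicelle()] and then solves
#' for intrinsic hydrophobicities that make the observed distribution
#' approximate the environment-modified target \eqn{M(T, K_{true})}. The
#' observed profile is linear in the hydrophobicities, so a damped
#' multiplicative update (ratio clipped to `[0.5, 2]`, square-root damping,
#' rescaled to max 1) converges to a non-negative solution; points with no
#' neighbour inside the cutoff cannot reach their target and are left
#' where the clip puts them.
#'
#' @param n number of residues, >= 10.
#' @param seed RNG seed.
#' @param kTrue the environment parameter the observed profile should
#'   encode, >= 0. `kTrue = 0` reproduces micelle-like statistics.
#' @param sigmas generating Gaussian sigmas, as in [makeMicelle()].
#' @param cutoff interaction cutoff used when solving, in Angstroms.
#' @param iterations fixed-point iterations.
#' @return list with elements `structure` ([EffectiveStructure-class]) and
#'   `kTrue`.
#' @examples
#' fx <- makeModified(n = 200, seed = 1, kTrue = 1)
#' kValue(fodStatus(fx$structure))   # recovers ~1
#' @export
makeModified <- function(n, seed = 1L, kTrue = 0, sigmas = c(6, 6, 6),
                         cutoff = 9, iterations = 200L) {
  stopifnot(n >= 10, kTrue >= 0)
  X <- with_seed(seed, matrix(stats::rnorm(3L * n, 0, rep(sigmas, each = n)),
                              nrow = n))
  s <- effectiveStructureFromPoints(
    X, hydro = 1, label = sprintf("modified_k%g_n%d_s%d", kTrue, n, seed))
  t <- tProfile(s)@values
  target <- mProfile(t, kTrue)@values
  W <- interactionWeight(as.matrix(stats::dist(X)), cutoff)
  diag(W) <- 0
  rs <- rowSums(W)
  h <- target / max(target)
  for (it in seq_len(iterations)) {
    o <- h * rs + as.vector(W %*% h)
    o <- o / sum(o)
    ratio <- pmin(pmax(target / pmax(o, 1e-12), 0.5), 2)
    h <- h * sqrt(ratio)
    h <- h / max(h)
  }
  s@residues$hydro <- h
  s@residues$aa_code <- nearest_aa(h)
  list(structure = s, kTrue = kTrue)
}

#' Synthetic swapped-domain pair
#'
#' Builds one micelle-like cloud and splits it into a host "chain" A and a
#' guest "chain" B by a plane through the cloud, mimicking a domain
#' completed by a fragment donated from another chain. With
#' `complete = TRUE` the guest carries the hydrophobicities that finish the
#' common core, so the combined unit scores a lower RD than the host alone
#' (negative RD delta in [guestContribution()]). With `complete = FALSE`
#' the guest's hydrophobicities are inverted (polar core, hydrophobic
#' surface) and the guest degrades the core instead.
#'
#' @param n total number of residues, >= 20.
#' @param seed RNG seed.
#' @param complete whether the guest completes the hydrophobic core.
#' @param sigmas generating Gaussian sigmas.
#' @param hostFraction fraction of points assigned to the host chain.
#' @return list with elements `structure` ([EffectiveStructure-class]
#'   holding both chains), `host` and `guest` ([UnitSelection-class],
#'   disjoint).
#' @examples
#' sp <- makeSwappedPair(n = 120, seed = 1, complete = TRUE)
#' guestContribution(sp$structure, sp$host, sp$guest)
#' @export
makeSwappedPair <- function(n, seed = 1L, complete = TRUE,
                            sigmas = c(6, 6, 6), hostFraction = 0.55) {
  stopifnot(n >= 20, hostFraction > 0.2, hostFraction < 0.8)
  X <- with_seed(seed, matrix(stats::rnorm(3L * n, 0, rep(sigmas, each = n)),
                              nrow = n))
  s <- effectiveStructureFromPoints(X, hydro = 1, label = "swapped_pair")
  t <- tProfile(s)@values
  h <- (t - min(t)) / (max(t) - min(t))
  isHost <- X[, 1L] <= stats::quantile(X[, 1L], hostFraction)
  if (!complete) h[!isHost] <- 1 - h[!isHost]
  nh <- sum(isHost); ng <- n - nh
  res <- data.frame(
    chain = c(rep("A", nh), rep("B", ng)),
    seq_id = c(seq_len(nh), seq_len(ng)),
    aa_code = nearest_aa(c(h[isHost], h[!isHost])),
    x = c(X[isHost, 1L], X[!isHost, 1L]),
    y = c(X[isHost, 2L], X[!isHost, 2L]),
    z = c(X[isHost, 3L], X[!isHost, 3L]),
    hydro = c(h[isHost], h[!isHost]),
    stringsAsFactors = FALSE)
  structure <- new("EffectiveStructure", residues = res,
                   unitLabel = sprintf("swapped_n%d_s%d_%s", n, seed,
                                       if (complete) "complete" else "broken"))
  list(structure = structure,
       host = unitSelection("A", 1L, nh, label = "host_A"),
       guest = unitSelection("B", 1L, ng, label = "guest_B"))
}
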
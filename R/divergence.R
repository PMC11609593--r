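# Kullback-Leibler comparison of hydrophobicity distributions, the RD
# statistic, per-residue excess/deficiency status, and re-assessment after
# residue elimination.

profile_values <- function(p) {
  if (is(p, "HydroProfile")) p@values else as.numeric(p)
}

#' Kullback-Leibler divergence between two profiles
#'
#' \eqn{D_{KL}(P|Q) = \sum_i P_i \log_2(P_i/Q_i)} in bits, with the usual
#' convention \eqn{0 \log(0/q) = 0}. Both inputs must be normalised
#' distributions of equal length, and `Q` must be positive wherever `P` is.
#'
#' @param p,q [HydroProfile-class] objects or normalised numeric vectors.
#' @return divergence in bits (non-negative).
#' @examples
#' klDivergence(c(1, 0), c(0.5, 0.5))   # exactly 1 bit
#' @export
klDivergence <- function(p, q) {
  P <- profile_values(p); Q <- profile_values(q)
  if (length(P) != length(Q))
    stop("profiles have different lengths (", length(P), " vs ", length(Q), ")")
  if (abs(sum(P) - 1) > 1e-6 || abs(sum(Q) - 1) > 1e-6)
    stop("profiles must be normalised")
  i <- P > 0
  if (any(Q[i] <= 0))
    stop("divergence undefined: reference is zero where P is positive")
  sum(P[i] * log2(P[i] / Q[i]))
}

#' Uniform reference profile R
#'
#' The distribution devoid of any hydrophobic core: every residue carries
#' `1/n`.
#'
#' @param n number of residues, >= 2.
#' @param label unit label.
#' @return a [HydroProfile-class] with role `"R"`.
#' @export
rProfile <- function(n, label = "uniform") {
  stopifnot(n >= 2)
  new("HydroProfile", values = rep(1 / n, n), role = "R", unitLabel = label)
}

#' Relative distance RD between observed and theoretical distributions
#'
#' \deqn{RD = \frac{D_{KL}(O|T)}{D_{KL}(O|T) + D_{KL}(O|R)}}
#' with `R` the uniform reference of the same length. RD < 0.5 indicates a
#' centric hydrophobic core (O closer to T than to featureless R); RD > 0.5
#' its absence. When O, T and R all coincide both divergences vanish and RD
#' is defined as 0 with a warning.
#'
#' @param O,T_ observed and theoretical profiles ([HydroProfile-class] or
#'   normalised numeric vectors of equal length).
#' @return RD in `[0, 1]`.
#' @export
relativeDistance <- function(O, T_) {
  o <- profile_values(O); t <- profile_values(T_)
  dOT <- klDivergence(o, t)
  dOR <- klDivergence(o, rep(1 / length(o), length(o)))
  if (dOT + dOR == 0) {
    warning("O, T and R coincide; RD defined as 0")
    return(0)
  }
  dOT / (dOT + dOR)
}

#' Per-residue hydrophobicity excess and deficiency
#'
#' Classifies each residue by the sign of \eqn{O_i - T_i}: `excess`
#' (above `tau`) marks potential protein-protein interface patches,
#' `deficiency` (below `-tau`) marks potential ligand-binding cavities,
#' and `matched` otherwise. Magnitudes are always reported; over a unit
#' they sum to zero because both profiles are normalised.
#'
#' @param O,T_ observed and theoretical profiles.
#' @param tau non-negative threshold on `|O_i - T_i|`; default 0.
#' @return data.frame with columns `index`, `delta` (= `O_i - T_i`) and
#'   `status`.
#' @export
residueStatus <- function(O, T_, tau = 0) {
  o <- profile_values(O); t <- profile_values(T_)
  stopifnot(length(o) == length(t), tau >= 0)
  delta <- o - t
  status <- ifelse(delta > tau, "excess",
                   ifelse(delta < -tau, "deficiency", "matched"))
  data.frame(index = seq_along(delta), delta = delta, status = status,
             stringsAsFactors = FALSE)
}

#' Re-assess a unit after eliminating residues
#'
#' Removes the named residues and recomputes the full assessment (envelope
#' re-fit, T, O, RD and K) on the remainder as a fresh structural unit --
#' the operation behind statements like "eliminating the loose loop lowers
#' RD below 0.5". Elimination is explicit (indices or a selection); no
#' automated search is performed.
#'
#' @param structure an [EffectiveStructure-class].
#' @param exclude integer residue indices (positions in the unit), or a
#'   [UnitSelection-class]/selection string naming chain ranges to drop.
#'   `NULL` or empty excludes nothing.
#' @param config a [fodConfig()] list.
#' @return a [FodStatus-class] for the reduced unit.
#' @export
rdExcluding <- function(structure, exclude = NULL, config = fodConfig()) {
  stopifnot(is(structure, "EffectiveStructure"))
  res <- structure@residues
  drop <- rep(FALSE, nrow(res))
  if (is.numeric(exclude) && length(exclude)) {
    stopifnot(all(exclude >= 1), all(exclude <= nrow(res)))
    drop[as.integer(exclude)] <- TRUE
  } else if (is.character(exclude) || is(exclude, "UnitSelection")) {
    sel <- as_selection(exclude)
    fr <- sel@fragments
    for (i in seq_len(nrow(fr))) {
      hit <- res$chain == fr$chain[i]
      if (!is.na(fr$first[i]))
        hit <- hit & res$seq_id >= fr$first[i] & res$seq_id <= fr$last[i]
      drop <- drop | hit
    }
  }
  if (all(!drop)) return(fodStatus(structure, config))
  if (sum(!drop) < 2L)
    stop("exclusion leaves fewer than 2 residues in unit '",
         structure@unitLabel, "'")
  kept <- res[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  reduced <- new("EffectiveStructure", residues = kept,
                 unitLabel = paste0(structure@unitLabel, " (reduced)"))
  fodStatus(reduced, config)
}
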
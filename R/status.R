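# Orchestration: configuration and the full per-unit assessment.

#' Assessment configuration
#'
#' Collects every tunable of the pipeline in one list so that paired
#' analyses (host vs host+guest, batches, mutants) are guaranteed to use
#' identical settings.
#'
#' @param scale a [ScaleTable-class]; default [defaultScale()].
#' @param cutoff interaction cutoff in Angstroms; defaults to the cutoff
#'   carried by `scale`.
#' @param sigmaFactor divisor for the envelope sigma bounding rule
#'   (see [fitEnvelope()]).
#' @param sigmaFloor minimal envelope sigma in Angstroms.
#' @param kMax,kStep,kFine K-search grid (see [fitK()]).
#' @param includeSelf include the self term in the observed profile.
#' @param model model index for multi-model coordinate files.
#' @param tau threshold for [residueStatus()] classification.
#' @return a named list of class `"fodConfig"`.
#' @export
fodConfig <- function(scale = defaultScale(), cutoff = NULL,
                      sigmaFactor = 3, sigmaFloor = 1.0,
                      kMax = 10, kStep = 0.1, kFine = 0.01,
                      includeSelf = FALSE, model = 1L, tau = 0) {
  stopifnot(is(scale, "ScaleTable"))
  if (is.null(cutoff)) cutoff <- scaleCutoff(scale)
  structure(list(scale = scale, cutoff = cutoff, sigmaFactor = sigmaFactor,
                 sigmaFloor = sigmaFloor, kMax = kMax, kStep = kStep,
                 kFine = kFine, includeSelf = includeSelf,
                 model = as.integer(model), tau = tau),
            class = "fodConfig")
}

#' Full fuzzy-oil-drop assessment of a structural unit
#'
#' Runs the whole pipeline on an effective structure: fits the Gaussian
#' envelope, evaluates the theoretical (T) and observed (O) distributions,
#' compares them through Kullback-Leibler divergence against the uniform
#' reference (RD), and fits the environment parameter K of the modified
#' distribution M.
#'
#' @param structure an [EffectiveStructure-class].
#' @param config a [fodConfig()] list.
#' @return a [FodStatus-class].
#' @examples
#' s <- makeMicelle(n = 50, seed = 7)
#' fodStatus(s)
#' @export
fodStatus <- function(structure, config = fodConfig()) {
  stopifnot(is(structure, "EffectiveStructure"))
  env <- fitEnvelope(structure, sigmaFactor = config$sigmaFactor,
                     sigmaFloor = config$sigmaFloor)
  T_ <- tProfile(structure, env)
  O <- oProfile(structure, cutoff = config$cutoff,
                includeSelf = config$includeSelf)
  dOT <- klDivergence(O, T_)
  dOR <- klDivergence(O, rProfile(length(O)))
  rd <- if (dOT + dOR == 0) 0 else dOT / (dOT + dOR)
  kf <- fitK(O, T_, kMax = config$kMax, kStep = config$kStep,
             kFine = config$kFine)
  new("FodStatus", unitLabel = structure@unitLabel,
      N = nResidues(structure), dklOT = dOT, dklOR = dOR, rd = rd,
      k = kf$k, dklOM = kf$dkl)
}

#' Per-residue profile table for a unit
#'
#' Computes T, O and M (at the fitted K) for a unit and returns them as a
#' per-residue table ready for CSV export, plotting or averaging across
#' homologous structures. The fitted K and RD are attached as attributes
#' `"k"` and `"rd"`.
#'
#' @param structure an [EffectiveStructure-class].
#' @param config a [fodConfig()] list.
#' @return data.frame with columns `chain`, `seq_id`, `aa_code`, `T`, `O`,
#'   `M`, `delta` (O - T) and `status`.
#' @export
profileTable <- function(structure, config = fodConfig()) {
  stopifnot(is(structure, "EffectiveStructure"))
  env <- fitEnvelope(structure, sigmaFactor = config$sigmaFactor,
                     sigmaFloor = config$sigmaFloor)
  T_ <- tProfile(structure, env)
  O <- oProfile(structure, cutoff = config$cutoff,
                includeSelf = config$includeSelf)
  kf <- fitK(O, T_, kMax = config$kMax, kStep = config$kStep,
             kFine = config$kFine)
  M <- mProfile(T_, kf$k)
  st <- residueStatus(O, T_, tau = config$tau)
  res <- structure@residues
  out <- data.frame(chain = res$chain, seq_id = res$seq_id,
                    aa_code = res$aa_code,
                    T = T_@values, O = O@values, M = M@values,
                    delta = st$delta, status = st$status,
                    stringsAsFactors = FALSE)
  dOT <- klDivergence(O, T_)
  dOR <- klDivergence(O, rProfile(length(O)))
  attr(out, "k") <- kf$k
  attr(out, "rd") <- if (dOT + dOR == 0) 0 else dOT / (dOT + dOR)
  attr(out, "unitLabel") <- structure@unitLabel
  out
}

#' Export a unit status as a JSON record
#'
#' Writes `{label, N, D_KL_OT, D_KL_OR, RD, K, D_KL_OM}` with full
#' precision (table outputs round RD to 3 decimals and K to 1, JSON does
#' not).
#'
#' @param status a [FodStatus-class].
#' @param path output file; when `NULL` the JSON string is returned.
#' @export
exportStatusJson <- function(status, path = NULL) {
  stopifnot(is(status, "FodStatus"))
  rec <- list(label = status@unitLabel, N = status@N,
              D_KL_OT = status@dklOT, D_KL_OR = status@dklOR,
              RD = status@rd, K = status@k, D_KL_OM = status@dklOM)
  if (is.null(path))
    return(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
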
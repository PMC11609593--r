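---
title: "The fuzzy-oil-drop model in fodm: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fuzzy-oil-drop model in fodm: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodm)
```

## The model and its assumptions

The model assumes that a polypeptide folding in polar water tends towards a
micelle-like arrangement: hydrophobic residues concentrated in a centric
core, polar residues on the surface. A structural unit is any set of
residues assessed as one body — a domain, a chain, a complex, or a domain
composed of fragments donated by different chains (domain swapping). Each
residue is collapsed to an *effective atom*, the unweighted mean of all its
atom coordinates (hydrogens included when present), carrying an intrinsic
hydrophobicity $H^r$ from a residue-type scale.

Four per-residue distributions, all normalised to sum to one over the
unit's $N$ residues, carry the analysis:

* **T** — a 3D Gaussian envelope is fitted over the unit and evaluated at
  the effective positions. Its value is the hydrophobicity an idealised
  micelle would put at that point: maximal in the centre, vanishing at the
  surface.
* **O** — the hydrophobicity actually observed, collected from pairwise
  interactions: $\tilde O_i = \sum_{j \neq i}(H^r_i + H^r_j)\,w(r_{ij},c)$
  with the polynomial contact weight
  $w(r) = 1-\tfrac12\!\left(7x^2-9x^4+5x^6-x^8\right)$, $x = r/c$,
  which decays smoothly from 1 at contact to 0 at the cutoff $c$.
* **R** — the uniform distribution $R_i = 1/N$: no core at all.
* **M** — the environment-modified reference
  $\tilde M_i = T_i + K\,(T_{\mathrm{MAX}} - T_i)$, where
  $T_{\mathrm{MAX}}$ is the maximum of the unit's normalised T values.
  $K=0$ reproduces T; $K=1$ is uniform; $K>1$ progressively inverts the
  pattern towards the membrane-like ideal of hydrophobicity exposed at the
  surface.

Two statistics summarise a unit. The relative distance
$$\mathrm{RD} = \frac{D_{KL}(O|T)}{D_{KL}(O|T)+D_{KL}(O|R)}$$
(divergences in bits, base-2 logarithm) places O between the two
references: RD $<$ 0.5 indicates a centric hydrophobic core, RD $>$ 0.5
its absence. The environment parameter $K$ is fitted by minimising
$D_{KL}(O\,|\,M(K))$ and is read as the degree of contribution of an
environment different from polar water. Per residue, the sign of
$O_i - T_i$ classifies local *excess* (candidate protein–protein
interface) versus *deficiency* (candidate ligand cavity).

For swapped domains, the question is what a guest fragment contributes to
the host's core: the host is assessed alone and together with the guest,
each time with a freshly fitted envelope over exactly the selected
residues, and the RD/K deltas are reported. Likewise, re-assessment after
eliminating named residues (a loose loop, say) is a full recomputation on
the remaining residues as a new unit; the package deliberately provides no
automated search for which residues to eliminate.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| scale | Kyte–Doolittle rescaled to $[0,1]$ | intrinsic $H^r$ per residue type |
| cutoff $c$ | 9.0 Å | range of the contact weight in O |
| sigmaFactor | 3 | envelope $\sigma$ = max extent along a principal axis / 3 |
| sigmaFloor | 1.0 Å | minimal $\sigma$ for degenerate directions |
| kMax, kStep, kFine | 10, 0.1, 0.01 | K-search grid and refinement |
| tau | 0 | threshold for excess/deficiency classification |

The intrinsic scale and cutoff are configuration, not model constants: the
scale ships as a plain TSV (`loadScale()` substitutes any other), and every
analysis records which one was used through the `fodConfig()` object, so
paired analyses are guaranteed identical settings. Absolute RD values do
depend on these choices; comparisons *within* one configuration are the
robust use of the model. The K grid bound of 10 is far above values seen
in practice (K rarely exceeds ~2.5).

## Numerical choices

* **Envelope orientation.** The envelope axes are the principal axes of the
  effective-position covariance, making every result independent of the
  deposited coordinate frame; the test suite checks RD is stable to
  1e-9 under random rigid motions. Axis signs are irrelevant because only
  absolute coordinates enter the sigma rule.
* **Degenerate geometry.** Collinear or coincident points give a vanishing
  extent on some axis; sigmas are floored at `sigmaFloor` with a warning
  rather than refused, because tiny synthetic and fragment units are
  legitimate inputs.
* **Zero handling in divergences.** $0\log(0/q)=0$; T is strictly positive
  by construction so $D_{KL}(O|T)$ is always defined; an O that is zero
  where a reference is zero contributes nothing. A unit with *no*
  interacting pair within the cutoff has no observed distribution and is
  rejected as degenerate.
* **K fitting.** Coarse grid step 0.1 on $[0, 10]$, refined at 0.01 around
  the coarse minimum, ties broken towards smaller K (so O = T yields
  exactly K = 0). The objective is $D_{KL}(O|M)$ — "the best fit of the
  modified theoretical distribution to the observed one" — which reduces
  to the plain O-vs-T divergence at K = 0 and therefore can never be worse
  than it.
* **RD edge case.** If O, T and R all coincide both divergences vanish;
  RD is defined as 0 with a warning.
* **Coordinate input.** Author (PDB) numbering throughout, ranges inclusive
  on both ends; insertion-coded residues ride along in file order at their
  number. Highest-occupancy altloc conformer only (ties by letter). First
  model of multi-model files unless configured otherwise. Waters and
  unrecognised heteroatoms are excluded; modified residues with a standard
  parent (MSE → MET, …) are kept and looked up under the parent. Missing
  side chains are averaged over whatever atoms exist — the effective atom
  has no completeness requirement.
* **Reported precision.** Tables round RD to 3 decimals and K to 1, the
  convention of the field's summary tables; JSON exports keep full
  precision. RD is compared against 0.5 unrounded.

## The synthetic generators

Every stage is testable without downloads through generators that emulate
effective-atom clouds of known statistics; all are deterministic given
(parameters, seed).

* `makeMicelle(n, seed, sigmas)` samples a 3D Gaussian cloud (default
  isotropic σ = 6 Å, the bulk of a compact ~100-residue domain) and
  assigns each point $H^r$ proportional to its own T value rescaled to
  $[0,1]$ — the simplest rule that makes O track T through the contact
  weighting. Assessed, it lands at RD ≈ 0.05–0.13 with K = 0.
* `makeUniform(n, seed, spacing)` places points on a compact cubic lattice
  (spacing 0.3 Å, tiny seeded jitter) with one constant $H^r$: all contact
  weights are nearly equal, so O is featureless (spread below $0.1/n$)
  while the envelope still concentrates T centrally — RD ≈ 0.99. The
  deliberately sub-Ångström lattice triggers the degenerate-sigma warning;
  that is the fixture's point, not an accident.
* `makeModified(n, seed, kTrue)` keeps the micelle geometry but solves for
  hydrophobicities whose O approximates $M(T, K_{true})$. O is linear in
  $H^r$, and a damped multiplicative fixed-point update (ratio clipped to
  $[1/2, 2]$, square-root damping, 200 iterations) converges to a
  non-negative solution; isolated points with no neighbour inside the
  cutoff cannot reach their target and are left clipped. Fitted K recovers
  $K_{true} \in \{0.5, 1, 2\}$ within ±0.2 at $n = 200$.
* `makeSwappedPair(n, seed, complete)` splits one micelle cloud by a plane
  into a host "chain" A and guest "chain" B. With `complete = TRUE` the
  guest carries the hydrophobicities that finish the core and the
  combined unit beats the host alone (negative RD delta); with
  `complete = FALSE` the guest's $H^r$ are inverted and it degrades the
  core instead.

What the generators do **not** emulate: bonded geometry, secondary
structure, realistic packing densities, sequence statistics, or
experimental noise. Passing tests therefore demonstrate that the
statistical machinery — envelope fitting, profile construction, divergence
comparison, K recovery, guest deltas — behaves correctly on clouds with
controlled hydrophobicity patterns; they do not validate biological
conclusions about any particular protein.

## Design choices where the design was open

* **Sigma rule.** "Adjusted to the size and shape" admits several
  conventions; the package uses the 3-sigma bounding rule on principal
  axes (max |coordinate| / 3), the standard choice in this model family,
  with the divisor configurable.
* **$T_{\mathrm{MAX}}$** is the maximum of the unit's *normalised* T
  values, not the analytic Gaussian peak — the two differ whenever no
  residue sits exactly at the centre.
* **Self term in O.** Excluded by default (O expresses *inter*-residue
  interaction); a flag enables the self-inclusive variant for calibration
  against other implementations.
* **Default scale.** The model family does not fix a unique scale; the
  bundled one is Kyte–Doolittle linearly rescaled to $[0,1]$, chosen for
  transparency and familiarity. Because of this freedom, reproducing
  third-party RD/K tables to the third decimal may require substituting
  the original authors' scale/cutoff/sigma convention via `fodConfig()` —
  the qualitative classification (RD below/above 0.5) is much less
  sensitive.
* **Averaging across homologues** (mutant series sharing numbering) aligns
  positions by the chain + author-number intersection — no sequence
  alignment — and reports per-position mean and *population* standard
  deviation (divide by $n$), plus the mean fitted K.
* **Elimination is explicit.** `rdExcluding()` takes named indices or
  ranges; searching for a minimal set achieving RD < 0.5 is out of scope.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic units
of 27–200 residues (15 K-recovery fits at $n = 200$ are the largest item),
sizes chosen to match the domains the model is typically applied to while
keeping a full run in seconds on one core. The pipeline itself is
$O(N^2)$ in the pairwise distance matrix and comfortably handles
multi-chain complexes of a few thousand residues.

## Known limitations

* Absolute RD/K values depend on the scale, cutoff and sigma convention;
  cross-study comparisons need matched configuration.
* Units are defined on deposited chains; no biological-assembly expansion,
  superposition or geometry repair is performed.
* Disulfide bonds, catalytic-site and interface annotations are inputs
  (passed through to reports), never computed.
* The effective-atom reduction discards side-chain orientation; two
  rotamers with the same centroid are indistinguishable to the model.

## A worked assessment

```{r}
mic <- makeMicelle(n = 100, seed = 1)
fodStatus(mic)

sp <- makeSwappedPair(n = 120, seed = 1, complete = TRUE)
guestContribution(sp$structure, sp$host, sp$guest)
```

```{r, fig.width = 7, fig.height = 4}
plotProfiles(mic)
```
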
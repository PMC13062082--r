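---
title: "Quantifying cleavage-competent GPS geometry, conservation and kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cleavage-competent GPS geometry, conservation and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpscleave)
```

## The problem

Adhesion G-protein coupled receptors (aGPCRs) carry a GAIN domain that can
cleave itself at the GPCR proteolysis site (GPS), a His-X-Ser/Thr triad in
which the histidine acts as a general base: it abstracts the hydroxyl
proton of the Ser/Thr at GPS.+1, and the resulting alkoxide attacks the
carbonyl carbon of the scissile peptide bond between GPS.-1 and GPS.+1
(an N→O acyl shift followed by ester hydrolysis). Whether a given
receptor actually cleaves depends on how often its conformational
ensemble visits geometries in which this first step is feasible.
`gpscleave` turns that question into numbers: per-conformer geometric
descriptors of catalytic competence, ensemble-level summaries, structure
comparison and editing tools for rotamer what-if analyses, ortholog
conservation profiles, and a kinetic model for the (often extremely slow)
autocleavage of purified ectodomains.

## Per-conformer descriptors

For each conformer the package measures, at the GPS:

* **Attack angles** `theta_x`, `theta_y`. A local orthonormal frame is
  anchored at the scissile carbonyl carbon C: `x` along C→N (the leaving
  amide nitrogen of GPS.+1), `z` along the peptide-plane normal
  `(O−C) × (N−C)`, and `y = z × x` in-plane. The two angles are measured
  between the C→Oγ direction and the `x` and `y` axes. Perpendicular
  (Bürgi–Dunitz-like optimal) attack gives `(90, 90)`; because the axes
  are orthogonal, `cos²θx + cos²θy ≤ 1` always holds. The in-plane
  reference could equally be anchored on C→O; we fix C→N because the
  covalently tethered nucleophile then produces the characteristic
  low-`theta_x` cluster near (25, 72) that dominates unreactive
  conformers, and perpendicular attack keeps the interpretable (90, 90)
  optimum. A conformer is inside the **attack window** when both angles
  lie in [60, 120] (90 ± 30, inclusive at both edges).
* **Hydrogen-bond geometry** between the base and the nucleophile: the
  heavy-atom distance `d(N⋯Oγ)` to the accepting imidazole nitrogen, and
  the deviation of the O–H⋯N angle from linearity. With explicit
  hydrogens (MD frames) the measured hydrogen is used; otherwise the
  hydroxyl hydrogen is idealised on the cone with |O–H| = 0.96 Å and a
  C–O–H angle of 108.5°, at the cone position minimising the deviation
  (closed form: the in-plane position towards the acceptor). A geometry
  is **favourable** when `d ≤ 3.2 Å` (inclusive) and the deviation is
  `< 30°` (strict). The acceptor nitrogen follows the declared tautomer
  (HSE → Nδ, HSD → Nε); for structures without hydrogens the `best`
  policy (smaller distance) or an explicit choice is available.
* **χ1 rotamer bins** for the base and the nucleophile, assigned to +60
  (p), −60 (m) or 180 (t) when the circular distance to the canonical
  value is strictly below 30°, otherwise unassigned; the 180 bin wraps
  across ±180.
* **ω planarity strain** of the scissile bond: the smaller circular
  distance of the Cα-C-N-Cα torsion to 180° (trans) or 0° (cis), with
  **strained** meaning strictly more than 25° deviation.
* **φ/ψ of GPS.+1**, by the standard backbone definitions; undefined
  torsions at chain ends propagate as `NA`, never as sentinel values.

A conformer is **GPS-active** when it is inside the attack window *and*
has a favourable hydrogen bond. All boundary semantics follow the
defining criteria literally (inclusive distance and window, strict angle
and strain cutoffs); they are centralised in one place in the package so
bit-exact recounts are possible.

## Ensemble summaries

`summarize_conditions()` counts, per replica, the frames in the attack
window, with a favourable H-bond, and their conjunction, plus χ1-bin
percentages over all frames (the unassigned bin closes the partition) and
strain counts over all and over active frames; `merge_replicas()` pools
replicas by summing counts and reweighting percentages by frame numbers.
`theta_density()` bins (θx, θy) on a half-open, lower-inclusive grid over
[0, 180]² (default 1°; totals are conserved exactly, the single value 180
falls in the last bin). `strain_enrichment()` reports the percentage of
strained frames among active frames and among all frames and their ratio
— the observation that strain is strongly enriched in reactive
conformations is the scientific point this number carries. With no active
frames the enrichment is undefined and reported as `NA`.
`rmsf_profile()` superposes every frame onto a reference (first frame, or
a mean structure iterated to self-consistency: at most 10 iterations or a
mean change below 1e-6 Å) over a selectable alignment set — the default
is all Cα atoms, since trajectory practice varies and no single choice is
canonical — and reports per-atom root mean square fluctuations about the
time-mean positions.

## Structure editing and comparison

`set_chi1()` rigidly rotates everything distal to CB about the CA–CB axis
to a target χ1 (exact to 1e-6°, side-chain internal geometry untouched);
`flip_imidazole()` performs the physical 180° χ2 rotation of the ring.
Because the imidazole is only approximately symmetric, the flipped Nδ
lands near — within a few tenths of an Ångström, not exactly on — the
former position of its ring counterpart; we implement the flip as a
rotation rather than an atom-name swap so slightly non-ideal rings stay
physically consistent. These two edits together express the rotamer
what-if that turns a crystallographically observed unreactive triad into
a hydrogen-bond-capable one.

`kabsch_superpose()` is the SVD (Kabsch) least-squares superposition with
the proper-rotation correction; `pair_common_calpha()` pairs residues of
two chains by global sequence alignment (match +1 / mismatch −1 / gap −2
by default) and keeps aligned non-gap columns with resolved Cα atoms, so
disordered loops drop out of the pairing naturally;
`rmsd_outlier_trim()` iteratively removes pairs deviating by more than a
threshold (default 3.5 Å, standard core-superposition practice) until
convergence. How "common Cα atoms" were selected for published pairwise
RMSD figures is usually not fully specified; the sequence-alignment
pairing above is this package's operational definition, and both plain
and trimmed modes are exposed.

## Conservation

`column_profile()` and `shannon_entropy()` compute per-column residue
frequencies and `H = −Σ p log p` over ortholog alignments. Gaps are
excluded and frequencies renormalised by default (a `count_as_symbol`
policy is available); ambiguity codes are rejected under the strict
policy or optionally converted to gaps. The logarithm base defaults to
natural log, with bits and a log-20 normalisation available, since
published conservation colourings rarely state the base.
`map_entropy_to_structure()` matches an alignment row to a structure
chain (≥ 95 % identity required) and exports per-residue entropies into
the B-factor column of a PDB file for visualisation.

## Kinetics

Slow autocleavage of purified HormR-GAIN ectodomains follows a
first-order reaction towards complete cleavage, so the cleavage fraction
(in percent, `100·NTF/(NTF+FL)` from band intensities) is modelled as a
one-phase decay with the plateau fixed at 100 %:

    f(t) = 100 + (f0 − 100) · exp(−k t),    half-life = ln 2 / k

with `t` in days and `t = 0` at elution after purification; transfection
sits at −2 days, and back-extrapolating the fitted curve there
distinguishes constructs that cleaved mostly before purification from
those that did not. `fit_one_phase_decay()` estimates `(k, f0)` by
Levenberg–Marquardt nonlinear least squares with `k` constrained
positive, deterministic initialisation (log-linear regression of
`100 − f` for `k`, the earliest observation for `f0`) and standard errors
from the Jacobian at the optimum; parameter tolerances are set to
machine-level (1e-15 relative) so exact data are recovered exactly.
Replicates are fitted as independent observations by default, preserving
the error structure; an `aggregate = "mean"` mode fits per-timepoint
means for parity with mean ± SD plots. The returned `decay_fit` object
carries the usual modelling methods (`print`, `summary`, `coef`,
`predict`, `residuals`, `plot`, `simulate`, plus `extrapolate()`).

## Synthetic data and what passing tests show

Every analysis stage has a seeded generator with machine-readable ground
truth:

* `build_gps_model()` / `build_gps_fixture()` construct idealised
  His-Leu-Ser conformers (standard bond lengths/angles, an L-configured
  backbone, a planar imidazole) with prescribed backbone torsions, χ1
  values, scissile ω, and either a covalent or an explicitly placed Oγ at
  requested (θx, θy, d) in the attack frame. A planted Nδ⋯Oγ distance is
  realised exactly by a closed-form ring rotation about CB–CG (the
  squared distance is sinusoidal in the rotation), choosing the solution
  with the better hydrogen-bond linearity; geometrically impossible
  requests fail loudly with the achievable range rather than being
  silently adjusted. Jitter is an independent wrapped Gaussian per angle
  (default jitters 0; the clustered-ensemble checks use 5°, the mixture
  checks 3–6°), with jointly infeasible attack-angle draws redrawn —
  truncation that does not move the interior mode. Per-frame realised
  values, bins and flags are recorded as the planted truth.
* `synth_kinetics()` draws time courses on the 0/1/2/4/7/10/14-day design
  with Gaussian noise (optionally truncated to [0, 100] %).
* `synth_alignment()` samples alignment columns from known profiles.

These fixtures are *geometric, not chemical*: an off-covalent Oγ
placement, a jitter model with independent angles, and a tripeptide
stripped of its domain context are nothing like a force-field ensemble of
a glycosylated GAIN domain in water. Passing round trips therefore
demonstrate that the measurement, counting and fitting machinery is
exact on known inputs — not that any real receptor has a particular
active-frame count. Real-data conclusions additionally require the
deposited crystal structures and trajectories as inputs; the descriptor
definitions applied there are identical.

## Problem sizes and numerical choices

The shipped checks use ensembles of 10^2–10^4 synthetic conformers
(10,000 for density-mode and RMSF closed-form checks, where the
mode of a 1°-binned grid is still sampling-noise-limited, so modes are
read from 3° bins), 500 simulated kinetic experiments at 2 % noise, and
10,000-row sampled alignments. Torsion measurement, frame construction
and superposition agree with independent brute-force oracles
(spherical construction, dense cone sampling, a quaternion-eigenvalue
superposition, circular-distance grids) to 1e-6 degrees or 1e-9 Å as
appropriate; multi-model PDB coordinates round-trip at the format's
0.001 Å precision. Degenerate geometry (coincident or collinear points,
all-gap columns, empty ensembles, unreachable planted distances) raises
explicit errors, never silent zeros.

## Known limitations

* mmCIF reading is supported through the same interface as PDB, but
  compressed MD trajectory formats are out of scope; ensembles enter as
  multi-model PDB (or are built in memory).
* The attack-frame in-plane axis convention (C→N) is a documented choice;
  an ensemble analysed under a C→O convention would swap the roles of the
  two in-plane angles.
* Protonation states are never predicted: tautomers are taken from
  explicit hydrogens or declared by the user.
* The conservation module consumes existing alignments; ortholog
  retrieval and alignment construction happen upstream.
* Strain flags summarise single-bond planarity only; no energetic
  statement is attached to them.
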
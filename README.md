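# gpscleave

Geometric and kinetic analysis of GAIN-domain autoproteolysis at the
GPCR proteolysis site (GPS) of adhesion GPCRs, for structural biologists
working with crystal structures, predicted models and MD conformational
ensembles of these receptors.

Many adhesion GPCRs cleave themselves within the GAIN domain at the GPS,
a His-X-Ser/Thr triad: the histidine base deprotonates the Ser/Thr
hydroxyl, whose alkoxide attacks the carbonyl carbon of the scissile
X–Ser/Thr peptide bond (N→O acyl shift, then ester hydrolysis). Whether
cleavage actually happens depends on how often the ensemble visits
conformations in which this first step is geometrically feasible — and,
for slow receptors, on reaction kinetics measurable over days.
`gpscleave` quantifies both.

## What it computes

Per conformer, at a located (or motif-scanned) H-X-[ST] site:

* **Attack angles** θx, θy of the Oγ nucleophile in an orthonormal frame
  at the scissile carbonyl carbon C (x along C→N toward the leaving
  nitrogen, z along the peptide-plane normal (O−C)×(N−C), y = z×x).
  Perpendicular attack gives (90°, 90°); the *attack window* is
  90° ± 30° in both angles (inclusive).
* **Base–nucleophile hydrogen bond**: d(N⋯Oγ) to the accepting imidazole
  nitrogen (chosen by tautomer, or `best`) and the O–H⋯N deviation from
  linearity (explicit H, or idealised at |O–H| = 0.96 Å,
  ∠C–O–H = 108.5° at the deviation-minimising cone position).
  *Favourable*: d ≤ 3.2 Å and deviation < 30°.
* **χ1 rotamer bins** (+60/−60/180, strict 30° radius, wrap-aware),
  **ω planarity strain** of the scissile bond (strained ⇔ deviation
  from planarity > 25°), and **φ/ψ** of the GPS.+1 residue.
* A conformer is **GPS-active** when it is in the attack window *and*
  hydrogen-bond favourable.

Per ensemble: condition counts and χ1 percentages per replica with exact
pooling across replicas, 2-D (θx, θy) density grids, strain enrichment in
active frames, and per-residue RMSF after least-squares superposition.
Plus: rotamer what-if edits (`set_chi1`, `flip_imidazole`), Kabsch
superposition with sequence-based Cα pairing and outlier trimming,
per-column Shannon-entropy conservation profiles mapped onto structures,
and one-phase-decay autocleavage kinetics with the plateau fixed at
100 %:

    f(t) = 100 + (f0 − 100)·exp(−k·t),   half-life = ln 2 / k

Seeded synthetic-data generators (`build_gps_fixture`, `synth_kinetics`,
`synth_alignment`) emit ensembles, time courses and alignments with
planted ground truth for every stage.

## Worked example

Plant a mixture of 60 reactive-geometry conformers (perpendicular
attack, 2.9 Å base contact, strained scissile bond) among 940 conformers
at the unreactive tethered-nucleophile cluster (θx ≈ 25°, θy ≈ 72°),
then recover the composition:

```r
library(gpscleave)

fx_active <- build_gps_fixture(60, theta_x = 90, theta_y = 90,
                               theta_jitter = 5, d_no = 2.9,
                               d_no_jitter = 0.1, omega = 150,
                               omega_jitter = 10, seed = 1)
fx_rest <- build_gps_fixture(940, theta_x = 25, theta_y = 72,
                             theta_jitter = 6, omega = 180,
                             omega_jitter = 8, seed = 2)
mix <- bind_fixtures(fx_active, fx_rest)

site <- locate_gps(mix$ensemble, "A", nucleophile_residue = 912)
rec <- descriptor_table(mix$ensemble, site, acceptor_policy = "ND1")
summarize_conditions(rec, replica_id = "r1")
#> <condition_summary> replica r1: 1000 frames
#>   theta in [60, 120]: 60   H-bond: 60   active: 60
#>   chi1 His %: +60=0.0 -60=0.0 180=100.0 unassigned=0.0
#>   chi1 Ser/Thr %: +60=90.8 -60=0.0 180=0.0 unassigned=9.2
#>   strained: 39 (all) / 37 (active)

en <- strain_enrichment(rec)
#> strained: 61.7% of active vs 3.9% of all (enrichment 15.8)
```

All 60 planted reactive conformers are counted as GPS-active, none of
the cluster conformers leak in, and scissile-bond strain is strongly
enriched among the active frames — the geometric signature of a
cleavage-competent ensemble.

Kinetics of a slow-cleaving ectodomain (rate ln 2/100 per day, 2 %
initial cleavage, 2 % measurement noise, three replicates on the
0–14-day sampling design):

```r
ts <- synth_kinetics(k = log(2) / 100, f0 = 2, sigma = 2,
                     n_replicates = 3, seed = 3)
fit <- fit_one_phase_decay(ts)
fit
#> One-phase decay fit (plateau fixed at 100 % cleavage)
#>   k         = 0.007085 per day (SE 0.0007737)
#>   f0        = 1.532 % (SE 0.5279)
#>   half-life = 97.83 days
extrapolate(fit, -2)   # transfection, 2 days before purification
#> 0.13 %
```

The fitted half-life is ~100 days and the curve back-extrapolates to
essentially 0 % cleavage at transfection, i.e. the protein left the cell
uncleaved and cleaves slowly in the tube.

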
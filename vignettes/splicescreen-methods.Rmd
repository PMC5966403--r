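---
title: "SpliceScreen: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpliceScreen: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceScreen)
```

SpliceScreen implements the analysis chain of a target-based
RNA-structure drug-discovery campaign: a structured RNA hairpin that
overlaps a 5′ splice site is screened against a compound library by
fluorescence displacement, actives are validated on exon inclusion,
transcriptome-wide splicing responses are triaged into on-target and
off-target classes, and the hairpin's conformational ensemble is
analysed geometrically.  This vignette records the models behind each
stage, the parameters that matter, the numerical conventions, and the
design choices that were genuinely open — in enough detail that a
maintainer can judge every default.

## 1. Fluorescence-displacement screening

### The activity model

A dye that fluoresces when bound to the target RNA is displaced by
RNA-binding compounds.  Four well roles define the measurement: `A`
(dye + RNA + compound), `B` (dye + compound), `C` (dye + RNA) and `D`
(dye alone).  Displacement activity is

$$\mathrm{activity}\,(\%) \;=\; 100 -
  \frac{A - B}{C - D}\times 100 .$$

`B` subtracts compound autofluorescence from the measurement well, and
`C − D` is the RNA-dependent dye signal (the assay window).  Activity
is deliberately **not clamped**: compounds that enhance fluorescence
produce negative values and are reported as such, because enhancers
are real (and flag optical artefacts).

Two aggregation conventions were open:

* **Compound wells** enter per replicate index `i` — `computeActivity()`
  evaluates one activity per replicate quadruple and reports the mean,
  SD and per-replicate values, which is what enables SEM bars and
  per-compound t-tests.
* **Control wells** are averaged before forming the ratio: the window
  is $\bar C - \bar D$, not $C_i - D_i$.  Control wells carry no
  physical pairing with compound replicates (pairing them by index is
  an arbitrary bookkeeping accident), and propagating per-well control
  noise into every compound activity inflates the per-replicate
  activity SD by roughly 40% under the default noise model, degrading
  hit-calling power for no informational gain.  The window is a
  plate-level property and is treated as one.

An assay-window guard refuses the computation when
$\bar C - \bar D \le \varepsilon\,\bar D$ (default
$\varepsilon = 0.05$): if the RNA adds essentially no dye signal the
ratio is unstable, and the right behaviour is a loud
`AssayWindowInvalid` error, not a wild number.

### Quality control

`zFactor()` implements the control-based screening-window coefficient

$$Z' = 1 - \frac{3(\sigma_{+} + \sigma_{-})}{|\mu_{+} - \mu_{-}|},$$

with sample standard deviations.  $Z' \le 1$ always, it decreases
strictly as control spread grows, and it is *undefined* (an error, not
`NaN`) when the control means coincide.  Controls with SD 5 on a
100-unit window give $Z' = 0.70$, the regime in which such an assay is
considered screen-suitable.

### Hit calling

`callHits()` labels a compound a hit iff

1. mean activity strictly exceeds the cutoff (default 20%), and
2. the two-tailed Welch test of its replicate activities against the
   pooled DMSO vehicle activities survives Bonferroni correction at
   `alpha = 0.05`.

The Bonferroni factor is the number of compounds tested (304 by
default), not the number of wells.  The cutoff is applied to the
*mean* activity (the per-replicate alternative was open; the mean
matches how ranked hit lists are reported).  Output is sorted by mean
activity descending with lexicographic ties on compound id, so ranking
is total and reproducible.  Equality at the cutoff is *not* a hit
(strict inequality), and `p_adj = min(1, m·p)` never drops below the
raw p-value.

A known operating characteristic of this rule deserves honesty: with
quadruplicates, the per-compound variance estimate has only 3 degrees
of freedom, and the Welch–Satterthwaite df against a large vehicle
pool collapses to ≈ 4–5.  Compounds whose *sampled* replicate SD lands
in the upper quarter of its sampling distribution can miss the
Bonferroni threshold even at a true 40% displacement, capping
sensitivity near 75–80% under the default noise model while keeping
the familywise false-positive rate and precision essentially perfect.
More replicates, not a looser correction, is the remedy the analysis
points to.

`flagAutofluorescence()` is a simple plate-level screen:
`(mean(B) − mean(D))/mean(D) > 0.2` (strict) flags the compound.  The
threshold is a convention; the displacement ratio itself already cancels
autofluorescence in expectation, so the flag exists to warn assays
(e.g. fluorescent-base probes) that cannot.

### Four-parameter logistic fits

`fit4PL()` fits

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
  {1 + (\mathrm{EC50}/x)^{\mathrm{hill}}}$$

by Levenberg–Marquardt least squares on the residual function,
parameterised in `log(EC50)` so the concentration scale is handled in
its natural (log) space.  Numerical choices:

* start values `top = max(y)`, `bottom = min(y)`, EC50 at the
  geometric mid-concentration, `hill = 1`;
* `hill` constrained positive (a box bound at 10⁻³), so "descending"
  readouts must be supplied as descending responses, not negative
  slopes — this removes a reflection degeneracy;
* convergence tolerances 10⁻¹⁴ so noiseless data are recovered to
  ≈ 10⁻⁶ relative error (asserted in the tests);
* at least 4 distinct concentrations are required
  (`InsufficientDoses`), constant responses are declared
  unidentifiable without optimisation, and an EC50 estimate outside
  the tested range extended ten-fold either way is **refused** — the
  fit returns `converged = FALSE` with a message, and the `ec50()`
  accessor warns and returns `NA`.  The invariant is that an EC50 is
  only ever reported from a converged, range-supported fit.

`splicingDoseResponse()` reuses the same machinery with percent
inclusion as the response, validating the 0–100 range.

## 2. Exon-inclusion quantification

`percentInclusion(inc, skip)` is `100·inc/(inc + skip)` after optional
constant background subtraction (floored at zero).  Densitometry
pipelines rarely publish a formula; the plain two-band ratio without
isoform amplification-bias correction mirrors how such gels are
actually read.  `percentInclusion(a, b) + percentInclusion(b, a) = 100`
exactly.

`mip()` normalises a treatment-induced inclusion gain by the remaining
headroom:

$$\%\mathrm{MIP} = 100\cdot
  \frac{E7_{\mathrm{treated}} - E7_{\mathrm{control}}}
       {100 - E7_{\mathrm{control}}}.$$

It is 0 at no change, 100 at complete inclusion, negative when
treatment reduces inclusion, equals the treated level when the control
is 0, and is undefined (error) at a 100% control.  One reporting
ambiguity is worth recording: phrases like "inclusion rose to 97%
(41% increase)" can mean percentage points or relative change; the
package never infers baselines from such phrases and reports the
explicit quantities instead.

`ddctFold()` implements $2^{-\Delta\Delta Ct}$ with
$\Delta\Delta Ct = (Ct^{tgt}_{trt} - Ct^{ref}_{trt}) -
(Ct^{tgt}_{ctl} - Ct^{ref}_{ctl})$; shifting all four Ct values by a
constant leaves the fold unchanged (no efficiency calibration is
attempted).

`probeDeltaCorrelation()` averages replicates per hairpin variant,
expresses each variant's probe signal as a percent change against the
reference variant, and reports the **Pearson** correlation (with
t-based two-tailed p) between those deltas and exon inclusion across
variants — Pearson, not Spearman, because the claim being checked is a
linear tracking of inclusion with structural signal, and with ~6
variants a rank test has essentially no resolution.  A constant signal
is an error (`ConstantSignal`), never a silent `NaN`.

`cdExtrema()` locates the positive band in 240–300 nm and the negative
band in 200–235 nm by discrete argmax/argmin refined with three-point
parabolic interpolation, giving sub-nm peak positions from nm-spaced
grids; peak shifts are differences of refined positions and are
antisymmetric under swapping variant and reference.  A window not
covered by ≥ 5 points, or a window with no sign-consistent extremum
(e.g. a flat spectrum), is an error.

## 3. Junction-count differential splicing

### PSI and ΔPSI

For a cassette exon, an included transcript spans *two* junctions
(upstream and downstream of the exon) where a skipped transcript spans
one.  With `I` the summed inclusion-junction count and `S` the
skipping count,

$$\mathrm{PSI} = \frac{I/2}{I/2 + S}$$

— the factor 2 is the normalisation that makes the estimator unbiased
for the transcript-level inclusion fraction (bias < 0.001 at depth 200
in the acceptance suite).  PSI lives on [0, 1]; percent is display
only.  Samples with zero coverage are excluded (logged `NA`), events
with no covered sample are dropped with a warning.

`deltaPsiFilter()` computes group-mean PSI and
`dpsi = mean(treated) − mean(control)`, flagging `|dpsi| > 0.4` as
modified and `|dpsi| > 0.65` as strongly affected.  The **absolute
value** convention is deliberate: splicing modifiers both promote and
reduce inclusion of different exons, and a one-sided reading would
silently discard half the biology.  `t2 ≥ t1` is enforced, so the
strong set is always nested.  Gene-level roll-ups count distinct gene
ids among flagged events.

### The response classifier

Genes responding to treatment *because* a deficient protein was
restored should respond in the deficient (SMA) background but not in
wild-type cells, which never lacked the protein; direct off-targets
should respond in both.  `classifySmnDependence()` runs one Welch test
per background (treated vs control) and labels:

| SMA significant | WT significant | same direction | label |
|---|---|---|---|
| yes | no | — | `smn_mediated` |
| yes | yes | yes | `off_target` |
| no | yes | — | `wt_only` |
| otherwise | | | `non_responsive` |

`alpha = 0.05` per test without multiplicity correction, matching how
small qRT-PCR validation panels are read gene by gene; the level is
configurable.  Under a global null the mislabel probability is at most
`2·alpha` (two tests), which the test suite checks by simulation.
Both-significant-but-opposite-direction falls to `non_responsive` by
the rule's construction — a deliberate conservative choice, since the
pattern fits neither mechanism.

### Donor-motif enrichment

`motifEnrichment()` asks whether a given motif (default the enriched
donor heptamer `AGGTAAG`) is over-represented among the donor windows
of affected exons versus the pooled affected + background windows.  A
window "contains" the motif iff some offset matches with Hamming
distance ≤ `maxMismatch`; IUPAC codes in the motif are honoured
(matching via `Biostrings`, windows read literally).  The p-value is
the one-sided hypergeometric tail, which the tests pin against
brute-force enumeration over all draws for populations ≤ 25.  The
canonical window is the 9-mer from the last 3 exonic to the first 6
intronic bases, supplied exon-then-intron on the plus strand — callers
pre-orient.  De-novo motif *discovery* is explicitly out of scope;
this is a verification test for a stated motif.

## 4. Stem-loop ensemble geometry

### Containers and I/O

`HairpinEnsemble` stores an `n_atoms × 3 × n_frames` coordinate array
over a fixed atom roster (1-based contiguous residues, a C1′ atom per
residue, masses by element).  `readEnsemblePDB()` parses
`MODEL`/`ENDMDL` blocks from fixed-width records, accepts both `C1'`
and `C1*` name dialects, keeps the highest-occupancy altloc, ignores
chain ids (single-chain convention) and **validates roster congruence
across models**, reporting the offending model and atom by name — the
error contract that motivated a dedicated parser.  Coordinates
round-trip through `writeEnsemblePDB()` at the format's 10⁻³ Å
precision.

### Superposition and precision statistics

`kabsch()` computes the least-squares rigid superposition via SVD of
the cross-covariance matrix with the determinant-sign correction, so
only proper rotations are returned (a mirror image never superposes to
zero).  Near-collinear atom sets are flagged with a warning, n < 3 is
an error.  The tests pin the SVD route against an algebraically
independent quaternion (Horn) solution to 10⁻⁸.

`pairwiseBundleRmsd()` superposes **every unordered model pair
independently on the selected atoms** and reports mean ± SD over all
N(N−1)/2 pairs — the convention chosen for the bundle-precision
statistic, with the selection (all-heavy; stem residues 1–7 and 13–19;
loop residues 8–12) identical for fitting and deviation.  Whether
published ensemble statistics used per-pair or mean-structure
superposition is typically unstated; per-pair is the stricter and more
common reading, and the alternative differs by a few hundredths of an
Å at bundle-like spreads, which is why comparisons to published values
carry a widened ±0.15 Å band.

`rmsfProfile()` superposes all frames onto an iteratively refined mean
structure (3 passes; the mean, not frame 1, as reference removes the
arbitrary-frame bias), then reports per-atom RMSF and the unweighted
per-residue mean over selected atoms.  For isotropic per-axis jitter σ
the analytic expectation is $\sigma\sqrt 3$; the measured value runs
≈ 1.3% low because superposition absorbs six rigid degrees of freedom
out of 3N coordinates — inside the 2% band the acceptance suite
checks at 10⁴ frames.

### Distance observables and loop states

`residueDistanceSeries()` returns per-frame internal distances —
terminal opening as C1′(1)–C1′(19), loop closure between residues 8
and 12 — with no superposition (internal coordinates are rigid-motion
invariant, which the tests assert to 10⁻⁶).  "Centre of mass" means
the mass-weighted centre of the residue's heavy atoms; the C1′-only
mode is exposed as an equal citizen because figure captions and body
text in the literature disagree on which atom set such indicators use.

`classifyLoopState()` calls a frame *triloop* iff its loop-closing
distance is strictly below the threshold (a frame exactly at threshold
is pentaloop — the boundary must fall somewhere, and strictness makes
the rule total and testable).  The default threshold is the midpoint
of the generator's two reference distances when the ensemble carries
them, else 7.0 Å for the centre-of-mass observable — a calibration
constant, not a measured value.  State fractions come with
Clopper–Pearson binomial intervals and are frame-order invariant.

`openingShift()` compares mean terminal opening between two ensembles
with a moving-block bootstrap (default block 50 frames): frames within
a block stay together, respecting the serial correlation of
trajectory data that an i.i.d. bootstrap would ignore.  It also
reports the within-ensemble Pearson correlation between terminal
opening and loop closure, the observable that links the two
conformational indicators.

## 5. What the generators emulate — and what they do not

Every generator takes a mandatory seed, draws under
`withr::with_seed`, and returns data plus a ground-truth table, so
identical calls are byte-identical and recovery is always scorable.

* **Plates** (`simPlate`): per-compound A/B quadruplicates, plate-level
  C/D control quadruplicates, DMSO pseudo-compounds as the vehicle
  reference.  Noise is multiplicative lognormal (plate-reader noise
  scales with signal) with CV 5% by default.  Defaults: 304 compounds,
  18% binders, binder displacement ~ Normal(40, 8) truncated at zero
  (screening hit lists span roughly 20–65% displacement), 5% of
  compounds autofluorescent with ~300 a.u. added to A and B wells
  (which cancels in the ratio, as in the physical assay), control
  means C = 1000, D = 200 a.u.  Not modelled: plate spatial/edge
  effects, inner-filter corrections, dye-binding thermodynamics.
* **Dose series** (`simDoseResponse`): exact 4PL mean (default EC50
  16 μM across 8 log-spaced doses 0.5–256 μM, quadruplicates) with
  lognormal CV on the response above baseline, so `cv = 0` reproduces
  the closed form exactly.
* **Junction tables** (`simJunctionTable`): per sample,
  `k ~ BetaBinomial(depth, PSI, ρ)` included transcripts out of
  `depth`, emitted as `I = 2k` inclusion and `S = depth − k` skipping
  junction counts — matching the estimator's normalisation by
  construction.  One overdispersion ρ per dataset (default 0.01),
  depth 200, 4 samples per group, 200 events with 30 planted at
  |ΔPSI| = 0.5.  Planting picks the direction that keeps PSI in
  [0, 1].  No read simulation, no alignment artefacts, no
  isoform-level complexity.
* **Hairpin ensembles** (`simHairpinEnsemble`): an idealized
  19-residue hairpin — helical stem (rise 2.8 Å, twist 33°/bp, a
  drawing convention, not fitted geometry) for residues 1–7 paired
  13–19, an arc for loop 8–12, four labelled heavy atoms per residue
  including C1′.  Two reference conformations implement the two-state
  picture: *pentaloop* (8–12 open, terminus closed) and *triloop*
  (8–12 closed to 5.5 Å, residues 9–11 lifted, terminal pair opened
  +2 Å), so terminal opening and loop closing are anticorrelated
  across any mixed ensemble by construction.  Frame states are i.i.d.
  Bernoulli(`pTriloop`) — no Markov dwell times, a documented
  limitation that is immaterial for the frame-marginal analyses
  implemented here but means autocorrelation-sensitive methods should
  not be validated on it.  Isotropic jitter σ = 0.75 Å by default,
  which puts synthetic-bundle pairwise RMSD in the ~1.9 Å range
  typical of refined NMR bundles.  Only residue-identity semantics
  (terminal A1–U19, wobble U2·G18, loop-closing A8–U12, triloop
  A9–U11, G15) are pinned; other positions default to A and are
  configurable.  One sequence quirk is intentionally left unresolved:
  a fluorescent adenine analogue "substituting G" at position 15 is
  chemically inconsistent as stated in the source protocols, and the
  probe-panel generator models intensities only.
* **Probe panels, gels, CD, Ct tables**: planted
  correlation/inclusion/fold-change truths with lognormal or Gaussian
  replicate noise; CD spectra are sums of signed Gaussians (positive
  band near 265 nm, negative near 210 nm) with configurable peak
  shift.

Passing recovery tests on these generators demonstrates that the
*analysis chain* is correct and well-calibrated under its stated noise
model; it does not certify performance on real data, whose artefacts
(spatial plate effects, gel saturation, alignment biases, force-field
errors) are deliberately outside the emulation.

## 6. Orchestration and reproducibility

`validateConfig()` resolves a YAML file against documented defaults,
rejects unknown keys by name, type-checks every parameter (a string
`"20%"` where a number belongs is an error naming the key), enforces
`t2 ≥ t1`, and verifies referenced input files exist.  `runPipeline()`
executes `simulate → screen → splicing → psi → struct`, writes
per-stage TSVs that re-parse through the same modules, logs the full
resolved configuration (no hidden defaults), and aborts on stage
failure naming the stage.  The single global seed fans out to
per-stage sub-seeds by stable string hashing of stage names, so
toggling one stage never perturbs another stage's stream; identical
config + seed reproduces byte-identical tables.

### Validation problem sizes

The shipped validation suites run at sizes chosen to make Monte-Carlo
bounds tight while keeping the whole suite interactive: 1000 null
plates for the familywise error rate, 20 plates for sensitivity and
precision, 200 titrations for EC50 recovery, 300 events at depth 200
for PSI bias, 10⁴ frames for the RMSF calibration and 5000 for state
fractions, and exact enumeration (populations ≤ 25) for the
hypergeometric cross-check.

## 7. Known limitations

* Hit-calling sensitivity at quadruplicate scale is df-limited (see
  §1); the package reports per-compound SDs so users can see when
  they are in that regime.
* PSI is event-level; no claim of equivalence with isoform-level
  estimators from vendor RNA-seq pipelines is made, and event counts
  from such pipelines are not expected to be reproduced.
* The geometry module analyses ensembles it is given; it performs no
  dynamics, docking, force-field evaluation or restraint handling.
* The CD module extracts extrema and shifts; it does not deconvolve
  secondary-structure fractions.
* Comparisons to published ensemble statistics inherit the unstated
  superposition/selection conventions of those publications (§4) and
  should be read with the widened tolerance that implies.
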
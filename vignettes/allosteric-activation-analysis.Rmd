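---
title: "Methods: mechanism and enzymology of allosteric PRC2 re-activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanism and enzymology of allosteric PRC2 re-activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each step, the defaults and why they were chosen, and
what the synthetic validation does — and does not — establish.

## The scientific setting

PRC2 trimethylates histone H3 at lysine 27. Its catalytic subunit EZH2 is
only active when the stimulation-responsive motif (SRM) helix (residues
143–153) is folded against the catalytic domain, and that folded state is
stabilised allosterically: a methylated activator peptide bound in the
aromatic cage of the reader subunit EED bridges to a flexible acidic loop
of EZH2 (residues 136–142), most importantly through a salt bridge to
D140. The EED-I363M mutation weakens activator binding, the bridge is
formed less often, the helix unfolds, and catalysis drops roughly
four-fold. A cationic peptidomimetic that restores the bridge — and, in
the mutant, gains additional reader-side contacts: a salt bridge to D362
(d1), a cation–π interaction with W364 (d2), both coupled to a contact
between the ligand's pyrrolidinium and the M363 sulfur (d3) — can
selectively re-activate the mutant complex.

The package quantifies both halves of that argument: the *mechanism*
half on multi-frame structural ensembles, and the *enzymology* half on
plate-reader assay tables.

## Trajectory mechanics

**Units and conventions.** All lengths are nm internally (PDB I/O
converts from Å); residue ranges are 1-based and inclusive on both ends,
matching crystallographic numbering. Hydrogens are optional in the
inputs: every distance-based analysis defaults to heavy atoms, which
makes results insensitive to protonation conventions.

**Superposition.** `superpose()` computes the least-squares rigid
transform (Kabsch procedure, proper rotation with det = +1) via the SVD
of the 3×3 cross-covariance of the centred point sets. Fewer than three
atom pairs, or a centred mobile set whose second singular value is below
`1e-8` times the first (collinear geometry), is an error — the rotation
would be undetermined.

**Unbound-frame filtering.** A frame is removed iff the ligand RMSD
against its reference pose is *strictly* greater than the threshold
(default 0.8 nm); a frame exactly at the threshold is kept, with a 1e-9
nm slack absorbing superposition round-off. The fit frame is not part of
the threshold convention, so the package fixes it: each frame is
superposed on the receptor backbone (N/CA/C/O of the enzyme and reader
regions) before the ligand heavy atoms are measured. Fitting on the
backbone of both receptor chains makes the measurement robust to
side-chain motion and to partial unfolding of the helix. The filter is
idempotent, and the frame mask (kept flag plus per-frame ligand RMSD) is
part of every pipeline report so that downstream stages can be audited
against it.

**Contact maps.** Entry (i, j) is the arithmetic mean over kept frames
of the per-frame *minimum* heavy-atom distance between residues i and j
("average minimum" in that order — not the minimum of means, which would
under-report intermittent contacts). Whether averaging should run over
all frames or only bound frames is genuinely open for a ligand-bearing
system; the pipeline applies the unbound-frame filter first wherever a
ligand is annotated, and `contact_map()` itself accepts any ensemble, so
both conventions are available.

**Region RMSD.** Per frame: superpose on the fit region, then measure
the RMSD of the measured region *without refitting*, so the number
reports the displacement of the measured region in the frame of the fit
region. The default atom selection is CA-only: helix folding is a
backbone phenomenon and CA-only RMSD is insensitive to side-chain
rotamers. Both the fit and measure selections are configurable
(`atom_filter` accepts `all`, `heavy`, `side_chain` or a named atom
set).

## Interaction statistics

* **Occupancy** is the fraction of frames with distance ≤ cutoff.
  Defaults: 0.4 nm for salt bridges (minimum distance between side-chain
  N/O atoms of the charged groups) and 0.6 nm for cation–π contacts
  (cationic-group centroid to aromatic-ring heavy-atom centroid). These
  are conventional structural-biology operational distances; both are
  exposed in the pipeline configuration. d3 is measured from the
  sulfur atom to the cationic-group marker in minimum-distance mode.
* **Median [MAD]**: the MAD is reported *unscaled* (no 1.4826
  normal-consistency factor) — it is quoted directly in brackets next to
  the median as a robust spread number, and rescaling it would change
  the printed values without adding information.
* **Correlation** is Pearson's product–moment r (Spearman available as
  an option); series shorter than 3 or with zero variance are errors
  rather than NaNs.
* **2D KDE**: product-Gaussian kernels with Scott's rule per axis
  (`sd(x) * n^(-1/6)`), evaluated on a regular grid spanning the data
  range plus four bandwidths per side, so the grid captures essentially
  all kernel mass (trapezoidal integral ≥ 0.95). The kernel, not the
  bandwidth, is the fixed choice; the bandwidth argument accepts fixed
  per-axis values. All-identical samples give a zero bandwidth and are
  rejected.

## Enzymology

**Normalisation.** Within each dataset the mean CPM of the no-compound
control wells defines 100 % activity and the mean CPM of the no-enzyme
background wells defines 0 %. The transform is affine, so any joint
rescaling or offset of the counter leaves percent activity unchanged; a
control mean at or below background is a degenerate-window error.

**kcat.** `kcat = slope(product vs time) / [E]`, with the slope from
ordinary least squares. Endpoint designs (all observations at one time)
force the line through the origin — the product curve starts at zero and
a single time point cannot estimate an intercept; multi-timepoint input
fits a free intercept unless told otherwise. A negative slope is clipped
to zero and flagged rather than reported as a negative turnover. The
CPM→product conversion (counts per pmol, reaction volume) is linear and
must be declared; the synthetic generator declares its own (500
counts/pmol, 10 µL).

**Dose-response.** The 4-parameter logistic is fitted by
Levenberg–Marquardt on all replicate wells jointly (not on means — the
replicate scatter is information). The Hill slope is free but bounded to
(0.2, 5): values outside that band are not pharmacologically
interpretable for a single-site activator and destabilise the fit.
Activation versus inhibition is not hard-coded; it is read off the sign
of top − bottom, so the same operation serves agonists and antagonists.
Zero-concentration control wells are excluded from the fit (they define
the normalisation, and the 4PL is parameterised on log-concentration).
Start values come from the extreme-concentration means and the geometric
mid-range; an EC50 outside the tested range or with a standard error
larger than itself carries a wide-interval warning.

**FP binding.** With tracer (40 nM) comparable to Kd (~150 nM), the
hyperbolic model is biased, so the bound fraction uses the exact
quadratic solution of P + L ⇌ PL at total concentrations. The quadratic
reduces to the hyperbola within 1 % once tracer ≤ Kd/100. A titration
that does not approach saturation cannot pin Kd; the fit is flagged when
the fitted maximal bound fraction stays below 0.5 *or* the relative
standard error of Kd exceeds 50 % — the second condition is needed
because a truncated titration can be fitted exactly by a shallow curve
with a collapsed window, which the bound-fraction check alone does not
catch.

**Uncertainty conventions.** Fold changes propagate relative errors in
first order. Panel uncertainties are reported as SD over replicates
(n = 3 by default), matching the convention of the reference turnover
panel bundled as `reference_kcat_table()` — printed measurements that
serve as generating truths for the synthetic panel and as operands of
the fold-change checks. That table contains two vehicle-free
wildtype/mutant turnover pairs from distinct experiments (23/6 and the
panel's 24/9, both in 1/h on peptide); they are kept as separate
datasets and never reconciled.

## The synthetic-data generator

The generator's job is controllable statistical structure, not physics.
Its defaults *are* the study conditions; they were set once and are not
tuned against test outcomes.

* **Toy complex** (`build_reference_complex()`): an enzyme chain
  (residues 130–160) with an ideal α-helix for 143–153 (0.15 nm rise per
  residue, 0.23 nm radius, 100° twist) and aspartates at 136/140; a
  zig-zag reader strand (355–370) carrying D362, the M363 sulfur and a
  six-membered W364 ring; a cationic ligand bridging the two, its
  ammonium nitrogen placed 0.30 nm from the D140 carboxylate —
  the engineered persistent salt bridge that the contact map must find
  as its argmin.
* **Distances by construction**: (d1, d2, d3) are sampled per frame from
  a multivariate lognormal — lognormal so distances are positive by
  construction, with the correlation specified on the underlying normal
  (log) scale and the medians mapping directly to exp(µ). With log-sd
  0.25 the induced distance-scale Pearson correlation is within ~0.01 of
  the specified value (e.g. 0.744 for 0.75), which the tests verify
  empirically. Sampled distances are *realised exactly* by dedicated
  marker atoms placed along fixed directions from their anchors
  (direction chosen so the group-minimum equals the sampled value);
  placement inversion is tested to 1e-6 nm.
* **States**: bound/unbound is Bernoulli per frame (unbound frames
  displace the whole ligand rigidly by 2.0 nm — far beyond the 0.8 nm
  divide, so ground-truth labels and filter decisions must coincide);
  folded/unfolded is Bernoulli per frame (unfolded frames perturb helix
  atoms with 0.3 nm Gaussian noise, putting CA RMSD around 0.5 nm,
  clearly above the 0.35 nm folded band). Isotropic 0.01 nm coordinate
  noise is added to every atom last.
* **Presets**: `mutant_like_scenario()` (bound fraction 0.9, unfold
  probability 0.1, medians 0.35/0.45/0.40 nm, log-scale correlations
  r(d1,d3) = 0.75 and r(d2,d3) = 0.61) and `wt_like_scenario()` (0.8,
  0.5, 0.55/0.65/0.60 nm, 0.35/0.25). The presets differ only in these
  declared parameters and mirror the qualitative wildtype/mutant
  contrast — persistent contacts and a folded helix versus intermittent
  contacts and frequent partial unfolding — without any claim of
  reproducing real dynamics.
* **Assays**: endpoint (or multi-point) timecourses at 20 nM enzyme,
  dose-responses on an 8-point half-log-ish ladder from 0.03 to 100 µM
  spanning the 2.3 µM transition, and a 12-point 2-fold FP titration
  from 2 µM — the solubility ceiling of the mutant complex — at 40 nM
  tracer. Noise is multiplicative Gaussian on the signal (3 % for
  dose-response, 2 % for FP, 5 % for the activity panel). Every table
  carries its own controls; the normalisation path refuses datasets
  without them.
* **Determinism**: one integer seed governs everything through fixed
  sub-stream offsets (states, distances, displacement directions, helix
  perturbations, coordinate noise draw from separate streams), so
  identical scenarios produce bit-identical outputs and growing one
  stream never perturbs another.

**What passing tests show — and what they do not.** The synthetic
trajectories have rigid receptor geometry, exactly realised interaction
distances, uncorrelated frame-to-frame states and no periodic boundary
conditions, solvent, or force-field realism. Validation against them
establishes that the *analysis operations* are correct (filters count
what they should, contact maps average what they should, estimators
recover known truths at realistic noise), not that the biological system
behaves as the generator assumes. In particular the package does not
image periodic boundaries (inputs must be whole), does not assign
secondary structure, and judges helix folding purely by RMSD to the
reference.

## Problem sizes and runtime choices

Default trajectory analyses run at 2 500 frames — enough that a Pearson
correlation of 0.75 is estimated to ±0.01–0.02 (standard error
(1 − r²)/√n ≈ 0.009) and medians to well under 1 % — and the heaviest
validation runs the full mechanism pipeline at 5 000 frames. The
dose-response recovery study uses 60 simulated datasets, which bounds
the median-EC50 check to a few percent while keeping the suite fast.
These sizes are the package's own accuracy/runtime trade-off; all of
them are parameters, not limits.

## Known limitations

* The ligand-RMSD filter's fit frame (receptor backbone) and the
  CA-only helix RMSD are conventions; other reasonable choices exist
  and are reachable through the exported arguments, but the defaults
  are what the pipeline reports.
* The 4PL fit needs plateaus on both sides of the transition to
  constrain EC50 tightly; with the standard 8-point design at 3 %
  multiplicative noise the single-dataset EC50 estimate has a sampling
  SD of roughly 0.24 µM around an unbiased centre — the same order as
  the replicate SD quoted for the real assay — so individual synthetic
  datasets scatter accordingly.
* The FP model assumes one site, no background drift and a linear
  FP–bound-fraction mapping.
* Contact maps are O(residues² × frames) in minimum-distance
  evaluations; the implementation vectorises over frames but very large
  residue grids will dominate runtime.
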
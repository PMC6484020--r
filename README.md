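# allostat

Analysis toolkit for studying how a designed ligand bound at the
methyl-lysine reader pocket of EED can re-activate the PRC2
histone-methyltransferase complex carrying the loss-of-function EED-I363M
mutation. The mutation impairs binding of the endogenous activators
(H3K27me3, methylated JARID2) to EED's aromatic cage, destabilising the
stimulation-responsive motif (SRM) helix of EZH2 (residues 143–153) and
with it the catalytically active conformation. Peptidomimetic agonists
that restore the key contacts — in particular a salt bridge between a
cationic side chain of the ligand and D140 in the flexible EZH2 loop
(residues 136–142) — can selectively re-activate the mutant complex.

The package implements the two analysis arms with which that claim is
established, and a synthetic-data generator so both arms run end to end
at desk scale with known ground truth:

1. **Trajectory mechanics and interaction statistics** over multi-frame
   structural ensembles:
   * unbound-ligand frame filtering — a frame is removed iff the ligand
     RMSD against its reference pose (after superposing the frame on the
     receptor backbone) exceeds 0.8 nm;
   * inter-chain contact maps of *average minimum residue–residue
     distances*: entry (i, j) is the mean over frames of
     min over heavy-atom pairs of d(a_i, b_j);
   * region RMSD after least-squares (Kabsch) superposition, used to
     follow the folding state of the SRM helix;
   * named interaction distances — d1 (salt bridge to D362, minimum
     side-chain N/O distance), d2 (cation–π to the W364 ring,
     centroid–centroid), d3 (contact of the M363 sulfur with the cationic
     pyrrolidine) — with occupancy (fraction of frames ≤ cutoff), median
     [MAD] summaries (MAD unscaled), Pearson correlation and 2D
     Gaussian-kernel density estimates (Scott bandwidths).
2. **Enzymology**:
   * scintillation-proximity CPM counts normalised per dataset
     (no-compound control = 100 %, no-enzyme background = 0 %);
   * turnover numbers `kcat = slope(product vs time) / [E]`;
   * activation EC50 from the 4-parameter logistic
     `y = bottom + (top − bottom) / (1 + (EC50/c)^h)`;
   * fold activation with first-order error propagation;
   * tracer Kd from a fluorescence-polarization titration with the exact
     ligand-depletion (quadratic) bound fraction
     `fb = (P + L + Kd − sqrt((P + L + Kd)² − 4PL)) / 2L`.

Internal length unit is nm throughout (PDB I/O converts from/to Å);
residue ranges are 1-based and inclusive.

## Worked example

The numbered scripts under `analysis/` run the whole workflow and write
tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R   # toy complex, trajectories, assays
Rscript analysis/02_mechanism.R         # contact map, helix RMSD, d1/d2/d3
Rscript analysis/03_enzymology.R        # kcat panel, folds, EC50, Kd
```

`02_mechanism.R` compares a wildtype-like and a mutant-like synthetic
system (2500 frames each, seed 1) and prints:

```
                  quantity wt_like mutant_like
1      kept frame fraction  0.7808      0.8940
2   helix RMSD median (nm)  0.0208      0.0169
3  helix unfolded fraction  0.4805      0.1011
4           d1 median (nm)  0.5471      0.3505
5 d1 occupancy (<= 0.4 nm)  0.1066      0.7114
6                 r(d1,d3)  0.3469      0.7313
7                 r(d2,d3)  0.2151      0.5820
```

Reading the table: the analysis recovers, from the coordinates alone, the
contrast the generator was built with — in the mutant-like system the
ligand stays bound more often, the d1 salt bridge is formed in 71 % of
bound frames (11 % in the wildtype-like system), the SRM helix is
partially unfolded in only 10 % of bound frames (48 %), and the
reader-side contacts are strongly coupled to the sulfur contact
(r(d1,d3) = 0.73 vs 0.35).

`03_enzymology.R` fits the simulated activity panel and prints fold
activation of the mutant complex by the active compounds
(2.1- and 2.3-fold on peptide substrate, vehicle = 1), an activation
EC50 of 2.78 µM (generating truth 2.3 µM at 3 % assay noise) and a
tracer Kd of 160 nM (truth 156 nM, 40 nM tracer).

Programmatic use mirrors the scripts:

```r
library(allostat)
ref <- build_reference_complex()
ens <- simulate_trajectory(mutant_like_scenario(n_frames = 1000, seed = 1), ref)
flt <- filter_unbound_frames(ens, ref, threshold_nm = 0.8)
cm  <- contact_map(flt$ensemble, chain_a = "E", chain_b = "L")
print(cm)
#> contact_matrix: 31 x 1 residues, averaged over 892 frames
#>   closest pair: E:ASP140 -- L:LIG1 (0.301 nm)
```

## File formats

* **PDB** — ATOM/HETATM/MODEL/ENDMDL subset, fixed-width wwPDB v3.3;
  first alternate location kept, insertion codes rejected.
* **XYZ trajectory dialect** — per frame: line 1 the atom count, line 2
  `t=<time in ns>`, then one `element x y z` line per atom with
  coordinates in nm.
* **Region annotations** — YAML/JSON mapping role →
  `{chain, start, end}` (see `inst/extdata/regions_toy.yaml`).
* **Assay tables** — tidy CSV, one row per well (`dataset`, `role`,
  `cpm`, `compound_conc`, `enzyme_conc`, `time`, `replicate`, …).

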
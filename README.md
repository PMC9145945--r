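# pdlscreen

Integrated virtual screening and assay analysis for small-molecule
inhibitors of the PD1–PDL1 immune checkpoint.

Blocking the PD1–PDL1 interaction reactivates anti-tumor T-cell responses,
but the interface is a large, featureless protein–protein contact that is
hard to drug with small molecules. One productive route is *PDL1
dimerization*: small molecules that bind a tunnel at the interface of two
PDL1 copies, sequestering them and occluding the PD1-binding face.
`pdlscreen` implements the computational funnel used to discover such
molecules, for computational chemists who want to rerun or extend it:

1. **Corpus assembly** (`read_library()`, `compute_properties()`,
   `match_decoys()`, `split_corpus()`) — labeled ACTIVE/INACTIVE corpora
   with DUD-E style property-matched decoys (MW, clogP, HBD, HBA,
   rotatable bonds, net charge; greedy nearest-first within windows).
2. **Fingerprints** (`featurize_all()`) — six 2D descriptors per molecule:
   FP2, FP4 and MACCS through the OpenBabel backend; Morgan (circular,
   radius 2, 2048 bits), RDKit-style linear-path and Layered path
   fingerprints computed natively on the molecular graph.
3. **Random Forest ensemble** (`train_ensemble()`, `consensus_screen()`) —
   one probability forest per fingerprint (n_estimators = 500,
   oob_score = TRUE, max_features = 6, min_samples_split = 6), model
   quality as the point-biserial correlation R (and R²) between predicted
   ACTIVE probability and the binary label, and library screening by the
   *at-least-k-of-6* consensus rule (k = 1 by default).
4. **Docking adapter** (`run_docking()`, `parse_vina_log()`,
   `docking_box()`) — AutoDock Vina driver with the published PDL1-dimer
   search box (center 31.9429, 12.7403, 133.7878; 20 Å cube) and a
   deterministic mock backend for pipelines without a docking binary.
5. **Interaction fingerprints** (`detect_interactions()`,
   `apply_filter()`, `shortlist_poses()`) — per-residue SIFt counts
   (hydrophobic, H-bond donor/acceptor, π–π, halogen, ionic) from
   geometric first principles, and a boolean key-residue filter language,
   e.g. `PI_PI@TYR56 | HBOND@{ASP122,LYS124,ARG125}`, to triage poses.
6. **MD post-analysis** (`compute_rmsd()`, `compute_persistence()`) —
   ligand/backbone RMSD against the first frame (with optional backbone
   superposition) and normalized per-residue contact persistence, which
   may exceed 1.0 when a residue makes several simultaneous contacts.
7. **HTRF assay analysis** (`percent_inhibition()`, `fit_ic50()`,
   `fit_plate()`) — plate normalization
   `%I = 100·(S_ctrl − S)/(S_ctrl − S_neg)` and variable-slope 4PL fits
   `%I(c) = bottom + (top − bottom)/(1 + (IC50/c)^hill)`.
8. **Synthetic fixtures** (`gen_corpus()`, `gen_complex()`,
   `gen_trajectory()`, `gen_plate()`) — deterministic generators for
   separable SMILES corpora with planted hits, toy complexes with exact
   planted interaction geometries, toy trajectories and synthetic plates,
   so the whole funnel runs with no external data.

## Worked example

```r
library(pdlscreen)

# deterministic synthetic study: 300 scaffold-bearing actives, 300
# scaffold-free inactives, decoys, and a 500-molecule screening library
# with 25 planted actives
fx <- gen_corpus(fixture_spec(n_actives = 300, n_inactives = 300,
                              n_decoy_pool = 1200, n_library = 500,
                              n_planted = 25))
model <- train_ensemble(fx$split)
model_report(model, fx$split)[, c("fp_type", "R2_train", "R2_test")]
#>   fp_type R2_train R2_test
#> 1     FP2    0.996   0.999
#> 2     FP4    0.945   0.947
#> 3   MACCS    0.999   1.000
#> 4  Morgan    0.989   0.992
#> 5 Layered    0.992   0.997
#> 6   RDKit    0.978   0.990

hits <- consensus_screen(model, fx$library, k = 1)
nrow(hits)                               # 25
all(fx$planted_ids %in% hits$id)         # TRUE: every planted active found
funnel_reduction(nrow(fx$library), nrow(hits))  # 95: % of library removed
```

Each `R2_*` is the squared point-biserial correlation between a member's
predicted ACTIVE probability and the true 0/1 label; the screen recovered
all 25 planted actives while discarding 95% of the library.

Pose triage and assay analysis work the same way:

```r
g <- gen_complex("PI_PI")                 # toy pose stacked on Tyr56
detect_interactions(g$cpx)
#>   chain resnum resname interaction count
#> 1     A     56     TYR       PI_PI     1

plate <- gen_plate(c(cpd1 = 22.35), noise_frac = 0.05)
glance(fit_ic50(percent_inhibition(plate), "cpd1"))[, c("ic50_uM", "hill")]
#>   ic50_uM  hill
#> 1    22.4  1.04   (values vary with the plate seed)
```

A command-line wrapper over the same functions is installed at
`inst/scripts/pdlscreen-cli.R` (subcommands `fixtures`, `train`, `screen`,
`dock`, `sift`, `filter`, `mdanalyze`, `fit`).

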
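# torsionconf

Conformer ensembles for drug-like small molecules, generated in torsion
space: an energy-conditioned autoregressive transformer predicts the
normalized torsion angles of all rotatable bonds from the 2D molecular
graph, and conformers are rebuilt by rigidly rotating fragments of an
initial distance-geometry structure. Bond lengths and angles are never
predicted — they come from the initial structure — so generated conformers
keep valid local geometry by construction.

The package is for computational chemists and method developers who need
(a) a fast, valid-by-construction conformer generator conditioned on
relative energy, and (b) a complete, tested reference implementation of
the torsion-space pipeline: graph featurization, Weisfeiler-Lehman graph
position encodings, normalized torsion geometry, the transformer
encoder/decoder, training, and COV/MAT ensemble evaluation.

## The method in brief

For a molecule with rotatable bonds $l = 1 \dots L$, the model factorizes

$$T^0 = F_r(G), \qquad \hat{A} = F_t(T^0 \mid E),$$

where $F_r$ maps the featurized graph $G$ to per-bond torsion
representations via full-graph self-attention plus a three-part node
position vector $pos = pos_{wl} \| pos_d \| pos_a$ (Weisfeiler-Lehman
label embedding, degree embedding, adjacency-row projection), and $F_t$ is
a transformer encoder/decoder that emits the angle sequence
$\hat A = (\hat\alpha_1, \dots, \hat\alpha_L)$ autoregressively,
conditioned on a relative energy $E$ (kcal/mol) and on all previously
generated angles. Each bond's angle is the *normalized torsion*

$$\alpha = \operatorname{atan2}\Big(\textstyle\sum_{m,n} c_{mn}
\sin\Delta_{a_m b_n},\ \sum_{m,n} c_{mn} \cos\Delta_{a_m b_n}\Big),$$

a terminal-atom-independent summary of all dihedrals around the bond that
shifts by exactly $\gamma$ when the bond rotates by $\gamma$. Ensembles are
scored with coverage/matching metrics (COV-R/P, MAT-R/P) at
$\delta = 1.25$ Å using heavy-atom, best-fit, automorphism-aware RMSD.

## Worked example

```r
library(torsionconf)

# train a compact model on the synthetic fixture ensembles (~1 min)
demo <- train_fixture_demo(seed = 0)
round(demo$error$mean_error_deg, 1)
#> [1] 7.5

# predict torsions for n-pentane at two conditioning energies
g     <- read_molecule("CCCCC")
specs <- find_rotatable_bonds(g)
length(specs)
#> [1] 2
pred <- model_predict(demo$model, g, specs, energy = c(0, 3.5),
                      n_samples = 2, seed = 1)
round(pred[[1]] * 180 / pi)   # low-energy request: anti/anti
#> [1] -180 -180
round(pred[[2]] * 180 / pi)   # high-energy request: eclipsed/eclipsed
#> [1] -126 -126

# rebuild 3D conformers from a seeded initial embedding and score them
init <- embed_initial("CCCCC", seed = 1)
gen  <- lapply(pred, function(a) apply_torsion_sequence(init, g, specs, a))
refs <- lapply(Filter(function(r) r$graph$n == 5, demo$records),
               function(r) r$conformer)
coverage_matching(gen, refs, g, delta = 1.25)
#> <tc_metrics> delta = 1.25 A
#>   COV-R 100.00 %   MAT-R 0.1861 A
#>   COV-P 100.00 %   MAT-P 0.0306 A
```

The numbers mean: the trained model recovers the fixture torsion map to
~7.5° mean wrapped error; conditioning on relative energy 0 vs 3.5
kcal/mol reproduces the anti pair (±180°) vs the eclipsed pair (−120°, the
barrier top of the 3-fold fixture potential) of the corresponding
reference conformers; and the two generated conformers sit within
0.03 Å of reference members (MAT-P) while covering all four reference
conformers within the 1.25 Å threshold (COV-R 100%).

A command-line surface wraps the same pipeline:

```sh
Rscript exec/torsionconf train    --config cfg.json --out run/ --seed 7
Rscript exec/torsionconf generate --checkpoint run/checkpoint.rds \
                                  --smiles CCCCC --n 6 --energies 0,1 \
                                  --seed 7 --out gen/
Rscript exec/torsionconf eval     --generated gen/generated.sdf \
                                  --reference refs.sdf --out metrics/
```

Every command writes a run manifest and is byte-reproducible for a fixed
seed. Conformers travel as multi-record SDF with the relative energy in a
`REL_ENERGY_KCAL` data field.

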
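---
title: "Torsion-space conformer generation: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsion-space conformer generation: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the modelling assumption

A drug-like molecule's conformational space is, to a good approximation,
spanned by rotations about its rotatable single bonds: bond lengths and bond
angles are stiff, torsions are soft. `torsionconf` exploits this by
splitting conformer generation into two stages:

1. **Torsion prediction.** A neural sequence model maps the 2D molecular
   graph (plus a conditioning relative energy in kcal/mol) to the sequence
   of *normalized torsion angles* of all rotatable bonds, one angle at a
   time, autoregressively.
2. **Reconstruction.** The predicted angles are imposed on an initial 3D
   conformer (from a seeded distance-geometry embedding) by rigid fragment
   rotation. Local geometry — every bond length and angle — comes from the
   initial conformer and is never touched, so generated structures cannot
   acquire distorted rings or broken local geometry.

Because the model reads only the graph, predictions are exactly SE(3)
invariant; all 3D information enters through the reconstruction stage.

## The normalized torsion angle

An ordinary dihedral around bond $(i,j)$ depends on an arbitrary choice of
terminal atoms $a_m$ and $b_n$. The normalized angle removes that choice:
each terminal pair contributes a unit vector
$s_{a_m b_n} = (\cos\Delta_{a_m b_n},\ \sin\Delta_{a_m b_n})$, the vectors
are combined in a weighted sum $s = \sum_{m,n} c_{mn}\, s_{a_m b_n}$, and

$$\alpha \;=\; \operatorname{atan2}(s_2,\ s_1).$$

The key property — tested to $10^{-6}$ rad over random molecules, bonds and
angles — is *equivariance*: rotating the bond by $\gamma$ shifts $\alpha$ by
exactly $\gamma$.

Two numerical decisions matter here:

* **Pair weights.** A single shared constant weight cannot prevent the
  $(\cos,\sin)$ vectors of a symmetric terminal group (e.g. the three
  fluorines of a CF3 group, whose dihedrals differ by exactly $2\pi/3$)
  from summing to zero. We therefore use distinct deterministic weights
  $c_{mn} = 2^{-(m+n)}$, with $m,n$ the 1-based positions inside the
  canonically ranked terminal groups. With these weights the sum is provably
  non-zero for 3-fold and 2-fold symmetric groups, and the CF3 fixture
  exercises the case directly.
* **Sign convention.** $\alpha$ is the two-argument arctangent of the
  weighted $(\cos, \sin)$ sums, with no leading sign flip: this is the
  orientation for which the equivariance property holds with the IUPAC
  dihedral convention and a right-handed rotation about the $i \to j$ axis.
  The absolute sign is a convention; the equivariance contract is what the
  tests pin down.

Angles live on $(-\pi, \pi]$ throughout, and every comparison uses the
wrapped difference.

## Setting torsions

`set_torsion()` rotates the *smaller* of the two fragments (ties go to the
fragment containing $j$) rigidly about the bond axis by the wrapped
difference between target and current angle. Only bridge (non-ring) bonds
can be set; ring bonds are refused. Because each rotation is rigid within
each fragment and distinct bridge bonds separate the molecule into nested
fragments, setting several torsions in sequence leaves every previously set
angle unchanged — the suite asserts commutation numerically, along with
within-fragment distance preservation to $10^{-9}$ Å.

## Graph stage: features and position encodings

Atoms carry a 40-wide feature vector (element one-hot over
{B,C,N,O,F,Si,P,S,Cl,As,Se,Br,Te,I,At,other}, heavy degree, formal charge,
hybridization, aromaticity, attached-H count, ring membership, chirality
slots); bonds carry a 10-wide vector (type, conjugation, ring membership,
stereo slots). Graph nodes are heavy atoms only — hydrogens appear as the
attached-H count, which matches the heavy-atom RMSD used for evaluation.
The stereo/radical slots are reserved and zero under the current reader.

Full (unmasked) self-attention over all atoms replaces neighborhood message
passing, so long-range dependencies do not have to survive many hops. In
exchange, attention needs to know *where* each atom sits in the graph.
Each atom therefore receives a three-part position vector

$$pos = pos_{wl} \,\|\, pos_d \,\|\, pos_a$$

* $pos_{wl}$: a learned embedding of the atom's Weisfeiler-Lehman label
  (3 refinement rounds by default — enough to separate symmetric nodes
  beyond the ~3-hop blind spot of conventional message passing). Labels are
  hashed into 1024 embedding buckets with a stable polynomial string hash,
  so they are identical across runs and platforms.
* $pos_d$: a learned embedding of the degree.
* $pos_a$: a learned linear projection of the atom's adjacency row, zero
  padded to `max_atoms` (default 64; larger molecules are rejected rather
  than silently truncated).

WL and degree parts are identical for automorphism-equivalent atoms; the
adjacency projection is the one part that depends on the atom numbering,
which is documented and tested. Three ablation modes are exposed
(`pos_mode`): `"none"`, `"learnable"` (plain index embedding), and
`"full"`.

## Torsion readout and the sequence model

For each rotatable bond the readout concatenates the means of the terminal
atoms' representations with the bond atoms' representations
($h_a \| h_i \| h_j \| h_b$) and the means of the neighboring edge features
($e_{ai} \| e_{ij} \| e_{bj}$), projected to the model width. The torsion
sequence — ordered canonically by the bond atoms' canonical ranks, a
deterministic, permutation-invariant order — then passes through:

* a transformer **encoder** with *no* added positional encoding (the torsion
  representations already carry graph position); Gaussian noise with
  standard deviation `noise_std` (default 5.0, in representation units) is
  added to the input representations, and is the source of sample
  diversity at generation time;
* an autoregressive **decoder** whose start token is a two-layer
  feed-forward embedding of the conformer's relative energy (kcal/mol) and
  whose later tokens embed the previously generated angles as
  $(\sin, \cos)$ pairs plus a sinusoidal encoding of the sequence position.
  Causal masking enforces that step $l$ sees only steps $< l$; the test
  suite asserts bitwise prefix stability under perturbation of later
  teacher inputs. An alternative conditioning mode adds the energy
  embedding to every decoder token (`energy_mode = "every_step"`).

The output head emits a 2-vector per torsion, L2-normalized into an exact
$(\cos, \sin)$ pair and converted with atan2 — avoiding any discontinuity
at $\pm\pi$ that a direct angle regression would suffer.

Default depths are 2 atomic attention layers, 4 encoder and 4 decoder
layers, 4 heads, width 128. These are configuration defaults chosen for
desk-scale work; every one is exposed in `model_config()`.

## Training

One training example is one (molecule, conformer, relative energy) triple;
the decoder is teacher-forced, and the loss is the periodic cosine loss
$\frac{1}{L}\sum_l \big(1 - \cos(\hat\alpha_l - \alpha_l)\big)$, which is
smooth across the branch cut and invariant to $2\pi$ shifts (a
$(\sin,\cos)$ MSE variant is selectable). Optimization is Adam with a fixed
step; gradients come from the package's own reverse-mode tape and are
verified against central finite differences for every parameter tensor in
the test suite. Conditioning each example on its conformer's relative
energy is what makes inference energy-guided: at generation time, varying
the input energy steers the model toward the corresponding region of the
ensemble.

## The synthetic fixture landscape

Real reference ensembles (CREST/semi-empirical sampling over hundreds of
thousands of drug-like molecules) are far beyond a test suite. The fixture
generator instead builds ensembles with a *closed-form* energy model:
conformers are enumerated on a torsion grid (anchored at the anti
conformation, 180°), scored with independent per-bond 3-fold potentials
$E(\theta) = \sum_l V_l (1 + \cos 3\theta_l)/2$, and the lowest-energy
grid points are kept, shifted so the minimum is exactly 0 kcal/mol — the
convention of energy-annotated conformer datasets. Barrier heights of
1-2.5 kcal/mol match alkane-like rotation barriers.

A 3-fold potential has three degenerate minima per bond, so a raw grid
yields many conformers at the same relative energy, and a deterministic
map (graph, energy) → angles does not exist. The training fixtures
therefore keep at most one conformer per distinct energy level
(`distinct_energies = TRUE`), with distinct per-bond barriers so that
different bonds contribute distinguishable energy levels.

What passing these fixtures shows — and does not show. The overfit
demonstration (mean wrapped angular error below 15° on held-in conformers,
energy conditioning separating a two-level ensemble) establishes that the
architecture can represent and recover the torsion map, that conditioning
works, and that every pipeline contract (equivariance, causality,
determinism) holds end-to-end. It does not establish chemical accuracy on
real ensembles: the synthetic landscape has no coupling between torsions,
no steric clashes, no ring flexibility, and far fewer conformers per
molecule than real data.

## Evaluation

Ensembles are compared with coverage and matching scores at a threshold of
$\delta = 1.25$ Å: COV-R is the percentage of reference conformers with a
generated neighbor strictly closer than $\delta$ in RMSD; MAT-R is the mean
over references of the minimum RMSD; COV-P/MAT-P swap the two sets.
Following the common convention, generation produces $2k$ conformers for a
$k$-conformer reference ensemble (each reference energy is used twice with
different noise draws; the convention fixes the count, the energy schedule
is this package's documented choice). RMSD is heavy-atom, best-fit
(Kabsch), and minimized over the molecule's graph automorphisms (igraph
VF2, colored by element) so that relabelings of topologically equivalent
atoms — a flipped phenyl, a rotated CF3 — do not register as deviation;
a flag disables the automorphism search for the plain variant.

## Numerical and design choices, in one place

| choice | value | why |
|---|---|---|
| angle domain | $(-\pi, \pi]$ | single wrap convention everywhere |
| pair weights $c_{mn}$ | $2^{-(m+n)}$ | breaks symmetric cancellation deterministically |
| torsion order | by canonical rank of bond atoms | permutation invariant, deterministic |
| canonical ranks | iterative neighborhood refinement | no toolkit canonical ranking available |
| WL rounds / buckets | 3 / 1024 | covers >3-hop symmetry; collision-safe at small scale |
| `max_atoms` | 64 | fixes adjacency-projection width; explicit rejection above |
| noise_std | 5.0 | sampling diversity; 0 = deterministic encoder |
| loss | $1-\cos$ | periodic, smooth at the branch cut |
| $\delta$ | 1.25 Å | standard coverage threshold |
| initial embedding | seeded distance geometry + MMFF | deterministic per (SMILES, seed) |

Degenerate inputs are handled explicitly: rigid molecules produce empty
torsion sequences and pass the initial conformer through (with a warning);
ring bonds cannot be set; collinear dihedral geometries and zero-norm
normalized-torsion sums raise errors rather than returning arbitrary
values; a NaN loss aborts training with a diagnostic.

## Problem sizes used by the shipped demonstrations

The test suite and the acceptance script train on 8 fixture records
(butane, n-pentane with two distinct barriers, 1,1,1-trifluoropropane; at
most 4 distinct-energy conformers each) with a compact configuration
(width 32, 1 atomic layer, 2+2 transformer layers) for 300 + 150 epochs —
about a minute per seed on one core. These sizes are the package's choice
of a minimal convincing demonstration; the configuration scales up by
changing `model_config()` arguments only.

## Known limitations

* Stereochemistry is carried in reserved feature slots but not perceived by
  the current reader; tautomers are not normalized; macrocycles get no
  special torsion rules.
* Single-heavy-atom molecules are rejected by the reader (they have no
  torsions to predict).
* Formal-charge support covers the MDL charge codes written by the
  underlying toolkit; exotic charge blocks are not parsed.
* The adjacency-row position part is numbering-dependent by construction;
  only the WL and degree parts are guaranteed identical for automorphic
  atoms.
* The automorphism enumeration is exact but capped (default 10000); beyond
  the cap a warning is raised and a subset is used.
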
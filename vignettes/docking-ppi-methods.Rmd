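---
title: "Methods: docking-based PPI inference with docknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: docking-based PPI inference with docknet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docknet)
```

## The model

Rigid-body docking of a protein pair produces a ranked list of candidate
poses with shape-complementarity scores.  For a genuinely interacting pair
the best pose tends to be an outlier of the pose-score distribution; for a
random pair it is just the maximum of noise.  `docknet`'s central statistic
standardizes the top score against the pair's own decoys:

$$z = \frac{s_1 - \bar{s}_{2..K}}{\mathrm{sd}(s_{2..K})},$$

with $K$ the pose depth (2000 by default).  Because each pair is referenced
to its own decoy distribution, $z$ is invariant under any affine rescaling
of the raw scores (asserted by property tests), which makes it comparable
across pairs, score functions and program versions.  A pair is predicted to
interact when $z \ge t$.

### Conventions chosen where the statistic is underspecified

* **Decoy set**: ranks $2..K$, excluding the top pose.  At $K = 2000$
  including it changes $z$ by well under 0.1%; exclusion makes the
  synthetic-generator round trip exact.  `dock_z_score(include_top = TRUE)`
  restores the other reading.
* **Spread**: sample standard deviation ($n - 1$), since the decoys are a
  sample of the pose-score distribution.
* **Decision rule**: inclusive ($z \ge t$), so the calibrated threshold
  itself predicts positive.
* **Pose order**: pose lists are trusted as rank-ordered engine output and
  never re-sorted.

## Threshold calibration under class imbalance

Random protein pairs vastly outnumber interacting ones, so the operating
threshold must be calibrated at a realistic class ratio.
`calibrate_threshold()` sweeps the distinct observed z values (not a fixed
grid, so exact optima on small sets are reproduced) and maximizes the
F-measure; ties are broken toward the *largest* candidate threshold, the
conservative choice that minimizes false positives.  On a balanced set with
heavily overlapping classes the optimum degenerates to the all-positive rule
(F = 2/3 at precision 0.5, recall 1); as negatives are added at a fixed score
distribution, precision at any threshold falls, the optimum moves up, and
its FPR falls — the 1:1 → 1:10 → 1:100 trend the acceptance suite asserts
over ten seeds.  The package default `t = 8.8` is the 1:100-calibrated
operating point of the emulated study system.

Supporting machinery: `shuffle_negatives()` re-pairs the proteins of the
positive set uniformly (rejecting positives, self-pairs and duplicates;
seeded), `roc_auc()` sweeps thresholds with tie grouping so its trapezoidal
AUC equals the Mann–Whitney statistic exactly (checked against a
pair-counting oracle), and precision is defined as 0 (with a warning) when
nothing is predicted positive so sweeps are total.

## Structural model QC

Homology models feeding a docking pipeline are filtered on strict
template-alignment bounds (identity > 0.50 and coverage > 0.80; models with
identity ≥ 0.95 are template self-hits and excluded from benchmarks) and
summarized by superposition statistics:

* `kabsch_superpose()` — closed-form least-squares rigid superposition (SVD
  with determinant correction, reflections excluded).  Collinear point sets
  raise an error rather than returning an arbitrary rotation.  Equivalence
  with a brute-force rotation-grid search is asserted to 0.01 Å on small
  instances.
* `tm_score()` — $\mathrm{TM} = \frac{1}{L_{ref}} \sum_i
  \frac{1}{1 + (d_i/d_0)^2}$ with $d_0 = 1.24\,(L_{ref} - 15)^{1/3} - 1.8$ Å.
  The maximization over superpositions uses iterative cutoff refinement:
  Kabsch on all pairs, then repeated re-superposition on pairs with
  $d_i$ below a $d_0$-scaled cutoff (floored at 2 Å so tiny subsets cannot
  hijack the search) until the score converges (1e-6, max 20 iterations),
  keeping the best score seen.  $d_0$ is clamped at 0.5 Å for
  $L_{ref} \le 21$ so toy-scale fixtures stay defined.  This single-start
  search can in principle undershoot the global TM optimum on pathological
  inputs; for the QC summaries here (identity and near-identity
  comparisons) it is exact.

Summary percentages (`summarize_qc`, `fraction_pct`) are rounded to one
decimal, matching report conventions.

## The toy docking engine

`toy_dock()` exists so the whole pipeline can run with no external docking
program.  It is a miniature of the classic FFT grid-correlation
(soft-docking) scheme: structures are rasterized onto a 3D occupancy grid
(1.2 Å cells, 1.8 Å occupancy radius per heavy atom); the receptor
contributes +1 in its *exterior surface shell* (empty cells within two grid
layers of the molecule) and −9 in every occupied cell, the ligand
contributes +1 per occupied cell, and every translation of every sampled
ligand rotation is scored by FFT cross-correlation.  Close surface contact
is rewarded, interpenetration is heavily punished.

A design note: a first implementation weighted the receptor's *occupied*
surface cells +1, which only rewards poses whose shells interpenetrate by
roughly one cell — planted complementary poses then score below random
contacts.  Moving the +1 layer to the exterior contact shell (the standard
soft-docking formulation) fixes this, and the planted
shape-complementary pose of the `half_sphere_pair` fixture then beats the
95th percentile of pose scores across seeds.  The weights are fixture
parameters of a toy engine, not a reproduction of any production scoring
function.

## Variant impact

`annotate_substitution()` is a deliberately minimal SNV-only consequence
caller: it verifies the reference base, locates the variant in cumulative
CDS coordinates (reverse-complementing on minus-strand genes), edits the
affected codon and translates with the standard genetic code.  It is tested
against an independent oracle that rebuilds the full spliced mRNA with
Biostrings and diffs the translated proteins, over 200 random toy genes per
strand.  Interface residues use the common 5.5 Å heavy-atom contact
convention (configurable).  Binding-affinity perturbation uses
$\Delta\Delta G = \Delta G_{REF} - \Delta G_{ALT}$ with strict bounds at
±1 kcal/mol (boundary values are neutral); positive values mean the
alternative allele binds more strongly.  $\Delta\Delta G$ values are
*inputs* (external predictors are out of scope); `stub_binding_energy()` is
a contact-count stand-in used only to exercise the pipeline.  Because one
variant can strengthen some interactions and weaken others,
`summarize_perturbation()` reports per-class counts *and* the distinct
union, so either counting convention can be read off.

## Orthogonal validation

* **Interologs**: a pair is transferred when its orthologs interact in at
  least one reference organism; support lists are attached and the
  prediction is monotone in the reference sets.
* **Co-localization**: winner-takes-all compartment assignment (score ties
  broken by a fixed, configurable priority list; alphabetical by default),
  then a hypergeometric upper-tail test.  The universe is all unordered
  pairs over the *located* proteins of the docked set — the comparison
  actually available — rather than the whole proteome; this is configurable
  by passing different `locs`.  p-values are reported raw (no
  multiple-testing correction across compartments).
* **Coexpression**: the emulated study only states a significant
  coexpression trend without naming a test; a one-sided Wilcoxon rank-sum
  test (network > random) was chosen as the distribution-free default.
  Exact p for min(n, m) ≤ 8 without ties, normal approximation with tie
  correction otherwise; fully tied samples return p = 0.5 (no evidence of
  shift).

## The synthetic-data world

The generators state a world once and the tests live in it:

* `gen_pose_list(z_target)` draws $K - 1$ decoys from
  $\mathcal{N}(20, 4)$ (scale arbitrary — z is scale-free) and sets the top
  score so `dock_z_score()` returns exactly `z_target` (round trip ≤ 1e-9).
* `gen_benchmark()` draws per-pair z targets from
  $\mathcal{N}(\mu_{class}, 1.5)$.  The class means are the emulated
  regimes: 10.0 vs 5.8 (experimental structures), 6.6 vs 5.9 (homology
  models).  The spread 1.5 is a free simulator parameter — only class means
  are constrained — so absolute AUCs of generated sets are simulator
  properties; tests assert only the ordering (experimental > model) and
  mean recovery within 3 standard errors.
* `gen_toy_structures()` builds poly-alanine helices, shells, and the
  complementary ball-plus-cap pair.  The cap sits 4.6 Å above the ball
  surface: inside the 5.5 Å interface cutoff, outside the docking grid's
  clash zone.  (A literal equatorial split of one shell was rejected: its
  halves clash at the rim when assembled.)
* `gen_toy_genome()` writes random intron-split genes on both strands and
  plants SNVs whose truth labels are derived from the edited codon itself,
  independently of the coordinate arithmetic under test.

What a green suite establishes: the statistics, calibration machinery,
coordinate arithmetic and bookkeeping are correct on data whose truth is
known by construction.  What it does not establish: anything about real
docking energetics, real genome annotation quirks (overlapping genes,
splice isoforms, indels), or the biological accuracy of any specific
interactome — reproducing a published full-scale network requires the
original external docking runs and predictors, which are out of scope by
design.

## Numerical choices and degenerate inputs

* Zero-variance decoys raise a degenerate-distribution error rather than an
  infinite z.
* Percentages round half-to-even to one decimal (R's `round`), which
  reproduces every printed summary value used in the acceptance checks.
* `f_measure(0, 0) = 0`; single-class inputs to `roc_auc()` error.
* Duplicate pair entries are merged when their z agrees (≤ 1e-9) and
  rejected otherwise; self-pairs are rejected at parse time.
* Gene models must have non-overlapping CDS segments with total length
  divisible by 3; CDS phase is recomputed, never trusted.
* Seeds: every stochastic generator is a pure function of (configuration,
  seed); RNG state is saved and restored around each call.

## Known limitations

* The TM-score search is single-start (see above).
* `toy_dock` samples rotations randomly rather than on a deterministic
  quasi-uniform net; pose coverage at small `n_rotations` is accordingly
  rough.
* The consequence annotator handles SNVs only — no indels, splice-site or
  start/stop-adjacent special cases — and assumes structure residue
  numbering matches protein coordinates unless a mapping is supplied.
* `shuffle_negatives` enumerates the admissible pair universe when it is
  small (≤ 2e6) and falls back to rejection sampling above that, so very
  dense positive sets over few proteins are the slow case.
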
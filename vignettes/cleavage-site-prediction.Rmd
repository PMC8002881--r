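---
title: "Cleavage-site prediction and proteolytic susceptibility scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleavage-site prediction and proteolytic susceptibility scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tissue remodeling in aging and disease is driven in part by proteolysis:
matrix metalloproteinases (MMPs), cathepsins, elastase and granzyme B cleave
extracellular-matrix proteins at sequence- and structure-dependent sites,
while ultraviolet radiation (UV) and reactive oxygen species (ROS) attack
specific residue chemistries. `protcleave` bundles the two calculations a
degradomics analysis needs:

1. a **cleavage-site classifier** - a deep bidirectional LSTM ensemble that
   scores every inter-residue bond of a protein for cleavage by a given
   protease, and
2. a **susceptibility calculus** - per-protein percentages quantifying
   vulnerability to UV, ROS and protease attack, combining amino-acid
   composition, disulfide content and high-confidence predicted sites.

Coordinates follow the degradomics P-nomenclature: a site is named by its P1
residue index (1-based), the scissile bond lies between residues `p1` and
`p1 + 1`, and positions P4..P1 run N-terminal of the bond, P1'..P4'
C-terminal. Every inter-residue bond (`p1` in `1..L-1`) is a candidate site;
a protease's negative class is the candidate set minus its annotated
positives.

## Window encoding

Each candidate site becomes an 8 x 30 matrix: the eight residues P4..P4'
around the bond, each described by

* a 20-dimensional one-hot amino-acid block (columns ordered alphabetically
  by one-letter code - the order is arbitrary but fixed and
  self-documenting);
* a 3-dimensional secondary-structure one-hot (coil / strand / helix);
* a 2-dimensional solvent-accessibility one-hot (exposed / buried);
* a 2-dimensional disorder one-hot (disordered / ordered);
* a 3-dimensional coordinate triple.

Window positions beyond either terminus are all-zero rows, and non-standard
residue letters (B, J, O, U, X, Z) keep an all-zero amino-acid block - the
same zeroing convention as terminal padding, chosen because these letters
carry no composition information the model should rely on. Raw structural
coordinates are scale-arbitrary, so they are z-scored per protein per axis
before insertion; padding coordinates are zero. Structural features come
from a pluggable *provider*: stored features, a precomputed per-residue
table (the route for external structure annotators), an on-the-fly
simulator, or a zero provider when no structure is available.

An 8-residue window with no row for the bond itself is used because "four
upstream plus four downstream of the bond" totals exactly eight residues;
the bond sits between rows 4 and 5. Encoding is injective up to the stated
zero conventions, and every categorical block sums to 0 or 1 everywhere -
both properties are tested.

## The classifier

The production architecture is four bidirectional LSTM layers (concatenated
forward/backward states feed the next layer), a fully connected dense layer
with ReLU, and a single sigmoid output. The final representation
concatenates the forward direction's state after reading the window
left-to-right with the backward direction's state after reading it
right-to-left. Training uses:

* **class-weighted binary cross-entropy**: sites are outnumbered by
  non-sites roughly 10:1 even in the synthetic fixture (far worse in curated
  substrate databases), so class `c` is weighted `N / (2 N_c)`;
* **Adam** with global gradient-norm clipping at 5 (recurrent stacks
  otherwise occasionally take destabilizing steps early in training);
* **protein-level 70/15/15 splitting**: proteins - not windows - are
  shuffled into train/test/validate partitions (`floor(0.15 n)` each for
  test and validate, remainder train), so homologous windows from one
  protein can never leak across partitions;
* **early stopping on validation F1** at decision threshold 0.5, with a
  patience of 20 epochs and a very large epoch ceiling (10,000); the
  returned weights are those of the best-F1 epoch. F1 is monitored at 0.5
  because the training-time metric needs a fixed operating point; the
  threshold for reported metrics is configurable.

The LSTM forward pass, backpropagation through time, Adam and the early
stopping loop are implemented in compiled code (RcppArmadillo) inside the
package; analytic gradients are verified against central finite differences
in the test suite (relative error below 1e-4 on every parameter block
sampled).

**Transfer learning.** A group-generic model is pretrained on windows pooled
over all proteases of one registry group (all MMPs, or all "other"
proteases), labeling a window positive when *any* group member cleaves
there; the pool includes the target protease's own sites. The
protease-specific model then starts from the generic weights, freezes the
*first* bidirectional layer (the most literal reading of freezing "the
initial layer"; the count is configurable) and fine-tunes the rest. The
frozen layer's parameters are bit-identical before and after fine-tuning -
asserted, not assumed.

**Ensembling.** Five members are trained with seeds `seed + 0..4` on
identical data and configuration; diversity comes from weight
initialization and minibatch shuffling only, since no resampling scheme is
part of the design. The ensemble score of a site is the arithmetic mean of
member sigmoid outputs.

Determinism: all randomness flows from explicit seeds (R-side generation
and splitting; a Mersenne Twister inside the training core for shuffling),
so a fixed configuration reproduces training logs and predictions exactly
on one machine. Across BLAS builds only statistical (AUC-level)
reproducibility is promised.

## Synthetic data: what it emulates and what it does not

Real substrate-cleavage corpora cannot be redistributed here, so the
package ships a seeded generator that gives every stage a ground-truth
oracle:

* **Sequences**: i.i.d. draws from a 20-residue frequency vector
  (default uniform).
* **Cleavage rules**: the classical protease specificities - trypsin
  cleaves C-terminal of Arg/Lys unless Pro follows; V8-GluC cleaves
  C-terminal of Glu in preference to Asp, modeled as a primary residue set
  (Glu, emission probability 1.0 by default) and a secondary one (Asp,
  0.2). Two noise dials mimic real annotation heterogeneity:
  `site_probability` (miscleavage) and `decoy_rate` (spurious background
  sites).
* **Structure**: a 3-state Markov chain with persistence 0.8 for secondary
  structure (mean run length 5, roughly element-like), Bernoulli exposure
  (0.4 exposed - a typical surface fraction for globular chains) and
  disorder (0.1), and a smoothed 3D random walk for coordinates. These
  marginals are plausible but the fields are *uninformative about cleavage*
  by construction.
* **Digests**: in-silico tryptic digestion with configurable missed
  cleavages, the counterpart of trypsin sample preparation upstream of
  LC-MS/MS.

The standard fixture is 300 proteins of 200-400 residues, uniform
frequencies, trypsin rule - large enough for stable held-out AUC, small
enough to train in CPU-minutes. In the noise-free limit the generated
annotations equal the deterministic rule enumeration exactly (tested), so
the whole pipeline has a closed-form oracle.

What passing on this generator shows: the encoder, training loop, transfer
and ensembling machinery can recover a true positional specificity pattern
from imbalanced, optionally noisy labels, with honest protein-level
evaluation. What it does not show: performance on real proteases, whose
specificity depends on higher-order structure, long-range context and
heterogeneous experimental evidence far beyond a P1/P1' rule. Real
structural features are informative; the simulated ones are noise, so the
synthetic task is purely sequence-driven by design.

**Rule recovery.** Evaluation on the fixture is always against the
noise-free rule enumeration on held-out proteins; the generator's noise
dials perturb only the *training* labels. This is deliberate: the question
the fixture answers is whether the pipeline recovers the underlying rule
(a parameter-recovery analogue), not whether it can reproduce the noise.
(Measured against noisy labels, a 5% decoy rate alone caps the achievable
AUC near 0.84 - decoy positives are statistically indistinguishable from
negatives - which would conflate label noise with model failure.)

## Evaluation machinery

* **MCC** is computed from the confusion counts with the 0/0 convention
  (any zero marginal factor gives 0); counts are held as doubles because
  the four-marginal product overflows 32-bit integers on realistic site
  universes. **F1** is `2TP / (2TP + FP + FN)`, defined 0 when the
  denominator vanishes. Both are verified exhaustively against brute-force
  oracles for all confusion matrices with entries up to 10.
* **AUC** is the Mann-Whitney probability that a random positive outscores
  a random negative (ties one half, midrank form), which equals the
  trapezoidal integral of the ROC curve - the equivalence is tested on
  1,000 random instances, and agreement with an independent external
  implementation is also checked. The 95% confidence interval is a seeded
  stratified percentile bootstrap (default 2,000 resamples); the method
  and seed are recorded in the result because no single canonical AUC
  interval construction exists.
* **Non-tryptic site extraction** inverts trypsin specificity on peptide
  evidence: a peptide boundary that is not "after Lys/Arg, not before Pro"
  is evidence of another protease's action. Protein termini are never
  sites; Lys/Arg before Pro *is* non-tryptic (the rule applied literally);
  peptides that do not map, or map ambiguously, are excluded and reported
  rather than multiply counted - exclusion avoids fabricating sites. A
  tryptic terminus of a semi-tryptic peptide is not taken as evidence of
  anything.
* **Cleavage-density maps** count sites per 50-residue bin (configurable),
  truncating the last bin at `L - 1`.
* **Group comparison** is the pooled-variance two-sided Student's t-test
  with `df = n_a + n_b - 2`, e.g. comparing predicted susceptibilities of
  proteins with vs without experimentally detected sites.

## The susceptibility calculus

For a protein of length `L` with `W, Y, M, C, H` counts of Trp, Tyr, Met,
Cys, His and `B` cysteines engaged in annotated disulfide bonds
(`[Cys=Cys]`, so `B/2` bonds):

* UV susceptibility `= (W + Y + B/2) / L * 100`
* ROS susceptibility `= (W + Y + M + C + H) / L * 100`
* UV-ROS susceptibility `= (W + Y + M + C + H + B/2) / L * 100`
* Protease susceptibility `= 100 * |{sites with score > 0.8}| / L`

As printed, the UV-ROS formula counts a bonded cysteine twice - once in the
`C` term and once via `B/2`. Whether that double counting is intended
cannot be resolved from the formula alone, so it is implemented exactly as
written, with `double_count_bonded_cys = FALSE` as an escape hatch (a
bonded pair then counts once, as a single cystine unit, via the `B/2`
term).
`[Cys=Cys]` is read as the number of disulfide-engaged cysteine residues
(so the `/2` converts to bond count), matching its definition as disulfide
bound cystine. Proteins without disulfide annotation are treated as
cystine-free, which makes UV-ROS reduce exactly to ROS.

Composition thresholds classify proteins as UV-susceptible above 5%
chromophore content and ROS-susceptible above 10% oxidation-sensitive
content; the inequalities are strict because the cut-offs are worded as
"more than", and both are configurable. The 0.8 cleavage-score cut-off
selects highly confident sites only; raising it can never raise a protease
score (tested as a monotonicity property). The proteome report orders rows
by descending UV-ROS susceptibility with ties broken by id, so output is
deterministic.

Substrate annotation tables are ingested as a normalized three-column TSV
(`protease`, `protein_id`, `p1`); the package never scrapes the source
databases. P1 indexing of such tables is assumed (the alternative P1'
reading would shift every site by one); this convention is applied
uniformly on read and write, so round-trips are exact either way.

## Numerical and design choices

* Decision threshold for counted metrics defaults to 0.5; the confidence
  threshold for susceptibility defaults to 0.8. Both are explicit
  arguments, never hard-coded at call sites.
* Ties in early stopping: the *first* epoch achieving the best validation
  F1 wins, so the stopping epoch never exceeds best epoch + patience.
* `max_epochs = 0` in a transfer returns the generic model unchanged
  (useful as an identity check and for freezing experiments).
* Per-protein candidate enumeration of an `L = 1` protein is empty rather
  than an error; empty annotation tables flow through every operation.
* Degenerate single-class training sets and single-class evaluation labels
  are hard errors, never silently absorbed.
* Glorot-uniform initialization with forget-gate biases at 1.

## Problem sizes used by the shipped checks

The package's own test suite and the `scripts/acceptance.R` driver run the
full pipeline at the standard fixture (300 proteins, 5-member ensemble with
generic pretraining and frozen-layer transfer) with a deliberately small
model - 16 LSTM units per direction, 16 dense units, learning rate 3e-3,
a 6-epoch generic budget and 4 fine-tuning epochs per member. The synthetic
rules are two-residue patterns that this configuration learns to held-out
AUC > 0.99 within those budgets; the production-scale defaults (64 units,
patience-20 early stopping under a 10,000-epoch ceiling) remain the
package defaults for real data. Unit tests of the training machinery use
smaller fixtures (12-60 proteins, 2-4 layer stacks of 5-12 units) chosen to
exercise every contract in seconds.

## Known limitations

* The synthetic generator draws i.i.d. sequences: no homology, no domain
  structure, no compositional bias unless configured. Protein-level
  splitting is therefore *easier* to satisfy than on real proteomes with
  paralogs.
* Simulated structural features carry no signal about cleavage, so the
  fixture cannot measure the value of structural inputs - only that they
  are encoded and plumbed correctly.
* The susceptibility calculus is linear in composition and ignores residue
  context (e.g. buried chromophores count the same as exposed ones).
* Training is single-threaded CPU; the implementation favors correctness
  and reproducibility over throughput, and no GPU path exists.
* External predictor score files can be evaluated but not produced; the
  package does not reimplement other published predictors.
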
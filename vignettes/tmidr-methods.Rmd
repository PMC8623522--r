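---
title: "Topology-aware disorder prediction in transmembrane proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-aware disorder prediction in transmembrane proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intrinsically disordered regions (IDRs) are protein segments without a
stable tertiary structure. General-purpose disorder predictors perform
poorly on transmembrane proteins (TMPs): disorder is conditional on the
environment, and the cytosolic and extracellular faces of a membrane,
as well as the lipid-adjacent zone, impose very different
physico-chemical constraints. `tmidr` addresses this by making membrane
topology a first-class input: every water-exposed residue is assigned
to one of four compartments and scored by a model trained only on
residues from that compartment.

## The compartment partition

Given a per-residue topology track over inside (`I`), outside (`O`),
membrane (`M`) and re-entrant loop (`L`) labels, each non-membrane
residue is classified by its side and its sequence distance to the
nearest membrane residue:

| category         | side          | membrane distance |
|------------------|---------------|-------------------|
| `EXTRA_DISTANT`  | extracellular | > 15              |
| `EXTRA_PROXIMAL` | extracellular | <= 15             |
| `INTRA_DISTANT`  | cytosolic     | > 15              |
| `INTRA_PROXIMAL` | cytosolic     | <= 15             |
| `MEMBRANE`       | in bilayer    | 0                 |

Distance is counted in residues (sequence positions), the boundary is
inclusive at 15, and distance 16 is distant. Re-entrant loop residues
sit in the bilayer, so they are treated as membrane: they are never
scored by a compartment model, and they feed a zero score into the
smoother. The topology of a re-entrant loop is a genuinely open
question in the source material for this class of method; treating it
as membrane is this package's declared assumption and is confined to
`categorize()`.

Proteins without any membrane residue are rejected: the method is
TMP-specific by construction, and a soluble protein would leave the
compartment partition undefined.

## Per-residue features (the 11 x 39 window matrix)

Each scored residue is represented by an 11-row window (the residue
plus/minus 5 positions) of 39 named features per row:

* **20 profile channels** — a position-specific scoring matrix row. If
  a PSI-BLAST ASCII PSSM is supplied it is parsed and aligned against
  the sequence; otherwise a deterministic fallback substitutes the
  BLOSUM62 column of the residue. Log-odds scores are scaled by 0.1 to
  sit near unit range.
* **9 amino-acid scale channels** — a small non-redundant scale set:
  Kyte–Doolittle hydropathy, Grantham polarity, Zamyatnin volume,
  Vihinen flexibility, unit net charge, Chou–Fasman helix/sheet/turn
  propensities, and an aromaticity indicator.
* **3 ProtParam descriptors** — molecular weight (average residue
  masses plus one water), isoelectric point (bisection root of the
  Henderson–Hasselbalch net charge, ProtParam pKa set, free termini)
  and the Guruprasad instability index, each computed on the +/-5
  window centred at the row's position. Whether the original method
  computed these per window or per protein is unstated; per-window was
  chosen because the training unit is a residue, and it is what the
  window matrix can carry without leaking global context.
* **4 compartment indicators** — one-hot category of the window
  position (all zero for membrane positions).
* **1 accessibility value** — externally predicted relative solvent
  accessibility in [0, 1] when supplied, otherwise a constant 0.5
  fallback (the synthetic generator supplies a surrogate track).
* **1 low-complexity flag** — a SEG-style two-threshold entropy scan
  (window 12, trigger 2.2 bits, extension 2.5 bits, the canonical SEG
  defaults, since the method names SEG without parameters).
* **1 validity indicator** — 1 for real positions, 0 for padding rows
  beyond the sequence ends, which are otherwise all-zero so the
  network can tell padding from genuine zeros.

The exact 39-feature inventory of the original method is not published;
this schema is the package's versioned stand-in. It is a config object
(`feature_schema()`) with a content hash that is frozen into every
model artifact; prediction refuses inputs built under a different
schema. Membrane residues inside a window contribute their real feature
values — they are features of a labelled neighbour, not labelled
examples themselves.

Continuous columns are z-normalized with statistics estimated on the
training residues and stored in the artifact; indicator columns and
padding rows are left untouched.

## Dataset construction

Training data follows the published rules end to end:

* **Consensus labels.** Given repeated observed/missing structure
  observations, a residue is disordered when at least 90% of
  observations mark it missing, ordered when at least 90% mark it
  observed, and unobserved otherwise; exactly 90% counts as agreement.
* **Fragments.** Every maximal disordered run becomes one fragment
  together with up to 15 ordered residues of flank on each side,
  truncated at unobserved residues and chain ends. Ordered control
  fragments are then drawn at random from fully ordered stretches. The
  original count/length policy is unstated; the package draws one
  ordered fragment per IDR fragment (one for fully ordered proteins)
  with lengths sampled from the protein's own IDR-fragment length
  distribution, which keeps the class and length composition matched.
* **Balancing.** Within each compartment, the majority class is
  downsampled to `floor(1.1 * minority)` so the class counts differ by
  at most 10%. Balancing acts on residues, not fragments, because
  residues are the training unit. A compartment missing a class is
  excluded with a warning.
* **Redundancy and leakage.** A greedy longest-first clusterer (in the
  style of CD-HIT, but internal, so no external binary is needed)
  groups sequences at >= 40% global identity — identical positions over
  the global alignment length under BLOSUM62 with gap opening 10 and
  extension 0.5; 40% exactly is redundant. Fragment splits are seeded
  random cuts at the requested ratios followed by a repair pass that
  moves any test fragment with >= 40% identity to a train or validation
  fragment into the training set, iterated to a fixed point. An
  inverted 3-mer index (Jaccard >= 0.08 by default) screens pairs
  before alignment; setting `word_filter = 0` disables the screen and
  checks every pair. The published PSI-BLAST-hit holdback is an
  exclusion list in this implementation: running PSI-BLAST is out of
  scope, but IDs supplied by the user can be dropped from the test set.

## Models

**Compartment CNNs.** Each of the four compartments has its own
convolutional network over the 11-position window axis: two
convolutions (kernel 3; 32 then 16 channels; ReLU), global average
pooling, and a sigmoid head; binary cross-entropy loss, Adam
(learning rate 1e-3), batch 64. The original architecture is
unpublished; this one is small enough to train on one CPU while
matching the published training regime (early stopping on validation
loss with patience 10). Training restores the weights of the
best-validation epoch. Membrane residues are never scored; their raw
score is 0 by convention.

**Bidirectional recurrent smoother.** A second model refines the raw
track along the chain. Per residue it receives, for each of the 12
preceding and 12 following positions plus itself, the tuple (raw CNN
score, 4-bit compartment one-hot, membrane bit); membrane positions
carry score 0. Each direction runs a tanh recurrent cell (hidden size
8) over its 13-step window; the two final hidden states feed a sigmoid
output. The 12-step truncation is exact by construction: a perturbation
more than 12 positions away cannot change a residue's output, which is
pinned by a perturbation-probe test. The published description names an
LSTM; with windows this short, a gate-free recurrent cell trains
substantially faster on CPU and the properties the method relies on —
bidirectionality, bounded lookback, zeroed membrane input, topology in
the input — are independent of the cell type. The smoother is trained
on full-length fragments, membrane positions included, with the loss
masked to labelled non-membrane residues. (The source text says 12 time
steps in one place and 10 in a figure caption; 12 is adopted and the
value is configurable.)

## Output modes and post-processing

Two published operating points are exposed:

* **specific** — the raw CNN track, smoothed with a +/-4 residue
  moving average, thresholded at 0.65;
* **sensitive** — the smoother's refined track, smoothed with +/-7,
  thresholded at 0.65. The original text states the 0.65 cutoff only
  in its CNN discussion; using it for the sensitive mode as well is a
  declared, configurable assumption. Smoothing is applied to the
  recurrent track (smooth-after-refine), the reading most consistent
  with the published description.

The moving average is truncated at chain ends (the mean over however
many positions remain) and skips membrane positions entirely: they
neither receive a smoothed value (their output is 0) nor dilute their
neighbours' averages. The smoothing operator is a plain moving average;
a median variant would be a one-line config change but is not the
default because the published description says only "smoothing".

Display scores rescale the smoothed track piecewise-linearly so that
the cutoff maps to 0.5: `[0, 0.65] -> [0, 0.5]` and
`[0.65, 1] -> [0.5, 1]`. Calls are boundary-inclusive (score >= cutoff
is disordered), which makes 0.5 the first disordered display value.

## Evaluation

Residue-level evaluation is restricted to the evaluation fragments:
only their labelled, non-membrane residues enter the confusion counts,
even though prediction runs on full chains. Reported metrics are
sensitivity, specificity, balanced accuracy, Matthews correlation and
rank-based (Mann–Whitney) AUC with ties counted half; metrics with a
zero denominator are reported as missing, never as 0. AUC is computed
on the smoothed, pre-rescale scores — the rescaling is strictly
monotone, so this choice cannot change the value; raw vs smoothed does
matter and is configurable. Region-level detection counts a region as
found when at least 60% of its residues are called disordered
(inclusive).

## The synthetic generator

The generator exists so the entire pipeline — features, dataset rules,
training, post-processing, evaluation — runs end to end with no
external data. It emulates the architecture of a TMP: a random inside
or outside start side, 1–4 hydrophobic membrane segments of 17–25
residues, loops (mean 30) and terminal tails (mean 50) alternating
sides. Disordered stretches are planted per non-membrane segment with
side-specific probability (0.5 inside, 0.25 outside, so the
compartment routing has signal to exploit), covering 40–90% of the
segment with a 6-residue minimum. Disorder is carried by two channels
that mimic the real feature channels:

* compositional bias — disorder-promoting residues (P, E, S, Q, K, G)
  enriched 1.5-fold in disordered stretches, order-promoting residues
  (C, W, F, I, L, V, Y) enriched 1.3-fold in ordered ones;
* a surrogate accessibility track — Gaussian around 0.62 (disordered),
  0.40 (ordered) and 0.12 (membrane), sd 0.15, clamped to [0, 1].

These effect sizes were chosen once, before the acceptance suite was
frozen, so that a windowed composition-only score is genuinely
informative (AUC around 0.84 on held-out fragments) yet clearly below
the trained ensemble, and neither channel alone suffices — the model
has to combine them to clear the bar. Labels equal the planted truth
except for a 3% flip rate, and 30% of proteins carry one short
unobserved run, exercising the flank-truncation rule.

What the generator does *not* emulate: real evolutionary profiles
(the pseudo-profile is a substitution-matrix lookup, so profile
channels carry composition, not conservation), sequence correlations
beyond composition, biophysically realistic loop/tail length
distributions, disorder that binds the membrane surface, and
structured extracellular domains with disulfide topology.
Consequently, passing the parameter-recovery bar here demonstrates
that the pipeline is correctly wired and that the models can learn a
planted, multi-channel disorder signal — it does not certify accuracy
on real proteins, for which external profiles and accessibility
predictions would be supplied.

## Numerical choices and problem sizes

* Weight initialisation is seeded (He-style for convolutions); minibatch
  order, fragment placement, splits and subsampling all derive from
  explicit seeds, so runs are reproducible.
* Early stopping uses patience 10 with a minimum improvement of 1e-4 on
  validation loss; the epoch cap defaults to 500, which the patience
  rule makes non-binding in practice on the synthetic task (observed
  stops below 60 epochs).
* Per-compartment training residues are capped at 6000 (validation
  2000) and smoother windows at 20 000 (validation 5000) by seeded
  subsampling; the default end-to-end run uses the 500-protein
  scenario, which trains in a few minutes on one CPU.
* The isoelectric-point bisection runs on [0, 14] to an absolute
  net-charge tolerance of 1e-4 and is vectorized across all windows of
  a protein simultaneously.
* Degenerate inputs have defined behaviour: windows with no standard
  residue, empty score tracks, single-class training sets, soluble
  proteins, fragments outside the sequence, and all-redundant splits
  raise errors; compartments missing a class warn and are excluded.

## Known limitations

* The 39-feature inventory and the CNN/LSTM hyperparameters of the
  original method are unpublished; this package's schema and
  architecture are declared stand-ins behind config objects, not
  reproductions, and its trained weights will not match the original
  server's output.
* Topology must be supplied (or generated); topology prediction is out
  of scope by design.
* The greedy identity clusterer is exact but quadratic without the
  word filter; for corpora far beyond the default scenario a dedicated
  tool would be preferable.
* Published headline numbers on the authors' curated dataset (AUC
  0.83–0.84) are not reproducible without that dataset; the package's
  own bar is the synthetic parameter-recovery suite described above.
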
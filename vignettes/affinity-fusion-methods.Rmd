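---
title: "Methods: grammar-based drug-target affinity regression with perturbation features"
author: "gramdta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grammar-based drug-target affinity regression with perturbation features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Drug-target affinity (DTA) regression predicts a continuous binding
strength — a pKd, or a unified score such as KIBA — for a (small molecule,
protein) pair given only the molecule's SMILES string and the protein's
amino-acid sequence. `gramdta` implements a three-view approach: alongside
the two structural views (drug string, protein string) it adds a
*functional* view of the drug, derived from a chemical-perturbation assay
that records which of 978 landmark genes each compound up- or
down-regulates in treated cell lines. The hypothesis embodied by the model
is that two drugs with similar transcriptional consequences tend to bind
similar targets, so the perturbation signature carries information the
structure alone does not.

## Drug view: grammar one-hot encoding

SMILES strings are first canonicalized with the Open Babel toolkit, so that
alternative spellings of one molecule collapse to a single representation.
The canonical string is tokenized by maximal munch over the terminal
alphabet of a context-free SMILES grammar (the 76-production rule set of
the grammar-variational-autoencoder line of work, shipped as a plain-text
asset in `inst/extdata/zinc_grammar.txt`). An Earley chart parser then
recovers the unique parse tree whose left-to-right leaves reproduce the
token sequence, and emits the rule indices of its leftmost derivation
\(I_1, \dots, I_q\).

The encoding is the binary matrix \(O \in \{0,1\}^{M \times N}\) with
\(M = 277\) rows and \(N = 76\) columns: row \(j \le q\) has its single 1
in column \(I_j\); rows \(q+1, \dots, M\) carry the end-of-sequence
padding rule in the final column. Every row sums to exactly 1, and
`decode_one_hot()` inverts the construction, which makes the round trip
tokenize → parse → encode → decode → replay an exact identity — a property
the test suite checks on grammar-sampled strings and that the acceptance
script recomputes on 100 fresh samples.

Two parser design points are worth recording. First, a chart parser is
used (rather than a deterministic recursive-descent parser) because
ambiguity should be *detected*: if the same constituent completes through
two different rule/split routes, the derivation with the lower rule index
(then the smaller first split) is kept and a warning is emitted. Second,
rule indices are 1-based inside the package, as is natural in R; the
padding rule is rule 76 and occupies the final column.

Strings outside the grammar's language — stereo descriptors the rule set
lacks, two-digit ring closures (`%nn`), tokens like `9`/`0` that are not
grammar digits — are *skipped with a warning and a tally*, never silently
dropped. Derivations longer than 277 rules are likewise skipped, because
the fixed-shape encoding cannot represent them. How the original
benchmark processing handled such strings is not documented anywhere we
know of; skip-and-log is this package's policy and the tallies make the
loss auditable.

## Functional view: regulatory vectors

The perturbation export is replicate-level: one row per (perturbagen,
replicate) with a dose and two gene lists (up- and down-regulated), drawn
from a fixed 978-gene landmark panel. Processing follows five steps:

1. read the replicate table;
2. keep only replicates at the 10 µM reference dose — doses are normalized
   to micromolar first (so `10000 nM` matches) and compared with relative
   tolerance 1e-6, because real exports mix unit spellings;
3. map each perturbagen id to its canonical SMILES, dropping (and
   counting) unmapped perturbagens;
4. for each perturbagen \(i\) and gene \(j\), count the replicates listing
   \(j\) as up-regulated and divide by the perturbagen's replicate count
   \(\mathrm{count}(p_i)\), and likewise for down-regulation:
   \(v_i = \frac{1}{\mathrm{count}(p_i)}\bigl(\sum_j x^{up}_{ij},
   \sum_j x^{down}_{ij}\bigr)\), giving a 978 × 2 matrix of frequencies in
   \([0,1]\);
5. stack the \(k\) per-perturbagen matrices into a \(k \times 978 \times 2\)
   array, ordered by perturbagen id.

Counting conventions the definition leaves open, fixed here: duplicate
gene mentions within one replicate count once (the per-replicate entry is
an indicator); a gene listed up in one replicate and down in another
contributes to both channels independently; \(\mathrm{count}(p_i)\) is the
number of replicates *surviving the dose filter*, not the raw appearance
count; genes outside the landmark panel are dropped with a tally. When two
perturbagen ids map to the same molecule, `regulatory_by_smiles()` pools
their slices by replicate-weighted averaging, which is algebraically the
recount over the union of their replicates.

The whole computation is parallel-checked in the tests against a plain
nested-loop count over (perturbagen, gene, replicate), which must agree
exactly — the arithmetic is rational counting, so no tolerance is needed.

## Protein view: one-hot sequences

Sequences are encoded over a fixed 26-symbol dictionary into 26 × 1000
binary matrices: column \(c\) one-hots residue \(c\); sequences longer
than 1000 keep their N-terminal 1000 residues; shorter sequences leave
trailing zero columns. The dictionary is the 26 uppercase letters A-Z:
the dictionary length is fixed at 26 by the encoding contract, but its
symbols are not pinned down anywhere, and A-Z covers the 20 canonical
residues plus the ambiguity codes (B, J, O, U, X, Z) without arbitrary
exclusions. Lowercase input (common in FASTA exports) is uppercased with
a warning.

## The network

Three encoder branches feed a fully connected regression head
(configuration object: `gramdta_config()`):

* **Drug encoder** — three 1-D convolutions along the 277-step derivation
  axis (filters 9, 9, 10; kernels 9, 9, 11; valid padding), flattened and
  projected to the variational statistics of a 56-dimensional latent. The
  posterior mean is used as a deterministic latent everywhere: no
  sampling, and no KL term in the DTA loss. Pretrained encoder weights
  from a molecule-autoencoding corpus are not bundled; the branch trains
  from scratch, and can be frozen via a zero learning rate if the
  pretrained-and-frozen regime is to be mimicked.
* **RNA-Seq encoder** — the 978 × 2 matrix flattened to 1956 features,
  then two dense ReLU layers (256 → 128).
* **Protein encoder** — either three 1-D convolutions (filters 32, 64,
  96; kernels 4, 8, 12) with global max pooling, or two stacked LSTM
  layers (hidden size 64) whose final hidden state (taken at each
  sequence's true length, so zero padding is never consumed) is densely
  projected. Both produce a 128-dimensional latent.
* **Head** — the concatenated latents (56 + 128 + 128, or 56 + 128 in the
  structure-only ablation) pass through dense layers 256 → 256 → 1.

Only the convolution/kernel counts, the 56-d drug latent, the RNA-Seq
depth (2), the head depth (3) and the LSTM depth (2) are fixed by the
reference architecture; hidden widths, activations, pooling and dropout
are not, so this package defaults to conventional choices — 256-wide
hidden dense layers, ReLU, global max pooling, no dropout — and exposes
every one of them in `gramdta_config()`.

All layers, backpropagation and the Adam optimizer are implemented in
base R with BLAS-backed matrix products (there is no deep-learning
framework dependency). The backward pass of every layer type is validated
against central finite differences in the test suite; the checks jitter
the (zero-initialized) biases first, because sparse one-hot inputs put
many pre-activations exactly on the ReLU kink where a two-sided
difference quotient does not equal the subgradient the code uses.

One numerical device deserves note. The protein encoding is a fixed
26 × 1000 matrix, but most sequences are far shorter, and under valid
convolutions the trailing all-zero columns produce *constant* feature
columns which global max pooling collapses. Batches are therefore
assembled at the batch's maximum true length plus one full receptive
field (22 positions) of zeros — enough for the deepest feature map to
contain one representative "tail" column — which reproduces the
fixed-width computation *exactly* (asserted in the tests) while making
the cost proportional to actual sequence length.

## Training and evaluation

Training minimises plain MSE on the transformed labels with Adam
(defaults: 500 epochs, initial learning rate 0.001, batch size 256). The
"adaptive" learning rate is implemented as reduce-on-plateau — halve when
the validation MSE has not improved for 20 epochs — switchable to a
constant schedule; both modes exist because "adaptive" alone does not
pin down a policy. Early stopping is off by default (a fixed epoch budget
is the reference regime), but the best-validation checkpoint is retained
and used for reported metrics. Affinity labels: Kd values in nM become
pKd \(= -\log_{10}(K_d \cdot 10^{-9})\), the standard label in this
model family; KIBA scores pass through unchanged since the score is
already a unified log-scale quantity. Splits are random by interaction;
cold-drug/cold-target protocols are a deliberate non-goal here.

Evaluation reports MSE and the concordance index. CI counts, over all
pairs with *distinct* actual values, the fraction ordered consistently by
the predictions, with prediction ties scoring 0.5 — the convention of the
DTA literature; pairs tied in the actual labels are excluded from the
denominator, and an all-tied label vector raises an error rather than
returning a number. CI is checked against a brute-force \(O(n^2)\) pair
loop and is invariant under strictly monotone transforms of the
predictions.

## Synthetic data: what it emulates, what it does not

Every stage is testable offline through `gen_fixture_set()`, which writes
real files (exercising the readers, not just in-memory paths):

* `gen_smiles()` draws random leftmost derivations from the grammar —
  biased towards small acyclic molecules and away from ring bonds and
  bracket atoms, since unmatched ring digits are syntactically legal but
  chemically meaningless — and keeps only draws whose canonical form also
  parses. Every output is guaranteed to tokenize, parse (q ≤ 277) and
  re-canonicalize to itself.
* `gen_perturbation_export()` writes a replicate table with 3 on-target
  (10 µM) and 1 off-target (1 µM) replicates per drug by default, with a
  third of on-target doses spelled `10000 nM` to exercise unit
  normalization, plus the id → SMILES mapping. Its closed-form ground
  truth (computable because the generator knows the sampled gene sets) is
  returned and written alongside, giving the pipeline an exact oracle.
* `gen_dta_table()` labels sampled (drug, protein) pairs under three
  models: `random`; `planted_rnaseq`, where the label is a fixed linear
  functional of the drug's regulatory vector plus Gaussian noise
  (sd 0.1) — the construction behind the ablation property, since the
  signal is carried entirely by the RNA-Seq view; and `planted_linear`, a
  deterministic function of simple drug/protein descriptors used for
  overfitting contracts. Labels are centred at a pKd-like 7 with
  unit-scale spread.

Fixture proteins default to 80-160 residues and fixture molecules to a
few heavy atoms — an order of magnitude below real kinase domains and
drug-like molecules. This is a deliberate desk-scale choice: it keeps the
full test suite and the acceptance script re-runnable in minutes on one
core while every tensor contract (277 × 76, 978 × 2, 26 × 1000) stays at
full size. What passing tests demonstrate is therefore *mechanistic*
correctness — encodings, counting, gradients, optimization, the
ablation direction on planted signal — not predictive performance on
real affinity benchmarks, which depends on external data releases and
full-scale (hundreds of epochs, hundreds of thousands of pairs) training
runs outside the scope of this package's checks.

The desk-scale experiment sizes used by the acceptance checks were fixed
in advance as part of the study design: the overfitting contract trains
on 64 zero-noise planted-linear pairs for 200 epochs at batch 16 and must
reach train MSE < 0.05; the ablation fits 500 planted-rnaseq interactions
for 8 epochs at batch 64 under 5 seeds, enough optimization for the
linear-in-features RNA-Seq branch to converge while the structure-only
model is still far from memorizing drug identities, and requires the
RNA-Seq model to win on validation MSE and CI in at least 4 of 5 seeds.

## Degenerate inputs and edge policies

* Empty production sequences, all-padding one-hot matrices, and rows with
  zero or multiple ones are rejected as malformed (q ≥ 1 by invariant).
* A perturbagen with zero surviving replicates cannot produce a vector
  (contract error); a gene never mentioned scores 0 in both channels.
* An all-zero protein matrix (no residues) is accepted by the forward
  passes — the CNN sees pure padding, the LSTM returns its initial
  state — and yields finite latents.
* Non-finite training loss aborts with a diagnostic rather than
  continuing silently; `learning_rate = 0` is legal and provably a no-op,
  which the tests use as an optimizer contract.
* Duplicate (drug, protein) pairs keep their first occurrence with a
  tally; determinism everywhere is seed-driven (`train_config(seed = )`
  governs initialisation and shuffling; fixed seeds reproduce epoch-1
  losses bit-for-bit).

## Known limitations

* The grammar covers a practical but not exhaustive subset of SMILES
  (no two-digit ring closures unless the asset is extended, no isotopes
  beyond three digits, digits 1-8 only); out-of-language molecules are
  dropped, which on real libraries loses records — tallied, but lost.
* Chemical validity is not checked beyond toolkit canonicalization;
  grammar-sampled fixtures can contain exotic valences.
* The LSTM branch is an order of magnitude slower than the CNN branch in
  this base-R implementation and is best reserved for small studies.
* Pooling perturbagens that share a molecule assumes replicates are
  exchangeable across assay contexts (cell line, time), which the
  replicate schema here does not record.
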
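---
title: "Hidden neural networks for transmembrane topology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden neural networks for transmembrane topology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnntm)
```

## The model

A class hidden Markov model (CHMM) describes a protein sequence
$\mathbf{x} = x_1 \ldots x_L$ together with a per-residue label sequence
$\mathbf{y} = y_1 \ldots y_L$ (here: inside loop `i`, membrane `M`, outside
loop `o`). States $k$ carry transition probabilities $a_{kl}$, emission
probabilities $e_k(x_i)$, and a delta-function label map $\delta_k$
assigning each state exactly one label, so a state path implies a labeling.
Two quantities drive everything:

* the **free-running** likelihood
  $P(\mathbf{x}\mid\theta) = \sum_\pi a_{B\pi_1} \prod_i
  e_{\pi_i}(x_i)\, a_{\pi_i \pi_{i+1}}$, summing over all state paths, and
* the **clamped** likelihood $P(\mathbf{x}, \mathbf{y}\mid\theta)$, the same
  sum restricted to paths whose labels agree with $\mathbf{y}$.

Maximum-likelihood training of the CHMM maximizes the clamped likelihood by
labeled Baum–Welch (`baum_welch_labeled()`). Discriminative (conditional
maximum likelihood, CML) training instead minimizes
$\ell = \ell_c - \ell_f$ with $\ell_c = -\log P(\mathbf{x},\mathbf{y})$ and
$\ell_f = -\log P(\mathbf{x})$, i.e. maximizes the probability of the
*labeling given the sequence*. EM does not apply to this difference of
likelihoods, so CML training is gradient-based throughout.

The **hidden neural network** (HNN) keeps the CHMM state graph but replaces
each state's emission probability by the output of a small one-hidden-layer
perceptron $e_k(s_i; w_k) \in (0,1)$, where $s_i$ encodes a window of
sequence context around position $i$ (20 inputs per window position: one-hot
residue blocks, or profile rows when an alignment-derived PSSM is supplied;
out-of-range positions are zero-padded). Because each factor now depends on
the local context rather than on $x_i$ alone, the model can exploit
correlations between neighboring residues that a first-order CHMM cannot
represent. The trellis value is then a *path score* rather than a normalized
sequence probability; all decoding and CML quantities remain well defined
because they only compare scores under the same parameterization.

## Training procedure

**Initialization.** One network per label is trained (full-batch RPROP,
cross entropy by default — it trains faster and better than RMSE for this
0/1 classification — `init_loss = "RMSE"` is available) to output 1 on
windows whose central residue carries that label, 0 otherwise. Each state
then receives a copy of its label's network; copies are untied afterwards
(states of one label may diverge during joint training), with an optional
`tie_networks` flag for permanently shared networks. Initial weights are
uniform in $[-0.1, 0.1]$ from the run seed.

**Joint CML training** (`train_hnn()`). Each epoch runs the free and
clamped forward–backward passes per training sequence (two passes each),
forms the error signal at every network's output pre-activation
$h$ — the difference of free and clamped state posteriors chained through
the output sigmoid,
$\varepsilon_k(x_i) = (\gamma^f_{k,i} - \gamma^c_{k,i})(1 - e_k(s_i))$ —
and backpropagates it to all weights. Transition and begin parameters are
trained jointly by default through a row-softmax reparameterization of
their unconstrained logs; a `joint = FALSE` switch freezes them, since it
is genuinely open whether transitions should move with the networks, and
both modes are useful. The sole correctness contract for the assembled
gradient is agreement with central differences of $\ell$, which the test
suite enforces at relative $10^{-4}$ on seeded tiny models.

**Optimizer.** Full-batch RPROP (variant iRPROP$^-$): per-weight step sizes
grow by $e_a = 1.2$ on consistent gradient signs, shrink by $e_d = 0.5$ on a
sign flip (with the stored derivative zeroed, so the weight holds for that
step), bounded to $[10^{-8}, 1]$, initial step $0.01$. RPROP uses only
gradient signs, which is why training is full-batch: mini-batch sign noise
would defeat the step-size adaptation. Momentum applies only to the optional
plain-gradient path; weight decay ($\lambda\,w$ added to network gradients)
is opt-in with default 0.

**Early stopping.** A seeded 10% of training sequences (by sequence, at
least one) is held back; the held-out CML loss is evaluated after every
epoch and the returned model is the snapshot at its minimum. Training stops
at 50 epochs (the fitted models here reach their held-out minimum well
before that) or after 10 epochs without improvement.

## Numerical choices

* Forward/backward use per-position scaling, with the log-likelihood
  accumulated from log scaling factors; the backward-derived value must
  agree within $10^{-8}$. The scaled recursions are verified against
  brute-force path enumeration (tolerance $10^{-9}$ in log domain for
  CHMMs, $10^{-7}$ for HNNs) on hundreds of seeded tiny instances.
* Network outputs are clamped to $[10^{-6}, 1-10^{-6}]$ before logs, so
  every path score is finite for every input.
* A sequence no state can emit, or labels that demand a forbidden
  transition, yield a `-Inf` log-likelihood *flag* (with the first blocked
  position), not an exception; losses become `+Inf` flagged.
* Baum–Welch floors re-estimated probabilities at $10^{-10}$
  (renormalizing), so no allowed parameter collapses to a hard zero;
  structurally forbidden transitions stay exactly 0 and carry zero
  gradient. Labeled-ML convergence: $|\Delta \log P(\mathbf{x,y})| <
  10^{-6}$, at most 200 iterations.
* Viterbi and the posterior decoder break ties toward the lowest state
  index at each backtrack step, making decoded paths deterministic.
* Unknown residues (`X`, `B`, `Z`, ...) present an all-zero context block
  to the networks and emit $1/20$ in table mode; positions are flagged.

## Decoding and evaluation

Viterbi decoding is provided for completeness, but a CML-trained model is
optimized for the probability of correct *labeling*, not of the single best
path, so the default is the optimal-accuracy posterior decoder: per-position
label posteriors (free-phase state posteriors aggregated by label) feed a
dynamic program over the state graph that maximizes the summed chosen-label
posterior over all labelings realizable by an allowed state path. Running
the DP on states rather than on a label-adjacency graph means grammar
constraints — including minimum segment lengths enforced by chained states —
hold exactly in every decoded labeling.

Evaluation uses the two-state (TM vs non-TM) projection: per-residue
accuracy Q2; the 1999 revision of the segment-overlap score SOV
(length-weighted over both classes, with the $\delta$ allowance term) — the
community-standard definition, stated explicitly in `?sov` since published
variants differ; a correct-topology criterion (equal TM segment counts,
in-order pairwise overlap of at least one residue, and — for alpha-helical
mode — matching loop sidedness, compared by each loop's majority non-TM
label with terminally-empty loops skipped); and a correct-segment-count
criterion. The overlap threshold and sidedness rule are deliberately
explicit and configurable because published benchmarks are sensitive to
this criterion. Discrimination performance uses sensitivity, specificity
and the Matthews correlation coefficient, with MCC defined as 0 when a
denominator factor vanishes.

## Discrimination features

For membrane-protein detection, a logistic classifier consumes
model-derived features: sequence length, log-odds
($\log P(\mathbf{x}\mid\text{model}) - \log P(\mathbf{x}\mid\text{null})$,
with a single-state null model whose emissions are training-set residue
frequencies), length-normalized log-probability (normalized because raw
log-probability would be collinear with the separate length feature),
max probability (maximum chosen-label posterior), decoder score (the
decoding objective per residue), reliability (mean chosen-label posterior),
number of TM segments, and TM/length ratio. The last three posterior-based
quantities are this package's explicit definitions — the feature names are
standard but not standardized. The beta-barrel subset uses six of these,
the alpha-helical subset seven (swapping log-probability for max
probability and decoder score). Features are standardized and fitted by
penalized maximum likelihood with an L2 ridge of $10^{-6}$ on the slopes,
which stabilizes the small-sample fits without materially biasing
coefficients.

## The synthetic generators, and what they do (not) show

Every stage is testable without downloads through two seeded generators
built on a fully documented toy grammar (`toy_topology_model()`): loop
states `i`/`o` and a five-state membrane chain enforcing a minimum TM
segment length of 5, with hydrophobic-biased membrane emissions and
polar/turn-biased loop emissions. Sampled paths are conditioned on ending
outside the membrane so chained TM states are never truncated by the
sequence end. Default sequence lengths are uniform on $[60, 120]$ —
desk-scale but long enough for several TM segments per protein.

* The `chmm` kind samples from the grammar's own emission tables, so
  labeled Baum–Welch should recover the generating parameters; with 300
  sequences the recovered transitions and (tied) emissions land within
  0.02 of truth.
* The `context` kind keeps the label process but draws each residue
  conditional on the *previous residue*: membrane positions repeat their
  predecessor with probability 0.5 (otherwise a hydrophobic-biased table,
  mass 0.6 on A/I/L/V/F), loop positions draw uniformly from the 19
  non-predecessor residues. The per-position marginals give a first-order
  CHMM weak but real signal, while the repeat/avoid pattern is visible only
  to a model that sees a window of context — by construction, the
  Bayes-optimal predictor uses neighbor information. On this process a
  window-5, 5-hidden-unit HNN (20 training and 15 test sequences, 5
  seeds, 50-epoch cap) consistently beats the CHMM trained on identical
  data, and both beat the majority-label baseline.

These generators emulate the *statistical structure* the architecture
targets — grammar-constrained labels, context-dependent emissions — not
real membrane-protein biology: no hydrophobicity scales, no signal
peptides, no evolutionary profiles, no length/composition diversity of real
proteomes. Passing tests therefore demonstrate algorithmic correctness and
the discriminative advantage of context-aware emissions, not benchmark
performance on curated structure datasets, which requires external data and
homology-reduced evaluation sets.

## Problem sizes and defaults

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is statistically meaningful:
enumeration checks on models with at most 3 states, alphabet at most 4 and
$L \le 6$ (hundreds of instances); gradient checks on tiny HNNs
($H \le 3$, window $\le 3$, $L \le 8$); Baum–Welch recovery at 300
sequences; the HNN-vs-CHMM comparison at 20/15 sequences over 5 seeds. The
window/hidden-unit defaults in the run-level helpers (window 7, 5 hidden
units) are sensible starting points for the toy grammar; for real
predictors these are the key tuning dimensions, and published topology
models favor windows near the minimum TM segment length of the fold class
with roughly 7–11 hidden units.

## Known limitations

* Emission networks only; transition probabilities stay scalar (trained or
  frozen), and no recurrent/deep architectures.
* HNN trellis values are unnormalized path scores; compare them only
  within one model parameterization (the discrimination features do this
  via the fitted classifier, not raw score thresholds).
* Labels are hard per-state assignments; soft label probabilities are not
  supported.
* The nucleotide case is structurally possible through the `Alphabet`
  abstraction but untested; profile input is consumed, never produced (no
  alignment searches).
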
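---
title: "Network-weighted prognostic biomarker discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-weighted prognostic biomarker discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omnirank)
```

## The problem

Prognostic biomarker discovery asks which genes discriminate cancer patients
with good versus poor prognosis. Single-gene statistics are noisy in the
high-dimension/low-sample-size regime typical of tumour cohorts (about
10,000 genes against tens of patients), and network propagation methods that
pool evidence over a gene-interaction graph tend to over-reward hub genes
(e.g. UBC-like nodes) regardless of disease relevance. omnirank implements a
pipeline that counters both problems: it restricts the interaction network
to the neighbourhood of genes with differential signal in at least one omics
layer, *learns* edge weights from the patients' omics profiles with an
adversarial network whose generator can only use real biological edges, and
then scores genes by weighted PageRank so that propagation follows learned,
data-supported edges rather than raw connectivity.

## Pipeline model, stage by stage

**Normalization and differential signal.** Each omics matrix (genes x
samples; mRNA expression, copy number, DNA methylation, mutation scores) is
z-scored. For each gene and layer we compute the pooled equal-variance
two-sample t-statistic between poor and good samples,

$$t_i = \frac{\bar x_{i,p} - \bar x_{i,g}}{s_i\sqrt{1/n_p + 1/n_g}},
\qquad
s_i^2 = \frac{(n_p-1)S_{x_{i,p}}^2 + (n_g-1)S_{x_{i,g}}^2}{n_p+n_g-2},$$

with the sign convention poor minus good. The top $N$ genes by $|t|$ in
the mRNA, CNV, methylation and SNP layers form the sets $M, C, T, S$; their
union $U$ drives network reconstruction: an interaction edge is retained iff
at least one endpoint lies in $U$. Non-$U$ neighbours of $U$ genes therefore
remain nodes — the feature-assignment stage needs them.

**Adversarial edge-weight learning.** Per patient we build one real vector
over the reconstructed network's $n$ genes, taking each gene's values from
the layer where its $|t|$ is largest. A generator with no hidden layer maps
standard-normal noise $z$ through the masked symmetric weight matrix,
$\mathrm{output} = \sigma\!\big(z\,(A \odot w \odot w^\top)\big)$ with
$\sigma$ a rectifier and $A$ the 0/1 adjacency, so the only trainable
connections are real network edges and symmetry is guaranteed by the
$w \odot w^\top$ parametrization. A dense discriminator
($n \to 256 \to 1$, rectifier then sigmoid) plays the standard minimax game;
updates alternate one Adam step each (learning rate 2e-4, batch size 1),
and the generator uses the non-saturating form of its loss, the standard
practical choice. After training, edge weights are finalized as
$|A \odot w \odot w^\top|$.

**Scoring and stability selection.** Weighted PageRank iterates

$$PR_i = \frac{1-d}{n} + d \sum_{j \in M_i}
\frac{|G_{ij}|}{\sum_{t \in M_j} |G_{tj}|}\, PR_j$$

from the uniform vector until the largest per-gene change drops below a
threshold (default 0.005). Because adversarial training starts from random
weights, the whole learn-then-rank step is repeated $t$ times and genes
appearing in at least $b$ of the $t$ per-run top lists are kept
(inclusive reading of the threshold, so $b = t$ is permitted).

**Feature assignment and evaluation.** A selected gene that belongs to one
or more of $M, C, T, S$ contributes the corresponding layer(s) as features;
a non-member gene is assigned by a neighbour vote over the reconstructed
network, ties broken by the fixed priority mRNA > CNV > methylation > SNP,
and a non-member with no member neighbours falls back to its max-$|t|$
layer (flagged in the provenance). The assembled samples x features table
feeds a single-hidden-layer rectifier perceptron with an L2 penalty,
evaluated by stratified k-fold cross-validated ROC AUC.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_top` (N) | 400 | genes kept per layer by &#124;t&#124;; at synthetic scale we use 2 x planted count |
| `runs` (t) | 10 | adversarial scoring repetitions |
| `min_count` (b) | 6 | stability threshold, b <= t |
| `rank_top` | 100 | per-run PageRank cutoff; for cohorts with an expected signature size, set it near that size |
| `damping` (d) | 0.85 | PageRank teleportation balance (standard choice; the source method leaves it unstated) |
| `tol` | 0.005 | PageRank stopping threshold on the max absolute change |
| `gan$epochs` | 2 | passes over the cohort; the published recipe's value, kept as the pipeline default |
| `gan$learning_rate` | 2e-4 | Adam step for both players |
| `gan$init_range` | 0.1 | generator weights start uniform on (0, 0.1); values below 1 make w odot w^T shrink, an implicit L2-like regularizer |
| `hidden`, `l2` | 64, 1e-3 | classifier capacity and penalty |

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces layers of Gaussian noise in which a planted set
of genes carries a standardized mean shift (`effect_size`, default 2)
between poor and good samples in exactly one layer each, on a
preferential-attachment network (right-skewed degrees, so hub dominance is
present, as in real interaction networks). Planted genes are placed as a
connected network module by default: network propagation methods presuppose
that disease genes cluster in pathway neighbourhoods, and a simulator that
scattered signal genes uniformly would remove the very structure the method
exploits. Defaults describe a pancreatic-like cohort: 200 genes, 20 good +
20 poor samples, four layers, 20 planted genes.

The generator makes no attempt to mimic copy-number segmentation,
beta-distributed methylation values, sparse mutation calls, inter-layer
correlation of real tumours, or realistic gene counts. Passing tests on
these cohorts therefore demonstrates the *mechanics* of the pipeline —
calibration of the t-statistics, correctness of the propagation algebra,
behaviour of the adversarial game, leakage-free evaluation — not that the
method will attain any particular accuracy on clinical data.

## Numerical and design choices

- **z-score convention.** Scaling uses the sample standard deviation (n-1),
  matching the pooled-variance weights; zero-variance genes map to zero and
  their t is undefined, which excludes them from top-N ranking. The default
  axis is per-gene (across samples), which makes t-statistics comparable
  across genes; `normalize_axis = "sample"` standardizes each patient
  profile instead, the reading used in the original protocol. The
  end-to-end validation runs use the per-sample axis: it preserves
  between-gene variance differences, which is precisely the signal the
  adversarial stage can learn from.
- **Ties.** Top-N selection orders by descending |t| then ascending gene
  identifier; neighbour votes and max-|t| fallbacks use the fixed layer
  priority. All tie-breaks are deterministic so identical inputs give
  identical selections on any platform.
- **Dangling nodes.** A node whose incident weights sum to zero
  redistributes uniformly, keeping the iteration stochastic; scores then
  always sum to 1 (asserted to 1e-9 in the tests).
- **Weight finalization.** Negative effective weights are converted to
  positive once, after training. Converting after every step would change
  nothing downstream, because PageRank consumes magnitudes only.
- **Adversarial dynamics.** The rectifier output of the generator cannot
  produce negative values while z-scored patient vectors are signed, so the
  discriminator can always find residual separation and, with unlimited
  training, the generator's best response drifts toward zero output (the
  nonnegative point closest to the data mean). The informative regime is
  the transient before that collapse: there the generator demonstrably
  shifts weight onto edges incident to high-variance, correlated gene
  modules (the planted signal). Convergence-style checks therefore train
  for 150 epochs at the 200-gene scale — well past the loss plateau, before
  weight structure decays — and the two-sided discriminator mean
  (real and generated batches pooled) is the equilibrium diagnostic; the
  binary cross-entropy objective keeps it near 0.5 whenever training is
  balanced, which is what the equilibrium claim measures at cohort scale.
  An `generator_activation = "identity"` escape hatch exists for signed
  data but is off by default, preserving the published architecture.
- **Evaluation protocol.** `selection_mode = "paper"` reproduces the
  original protocol in which t-tests and biomarker selection precede
  cross-validation; this leaks test labels into selection and inflates
  AUC. `selection_mode = "nested"` refits the entire selection pipeline
  inside each training fold; the package's null-calibration tests use the
  nested mode and verify chance-level AUC under permuted labels.
- **Problem sizes in the test-suite.** Oracle comparisons run on graphs of
  up to 50 nodes against dense linear solves; end-to-end checks use the
  default 200-gene cohorts with 10 adversarial repetitions at 100-150
  epochs, and the null calibration uses 100-gene cohorts with 3
  repetitions of a 5-epoch adversarial stage over 20 permutations. These
  sizes were chosen so the full suite exercises every stage at realistic
  shape while remaining fast on a single CPU.

## Known limitations

- The rectifier/signed-data mismatch above bounds how faithfully the
  generator can match patient vectors; recovery of planted modules is
  partial (roughly half to three quarters of planted genes at default
  settings) because low-degree planted genes receive limited propagated
  score even under favourable weights.
- With the published two-epoch default, the adversarial stage barely moves
  the weights from initialization; the stability selection then mostly
  reflects network degree. Extended epochs (order 100) are needed before
  the learned weights depart meaningfully from random initialization.
- PageRank's uniform-teleportation form only; no personalized restart.
- The classifier is intentionally small; it is an evaluation instrument,
  not a tuned predictor.

## A worked micro-example

```{r example, eval = FALSE}
coh <- simulate_cohort(sim_config(n_genes = 120, planted_genes = 12,
                                  n_layers = 2, seed = 5))
fit <- omnirank(coh, n_top = 24, runs = 5, min_count = 3, rank_top = 15,
                gan = gan_config(epochs = 60), normalize_axis = "sample",
                n_folds = 5, seed = 1)
summary(fit)
plot(fit)          # mean PageRank vs degree, biomarkers highlighted
predict(fit, coh)[1:5]
```
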
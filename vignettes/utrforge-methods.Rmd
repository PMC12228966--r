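---
title: "Designing 5' UTRs with utrforge: model, optimization, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing 5' UTRs with utrforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrforge)
```

## The problem

The 5' untranslated region of an mRNA controls translation initiation and
transcript stability, which makes it a prime engineering target for mRNA
therapeutics and synthetic gene circuits. `utrforge` implements a two-stage
design loop:

1. a **generative model** — a Wasserstein GAN with gradient penalty
   (WGAN-GP) — learns the distribution of natural human-like 5' UTR
   sequences of variable length (up to 128 nt), and
2. a **latent-space optimizer** tunes *the generator's input*, never its
   weights, by gradient ascent against any differentiable sequence scorer:
   ribosome-load / translation-efficiency style scorers that consume the
   UTR alone, or expression-style scorers that consume a fixed 10.5 kb gene
   window with the UTR embedded at the transcription start site (TSS).

Because optimization happens in latent space, every intermediate candidate
remains on the generator's learned manifold of natural-like sequences.

## Sequence representation

Sequences are encoded as 128 x 5 row-stochastic matrices over the channels
(A, C, G, T, PAD). The PAD channel is the variable-length device: a hard
sequence of length L has unit PAD vectors at positions L+1..128, and
decoding takes the per-position argmax and truncates at the first PAD. The
generator is free to emit interior PAD mass; the decode rule defines the
canonical reading, so decoding can never fail. The channel order is a fixed
package convention, chosen so checkpoints and tests are portable.

## The GAN

The generator maps a latent vector $z \in \mathbb{R}^{40}$, drawn i.i.d.
from $\mathcal{N}(0, 1)$, through a dense up-projection, five
pre-activation residual convolution blocks (two convolutions per block,
shared channel count), and a final 5-channel convolution with a
per-position softmax. The critic mirrors this: an input convolution, five
residual blocks, and a dense layer with a single unbounded output and no
saturating activation — it scores, it does not classify.

Training minimizes the WGAN-GP objective

$$L = \mathbb{E}_{\tilde x \sim P_g}[D(\tilde x)]
    - \mathbb{E}_{x \sim P_r}[D(x)]
    + \lambda\, \mathbb{E}_{\hat x}\big[(\lVert \nabla_{\hat x} D(\hat x)
      \rVert_2 - 1)^2\big],$$

with interpolates $\hat x = \epsilon x + (1-\epsilon)\tilde x$,
$\epsilon \sim U(0,1)$ per pair. The critic takes 5 updates per generator
update; initial weights are $\mathcal{N}(0, 0.1)$; both networks use Adam.
Defaults: $\lambda = 10$, Adam(lr $10^{-4}$, $\beta = (0.5, 0.9)$), batch
64, kernel 5, 128 channels, 3000 generator steps. The residual block
internals, optimizer settings and channel count are package choices exposed
in the configuration; only the block count, the critic regimen, the latent
law and the initialization scale are fixed by the method.

### Numerical choice: the penalty's parameter gradient

The penalty value uses the exact reverse-mode input gradient. Its gradient
with respect to the critic's *parameters* is a second-order quantity; we
compute it as a Hessian-vector product by central finite differences: with
$u = \nabla_{\hat x} D(\hat x)$, $g = \lVert u \rVert$ and $v = u / g$,

$$\frac{\partial}{\partial \theta}(g - 1)^2
  = 2 (g-1) \frac{\partial}{\partial \theta}
    \Big[\tfrac{D(\hat x + \varepsilon v) - D(\hat x - \varepsilon v)}
         {2\varepsilon}\Big],$$

evaluated with ordinary backpropagation at the two displaced inputs
($\varepsilon = 10^{-3}$, $v$ held fixed). The approximation is
$O(\varepsilon^2)$ and is validated in the test suite against finite
differences of the exact penalty value (agreement to ~1e-9 at desk scale).
Samples with $g = 0$ (where the norm is not differentiable) contribute
nothing.

## Latent optimization

The update is plain gradient ascent, $z \leftarrow z + s \cdot \nabla_z
\,\text{obj}(G(z))$, with a default unit step $s = 1$ mirroring the raw
`z + gradient` update; a step-size override and optional per-element
gradient normalization are available because a unit step can overshoot for
sharp scorers. No momentum or adaptivity by default. Scores of every
iteration (0..N) are stored and, per batch element independently, the
best-scoring iteration wins, with ties broken toward the earliest
iteration. The selected score can therefore never fall below the initial
score: a run that only degrades falls back to its starting sequence
automatically. Default iteration counts: 10 000 for UTR-only objectives,
3000 for gene-window (expression) objectives.

Soft sequences flow into the scorers end-to-end — hard argmax decoding is
for reporting only — so gradients are exact everywhere. Batch elements
never interact: running an element alone reproduces its batched trajectory
bit for bit (tested).

### Gene windows and the replacement function

Expression-style predictors consume a fixed window of 10 500 nt: 7000 nt
upstream of the TSS and 3500 nt from the TSS on, so the TSS sits at 0-based
index 7000 and the UTR occupies $[7000, 7000 + L)$. Replacing the native
UTR with a designed one keeps the window length and TSS position fixed:
remove the native UTR, insert the new one, and re-fill the tail from
downstream source-gene context (neutral `N` fill, encoded as the uniform
4-channel vector, once context runs out; fills are logged). A literal
slicing arithmetic that does *not* preserve length is retained behind
`replace_utr(..., literal = TRUE)` for audit, because the two behaviors
genuinely differ when UTR lengths differ; the length-preserving contract is
what a fixed-input-width predictor requires, so it is the default.

Per iteration, each element's current length L comes from its argmax decode
(first-PAD rule) — how L should track a changing soft sequence is a package
choice; re-decoding each iteration is the simplest rule consistent with the
reporting decode. The window gradient is sliced to $[7000, 7000 + L)$ —
upstream positions may carry nonzero predictor gradient, but only the UTR
span may act on $z$ (tested: two predictors differing only upstream produce
identical trajectories). Elements whose decode is momentarily empty score
`NA` for that iteration and receive no update. Scores are averaged over the
window set, so one UTR can be tuned for a panel of genes at once; joint
objectives add weighted UTR-only terms (e.g. a GC-content constraint
$-w\,(\text{GC} - t)^2$) on top of the window score.

### Built-in scorers

Pretrained expression/ribosome-load/translation-efficiency networks are
*not* bundled; external models plug in through `adapt_external()`, which
strips the PAD channel and renormalizes the remaining four per position
(with the gradient chained through that renormalization) for models trained
on 4-letter inputs. For testing and desk-scale runs the package ships
analytically tractable scorers with known optima: a GC-target scorer
$-s\,(\text{softGC}(x) - t)^2$ (an all-PAD sequence has zero non-PAD mass;
its score is defined as $-s\,t^2$ with zero gradient), a PWM scorer (max
inner product over windows restricted to the pre-PAD span; subgradient at
the best window, earliest on ties), and a window-level toy expression
scorer that rewards C+G mass just downstream of the TSS and deliberately
carries a small upstream gradient so tests can observe the slicing. Every
scorer must pass `check_scorer()`: determinism, finite gradients, and
central-finite-difference agreement (step 1e-4, relative error < 1e-3) at
random row-stochastic inputs.

## Evaluation

Generated sets are compared to a natural reference set per sequence:

* **Nearest-neighbour Levenshtein distance** (edit distance via
  `utils::adist`) to the closest reference sequence; for a set compared
  against itself, exact string matches are excluded. Exclusions are always
  explicit and logged — no hidden outlier filtering.
* **Nearest-neighbour 4-mer distance**: Euclidean distance between
  length-normalized overlapping k-mer frequency vectors (cosine and L1
  variants available; the Euclidean form is the package's documented
  definition since "k-mer frequency distance" admits several).
* **GC content**, **length**, and **MFE** — folding is always delegated to
  a backend (ViennaRNA's `RNAfold` when present), cached per backend, and
  skipped with a warning when no backend exists, never fabricated.
* **Motif scans**: uORFs (an `ATG` with an in-frame stop; each qualifying
  start counts once), G-quadruplexes (canonical
  `G{3,}(N{1,7}G{3,}){3}`, configurable since published definitions vary),
  and best sliding-window identity to the Kozak consensus
  `GCCGCCACCATGG`.
* **Set comparisons**: two-sample Kolmogorov–Smirnov by default (Wilcoxon
  available); degenerate distributions are reported as such, not tested.

## Synthetic data

`simulate_utrs()` draws per-sequence GC from a truncated normal (defaults:
mean 0.6, sd 0.05 — a human-5'-UTR-like composition), lengths uniform in
[32, 128] by default, bases i.i.d. given GC, and optionally plants
canonical motifs at known spans so the scanners can be checked against
ground truth. `simulate_gene_windows()` builds 10 500 nt windows with the
TSS at index 7000 from synthetic genes long enough to need no fill. The
i.i.d. base model has no positional or dinucleotide structure, no codon
bias and no secondary-structure signal: passing tests show that the
*machinery* (training dynamics, gradients, geometry, bookkeeping) is
correct on distributions with known parameters, not that the model captures
real human UTR biology. Conclusions about real UTRdb-scale data require
retraining on that data at full scale.

## Problem sizes

Tests and the acceptance script run a deliberately small profile chosen to
exercise full training dynamics in minutes on one core: 200 fixture UTRs of
16–56 nt, sequence width 64, 8 channels, batch 16, Adam lr $10^{-3}$, 500
generator steps (2500 critic updates). At this scale the trained generator
reproduces the fixture GC mean to well within 0.1, matches the fixture
length range, and the critic's interpolate gradient norms settle near 1 —
the behaviors that indicate healthy WGAN-GP training. The paper-scale
defaults (width 128, 128 channels, batch 64, lr $10^{-4}$, 3000 steps)
remain the package defaults for real use. Optimization checks use batch 16
with 500 iterations (UTR-only) and 150 iterations over 8 windows
(expression-style).

## Determinism

All randomness flows through R's RNG: a single seed fixes initialization,
minibatch draws, latent draws and fixture generation, and the CLI fans one
global seed out to named substreams so one stage's RNG consumption cannot
perturb another's. Runs are bit-reproducible on a fixed platform with
single-threaded BLAS; multi-threaded BLAS reductions may reorder floating
point sums, so set `OPENBLAS_NUM_THREADS=1` (or equivalent) when exact
replay matters.

## Known limitations

* The fidelity claims above are desk-scale; no pretrained predictor
  weights are shipped, so headline effect sizes against real expression /
  MRL / TE models are out of scope by design and must be reproduced with
  user-supplied model bindings through `adapt_external()`.
* The critic's penalty parameter-gradient is an $O(\varepsilon^2)$
  finite-difference Hessian-vector product, not exact double
  backpropagation; at the validated scales the discrepancy is far below
  optimization noise.
* `optimize_latent`'s unit default step follows the plain update rule and
  can overshoot sharp external scorers — use `step_size` or
  `normalize_grad` there.
* IRES motifs are not scanned (no operational definition is bundled), and
  uORF/G4 definitions are the package's documented operationalizations.
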
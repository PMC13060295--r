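---
title: "Repeat-robust k-mer estimation of substitution rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-robust k-mer estimation of substitution rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kmerrate)
```

## The mutation model and its assumptions

The package estimates the rate of a simple substitution process: a target
sequence $t$ arises from a source $s$ by flipping each position
independently with probability $r$, the substituted base chosen uniformly
among the three alternatives (and never equal to the original). The model
is strand-fixed — $s$ is mutated as written, without reverse-complement
symmetry — and has no indels, no ploidy, and no transition/transversion
asymmetry. `mutateSequence()` is the exact mechanization: one uniform
draw per position, a uniform choice among the three alternatives on a
hit.

Estimation goes through the k-mer mutation probability
$q = 1 - (1-r)^k$ (`qOfR`), with every estimator defined on the $q$ scale
and inverted by $\hat r = 1 - (1-\hat q)^{1/k}$ (`rOfQ`). This is the
method of moments: observe a statistic, equate it to its (possibly
approximate) model expectation, solve for $q$.

## The estimators

Let $sp(s)$ be the set of distinct k-mers of $s$, $occ(\tau, s)$ the
occurrence count of $\tau$, and $L = |s| - k + 1$ the number of k-mer
positions. From a pair of spectra the package extracts
(`kmerObservations`):

* $I^{pp} = |sp(s) \cap sp(t)|$ — shared distinct k-mers,
* $N^{pp} = |sp(t) \setminus sp(s)|$ — novel distinct k-mers,
* $N^{pc} = \sum_{\tau \in sp(t) \setminus sp(s)} occ(\tau, t)$ —
  occurrence-weighted novel k-mers,
* $I^{cc} = \sum_\tau \min(occ(\tau, s), occ(\tau, t))$ — weighted
  intersection.

The two intersection-based comparators are
$\hat q_{obl} = (L - I^{pp})/L$ and the Jaccard transform
$\hat q_{mash} = (1 - J)/(1 + J)$ with $J = I^{pp}/|sp(s) \cup sp(t)|$.
In the idealized *k-span* regime — all k-mers of both sequences distinct,
no mutated k-mer falling back into $sp(s)$ — both are algebraically equal
to $\hat q_{pp} = N^{pp}/L$, and the package's test suite checks the
equality bit-for-bit. On repetitive sequences they diverge: a mutation in
one copy of a repeated k-mer does not remove it from the intersection,
but it always creates a novel k-mer. Counting novel k-mers is therefore
the repeat-robust choice.

$\hat q_{pc} = N^{pc}/L$ additionally counts each novel k-mer with its
multiplicity, accounting for two copies of a repeated k-mer mutating to
the same novel k-mer. Its expectation admits a closed form:

$$E[N^{pc}] = Lq - \sum_{\tau \in sp(s)} occ(\tau, s)\, R(\tau, s),
\qquad
R(\tau, s) = \sum_{j=1}^{k} d_j(\tau, s) (1-r)^{k-j} (r/3)^j,$$

where $d_j(\tau, s)$ counts spectrum members at Hamming distance exactly
$j$ from $\tau$ — $R(\tau, s)$ is the probability that $\tau$ mutates
into a *different* k-mer that already exists in $s$. The bias
$E[\hat q_{pc}] - q = -\sum_j \sum_\tau occ(\tau,s) R_j(\tau,s)/L$ is a
sum of non-positive terms. The package carries an exhaustive-enumeration
oracle (`enumerateOutcomes`, `exactExpectation`) that evaluates these
identities exactly on tiny strings (every one of the $4^{|s|}$ outcomes,
double precision, residual tolerance $10^{-9}$); `lemma1Rhs` and
`theorem1Bias` are the closed forms.

$\hat q_{cc}$ folds the dominant $j = 1$ bias term back into the
estimate:

$$\hat q_{cc} = \frac{N^{pc}_{obs}}{L} + (1 - \hat r_{pc})^{k-1}
\frac{\hat r_{pc}}{3L} \sum_{\tau \in sp(s)} occ(\tau, s)\, d_1(\tau, s).$$

The moment equation containing this term cannot be solved for $r$ in
closed form, and a numerical solver is not guaranteed a unique root, so
the estimator is a deliberate plug-in: compute $\hat r_{pc}$ first,
substitute. `d1Table()` computes $d_1$ for all spectrum members by
enumerating the $3k$ single-substitution neighbors against a hash set —
linear in the spectrum and well under a second at the package's scales,
so no suffix-array machinery is used. The weighted sum
$C = \sum_\tau occ\cdot d_1$ is a single constant per source sequence.

The weighted-intersection comparator $\hat q_{wi} = 1 - I^{cc}/L$ is
included; it shares the count information of $\hat q_{cc}$ but does not
model mutations landing on close neighbors.

## FracMinHash sketching

A sketch (`sketchSpectrum`) retains exactly the k-mers whose seeded
64-bit hash falls below $\theta \cdot 2^{64}$ (integer comparison against
the floored threshold), counts carried over unchanged. The sketched
estimators divide by $\theta L$ with the *true* $L$ — sequence length is
observable even when the spectra are sketched — and are capped at 1,
because sketching variance can push the retained counts above
$\theta L$. Sketching is bias-neutral for $\hat q_{pp}$ and
$\hat q_{pc}$: retention is independent of mutation, so
$E[N^{pc}_\theta] = \theta E[N^{pc}]$ and the bias is unchanged; the test
suite and the acceptance script verify this by comparing grand means over
$10^4$ replicate (mutation, hash-seed) draws at $\theta = 0.5$. The cost
of sketching is variance, growing as $\theta$ shrinks. For
$\hat q_{cc,\theta}$ the $d_1$ constant must be the full-spectrum $C$,
precomputed before sketching; `writeSketch`/`readSketch` store it in the
sketch JSON so a genome can be sketched once and compared many times.

The hash is FNV-1a over the k-mer bytes with a splitmix64-style
finalizer, seeded; any stable 64-bit hash would do, with the documented
consequence that sketch files are only comparable across runs sharing the
hash and seed. Both sides of a comparison must share $(k, \theta,
\text{seed})$; `sketchedObservations` enforces this rather than assuming
it.

## Parameters that matter

* **k** (k-mer length, bp). Larger k separates repeats but saturates
  sooner: all estimators blow up to $\hat r = 1$ when $kr$ is large
  (essentially every k-mer mutates). The package follows common practice:
  k = 30 for repeat-array benchmarking, k = 19 for sketched ANI. The
  evaluation default grid {12, 16, 20, 24, 28, 32} spans the transition
  into blow-up; it is a package choice, as is the benchmark rate grid
  0.001 to 0.251 in steps of 0.02 (relative error is undefined at r = 0,
  so grids must start above it).
* **θ** (FracMinHash fraction, unitless in (0, 1]). Default 1 (no
  sketching) everywhere except ANI mode, which uses 0.01 following
  sketched-ANI practice. Only affects variance.
* **n** (replicates per condition). Default 100 for error grids; the
  bias-preservation checks use 10⁴ because they resolve a standard-error
  sized effect.
* **canonical** (strand folding). Off by default — the model is
  strand-fixed and the bias theory assumes it — and on by default only in
  ANI mode, where real genomes arrive in arbitrary orientation. This is
  a documented deviation from the model, overridable.

## The synthetic repeat array

`tandemRepeatSequence()` emulates a centromeric alpha-satellite array:
a random 171 bp monomer (the alpha-satellite monomer length) repeated
585 times (~100 kbp). The default divergence model is a *lineage*: copy
$i$ is copy $i-1$ passed through the substitution process at rate 0.0013
per copy. Inherited variants are what make real satellite arrays hard —
the same variant k-mer recurs across many copies — and the lineage model
reproduces the hallmark profile of a hard centromeric extraction at
k = 30: on the order of 4 × 10³ distinct 30-mers in 100 kbp, well over
70% of them occurring more than once, and at least one Hamming-distance-1
spectrum neighbor per distinct 30-mer on average. The generator
self-checks the latter two hallmarks and warns when they fail.

An independent-divergence mode (every copy mutated from the root monomer)
is retained as the simpler null model; it cannot reach a majority of
repeated distinct 30-mers at any divergence, because variants are shared
only by hash-collision-like coincidence, which is why it is not the
default.

What the surrogate does *not* emulate: higher-order repeat (HOR) blocks,
gene conversion tracts, CENP-B boxes, transition bias, indels — real
arrays have structure beyond a single mutating lineage. One practical
consequence shows up in benchmarking: the intersection-based estimators
$\hat q_{obl}$ and $\hat q_{mash}$ have biases of opposite sign whose
magnitudes depend on the array's repetitiveness, and each crosses zero at
some divergence level (mash near the default, obl near 1% per copy). At
such a crossing the mis-modeled estimator transiently looks accurate, so
error *orderings* against it on the surrogate are sensitive to the
divergence parameter in a way the corrected count-based estimators are
not. Passing trend tests on the surrogate therefore demonstrate
robustness of the novel-k-mer estimators, not uniform dominance over
every comparator at every repetitiveness level.

## Numerical and interface choices

* All estimators clamp $\hat q$ into [0, 1] before inversion, and `rOfQ`
  clamps its input; the blow-up limit is then consistent: once
  $\hat q_{pc}$ is capped at 1, $(1-\hat r_{pc})^{k-1} = 0$ and the cc
  correction vanishes.
* $\hat q_{mash}$ is computed in the integer form
  $(U - I^{pp})/(U + I^{pp})$ ($U$ = union size) rather than via $J$:
  one floating-point rounding instead of three, which makes the k-span
  equality with $\hat q_{pp}$ exact at the bit level.
* Non-ACGT characters: windows containing them are skipped and excluded
  from $L$ (real assemblies contain N runs; the model lives on a clean
  4-letter alphabet). Input is uppercased, so soft-masked FASTA works.
* Multi-record genomes are pooled per record — no k-mer spans a contig
  boundary; $L$ is the pooled count. For unequal-length pairs (ANI
  mode), $L$ comes from the first (query) sequence, since the model
  defines $L$ from $s$; a `symmetric` flag averages both directions.
* The Jaccard-transform estimator implemented is exactly the
  $(1-J)/(1+J)$ form, not the classical $-\frac{1}{k}\ln\frac{2J}{1+J}$
  Mash distance; the two differ outside the small-$r$ regime.
* Reproducibility: every simulation consumes seeds derived by a fixed
  31-bit mixing function (`replicate i` of cell `(k-index, r-index)`
  under base seed $b$ uses `mixSeed(b, ki, ri, i)`), so any cell of any
  grid can be re-run in isolation, bit-for-bit, and seeded functions
  restore the caller's RNG state.
* The exhaustive oracle enumerates up to $4^{12}$ outcomes in double
  precision; the smallest probabilities involved ($\ge (r/3)^{12}$)
  are far above underflow, and the theorem checks are short sums, so
  exact rational arithmetic is unnecessary at the $10^{-9}$ tolerance.
  Within the test suite, pair statistics are additionally recomputed by
  a deliberately naive second implementation to avoid shared-bug
  blindness.

## Problem sizes used by the test suite

The suite checks the bias identities on all strings of a 30-instance
grid (lengths 6–8, k ∈ {2, 3}, r ∈ {0.05, 0.2, 0.5}), k-span equality on
100 realized pairs, bias preservation with 10⁴ replicates on a 5 kbp
array at θ = 0.5, and the benchmark trends with 100 replicates per
condition on the ~100 kbp surrogate at k = 30, r = 0.10. These sizes were
chosen to resolve the effects being tested (standard errors well below
the asserted margins) while keeping the default run in the minutes range.

## Known limitations

* The substitution-only model: indels shift every downstream k-mer and
  are not handled; divergence estimates on real genomes fold indel
  effects into $\hat r$.
* $\hat q_{cc}$ corrects the Hamming-distance-1 bias term only; at high
  $r$ the $j \ge 2$ terms contribute and a small negative bias remains.
* The cc plug-in has no finite-sample optimality guarantee — its
  construction trades provability for empirical accuracy.
* ANI mode's canonical k-mers break the strand-fixed assumptions of the
  bias theory; the estimators are applied as-is, which matches how
  sketched ANI tools are used in practice but is not covered by the
  theorems.
* Sketch files are hash/seed-specific; there is no cross-tool sketch
  compatibility.
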
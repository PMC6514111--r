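---
title: "The gap-aware two-parameter model behind k2pgap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gap-aware two-parameter model behind k2pgap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(k2pgap)
```

## The model

Classic two-parameter (K2P) distances discard every alignment column that
contains a gap, so insertions and deletions — which are evolutionary events
like substitutions — contribute nothing to the estimated divergence.
`k2pgap` implements a continuous-time model over the five states
$\{A, C, G, T, -\}$ in which a site carrying a nucleotide undergoes

* transitions ($A \leftrightarrow G$, $C \leftrightarrow T$) at rate
  $\alpha$ per site per unit time,
* transversions at total rate $2\beta$ (each of the two possible
  transversion targets at rate $\beta$),
* deletion (replacement by a gap) at rate $\varepsilon$,

while a gap site is replaced by each nucleotide at rate $\varepsilon/4$
(total insertion rate $\varepsilon$). Sequence length is fixed: indels are
modelled as state replacements at homologous positions, which is what an
alignment column records. With $w$ the probability that a site carries a
nucleotide in the ancestral sequence, the total change rate per site is

$$k = w(\alpha + 2\beta + \varepsilon) + (1 - w)\,\varepsilon .$$

Only the products $\alpha t$, $\beta t$, $\varepsilon t$ are identifiable
from a sequence pair, so `t` is treated as dimensionless scaled time
throughout the API.

For a pair of sequences that diverged $t$ time units ago, a homologous site
pair falls in one of five categories — identical ($S_t$), transition-type
($P_t$), transversion-type ($Q_t$), nucleotide–gap ($G_t$), gap–gap
($N_t$) — whose probabilities obey four coupled linear differential
equations (the fifth, $G_t$, is carried as the complement
$1 - S - P - Q - N$; the system determines it and no separate equation is
integrated, in either code path). `pair_probabilities()` evaluates the
closed-form solutions; `ode_pair_probabilities()` integrates the
differential equations directly with fixed-step classical Runge–Kutta and
exists purely as a numerical cross-check: the two are written from
different starting points and the test suite requires them to agree to
$10^{-8}$ over a parameter grid (measured agreement is $\sim 10^{-14}$).

```{r}
p <- rate_parameters(alpha = 0.1, beta = 0.05, epsilon = 0.02, w = 0.9)
total_change_rate(p)
pair_probabilities(p, t = 1)
```

Inverting the closed forms gives the rate–time products from observed
category proportions (`invert_rates()`, natural logarithms — any other base
breaks the round-trip identity with the exponentials $e^{-2(\cdot)t}$). The
map is defined only for $w > 1/2$ and while every logarithm argument stays
positive; outside that region the pair is *saturated* and the divergence is
not recoverable.

## The distance estimator

For one aligned pair, `count_pair()` tallies the five categories over all
$n$ compared columns. The gap-aware distance composes the inversion
formulas with the expected total change count $K = 2tk$ and simplifies to

$$\hat K = \tfrac34\,\hat w\,\log \hat w \;-\;
  \tfrac{\hat w}{2}\,\log\!\big[(S - P)\sqrt{S + P - Q}\big],$$

with $S, P, Q$ the identical/transition/transversion proportions.

**Estimating $w$.** The ancestral nucleotide-existence probability is not
observable from a pair. `k2pgap` uses the observed nucleotide fraction
among the $2n$ characters of the pair, $\hat w = S + P + Q + G/2$. This is
not merely a plug-in: composing the inversion formulas into $K = 2tk$
leaves a residual term $(3w/4 - 1)\log[(S+P+Q-N)/(2w-1)]$ that vanishes
identically when $2\hat w - 1 = S + P + Q - N$, i.e. exactly for this
estimator. The displayed formula is therefore the *exact* composition, a
property the test suite checks to $10^{-12}$. A side effect worth knowing:
under this $\hat w$ the inverted $\hat\varepsilon t$ is identically zero,
so indel divergence enters the estimate only through $\hat w$ and the
category proportions, not through an explicit indel term.

For a gap-free pair $\hat w = 1$ and $\hat K$ reduces algebraically to the
classic two-term K2P distance
$-\tfrac12\log(1 - 2P - Q) - \tfrac14\log(1 - 2Q)$ (tested to $10^{-12}$).

```{r}
cnt <- count_pair("ACGTACGTAC-TGGA-ACCT", "ACGTACATACGTG-ATACGT")
cnt
k2p_gap_distance(cnt)
```

**Saturation.** When $S - P \le 0$ or $S + P - Q \le 0$ the logarithms
leave their domain: the distance is reported as an explicit `NA` with a
`saturated` flag, never as a silent `NaN` or an error, and `NA` cells are
preserved in distance matrices. Callers choose the replacement policy:
`replace_undefined()` substitutes twice the largest finite off-diagonal
entry ("farther than anything measured"), a fixed constant if requested,
or 1.0 when the entire matrix is undefined. The factor-2 rule is a design
choice for tree building — saturated pairs must end up *outside* every
measured cluster — and its arbitrariness is confined to cases the distance
cannot resolve anyway; the all-undefined fallback yields a fully tied
matrix whose NJ resolution is then essentially arbitrary, which is the
honest representation of "no usable signal".

Three gap treatments are exposed by `distance_matrix()`: `k2p_gap` (keep
gap columns, gap-aware estimator), `k2p_complete` (drop every column
gapped in *any* sequence, classic K2P), `k2p_pairwise` (drop gap columns
per pair, classic K2P). Alphabet handling is uniform: uppercase, `U → T`,
`-` (optionally `.`) as gap; any other character — IUPAC ambiguity codes,
`N` — makes that column *excluded for that pair*, since the model has no
ambiguity states. Distances consume integer counts, never pre-rounded
proportions.

## The simulation benchmark

`simulate_replicate()` generates the benchmark data: an ancestor of
i.i.d. uniform nucleotides evolves down a perfect binary tree; on every
edge every site independently moves to each of the four other states of
$\{A, C, G, T, -\}$ with probability `p_change` (one multinomial draw per
site per edge — the model is a per-branch change *probability*, not a
rate, so a branch cannot hit the same site twice). Because length is
fixed, leaf sequences are positionally homologous by construction and are
never realigned. The default study conditions are taxa
$\in \{16, 32, 64, 128, 256\}$, lengths $\{250, 500, 750, 1000\}$,
`p_change` $\in \{0.001, 0.005, 0.01\}$ (low/medium/high) and 100
replicates per condition; benchmark cells average the four lengths with
equal weight (`summarize_benchmark()`).

Reproducibility: each replicate derives an independent 31-bit RNG
substream from the master seed and the (replicate, condition) indices, so
replicate sets are order-independent and every distance method is
evaluated on *identical* alignments (paired design).

Trees are rebuilt with `neighbor_joining()` — a vectorized Saitou–Nei
implementation in which exact ties in the Q-criterion are broken by the
smallest (row, column) pair in current label order and a joined cluster
inherits its first member's position, making runs bit-reproducible — and
scored correct when the Robinson–Foulds distance to the (unrooted) model
tree is zero. Negative NJ branch lengths are kept internally (topology is
unaffected) and clamped only optionally at Newick output.

**What the generator does and does not emulate.** It produces equal base
frequencies, site-independent evolution, single-column indels and
perfectly known homology. Real barcode alignments have none of these
luxuries: multi-residue indels, alignment error, compositional bias and
rate heterogeneity are all absent, so green benchmark results demonstrate
correctness of the estimators under the model's own assumptions, not
field performance.

**A structural property of the low-rate condition.** At
`p_change = 0.001` the per-edge total change probability is $0.004$, so an
internal edge of the 16-taxon tree is supported by at least one change
with probability $1 - 0.996^L$ ($\approx 0.63$ at $L = 250$). The chance
that *all* twelve single internal edges receive any change is then below
1% at $L = 250$, and unsupported edges can only be recovered by luck
($\approx 1/3$ each). Topology accuracy under this condition is therefore
capped well below 100% for any distance method — the relevant comparison
is *between* methods under identical replicates, where keeping gap columns
consistently helps (the shipped acceptance script computes the actual
percentages).

## Barcoding analytics

`partition_pairs()` splits all $\binom{n}{2}$ sequence pairs into
intraspecific and interspecific sets from an id→species table;
`summarize_overlap()` reports means, population standard deviations
(sample SD available via `sd_type`), the maximum intraspecific distance,
the overlap (percentage of interspecific pairs *strictly* below that
maximum — a pair exactly at the maximum is not overlapping), the trimmed
overlap, and zero-distance interspecific pair counts at exact numeric zero
(both sequence pairs and distinct species pairs).

Trimming removes exactly $\lceil \text{trim} \cdot N \rceil$ values from
the stated tail of each list (largest intraspecific, smallest
interspecific) after a stable sort — ties are not grouped; trimming an
$N = 1$ list empties it and the result is flagged undefined rather than
computed on nothing. Undefined distances never enter any summary; they are
counted separately.

## Numerical choices

* RK4 step: $10^{-3}/(\alpha + 2\beta + \varepsilon + 1)$ by default, so
  the $O(\text{step}^4)$ truncation error sits far below the $10^{-8}$
  cross-check tolerance; steps above $0.5/(\alpha+2\beta+\varepsilon)$ are
  rejected as unstable.
* All logarithms natural; distances printed at 6 decimals by the writers,
  computed at full double precision internally.
* Matrix cells and single-pair calls share one counting kernel; a fast
  index path is used when the alignment contains no excluded characters
  and is tested cell-by-cell against the single-pair path.
* Test problem sizes: the model grid uses
  $\alpha,\beta,\varepsilon \in \{0, 0.01, 0.1\}$, $w \in \{0.6,0.9,1\}$,
  $t \in \{0.1,1,5\}$; benchmark checks run 100 replicates × 4 lengths at
  16 and 64 taxa and 20 replicates at 256 taxa — sizes chosen to keep the
  binomial standard error of an accuracy cell near 2.5 percentage points.

## Known limitations

* $w$ must exceed $1/2$ for the inversion to exist; alignments that are
  mostly gap for a pair give undefined distances.
* The indel process is symmetric (deletion rate = total insertion rate)
  and strictly single-site; there is no gamma rate heterogeneity and no
  distance variance formula.
* The barcoding layer consumes alignments; it neither builds them nor
  corrects them, and empirical results inherit whatever alignment was
  supplied.
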
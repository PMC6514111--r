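# k2pgap

Indel-aware genetic distances for aligned nucleotide sequences, with a
simulation benchmark for tree-reconstruction accuracy and DNA-barcoding
overlap analytics.

## The problem

The Kimura two-parameter (K2P) distance is the default divergence measure
in molecular evolution and DNA barcoding, but it throws away every
alignment column containing a gap — insertions and deletions simply do not
count as evolution. For loci where indels carry much of the signal (ITS2
and other barcode markers, closely related species), that discards exactly
the characters that separate taxa, inflates the overlap between intra- and
interspecific distances, and degrades distance-based trees.

`k2pgap` implements a five-state extension of the K2P model in which the
gap is a character state: transitions occur at rate α, transversions at
total rate 2β, deletions (nucleotide → gap) at rate ε and insertions
(gap → nucleotide) at total rate ε, with *w* the probability that a site
carries a nucleotide. Site-pair categories (identical *S*, transition *P*,
transversion *Q*, nucleotide–gap *G*, gap–gap *N*) evolve by known closed
forms, and inverting them yields the gap-aware distance

K̂ = (3/4)·ŵ·log ŵ − (ŵ/2)·log[(S − P)·√(S + P − Q)],

with ŵ = S + P + Q + G/2 the observed nucleotide fraction of the pair.
For gap-free pairs ŵ = 1 and K̂ reduces exactly to the classic K2P
distance −(1/2)log(1 − 2P − Q) − (1/4)log(1 − 2Q).

The package provides, per module:

* **model layer** — rates, closed-form category probabilities, an
  independent Runge–Kutta integrator of the model's differential
  equations used as a numerical cross-check, inversion formulas
  (`rate_parameters()`, `pair_probabilities()`,
  `ode_pair_probabilities()`, `invert_rates()`);
* **distances** — site-pair classification, counts, the gap-aware
  estimator and classic K2P under complete-deletion / pairwise-deletion
  gap handling, matrices with explicit undefined (saturated) cells
  (`count_pair()`, `k2p_gap_distance()`, `k2p_distance()`,
  `distance_matrix()`, `replace_undefined()`);
* **trees** — reproducible Saitou–Nei neighbor joining and
  Robinson–Foulds topology comparison (`neighbor_joining()`,
  `robinson_foulds()`, `unrooted_topologies_equal()`);
* **simulator** — five-state sequence evolution on perfect binary trees
  and a paired-design topology-accuracy benchmark
  (`simulate_replicate()`, `run_benchmark()`);
* **barcoding** — intra-/interspecific pair partition, overlap and
  trimmed-overlap percentages, zero-distance pair counts
  (`partition_pairs()`, `summarize_overlap()`);
* **I/O** — aligned FASTA, square PHYLIP matrices, Newick, long-format
  TSV pair tables, and a thin command-line wrapper
  (`system.file("scripts", "k2pgap.R", package = "k2pgap")`) with
  `dist`, `nj`, `simulate`, `benchmark` and `barcode` subcommands.

## Worked example

```r
library(k2pgap)

cnt <- count_pair("ACGTACGTAC-TGGA-ACCT", "ACGTACATACGTG-ATACGT")
cnt
#> Site-pair counts over 20 compared sites (alignment length 20, 0 excluded):
#>   identical 15, transition 1, transversion 1, nuc-gap 3, gap-gap 0

k2p_gap_distance(cnt)
#> k2p_gap distance: 0.177403  (w_hat = 0.9250)  [n = 20]
```

The pair differs by one transition, one transversion and three single-site
indels over 20 columns; ŵ = 0.925 is the fraction of the 40 characters
that are nucleotides. The gap-aware estimate, 0.177 changes per site,
counts the indels as events. Dropping the gap columns instead hides them:

```r
k2p_distance(count_pair("ACGTACGTAC-TGGA-ACCT", "ACGTACATACGTG-ATACGT",
                        "drop_gap_sites"))
#> k2p distance: 0.128369  [n = 17]
```

The same contrast drives tree accuracy. On sequences evolved along a
16-leaf perfect binary tree (medium change rate, 25 replicates at two
lengths, both methods scored on identical data):

```r
res <- run_benchmark(16, c(250, 500), 0.005,
                     methods = c("k2p_gap", "k2p_complete"),
                     n_replicates = 25, seed = 7)
summarize_benchmark(res)
#>   n_taxa p_change       method n_replicates accuracy_pct
#> 1     16    0.005 k2p_complete           50           74
#> 2     16    0.005      k2p_gap           50           92
```

Keeping the gap columns recovers the true topology in 92% of replicates
versus 74% for complete deletion of gapped columns.

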
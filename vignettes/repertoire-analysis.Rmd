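---
title: "Methods: downstream analysis of TCR repertoires with clonotools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream analysis of TCR repertoires with clonotools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotools)
```

## Scope and data model

`clonotools` operates *downstream* of CDR3 extraction: its input is a
clonotype table — one row per clonotype (a class of sequencing reads sharing
a CDR3 sequence and V/J gene assignment) with a read count, CDR3 nucleotide
and amino-acid sequences, V/D/J gene names, junction borders and insertion
counts. It does not process raw reads, correct sequencing errors, or align
to germline references.

A repertoire is a plain `data.frame` with a `repertoire` class, so base R
subsetting and transformation idioms work unchanged. Junction borders are
normalized internally to 0-based half-open coordinates; the I/O *dialect*
declares the source convention (the bundled MiTCR-style dialect stores
0-based inclusive "last V/D nucleotide" positions, converted on read and
restored on write). Undefined values use fixed sentinels: `-1` for integer
fields, `""` for gene names. Column headers of exporters drift over time, so
the dialect is a user-editable mapping (JSON/YAML) rather than a hard-coded
header list; only the read count and the CDR3 nucleotide sequence are
mandatory.

Two conventions apply everywhere and make every output deterministic:

* **Clonotype identity** is one of five keys: `nt`, `aa`, `nt+v`, `aa+v`,
  `aa+v+j`. Gene names are compared after stripping allele suffixes
  (`*01`), since analyses compare genes, not alleles (a flag disables
  stripping).
* **Ordering** is read count descending, key string ascending. All ranked
  operations (collapsing, top-cross, clonal proportion) use it, so ties
  never depend on input order.

In-frame means: CDR3 nucleotide length divisible by 3 *and* no stop codon
in the translation — the standard AIRR convention.

## Descriptive statistics

`summary_stats()` reports distinct nucleotide/amino-acid clonotype counts,
total reads, the in-frame fraction and the clonal count skewness. Skewness
is the sample Pearson moment coefficient
\(g_1 = m_3 / m_2^{3/2}\) on the read-count vector; because clonal counts
are heavy-tailed, a `log10_counts` flag takes moments of
\(\log_{10}\) counts instead. `clonal_proportion(x, q)` is the minimal
number of top-ranked clones whose cumulative share of reads reaches
\(q/100\).

The in-silico spectratype is the V-gene × CDR3-length cross-tabulation,
weighted by clonotypes or reads. Its margins reproduce the 1-D length
distribution and the V-usage tallies exactly — this identity is enforced in
the test suite. The length axis keeps only observed lengths by default; a
`dense` flag zero-pads the full range for plotting.

## Gene usage, entropy, JSD, PCA

Gene usage is the frequency of each V (or J) segment, weighted by
clonotypes (default) or reads. Comparisons use Shannon entropy
\(H=-\sum p_i \log p_i\) and the Jensen–Shannon divergence
\(\mathrm{JSD}(p,q) = H(\tfrac{p+q}{2}) - \tfrac{H(p)+H(q)}{2}\),
computed after aligning the two distributions on the union of gene names
with zero fill. Logarithms are natural by default (JSD maximum
\(\ln 2 \approx 0.693\)); any base > 1 can be requested. Zero-probability
terms contribute nothing; distributions must sum to 1 within `1e-6`.

PCA of the samples × genes usage matrix uses the covariance (not
correlation) of frequencies via `stats::prcomp`; frequencies share a scale,
so correlation scaling would only amplify rare-gene noise. The sign of each
component is fixed by making its largest-magnitude loading positive, which
makes scores reproducible across platforms.

## Overlap statistics

Shared-clonotype analysis collapses each repertoire by the chosen key and
intersects key sets. Similarity measures:

* Jaccard index \(|A\cap B|/|A\cup B|\) on key sets;
* Morisita's overlap — both forms, because the name is used for two
  different estimators. The **classic unbiased** index
  \(C = 2\sum x_iy_i / ((D_x+D_y)XY)\) with
  \(D_x=\sum x_i(x_i-1)/(X(X-1))\) can exceed 1 and needs ≥ 2 reads per
  sample; the **Morisita–Horn** index
  \(C_H = 2\sum p_iq_i/(\sum p_i^2+\sum q_i^2)\) is proportion-based and
  bounded in [0, 1]. Horn is the default: bounded, total, and the common
  choice for repertoire comparisons.
* The **top-cross** curve intersects the k most abundant clonotypes of two
  samples over an increasing ladder of k. "Normalised" is implemented as
  division by \(\min(k, |a|, |b|)\) — the only normalization that keeps two
  identical repertoires at exactly 1 at every step. A step larger than a
  repertoire takes the whole repertoire, so one step grid serves unequal
  sample sizes.

Multi-sample heatmap tables default to the amino-acid key; top-cross
defaults to the nucleotide key (amino-acid convergence inflates top-rank
sharing).

## Diversity estimation

All estimators act on the per-clonotype count vector after collapsing by a
key. Implemented: Hill numbers
\({}^qD = (\sum p_i^q)^{1/(1-q)}\) with the \(q\to1\) limit
\(\exp(-\sum p_i\ln p_i)\) and \({}^\infty D = 1/\max p_i\); the Gini
coefficient (computed by the \(O(n\log n)\) sorted form of the pairwise
absolute-difference sum); Gini–Simpson \(1-\sum p_i^2\); inverse Simpson;
Chao1 in the classic and bias-corrected forms (bias-corrected is the
default because it is defined when no doubletons exist); and rarefaction.

Exact rarefaction uses the hypergeometric expectation
\(E[S(m)] = \sum_i \left(1 - \binom{N-x_i}{m}\big/\binom{N}{m}\right)\)
evaluated with `lchoose` so that repertoires with millions of reads do not
overflow. Resampled rarefaction draws subsamples of reads without
replacement (the multivariate hypergeometric) and reports mean ± sd over
replicates; both modes are provided because either convention appears in
practice, and the suite checks they agree within Monte-Carlo error.

The default diversity profile grid is \(q = (0, 0.5, 1, 2, 4, \infty)\),
spanning richness-dominated to dominance-dominated orders.

## The generative simulator

`generate_repertoire()` draws independent recombination events from a
factorized model: V from \(P(V)\); the (D, J) pair jointly from
\(P(D,J)\) (V independent of (D, J), as in factorized models of TRB
recombination); deletion lengths at the V 3′ end, J 5′ end and both D ends
from per-segment distributions; insertion lengths at both junctions from
length distributions; inserted nucleotides from first-order Markov chains.
Both insertion chains run 5′→3′ on the top strand — a simplification
relative to models that treat the DJ junction on the reverse strand. The
event assembles `trimmed-V + VD-insert + trimmed-D + DJ-insert + trimmed-J`;
identical sequences collapse into clonotypes with summed counts.

Numerical/sampling choices:

* **Infeasible deletions.** When a drawn segment is shorter than a deletion
  distribution's support, the distribution is renormalized to the feasible
  lengths (for D, the 5′ deletion is drawn first and the 3′ distribution is
  renormalized to the remaining length). A `truncate` policy (clamp to the
  segment length) is available behind a flag. Renormalization keeps
  sampling total — no rejection loops, so a fixed seed yields a fixed
  output.
* **Determinism.** All randomness flows through R's RNG seeded once per
  call; identical `(model, n, seed)` give bit-identical repertoires.
* **Clone sizes.** Each draw has count 1, so raw output is nearly flat. An
  optional `expansion` exponent draws per-event counts from a discrete
  power law \(P(c) \propto c^{-(\alpha+1)}\) (capped at \(10^4\)) to create
  the skewed clone-size distributions that diversity statistics are meant
  to summarize.

The bundled `default_model()` is **synthetic**: 12 V, 2 D and 6 J toy
segments (V segments start with the canonical cysteine codon `TGT`,
J segments end in a fixed motif), mildly non-uniform gene probabilities
drawn once from a seeded gamma profile, geometric-like deletion (support
0–6 nt, ratio 0.6) and insertion (support 0–8 nt, ratio 0.7) profiles, and
gently biased insertion Markov chains. These values are chosen to give
realistic-looking junction structure — a few trimmed bases and a few
inserted bases per junction, CDR3 lengths around 30–45 nt — while staying
small enough to exercise every code path quickly. They are *not* inferred
from data; biologically calibrated parameter sets load from the documented
JSON schema (`read_generative_model()`). Consequently, what the simulator
validates is self-consistency (empirical marginals converge to the model,
assembly and borders agree, seeds reproduce), not biological realism: tests
passing on simulated data say nothing about, e.g., real V-usage skew,
allele-level variation, or sequencing error, which the generator does not
emulate.

## Reports and figures

`run_single_report()` and `run_group_report()` compute every enabled
section through the same public functions a user would call, write each
table as TSV, and render a markdown report plus a small self-contained HTML
version. Reports are pure functions of (inputs, config, seed): timestamps
are off by default so two runs are byte-identical, and the acceptance
script verifies this. Figures (`render_plots()`) are drawn from the bundle
tables only and each gets a TSV sidecar with exactly the plotted numbers —
plots are views, never computations. The CLI (`exec/clonotools`) is a thin
wrapper over these functions with exit codes 0 (success), 1 (usage error),
2 (data/format error).

## Problem sizes used in the checks

The test suite works on generated fixtures of 20–200 clonotypes (50 random
fixtures for the oracle-equivalence checks) and simulator runs of 400–2,000
draws; the simulator self-consistency check uses 100,000 draws, where
binomial 4-standard-deviation bands and a total-variation bound of 0.02 on
insertion-length marginals are comfortably discriminating. The acceptance
script simulates three samples of 20,000 draws each for the overlap,
gene-usage and diversity quantities, and compares Monte-Carlo rarefaction
(200 replicates) against the exact curve. These sizes were chosen so that
stochastic checks have narrow sampling bands while the whole suite stays
quick to run.

## Known limitations

* Gene-name handling is string-based; no IMGT ontology validation.
* The motif search is a windowed Hamming match with a single-character
  wildcard `X`; it does not do gapped or position-weight-matrix matching.
* Classic Morisita is undefined for samples with fewer than two reads and
  the classic Chao1 for repertoires without doubletons; both raise
  informative errors and have total-function defaults (Horn,
  bias-corrected).
* No inference of generative-model parameters from data: the simulator
  generates, it does not fit.
* No statistical testing layer (overlap significance, differential usage);
  the outputs are descriptive tables and measures.
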
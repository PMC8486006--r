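---
title: "Plastome repeat architecture and inversion analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome repeat architecture and inversion analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastrep)
```

# Scope and model

`plastrep` analyses the repeat architecture of circular plastid genomes and
its relationship to large inversions. The package treats a plastome as a
linear sequence of length $L$ with an explicit origin: coordinates are
0-based and half-open throughout, and a feature crossing the origin is stored
as a single record with `end > L` rather than as two split records (splitting
happens only at GFF3 export). Statistics near the origin use padded feature
sets (`pad_features()`): features overlapping the first and last `pad` bases
are duplicated shifted by $\pm L$, so windows near the origin see the same
neighbourhood as interior windows — the standard linearization trick for
circular molecules. Genomes are rotated (`rotate_genome()`) when an analysed
segment would cross the origin.

# Repeat discovery

**Dispersed repeats.** `find_dispersed_repeats()` performs a seed-and-extend
self-comparison in both orientations: exact `word`-length seeds (default 11)
shared by two positions are merged along their diagonal and extended
gaplessly with X-drop scoring (+1 match, −2 mismatch, drop 6), then trimmed
to the maximal-scoring span. Pairs are kept when the aligned length is at
least `min_len` (default 30 bp) and identity (matches / columns) is at least
`min_identity` (default 0.90). The extension is gapless: at plastome repeat
lengths (tens to a few hundred bp between very close copies) indels within a
repeat pair are rare, and the identity threshold absorbs the cases an
affine-gap extension would rescue. With `min_identity = 1` and `xdrop = 0`
the output provably equals the set of maximal exact repeat pairs — the
property the test suite checks against a brute-force per-diagonal oracle.
One consequence worth knowing: a "planted" repeat can legitimately be
reported a few bases longer than planted, because flanking bases match by
chance (probability 1/4 per position); the reported pair is the maximal one.

**Tandem arrays.** `find_tandem_repeats()` compares the sequence with itself
at every candidate period $p$ (1–500 bp): positions with `s[i] == s[i+p]`
form match runs that are merged across interruptions only while (a) overall
identity stays at or above `min_identity` (default 0.80) and (b) each bridged
gap is locally paid for by the incoming run — without the local rule, random
flanking sequence (25% expected identity) can creep into an array while the
cumulative ratio stays above threshold. Arrays spanning at least 30 bp are
reported with period, copy number, and consensus; arrays explained by a
smaller period at the same location are dropped.

**Merging and grouping.** All implicated intervals are unioned into
disjoint, sorted repeat features (`merge_repeat_intervals()`; idempotent),
and features linked by any repeat pair are grouped into connected components
(`group_repeats()`), mirroring the practice of exporting one representative
sequence per repeat group.

# Cross-taxon clustering

`build_similarity_graph()` aligns every pair of group representatives
locally (match +2, mismatch −3, gap open −5, gap extend −2) **on both
strands** — repeats carried inside an inverted segment are stored
reverse-complemented, and a single-strand comparison would spuriously
isolate the inversion carrier. An edge requires score ≥ 50 (25 identical
bases) and aligned coverage of at least half the shorter representative;
these thresholds are exposed because the original tool chain's exact
settings are not recoverable.

`markov_cluster()` is a from-scratch Markov Cluster implementation:
self-loops (column maximum), column normalization, then alternating
expansion (matrix square) and inflation (elementwise power 2.0, pruning at
$10^{-6}$, renormalization) to convergence; clusters are connected
components over the nonzero entries of the limit matrix. Occupancy
categories follow the rule: *all* = every taxon; *majority* = more than half
but not all; *minority* = at least two up to half; *unique* = single taxon.
The majority/minority boundary is a package convention (strictly more than
half), stated here because the source tool chain never printed one.

# Window dispersion statistics

Repeats are counted in nonoverlapping 3-kb windows **by start coordinate**,
so counts sum to the number of repeats; the trailing partial window is
discarded — the only rule consistent with every published (plastome length,
df) pair, giving $\mathrm{df} = \lfloor L/3000\rfloor - 1$. The
interval-overlap alternative (a repeat spanning two windows counted twice)
is not used because it cannot be reconciled with published totals.

The dispersion test is the Pearson chi-square against the Poisson
expectation of variance equal to the mean:
$\chi^2 = \sum_i (x_i - \bar x)^2/\bar x$, $\mathrm{df} = n-1$, two-tailed
$p = \min(1,\, 2\min(F(\chi^2), 1 - F(\chi^2)))$. Because the sample
variance uses the $n-1$ denominator, $\chi^2/\mathrm{df}$ equals the
variance:mean ratio exactly — an identity the published tables obey and the
package asserts. Classification at $\alpha = 0.05$: Overdispersed when
$p \le \alpha$ and ratio > 1, Underdispersed when $p \le \alpha$ and
ratio < 1, else Poisson. Published statistics are rounded to two decimals,
so a p-value recomputed from a printed $\chi^2$ can differ from the printed
p in its last significant digit (e.g. $\chi^2 = 89.71$, df 39 gives
$1.436\times10^{-5}$ where $1.43\times10^{-5}$ was printed from the
unrounded statistic).

Sliding densities use 3-kb windows advanced by 100 bp over the padded axis;
each 100-bp segment reports the mean count over all windows overlapping it,
and padding segments are removed before output. Endpoint enrichment uses a
1-df goodness-of-fit over {region, complement} with
$E = N \cdot \ell_{\text{region}}/\ell_{\text{reference}}$, reported
one-sided for enrichment; the reference is either the whole genome or the
union of intergenic spacers.

# Inversion detection and endpoint refinement

Anchors are maximal runs of `min_len`-mers (default 20) unique in both
sequences, in both orientations — a maximal-unique-match construction.
Same-orientation anchors are chained into blocks by query coordinate; a
reverse block spanning at least 1 kb is one inversion, with approximate
endpoints at the midpoints of the anchor gaps. Chance matches can extend a
flanking forward anchor a few bases past the true junction, so flank blocks
are selected by start position and slight overlaps are tolerated.

**Refinement.** The published procedure localizes exact endpoints by
minimizing gaps/poor alignment in junction alignments; the package
formalizes this as: over all candidate pairs $(a, b)$ within ±250 bp of the
approximations, score the reversion at $(a,b)$ by the total number of
mismatching positions in the four 250-bp junction flanks of the reverted
query against the reference, and return the argmin with ties broken toward
smaller $a$, then smaller $b$. Because the candidate grid itself slides the
junctions, a gap-free per-candidate comparison scores exactly the alignments
an indel-aware aligner would produce whenever query and reference are
colinear outside the inversion (true by construction in the generator, and
very nearly true for closely related plastomes); it is computed exactly and
cheaply from diagonal match-vector cumulative sums. Refinement fails
explicitly when no candidate beats the unreverted alignment.

**Microhomology and identifiability.** A microhomology at the endpoints
makes the endpoint pair fundamentally ambiguous: if the $r$ bases entering
the segment at one end complement the $r$ bases leaving it at the other,
every pair $(a-k, b+k)$, $k \le r$, reverts to the *same* genome. The
package resolves the tie leftward (smallest $a$), and
`scan_microhomology()` therefore reads the signature just inside the refined
junctions: site $i$ matches when base $a+i-1$ complements base $b-i$. A hit
is flagged MMBIR-consistent when the leading complementary run is ≥ 4 and at
least 80% of the first 10–12 sites complement — descriptive thresholds for
microhomology-mediated break-induced replication, not significance tests; on
random junctions the leading run is geometric with success probability 1/4.
Under sequence divergence, endpoint recovery is exact only up to a shift
within the complementary run — a property of the data, not the algorithm.

**Endpoint geometry.** `find_short_irs()` enumerates all
containment-maximal repeat pairs ≥ 10 bp with ≤ 10% mismatches (both
orientations, matching terminal bases) — seeded by the pigeonhole guarantee
that any valid pair contains an exact run of ≥ 5 matches, with maximality
resolved over mismatch-bounded segments. `classify_endpoint_repeat_geometry()`
finds inverted pairs linking the two endpoint vicinities (1 kb), maps the
best pair back through the reversion, and reports `direct-repeats-one-end`
when the copies ancestrally sat on the same side in the same orientation
(the constructive mechanism below), `inverted-repeats-both-ends` when they
ancestrally flanked both endpoints in opposite orientation, else `none`.
Short chance pairs are ubiquitous (a 12-bp pair with one mismatch is
expected several times over between two 2-kb regions), so classifications
based on pairs near the minimum length should be read against that
background expectation.

# Comparative methods

Traits (total repeat length, repeat content, density per 3 kb, and the
variance:mean ratio) are natural-log transformed before analysis. The
Brownian-motion likelihood with Pagel's $\lambda$ multiplies the
off-diagonal entries of the shared-path covariance $C$ by $\lambda$;
$\hat\mu$ and $\hat\sigma^2$ are profiled GLS estimates and $\hat\lambda$ is
found by bounded scalar optimization on $[0,1]$ (tolerance $10^{-6}$,
endpoints checked). Significance is assessed against $\lambda = 0$ by a
likelihood-ratio statistic on $\chi^2_1$ — the conventional construction,
stated here because published λ values come with p-values but not with the
test definition. PGLS uses the Cholesky-whitened regression with $t$ tests
on $n - p$ df and reduces exactly to OLS under identity covariance; the
phylogenetic t-test is PGLS on a group indicator, with Brownian ($\lambda=1$)
covariance by default and a one-sided option for directional hypotheses.
The suite cross-checks $\hat\lambda$, its likelihood, and p-value against an
independent implementation, and calibrates the t-test's p-values (uniform
under the matching null).

# The synthetic generator: what it emulates, and what it does not

`simulate_plastome_set()` produces the study conditions the pipeline
assumes: an ultrametric pure-birth tree; a root genome with a gene skeleton
(600-bp genes alternating strands, 400-bp spacers, every fourth gene with an
intron); repeat families planted at conserved positions as **single gains on
the stem of the occupying clade** with no subsequent losses — the simplest
process producing nested occupancy categories (a loss process can be layered
on top, but is deliberately not the default); per-branch point mutations
(0.003 substitutions per site per unit branch length, giving ~1% tip-pair
divergence on a unit-depth tree); and Brownian traits with configurable
$\lambda$ and rate.

Defaults mirror the empirical study conditions: occupancy mixture
10% all / 20% majority / 45% minority / 25% unique (following the observed
10/19/42 multi-taxon cluster split with about a quarter of repeats
taxon-unique); family length bins 30–99 / 100–199 / ≥200 bp with count
weights 0.79 / 0.165 / 0.045, chosen so the three bins contribute roughly
57/30/13% of total repeat *length*; about one family per 2 kb of genome
(matching the empirical density of ~50 repeats per 123-kb plastome);
placement uniform (Poisson null) or Neyman–Scott clustered (4 parents,
400-bp normal offsets) for the overdispersed alternative. The default test
scale is 12 taxa × 20 kb so the full pipeline runs in tens of seconds; all
parameters, including a full 123-kb plastome scale, are exposed in
`simulation_config()`.

**Inversion scenarios** are constructive: on the ancestral sequence the
generator plants two *direct* repeat copies flanking the right endpoint (one
just inside, one just outside) and makes the bases entering the left
endpoint the reverse complement of the bases leaving the right endpoint
(10-bp microhomology), then applies the reversion. After the inversion the
two copies are inverted relative to each other at opposite ends of the
segment — exactly the arrangement the mechanistic model predicts — and the
truth table records the *canonical* (leftmost) endpoint representative, the
pair the refinement reports. Endpoints are placed in intergenic gaps clear
of planted repeats, so no feature straddles a boundary.

What the generator does **not** emulate: realistic nucleotide substitution
models (no transition/transversion bias, no rate heterogeneity), indels,
gene-content evolution, repeat turnover (births/deaths of family copies),
heteroplasmy, or the quadripartite structure (the clade analysed has lost
one IR copy). Passing the suite therefore demonstrates correctness of the
machinery under the stated generative assumptions, not performance on
assembly artefacts or deeply diverged genomes.

# Numerical choices and degenerate inputs

- Two-tailed p capped at 1; sample variance with $n-1$ (forced by the
  $\chi^2 = \mathrm{df}\times$ratio identity); mean window count of zero is
  an error, equal counts classify as Underdispersed (lower-tail extreme).
- Extension ties in repeat discovery break toward the longer alignment, then
  the lower start coordinate; cluster and group ids are assigned in
  deterministic (taxon, coordinate) order so runs are reproducible.
- Features straddling a reversion boundary are split at the boundary with a
  warning (none arise from the generator; the case is untestable against the
  source data because it never occurred there).
- `simulate_plastome_set()` is fully determined by its config (one seed);
  written run directories are byte-identical across replicate calls.
- Test problem sizes (20-kb genomes, 12 taxa, 100–1,000 replicate
  simulations, 200-tip trees) were chosen so the whole suite completes in a
  few minutes while keeping Monte-Carlo error well inside the asserted
  tolerances.

# Known limitations

- Nested or overlapping inversions are collapsed to the outermost candidate
  with a warning; rearrangement *distances* (sorting by reversals) are out
  of scope.
- The gap-free junction score assumes colinearity outside the inversion;
  plastomes with large indels near junctions would need the search radius
  widened or an affine-gap rescoring of the top candidates.
- Anchor uniqueness is assessed at the seed length (20-mers), which can
  split a long maximal match whose interior k-mers recur elsewhere; for
  breakpoint bracketing this is inconsequential.
- MCL clusters depend on the similarity-graph thresholds; with sparse,
  short representatives the graph — not the clustering — is the binding
  constraint.
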
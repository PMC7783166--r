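---
title: "Methods: read-through error mitigation, ASC nulls, and phylogenetic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-through error mitigation, ASC nulls, and phylogenetic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`readthru` quantifies two local defences against translational
read-through — preference for the least leaky primary stop codon (TAA)
and enrichment of in-frame additional stop codons (ASCs) in the 3′-UTR —
and relates them to effective population size and cellularity under
phylogenetic control. This vignette explains the statistical models, the
parameters that matter, the numerical choices, and what the synthetic
data generators do and do not emulate.

## Stop-context extraction

Every downstream statistic is computed on *stop contexts*: for each gene,
the primary stop codon, the 30 nt of coding sequence before it, and the
97 nt of 3′-UTR after it, with the stop occupying positions +1..+3 and
the first UTR base at +4 (so "+4G" reads as the base immediately after
the stop). A gene is retained only if

* its 3′ intergenic space is **strictly greater than** `min_intergenic`
  (default 100 bp) — the threshold is a strict inequality;
* its CDS length is a multiple of 3 and its terminal codon is TAA, TGA
  or TAG;
* it has exactly one in-frame stop after the initiator, located
  terminally — this reading of the single-stop rule excludes annotation
  artifacts with internal stops;
* the 130-nt window (30 + 3 + 97) lies fully on the contig and contains
  only A, C, G, T.

Genes failing several rules are counted once in the `FilterReport`,
under the first failing rule in the fixed order: length, terminal stop,
internal stop, intergenic distance, truncation, alphabet. The retained
*set* is order-independent; only the report's attribution depends on this
order, which is therefore documented and mirrored by the genome
generator's truth table.

Two points were genuinely open and are resolved as follows. The
intergenic distance is measured from the first base after the stop, in
the transcription direction, to the nearest *transcription start* of any
other annotated gene on either strand (both-strand is the conservative
reading), or to the contig end. And the 100-bp rule is applied to CDS
ends, not annotated UTR ends, since UTR annotation quality varies widely
across genomes. Where a gene has several transcripts the longest CDS is
used, ties broken by the lexicographically smallest transcript id, so
results are reproducible across annotation orderings.

HEGs and LEGs are the top and bottom abundance quartiles, each of size
`floor(n/4)`, with a deterministic tie-break (descending abundance, then
ascending gene id). Partitioning refuses fewer than 400 expressed genes,
the species-inclusion threshold of the analysis design.

## Stop usage and per-site enrichment

The standardized frequency difference for a stop codon is
SFD = (HEG frequency − LEG frequency) / LEG frequency; it is zero exactly
when the two frequencies agree, +Inf when a codon is absent from LEGs but
present in HEGs, and defined as 0 (with a message) when absent from both.

Per-site nucleotide enrichment compares, at each position around the
stop, the HEG count of each base with the expectation under the
genome-wide frequency at the same position. The test is a 1-df Pearson
chi-square on the 2-cell split (genes carrying the base vs not),
**without** Yates continuity correction — the plain Pearson form is what
1-df statistics of this analysis family report. A 2-cell-per-nucleotide
test (rather than one 4-cell test per site) was chosen because calls are
made per base ("enriched"/"depleted" for each nucleotide). Significance
is flagged at the raw `alpha` with no multiple-testing correction, by
design; the caller decides how to treat the grid. Upstream sites are
reported but flagged `context_only`: amino-acid-level selection on the
CDS confounds any nucleotide-level interpretation 5′ of the stop. When a
base has zero genome-wide frequency at a site but a nonzero HEG count,
the expected count is floored at 0.5 with a warning rather than
producing an infinite statistic.

## ASC enrichment and its two nulls

ASCs are in-frame stop triplets at UTR codon positions +1..+6 (position
*n* covers UTR nucleotides 3(n−1)+1..3n). Two observed statistics are
maintained: *any-ASC* counts (genes with a stop triplet at the position)
and *first-ASC* counts (genes whose first downstream in-frame stop is at
the position). The analytic null is explicitly a first-stop model, so it
is paired with first-ASC counts; the simulation null makes no such
commitment and is paired with any-ASC counts. Both statistics are always
computed so either pairing can be inspected.

**Geometric (first-ASC) null.** With `p` the pooled fraction of in-frame
stop triplets over the whole 97-nt window (32 triplets per gene, pooled
across genes — pooling is the resolution of an open question; per-gene
estimates would be extremely noisy at 32 triplets each), the expected
first-ASC frequency at position *n* is `p(1 − p)^(n−1)`. The infinite
sum is 1; truncation to +1..+6 under-counts by exactly `(1 − p)^6`,
which the tests assert.

**Dinucleotide-controlled null.** A first-order Markov chain is fitted
to the observed UTRs: the initial distribution is the empirical +4
marginal and the 16 transition probabilities are empirical conditional
frequencies. The first simulated base is conditioned on the +4 marginal
rather than on the stop's last base: codon +1 lies wholly inside the
UTR, so cross-boundary dinucleotides cannot affect ASC positions.
`n_sim` (default 10,000) UTRs of 97 nt are simulated and the expected
any-ASC frequency at each position is the simulant fraction carrying a
stop triplet there. Smoothing is applied **only to from-states never
observed in training** (they get a uniform row): this avoids
zero-probability deadlocks without distorting observed transition rows,
so a degenerate training set (e.g. all-A UTRs) reproduces itself
exactly. Comparison to the real genome uses expected counts = simulant
frequency × real gene count in a 1-df chi-square, not an empirical rank
p-value, matching the chi-square framing of the analysis. The seed is
mandatory and recorded; a fixed seed gives bit-identical expected
frequencies.

For validation, `markov_asc_null()` computes the same expectation in
closed form from known chain parameters (propagating the initial
distribution through the transition matrix), which the simulation must
approach at the binomial rate; the simulant dinucleotide table must also
converge on the training table (total-variation distance below 0.01 at
10,000 simulants).

**Genome calls and cross-genome tests.** PES = (Observed − Expected) /
Expected per position; a genome is called enriched if any position shows
a raw excess *and* a chi-square p-value below 0.05/6 (≈0.0083); the
genome's enrichment score is the mean PES over the six positions. The
per-genome chance probability of at least one significant position is
1 − (1 − 0.05/6)^6 ≈ 0.049, which feeds exact binomial tests on the
number of enriched genomes; Fisher's exact test (probability-mass rule
for the two-sided form) compares enrichment between genome groups. One
subtlety is worth recording: the 0.049 arithmetic counts each position
as firing at the full per-test level, while the raw-excess clause
restricts calls to the upper tail. In the Gaussian limit that would
halve the rate; at realistic per-position expected counts (a few tens of
genes), however, the right skew of the binomial places nearly all of the
two-sided chi-square mass in the excess tail, and the measured null fire
rate on 400-gene replicate genomes is compatible with 0.049. The
calibration is an empirical property of the test at its operating scale,
not an identity; at much larger gene counts the rate drifts toward half.

## Substitution profiles by outgroup parsimony

Three-taxon ortholog alignments (two sister ingroups, one outgroup) are
quality-filtered: every record needs an in-frame terminal stop with no
premature in-frame stop, all three stops must be the same codon in the
same alignment columns, and no gap may occur within ten codons of the
stop on either side (alignments not extending that far are rejected).
An optional `cds_len=` header tag pins each record's CDS length; without
it the primary stop is taken as the first in-frame stop of the ungapped
sequence, which is exact for sequences that satisfy the premature-stop
filter.

At each column the ancestral base of the ingroup pair is the outgroup
base when it matches at least one ingroup, otherwise the site is
unresolved and skipped. This rule is provably equivalent to exhaustive
minimum-change parsimony on the rooted triplet when ancestral calls are
only accepted if the minimising labelling is unique at both internal
nodes; the test suite enumerates all 64 columns against that oracle.
Columns where the outgroup matches one ingroup while the other differs
count one substitution (the parsimony minimum).

Substitutions are counted on **both** ingroup lineages and divided by
2 × the number of valid genes of the stop class resolved at that site, so
frequencies are per-lineage rates (the normalisation is per-site because
unresolved columns drop out of both numerator and denominator). Counting
one focal lineage instead would halve the numerator and denominator
alike; the rate interpretation, not the absolute scale, is what the
profile is for.

## Comparative analysis

TAA *usage* at a position is the TAA share among stop triplets there;
the TAA enrichment score compares primary usage with the unweighted mean
usage over +1..+6 (positions with no stop triplet at all are dropped
from the mean with a warning). TAA *disparity* is the HEG/LEG ratio of
primary TAA frequencies. Effective population size is π/(4µ).

PGLS is implemented from first principles because the λ-transformed
covariance and its profile likelihood are the analytical core of the
comparative stage: residual covariance σ²V(λ), with V the Brownian
path-length matrix and λ multiplying its off-diagonals. λ is estimated
by maximising the profile log-likelihood over a 0..1 grid (step 0.01)
followed by golden-section refinement to 1e−6; ML is the default
(REML is available). Coefficient tests use t on n − p − 1 df; r² is
computed on the V(λ)-whitened model against the whitened intercept-only
fit and adjusted with the standard small-sample correction, so it can be
negative when the model underperforms the null. Likelihood-ratio tests
against λ = 0 and λ = 1 use a 1-df chi-square (a boundary-conservative
convention). Fixing λ = 0 reproduces OLS to numerical precision, and
fits agree with `nlme::gls` + `ape::corPagel` (the independent oracle in
the tests) in coefficients and log-likelihood. Non-ultrametric trees are
accepted with a warning; N<sub>e</sub> enters the design matrix as given
(the trait table may carry `log_ne` if a log scale is wanted — the
generator provides both columns).

## What the generators emulate — and what they do not

`generate_genome()` emulates the statistical structure extraction
assumes: single-exon, one-gene-per-contig models with ATG-started,
internally stop-free CDSs; 97-nt UTRs from a configurable first-order
Markov chain (default: independence rows at the target GC, so each
position's stop-triplet probability is 3/64 at GC 0.5); log-normal(0, 1)
abundances (only ranks matter for quartiling); a logistic tilt of TAA
odds by `exp(link·z)` on standard-normal log-abundance; optional ASC
injection that overwrites the triplet at one position with a uniformly
chosen stop (overwriting post-hoc preserves the marginal Markov
structure elsewhere, and the truth table records it); and a rejection
plan that appends genes each carrying exactly one filter fault,
classified by the same precedence the extractor documents. It does not
emulate multi-exon structure, isoforms, gene-dense contigs, real codon
usage, or GC heterogeneity along the genome — so passing tests validate
the statistical machinery, not annotation robustness on messy real
genomes (multi-exon and multi-gene layouts are covered separately by
hand-built fixtures).

`generate_triplets()` evolves a stop-anchored root (10 stop-free coding
codons, the stop, 30 UTR nt) along three lineages under Jukes–Cantor
with per-site rate multipliers, gapless, with a zero-length internal
branch so outgroup parsimony is exact up to multiple hits. Jukes–Cantor
keeps the truth analytic — richer substitution models would add realism
without adding validation power for a parsimony counter. Quality
filtering itself slightly biases recovered upstream frequencies downward
(genes in which a mutation created a premature stop are excluded); at
the default divergences this bias is well inside the binomial
3-SD bands the tests use.

`generate_comparative()` draws a pure-birth tree (rescaled to unit
depth), Brownian log-N<sub>e</sub>, and a response
a + b·log N<sub>e</sub> + ε with ε ~ N(0, σ²V(λ_true)); cellularity is
an independent Bernoulli tip trait. It does not simulate correlated
predictors or measurement error in π and µ.

## Problem sizes and test design

The validation suites run at deliberately chosen scales: 1,000 null
replicate genomes of 400 genes (the species-inclusion threshold) for the
genome-call calibration; 5,000-gene genomes for ASC-excess recovery;
500 replicate trees of 50 tips for PGLS slope coverage and λ recovery;
10,000 simulants for the dinucleotide convergence check. Recovery
tolerances of 0.1 (PES) and 0.05 (TAA score) are of the same order as a
*single* genome's sampling SD at these sizes (delta-method: ≈0.12 and
≈0.05 respectively), so those checks compare the mean over a small
number of replicate genomes rather than one draw; the replicate counts
(12 and 4–6) were fixed from that calculation, not tuned.

## Known limitations

* Extraction trusts the annotation's CDS coordinates; no correction for
  mis-annotated stops beyond the filters.
* The dinucleotide null is first-order; higher-order composition (codon
  bias bleeding into the UTR near the stop) is not captured.
* The parsimony counter underestimates at high divergence (multiple
  hits); it is intended for closely related triplets.
* PGLS assumes a single λ for the residuals and no measurement error in
  the predictors; λ is constrained to [0, 1].
* The simulation null is single-threaded; results are fully determined
  by the recorded seed.
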
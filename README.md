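# readthru

Translation does not always stop where it should. When a ribosome reads
through the primary stop codon of an mRNA, it runs into the 3′-UTR and
produces a C-terminally extended, potentially toxic protein. Two local
mechanisms can mitigate this error: using the least leaky stop codon (TAA
rather than TGA or TAG) and keeping in-frame *additional stop codons*
(ASCs) in the 3′-UTR as fail-safe terminators. `readthru` is an R package
for quantifying both signals in eukaryotic genomes and for asking, with
phylogenetic control, whether they track effective population size
(selection efficiency) or cellularity.

The package covers the full analysis path:

- **Context extraction** — from a genome FASTA + GFF3 (and optionally a
  PaxDb-style protein abundance table), build per-gene stop contexts: the
  primary stop, the last 30 nt of CDS, and 97 nt of 3′-UTR, under strict
  quality filters (3′ intergenic space > 100 bp, CDS length a multiple of
  3, a single terminal in-frame stop, pure A/C/G/T windows).
- **Stop usage** — primary stop frequencies, the standardized frequency
  difference between highly and lowly expressed genes
  (SFD = (HEG − LEG)/LEG), and per-site nucleotide enrichment of HEGs
  against a genome-wide null (1-df chi-square per base and site).
- **ASC enrichment** — detection of in-frame UTR stops at codon positions
  +1..+6; two null models: an analytic geometric first-ASC null
  `p(1 − p)^(n−1)` with `p` the pooled in-frame UTR stop-triplet
  frequency, and a dinucleotide-controlled Monte-Carlo null (10,000
  simulated UTRs from a first-order Markov chain fitted to the real
  UTRs); positional enrichment scores PES = (O − E)/E; genome-level calls
  at the Bonferroni threshold 0.05/6 with the raw-excess requirement; and
  the exact binomial / Fisher machinery for cross-genome claims.
- **Substitution profiles** — outgroup parsimony on aligned three-taxon
  ortholog triplets, giving per-site substitution frequencies from ten
  codons upstream to ten "codons" downstream of the stop.
- **Comparative analysis** — TAA enrichment scores, TAA disparity,
  N<sub>e</sub> = π/(4µ), and phylogenetic generalised least squares with
  Pagel's λ estimated by maximum likelihood (implemented from first
  principles; validated against `nlme::gls` + `ape::corPagel`).
- **Synthetic data** — generators for genomes, ortholog triplets, and
  trait/tree sets with recorded ground truth, so every stage is testable
  without downloads.

## Worked example

A synthetic genome with an expression-linked TAA preference, analysed end
to end:

```r
library(readthru)

g <- generate_genome(2000, expression_link = 0.4, seed = 7)
res <- extract_stop_contexts(g$genome, g$expression)
parts <- partition_heg_leg(res$contexts)

sfd(parts$heg, parts$leg)$sfd
#>    TAA    TGA    TAG
#>  0.607 -0.345 -0.232
taa_disparity(parts$heg, parts$leg)
#> [1] 1.607
```

TAA is used 60.7% more often in the top expression quartile than in the
bottom one — the generator's logistic link recovered as an SFD — while
TGA and TAG are correspondingly depleted. ASC enrichment against the
analytic first-ASC null:

```r
ph <- estimate_p_hat(res$contexts)     # 0.046: in-frame UTR stop-triplet rate
enr <- positional_enrichment(asc_profile(res$contexts), ac_null(ph))
genome_call(enr)[c("enriched", "score")]
#> $enriched
#> [1] FALSE
#> $score
#> [1] 0.028
```

No position reaches the 0.05/6 threshold with a raw excess, so this
genome (no injected ASC excess) is correctly not called enriched. A
phylogenetically controlled regression on simulated traits:

```r
cmp <- generate_comparative(50, b = 1, lambda_true = 1, sigma2 = 0.5, seed = 7)
pgls_fit(taa_enrichment ~ log_ne, cmp$traits, cmp$tree)
#> PGLS fit (Pagel's lambda)
#> lambda = 1  logLik = -11.7408
#>             Estimate Std. Error t value  Pr(>|t|)
#> (Intercept) -1.24560    1.63991 -0.7596    0.4512
#> log_ne       1.10246    0.11462  9.6180 8.924e-13 ***
#> r^2 = 0.6584  adjusted r^2 = 0.6513
```

The true slope (1) lies inside the confidence interval and the residual
phylogenetic signal (λ = 1) is recovered at the boundary.

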
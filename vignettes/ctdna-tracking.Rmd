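---
title: "Tracking somatic mutations in plasma: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking somatic mutations in plasma: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnatrack)
```

# The problem

Plasma cell-free DNA (cfDNA) of a cancer patient is a mixture: most
fragments come from normal hematopoietic turnover, a minority — the
circulating tumor DNA (ctDNA) — from tumor cells. Somatic point mutations
observed in plasma can therefore be used to monitor a tumor through
chemotherapy without repeated biopsies, but two obstacles dominate: the
tumor-derived signal is diluted (variant allele fractions of a few percent),
and at such fractions sequencing error, germline variation and alignment
artifacts produce candidate calls that outnumber true somatic mutations.
`ctdnatrack` implements a complete, testable treatment of this problem:
physical enrichment of tumor fragments by size, a five-condition filter
cascade over paired tumor/normal pileup evidence, trinucleotide
mutation-spectrum and signature analysis, and the longitudinal statistics
that connect mutation dynamics to treatment response and survival. Because
patient-level plasma sequencing data of this kind are not publicly
deposited, the package carries a synthetic-data generator as a first-class,
tested module: every downstream method can be exercised against known
truth.

# Fragment-size selection

Nucleosome protection leaves background cfDNA with a dominant fragment
length near 167 bp, while ctDNA fragments run shorter, peaking near 133 bp;
the proportion of sub-150 bp fragments correlates with tumor content.
`select_short_fragments()` retains fragments with |insert size| strictly
below a threshold (default 150 bp), reconstructing the tumor-enriched
("remoulded") read set.

The generator's fragment model (`frag_model()`) is a two-component
truncated Normal: means 167/133 bp, shared SD 15 bp, truncated at 50 bp.
Only the two peak positions are externally given; the Normal shape and the
15-bp spread are this package's modelling choice — the simplest
two-component model that reproduces the short-fragment enrichment (with
these defaults, a 20% tumor fraction yields roughly 60% tumor-origin reads
after selection). Reads are modelled at fragment level (one record per
fragment, the insert size *is* the fragment length) because every
downstream computation consumes only insert sizes and allele observations;
paired 100-bp mates would add bookkeeping without changing any statistic.
Records with insert size 0 or missing are dropped and counted separately:
they carry no usable fragment length.

# The filter cascade

Candidates (from external callers in a real deployment; from the naive
pileup scanner `make_candidates()` on synthetic data) are judged by five
conditions evaluated jointly — no short-circuiting — so each verdict lists
every failed condition and per-condition audit counts are meaningful.

**Condition 1 — support, contamination, coverage, databases.** The tumor
must show ≥ 4 mutant reads with ≥ 1 on each strand; the matched normal may
show ≤ 2 mutant reads with normal VAF < 0.01 and the site must not be a
known SNP; both samples need ≥ 40-fold coverage; and a site is removed if
it has ≥ 1 supporting normal read and population allele frequency ≥ 0.001,
or ≥ 2 supporting normal reads without known somatic-hotspot membership.
The hotspot clause acts as a rescue: recurrent somatic sites tolerate two
stray normal reads, unknown sites do not. VAF at zero depth is defined as
0, so a depth-0 site fails coverage rather than raising a division error.

**Condition 2 — local context (11-bp window).** The mutant count must be an
outlier against the mismatch counts at the 10 other window positions
(greater than mean + k·SD, k = 3 by default); fewer than 3 small
insertions/deletions may fall within 10 bp; and mismatches must not be
enriched around the site. Enrichment is operationalised two ways: no
flanking position may exceed the site's own mutant count, and
mutant-supporting reads must be essentially free of additional mismatches
inside the window. For the read-level rule we use a proportion test rather
than a strict zero: the variant fails when at least 2 supporting reads
carry extra window mismatches *and* their fraction exceeds 20%. A strict
zero is the natural reading of "no other mismatches on mutant reads", but
it conflates two generating processes: a misalignment artifact puts the
extra mismatches on essentially *all* supporting reads (they share the
mispriming source), whereas independent sequencing errors at rate
$e = 10^{-3}$ hit a supporting read within the window with probability
$\approx 10e = 1\%$ — so a high-VAF variant with dozens of supporting reads
would be vetoed by a single expected stray error under the strict rule,
while the 20% fraction cleanly separates the two regimes (observed
fractions ≈ 1% for true variants, ≈ 100% for shared-source artifacts). A
window truncated below 10 flanking positions (contig edge, missing pileup)
marks the variant *unevaluable* — excluded from the pass set and counted
separately, never silently passed.

**Condition 3 — detection power.** The probability that a true variant at
an assumed VAF $v$ would have been detected at the observed depth $d$:

$$\mathrm{power}(d, v) = \sum_{a \ge 4} \binom{d}{a} v^a (1-v)^{d-a}
  \; P\!\left(1 \le F \le a-1 \,\middle|\, F \sim \mathrm{Bin}(a, \tfrac12)\right),$$

i.e. the binomial probability of reaching the condition-1 support rule
(≥ 4 mutant reads, both strands) with strands equiprobable. Variants with
power > 0.80 are kept; the criterion removes sites whose depth could not
have revealed the mutation anyway, so an absence of signal there is
uninformative. The assumed VAF defaults to max(observed tumor VAF, 0.01),
the 1% floor matching the working range of plasma variant detection. The
threshold is read on the probability scale (0.80); power is exactly
monotone in depth and in $v$, and the implementation agrees with exhaustive
enumeration over all (mutant count, strand split) outcomes to 10⁻¹² for
every depth ≤ 60.

**Condition 4 — posterior probability.** A two-hypothesis Bayes rule
comparing the observed mutant count $a$ at depth $d$ under a somatic
hypothesis ($\mathrm{Bin}(d, \max(\hat v, e))$, $\hat v$ the observed VAF)
against an artifact hypothesis ($\mathrm{Bin}(d, e)$) at error rate $e$:

$$P(\mathrm{somatic} \mid a, d) =
  \frac{\pi L_1}{\pi L_1 + (1 - \pi) L_0}, \qquad
  \pi(r) = \frac{r + c}{r + c + 1/\pi_0 - 1},$$

with the prior odds scaled by how often the site (or its gene) recurs in an
external somatic catalog ($r$ the recurrence count, $c = 1$ the
pseudocount, $\pi_0 = 0.5$ the baseline prior, so $\pi(0) = \pi_0$).
Variants with posterior > 0.8 are kept. The external criterion this
implements is stated only as a recurrence-database-informed posterior; the
two-hypothesis construction with a recurrence-weighted prior is this
package's concrete interpretation, chosen because it is the minimal Bayes
rule with the two required monotonicities (in recurrence, and in mutant
count above the error rate). Both positional and gene-level recurrence keys
are supported since the original granularity is unspecified. Flooring the
somatic likelihood at the error rate makes the two hypotheses coincide at
zero evidence, so an unsupported site never scores above its prior.

Thresholds are strict (`>`), so setting both to 0 reduces the cascade
exactly to conditions 1–2. Raising either threshold can only shrink the
pass set.

# Mutation spectra and signatures

Passed SNVs are classified into the 6 pyrimidine-centred substitution
classes and the 96 trinucleotide channels (`A[C>A]A` … `T[T>G]T`,
substitution-major, context-alphabetical); purine-reference substitutions
are reverse-complemented, making the classification strand-symmetric and a
bijection over the 96 canonical inputs. Variants at contig edges without a
full 3-mer context go to an explicit uncontexted bucket, so catalog totals
are always conserved.

Signature decomposition is non-negative least squares
(`pracma::lsqnonneg`, Lawson–Hanson): weights minimise
$\lVert S w - y \rVert_2$ subject to $w \ge 0$ over a 96 × K signature
matrix. Fitting is on raw counts by default (weights are then attributed
mutation counts); a proportions mode exists. The fit is validated two ways
in the test suite: parameter recovery on catalogs sampled from known
mixtures (mean absolute weight-fraction error ≤ 0.05 at n = 10,000 over 20
seeds) and optimality against a 0.01-step simplex grid search for K ≤ 4.

Etiology labelling assigns "smoking" or "platinum" when the summed weight
fraction of the corresponding signature set (defaults {4, 16, 29} and {3}
in a 30-column catalog) reaches a dominance threshold. "Characterised by" a
signature family has no quantitative definition in the source convention;
we use 0.25 — above one uniformly-spread signature's share by an order of
magnitude, below a strict majority — and expose it as a parameter. The
bundled 30-column catalog (`synthetic_signature_catalog()`) is *synthetic*:
real curated catalogs are redistributed under their own terms, so the
package generates a deterministic stand-in with the structural features the
methods need (sparse profiles; a C>T-at-NpCpG clock-like column 1, a flat
column 3, C>A/T>C-heavy columns 4, 16, 29). Any genuine 96 × K matrix can
be supplied in its place.

# Longitudinal statistics

Per-sample burden records (total = nonsilent + silent + noncoding, the
invariant is enforced) feed a pre- vs post-treatment two-sample t-test plus
a per-patient paired view (baseline vs mean post); patients without a
baseline are excluded from the paired view only, with a message. VAF
comparisons per mutation, gene or pathway use the Mann–Whitney U test
(exact for tie-free samples of ≤ 20 per group, normal approximation with
tie correction otherwise), Student's t, or one-way ANOVA for 3+ groups;
per-key runs report Benjamini–Hochberg adjusted p-values alongside raw
ones (raw values remain the primary, convention-matching output).
Contingency analyses use Fisher's exact test and the
Cochran–Mantel–Haenszel test without continuity correction (stated in the
result object). Survival uses Kaplan–Meier product-limit curves and the
log-rank test (`survival::survfit`/`survdiff`); the suite checks the
statistic against a direct observed-minus-expected accumulation to 10⁻¹⁰.
All comparisons are two-sided by default. An empty group anywhere yields an
explicit "not-evaluable" result, never a fabricated p-value.

Plasma–tissue concordance reports the overlap together with *three*
labelled fraction conventions (union-based, per-plasma, per-tissue),
because published overlap percentages of this kind are ambiguous about the
denominator; the union-based fraction is symmetric under set exchange.
Actionability joins match (gene, protein change) exactly with an optional
gene-level fallback that can only add matches, and group patients by
pre-only / pre-and-post / post-only target availability.

# The synthetic cohort

`make_cohort()` emulates the study design the longitudinal statistics
expect — roughly 30 patients with a pre-treatment baseline and ~2
on-treatment samples each — with known generative parameters. Baseline
burden is Poisson with mean 16 (so the nonsilent fraction of ≈ 0.41 gives
a nonsilent median near 7, consistent with a cohort detecting 1–75
mutations per sample); each mutation survives a cycle with probability
`decay` (thinning), making the expected per-cycle burden ratio exactly the
decay parameter — this is what the generator's Monte-Carlo tests pin down.
Sensitive patients (PR/SDa) default to decay 0.5, insensitive (SD/SDb/PD)
to 0.85; the SDa/SDb sub-split of stable disease has no published
definition and is taken as given in the metadata. Smoker fraction 0.6 and
a 53/41/6 regimen mix follow the cohort composition the design emulates;
survival is exponential (OS means 24/12 months by sensitivity, PFS 8/4)
with administrative censoring at 36/18 months. Effect classes are drawn at
the 0.409/0.168/0.423 nonsilent/silent/noncoding mix of a plasma panel
call set. No cohort-level generative quantities are published for data of
this kind, so these defaults are explicitly arbitrary, documented, and
configurable — they were chosen once, from the design description, and are
not tuned against any test outcome.

What the generator does *not* emulate: context-dependent sequencing error,
indel and structural-variant truth (indels appear only as window-noise
counts), copy-number change, clonal structure, or inter-patient burden
heterogeneity beyond Poisson. Passing tests therefore demonstrate that the
algorithms are correct under their stated models, not that real plasma data
meet those models.

# Numerical and design notes

- Truth variants are placed with a minimum spacing of 25 bp so no variant
  sits inside another's 11-bp window; without this, a germline
  heterozygote next to a somatic site would legitimately trip the
  mismatch-enrichment rule and recall measurements would entangle the two
  sites.
- Every generator is a pure function of its seed and parameters, and
  restores the caller's RNG stream; pipeline stage seeds are derived as
  fixed offsets from the master seed, and identical configurations produce
  byte-identical outputs.
- The outlier rule uses the sample SD of the 10 flanking counts; for a
  constant flank vector the SD is 0 and the rule degenerates to "site
  count strictly above the flank level", which is the intended behaviour
  for the equal-counts tie case.
- Candidate merging across callers, when multiple call sets are supplied,
  is by union on (contig, position, alt) before filtering.
- Both calling paths — on all reads or on the size-selected subset — are
  supported (`select_fragments` in the pipeline configuration), since size
  selection before calling is a documented option rather than a certainty.
- Test problem sizes (3 kb reference, ~9,000 fragments, depth ≈ 400; 1,000
  replicates for test-size simulations) were chosen as the smallest scales
  at which the checked properties are statistically identifiable; they are
  the package's own reproducibility settings.

# Known limitations

The candidate generator is deliberately naive (no base qualities, no
realignment); real deployments should feed caller output into the evidence
assembly instead. The posterior is a pragmatic interpretation of an
under-specified criterion and should be read as a calibrated score, not a
literal probability. Multivariable survival modelling is out of scope —
per-factor log-rank comparisons replace it. The synthetic signature catalog
supports method validation, not biological interpretation of real samples.
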
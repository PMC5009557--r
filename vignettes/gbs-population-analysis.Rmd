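---
title: "Models and methods behind gbspop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gbspop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gbspop` analyses genotype-by-sequencing (GBS) experiments on plant
breeding populations: lane demultiplexing, population VCF construction
and filtering, diversity statistics, segregation-based quality control and
HMM imputation. This vignette explains the models, the tunable parameters
and the design choices; it states no empirical result beyond what the
package's tests and acceptance script themselves compute.

## The data model

The central container is a `population_vcf`: an ordered sample list plus
variant records sorted by (chromosome, 1-based position). Genotypes are
unphased allele-index pairs stored in two sites-by-samples integer
matrices, with genotype quality (GQ) and depth (DP) carried alongside.
Only GT, GQ and DP are retained from the FORMAT column: they are the only
fields the downstream statistics and filters consume, and keeping the
model this small makes merging and masking cheap. Per-site INFO strings
are passed through opaquely on read/write (merging drops them, with a
message). Missing calls carry no allele indices and, once a call is
masked by a quality filter, no GQ/DP either.

Merging per-sample files keys sites on (chromosome, position, reference
allele): genotype callers run per sample frequently disagree on the
alternate-allele list, so alternate lists are unioned and allele indices
remapped, while a disagreement on the *reference* allele is treated as an
error. A sample with no record at a union site gets a missing call, which
is the correct semantics for merging per-sample genotyping output.

## Filtering

Genotype-call filters (minimum GQ, minimum DP) mask individual calls and
never change the matrix shape. Site filters are set intersections —
individuals genotyped, MAF bounds, region keep/drop lists,
biallelic-SNP-only, observed-heterozygosity bounds, monomorphic-alternate
removal, GC-content bounds — and therefore commute; the single exception
is the inter-marker distance filter, a greedy left-to-right scan keeping
the first site and then the next site at least d bp downstream, which is
order-defined by construction and applied last. Re-applying it to its own
output changes nothing, so filtering stays idempotent.

Choices where the toolkit had latitude:

* **MAF** is computed over non-missing called alleles; a site with no
  called genotype fails any active MAF bound. For multiallelic sites the
  MAF is the frequency of the second-most-frequent allele.
* **Region lists** are read as BED-like 3-column text (0-based,
  half-open) and converted once to 1-based inclusive coordinates; the
  conversion is covered by an explicit test.
* **GC windows** are centred on the site with total width `gc_window`
  (default 100 bp, site base included), truncated at chromosome ends.
  The window size is configurable because "the region surrounding a SNP"
  depends on the downstream genotyping platform.
* The distance filter keeps the *first* of two close markers rather than
  the higher-quality one: it keeps the scan one-pass and deterministic.
* A call lacking GQ (or DP) fails any strictly positive threshold on that
  field — the conservative reading when a quality filter is requested but
  the producer did not emit the field.

## Population statistics

Per site: MAF; observed heterozygosity `Ho` (fraction of called genotypes
with two distinct allele indices — this covers multiallelic
heterozygotes); expected heterozygosity `He = 1 - sum p_i^2` (`2pq` for
biallelic sites); Hardy-Weinberg deviation as a chi-square goodness of
fit of the three genotype counts against `p^2 / 2pq / q^2` with 1 degree
of freedom and no continuity correction (the era-standard test, and the
one an independent oracle can verify digit-for-digit; an exact test is
future work); and `Fis = 1 - Ho/He`. These implementations are the single
source of truth: the site filters and the segregation QC call exactly the
same functions, so a threshold applied in one module means the same thing
in another.

With a subpopulation map the same statistics are computed per group, plus
a Nei-style differentiation index `Fst = (Ht - mean(Hs)) / Ht`, where `Ht`
is the expected heterozygosity of the pooled grouped samples. No
sample-size correction is applied (Weir–Cockerham is out of scope and
would invite false precision at GBS call rates); `Fst` is undefined when
`Ht = 0` or when a group has no called genotype at the site.

Pairwise comparison between two files (or a file and itself) restricts to
shared site keys and counts, per sample pair, co-called differing
genotypes, co-called sites, and homozygous differences — both calls
homozygous for different alleles. The last quantity drives the
family-integrity screen: an offspring homozygous for an allele its parent
does not carry (given a homozygous parent call) is impossible under
Mendelian inheritance, so in a true offspring the rate only reflects
genotyping error, while an unrelated sample shows a rate an order of
magnitude larger. Missing calls never count as differences.

## Segregation QC for F1 families

Classification uses the population's observed `Ho`/MAF rather than the
parental genotypes (parents may be uncalled or miscalled):
`Ho < 0.2` → C1 (AAxAA), `Ho > 0.8` → C4 (AAxaa), otherwise C2 (AAxAa)
if `MAF <= 0.37` and C3 (AaxAa) if `MAF > 0.37`. The thresholds
partition the whole `(Ho, MAF)` plane — a property test sweeps a grid to
confirm no gaps or overlaps. Classification statistics include the
parents by default (configurable): the parents are two genotyped samples
like any other, and at family sizes of 100+ their influence on `Ho`/MAF
is negligible while excluding them would silently change the denominator
of the individuals-genotyped filter.

Error rules per category: C1 — any call carrying a minor allele
(heterozygotes included); C2 — homozygotes for the minor allele, plus
parental deviations from the expected {homozygous-major, heterozygous}
pair, counted only when both parents are called (with a single called
parent the expected pair is ambiguous); C3 — each called
non-heterozygous parent; C4 — each called heterozygous parent and each
homozygous sibling. When parents disagree with the category implied by
the population, deviations are counted against the category's expected
parental pair — an interpretation, flagged as such.

The quality sweep re-applies the site filters (minimum individuals,
repeat regions, monomorphic-alternate removal) *after* masking calls at
each threshold, then reclassifies and recounts — filtering after
thresholding, which is the order that mirrors how such datasets are
prepared.

## MAGIC heterozygosity and the halving law

Under single-seed descent a heterozygous site stays heterozygous in the
offspring with probability 1/2, so the per-site heterozygous fraction
decays as `H0 * 2^-g`. For an 8-founder intercross with initial per-site
heterozygosity in the 25–50% range, four selfing generations leave
1.5625–3.125%; heterozygous calls far in excess of that band are almost
certainly errors. `magic_het_assessment` reports calls vs heterozygous
calls, SNPs vs SNPs with `Ho > 0.05`, and the analytic band; the band is
computed exactly, not from the rounded 1.5–3% presentation.

Two subtleties are deliberate:

* The law check in the test-suite uses `simulate_selfing_decay`, a cohort
  of unlinked sites, because binomial standard errors — the yardstick the
  check uses — require independent sites. The full MAGIC simulator has
  linked sites (founder blocks), which inflates the variance of the
  realized fraction; its output is instead checked against the analytic
  band widened by the empirical between-line standard error.
* In the MAGIC generator the number of founders carrying the alternate
  allele is uniform on 1..7 per site. The expected probability that the
  two haplotypes of an 8-way intercross individual differ is then ~0.43.
  Note the without-replacement effect: two *distinct* founders are more
  likely to differ than `2pq` suggests, so founder configurations
  concentrated near 4/8 would push initial heterozygosity above 0.5.

## The haplotype-cluster HMM

The imputation model is the haploid variant of the classical
haplotype-cluster HMM for inbred lines. Lines are first *haploidized*:
homozygous calls collapse to one allele, heterozygous calls become
missing (their count is reported — at F5 levels this loses ~2–3% of
calls, and the model could not represent them anyway). Latent states are
K ancestral haplotype clusters; cluster c emits the alternate allele at
marker m with probability `theta(c, m)`; across interval i the chain
stays put with probability `exp(-rho_i)` and otherwise switches to
cluster c' with probability `alpha_i(c')` (column 1 of `alpha` is the
initial distribution). Missing observations emit 1.

Estimation is EM on scaled forward–backward recursions, vectorised over
samples (the per-marker scaling keeps the recursion stable for long maps;
an independent exhaustive-enumeration oracle checks the posteriors to
1e-10 on instances with up to 4 markers and 3 clusters). All M-steps are
exact *constrained* maximisers — `theta` clamped to
`[theta_floor, 1 - theta_floor]`, `exp(-rho_i)` the expected
stay-probability, `alpha_i` the normalised expected switch-in counts — so
the log-likelihood is non-decreasing by the EM argument even at the
constraint boundary, and the test-suite asserts it on every fit.

Defaults and why:

* `k = 8` clusters — matches the founder count of the motivating
  multiparent design and is a common default for breeding populations;
* `theta_floor = 1e-3` — keeps emissions away from 0/1 so a single
  miscall cannot acquire infinite evidence;
* `tol = 1e-4` relative log-likelihood, `max_iter = 50`;
* `rho_init = 0.05`; with strong linkage a smaller initial value helps the
  chain lock onto long blocks before switch rates are re-estimated;
* `n_starts` (default 1) refits from multiple seeded initialisations and
  keeps the best final log-likelihood — useful for small K where
  segmental label-swapping optima exist and are clearly distinguishable
  by likelihood;
* initial `theta` is seeded from randomly chosen sample haplotypes shrunk
  towards the population frequency; the seed is a required argument.
* clusters *can* optionally be compared against founder lines downstream,
  but founder-seeded initialisation is not claimed or enabled by default.

Imputation computes, per sample and marker, the posterior
alternate-allele probability `sum_c gamma(c) * theta(c, m)`; each
originally missing cell receives the homozygous genotype of the majority
allele (ties to reference at exactly 0.5), an imputation flag (`IM`
FORMAT subfield on write) and a phred-scaled quality derived from the
posterior. Observed calls are never modified; heterozygous source calls
are kept unless `replace_het = TRUE`.

## The simulators and what they do (not) emulate

`simulate_f1` draws per-site categories from a configurable mix (default
10/35/35/20% for C1–C4, typical of an outbred F1), parental genotypes per
category, offspring by Mendelian sampling, then observation noise:
per-call flips between homozygous and heterozygous (the dominant
discrepancy mode between genotyping pipelines), per-call missingness,
and GQ drawn from a high-mean normal for correct calls (mean 60, sd 15)
vs a low-mean normal for erroneous calls (mean 25, sd 10), so quality
sweeps behave like real data. Defaults: 137 offspring, 5000 sites,
1% error, 10% missing. Flips are book-kept exactly, which the
exact-recovery tests rely on; a separate helper injects
category-rule-violating genotypes with exact counts, because generic
hom/het flips in C2/C3 are not always rule violations.

`simulate_magic` builds each line through its own randomised funnel
(pairwise crosses, crosses of the F1s, an 8-way intercross, then g
selfing generations of single-seed descent), with meioses as Markov
switching between parental haplotypes at `recombination_rate` per
interval (default 0.001 — founder blocks of roughly a hundred markers, a
dense single-chromosome GBS map). Founder mosaics are retained as
imputation ground truth. Defaults: 8 founders, 200 lines, 2000 sites,
g = 4, 0.5% error, 20% missing.

`simulate_lane` writes barcoded reads with the adapter tag inserted at a
known offset in a configurable fraction of reads (default 0.35);
background sequence is rejection-screened so the tag never occurs by
chance and recorded trim points stay exact.

None of the generators emulate base-level sequencing error profiles,
restriction-site digestion, reference-alignment artefacts or allele-drop
biases; passing tests therefore demonstrate correctness of the
*statistical machinery* on data with known truth, not robustness to
every artefact of real GBS libraries.

## Problem sizes and numerical choices

The test-suite exercises the framework at: 300 offspring x 10,000 sites
(zero-error and exact-recovery checks), the MAGIC defaults
(200 x 2000, 20% of calls masked) for imputation recovery, 200 x 2000
unlinked cells for the selfing law, 4000-read lanes for demultiplexing,
and exhaustive HMM instances up to 4 markers x 3 clusters. These sizes
were chosen to match the scale of the motivating experiments while
remaining comfortable on a single CPU.

Degenerate inputs are defined throughout: zero-called sites give `NA`
statistics and fail MAF bounds; monomorphic sites give HWE (0, 1);
all-missing matrices are rejected by the HMM; empty populations write
valid header-only VCFs; empty lanes produce zero-count reports.

## Known limitations

* Diploid/heterozygous-aware imputation, phasing and reference-panel
  imputation are out of scope; the haploid model targets inbred lines.
* BCF, tabix indexing and annotation computation are not provided.
* The exact Hardy-Weinberg test and Weir–Cockerham F-statistics are
  documented alternatives, not implemented.
* `pairwise_differences` is quadratic in samples; it is intended for
  cohort-scale (hundreds of samples) duplicate screening, not biobanks.
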
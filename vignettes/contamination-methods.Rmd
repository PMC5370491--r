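---
title: "Detecting and correcting cross-contamination in multi-sample sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting cross-contamination in multi-sample sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcontam)
```

## The problem

Projects that process many samples — often many species — through one
laboratory and shared sequencing runs are exposed to cross-contamination:
reads that belong to one sample ending up attributed to another, whether
through physical transfer of material during library construction or
through index mis-assignment on the flowcell. Between species the
contaminant is usually detectable by sequence divergence; between
individuals of the *same* species it is nearly invisible, yet it is the
more damaging case for population genetics, because leaked alleles
masquerade as heterozygosity.

seqcontam implements both sides of the problem: a barcode-based screen
for between-species contamination, a read-count statistic for
within-species allele leakage, a genotype caller that models leakage
explicitly, downstream population-genomic summaries, and permutation
tests that relate the inferred contamination pattern to laboratory
metadata (who handled which sample, when it was shipped, and on which
flowcell and lane it was sequenced). A set of seeded simulators produces
every input format with known ground truth, so the whole chain is
testable without any external data.

## Between-species screen

Reads are mapped, ungapped and on both strands, against an aligned panel
of equal-length cox1 barcode sequences carrying a species label and a
component tag (`target` for species handled by the project, `companion`
for never-handled relatives serving as negative controls, `model` for
common laboratory organisms). The mismatch tolerance follows read
length: one mismatch up to 50 bp, two above. Ties between references are
broken uniformly at random with a user-seeded generator, and the tie set
is reported, so runs are reproducible even where a production mapper
would be stochastic.

Hits are tallied per species and normalised to **prevalence per million
reads**. A species pair is *diagnostic* only when the minimum p-distance
between any two of their panel sequences exceeds a threshold (default
5%; 10% is a robustness variant): below that, mapping cannot separate
them and cross-hits attest nothing. Per sample, hits split into
*expected* (to the sample's own species), *unexpected* (to species
diagnostic against the expected one), and non-diagnostic. A directed
contamination matrix **M** sets `m[i, j] = 1` when reads from samples of
species *j* hit references of species *i* at least `min_reads` times
(default 1 — a single read attests an event; 10 is the conservative
variant), with non-diagnostic pairs left missing. The matrix's overall
proportion of ones among non-missing cells, *p*, is the base rate used
by the permutation nulls.

Design notes: the mapper is deliberately ungapped (the references are
barcode-length and the tolerance is a mismatch count, not an alignment
score); ambiguous bases count as mismatches; reads under 30 bp are
skipped as uninformative. Gapped or spliced contaminant reads are
therefore invisible to this screen — a known limitation.

## Within-species leakage: homo-quartets, λ and λ′

The atomic observation is the **quartet**: the A/C/G/T read counts of
one individual at one position. A **homo-quartet** is a quartet with
exactly two observed states, a major count strictly above 40 and a minor
count of exactly one — the signature of a homozygote carrying a single
erroneous (or leaked) read. "Above 40" is read strictly, and the
remaining two states must be exactly zero; both choices are literal
readings of the definition and are pinned by unit tests.

Positions are classified from read counts pooled over all genotyped
individuals, focal individual included (the alternative — excluding the
focal individual — is not what the definition says, and including it
keeps the classification independent of which record is being scored):

* **monoallelic** — the major state exceeds 95% of the pooled total;
* **biallelic** — otherwise, the second-ranked state exceeds 10 *n*
  reads for *n* individuals (ties for second rank broken by the fixed
  base order A < C < G < T);
* anything else is disregarded.

Homo-quartets at monoallelic positions estimate the contamination-free
**error matrix** `P(a, b)`: the row-normalised counts of minor state
*b* given major state *a*. At biallelic positions, let *z* be the
segregating allele other than the record's major state; records whose
major state is neither of the two segregating alleles are excluded
(their *z* would be ambiguous) and counted. The observed fraction
`q_obs` of records whose minor state equals *z* is compared with its
error-only expectation `q_exp`, the mean of `P(a, z)` over records, and

λ = (q_obs − q_exp) / q_exp

is the **allele-leakage index**: zero in the absence of contamination,
positive when minor states track the alleles actually segregating in the
sample — the footprint of reads leaking between individuals. Because the
statistic needs a stable denominator, per-species reports require at
least 50 biallelic homo-quartets by default before λ is quoted.

**λ′** restricts the same contrast to leakage *between* groups of
samples (typically shipment batches): only homo-quartets at positions
biallelic in the whole sample but monoallelic *within the focal
individual's group* are scored, so any allele matching the minor state
must have come from outside the group. The within-group monoallelic test
reuses the 95% rule on group-restricted totals (the source definition
names no separate threshold), and numerators and denominators are pooled
across species — each record scored against its own species' **P** —
because per-species counts are too small to be stable.

The error matrix also yields a strand-ambiguous error-class summary.
Without strand information, X→Y cannot be told from its complement, so
the twelve error types pool into six classes. Under errors uniform over
the three alternative bases the expected transition share is 1/3
*whatever* the base composition (every base has exactly one transition
partner), so the composition-corrected transition:transversion ratio
equals the raw count ratio and equals 0.5 under random error. The share
of the A→C/T→G class among transversions does depend on composition; it
is reported next to its compositional expectation (1/3 at equal
composition), and we do not attempt to reproduce any other scale for
this quantity.

## Contamination-aware genotyping

The caller models a quartet as a multinomial draw whose per-read state
probabilities depend on the diploid genotype {y, z}, class-specific
error rates, and a contamination probability γ. A read is, with
probability 1 − γ, an ordinary read: one of the two gametic alleles
passed through the error channel, where the genuine state is called with
probability 1 − (ε_ts + 2 ε_tv), the transition partner with ε_ts and
each transversion partner with ε_tv. With probability γ it is a
**leaked read**: its true state is drawn from f′, the read-frequency
vector at the position *excluding the focal individual*, and then passed
through the same error channel — so even contaminant reads can carry
sequencing errors. At γ = 0 the model reduces exactly (bit-for-bit, and
regression-tested as such) to the contamination-free emission.

The likelihood of a quartet sums the ten diploid genotypes weighted by
Hardy–Weinberg priors from the position's pooled read-frequency estimate
of the allele frequencies. The heterozygote prior carries the factor
2 f_a f_b; the factor is exposed as a switch (`het_factor2`) because the
single-ε formulation of this likelihood is sometimes printed without it,
but with the factor the prior is a proper distribution and the
enumeration tests (likelihood summing to one over all quartets of fixed
size) only pass with it included — which is why it is the default.

Parameters and defaults:

* `eps_ts`, `eps_tv` — per-read error rates by substitution class,
  estimated by bounded maximum likelihood (box [0, 0.2], three fixed
  starts, log-likelihood tolerance 1e-8, deterministic); degenerate
  error-free data drive the estimates to the zero bound, which is
  flagged.
* `gamma` — profiled over the grid {0, 0.05, 0.1, 0.2} by default;
  `select_gamma` refits the error rates at every grid value (each refit
  warm-started from the previous grid point) and returns the maximally
  likely value γ*, breaking exact ties toward the smaller γ.
* `posterior_threshold` — a genotype is called when its posterior
  reaches 0.95 (a conventional calling bar; configurable);
  zero-coverage quartets are never called. A SNP is a position with at
  least two distinct alleles among called genotypes.

When a position carries no non-focal reads, f′ is undefined and the
quartet falls back to γ = 0; the kernel treats a zero f′ row as that
signal. The likelihood kernel is compiled (Rcpp) because model selection
refits the error rates a dozen times over ~10^5 quartets.

## Population-genomic summaries

From called genotypes the package computes the SNP count, π_S, π_N,
π_N/π_S, F_IT and Tajima's D (synonymous and non-synonymous separately):

* per-site diversity is the unbiased heterozygosity
  (m/(m−1))(1 − Σp²) over the m called allele copies — identical to the
  mean pairwise difference;
* synonymous/non-synonymous site counts are Nei–Gojobori fractional
  counts under the standard genetic code; SNP effects are classified by
  codon translation against the reference codon, tri-allelic sites per
  minor allele against the major one (flagged), stop-gaining changes as
  non-synonymous;
* π_S and π_N, and F_IT's heterozygosity sums, are ratios of sums
  across sites, not means of ratios — the standard multi-locus practice
  and the stable choice when SNPs are few;
* Tajima's D uses the canonical constants with m set to the called
  allele-copy count at the median site (per-site weighting is possible
  but the median is transparent and stable at these sample sizes).

## Metadata permutation tests

Five pair predictors are derived per unordered species pair:
`lab_overlap` (days of intersection of the two species' laboratory
periods, entry to last shipment), `same_technician`, `same_shipment`
(same day *and* same center), `same_flowcell`, `same_lane` — the last
two undefined for pairs involving species with missing flowcell/lane
records, which excludes those pairs from the tiered analyses. The
synthetic `LAB` coding is positive when `same_technician` holds and the
overlap exceeds 200 days (the threshold direction is exposed as a flag
because it can be read either way); `CENTER` tiers are −/+/++/+++ for
distinct shipments / same shipment / same flowcell / same lane, and the
probability grid reports the shipment tiers cumulatively — the nesting
of the variables makes the cumulative counts the natural presentation —
with a disjoint-tier option.

The observed statistic is the mean predictor value over contaminated
cells. Nulls are cellwise Bernoulli redraws of the directed matrix with
the missing mask frozen: unconditional with the global probability *p*,
or conditional with per-stratum probabilities taken from the observed
matrix (boolean conditioners stratify by value; `lab_overlap` is binned
into quartiles — the conditioning variable is continuous and no binning
scheme is canonical, so the quartile choice is documented here and fixed
by tests). P-values use the add-one estimator (k + 1)/(N + 1), upper
tail by default. A control subsampling keeps one species per
(technician, shipment) stratum — species spanning strata are assigned to
their earliest stratum by date, with an "all strata" mode — to break the
induced correlation between technician and shipment when samples are
boxed by technician at shipping time.

## What the simulators emulate — and what they do not

`simulate_quartet_dataset` draws Hardy–Weinberg genotypes (optional
inbreeding coefficient) over a random stop-free coding sequence,
Poisson coverage, class-specific read errors, and read-level leakage:
each read is, with probability γ, replaced by the state of a uniformly
chosen *native* read of the other individuals, re-exposed to the error
channel — mirroring the f′ formulation of the caller. Defaults are six
individuals, 20,000 positions, coverage 60, ε_ts = 0.003,
ε_tv = 0.001, with 30% of positions polymorphic and minor-allele counts
following the folded neutral-like 1/i law. These defaults were fixed
once as the package's reference conditions: the error rates and
coverage are ordinary Illumina transcriptome values, and the polymorphic
fraction is deliberately SNP-dense so that leakage statistics have
stable denominators at desk scale.

The calibration and recovery checks in the test suite run at these
reference conditions: the leakage index on a γ = 0 simulation
(20,000 positions) must sit within ±0.05 of zero; γ* must recover the
generating γ over the grid in at least 9 of 10 seeded replicates
(40 model-selection runs of ~120,000 quartets each — the bulk of the
suite's runtime); the error-class ratio is calibrated on 10^5 simulated
homo-quartets.

The directional sensitivity check of the population-genomic statistics
runs at coverage 15 instead. This is a scientific choice, not a
shortcut: pruning of spurious heterozygotes by the γ-aware caller
operates through read-balance ambiguity, and at coverage 60 the binomial
read balance of a true heterozygote is so tight that genotypes are
essentially noiseless — the correction then has nothing to prune and
π_S barely moves. At RNAseq-like per-site depths (~15 after
deduplication) the expected pattern appears and is asserted: calling at
the generating γ lowers π_S and raises F_IT relative to γ = 0 calling,
monotonically across the grid, with π_N/π_S markedly less sensitive
than π_S.

What the simulators do *not* emulate: linkage (positions are
independent; no coalescent), expression-level variation between alleles
and individuals, PCR duplicates, hidden paralogy, and over-dispersed
read counts generally. This matters for interpretation: on real
transcriptome data those processes inflate the leakage signal and can
confound γ estimation (paralogous families in particular mimic
contamination by giving every individual similar two-state read counts),
so passing tests here demonstrate correctness of the statistics under
their own model, not that γ* equals the true contamination rate in real
data. The barcode simulator generates species sequences by independent
mutation from a common ancestor — enough to control pairwise divergence
(including deliberately non-diagnostic close pairs) but with no
phylogenetic structure, and its "total reads" is a nominal denominator
rather than a simulated background.

## Numerical and degenerate-input choices

* Likelihoods are accumulated in log space with a max-shift; genotypes
  with zero prior are skipped; a quartet with zero coverage contributes
  zero log-likelihood and is never called.
* Zero-coverage site columns raise an explicit error in position
  classification; empty record sets make the error matrix, q_obs,
  q_exp, λ and λ′ signal undefined rather than return silent zeros.
* Undefined rows of **P** (no observed errors from that major state)
  drop their records from both the numerator and denominator of q_exp,
  with a counter.
* Positions are carried 1-based end to end, matching the TSV interface;
  codon lookup is (pos − 1) %/% 3. Nothing in the pipeline performs
  interval arithmetic that would favour half-open coordinates.
* All tie-breaks (second-ranked state, genotype argmax, γ ties) are
  fixed and documented; the only intentional randomness outside the
  simulators is mapper tie-breaking, which uses R's seeded RNG.

## Known limitations

The screen cannot see contamination between species below the
divergence threshold, by construction. λ is sample-level: it cannot
attribute leakage to a source individual. γ is global per dataset —
per-individual or per-pair contamination rates are not modelled — and on
real data it absorbs every source of read-count over-dispersion, so it
should be read as an upper-bound-style nuisance parameter rather than a
contamination estimate. Indels are not genotyped, and the popgen layer
assumes in-frame, stop-free coding annotation.
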
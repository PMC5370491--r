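# seqcontam

Cross-contamination is a structural hazard of multi-sample sequencing
projects: when many samples — often from many species — move through one
laboratory and shared sequencing runs, reads leak between them, either
as physical carry-over during library construction or as index
mis-assignment on the flowcell. Between species the contaminant can be
recognised by divergence; between individuals of the same species it is
nearly invisible, yet it silently inflates heterozygosity and distorts
every downstream population-genetic statistic.

seqcontam is an R toolkit for people running or auditing such projects
— molecular ecologists, population genomicists, sequencing facilities.
It provides:

* **Barcode screen** — maps reads to an aligned cox1 reference panel
  (ungapped, both strands, mismatch tolerance 1 for ≤50 bp reads, else
  2), masks species pairs with minimum barcode p-distance below 5% as
  non-diagnostic, reports per-species hit prevalences per million
  reads, and assembles a directed contamination matrix **M** where
  `m[i, j] = 1` records contamination of species *j* by species *i*.
* **Allele-leakage statistic** — from "homo-quartets" (read-count
  vectors with exactly two states, major count > 40, minor count
  exactly 1) it estimates the error matrix **P** at monoallelic
  positions and, at biallelic positions, compares the observed rate
  `q_obs` at which the minor state matches the other segregating allele
  *z* with its error-only expectation `q_exp = mean P(a, z)`. The
  leakage index

  λ = (q_obs − q_exp) / q_exp

  is 0 without contamination and positive when alleles leak between
  individuals; λ′ restricts the signal to leakage between shipment
  groups.
* **Contamination-aware genotyper** — a multinomial mixture over the
  10 diploid genotypes with Hardy–Weinberg priors, class-specific error
  rates (ε_ts, ε_tv) and a contamination probability γ: each read is,
  with probability γ, drawn from the read frequencies f′ of the *other*
  individuals at the position, then passed through the error channel.
  ε is estimated by maximum likelihood; γ is profiled over
  {0, 0.05, 0.1, 0.2} and the maximally likely value γ* selected.
* **Population genomics** — π_S, π_N, π_N/π_S, F_IT and Tajima's D
  from the calls (unbiased per-site heterozygosity, Nei–Gojobori site
  counts, ratio-of-sums across sites).
* **Metadata permutation tests** — pair predictors (lab_overlap,
  same_technician, same_shipment, same_flowcell, same_lane),
  unconditional and conditional Bernoulli randomisations of **M** with
  the missing mask frozen, add-one empirical p-values, a
  laboratory-by-center probability grid, and a one-species-per-stratum
  control.
* **Simulators** — seeded generators for quartet tables, barcode
  panels/reads and metadata, with logged ground truth.

## Worked example

Simulate a six-individual dataset with 10% read leakage, measure λ,
select γ, and summarise diversity at the selected γ:

```r
library(seqcontam)

sim <- simulate_quartet_dataset(n_individuals = 6, n_positions = 6000,
                                coverage = 60, gamma = 0.1, seed = 42)

leakage_report(sim$quartets)
#>   species h_mono h_bi q_obs q_exp lambda
#> 1   simsp   6454  600 0.892 0.304   1.93

sel <- select_gamma(sim$quartets)
sel$profile
#>   gamma   loglik     eps_ts      eps_tv
#> 1  0.00 -74930.0 0.00460280 0.002447679
#> 2  0.05 -59148.1 0.00326287 0.001071992
#> 3  0.10 -57222.6 0.00296279 0.000958888
#> 4  0.20 -60249.4 0.00260818 0.000854036
sel$gamma_star
#> [1] 0.1

gt <- call_genotypes(sim$quartets, gamma = sel$gamma_star)
diversity_summary(gt$calls, c(cds1 = sim$truth$cds))
#>   n_snps   pi_S   pi_N pi_N_over_pi_S   f_it tajimas_d_syn ...
#> 1   1470 0.0882 0.0844          0.957 0.0163         0.281 ...
```

Reading the output: 600 homo-quartets fell at biallelic positions, and
89% of their minor states matched the other segregating allele against
an error-only expectation of 30% — λ ≈ 1.9, a strong leakage signal.
The likelihood profile picks γ* = 0.1, the generating value, and the
error-rate estimates at γ* (0.0030, 0.0010) recover the simulation
truth (0.003, 0.001); at γ = 0 they are inflated because errors must
absorb the leaked reads. Diversity is then summarised from calls made
at γ*.

A command-line surface over the same functions ships in
`inst/cli/seqcontam-cli.R` (subcommands `screen`, `matrix`, `leakage`,
`genotype`, `popstats`, `metatest`, `simulate`; `--seed` is mandatory
for the stochastic ones, and every run writes a manifest).

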
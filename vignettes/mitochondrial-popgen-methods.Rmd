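---
title: "Methods: mitochondrial marker population genetics with popgenmt"
author: "popgenmt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial marker population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenmt)
```

`popgenmt` implements the standard analysis chain for aligned mitochondrial
marker sequences (e.g. *COI* and *Cytb* fragments) sampled from a hierarchy of
populations nested in geographic regions: haplotype structure, diversity and
neutrality statistics, hierarchical AMOVA with permutation tests, isolation by
distance, mismatch-based demographic inference, and statistical-parsimony
networks. This vignette documents the models, the numerical choices, and what
the bundled simulators do and do not emulate.

## Data model and the analyzed-site convention

A dataset is an equal-length alignment joined strictly to per-sample
metadata (population, region, decimal-degree coordinates; every population
belongs to exactly one region). All statistics share a single *analyzed-site*
set: alignment columns that carry only unambiguous A/C/G/T in every sample.
Columns containing any gap or IUPAC ambiguity anywhere in the dataset are
excluded once, dataset-wide (the complete-deletion convention). This makes the
segregating-site count S, haplotype number Hn, haplotype diversity Hd, mean
pairwise differences k and the distance matrices mutually consistent and
deterministic; the excluded column set is reported by `site_summary()`.
Sequences are never trimmed or re-aligned — inputs are assumed aligned
upstream.

Two markers from the same (non-recombining) mitochondrial genome are combined
per individual with `concatenate_loci()`; individuals sequenced at only one
marker are dropped from the combined analysis with a warning, since a
half-missing concatenation would distort every pairwise distance.

## Diversity and neutrality

Per group (population, region, pooled total) `diversity_stats()` reports
Nei's unbiased haplotype diversity \(Hd = \frac{N}{N-1}(1 - \sum_h p_h^2)\),
the mean number of pairwise nucleotide differences \(k\) over all
\(\binom{N}{2}\) pairs, and nucleotide diversity \(\pi = k/L\) with \(L\) the
number of analyzed sites. Summaries are emitted both pooled (all sequences of
a level together) and averaged over groups, and labelled as such, because the
two differ and both appear in the literature's summary tables.

Tajima's D is computed from \((S, N, k)\) with the 1989 constants; \(S = 0\)
yields an explicit *undefined* flag rather than an error, matching table
conventions. Fu's Fs uses the Ewens sampling formula,
\(P(K = j) = |s(N, j)|\,\theta^j / \theta^{(N)}\), with unsigned Stirling
numbers of the first kind computed by the standard recurrence entirely in log
space, so sample sizes of several hundred are exact to double precision;
\(S' = P(K \ge k_0)\) and \(F_s = \ln(S'/(1-S'))\). \(\theta\) is estimated by
\(k\) (Fu's own choice). \(k_0 = 1\) gives \(S' = 1\) and an undefined,
flagged Fs.

Significance for both statistics comes from simulating neutral constant-size
coalescent samples of the observed size conditioned on \(\hat\theta = k\)
(`simulate_neutral_coalescent()`), with
\(p = \Pr(\text{simulated} \le \text{observed})\), one-tailed toward the
negative (expansion-side) alternative. The documentation notes the literature
convention of judging Fs at the 0.02 level; the raw simulation p is what the
package reports.

## AMOVA and gene flow

`amova()` partitions squared molecular distances — raw pairwise difference
counts, the conventional substrate for Phi-statistics on haplotype data —
among strata of the sampling hierarchy using the Excoffier–Smouse–Quattro
sums of squares, with method-of-moments variance components for unequal group
sizes. The two-level design returns \(F_{CT}\) (among regions), \(F_{SC}\)
(among populations within regions) and \(F_{ST}\) (within populations), which
satisfy \((1-F_{CT})(1-F_{SC}) = (1-F_{ST})\) to numerical precision.
Negative variance components are reported as-is and flagged, never truncated:
truncation would bias pairwise tables whose small negative entries are
meaningful null noise.

Permutation schemes follow the stratum being tested: individuals among all
populations for \(F_{ST}\); individuals among populations within their region
for \(F_{SC}\); whole populations among regions for \(F_{CT}\). Each p-value
is \((\#\{\text{permuted} \ge \text{observed}\} + 1)/(B + 1)\). Defaults are
1023 permutations for the hierarchical design and 1000 for pairwise
\(\Phi_{ST}\) tests, both overridable. `gene_flow_nm()` converts a fixation
index by the island-model relation \(Nm = (1 - F_{ST})/(4 F_{ST})\), with
explicit infinite-flow/zero-flow flags outside (0, 1).

## Isolation by distance

`ibd_test()` compares linearised genetic distance \(F_{ST}/(1-F_{ST})\) with
log great-circle distance (haversine, IUGG mean radius 6371.0088 km) between
population sites, using a Mantel test on the lower triangles with
simultaneous row/column permutation. The test is one-tailed for positive
association, the direction isolation by distance predicts. Negative pairwise
\(F_{ST}\) maps to genetic distance 0 (clamped, counted and reported) rather
than being dropped, keeping the matrix complete; \(F_{ST} \ge 1\) or
coincident sites exclude the pair with a warning. Each population is one
collection site; no centroid logic is attempted.

## Mismatch distributions and sudden expansion

The observed mismatch spectrum is the histogram of all pairwise difference
counts. The expected spectrum under an instantaneous expansion from
\(\theta_0\) to \(\theta_1\) at mutational time \(\tau\) follows from the
pairwise coalescence-time density (hazard \(1/\theta_1\) until \(\tau\),
\(1/\theta_0\) beyond, Poisson differences given the coalescence time):

\[
F_j = \hat F_j(\theta_1)\, P\!\left(\Gamma_{j+1} \le \tau\tfrac{1+\theta_1}{\theta_1}\right)
 + e^{-\tau/\theta_1} \sum_{m=0}^{j} \operatorname{Pois}(j-m;\tau)\, \hat F_m(\theta_0),
\]

with \(\hat F_j(\theta) = \theta^j/(1+\theta)^{j+1}\) the equilibrium
spectrum. This closed form (regularised incomplete gamma plus a Poisson
convolution) sums to 1 and reduces to \(\hat F_j(\theta_0)\) at \(\tau = 0\).
`fit_sudden_expansion()` minimises the sum of squared deviations over the
observed support by bounded L-BFGS-B from a deterministic grid of restarts;
\(\theta_1\) is capped at 99999, the conventional bound, and the fitted SSD is
verified against every restart. Harpending's raggedness
\(r = \sum_{j=1}^{d+1}(f_j - f_{j-1})^2\) is computed on the observed spectrum
only. Goodness of fit is a parametric bootstrap: coalescent samples under the
fitted two-epoch history are refitted and the simulated SSD and raggedness
compared with the observed values (default 1000 replicates, seed mandatory).
Expansion times convert as \(t = \tau/(2\mu L)\) with an explicit per-site
per-year rate argument; a divergence rate quoted as "2.3% per million years"
enters as \(2.3\times10^{-8}\). Because \(t\) is inversely proportional to
\(L\), the longer marker necessarily dates a given \(\tau\) more recently:
\(\tau = 3.842\) at 652 sites gives ~128 ka while \(\tau = 2.016\) at 421
sites gives ~104 ka. Whether a quoted rate is per lineage or a pairwise
divergence rate is left to the caller; the default reproduces the
per-site-per-year reading above.

## Statistical-parsimony networks

`parsimony_connection_limit()` computes the largest number of steps at which
two haplotypes are still connected with probability of parsimony above the
confidence level (default 0.95). The probability of parsimony is estimated by
a Bayesian multiple-hit model: conditional on \(h\) true substitutions thrown
uniformly on \(L\) sites, the chance that exactly \(j\) sites differ is the
occupancy probability \(C(L,j)\,S_2(h,j)\,j!/L^h\); with a uniform prior on
\(h \ge j\), parsimony (no superimposed hit) has posterior
\(O(j\mid j)/\sum_{h\ge j} O(j\mid h)\). This estimator is deliberately
conservative relative to the classical software implementations (it ignores
the extra credit those give for parallel changes landing on distinct
lineages), so limits are a step or two shorter; since the network is used
descriptively (shared vs private haplotypes, star shapes), that conservatism
does not change any reported statistic.

`build_network()` joins haplotype pairs in ascending distance order up to the
limit; a d-step join inserts d−1 zero-count "missing" intermediates so every
edge is one mutational step. Equal-distance ties link higher-frequency
haplotypes first, then lexicographically earlier names; a same-component pair
whose distance and tie-break keys exactly match the link that merged its
components is added as a reported loop — the full cladogram-estimation loop
resolution of the original method is intentionally out of scope.

## The simulators: what they emulate, and what they do not

`simulate_structured_dataset()` realises a structured coalescent over demes
(populations) with backward migration, one shared genealogy for all
completely linked markers, infinite-sites mutations mapped onto an AT-biased
background (default A+T = 0.70, matching insect mitochondrial composition),
and coordinates placed so between-region distances exceed within-region
scatter. Two migration models are provided: a hierarchical island model
(within-region vs between-region rates) and a linear nearest-neighbour
stepping stone for isolation-by-distance scenarios. A sudden expansion can be
applied to one region's demes as an instantaneous size change at coalescent
time \(\tau/\theta_{\text{ref}}\).

The default configuration emulates the 15-population, 3-region,
437-individual two-marker survey design: study-like per-population sample
sizes (8–37), marker lengths 652 and 421 bp, per-deme \(\theta\) = (0.30,
0.21), within-region migration 5, between-region migration 0.12, and a
central-region expansion (\(\tau = 2.2\), \(\theta_0 = 0.02\)). Across seeds
this yields overall haplotype diversity ≈ 0.87 ± 0.04, A+T ≈ 0.70, and a
fixation-index hierarchy \(F_{CT} \gg F_{SC}\) — the qualitative structure
the analysis chain is designed to detect. Two caveats matter for
interpreting test results on real data. First, an *equilibrium* island model
cannot jointly reproduce a very large count of rare haplotypes (tens of
singletons) at small \(k\); that pattern requires a species-wide
non-equilibrium history, so simulated haplotype and segregating-site counts
run below survey-like values even where Hd and the Phi-statistics match.
Second, single-locus mitochondrial data carry large genealogical variance:
point estimates of \(F_{CT}\) or \(\tau\) fluctuate strongly across seeds, as
they would across real replicate loci. Passing tests therefore demonstrate
correctness of the estimators and calibration of their null distributions,
not that any single-locus estimate is precise.

Problem sizes in the test suite are chosen to keep the full run to a few
minutes on one CPU: neutrality nulls use 100–200 coalescent replicates per
group, the simulator calibration uses 2000 replicates at n = 10, parameter
recovery uses 20 seeds at n = 100, and the qualitative hierarchy and
isolation-by-distance properties use 100 and 20 seeded replicates of compact
designs (6 demes × 12 samples; 15 demes × 20 samples). Report-facing defaults
(1023/1000/10000 permutations, 1000 bootstrap replicates) match standard
practice and remain the function defaults.

## Numerical and design choices

* **Seeds.** Every stochastic routine requires a seed and restores the
  caller's RNG state; `run_full_analysis()` derives one deterministic
  sub-seed per stage from the single run seed, so any stage can be reproduced
  in isolation and a rerun is byte-identical.
* **Log-space probability work.** Stirling numbers (both kinds), Ewens
  probabilities and the parsimony posterior are computed in log space;
  equilibrium mismatch terms use `log1p` to survive \(\theta_1\) at its
  99999 cap.
* **p-value conventions.** Permutation tests use the add-one rule
  \((c+1)/(B+1)\), keeping p in (0, 1]; simulation p-values for neutrality
  report raw fractions in [0, 1].
* **Degenerate inputs.** \(S=0\) groups flag statistics undefined; pairs of
  populations with zero molecular variance yield an undefined pairwise
  \(\Phi_{ST}\) cell rather than an arbitrary zero; a point-mass mismatch
  spectrum returns the no-variation limit (\(\tau = 0, \theta_0 = 0\),
  SSD = 0) without optimisation.
* **Rounding.** Only the CSV/report layer rounds (three decimals for
  diversity and fixation indices, one decimal for percentages); the JSON
  summary and all return values keep full precision.

## Known limitations

No substitution-model correction is applied inside AMOVA distances (raw
counts are the Phi convention); no partial Mantel tests, median-joining
networks, Bayesian demographic inference or recombination/selection models
are provided. The expansion-time conversion inherits the usual ambiguity of
published divergence rates. The TCS-style connection limit is a conservative
re-derivation, not a line-for-line port of the original recursion.
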
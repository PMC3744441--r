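---
title: "Integrated de novo and inherited rare-variant association: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated de novo and inherited rare-variant association: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadar)
```

## The problem

Exome sequencing of family trios yields several kinds of evidence about a
gene's role in a disorder such as autism spectrum disorder (ASD): de novo
mutations in affected children, rare damaging variants transmitted (or not
transmitted) from carrier parents, and carrier counts in unrelated cases
and controls. Early trio studies used only the most striking signal —
recurrent de novo loss-of-function (LoF) events in the same gene — and
discarded the rest. `tadar` implements a gene-level model that uses all of
these counts at once, the TADA (transmission and de novo association)
framework, together with the simpler tests it is compared against and the
simulation machinery needed to study power and false discovery.

## The count model

All damaging variants of one category (LoF, or probably-damaging missense,
"Mis3") in one gene are collapsed into a single rare "allele" with
population frequency $q$, per-chromosome mutation rate $\mu$, and
multiplicative relative risk $\gamma$ for carriers ($\gamma = 1$ for a gene
unrelated to the disorder). Because $q$ is small, in $N$ trios, $N_1$
cases and $N_0$ controls the observed counts are approximately independent
Poissons:

* de novo events: $X_{dn} \sim \mathrm{Pois}(2 N \mu \gamma)$;
* transmitted / nontransmitted variants:
  $\mathrm{Pois}(2 N q \gamma)$ / $\mathrm{Pois}(2 N q)$;
* case / control carriers: $\mathrm{Pois}(2 N_1 q \gamma)$ /
  $\mathrm{Pois}(2 N_0 q)$.

Transmission counts are therefore case-control counts in disguise, and the
model works with the merged pseudo-case count $x_1 = \mathrm{case} +
\mathrm{transmitted}$ with exposure $e_1 = 2(N_1 + N)$ and pseudo-control
count $x_0 = \mathrm{control} + \mathrm{nontransmitted}$ with exposure
$e_0 = 2(N_0 + N)$ (`compute_rates()`). The first-order constants live in
one function so the contract that matters — equal per-exposure arm rates
under $\gamma = 1$, linearity in sample sizes, $\mu$ and $q$ — is
independent of the particular constant.

Category-level mutation rates are the gene's total rate times the category
fraction (`scale_mutation_rate()`); the default LoF fraction 34/461 is the
proportion of LoF variants among de novo coding SNVs in unaffected
siblings. Input preprocessing (`preprocess_counts()`) excludes common
variants (default frequency threshold 0.01, configurable), drops genes
with more than 10 control LoF events, and counts one carrier per
individual per gene and category.

## Hierarchical model and Bayes factor

A fraction $\pi$ of genes are risk genes (model $H_1$); the rest follow
the null $H_0$. Under $H_1$, $\gamma \sim
\Gamma(\bar\gamma\beta, \beta)$ — mean $\bar\gamma$, with $\beta$ acting
as a precision/pseudo-count — and $q \sim \Gamma(\rho_1, \nu_1)$; under
$H_0$, $\gamma = 1$ and $q \sim \Gamma(\rho_0, \nu_0)$. Allowing the two
frequency priors to differ matters: alleles of genuine risk genes are
held rarer by stronger purifying selection, and the data say so.

The per-gene, per-category Bayes factor is the ratio of marginal
likelihoods,
$$
\mathrm{BF}_i = \frac{P(x_{dn,i}, x_{1,i}, x_{0,i} \mid H_1)}
                     {P(x_{dn,i}, x_{1,i}, x_{0,i} \mid H_0)},
$$
with $q$ integrated in closed conjugate form and $\gamma$ by quadrature
(`bayes_factor_gene()`). Both streams share a single $\gamma$ integral by
default (`joint = TRUE`), which is how the model is written; the
factorized product of a de novo Bayes factor and a case-control Bayes
factor (`joint = FALSE`) is retained because it is common field practice,
is what the de-novo-only test uses, and agrees with the joint version to
high rank correlation.

Categories are independent evidence, so a gene's total Bayes factor is the
product over categories. Predicted-damaging missense calls are only partly
real: with probability $w$ a Mis3 variant is truly damaging, so that
category's Bayes factor is shrunk toward 1 as $w\,\mathrm{BF} + (1 - w)$
before the product. We default to $w = 0.5$, a coin-flip on the
bioinformatic prediction; it is a configuration knob (`--w-mis` on the
command line).

A cheaper likelihood-ratio-style approximation (`approx_bayes_factor()`)
replaces the integrals with conjugate posterior-mean plug-ins; the
frequency estimate is the prior mean weighted by $\nu/(\nu + e)$ against
the count-based estimate. It tracks the exact Bayes factor closely for
genes that carry data, but an empty gene's exact Bayes factor reflects
purely the difference between the two frequency priors, which no point
estimate reproduces — it is a ranking convenience, not a substitute.

## Empirical-Bayes fitting

The six free hyperparameters $(\bar\gamma, \beta, \rho_1, \nu_1, \rho_0,
\nu_0)$ are estimated per category by maximizing the mixture marginal
likelihood $\sum_i \log[\pi P(d_i \mid H_1) + (1-\pi) P(d_i \mid H_0)]$
with $\pi$ held fixed (`fit_hyperparameters()`; default $\pi =
1000/18000$). The fraction of risk genes and the effect-size distribution
are nearly confounded in this likelihood, which is why $\pi$ is supplied,
not estimated; `refine_k_hb()` profiles the likelihood over a grid of
$\pi = k/m$ values when an estimate of the risk-gene count $k$ is itself
the goal.

Numerics: the search runs on log-parameters (which makes it invariant to
parameter rescaling) inside box bounds $\bar\gamma \in [1.1, 500]$,
$\beta \in [10^{-3}, 10^3]$, prior frequency means in $[10^{-7}, 0.05]$.
The surface is smooth but can be flat in $\beta$, so several short
Nelder-Mead explorations from jittered starts precede an L-BFGS-B polish
of the best one; the default start anchors the null frequency prior at the
pooled carrier frequency. One genome-scale evaluation (18,000 genes) costs
tens of milliseconds because the case-control kernel is evaluated on the
unique $(x_1, x_0)$ patterns only, and a full fit takes roughly half a
minute.

The $\gamma$ integrals use Gauss–Legendre quadrature on $\log\gamma$ over
the central $1 - 10^{-10}$ prior mass, where the integrand is smooth and
unimodal: 32 nodes during fitting and 64 for reported Bayes factors, both
verified against 128-node references (differences below $10^{-10}$ in
$\log_{10}$ BF); the scalar `marginal_casecontrol()` doubles nodes
adaptively to a $10^{-6}$ relative tolerance. Everything is computed in
natural-log space and reported as $\log_{10}$; empty exposure and
zero-count corner cases resolve to unit likelihoods rather than NaN.

## Significance

The Bayes factor's significance is calibrated by simulation from the
fitted null (`null_bf_pool()`): each of $B$ replicates picks a gene
uniformly (inheriting its $\mu$), draws $q$ from the $H_0$ prior,
generates counts at the null rates, and records the total Bayes factor.
Pooling across genes matches the genome-wide question asked of the ranking
(a per-gene null is available by passing a single-gene table). The
empirical p-value is $(1 + \#\{\mathrm{pool} \ge \mathrm{obs}\}) / (1 +
B)$ — never zero, floored at $1/(1+B)$, so the default $B = 10^6$ supports
genome-wide tails. Benjamini–Hochberg q-values (`bh_adjust()`, a validated
wrapper over `stats::p.adjust`) control FDR, and a median-based
genomic-control factor $\lambda$ (`genomic_control()`) flags systematic
inflation. `run_full_analysis()` chains fit, Bayes factors, p-values,
q-values and $\lambda$ into the real-data pipeline.

## Baseline tests

For comparison the package provides the tests that predate the integrated
model: the multiplicity rule (call any gene with $\ge c$ de novo events,
`multiplicity_test()`); the Poisson de novo test
(`denovo_test_pvalue()`), its gene-specific refinement; the one-sided
Fisher exact test on the merged pseudo case-control table
(`transmission_cc_pvalue()`, hypergeometric tail on chromosome-count
exposures — one-sided because the model concerns adverse minor alleles);
and the meta test combining exactly those two p-values by Fisher's method
(`meta_test()`). The meta test illustrates why integration helps: a gene
with no de novo events contributes $p_{dn} = 1$, and Fisher's method
penalizes the combined statistic, whereas the Bayes factor of an
uninformative stream is simply near 1. `tada_denovo()` is the integrated
test restricted to de novo data.

## Genetic architecture

With $m$ genes, a $\lambda$-fold proband/sibling de novo enrichment, and
risk genes of mean relative risk $\bar\gamma$, matching expected
enrichment gives $k = m(\lambda - 1)/(\bar\gamma - 1)$
(`enrichment_to_k()`, inverted by `enrichment_to_gamma()`): at $m =
18{,}000$ and $\lambda = 2$ the curve passes through $(k, \bar\gamma)
\approx (1000, 19)$. The expected number of multi-hit genes ($\ge 2$ de
novo events; `expected_multihit()`) pins $k$ along that curve:
`k_interval()` inverts the decreasing curve at a plausibility band around
the observed multi-hit count, and `refine_k_hb()` picks the likeliest $k$
inside the interval by profiling the hierarchical likelihood. Both
mutation-rate and relative-risk heterogeneity inflate the multi-hit
expectation (tail probabilities are convex in the Poisson rate), so
equal-rate approximations understate $k$ — the package computes the
heterogeneous expectation directly. The relative-risk spread defaults to a
Gamma with unit coefficient of variation (`rr_shape = 1`), a deliberately
broad choice; it is a configuration knob, and the recovery tests run at
the default.

## The simulator

`simulate_genome()` generates the synthetic genomes used for calibration,
power and recovery studies. Defaults are the study conditions the package
is tested under: $m = 18{,}000$ genes, $k = 1000$ risk genes,
$\bar\gamma = 20$ with unit coefficient of variation, risk-gene frequency
mean $5 \times 10^{-5}$ versus $10^{-3}$ for other genes (Gamma, shape 1),
and cohorts of 1,000 trios plus 1,000 cases and 1,000 controls. Per-gene
LoF mutation rates are log-normal (median $1.5 \times 10^{-6}$, sdlog 1,
mean $\approx 2.5 \times 10^{-6}$), which yields about 0.09 expected de
novo LoF events per child genome-wide, consistent with sibling counts in
ASD cohorts; a user-supplied rate table overrides. A
`mutation_selection` mode draws $\gamma$ first and sets $q = c\mu/\gamma$
(mutation-selection balance, $c$ solved from the configured means) so
frequency and risk are inversely tied; frequencies are clamped at 0.05
with a warning.

Counts are drawn from the model's Poisson rates with a dedicated RNG
substream per gene, keyed on (seed, gene index), so any subset of genes
reproduces its counts exactly. What the generator does *not* emulate:
linkage and haplotype structure, population stratification, variable
capture/calling sensitivity across studies, mutation-rate estimation
error, and ascertainment beyond the affected-child conditioning already in
the rates. Passing calibration and recovery tests on these genomes
therefore demonstrates correctness of the statistical machinery under the
model's own assumptions, not robustness to everything real data can do —
the sensitivity scan (`sensitivity_analysis()`), which varies mutation
rates twofold in both directions and the risk prior from 10 to 20, probes
the first-order robustness questions.

## Evaluation experiments

`per_gene_power()` estimates each test's power at fixed type-I error by
simulating replicate genes (default $10^4$; the Bayes test's threshold
comes from its own null pool). `genomewide_experiment()` simulates a full
genome and counts true discoveries with each test's threshold set by
oracle calibration — the most liberal cutoff whose realized
false-discovery proportion, known from the simulation truth, stays within
the target — which is the right calibration when truth is available;
real-data analyses use Benjamini–Hochberg instead.
`multiplicity_study()` computes the recurrence rule's expected discoveries
and FDR analytically. At the default architecture the integrated test
dominates the meta test, which dominates the de novo test, per gene and
genome-wide.

## Problem sizes used by the shipped tests

Unit tests run on reduced genomes (hundreds to a few thousand genes) with
correspondingly reduced null pools; the acceptance suite runs the
headline experiments at the full study conditions — 5,000-gene null
calibration, five replicate 18,000-gene recovery fits, ten-seed power
orderings — with null pools of $10^5$–$2 \times 10^5$ where p-value
resolution of $10^{-3}$ or better is needed. These sizes are the
package's chosen trade-off between Monte Carlo error and turnaround;
every stochastic assertion uses explicit seeds and tolerance bands
derived from the binomial or Monte Carlo standard error.

## Known limitations

* Dominant-acting rare variants only: no recessive model, covariates, or
  quantitative traits.
* Mutation rates are inputs; the package does not estimate them from
  sequence composition.
* The plug-in Bayes factor is uninformative for genes without any
  observed events (see above).
* The genomic-control factor is the standard median-based $\lambda$;
  p-values near 1 from discrete null pools make it a coarse diagnostic
  here.
* $\pi$ (equivalently $k$) is supplied, not jointly estimated; use
  `refine_k_hb()` for a profiled estimate.
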
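---
title: "Crossover patterning and Weinstein tetrad analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover patterning and Weinstein tetrad analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradr)
```

## The problem

In *Drosophila melanogaster* females, meiotic crossovers are formed in the
context of the synaptonemal complex, and their number and placement along
each chromosome arm follow a characteristic pattern: strong suppression near
the centromere (the centromere effect), interference between nearby
exchanges, and near-zero exchange-free bivalents for the major chromosomes.
Classical multiply-marked crosses read this pattern out genetically: females
heterozygous for a chromosome carrying several recessive visible markers are
crossed to marker-bearing males, and each scored offspring reveals, locus by
locus, which parental chromosome contributed its allele. A switch of
parental origin between two adjacent marked loci is an observed crossover in
that interval.

`tetradr` implements the complete analysis of such crosses: crossover
calling and class tabulation, interval genetic maps, Weinstein tetrad
analysis, genotype comparisons by Fisher's exact test, viability-adjusted
nondisjunction rates, and a forward simulator of female meiosis used to
validate the whole pipeline.

## From phenotypes to crossover classes

The package works on parental-origin codes (`P1`/`P2`), not raw phenotype
strings: decoding recessive visible phenotypes into origins is
cross-specific and happens upstream. A `marker_map()` fixes the locus order;
`call_crossovers()` scans each record for origin switches between adjacent
scored loci.

Missing marker calls are never imputed. A switch flanked by a run of missing
loci is still assigned when the flanking scored loci are one interval apart;
if they are further apart the crossover cannot be placed and the record is
dropped and logged. Note the intrinsic censoring of this design: an even
number of crossovers between adjacent scored loci cancels and is invisible,
so all counts are of *observable* phase switches, which is also what the
published tables report.

```{r}
x <- marker_map_x()   # sc, cv, v, f, y+ ; f-y+ spans the centromere
x
```

The scored X chromosome carries the duplicated yellow body locus (y1 distal,
the wild-type y+ marker translocated proximal to the centromere on the right
arm); only the five loci delimiting the four scored intervals enter the map,
so the centromere-spanning interval is f–y+.

## The Weinstein recovery model

Each female meiosis yields one recovered chromatid out of the four in the
tetrad. If a tetrad underwent $k$ exchanges and each exchange involves one
randomly chosen chromatid per homolog, independently across exchanges (no
chromatid interference), a recovered chromatid carries $j$ crossovers with
probability $\binom{k}{j}/2^k$. Writing $E_k$ for the frequency of rank-$k$
tetrads, the chromatid class probabilities are

$$p_j \;=\; \sum_{k \ge j} E_k \, \binom{k}{j} \, 2^{-k}.$$

Two estimators invert this model from the observed class counts
$n_0, n_1, \dots$ (NCO, SCO, DCO, TCO, ...):

* **Direct inversion** (`weinstein_direct()`). The linear system is
  triangular, so it is solved top-down,
  $E_k = 2^k\,(\hat p_k - \sum_{m>k} E_m \binom{m}{k} 2^{-m})$, with
  $E_0 = 1 - \sum_{k\ge1} E_k$. When the observed frequencies are
  incompatible with the model this produces negative frequencies; the result
  is returned *unclamped* with `feasible = FALSE`, preserving the classical
  diagnostic value of an infeasible Weinstein solution.

* **Constrained maximum likelihood** (`weinstein_mle()`). The multinomial
  log-likelihood $\sum_j n_j \log p_j(E)$ is maximised over the simplex
  $E_k \ge 0$, $\sum_k E_k = 1$. Because $p_j$ is linear in $E$, the
  log-likelihood is concave, so the constrained optimum is global. On
  feasible data the model is saturated and the MLE coincides with the direct
  inversion; on infeasible data it lands on a boundary face with some
  $E_k = 0$.

```{r}
cc <- example_class_counts("X", "control")
fit <- weinstein_mle(cc)
tidy(fit)
glance(fit)
```

### The optimizer

The MLE is fitted by expectation–maximisation over the latent exchange rank
of each chromatid: class-$j$ chromatids are attributed to ranks $k \ge j$
with posterior weight proportional to $E_k \binom{k}{j} 2^{-k}$, and the
M-step averages the weights. EM was chosen because every iterate stays on
the simplex, so the non-negativity constraints need no projection, and the
update is closed-form.

Plain EM, however, approaches *boundary* optima only harmonically: a
component converging to zero shrinks like $1/t$. The implementation
therefore runs an active-set variant: when a pass stalls at the iteration
cap (10,000), components that are both tiny ($<10^{-3}$) and still shrinking
are clamped to exact zero (EM keeps exact zeros at zero, so the run
continues on that face, where convergence is geometric), and a converged
face solution is accepted only after a Karush–Kuhn–Tucker check — the EM
multiplier $s_k = \frac{1}{N}\sum_j n_j B_{kj}/p_j$ must satisfy
$s_k \le 1$ for every clamped component, since the directional derivative of
the log-likelihood into component $k$ is $N(s_k - 1)$. Violators re-enter
the active set at $10^{-3}$ and the fit resumes.

Convergence itself is certified rather than guessed: by concavity the
log-likelihood cannot exceed the current value by more than
$N(\max_k s_k - 1)$ on the current face, and iteration stops when this bound
falls below `tol` ($10^{-10}$ by default). Ties between multiple optima on a
flat boundary face (possible when some observed classes are empty) are
broken deterministically by always starting from the uniform simplex point;
the fit involves no randomness.

`kmax` defaults to the largest observed crossover class: tetrads of higher
rank than any observed chromatid are identifiable only through the
likelihood, so raising `kmax` merely pads zeros. It can be overridden for
comparability across genotypes.

### Map length and summaries

Total map length in centimorgans is $100 \sum_j j\, n_j / N$; because every
observed crossover falls in exactly one interval, interval map lengths
(`interval_map()`) sum to this total exactly (before any rounding). Since a
chromatid carries on average half of its tetrad's exchanges,
`mean_exchanges()` always equals `2 * total_map_length / 100` on the same
counts — a useful internal consistency check that the test suite enforces.

```{r}
total_map_length(cc)
mean_exchanges(fit)
```

All internal arithmetic is unrounded; rounding to the conventional display
precision (exchange ranks to 4 decimals, centimorgans to 1 decimal, percent
of control to integer percent, nondisjunction to 2 decimals) happens only in
presentation columns and printed output. One consequence worth knowing:
percent-of-control ratios are computed from unrounded map lengths, so they
can differ by one integer percent from a ratio recomputed from the rounded
per-interval values.

## Genotype comparisons

`class_collapse_test()` collapses each genotype's classes into NCO+SCO
versus DCO-and-above and applies a two-sided Fisher exact test; a
significant result flags an excess of multi-crossover chromatids.
`compare_genetic_maps()` tests each interval's recombinant versus
non-recombinant counts between genotypes and reports percent-of-control
ratios — the standard readout for a weakened centromere effect is a
disproportionate increase in the centromere-spanning interval.

The two-sided Fisher p-value sums the probabilities of all tables with the
observed margins whose point probability does not exceed the observed
table's (with a relative tie tolerance of $10^{-7}$), the convention of the
common online calculators and of `stats::fisher.test()`; this is stated
explicitly because two-sided Fisher conventions differ. P-values are
reported raw, without multiple-testing correction, matching how such
per-interval tables are conventionally annotated; the 0.05/0.01 stars are
presentation only. The reported odds ratio is the sample odds ratio
$(ad)/(bc)$, not the conditional MLE.

## Nondisjunction rates

In the standard X^Y / compound-4 segregation assay, each recovered
X-exceptional class (diplo-X and nullo-X ova) has a reciprocal zygote class
that dies. `ndj_rates()` therefore counts every recovered exceptional twice
and adds one inviable zygote per recovered X-exceptional to the denominator:
`adjusted_total = regular + 2 * x_exceptional`, with
`%X NDJ = 100 * 2 * x_exceptional / adjusted_total`. Fourth-chromosome
exceptionals are doubled identically but do not enter the adjusted total,
which is the X-assay denominator used for both rates. Which phenotype
classes count as exceptional is a property of the cross design and is
decided upstream of these functions.

Published tables often print only the percentage and adjusted total;
`ndj_invert()` back-solves the integer exceptional count and verifies
consistency. Under this formula the shipped example table's X rows invert
exactly (6 and 1 recovered exceptionals); the 4th-chromosome percentage of
the control row (0.16 of 1878) does not invert to an integer under doubling
(it is consistent with 3 undoubled exceptionals), suggesting the original
4th-chromosome bookkeeping differed in detail — the package keeps the
symmetric doubling convention and documents the discrepancy rather than
special-casing it. `ndj_compare()` tests genotype differences with an exact
conditional (Fisher) comparison of the doubled event counts against the
adjusted totals; this is a documented stand-in for the classical
normal-approximation treatment of such assays and is flagged as an
approximation in its output.

## The forward simulator

`simulate_meiosis()` generates progeny tables with exactly the statistical
structure the Weinstein estimator assumes — it is the package's testbed, not
a mechanistic model of meiosis. Per meiosis it draws the tetrad rank
$k \sim E$, places each exchange into a marked interval according to the
placement weights, involves one uniformly chosen chromatid per homolog per
exchange, and recovers one of the four chromatids uniformly at random.

Design choices worth spelling out:

* **Distinct intervals by default.** Exchanges of one tetrad are placed by
  weighted sampling *without* replacement, so every exchange is observable
  and the forward model holds exactly. This requires at least as many
  positively-weighted intervals as the largest occupied rank; the
  configuration is rejected otherwise. With-replacement placement
  (`allow_double_exchange = TRUE`) is available to study undetected-double
  bias but is excluded from the validation suite.
* **Successive weighted draws.** Under without-replacement placement the
  marginal probability that an interval receives an exchange in a rank-2 or
  rank-3 tetrad is its *inclusion probability* under successive weighted
  draws, which deviates slightly from proportionality to the weights; the
  round-trip tests compare against this exact expectation (computed by
  enumeration), not against naive proportionality.
* **No interference beyond E.** Crossover interference and the centromere
  effect are expressed only through the rank distribution and the interval
  weights (count-then-place); there is no coarsening or polymer model, and
  no chromatid interference — exactly the assumption set of the estimator
  being validated.
* **Fixed draw order.** Randomness is consumed in a documented order (all
  ranks, then placements, then chromatid picks, then recovery picks), so a
  fixed seed reproduces the progeny table byte for byte.

What passing the simulation tests does *not* show: real data may violate the
no-chromatid-interference assumption, may contain genuinely undetected
double crossovers within long intervals, and its viability differences
across marker classes are not modelled. The simulator validates the
inference machinery under its own assumptions, nothing more.

```{r}
E_true <- c(0.0967, 0.5941, 0.2970, 0.0122)
prog <- simulate_meiosis(20000, x, E_true,
                         interval_weights = c(13.6, 20.8, 19.5, 7.3) / 61.2,
                         seed = 7)
fit <- recover_parameters(prog, x)
tidy(fit$exchange_ranks)
```

## Problem sizes and tolerances used in validation

The test suite exercises: exact reproduction of the shipped example tables
(N between 1,549 and 2,626); forward–inverse round trips on 1,000 random
simplex points at tolerance $10^{-12}$; MLE optimality against an exhaustive
$0.01$-step simplex grid on 20 random small-count datasets; agreement of the
Fisher p-value with full hypergeometric enumeration on every 2×2 table with
all margins between 1 and 30; and full-pipeline parameter recovery from
200,000 simulated meioses, which recovers each $E_k$ within $\pm 0.01$ and
the map total within $\pm 0.3$ cM. These sizes keep the whole suite under a
minute on a single core while leaving the stochastic checks far from their
tolerance boundaries.

## Known limitations

* Exchange ranks are point estimates; no confidence intervals are provided
  (a bootstrap over progeny records is straightforward with
  `simulate_meiosis()`/`tabulate_classes()` if needed).
* No map functions (Kosambi/Haldane) and no coefficient-of-coincidence
  statistics: the package reports observed recombination frequencies only.
* Locus order is taken as given; the package does not estimate marker order.
* The nondisjunction module implements the viability bookkeeping at the
  level of tallied exceptional counts; mapping phenotype classes to
  exceptional categories for a new cross design is the user's
  responsibility.
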
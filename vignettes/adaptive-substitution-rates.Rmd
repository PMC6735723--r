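---
title: "Estimating adaptive and non-adaptive protein substitution rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating adaptive and non-adaptive protein substitution rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrate)
```

## The model

`adaptrate` estimates how fast proteins accumulate adaptive amino-acid
substitutions, and how that rate varies with gene- and residue-level
covariates such as relative solvent accessibility (RSA), secondary
structure, intrinsic disorder and expression level.

The starting point is the McDonald–Kreitman contrast between polymorphism
and divergence.  For a set of coding sites observed in $n$ chromosomes of an
ingroup population plus one outgroup sequence, we summarize the data as a
*spectrum set*: the synonymous and nonsynonymous unfolded site frequency
spectra (SFS) $s_i$ and $x_i$ ($i = 1..n-1$ derived copies), the fractional
site opportunities $L_s$ and $L_n$ (Nei–Gojobori counting, mutations to stop
codons excluded from both classes), and the fixed-difference counts $D_s$
and $D_n$.  The rate of protein evolution is
$\omega = (D_n/L_n)/(D_s/L_s)$.

$\omega$ mixes relaxed constraint with positive selection.  To separate
them we fit a distribution of fitness effects (DFE) of scaled selection
coefficients $S = 4 N_e s$ to the two SFS by Poisson maximum likelihood.
Under the standard diffusion approximation, a mutation class with
coefficient $S$ contributes sojourn density
$$h(x; S) = \frac{1 - e^{-S(1-x)}}{(1 - e^{-S})\,x(1-x)},$$
and the expected number of nonsynonymous sites seen at derived count $i$ is
$$E[x_i] = \theta L_n \int f(S)\, G(S, i, n)\, dS,\qquad
G(S,i,n) = \int_0^1 \binom{n}{i} x^i (1-x)^{n-i} h(x;S)\, dx,$$
with $E[s_i] = \theta L_s / i$ for neutral synonymous sites.  Three DFE
families are fitted and compared by AIC:

* **Neutral** — all nonsynonymous mutations neutral (1 parameter);
* **Gamma** — deleterious coefficients $-S \sim$ Gamma(shape $\beta$, mean
  $\bar S_d$) (3 parameters);
* **GammaExpo** — the Gamma family mixed with an exponential distribution
  of beneficial coefficients (mean $\bar S_b$) with weight $p_b$
  (5 parameters).

The expected non-adaptive rate is the mean relative fixation probability
over the deleterious component,
$\omega_{na} = (1 - p_b)\, E[\,S/(1-e^{-S})\,]$, and the adaptive rate is
the remainder: $\omega_a = \omega - \omega_{na}$, with
$\alpha = \omega_a/\omega$ the proportion of adaptive substitutions.
Beneficial fixations — including weakly beneficial ones — are counted as
adaptive.  Divergence counts enter only through $\omega$; the likelihood
uses the SFS alone, so polymorphism estimates the DFE and divergence
calibrates the rates, the classical division of labor in this framework.

### Assumptions

Sites are treated as independent (free recombination), mutation is
Poisson at rate $\theta$ per site shared by the two classes, synonymous
sites are neutral, and the population is at demographic equilibrium.
Optional per-class multipliers $r_2..r_{n-1}$ (shared between synonymous
and nonsynonymous spectra, $r_1 \equiv 1$) absorb demography- or
ascertainment-driven distortions; an optional $\varepsilon$ mixes class
$i$ with class $n-i$ to model ancestral misidentification.  Both are off
by default: the synthetic data used for validation satisfy the equilibrium
assumptions, and every extra parameter slows the category-level bootstrap
considerably.

## From alignments to spectra

`build_spectrum()` walks the codon columns of an in-frame alignment
(ingroup sample + one outgroup row).  Rules, in order:

* codons containing `N` or gaps in the ingroup, or missing outgroup data,
  are excluded (`ingroup_missing` / `outgroup_missing`);
* genes with a premature stop codon are rejected outright; a terminal stop
  column is dropped silently;
* codons segregating at two or more nucleotide positions are excluded
  (`multi_hit`): with multiple hits the mutational pathway is ambiguous;
* at a single segregating position, three or more alleles
  (`multi_allelic`) or an outgroup allele matching neither ingroup allele
  (`polarization`) exclude the site;
* a polymorphic codon whose outgroup differs at a *different* position is
  counted as polymorphic only — the associated divergence is discarded
  rather than double-counted;
* monomorphic codons differing from the outgroup at one position become
  fixed differences, typed synonymous/nonsynonymous by the amino-acid
  change.

Opportunities are the frequency-weighted mean of the Nei–Gojobori
fractional counts across the ingroup sequences at each retained codon.
Sites observed in more chromosomes than the target sample size are
down-sampled hypergeometrically — randomly (seeded) or in expectation
(`project_site()`), the latter producing deterministic fractional spectra
convenient for regression tests.  Exclusion reasons are tallied on the
returned object.

## Numerical choices

* $G(S,i,n)$ uses 128-node Gauss–Legendre quadrature on $(0,1)$.  The
  integrand is polynomial-times-$h$; at $S=0$ the rule is exact for the
  Beta integral ($G = 1/i$), and across $|S| \le 100$ it agrees with a
  $10^5$-interval midpoint oracle to better than $10^{-4}$ relative error
  (asserted in the tests).
* The DFE integral uses a fixed 400-point log-spaced grid of coefficient
  magnitudes spanning $[10^{-4}, 10^5]$, per component.  Grid weights are
  renormalized to the density mass on the grid, so the integral is a
  proper expectation even for extreme shapes.  Because the grid is fixed,
  the $G$ matrices are computed once per sample size and cached; a
  likelihood evaluation is then two small matrix–vector products.
* $h$ and $Q(S) = S/(1-e^{-S})$ are evaluated in `expm1` form, with the
  $S < 0$ branch rewritten as $e^{-|S|x}(1-e^{-|S|(1-x)})/(1-e^{-|S|})$;
  both are stable to $|S| = 10^4$ and degrade gracefully beyond.
* Optimization is bounded L-BFGS-B in log-parameter space
  ($\beta \in [0.01, 10]$, $\bar S_d \in [10^{-2}, 10^6]$,
  $p_b \in [0, 0.5]$, $\bar S_b \in [10^{-2}, 10^3]$) over five
  deterministic starting points.  $\theta$ — and, when enabled, all $r_i$
  — are profiled out in closed form at every evaluation (the Poisson MLE
  of a shared scale is the ratio of total observed to total expected
  counts), so only the DFE shape parameters are optimized numerically.
* Bootstrap replicate fits warm-start from the category point estimate
  with a single start and a looser convergence tolerance
  (`factr = 1e9`); on identical data this reproduces the point estimate
  to three decimals and cuts replicate cost roughly tenfold.

## Categorization and testing

Covariates are discretized by `equal_count_bins()`: rank-based
equal-count categories, ties assigned to the lower-quantile side, with an
optional dedicated category for exactly-zero values — used for RSA, where
totally buried residues (RSA = 0) form their own class.  Residues are
called buried below RSA 0.05 (strictly) and exposed at or above it.
Disorder is flagged by the strict top quartile of disorder probabilities
across the whole proteome (linear-interpolation percentile).  Grantham
volume and polarity tables classify amino-acid changes as radical when
either index difference exceeds its cutoff; the cutoffs default to the
midpoint of each index's range and are configurable, since no canonical
value exists.

Per category, `bootstrap_categories()` resamples units (genes, or
gene-by-category cells of residue sites) with replacement, refits the DFE,
and `trim_replicates()` removes replicates whose DFE mean or shape falls
strictly outside the 1st–99th percentile band of that category (union over
the two parameters, applied per category) — the guard against the
occasional degenerate refit.  Summaries are means with percentile 95%
intervals.  Trends across ordered categories use Kendall's $\tau$ on
category means (`cor.test`, exact P without ties for small category
counts).  Two-category contrasts use the bootstrap statistic $k$: pair the
replicates (seeded random permutation by default; index pairing available
for regression tests), count differences below and above zero, let $k$ be
the smaller count (zeros split evenly), and take $P = (2k+1)/(N+1)$.
Families of pairwise tests are corrected by Benjamini–Hochberg FDR.
`ancova_partition()` decomposes the variance of category-level rates into
RSA, disorder and interaction terms by sequential sums of squares with RSA
entered first — matching the reading "RSA explains X% of the variation";
the term order is an argument.

`stratified_refit()` re-runs any scheme inside buried and exposed site
sets separately, the confound control that reveals when an apparent
covariate effect is a by-product of solvent exposure.

## The synthetic-data generator

Validation runs entirely on synthetic data with analytic ground truth.
`simulate_features()` draws gene lengths log-normal (median about 400
codons), expression log-normal with Spearman correlation $-0.3$ to length
(highly expressed genes are shorter), per-residue RSA from a zero-inflated
Beta with an 11% point mass at zero (the share of totally buried residues
in large structure-mapped data sets), secondary structure from a
persistent three-state Markov chain, and disorder rank-correlated $+0.3$
with RSA and elevated in loops.  `simulate_spectra()` draws SFS counts
independently per frequency class from the model's own Poisson
expectation, and divergence from $D_s \sim \mathrm{Pois}(\lambda L_s)$,
$D_n \sim \mathrm{Pois}(\lambda L_n \omega_{true})$ with synonymous
divergence rate $\lambda = 0.15$ per site; $\omega_{true}$,
$\omega_{na,true}$ and $\alpha_{true}$ are computed analytically from the
generating DFE, so recovery is a well-posed check of the estimator rather
than of a different stochastic process.  The default generating DFE is
Drosophila-like in magnitude: $\theta = 0.01$/site, $\beta = 0.3$,
$\bar S_d = 2000$, $p_b = 0.005$, $\bar S_b = 10$.

This count-noise model deliberately omits linked selection, demographic
non-equilibrium, and within-gene correlation of genealogies.  Passing
recovery tests therefore demonstrates correctness of the likelihood,
optimizer and pipeline plumbing — not robustness to demography or linkage,
which real data analyses must address with the $r_i$ multipliers and by
caution in interpretation.

`simulate_rsa_study()` assembles the full synthetic twin of a site-level
exposure analysis: residues are binned into 19 equal-count RSA categories
(with the RSA = 0 category) — matching the category counts used in
published residue-level analyses — gene-by-category cells of codon sites
become the resampling units, and the beneficial proportion $p_b$ is
planted either as a log-linear gradient across categories (default
10-fold from most buried to most exposed), as a two-level step at the
burial threshold, or flat (null).

## Problem sizes used in the tests

Single-fit recovery checks run at $L_s = 2\times10^6$, $L_n = 6\times10^6$,
$n = 20$, 20 seeds: median $|\hat\alpha - \alpha_{true}|$ is about 0.02
(tolerance 0.05), median shape error about 4% (tolerance 20%), and the
null-$\alpha$ median sits well inside $\pm 0.03$.  End-to-end trend
recovery uses $G = 2000$ genes, $n = 20$, 19 RSA categories and $B = 20$
bootstrap replicates per category for the trend (category means are stable
in $B$ well before the test statistic is), and $B = 100$ for the
two-category buried/exposed contrast where the granularity of
$P = (2k+1)/(N+1)$ depends directly on $N$.  These sizes keep a full
20-run trend experiment within a few minutes on one CPU while leaving the
per-category data (about 45,000 codon sites) at the scale of the
residue-level categories in real analyses.  At that scale the per-category
$\hat\omega_a$ has a standard deviation near 0.02 — an honest property of
the GammaExpo likelihood at $n = 20$ — which is why trend detection uses
many ordered categories rather than a single coarse split.

## Known limitations

* The GammaExpo beneficial component ($p_b$, $\bar S_b$) is weakly
  identified from $n = 20$ spectra; category-level $\omega_a$ estimates
  carry substantial variance, partially mitigated by trimming and by
  aggregating over categories in trend tests.
* The folded-SFS likelihood folds the expectation; polarization-error
  modeling ($\varepsilon$) and nuisance $r_i$ are available but not
  exercised by the default synthetic conditions.
* The generator's independence assumptions make bootstrap intervals
  approximately nominal by construction; on real data, gene-level
  resampling absorbs within-gene correlation but not genome-scale linkage
  disequilibrium.
* Only the Neutral, Gamma and Gamma-Exponential families are implemented;
  heavier-tailed alternatives are out of scope.

## A minimal run

```{r example, eval = FALSE}
st <- simulate_rsa_study(G = 500, n = 20, seed = 1, k = 8)
sc <- run_scan(st$spectra, st$units,
               list(scan_scheme("rsa", "rsa", k = 8, zero_special = TRUE,
                                unit = "site"),
                    scan_scheme("exposure", "exposure", unit = "site")),
               B = 50, seed = 1)
sc$table_continuous   # Kendall tau per estimator across RSA categories
sc$table_discrete     # buried vs exposed pairwise bootstrap contrasts
```
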
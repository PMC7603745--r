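---
title: "Simulating correlated traits with pleiosim: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating correlated traits with pleiosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiosim)
```

## The problem

Multivariate GWAS and genomic-selection methods claim to detect pleiotropy —
loci affecting several traits at once. Assessing those claims requires
benchmark data in which the causal loci (quantitative trait nucleotides,
QTNs) and their degree of pleiotropy are known exactly. `pleiosim` simulates
such data from biallelic marker matrices: real panels read from HapMap, VCF,
Plink ped/map or numeric files, or synthetic panels from the built-in
generator.

## Genetic model

Genotypes are coded $-1/0/+1$ (homozygote, heterozygote, other homozygote).
Three effect models map a genotype to a QTN contribution:

| genotype | additive | dominance | epistatic (pair $g_1, g_2$) |
|---------:|---------:|----------:|---------------------------:|
| $-1$     | $-a$     | $0$       | $e\,g_1 g_2$               |
| $0$      | $0$      | $d$       | (0 whenever either locus   |
| $+1$     | $+a$     | $0$       | is heterozygous)           |

The epistatic model is additive-by-additive: matching homozygotes contribute
$+e$, opposite homozygotes $-e$. A trait's genetic value is the sum of its
QTN contributions; the per-QTN contribution matrix is retained so the
variance explained by each QTN can be decomposed afterwards.

Effect sizes are supplied either explicitly (one vector per trait, largest
effect first) or as a per-trait geometric series base $b$, giving effects
$b^1, b^2, \dots, b^n$ for the $n$ QTNs in sampling order. The series is
1-indexed so that base $0.1$ yields a first effect of $0.10$, not $1$.

## Multi-trait architectures

* **Pleiotropy** — one QTN sample controls every trait; traits differ only
  through their effect vectors (and noise).
* **Partial pleiotropy** — a shared QTN set controls all traits; each trait
  additionally gets a disjoint trait-specific set
  (`add_QTN_num = list(shared = 4, specific = c(7, 9))` gives trait 1
  eleven QTNs, trait 2 thirteen, intersecting in exactly the four shared
  ones).
* **Spurious pleiotropy** — two traits with *disjoint* QTN sets that merely
  appear pleiotropic through linkage disequilibrium (LD, measured as the
  signed Pearson correlation $r$ of coded genotype scores — composite LD,
  appropriate for unphased inbred panels). In `indirect` mode each QTN slot
  gets a randomly drawn *linking marker*; its positional neighbourhood is
  scanned for one upstream and one downstream marker with
  $|r| \le$ `ld` against the linking marker; those become QTNs of trait 1
  and trait 2 respectively. In `direct` mode the ceiling constrains the
  paired QTNs themselves. Realized $r$ values are recorded in the LD
  summary table.

Two design choices deserve comment. First, the `ld` parameter is a
*ceiling* on $|r|$, not a target: among qualifying candidates we take the
one with $|r|$ closest to the ceiling, so the linking signal is as
informative as the constraint allows, but realized LD can sit well below
the input when the panel offers nothing stronger. Second, the candidate
scan is capped (default 50 markers each side, same chromosome) to bound
runtime; with block-structured LD the flanking QTNs therefore come from the
linking marker's physical neighbourhood, as they would in real data.
Spurious pleiotropy is implemented for exactly two traits with additive
QTNs, the geometry the architecture is defined for.

QTN eligibility can be restricted to a minor-allele-frequency window
`maf_above` $<$ MAF $<$ `maf_below`. Both bounds are exclusive — a marker
whose MAF equals a bound is rejected — which is the conservative reading of
"between" and the one that is cleanly testable. With no window, all
polymorphic markers are eligible. `vary_QTN` controls whether each
replicate ("experiment") re-draws QTNs or reuses one draw.

## Imposing genetic correlations exactly

Beyond the indirect correlation induced by shared QTNs with different
effects, a target correlation matrix $\Sigma'$ can be imposed on the
genetic values by a whitening/coloring transform: centre and scale the
genetic-value columns $Y$; compute their *sample* correlation
$\Sigma = LL^\top$ (lower Cholesky); whiten, $X = L^{-1}Y$; colour,
$Y' = L'X$ with $\Sigma' = L'L'^\top$; then restore each column's original
mean and standard deviation. Because $\Sigma$ is the sample correlation of
the very matrix being transformed, the realized correlation equals
$\Sigma'$ to machine precision — not just in expectation — and each trait
keeps its sample mean and variance. (Note the exponents: only
$X = L^{-1}Y$, $Y' = L'X$ makes $\mathrm{cor}(X) = I$ and
$\mathrm{cor}(Y') = \Sigma'$ hold; "square-root" variants of the factors do
not.) The transform needs $\Sigma$ positive definite, i.e. no collinear
genetic-value columns; the error message names the offending matrix.

## Heritability calibration and noise

Trait variance is dichotomized into genetic variance and the variance of
normally distributed non-genetic error. Given a target heritability $h^2$,
the residual variance is calibrated per replicate from the *sample*
variance of that replicate's genetic values,
$\sigma^2_e = \sigma^2_g (1 - h^2)/h^2$, which makes the realized
$h^2 = \mathrm{var}(G)/(\mathrm{var}(G) + \mathrm{var}(E))$ unbiased per
replicate rather than only asymptotically. Errors are independent across
traits by default; a residual correlation matrix `cor_res` is honoured by
colouring the standard-normal draws with its Cholesky factor. At
$h^2 = 1$ the error matrix is exactly zero and phenotypes equal genetic
values bit for bit.

Variance explained by each QTN is computed on the pre-transform scale
(before whitening/coloring, whose mixing would blur per-QTN attribution)
as $\mathrm{var}(\text{contribution}) / (\mathrm{var}(G)/h^2)$ — a
fraction of *phenotypic* variance, with the denominator being the genetic
variance inflated to the target heritability. A single-QTN trait therefore
explains exactly $h^2$ of its variance.

## Determinism and provenance

All randomness flows from one root seed through a documented derivation:
child seed $=$ (root $+ 1000003\,\mathrm{rep} + 7919\,\mathrm{stream})
\bmod (2^{31}-1)$, with separate streams for QTN selection, noise and
fixture generation. Toggling `remove_QTN` or an output format therefore
never perturbs the simulated values, and identical configuration plus root
seed reproduces every output file byte for byte. Outputs include: phenotype
files (GEMMA: headerless whitespace-separated columns; TASSEL trait
format; wide/long tables with replicate identifiers), the QTN map table
(replication, marker type, marker, alleles, chromosome, position, cM,
MAF), the LD summary table (linking marker, input LD, realized LD per
trait, QTN pair, LD between QTNs), per-QTN variance explained, per-replicate
seeds, the marker data with QTN columns removed (`remove_QTN = TRUE`;
linking markers are *kept* — they are the discoverable signal), and a log
comparing target with realized heritabilities and correlations.

## Marker input and numericalization

Letter-based formats are numericalized with a deterministic direction:
$+1$ is the homozygote of the alphabetically-second observed allele
(VCF: the ALT homozygote), heterozygotes are $0$. The direction is
recorded per marker; since every simulated architecture is sign-symmetric,
the choice affects only signs, never distributions. Multiallelic and
monomorphic markers are dropped at read time with recorded counts
(monomorphic markers cannot be QTNs and break MAF/LD computation); missing
calls are imputed to $0$ — the mean-like, direction-free value — with a
recorded count, so genetic values are defined for every individual. The
package does not phase, impute beyond mean-fill, or handle structural or
multiallelic variants; Plink binary bed and GDS readers are out of scope
(ped/map text is supported).

## The fixture generator

`make_fixture()` emulates a diversity-panel genotype matrix (hundreds of
individuals by thousands of markers) via a latent-haplotype mosaic: each LD
block shares a latent binary haplotype indicator of frequency $0.5$, and
each block marker copies it with flip probability $(1 - \sqrt{|r|})/2$,
giving pairwise within-block genotype correlation near the target $r$
(exact for symmetric allele frequencies; realized mean $|r|$ is within
about $0.1$ of the target at $n \ge 200$). Background markers are
independent with allele frequencies drawn uniformly or U-shaped
(Beta(0.35, 0.35)) inside `maf_range`. A fraction `inbred_fraction`
(default 1, matching inbred diversity panels) of individuals carries two
identical haplotypes and hence no heterozygous calls; the remainder pairs
independent haplotypes so dominance and heterozygote paths are exercised.

What the generator does *not* emulate: coalescent genealogy, LD decay with
physical distance, population structure, selection, genotyping error.
Passing tests on fixtures therefore demonstrate the correctness of the
simulation machinery — selection constraints, effect arithmetic, exact
correlation recovery, calibration — not robustness to every property of
real panels.

## Problem sizes and numerical tolerances

The test suite exercises: correlation recovery to $10^{-10}$ at $n = 280$
for 2, 3 and 5 traits (exactness is algebraic, so the tolerance is close to
accumulated floating-point error); heritability recovery at target 0.5
within 0.02 of the mean over 1,000 replicates of a 280 × 5,000 panel (the
binomial-like Monte-Carlo error of that mean is an order of magnitude
smaller); LD-ceiling and MAF-window invariants over 100 replicates each.
These sizes mirror a typical maize diversity panel and keep the full suite
under a minute on one core.

## A worked example

```{r, eval = FALSE}
g <- make_fixture(280, 5000,
                  ld_blocks = data.frame(n_markers = rep(15, 40),
                                         r = rep(0.6, 40)),
                  seed = 1)
sim <- create_phenotypes(
  g, architecture = "spurious_pleiotropy", ntraits = 2, add_QTN_num = 3,
  add_effect = list(c(0.2, 0.1, 0.05), c(0.3, 0.2, 0.1)),
  h2 = c(0.5, 0.5), ld = 0.7, type_of_ld = "indirect",
  rep = 10, vary_QTN = TRUE, seed = 165, out = "sim_out",
  output_format = c("gemma", "wide_table"), remove_QTN = TRUE
)
sim
sim$ld_summary
```

## Known limitations

No background polygenic term or non-genetic covariates (trait variance is
strictly QTN variance plus residual); no dominance-by-dominance or
additive-by-dominance epistasis; no per-replicate correlation targets; the
spurious architecture is two-trait; realized genetic correlation under the
*indirect* (shared-QTN) route is an emergent quantity, not a controlled
one — use `cor` when an exact value is needed.
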
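# pleiosim

Simulation of pleiotropic, linked and epistatic quantitative traits from
biallelic marker data, for benchmarking multivariate GWAS and genomic
selection methods.

Testing whether a multi-trait method truly detects pleiotropy requires data
in which the causal loci are known. `pleiosim` takes a genotype matrix
(real or synthetic) and simulates traits controlled by additive, dominance
and additive×additive epistatic quantitative trait nucleotides (QTNs) under
three multi-trait architectures:

* **pleiotropy** — the same QTNs control every trait;
* **partial pleiotropy** — a shared QTN set plus disjoint trait-specific
  sets;
* **spurious pleiotropy** — disjoint QTN sets per trait that only appear
  shared because each is in linkage disequilibrium (LD) with a common
  linking marker (indirect mode), or with each other (direct mode), subject
  to a user ceiling on |r|.

## Model

Genotypes are coded −1/0/+1. A QTN contributes `−a/0/+a` (additive),
`0/d/0` (dominance), or `e·g₁·g₂` for an epistatic pair. Effect sizes are
explicit vectors or a geometric series `bⁱ` (base 0.4 → 0.40, 0.16, …).
Trait variance is genetic variance plus normal residual variance calibrated
from the target heritability, `σ²ₑ = σ²_g (1 − h²)/h²`. A target genetic
correlation matrix Σ′ is imposed *exactly* on the genetic values by a
Cholesky whitening/coloring transform (whiten with the inverse Cholesky
factor of the sample correlation, colour with the Cholesky factor of Σ′);
residual correlations are optionally imposed on the noise. All randomness
derives from one root seed, and identical configurations reproduce every
output file byte for byte.

## Worked example

```r
library(pleiosim)

# synthetic diversity panel: 280 inbred lines x 5000 SNPs with LD blocks
g <- make_fixture(280, 5000,
                  ld_blocks = data.frame(n_markers = rep(15, 40),
                                         r = rep(0.6, 40)),
                  seed = 1)

sim <- create_phenotypes(
  g, architecture = "spurious_pleiotropy", ntraits = 2, add_QTN_num = 3,
  add_effect = list(c(0.2, 0.1, 0.05), c(0.3, 0.2, 0.1)),
  h2 = c(0.5, 0.5), ld = 0.7, type_of_ld = "indirect",
  rep = 10, vary_QTN = TRUE, seed = 165
)
sim
#> pleiosim simulation: spurious_pleiotropy, 2 traits, 10 replicates
#>   realized h2 (mean): 0.496, 0.497
#>   realized genetic cor (mean, upper tri): 0.042

head(sim$ld_summary, 3)
#>   Replication Marker_causing_LD input_LD Actual_LD_with_QTN_of_Trait_1
#> 1           1          snp02592      0.7                    -0.1677804
#> 2           1          snp01632      0.7                    -0.1400014
#> 3           1          snp01352      0.7                    -0.1566013
#>   Actual_LD_with_QTN_of_Trait_2 QTN_for_Trait_1 QTN_for_Trait_2 LD_between_QTNs
#> 1                     0.1196005        snp02544        snp02637     -0.07284644
#> 2                     0.1621103        snp01624        snp01643     -0.03217953
#> 3                    -0.1402279        snp01310        snp01381     -0.04364358
```

Each replicate's two traits recover the configured heritability of 0.5 on
average; the LD summary records, per QTN slot, the linking marker, the
ceiling supplied as input, and the realized signed r between the linking
marker and each trait's QTN — all within the 0.7 ceiling, and well below it
when the panel offers no stronger pair, exactly as with real marker data.
Each trait's QTN sets are disjoint, so any joint association at the linking
marker is spurious by construction.

Passing `out = "dir"` additionally writes phenotype files (GEMMA-style
headerless columns, TASSEL trait format, wide/long tables), the QTN map and
LD provenance tables, per-QTN variance explained, per-replicate seeds, a
log comparing target with realized statistics, and (with
`remove_QTN = TRUE`) the marker data without the causal SNPs.

Real marker data come in with
`read_genotypes(path, format = c("numeric", "hapmap", "vcf", "plink_ped"))`.

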
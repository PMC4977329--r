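# pedblock

Consistent, phased, multi-allelic haploblock genotypes for every individual
in a pedigree, derived from phased SNP (or SSR) marker data.

## The problem

In multi-founder, multi-generation pedigrees — crop breeding programs are
the archetype — individual bi-allelic SNPs carry little information, and
scoring errors, missing calls and phasing slips corrupt identity-by-descent
inference and QTL mapping. Treating a set of closely linked, map-contiguous
markers as one multi-allelic locus (a *haploblock*) compresses the data,
makes inheritance legible to the human eye, and exposes errors as Mendelian
conflicts. `pedblock` performs the final step of that workflow: given a
linkage map, haploblock definitions, a pedigree and phased marker genotypes,
it assigns every individual a consistent pair of numbered haploblock
alleles, imputing missing marker data and rejecting conflicting data on the
way.

The core assumption is that no recombination occurs within a block across
the pedigree, so each transmitted gamete carries one parental block
haplotype in its entirety. Writing $a \sim b$ when two marker-haplotype
vectors never disagree at a co-observed marker and share at least one
observed value (*compatible*), the engine decomposes the pedigree into
half-sib families (all gametes transmitted by one parent), groups each
family's transmitted haplotypes into compatibility classes, confronts the
class consensuses with the two parental alleles, and iterates over families
— largest first, with immediate updates — until the configuration is stable
or recurs. Conflicts resolve by imputation, by deleting the differentiating
marker data, or by rejecting an allele entirely; every mutation is logged.
A family of 15+ members whose transmitted haplotypes form a single class
marks its parent homozygous; smaller families are resolved conservatively,
merging a child's haplotype with a parental allele only when the child's
data conflict with the *other* parental allele (proof of which gamete it
received).

## Worked example

Simulate a four-founder, two-generation pedigree (30 individuals, 3 blocks
of 6 markers) with 15% missing calls and no genotyping errors, then assign
haploblock genotypes and score the result against the hidden truth:

```r
library(pedblock)

sim <- simulate_dataset(sim_config(n_founders = 4, n_generations = 2,
                                   n_blocks = 3, missing_rate = 0.15,
                                   error_rate = 0, seed = 42))
fit <- assign_haploblocks(sim$data)
fit
#> Haploblock assignment: 3 block(s), 30 individuals
#>   converged: 3  cycle-converged: 0  not converged: 0
#>   missing haploblock alleles: 0.0%
#>   diagnostics logged: 110 event(s)

evaluate_assignment(fit, sim)
#> Assignment evaluation against truth:
#>   imputed correct : 167
#>   imputed wrong   : 0
#>   still missing   : 8
#>   consistency violations (converged blocks): 0
#>   informative meioses: 54.8% per marker, 94.8% per block
```

All three blocks converge; of the 175 corrupted marker calls the engine
recovers 167 exactly, invents nothing (0 wrong — with no genotyping errors,
every write is implied by the data plus the no-recombination assumption),
and leaves 8 genuinely undecidable calls missing. The consistency audit
confirms that every assigned child allele matches a parental allele. The
informativeness contrast (95% of meioses informative per block versus 55%
per single marker here) is the reason to work with haploblocks at all.

The genotype table and per-block allele catalog are plain data frames:

```r
head(fit$genotypes[fit$genotypes$block == "B01", ], 5)
#>   individual block allele_mat allele_pat
#> 1        F01   B01          1          2
#> 2        F02   B01          3          4
#> 3        F03   B01          5          6
#> 4        F04   B01          7          1
#> 5     G1_001   B01          2          4

fit$catalogs$B01[1:4, ]
#>   allele B01M1 B01M2 B01M3 B01M4 B01M5 B01M6
#> 1      1     B     B     A     B     B     B
#> 2      2     A     B     B     A     B     B
#> 3      3     A     A     B     B     A     A
#> 4      4     A     B     B     A     A     B
```

`write_outputs(fit, dir)` writes the haploblock genotype table, the allele
composition table, the imputed phased marker genotypes and a Pedimap-style
pedigree+genotype file; `write_diagnostics()` dumps the event log. File
workflows (and a thin command-line front end in `inst/scripts/pedblock`) are
covered by `run_simulate()`, `run_assign()` and `run_evaluate()`.

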
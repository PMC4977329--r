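---
title: "Consistent phased haploblock genotypes in pedigrees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistent phased haploblock genotypes in pedigrees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedblock)
```

## The problem

High-density SNP platforms genotype breeding pedigrees at thousands of
bi-allelic markers. Individually these markers carry little information: in a
multi-founder pedigree, identity-by-descent of a chromosome segment is much
easier to follow (by software and by eye) when several closely linked,
map-contiguous SNPs are condensed into a single multi-allelic locus — a
*haploblock* — whose alleles are the distinct SNP haplotypes segregating in
the pedigree. `pedblock` takes phased marker data, a linkage map, haploblock
definitions and a pedigree, and assigns every individual a consistent, phased
pair of numbered haploblock alleles, imputing missing marker calls and
detecting (and removing) conflicting ones along the way. Phasing itself and
the choice of block boundaries are upstream steps performed by other tools;
here they are inputs.

The key modelling assumption is that **no recombination occurs within a
haploblock across the pedigree**. A transmitted gamete therefore carries one
of the parent's two block haplotypes in its entirety, which turns block-level
inheritance into a discrete constraint-satisfaction problem. Recombination
within a block is tolerated only in the final generation, where the
recombinant allele is expected to surface as a conflict and be replaced by
missing data rather than propagate.

## Haploblock alleles and their algebra

For one block with $K$ markers, a *haploblock allele* is a length-$K$ vector
of marker allele codes, any of which may be missing. Three primitive notions
drive everything:

* two alleles are **incompatible** when some marker is observed in both with
  different codes;
* **compatible** when they never conflict and share at least one observed,
  equal code;
* **disjoint** when no marker is observed in both.

The **consensus** of a set of pairwise non-conflicting alleles is the
positionwise union: the observed value wherever any member has one. Each
distinct observed sequence (including partially missing ones) receives its
own allele number, dense from 1 in order of first appearance over individuals
in pedigree order (maternal haplotype before paternal). Because alleles that
differ only in missing data receive different numbers, the
`include_missing_count_in_names` option appends `_m<k>` (with `k` missing
markers) to allele names so such cases are visible in output tables.

## The half-sib family engine

The pedigree is decomposed into **half-sib (HS) families**: one family per
parent, whose members are the (individual, slot) pairs that inherited a
gamete from it — the maternal slot of each of its offspring as a mother, the
paternal slot as a father, both slots under self-fertilization. Families are
processed in order of decreasing size (ties: alphabetical parent id), so the
most informative families act first.

Processing one family starts by **grouping** the members' alleles: groups
are grown greedily, seeding with the allele observing most markers; a member
joins the unique group whose consensus it is compatible with, conflicts with
every group seed a new one, and members compatible with two or more
consensuses — ambiguous due to missing data — stay ungrouped, as do members
sharing no observed marker with any group. A final sweep re-tests ungrouped
members against the finished consensuses. The resulting group consensuses
are pairwise incompatible; at most two groups can be real (a parent has two
alleles), so more than two indicate errors and only the two best-supported
groups are retained (ties broken by observed-marker count, then seniority).

The group consensuses are then confronted with the two parental alleles:

* **One group in a family of at least `homozygous_family_min` members
  (default 15):** the parent is presumed homozygous. Parental alleles are
  merged with the progeny consensus when they do not conflict with it; a
  parental allele conflicting with each other parental allele (but not the
  progeny) has the differentiating marker data deleted; a parental allele
  conflicting with the progeny consensus is rejected outright (all its
  marker data set missing). The resulting updated consensus is imputed into
  the parent and all progeny slots. With 15+ members all in one group, a
  truly heterozygous parent would require every cross-allele pair of
  offspring to have mutually masked differences — vanishingly unlikely,
  which is what justifies the default threshold.
* **One group, smaller family:** homozygosity cannot be presumed, and the
  single group may in truth mix gametes from both parental alleles whose
  differences happen to be masked by missing data. The engine therefore only
  merges a progeny slot with a parental allele when the slot's data
  *conflict with the other parental allele* — positive proof of which gamete
  was received. If both parental alleles conflict with the progeny
  consensus, the side with less weight loses: the parental alleles are
  rejected when the group reaches `min_group_support` members, otherwise the
  conflicting progeny data are removed.
* **Two groups:** the parent is treated as heterozygous. Each parental
  allele is matched to the unique group consensus it is compatible with
  (compatible with both: left undecided this round; conflicting with both:
  rejected). Matched pairs are merged and written back to the parent and to
  the group members proven (again by conflict with the other parental
  allele) to carry that gamete. A group with no matching parental allele is
  promoted into a free parental slot when at least `min_group_support` of
  its members carry that proof. Ungrouped members are ambiguous between the
  two transmitted alleles; their distinguishing data are treated as missing,
  keeping only marker values obligate under both parental alleles.
* **A fully observed homozygous parent** forces its allele on every
  transmitted slot directly; conflicting progeny data are removed (and
  re-imputed with the parental allele on a later pass). A parent whose
  alleles are entirely missing alongside progeny in two supported groups is
  rebuilt from the progeny, one group per parental slot, using the same
  proof rule.

Two closing steps run for every family: progeny slots conflicting with
*both* current parental alleles are blanked (such a slot cannot have been
transmitted), and marker values on which both parental alleles agree are
imputed into missing progeny positions (they are transmitted regardless of
which gamete was passed).

The published description of this method spells out the large-family
homozygous cases and leaves the smaller-family and multi-group chains as
implementation detail decided by "quantitative considerations". The
proof-based completion above is this package's own design. It was chosen to
make the engine *conservative under missingness*: when genotyping errors are
absent, every value the engine writes is implied by the data plus the
no-recombination assumption (up to the deliberately probabilistic 15-member
homozygosity rule), so pure missing data can never cause a wrong imputation.
The test suite asserts exactly this property on error-free simulations. The
price is that some theoretically recoverable imputations (e.g. rebuilding
both alleles of an ungenotyped parent from few, mutually masked offspring)
are forgone because they would be guesses.

## Iteration, convergence, cycles

Families are processed one by one; changes take effect immediately, so later
families in a pass see updates from earlier ones. After each pass the
pass-level consistency sweep blanks any slot conflicting with both of its
parental alleles, so every end-of-pass configuration is parent-offspring
consistent. Passes repeat until

* a pass changes nothing (`CONVERGED`);
* an end-of-pass configuration recurs (`CYCLE_CONVERGED`) — with
  conflicting evidence the engine can enter a deterministic delete/re-impute
  loop, in which case the recurring configuration is kept (because every
  end-of-pass state is already consistent, re-running the engine on the
  returned state reproduces it exactly); or
* `max_iter` passes elapse (`MAX_ITER`): the block's genotypes are all set
  missing and a `NON_CONVERGENCE` diagnostic is written. Genotypes are only
  assigned for blocks that converged.

Because most individuals belong to two families and parent one, data deleted
while processing one family are routinely re-imputed later from the other
side of the pedigree; this is why iteration, not a single sweep, is needed.

Blocks are processed independently of each other; the allele catalog is
rebuilt from the converged configuration, so imputation can merge alleles
that initially differed only in missing data.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `homozygous_family_min` | 15 members | family size at which a single progeny group implies a homozygous parent |
| `min_allele_count` | 3 haplotypes | minimum occurrences of every observed allele of a polymorphic marker; rarer markers are rejected before assignment |
| `max_iter` | 100 passes | iteration cap per block |
| `min_group_support` | 2 members | support needed to promote an unmatched progeny group to a parental allele, or to let progeny outvote conflicting parents |
| `include_missing_count_in_names` | off | append `_m<k>` to allele names |

The marker filter counts haplotype occurrences (two per diploid individual),
the most literal reading of an "occurrences of marker alleles" threshold.
Monomorphic markers are retained — they cannot create conflicts — and
rejected markers are removed from their block definition entirely rather
than per individual, keeping the allele catalog well defined; a block losing
all markers is dropped with a diagnostic.

## The gene-drop simulator

Because real multi-generation datasets of this kind are proprietary, the
package ships a simulator that emulates exactly the four input tables plus a
hidden truth set. A deterministic pedigree (founders, then round-robin
crosses; the final generation includes a selfed offspring and one offspring
with unknown father when the parental generation has at least four members)
is populated by gene drop: founder haplotypes drawn marker-wise (allele
`"A"` with probability `founder_allele_freq`, default 0.5), each
transmission copying one whole parental block haplotype, optionally spliced
at a uniform breakpoint in the final generation. Observed data are the truth
corrupted by per-call missingness (`missing_rate`) and symmetric allele
flips (`error_rate`); the error model is a uniform draw among the marker's
other symbols, since the data sources it mimics (array scoring errors)
motivate no particular structure. A slot whose parent is unknown receives a
fresh founder-style haplotype.

What the simulator does *not* emulate: linkage disequilibrium between
blocks, realistic recombination maps, selection, genotyping artefacts with
structure (null alleles, batch effects), or phasing errors (inputs are
assumed phased; a phase error manifests like two coordinated scoring
errors). Passing tests on simulated data therefore demonstrate the
engine's combinatorial correctness under the stated model, not robustness
to every artefact of a real array dataset.

The standard validation battery (`sim_battery_configs()`) holds 50 seeded
scenarios spanning 2-4 generations (about 65-190 individuals), 20 blocks of
6 markers, missing rates 0.05-0.2 and error rates 0-0.02, half of them
error-free. These sizes keep a full battery (simulate, assign, evaluate,
idempotence re-run) around two minutes on one CPU while covering family
sizes from one to dozens of members.

## Evaluation metrics

* `imputation_accuracy()` classifies every call that was missing or wrong in
  the observed data: recovered correctly, imputed wrongly, or still missing.
* `consistency_audit()` counts (child, slot, block) combinations whose
  allele matches neither allele of a fully genotyped transmitting parent.
  Without a catalog the comparison is by allele number — the strict view,
  under which alleles differing only in missing data count as different
  (such apparent inconsistencies are an acknowledged residue of sparse
  data). Given the fit's catalogs, a violation requires a genuine marker
  conflict with both parental alleles; on converged blocks the engine
  guarantees zero such violations, and the acceptance suite verifies it
  across the battery.
* `informative_fraction()` reports the fraction of meioses informative at
  marker and at block level. A *meiosis* is one (child, slot) transmission
  whose parent has two not-entirely-missing block haplotypes; it is
  informative when the parent is heterozygous at the locus considered. Both
  levels share that denominator, so within a block no marker can beat the
  block and the block-level mean dominates the marker-level mean whenever
  blocks have equal width — the qualitative advantage of haploblocks over
  single SNPs that motivates the method. On the battery conditions the
  means are roughly 42% per marker versus 88% per block; the exact values
  are functions of the simulated allele frequencies and pedigree shape.

## Numerical and degenerate-input choices

* Ties everywhere are broken deterministically (family size, then parent
  id; observed-marker count, then member id; group size, then consensus
  observedness, then seniority), so results are reproducible run to run.
* Cycle detection stores one digest per end-of-pass configuration and
  compares full states only via their digests (states are small strings;
  collisions are not a practical concern at these sizes).
* `max_iter = 0` is allowed and marks every block non-converged — useful for
  smoke-testing pipelines.
* An empty pedigree, a childless pedigree, or a block left without markers
  all produce empty-but-well-formed outputs rather than errors.
* Self-fertilization contributes one family member per slot, so a selfed
  offspring counts twice toward its parent's family size; whether the
  original method counts once or twice is unstated, and counting
  transmissions (not individuals) matches the engine's gamete-level logic.
* Unknown parents may be written as `0` or an empty field in pedigree files.

## Known limitations

* The engine is combinatorial, not probabilistic: it never weighs competing
  imputations by likelihood, and data it cannot prove are left missing or
  removed. Likelihood-based phasing/imputation tools solve a different
  problem (and are expected upstream).
* Mid-pedigree recombination within a block violates the core assumption;
  it surfaces as conflicts, mass missingness, or (rarely) a non-converged
  block — it is detected, not repaired.
* Genotyping errors in a parent that are consistent with its progeny (or
  errors in large masked sets) can still propagate; with error rates around
  2% a small fraction of imputations is wrong, concentrated in
  cycle-converged blocks.
* The FlexQTL and Pedimap output dialects are reduced to documented
  tab-delimited equivalents; byte-level compatibility with those tools'
  readers is not attempted.
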
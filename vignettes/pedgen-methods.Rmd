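---
title: "Methods: pedigree and genomic diversity analysis with pedgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree and genomic diversity analysis with pedgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedgen)
```

## Scope

`pedgen` implements the standard monitoring toolkit for genetic diversity in
a closed livestock population — the kind of analysis run for local breeds
such as the Tropical Milking Criollo cattle of Mexico, where a herd book of
a few thousand animals coexists with a few dozen medium-density SNP
genotypes. It covers pedigree inbreeding and relatedness, pedigree-depth
diagnostics, probability-of-gene-origin parameters, realized effective
population size, genomic inbreeding (GRM diagonal and runs of
homozygosity), ROH-island scanning, estimator comparison, and a
gene-dropping simulator that supplies identity-by-descent ground truth so
that every stage can be validated without access to confidential herd data.

## Pedigree model

A pedigree is a set of animal records with optional sire/dam links
(unknown parents coded `"0"` by default, configurable). Parents referenced
but never listed are materialized as founder records, matching how
herd-book extracts behave. All recursions run over an internal dense
renumbering in topological order (every parent precedes its offspring);
cycles are rejected with a named offender.

**Inbreeding.** `inbreeding_ml()` computes `F` — the probability that the
two alleles at a locus are identical by descent — by ancestor tracing
through the `A = L D L'` decomposition of the numerator relationship
matrix, in linear memory. The dense tabular method
(`relationship_matrix()`) is retained as an independent oracle; the test
suite checks exact agreement (`< 1e-12`) on hundreds of random pedigrees.
An animal with an unknown parent has `F = 0`: no correction for
unknown-parent groups is attempted (out of scope).

**Average relatedness.** `AR_i` is the mean of row `i` of `A` divided by
two — the chance that a random allele from the whole pedigree traces to
animal `i`. It is computed indirectly (gene-flow passes through `T` and
`D`), and always over the *whole* pedigree file even when a reference
subset is analyzed, because that is the definition's population.

**Depth metrics.** Equivalent complete generations
`EqG = sum (1/2)^n` over known ancestors; maximum (`maxg`) and complete
(`comg`) generations traced; and a MacCluer-style completeness index:
per parental line, `C_L(d)` averages the proportion of known ancestors
over generations `1..d`, and `PCI(d)` is the harmonic mean of the sire and
dam lines — zero when either parent is unknown, however deep the other
line is. `comg` uses the standard "all `2^g` ancestors known at depth `g`"
definition.

**Generation intervals.** A (parent, offspring) pair counts on a path only
when the offspring itself reproduced, and the path (sire–sire, sire–dam,
dam–sire, dam–dam) is decided by the offspring's *role* — whether it
appears as a sire or a dam of some record — rather than its recorded sex
code, which may be missing. Intervals are in whole years (the pedigree
carries birth years, not dates). The overall interval defaults to the
count-weighted mean across the four paths (the "Total" row convention of
published tables); the plain four-path average is available with
`weighted = FALSE`.

**Rate of inbreeding and Ne.** The individual increase in inbreeding is
`dF_i = 1 - (1 - F_i)^(1/(EqG_i - 1))`, and `Ne = 1/(2 mean(dF))`.
Animals with `EqG <= 1` (founders and unknown-parent animals) are excluded
from the mean by default — `dF` is undefined for them; an
`include_all = TRUE` mode averages them in as zeros since the source
methodology is silent on this point. If no animal qualifies, `Ne` is `NA`.

## Probability of gene origin

`founder_contributions()` traces expected gene flow upward from the
reference population: each reference animal starts with weight `1/N`, half
of a node's weight goes to each parent, and weight is absorbed at founders.
An animal with exactly one unknown parent contributes a distinct *phantom
founder* for that side, which keeps `sum(q) = 1`; the effective number of
founders is Lacy's `Fe = 1/sum(q^2)`.

`ancestor_contributions()` implements the iterative greedy extraction of
ancestors with the largest *marginal* contribution. Two pieces of
bookkeeping matter, and both were validated by property tests on random
pedigrees (`sum(p) = 1` after full extraction, selection values
non-increasing):

* gene flow stops at already-selected ancestors (their parent links are
  effectively severed), so genes explained by an earlier ancestor are not
  re-attributed to nodes above it;
* a candidate's flow is multiplied by one minus the fraction of its *own*
  genome already explained by selected ancestors (or selected phantom
  sides). Without this downward discount, extracting a descendant of an
  already-selected ancestor double-counts.

Self-explanation is excluded for non-founders: a reference animal's own
genome must be explained by its ancestors, not by itself (otherwise the
trivial solution "each reference animal explains itself" would make the
effective number of ancestors meaningless). Reference founders do absorb
their own weight — no ancestor exists. Phantom sides are selectable, so
the residual converges to zero and the number of ancestors explaining 50%
is always reachable. Ties are broken by the smallest internal
(topological) index and are deterministic.

`Fa = 1/sum(p^2)` over all extracted ancestors; bottlenecks drive
`Fa` below `Fe` (asserted on the bottleneck fixture where `Fe = 4`,
`Fa = 8/3` exactly).

## Genotypes and QC

PLINK text (`PED`/`MAP`) and binary (`BED`/`BIM`/`FAM`, SNP-major, magic
bytes `6c 1b 01`) filesets are read and written natively; dosages count the
A1 allele. In text files allele identity is not declared, so A1 is the
alphabetically first observed allele — deterministic, and stable under
round trips whenever both alleles are observed.

QC follows single-breed practice: drop non-autosomal or unmapped SNPs
(29 autosomes by default, configurable), then SNPs with call rate < 0.90,
then animals with call rate < 0.90 — and **no** minor-allele-frequency
filter, because monomorphic stretches are exactly the homozygosity signal
of interest. The SNP-then-animal filter order is a documented choice (the
source methodology is silent); all counts are logged so the alternative
order's effect is visible.

## Genomic inbreeding

**GRM.** `grm_yang()` builds Yang's SNP-based relationship matrix with
pairwise-complete missing handling and sample allele frequencies by
default (no external base-population frequencies usually exist for local
breeds). `FGRM = diag(G) - 1` ranges from −1 (maximally heterozygous
relative to the assumed frequencies) upwards, and is sensitive to those
frequencies — with sample frequencies the mean FGRM is slightly negative
by construction, which is the usual explanation for negative published
means. Supplying true base-population frequencies (as the simulator can)
makes it unbiased; the acceptance suite asserts the hand-computable
diagonal values at `p = 0.5` and a mean within 3 SE of zero on a
Hardy–Weinberg founder population with known frequencies.

**ROH.** `detect_roh()` is a sliding-window detector: 20-SNP windows, a
window is homozygous when it has at most 0 heterozygous and 1 missing
calls; a SNP is in-run when the fraction of homozygous windows covering it
reaches 0.05; maximal in-run stretches are split at inter-SNP gaps over
1 Mb and filtered on at least 15 SNPs, 1 Mb length, and 1 SNP / 1000 kb
density. The window allowances, coverage threshold and minimum SNP count
are not stated by the source methodology; the defaults are the documented
defaults of the commonly used detection package and all are exposed in
`roh_params()` and recorded in every output header. One deliberate
convention: the coverage comparison is *inclusive* (`>=`), so the default
0.05 with 20-SNP windows means exactly "covered by at least one homozygous
window" — this is also what makes the detector provably equivalent to a
brute-force enumerator of homozygous stretches, which the acceptance suite
checks on 1000 randomized small panels.

**FROH.** `froh()` uses `F_ROH = L_ROH / L_AUT` with `L_AUT` the
SNP-covered span (first-to-last SNP per chromosome) — the convention under
which a fully homozygous animal attains `FROH = 1`. Length-restricted
columns (`FROH >= 1, 2, 4, 8, 16 Mb`) are non-increasing in the threshold
by construction; length classes are half-open and lower-inclusive
(`[1,2), [2,4), [4,8), [8,16), [16,Inf)` Mb), so a 2.0 Mb run falls in the
2–4 class and the `>= k Mb` columns align with the class bins.

**Islands.** Per-SNP incidence is the percentage of animals whose runs
cover the SNP; islands are maximal consecutive stretches with incidence
*strictly above* the threshold (50% by default, so exactly 50% is not a
member). Gene annotation is a plain coordinate-overlap join against a
user-supplied interval file; no external databases are consulted.

**Estimator comparison.** Pearson correlations among FPED, FGRM and the
FROH columns, with two-sided p-values from the t transformation on
`n - 2` df and the conventional `ns/*/**/***` codes at 0.05/0.01/0.001,
no multiple-testing correction, listwise deletion for missing values with
`n` reported.

## The simulator: what it emulates, and what it does not

`simulate_pedigree()` builds discrete-generation pedigrees under four
mating schemes (random, circular, repeated full-sib line, sire
bottleneck), assigns birth years by generation, records true `F` on the
*complete* pedigree, and only then erases parent links at the configured
rate — so pedigree-based estimates can be compared against truth under
realistic incompleteness. Default scale (founders from 1956, ~7-year
generation spacing) mirrors a mid-20th-century closed nucleus herd;
genome defaults (five 100-Mb autosomes, 1000–2000 SNPs each, uniform
1 cM/Mb recombination, founder MAF uniform on [0.05, 0.5]) are a
deliberately simplified bovine-like genome at a desk-testable scale.

One scheme detail: `sire_bottleneck` mates the founder generation randomly
and bottlenecks from the second generation on. If the founder generation
is also sired by a single founder, that founder's expected contribution
ties the bottleneck sires' at exactly 0.5 and the deterministic tie-break
selects the founder, collapsing `Fa` back to `Fe`; starting from a diverse
founder background makes the bottleneck ancestor detectable, which is the
scheme's purpose.

`gene_drop()` assigns two uniquely labeled chromosomes per founder and
transmits them with Haldane (Poisson, no interference) crossovers.
Realized autozygosity — the genome fraction where both haplotype labels
share founder origin — is the ground truth that pedigree `F` only predicts
in expectation. SNP alleles are painted onto founder haplotypes from
per-SNP frequencies, so homozygous stretches arise mechanistically from
IBD, not from a tuned ROH generator.

What a green test does **not** establish: the simulator has no realistic
linkage-disequilibrium structure, no mutation, no selection on phenotypes,
no sex chromosomes, and uniform recombination; published magnitudes from
real herds (e.g., a 10.9% mean FROH) are data-dependent and are *not*
targets. Validation claims are therefore of the parameter-recovery kind:
FROH correlates > 0.9 with true autozygosity on dense maps; cohort mean
autozygosity matches pedigree F within Monte-Carlo error (with standard
errors clustered by family, because sibs share parental meioses); founder
origin fractions match expected contributions `q`.

## Numerical choices and degenerate inputs

* `%` inbred counts `F > 1e-12` (floating-point guard for "F > 0").
* Boichard extraction stops at residual `< 1e-10` or `max_ancestors`.
* Zero-variance estimator columns yield `NA` correlations with a warning;
  fewer than 3 complete observations is an error.
* All-monomorphic panels, empty post-QC panels, empty reference sets, and
  infeasible mating schemes raise immediate errors rather than NA results.
* Chromosomes with fewer SNPs than one window are skipped and logged.
* 1 Mb means 1,000,000 bp everywhere; segment length is `end − start + 1`.
* Every randomized routine takes an explicit seed; identical seeds give
  byte-identical outputs, which the tests assert.

## Known limitations

Pedigree error correction, parentage inference, unknown-parent groups,
VanRaden-flavoured GRMs, imputation, exact-date generation intervals, and
gene-function interpretation of islands are out of scope. The PED text
format cannot preserve allele identity for SNPs where only the reference
allele is absent; binary BED round trips are exact.
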
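---
title: "Methods: exact two-library testing and sex-biased gene classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact two-library testing and sex-biased gene classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segdig)
```

## The problem and the design

`segdig` analyses a replicate-free RNA-seq design common in developmental
studies of gonochoristic fish: two genotype groups (XX females and XY males)
sequenced once each at several developmental stages — in the standard design,
5, 30, 90 and 180 days after hatching (dah), eight libraries in all. With one
library per group per stage there is no within-group variance to estimate, so
differential expression between the sexes at a stage must rest on an exact
test for a count difference between exactly two libraries of known sizes.

The pipeline is: RPKM quantification → per-stage exact tests with FDR
control → per-stage five-type classification → cross-stage gene sets. Every
step is a plain function over matrices and data frames, so each is testable
in isolation and the whole chain is deterministic.

## Quantification

Expression is reported as reads per kilobase of gene model per million mapped
reads,

$$\mathrm{RPKM} = \frac{10^9\, C}{N\, L},$$

with $C$ the mapped read count of the gene, $L$ its exonic length in
nucleotides, and $N$ the library's total mapped read count. Two conventions
matter:

* $N$ is taken from the library metadata rather than from column sums of the
  count matrix, because multi-mapped reads make column sums differ from the
  mapped total.
* When lengths come from a GFF3 annotation, $L$ is the length of the union
  of the gene's exon intervals in 1-based end-inclusive coordinates
  ($\sum (\mathrm{end} - \mathrm{start} + 1)$ over the merged set). This is
  the usual gene-model convention and is deterministic.

A gene counts as *detected* ("expressed") in a library when it has at least
`min_count` mapped reads (default 1). Detection is deliberately decoupled
from RPKM cutoffs: per-library summaries report genes detected and genes at
RPKM ≥ 1 and ≥ 5 as separate tallies.

## The exact two-library test

Given $x$ reads for a gene in library 1 (size $n_1$), the Audic–Claverie
conditional probability of seeing $k$ reads in library 2 (size $n_2$) is

$$P(k \mid x) = \left(\frac{n_2}{n_1}\right)^{\!k}
  \frac{(x+k)!}{x!\,k!\,\bigl(1 + n_2/n_1\bigr)^{x+k+1}},$$

the posterior predictive of a Poisson rate under a flat prior. The two-sided
p-value is twice the smaller tail that includes the observed $y$, capped at
one:

$$p = \min\!\Bigl(1,\; 2\min\bigl(\textstyle\sum_{k \le y} P(k|x),\;
  \sum_{k \ge y} P(k|x)\bigr)\Bigr).$$

This doubled-minimal-tail convention is the standard two-sided choice for
discrete exact tests and calls genes in either direction.

Numerical policy:

* every term is evaluated in log space through `lgamma`, with
  $\log(n_2/n_1)$ and $\log(1 + n_2/n_1)$ formed as differences of logs of
  the raw library sizes so no ratio is ever explicitly formed;
* terms of $P(k\mid x)$ decrease monotonically as $k$ moves away from the
  observed $y$ on the side opposite the distribution's mode, so the smaller
  tail is summed outward from $y$ relative to $P(y|x)$ and truncated when
  terms fall below $10^{-18}$ of the point mass; the larger tail is then
  recovered from the exact identity $S(y) = 1 - F(y) + P(y|x)$, which never
  subtracts nearly equal numbers because the directly summed tail is the
  smaller one. This makes each call $O(\sqrt{\mu})$ rather than $O(\mu)$ in
  the expected count;
* a p-value that underflows is floored at the smallest positive normal
  double, keeping $p \in (0, 1]$.

The test suite checks this implementation against two independent routes: a
direct double-precision recurrence summation of the terms, and the
negative-binomial identity
$\sum_{k \le y} P(k|x) = F_{\mathrm{NB}}(y;\, x{+}1,\, n_1/(n_1{+}n_2))$
through `pnbinom`. Agreement is required to a relative error of $10^{-8}$
over all $x, y \le 200$ at size ratios 0.5, 1 and 2, and spot-checked at
expected counts in the thousands.

One property the statistic does *not* have is exact symmetry under swapping
the libraries: the distribution conditions on the count in the first library,
so $p(x, y, n_1, n_2)$ and $p(y, x, n_2, n_1)$ differ — visibly at small
counts (e.g. 0.0625 vs 0.03125 for counts 0 and 5 in equal-size libraries)
and negligibly at large ones. The package fixes the orientation once: the
first group (the "XX" role) supplies $x$, the second supplies $y$, and the
ratio is always $\log_2(\mathrm{XX}/\mathrm{XY})$.

p-values are adjusted with the Benjamini–Hochberg step-up (`p.adjust`),
with the Benjamini–Yekutieli variant available as an option. The FDR family
is *all genes tested at one stage* — one XX-vs-XY comparison — not the pool
of all stages; per-stage adjustment matches how per-stage differential
counts are reported in this design.

## The five-type classification

At each stage, with thresholds FDR ≤ $10^{-2}$ and
$|\log_2(\mathrm{XX}/\mathrm{XY})| \ge 1$ (both configurable):

| detection | criteria met | label |
|---|---|---|
| both groups | both, ratio > 0 | `XX-DIG` |
| both groups | both, ratio < 0 | `XY-DIG` |
| both groups | otherwise | `COG` |
| one group | FDR criterion | `XX-SEG` / `XY-SEG` |
| one group | otherwise | `ND-SEG` |
| neither | — | `NOT-EXPRESSED` |

For a gene detected on one side only, the RPKM ratio is infinite, so the
fold-change clause is automatically satisfied and specific-gene status
reduces to the FDR test. This is the only reading under which applying "both
criteria" to single-side genes is coherent, and it is the one implemented.

Cross-stage sets:

* **sex-specific genes** — detected in at least one library of one group and
  in none of the other group's, across all stages (the two-set Venn reading
  of detection);
* **all-stage co-expressed genes** — labelled `COG` at every stage;
* **enhanced genes** — a gene is XX-enhanced when it favours XX (`XX-DIG` or
  `XX-SEG`) at the anchor stage (5 dah) *and* at ≥ 2 of the other three
  stages; symmetrically for XY. A stage where the gene is untested
  (`NOT-EXPRESSED`) simply fails that stage's criterion without disqualifying
  the gene: candidacy via the remaining stages is preserved. The supporting
  stages are recorded per gene, so the admissible patterns (all four stages,
  or the anchor plus exactly two others) can be partitioned directly. A gene
  can never be both XX- and XY-enhanced, since both would require opposing
  labels at the anchor stage.

Because detection-based sex-specific sets and per-stage SEG calls are
related but distinct constructions, both are emitted, labelled distinctly
(`xx_specific`/`xy_specific` vs the per-stage `XX-SEG`/`XY-SEG` columns).

## The simulator and what it does (and does not) emulate

`simulation_config()` / `generate_dataset()` produce count tables with the
statistical structure the analysis assumes. Counts are Poisson with mean
$\mu = q\,L\,N/10^9$ — the RPKM formula inverted — where $q$ is the planted
true expression on the RPKM scale. The count model is deliberately Poisson,
not negative binomial: the exact test's null is Poisson sampling of reads
between two libraries, so type-I-error checks against the simulator are
meaningful. Overdispersion is out of scope by design; with biological
replicates one would use a replicate-aware model instead of this test.

Planted classes per gene (optionally per gene *and* stage through
`class_schedule`): co-expressed (`cog`, identical $q$ in both groups),
differential (`xx_dig`/`xy_dig`, $q$ multiplied by `dig_fold` in the named
group), specific (`xx_seg`/`xy_seg`, $q$ in the named group and exactly 0 in
the other), and `silent` (0 everywhere).

Default conditions, chosen once as a realistic desk-scale emulation of the
eight-library design: 21,000 genes; stages 5/30/90/180 dah; groups XX/XY;
5×10⁶ mapped reads per library; gene lengths uniform on 500–3000 nt
(lengths only enter RPKM denominators, so the distribution's shape is
immaterial); baseline expression uniform on 40–200 RPKM, which with the
shortest genes and the default library size gives every expressed gene an
expected count of at least 100; `dig_fold` 8; class fractions 70% cog, 8%
each DIG direction, 2% each SEG direction, 10% silent. The fold must be ≥ 2
so planted differential genes clear the $|\log_2| \ge 1$ bound in
expectation.

Determinism: gene-level draws use the master seed; each library's counts use
a seed derived from (master seed, library index), so identical
configurations reproduce bit-identical counts and appending stages never
perturbs earlier columns.

What passing the recovery and error-control suites shows: at fold-8 effects
with expected counts ≥ 100 the classification recovers planted labels
essentially perfectly, and under the matched Poisson null the stagewise
fraction of genes at q ≤ 10⁻² stays far below the nominal level. What it
does not show: robustness to overdispersion, to multi-mapping artefacts in
the counts, or to effects near the detection limit — real libraries violate
the Poisson assumption to varying degrees, and fold changes near the
threshold will not be recovered at these rates.

## Problem sizes and numerical choices in the shipped analyses

The bundled analysis scripts and validation suites run at desk scale chosen
for thorough coverage at interactive runtimes: the workflow scripts simulate
the full 21,000-gene design; the error-control study uses three independent
10,000-gene all-co-expressed datasets; recovery uses a 4,000-gene planted
mixture and a 300-gene stage-schedule planting. Oracle equivalence for the
exact test is exhaustive over the $201 \times 201$ count grid at three size
ratios.

Tie handling in the step-up adjustment is inherited from the min-over-suffix
construction: equal p-values receive equal q-values. Degenerate inputs are
rejected with errors naming the offending gene, library or cell; a
configuration whose class fractions do not sum to 1 (within $10^{-9}$), a
fold below 2, or library-size vectors of the wrong length never reach the
generator.

## Known limitations

* No replicates, hence no dispersion estimation; the test is exactly the
  two-library comparison it claims to be and nothing more.
* Whether the historical analyses this design descends from used BH or BY
  adjustment is not documented; BH is the default here and BY a switch, with
  no claim of fidelity either way.
* The classification of edge cases on the single-side branch (e.g. a gene
  with q ≤ 10⁻² detected on one side at trivial depth) follows the coherent
  reading described above; alternative decision tables exist and would
  differ only in those cells.
* The sex-specific totals of a published study may follow either the
  detection-Venn or the per-stage-SEG construction; both are emitted so
  either can be compared.
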
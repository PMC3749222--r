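---
title: "Y-STR haplotype analysis in a haplogroup framework: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Y-STR haplotype analysis in a haplogroup framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yhapq)
```

# Scope

`yhapq` implements the standard analysis chain applied to Y-chromosome
short-tandem-repeat (Y-STR) haplotypes sampled within a SNP-defined
haplogroup — the setting of population surveys of haplogroup Q in the
Americas, but nothing in the package is specific to Q except the bundled
tree fixture.  The chain is:

1. parse and validate repeat-count haplotype tables, flag and exclude
   *atypical alleles*;
2. classify each sample into a haplogroup-tree node from biallelic marker
   calls and tabulate direct-count frequencies;
3. summarise within-group variation (haplotype diversity, repeat-number
   variance, shared haplotypes) on the forensic minimal haplotype;
4. ordinate individuals by pairwise multi-locus distances (PCoA);
5. draw variance-weighted median-joining networks;
6. date lineage expansions by the average squared distance (ASD) method.

A stepwise-mutation-model simulator generates data with the statistical
structure these analyses assume, so each stage is validated without any
external dataset.

# Data model and filtering rules

An STR profile is a row of repeat counts over a locus catalogue.  Three
conventions matter and are fixed package-wide:

* **Duplicated systems.** YCAIIa/b, DYS385a/b, DYS459 and DYS464 occur in
  two or more copies whose alleles cannot be assigned to a copy; they are
  stored comma-joined in one column and excluded from all per-locus
  arithmetic.
* **Micro-variants.** Partial-repeat alleles keep their decimal notation
  (e.g. DYS19 = 13.2) exactly; they are never rounded.
* **DYS389B.** The minimal haplotype uses DYS389B = DYS389II − DYS389I;
  the reader computes it when a table carries the raw I/II columns, and
  accepts a DYS389B column directly.

`filter_atypical()` excludes samples carrying a second allele at a
single-copy locus (a somatic or germline duplication) or a fractional
allele, at the loci the downstream stage will use.  Diversity, network and
dating stages require this filter; ordination does **not** exclude
micro-variant carriers, because fractional alleles subtract cleanly
(a 13.2 vs 13 difference is 0.2 repeats) — only duplicated alleles are
unscorable there.  Missing data at a required locus is an error rather than
a silent drop: the caller decides, and the pipeline stage records every
exclusion.

# Haplogroup classification

The haplogroup tree is a rooted, marker-labelled tree.  A sample is
assigned to the deepest node whose defining marker is in the derived state,
subject to path consistency (derived below typed-ancestral is an error
naming both markers, as is derived on diverging branches).  Untyped markers
are treated as *not examined*: surveys type markers hierarchically, so deep
branches are usually untyped once an upstream marker is ancestral.  A label
gains the paragroup star (`Q1a3a1a-M3*`) when at least one child-defining
marker was examined and ancestral and none was derived — i.e. the
chromosome belongs to the node itself, not to any examined sub-branch.
Frequencies are direct counts, with percentages relative to each
population's classified total (1 decimal).

# Diversity statistics

Haplotype diversity is Nei's unbiased gene diversity on minimal-haplotype
frequencies,

$$h \;=\; \frac{n}{n-1}\Bigl(1 - \sum_i p_i^2\Bigr),$$

which is 0 exactly when the sample is monomorphic and exactly 1 when all
haplotypes are distinct.  Repeat-number variance is the per-locus sample
variance (n − 1 denominator) and `V` its unweighted mean over the seven
single-copy minHt loci — DYS385a/b is disregarded and atypical samples are
pre-excluded.  Whether published variance tables used 7 or 33 loci is not
always stated; this package's choice (7) is declared in its output
metadata and follows from computing all diversity parameters on the
minimal haplotype.

# Individual distances and PCoA

The individual-by-individual distance is the microsatellite convention

$$d(i,j) \;=\; \sum_l \,(a_{il} - a_{jl})^2$$

over the single-copy loci (33 with the default panel); a mismatch-count
metric is available behind a flag, and the metric used is recorded on the
result, since the exact option used by spreadsheet tools in published
figures is rarely stated.  PCoA treats this `d` as a *squared* distance:
the Gower-centered matrix −½ J d J is eigendecomposed and coordinates are
eigenvectors scaled by the square root of their eigenvalues.  Negative
eigenvalues (non-Euclidean input) are counted and reported, never silently
dropped; explained variance is computed over the positive spectrum.  Axes
are deterministic up to sign; the package fixes the sign so the
largest-magnitude coordinate on each axis is positive, and tests compare
configurations through their distance matrices, never through raw signs.

# Median-joining networks

Networks are built on 7-locus haplotypes under the weighted stepwise
distance $d(u,v) = \sum_l w_l\,|u_l - v_l|$.  Weights are proportional to
the inverse of each locus's repeat variance, scaled so the smallest is at
least 1, rounded to integers, capped at 99 (zero-variance loci get the
cap) — volatile loci should not dominate network length.

The construction iterates two steps to a fixpoint: build the minimum
spanning network at tolerance ε (an edge survives iff its endpoints are not
already connected by strictly shorter edges, minus ε; at ε = 0 this is
exactly the union of all minimum spanning trees), then add the per-locus
middle value of a connected triplet as a *median vector* whenever doing so
strictly reduces total spanning length, taking the best candidate first
with a lexicographic tie-break.  For ordinal STR data the middle value is
the cost-minimising Steiner point per locus under linear cost, and a
median of a triplet can never tie given complete data.  Unobserved medians
whose degree falls to two or less and whose removal does not lengthen the
network are pruned.  Node order is lexicographic throughout, so the result
is deterministic.  ε defaults to 0, the convention of the widely used
desktop software.

**Reduced-median preprocessing.**  On the cumulative binary expansion of an
ordinal locus (one indicator per repeat-count threshold), the per-character
majority of three haplotypes equals the per-locus middle value, so the
binary construction can run directly on repeat counts.  The classical
reduction parameter trades off how aggressively unlikely parallelisms are
resolved; the original frequency-ratio rule is not reproducible in full
detail from the published summaries, so this package uses a documented
deterministic variant: a candidate median `m` from a triplet is accepted
iff

$$r \cdot \bigl(\mathrm{mst}(H) + d(m,H) - \mathrm{mst}(H \cup m)\bigr)
  \;\ge\; d(m,H),$$

i.e. `m` must recover at least 1/r of its connection cost in spanning-length
reduction.  `r = 1` keeps the fewest candidates, `r` → ∞ keeps all, and the
default `r = 2` mirrors the conventional default.  This is the package's
own design choice and is stated here rather than attributed.

# ASD dating

The age of the STR variation within a lineage is estimated as

$$\hat T \;=\; \frac{\overline{ASD}}{\mu_{\text{eff}}} \times g,
\qquad
ASD_l \;=\; \frac1n \sum_i (a_{il} - c_l)^2,$$

with the median haplotype as centre `c`, the *evolutionary effective*
per-locus mutation rate μ~eff~ = 6.9 × 10⁻⁴ per generation, and g = 25
years per generation.  The effective rate is calibrated for evolutionary
time depths (≥ roughly 40 generations); pedigree rates are deliberately not
offered, as they are known to give inconsistent results at these depths.
Standard errors are computed **over loci**: per-locus ages
$T_l = ASD_l/\mu_{\text{eff}} \cdot g$ and $SE = sd(T_l)/\sqrt L$.  The
alternative (propagating the sd of per-locus ASD) differs only by the
common scale factor, so the choice is cosmetic but is declared in every
output.  Two tie-breaks are fixed for determinism: the per-locus median
takes the lower of two central values at even n, and a monomorphic sample
returns T = 0 with SE = 0 rather than an error.  Under the symmetric
stepwise mutation model on a star genealogy, E[ASD about the founder] =
μT, so the estimator is unbiased there; centering on the sample median
instead of the (unknown) founder introduces a small O(1/n) bias that the
package's recovery tests bound below 10% at n = 100.

# The synthetic-data generator

`simulate_star()` models the limiting genealogy of a rapid expansion:
every lineage descends independently from the founder for `T_g`
generations, each locus mutating per generation with probability μ and
stepping ±1 with equal probability.  The implementation draws the mutation
count per lineage-locus as Binomial(T~g~, μ) and the net displacement as a
symmetric random walk over that count — exactly the same distribution as
the generation-by-generation Bernoulli process, at a fraction of the cost.
`simulate_coalescent()` draws a Kingman n-coalescent (pairwise coalescence
rate 1/(2N~e~) per generation, so E[TMRCA] = 2N~e~ at n = 2), drops
Poisson(μ × branch length) mutations per locus on branches, and places SNP
markers on chosen branches so that exactly the subtended samples are
derived.  No range constraints or reflecting boundaries are imposed on
repeat counts: boundaries would bias ASD against the effective-rate model
the dating stage assumes.  Default parameters are the stated world of the
analyses: μ = 6.9 × 10⁻⁴, 7 minHt loci, a typical Native American modal
founder haplotype, 25-year generations.

Anomaly injection (`inject_anomalies()`) adds the two atypical-allele
classes the filters must catch — +0.2 partial repeats and duplicated
alleles — at configurable per-sample rates.

All stochastic operations draw from named substreams derived from one
master seed, so adding an operation to a pipeline never changes the
output of the others.

**What a green test does and does not establish.**  The generator matches
the analyses' *assumptions* (star or neutral coalescent genealogies,
symmetric single-step mutation, locus independence, complete 7-locus data).
Real Y-STR surveys violate several of these: population structure and
founder effects mix genealogy shapes, loci differ in mutation rate (the
effective rate is an average), some loci show multi-step mutations and
range constraints, and genealogical correlation makes haplotypes recur far
more than under a star model at the same depth.  Green simulation-based
tests therefore establish internal correctness of the estimators under
their stated model, not the historical accuracy of any particular
published age.

# Numerical and degenerate-input choices

* Distances and network lengths are integer-weighted sums of absolute or
  squared repeat differences; comparisons use a 10⁻⁹ slack only where
  floating arithmetic enters (MST totals).
* An all-zero distance matrix yields all-zero coordinates with a warning.
* `estimate_age()` refuses n < 2; a single locus gives SE = NA.
* Profiles with missing required loci raise errors naming sample and
  locus; pipeline stages report every exclusion in `exclusions.tsv` and
  the JSON manifest.
* Network determinism: haplotypes are sorted lexicographically before any
  iteration; candidate medians are added best-gain-first with a
  lexicographic tie-break.

# Known limitations

* The reduced-median acceptance rule is a documented variant, not a
  line-by-line reimplementation of the original reduction; networks
  produced with `reduced = TRUE` can differ from legacy desktop software.
* Median-joining enumerates medians of connected triplets only (as the
  original algorithm does); it is a heuristic for the Steiner problem and
  is quadratic-to-cubic in the number of distinct haplotypes — practical
  for the dozens of distinct 7-locus haplotypes typical of sub-lineage
  networks, not for hundreds of all-distinct haplotypes.
* ASD confidence intervals over loci ignore the genealogical correlation
  between loci sharing one genealogy; they understate total uncertainty,
  as is conventional for this estimator.
* The classifier requires a call for the root marker and treats equivalent
  markers on one node as interchangeable; within-node conflicts are
  errors, not votes.
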
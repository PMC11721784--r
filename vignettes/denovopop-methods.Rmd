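---
title: "Methods: population-scale presence, evolution and selection analyses of de novo genes"
author: "denovopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-scale presence, evolution and selection analyses of de novo genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovopop)
```

# Scope and model of the data

Genes born from previously noncoding sequence (de novo genes) segregate in
natural populations: an accession either carries a functional open reading
frame (ORF) or carries loss-of-function (LoF) alleles that destroy it. For a
selfing plant such as *Arabidopsis thaliana*, resequenced accessions are
effectively haploid at this resolution, so gene presence is a per-accession
binary trait. `denovopop` implements the computational chain around that
trait:

1. **Presence calling** (`call_presence`): apply an accession's variants to
   the reference CDS and classify the edited ORF.
2. **Frequency spectra** (`compute_frequency`, `bin_frequency`,
   `summarize_population`): per-population presence frequencies, decade
   spectrum bins, nearly-fixed and low-frequency classes, plus Wilcoxon
   rank-sum feature contrasts between frequency classes
   (`compare_features`).
3. **ORF evolutionary history** (`reconstruct_ancestor_parsimony`,
   `annotate_branch_events`, `scan_tsd`, `filter_homology_hits`): ancestral
   sequence by outgroup-rooted parsimony, per-branch substitution and indel
   events in a fixed reference reading frame, target-site-duplication motif
   scanning, homology-hit filtering.
4. **Environmental association** (`ttest_env`, `permutation_test`,
   `filter_collinear`): two-group climate-factor comparisons with a
   subsampling permutation null, and the collinearity pre-filter used before
   ordination.
5. **Selective-sweep scanning** (`scan_omega`, `call_selected`,
   `overlap_genes`, `compute_pi`): the linkage-disequilibrium omega
   statistic on a 10-kb grid with 10-100-kb windows, top-5% region calling
   and gene overlap.
6. **Synthetic data** (`gen_*`): generators for every input class with
   serialized ground truth, so the whole chain is testable offline.

Headline numbers from real data (1,115 accessions, climate rasters,
RNA-seq) require inputs that are not redistributable at desk scale; the
package is therefore validated against planted-truth synthetic data and
exact small-sample oracles.

# ORF classification

## Edit semantics

A variant `(pos, ref, alt)` replaces the half-open slice
`[pos, pos + len(ref))` of the CDS with `alt` (VCF-style left anchoring,
0-based). Variants are applied in descending coordinate order, which makes
the result independent of input order for non-overlapping variants; a
reference mismatch or overlap is an error, never a silent skip.

## Decision rule

Classification walks codons from position 0 of the edited sequence:

* not beginning with `ATG` (the only start codon considered) →
  `START_LOST`;
* first in-frame stop codon strictly before the reference terminal codon
  position → `PREMATURE_STOP` — any truncation counts, with no
  near-terminal exemption, because observed absent accessions carry single
  truncating variants with no positional caveat;
* no stop codon by the end of the sequence → `STOP_LOST`;
* otherwise `FUNCTIONAL`.

Frameshifting indels need no special casing: their translated consequence
surfaces as one of the above. One corner follows directly from the rule: a
first stop at a codon index **at or beyond** the reference protein length
(reachable only through indels) is `FUNCTIONAL` — the ORF reaches at least
reference length. The classifier stops at the first decisive event; edits
downstream of an early stop are not re-examined.

Heterozygous or missing genotypes at a gene variant are handled by policy:
`strict` (default) marks the accession `UNRESOLVED` and removes it from
frequency denominators — in a selfing species heterozygous calls are most
plausibly genotyping errors — while `any-functional` ignores such sites,
since the reference-allele haplotype remains intact.

# Frequency spectra and feature contrasts

Presence frequency is `100 * n_present / n_called` per gene and population,
with `UNRESOLVED` calls shrinking the denominator rather than counting as
absent (conservative: absence is never inflated by missing data). Spectrum
bins label exact 0 and exact 100 as their own classes and everything else
by decade midpoints (`5` for (0,10), `15` for [10,20), ... `95` for
[90,100)).

Two threshold conventions coexist in the literature this package serves:
the nearly-fixed summary uses a strict `> 90%` rule, while feature
contrasts are conventionally defined on `< 10%` versus `>= 90%` classes.
Both the thresholds and the strictness are arguments
(`summarize_population(strict = )`), with the strict rule as default; the
package takes no position on which convention is canonical.

Feature contrasts use the two-sided Wilcoxon rank-sum test (exact whenever
`stats::wilcox.test` can be exact: no ties, small n) with
Benjamini-Hochberg adjustment across the feature list of one contrast —
not across populations, mirroring how a single panel family is corrected.
Gene features such as methylation level or codon usage bias arrive as
table columns; computing them from raw data is out of scope by design.

# Ancestral reconstruction and branch events

## Parsimony with outgroup tie-breaking

Ancestral states are computed column-wise by Fitch parsimony over the
ingroup leaves, with gaps as a fifth character state and the generalized
(majority-count) rule at multifurcations. The outgroup is excluded from the
ingroup pass and used afterwards: when the root state set has several
members, the outgroup state is chosen if it belongs to the set; remaining
ties fall back to the reference state, then to a fixed `A < C < G < T < -`
order so reconstruction is deterministic. The test suite checks the root
set against exhaustive minimum-change enumeration on all small instances.
An externally produced ancestor (e.g. from a maximum-likelihood tool) can
be supplied verbatim to `annotate_branch_events` instead.

## Event annotation in the reference frame

All codon indexing lives on the reference sequence's non-gap columns:
indels in individual sequences never shift the frame. Maximal runs of
gap-versus-base columns are single `INS`/`DEL` events with a column span.
Each substituted column is classified by substituting that site alone while
holding the other two codon positions at the **parent** state, because
events are counted along a branch from the inferred ancestor: parent stop
to non-stop is `STOP_LOSS`, the reverse `STOP_GAIN`, destruction of the
reference start codon `START_LOST`, otherwise `SYN`/`NONSYN` by the
standard genetic code. Stop and start events take precedence over the
`SYN`/`NONSYN` label. Codons with more than one substituted site are
flagged `multi_hit` under the default per-site rule; a `per-codon` mode
emits one event per such codon instead. The per-site rule is the default
because it preserves the column-count identity (SYN + NONSYN + stop events
= substituted in-frame columns); published synonymous:nonsynonymous counts
may follow either convention, and the package exposes both without
claiming one.

Substitutions at columns where the reference is gapped cannot be assigned a
codon; they are recorded with `codon_index = NA` and no `SYN`/`NONSYN`
call.

## TSD scanning

Target-site-duplication remnants are reported with absolute coordinates and
a distance measured 1-based from the motif's 3' end to the base immediately
5' of the first base of `ATG` (a motif ending directly before the start
codon has distance 1). The convention is documented here precisely because
"bp upstream" phrasing is ambiguous in the literature. Mismatch tolerance
defaults to 0 (exact matches).

Homology-hit filtering retains rows with E-value ≤ 1e-5, identity ≥ 60%
and query coverage ≥ 70%, all bounds inclusive; coverage is derived from
`align_len / query_length` when not supplied.

# Environmental association

`ttest_env` uses the equal-variance two-sided Student's t test (not Welch)
because that is the test named by the convention this package reproduces;
BH-adjusted p-values are reported alongside raw ones, but significance
calls default to raw p for faithfulness.

`permutation_test` draws `n_perm = 1000` subsamples of size `k =
length(absent)` from the present-group values **without replacement**
(with-replacement is an option), records each subsample mean, and compares
the observed absent-group mean to the empirical 2.5th/97.5th percentiles
(`quantile` type 7). Significance is the observed mean falling outside that
interval; the empirical p-value uses the plus-one rule
`(1 + 2 min(#null <= obs, #null >= obs)) / (n_perm + 1)`, capped at 1, so
it can never be exactly 0. Because captions sometimes describe the same
figure as a "distribution of the difference", a `statistic = "diff"`
variant (subsample mean minus remaining-present mean, observed
`mean(absent) - mean(present)`) is also implemented; the default is the
resampled-means reading, which matches the procedural description.

**Known property: this null is anti-conservative.** The subsampling null
has variance ≈ `(σ²/k)(n-k)/(n-1)` around the present-sample mean, whereas
the observed quantity varies with `σ²/k + σ²/n` around the population
mean, and the finite-permutation percentile estimates add noise. For
k = 5, n = 55 the analytic two-sided rejection rate under the null is
≈ 0.073, and the acceptance suite measures ≈ 0.08 rather than the nominal
0.05. The package implements the published procedure faithfully and
documents the miscalibration instead of silently recentering or
studentizing the statistic; the corresponding acceptance criterion is
expected to fail and is left failing deliberately. Power is unaffected in
practice: a 5-standard-deviation group shift with k = 5 is detected in
more than 99% of runs.

`filter_collinear` eliminates greedily: while any factor pair exceeds
|r| > 0.7 (pairwise-complete Pearson), the factor with the largest mean
absolute correlation to the remaining factors is dropped, ties broken by
column order, zero-variance factors dropped first. Greedy elimination is
deterministic and order-stable, which matters more here than optimality of
the retained subset.

# Omega sweep scan

For a grid center `c` and one-sided window extent `w`, sites inside
`[c - w, c)` form the left flank L and `[c, c + w)` the right flank R, and

$$\omega = \frac{\left(\binom{l}{2} + \binom{r}{2}\right)^{-1}
\left(\sum_{i<j \in L} r^2_{ij} + \sum_{i<j \in R} r^2_{ij}\right)}
{(lr)^{-1} \sum_{i \in L, j \in R} r^2_{ij}}$$

with `r² = D²/(p(1-p)q(1-q))` computed over pairwise-complete haplotypes.
A completed sweep leaves high LD within each flank but little across the
swept site, so ω peaks at the sweep center. Choices that required a
decision:

* **Window ladder.** The published scanner maximizes over window
  boundaries exhaustively; here ω is maximized over 10 geometrically
  spaced symmetric extents between `minwin = 10000` and `maxwin = 100000`
  bp (the two published parameters). This is a documented simplification
  with the same endpoints.
* **Cap sentinel.** When the cross-flank LD sum is exactly 0 with positive
  within-flank LD, ω is reported as `1e6`, keeping the quantile machinery
  finite and rank-correct; a zero within-flank sum with zero cross sum
  yields 0.
* **Grid.** Centers are every multiple of `grid_step = 10000` strictly
  between the first and last polymorphic site; flanks with fewer than two
  usable sites at every ladder extent give `omega = NA`.
* **Selected regions.** The threshold is the 95th percentile (`quantile`
  type 7) of finite ω per population genome-wide — a single top-5% rule
  per scan, not per chromosome. Grid points at or above the threshold
  (ties included) become `[center - step/2, center + step/2)` regions;
  book-ended regions merge by default (`merge = FALSE` disables it, since
  whether published pipelines merged before gene overlap is unstated).
  Gene overlap requires ≥ 1 bp on half-open intervals, so abutting
  features do not overlap.

Nucleotide diversity is `π = Σ_sites 2p(1-p)·n/(n-1) / L`, identical to
the mean per-site Hamming distance over all haplotype pairs for complete
data; `L` defaults to the polymorphic-site count but can be set to the
surveyed length.

# The synthetic world

Generator defaults are fixed, stated conditions — not tuning knobs:

* **Gene catalog** (`gen_catalog_variants`): well-formed reference ORFs
  (ATG, non-stop codons, terminal stop; default 50 codons), one planted
  LoF variant per gene drawn uniformly from premature-stop SNP, start-loss
  SNP, stop-loss SNP, 1-bp frameshift deletion. Per-population absence
  counts are exact census counts `round(freq·n)`, not binomial draws, so
  frequency recovery is exact and classifier bugs cannot hide behind
  sampling noise. The realized count is recorded in the truth when
  `freq·n` is not an integer.
* **Sweep haplotypes** (`gen_sweep_haplotypes`): 100 haplotypes over a
  200-kb region with one polymorphic site per 500 bp (conservative for a
  within-population *Arabidopsis* sample); background sites are
  independent Bernoulli columns with minor-allele frequencies uniform on
  [0.1, 0.5]. Inside the sweep each haplotype draws one of two block
  patterns per flank, independently left and right, giving within-flank
  r² = 1 and cross-flank r² ≈ 0. Flank width defaults to 10 kb per side —
  the scan's grid and minimum-window scale — so the planted signal is
  localized to one grid cell, which is the resolution the argmax check
  asks the scan to recover. With two haplogroups all flank sites are
  copies of one underlying column, so the center's cross-flank sum is a
  single random draw; much wider flanks would let sweep-edge centers
  (one flank of pure block sites) out-compete an unlucky center draw.
* **Environment** (`gen_env`): 19 factors as independent standard normals
  (the source conventions state no distributions); the planted effect is a
  mean shift on the focal factor (`bio17`) of the absent group, in sd
  units, with 55 present and 5 absent accessions by default — the
  published African-population group sizes.
* **Ortholog quartets** (`gen_ortholog_quartet`): fixed topology
  `((ingroup1, ingroup2), outgroup)` with a 70-codon ancestor (≈ the size
  of a small de novo protein). Events are planted at distinct interior
  codons (no multi-hit collisions by construction); substitutions change
  one base, indels are whole codons so the reference frame stays intact;
  insertion anchors are globally unique and same-branch deletions
  non-adjacent so that run-grouping recovers event counts exactly.

Each generator derives its RNG stream from the global seed by stable
hashing of the scenario name (`derive_seed`), so scenarios are independent
and byte-reproducible. What a green test establishes is recovery of
*planted* truth under this idealized world: independent background sites,
no recombination mosaic, no genotyping error, census-exact frequencies. It
does not establish performance on real resequencing panels, where missing
data, population structure and LD decay profiles differ.

# Degenerate inputs and numerical conventions

* Duplicate FASTA ids, ref/alt mismatches, overlapping variants,
  inconsistent strands and out-of-bounds intervals are errors, not
  warnings.
* Star alleles in VCFs are dropped with a warning; phasing is ignored.
* Constant features and identical groups give p = 1 (a `NaN` from an
  all-ties rank test is mapped to 1, direction 0).
* All internal genomic coordinates are 0-based half-open; conversion
  happens only at I/O boundaries. Alignment columns are 1-based, the R
  string convention.
* Quantiles are `stats::quantile` type 7 throughout.
* `run_pipeline` manifests record the seed and every threshold actually
  used; reruns with the same config are byte-identical (no timestamps).

# Known limitations

* The permutation null is anti-conservative as published (see above).
* The window-ladder ω is a simplification of exhaustive boundary
  maximization; absolute ω values are not comparable to the original
  scanner's, though ranks and the top-5% calls behave equivalently on the
  synthetic world.
* Splice-aware LoF, transcript isoform choice and ML ancestral
  reconstruction are out of scope; the parsimony ancestor is a
  deterministic substitute that accepts an external ancestor when one is
  available.
* The configuration file is JSON (no YAML dependency).
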
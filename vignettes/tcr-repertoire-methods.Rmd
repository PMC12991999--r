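---
title: "Methods: TCR repertoire analysis for acute GVHD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCR repertoire analysis for acute GVHD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrgvhd)
```

## Scope and model of the data

`tcrgvhd` analyzes bulk T-cell receptor (TCR) repertoires sampled from
patients after allogeneic hematopoietic stem cell transplantation
(allo-HSCT), with acute graft-versus-host disease (aGVHD) as the clinical
contrast of interest. The unit of analysis is the **clonotype**: a unique
(CDR3 amino-acid sequence, V segment, J segment) triple with a productive
read count. A **repertoire** is one sample's clonotype collection plus
subject, group (`GVHD`, `NO_GVHD`, `HI` for healthy individuals, and
`GVHD_PRE` for pre-symptomatic patients who later develop disease) and an
optional longitudinal stage (0 = pre-onset, 1 = active disease,
2 = resolved).

Clonotype identity is amino-acid level by default because every cross-sample
comparison in the workflow (specificity grouping, database annotation,
tissue sharing) operates on CDR3 amino-acid strings; nucleotide sequences
are carried through when present but never used as the key. Frequencies are
never stored — they are always derived as `count / total_reads`, which keeps
merging and downsampling exact.

## Depth normalization

Sequencing depth varies across libraries, and every diversity statistic
below is depth-sensitive. Before any statistic is computed, each repertoire
is down-sampled to a common number of productive reads (default
1,000,000). Sampling is **without replacement** — a multivariate
hypergeometric draw over the clonotype counts — because the operation
models resampling of actual reads; a multinomial mode exists behind a flag
for speed comparisons only. The draw is realized by sampling
`target` distinct read indices uniformly and mapping them back to clonotype
intervals, which is exactly equivalent to the sequential conditional
hypergeometric scheme but runs in O(total reads drawn).

Two depth policies are provided: a fixed target (the default), and the
minimum depth over the cohort, optionally bounded below by a
`min_acceptable` threshold whose value is deliberately left to the analyst.
Samples below the target are retained and flagged, never silently dropped:
exclusion is a judgement call the software should surface, not make.

## Diversity and clonal expansion statistics

For a normalized repertoire with counts $n_i$, total $N$ and frequencies
$p_i = n_i/N$:

* **Richness**: number of distinct clonotypes.
* **Chao1**: $S_{obs} + f_1^2/(2 f_2)$ with $f_1, f_2$ the singleton and
  doubleton counts; when $f_2 = 0$ the bias-corrected fallback
  $S_{obs} + f_1(f_1-1)/2$ is used. This is the classical branch form; note
  that some ecology packages always apply the bias-corrected variant, so
  cross-package comparisons should check the formula.
* **Inverse Simpson index (ISI)**: $1/\sum_i p_i^2$, the evenness-weighted
  effective clonotype number, bounded by $1 \le ISI \le$ richness and
  invariant to uniform count rescaling.
* **Expanded clonotypes**: counts are standardized
  ($z_i = (n_i - \bar n)/s$) and clones with $z_i > 2$ (strict) are counted.
  The sample standard deviation ($n-1$ denominator) is used, matching the
  default of standard statistical software; a population-sd flag exists.
  Standardizing frequencies instead of counts gives identical z-scores by
  affine invariance. The expanded-clone read mass is reported as a
  secondary output alongside the raw count.
* **Low-frequency clonotypes**: count of clones with read count strictly
  below 100 (comparable across samples only after normalization).
* **Rank-band mass**: fractions of reads held by the clones ranked 1–10,
  11–100, 101–1000, >1000 (ties broken lexicographically by CDR3 then V).
* **Frequency-band richness**: clones at or below 0.1% frequency versus
  above it; a clone at exactly 0.1% falls in the low band (closed upper
  bound).
* **CDR3 length spectra and V/J usage**: read-weighted by default (the
  spectra describe reads, not clones); clonotype weighting is available.
  Gene names are allele-stripped at ingestion (`TRBV15*01` → `TRBV15`) so
  usage aggregates at the segment level.

All strict/non-strict threshold choices above are deliberate and are locked
by boundary tests. Group comparisons delegate to R's `wilcox.test`,
`ks.test` and `fisher.test`; nothing statistical is re-implemented. In the
pipeline report, families of simultaneous tests (e.g. per-segment usage)
carry both raw and Benjamini–Hochberg-adjusted p-values, because dozens of
segments are tested at once.

## Specificity grouping (GLIPH-style)

TCRs that recognize the same peptide-MHC tend to share either short
interior CDR3 motifs ("local" similarity) or near-identical full CDR3s
("global" similarity). The package implements a faithful-in-spirit
re-implementation of this idea, not a port of any particular tool, with
every threshold exposed in `gliph_config()`:

* Input pool: per sample, clonotypes with frequency strictly above 0.01%
  and CDR3 length ≥ 8, pooled across all samples.
* Interiors: the first and last 3 residues are trimmed before any
  comparison — the termini are germline-dominated and uninformative for
  specificity.
* **Local groups**: for each interior k-mer (k ∈ {2,3,4}) supported by at
  least `kmer_min_depth = 3` distinct pool CDR3s, the observed support is
  compared with its distribution over `simulation_depth = 1000` random
  reference subsets of the same CDR3 count as the pool. Because the subset
  support of a single motif is exactly
  $\mathrm{Hypergeometric}(N_{ref}, K_{motif}, m_{pool})$, the subset
  supports are drawn directly from that distribution; a brute-force
  explicit-subset oracle in the test suite confirms the equivalence. The
  empirical p uses the add-one rule
  $p = (1 + \#\{sim \ge obs\})/(depth + 1)$ so it is never zero, and a
  motif is retained when $p \le 0.05$ **and** its fold enrichment
  (observed over mean simulated support) is at least 10.
* **Global groups**: connected components of CDR3s of equal length whose
  interiors differ at ≤ 1 position, found by single-position wildcard
  bucketing (exactly equivalent to all-pairs Hamming comparison, verified
  against an O(n²) oracle).
* Group identifiers are `local:<motif>` / `global:<smallest member>`, which
  are stable and deterministic.

One calibration subtlety deserves emphasis. The minimum-support filter
tests only motifs whose *observed* support reached 3. For motifs whose
expected support is well above that, the filter is inert and the empirical
p-values are super-uniform, as the null-calibration test verifies on
densely supported (k = 2) motifs. For motifs whose expected support is
below the filter (sparse k-mers in small pools), being tested at all is an
upper-tail event, so the marginal p of that selected subset is
anti-conservative *by construction*. This is inherent to minimum-depth
filters in GLIPH-style methods; it is the 10-fold enrichment requirement,
not the p-value, that screens such motifs out of the retained groups. The
reference repertoire should be at least 10× the pool (a warning is emitted
otherwise), and reference CDR3s can come from any user table or from the
bundled motif-free generator.

## Cross-sample similarity and library classification

Each sample's **membership profile** is the set of group identifiers in
which it has at least one member clonotype (a clonotype-set mode exists
behind a flag; group-membership sets are the default because the groups are
the unit of interpretation). Pairwise sharing is the Jaccard index
$|A \cap B| / |A \cup B|$, with the convention that two empty sets score 0:
an uninformative sample must not look similar to anything.

A pre-symptomatic query is classified against a GVHD library and a no-GVHD
library by the **median** Jaccard similarity to each library's profiles —
median rather than mean so a single highly similar relative cannot carry
the decision — with ties (including empty queries) reported as
`indeterminate` rather than forced. A rank-sum p-value between the two sets
of query-versus-library similarities accompanies the label. This decision
rule is the module's main interpretive choice: the underlying comparison in
the literature is descriptive (boxplots of pairwise indices), and any
operationalization had to be chosen here.

## Longitudinal tracking and stage overlap

For a subject sampled at several stages, the top-100 clonotypes of a chosen
reference stage (either direction is supported) are looked up in every
stage; absent clones get frequency 0 and an explicit `absent` status.
Between-stage overlap uses the **Morisita–Horn** index
$C = 2\sum x_i y_i / ((d_x + d_y) X Y)$, the frequency-based variant:
it is scale-invariant, bounded in [0, 1], and robust to unequal depths,
which is why repertoire tooling conventionally uses it where the
literature says "Morisita index". The classical count-based index is
available behind a flag (note it can slightly exceed 1 at small totals).

## Antigen and tissue annotation

High-frequency clones (frequency strictly above 0.01%) are intersected with
annotated CDR3 tables — VDJdb-dialect exports or a simple two-column
dialect (tissue-derived sets are consumed this way; no downloader is
shipped). Matching is exact, case-normalized string equality on the CDR3
(never substring), optionally requiring the V segment to co-match. Each
sample × set gets the number of shared clones and their summed read
frequency — both are reported because "frequency of shared clonotypes" is
ambiguous between the two — plus a per-species breakdown and a rank-sum
group comparison.

## The synthetic cohort generator

No patient data ships with the package; every stage is exercised on a
generator that reproduces the *qualitative contrasts* the analyses test,
with defaults set to the study design the package targets: 15 GVHD, 13
no-GVHD and 15 healthy samples; 1.2 million reads per sample before
normalization to 1 million; richness ordering GVHD > HI > no-GVHD.

* **Clone sizes** follow a rank-abundance power law
  $count(r) \propto r^{-\alpha}$ (default $\alpha = 1$), a widely observed
  shape for TCR clone-size distributions; the generator refuses
  configurations whose smallest rank would round to zero reads. Exponent 0
  gives a uniform repertoire, for which ISI equals richness exactly — a
  closed-form anchor used in tests.
* **CDR3s** are framed by the conserved C…F residues with interior residues
  drawn from a fixed glycine/serine-heavy junctional profile and lengths
  from a rounded normal (mean 14.5, sd 1.8, floored at 8). No D-segment or
  junctional-nucleotide modelling is attempted.
* **Shared specificity signal** is emulated by spiking a panel of interior
  k-mer motifs into a configurable fraction (default 5%) of each designated
  sample's clonotypes. Spiked motifs are placed at random offsets that
  never touch the first or last 3 residues, so trimming cannot destroy
  them. Each spiked clone draws its motif from the panel *with
  replacement*, so each sample carries its own random subset of the public
  panel — without this, all spiked samples would have identical group
  profiles and similarity comparisons would degenerate to ties.
* **Stage dynamics**: stage 1 is stage 0 with mild lognormal jitter (the
  pre-onset and active repertoires share their dominant clones); stage 2
  contracts the stage-1 top-20 clones by a fold of 0.05 **and** expands a
  small emergent set (default: the 5 next-ranked clones, 200-fold). Both
  knobs matter: contraction alone redistributes mass toward the tail and
  therefore *increases* evenness and ISI — it is mathematically incapable
  of producing the diversity drop observed at resolution. The emergent
  expansion models the new oligoclonal expansions that accompany
  resolution, and together the two effects yield both the disappearance of
  onset-dominant clones in tracking plots and the ISI decline.
* **Determinism**: per-subject seeds are derived from the master seed by
  string hashing, so adding a subject never perturbs any other subject's
  repertoire, and reruns are bit-identical across platforms (only R's own
  RNG is used, never container iteration order).
* A **reference generator** produces large motif-free CDR3 pools (any CDR3
  containing a panel motif is rejected) for the enrichment null.

What the generator does *not* emulate — V(D)J recombination biology, public
clones arising from convergent recombination, CD4/CD8 subset structure,
HLA restriction — bounds what green tests mean: they demonstrate that the
statistics, the grouping machinery and the decision rules behave correctly
on data with the assumed structure, not that the biological effect sizes in
any real cohort match.

## Problem sizes used by the test and acceptance suites

The simulation-based checks run at deliberately scaled sizes chosen as the
package's own test design: oracle equivalence on 1,000 random repertoires
of richness ≤ 50; downsampling expectation over 10,000 seeded draws of a
two-clone repertoire; null calibration with a 300-CDR3 pool drawn from a
6,000-CDR3 reference at simulation depth 200; motif recovery on 10-sample
cohorts of richness 300 over 5 seeds; group-contrast recovery with richness
20,000 vs 6,000 at 200,000 reads over 20 seeds; classification with
8-sample libraries over 20 seeds, plus a 200-query null pooled over 10
independent cohorts (pooling across cohorts removes the shared
library-realization bias that a single cohort imposes on all its queries);
stage dynamics over 10 subjects; and a full pipeline determinism check.
The acceptance script runs the complete workflow at the full study design
(43 samples, 1 million reads) and reports its headline quantities.

## Known limitations

* The empirical-p anti-conservativeness for sparse motifs described above
  is reported, not corrected; interpret local groups through the joint
  fold-and-p retention rule.
* The classifier is a two-library median rule; it does not model time to
  onset, disease grade, or more than two outcome libraries.
* Annotation matching is exact; no fuzzy or biochemical-similarity matching
  of CDR3s against databases is attempted.
* Chronic GVHD, B-cell receptor repertoires and raw-read processing
  (alignment, clonotype assembly) are out of scope; the pipeline consumes
  clonotype tables.
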
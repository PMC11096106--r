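---
title: "Methods and design notes for pansynkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for pansynkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansynkit)
```

pansynkit implements the analysis layer of a gene-based pan-genome study of
a panel of chromosome-level assemblies from inbred lines: gene-family
classification with orthogroup correction, pan/core rarefaction, windowed
synteny-diversity statistics on a shared reference coordinate system,
cross-accession structural-variant (SV) merging, and centromeric
tandem-repeat quantification with depth-based completeness estimation.
This vignette records the models, the parameters that matter, and the
design choices made where the method definitions left room.

## Gene-family classification

The unit of analysis is the gene family (orthogroup): a cluster of genes
across genomes consumed from an upstream all-vs-all orthology clustering.
For each family the presence count $m$ is the number of accessions with at
least one member gene. With $n$ accessions the categories are

* **core**: $m = n$;
* **softcore**: $n > m > f \cdot n$ with the softcore fraction $f = 0.9$
  and a *strict* inequality — at $n = 69$ this yields the range 63–68;
* **dispensable**: $2 \le m \le \lfloor f \cdot n \rfloor$ (62 at
  $n = 69$);
* **private**: $m = 1$.

The strict inequality is deliberate: it makes the softcore range *empty*
for some panel sizes (e.g. $n = 10$, where no integer satisfies
$9 < m < 10$). `classify_families()` applies the rule as stated;
`simulate_pav()` refuses a configuration that asks for softcore mass at
such an $n$ rather than silently reassigning it.

Two corrections precede classification.

**Orthogroup fusion.** Clustering can over-split a family. A homology hit
qualifies as fusion evidence when query and target coverage are both at
least `cov_threshold` (default 0.95) *and* the pair is a reciprocal best
hit — each gene is the other's highest-scoring match, with score ties
broken lexicographically by gene id so the result is deterministic.
Qualifying hits spanning two families merge them; the closure is computed
with a union–find, so the operation is idempotent, independent of hit
order, and can only decrease the family count.

**Split/merge flagging.** Apparent presence/absence differences can arise
when one locus is annotated as one gene in some accessions and two in
others. A family is flagged when some accession carries $\ge 2$ genes,
adjacent in that accession's gene order, whose alignments to the family
representative each cover $< 0.95$ of it while the *union of covered
positions* reaches $0.95$. Because a union of intervals cannot be
reconstructed from coverage fractions (two genes covering the same half
must not count as a full tiling), the hit table carries the covered span
on the target (`t_start`, `t_end`) in addition to the coverage fields.
The representative is the member from the reference accession when one
exists, otherwise the longest member; flags are computed after fusion.

**Composition** is reported gene-level per accession: the fraction of an
accession's gene count (not its families) in each category, which is why a
panel with 60% core families typically shows a much higher per-genome core
gene fraction — core families are present in every genome while private
families contribute to only one.

## Rarefaction

`rarefaction_mc()` draws, for each subset size $k$, `replicates`
(default 2,000) uniform subsets of accessions without replacement and
counts pan families (present in $\ge 1$ sampled accession) and core
families (present in all sampled), reporting mean and standard deviation.
Subsets may repeat across replicates; the curve is deterministic given the
seed. `rarefaction_exact()` is the closed-form oracle,

$$E[\mathrm{pan}(k)] = \sum_f \left(1 - \binom{n-m_f}{k}\Big/\binom{n}{k}\right),
\qquad
E[\mathrm{core}(k)] = \sum_f \binom{m_f}{k}\Big/\binom{n}{k},$$

evaluated with `lchoose` for numerical stability. The tests check the
closed form against exhaustive subset enumeration and the Monte Carlo mean
against the closed form within $4\,\mathrm{sd}/\sqrt{R}$ for every $k$.

## Synteny diversity

Each accession's whole-genome-alignment annotation against the reference
is projected to a per-position indicator: $s_i(p) = 1$ iff position $p$ is
covered by a SYN block of accession $i$. Rearranged-but-aligned positions
(INV, TRANS, DUP and their compound codes) count as **non**-syntenic, as
do unaligned (NOTAL) and uncovered positions — the statistic exists to
highlight rearrangement, and inverted regions must score as diverged.
Two accessions are treated as jointly syntenic at $p$ iff both are
syntenic *to the reference* at $p$; true all-pairs alignment is out of
scope, and this reference-projection approximation is exact when the
reference is colinear with at least one of the two.

For a window $w$ over $n \ge 2$ accessions,

$$\pi_{syn}(w) \;=\; \frac{2}{n(n-1)} \sum_{i<j} \frac{1}{|w|}
\sum_{p \in w} \bigl(1 - s_i(p)\,s_j(p)\bigr).$$

Since $s_i(p) \in \{0,1\}$, the pair sum collapses position-wise to
$\binom{S(p)}{2}$ with $S(p) = \sum_i s_i(p)$; the implementation computes
$S$ as a run-length-encoded coverage sum and evaluates windows with
run-length views, which is what makes full-length chromosomes cheap. The
per-position brute force over all pairs is kept as an independent oracle
in the tests (agreement to $10^{-12}$).

Windows are anchored at position 1, advance by the step, and the final
partial window is kept with its true length — the simplest convention, as
none was prescribed. The statistic is position-weighted (every position in
a window counts equally) rather than alignment-length-weighted per pair;
this is the natural reading of an "average pairwise diversity" and is the
choice adopted here. Threshold fractions (`fraction_by_threshold`, defaults
0.2 and 0.5) are window-length-weighted. `pairwise_colinearity()` restricts
to an arm mask (centromeres/pericentromeres excluded) and reports the
fraction of masked-in positions jointly syntenic per accession pair, with
each accession's own reference-syntenic fraction on the diagonal.

## SV merging

Records of the same type on the same chromosome link when both
$|\Delta\mathrm{start}|$ and $|\Delta\mathrm{end}|$ are at most
`max_dist`; clusters are the single-linkage transitive closure. The two
tiers mirror common practice for this data type: 20 bp–10 kb merged at
1 kb, > 10 kb merged at 20 kb. The six-field parameter string of the
upstream merging tool is read as (max distance, min callers, type match
on, strand match off, no distance estimate, min size); only the distance
and type-match semantics affect this implementation. Cluster
representative coordinates are per-coordinate medians (robust,
deterministic); support is the number of distinct accessions. With
`max_dist = 0` the operation degenerates to exact-coordinate
deduplication, which the tests exploit as an oracle.

## Centromere sizing

**Array annotation.** Assembled tandem arrays are found by approximate
motif matching: all matches of the motif (and its reverse complement)
within edit distance `max_divergence × motif length` (default 0.20), a
greedy left-to-right non-overlapping tiling, and gap-merging of matches
separated by at most one motif length. This replaces short-read alignment
for assembly-side annotation — no read mapper is needed to scan an
assembly, and the divergence threshold is explicit and configurable.
`copy_estimate` is array length divided by motif length.

**Depth-ratio estimation.** The true genomic repeat abundance, independent
of how much of the array was assembled, is estimated from the read depth
piled onto a short concatemer of the motif (4 copies):

$$\widehat{L}_{rep} = \frac{\sum_p d_{concat}(p)}{\bar{d}_{genome}},$$

in bp. The genome mean depth is computed over non-repeat positions
(annotated arrays masked) to avoid the circularity of partially assembled
arrays depressing the denominator. The estimator is scale-invariant
(multiplying all depths by a constant cancels) and its relative error at
30× coverage is far below 5% because the summed concatemer depth
aggregates tens of thousands of read placements.
`completeness_ratio()` = assembled/estimated serves both for repeat arrays
and, given assembly size and an orthogonal genome-size estimate, for whole
assemblies; values above 1 are legal and flagged.

**Size attribution.** `size_correlations()` is standard product-moment
correlation with the $t$-transform $p$-value; zero-variance columns are
reported as undefined rather than erroring. Per-chromosome estimated
lengths are not apportioned from the single concatemer signal — the
concatemer measures a genome-wide total, so per-chromosome values come
only from assembled arrays.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with ground truth for every stage. Its defaults are the study conditions
of the motivating panel: 69 accessions; category proportions
60/5/17/18% (core/softcore/dispensable/private); five reference
chromosomes (30/20/23/18/27 Mb) with multi-megabase centromere spans;
rare megabase arm inversions (Poisson, 0.1 per genome, 1–2.4 Mb) plus one
1.2 Mb inversion shared by 8 accessions; indels of 20 bp–10 kb; a 178-bp
centromeric satellite monomer and the 7-bp plant telomeric repeat
TTTAGGG; and 30× short-read depth. Where the source analysis reports only
range bounds, maximum-entropy defaults are used: softcore and dispensable
presence counts are uniform over their legal ranges, and the distribution
of dispensable presence counts is flagged as unverified. The 178-bp motif
itself is a fixed synthetic AT-rich sequence — no algorithm depends on the
real satellite consensus.

Sequence-level components run at desk scale by choice: repeat simulations
use a configurable non-repeat background (default 20 kb per chromosome;
the test fixtures use 6 kb and 20–300 motif copies per chromosome), while
the coordinate-only synteny simulation keeps full-length chromosomes since
intervals cost nothing. Genome size is coupled to repeat content linearly,
size = constant + total repeat length + Gaussian noise
(`size_coupling_noise_sd`), the minimal emulation of a strong linear
relation; with the noise at 0 the correlation is exactly 1, which the
acceptance checks use. Per-copy satellite divergence is i.i.d.
substitution (default 5%) — enough to exercise approximate matching
without modelling satellite evolution or higher-order repeat structure.
Depth tracks are Poisson around the mean (genome track) and around
`depth_mean × true repeat length / concatemer length` per concatemer
position, so the summed concatemer depth is the estimator's noisy input by
construction.

One master seed drives fixed per-component substreams (presence/absence,
homology, synteny, repeats, fusion cases, pipeline), so components are
independently reproducible and all outputs are byte-identical across runs
with the same configuration.

What the generator does **not** model — and what passing tests therefore
do not show about real data: read-level noise (no FASTQ, no mapping
artifacts), sequence-level gene content, satellite higher-order repeat
structure, cross-family split artifacts involving private families
(splits are planted only in families present in at least two accessions,
so a real panel's private-category split/merge rate has no synthetic
counterpart), reference bias in the synteny projection, and assembly
errors other than clean array truncation.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; any half-open arithmetic
  is confined to the window code.
* Families absent from every accession are excluded from classification
  (labelled `absent`).
* Unknown annotation codes in alignment files are skipped with one
  warning; ragged rows and duplicate ids are errors.
* RBH score ties break lexicographically; merged families take the
  lexicographically smallest member id.
* Cluster medians of an even member count use the numeric median
  (possibly half-integral); no rounding is applied.
* `rarefaction_exact` relies on `lchoose(n - m, k) = -Inf` when
  `n - m < k`, which is exactly the always-hit case.
* Empty SV input produces an empty, well-typed cluster table; empty window
  tables and empty arm masks are errors, since a fraction over nothing is
  undefined.

## Problem sizes used by the test and acceptance runs

Chosen so the full suite runs in minutes on one core: classification and
recovery at $n = 69$ with 5,000 families; rarefaction oracles on a
10 × 200 matrix with exhaustive enumeration; 20–50 brute-force
window-statistic instances of 10 accessions × 50–100 kb; 1,000 planted
fusion cases; SV recovery on the full 69-accession five-chromosome
coordinate simulation; 100 Poisson replicates of the depth estimator at
30×. These sizes are the package's own validation choices, not limits of
the methods.

## Known limitations

* The reference-projection approximation undercounts colinearity between
  two accessions that share a rearrangement relative to the reference.
* Greedy motif tiling is asymmetric at overlapping candidate matches; the
  strand-symmetry property is exact for clean tandem arrays and
  approximate at array boundaries under indel-containing divergence.
* `flag_split_merge` requires gene coordinates for every gene in the
  table; partially annotated panels must be filtered first.
* The SV clustering is single-linkage: long chains of pairwise-close
  records can merge records farther apart than `max_dist`, which is
  inherent to the chosen semantics.
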
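---
title: "Coverage-based discovery of sex-specific regions and in-silico sexing assay design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based discovery of sex-specific regions and in-silico sexing assay design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a female-heterogametic (ZZ/ZW) species, segments of the W chromosome
exist in exactly one copy in females and zero copies in males. With
whole-genome resequencing of phenotypically sexed individuals, such
segments leave an unmistakable coverage signature against a reference
assembled from a heterogametic (ZW) individual: read depth near **half**
the genome-wide mean in females, and **zero** in males. `sexscan`
implements that signature as a reusable scan, verifies hemizygosity via
the depth ratio, characterises the deletion-type structural variant that
distinguishes the W region from its diploid paralog, and turns the length
difference into a single-reaction PCR sexing assay whose banding pattern
(two bands = ZW, one band = ZZ) is validated in silico. The same machinery
applies unchanged to XX/XY systems by setting `target_sex = "M"`.

## The scan model

For each genome position the per-sample depths are split by sex into
groups of sizes $n_F, n_M \ge 2$. Welch's unequal-variance $t$ statistic

$$t = \frac{\bar d_F - \bar d_M}{\sqrt{s_F^2/n_F + s_M^2/n_M}},\qquad
\nu = \frac{(s_F^2/n_F + s_M^2/n_M)^2}
{\frac{(s_F^2/n_F)^2}{n_F-1} + \frac{(s_M^2/n_M)^2}{n_M-1}}$$

gives a two-sided p-value from the $t_\nu$ distribution ($s^2$ are
unbiased group variances). A position is called *female-specific* when

* the female group mean is at least `min_group_depth` (default 5 reads),
* every male sample is at or below `absent_max_depth` (default 0), and
* the test is significant at `p_threshold` (default $10^{-4}$, raw — no
  multiple-testing correction is applied; the number of tests performed is
  reported instead), **or** the male group is identically absent.

The last clause matters: a truly W-specific position has all-zero male
depths, hence zero male variance, and when the female depths happen to tie
as well the Welch statistic is undefined. Presence/absence is then the
evidence, exactly as in the degenerate case the statistic was meant to
formalise. Calls are made per base (no windowing), which is what allows
region boundaries to be reproduced to the base pair; consecutive target
calls are merged into regions and filtered to `min_region_length_bp = 51`
("larger than 50 bp", strict).

### Why `merge_gap_bp` defaults to 10

At roughly 13&times; genome-wide coverage a hemizygous region sequences at
about 6.5&times; in females. The per-position female group mean over 20
samples then dips below the depth filter by pure Poisson noise at roughly
1 position per thousand. Under strict contiguity (`merge_gap_bp = 0`) a
single such dip splits an otherwise continuous several-hundred-bp region
into fragments, and the split point is uniformly distributed, so close to
half the simulated replicates would fail a 95% reciprocal-overlap recovery
check — not because the signal is absent but because of a bookkeeping
convention. Bridging internal non-target runs of up to 10 positions (a
scale far below the 51 bp reporting threshold) removes that artifact
without ever joining two genuinely separate regions in our simulations.
Strict contiguity remains available and is exercised by the merge-oracle
tests.

### Reading of "overall depth of coverage ≥ 5 in at least one sex group"

The filter is applied as *group mean depth at the position* $\ge 5$. This
is the simplest statistic consistent with "overall", and makes the filter
symmetric in the two sexes: positions where both group means fall below
the threshold are reported as `low_coverage` and can never seed a region.
The alternative reading (every sample $\ge 5$) would make calls depend
heavily on the weakest library and is not offered.

## Hemizygosity check

For a called region, $r$ = (region mean depth in the present sex) /
(genome-wide mean depth of that sex). Expected values are $r = 0.5$ for a
hemizygous (single-copy) segment, $1$ for diploid, $0$ for absent. The
haploid acceptance window defaults to $[0.3, 0.7]$: over a ~600 bp region
at 13&times; the sampling standard deviation of the region mean is a few
percent, but mappability and GC effects in real data motivate a generous
band. `absent` requires $r \le 0.05$ and `diploid` $r \ge 0.8$; values in
between are `ambiguous` rather than silently forced into a class.

## Paralog location and alignment

The W region's paralog is found by exact 15-mer anchoring against every
reference scaffold (both orientations), chaining hits whose diagonals
agree within a band of 500 bp (comfortably above the expected summed indel
length), excluding hits that overlap the query's own locus. The chain is
extrapolated to the full query span, which is exact whenever the
outermost stretches of the paralogs are conserved; any residual padding is
removed after alignment by trimming terminal gap columns.

The pair is aligned with an affine-gap Gotoh global aligner (compiled
code): match $+2$, mismatch $-3$, a gap of length $L$ costing $-6 - 2L$.
The gap-opening penalty is deliberately set *strictly above*
`match − mismatch`: at $-5$ the alignment may split a true deletion around
a single coincidentally matching interior base at zero score cost, making
the optimal gap **count** ambiguous; at $-6$ the single-gap representation
is uniquely optimal, so the gap inventory of a deletion-only variant
equals the deletion count. Ties that remain are broken deterministically
(substitution column preferred over opening a gap; gaps placed against the
longer sequence first). Optimality is tested against a brute-force
enumeration of all alignments on short pairs — not against any external
aligner.

The *gap inventory* lists maximal gap runs per side; the difference of the
two sides' totals always equals the input length difference, an invariant
the tests enforce on random pairs. ORFs are annotated as ATG-to-stop runs
(standard code, both strands, first ATG after the previous in-frame stop),
so a 132-aa protein occupies $399 = 3 \times (132+1)$ nt including its
stop. Protein similarity between the paralogs' products is reported as
alignment identity by default; a BLOSUM62-positive "similarity" mode
exists because published percent-similarity figures often count
conservative substitutions, and the two conventions can differ by tens of
percentage points.

## Assay design

Primer candidates are enumerated from *conserved flank windows*: alignment
windows outside the gapped core with zero gap columns and (by default)
zero mismatches, present identically in both paralogs — the consensus
flanking sequence in which a single primer pair can amplify both loci.
Constraints are explicit and configurable: length 17–25 nt, GC fraction
0.40–0.60, and a crude melting estimate (Wallace rule up to 14 nt, else
$64.9 + 41\,(n_{GC} - 16.4)/N$). Pairs are ranked by Tm balance, then by
the product-size difference between templates (larger is better — the gel
must separate the bands), and verified by in-silico PCR: a product is an
oppositely oriented pair of exact primer sites with inward-facing 3' ends,
its length the spanned distance inclusive of both primers. Mismatch
tolerance exists only for robustness experiments; a diagnostic assay wants
exact binding. Banding then follows from copy number: the shared locus
amplifies in everyone, the W locus only in ZW individuals, so ZW shows two
bands (the W band from a single-copy template, hence fainter — reported as
a copy-number annotation, not modelled quantitatively) and ZZ one. Bands
are flagged unresolvable below a 10% relative size difference, about what
routine agarose electrophoresis separates.

## What the simulator emulates — and what it does not

`simulate_reference()` builds a small multi-scaffold reference with a
planted pair of paralogous loci: a shared diploid locus and a W copy
derived from it by `n_deletions` non-overlapping deletions totalling
`total_deleted` bp plus point substitutions. Defaults state the structure
this pipeline is designed to find: a **598 bp** W region whose paralog
differs by **nine deletions totalling 230 bp**, both copies carrying an
intact **132-aa** ORF, embedded mid-scaffold in a 24 kb, three-scaffold
genome (desk scale; coordinates shrink, the statistical structure does
not). The outer 50 bp of each locus are kept identical (conserved primer
sites); deletions are at least 5 bp, mutually separated, and buffered from
substitutions so the planted inventory is unambiguous; competing ORFs of
the planted length or longer are suppressed by coordinated single-base
edits in both copies so "the longest ORF in the region" is well defined.

`simulate_depth()` draws per-sample mean depths $\lambda_s$ uniformly from
12–15&times; (the coverage regime of the motivating study) and per-position
depths as Poisson with mean $\lambda_s \cdot c/2$ for local copy number
$c$ — so males are exactly zero inside the W locus. Negative-binomial
overdispersion and a uniform dropout probability are available as knobs
for robustness tests but default off.

Not modelled: read-level artifacts (mapping ambiguity, duplicates,
GC-coverage bias), mismapping of reads from the paralog into the W region
(which in real data makes "zero male depth" only approximately true —
`absent_max_depth` exists for exactly that), repeat content, and
assembly errors. A green recovery test therefore establishes that the
statistics and bookkeeping are correct under the stated model, not that
any particular real dataset will be as clean.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive throughout; conversion to BED's
  0-based half-open convention happens only at the BED boundary, and
  preserves lengths by construction.
* Depth files are interpreted densely by default (absent positions =
  depth 0, the `samtools depth -a` reading), because breadth of coverage
  and presence/absence calls need zero-depth sites to be real.
* Sample column order in depth tables is always supplied explicitly,
  never inferred.
* Welch with both variances zero: equal means give $t=0, p=1$; unequal
  means give an undefined $p$ and the presence/absence rule governs.
* `merge_calls` on an unsorted position vector is an error, not a sort.
* Alignment of two empty sequences is an error; one empty sequence yields
  a single all-gap alignment.
* All simulation is deterministic given the seed; fixture bundles are
  byte-identical across repeated calls with the same seed.

## Known limitations

* The scan assumes the reference contains the W region (it must be
  assembled from the heterogametic sex); a Z-only reference makes the
  method blind by construction.
* Per-base testing at 20+20 samples has limited power below ~5&times;
  group mean depth; hemizygous regions in poorly covered genome segments
  are reported as `low_coverage`, not discovered.
* The melting-temperature estimate is deliberately crude; candidate pairs
  should be re-checked with a thermodynamic tool before ordering oligos.
* In-silico PCR is exact-match; primer sites carrying population-level
  SNPs will amplify in silico but can drop out in the field.
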
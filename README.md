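# sexscan

Coverage-based discovery of sex-specific genomic regions and in-silico
design of a PCR sexing assay.

## The problem

Many fishes (and other taxa) have genetic sex determination but no
visually distinct sex chromosomes and no external dimorphism before
maturity. In a ZZ/ZW (female-heterogametic) species, W-linked sequence is
present in one copy in females and absent in males, so whole-genome
resequencing of sexed individuals carries a clean signal: read depth of a
W-specific region is ~half the genome-wide mean in females and ~zero in
males. `sexscan` is for geneticists and breeders who have such sexed
resequencing coverage and want (1) the female-specific (or, in XY systems,
male-specific) regions, with evidence, and (2) a one-reaction PCR assay
that sexes individuals on an agarose gel.

## What it computes

For each genome position, per-sample depths are compared between the
sexes with **Welch's t-test**,

t = (d̄_F − d̄_M) / √(s²_F/n_F + s²_M/n_M),

with Welch–Satterthwaite degrees of freedom and two-sided p-values.
Positions with present-sex group mean ≥ 5, absent-sex per-sample depth
≤ 0, and p < 1e-4 (or an identically absent group — the degenerate
zero-variance case where presence/absence is the evidence) are merged into
regions larger than 50 bp. Hemizygosity is verified by the depth ratio
r = region mean / genome mean (≈ 0.5 for a single copy). The region's
diploid paralog is located by exact k-mer anchoring, aligned with an
affine-gap Gotoh aligner, and the deletions separating the two copies are
inventoried. A single primer pair designed in the conserved flanks
co-amplifies both loci, so its products differ by the summed deletion
length: ZW individuals show two bands, ZZ one.

A seeded synthetic-data module generates the whole stated world — a
multi-scaffold reference with a planted 598 bp hemizygous region whose
paralog differs by nine deletions totalling 230 bp, plus 20 F + 20 M
Poisson depth tables at 12–15× — and records the ground truth for
recovery testing.

## Worked example

```r
library(sexscan)

ref    <- simulate_reference(seed = 1)                 # planted-truth genome
sheet  <- default_cohort()                             # 20 F + 20 M
tables <- simulate_depth(ref$layout, sheet, depth_model(), seed = 2)

(scan <- scan_sex_regions(tables, sheet))
#> <sex_scan> target sex F: 1 region(s); 24000 Welch tests performed
#>        contig start  end length n_positions mean_depth_present frac_significant
#> 1 scaffold195  3702 4299    598         598           6.752759                1
```

One region, 598 bp: every position is female-covered, male-empty, and
significant. Its depth ratio confirms a single copy:

```r
region <- genomic_interval("scaffold195", 3702, 4299)
region_depth_ratio(region, tables, sheet, sex = "F")
#> <ploidy_call> scaffold195:3702-4299 [F]: region 6.75 / genome 13.37 = 0.505 -> haploid
```

Locate and align the diploid paralog, inventory the structural variant,
annotate the gene it contains:

```r
rs  <- substr(ref$genome[["scaffold195"]], 3702, 4299)
hit <- find_paralog(rs, ref$genome, self_exclude = region)
ss  <- substr(ref$genome[[hit$contig]], hit$start, hit$end)
aln <- trim_terminal_gaps(global_align(rs, ss, a_id = "w", b_id = "shared"))$aln
gap_inventory(aln)
#> <gap_inventory> 9 gap(s); side a total 230 bp, side b total 0 bp
find_orfs(rs, min_aa = 50)[1, c("start", "end", "strand", "nt_length", "aa_length")]
#>   start end strand nt_length aa_length
#> 1   107 505      +       399       132
```

The W copy lacks 230 bp in nine deletions and encodes a 132-aa protein
(399 nt including the stop). Design the assay and predict the gel:

```r
pairs <- design_primer_pair(aln, aln$a, aln$b)
pairs[1, c("fwd_seq", "rev_seq", "product_a", "product_b", "product_diff")]
#>             fwd_seq           rev_seq product_a product_b product_diff
#> 1 GAAACCCCGAGAAAACA GCTTGTCTGTGCTTTGT       548       778          230

top <- pairs[1, ]
predict_banding("ZW", top$product_b, top$product_a)$bands   # 778 548 : two bands
predict_banding("ZZ", top$product_b, top$product_a)$bands   # 778     : one band
sex_call(c(778, 548), shared_size = 778, w_size = 548)      # "ZW"
```

The two products differ by exactly the planted 230 bp, so females (ZW)
show two well-separated bands and males (ZZ) one — a single PCR sexes any
individual. `run_all(run_config(outdir, seed))` chains all of the above
and writes `regions.bed`, `coverage.tsv`, `ploidy.json`, `alignment.txt`,
`gaps.tsv`, `orfs.tsv`, `primers.tsv`, `amplicons.fasta` and
`summary.json`; `sexscan_cli()` (installed as `inst/cli/sexscan.R`)
exposes `simulate`, `scan`, `ploidy`, `run-all` and `sex-call`
subcommands.

## Scope

The package consumes per-base depth tables (`samtools depth` dialect) —
read alignment itself, BLAST searches, phylogenetics and wet-lab
protocols are out of scope. See `vignettes/sexscan-methods.Rmd` for the
model, parameter rationale, simulator assumptions and limitations.
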
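test_that("global_align handles forced and degenerate cases", {
  a <- "ACGTACGTACGT"
  aln <- global_align(a, a)
  expect_equal(aln$aligned_a, a)
  expect_equal(aln$aligned_b, a)
  expect_equal(gap_inventory(aln)$n_gaps, 0L)

  # one internal 5 bp deletion: forced single gap on b's side
  b <- paste0(substr(a, 1, 4), substr(a, 10, 12))
  aln <- global_align(a, b)
  inv <- gap_inventory(aln)
  expect_equal(inv$n_gaps, 1L)
  expect_equal(inv$total_b, 5L)
  expect_equal(inv$total_a, 0L)

  expect_error(global_align("ACGT", "ACXT"), "invalid dna residue 'X' at position 3")
  expect_error(global_align("", ""), "empty")

  # protein alphabet accepted
  p <- global_align("MKV", "MKV", alphabet = "protein")
  expect_equal(p$score, 3 * 2)
})

test_that("alignment score equals exhaustive enumeration on small pairs", {
  set.seed(51)
  sc <- align_scoring()
  for (case in 1:60) {
    a <- random_dna_str(sample(0:6, 1))
    b <- random_dna_str(sample(1:6, 1))
    aln <- global_align(a, b)
    expect_equal(aln$score, enumerate_align_score(a, b, sc),
                 label = paste("case", case, a, b))
    # de-gapping recovers the inputs
    expect_equal(gsub("-", "", aln$aligned_a), a)
    expect_equal(gsub("-", "", aln$aligned_b), b)
    # symmetric scoring: score invariant under argument swap
    expect_equal(global_align(b, a)$score, aln$score)
  }
})

test_that("gap inventory conserves the length difference", {
  set.seed(52)
  for (case in 1:25) {
    a <- random_dna_str(sample(5:60, 1))
    b <- random_dna_str(sample(5:60, 1))
    inv <- gap_inventory(global_align(a, b))
    expect_equal(inv$total_a - inv$total_b, nchar(b) - nchar(a))
  }
})

test_that("terminal gap trimming refines padded subject intervals", {
  set.seed(53)
  core <- random_dna_str(120)
  padded <- paste0(random_dna_str(15), core, random_dna_str(7))
  tr <- trim_terminal_gaps(global_align(core, padded))
  expect_equal(tr$trimmed_b[1L], 15L)
  expect_equal(tr$trimmed_b[2L], 7L)
  expect_equal(tr$aln$b, core)
  expect_equal(gap_inventory(tr$aln)$n_gaps, 0L)
})

test_that("find_paralog locates the planted shared locus exactly", {
  world <- default_world()
  ref <- world$ref
  wl <- ref$layout$w_locus
  rs <- substr(ref$genome[[wl$contig]], wl$start, wl$end)
  hit <- find_paralog(rs, ref$genome, self_exclude = wl)
  expect_equal(hit$contig, "scaffold4")
  expect_equal(hit$start, ref$layout$shared_locus$start)
  expect_equal(hit$end, ref$layout$shared_locus$end)
  expect_equal(hit$strand, "+")

  # no paralog anywhere: empty result
  set.seed(54)
  lonely <- c(s1 = random_dna_str(4000))
  expect_null(find_paralog(random_dna_str(300), lonely))

  # self-hit excluded: querying the W locus against its own scaffold only
  # still returns nothing but the excluded self interval
  sub <- ref$genome["scaffold195"]
  expect_null(find_paralog(rs, sub, self_exclude = wl))

  # reverse-strand paralog detected
  genome2 <- ref$genome
  genome2[["scaffold1"]] <- paste0(
    substr(genome2[["scaffold1"]], 1, 1000),
    sexscan:::revcomp(rs),
    substr(genome2[["scaffold1"]], 1001, 4000))
  hit2 <- find_paralog(rs, genome2["scaffold1"])
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$start, 1001L)
  expect_equal(hit2$end, 1000L + nchar(rs))
})

test_that("fixture paralog alignment recovers the planted deletions", {
  fx <- default_alignment()
  inv <- gap_inventory(fx$aln)
  expect_equal(inv$n_gaps, 9L)
  expect_equal(inv$total_a, 230L)
  expect_equal(inv$total_b, 0L)
  # recovered gap sizes match the planted deletion sizes exactly
  truth <- default_world()$ref$truth$deletions
  expect_equal(sort(inv$gaps$length), sort(truth$length))
})

test_that("ORF finding and translation follow the standard code", {
  expect_equal(find_orfs("ATGTAA", min_aa = 1)$protein, "M")
  expect_equal(nrow(find_orfs("CCCCCCTAACCC", min_aa = 1)), 0L)

  # 399 nt CDS -> 132 aa, as for a (stop-inclusive) 101,840..102,238 gene
  set.seed(55)
  cds <- sexscan:::random_orf(132L)
  expect_equal(nchar(cds), 399L)
  expect_equal(nchar(translate_cds(cds)), 132L)
  hit <- find_orfs(paste0("CCTAGCC", cds, "GGC"), min_aa = 100)
  expect_equal(hit$nt_length[1L], 399L)
  expect_equal(hit$aa_length[1L], 132L)
  expect_equal(hit$start[1L], 8L)

  # minus-strand ORF reported in forward coordinates
  rc <- sexscan:::revcomp(paste0("GG", cds, "AA"))
  hits <- find_orfs(rc, min_aa = 100)
  expect_equal(hits$strand[1L], "-")
  expect_equal(hits$aa_length[1L], 132L)
  expect_equal(hits$start[1L], 3L)
  expect_equal(hits$end[1L], 401L)
  expect_equal(hits$protein[1L], translate_cds(cds))
})

test_that("translate_cds validates frame and internal stops", {
  expect_error(translate_cds("ATGAA"), "not a multiple of 3")
  expect_error(translate_cds("ATGTAAAAATAA"), "internal stop codon at codon 2")
  expect_equal(translate_cds("ATGGCT"), "MA")
})

test_that("protein identity counts identical columns", {
  p <- "MKVLAATNWQRSDEFGHIKL"
  expect_equal(protein_identity(global_align(p, p, alphabet = "protein")), 1)
  # exactly 5 of 20 residues substituted -> identity 0.75
  q <- p
  substr(q, 2, 2) <- "A"; substr(q, 5, 5) <- "G"; substr(q, 9, 9) <- "C"
  substr(q, 13, 13) <- "W"; substr(q, 17, 17) <- "Y"
  aln <- global_align(p, q, alphabet = "protein")
  expect_equal(protein_identity(aln), 0.75)
  # fully disjoint residues
  aln0 <- global_align("AAAA", "WWWW", alphabet = "protein")
  expect_equal(protein_identity(aln0), 0)
})
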
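test_that("simulated paralog pair has the planted structure", {
  ref <- default_world()$ref
  tr <- ref$truth
  expect_equal(interval_length(ref$layout$w_locus), 598L)
  expect_equal(interval_length(ref$layout$shared_locus), 828L)
  # length difference equals the planted total deletion size
  expect_equal(interval_length(ref$layout$shared_locus) -
                 interval_length(ref$layout$w_locus), 230L)
  expect_equal(nrow(tr$deletions), 9L)
  expect_equal(sum(tr$deletions$length), 230L)
  # deletions do not overlap and stay clear of the conserved flanks
  d <- tr$deletions[order(tr$deletions$start), ]
  expect_true(all(diff(d$start) >= head(d$length, -1L)))
  expect_true(min(d$start) > tr$flank_len)
  expect_true(max(d$start + d$length - 1L) <= 828L - tr$flank_len)
  # flanks identical between copies
  w_seq <- substr(ref$genome[["scaffold195"]], ref$layout$w_locus$start,
                  ref$layout$w_locus$end)
  s_seq <- substr(ref$genome[["scaffold4"]], ref$layout$shared_locus$start,
                  ref$layout$shared_locus$end)
  fl <- tr$flank_len
  expect_identical(substr(w_seq, 1, fl), substr(s_seq, 1, fl))
  expect_identical(substr(w_seq, 599 - fl, 598), substr(s_seq, 829 - fl, 828))
  # the planted ORF translates to the stated protein length
  orf_seq <- substr(w_seq, tr$orf_w_local[1L], tr$orf_w_local[2L])
  expect_equal(nchar(orf_seq), 399L)
  expect_equal(nchar(translate_cds(orf_seq)), 132L)
})

test_that("degenerate generator settings behave as constructed", {
  # no deletions, no substitutions: identical paralogs
  ref0 <- simulate_reference(seed = 3, n_deletions = 0L, total_deleted = 0L,
                             substitution_rate = 0)
  w <- ref0$layout$w_locus; s <- ref0$layout$shared_locus
  expect_identical(substr(ref0$genome[[w$contig]], w$start, w$end),
                   substr(ref0$genome[[s$contig]], s$start, s$end))

  # k = 3 deletions totalling 60: gap inventory (3, 60) after alignment
  ref3 <- simulate_reference(seed = 4, n_deletions = 3L, total_deleted = 60L,
                             substitution_rate = 0)
  w <- ref3$layout$w_locus; s <- ref3$layout$shared_locus
  aln <- global_align(substr(ref3$genome[[w$contig]], w$start, w$end),
                      substr(ref3$genome[[s$contig]], s$start, s$end))
  inv <- gap_inventory(aln)
  expect_equal(inv$n_gaps, 3L)
  expect_equal(inv$total_a, 60L)
  expect_equal(inv$total_b, 0L)

  # no room for flanks errors out
  expect_error(simulate_reference(seed = 5, w_region_length = 100L,
                                  total_deleted = 230L),
               "no room")
})

test_that("depth model produces the copy-number signal", {
  world <- default_world()
  layout <- world$ref$layout
  tabs <- world$tables
  wv <- layout$w_locus
  males <- world$sheet$sample[world$sheet$sex == "M"]
  females <- world$sheet$sample[world$sheet$sex == "F"]
  wdepth <- tabs$scaffold195$depth[wv$start:wv$end, , drop = FALSE]
  # copy number 0: exact zeros for every male across the W locus
  expect_true(all(wdepth[, males] == 0L))
  # copy number 1 in females: empirical mean ~ lambda/2 within 3 sigma
  lambda <- attr(tabs, "lambda")[females]
  mu <- mean(lambda) / 2
  n <- length(wdepth[, females])
  expect_lt(abs(mean(wdepth[, females]) - mu), 3 * sqrt(mu / n))

  # diploid background: sample mean ~ lambda within 3 sigma (Poisson)
  samp <- females[1L]
  bg <- tabs$scaffold1$depth[, samp]
  lam <- attr(tabs, "lambda")[samp]
  expect_lt(abs(mean(bg) - lam), 3 * sqrt(lam / length(bg)))
})

test_that("single-copy mean halves relative to two-copy mean", {
  sheet <- sample_sheet(c("f1", "f2", "m1", "m2"), c("F", "F", "M", "M"))
  layout <- list(scaffold_lengths = c(big = 100000L, w = 2000L),
                 w_locus = genomic_interval("w", 501L, 1500L),
                 shared_locus = genomic_interval("big", 1L, 100L),
                 heterogametic_sex = "F")
  tabs <- simulate_depth(layout, sheet, depth_model(c(12, 12)), seed = 11)
  m <- mean(tabs$big$depth[, "f1"])
  expect_lt(abs(m - 12), 3 * sqrt(12 / 1e5))
  m1 <- mean(tabs$w$depth[501:1500, c("f1", "f2")])
  expect_lt(abs(m1 - 6), 3 * sqrt(6 / 2000))
  expect_true(all(tabs$w$depth[501:1500, c("m1", "m2")] == 0L))
})

test_that("negative binomial and dropout options change the right things", {
  sheet <- sample_sheet(c("f1", "f2", "m1", "m2"), c("F", "F", "M", "M"))
  layout <- list(scaffold_lengths = c(s = 20000L, w = 1000L),
                 w_locus = genomic_interval("w", 301L, 700L),
                 shared_locus = genomic_interval("s", 1L, 100L),
                 heterogametic_sex = "F")
  nb <- simulate_depth(layout, sheet, depth_model(c(12, 12), dispersion = 0.3),
                       seed = 12)
  x <- as.numeric(nb$s$depth[, "f1"])
  # variance well above Poisson (expected mu + 0.3 mu^2 = 55.2 at mu = 12)
  expect_gt(var(x), 2 * mean(x))

  q <- 0.2
  dp <- simulate_depth(layout, sheet, depth_model(c(12, 12), dropout = q),
                       seed = 13)
  cov <- coverage_summary(dp["s"], sheet)
  # breadth ~ (1 - q) within binomial 3 sigma (P(Pois(12) = 0) is negligible)
  tol <- 3 * sqrt(q * (1 - q) / 20000)
  expect_true(all(abs(cov$samples$breadth - (1 - q)) < tol + 1e-5))
})

test_that("fixture bundles are deterministic and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  small <- list(scaffold_lengths = c(scaffold4 = 3000L, scaffold195 = 2500L))
  b1 <- make_fixture_bundle(d1, seed = 21, reference_params = small,
                            sheet = default_cohort(3L, 3L))
  b2 <- make_fixture_bundle(d2, seed = 21, reference_params = small,
                            sheet = default_cohort(3L, 3L))
  for (f in c("genome.fasta", "depth.tsv", "samples.tsv", "truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$w_region_length, 598L)
  expect_equal(truth$w_region$end - truth$w_region$start + 1L, 598L)
  # bundle is readable by the io layer
  sheet <- read_sample_sheet(b1$paths$samples)
  tabs <- read_depth_tsv(b1$paths$depth, sheet$sample)
  expect_setequal(names(tabs), c("scaffold4", "scaffold195"))
})
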
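test_that("welch_t matches closed forms, t.test, and handles degeneracy", {
  # frozen worked example, recomputed by the quadrature oracle
  r <- welch_t(c(10, 11, 12, 13), c(2, 3, 4, 5))
  o <- welch_oracle(c(10, 11, 12, 13), c(2, 3, 4, 5))
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(r$df, o$df, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-10)

  # identical groups
  r <- welch_t(c(10, 12, 14), c(10, 12, 14))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # antisymmetry under group swap
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1), 5, 2)
    b <- rnorm(sample(2:8, 1), 3, 1)
    ra <- welch_t(a, b); rb <- welch_t(b, a)
    expect_equal(ra$t, -rb$t)
    expect_equal(ra$p, rb$p)
    # agreement with stats::t.test as an independent route
    tt <- t.test(a, b)
    expect_equal(ra$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(ra$df, unname(tt$parameter), tolerance = 1e-12)
    expect_equal(ra$p, tt$p.value, tolerance = 1e-12)
  }

  # both variances zero, means differ: degenerate, p undefined
  r <- welch_t(c(6, 6, 6), c(0, 0, 0))
  expect_true(r$degenerate)
  expect_true(is.na(r$p))

  expect_error(welch_t(5, c(1, 2)), "at least 2")
})

test_that("classify_position applies depth and presence/absence rules", {
  cfg <- scan_config()
  # hemizygous signature: female mean 6.6, all males zero
  f <- c(7, 6, 7, 6, 7); m <- c(0, 0, 0, 0, 0)
  expect_equal(classify_position(f, m, cfg)$status, "female_specific")
  # no signal anywhere
  expect_equal(classify_position(rep(0, 5), rep(0, 5), cfg)$status,
               "low_coverage")
  # female mean below the depth filter: rule-forced low coverage
  expect_equal(classify_position(c(5, 5, 5, 5, 4.5), rep(0, 5), cfg)$status,
               "low_coverage")
  # strong coverage in both sexes
  expect_equal(classify_position(c(12, 13, 14), c(13, 12, 14), cfg)$status,
               "shared")
  # male-specific is symmetric
  expect_equal(classify_position(rep(0, 4), c(6, 7, 6, 7), cfg)$status,
               "male_specific")
  # one male read disqualifies female specificity (absent_max_depth = 0)
  expect_equal(classify_position(c(7, 6, 7, 6), c(1, 0, 0, 0), cfg)$status,
               "shared")
})

test_that("merge_calls equals brute-force interval enumeration", {
  # deterministic threshold cases
  cfg <- scan_config(merge_gap_bp = 0L)
  run61 <- merge_calls(1:61, rep("female_specific", 61), cfg)
  expect_equal(nrow(run61), 1L)
  expect_equal(run61$length, 61L)
  expect_equal(nrow(merge_calls(1:50, rep("female_specific", 50), cfg)), 0L)
  expect_equal(nrow(merge_calls(1:80, rep("shared", 80), cfg)), 0L)
  expect_error(merge_calls(c(3L, 1L), rep("shared", 2), cfg), "sorted")

  # randomized suite vs the oracle, tables up to 200 positions
  set.seed(41)
  statuses <- c("female_specific", "male_specific", "shared", "low_coverage")
  for (case in 1:60) {
    n <- sample(0:200, 1)
    pos <- sort(sample.int(300, n))
    status <- sample(statuses, n, replace = TRUE,
                     prob = c(0.45, 0.05, 0.3, 0.2))
    cfg <- scan_config(min_region_length_bp = sample(c(1L, 3L, 10L, 51L), 1),
                       merge_gap_bp = sample(c(0L, 1L, 5L, 10L), 1),
                       target_sex = sample(c("F", "M"), 1))
    got <- merge_calls(pos, status, cfg)
    want <- merge_oracle(pos, status, cfg)
    expect_equal(got[, c("start", "end")], want,
                 ignore_attr = TRUE, label = paste("case", case))
  }
})

test_that("scan recovers the planted hemizygous region", {
  world <- default_world()
  sc <- scan_sex_regions(world$tables, world$sheet)
  expect_equal(nrow(sc$regions), 1L)
  r <- sc$regions[1L, ]
  truth <- world$ref$layout$w_locus
  expect_equal(r$contig, truth$contig)
  ov <- reciprocal_overlap(genomic_interval(r$contig, r$start, r$end), truth)
  expect_gte(ov, 0.95)
  # the presence-sex depth sits near half the genome-wide mean
  expect_gt(r$mean_depth_present, 5)
  expect_lt(r$mean_depth_present, 9)
  expect_gt(sc$n_tests, 0L)
})

test_that("scan is monotone in its thresholds", {
  world <- default_world()
  base <- scan_sex_regions(world$tables, world$sheet)
  stricter <- scan_sex_regions(world$tables, world$sheet,
                               scan_config(min_region_length_bp = 599L))
  expect_lte(nrow(stricter$regions), nrow(base$regions))
  # lowering p_threshold never increases the count of qualified positions
  loose <- scan_sex_regions(world$tables, world$sheet,
                            scan_config(p_threshold = 1e-2))
  tight <- scan_sex_regions(world$tables, world$sheet,
                            scan_config(p_threshold = 1e-8))
  expect_lte(tight$position_counts[["female_specific"]],
             loose$position_counts[["female_specific"]])
})

test_that("sex-swapped world gives the mirror-image result", {
  ref <- simulate_reference(seed = 101L, heterogametic_sex = "M")
  sheet <- default_cohort()
  tabs <- simulate_depth(ref$layout, sheet, depth_model(), seed = 103L)
  scM <- scan_sex_regions(tabs, sheet, scan_config(target_sex = "M"))
  expect_equal(nrow(scM$regions), 1L)
  expect_gte(reciprocal_overlap(
    genomic_interval(scM$regions$contig[1L], scM$regions$start[1L],
                     scM$regions$end[1L]),
    ref$layout$w_locus), 0.95)

  # exact symmetry: swapping the labels on the same depth matrices and
  # retargeting the scan reproduces the female-target result
  world <- default_world()
  swapped <- sample_sheet(world$sheet$sample,
                          ifelse(world$sheet$sex == "F", "M", "F"))
  a <- scan_sex_regions(world$tables, world$sheet, scan_config(target_sex = "F"))
  b <- scan_sex_regions(world$tables, swapped, scan_config(target_sex = "M"))
  expect_equal(a$regions[, c("contig", "start", "end", "length")],
               b$regions[, c("contig", "start", "end", "length")])

  expect_error(scan_sex_regions(world$tables,
                                sample_sheet(letters[1:4], rep("M", 4))),
               "at least 2 samples per sex")
})
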
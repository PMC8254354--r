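#' Scan configuration
#'
#' Thresholds follow the source analysis where stated: positions are usable
#' when mean depth is >= `min_group_depth` (default 5) in at least one sex
#' group; sex-differential depth is significant at two-sided Welch
#' `p < p_threshold` (default 1e-4, no multiple-testing correction — the
#' number of tests performed is reported instead); reported regions must be
#' larger than 50 bp, i.e. `min_region_length_bp = 51`; the absent sex may
#' show at most `absent_max_depth` reads per sample (default 0). A region
#' may bridge internal runs of at most `merge_gap_bp` non-target positions
#' (default 10) so that isolated positions dipping below the depth filter by
#' sampling noise do not fragment a real hemizygous region; set it to 0 for
#' strict contiguity.
#'
#' @param min_group_depth position is usable if some sex group mean >= this
#' @param p_threshold two-sided Welch p-value cutoff
#' @param min_region_length_bp smallest reported region (51 = "larger than
#'   50 bp")
#' @param absent_max_depth maximum per-sample depth tolerated in the sex the
#'   region is absent from
#' @param merge_gap_bp largest internal non-target gap bridged when merging
#' @param target_sex which sex the region must be specific to (`"F"`/`"M"`)
#' @return list of class `"scan_config"`
#' @export
scan_config <- function(min_group_depth = 5, p_threshold = 1e-4,
                        min_region_length_bp = 51L, absent_max_depth = 0,
                        merge_gap_bp = 10L, target_sex = "F") {
  stopifnot(min_group_depth >= 0, p_threshold > 0, p_threshold < 1,
            min_region_length_bp >= 0, absent_max_depth >= 0,
            merge_gap_bp >= 0, target_sex %in% c("F", "M"))
  structure(list(min_group_depth = min_group_depth, p_threshold = p_threshold,
                 min_region_length_bp = as.integer(min_region_length_bp),
                 absent_max_depth = absent_max_depth,
                 merge_gap_bp = as.integer(merge_gap_bp),
                 target_sex = target_sex),
            class = "scan_config")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch–Satterthwaite degrees of freedom and
#' a two-sided p-value. When both group variances are zero the test is
#' degenerate: equal means give `t = 0, p = 1`; unequal means give an
#' undefined p (`NA`) with `degenerate = TRUE`, and presence/absence rules
#' take over in [classify_position()].
#'
#' @param a,b numeric vectors, each of length >= 2
#' @return list with `t`, `df`, `p`, `degenerate`
#' @examples
#' welch_t(c(10, 11, 12, 13), c(2, 3, 4, 5))
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("Welch's t-test needs at least 2 observations per group")
  s <- welch_stats(matrix(a, nrow = 1L), matrix(b, nrow = 1L))
  list(t = s$t, df = s$df, p = s$p, degenerate = s$degenerate)
}

# vectorised Welch over rows of two matrices (rows = positions)
welch_stats <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- (rowSums(A * A) - na * ma^2) / (na - 1)
  vb <- (rowSums(B * B) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)     # guard tiny negative round-off
  se2 <- va / na + vb / nb
  t <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), ifelse(ma == mb, 0, NA_real_))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t), df), ifelse(ma == mb, 1, NA_real_))
  degenerate <- se2 == 0 & ma != mb
  data.frame(mean_a = ma, var_a = va, mean_b = mb, var_b = vb,
             t = t, df = df, p = p, degenerate = degenerate)
}

# vectorised per-position status given group summaries
classify_status <- function(mF, vF, maxF, mM, vM, maxM, p, config) {
  low <- mF < config$min_group_depth & mM < config$min_group_depth
  sig_f <- ifelse(is.na(p), TRUE, p < config$p_threshold | vM == 0)
  sig_m <- ifelse(is.na(p), TRUE, p < config$p_threshold | vF == 0)
  fs <- !low & mF >= config$min_group_depth & maxM <= config$absent_max_depth & sig_f
  ms <- !low & mM >= config$min_group_depth & maxF <= config$absent_max_depth & sig_m
  status <- rep("shared", length(mF))
  status[low] <- "low_coverage"
  status[fs] <- "female_specific"
  status[ms & !fs] <- "male_specific"
  status
}

#' Classify one position by sex-differential depth
#'
#' A position is `low_coverage` when both sex-group means fall below
#' `min_group_depth`; `female_specific` when the female mean passes that
#' filter, every male sample is at or below `absent_max_depth`, and either
#' the Welch p-value is below `p_threshold` or the male group is identically
#' absent (the zero-variance degenerate case, where presence/absence stands
#' in for the test); symmetrically for `male_specific`; otherwise `shared`.
#'
#' @param depths_F,depths_M per-sample depths at the position
#' @param config a [scan_config]
#' @return list with group summaries, the [welch_t] result and `status`
#' @export
classify_position <- function(depths_F, depths_M, config = scan_config()) {
  w <- welch_t(depths_F, depths_M)
  status <- classify_status(mean(depths_F), var(depths_F), max(depths_F),
                            mean(depths_M), var(depths_M), max(depths_M),
                            w$p, config)
  list(mean_F = mean(depths_F), mean_M = mean(depths_M),
       var_F = var(depths_F), var_M = var(depths_M),
       max_F = max(depths_F), max_M = max(depths_M),
       welch = w, status = status)
}

#' Merge per-position calls into sex-specific regions
#'
#' Maximal runs of target-status positions are joined when separated by at
#' most `merge_gap_bp` positions of other status, then filtered to
#' `min_region_length_bp`. Output intervals are sorted and non-overlapping.
#'
#' @param pos sorted integer positions
#' @param status character vector of per-position statuses, parallel to `pos`
#' @param config a [scan_config]; `target_sex` selects the target status
#' @return data.frame with `start`, `end`, `length`, `n_positions` (target
#'   positions inside the interval)
#' @export
merge_calls <- function(pos, status, config = scan_config()) {
  stopifnot(length(pos) == length(status))
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be sorted")
  target <- paste0(ifelse(config$target_sex == "F", "female", "male"), "_specific")
  tpos <- pos[status == target]
  if (!length(tpos))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), n_positions = integer(0)))
  brk <- which(diff(tpos) > config$merge_gap_bp + 1L)
  run_start <- tpos[c(1L, brk + 1L)]
  run_end <- tpos[c(brk, length(tpos))]
  n_in <- vapply(seq_along(run_start), function(i)
    sum(tpos >= run_start[i] & tpos <= run_end[i]), integer(1L))
  out <- data.frame(start = run_start, end = run_end,
                    length = run_end - run_start + 1L, n_positions = n_in)
  out[out$length >= config$min_region_length_bp, , drop = FALSE]
}

#' Genome scan for sex-specific regions
#'
#' Runs [classify_position()] logic across every position of every contig
#' (vectorised) and merges target calls with [merge_calls()]. Requires at
#' least two samples per sex.
#'
#' @param tables list of [depth_table] objects (e.g. from
#'   [read_depth_tsv()] or [simulate_depth()])
#' @param sheet a [sample_sheet]
#' @param config a [scan_config]
#' @return object of class `"sex_scan"`: `regions` (data.frame with contig,
#'   coordinates, mean depth in the present sex, fraction of positions with
#'   defined p below threshold), `position_counts` per status,
#'   `n_tests` (positions with a defined p-value), and the `config`
#' @export
scan_sex_regions <- function(tables, sheet, config = scan_config()) {
  groups <- sex_groups(sheet)
  present <- if (config$target_sex == "F") groups$F else groups$M
  regions <- list()
  counts <- c(female_specific = 0L, male_specific = 0L, shared = 0L,
              low_coverage = 0L)
  n_tests <- 0L
  for (tb in tables) {
    missing <- setdiff(sheet$sample, colnames(tb$depth))
    if (length(missing))
      stop("samples missing from depth table ", tb$contig, ": ",
           paste(missing, collapse = ", "))
    Fm <- tb$depth[, groups$F, drop = FALSE]
    Mm <- tb$depth[, groups$M, drop = FALSE]
    st <- welch_stats(Fm, Mm)
    maxF <- do.call(pmax, as.data.frame(Fm))
    maxM <- do.call(pmax, as.data.frame(Mm))
    status <- classify_status(st$mean_a, st$var_a, maxF,
                              st$mean_b, st$var_b, maxM, st$p, config)
    tab <- table(factor(status, levels = names(counts)))
    counts <- counts + as.integer(tab)
    n_tests <- n_tests + sum(!is.na(st$p))
    reg <- merge_calls(tb$pos, status, config)
    if (nrow(reg)) {
      pres_mean <- if (config$target_sex == "F") st$mean_a else st$mean_b
      reg$contig <- tb$contig
      reg$mean_depth_present <- NA_real_
      reg$frac_significant <- NA_real_
      for (i in seq_len(nrow(reg))) {
        idx <- which(tb$pos >= reg$start[i] & tb$pos <= reg$end[i])
        reg$mean_depth_present[i] <- mean(pres_mean[idx])
        pp <- st$p[idx]
        reg$frac_significant[i] <- mean(!is.na(pp) & pp < config$p_threshold)
      }
      regions[[tb$contig]] <- reg
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               n_positions = integer(0), contig = character(0),
               mean_depth_present = numeric(0), frac_significant = numeric(0))
  rownames(regions) <- NULL
  regions <- regions[, c("contig", "start", "end", "length", "n_positions",
                         "mean_depth_present", "frac_significant")]
  structure(list(regions = regions, position_counts = counts,
                 n_tests = n_tests, config = config),
            class = "sex_scan")
}

#' @export
print.sex_scan <- function(x, ...) {
  cat("<sex_scan> target sex ", x$config$target_sex, ": ",
      nrow(x$regions), " region(s); ", x$n_tests,
      " Welch tests performed\n", sep = "")
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' Write scan outputs (BED + TSV report)
#' @param scan a `sex_scan`
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
write_scan_report <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bed <- file.path(dir, "regions.bed")
  tsv <- file.path(dir, "regions.tsv")
  write_bed(scan$regions, bed)
  data.table::fwrite(scan$regions, tsv, sep = "\t")
  invisible(c(bed = bed, tsv = tsv))
}
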
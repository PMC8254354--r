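#' Per-sample coverage breadth and depth summary
#'
#' Breadth is the fraction of positions with depth at least
#' `breadth_min_depth` (default 1; the minimum depth that counts as
#' "covered" is a convention, not a biological constant). Assumes dense
#' tables where zero-depth positions are explicit.
#'
#' @param tables list of [depth_table] objects
#' @param sheet a [sample_sheet]
#' @param breadth_min_depth minimum depth for a position to count as covered
#' @return list of class `"coverage_summary"`: `samples` data.frame
#'   (sample, sex, breadth, mean_depth) and `groups` data.frame (sex,
#'   mean_breadth, mean_depth)
#' @export
coverage_summary <- function(tables, sheet, breadth_min_depth = 1L) {
  if (!length(tables) || !sum(vapply(tables, function(t) length(t$pos), 0L)))
    stop("empty depth tables")
  total <- 0L
  covered <- depth_sum <- setNames(numeric(nrow(sheet)), sheet$sample)
  for (tb in tables) {
    d <- tb$depth[, sheet$sample, drop = FALSE]
    total <- total + nrow(d)
    covered <- covered + colSums(d >= breadth_min_depth)
    depth_sum <- depth_sum + colSums(d)
  }
  samples <- data.frame(sample = sheet$sample, sex = sheet$sex,
                        breadth = covered / total,
                        mean_depth = depth_sum / total)
  groups <- do.call(rbind, lapply(split(samples, samples$sex), function(g)
    data.frame(sex = g$sex[1L], mean_breadth = mean(g$breadth),
               mean_depth = mean(g$mean_depth))))
  rownames(groups) <- NULL
  structure(list(samples = samples, groups = groups,
                 breadth_min_depth = breadth_min_depth),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat("<coverage_summary> breadth ",
      sprintf("%.2f-%.2f%%", 100 * min(x$samples$breadth),
              100 * max(x$samples$breadth)), "; group mean depths: ",
      paste(sprintf("%s=%.2f", x$groups$sex, x$groups$mean_depth),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Hemizygosity check via the region/genome depth ratio
#'
#' Computes r = (mean depth over the region in the present sex) /
#' (genome-wide mean depth of that sex). In a diploid, a single-copy
#' (hemizygous) segment sequences at about half the genome-wide depth, so
#' r near 0.5 calls `haploid`; r near 1 calls `diploid`; r near 0 `absent`;
#' anything else `ambiguous`. The default haploid window \[0.3, 0.7\] is
#' deliberately generous: at ~13x coverage, the sampling noise of a mean
#' over a few hundred positions is substantial.
#'
#' @param region a [genomic_interval] (or 1-row data.frame with contig,
#'   start, end)
#' @param tables list of [depth_table] objects covering the region's contig
#' @param sheet a [sample_sheet]
#' @param sex which sex the region is present in (`"F"`/`"M"`)
#' @param haploid_window,diploid_low,absent_high call thresholds on r
#' @return list of class `"ploidy_call"`: `ratio`, `call`, `region_mean`,
#'   `genome_mean`
#' @export
region_depth_ratio <- function(region, tables, sheet, sex = "F",
                               haploid_window = c(0.3, 0.7),
                               diploid_low = 0.8, absent_high = 0.05) {
  samples <- sheet$sample[sheet$sex == sex]
  if (!length(samples)) stop("no samples of sex ", sex)
  tb <- NULL
  for (t in tables) if (t$contig == region$contig) tb <- t
  if (is.null(tb)) stop("no depth table for contig ", region$contig)
  idx <- which(tb$pos >= region$start & tb$pos <= region$end)
  if (length(idx) == 0L) stop("region outside depth table coordinates")
  region_mean <- mean(tb$depth[idx, samples, drop = FALSE])
  gsum <- 0; gn <- 0
  for (t in tables) {
    gsum <- gsum + sum(as.numeric(t$depth[, samples, drop = FALSE]))
    gn <- gn + length(t$pos) * length(samples)
  }
  genome_mean <- gsum / gn
  if (genome_mean == 0) stop("zero genome-wide mean depth for sex ", sex)
  r <- region_mean / genome_mean
  call <- if (r <= absent_high) "absent"
  else if (r >= haploid_window[1L] && r <= haploid_window[2L]) "haploid"
  else if (r >= diploid_low) "diploid"
  else "ambiguous"
  structure(list(region = region, sex = sex, ratio = r, call = call,
                 region_mean = region_mean, genome_mean = genome_mean),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("<ploidy_call> %s:%d-%d [%s]: region %.2f / genome %.2f = %.3f -> %s\n",
              x$region$contig, x$region$start, x$region$end, x$sex,
              x$region_mean, x$genome_mean, x$ratio, x$call))
  invisible(x)
}
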
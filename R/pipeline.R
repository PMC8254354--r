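#' Run configuration for the full pipeline
#'
#' Bundles all stage configurations. Defaults equal the thresholds of the
#' underlying analysis where one exists (depth filter 5, p < 1e-4, regions
#' larger than 50 bp, zero tolerated depth in the absent sex); everything
#' else is an explicit, logged package default.
#'
#' @param outdir output directory
#' @param seed integer seed used by the simulation stage
#' @param fixture_dir optional directory with existing inputs
#'   (`genome.fasta`, `depth.tsv`, `samples.tsv`); when `NULL` a fixture is
#'   simulated into `outdir/fixture`
#' @param reference_params overrides for [simulate_reference()]
#' @param model a [depth_model]
#' @param sheet a [sample_sheet] used when simulating
#' @param scan a [scan_config]
#' @param scoring an [align_scoring]
#' @param min_orf_aa smallest ORF annotated in the called region
#' @param design_params overrides for [design_primer_pair()]
#' @return list of class `"run_config"`
#' @export
run_config <- function(outdir, seed = 1L, fixture_dir = NULL,
                       reference_params = list(), model = depth_model(),
                       sheet = default_cohort(), scan = scan_config(),
                       scoring = align_scoring(), min_orf_aa = 50L,
                       design_params = list()) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 fixture_dir = fixture_dir,
                 reference_params = reference_params, model = model,
                 sheet = sheet, scan = scan, scoring = scoring,
                 min_orf_aa = min_orf_aa, design_params = design_params),
            class = "run_config")
}

precondition_error <- function(msg) {
  stop(structure(class = c("sexscan_precondition", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stage <- function(name, expr) {
  tryCatch(expr, sexscan_precondition = function(e) stop(e), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full discovery-to-assay pipeline
#'
#' simulate (or load) -> scan -> coverage/ploidy -> paralog alignment ->
#' gap inventory -> ORF annotation -> primer design -> in-silico PCR ->
#' banding prediction. Writes `regions.bed`, `regions.tsv`,
#' `coverage.tsv`, `ploidy.json`, `alignment.txt`, `gaps.tsv`, `orfs.tsv`,
#' `primers.tsv`, `amplicons.fasta`, `config.json` and `summary.json`
#' under `config$outdir`. Deterministic given the seed: re-running with the
#' same configuration reproduces `summary.json` exactly.
#'
#' @param config a [run_config]
#' @return invisibly, the summary list (also serialized as `summary.json`)
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, scan = unclass(config$scan),
         scoring = unclass(config$scoring),
         model = unclass(config$model), min_orf_aa = config$min_orf_aa),
    file.path(config$outdir, "config.json"), auto_unbox = TRUE, digits = NA)

  inputs <- stage("inputs", {
    if (is.null(config$fixture_dir)) {
      make_fixture_bundle(file.path(config$outdir, "fixture"),
                          seed = config$seed,
                          reference_params = config$reference_params,
                          model = config$model, sheet = config$sheet)$dir
    } else {
      for (f in c("genome.fasta", "depth.tsv", "samples.tsv"))
        if (!file.exists(file.path(config$fixture_dir, f)))
          precondition_error(paste0("missing input file: ",
                                    file.path(config$fixture_dir, f)))
      config$fixture_dir
    }
  })

  genome <- stage("inputs", read_fasta(file.path(inputs, "genome.fasta")))
  sheet <- stage("inputs", read_sample_sheet(file.path(inputs, "samples.tsv")))
  tables <- stage("inputs", {
    lens <- setNames(nchar(genome), names(genome))
    read_depth_tsv(file.path(inputs, "depth.tsv"), sheet$sample,
                   dense = TRUE, contig_lengths = lens)
  })

  scan <- stage("scan", {
    if (length(unique(sheet$sex)) < 2L)
      precondition_error("sample sheet must contain both sexes")
    scan_sex_regions(tables, sheet, config$scan)
  })
  write_scan_report(scan, config$outdir)

  cov <- stage("ploidy", coverage_summary(tables, sheet))
  data.table::fwrite(cov$samples, file.path(config$outdir, "coverage.tsv"),
                     sep = "\t")
  ploidy <- stage("ploidy", lapply(seq_len(nrow(scan$regions)), function(i) {
    r <- scan$regions[i, ]
    pc <- region_depth_ratio(genomic_interval(r$contig, r$start, r$end),
                             tables, sheet, sex = config$scan$target_sex)
    list(contig = r$contig, start = r$start, end = r$end,
         ratio = pc$ratio, call = pc$call,
         region_mean = pc$region_mean, genome_mean = pc$genome_mean)
  }))
  jsonlite::write_json(ploidy, file.path(config$outdir, "ploidy.json"),
                       auto_unbox = TRUE, digits = NA)

  summary <- list(seed = config$seed, n_regions = nrow(scan$regions),
                  regions = scan$regions, n_tests = scan$n_tests,
                  ploidy = ploidy)

  if (nrow(scan$regions)) {
    main <- scan$regions[which.max(scan$regions$length), ]
    region_iv <- genomic_interval(main$contig, main$start, main$end)
    region_seq <- substr(genome[[main$contig]], main$start, main$end)

    paralog <- stage("paralog", find_paralog(region_seq, genome,
                                             self_exclude = region_iv))
    if (is.null(paralog)) {
      summary$paralog <- NULL
    } else {
      subj_seq <- substr(genome[[paralog$contig]], paralog$start, paralog$end)
      if (paralog$strand == "-") subj_seq <- revcomp(subj_seq)
      aln0 <- stage("paralog", global_align(
        region_seq, subj_seq, scoring = config$scoring,
        a_id = "w_region", b_id = "paralog"))
      # drop the padding find_paralog added around the true paralog
      tr <- stage("paralog", trim_terminal_gaps(aln0))
      aln <- tr$aln
      if (paralog$strand == "+") {
        paralog$start <- paralog$start + tr$trimmed_b[1L]
        paralog$end <- paralog$end - tr$trimmed_b[2L]
      } else {
        paralog$start <- paralog$start + tr$trimmed_b[2L]
        paralog$end <- paralog$end - tr$trimmed_b[1L]
      }
      subj_seq <- aln$b
      region_seq <- aln$a
      writeLines(format_alignment(aln), file.path(config$outdir, "alignment.txt"))
      inv <- gap_inventory(aln)
      data.table::fwrite(inv$gaps, file.path(config$outdir, "gaps.tsv"),
                         sep = "\t")
      orfs <- stage("paralog", find_orfs(region_seq, min_aa = config$min_orf_aa))
      data.table::fwrite(orfs, file.path(config$outdir, "orfs.tsv"), sep = "\t")

      pairs <- stage("design", do.call(design_primer_pair, c(
        list(aln = aln, template_a = region_seq, template_b = subj_seq),
        config$design_params)))
      data.table::fwrite(pairs, file.path(config$outdir, "primers.tsv"),
                         sep = "\t")

      summary$paralog <- paralog
      summary$alignment_score <- aln$score
      summary$gap_inventory <- list(n_gaps = inv$n_gaps,
                                    total_a = inv$total_a,
                                    total_b = inv$total_b)
      summary$orf_aa <- if (nrow(orfs)) orfs$aa_length[1L] else NA_integer_

      if (nrow(pairs)) {
        top <- pairs[1L, ]
        pcr <- stage("pcr", in_silico_pcr(top$fwd_seq, top$rev_seq, genome))
        amp <- setNames(
          substring(genome[pcr$template], pcr$start, pcr$end),
          sprintf("%s_%d_%d_%dbp", pcr$template, pcr$start, pcr$end, pcr$length))
        if (length(amp))
          write_fasta(amp, file.path(config$outdir, "amplicons.fasta"))
        banding <- list(ZZ = predict_banding("ZZ", top$product_b, top$product_a),
                        ZW = predict_banding("ZW", top$product_b, top$product_a))
        summary$primer_pair <- as.list(top)
        summary$genome_products <- pcr$length
        summary$banding <- banding
      }
    }
  }

  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Call genetic sex from an observed banding pattern
#'
#' Two expected bands (shared + W) call ZW; the shared band alone calls
#' ZZ; anything else — no bands, only the W band, or unexpected sizes — is
#' indeterminate.
#'
#' @param bands observed band sizes (bp), possibly empty
#' @param shared_size,w_size expected product sizes of the shared and
#'   W-specific locus
#' @param tol_bp size-matching tolerance (bp), e.g. gel-reading error
#' @return `"ZW"`, `"ZZ"` or `"indeterminate"`
#' @export
sex_call <- function(bands, shared_size, w_size, tol_bp = 0) {
  bands <- as.numeric(bands)
  is_shared <- abs(bands - shared_size) <= tol_bp
  is_w <- abs(bands - w_size) <= tol_bp & !is_shared
  if (any(!is_shared & !is_w)) return("indeterminate")
  has_shared <- any(is_shared); has_w <- any(is_w)
  if (has_shared && has_w) "ZW"
  else if (has_shared) "ZZ"
  else "indeterminate"
}
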
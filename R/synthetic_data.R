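#' @importFrom stats rmultinom
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# random open reading frame: ATG + (aa-1) non-stop codons + TAA
random_orf <- function(aa) {
  codons <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES)
  codons <- apply(codons[, 3:1], 1L, paste, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  paste0("ATG", paste(sample(sense, aa - 1L, replace = TRUE), collapse = ""), "TAA")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Simulate a reference genome with a planted hemizygous paralog pair
#'
#' Builds a small multi-scaffold diploid reference containing a "shared"
#' diploid locus and a W-specific locus derived from it by `n_deletions`
#' non-overlapping deletions totalling `total_deleted` bp plus point
#' substitutions, mirroring a deletion-type structural variant between a
#' female-specific region and its paralog. Both copies carry an intact open
#' reading frame of `orf_aa` amino acids, and the outer `flank_len` bases of
#' the locus are kept identical between copies (conserved primer sites).
#' The defaults state the kind of variant this pipeline targets: a 598 bp
#' hemizygous W segment whose paralog differs by nine deletions totalling
#' 230 bp, encoding a 132-aa protein.
#'
#' @param seed integer seed; the function is deterministic given it
#' @param scaffold_lengths named integer vector of scaffold lengths
#' @param w_region_length length (bp) of the W-specific locus
#' @param n_deletions number of deletions distinguishing the copies
#' @param total_deleted summed deletion length (bp); the shared locus is
#'   `w_region_length + total_deleted` long
#' @param substitution_rate per-base substitution probability applied to the
#'   W copy outside flanks, the ORF, and deletion-edge buffers
#' @param flank_len conserved flank length (bp) at each locus end
#' @param orf_aa planted protein length (aa); CDS is `3 * (orf_aa + 1)` nt
#' @param min_deletion,deletion_spacing smallest deletion size and minimum
#'   conserved spacing between deletions / zone edges
#' @param heterogametic_sex which sex carries the single-copy locus
#'   (`"F"` for a ZW system, `"M"` for XY)
#' @return list with `genome` (named character vector of scaffold
#'   sequences), `layout` (scaffold lengths, locus intervals, heterogametic
#'   sex) and `truth` (exact planted coordinates: W and shared intervals,
#'   per-deletion shared-locus offsets and sizes, ORF coordinates in both
#'   copies, substituted sites)
#' @export
simulate_reference <- function(seed = 1L,
                               scaffold_lengths = c(scaffold1 = 4000L,
                                                    scaffold4 = 12000L,
                                                    scaffold195 = 8000L),
                               w_region_length = 598L,
                               n_deletions = 9L,
                               total_deleted = 230L,
                               substitution_rate = 0.05,
                               flank_len = 50L,
                               orf_aa = 132L,
                               min_deletion = 5L,
                               deletion_spacing = 6L,
                               heterogametic_sex = "F") {
  set.seed(seed)
  stopifnot(n_deletions >= 0L, (n_deletions == 0L) == (total_deleted == 0L),
            total_deleted >= n_deletions * min_deletion,
            heterogametic_sex %in% c("F", "M"),
            all(c("scaffold4", "scaffold195") %in% names(scaffold_lengths)))
  shared_len <- w_region_length + total_deleted
  orf_nt <- 3L * (orf_aa + 1L)
  interior <- shared_len - 2L * flank_len
  if (interior < orf_nt + total_deleted + (n_deletions + 2L) * deletion_spacing)
    stop("parameters leave no room for conserved flanks: interior ", interior,
         " bp cannot hold a ", orf_nt, " nt ORF plus ", total_deleted,
         " bp of spaced deletions")

  ## shared locus: [flank][zone A][ORF][zone B][flank]; deletions live in the
  ## zones only, so the W copy keeps the ORF and both flanks intact
  zones_total <- interior - orf_nt
  zoneA_len <- zones_total %/% 2L
  orf_start <- flank_len + zoneA_len + 1L
  orf_end <- orf_start + orf_nt - 1L
  zoneA <- c(flank_len + 1L, orf_start - 1L)
  zoneB <- c(orf_end + 1L, shared_len - flank_len)

  shared_seq <- strsplit(random_dna(shared_len), "")[[1L]]
  shared_seq[orf_start:orf_end] <- strsplit(random_orf(orf_aa), "")[[1L]]

  del <- if (n_deletions > 0L)
    place_deletions(n_deletions, total_deleted, min_deletion,
                    deletion_spacing, list(zoneA, zoneB))
  else data.frame(start = integer(0), length = integer(0))

  deleted <- logical(shared_len)
  for (i in seq_len(nrow(del))) deleted[del$start[i]:(del$start[i] + del$length[i] - 1L)] <- TRUE
  w_from_shared <- which(!deleted)      # shared coordinate of each W base
  w_seq <- shared_seq[w_from_shared]
  stopifnot(length(w_seq) == w_region_length)

  ## W-only substitutions outside flanks, ORF and deletion-edge buffers
  buffer <- 3L
  w_pos <- seq_len(w_region_length)
  near_junction <- rep(FALSE, w_region_length)
  junctions <- which(diff(w_from_shared) > 1L)   # W index left of each junction
  for (j in junctions) {
    lo <- max(1L, j - buffer + 1L); hi <- min(w_region_length, j + buffer)
    near_junction[lo:hi] <- TRUE
  }
  orf_in_w <- match(orf_start, w_from_shared) + c(0L, orf_nt - 1L)
  eligible <- w_pos > flank_len & w_pos <= w_region_length - flank_len &
    !(w_pos >= orf_in_w[1L] & w_pos <= orf_in_w[2L]) & !near_junction
  sub_at <- which(eligible & runif(w_region_length) < substitution_rate)
  for (i in sub_at) w_seq[i] <- sample(setdiff(DNA_BASES, w_seq[i]), 1L)

  ## suppress spurious ORFs >= orf_aa so the planted one is the longest
  planted_local <- c(orf_in_w[1L], orf_in_w[2L])
  repeat {
    fixed <- suppress_competing_orfs(w_seq, shared_seq, w_from_shared,
                                     planted_local, c(orf_start, orf_end), orf_aa)
    if (fixed$clean) break
    w_seq <- fixed$w; shared_seq <- fixed$shared
  }

  ## embed loci mid-scaffold
  genome <- vapply(scaffold_lengths, random_dna, character(1L))
  embed <- function(scaf, locus_chars) {
    len <- scaffold_lengths[[scaf]]
    llen <- length(locus_chars)
    if (len < llen + 200L) stop("scaffold ", scaf, " too short for its locus")
    start <- (len - llen) %/% 2L + 1L
    chars <- strsplit(genome[[scaf]], "")[[1L]]
    chars[start:(start + llen - 1L)] <- locus_chars
    genome[[scaf]] <<- paste(chars, collapse = "")
    c(start, start + llen - 1L)
  }
  sh <- embed("scaffold4", shared_seq)
  wl <- embed("scaffold195", w_seq)

  layout <- list(
    scaffold_lengths = scaffold_lengths,
    shared_locus = genomic_interval("scaffold4", sh[1L], sh[2L]),
    w_locus = genomic_interval("scaffold195", wl[1L], wl[2L]),
    heterogametic_sex = heterogametic_sex)
  truth <- list(
    w_region = layout$w_locus,
    shared_region = layout$shared_locus,
    w_region_length = w_region_length,
    n_deletions = n_deletions,
    total_deleted = total_deleted,
    deletions = del,                     # shared-locus-local coordinates
    orf_shared_local = c(orf_start, orf_end),
    orf_w_local = planted_local,
    orf_w = genomic_interval("scaffold195", wl[1L] + planted_local[1L] - 1L,
                             wl[1L] + planted_local[2L] - 1L),
    orf_aa = orf_aa,
    flank_len = flank_len,
    substituted_w_local = sub_at)
  list(genome = genome, layout = layout, truth = truth)
}

# distribute n non-overlapping deletion sizes across zones with spacing
place_deletions <- function(n, total, min_size, spacing, zones) {
  extra <- total - n * min_size
  sizes <- min_size + as.integer(rmultinom(1L, extra, rep(1, n)))
  cap <- vapply(zones, function(z) z[2L] - z[1L] + 1L, integer(1L))
  assign <- integer(n)
  used <- integer(length(zones))
  count <- integer(length(zones))
  for (i in order(sizes, decreasing = TRUE)) {
    room <- cap - used - (count + 2L) * spacing - sizes[i]
    z <- which.max(room)
    if (room[z] < 0L) stop("parameters leave no room for conserved flanks/spacing")
    assign[i] <- z
    used[z] <- used[z] + sizes[i]
    count[z] <- count[z] + 1L
  }
  out <- list()
  for (z in seq_along(zones)) {
    idx <- which(assign == z)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]   # shuffle order within the zone
    k <- length(idx)
    free <- cap[z] - sum(sizes[idx]) - (k + 1L) * spacing
    slack <- as.integer(rmultinom(1L, free, rep(1, k + 1L)))
    at <- zones[[z]][1L]
    for (m in seq_len(k)) {
      at <- at + spacing + slack[m]
      out[[length(out) + 1L]] <- data.frame(start = at, length = sizes[idx[m]])
      at <- at + sizes[idx[m]]
    }
  }
  del <- do.call(rbind, out)
  del[order(del$start), , drop = FALSE]
}

# mutate the start codon of any non-planted ORF >= orf_aa, coordinated
# between the W copy and the shared copy so flank identity is preserved
suppress_competing_orfs <- function(w_seq, shared_seq, w_from_shared,
                                    planted_w, planted_shared, orf_aa) {
  fix_one <- function(chars, protect) {
    orfs <- find_orfs(paste(chars, collapse = ""), min_aa = orf_aa)
    for (i in seq_len(nrow(orfs))) {
      o <- orfs[i, ]
      if (o$start == protect[1L] && o$end == protect[2L] && o$strand == "+") next
      mid <- if (o$strand == "+") o$start + 1L else o$end - 1L
      if (mid >= protect[1L] && mid <= protect[2L]) next  # overlaps planted CDS
      return(mid)
    }
    NULL
  }
  m <- fix_one(w_seq, planted_w)
  if (!is.null(m)) {
    w_seq[m] <- "G"
    shared_seq[w_from_shared[m]] <- "G"
    return(list(clean = FALSE, w = w_seq, shared = shared_seq))
  }
  m <- fix_one(shared_seq, planted_shared)
  if (!is.null(m)) {
    shared_seq[m] <- "G"
    wi <- match(m, w_from_shared)
    if (!is.na(wi)) w_seq[wi] <- "G"
    return(list(clean = FALSE, w = w_seq, shared = shared_seq))
  }
  list(clean = TRUE, w = w_seq, shared = shared_seq)
}

#' Depth model for simulated resequencing coverage
#'
#' Per-sample mean depth \eqn{\lambda_s} is drawn uniformly from
#' `mean_depth_range` (default 12–15x, typical of the low-coverage
#' resequencing this analysis targets). Depth at a position with copy
#' number c is Poisson with mean \eqn{\lambda_s c / 2}, or negative
#' binomial with that mean and dispersion `dispersion` (variance
#' \eqn{\mu + dispersion \mu^2}) when `dispersion > 0`. `dropout` zeroes
#' each (position, sample) cell independently, a crude stand-in for
#' unmappable sites.
#'
#' @param mean_depth_range length-2 numeric, range for \eqn{\lambda_s}
#' @param dispersion negative-binomial overdispersion; 0 = Poisson
#' @param dropout per-cell zeroing probability in \[0, 1)
#' @return list of class `"depth_model"`
#' @export
depth_model <- function(mean_depth_range = c(12, 15), dispersion = 0,
                        dropout = 0) {
  stopifnot(length(mean_depth_range) == 2L, all(mean_depth_range > 0),
            dispersion >= 0, dropout >= 0, dropout < 1)
  structure(list(mean_depth_range = as.numeric(mean_depth_range),
                 dispersion = dispersion, dropout = dropout),
            class = "depth_model")
}

#' Simulate per-sample depth tables over a genome layout
#'
#' Every position has copy number 2 except the W locus, where the
#' heterogametic sex has copy number 1 and the other sex 0; expected depth
#' is \eqn{\lambda_s \times cn / 2}, so samples of the absent sex get exact
#' zeros inside the W locus.
#'
#' @param layout `layout` element from [simulate_reference()]
#' @param sheet a [sample_sheet]
#' @param model a [depth_model]
#' @param seed integer seed
#' @return named list of [depth_table] objects, one per scaffold
#' @export
simulate_depth <- function(layout, sheet, model = depth_model(), seed = 1L) {
  set.seed(seed)
  n <- nrow(sheet)
  lambda <- runif(n, model$mean_depth_range[1L], model$mean_depth_range[2L])
  names(lambda) <- sheet$sample
  draw <- function(len, mu) {
    if (mu == 0) return(integer(len))
    if (model$dispersion > 0)
      rnbinom(len, mu = mu, size = 1 / model$dispersion)
    else rpois(len, mu)
  }
  het <- layout$heterogametic_sex
  out <- list()
  for (scaf in names(layout$scaffold_lengths)) {
    len <- layout$scaffold_lengths[[scaf]]
    mat <- matrix(0L, nrow = len, ncol = n, dimnames = list(NULL, sheet$sample))
    wreg <- if (layout$w_locus$contig == scaf)
      layout$w_locus$start:layout$w_locus$end else integer(0)
    for (j in seq_len(n)) {
      mat[, j] <- draw(len, lambda[j])
      if (length(wreg)) {
        cn <- if (sheet$sex[j] == het) 1L else 0L
        mat[wreg, j] <- draw(length(wreg), lambda[j] * cn / 2)
      }
    }
    if (model$dropout > 0)
      mat[matrix(runif(length(mat)) < model$dropout, nrow = len)] <- 0L
    out[[scaf]] <- depth_table(scaf, seq_len(len), mat)
  }
  attr(out, "lambda") <- lambda
  out
}

#' Default 20 F + 20 M discovery cohort
#' @param n_f,n_m group sizes
#' @return a [sample_sheet]
#' @export
default_cohort <- function(n_f = 20L, n_m = 20L) {
  sample_sheet(c(sprintf("F%02d", seq_len(n_f)), sprintf("M%02d", seq_len(n_m))),
               rep(c("F", "M"), c(n_f, n_m)))
}

#' Write a complete simulated fixture bundle to disk
#'
#' Deterministic given `seed`: reference FASTA, dense depth TSV
#' (`samtools depth -a` dialect), sample sheet, a GFF-like gene table for
#' the planted ORF, and a `truth.json` recording the planted coordinates.
#'
#' @param dir output directory (created)
#' @param seed integer seed
#' @param reference_params list of overrides for [simulate_reference()]
#' @param model a [depth_model]
#' @param sheet a [sample_sheet]
#' @return invisibly, a list with the simulation objects and file paths
#' @export
make_fixture_bundle <- function(dir, seed = 1L, reference_params = list(),
                                model = depth_model(),
                                sheet = default_cohort()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed %% 2147480000)   # keep seed and offsets in int range
  ref <- do.call(simulate_reference, c(list(seed = seed), reference_params))
  tables <- simulate_depth(ref$layout, sheet, model, seed = seed + 1000L)
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    depth = file.path(dir, "depth.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genes = file.path(dir, "genes.tsv"),
    truth = file.path(dir, "truth.json"))
  write_fasta(ref$genome, paths$genome)
  write_depth_tsv(tables, paths$depth)
  data.table::fwrite(data.table::data.table(sample = sheet$sample,
                                            sex = as.character(sheet$sex)),
                     paths$samples, sep = "\t", col.names = FALSE)
  orf <- ref$truth$orf_w
  data.table::fwrite(data.table::data.table(
    gene_id = "planted_orf", contig = orf$contig, start = orf$start,
    end = orf$end, strand = "+"), paths$genes, sep = "\t")
  truth <- ref$truth
  truth$w_region <- as.list(truth$w_region)
  truth$shared_region <- as.list(truth$shared_region)
  truth$orf_w <- as.list(truth$orf_w)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(reference = ref, tables = tables, sheet = sheet,
                 paths = paths, dir = dir, seed = seed))
}
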
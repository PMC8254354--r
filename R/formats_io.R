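#' Depth table: per-position, per-sample read depths for one contig
#'
#' The substrate of the coverage scan. Positions are 1-based, strictly
#' increasing; `depth` is an integer matrix with one row per position and
#' one named column per sample; all depths are >= 0.
#'
#' @param contig contig name
#' @param pos integer vector of 1-based positions, strictly increasing
#' @param depth integer matrix, `length(pos)` rows, sample names as colnames
#' @return an object of class `"depth_table"`
#' @export
depth_table <- function(contig, pos, depth) {
  pos <- as.integer(pos)
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (nrow(depth) != length(pos))
    stop("depth matrix has ", nrow(depth), " rows but ", length(pos), " positions")
  if (length(pos) && (anyNA(pos) || any(diff(pos) <= 0L) || pos[1L] < 1L))
    stop("positions must be >= 1 and strictly increasing within a contig")
  if (is.null(colnames(depth)) || anyDuplicated(colnames(depth)))
    stop("depth matrix needs unique sample column names")
  if (length(depth) && (anyNA(depth) || any(depth < 0L)))
    stop("depths must be non-negative integers")
  structure(list(contig = as.character(contig), pos = pos, depth = depth),
            class = "depth_table")
}

#' @export
print.depth_table <- function(x, ...) {
  cat("<depth_table> ", x$contig, ": ", length(x$pos), " positions x ",
      ncol(x$depth), " samples\n", sep = "")
  invisible(x)
}

#' Read per-base depth tables in `samtools depth` format
#'
#' Expects tab-separated rows `contig  pos  d1 ... dn` (no header, as
#' emitted by `samtools depth`), with one depth column per sample in the
#' order given by `sample_ids`. Positions are 1-based. With `dense = TRUE`
#' (the default) positions absent from the file are filled in as depth 0 —
#' the `-a` interpretation, under which zero-coverage sites are meaningful
#' for breadth-of-coverage and presence/absence calls; contig lengths, if
#' known, extend the fill to the full contig.
#'
#' @param path path to the TSV
#' @param sample_ids character vector naming the depth columns, in order;
#'   never inferred from the data
#' @param dense fill missing positions with 0 depth?
#' @param contig_lengths optional named integer vector; with `dense = TRUE`,
#'   contigs are padded with zeros out to these lengths
#' @return named list of [depth_table] objects, one per contig, in order of
#'   first appearance
#' @export
read_depth_tsv <- function(path, sample_ids, dense = TRUE, contig_lengths = NULL) {
  stopifnot(is.character(sample_ids), length(sample_ids) >= 1L,
            !anyDuplicated(sample_ids))
  if (file.size(path) == 0L) {
    warning("empty depth file: ", path)
    return(structure(list(), names = character(0)))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1L), showProgress = FALSE)
  if (nrow(dt) == 0L) {
    warning("empty depth file: ", path)
    return(structure(list(), names = character(0)))
  }
  if (ncol(dt) != 2L + length(sample_ids))
    stop("depth file has ", ncol(dt), " columns; expected ",
         2L + length(sample_ids), " (contig, pos, ", length(sample_ids),
         " samples)")
  for (j in 2:ncol(dt)) {
    v <- dt[[j]]
    if (!(is.integer(v) || (is.numeric(v) && all(v == floor(v))))) {
      bad <- which(!grepl("^-?[0-9]+$", as.character(v)))[1L]
      stop("non-integer value in column ", j, " at line ", bad, " of ", path)
    }
  }
  depths <- as.matrix(dt[, -(1:2)])
  storage.mode(depths) <- "integer"
  if (any(depths < 0L)) {
    bad <- which(rowSums(depths < 0L) > 0L)[1L]
    stop("negative depth at line ", bad, " of ", path)
  }
  colnames(depths) <- sample_ids
  contig <- dt[[1L]]
  pos <- as.integer(dt[[2L]])
  out <- list()
  for (ctg in unique(contig)) {
    i <- which(contig == ctg)
    p <- pos[i]
    if (anyDuplicated(p))
      stop("duplicated position ", p[anyDuplicated(p)], " on contig ", ctg)
    o <- order(p)
    p <- p[o]
    d <- depths[i[o], , drop = FALSE]
    if (dense) {
      len <- if (!is.null(contig_lengths) && ctg %in% names(contig_lengths))
        as.integer(contig_lengths[[ctg]]) else max(p)
      full <- matrix(0L, nrow = len, ncol = ncol(d),
                     dimnames = list(NULL, colnames(d)))
      full[p, ] <- d
      out[[ctg]] <- depth_table(ctg, seq_len(len), full)
    } else {
      out[[ctg]] <- depth_table(ctg, p, d)
    }
  }
  out
}

#' Write depth tables in `samtools depth` format
#'
#' @param tables a [depth_table] or list of them
#' @param path output TSV path
#' @export
write_depth_tsv <- function(tables, path) {
  if (inherits(tables, "depth_table")) tables <- list(tables)
  parts <- lapply(tables, function(tb)
    data.table::data.table(contig = tb$contig, pos = tb$pos, tb$depth))
  data.table::fwrite(data.table::rbindlist(parts), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet mapping sample id to phenotypic sex
#'
#' TSV with two columns `sample  sex`; a header line is accepted and
#' detected by `sex`/`sample` keywords. Sex labels are case-insensitive
#' `F`/`M` (also `female`/`male`).
#'
#' @param path path to the TSV
#' @return data.frame of class `"sample_sheet"` with columns `sample`,
#'   `sex` (factor with levels F, M)
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", showProgress = FALSE)
  if (ncol(dt) != 2L) stop("sample sheet must have exactly 2 columns")
  if (nrow(dt) && tolower(dt[[2L]][1L]) %in% c("sex", "phenotype"))
    dt <- dt[-1L]
  sample_sheet(dt[[1L]], dt[[2L]])
}

#' @rdname read_sample_sheet
#' @param sample character vector of sample ids (unique)
#' @param sex vector of sex labels, `F`/`M` (case-insensitive)
#' @export
sample_sheet <- function(sample, sex) {
  sample <- as.character(sample)
  sex <- toupper(as.character(sex))
  sex[sex == "FEMALE"] <- "F"
  sex[sex == "MALE"] <- "M"
  if (anyDuplicated(sample))
    stop("duplicate sample id: ", sample[anyDuplicated(sample)])
  bad <- setdiff(unique(sex), c("F", "M"))
  if (length(bad)) stop("unknown sex label: ", paste(bad, collapse = ", "))
  structure(data.frame(sample = sample, sex = factor(sex, levels = c("F", "M")),
                       stringsAsFactors = FALSE),
            class = c("sample_sheet", "data.frame"))
}

#' Split sample ids by sex, checking group sizes
#' @param sheet a [sample_sheet]
#' @param min_per_group smallest group size allowed (Welch's t needs n >= 2)
#' @return list with character vectors `F` and `M`
#' @keywords internal
sex_groups <- function(sheet, min_per_group = 2L) {
  g <- split(sheet$sample, sheet$sex)
  if (length(g$F) < min_per_group || length(g$M) < min_per_group)
    stop("need at least ", min_per_group, " samples per sex; got ",
         length(g$F), " F and ", length(g$M), " M")
  g
}

#' Write regions as BED (0-based, half-open)
#'
#' Internal coordinates are 1-based inclusive, so a region
#' (101629, 102226) becomes the BED line `chrom 101628 102226`; interval
#' length is preserved as `end_bed - start_bed`.
#'
#' @param regions data.frame with columns `contig`, `start`, `end` and
#'   optionally `name`, `score`
#' @param path output path
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(regions)))
  bed <- data.table::data.table(
    chrom = regions$contig,
    chromStart = as.integer(regions$start) - 1L,
    chromEnd = as.integer(regions$end),
    name = if ("name" %in% names(regions)) regions$name else
      sprintf("region_%d", seq_len(nrow(regions))),
    score = if ("score" %in% names(regions)) regions$score else 0L)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @return `read_bed()`: data.frame with 1-based inclusive `start`, `end`
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", showProgress = FALSE)
  data.frame(contig = as.character(dt[[1L]]), start = as.integer(dt[[2L]]) + 1L,
             end = as.integer(dt[[3L]]),
             name = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else NA_character_,
             stringsAsFactors = FALSE)
}

#' FASTA input/output
#'
#' Thin wrappers over Biostrings keeping sequences as plain named uppercase
#' character vectors, the representation the rest of the package uses.
#' Round-tripping preserves sequence content byte-for-byte (line wrapping
#' may differ).
#'
#' @param path FASTA path
#' @return `read_fasta()`: named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a GFF-like gene prediction table
#'
#' Plain TSV `gene_id  contig  start  end  strand` with 1-based inclusive
#' CDS coordinates, strand `+`/`-`.
#'
#' @param path path to the table
#' @return data.frame with those columns; CDS length must be >= 3
#' @export
read_gene_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", showProgress = FALSE)
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in% names(dt)))
  out <- as.data.frame(dt)
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  if (any(out$end - out$start + 1L < 3L)) stop("CDS shorter than 3 nt")
  if (!all(out$strand %in% c("+", "-"))) stop("strand must be + or -")
  out
}
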
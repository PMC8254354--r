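#' Alignment scoring scheme
#'
#' Defaults: match +2, mismatch -3, and affine gap penalties where a gap of
#' length L costs `gap_open + L * gap_extend` (-6 - 2L). The gap-opening
#' penalty is deliberately set strictly above `match - mismatch` so that
#' splitting a deletion around a single coincidentally matching base is
#' never score-neutral — the optimal gap count of a deletion-only variant
#' is then unique and equals the number of deletions. The scheme is a
#' package choice exposed for configuration; optimality is tested against a
#' brute-force enumeration oracle, not against any external aligner's
#' scores.
#'
#' @param match,mismatch per-column substitution scores
#' @param gap_open,gap_extend affine gap penalties (non-positive)
#' @return list of class `"align_scoring"`
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -6,
                          gap_extend = -2) {
  stopifnot(gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

validate_residues <- function(seq, alphabet, what) {
  ok <- switch(alphabet,
               dna = "ACGTN",
               protein = "ACDEFGHIKLMNPQRSTVWYX*")
  bad <- regexpr(sprintf("[^%s]", ok), seq)
  if (bad > 0L)
    stop("invalid ", alphabet, " residue '", substr(seq, bad, bad),
         "' at position ", bad, " of ", what)
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal global (Needleman–Wunsch/Gotoh) alignment under the affine
#' scheme of [align_scoring()]. Tie-breaking is deterministic: a
#' match/mismatch column is preferred over opening a gap, and gaps are
#' placed against the longer input sequence first.
#'
#' @param a,b sequences (character scalars); `a` is conventionally the
#'   query (e.g. the W region), `b` the subject (its paralog)
#' @param scoring an [align_scoring]
#' @param alphabet `"dna"` or `"protein"` (residue validation only)
#' @param a_id,b_id labels used in printing and reports
#' @return object of class `"pairwise_alignment"`: `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, inputs and scheme.
#'   De-gapping the aligned strings recovers the inputs exactly.
#' @export
global_align <- function(a, b, scoring = align_scoring(), alphabet = "dna",
                         a_id = "a", b_id = "b") {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L && nchar(b) == 0L)
    stop("cannot align two empty sequences")
  validate_residues(a, alphabet, "a")
  validate_residues(b, alphabet, "b")
  res <- .gotoh_align(a, b, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend,
                      prefer_x = nchar(a) >= nchar(b))
  structure(list(a_id = a_id, b_id = b_id, a = a, b = b,
                 aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, scoring = scoring, alphabet = alphabet),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, width = 60L, ...) {
  cat(format_alignment(x, width))
  invisible(x)
}

#' Human-readable alignment block
#' @param aln a `pairwise_alignment`
#' @param width characters per block line
#' @return a single string
#' @export
format_alignment <- function(aln, width = 60L) {
  n <- nchar(aln$aligned_a)
  out <- sprintf("# %s (%d nt) vs %s (%d nt), score %g\n",
                 aln$a_id, nchar(aln$a), aln$b_id, nchar(aln$b), aln$score)
  ac <- strsplit(aln$aligned_a, "")[[1L]]
  bc <- strsplit(aln$aligned_b, "")[[1L]]
  bar <- ifelse(ac == bc, "|", ifelse(ac == "-" | bc == "-", " ", "."))
  for (s in seq(1L, max(n, 1L), by = width)) {
    e <- min(s + width - 1L, n)
    out <- paste0(out,
                  sprintf("%-6s %s\n", aln$a_id, paste(ac[s:e], collapse = "")),
                  sprintf("%-6s %s\n", "", paste(bar[s:e], collapse = "")),
                  sprintf("%-6s %s\n\n", aln$b_id, paste(bc[s:e], collapse = "")))
  }
  out
}

#' Trim terminal gap columns from a pairwise alignment
#'
#' [find_paralog()] pads its candidate interval, so a global alignment of
#' the query against it typically starts and ends with gap columns in the
#' query's row. This trims maximal terminal gap runs (on either row) and
#' returns the alignment of the correspondingly shortened sequences, plus
#' how many residues were trimmed from each end of each sequence — used to
#' refine subject coordinates.
#'
#' @param aln a `pairwise_alignment`
#' @return list: `aln` (trimmed `pairwise_alignment`), `trimmed_a`,
#'   `trimmed_b` (integer length-2 vectors: residues removed at left/right
#'   ends of `a` and `b`)
#' @export
trim_terminal_gaps <- function(aln) {
  a <- strsplit(aln$aligned_a, "")[[1L]]
  b <- strsplit(aln$aligned_b, "")[[1L]]
  gapcol <- a == "-" | b == "-"
  n <- length(a)
  lead <- if (gapcol[1L]) rle(gapcol)$lengths[1L] else 0L
  trail <- if (gapcol[n]) tail(rle(gapcol)$lengths, 1L) else 0L
  if (lead + trail >= n)
    stop("alignment consists entirely of gap columns")
  keep <- seq.int(lead + 1L, n - trail)
  ta <- c(sum(a[seq_len(lead)] != "-"),
          if (trail) sum(a[(n - trail + 1L):n] != "-") else 0L)
  tb <- c(sum(b[seq_len(lead)] != "-"),
          if (trail) sum(b[(n - trail + 1L):n] != "-") else 0L)
  new_a <- paste(a[keep], collapse = "")
  new_b <- paste(b[keep], collapse = "")
  out <- aln
  out$aligned_a <- new_a
  out$aligned_b <- new_b
  out$a <- gsub("-", "", new_a)
  out$b <- gsub("-", "", new_b)
  out$score <- NA_real_   # score of the trimmed columns is not re-derived
  list(aln = out, trimmed_a = as.integer(ta), trimmed_b = as.integer(tb))
}

#' Inventory of gaps in a pairwise alignment
#'
#' Enumerates maximal gap runs on each side. A gap on side `a` means gap
#' characters in `a`'s row (sequence missing from `a`, e.g. a deletion in
#' the W copy relative to its paralog). The difference of the two sides'
#' totals always equals the input length difference.
#'
#' @param aln a `pairwise_alignment`
#' @return list of class `"gap_inventory"`: `gaps` data.frame (side,
#'   col_start, length), `n_gaps`, `total_a`, `total_b`
#' @export
gap_inventory <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  one_side <- function(row, side) {
    r <- rle(strsplit(row, "")[[1L]] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(side = rep(side, sum(keep)), col_start = starts[keep],
               length = r$lengths[keep])
  }
  gaps <- rbind(one_side(aln$aligned_a, "a"), one_side(aln$aligned_b, "b"))
  gaps <- gaps[order(gaps$col_start), , drop = FALSE]
  rownames(gaps) <- NULL
  structure(list(gaps = gaps, n_gaps = nrow(gaps),
                 total_a = sum(gaps$length[gaps$side == "a"]),
                 total_b = sum(gaps$length[gaps$side == "b"])),
            class = "gap_inventory")
}

#' @export
print.gap_inventory <- function(x, ...) {
  cat("<gap_inventory> ", x$n_gaps, " gap(s); side a total ", x$total_a,
      " bp, side b total ", x$total_b, " bp\n", sep = "")
  invisible(x)
}

#' Locate a query's paralog in a reference by exact k-mer anchoring
#'
#' Seeds every k-mer of the query (both orientations) against each
#' reference scaffold, chains hits on nearby diagonals, excludes hits
#' overlapping the query's own locus, and returns the best-supported
#' candidate subject interval (slightly padded; [global_align()] refines
#' the boundaries). Exactness is not required at this stage.
#'
#' @param region_seq query sequence
#' @param genome named character vector of reference scaffolds
#' @param k k-mer anchor length
#' @param min_anchors minimum chained hits to report a candidate
#' @param band diagonal tolerance when chaining (should exceed the summed
#'   indel length between the paralogs)
#' @param self_exclude optional [genomic_interval] of the query's own locus
#' @param pad bp added on each side of the chained span; the default 0
#'   relies on the anchor chain extrapolating the full query span, which is
#'   exact when the paralogs' outermost stretches are conserved — terminal
#'   pad, if used, is removed downstream by [trim_terminal_gaps()]
#' @return list with `contig`, `start`, `end`, `strand`, `n_anchors`, or
#'   `NULL` when nothing reaches `min_anchors`
#' @export
find_paralog <- function(region_seq, genome, k = 15L, min_anchors = 3L,
                         band = 500L, self_exclude = NULL, pad = 0L) {
  region_seq <- toupper(region_seq)
  qlen <- nchar(region_seq)
  if (qlen < k) stop("query shorter than anchor length k = ", k)
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") region_seq else revcomp(region_seq)
    starts <- seq_len(qlen - k + 1L)
    kmers <- substring(q, starts, starts + k - 1L)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
    for (scaf in names(genome)) {
      subj <- Biostrings::DNAString(genome[[scaf]])
      hits <- Biostrings::matchPDict(pd, subj)
      qpos <- rep(starts, lengths(Biostrings::startIndex(hits)))
      spos <- unlist(Biostrings::startIndex(hits), use.names = FALSE)
      if (!length(spos)) next
      if (!is.null(self_exclude) && scaf == self_exclude$contig) {
        keep <- spos + k - 1L < self_exclude$start | spos > self_exclude$end
        qpos <- qpos[keep]; spos <- spos[keep]
      }
      if (!length(spos)) next
      o <- order(spos - qpos, spos)
      qpos <- qpos[o]; spos <- spos[o]
      diag <- spos - qpos
      grp <- cumsum(c(1L, diff(diag) > band))
      for (g in unique(grp)) {
        i <- which(grp == g)
        if (length(i) < min_anchors) next
        cand <- list(
          contig = scaf,
          start = max(1L, min(spos[i]) - (min(qpos[i]) - 1L) - pad),
          end = min(nchar(genome[[scaf]]),
                    max(spos[i] + k - 1L) + (qlen - max(qpos[i] + k - 1L)) + pad),
          strand = strand, n_anchors = length(i))
        if (is.null(best) || cand$n_anchors > best$n_anchors) best <- cand
      }
    }
  }
  best
}
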
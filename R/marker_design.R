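#' Primer melting-temperature estimate
#'
#' Wallace rule 2(A+T) + 4(G+C) for primers of 14 nt or shorter, otherwise
#' the salt-free approximation 64.9 + 41 * (nGC - 16.4) / N. Crude but
#' explicit and monotone in GC content, which is all the ranking needs.
#'
#' @param seq primer sequence(s), 5'->3'
#' @return numeric Tm estimate(s) in degrees C
#' @export
primer_tm <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ngc <- nchar(gsub("[^GC]", "", seq))
  ifelse(n <= 14L, 2 * (n - ngc) + 4 * ngc, 64.9 + 41 * (ngc - 16.4) / n)
}

#' @rdname primer_tm
#' @return `gc_fraction()`: fraction of G/C bases
#' @export
gc_fraction <- function(seq) {
  nchar(gsub("[^GCgc]", "", seq)) / nchar(seq)
}

#' Conserved flank windows around the variable core of an alignment
#'
#' Slides windows of `window_len` alignment columns over the regions left
#' and right of the variable (gapped) core — the span from the first to the
#' last gap column — keeping windows with zero gap columns and at most
#' `max_mismatch` mismatches. These are the consensus sites where a single
#' primer pair can bind both paralogs.
#'
#' @param aln a `pairwise_alignment` (query = W copy, subject = paralog)
#' @param window_len window width in alignment columns
#' @param max_mismatch mismatches tolerated inside a window
#' @return data.frame: `side` (left/right of the core), alignment columns
#'   `col_start`/`col_end`, ungapped coordinates on each sequence
#'   (`a_start`..`b_end`), `mismatches`, and the window sequences `seq_a`,
#'   `seq_b`. Empty (zero rows) when the alignment has no gapped core or no
#'   qualifying window.
#' @export
conserved_flanks <- function(aln, window_len = 18L, max_mismatch = 0L) {
  a <- strsplit(aln$aligned_a, "")[[1L]]
  b <- strsplit(aln$aligned_b, "")[[1L]]
  n <- length(a)
  empty <- data.frame(side = character(0), col_start = integer(0),
                      col_end = integer(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), mismatches = integer(0),
                      seq_a = character(0), seq_b = character(0))
  gapcol <- a == "-" | b == "-"
  if (!any(gapcol) || n < window_len) return(empty)
  core <- range(which(gapcol))
  mm <- as.integer(!gapcol & a != b)
  cmm <- cumsum(mm); cgap <- cumsum(gapcol)
  ca <- cumsum(a != "-"); cb <- cumsum(b != "-")
  window_at <- function(starts, side) {
    if (!length(starts)) return(empty)
    ends <- starts + window_len - 1L
    gaps <- cgap[ends] - c(0L, cgap)[starts]
    mms <- cmm[ends] - c(0L, cmm)[starts]
    keep <- gaps == 0L & mms <= max_mismatch
    starts <- starts[keep]; ends <- ends[keep]; mms <- mms[keep]
    if (!length(starts)) return(empty)
    data.frame(side = side, col_start = starts, col_end = ends,
               a_start = c(0L, ca)[starts] + 1L, a_end = ca[ends],
               b_start = c(0L, cb)[starts] + 1L, b_end = cb[ends],
               mismatches = mms,
               seq_a = substring(gsub("-", "", aln$aligned_a),
                                 c(0L, ca)[starts] + 1L, ca[ends]),
               seq_b = substring(gsub("-", "", aln$aligned_b),
                                 c(0L, cb)[starts] + 1L, cb[ends]))
  }
  left <- window_at(seq_len(max(0L, core[1L] - window_len)), "left")
  rs <- if (core[2L] + window_len <= n) (core[2L] + 1L):(n - window_len + 1L)
        else integer(0)
  right <- window_at(rs, "right")
  out <- rbind(left, right)
  rownames(out) <- NULL
  out
}

#' Design a primer pair in conserved flanks
#'
#' Enumerates forward primers from left-flank windows and reverse primers
#' (reverse complement) from right-flank windows across the allowed length
#' range, filters on GC content and optional Tm bounds, ranks pairs by
#' Tm balance (smallest |Tm_f - Tm_r|) breaking ties by the largest
#' product-size difference between the two templates, and verifies the top
#' candidates by [in_silico_pcr()] against both templates (each must yield
#' exactly one product within `product_range`).
#'
#' @param aln a `pairwise_alignment` of the W copy (`a`) vs its paralog
#'   (`b`)
#' @param template_a,template_b the two template sequences the primers must
#'   amplify (typically the aligned W and shared locus sequences)
#' @param primer_len length-2 integer range of primer lengths
#' @param gc_range allowed GC fraction range
#' @param tm_range allowed Tm range (degrees C)
#' @param product_range allowed product length range on either template
#' @param max_mismatch mismatches tolerated in the conserved windows
#' @param max_report verify and return at most this many ranked pairs
#' @return data.frame of ranked primer pairs: sequences, coordinates on
#'   template a, length/GC/Tm per primer, `product_a`, `product_b`,
#'   `product_diff`; zero rows (with a `diagnostic` attribute) when no pair
#'   is feasible
#' @export
design_primer_pair <- function(aln, template_a, template_b,
                               primer_len = c(17L, 25L),
                               gc_range = c(0.4, 0.6),
                               tm_range = c(40, 75),
                               product_range = c(100L, 3000L),
                               max_mismatch = 0L, max_report = 20L) {
  cands <- list(left = list(), right = list())
  for (len in primer_len[1L]:primer_len[2L]) {
    fl <- conserved_flanks(aln, window_len = len, max_mismatch = max_mismatch)
    if (!nrow(fl)) next
    fl$primer <- ifelse(fl$side == "left", fl$seq_a, revcomp_each(fl$seq_a))
    fl$gc <- gc_fraction(fl$primer)
    fl$tm <- primer_tm(fl$primer)
    fl <- fl[fl$gc >= gc_range[1L] & fl$gc <= gc_range[2L] &
               fl$tm >= tm_range[1L] & fl$tm <= tm_range[2L], , drop = FALSE]
    for (side in c("left", "right"))
      cands[[side]][[as.character(len)]] <- fl[fl$side == side, , drop = FALSE]
  }
  left <- do.call(rbind, cands$left)
  right <- do.call(rbind, cands$right)
  fail <- function(msg) {
    out <- data.frame()
    attr(out, "diagnostic") <- msg
    out
  }
  if (is.null(left) || !nrow(left)) return(fail("no feasible forward primer in left flank"))
  if (is.null(right) || !nrow(right)) return(fail("no feasible reverse primer in right flank"))
  grid <- expand.grid(f = seq_len(nrow(left)), r = seq_len(nrow(right)))
  grid$tm_diff <- abs(left$tm[grid$f] - right$tm[grid$r])
  grid <- grid[order(grid$tm_diff), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(grid))) {
    if (length(out) >= max_report) break
    fw <- left[grid$f[i], ]; rv <- right[grid$r[i], ]
    pcr_a <- in_silico_pcr(fw$primer, rv$primer,
                           c(template_a = template_a),
                           max_product = product_range[2L])
    pcr_b <- in_silico_pcr(fw$primer, rv$primer,
                           c(template_b = template_b),
                           max_product = product_range[2L])
    ok <- function(p) nrow(p) == 1L && p$length >= product_range[1L]
    if (!ok(pcr_a) || !ok(pcr_b)) next
    out[[length(out) + 1L]] <- data.frame(
      fwd_seq = fw$primer, rev_seq = rv$primer,
      fwd_start_a = fw$a_start, fwd_end_a = fw$a_end,
      rev_start_a = rv$a_start, rev_end_a = rv$a_end,
      fwd_len = nchar(fw$primer), rev_len = nchar(rv$primer),
      fwd_gc = fw$gc, rev_gc = rv$gc,
      fwd_tm = fw$tm, rev_tm = rv$tm, tm_diff = grid$tm_diff[i],
      product_a = pcr_a$length, product_b = pcr_b$length,
      product_diff = pcr_b$length - pcr_a$length)
  }
  if (!length(out)) return(fail("no primer pair amplifies both templates uniquely"))
  out <- do.call(rbind, out)
  out <- out[order(out$tm_diff, -abs(out$product_diff)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

revcomp_each <- function(x) {
  vapply(x, function(s) revcomp(s), character(1L), USE.NAMES = FALSE)
}

#' In-silico PCR
#'
#' Finds products defined by oppositely oriented primer binding sites with
#' inward-facing 3' ends, on either strand of each template: for primer P
#' matching the plus strand at position p and the reverse complement of
#' primer Q matching at q >= p, the product spans p .. q + len(Q) - 1.
#' Binding is exact by default (`max_mismatch = 0`), as a diagnostic assay
#' demands. Product lengths are strand-symmetric: reverse-complementing a
#' template yields the same lengths.
#'
#' @param fwd,rev primer sequences, 5'->3'
#' @param templates named character vector of template sequences
#' @param max_mismatch mismatches tolerated per binding site
#' @param max_product largest product reported (bp)
#' @return data.frame: `template`, `start`, `end`, `length`,
#'   `plus_primer` (which primer annealed to the plus strand), sorted by
#'   template then start; zero rows when nothing amplifies
#' @export
in_silico_pcr <- function(fwd, rev, templates, max_mismatch = 0L,
                          max_product = 5000L) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  stopifnot(!is.null(names(templates)))
  validate_residues(fwd, "dna", "forward primer")
  validate_residues(rev, "dna", "reverse primer")
  hits <- function(primer, subject)
    Biostrings::start(Biostrings::matchPattern(primer, subject,
                                               max.mismatch = max_mismatch))
  out <- list()
  for (nm in names(templates)) {
    subject <- Biostrings::DNAString(toupper(templates[[nm]]))
    for (ori in list(c(fwd, rev), c(rev, fwd))) {
      p_start <- hits(ori[1L], subject)
      q_start <- hits(revcomp(ori[2L]), subject)
      if (!length(p_start) || !length(q_start)) next
      for (p in p_start) for (q in q_start) {
        len <- q + nchar(ori[2L]) - 1L - p + 1L
        if (q < p || len > max_product ||
            len < max(nchar(ori[1L]), nchar(ori[2L]))) next
        out[[length(out) + 1L]] <- data.frame(
          template = nm, start = p, end = q + nchar(ori[2L]) - 1L,
          length = len, plus_primer = if (identical(ori[1L], fwd)) "fwd" else "rev")
      }
    }
  }
  if (!length(out))
    return(data.frame(template = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      plus_primer = character(0)))
  out <- do.call(rbind, out)
  out <- unique(out[, c("template", "start", "end", "length", "plus_primer")])
  out <- out[order(out$template, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predicted gel banding per genotype
#'
#' The shared (diploid) locus amplifies in both sexes; the W locus only in
#' ZW individuals. ZZ therefore shows the shared band alone and ZW both
#' bands. Bands are resolvable on a routine agarose gel when their relative
#' size difference is at least `min_rel_diff`.
#'
#' @param genotype `"ZZ"` or `"ZW"`
#' @param shared_product,w_product product lengths (bp) of the two loci
#' @param min_rel_diff smallest resolvable relative size difference
#' @return list: `bands` (sizes, sorted descending), `resolvable`, and
#'   `copy_number` per band (the W band is haploid in ZW, hence fainter)
#' @export
predict_banding <- function(genotype, shared_product, w_product,
                            min_rel_diff = 0.1) {
  if (!genotype %in% c("ZZ", "ZW"))
    stop("unknown genotype label: ", genotype)
  if (genotype == "ZZ") {
    bands <- shared_product
    cn <- 2L
    resolvable <- TRUE
  } else {
    bands <- c(shared_product, w_product)
    o <- order(bands, decreasing = TRUE)
    cn <- c(2L, 1L)[o]
    bands <- bands[o]
    resolvable <- length(unique(bands)) == 2L &&
      abs(diff(bands)) / max(bands) >= min_rel_diff
  }
  list(genotype = genotype, bands = bands, copy_number = cn,
       resolvable = resolvable)
}
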
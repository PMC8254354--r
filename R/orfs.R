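#' Find open reading frames
#'
#' Scans all six frames for ATG...stop ORFs under the standard genetic
#' code. For each stop, the ORF starts at the first ATG after the previous
#' in-frame stop; ORFs lacking a terminating stop within the sequence are
#' not reported. Reported coordinates are 1-based inclusive on the input
#' (forward) strand and include the stop codon, so a 132-aa protein
#' occupies (132 + 1) * 3 = 399 nt.
#'
#' @param seq nucleotide sequence (character scalar)
#' @param min_aa smallest protein length reported (stop excluded)
#' @param both_strands scan the reverse complement too?
#' @return data.frame: `start`, `end`, `strand`, `nt_length`, `aa_length`,
#'   `protein`, sorted by decreasing `aa_length`
#' @export
find_orfs <- function(seq, min_aa = 50L, both_strands = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  scan_strand <- function(s, strand) {
    hits <- list()
    chars <- strsplit(s, "")[[1L]]
    for (frame in 0:2) {
      starts <- seq.int(1L + frame, n - 2L, by = 3L)
      if (!length(starts) || tail(starts, 1L) + 2L > n)
        starts <- starts[starts + 2L <= n]
      if (!length(starts)) next
      codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
      stop_i <- which(codons %in% STOP_CODONS)
      atg_i <- which(codons == "ATG")
      prev <- 0L
      for (si in stop_i) {
        a <- atg_i[atg_i > prev & atg_i < si]
        if (length(a)) {
          a <- a[1L]
          aa <- si - a        # translated codons, ATG included, stop excluded
          if (aa >= min_aa) {
            s1 <- starts[a]; s2 <- starts[si] + 2L
            hits[[length(hits) + 1L]] <- data.frame(
              start = if (strand == "+") s1 else n - s2 + 1L,
              end = if (strand == "+") s2 else n - s1 + 1L,
              strand = strand, nt_length = s2 - s1 + 1L, aa_length = aa,
              protein = translate_cds(substr(s, s1, s2)))
          }
        }
        prev <- si
      }
    }
    hits
  }
  hits <- scan_strand(seq, "+")
  if (both_strands && n >= 6L)
    hits <- c(hits, scan_strand(revcomp(seq), "-"))
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), nt_length = integer(0),
                      aa_length = integer(0), protein = character(0)))
  out <- do.call(rbind, hits)
  out <- out[order(-out$aa_length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate a coding sequence
#'
#' Standard genetic code. The CDS length must be a multiple of 3; a
#' terminal stop codon is allowed and excluded from the protein; an
#' internal stop is an error.
#'
#' @param cds nucleotide sequence, length divisible by 3
#' @return protein sequence (character scalar, no stop)
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length ", nchar(cds), " is not a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  chars <- strsplit(aa, "")[[1L]]
  stops <- which(chars == "*")
  if (length(stops) && any(stops < length(chars)))
    stop("internal stop codon at codon ", stops[1L])
  if (length(chars) && chars[length(chars)] == "*")
    aa <- substr(aa, 1L, nchar(aa) - 1L)
  aa
}

#' Fraction of identical residues in a protein alignment
#'
#' Identity = identical non-gap columns / total alignment columns
#' (columns where both rows are gaps cannot occur in a pairwise
#' alignment; columns pairing a residue with a gap count in the
#' denominator). `mode = "similarity"` additionally counts
#' positive-scoring BLOSUM62 pairs.
#'
#' @param aln a `pairwise_alignment` of two proteins (see [global_align()]
#'   with `alphabet = "protein"`)
#' @param mode `"identity"` or `"similarity"`
#' @return fraction in \[0, 1\]
#' @export
protein_identity <- function(aln, mode = c("identity", "similarity")) {
  mode <- match.arg(mode)
  a <- strsplit(aln$aligned_a, "")[[1L]]
  b <- strsplit(aln$aligned_b, "")[[1L]]
  cols <- !(a == "-" & b == "-")
  same <- a == b & a != "-"
  if (mode == "similarity") {
    blosum <- try(get(utils::data("BLOSUM62", package = "Biostrings",
                                  envir = environment())), silent = TRUE)
    if (!inherits(blosum, "try-error")) {
      ok <- a != "-" & b != "-" & a %in% rownames(blosum) & b %in% rownames(blosum)
      pos <- ok & blosum[cbind(match(a, rownames(blosum)),
                               match(b, colnames(blosum)))] > 0
      pos[is.na(pos)] <- FALSE
      same <- same | pos
    }
  }
  sum(same[cols]) / sum(cols)
}
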
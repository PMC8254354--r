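# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the code paths they check: the alignment oracle enumerates every
# monotone alignment recursively (no DP), the merge oracle tests all
# candidate intervals, and the Welch oracle recomputes the closed forms and
# integrates the t density by quadrature.

# exhaustive best alignment score under affine gaps (gap of length L costs
# open + L * extend); state: 0 = after match/mismatch, 1 = in gap consuming
# a, 2 = in gap consuming b
enumerate_align_score <- function(a, b, sc = align_scoring()) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, state, acc) {
    if (i > n && j > m) {
      if (acc > best) best <<- acc
      return(NULL)
    }
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, 0L,
          acc + if (av[i] == bv[j]) sc$match else sc$mismatch)
    if (i <= n)
      rec(i + 1L, j, 1L,
          acc + sc$gap_extend + if (state == 1L) 0 else sc$gap_open)
    if (j <= m)
      rec(i, j + 1L, 2L,
          acc + sc$gap_extend + if (state == 2L) 0 else sc$gap_open)
  }
  rec(1L, 1L, 0L, 0)
  best
}

# brute-force region merging: test every pair of target positions as
# interval endpoints, keep maximal qualifying intervals
merge_oracle <- function(pos, status, config) {
  target <- paste0(ifelse(config$target_sex == "F", "female", "male"),
                   "_specific")
  tp <- pos[status == target]
  k <- length(tp)
  if (!k) return(data.frame(start = integer(0), end = integer(0)))
  qual <- function(i, j) all(diff(tp[i:j]) <= config$merge_gap_bp + 1L)
  out <- list()
  for (i in seq_len(k)) for (j in i:k) {
    if (!qual(i, j)) next
    if (i > 1L && qual(i - 1L, j)) next
    if (j < k && qual(i, j + 1L)) next
    if (tp[j] - tp[i] + 1L < config$min_region_length_bp) next
    out[[length(out) + 1L]] <- data.frame(start = tp[i], end = tp[j])
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  unique(do.call(rbind, out))
}

# Welch's statistic from the closed forms, p by quadrature of the t density
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * integrate(function(x) dt(x, df), lower = abs(t), upper = Inf,
                     rel.tol = 1e-13, abs.tol = 1e-300)$value
  list(t = t, df = df, p = p)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
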
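# Independent oracles used across test files.

# Exhaustive enumeration over all 2^r mutant/reference read outcomes: the
# probability that, among r reads each carrying the mutant with
# probability b/n, both alleles end up supported by MORE than z reads.
enum_detect_prob <- function(b, n, r, z = 0) {
  if (r == 0) return(0)
  p <- b / n
  outcomes <- expand.grid(rep(list(c(0L, 1L)), r))
  x <- rowSums(outcomes)
  prob <- p^x * (1 - p)^(r - x)
  sum(prob[x > z & (r - x) > z])
}

# direct summation oracle for harmonic-type sums
sum_reciprocal <- function(from, to) {
  if (from > to) 0 else sum(1 / seq(from, to))
}

# small helper to build a one-application count table quickly
make_counts <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  site_counts(seq_len(nrow(m)), m[, 1], m[, 2], m[, 3], m[, 4])
}
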
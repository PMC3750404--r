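#' Harmonic number used by Watterson's estimator
#'
#' Computes \eqn{a_n = \sum_{i=1}^{n-1} 1/i}, the normalising constant that
#' relates the expected number of segregating sites in a sample of `n`
#' haploid genomes to the population-scaled mutation rate:
#' \eqn{E[S] = a_n \theta l}.
#'
#' @param n Integer (vectorised), number of haploid genomes sampled; must be
#'   at least 2.
#' @return `a_n`, a positive number (or vector).
#' @examples
#' harmonic_a(2)   # 1
#' harmonic_a(50)  # ~4.479
#' @export
harmonic_a <- function(n) {
  n <- .check_n(n)
  vapply(n, function(ni) sum(1 / seq_len(ni - 1L)), numeric(1))
}

#' Truncated harmonic number for frequency-class filtering
#'
#' When variant classes up to frequency `z` are discarded (singletons for
#' `z = 1`, singletons and doubletons for `z = 2`), the expected number of
#' retained segregating sites is \eqn{a'_n \theta l} with
#' \eqn{a'_n = \sum_{i=1+z}^{n-1-z} 1/i}.  An empty summation range
#' (`n < 2z + 2`) yields 0.
#'
#' @inheritParams harmonic_a
#' @param z Non-negative integer truncation level.
#' @return `a'_n` (0 when the range is empty).
#' @export
truncated_harmonic <- function(n, z) {
  n <- .check_n(n)
  z <- .check_z(z)
  vapply(n, function(ni) {
    lo <- 1L + z
    hi <- ni - 1L - z
    if (lo > hi) 0 else sum(1 / (lo:hi))
  }, numeric(1))
}

#' Ewens frequency spectrum
#'
#' Probability that a neutral mutant segregating in a sample of `n` haploid
#' genomes is carried by exactly `b` of them: \eqn{q_n(b) = (1/b)/a_n}.
#'
#' @param b Mutant count(s), between 1 and `n - 1`.
#' @param n Sample size (haploid genomes), scalar.
#' @return Probability vector, summing to 1 over `b = 1, ..., n - 1`.
#' @export
ewens_prob <- function(b, n) {
  n <- .check_n(n)
  .check_b(b, n)
  (1 / b) / harmonic_a(n)
}

#' Probability that a segregating site is detected by reads
#'
#' With `b` mutant copies among `n` pooled haploid genomes, each of `r`
#' reads carries the mutant allele independently with probability `b/n`.
#' The site is detected as segregating when both alleles appear at least
#' once among the reads:
#' \deqn{q_1(b, r) = 1 - (1 - b/n)^r - (b/n)^r.}
#'
#' @param b Mutant count(s), between 1 and `n - 1`.
#' @param n Pool size (haploid genomes), scalar.
#' @param r Read depth(s), non-negative.
#' @return Detection probability, in `[0, 1]`.
#' @export
detect_prob <- function(b, n, r) {
  n <- .check_n(n)
  .check_b(b, n)
  .check_r(r)
  p <- b / n
  pmax(0, 1 - (1 - p)^r - p^r)
}

#' Detection probability averaged over the Ewens spectrum
#'
#' \eqn{q_2(r) = \sum_{b=1}^{n-1} q_n(b)\, q_1(b, r)}: the probability that
#' a segregating site with frequency drawn from the neutral spectrum is
#' detected by `r` reads.
#'
#' @inheritParams detect_prob
#' @return Probability vector, one element per value of `r`.
#' @export
detect_prob_any <- function(n, r) {
  n <- .check_n(n)
  .check_r(r)
  b <- seq_len(n - 1L)
  qb <- ewens_prob(b, n)
  vapply(r, function(ri) sum(qb * detect_prob(b, n, ri)), numeric(1))
}

#' Detection probability under read-count truncation
#'
#' Probability that among `r` reads both alleles are each supported by
#' MORE than `z` reads, i.e. that the mutant-read count \eqn{X \sim
#' \mathrm{Binomial}(r, b/n)} satisfies \eqn{z < X < r - z}.  Reduces to
#' [detect_prob()] at `z = 0`; the event is impossible (probability 0)
#' whenever `r <= 2z + 1`.
#'
#' @param z Truncation level (minor allele must exceed `z` reads).
#' @inheritParams detect_prob
#' @return Probability in `[0, 1]`.
#' @export
detect_prob_filtered <- function(z, b, n, r) {
  z <- .check_z(z)
  if (z == 0L) return(detect_prob(b, n, r))  # closed form; exact reduction
  n <- .check_n(n)
  .check_b(b, n)
  .check_r(r)
  p <- b / n
  pmax(0, stats::pbinom(r - z - 1, r, p) - stats::pbinom(z, r, p))
}

#' Detection probability in two independent sequencing applications
#'
#' A segregating site is confirmed only when both alleles appear in both
#' applications; with depths `r1`, `r2` the probability is the product of
#' the single-application detection probabilities ([detect_prob()]).
#'
#' @inheritParams detect_prob
#' @param r1,r2 Read depths in the first and second application.
#' @export
dual_detect_prob <- function(b, n, r1, r2) {
  detect_prob(b, n, r1) * detect_prob(b, n, r2)
}

#' Truncated detection probability in two applications
#'
#' Product over the two applications of [detect_prob_filtered()]: both
#' alleles must exceed `z` reads in each application separately.
#'
#' @inheritParams detect_prob_filtered
#' @param r1,r2 Read depths in the first and second application.
#' @export
dual_detect_prob_filtered <- function(z, b, n, r1, r2) {
  detect_prob_filtered(z, b, n, r1) * detect_prob_filtered(z, b, n, r2)
}

#' Probability of x error reads at a non-segregating site
#'
#' Binomial probability \eqn{P_\epsilon(r, x) = C(r, x)\epsilon^x
#' (1-\epsilon)^{r-x}} that exactly `x` of `r` reads carry a sequencing
#' error, given per-read error rate `epsilon`.
#'
#' @param r Read depth.
#' @param x Number of mismatching reads, `0 <= x <= r`.
#' @param epsilon Per-read, per-site error probability.
#' @export
error_prob <- function(r, x, epsilon) {
  .check_r(r)
  if (any(x < 0) || any(x > r)) stop("`x` must lie in [0, r]")
  if (any(epsilon < 0) || any(epsilon > 1)) stop("`epsilon` must lie in [0, 1]")
  stats::dbinom(x, r, epsilon)
}

#' Probability that a true polymorphism shows a low minor allele frequency
#'
#' At a site with true minor-allele frequency `true_freq` sequenced to
#' `depth` reads, the observed minor-read count is
#' \eqn{X \sim \mathrm{Binomial}(depth, true\_freq)}.  Returns
#' \eqn{P(X / depth < maf\_cutoff)}, the binomial distribution-function
#' probability that the site would pass a strict MAF screen and thus be
#' mistaken for a sequencing-error site.  "Below the cutoff" is strict:
#' \eqn{P(X \le \lceil cutoff \cdot depth \rceil - 1)}.  A cutoff of 1 or
#' more returns exactly 1, since a minor-allele fraction is by definition
#' below 1.
#'
#' @param depth Read depth at the site (>= 1).
#' @param true_freq True allele frequency of the variant, in (0, 1).
#' @param maf_cutoff MAF threshold of the screen.
#' @return Probability in `[0, 1]`.
#' @examples
#' # a singleton in 70 pooled haploid genomes at 2000X:
#' maf_below_prob(2000, 1 / 70, 0.01)  # 0.0375
#' @export
maf_below_prob <- function(depth, true_freq, maf_cutoff) {
  if (any(depth < 1)) stop("`depth` must be at least 1")
  if (any(true_freq <= 0) || any(true_freq >= 1)) {
    stop("`true_freq` must lie strictly in (0, 1)")
  }
  if (any(maf_cutoff <= 0)) stop("`maf_cutoff` must be positive")
  k <- ceiling(maf_cutoff * depth) - 1
  out <- stats::pbinom(k, depth, true_freq)
  out[maf_cutoff >= 1] <- 1
  out
}

# ---- argument checks (shared) ----

.check_n <- function(n) {
  if (any(n < 2) || any(n != floor(n))) {
    stop("sample size `n` must be an integer >= 2")
  }
  as.integer(n)
}

.check_z <- function(z) {
  if (length(z) != 1L || z < 0 || z != floor(z)) {
    stop("truncation level `z` must be a single non-negative integer")
  }
  as.integer(z)
}

.check_b <- function(b, n) {
  if (any(b < 1) || any(b > n - 1) || any(b != floor(b))) {
    stop("mutant count `b` must be an integer in [1, n - 1]")
  }
  invisible(b)
}

.check_r <- function(r) {
  if (any(r < 0) || any(r != floor(r))) {
    stop("read depth must be a non-negative integer")
  }
  invisible(r)
}
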
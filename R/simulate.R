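#' Simulate the true polymorphism state of a region
#'
#' Places segregating sites along a region of `l` sites under the neutral
#' infinite-sites model.  Each site is independently segregating with
#' probability \eqn{a_n \theta} (so that \eqn{E[S] = a_n \theta l},
#' Watterson's expectation), and the mutant count `b` of a segregating
#' site is drawn from the Ewens frequency spectrum
#' \eqn{q_n(b) \propto 1/b}.  Reference alleles are uniform over the four
#' nucleotides; the mutant allele is uniform over the remaining three.
#'
#' @param l Region length in sites.
#' @param theta Per-site diversity (e.g. `1e-4` for 0.1/kb).
#' @param n Number of haploid genomes the truth describes (pool size, or
#'   one haploid per individual for the single-line design).
#' @param placement `"bernoulli"`: each site is independently segregating
#'   with probability \eqn{a_n \theta}, so the segregating-site count
#'   varies around its expectation between draws.  `"fixed_count"`:
#'   exactly \eqn{S = \mathrm{round}(a_n \theta l)} segregating sites are
#'   placed at uniformly sampled positions, so the regional polymorphism
#'   level is held at its expectation and replicate experiments isolate
#'   sequencing noise (see [run_experiment()]).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return A data frame of class `"site_truth"` with columns `position`,
#'   `b` (mutant count, 0 at monomorphic sites), `ref` and `mut`
#'   (nucleotides; `mut` is `NA` at monomorphic sites), and attributes
#'   `n`, `theta`, `l`.
#' @export
simulate_truth <- function(l, theta, n, placement = c("bernoulli", "fixed_count"),
                           seed = NULL) {
  n <- .check_n(n)
  placement <- match.arg(placement)
  if (l < 1 || l != floor(l)) stop("`l` must be a positive integer")
  if (theta < 0) stop("`theta` must be non-negative")
  p_seg <- harmonic_a(n) * theta
  if (p_seg >= 1) {
    stop("a_n * theta >= 1: per-site segregation probability exceeds 1")
  }
  if (!is.null(seed)) set.seed(seed)
  seg <- logical(l)
  if (placement == "bernoulli") {
    seg <- stats::runif(l) < p_seg
  } else {
    seg[sample.int(l, round(p_seg * l))] <- TRUE
  }
  nseg <- sum(seg)
  b <- integer(l)
  bvals <- seq_len(n - 1L)
  b[seg] <- sample(bvals, nseg, replace = TRUE, prob = 1 / bvals)
  ref <- sample.int(4L, l, replace = TRUE)
  mut <- rep(NA_integer_, l)
  # mutant allele: uniform over the three non-reference nucleotides
  mut[seg] <- ((ref[seg] - 1L + sample.int(3L, nseg, replace = TRUE)) %% 4L) + 1L
  structure(data.frame(position = seq_len(as.integer(l)), b = b,
                       ref = ALLELES[ref], mut = ALLELES[mut]),
            class = c("site_truth", "data.frame"),
            n = n, theta = theta, l = as.integer(l))
}

#' Simulate pooled-sample sequencing reads as allele counts
#'
#' Sequencing of a pooled DNA sample is modelled per site and application:
#' read depth is Poisson with mean `n * mean_depth` (`mean_depth` is the
#' per-haploid coverage); each read carries the mutant allele with
#' probability `b/n`, i.e. reads sample the pooled haploid genomes with
#' replacement; each read is then independently misread with the
#' per-site error probability into one of the three other nucleotides
#' with equal chance.  Under a [beta_error()] model the per-site error
#' rate is drawn afresh for each application by default, so that the
#' error-prone locations of the two runs are uncorrelated — the regime in
#' which two sequencing applications can cancel each other's errors;
#' `shared_site_error = TRUE` instead shares each site's error rate
#' across both applications, modelling site-specific error propensity
#' common to the two runs (error events remain independent either way).
#'
#' @param truth A `"site_truth"` object from [simulate_truth()].
#' @param mean_depth Mean coverage per haploid genome per application.
#' @param error An [constant_error()] or [beta_error()] model.
#' @param applications 1 (single platform) or 2 (dual applications).
#' @param shared_site_error For the Beta model with two applications:
#'   share the per-site error rate across applications (`TRUE`) or draw
#'   it independently for each (`FALSE`, default).
#' @param seed Optional integer seed.
#' @return A list of `applications` [site_counts] tables.
#' @export
simulate_pooled_counts <- function(truth, mean_depth, error = constant_error(0),
                                   applications = 1L, shared_site_error = FALSE,
                                   seed = NULL) {
  stopifnot(inherits(truth, "site_truth"))
  if (!applications %in% c(1L, 2L)) stop("`applications` must be 1 or 2")
  if (mean_depth <= 0) stop("`mean_depth` must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- attr(truth, "n", exact = TRUE)
  l <- nrow(truth)
  ref <- match(truth$ref, ALLELES)
  mut <- match(truth$mut, ALLELES)
  eps_shared <- if (shared_site_error) .draw_epsilon(error, l) else NULL
  lapply(seq_len(applications), function(k) {
    eps <- if (is.null(eps_shared)) .draw_epsilon(error, l) else eps_shared
    r <- stats::rpois(l, n * mean_depth)
    m <- stats::rbinom(l, r, truth$b / n)
    cnt <- .reads_to_counts(l, ref, mut, r - m, m, eps)
    .as_site_counts(cnt, truth$position, n = n, application = k,
                    region = "simulated")
  })
}

#' Simulate single-line data: one haploid genome per covered individual
#'
#' Each diploid individual is sequenced to a Poisson (`mean_depth`) depth
#' at every site; individuals with zero reads are uncovered there.  For
#' each covered individual one read is taken to represent one of its two
#' haploid genomes, and that read is error-perturbed like any other.  The
#' truth therefore describes `n = 2 * n_individuals` haploid genomes, of
#' which at most `n_individuals` are observed per site (`Max(n_j)` equals
#' the number of individuals).  At 2X coverage a fraction
#' \eqn{1 - e^{-2} \approx 0.86} of individuals is covered per site.
#'
#' Because the set of sampled haploids (one random haploid from each of a
#' random subset of individuals) is a uniform random subset of the `n`
#' haploid genomes, the sampled mutant count at a segregating site is
#' hypergeometric, and the truncated-harmonic estimator applied to the
#' sampled alleles remains unbiased.
#'
#' @param truth A `"site_truth"` from [simulate_truth()] with `n` equal
#'   to twice the number of individuals.
#' @param mean_depth Mean coverage per diploid individual.
#' @param n_individuals Number of diploid individuals; defaults to half
#'   the truth's haploid sample size.
#' @inheritParams simulate_pooled_counts
#' @return A [site_counts] table of sampled haploid alleles (depth at a
#'   site = number of covered individuals, `n_j`).
#' @export
simulate_single_line <- function(truth, mean_depth, error = constant_error(0),
                                 n_individuals = attr(truth, "n", exact = TRUE) %/% 2L,
                                 seed = NULL) {
  stopifnot(inherits(truth, "site_truth"))
  if (mean_depth <= 0) stop("`mean_depth` must be positive")
  n <- attr(truth, "n", exact = TRUE)
  if (n_individuals < 1L || 2L * n_individuals > n) {
    stop("`n_individuals` must be between 1 and n/2 haplotype pairs")
  }
  if (!is.null(seed)) set.seed(seed)
  l <- nrow(truth)
  ref <- match(truth$ref, ALLELES)
  mut <- match(truth$mut, ALLELES)
  nj <- stats::rbinom(l, n_individuals, 1 - exp(-mean_depth))
  # sampled haploids form a uniform subset of the n: hypergeometric draw
  m <- integer(l)
  seg <- truth$b > 0L
  m[seg] <- stats::rhyper(sum(seg), truth$b[seg], n - truth$b[seg], nj[seg])
  eps <- .draw_epsilon(error, l)
  cnt <- .reads_to_counts(l, ref, mut, nj - m, m, eps)
  .as_site_counts(cnt, truth$position, n = n, application = "single-line",
                  region = "simulated")
}

# internal: distribute reference/mutant reads into a l x 4 count matrix,
# flipping each read with per-site probability eps to a uniformly chosen
# one of the three other nucleotides
.reads_to_counts <- function(l, ref, mut, ref_reads, mut_reads, eps) {
  OTHERS <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  idx <- seq_len(l)
  cnt <- matrix(0L, l, 4L)
  e_ref <- stats::rbinom(l, ref_reads, eps)
  cnt[cbind(idx, ref)] <- ref_reads - e_ref
  has_mut <- mut_reads > 0L
  e_mut <- integer(l)
  if (any(has_mut)) {
    e_mut[has_mut] <- stats::rbinom(sum(has_mut), mut_reads[has_mut], eps[has_mut])
    w <- which(has_mut)
    cnt[cbind(w, mut[w])] <- mut_reads[w] - e_mut[w]
  }
  spread <- function(cnt, src, e) {
    s1 <- stats::rbinom(l, e, 1 / 3)
    s2 <- stats::rbinom(l, e - s1, 1 / 2)
    s3 <- e - s1 - s2
    o <- OTHERS[src, , drop = FALSE]
    cnt[cbind(idx, o[, 1L])] <- cnt[cbind(idx, o[, 1L])] + s1
    cnt[cbind(idx, o[, 2L])] <- cnt[cbind(idx, o[, 2L])] + s2
    cnt[cbind(idx, o[, 3L])] <- cnt[cbind(idx, o[, 3L])] + s3
    cnt
  }
  cnt <- spread(cnt, ref, e_ref)
  if (any(has_mut)) {
    src <- ref
    src[has_mut] <- mut[has_mut]
    cnt <- spread(cnt, src, e_mut)
  }
  cnt
}
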
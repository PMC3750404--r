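#' Watterson's theta from pooled-sample single-platform counts
#'
#' Estimates per-site diversity from a pooled sequencing run.  Sites are
#' classified by [classify_sites()]; the estimate is the number of
#' segregating sites whose alleles both exceed `z` reads, divided by the
#' summed detection probability over all non-missing sites:
#' \deqn{\hat\theta = S_{>z} \Big/ \sum_{j}\sum_{b=1}^{n-1}
#'   q_1(z, b, r_j) / b,}
#' where \eqn{q_1} is [detect_prob_filtered()] and the outer sum runs over
#' retained (non-missing) sites only.  The denominator corrects both for
#' the binomial sampling of alleles by reads and for the loss of
#' low-frequency variants to the truncation filter, so the estimator is
#' unbiased under error-free sequencing.
#'
#' @param sites A [site_counts] table for one sequencing application.
#' @param n Pool size: number of haploid genomes in the pool.
#' @param policy A [filter_policy] giving `r_min` and `z`.
#' @return A `"theta_estimate"` object: a list with `theta_per_site`,
#'   `theta_per_kb`, `s_count`, `denominator`, `usable_sites`, and the
#'   parameters used.
#' @export
estimate_pooled_single <- function(sites, n, policy = filter_policy()) {
  n <- .check_n(n)
  cnt <- .count_matrix(sites)
  cls <- .classify_single(cnt, policy)
  keep <- cls$status > 0L
  if (!any(keep)) stop("no usable sites: every site is missing under this policy")
  s <- sum(cls$status == 2L)
  den <- .detect_weight_sum_single(cls$depth[keep], n, policy$z)
  .theta_estimate(s, den, sum(keep), scheme = "pooled_single",
                  n = n, policy = policy)
}

#' Watterson's theta from dual sequencing applications
#'
#' Estimates per-site diversity from two independent sequencing runs of
#' the same pooled sample.  Because sequencing errors of two applications
#' rarely strike the same site with the same wrong nucleotide, requiring
#' every allele to be seen in both runs removes nearly all error-driven
#' false segregating sites.  The denominator uses the dual detection
#' probability [dual_detect_prob_filtered()], the product of the two
#' single-run probabilities at depths \eqn{r_{1j}}, \eqn{r_{2j}}.
#'
#' @param app1,app2 [site_counts] tables over identical positions.
#' @inheritParams estimate_pooled_single
#' @inherit estimate_pooled_single return
#' @export
estimate_pooled_dual <- function(app1, app2, n, policy = filter_policy()) {
  n <- .check_n(n)
  .check_positions_match(app1, app2)
  c1 <- .count_matrix(app1)
  c2 <- .count_matrix(app2)
  cls <- .classify_dual(c1, c2, policy)
  keep <- cls$status > 0L
  if (!any(keep)) stop("no usable sites: every site is missing under this policy")
  s <- sum(cls$status == 2L)
  den <- .detect_weight_sum_dual(cls$depth1[keep], cls$depth2[keep], n, policy$z)
  .theta_estimate(s, den, sum(keep), scheme = "pooled_dual",
                  n = n, policy = policy)
}

#' Watterson's theta from single-line (one haploid per individual) data
#'
#' For individually sequenced (or barcoded) diploids at low coverage, one
#' read per covered individual is taken to represent one haploid genome.
#' At site `j` with `n_j` covered individuals, the site contributes
#' \eqn{S_j / a'_{n_j}} where \eqn{S_j = 1} when at least two alleles are
#' each carried by more than `z` of the sampled haploids, and
#' \eqn{a'_{n_j}} is the truncated harmonic number
#' ([truncated_harmonic()]).  The estimate is the average contribution
#' over the region:
#' \deqn{\hat\theta = \frac{1}{l}\sum_j S_j / a'_{n_j}.}
#' Sites with `n_j < 2z + 2` have an empty truncated spectrum and are
#' excluded from both the sum and the effective region length.
#'
#' @param sites A [site_counts] table of sampled haploid alleles: the
#'   count columns hold how many covered individuals carried each
#'   nucleotide, so depth equals `n_j`.  Sites absent from the table are
#'   treated as uncovered (`n_j = 0`).
#' @param z Truncation level.
#' @param region_length Total number of sites `l` in the surveyed region.
#' @inherit estimate_pooled_single return
#' @export
estimate_single_line <- function(sites, z = 0L, region_length) {
  z <- .check_z(z)
  if (length(region_length) != 1L || region_length < 1) {
    stop("`region_length` must be a positive scalar")
  }
  if (region_length < nrow(sites)) {
    stop("`region_length` is smaller than the number of sites supplied")
  }
  cnt <- .count_matrix(sites)
  nj <- rowSums(cnt)
  usable <- nj >= 2L * z + 2L
  # sites with too few covered individuals (including uncovered sites not
  # present in the table) have an empty truncated spectrum: drop from l
  l_eff <- sum(usable)
  if (l_eff <= 0) stop("no usable sites: effective region length is zero")
  seg <- rowSums(cnt > z) >= 2L & usable
  aprime <- numeric(nrow(cnt))
  segidx <- which(seg)
  if (length(segidx)) {
    aprime[segidx] <- truncated_harmonic(nj[segidx], z)
  }
  theta <- sum(1 / aprime[segidx]) / l_eff
  out <- .theta_estimate(sum(seg), NA_real_, l_eff, scheme = "single_line",
                         n = NA_integer_,
                         policy = list(r_min = NA_integer_, z = z))
  out$theta_per_site <- theta
  out$theta_per_kb <- 1000 * theta
  out
}

# ---- detection-probability denominators ----

# per-depth weight w(r) = sum_b q1(z, b, r)/b
.depth_weights <- function(ur, n, z) {
  b <- seq_len(n - 1L)
  vapply(ur, function(ri) sum(detect_prob_filtered(z, b, n, ri) / b), numeric(1))
}

# sum over sites of w(r_j); depths are tabulated so the weight is computed
# once per distinct depth
.detect_weight_sum_single <- function(r, n, z) {
  tab <- tabulate(r + 1L, nbins = max(r) + 1L)
  ur <- which(tab > 0L) - 1L
  sum(.depth_weights(ur, n, z) * tab[ur + 1L])
}

# sum over sites of sum_b q1(z, b, r1j) q1(z, b, r2j)/b, via the outer
# product of per-depth detection profiles over distinct depth pairs
.detect_weight_sum_dual <- function(r1, r2, n, z) {
  u1 <- sort(unique(r1))
  u2 <- sort(unique(r2))
  b <- seq_len(n - 1L)
  q <- function(u) t(vapply(u, function(ri) detect_prob_filtered(z, b, n, ri),
                            numeric(n - 1L)))
  W <- q(u1) %*% (t(q(u2)) / b)  # length(u1) x length(u2)
  # column-major linear index into W for each site's (r1, r2) pair
  key <- (match(r2, u2) - 1L) * length(u1) + match(r1, u1)
  tab <- tabulate(key, nbins = length(u1) * length(u2))
  nz <- which(tab > 0L)
  sum(W[nz] * tab[nz])
}

# ---- estimate object ----

.theta_estimate <- function(s, den, usable, scheme, n, policy) {
  theta <- if (is.na(den)) NA_real_ else if (den > 0) s / den else 0
  structure(list(theta_per_site = theta,
                 theta_per_kb = 1000 * theta,
                 s_count = as.integer(s),
                 denominator = den,
                 usable_sites = usable,
                 scheme = scheme,
                 n = n,
                 r_min = policy$r_min,
                 z = policy$z),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("Watterson's theta estimate (%s scheme)\n", x$scheme))
  cat(sprintf("  theta: %.6g per site  (%.4g per kb)\n",
              x$theta_per_site, x$theta_per_kb))
  cat(sprintf("  segregating sites S_>%d: %d\n", x$z, x$s_count))
  if (!is.na(x$denominator)) {
    cat(sprintf("  detection-probability denominator: %.6g\n", x$denominator))
  }
  cat(sprintf("  usable sites: %d\n", x$usable_sites))
  invisible(x)
}

#' @export
as.data.frame.theta_estimate <- function(x, ...) {
  data.frame(scheme = x$scheme, theta_per_site = x$theta_per_site,
             theta_per_kb = x$theta_per_kb, s_count = x$s_count,
             denominator = x$denominator, usable_sites = x$usable_sites,
             z = x$z, r_min = x$r_min)
}
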
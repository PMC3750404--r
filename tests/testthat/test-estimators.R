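test_that("single-line estimator reproduces the hand-computed single-site case", {
  # one polymorphic site (minor count 3 of 10 sampled haploids) in 1 kb,
  # plus fully monomorphic coverage elsewhere
  tab <- site_counts(1:1000,
                     A = c(7, rep(10, 999)),
                     C = c(3, rep(0, 999)))
  est <- estimate_single_line(tab, z = 0, region_length = 1000)
  expect_equal(est$theta_per_site, (1 / 1000) / harmonic_a(10))
  expect_equal(est$s_count, 1L)
  expect_equal(est$usable_sites, 1000L)
  # truncation: minor count 3 survives z = 2 but not z = 3 spectra
  expect_equal(estimate_single_line(tab, 2, 1000)$theta_per_site,
               (1 / 1000) / truncated_harmonic(10, 2))
  expect_equal(estimate_single_line(tab, 3, 1000)$s_count, 0L)
})

test_that("single-line sites below the truncation floor shrink the usable region", {
  tab <- site_counts(1:10, A = c(rep(10, 5), rep(3, 5)))
  est <- estimate_single_line(tab, z = 1, region_length = 10)
  expect_equal(est$usable_sites, 5L)  # n_j = 3 < 2z + 2 dropped
  expect_error(estimate_single_line(tab, 5, 10), "usable")
  expect_error(estimate_single_line(tab, 0, 5), "region_length")
})

test_that("pooled single-platform estimator matches a hand-built denominator", {
  # a single segregating site at depth 6 in a pool of 4 haploids
  tab <- make_counts(c(4, 2, 0, 0))
  est <- estimate_pooled_single(tab, n = 4, filter_policy(6, 0))
  den <- sum(detect_prob_filtered(0, 1:3, 4, 6) / (1:3))
  expect_equal(est$theta_per_site, 1 / den)
  expect_equal(est$s_count, 1L)
  # all monomorphic -> zero estimate with a positive denominator
  mono <- make_counts(c(50, 0, 0, 0), c(0, 60, 0, 0))
  est0 <- estimate_pooled_single(mono, 50, filter_policy())
  expect_equal(est0$theta_per_site, 0)
  expect_gt(est0$denominator, 0)
  # every site below r_min -> undefined estimate
  thin <- make_counts(c(2, 0, 0, 0))
  expect_error(estimate_pooled_single(thin, 50, filter_policy()), "usable")
})

test_that("dual estimator denominator is the product form of the single one", {
  app1 <- make_counts(c(4, 3, 0, 0), c(20, 0, 0, 0))
  app2 <- make_counts(c(5, 2, 0, 0), c(18, 0, 0, 0))
  pol <- filter_policy(6, 1)
  est <- estimate_pooled_dual(app1, app2, n = 10, pol)
  b <- 1:9
  den <- sum(detect_prob_filtered(1, b, 10, 7) * detect_prob_filtered(1, b, 10, 7) / b) +
    sum(detect_prob_filtered(1, b, 10, 20) * detect_prob_filtered(1, b, 10, 18) / b)
  expect_equal(est$denominator, den)
  expect_equal(est$s_count, 1L)
  expect_equal(est$theta_per_site, 1 / den)
  # the dual denominator never exceeds either single-application one
  est1 <- estimate_pooled_single(app1, 10, pol)
  expect_lte(est$denominator, est1$denominator)
  expect_error(estimate_pooled_dual(app1, app2[1:1, ], 10, pol), "positions")
})

test_that("estimates are invariant to nucleotide relabelling", {
  set.seed(42)
  truth <- simulate_truth(5000, 2e-4, 50)
  app <- simulate_pooled_counts(truth, 2, constant_error(0.005))[[1]]
  pol <- filter_policy(6, 1)
  est <- estimate_pooled_single(app, 50, pol)
  # swap A<->G and C<->T everywhere
  swapped <- site_counts(app$position, A = app$G, C = app$T, G = app$A, T = app$C)
  est_sw <- estimate_pooled_single(swapped, 50, pol)
  expect_equal(est_sw$theta_per_site, est$theta_per_site)
  expect_equal(est_sw$s_count, est$s_count)
})

test_that("duplicating every site leaves the pooled estimate unchanged", {
  set.seed(7)
  truth <- simulate_truth(3000, 3e-4, 50)
  app <- simulate_pooled_counts(truth, 2, constant_error(0.001))[[1]]
  est <- estimate_pooled_single(app, 50, filter_policy())
  dup <- site_counts(seq_len(2 * nrow(app)),
                     A = rep(app$A, 2), C = rep(app$C, 2),
                     G = rep(app$G, 2), T = rep(app$T, 2))
  est2 <- estimate_pooled_single(dup, 50, filter_policy())
  expect_equal(est2$theta_per_site, est$theta_per_site)
  expect_equal(est2$s_count, 2L * est$s_count)
})

test_that("raising the truncation level never increases the segregating count", {
  set.seed(11)
  truth <- simulate_truth(20000, 1e-4, 50)
  app <- simulate_pooled_counts(truth, 2, constant_error(0.01))[[1]]
  s <- vapply(0:2, function(z) {
    sum(classify_sites(app, filter_policy(6, z))$status == "segregating")
  }, integer(1))
  expect_true(all(diff(s) <= 0))
  expect_gt(s[1], s[3])  # errors really are suppressed by truncation
})
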
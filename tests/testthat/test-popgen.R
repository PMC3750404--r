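test_that("harmonic numbers match direct summation and reject n < 2", {
  expect_equal(harmonic_a(2), 1)
  expect_equal(harmonic_a(3), 1.5)
  expect_equal(harmonic_a(50), sum_reciprocal(1, 49))
  expect_equal(harmonic_a(c(2, 3, 10)), c(1, 1.5, sum_reciprocal(1, 9)))
  expect_error(harmonic_a(1), "n")
  expect_error(harmonic_a(2.5), "n")
})

test_that("truncated harmonic sums truncate both spectrum ends", {
  expect_equal(truncated_harmonic(10, 0), harmonic_a(10))
  expect_equal(truncated_harmonic(10, 1), sum_reciprocal(2, 8))
  expect_equal(truncated_harmonic(25, 2), sum_reciprocal(3, 22))
  # empty range when n < 2z + 2
  expect_equal(truncated_harmonic(4, 2), 0)
  expect_equal(truncated_harmonic(2, 1), 0)
})

test_that("Ewens spectrum is a proper distribution proportional to 1/b", {
  expect_equal(ewens_prob(1, 2), 1)
  expect_equal(ewens_prob(2, 5), 0.24)
  for (n in c(2, 5, 17, 50, 200)) {
    expect_equal(sum(ewens_prob(seq_len(n - 1), n)), 1, tolerance = 1e-12)
  }
  expect_error(ewens_prob(0, 5), "b")
  expect_error(ewens_prob(5, 5), "b")
})

test_that("detection probabilities agree with exhaustive read enumeration", {
  expect_equal(detect_prob(3, 10, 1), 0)
  expect_equal(detect_prob(25, 50, 2), 0.5)
  expect_equal(detect_prob(10, 50, 8), 1 - 0.8^8 - 0.2^8)
  cases <- expand.grid(b = c(1, 3, 7), n = c(8, 50), r = c(2, 5, 8), z = 0:2)
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      expect_equal(detect_prob_filtered(z, b, n, r), enum_detect_prob(b, n, r, z),
                   tolerance = 1e-12,
                   label = sprintf("b=%d n=%d r=%d z=%d", b, n, r, z))
      if (z == 0) {
        expect_equal(detect_prob(b, n, r), enum_detect_prob(b, n, r, 0),
                     tolerance = 1e-12)
      }
    })
  }
})

test_that("truncated detection handles impossible and boundary depths", {
  # with z = 1 both alleles need >= 2 of 3 reads: impossible
  expect_equal(detect_prob_filtered(1, 10, 50, 3), 0)
  expect_equal(detect_prob_filtered(2, 25, 50, 5), 0)
  expect_equal(detect_prob_filtered(0, 25, 50, 0), 0)
  # binomial-CDF oracle at the half-frequency point
  expect_equal(detect_prob_filtered(1, 25, 50, 6), sum(dbinom(2:4, 6, 0.5)),
               tolerance = 1e-12)
  # z = 0 reduces exactly to the unfiltered form
  for (r in 0:12) {
    expect_identical(detect_prob_filtered(0, 7, 20, r), detect_prob(7, 20, r))
  }
})

test_that("detection probabilities are monotone in depth and symmetric in b", {
  for (z in 0:2) {
    q <- detect_prob_filtered(z, 5, 50, 0:60)
    expect_true(all(diff(q) >= -1e-15))
    expect_true(all(q >= 0 & q <= 1))
  }
  for (b in 1:24) {
    expect_equal(detect_prob(b, 25, 7), detect_prob(25 - b, 25, 7))
    expect_equal(detect_prob_filtered(1, b, 25, 9),
                 detect_prob_filtered(1, 25 - b, 25, 9))
    expect_equal(dual_detect_prob(b, 25, 5, 9), dual_detect_prob(25 - b, 25, 5, 9))
  }
})

test_that("spectrum-averaged detection probability behaves at its limits", {
  expect_equal(detect_prob_any(50, 1), 0)
  expect_equal(detect_prob_any(4, 3), 6.75 / 11)  # hand-computed 3-term sum
  expect_gt(detect_prob_any(50, 5000), 1 - 1e-6)
  b <- 1:49
  expect_equal(detect_prob_any(50, 10),
               sum(ewens_prob(b, 50) * detect_prob(b, 50, 10)))
})

test_that("dual detection is the product of the applications and bounded by each", {
  expect_equal(dual_detect_prob(10, 50, 4, 0), 0)
  expect_equal(dual_detect_prob(10, 50, 6, 6), detect_prob(10, 50, 6)^2)
  expect_equal(dual_detect_prob(10, 50, 4, 6),
               detect_prob(10, 50, 4) * detect_prob(10, 50, 6))
  expect_equal(dual_detect_prob_filtered(1, 25, 50, 6, 6),
               detect_prob_filtered(1, 25, 50, 6)^2)
  expect_equal(dual_detect_prob_filtered(1, 25, 50, 3, 100), 0)
  for (b in c(1, 10, 30)) {
    expect_lte(dual_detect_prob(b, 50, 8, 13),
               min(detect_prob(b, 50, 8), detect_prob(b, 50, 13)))
  }
  expect_identical(dual_detect_prob_filtered(0, 9, 50, 7, 11),
                   dual_detect_prob(9, 50, 7, 11))
})

test_that("error-read probability is the binomial mass function", {
  expect_equal(error_prob(5, 0, 0), 1)
  expect_equal(error_prob(1, 1, 0.01), 0.01)
  expect_equal(error_prob(10, 2, 0.005), choose(10, 2) * 0.005^2 * 0.995^8)
  expect_error(error_prob(5, 6, 0.01), "x")
})

test_that("MAF screen probability uses the strict binomial distribution function", {
  # enumeration oracle at small depth
  expect_equal(maf_below_prob(10, 0.5, 0.25), sum(dbinom(0:2, 10, 0.5)))
  # threshold is strict: at cutoff 0.3 and depth 10, X < 3 means X <= 2
  expect_equal(maf_below_prob(10, 0.5, 0.3), pbinom(2, 10, 0.5))
  expect_equal(maf_below_prob(10, 0.5, 1), 1)
  expect_error(maf_below_prob(0, 0.5, 0.1), "depth")
  expect_error(maf_below_prob(10, 1.2, 0.1), "true_freq")
})
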
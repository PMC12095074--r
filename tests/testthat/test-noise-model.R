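test_that("binomial tail handles boundaries and matches enumeration", {
  expect_equal(binomial_tail(0, 50, 0.01), 1)
  expect_equal(binomial_tail(1, 1, 0.5), 0.5)
  expect_equal(binomial_tail(51, 50, 0.5), 0)
  # frozen from the choose()-arithmetic oracle at (2, 100, 0.001)
  expect_equal(binomial_tail(2, 100, 0.001),
               enum_binomial_tail(2, 100, 0.001), tolerance = 1e-13)
  expect_equal(binomial_tail(2, 100, 0.001), 0.00463806839042419,
               tolerance = 1e-12)
  expect_error(binomial_tail(5, 3, 0.5), "m_thr")
  expect_error(binomial_tail(1, 10, 1.5), "q must lie")
})

test_that("binomial tail agrees with exhaustive enumeration to 12 digits", {
  for (q in c(0.1, 0.5, 0.9)) {
    for (N in 0:20) {
      m <- 0:(N + 1)
      got <- binomial_tail(m, N, q)
      want <- vapply(m, enum_binomial_tail, numeric(1), N = N, q = q)
      expect_signif_equal(got, want, 12)
    }
  }
})

test_that("criteria normalise strict thresholds and multiply per-SNP errors", {
  crit <- published_criteria()
  expect_equal(crit$gt3$m_thr, 4L)  # >3 reads is >=4 reads
  expect_equal(criterion_fp_probability(crit$gt3, 1000, 0.001),
               binomial_tail(4, 1000, 0.001))
  # no reads, no false call
  expect_equal(criterion_fp_probability(crit$ge2, 0, 0.001), 0)
  # two SNPs on one read must both err: q^2
  expect_equal(criterion_fp_probability(crit$ge1_two_snps, 1e4, 1e-3),
               binomial_tail(1, 1e4, 1e-6))
})

test_that("two-SNP criterion matches Monte-Carlo paired-error draws", {
  set.seed(401)
  q <- 0.01
  N <- 200L
  reps <- 2e5L
  # a read falsely supports mobility when both its SNP bases err
  both_err <- matrix(runif(2 * reps) < q, ncol = 2)
  read_err_rate <- mean(both_err[, 1] & both_err[, 2])
  mc <- mean(replicate(200, {
    any(runif(N) < q^2)
  }))
  crit <- published_criteria()$ge1_two_snps
  p_closed <- criterion_fp_probability(crit, N, q)
  expect_equal(read_err_rate, q^2, tolerance = 3 * sqrt(q^2 / reps) / q^2)
  expect_equal(mc, p_closed, tolerance = 4 * sqrt(p_closed / 200) / p_closed)
})

test_that("expected false positives sum tails and grow with depth", {
  crit <- published_criteria()$ge2
  efp <- expected_false_positives(rep(1e4, 1000), crit, 1e-4)
  expect_equal(efp$expected, 1000 * binomial_tail(2, 1e4, 1e-4))
  expect_equal(efp$expected, 1000 * enum_binomial_tail(2, 1e4, 1e-4),
               tolerance = 1e-10)
  # monotone: doubling every depth never decreases the expectation
  d <- c(10, 100, 1000, 5000)
  e1 <- expected_false_positives(d, crit, 1e-3)$expected
  e2 <- expected_false_positives(2 * d, crit, 1e-3)$expected
  expect_gte(e2, e1)
  expect_true(!is.unsorted(efp$curve$fp_probability))
  expect_equal(expected_false_positives(rep(0, 5), crit, 1e-3)$expected, 0)
  expect_warning(expected_false_positives(numeric(0), crit, 1e-3), "empty")
})

test_that("fp probability is non-decreasing in N and q for every criterion", {
  Ns <- c(0, 1, 10, 100, 1000, 10000)
  qs <- c(1e-5, 1e-4, 1e-3, 1e-2, 0.1)
  for (crit in published_criteria()) {
    for (q in qs) {
      expect_true(!is.unsorted(criterion_fp_probability(crit, Ns, q)),
                  label = paste(crit$name, "monotone in N"))
    }
    for (N in Ns[-1]) {
      expect_true(!is.unsorted(vapply(qs, function(q) {
        criterion_fp_probability(crit, N, q)
      }, numeric(1))), label = paste(crit$name, "monotone in q"))
    }
  }
})

test_that("background estimation pools counts and updates the conjugate prior", {
  hom <- make_hom(make_sites(n_foreign = c(50L, 34L),
                             n_local = c(60000L, 39916L)))
  est <- estimate_background(hom)
  expect_equal(est$n_foreign_total, 84L)
  expect_equal(est$n_total, 100000L)
  expect_equal(est$rate_point, 0.00084)
  expect_equal(format_percent(est$rate_point), "0.084%")
  expect_equal(est$posterior_a, 1 + 84)
  expect_equal(est$posterior_b, 1 + 100000 - 84)

  # conjugate update with no observations of the foreign allele
  est0 <- estimate_background(make_hom(make_sites(0L, 10L)), 1, 1)
  expect_equal(est0$posterior_a, 1)
  expect_equal(est0$posterior_b, 11)

  expect_error(estimate_background(make_het(make_sites(1L, 9L))),
               "homograft")
  expect_error(estimate_background(make_hom(make_sites(0L, 0L))),
               "zero total depth")
})

test_that("simulated homograft background recovers e/3", {
  e <- 0.003
  ds <- simulate_experiment(simulation_config(
    n_genes = 300, base_error_rate = e,
    expression_log_mean = log(200), rng_seed = 91
  ))
  est <- estimate_background(ds$samples$hom_root,
                             total_definition = "all_nucleotides")
  post_sd <- sqrt(est$posterior_a * est$posterior_b /
                    ((est$posterior_a + est$posterior_b)^2 *
                       (est$posterior_a + est$posterior_b + 1)))
  expect_lt(abs(est$rate_point - e / 3), 3 * post_sd)
})

test_that("foreign read fraction is the pooled ratio with comparison flag", {
  het <- make_het(make_sites(n_foreign = c(1000L, 675L),
                             n_local = c(1000000L, 751504L)))
  f <- foreign_read_fraction(het)
  expect_equal(f$n_foreign, 1675L)
  expect_equal(f$n_total, 1753179L)
  expect_equal(format_percent(f$fraction, "decimals2"), "0.10%")
  expect_equal(foreign_read_fraction(make_het(make_sites(0L, 500L)))$fraction, 0)
  expect_error(foreign_read_fraction(make_het(make_sites(0L, 0L))), "zero")

  hom <- make_hom(make_sites(n_foreign = 20L, n_local = 9980L))
  cmp <- compare_foreign_fractions(het, hom)
  expect_true(cmp$no_excess)  # het 0.096% <= hom 0.2%: no transport signal
})
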
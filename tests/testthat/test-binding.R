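# Adhesion-frequency statistics.

test_that("binding probability handles edge cases and matches binomial theory", {
  z <- binding_probability(rep(0, 200), B = 100, seed = 1)
  expect_equal(z$p, 0)
  expect_equal(z$se, 0)
  expect_true(z$zero_events)
  expect_equal(z$rule_of_three, 3 / 200)

  # 57 events in 1052 trials: bootstrap s.e. ~ 0.7%
  out <- c(rep(1, 57), rep(0, 995))
  r <- binding_probability(out, B = 2000, seed = 3)
  expect_equal(r$p, 57 / 1052)
  expect_gt(r$se, 0.006)
  expect_lt(r$se, 0.008)

  # bootstrap s.e. within 10% of sqrt(p(1-p)/n) for n >= 500
  for (case in list(c(0.054, 1052), c(0.1, 500), c(0.3, 2000))) {
    o <- simulate_binding_outcomes(case[1], case[2], seed = 7)
    b <- binding_probability(o, B = 2000, seed = 8)
    closed <- sqrt(b$p * (1 - b$p) / b$n_trials)
    expect_lt(abs(b$se / closed - 1), 0.10)
  }
  expect_error(binding_probability(numeric(0), seed = 1),
               class = "dfs_domain_error")
  expect_error(binding_probability(c(0, 2), seed = 1),
               class = "dfs_domain_error")
})

test_that("binding probability is invariant to outcome ordering", {
  o <- simulate_binding_outcomes(0.08, 1000, seed = 5)
  b1 <- binding_probability(o, B = 2000, seed = 9)
  b2 <- binding_probability(rev(o), B = 2000, seed = 9)
  expect_equal(b1$p, b2$p)
  expect_lt(abs(b1$se - b2$se), 5e-4)
})

test_that("nonspecific baseline averages the two controls and propagates error", {
  o1 <- c(rep(1, 10), rep(0, 990))   # 1.0%
  o2 <- c(rep(1, 18), rep(0, 982))   # 1.8%
  bl <- nonspecific_baseline(o1, o2, B = 1000, seed = 2)
  expect_equal(bl$p_ns, 0.014)
  c1 <- bl$components[[1]]; c2 <- bl$components[[2]]
  expect_equal(bl$se_ns, sqrt(c1$se^2 + c2$se^2) / 2)

  z <- nonspecific_baseline(rep(0, 100), rep(0, 100), B = 100, seed = 2)
  expect_equal(z$p_ns, 0)
  expect_equal(z$se_ns, 0)

  # closed-form propagation oracle at n = 2000 per control
  oo1 <- simulate_binding_outcomes(0.012, 2000, seed = 21)
  oo2 <- simulate_binding_outcomes(0.016, 2000, seed = 22)
  bl2 <- nonspecific_baseline(oo1, oo2, B = 2000, seed = 23)
  p1 <- mean(oo1); p2 <- mean(oo2)
  closed <- sqrt(p1 * (1 - p1) / 2000 + p2 * (1 - p2) / 2000) / 2
  expect_lt(abs(bl2$se_ns / closed - 1), 0.10)
})

test_that("specific-vs-baseline comparison separates signal from null", {
  spec <- binding_probability(simulate_binding_outcomes(0.057, 2215, seed = 31),
                              B = 1000, seed = 32)
  base <- nonspecific_baseline(simulate_binding_outcomes(0.009, 2000, seed = 33),
                               simulate_binding_outcomes(0.009, 2000, seed = 34),
                               B = 1000, seed = 35)
  cmp <- compare_binding(spec, base)
  expect_equal(cmp$verdict, "specific")
  expect_gt(cmp$ci95[1], 0)

  null_spec <- binding_probability(simulate_binding_outcomes(0.012, 1500, seed = 41),
                                   B = 1000, seed = 42)
  null_base <- nonspecific_baseline(simulate_binding_outcomes(0.012, 1500, seed = 43),
                                    simulate_binding_outcomes(0.012, 1500, seed = 44),
                                    B = 1000, seed = 45)
  cmp0 <- compare_binding(null_spec, null_base)
  expect_equal(cmp0$verdict, "non-specific")
})

test_that("the null comparison false-specific rate is near the nominal 5%", {
  false_pos <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    s <- binding_probability(simulate_binding_outcomes(0.012, 800, seed = 3 * i),
                             B = 200, seed = 3 * i + 1)
    b <- nonspecific_baseline(simulate_binding_outcomes(0.012, 800, seed = 90000 + 3 * i),
                              simulate_binding_outcomes(0.012, 800, seed = 180000 + 3 * i),
                              B = 200, seed = 3 * i + 2)
    if (compare_binding(s, b)$verdict == "specific") false_pos <- false_pos + 1L
  }
  expect_gt(false_pos / n_rep, 0.005)
  expect_lt(false_pos / n_rep, 0.12)
})

test_that("Poisson single-bond fraction: limits, values, monotonicity", {
  expect_equal(poisson_single_bond_fraction(1e-9), 1, tolerance = 1e-8)
  # closed-form oracle lambda * e^-lambda / (1 - e^-lambda)
  lam <- -log(1 - 0.06)
  expect_equal(poisson_single_bond_fraction(0.06),
               lam * exp(-lam) / (1 - exp(-lam)), tolerance = 1e-12)
  expect_equal(poisson_single_bond_fraction(0.06), 0.9694, tolerance = 1e-4)
  expect_gt(poisson_single_bond_fraction(0.05), 0.97)
  expect_equal(poisson_single_bond_fraction(0.05), 0.9746, tolerance = 1e-4)
  g <- seq(0.005, 0.5, by = 0.005)
  expect_true(all(diff(poisson_single_bond_fraction(g)) < 0))
  expect_error(poisson_single_bond_fraction(0), class = "dfs_domain_error")
  expect_error(poisson_single_bond_fraction(1), class = "dfs_domain_error")
})
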
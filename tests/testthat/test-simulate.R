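# Synthetic force-curve generator: deterministic mechanics against
# independent root-finds, stochastic structure against closed forms.

test_that("empty curves are pure baseline and specific paths solve the series system", {
  cfg0 <- noiseless_config()
  r_empty <- simulate_retract_curve(cfg0, "empty", seed = 5, velocity = 1000)
  expect_true(all(r_empty$curve$force == 0))
  expect_true(is.na(r_empty$truth$true_rupture_force))

  r_spec <- simulate_retract_curve(cfg0, "specific", seed = 7, velocity = 1000)
  cv <- r_spec$curve
  teth <- cfg0$tether
  kc <- cfg0$spring_constant
  for (frac in c(0.3, 0.6, 0.9)) {
    i <- round(length(cv$time) * frac)
    d <- cv$tip_sample_distance[i]
    f_ref <- stats::uniroot(function(f) fjc_extension(f, teth) + f / kc - d,
                            c(0, 500), tol = 1e-12)$root
    expect_equal(cv$force[i], f_ref, tolerance = 1e-7)
  }
})

test_that("curve invariants hold: time grid, distance = v*t, metadata", {
  cfg <- quick_config()
  r <- simulate_retract_curve(cfg, "specific", seed = 3, velocity = 500)
  cv <- r$curve
  expect_true(all(diff(cv$time) > 0))
  expect_equal(cv$tip_sample_distance, cv$pulling_velocity * cv$time)
  expect_error(force_curve("x", c(0, 1, 1.5), c(0, 2, 4), c(0, 0, 0), 2, 10),
               class = "dfs_validation_error")
  expect_error(force_curve("x", c(0, 1), c(0, 1), c(0, 0), 1, -5),
               class = "dfs_validation_error")
})

test_that("experiment mixture, determinism and class fractions behave", {
  cfg_empty <- simulation_config(kin_slow(), velocities = 2000,
                                 curves_per_velocity = 10,
                                 fractions = c(0, 0, 1), seed = 11)
  sim <- simulate_experiment(cfg_empty)
  expect_true(all(sim$truth$true_class == "empty"))

  cfg <- simulation_config(kin_slow(), velocities = 2000,
                           curves_per_velocity = 20, seed = 12)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$curves, s2$curves)
  expect_identical(s1$truth, s2$truth)

  # specific count at the default 6% fraction: 99% binomial interval
  cfg_big <- simulation_config(kin_slow(), velocities = 5000,
                               curves_per_velocity = 5000,
                               fractions = c(0.06, 0.02, 0.92), seed = 13)
  simb <- simulate_experiment(cfg_big)
  n_spec <- sum(simb$truth$true_class == "specific")
  bounds <- stats::qbinom(c(0.005, 0.995), 5000, 0.06)
  expect_gte(n_spec, bounds[1])
  expect_lte(n_spec, bounds[2])
})

test_that("specific ruptures happen near the two-tether contour length", {
  cfg <- quick_config(seed = 21)
  d_at_rupture <- replicate(40, {
    r <- simulate_retract_curve(cfg, "specific",
                                seed = sample.int(1e6, 1), velocity = 1000)
    r$curve$tip_sample_distance[r$truth$true_rupture_index]
  })
  lc <- contour_length(cfg$tether)
  # low-force ruptures sit below Lc (partially aligned tether); the ensemble
  # still concentrates in a band around the two-tether contour length
  expect_gt(mean(d_at_rupture > 0.55 * lc & d_at_rupture < 1.5 * lc), 0.95)
  expect_gt(stats::median(d_at_rupture) / lc, 0.7)
  expect_lt(stats::median(d_at_rupture) / lc, 1.35)
})

test_that("rupture-force ensemble follows the path-hazard law and scales with velocity", {
  kin <- kin_slow()
  cfg <- simulation_config(kin, noise_sd = 0, lc_sd_frac = 0, seed = 31)
  v <- 1000
  set.seed(42)
  f_r <- replicate(800, {
    r <- simulate_retract_curve(cfg, "specific",
                                seed = sample.int(1e7, 1), velocity = v)
    r$truth$true_rupture_force
  })
  # oracle CDF: survival along the deterministic noiseless force path,
  # integrating the Bell hazard over time (independent trapezoid here)
  fs <- dfspec:::sampling_rate_for(cfg, v)
  r0 <- simulate_retract_curve(noiseless_config(), "specific", seed = 1,
                               velocity = v)
  f_path <- r0$curve$force
  tt <- r0$curve$time
  haz <- kin$k0_off * exp(f_path * kin$x_beta / kin$kBT)
  cum <- c(0, cumsum(0.5 * diff(tt) * (haz[-1] + haz[-length(haz)])))
  cdf <- function(q) {
    s <- exp(-stats::approx(f_path, cum, xout = pmin(q, max(f_path)),
                            rule = 2, ties = max)$y)
    1 - s
  }
  # rupture forces share the discrete sampling grid, so exact ties occur;
  # the KS p-value is still valid for this one-sample comparison
  expect_gt(suppressWarnings(stats::ks.test(f_r, cdf))$p.value, 0.01)

  mean_by_v <- vapply(c(200, 2000, 10000), function(vv) {
    mean(replicate(150, {
      r <- simulate_retract_curve(cfg, "specific",
                                  seed = sample.int(1e7, 1), velocity = vv)
      r$truth$true_rupture_force
    }))
  }, numeric(1))
  expect_true(all(diff(mean_by_v) > 0))
})

test_that("nonspecific curves rupture early with short contour lengths", {
  cfg <- quick_config(seed = 77)
  tr <- do.call(rbind, lapply(1:30, function(s)
    simulate_retract_curve(cfg, "nonspecific", seed = s * 101,
                           velocity = 1000)$truth))
  expect_true(all(tr$true_lc >= 5 & tr$true_lc <= 40))
  expect_true(all(tr$true_rupture_force <= 55))
})

test_that("binding outcomes are Bernoulli draws with binomial moments", {
  expect_true(all(simulate_binding_outcomes(0, 100, seed = 1) == 0))
  expect_true(all(simulate_binding_outcomes(1, 100, seed = 1) == 1))
  expect_identical(simulate_binding_outcomes(0.3, 500, seed = 9),
                   simulate_binding_outcomes(0.3, 500, seed = 9))
  counts <- vapply(1:300, function(s)
    sum(simulate_binding_outcomes(0.054, 1052, seed = s)), numeric(1))
  # closed-form binomial oracle: mean 56.8, sd 7.33
  expect_equal(mean(counts), 1052 * 0.054, tolerance = 0.03)
  expect_equal(sd(counts), sqrt(1052 * 0.054 * 0.946), tolerance = 0.15)
  expect_error(simulate_binding_outcomes(1.2, 10, seed = 1),
               class = "dfs_domain_error")
})
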
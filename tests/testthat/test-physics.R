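# Bell-Evans kinetics and extended-FJC tether: closed forms against
# independent numerical oracles.

test_that("bell_off_rate matches the Bell formula and is monotone", {
  kin <- kin_slow()
  expect_equal(bell_off_rate(0, kin), kin$k0_off)
  expect_equal(bell_off_rate(kin$kBT / kin$x_beta, kin), kin$k0_off * exp(1))
  # independent scalar evaluation, frozen
  expect_equal(bell_off_rate(50, kin), 7.664878, tolerance = 1e-6)
  grid <- seq(0, 300, by = 0.5)
  expect_true(all(diff(bell_off_rate(grid, kin)) > 0))
  expect_error(bell_off_rate(-1, kin), class = "dfs_domain_error")
})

test_that("most_probable_force matches the pdf mode and clamps at zero", {
  kin <- kin_slow()
  r_thr <- kin$k0_off * kin$kBT / kin$x_beta
  expect_equal(most_probable_force(r_thr, kin), 0)
  expect_equal(most_probable_force(r_thr / 10, kin), 0)
  expect_equal(most_probable_force(1000, kin), 80.892548, tolerance = 1e-6)
  # oracle: argmax of the rupture-force density on a fine grid
  g <- seq(0, 200, by = 1e-3)
  expect_equal(g[which.max(rupture_force_pdf(g, 1000, kin))],
               most_probable_force(1000, kin), tolerance = 2e-3)
  # increasing in ln r above the clamp
  rs <- 10^seq(1, 5, length.out = 20)
  expect_true(all(diff(most_probable_force(rs, kin)) >= 0))
  expect_error(most_probable_force(0, kin), class = "dfs_domain_error")
})

test_that("rupture_force_pdf normalises, starts at k0/r, peaks at F*", {
  for (p in list(c(0.2, 0.3, 1000), c(1.26, 0.25, 300), c(0.05, 0.5, 5000))) {
    kin <- kinetic_params(p[1], p[2])
    r <- p[3]
    expect_equal(stats::integrate(function(f) rupture_force_pdf(f, r, kin),
                                  0, Inf, rel.tol = 1e-9)$value,
                 1, tolerance = 1e-6)
    expect_equal(rupture_force_pdf(0, r, kin), kin$k0_off / r)
    g <- seq(0, 400, by = 0.002)
    expect_equal(g[which.max(rupture_force_pdf(g, r, kin))],
                 most_probable_force(r, kin), tolerance = 5e-3)
  }
})

test_that("mean_rupture_force equals the numerical mean of the density", {
  for (p in list(c(0.2, 0.3, 1000), c(1.26, 0.3, 250), c(0.5, 0.2, 20000))) {
    kin <- kinetic_params(p[1], p[2])
    r <- p[3]
    m_num <- stats::integrate(function(f) f * rupture_force_pdf(f, r, kin),
                              0, Inf, rel.tol = 1e-10)$value
    expect_equal(mean_rupture_force(r, kin), m_num, tolerance = 1e-7)
  }
})

test_that("sample_rupture_force inverts the survival function", {
  kin <- kin_slow()
  r <- 1000
  expect_equal(sample_rupture_force(r, kin, 1), 0)
  # oracle: numeric root of survival(F) = u
  surv <- function(f) exp((kin$k0_off * kin$kBT / (kin$x_beta * r)) *
                            (1 - exp(f * kin$x_beta / kin$kBT)))
  f_root <- stats::uniroot(function(f) surv(f) - exp(-1), c(0, 300),
                           tol = 1e-12)$root
  expect_equal(sample_rupture_force(r, kin, exp(-1)), f_root, tolerance = 1e-8)
  expect_equal(sample_rupture_force(r, kin, exp(-1)), 80.930108,
               tolerance = 1e-6)
  # stratified inverse-CDF identity: CDF(sample(u)) == 1 - u
  u <- seq(0.02, 0.98, by = 0.02)
  f <- sample_rupture_force(r, kin, u)
  expect_equal(surv(f), u, tolerance = 1e-10)
  expect_error(sample_rupture_force(r, kin, 0), class = "dfs_domain_error")
  expect_error(sample_rupture_force(r, kin, 1.5), class = "dfs_domain_error")
})

test_that("sampled rupture forces follow the density (KS) and shift with rate", {
  kin <- kin_slow()
  set.seed(7)
  f <- sample_rupture_force(1000, kin, runif(10000))
  cdf <- function(q) 1 - exp((kin$k0_off * kin$kBT / (kin$x_beta * 1000)) *
                               (1 - exp(q * kin$x_beta / kin$kBT)))
  expect_gt(stats::ks.test(f, cdf)$p.value, 0.01)
  means <- vapply(c(100, 1000, 10000, 1e5),
                  function(r) mean(sample_rupture_force(r, kin, runif(3000))),
                  numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("fjc_extension has the right limits and shape", {
  teth <- tether_model()
  expect_equal(fjc_extension(0, teth), 0)
  # helical state depopulated and Langevin factor ~1 at 500 pN
  conf <- fjc_extension(500, teth) - teth$n_monomers * 500 / teth$monomer_stiffness
  expect_equal(conf / contour_length(teth), 1, tolerance = 0.02)
  # frozen regression value from an independent scalar evaluation
  expect_equal(fjc_extension(100, teth), 65.02542449, tolerance = 1e-7)
  g <- seq(0.1, 490, by = 0.5)
  expect_true(all(diff(fjc_extension(g, teth)) > 0))
  expect_error(fjc_extension(-0.1, teth), class = "dfs_domain_error")
})

test_that("fjc_force inverts fjc_extension and enforces its bracket", {
  teth <- tether_model()
  expect_equal(fjc_force(0, teth), 0)
  for (f in c(0.1, 10, 50, 200, 300)) {
    expect_equal(fjc_force(fjc_extension(f, teth), teth) / f, 1,
                 tolerance = 1e-9)
  }
  x_over <- fjc_extension(500, teth) * 1.001
  err <- expect_error(fjc_force(x_over, teth), class = "dfs_range_error")
  expect_match(conditionMessage(err), "f_max")
})

test_that("parameter constructors validate their invariants", {
  expect_error(kinetic_params(-1, 0.3), class = "dfs_domain_error")
  expect_error(kinetic_params(0.2, 0), class = "dfs_domain_error")
  expect_error(tether_model(l_planar = 0.2, l_helical = 0.3),
               class = "dfs_domain_error")
  expect_error(tether_model(n_monomers = 0.5), class = "dfs_domain_error")
  expect_equal(contour_length(tether_model()), 226 * 0.358)
})
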
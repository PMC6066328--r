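# Bell-Evans fitting: self-consistency, robustness, bootstrap behaviour.

test_that("noiseless most-probable-force points are recovered to 1e-6", {
  kin <- kinetic_params(1.26, 0.25)
  r <- 10^seq(2, 4.5, length.out = 6)
  pts <- data.frame(mean_force = most_probable_force(r, kin),
                    mean_loading_rate = r)
  fit <- fit_bell_evans(pts, response = "mode")
  expect_equal(fit$k0_off / 1.26, 1, tolerance = 1e-6)
  expect_equal(fit$x_beta / 0.25, 1, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("noiseless mean-force and truncated mean-force points are recovered", {
  kin <- kinetic_params(0.8, 0.35)
  r <- 10^seq(2, 4.5, length.out = 6)
  pts <- data.frame(mean_force = mean_rupture_force(r, kin),
                    mean_loading_rate = r)
  fit <- fit_bell_evans(pts, response = "mean")
  expect_equal(fit$k0_off / 0.8, 1, tolerance = 1e-6)
  expect_equal(fit$x_beta / 0.35, 1, tolerance = 1e-6)

  b <- kin$kBT / kin$x_beta
  tr <- 25
  mu_tr <- tr + b * dfspec:::e1_scaled((kin$k0_off * b / r) * exp(tr / b))
  fit_tr <- fit_bell_evans(data.frame(mean_force = mu_tr,
                                      mean_loading_rate = r),
                           response = "mean", trunc = tr)
  expect_equal(fit_tr$k0_off / 0.8, 1, tolerance = 1e-6)
  expect_equal(fit_tr$x_beta / 0.35, 1, tolerance = 1e-6)
})

test_that("bisquare weights resist a gross outlier where unweighted fits do not", {
  kin <- kinetic_params(1.26, 0.25)
  r <- 10^seq(2, 4.5, length.out = 8)
  f <- most_probable_force(r, kin)
  f[4] <- f[4] * 3
  pts <- data.frame(mean_force = f, mean_loading_rate = r)
  robust <- fit_bell_evans(pts, response = "mode", bisquare = TRUE)
  plain <- fit_bell_evans(pts, response = "mode", bisquare = FALSE)
  expect_lt(abs(robust$k0_off / 1.26 - 1), 0.05)
  expect_lt(abs(robust$x_beta / 0.25 - 1), 0.05)
  expect_gt(abs(plain$k0_off / 1.26 - 1), abs(robust$k0_off / 1.26 - 1))
  expect_lt(robust$weights[4], 0.05)
})

test_that("IRLS agrees with an independent robust regression on the log-linear form", {
  set.seed(17)
  kin <- kinetic_params(0.9, 0.28)
  r <- 10^seq(2, 4.5, length.out = 10)
  f <- most_probable_force(r, kin) + stats::rnorm(10, 0, 2)
  fit <- fit_bell_evans(data.frame(mean_force = f, mean_loading_rate = r),
                        response = "mode")
  rfit <- MASS::rlm(f ~ log(r), psi = MASS::psi.bisquare, c = 4.685,
                    maxit = 100)
  b_ref <- unname(stats::coef(rfit)[2])
  a_ref <- unname(stats::coef(rfit)[1])
  expect_equal(fit$x_beta, 4.114 / b_ref, tolerance = 0.01)
  expect_equal(fit$k0_off, exp(-a_ref / b_ref) / b_ref, tolerance = 0.02)
})

test_that("degenerate inputs raise fit errors", {
  expect_error(fit_bell_evans(data.frame(mean_force = 50,
                                         mean_loading_rate = 100)),
               class = "dfs_fit_error")
  expect_error(fit_bell_evans(data.frame(mean_force = c(50, 60),
                                         mean_loading_rate = c(100, 100))),
               class = "dfs_fit_error")
  # decreasing forces: no physical slope
  expect_error(fit_bell_evans(data.frame(mean_force = c(80, 40),
                                         mean_loading_rate = c(100, 10000))),
               class = "dfs_fit_error")
})

test_that("fits are invariant to event order and to consistent unit rescaling", {
  set.seed(23)
  r <- 10^seq(2, 4.5, length.out = 6)
  kin <- kinetic_params(0.5, 0.3)
  f <- mean_rupture_force(r, kin) + stats::rnorm(6, 0, 1.5)
  pts <- data.frame(mean_force = f, mean_loading_rate = r)
  fit1 <- fit_bell_evans(pts)
  fit2 <- fit_bell_evans(pts[sample(6), ])
  expect_equal(fit1$k0_off, fit2$k0_off, tolerance = 1e-10)
  # pN -> fN (x1000) with kBT and rates rescaled likewise
  s <- 1000
  fit3 <- fit_bell_evans(data.frame(mean_force = f * s,
                                    mean_loading_rate = r * s),
                         kBT = 4.114 * s)
  expect_equal(fit3$k0_off, fit1$k0_off, tolerance = 1e-8)
  expect_equal(fit3$x_beta, fit1$x_beta, tolerance = 1e-8)
})

make_events <- function(kin, n_per = 50, seed = 1,
                        rates = 10^seq(2.3, 4.8, length.out = 6)) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(rates), function(i) {
    data.frame(rupture_force = sample_rupture_force(rates[i], kin,
                                                    runif(n_per)),
               loading_rate = rates[i] * stats::rlnorm(n_per, 0, 0.1),
               pulling_velocity = i)
  }))
}

test_that("bootstrap CIs are deterministic, ordered, and degenerate at B = 1", {
  ev <- make_events(kin_slow(), seed = 4)
  f1 <- bootstrap_bell_evans(ev, B = 200, seed = 11)
  f2 <- bootstrap_bell_evans(ev, B = 200, seed = 11)
  expect_identical(f1$ci95_k0_off, f2$ci95_k0_off)
  expect_identical(f1$ci95_x_beta, f2$ci95_x_beta)
  expect_lte(f1$ci95_k0_off[1], f1$k0_off)
  expect_gte(f1$ci95_k0_off[2], f1$k0_off)

  fd <- bootstrap_bell_evans(ev, B = 1, seed = 11)
  expect_true(fd$degenerate)
  expect_equal(fd$ci95_k0_off, rep(fd$k0_off, 2))

  fr <- bootstrap_bell_evans(ev, B = 100, seed = 11, mode = "recluster")
  expect_false(fr$degenerate)
  expect_true(fr$ci95_k0_off[1] < fr$ci95_k0_off[2])
})
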
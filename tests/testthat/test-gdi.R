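test_that("gdi formula evaluates and bounds correctly", {
  expect_equal(gdi_value(0, 0.002), 0)
  expect_equal(gdi_value(0, 1), 0)
  expect_equal(gdi_value(0.001, 0.002), 1 - exp(-1))
  expect_equal(gdi_value(0.001, 0.002), 0.632121, tolerance = 1e-6)
  # limit: gdi -> 1 as tau/theta grows, never attained
  expect_lt(gdi_value(0.01, 0.001), 1)
  expect_equal(gdi_value(0.01, 0.001), 1, tolerance = 1e-8)
  expect_error(gdi_value(0.001, 0), "theta")
  expect_error(gdi_value(-0.001, 0.01), "tau")
})

test_that("gdi is strictly increasing in tau and decreasing in theta", {
  taus <- seq(1e-4, 0.01, length.out = 15)
  thetas <- seq(2e-3, 0.02, length.out = 15)
  for (th in thetas)
    expect_true(all(diff(gdi_value(taus, th)) > 0))
  for (ta in taus)
    expect_true(all(diff(gdi_value(ta, thetas)) < 0))
})

test_that("classification uses strict 0.2/0.7 thresholds", {
  expect_equal(classify_gdi(0.89), "distinct")
  expect_equal(classify_gdi(0.10), "same")
  expect_equal(classify_gdi(0.45), "ambiguous")
  # boundaries are ambiguous (strict inequalities)
  expect_equal(classify_gdi(c(0.2, 0.7)), c("ambiguous", "ambiguous"))
})

test_that("per-draw gdi from traces matches hand arithmetic and a loop oracle", {
  tr <- data.frame(tau = 0.001, theta_a = 0.002, theta_b = 0.004)
  g <- gdi(tr, "a")
  expect_equal(g$mean, 1 - exp(-1))
  expect_equal(g$sd, 0)  # degenerate single-draw trace

  tr2 <- data.frame(tau = c(0.001, 0.002), theta_a = c(0.002, 0.002),
                    theta_b = c(0.002, 0.002))
  g2 <- gdi(tr2, "a")
  vals <- c(1 - exp(-1), 1 - exp(-2))
  expect_equal(g2$values, vals)
  expect_equal(g2$mean, mean(vals))
  expect_equal(g2$sd, sd(vals))

  # loop oracle on a fitted trace
  sim <- simulate_msc_dataset(tau = 0.005, theta_a = 0.002, seed = 15,
                              n_a = 5, n_b = 5, length = 400)
  fit <- fit_msc_pair(sim$locus, sim$popmap, central_priors(),
                      settings = mcmc_settings(500, 300, 1), n_runs = 1,
                      seed = 6)
  g <- gdi(fit, "both")
  loopA <- sapply(seq_len(nrow(fit$combined)), function(i)
    1 - exp(-2 * fit$combined$tau[i] / fit$combined$theta_a[i]))
  expect_equal(g$a$values, loopA, tolerance = 1e-12)
  expect_equal(g$a$mean, mean(loopA))
  # draws live in [0, 1); saturation may round to 1 in double precision
  expect_true(all(g$a$values >= 0 & g$a$values <= 1))
  expect_true(all(g$b$values >= 0 & g$b$values <= 1))
})

test_that("directions are symmetric under swapping labels and theta columns", {
  set.seed(44)
  tr <- data.frame(tau = runif(200, 0, 0.01),
                   theta_a = runif(200, 1e-3, 0.02),
                   theta_b = runif(200, 1e-3, 0.02))
  swapped <- data.frame(tau = tr$tau, theta_a = tr$theta_b,
                        theta_b = tr$theta_a)
  ga <- gdi(tr, "a"); gb <- gdi(swapped, "b")
  expect_equal(ga$values, gb$values)
  expect_equal(ga$mean, gb$mean)
  # deterministic for fixed traces
  expect_equal(gdi(tr, "a")$mean, ga$mean)
})

test_that("prior-only posteriors give wide gdi densities", {
  # empirical-style priors for a shallow pair: tau and theta means of the
  # same order, as calibration yields for recently diverged lineages
  pr <- prior_set(inv_gamma_prior(3, 0.004), inv_gamma_prior(3, 0.004))
  sim <- simulate_msc_dataset(tau = 0.005, n_a = 3, n_b = 3, length = 200,
                              seed = 26)
  fit <- fit_msc_pair(sim$locus, sim$popmap, pr,
                      settings = mcmc_settings(3000, 400, 5), n_runs = 1,
                      seed = 9, prior_only = TRUE)
  g <- gdi(fit, "both")
  expect_gt(g$a$sd, 0.15)
  expect_gt(g$b$sd, 0.15)
})

test_that("gdi errors on unusable traces", {
  expect_error(gdi(data.frame(tau = numeric(0), theta_a = numeric(0))),
               "empty")
  expect_error(gdi(data.frame(theta_a = 1), "a"), "tau")
  tr <- data.frame(tau = 0.001, theta_a = NA_real_, theta_b = 0.002)
  expect_error(gdi(tr, "a"), "direction 'a'")
})
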
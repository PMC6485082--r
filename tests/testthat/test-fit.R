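test_that("settings are validated", {
  expect_error(mcmc_settings(0, 0, 1), "samples")
  expect_error(mcmc_settings(100, 200, 1), "exceed burnin")
  expect_error(mcmc_settings(100, 10, 0), "thin")
  s <- mcmc_settings(1000, 100, 2)
  expect_equal(s$samples, 1000L)
})

test_that("fixed-tree single-population theta posterior matches the conjugate closed form", {
  a <- 3; b <- 0.002
  pr <- prior_set(inv_gamma_prior(a, b), inv_gamma_prior(3, 0.004))
  gt <- simulate_gene_tree(0, 0.004, 0.004, 0.004, 8, 0, seed = 17,
                           pops = c("P", "Q"))
  loc <- simulate_alignment(gt, 300, seed = 18)
  pm <- population_map(setNames(rep("P", 8), gt$tip_labels))
  fit <- fit_msc_pair(loc, pm, pr, settings = mcmc_settings(4000, 200, 1),
                      n_runs = 1, seed = 23, fix_gene_tree = TRUE,
                      init_gene_tree = gt)
  st <- r_single_pop_stats(gt)
  apost <- a + st$c
  bpost <- b + st$S
  exact_mean <- bpost / (apost - 1)
  exact_sd <- sqrt(bpost^2 / ((apost - 1)^2 * (apost - 2)))
  draws <- fit$combined$theta_root
  mc_sd <- exact_sd / sqrt(length(draws))   # Gibbs draws here are iid
  expect_lt(abs(mean(draws) - exact_mean), 3 * mc_sd)
  expect_equal(sd(draws), exact_sd, tolerance = 0.1)
})

test_that("prior-only runs reproduce the inverse-gamma marginals", {
  pr <- central_priors()
  sim <- simulate_msc_dataset(tau = 0.005, n_a = 3, n_b = 3, length = 200,
                              seed = 40)
  fit <- fit_msc_pair(sim$locus, sim$popmap, pr,
                      settings = mcmc_settings(4000, 500, 20),
                      n_runs = 1, seed = 19, prior_only = TRUE)
  tr <- fit$combined
  for (p in c("theta_a", "theta_b", "theta_root"))
    expect_gt(suppressWarnings(
      ks.test(tr[[p]], function(q) pinvgamma(q, pr$theta)))$p.value, 0.01)
  expect_gt(suppressWarnings(
    ks.test(tr$tau, function(q) pinvgamma(q, pr$tau)))$p.value, 0.01)
})

test_that("the posterior concentrates near the truth at study scale", {
  sim <- simulate_msc_dataset(tau = 0.005, theta_a = 0.002,
                              theta_b = 0.002, theta_root = 0.002,
                              seed = 77)
  pr <- prior_set(inv_gamma_prior(3, 0.004), inv_gamma_prior(3, 0.01))
  fit <- fit_msc_pair(sim$locus, sim$popmap, pr,
                      settings = mcmc_settings(1500, 800, 2),
                      n_runs = 2, seed = 5)
  ci_tau <- quantile(fit$combined$tau, c(0.025, 0.975))
  expect_gt(0.005, ci_tau[1])
  expect_lt(0.005, ci_tau[2])
  expect_equal(unname(coef(fit)[["tau"]]), 0.005, tolerance = 0.6)
  # methods on the fitted object
  expect_named(coef(fit), c("tau", "theta_a", "theta_b", "theta_root"))
  s <- summary(fit)
  expect_s3_class(s, "summary.msc_fit")
  expect_equal(rownames(s$table),
               c("tau", "theta_a", "theta_b", "theta_root"))
  expect_output(print(fit), "posterior means")
})

test_that("posterior-predictive simulation uses the fitted dimensions", {
  sim <- simulate_msc_dataset(tau = 0.008, n_a = 4, n_b = 3, length = 150,
                              seed = 10)
  fit <- fit_msc_pair(sim$locus, sim$popmap, central_priors(),
                      settings = mcmc_settings(300, 100, 1), n_runs = 1,
                      seed = 2)
  reps <- simulate(fit, nsim = 2, seed = 99)
  expect_length(reps, 2L)
  expect_equal(reps[[1]]$truth$n_a, 4)
  expect_equal(reps[[1]]$locus$length, 150)
  expect_true(reps[[1]]$truth$tau %in% fit$combined$tau)
})

test_that("traces round-trip through the TSV writer", {
  sim <- simulate_msc_dataset(tau = 0.005, n_a = 3, n_b = 3, length = 100,
                              seed = 3)
  fit <- fit_msc_pair(sim$locus, sim$popmap, central_priors(),
                      settings = mcmc_settings(200, 50, 1), n_runs = 2,
                      seed = 7)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_trace(fit, tsv)
  back <- read_trace(tsv)
  expect_equal(nrow(back), 400L)
  expect_equal(back$tau[1:200], fit$traces[[1]]$tau, tolerance = 1e-12)
  expect_equal(unique(back$run), c(1, 2))
})

test_that("degenerate inputs are rejected", {
  sim <- simulate_msc_dataset(tau = 0.005, n_a = 3, n_b = 3, length = 100,
                              seed = 3)
  pm3 <- population_map(setNames(c("A", "A", "A", "B", "B", "C"),
                                 sim$popmap$samples))
  expect_error(fit_msc_pair(sim$locus, pm3, central_priors(),
                            settings = mcmc_settings(10, 1, 1), n_runs = 1),
               "one or two populations")
  expect_error(fit_msc_pair(sim$locus, sim$popmap, central_priors(),
                            pair = c("A", "Z"),
                            settings = mcmc_settings(10, 1, 1), n_runs = 1),
               "'Z'")
})
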
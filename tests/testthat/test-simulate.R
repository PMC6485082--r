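test_that("gene-tree simulator honours structural constraints and seeds", {
  gt <- simulate_gene_tree(0.02, 0.002, 0.002, 0.002, 1, 1, seed = 5)
  expect_gte(gt$age[gt$root], 0.02)   # the single coalescence is above tau
  for (s in 1:10) {
    g <- simulate_gene_tree(0.02, 0.002, 0.002, 0.002, 1, 1, seed = s)
    expect_gte(g$age[g$root], 0.02)
  }
  g1 <- simulate_gene_tree(0.005, 0.002, 0.003, 0.004, 5, 4, seed = 9)
  g2 <- simulate_gene_tree(0.005, 0.002, 0.003, 0.004, 5, 4, seed = 9)
  expect_identical(g1, g2)
  # mixed nodes never younger than tau
  expect_true(all(g1$age[coaldelim:::gene_tree_mixed_nodes(g1, c("A", "B"))]
                  >= 0.005))
})

test_that("coalescence ages match closed-form exponential oracles", {
  theta <- 0.004
  # single population of two: age ~ Exp(rate 2/theta), mean theta/2
  set.seed(42)
  ages <- replicate(4000, {
    g <- simulate_gene_tree(0, theta, theta, theta, 2, 0)
    g$age[g$root]
  })
  expect_equal(mean(ages), theta / 2, tolerance = 0.05)
  ks <- ks.test(ages, pexp, rate = 2 / theta)
  expect_gt(ks$p.value, 0.01)

  # (1,1) cross pair: shifted exponential, mean tau + theta_root/2
  tau <- 0.01; thr <- 0.006
  ages <- replicate(4000, {
    g <- simulate_gene_tree(tau, theta, theta, thr, 1, 1)
    g$age[g$root]
  })
  expect_equal(mean(ages), tau + thr / 2, tolerance = 0.05)
  ks <- ks.test(ages - tau, pexp, rate = 2 / thr)
  expect_gt(ks$p.value, 0.01)
})

test_that("JC69 sequence simulation matches the expected divergence", {
  # two tips at tree distance d: E[p-distance] = 3/4 (1 - exp(-4d/3))
  t <- 0.025  # root age; tree distance 2t = 0.05
  gt <- gene_tree(rbind(c(0L, 0L), c(0L, 0L), c(1L, 2L)), c(0, 0, t),
                  c("a1", "b1"), c("A", "B"))
  L <- 1e5
  loc <- simulate_alignment(gt, L, seed = 8)
  expected <- 0.75 * (1 - exp(-4 * (2 * t) / 3))
  mc_sd <- sqrt(expected * (1 - expected) / L)
  obs <- p_distance_matrix(loc)$distance[1, 2]
  expect_lt(abs(obs - expected), 3 * mc_sd)

  # zero branch lengths: identical sequences
  gt0 <- gene_tree(rbind(c(0L, 0L), c(0L, 0L), c(1L, 2L)), c(0, 0, 1e-15),
                   c("a1", "b1"), c("A", "B"))
  loc0 <- simulate_alignment(gt0, 500, seed = 1)
  expect_equal(p_distance_matrix(loc0)$distance[1, 2], 0)

  expect_identical(simulate_alignment(gt, 100, seed = 3),
                   simulate_alignment(gt, 100, seed = 3))
})

test_that("within and between divergence track theta and 2 tau + theta_root", {
  # Monte Carlo over replicate datasets at study scale
  set.seed(123)
  tau <- 0.03; th <- 0.002
  wi <- c(); bw <- c()
  for (r in 1:40) {
    sim <- simulate_msc_dataset(tau = tau, theta_a = th, theta_b = th,
                                theta_root = th, n_a = 4, n_b = 4,
                                length = 600)
    dm <- p_distance_matrix(sim$locus)
    bw <- c(bw, between_population_summary(dm, sim$popmap, "A", "B")[["d_mean"]] / 100)
    wi <- c(wi, mean(c(within_population_diversity(dm, sim$popmap, "A"),
                       within_population_diversity(dm, sim$popmap, "B"))))
  }
  exp_between <- 0.75 * (1 - exp(-4 * (2 * tau + th) / 3))
  expect_equal(mean(bw), exp_between, tolerance = 0.05)
  # within-population divergence approximately theta in the small regime
  expect_equal(mean(wi), th, tolerance = 0.15)
})

test_that("simulated datasets are accepted by every downstream stage", {
  sim <- simulate_msc_dataset(tau = 0.02, theta_a = 0.01, theta_b = 0.01,
                              theta_root = 0.01, n_a = 4, n_b = 4,
                              length = 300, seed = 31)
  expect_true(validate_popmap(sim$locus, sim$popmap))
  dm <- p_distance_matrix(sim$locus)
  tax <- data.frame(population_a = "A", population_b = "B",
                    conspecific = TRUE)
  expect_s3_class(screen_candidates(dm, sim$popmap, tax), "candidate_screen")
  expect_s3_class(empirical_theta_prior(sim$locus, sim$popmap),
                  "inv_gamma_prior")
  ld <- coalescent_log_density(sim$gene_tree, 0.02, 0.01, 0.01, 0.01,
                               popmap = sim$popmap)
  expect_true(is.finite(ld))
  expect_true(is.finite(jc69_log_likelihood(sim$gene_tree, sim$locus)))
})

test_that("truth sidecar round-trips through the writer", {
  sim <- simulate_msc_dataset(tau = 0.005, n_a = 3, n_b = 3, length = 100,
                              seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  truth <- read.table(paths[["truth"]], sep = "\t",
                      col.names = c("key", "value"))
  expect_equal(truth$value[truth$key == "tau"], 0.005)
  back <- read_fasta_alignment(paths[["fasta"]])
  expect_equal(back$matrix, sim$locus$matrix)
  expect_equal(read_imap(paths[["imap"]]), sim$popmap)
})

test_that("panmictic data rarely screens as a split candidate", {
  set.seed(61)
  hits <- 0
  n_rep <- 60
  for (r in 1:n_rep) {
    sim <- simulate_msc_dataset(tau = 0, theta_root = 0.002,
                                n_a = 4, n_b = 4, length = 500)
    dm <- p_distance_matrix(sim$locus)
    tax <- data.frame(population_a = "A", population_b = "B",
                      conspecific = TRUE)
    sc <- screen_candidates(dm, sim$popmap, tax)
    hits <- hits + (sc$category == "split_candidate")
  }
  expect_lt(hits / n_rep, 0.10)
})
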
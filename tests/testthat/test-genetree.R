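two_tip_tree <- function(t, pops = c("A", "B")) {
  gene_tree(rbind(c(0L, 0L), c(0L, 0L), c(1L, 2L)), c(0, 0, t),
            c("a1", "b1"), pops)
}

test_that("gene tree construction enforces structural invariants", {
  gt <- two_tip_tree(0.01)
  expect_equal(gt$root, 3L)
  expect_error(gene_tree(rbind(c(0L, 0L), c(0L, 0L), c(1L, 2L)),
                         c(0, 0.001, 0.01), c("a", "b"), c("A", "B")),
               "tip ages")
  expect_error(gene_tree(rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L)),
                         c(0, 0, 0.01), c("a", "b"), c("A", "B")),
               "two parents")
  phy <- ape::as.phylo(gt)
  expect_s3_class(phy, "phylo")
  expect_equal(sum(phy$edge.length), 0.02)
})

test_that("coalescent density matches closed forms on tiny genealogies", {
  # one population, two lineages coalescing at t: (2/theta) exp(-2t/theta)
  th <- 0.01; t <- 0.005
  gt <- two_tip_tree(t, pops = c("A", "A"))
  ld <- coalescent_log_density(gt, tau = 0, theta_a = th, theta_b = th,
                               theta_root = th, pops = c("A", "Z"))
  expect_equal(ld, log(2 / th) - 2 * t / th)
  expect_equal(ld, log(200 * exp(-1)))

  # cross-population pair: density zero below tau, shifted above
  gt <- two_tip_tree(0.01)
  expect_equal(as.numeric(coalescent_log_density(gt, 0.02, 0.01, 0.01, 0.01)), -Inf)
  ld <- coalescent_log_density(gt, 0.005, 0.01, 0.01, 0.02)
  expect_equal(ld, log(2 / 0.02) - 2 * (0.01 - 0.005) / 0.02)
})

test_that("density factorizes over populations below tau", {
  # 2+2 tips, both within-population coalescences below tau
  children <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L),
                    c(1L, 2L), c(3L, 4L), c(5L, 6L))
  age <- c(0, 0, 0, 0, 0.001, 0.002, 0.03)
  gt <- gene_tree(children, age, c("a1", "a2", "b1", "b2"),
                  c("A", "A", "B", "B"))
  tau <- 0.02
  thA <- 0.004; thB <- 0.006; thR <- 0.01
  full <- coalescent_log_density(gt, tau, thA, thB, thR)
  # independent-oracle recomputation
  expect_equal(full, r_coal_logdensity(gt, tau, thA, thB, thR))
  # factorization: A-part + B-part + root-part computed separately
  partA <- log(2 / thA) - 2 * 0.001 / thA - 0  # k drops to 1 before tau
  partB <- log(2 / thB) - 2 * 0.002 / thB
  partR <- log(2 / thR) - 2 * (0.03 - tau) / thR
  expect_equal(full, partA + partB + partR)
})

test_that("engine density agrees with the independent R oracle on random trees", {
  set.seed(77)
  for (rep in 1:25) {
    tau <- runif(1, 0, 0.01)
    sim <- simulate_gene_tree(tau, 0.004, 0.006, 0.008,
                              sample(2:5, 1), sample(2:5, 1))
    th <- runif(3, 0.001, 0.02)
    expect_equal(
      coalescent_log_density(sim, tau, th[1], th[2], th[3]),
      r_coal_logdensity(sim, tau, th[1], th[2], th[3]),
      tolerance = 1e-10)
  }
})

test_that("tau-constraint violations return -Inf with a structured report", {
  gt <- two_tip_tree(0.01)
  ld <- coalescent_log_density(gt, 0.05, 0.01, 0.01, 0.01)
  expect_equal(as.numeric(ld), -Inf)
  expect_match(attr(ld, "violation"), "node 3.*both populations")
})

test_that("JC69 pruning matches closed-form special cases", {
  # identical gap-free sequences, all branch lengths 0: -L * log 4
  L <- 7
  seqs <- paste(rep("A", L), collapse = "")
  loc <- aligned_locus(c(a1 = seqs, b1 = seqs))
  gt <- two_tip_tree(1e-12)
  expect_equal(jc69_log_likelihood(gt, loc), -L * log(4), tolerance = 1e-6)

  # saturation: same-state transition probability tends to 1/4
  loc2 <- aligned_locus(c(a1 = "A", b1 = "A"))
  gt_far <- two_tip_tree(50)
  # two tips at huge distance: P(same site pair) = 1/4 * 1/4 * 4 = 1/16
  expect_equal(jc69_log_likelihood(gt_far, loc2), log(1 / 16),
               tolerance = 1e-6)
})

test_that("pruning equals brute-force state summation on all small topologies", {
  set.seed(13)
  worst <- 0
  for (n in 2:4) {
    labels <- paste0("t", 1:n)
    topos <- all_topologies(labels)
    # all rooted binary topologies: 1, 3, 15 for n = 2, 3, 4
    expect_length(topos, c(1, 3, 15)[n - 1])
    for (topo in topos) {
      gt <- build_gene_tree(topo, labels)
      L <- sample(1:5, 1)
      m <- matrix(sample(c("A", "C", "G", "T", "N", "-", "R", "Y"),
                         n * L, TRUE, prob = c(rep(1, 4), rep(0.4, 4))),
                  nrow = n)
      loc <- aligned_locus(m, samples = labels)
      a <- jc69_log_likelihood(gt, loc)
      b <- brute_force_jc69(gt, loc)
      worst <- max(worst, abs(a - b))
      expect_equal(a, b, tolerance = 1e-10)
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("pruning agrees with an established likelihood implementation", {
  set.seed(55)
  gt <- simulate_gene_tree(0.01, 0.004, 0.004, 0.006, 4, 3)
  loc <- simulate_alignment(gt, 200)
  phy <- ape::as.phylo(gt)
  dat <- phangorn::phyDat(loc$matrix[phy$tip.label, , drop = FALSE],
                          type = "DNA")
  ref <- phangorn::pml(phy, dat)$logLik   # JC69 is pml's default model
  expect_equal(jc69_log_likelihood(gt, loc), ref, tolerance = 1e-8)
})

test_that("joint density is finite and reproducible across evaluations", {
  set.seed(3)
  sim <- simulate_msc_dataset(tau = 0.004, n_a = 6, n_b = 6, length = 200)
  gt <- sim$gene_tree
  v1 <- coalescent_log_density(gt, 0.004, 0.002, 0.002, 0.002) +
    jc69_log_likelihood(gt, sim$locus)
  v2 <- coalescent_log_density(gt, 0.004, 0.002, 0.002, 0.002) +
    jc69_log_likelihood(gt, sim$locus)
  expect_true(is.finite(v1))
  expect_equal(v1, v2, tolerance = 1e-10)
})
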
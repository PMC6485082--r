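test_that("p-distance follows the pairwise-deletion definition", {
  expect_equal(p_distance("ACGT", "ACGT"),
               list(distance = 0, comparable_sites = 4L))
  expect_equal(p_distance("ACGT", "ACGA"),
               list(distance = 0.25, comparable_sites = 4L))
  # gaps and ambiguity codes excluded on either sequence
  expect_equal(p_distance("AC-TN", "ACGTA"),
               list(distance = 0, comparable_sites = 3L))
  expect_error(p_distance("ACG", "ACGT"), "unequal")
  expect_error(p_distance("NNN", "ACG"), "no comparable")
})

test_that("p-distance is symmetric and zero on self", {
  set.seed(11)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T", "N", "-"), 30, TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "N", "-"), 30, TRUE),
               collapse = "")
    pab <- try(p_distance(a, b), silent = TRUE)
    pba <- try(p_distance(b, a), silent = TRUE)
    if (inherits(pab, "try-error")) {
      expect_s3_class(pba, "try-error")
    } else {
      expect_equal(pab, pba)
    }
  }
  s <- "ACGTACGT"
  expect_equal(p_distance(s, s)$distance, 0)
})

test_that("distance matrix equals element-wise p_distance (brute force)", {
  set.seed(5)
  for (rep in 1:5) {
    loc <- random_locus(6, 60, alphabet = c("A", "C", "G", "T", "N", "-"))
    dm <- p_distance_matrix(loc)
    expect_equal(dm$distance, t(dm$distance))
    expect_true(all(diag(dm$distance) == 0))
    seqs <- as.character(loc)
    for (i in 1:5) for (j in (i + 1):6) {
      o <- p_distance(seqs[i], seqs[j])
      expect_equal(dm$distance[i, j], o$distance)
      expect_equal(dm$comparable_sites[i, j], o$comparable_sites)
    }
  }
  expect_equal(p_distance_matrix(aligned_locus(c(x = "ACGT", y = "ACGT")))$distance,
               matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y"))))
})

test_that("between-population summaries are in percent with exhaustive means", {
  fx <- make_pair_fixture(c(0.012, 0.023))
  dm <- p_distance_matrix(fx$locus)
  s <- between_population_summary(dm, fx$popmap, "A", "B")
  expect_equal(unname(s), c(1.2, 2.3, 1.75))
  expect_error(between_population_summary(dm, fx$popmap, "A", "Q"), "'Q'")

  # exhaustive oracle on random 6-sample fixtures
  set.seed(9)
  for (rep in 1:5) {
    loc <- random_locus(6, 80)
    pm <- population_map(setNames(c("A", "A", "A", "B", "B", "B"),
                                  loc$samples))
    dm <- p_distance_matrix(loc)
    s <- between_population_summary(dm, pm, "A", "B")
    cross <- as.vector(outer(1:3, 4:6, Vectorize(function(i, j)
      p_distance(as.character(loc)[i], as.character(loc)[j])$distance)))
    expect_equal(unname(s), 100 * c(min(cross), max(cross), mean(cross)))
  }
})

test_that("threshold screening reproduces the worked classifications", {
  fx <- make_pair_fixture(0.022)      # non-conspecific at 2.2%
  dm <- p_distance_matrix(fx$locus)
  tax <- data.frame(population_a = "A", population_b = "B",
                    conspecific = FALSE)
  sc <- screen_candidates(dm, fx$popmap, tax)
  expect_equal(sc$category, "lump_candidate")

  fx <- make_pair_fixture(c(0.052, 0.064))  # conspecific at 5.2-6.4%
  dm <- p_distance_matrix(fx$locus)
  tax$conspecific <- TRUE
  sc <- screen_candidates(dm, fx$popmap, tax)
  expect_equal(sc$category, "split_candidate")
  expect_equal(round(sc$d_min, 1), 5.2)
  expect_equal(round(sc$d_max, 1), 6.4)

  fx <- make_pair_fixture(c(0.007, 0.036))  # conspecific 0.7-3.6%: grey
  dm <- p_distance_matrix(fx$locus)
  sc <- screen_candidates(dm, fx$popmap, tax)
  expect_equal(sc$category, "grey_zone")

  expect_error(screen_candidates(dm, fx$popmap, tax, lower = 5, upper = 3),
               "lower < upper")
})

test_that("screening categories are monotone in the thresholds", {
  set.seed(21)
  dists <- runif(12, 0, 0.09)
  counts <- function(lower, upper, consp) {
    n <- 0
    for (d in dists) {
      fx <- make_pair_fixture(d)
      dm <- p_distance_matrix(fx$locus)
      tax <- data.frame(population_a = "A", population_b = "B",
                        conspecific = consp)
      sc <- screen_candidates(dm, fx$popmap, tax, lower, upper)
      n <- n + (sc$category == if (consp) "split_candidate"
                else "lump_candidate")
    }
    n
  }
  # raising the upper threshold never increases split candidates
  expect_gte(counts(3, 4, TRUE), counts(3, 5, TRUE))
  expect_gte(counts(3, 5, TRUE), counts(3, 7, TRUE))
  # lowering the lower threshold never increases lump candidates
  expect_gte(counts(3, 5, FALSE), counts(2, 5, FALSE))
  expect_gte(counts(2, 5, FALSE), counts(1, 5, FALSE))
})
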
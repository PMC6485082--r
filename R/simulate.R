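#' Simulate a gene tree under the two-population coalescent
#'
#' Standard multispecies-coalescent simulation: within each population,
#' with \code{k} lineages the waiting time to the next coalescence is
#' exponential with rate \code{k(k-1)/theta} (each pair at rate
#' \code{2/theta}), truncated at the divergence time \code{tau}; the
#' surviving lineages then coalesce in the ancestral population with
#' \code{theta_root}. \code{tau = 0} gives a panmictic (merged) genealogy
#' governed by \code{theta_root} alone.
#'
#' @param tau divergence time, expected substitutions/site (>= 0).
#' @param theta_a,theta_b,theta_root mutation-scaled population sizes.
#' @param n_a,n_b samples per population (>= 1; one of them may be 0 for
#'   a single-population genealogy).
#' @param pops labels of the two populations.
#' @param seed optional integer seed.
#' @return A \code{\link{gene_tree}} with tips \code{a1..}/\code{b1..}.
#' @export
simulate_gene_tree <- function(tau, theta_a, theta_b, theta_root,
                               n_a, n_b, pops = c("A", "B"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(tau >= 0, theta_root > 0, n_a >= 0, n_b >= 0, n_a + n_b >= 1)
  if (n_a > 0 && n_b > 0 && tau > 0) stopifnot(theta_a > 0, theta_b > 0)
  n <- n_a + n_b
  nn <- 2L * n - 1L
  tip_labels <- c(if (n_a) paste0("a", seq_len(n_a)),
                  if (n_b) paste0("b", seq_len(n_b)))
  tip_pop <- c(rep(pops[1L], n_a), rep(pops[2L], n_b))
  children <- matrix(0L, nn, 2L)
  age <- numeric(nn)
  nxt <- n + 1L  # next internal node index

  coalesce_phase <- function(active, t0, t_end, theta) {
    # returns list(active, t) after running the coalescent on [t0, t_end)
    t <- t0
    while (length(active) > 1L) {
      k <- length(active)
      w <- stats::rexp(1L, rate = k * (k - 1) / theta)
      if (t + w >= t_end) return(list(active = active, t = t_end))
      t <- t + w
      pick <- sample.int(k, 2L)
      children[nxt, ] <<- active[pick]
      age[nxt] <<- t
      active <- c(active[-pick], nxt)
      nxt <<- nxt + 1L
    }
    list(active = active, t = t)
  }

  act_a <- seq_len(n_a)
  act_b <- if (n_b) n_a + seq_len(n_b) else integer(0)
  if (tau > 0) {
    if (n_a > 1L) act_a <- coalesce_phase(act_a, 0, tau, theta_a)$active
    if (n_b > 1L) act_b <- coalesce_phase(act_b, 0, tau, theta_b)$active
  }
  res <- coalesce_phase(c(act_a, act_b), tau, Inf, theta_root)
  gene_tree(children, age, tip_labels, tip_pop)
}

#' Simulate sequences on a gene tree under JC69
#'
#' Sites evolve independently from a uniformly drawn root base down the
#' genealogy; along a branch of length \code{t} (expected
#' substitutions/site) a site keeps its state with probability
#' \code{1/4 + 3/4 exp(-4t/3)} and otherwise switches uniformly to one of
#' the other three bases. Output is gap-free.
#'
#' @param genetree a \code{\link{gene_tree}}.
#' @param length number of sites.
#' @param seed optional integer seed.
#' @param name locus label.
#' @return An \code{\link{aligned_locus}}.
#' @export
simulate_alignment <- function(genetree, length, seed = NULL,
                               name = "simulated") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(genetree, "gene_tree"), length >= 1)
  n <- genetree$n_tips
  nn <- 2L * n - 1L
  bases <- c("A", "C", "G", "T")
  states <- matrix(0L, nn, length)
  states[genetree$root, ] <- sample.int(4L, length, replace = TRUE)
  # pre-order: parents before children
  ord <- order(genetree$age, decreasing = TRUE)
  for (i in ord) {
    if (i == genetree$root) next
    p <- genetree$parent[i]
    t <- genetree$age[p] - genetree$age[i]
    p_same <- 0.25 + 0.75 * exp(-4 * t / 3)
    keep <- stats::runif(length) < p_same
    s <- states[p, ]
    if (any(!keep)) {
      nm <- sum(!keep)
      # uniform over the three other bases
      shift <- sample.int(3L, nm, replace = TRUE)
      s[!keep] <- ((s[!keep] - 1L + shift) %% 4L) + 1L
    }
    states[i, ] <- s
  }
  m <- matrix(bases[states[seq_len(n), , drop = FALSE]], nrow = n)
  rownames(m) <- genetree$tip_labels
  aligned_locus(m, samples = genetree$tip_labels, name = name)
}

#' Simulate a complete two-population dataset
#'
#' Bundles one multispecies-coalescent gene tree, a JC69 alignment, the
#' matching population map and the generating ("truth") parameters, at the
#' scale of a single-locus mitochondrial study (defaults: 10 + 10
#' samples, 1000 bp, tau and theta of order 1e-3).
#'
#' @inheritParams simulate_gene_tree
#' @param length alignment length in bp.
#' @param seed optional integer seed governing both the genealogy and the
#'   sequences.
#' @return An object of class \code{"msc_simulation"}: list with
#'   \code{locus}, \code{popmap}, \code{gene_tree} and \code{truth}.
#' @examples
#' sim <- simulate_msc_dataset(tau = 0.005, seed = 1)
#' sim$truth$tau
#' @export
simulate_msc_dataset <- function(tau = 0.005, theta_a = 0.002,
                                 theta_b = 0.002, theta_root = 0.002,
                                 n_a = 10, n_b = 10, length = 1000,
                                 pops = c("A", "B"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gt <- simulate_gene_tree(tau, theta_a, theta_b, theta_root, n_a, n_b,
                           pops = pops)
  locus <- simulate_alignment(gt, length)
  pm <- population_map(stats::setNames(gt$tip_pop, gt$tip_labels))
  structure(list(locus = locus, popmap = pm, gene_tree = gt,
                 truth = list(tau = tau, theta_a = theta_a,
                              theta_b = theta_b, theta_root = theta_root,
                              n_a = n_a, n_b = n_b, length = length)),
            class = "msc_simulation")
}

#' @export
print.msc_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated MSC dataset: %d + %d samples, %d bp (tau=%g, theta=%g/%g/%g)\n",
    x$truth$n_a, x$truth$n_b, x$truth$length, x$truth$tau,
    x$truth$theta_a, x$truth$theta_b, x$truth$theta_root))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the FASTA alignment, the imap file and a plain-text sidecar
#' recording the generating parameters.
#'
#' @param sim an \code{\link{simulate_msc_dataset}} result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "msc_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  im <- file.path(dir, paste0(prefix, ".imap.txt"))
  tr <- file.path(dir, paste0(prefix, ".truth.txt"))
  write_fasta_alignment(sim$locus, fa)
  write_imap(sim$popmap, im)
  writeLines(paste(names(sim$truth), unlist(sim$truth), sep = "\t"), tr)
  invisible(c(fasta = fa, imap = im, truth = tr))
}
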
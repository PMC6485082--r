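#' Gene tree for the two-population coalescent
#'
#' Rooted binary ultrametric genealogy over the sampled sequences. Nodes
#' \code{1..n} are tips (age 0), nodes \code{n+1..2n-1} internal; ages are
#' in expected substitutions per site. Each tip carries a population
#' label; under the two-population model no internal node whose
#' descendants span both populations may be younger than the divergence
#' time tau.
#'
#' @param children integer matrix \code{(2n-1) x 2}; rows for tips are
#'   \code{c(0, 0)}.
#' @param age numeric vector of node ages (tips 0).
#' @param tip_labels character vector of tip (sample) names.
#' @param tip_pop character vector of population labels per tip.
#' @return An object of class \code{"gene_tree"}.
#' @export
gene_tree <- function(children, age, tip_labels, tip_pop) {
  n <- length(tip_labels)
  nn <- 2L * n - 1L
  children <- matrix(as.integer(children), ncol = 2L)
  stopifnot(nrow(children) == nn, length(age) == nn,
            length(tip_pop) == n)
  if (any(age[seq_len(n)] != 0)) stop("tip ages must be 0")
  parent <- integer(nn)
  for (i in (n + 1L):nn) {
    for (k in 1:2) {
      ch <- children[i, k]
      if (ch < 1L || ch > nn) stop("invalid child index")
      if (parent[ch] != 0L) stop("node has two parents")
      parent[ch] <- i
      if (age[ch] >= age[i])
        stop(sprintf("child %d (age %g) not younger than parent %d (age %g)",
                     ch, age[ch], i, age[i]))
    }
  }
  root <- which(parent == 0L)
  root <- root[root > n]
  if (length(root) != 1L) stop("tree must have exactly one root")
  structure(list(n_tips = n, children = children, parent = parent,
                 age = as.numeric(age), root = as.integer(root),
                 tip_labels = as.character(tip_labels),
                 tip_pop = as.character(tip_pop)),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("Gene tree: %d tips (%s), root age %.4g subst/site\n",
              x$n_tips, paste(unique(x$tip_pop), collapse = "/"),
              x$age[x$root]))
  invisible(x)
}

#' Convert a gene tree to an ape phylo object
#'
#' @param x a \code{\link{gene_tree}}.
#' @param ... unused.
#' @return An \code{ape} \code{phylo} object with branch lengths.
#' @importFrom ape as.phylo
#' @method as.phylo gene_tree
#' @export
as.phylo.gene_tree <- function(x, ...) {
  n <- x$n_tips
  nn <- 2L * n - 1L
  # ape numbering: tips 1..n, root n+1; remap internals so root comes first
  internal <- c(x$root, setdiff((n + 1L):nn, x$root))
  remap <- integer(nn)
  remap[seq_len(n)] <- seq_len(n)
  remap[internal] <- n + seq_along(internal)
  edges <- NULL
  lens <- NULL
  for (i in (n + 1L):nn) {
    for (k in 1:2) {
      ch <- x$children[i, k]
      edges <- rbind(edges, c(remap[i], remap[ch]))
      lens <- c(lens, x$age[i] - x$age[ch])
    }
  }
  phy <- list(edge = edges, edge.length = lens,
              tip.label = x$tip_labels, Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# internal nodes whose descendant tips span both populations
gene_tree_mixed_nodes <- function(genetree, pops) {
  n <- genetree$n_tips
  nn <- 2L * n - 1L
  mask <- integer(nn)
  mask[seq_len(n)] <- ifelse(genetree$tip_pop == pops[1L], 1L, 2L)
  for (i in order(genetree$age)) {
    if (i <= n) next
    mask[i] <- bitwOr(mask[genetree$children[i, 1L]],
                      mask[genetree$children[i, 2L]])
  }
  which(mask == 3L)
}

tip_pop_lookup <- function(genetree, popmap) {
  idx <- match(genetree$tip_labels, popmap$samples)
  if (anyNA(idx))
    stop(sprintf("tip '%s' absent from population map",
                 genetree$tip_labels[which(is.na(idx))[1L]]))
  popmap$populations[idx]
}

# 0/1 population codes for the C engine; pops gives the (A, B) order
pop_codes <- function(tip_pop, pops) {
  code <- match(tip_pop, pops) - 1L
  if (anyNA(code))
    stop(sprintf("tip population '%s' not in (%s)",
                 tip_pop[which(is.na(code))[1L]], paste(pops, collapse = ", ")))
  code
}

#' Multispecies-coalescent log-density of a gene tree
#'
#' Log-density of the genealogy under the two-population coalescent:
#' within each daughter population, with \code{k} lineages every pair
#' coalesces at rate \code{2/theta} (aggregate \code{k(k-1)/theta}) until
#' the divergence time \code{tau}; surviving lineages continue in the
#' ancestral population with \code{theta_root}. A genealogy in which
#' lineages from the two populations meet before \code{tau} has density
#' zero (\code{-Inf} is returned, with the violating node reported in an
#' attribute).
#'
#' @param genetree a \code{\link{gene_tree}}.
#' @param tau divergence time (>= 0); use \code{tau = 0} with a single
#'   theta for the merged (panmictic) model.
#' @param theta_a,theta_b,theta_root mutation-scaled population sizes.
#' @param popmap optional \code{\link{population_map}} overriding the
#'   tip populations stored in the tree.
#' @param pops character vector of the two population labels, in the
#'   (A, B) order matching \code{theta_a}/\code{theta_b}.
#' @return Log-density (numeric scalar; \code{-Inf} when the genealogy is
#'   incompatible with \code{tau}).
#' @export
coalescent_log_density <- function(genetree, tau, theta_a, theta_b,
                                   theta_root, popmap = NULL, pops = NULL) {
  stopifnot(inherits(genetree, "gene_tree"))
  tip_pop <- if (is.null(popmap)) genetree$tip_pop
             else tip_pop_lookup(genetree, popmap)
  if (is.null(pops)) pops <- sort(unique(tip_pop))
  if (length(pops) == 1L) pops <- c(pops, ".none")
  if (length(pops) != 2L) stop("the pair model admits exactly 2 populations")
  code <- pop_codes(tip_pop, pops)
  res <- coal_logdensity_cpp(genetree$children, genetree$age,
                             genetree$n_tips, code, tau,
                             theta_a, theta_b, theta_root)
  ld <- res[[1L]]
  if (!is.finite(ld) && res[[2L]] > 0)
    attr(ld, "violation") <- sprintf(
      "node %d joins lineages of both populations at age %g < tau = %g",
      res[[2L]], genetree$age[res[[2L]]], tau)
  ld
}

#' JC69 log-likelihood of an alignment on a gene tree
#'
#' Felsenstein pruning under the Jukes-Cantor model (equal base
#' frequencies 1/4), with per-pattern scaling. Ambiguity codes and gaps
#' contribute a partial likelihood of 1 over their compatible states.
#'
#' @param genetree a \code{\link{gene_tree}} whose tips match the
#'   alignment samples.
#' @param locus an \code{\link{aligned_locus}}.
#' @return Log-likelihood (numeric scalar).
#' @export
jc69_log_likelihood <- function(genetree, locus) {
  stopifnot(inherits(genetree, "gene_tree"), inherits(locus, "aligned_locus"))
  pat <- site_patterns(locus, genetree$tip_labels)
  jc69_loglik_cpp(genetree$children, genetree$age, genetree$n_tips,
                  pat$states, pat$weights)
}

AMBIG_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, M = 3L, R = 5L, W = 9L,
                S = 6L, Y = 10L, K = 12L, V = 7L, H = 11L, D = 13L,
                B = 14L, N = 15L, "-" = 15L)

# collapse alignment columns into unique site patterns (bitmask coding)
site_patterns <- function(locus, tip_order) {
  idx <- match(tip_order, locus$samples)
  if (anyNA(idx))
    stop(sprintf("gene-tree tip '%s' absent from alignment",
                 tip_order[which(is.na(idx))[1L]]))
  m <- locus$matrix[idx, , drop = FALSE]
  masks <- matrix(AMBIG_MASK[m], nrow = nrow(m))
  key <- apply(masks, 2L, paste, collapse = ",")
  uk <- unique(key)
  states <- masks[, match(uk, key), drop = FALSE]
  weights <- as.numeric(table(key)[uk])
  list(states = states, weights = weights)
}
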
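# Independent oracles used across the suite: brute-force JC69 likelihood
# (explicit summation over internal states), an independently written
# coalescent density, and small fixture builders.

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, M = 3L, R = 5L, W = 9L,
                S = 6L, Y = 10L, K = 12L, V = 7L, H = 11L, D = 13L,
                B = 14L, N = 15L, "-" = 15L)

jc_P <- function(t) {
  e <- exp(-4 * t / 3)
  m <- matrix((1 - e) / 4, 4, 4)
  diag(m) <- (1 + 3 * e) / 4
  m
}

# explicit sum over all internal-state assignments (tiny trees only)
brute_force_jc69 <- function(gt, locus) {
  n <- gt$n_tips
  nn <- 2L * n - 1L
  chars <- locus$matrix[match(gt$tip_labels, locus$samples), , drop = FALSE]
  internals <- (n + 1L):nn
  combos <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  P <- vector("list", nn)
  for (v in seq_len(nn)) if (v != gt$root)
    P[[v]] <- jc_P(gt$age[gt$parent[v]] - gt$age[v])
  total <- 0
  for (s in seq_len(locus$length)) {
    tipbit <- IUPAC_BITS[chars[, s]]
    site <- 0
    for (r in seq_len(nrow(combos))) {
      st <- integer(nn)
      st[internals] <- combos[r, ]
      pr <- 0.25  # uniform root state
      for (v in seq_len(nn)) {
        if (v == gt$root) next
        if (v <= n) {
          # sum the tip's compatible states explicitly
          p <- 0
          for (x in 1:4) if (bitwAnd(tipbit[v], bitwShiftL(1L, x - 1L)))
            p <- p + P[[v]][st[gt$parent[v]], x]
          pr <- pr * p
        } else {
          pr <- pr * P[[v]][st[gt$parent[v]], st[v]]
        }
      }
      site <- site + pr
    }
    total <- total + log(site)
  }
  total
}

# coalescent log-density written independently of the engine
r_coal_logdensity <- function(gt, tau, thA, thB, thR, pops = c("A", "B")) {
  n <- gt$n_tips
  nn <- 2L * n - 1L
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  for (i in order(gt$age)) if (i > n)
    desc[[i]] <- c(desc[[gt$children[i, 1L]]], desc[[gt$children[i, 2L]]])
  popof <- gt$tip_pop
  ids <- (n + 1L):nn
  node_pop <- vapply(ids, function(i)
    paste(sort(unique(popof[desc[[i]]])), collapse = "+"), character(1L))
  ages <- gt$age[ids]
  both <- paste(sort(pops), collapse = "+")
  if (any(node_pop == both & ages < tau)) return(-Inf)
  piece <- function(k, t, evs, t_end, th) {
    evs <- sort(evs)
    ll <- 0
    for (e in evs) {
      ll <- ll - k * (k - 1) * (e - t) / th + log(2 / th)
      k <- k - 1; t <- e
    }
    if (is.finite(t_end) && k >= 2) ll <- ll - k * (k - 1) * (t_end - t) / th
    ll
  }
  evA <- ages[node_pop == pops[1L] & ages < tau]
  evB <- ages[node_pop == pops[2L] & ages < tau]
  evR <- ages[ages >= tau]
  nA <- sum(popof == pops[1L]); nB <- sum(popof == pops[2L])
  piece(nA, 0, evA, tau, thA) + piece(nB, 0, evB, tau, thB) +
    piece(nA - length(evA) + nB - length(evB), tau, evR, Inf, thR)
}

# every rooted binary topology over a label set, as nested pair lists
all_topologies <- function(labels) {
  if (length(labels) == 1L) return(list(labels[1L]))
  out <- list()
  others <- labels[-1L]
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(others)))
  for (r in seq_len(nrow(subsets))) {
    inc <- unlist(subsets[r, ])
    right <- others[!inc]
    if (!length(right)) next
    left <- c(labels[1L], others[inc])
    for (L in all_topologies(left))
      for (R in all_topologies(right))
        out[[length(out) + 1L]] <- list(L, R)
  }
  out
}

# materialize a nested-list topology as a gene_tree with random valid ages
build_gene_tree <- function(topo, tip_labels, mean_branch = 0.05) {
  n <- length(tip_labels)
  nn <- 2L * n - 1L
  children <- matrix(0L, nn, 2L)
  age <- numeric(nn)
  nxt <- n
  grow <- function(node) {
    if (!is.list(node)) return(match(node, tip_labels))
    l <- grow(node[[1L]]); r <- grow(node[[2L]])
    nxt <<- nxt + 1L
    children[nxt, ] <<- c(l, r)
    age[nxt] <<- max(age[l], age[r]) + rexp(1L, 1 / mean_branch)
    nxt
  }
  grow(topo)
  gene_tree(children, age, tip_labels, rep("A", n))
}

random_locus <- function(n, L, alphabet = c("A", "C", "G", "T"),
                         samples = paste0("s", seq_len(n))) {
  m <- matrix(sample(alphabet, n * L, replace = TRUE), nrow = n)
  aligned_locus(m, samples = samples)
}

central_priors <- function() {
  prior_set(inv_gamma_prior(3, 0.002), inv_gamma_prior(3, 0.004), "central")
}

make_pair_fixture <- function(cross_dists, L = 1000) {
  # two populations; sequences built so cross distances match requested
  # proportions (single population-A reference, B variants mutated)
  ref <- strsplit(paste(rep("A", L), collapse = ""), "")[[1]]
  seqs <- list(a1 = paste(ref, collapse = ""))
  for (k in seq_along(cross_dists)) {
    v <- ref
    nm <- round(cross_dists[k] * L)
    if (nm > 0) v[seq_len(nm)] <- "C"
    seqs[[paste0("b", k)]] <- paste(v, collapse = "")
  }
  loc <- aligned_locus(unlist(seqs))
  pm <- population_map(setNames(c("A", rep("B", length(cross_dists))),
                                names(seqs)))
  list(locus = loc, popmap = pm)
}

# independent sufficient-statistic computation for the conjugate oracle
r_single_pop_stats <- function(gt) {
  ev <- sort(gt$age[(gt$n_tips + 1):(2 * gt$n_tips - 1)])
  k <- gt$n_tips
  t <- 0; S <- 0
  for (e in ev) {
    S <- S + k * (k - 1) * (e - t)
    t <- e; k <- k - 1
  }
  list(c = length(ev), S = S)
}
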
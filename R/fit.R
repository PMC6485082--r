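#' MCMC settings
#'
#' Defaults follow the single-locus delimitation protocol this package
#' implements: 100000 recorded samples, burn-in of 10000 sweeps, one
#' sample every 5 sweeps. One sweep updates every internal node age,
#' attempts four topology moves, one tau random walk, a Gibbs update of
#' every theta, and one joint scaling move.
#'
#' @param samples number of recorded posterior draws (> burnin).
#' @param burnin number of discarded initial sweeps (>= 0).
#' @param thin sweeps between recorded draws (>= 1).
#' @return An object of class \code{"mcmc_settings"}.
#' @export
mcmc_settings <- function(samples = 100000, burnin = 10000, thin = 5) {
  if (!(samples > 0 && burnin >= 0 && thin >= 1))
    stop("need samples > 0, burnin >= 0, thin >= 1")
  if (!(samples > burnin))
    stop("samples must exceed burnin")
  structure(list(samples = as.integer(samples), burnin = as.integer(burnin),
                 thin = as.integer(thin)),
            class = "mcmc_settings")
}

# shared set-up for the samplers: pair selection, pattern compression,
# prior vector and an initial state drawn at the prior means
engine_inputs <- function(locus, popmap, pair, priors, run_seed,
                          init_gene_tree = NULL) {
  stopifnot(inherits(locus, "aligned_locus"),
            inherits(popmap, "population_map"),
            inherits(priors, "prior_set"))
  pops <- if (is.null(pair)) sort(unique(popmap$populations)) else pair
  keep <- popmap$samples[popmap$populations %in% pops]
  keep <- intersect(locus$samples, keep)
  if (length(pops) < 1L || length(pops) > 2L)
    stop("the pair model admits one or two populations")
  tip_pop <- popmap$populations[match(keep, popmap$samples)]
  for (p in pops)
    if (!any(tip_pop == p))
      stop(sprintf("no sequences for population '%s'", p))
  merged <- length(pops) == 1L
  n_a <- sum(tip_pop == pops[1L])
  n_b <- if (merged) 0L else sum(tip_pop == pops[2L])
  sub <- aligned_locus(locus$matrix[keep, , drop = FALSE], samples = keep,
                       name = locus$name)
  th0 <- priors$theta$mean
  tau0 <- priors$tau$mean
  set.seed(run_seed)
  if (is.null(init_gene_tree)) {
    gt <- if (merged)
      simulate_gene_tree(0, th0, th0, th0, n_a + n_b, 0,
                         pops = c(pops, ".none"))
    else
      simulate_gene_tree(tau0, th0, th0, th0, n_a, n_b, pops = pops)
    # data tips mapped to the simulated labels population by population
    ord <- c(keep[tip_pop == pops[1L]],
             if (!merged) keep[tip_pop == pops[2L]])
  } else {
    gt <- init_gene_tree
    ord <- gt$tip_labels
    if (!setequal(ord, keep))
      stop("initial gene tree tips do not match the selected samples")
    if (!merged)
      tau0 <- min(tau0,
                  0.9 * min(c(Inf, gt$age[gene_tree_mixed_nodes(gt, pops)])))
  }
  pat <- site_patterns(sub, ord)
  if (!is.null(init_gene_tree)) {
    tip_pop <- gt$tip_pop
    n_a <- sum(tip_pop == pops[1L])
    n_b <- if (merged) 0L else sum(tip_pop == pops[2L])
  }
  ordpop <- popmap$populations[match(ord, popmap$samples)]
  list(pops = pops, merged = merged, n_a = n_a, n_b = n_b,
       samples = ord, pat = pat, gt = gt,
       tipcode = if (merged) rep(0L, n_a + n_b)
                 else pop_codes(ordpop, pops),
       prior = c(priors$theta$alpha, priors$theta$beta,
                 priors$tau$alpha, priors$tau$beta),
       tau0 = tau0, theta0 = rep(th0, 3))
}

#' Fit the two-population multispecies-coalescent model
#'
#' Bayesian estimation of the divergence time tau and the mutation-scaled
#' population sizes theta_A, theta_B and theta_root for a fixed
#' two-population split, from a single aligned locus (the "A00" role of
#' the delimitation workflow). The sampler is Metropolis-within-Gibbs over
#' the gene tree (node-age slides, constrained subtree exchanges and a
#' joint scaling move) and the model parameters (theta by its conditional
#' inverse-gamma conjugacy given the genealogy, tau by multiplicative
#' random walk), with proposal steps tuned to a 0.2-0.4 acceptance rate
#' during burn-in and frozen afterwards. Several independent runs with
#' distinct seeds are performed and compared.
#'
#' @param locus an \code{\link{aligned_locus}}.
#' @param popmap a \code{\link{population_map}}; after restriction to
#'   \code{pair} it must contain exactly two populations (a single
#'   population fits the one-theta merged model instead).
#' @param priors a \code{\link{prior_set}}; the theta prior is shared by
#'   theta_A, theta_B and theta_root.
#' @param pair optional character vector of two population labels
#'   selecting (and ordering) the pair; defaults to all populations in
#'   the map, sorted.
#' @param settings an \code{\link{mcmc_settings}}.
#' @param n_runs number of independent MCMC runs (default 4); run
#'   \code{r} uses seed \code{seed + r - 1}.
#' @param seed integer seed.
#' @param prior_only if \code{TRUE}, the sequence likelihood is switched
#'   off and the sampler targets the prior (the prior-vs-posterior check).
#' @param fix_gene_tree if \code{TRUE}, the genealogy is held at its
#'   initial value and only the parameters are updated.
#' @param init_gene_tree optional \code{\link{gene_tree}} used as the
#'   initial (or, with \code{fix_gene_tree}, the fixed) genealogy; by
#'   default one is simulated from the coalescent at the prior means.
#' @return An object of class \code{"msc_fit"} with the per-run posterior
#'   traces (\code{$traces}, data frames with columns \code{tau},
#'   \code{theta_a}, \code{theta_b}, \code{theta_root}, \code{loglik}),
#'   the pooled trace (\code{$combined}), priors, settings and
#'   convergence diagnostics.
#' @seealso \code{\link{gdi}}, \code{\link{delimit_pair}},
#'   \code{\link{convergence_check}}
#' @export
fit_msc_pair <- function(locus, popmap, priors, pair = NULL,
                         settings = mcmc_settings(), n_runs = 4, seed = 1,
                         prior_only = FALSE, fix_gene_tree = FALSE,
                         init_gene_tree = NULL) {
  stopifnot(inherits(settings, "mcmc_settings"), n_runs >= 1)
  traces <- vector("list", n_runs)
  accept <- vector("list", n_runs)
  inp <- NULL
  for (r in seq_len(n_runs)) {
    inp <- engine_inputs(locus, popmap, pair, priors, seed + r - 1L,
                         init_gene_tree = init_gene_tree)
    res <- run_a00_cpp(inp$gt$children, inp$gt$age, inp$gt$n_tips,
                       inp$tipcode, inp$pat$states, inp$pat$weights,
                       inp$prior, inp$tau0, inp$theta0,
                       settings$samples, settings$burnin, settings$thin,
                       prior_only, fix_gene_tree, inp$merged)
    traces[[r]] <- as.data.frame(res$trace)
    accept[[r]] <- res$acceptance
  }
  fit <- structure(list(traces = traces,
                        combined = do.call(rbind, traces),
                        priors = priors, settings = settings,
                        pops = inp$pops, merged = inp$merged,
                        n_a = inp$n_a, n_b = inp$n_b,
                        n_sites = locus$length,
                        prior_only = prior_only, seed = seed,
                        acceptance = accept),
                   class = "msc_fit")
  fit$convergence <- if (n_runs >= 2L) convergence_check(fit) else NULL
  fit
}

msc_params <- function(fit) {
  if (fit$merged) "theta_root"
  else c("tau", "theta_a", "theta_b", "theta_root")
}

#' @export
print.msc_fit <- function(x, ...) {
  cat(sprintf("Two-population MSC fit%s: populations (%s), %d + %d sequences, %d bp\n",
              if (x$prior_only) " (prior only)" else "",
              paste(x$pops, collapse = ", "), x$n_a, x$n_b, x$n_sites))
  cat(sprintf("  %d runs x %d samples (burnin %d, thin %d)\n",
              length(x$traces), x$settings$samples, x$settings$burnin,
              x$settings$thin))
  cm <- coef(x)
  cat("  posterior means:",
      paste(sprintf("%s = %.4g", names(cm), cm), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.msc_fit <- function(object, ...) {
  p <- msc_params(object)
  vapply(p, function(v) mean(object$combined[[v]]), numeric(1L))
}

#' @export
summary.msc_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  p <- msc_params(object)
  tab <- t(vapply(p, function(v) {
    x <- object$combined[[v]]
    c(mean = mean(x), sd = stats::sd(x), stats::quantile(x, probs))
  }, numeric(2L + length(probs))))
  out <- list(table = tab, convergence = object$convergence,
              pops = object$pops, n_runs = length(object$traces),
              prior_only = object$prior_only)
  class(out) <- "summary.msc_fit"
  out
}

#' @export
print.summary.msc_fit <- function(x, ...) {
  cat(sprintf("Posterior summary (%d runs pooled%s), pair (%s):\n",
              x$n_runs, if (x$prior_only) ", prior only" else "",
              paste(x$pops, collapse = ", ")))
  print(round(x$table, 6))
  if (!is.null(x$convergence)) {
    cat("\nConvergence:\n")
    print(x$convergence)
  }
  invisible(x)
}

#' @export
plot.msc_fit <- function(x, params = msc_params(x), ...) {
  old <- graphics::par(mfrow = c(length(params), 2),
                       mar = c(4, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (p in params) {
    first <- TRUE
    for (r in seq_along(x$traces)) {
      v <- x$traces[[r]][[p]]
      if (first) {
        plot(v, type = "l", col = r, xlab = "draw", ylab = p,
             main = paste("trace:", p), ...)
        first <- FALSE
      } else graphics::lines(v, col = r)
    }
    d <- stats::density(x$combined[[p]], from = 0)
    plot(d, main = paste("posterior:", p), xlab = p)
  }
  invisible(x)
}

#' Posterior-predictive simulation from a fitted pair model
#'
#' Draws parameter vectors from the posterior trace and simulates new
#' datasets of the fitted dimensions under the two-population coalescent
#' with JC69 sequences.
#'
#' @param object an \code{\link{fit_msc_pair}} result (split model).
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of \code{nsim} \code{\link{simulate_msc_dataset}}
#'   results; each \code{truth} holds the posterior draw used.
#' @importFrom stats simulate
#' @method simulate msc_fit
#' @export
simulate.msc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$merged)
    stop("posterior-predictive simulation needs the split model")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$combined), nsim, replace = TRUE)
  lapply(idx, function(i) {
    d <- object$combined[i, ]
    simulate_msc_dataset(tau = d$tau, theta_a = d$theta_a,
                         theta_b = d$theta_b, theta_root = d$theta_root,
                         n_a = object$n_a, n_b = object$n_b,
                         length = object$n_sites, pops = object$pops)
  })
}

#' Write a posterior trace as TSV
#'
#' One draw per row with a leading run column, mirroring the mcmc.txt
#' layout of coalescent delimitation tools.
#'
#' @param fit an \code{\link{fit_msc_pair}} result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(fit, path) {
  stopifnot(inherits(fit, "msc_fit"))
  df <- do.call(rbind, lapply(seq_along(fit$traces), function(r)
    cbind(run = r, fit$traces[[r]])))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a posterior trace written by \code{\link{write_trace}}
#'
#' @param path TSV trace file.
#' @return A data frame with a \code{run} column and the parameter draws.
#' @export
read_trace <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
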
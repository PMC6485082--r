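#' Inverse-gamma prior
#'
#' Prior used for both the mutation-scaled population sizes theta and the
#' root divergence time tau, parameterised by shape \code{alpha} and scale
#' \code{beta}; the mean is \code{beta / (alpha - 1)} for \code{alpha > 1}
#' (the empirical-calibration formula requires \code{alpha > 2} so the
#' prior also has finite variance).
#'
#' @param alpha shape, > 0.
#' @param beta scale, > 0, in expected substitutions per site.
#' @return An object of class \code{"inv_gamma_prior"}.
#' @examples
#' inv_gamma_prior(3, 0.002)  # mean 0.001
#' @export
inv_gamma_prior <- function(alpha, beta) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0))
    stop("alpha must be a positive number")
  if (!(is.numeric(beta) && length(beta) == 1L && beta > 0))
    stop("beta must be a positive number")
  structure(list(alpha = alpha, beta = beta,
                 mean = if (alpha > 1) beta / (alpha - 1) else Inf),
            class = "inv_gamma_prior")
}

#' @export
print.inv_gamma_prior <- function(x, ...) {
  cat(sprintf("IG(%g, %g)  mean = %s\n", x$alpha, x$beta,
              if (is.finite(x$mean)) format(x$mean) else "undefined"))
  invisible(x)
}

#' @export
format.inv_gamma_prior <- function(x, ...) sprintf("IG(%g, %g)", x$alpha, x$beta)

#' Scale parameter from a target prior mean
#'
#' Inverts the inverse-gamma mean formula \code{m = beta / (alpha - 1)}
#' (valid for \code{alpha > 2}) to calibrate \code{beta} from an empirical
#' mean estimate.
#'
#' @param alpha shape, must exceed 2.
#' @param m target prior mean, > 0.
#' @return \code{beta = m * (alpha - 1)}.
#' @examples
#' beta_from_mean(3, 0.01)   # 0.02
#' @export
beta_from_mean <- function(alpha, m) {
  if (!(is.numeric(alpha) && alpha > 2))
    stop("mean calibration requires alpha > 2")
  if (!(is.numeric(m) && m > 0)) stop("prior mean m must be > 0")
  m * (alpha - 1)
}

#' A pair of priors for one analysis
#'
#' @param theta_prior,tau_prior \code{\link{inv_gamma_prior}} objects for
#'   theta and for the root age tau.
#' @param label identifier for the prior set (grid row or "empirical").
#' @return An object of class \code{"prior_set"}.
#' @export
prior_set <- function(theta_prior, tau_prior, label = "") {
  stopifnot(inherits(theta_prior, "inv_gamma_prior"),
            inherits(tau_prior, "inv_gamma_prior"))
  structure(list(theta = theta_prior, tau = tau_prior, label = label),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat(sprintf("Prior set '%s': theta ~ %s, tau ~ %s\n", x$label,
              format(x$theta), format(x$tau)))
  invisible(x)
}

#' The ten-set prior-sensitivity grid
#'
#' The grid varies the prior mean over two orders of magnitude around
#' central values, using shape alpha = 3 as a diffuse and alpha = 21 as an
#' informative prior: five theta priors are crossed with the central tau
#' prior IG(3, 0.004), and five tau priors with the central theta prior
#' IG(3, 0.002).
#'
#' @return A list of 10 \code{\link{prior_set}} objects with distinct
#'   labels.
#' @export
prior_grid <- function() {
  theta_rows <- list(c(3, 0.0002), c(3, 0.002), c(3, 0.02),
                     c(21, 0.02), c(21, 0.2))
  tau_rows <- list(c(3, 0.0004), c(3, 0.04), c(21, 0.004),
                   c(21, 0.04), c(21, 0.4))
  base_theta <- inv_gamma_prior(3, 0.002)
  base_tau <- inv_gamma_prior(3, 0.004)
  sets <- c(
    lapply(theta_rows, function(p) {
      th <- inv_gamma_prior(p[1], p[2])
      prior_set(th, base_tau,
                label = sprintf("theta=%s tau=%s", format(th), format(base_tau)))
    }),
    lapply(tau_rows, function(p) {
      ta <- inv_gamma_prior(p[1], p[2])
      prior_set(base_theta, ta,
                label = sprintf("theta=%s tau=%s", format(base_theta), format(ta)))
    }))
  sets
}

#' Empirical theta prior from nucleotide diversity
#'
#' Calibrates an inverse-gamma prior for theta by setting its mean to the
#' average within-population nucleotide diversity (mean pairwise
#' uncorrected p-distance, pairwise deletion) over populations with at
#' least two samples. When every population is a singleton, or when the
#' observed diversity is exactly zero, the mean cannot be calibrated; a
#' supplied fallback prior is returned with a warning, or an error is
#' raised when no fallback is given.
#'
#' @param locus an \code{\link{aligned_locus}}.
#' @param popmap a \code{\link{population_map}}.
#' @param alpha prior shape (> 2); default 3.
#' @param fallback optional \code{\link{inv_gamma_prior}} used when no
#'   population has two or more samples.
#' @return An \code{\link{inv_gamma_prior}}.
#' @export
empirical_theta_prior <- function(locus, popmap, alpha = 3, fallback = NULL) {
  stopifnot(inherits(locus, "aligned_locus"))
  dmat <- p_distance_matrix(locus)
  pops <- unique(popmap$populations)
  pis <- vapply(pops, function(p) within_population_diversity(dmat, popmap, p),
                numeric(1L))
  pis <- pis[!is.na(pis)]
  if (!length(pis)) {
    if (is.null(fallback))
      stop(paste("all populations are singletons: nucleotide diversity is",
                 "undefined and no fallback prior was supplied"))
    warning("all populations are singletons; using the fallback theta prior")
    return(fallback)
  }
  m <- mean(pis)
  if (m <= 0) {
    if (is.null(fallback))
      stop("degenerate empirical theta prior: mean nucleotide diversity is 0")
    warning("nucleotide diversity is 0; using the fallback theta prior")
    return(fallback)
  }
  inv_gamma_prior(alpha, beta_from_mean(alpha, m))
}

#' Empirical tau prior from a guide-tree node height
#'
#' Sets the prior mean for the pair's divergence time to the height of the
#' most recent common ancestor of the two populations on an ultrametric
#' guide tree (heights in expected substitutions per site).
#'
#' @param tree a \code{\link{guide_tree}}.
#' @param pair character vector of two population labels.
#' @param alpha prior shape (> 2); default 3.
#' @return An \code{\link{inv_gamma_prior}}.
#' @export
empirical_tau_prior <- function(tree, pair, alpha = 3) {
  stopifnot(length(pair) == 2L)
  m <- mrca_height(tree, pair[1L], pair[2L])
  if (m <= 0)
    stop(sprintf("degenerate tau prior: MRCA height of (%s, %s) is 0",
                 pair[1L], pair[2L]))
  inv_gamma_prior(alpha, beta_from_mean(alpha, m))
}

#' Draw from an inverse-gamma prior
#'
#' @param prior an \code{\link{inv_gamma_prior}}.
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of \code{n} inverse-gamma variates.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "inv_gamma_prior"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  1 / stats::rgamma(n, shape = prior$alpha, rate = prior$beta)
}

#' Inverse-gamma distribution function
#'
#' @param q quantiles.
#' @param prior an \code{\link{inv_gamma_prior}}.
#' @return \code{P(X <= q)}.
#' @export
pinvgamma <- function(q, prior) {
  stats::pgamma(1 / pmax(q, .Machine$double.xmin), shape = prior$alpha,
                rate = prior$beta, lower.tail = FALSE)
}

#' Inverse-gamma log-density
#'
#' @param x evaluation points (> 0).
#' @param prior an \code{\link{inv_gamma_prior}}.
#' @return Log-density values.
#' @export
dinvgamma_log <- function(x, prior) {
  a <- prior$alpha; b <- prior$beta
  ifelse(x > 0, a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x, -Inf)
}
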
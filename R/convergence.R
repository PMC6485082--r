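# FFT autocovariance (biased, as used for ESS estimation)
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, m - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m / n
}

rank_normalize <- function(x) {
  r <- rank(c(x))
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  array(z, dim = dim(as.matrix(x)))
}

# chains: n x m matrix (one chain per column), already rank-normalized
rhat_of <- function(chains) {
  n <- nrow(chains); m <- ncol(chains)
  mu <- colMeans(chains)
  B <- n * stats::var(mu)
  W <- mean(apply(chains, 2L, stats::var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_of <- function(chains) {
  n <- nrow(chains); m <- ncol(chains)
  W <- mean(apply(chains, 2L, stats::var))
  mu <- colMeans(chains)
  B <- if (m > 1) n * stats::var(mu) else 0
  varplus <- (n - 1) / n * W + B / n
  if (varplus == 0) return(NA_real_)
  ac <- sapply(seq_len(m), function(j) autocov_fft(chains[, j]))
  rho <- 1 - (W - rowMeans(ac)) / varplus
  # Geyer initial monotone positive sequence on paired sums
  maxpair <- floor((n - 2) / 2)
  tau <- 0; prev <- Inf
  for (k in 0:maxpair) {
    p <- rho[2 * k + 1] + rho[2 * k + 2]
    if (is.na(p) || p < 0) break
    p <- min(p, prev)
    tau <- tau + p
    prev <- p
  }
  ess <- n * m / max(2 * tau - 1, 1 / (n * m))
  min(ess, n * m)
}

split_chains <- function(mat) {
  n <- nrow(mat)
  h <- floor(n / 2)
  do.call(cbind, lapply(seq_len(ncol(mat)), function(j)
    cbind(mat[seq_len(h), j], mat[h + seq_len(h), j])))
}

#' Convergence diagnostics across independent MCMC runs
#'
#' For each model parameter: the largest across-run discrepancy in
#' posterior means (in pooled-SD units), the rank-normalized split-chain
#' potential scale reduction factor R-hat, and the effective sample size
#' (Geyer initial monotone sequence on the split, rank-normalized
#' chains). Parameters with R-hat > 1.05 or ESS < 200 are flagged.
#'
#' @param fit an \code{\link{fit_msc_pair}} result, or a list of at least
#'   two posterior trace data frames with identical columns and lengths.
#' @param params parameter columns to assess; defaults to all shared
#'   numeric columns except \code{loglik}.
#' @return A data.frame of class \code{"msc_convergence"} with one row
#'   per parameter: \code{mean_discrepancy}, \code{rhat}, \code{ess},
#'   \code{flagged}.
#' @export
convergence_check <- function(fit, params = NULL) {
  traces <- if (inherits(fit, "msc_fit")) fit$traces else fit
  if (!is.list(traces) || length(traces) < 2L)
    stop("need at least 2 traces")
  ns <- vapply(traces, nrow, integer(1L))
  if (length(unique(ns)) != 1L)
    stop("traces were run with unequal settings (different lengths)")
  if (is.null(params)) {
    params <- Reduce(intersect, lapply(traces, names))
    params <- setdiff(params, c("loglik", "run"))
    keep <- vapply(params, function(p)
      all(vapply(traces, function(tr) !anyNA(tr[[p]]), logical(1L))),
      logical(1L))
    params <- params[keep]
  }
  rows <- lapply(params, function(p) {
    mat <- sapply(traces, function(tr) tr[[p]])
    mus <- colMeans(mat)
    pooled_sd <- stats::sd(c(mat))
    disc <- if (pooled_sd > 0) diff(range(mus)) / pooled_sd else 0
    z <- rank_normalize(mat)
    dim(z) <- dim(mat)
    zs <- split_chains(z)
    rh <- rhat_of(zs)
    es <- ess_of(zs)
    data.frame(parameter = p, mean_discrepancy = disc, rhat = rh,
               ess = es, flagged = (rh > 1.05) || (!is.na(es) && es < 200),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("msc_convergence", class(out))
  out
}

#' @export
print.msc_convergence <- function(x, ...) {
  df <- as.data.frame(x)
  df$mean_discrepancy <- sprintf("%.3f", df$mean_discrepancy)
  df$rhat <- sprintf("%.4f", df$rhat)
  df$ess <- sprintf("%.0f", df$ess)
  print(df, row.names = FALSE)
  if (any(x$flagged))
    cat("Flagged parameters: R-hat > 1.05 or ESS < 200 -- inspect traces.\n")
  invisible(x)
}
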
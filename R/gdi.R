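#' Genealogical divergence index
#'
#' \code{gdi = 1 - exp(-2 * tau / theta)}: looking backward in time, the
#' probability that a lineage pair sampled within one population
#' coalesces before the divergence event at \code{tau}, given the
#' population's mutation-scaled size \code{theta}. Values above 0.7
#' indicate distinct species, values below 0.2 a single species.
#'
#' @param tau divergence time (>= 0), expected substitutions/site.
#' @param theta mutation-scaled population size (> 0).
#' @return gdi in \code{[0, 1)}; vectorized over both arguments.
#' @examples
#' gdi_value(0.001, 0.002)  # 1 - exp(-1)
#' @export
gdi_value <- function(tau, theta) {
  if (any(theta <= 0)) stop("theta must be > 0")
  if (any(tau < 0)) stop("tau must be >= 0")
  1 - exp(-2 * tau / theta)
}

#' Classify a gdi posterior mean
#'
#' Strict thresholds: \code{mean > 0.7} is \code{"distinct"},
#' \code{mean < 0.2} is \code{"same"}, anything else (including the
#' boundary values) \code{"ambiguous"}.
#'
#' @param mean_gdi posterior mean gdi.
#' @return Classification string; vectorized.
#' @export
classify_gdi <- function(mean_gdi) {
  stopifnot(is.numeric(mean_gdi))
  ifelse(mean_gdi > 0.7, "distinct",
         ifelse(mean_gdi < 0.2, "same", "ambiguous"))
}

#' Per-draw gdi from a posterior trace
#'
#' @param fit an \code{\link{fit_msc_pair}} result (split model), or a
#'   data frame with columns \code{tau}, \code{theta_a}, \code{theta_b}.
#' @param direction \code{"a"} (population A against B, using
#'   \code{2*tau/theta_A}), \code{"b"} (B against A, using
#'   \code{2*tau/theta_B}), or \code{"both"}.
#' @param ... unused.
#' @return For one direction, an object of class \code{"gdi_result"}
#'   with the per-draw values, mean, SD, classification and a Gaussian
#'   kernel density on \code{[0, 1)}; for \code{"both"}, a list with
#'   elements \code{a} and \code{b}.
#' @export
gdi <- function(fit, direction = c("both", "a", "b"), ...) {
  UseMethod("gdi")
}

gdi_one <- function(trace, direction, pops) {
  theta <- switch(direction, a = trace$theta_a, b = trace$theta_b)
  if (is.null(theta) || all(is.na(theta)))
    stop(sprintf("trace has no theta for direction '%s'", direction))
  vals <- gdi_value(trace$tau, theta)
  dens <- if (length(vals) >= 2L && stats::sd(vals) > 0)
    stats::density(vals, bw = "nrd0", from = 0, to = 1) else NULL
  structure(list(direction = direction,
                 pops = pops, values = vals, mean = mean(vals),
                 sd = if (length(vals) > 1L) stats::sd(vals) else 0,
                 classification = classify_gdi(mean(vals)),
                 density = dens),
            class = "gdi_result")
}

#' @rdname gdi
#' @export
gdi.msc_fit <- function(fit, direction = c("both", "a", "b"), ...) {
  if (fit$merged) stop("gdi needs the split (two-population) model")
  gdi.data.frame(fit$combined, direction, pops = fit$pops)
}

#' @rdname gdi
#' @param pops optional pair of population labels for reporting.
#' @export
gdi.data.frame <- function(fit, direction = c("both", "a", "b"),
                           pops = c("A", "B"), ...) {
  direction <- match.arg(direction)
  trace <- fit
  if (!nrow(trace)) stop("empty posterior trace")
  if (is.null(trace$tau)) stop("trace has no tau column")
  if (direction == "both")
    list(a = gdi_one(trace, "a", pops), b = gdi_one(trace, "b", pops))
  else gdi_one(trace, direction, pops)
}

#' @export
print.gdi_result <- function(x, ...) {
  who <- if (x$direction == "a")
    sprintf("%s vs %s (2*tau/theta_%s)", x$pops[1L], x$pops[2L], x$pops[1L])
  else
    sprintf("%s vs %s (2*tau/theta_%s)", x$pops[2L], x$pops[1L], x$pops[2L])
  cat(sprintf("gdi %s: %.2f ± %.2f  -> %s\n", who, x$mean, x$sd,
              x$classification))
  invisible(x)
}

#' @export
plot.gdi_result <- function(x, ...) {
  if (is.null(x$density)) stop("no density available (degenerate trace)")
  plot(x$density, main = sprintf("gdi density (%s), mean %.2f",
                                 x$direction, x$mean),
       xlab = "gdi", xlim = c(0, 1), ...)
  graphics::abline(v = c(0.2, 0.7), lty = 2, col = "red")
  invisible(x)
}
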
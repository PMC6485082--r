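#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among comparable sites, where a site is
#' comparable only when both sequences carry an unambiguous base (A, C, G
#' or T): gaps and ambiguity codes are dropped pairwise, the convention
#' used for barcoding-gap screening.
#'
#' @param seq_a,seq_b aligned IUPAC strings (or character vectors, one
#'   element per site) of equal length.
#' @return A list with \code{distance} (proportion in \code{[0, 1]}) and
#'   \code{comparable_sites} (number of sites compared).
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25 over 4 sites
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1L]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1L]] else toupper(seq_b)
  if (length(a) != length(b))
    stop(sprintf("sequences have unequal lengths (%d vs %d)",
                 length(a), length(b)))
  acgt <- c("A", "C", "G", "T")
  comp <- a %in% acgt & b %in% acgt
  n <- sum(comp)
  if (n == 0L)
    stop("undefined p-distance: no comparable (unambiguous, ungapped) sites")
  list(distance = sum(a[comp] != b[comp]) / n, comparable_sites = n)
}

#' Pairwise uncorrected p-distance matrix for an alignment
#'
#' @param locus an \code{\link{aligned_locus}} with at least two samples.
#' @return An object of class \code{"p_distance_matrix"}: a list with the
#'   symmetric \code{distance} matrix (proportions), the symmetric
#'   \code{comparable_sites} count matrix, and \code{samples}.
#' @export
p_distance_matrix <- function(locus) {
  stopifnot(inherits(locus, "aligned_locus"))
  n <- length(locus$samples)
  if (n < 2L) stop("need at least 2 samples for a distance matrix")
  m <- locus$matrix
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(locus$samples, locus$samples))
  cs <- matrix(locus$length, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop(sprintf(
          "undefined p-distance between '%s' and '%s': no comparable sites",
          locus$samples[i], locus$samples[j]))
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
      cs[i, j] <- cs[j, i] <- nc
    }
  }
  diag(cs) <- rowSums(ok)
  structure(list(distance = d, comparable_sites = cs,
                 samples = locus$samples),
            class = "p_distance_matrix")
}

#' @export
print.p_distance_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Uncorrected p-distance matrix, %d samples\n",
              length(x$samples)))
  print(round(x$distance, digits))
  invisible(x)
}

cross_pairs <- function(dmat, popmap, a, b) {
  for (p in c(a, b))
    if (!p %in% popmap$populations)
      stop(sprintf("unknown population label '%s'", p))
  ia <- match(popmap$samples[popmap$populations == a], dmat$samples)
  ib <- match(popmap$samples[popmap$populations == b], dmat$samples)
  ia <- ia[!is.na(ia)]; ib <- ib[!is.na(ib)]
  if (!length(ia) || !length(ib))
    stop(sprintf("no samples of '%s' or '%s' present in the distance matrix",
                 a, b))
  as.vector(dmat$distance[ia, ib, drop = FALSE])
}

#' Between-population divergence summary
#'
#' Minimum, maximum and mean uncorrected p-distance over all
#' cross-population sample pairs, in percent.
#'
#' @param dmat a \code{\link{p_distance_matrix}}.
#' @param popmap a \code{\link{population_map}}.
#' @param a,b population labels.
#' @return Named numeric vector \code{c(d_min, d_max, d_mean)} in percent.
#' @export
between_population_summary <- function(dmat, popmap, a, b) {
  d <- cross_pairs(dmat, popmap, a, b) * 100
  c(d_min = min(d), d_max = max(d), d_mean = mean(d))
}

#' Mean within-population p-distance (nucleotide diversity)
#'
#' Average pairwise uncorrected p-distance among samples of one
#' population; \code{NA} for singleton populations.
#'
#' @inheritParams between_population_summary
#' @param pop population label.
#' @return Mean pairwise distance as a proportion, or \code{NA}.
#' @export
within_population_diversity <- function(dmat, popmap, pop) {
  if (!pop %in% popmap$populations)
    stop(sprintf("unknown population label '%s'", pop))
  idx <- match(popmap$samples[popmap$populations == pop], dmat$samples)
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2L) return(NA_real_)
  sub <- dmat$distance[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Threshold screening of candidate population pairs
#'
#' Applies the mitochondrial divergence thresholds (defaults 3 and 5
#' percent) to every population pair with a known conspecificity status:
#' non-conspecific pairs entirely below the lower threshold are candidates
#' for lumping; conspecific pairs entirely above the upper threshold are
#' candidates for splitting; pairs whose divergence range touches the
#' \code{[lower, upper]} band fall in the grey zone; everything else is
#' unflagged. Thresholds are exclusive for lump/split calls and inclusive
#' for the grey zone.
#'
#' @param dmat a \code{\link{p_distance_matrix}}.
#' @param popmap a \code{\link{population_map}}.
#' @param taxonomy a data.frame with columns \code{population_a},
#'   \code{population_b}, \code{conspecific} (logical): the user-supplied
#'   current taxonomy for each pair to screen.
#' @param lower,upper thresholds in percent; \code{lower < upper}.
#' @return A data.frame of class \code{"candidate_screen"} with one row per
#'   pair: labels, conspecific flag, \code{d_min}/\code{d_max}/\code{d_mean}
#'   (percent), and \code{category} in \code{lump_candidate},
#'   \code{split_candidate}, \code{grey_zone}, \code{none}.
#' @export
screen_candidates <- function(dmat, popmap, taxonomy, lower = 3, upper = 5) {
  if (!all(c("population_a", "population_b", "conspecific") %in%
           names(taxonomy)))
    stop("taxonomy must have columns population_a, population_b, conspecific")
  if (!(is.numeric(lower) && is.numeric(upper) && lower < upper))
    stop("thresholds must satisfy lower < upper")
  rows <- lapply(seq_len(nrow(taxonomy)), function(i) {
    a <- taxonomy$population_a[i]
    b <- taxonomy$population_b[i]
    consp <- isTRUE(as.logical(taxonomy$conspecific[i]))
    s <- between_population_summary(dmat, popmap, a, b)
    overlap <- s[["d_max"]] >= lower && s[["d_min"]] <= upper
    category <- if (consp) {
      if (s[["d_min"]] > upper) "split_candidate"
      else if (overlap) "grey_zone" else "none"
    } else {
      if (s[["d_max"]] < lower) "lump_candidate"
      else if (overlap) "grey_zone" else "none"
    }
    data.frame(population_a = a, population_b = b, conspecific = consp,
               d_min = s[["d_min"]], d_max = s[["d_max"]],
               d_mean = s[["d_mean"]], category = category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("candidate_screen", class(out))
  out
}

#' @export
print.candidate_screen <- function(x, ...) {
  cat(sprintf("Candidate screen: %d pairs (%d flagged)\n", nrow(x),
              sum(x$category != "none")))
  df <- as.data.frame(x)
  df$d_min <- sprintf("%.2f", df$d_min)
  df$d_max <- sprintf("%.2f", df$d_max)
  df$d_mean <- sprintf("%.2f", df$d_mean)
  print(df, row.names = FALSE)
  invisible(x)
}
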
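#' @useDynLib coaldelim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Construct an aligned single-locus sequence matrix
#'
#' Container for one aligned locus (the role the 16S alignment plays in the
#' delimitation workflow). Sequences are stored uppercase as a
#' sample-by-site character matrix; \code{U} is normalised to \code{T} and
#' \code{?} to \code{N}.
#'
#' @param sequences character vector of aligned IUPAC DNA strings, or a
#'   character matrix with one row per sample.
#' @param samples sample identifiers; defaults to \code{names(sequences)}.
#' @param name locus label.
#' @return An object of class \code{"aligned_locus"}: a list with elements
#'   \code{name}, \code{samples}, \code{matrix} (character, samples x
#'   sites) and \code{length} (alignment length in bp).
#' @examples
#' aligned_locus(c(s1 = "ACGT", s2 = "ACGA"))
#' @export
aligned_locus <- function(sequences, samples = NULL, name = "locus") {
  if (is.matrix(sequences)) {
    m <- toupper(sequences)
    if (is.null(samples)) samples <- rownames(sequences)
  } else {
    if (is.null(samples)) samples <- names(sequences)
    if (length(sequences) < 1L) stop("alignment must contain at least one sequence")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      bad <- samples[which(lens != lens[1L])[1L]]
      stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                   if (is.null(bad)) "<unnamed>" else bad,
                   lens[lens != lens[1L]][1L], lens[1L]))
    }
    if (lens[1L] < 1L) stop("alignment length must be >= 1")
    m <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  }
  if (is.null(samples)) stop("sample identifiers are required")
  samples <- as.character(samples)
  if (anyNA(samples) || any(!nzchar(samples)))
    stop("sample identifiers must be nonempty")
  if (anyDuplicated(samples))
    stop(sprintf("duplicate sample identifier: '%s'",
                 samples[duplicated(samples)][1L]))
  m[m == "U"] <- "T"
  m[m == "?"] <- "N"
  bad <- !(m %in% IUPAC_CHARS)
  if (any(bad)) {
    idx <- which(bad, arr.ind = FALSE)[1L]
    row <- ((idx - 1L) %% nrow(m)) + 1L
    col <- ((idx - 1L) %/% nrow(m)) + 1L
    stop(sprintf("non-IUPAC character '%s' in sequence '%s' at site %d",
                 m[idx], samples[row], col))
  }
  dimnames(m) <- list(samples, NULL)
  structure(list(name = name, samples = samples, matrix = m,
                 length = ncol(m)),
            class = "aligned_locus")
}

#' @export
print.aligned_locus <- function(x, ...) {
  cat(sprintf("Aligned locus '%s': %d samples, %d sites\n",
              x$name, length(x$samples), x$length))
  invisible(x)
}

#' @export
as.character.aligned_locus <- function(x, ...) {
  out <- apply(x$matrix, 1L, paste, collapse = "")
  names(out) <- x$samples
  out
}

#' Read a FASTA alignment
#'
#' Reads an aligned FASTA file into an \code{\link{aligned_locus}},
#' preserving the input sample order and validating that all records have
#' equal length and contain only IUPAC nucleotide symbols.
#'
#' @param path path to a FASTA file.
#' @param name locus label; defaults to the file name without extension.
#' @return An \code{\link{aligned_locus}}.
#' @export
read_fasta_alignment <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 1L) stop(sprintf("no FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA header '%s' in %s",
                 ids[duplicated(ids)][1L], path))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  seqs <- as.character(set)
  names(seqs) <- ids
  aligned_locus(seqs, name = name)
}

#' Write an aligned locus to FASTA
#'
#' @param locus an \code{\link{aligned_locus}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta_alignment <- function(locus, path) {
  stopifnot(inherits(locus, "aligned_locus"))
  seqs <- as.character(locus)
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Construct a sample-to-population map
#'
#' @param assignments named character vector: names are sample identifiers,
#'   values are population labels.
#' @return An object of class \code{"population_map"}.
#' @export
population_map <- function(assignments) {
  samples <- names(assignments)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("assignments must be a named vector of population labels")
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    conf <- dup[vapply(dup, function(s)
      length(unique(assignments[samples == s])) > 1L, logical(1L))]
    if (length(conf))
      stop(sprintf("sample '%s' assigned to multiple populations", conf[1L]))
    keep <- !duplicated(samples)
    assignments <- assignments[keep]
    samples <- samples[keep]
  }
  if (any(!nzchar(assignments))) stop("population labels must be nonempty")
  structure(list(samples = samples,
                 populations = as.character(assignments)),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  tab <- table(x$populations)
  cat(sprintf("Population map: %d samples in %d populations\n",
              length(x$samples), length(tab)))
  for (p in names(tab)) cat(sprintf("  %s: %d\n", p, tab[[p]]))
  invisible(x)
}

#' Read a BPP-style imap file
#'
#' Two whitespace-delimited columns: sample identifier, population label.
#' Blank lines and lines starting with \code{#} are ignored.
#'
#' @param path path to the imap file.
#' @return A \code{\link{population_map}}.
#' @export
read_imap <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop(sprintf("no assignments in imap file %s", path))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop(sprintf("imap line %d has fewer than 2 columns: '%s'",
                 which(nf < 2L)[1L], lines[which(nf < 2L)[1L]]))
  ids <- vapply(fields, `[[`, character(1L), 1L)
  pops <- vapply(fields, `[[`, character(1L), 2L)
  names(pops) <- ids
  population_map(pops)
}

#' Write a population map as an imap file
#'
#' @param popmap a \code{\link{population_map}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_imap <- function(popmap, path) {
  stopifnot(inherits(popmap, "population_map"))
  writeLines(paste(popmap$samples, popmap$populations), path)
  invisible(path)
}

#' Check that a population map covers an alignment exactly
#'
#' @param locus an \code{\link{aligned_locus}}.
#' @param popmap a \code{\link{population_map}}.
#' @return \code{TRUE}, invisibly; otherwise an error naming the first
#'   uncovered or extraneous sample.
#' @export
validate_popmap <- function(locus, popmap) {
  miss <- setdiff(locus$samples, popmap$samples)
  if (length(miss))
    stop(sprintf("sample '%s' in alignment but not in population map", miss[1L]))
  extra <- setdiff(popmap$samples, locus$samples)
  if (length(extra))
    stop(sprintf("sample '%s' in population map but not in alignment", extra[1L]))
  invisible(TRUE)
}

#' Read an ultrametric guide tree
#'
#' Reads a newick tree whose branch lengths are in expected substitutions
#' per site, verifies ultrametricity, and records node heights (distance
#' from the tips).
#'
#' @param path newick file path.
#' @param tol ultrametricity tolerance on tip-height spread.
#' @return An object of class \code{"guide_tree"}: the \code{ape} phylo
#'   object plus per-node heights.
#' @export
read_guide_tree <- function(path, tol = 1e-8) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop(sprintf("could not parse newick in %s", path))
  guide_tree(phy, tol = tol)
}

#' @rdname read_guide_tree
#' @param phy an \code{ape} \code{phylo} object with branch lengths.
#' @export
guide_tree <- function(phy, tol = 1e-8) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("guide tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("guide tree has negative branch lengths")
  depths <- ape::node.depth.edgelength(phy)  # distance from root
  tipd <- depths[seq_len(ape::Ntip(phy))]
  if (diff(range(tipd)) > tol)
    stop(sprintf(
      "guide tree is not ultrametric: tip heights span %.3g (tolerance %.1g)",
      diff(range(tipd)), tol))
  heights <- max(tipd) - depths
  heights[seq_len(ape::Ntip(phy))] <- 0
  structure(list(phylo = phy, heights = heights,
                 tips = phy$tip.label),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat(sprintf("Guide tree: %d tips (%s), root height %.4g subst/site\n",
              length(x$tips), paste(x$tips, collapse = ", "),
              x$heights[ape::Ntip(x$phylo) + 1L]))
  invisible(x)
}

#' Height of the most recent common ancestor of two populations
#'
#' @param tree a \code{\link{guide_tree}}.
#' @param a,b tip (population) labels.
#' @return MRCA node height in expected substitutions per site.
#' @export
mrca_height <- function(tree, a, b) {
  stopifnot(inherits(tree, "guide_tree"))
  for (lab in c(a, b))
    if (!lab %in% tree$tips)
      stop(sprintf("population '%s' not found in guide tree", lab))
  if (a == b) return(0)
  node <- ape::getMRCA(tree$phylo, c(a, b))
  tree$heights[node]
}

fmt_pm <- function(mean, sd) sprintf("%.2f ± %.2f", mean, sd)

#' Write the per-pair evidence report
#'
#' Writes a tab-separated table with one row per candidate pair: the
#' between-population divergence range, the split-model posterior
#' probability and its support band, gdi mean and SD for both directions,
#' and the gdi classification(s).
#'
#' @param results a list of pair summaries as produced by
#'   \code{\link{run_pipeline}} (each with elements \code{pair},
#'   \code{divergence}, \code{pp_split}, \code{band}, \code{gdi_a},
#'   \code{gdi_b}, \code{verdict}).
#' @param path output file path.
#' @return The report \code{data.frame}, invisibly.
#' @export
write_pair_report <- function(results, path) {
  if (!length(results)) stop("no pair results to report")
  rows <- lapply(results, function(r) {
    data.frame(
      pair = paste(r$pair, collapse = " | "),
      divergence = sprintf("%.1f–%.1f%%", r$divergence[1L], r$divergence[2L]),
      pp_split = sprintf("%.2f", r$pp_split),
      support = r$band,
      gdi_a = fmt_pm(r$gdi_a$mean, r$gdi_a$sd),
      gdi_b = fmt_pm(r$gdi_b$mean, r$gdi_b$sd),
      classification_a = r$gdi_a$classification,
      classification_b = r$gdi_b$classification,
      verdict = r$verdict,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out)
}
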
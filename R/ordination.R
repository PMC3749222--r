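#' Pairwise individual-by-individual Y-STR distances
#'
#' Genetic distance between two multi-locus haplotypes over a set of
#' single-copy loci.  The default metric is the microsatellite convention of
#' summed squared repeat-count differences,
#' \eqn{d(i,j) = \sum_l (a_{il} - a_{jl})^2}; `metric = "mismatch"` counts
#' differing loci instead.  Fractional (partial-repeat) alleles are used
#' numerically — subtraction is still well defined — so micro-variant
#' carriers need not be excluded here.  Samples with a duplicated allele or
#' missing data at any of the loci cannot be scored and raise an error
#' naming the sample and locus; exclude them first.
#'
#' @param x a [str_profiles()] object, complete at `loci`.
#' @param loci locus names to use; defaults to the catalogue's single-copy
#'   loci (the 33-locus set with the default panel).
#' @param metric `"squared"` (default) or `"mismatch"`.
#' @return a symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames, and the metric recorded in attribute `"metric"`.
#' @export
str_distances <- function(x, loci = single_copy_loci(profile_catalog(x)),
                          metric = c("squared", "mismatch")) {
  stopifnot(inherits(x, "str_profiles"))
  metric <- match.arg(metric)
  n <- nrow(x)
  a <- matrix(NA_real_, n, length(loci), dimnames = list(x$sample_id, loci))
  for (l in loci) {
    vals <- allele_values(x, l)
    for (i in seq_along(vals)) {
      v <- vals[[i]]
      if (length(v) == 0)
        stop("sample ", x$sample_id[i], " is missing locus ", l)
      if (length(v) > 1)
        stop("sample ", x$sample_id[i], " has a duplicated allele at ", l)
      a[i, l] <- v
    }
  }
  d <- matrix(0, n, n, dimnames = list(x$sample_id, x$sample_id))
  for (l in seq_len(ncol(a))) {
    dl <- outer(a[, l], a[, l], "-")
    d <- d + if (metric == "squared") dl^2 else (dl != 0) + 0
  }
  attr(d, "metric") <- metric
  d
}

#' Principal coordinates analysis
#'
#' Classical metric multidimensional scaling by Gower double-centering.  The
#' input `d` is treated as a matrix of *squared* distances (consistent with
#' the squared-repeat-difference metric of [str_distances()]): the centered
#' matrix \eqn{-\tfrac12 J d J} is eigendecomposed and coordinates are the
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Negative eigenvalues, which arise when `d` is not Euclidean-embeddable,
#' are reported, not silently dropped; explained-variance percentages are
#' computed over the positive eigenvalues and sum to 100.
#'
#' Axes are deterministic up to sign; the sign is fixed so each axis's
#' largest-magnitude coordinate is positive.
#'
#' @param d symmetric matrix of squared distances (zero diagonal), e.g. from
#'   [str_distances()].
#' @param axes number of coordinate axes to return (default 2).
#' @return an object of class `pcoa_result`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending), `pct_variance`
#'   (per returned axis, % of positive-eigenvalue total) and
#'   `negative_eigenvalues` (count and most negative value).
#' @export
str_pcoa <- function(d, axes = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n == ncol(d), axes >= 1)
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0) || any(d < 0))
    stop("d must be a symmetric nonnegative matrix with zero diagonal")
  if (all(d == 0)) {
    warning("all distances are zero; coordinates are all zero")
    coords <- matrix(0, n, axes, dimnames = list(rownames(d),
                                                 paste0("Axis", seq_len(axes))))
    return(structure(list(coordinates = coords,
                          eigenvalues = rep(0, n),
                          pct_variance = rep(NA_real_, axes),
                          negative_eigenvalues = list(count = 0L, min = 0)),
                     class = "pcoa_result"))
  }
  # Gower double-centering of -d/2 (d already on the squared scale)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev) * 1e-12)
  k <- min(axes, length(pos))
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k)
  # sign convention: largest-magnitude coordinate positive on each axis
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  if (k < axes)
    coords <- cbind(coords, matrix(0, n, axes - k))
  dimnames(coords) <- list(rownames(d), paste0("Axis", seq_len(axes)))
  pct <- rep(NA_real_, axes)
  pct[seq_len(k)] <- 100 * ev[pos[seq_len(k)]] / sum(ev[pos])
  structure(list(
    coordinates = coords,
    eigenvalues = ev,
    pct_variance = pct,
    negative_eigenvalues = list(count = sum(ev < -max(abs(ev)) * 1e-12),
                                min = min(ev))
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", ncol(x$coordinates),
      "axes\n")
  cat("  % variance (positive eigenvalues):",
      paste(sprintf("%.1f", x$pct_variance), collapse = ", "), "\n")
  if (x$negative_eigenvalues$count > 0)
    cat("  negative eigenvalues:", x$negative_eigenvalues$count,
        "(min", format(x$negative_eigenvalues$min), ")\n")
  invisible(x)
}

#' Write PCoA coordinates as TSV
#'
#' @param x a [str_pcoa()] result.
#' @param path output path.
#' @param groups optional data frame of per-sample labels (same order) to
#'   append, e.g. population and haplogroup, for plotting.
#' @return `path`, invisibly.
#' @export
write_pcoa <- function(x, path, groups = NULL) {
  out <- data.frame(sample_id = rownames(x$coordinates), x$coordinates,
                    check.names = FALSE)
  if (!is.null(groups)) out <- cbind(out, groups)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
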
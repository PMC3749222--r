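#' Haplotype diversity (unbiased gene diversity)
#'
#' Nei's unbiased gene diversity on haplotype frequencies,
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}, the probability that
#' two haplotypes sampled without replacement differ.  Computed on minimal
#' haplotypes; h is 0 iff the sample is monomorphic and exactly 1 iff all
#' haplotypes are distinct.
#'
#' @param haplotypes a `minht` matrix ([to_minht()] / [as_minht()]).
#' @return `h` in `[0, 1]`.
#' @export
haplotype_diversity <- function(haplotypes) {
  n <- nrow(haplotypes)
  if (is.null(n) || n < 2) stop("haplotype diversity needs n >= 2")
  counts <- haplotype_counts(haplotypes)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

# multiplicity of each distinct haplotype
haplotype_counts <- function(haplotypes) {
  key <- apply(haplotypes, 1L, paste, collapse = "|")
  as.integer(table(key))
}

#' Per-locus repeat-number variance
#'
#' Sample variance (n - 1 denominator) of the repeat count at each locus,
#' and their unweighted mean V over the loci — the microsatellite variance
#' statistic used to contrast lineage diversity between regions.
#'
#' @param haplotypes a `minht` matrix.
#' @return a list with `per_locus` (named vector) and `V` (mean variance, in
#'   squared repeat units).
#' @export
repeat_variance <- function(haplotypes) {
  if (nrow(haplotypes) < 2) stop("repeat variance needs n >= 2")
  per_locus <- apply(haplotypes, 2L, stats::var)
  list(per_locus = per_locus, V = mean(per_locus))
}

#' Number of shared haplotypes
#'
#' Count of distinct haplotypes observed in two or more samples.
#'
#' @param haplotypes a `minht` matrix (zero rows allowed).
#' @return a non-negative integer.
#' @export
shared_haplotype_count <- function(haplotypes) {
  if (is.null(nrow(haplotypes)) || nrow(haplotypes) == 0) return(0L)
  sum(haplotype_counts(haplotypes) >= 2)
}

#' Diversity summary for a haplotype set
#'
#' Bundles sample size, distinct-haplotype count, haplotype diversity,
#' mean repeat variance and shared-haplotype count for one group.
#'
#' @param haplotypes a `minht` matrix with `n >= 2`.
#' @return a one-row data frame with columns `n`, `k`, `h`, `V`, `shared`.
#' @export
diversity_summary <- function(haplotypes) {
  counts <- haplotype_counts(haplotypes)
  data.frame(
    n = nrow(haplotypes),
    k = length(counts),
    h = haplotype_diversity(haplotypes),
    V = repeat_variance(haplotypes)$V,
    shared = shared_haplotype_count(haplotypes)
  )
}
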
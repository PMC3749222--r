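#' Locus catalogues for Y-STR panels
#'
#' A locus catalogue declares the Y-STR loci a dataset may contain, which of
#' them are duplicated (multi-copy) systems, and the ordered locus set of the
#' forensic minimal haplotype (minHt).  All readers, filters and analyses
#' consult the catalogue rather than hard-coding locus names.
#'
#' The minHt here is the seven single-copy loci DYS19, DYS389I, DYS389B,
#' DYS390, DYS391, DYS392, DYS393; the duplicated DYS385a/b system is
#' disregarded.  DYS389B is a derived locus: when a table carries DYS389I and
#' DYS389II instead, DYS389B is computed as DYS389II - DYS389I.
#'
#' @param loci character vector of single-copy locus names.
#' @param multi_copy character vector of duplicated-locus names.
#' @param minht_loci ordered character vector of minimal-haplotype loci; must
#'   all be single-copy.
#'
#' @return An object of class `locus_catalog`: a list with elements `loci`,
#'   `multi_copy` and `minht_loci`.
#' @examples
#' cat37 <- default_catalog()
#' cat37$minht_loci
#' @export
locus_catalog <- function(loci,
                          multi_copy = character(),
                          minht_loci = minht_locus_names()) {
  loci <- as.character(loci)
  multi_copy <- as.character(multi_copy)
  minht_loci <- as.character(minht_loci)
  if (anyDuplicated(c(loci, multi_copy)))
    stop("duplicated locus names in catalog")
  if (any(minht_loci %in% multi_copy))
    stop("minimal-haplotype loci must be single-copy")
  missing_min <- setdiff(minht_loci, c(loci, "DYS389B"))
  # DYS389B may be derived from DYS389I/II rather than listed directly
  if (length(missing_min) > 0 &&
      !all(missing_min == "DYS389B" | missing_min %in% loci))
    stop("minht loci absent from catalog: ",
         paste(missing_min, collapse = ", "))
  structure(
    list(loci = loci, multi_copy = multi_copy, minht_loci = minht_loci),
    class = "locus_catalog"
  )
}

#' @rdname locus_catalog
#' @export
minht_locus_names <- function() {
  c("DYS19", "DYS389I", "DYS389B", "DYS390", "DYS391", "DYS392", "DYS393")
}

#' @rdname locus_catalog
#' @details `default_catalog()` returns the 37-locus panel used by the large
#'   genealogical Y-STR surveys: 33 single-copy loci (including the minHt
#'   set, with DYS389B derivable from DYS389I/II) plus the four duplicated
#'   systems YCAIIa/b, DYS385a/b, DYS459 and DYS464.
#' @export
default_catalog <- function() {
  single <- c(
    "DYS19", "DYS388", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
    "DYS393", "DYS426", "DYS437", "DYS438", "DYS439", "DYS441", "DYS442",
    "DYS444", "DYS445", "DYS446", "DYS447", "DYS448", "DYS449", "DYS450",
    "DYS452", "DYS454", "DYS455", "DYS456", "DYS458", "DYS460", "DYS461",
    "DYS462", "DYS463", "GGAAT1B07", "YGATAA10", "YGATAH4"
  )
  locus_catalog(
    loci = single,
    multi_copy = c("YCAII", "DYS385", "DYS459", "DYS464")
  )
}

#' @export
print.locus_catalog <- function(x, ...) {
  cat("Y-STR locus catalog\n")
  cat("  single-copy loci:", length(x$loci), "\n")
  cat("  duplicated systems:",
      if (length(x$multi_copy)) paste(x$multi_copy, collapse = ", ")
      else "none", "\n")
  cat("  minimal haplotype:", paste(x$minht_loci, collapse = ", "), "\n")
  invisible(x)
}

#' Single-copy loci usable for distance analyses
#'
#' The single-copy locus set of a catalogue, i.e. all loci except the
#' duplicated systems.  With the default 37-locus panel this is the 33-locus
#' set used for individual-by-individual distances.
#'
#' @param catalog a [locus_catalog()].
#' @return character vector of locus names.
#' @export
single_copy_loci <- function(catalog) {
  stopifnot(inherits(catalog, "locus_catalog"))
  catalog$loci
}
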
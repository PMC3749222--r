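#' Y-STR profile tables
#'
#' A `str_profiles` object is a data frame with one row per sampled male and
#' the columns `sample_id`, `population`, `region`, `haplogroup` followed by
#' one character column per locus of its catalogue.  Allele cells hold repeat
#' counts; a duplicated system or an anomalous extra copy at a single-copy
#' locus is stored comma-joined (`"19,23"`), and a partial-repeat
#' micro-variant keeps its decimal notation (`"13.2"`) exactly as given.
#' Empty cells are missing data.
#'
#' @param x a data frame with the columns described above.
#' @param catalog the [locus_catalog()] the table conforms to.
#' @return `str_profiles()` returns a validated `str_profiles` object with
#'   the catalogue attached as attribute `"catalog"`.
#' @export
str_profiles <- function(x, catalog) {
  stopifnot(is.data.frame(x), inherits(catalog, "locus_catalog"))
  meta <- c("sample_id", "population", "region", "haplogroup")
  for (m in meta) if (is.null(x[[m]])) x[[m]] <- rep("", nrow(x))
  known <- c(catalog$loci, catalog$multi_copy, "DYS389B")
  locus_cols <- intersect(names(x), known)
  x <- x[, c(meta, locus_cols), drop = FALSE]
  for (l in locus_cols) x[[l]] <- as.character(x[[l]])
  x$sample_id <- as.character(x$sample_id)
  rownames(x) <- NULL
  structure(x, catalog = catalog, class = c("str_profiles", "data.frame"))
}

#' @rdname str_profiles
#' @export
profile_catalog <- function(x) attr(x, "catalog")

#' @rdname str_profiles
#' @export
profile_loci <- function(x) {
  meta <- c("sample_id", "population", "region", "haplogroup")
  setdiff(names(x), meta)
}

#' @export
print.str_profiles <- function(x, ...) {
  cat("str_profiles:", nrow(x), "samples,", length(profile_loci(x)),
      "locus columns\n")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# parse one allele cell into a numeric vector (possibly length > 1);
# NULL signals an unparseable cell
parse_alleles <- function(cell) {
  cell <- trimws(as.character(cell))
  if (is.na(cell) || cell == "" || cell == "NA") return(numeric(0))
  parts <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals)) return(NULL)
  vals
}

#' Allele values of a locus column
#'
#' @param x a [str_profiles()] object.
#' @param locus locus name.
#' @return a list (one element per sample) of numeric allele vectors; empty
#'   vector where the cell is missing.
#' @export
allele_values <- function(x, locus) {
  if (!locus %in% names(x)) stop("unknown locus: ", locus)
  lapply(x[[locus]], parse_alleles)
}

#' Read a tab-delimited Y-STR haplotype table
#'
#' Reads a header-driven, tab-delimited, UTF-8 table with one row per sample.
#' Duplicated systems may come as two suffixed columns (`DYS385a`, `DYS385b`)
#' which are merged comma-joined, or as one comma-joined column.  If the
#' table carries `DYS389I` and `DYS389II` but no `DYS389B`, the derived
#' `DYS389B = DYS389II - DYS389I` column is added.  Rows whose alleles are
#' unparseable, zero or negative are dropped and reported in the `"errors"`
#' attribute (columns `row`, `column`, `message`).
#'
#' @param path file path.
#' @param catalog a [locus_catalog()].
#' @return a [str_profiles()] object; `attr(, "errors")` holds the row-level
#'   error records (zero-row data frame when the file is clean).
#' @export
read_str_table <- function(path, catalog = default_catalog()) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (!"sample_id" %in% names(raw))
    stop("missing required column: sample_id")

  # merge suffixed duplicated-locus columns into comma-joined single columns
  for (mc in catalog$multi_copy) {
    suff <- paste0(mc, c("a", "b", "c", "d"))
    have <- intersect(suff, names(raw))
    if (length(have) > 0 && !mc %in% names(raw)) {
      vals <- do.call(cbind, lapply(have, function(cn) raw[[cn]]))
      raw[[mc]] <- apply(vals, 1L, function(v) {
        v <- trimws(v)
        paste(v[v != "" & !is.na(v)], collapse = ",")
      })
      raw <- raw[, setdiff(names(raw), have), drop = FALSE]
    }
  }

  prof <- str_profiles(raw, catalog)

  errors <- data.frame(row = integer(), column = character(),
                       message = character(), stringsAsFactors = FALSE)
  bad_rows <- logical(nrow(prof))
  for (l in profile_loci(prof)) {
    for (i in seq_len(nrow(prof))) {
      v <- parse_alleles(prof[[l]][i])
      if (is.null(v)) {
        errors <- rbind(errors, data.frame(
          row = i, column = l,
          message = paste0("unparseable allele '", prof[[l]][i], "'")))
        bad_rows[i] <- TRUE
      } else if (length(v) > 0 && any(v <= 0)) {
        errors <- rbind(errors, data.frame(
          row = i, column = l, message = "allele value must be > 0"))
        bad_rows[i] <- TRUE
      }
    }
  }

  # derived DYS389B when only DYS389I/II are given
  if (!"DYS389B" %in% names(prof) &&
      all(c("DYS389I", "DYS389II") %in% names(prof))) {
    b <- rep("", nrow(prof))
    for (i in seq_len(nrow(prof))) {
      v1 <- parse_alleles(prof$DYS389I[i]); v2 <- parse_alleles(prof$DYS389II[i])
      if (!is.null(v1) && !is.null(v2) &&
          length(v1) == 1 && length(v2) == 1)
        b[i] <- format(v2 - v1, trim = TRUE)
    }
    prof$DYS389B <- b
  }

  out <- str_profiles(as.data.frame(prof)[!bad_rows, , drop = FALSE], catalog)
  attr(out, "errors") <- errors
  out
}

#' Write a Y-STR haplotype table
#'
#' Writes the tab-delimited dialect [read_str_table()] reads: duplicated
#' systems comma-joined in one column, micro-variants in decimal notation.
#' A write/read round trip reproduces alleles, flags and labels exactly.
#'
#' @param x a [str_profiles()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_str_table <- function(x, path) {
  stopifnot(inherits(x, "str_profiles"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# per-sample anomaly scan over the given loci; returns a data frame of
# (index, sample_id, locus, reason) records, possibly zero rows
scan_atypical <- function(x, loci) {
  cat <- profile_catalog(x)
  unknown <- setdiff(loci, names(x))
  if (length(unknown) > 0)
    stop("unknown locus name(s): ", paste(unknown, collapse = ", "))
  rec <- list()
  for (l in loci) {
    vals <- allele_values(x, l)
    single <- !(l %in% cat$multi_copy)
    for (i in seq_along(vals)) {
      v <- vals[[i]]
      if (length(v) == 0) next
      if (single && length(v) > 1)
        rec[[length(rec) + 1L]] <- data.frame(
          index = i, sample_id = x$sample_id[i], locus = l,
          reason = "duplicated locus")
      if (any(v %% 1 != 0))
        rec[[length(rec) + 1L]] <- data.frame(
          index = i, sample_id = x$sample_id[i], locus = l,
          reason = "micro-variant")
    }
  }
  if (length(rec) == 0)
    return(data.frame(index = integer(), sample_id = character(),
                      locus = character(), reason = character()))
  do.call(rbind, rec)
}

#' Exclude samples with atypical alleles
#'
#' Partitions a profile table into samples clean at the given loci and
#' samples carrying an atypical allele there: a second allele at a
#' single-copy locus (duplication) or a fractional partial-repeat allele
#' (micro-variant).  Such samples are excluded from diversity, network and
#' dating analyses.  The operation is idempotent and preserves row order.
#'
#' @param x a [str_profiles()] object.
#' @param loci the locus set the downstream analysis will use; defaults to
#'   the catalogue's minimal-haplotype loci.
#' @return a list with elements `kept` and `excluded` (both `str_profiles`,
#'   together a partition of the input) and `report`, a data frame with one
#'   row per (sample, locus, reason) exclusion record.
#' @export
filter_atypical <- function(x, loci = profile_catalog(x)$minht_loci) {
  stopifnot(inherits(x, "str_profiles"))
  rep <- scan_atypical(x, loci)
  bad <- sort(unique(rep$index))
  keep <- setdiff(seq_len(nrow(x)), bad)
  cat <- profile_catalog(x)
  list(
    kept = str_profiles(as.data.frame(x)[keep, , drop = FALSE], cat),
    excluded = str_profiles(as.data.frame(x)[bad, , drop = FALSE], cat),
    report = rep[, c("sample_id", "locus", "reason")]
  )
}

#' Project profiles onto the minimal haplotype
#'
#' Extracts the ordered 7-locus minimal haplotype (integer repeat counts)
#' from each profile.  Profiles must be complete and integer-valued at the
#' minHt loci; filter with [filter_atypical()] first.
#'
#' @param x a [str_profiles()] object.
#' @param catalog a [locus_catalog()]; defaults to the table's own.
#' @return an integer matrix of class `minht`, one row per sample (rownames =
#'   sample ids), columns in minHt locus order.
#' @export
to_minht <- function(x, catalog = profile_catalog(x)) {
  stopifnot(inherits(x, "str_profiles"))
  loci <- catalog$minht_loci
  m <- matrix(NA_integer_, nrow(x), length(loci),
              dimnames = list(x$sample_id, loci))
  for (l in loci) {
    if (!l %in% names(x)) stop("profile table is missing locus ", l)
    vals <- allele_values(x, l)
    for (i in seq_along(vals)) {
      v <- vals[[i]]
      if (length(v) == 0)
        stop("sample ", x$sample_id[i], " is missing locus ", l)
      if (length(v) > 1)
        stop("sample ", x$sample_id[i], " has a duplicated allele at ", l,
             "; exclude atypical samples first")
      if (v %% 1 != 0)
        stop("sample ", x$sample_id[i], " has a micro-variant at ", l,
             "; exclude atypical samples first")
      m[i, l] <- as.integer(v)
    }
  }
  structure(m, class = c("minht", "matrix", "array"))
}

#' Construct a minimal-haplotype matrix directly
#'
#' @param m an integer matrix (samples x loci); column names default to the
#'   minHt locus names.
#' @return an integer matrix of class `minht`.
#' @export
as_minht <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (is.null(colnames(m)) && ncol(m) == 7) colnames(m) <- minht_locus_names()
  if (any(!is.finite(m)) || any(m <= 0))
    stop("minimal haplotypes must be positive integers")
  structure(m, class = c("minht", "matrix", "array"))
}
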
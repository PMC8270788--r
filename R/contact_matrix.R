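#' Construct a contact matrix
#'
#' A `contact_matrix` stores the cis contacts of one chromosome as
#' triplets `(i, j, value)` with 0-based bin indices and `i <= j`; the
#' implied dense matrix is symmetric.  Duplicate pixels are summed and
#' `(j, i)` entries are folded into `(i, j)`.
#'
#' @param bins a [bin_table()].
#' @param i,j 0-based bin indices.
#' @param value non-negative counts or normalized intensities.
#' @param tag normalization tag, one of `"raw"`, `"VC"`, `"VC_SQRT"`,
#'   `"balanced"` (an `"_oe"` suffix marks observed/expected values).
#' @return an object of class `contact_matrix`: a list with elements
#'   `bins`, `entries` (data.frame `i`, `j`, `value`), `tag`, and
#'   optionally `norm` (the [compute_normalization()] vector applied).
#' @export
contact_matrix <- function(bins, i = integer(), j = integer(),
                           value = numeric(), tag = "raw") {
  stopifnot(inherits(bins, "bin_table"),
            length(i) == length(j), length(j) == length(value))
  n <- nrow(bins)
  if (length(i)) {
    if (any(i < 0L) || any(j < 0L) || any(i >= n) || any(j >= n))
      stop("bin index out of range of the bin table")
    if (any(value < 0)) stop("contact values must be non-negative")
    ## fold lower triangle and sum duplicates
    ii <- pmin(i, j); jj <- pmax(i, j)
    key <- ii * n + jj
    agg <- rowsum(value, key)
    key <- as.numeric(rownames(agg))
    entries <- data.frame(i = as.integer(key %/% n),
                          j = as.integer(key %% n),
                          value = as.numeric(agg))
    entries <- entries[entries$value != 0, , drop = FALSE]
    entries <- entries[order(entries$i, entries$j), , drop = FALSE]
    rownames(entries) <- NULL
  } else {
    entries <- data.frame(i = integer(), j = integer(), value = numeric())
  }
  structure(list(bins = bins, entries = entries, tag = tag, norm = NULL),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins @ %d bp, %d pixels, tag=%s\n",
              x$bins$chrom[1], n_bins(x), bin_size(x),
              nrow(x$entries), x$tag))
  invisible(x)
}

#' Read a contact matrix from triplet text
#'
#' The triplet dialect is three tab- (or whitespace-) separated columns
#' `bin_i`, `bin_j`, `value` with 0-based `bin_id` indices against the
#' supplied bin table; header lines starting with `#` are ignored.
#' `(j, i)` entries are folded into `(i, j)` and duplicates summed.
#'
#' @param path triplet text file.
#' @param bins a [bin_table()].
#' @return a raw-tagged `contact_matrix`.
#' @examples
#' bt <- bin_table("chrS", 5e4, 1e4)
#' f <- tempfile()
#' writeLines(c("0\t1\t5", "1\t0\t3"), f)
#' cm <- read_contact_matrix(f, bt)
#' cm$entries  # single pixel (0,1) with value 8
#' @export
read_contact_matrix <- function(path, bins) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(contact_matrix(bins))
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("line %d: expected at least 3 columns", bad[1]))
  i <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  j <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(i) | is.na(j) | is.na(v))
  if (length(bad)) stop(sprintf("line %d: non-numeric field", bad[1]))
  n <- nrow(bins)
  bad <- which(i < 0 | j < 0 | i >= n | j >= n)
  if (length(bad))
    stop(sprintf("line %d: bin index out of range (%g, %g) for %d bins",
                 bad[1], i[bad[1]], j[bad[1]], n))
  bad <- which(v < 0)
  if (length(bad))
    stop(sprintf("line %d: negative count %g", bad[1], v[bad[1]]))
  contact_matrix(bins, as.integer(i), as.integer(j), v)
}

#' Write a contact matrix as triplet text
#'
#' Writes the upper-triangle triplets (`i <= j`, 0-based) in row-major
#' order so that read/write round-trips are byte-identical.
#'
#' @param cm a `contact_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path) {
  e <- cm$entries
  utils::write.table(data.frame(e$i, e$j, format(e$value, trim = TRUE,
                                                 scientific = FALSE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Dense symmetric matrix from a contact matrix
#'
#' @param cm a `contact_matrix`.
#' @param na_missing if `TRUE`, rows/columns of bins masked by an
#'   attached normalization vector are set to `NA`.
#' @return an `n x n` numeric matrix.
#' @export
as_dense <- function(cm, na_missing = FALSE) {
  n <- n_bins(cm)
  m <- matrix(0, n, n)
  e <- cm$entries
  if (nrow(e)) {
    m[cbind(e$i + 1L, e$j + 1L)] <- e$value
    m[cbind(e$j + 1L, e$i + 1L)] <- e$value
  }
  if (na_missing) {
    miss <- which(missing_bins(cm))
    if (length(miss)) {
      m[miss, ] <- NA_real_
      m[, miss] <- NA_real_
    }
  }
  m
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Sums raw counts over `factor x factor` blocks of bins, the standard
#' rebinning used to trade resolution for per-pixel depth (e.g. TAD
#' calling at 10 kb, compartment calling at a multiple of it).
#'
#' @param cm a raw `contact_matrix`.
#' @param factor integer number of bins to pool.
#' @return a `contact_matrix` on the coarser grid.
#' @export
coarsen_matrix <- function(cm, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(cm)
  bt <- cm$bins
  bt2 <- bin_table(bt$chrom[1], max(bt$end), bin_size(cm) * factor)
  e <- cm$entries
  contact_matrix(bt2, e$i %/% factor, e$j %/% factor, e$value, tag = cm$tag)
}

#' Logical mask of missing (unnormalizable) bins
#'
#' Bins masked by the attached normalization vector; all-`FALSE` when no
#' vector is attached.
#' @param cm a `contact_matrix`.
#' @return logical vector of length `n_bins(cm)`.
#' @export
missing_bins <- function(cm) {
  if (is.null(cm$norm)) rep(FALSE, n_bins(cm)) else is.na(cm$norm$weights)
}
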
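#' Build a bin table for a single chromosome
#'
#' A bin table tiles a chromosome into fixed-width, 0-based half-open
#' genomic bins.  It is the coordinate system shared by every contact
#' matrix, signal track and domain set in this package.  `bin_id` is a
#' consecutive 0-based integer index; the last bin may be shorter than
#' `bin_size` when the chromosome length is not a multiple of it.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in base pairs.
#' @param bin_size bin width in base pairs.
#' @return a `data.frame` of class `bin_table` with columns `chrom`,
#'   `start`, `end`, `bin_id` and attribute `bin_size`.
#' @examples
#' bt <- bin_table("chr1", 1e6, 1e4)
#' nrow(bt)  # 100 bins
#' @export
bin_table <- function(chrom, chrom_length, bin_size) {
  stopifnot(length(chrom) == 1L, chrom_length > 0, bin_size > 0)
  starts <- seq(0L, chrom_length - 1L, by = bin_size)
  bt <- data.frame(
    chrom = chrom,
    start = as.integer(starts),
    end = as.integer(pmin(starts + bin_size, chrom_length)),
    bin_id = seq_along(starts) - 1L
  )
  attr(bt, "bin_size") <- as.integer(bin_size)
  class(bt) <- c("bin_table", "data.frame")
  bt
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf(
    "bin_table: %s, %d bins of %d bp (%d-%d)\n",
    x$chrom[1], nrow(x), bin_size(x), min(x$start), max(x$end)
  ))
  invisible(x)
}

#' Bin size of a bin table or contact matrix
#' @param x a `bin_table` or `contact_matrix`.
#' @return bin width in base pairs.
#' @export
bin_size <- function(x) {
  if (inherits(x, "contact_matrix")) x <- x$bins
  attr(x, "bin_size")
}

#' Number of bins
#' @param x a `bin_table` or `contact_matrix`.
#' @return integer bin count.
#' @export
n_bins <- function(x) {
  if (inherits(x, "contact_matrix")) x <- x$bins
  nrow(x)
}

#' Read a bin table from a tab-separated file
#'
#' Expects four columns (chrom, start, end, bin_id); lines starting with
#' `#` are ignored.  The file must describe a single chromosome tiled
#' without gaps.
#'
#' @param path file path.
#' @return a `bin_table`.
#' @export
read_bin_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#",
                          col.names = c("chrom", "start", "end", "bin_id"),
                          colClasses = c("character", "integer", "integer", "integer"))
  if (length(unique(df$chrom)) != 1L)
    stop("bin table must describe a single chromosome")
  if (any(diff(df$bin_id) != 1L))
    stop("bin_id must be consecutive")
  if (any(df$start[-1] != df$end[-nrow(df)]))
    stop("bins must tile the chromosome without gaps or overlaps")
  attr(df, "bin_size") <- as.integer(df$end[1] - df$start[1])
  class(df) <- c("bin_table", "data.frame")
  df
}

#' Write a bin table
#' @param bt a `bin_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bin_table <- function(bt, path) {
  utils::write.table(as.data.frame(bt)[, c("chrom", "start", "end", "bin_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## 1-based bin index range of a bp interval [start, end) on the grid
.bp_to_bins <- function(start, end, bin_size) {
  list(first = as.integer(start %/% bin_size) + 1L,
       last = as.integer((end - 1L) %/% bin_size) + 1L)
}
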
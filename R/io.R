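#' Write a per-bin track as bedGraph
#'
#' @param bt a [bin_table()].
#' @param values numeric per-bin values; `NA` bins are skipped.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bt, values, path) {
  stopifnot(length(values) == nrow(bt))
  keep <- !is.na(values)
  utils::write.table(data.frame(bt$chrom, bt$start, bt$end,
                                values)[keep, ],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph onto a bin grid
#'
#' Values are placed on the bins whose start matches; bins without a
#' record become `NA`.
#'
#' @param path bedGraph file.
#' @param bt a [bin_table()].
#' @return numeric per-bin vector.
#' @export
read_bedgraph <- function(path, bt) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#")
  out <- rep(NA_real_, nrow(bt))
  idx <- match(df[[2]], bt$start)
  ok <- !is.na(idx) & df[[1]] == bt$chrom[1]
  out[idx[ok]] <- as.numeric(df[[4]][ok])
  out
}

#' Read a BED-like domain file into a domain set
#'
#' Requires columns 1-3 (chrom, start, end); column 4, when present, is
#' taken as the source/caller label.
#'
#' @param path BED file.
#' @param bin_size bp per bin of the grid the domains live on.
#' @param source default source label when column 4 is absent.
#' @return a [domain_set()].
#' @export
read_domains_bed <- function(path, bin_size, source = "bed") {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#")
  domain_set(data.frame(chrom = as.character(df[[1]]),
                        start = as.integer(df[[2]]),
                        end = as.integer(df[[3]]),
                        source = if (ncol(df) >= 4) as.character(df[[4]])
                                 else source),
             bin_size)
}

#' Write a domain set as BED
#'
#' Columns: chrom, start, end, source, score (diamond score scaled
#' 0-1000 when present, else 0), strand ("."), full-precision diamond
#' score, plus any of `loop_domain` / `cluster` present.
#'
#' @param ds a [domain_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domains_bed <- function(ds, path) {
  df <- as.data.frame(ds)
  if (!nrow(df)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  diam <- if ("diamond" %in% names(df)) df$diamond else rep(NA_real_, nrow(df))
  out <- data.frame(df$chrom, df$start, df$end,
                    if ("source" %in% names(df)) df$source else ".",
                    ifelse(is.na(diam), 0L, as.integer(round(diam * 1000))),
                    ".",
                    ifelse(is.na(diam), ".", format(diam, digits = 10)))
  for (col in c("loop_domain", "cluster"))
    if (col %in% names(df)) out[[col]] <- df[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read loops from BEDPE
#'
#' Columns 1-6 (chrom1, start1, end1, chrom2, start2, end2) required;
#' column 7, when numeric, becomes `strength`.
#'
#' @param path BEDPE file.
#' @return a loops data.frame (`chrom`, `start1`, `end1`, `start2`,
#'   `end2`, `strength`).
#' @export
read_loops_bedpe <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#")
  if (any(df[[1]] != df[[4]]))
    stop("only cis (same-chromosome) loops are supported")
  data.frame(chrom = as.character(df[[1]]),
             start1 = as.integer(df[[2]]), end1 = as.integer(df[[3]]),
             start2 = as.integer(df[[5]]), end2 = as.integer(df[[6]]),
             strength = if (ncol(df) >= 7)
               suppressWarnings(as.numeric(df[[7]])) else NA_real_)
}

#' Write loops as BEDPE
#' @param loops a loops data.frame (see [read_loops_bedpe()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loops_bedpe <- function(loops, path) {
  utils::write.table(data.frame(loops$chrom, loops$start1, loops$end1,
                                loops$chrom, loops$start2, loops$end2,
                                loops$strength),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
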
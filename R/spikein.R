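#' Spike-in scale factor
#'
#' The library scale factor of a spiked library is estimated by the
#' ratio of reads mapped to the target genome over reads mapped to the
#' spike-in genome, `S = N_target / N_spike`.
#'
#' @param n_target reads mapped to the target genome (>= 0).
#' @param n_spike reads mapped to the spike-in genome (> 0).
#' @return the scale factor `S`.
#' @examples
#' spike_scale_factor(2e6, 1e6)  # 2
#' @export
spike_scale_factor <- function(n_target, n_spike) {
  stopifnot(n_target >= 0, n_spike >= 0)
  if (n_spike == 0) stop("scale factor undefined: no spike-in reads")
  n_target / n_spike
}

#' Scale a signal track by a spike-in factor
#'
#' Divides every value by `S`, so deeper target libraries are scaled
#' down and libraries with equal true enrichment become comparable.
#'
#' @param track numeric signal values.
#' @param S scale factor (> 0), from [spike_scale_factor()].
#' @return the scaled track.
#' @export
scale_track <- function(track, S) {
  stopifnot(S > 0)
  track / S
}

#' Read spike-in counts from a two-genome TSV
#'
#' Expects three tab-separated columns: library, genome
#' (`target`/`spike`), reads.  Returns one scale factor per library.
#'
#' @param path TSV file.
#' @return data.frame with `library`, `n_target`, `n_spike`, `S`.
#' @export
read_spike_counts <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("library", "genome", "reads"),
                          comment.char = "#")
  libs <- unique(df$library)
  out <- do.call(rbind, lapply(libs, function(l) {
    nt <- sum(df$reads[df$library == l & df$genome == "target"])
    ns <- sum(df$reads[df$library == l & df$genome == "spike"])
    data.frame(library = l, n_target = nt, n_spike = ns,
               S = if (ns > 0) nt / ns else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
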
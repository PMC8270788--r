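#' Filter candidate loops by distance and vanilla-coverage signal
#'
#' Keeps loops whose anchor midpoint separation is at most
#' `max_distance` and whose vanilla-coverage-normalized contact values
#' in the pixel box spanned by a `+/- neighborhood` bp window at both
#' anchors satisfy the floor: spurious calls in sparse areas have
#' near-zero normalized signal around the peak pixel.  `stat = "min"`
#' (default) requires every pixel of the box to pass, the strictest
#' reading of "surrounding values < 1 are removed"; `stat = "mean"` is
#' the lenient alternative for fine resolutions where Poisson zeros
#' populate larger boxes.
#'
#' @param loops a loops data.frame ([read_loops_bedpe()] layout).
#' @param vc_cm a VC-normalized `contact_matrix` (produced by
#'   [apply_normalization()] with a `"VC"` vector) at the loop
#'   resolution.
#' @param max_distance maximum anchor separation in bp (default 2 Mb).
#' @param vc_floor minimum normalized value (default 1).
#' @param neighborhood half-width of the anchor window in bp (default
#'   5 kb).
#' @param stat `"min"` or `"mean"` over the pixel box.
#' @return the filtered loops data.frame, with a `removed` attribute
#'   giving per-loop reasons.
#' @export
filter_loops <- function(loops, vc_cm, max_distance = 2e6, vc_floor = 1,
                         neighborhood = 5000, stat = c("min", "mean")) {
  stat <- match.arg(stat)
  if (is.null(vc_cm$norm) || vc_cm$norm$method != "VC")
    stop("vc_cm must carry a VC normalization vector")
  bs <- bin_size(vc_cm)
  n <- n_bins(vc_cm)
  m <- as_dense(vc_cm, na_missing = TRUE)
  if (!nrow(loops)) {
    attr(loops, "removed") <- character()
    return(loops)
  }
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  window_bins <- function(mid) {
    first <- max(0L, as.integer((mid - neighborhood) %/% bs))
    last <- min(n - 1L, as.integer((mid + neighborhood - 1L) %/% bs))
    (first:last) + 1L
  }
  box_stat <- vapply(seq_len(nrow(loops)), function(k) {
    vals <- m[window_bins(mid1[k]), window_bins(mid2[k])]
    if (all(is.na(vals))) return(NA_real_)
    if (stat == "min") min(vals, na.rm = TRUE) else mean(vals, na.rm = TRUE)
  }, numeric(1))
  reason <- rep(NA_character_, nrow(loops))
  reason[mid2 - mid1 > max_distance] <- "distance"
  low <- is.na(box_stat) | box_stat < vc_floor
  reason[low & is.na(reason)] <- "low_coverage"
  out <- loops[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- reason[!is.na(reason)]
  out
}

#' Annotate loop domains
#'
#' A domain is a loop domain when some loop has its first anchor
#' midpoint within `tol` of the domain's 5' border and its second
#' anchor midpoint within `tol` of the 3' border, with
#' `tol = min(50 kb, 0.2 * domain length)`; all other domains are
#' ordinary.  Deterministic and independent of loop order.
#'
#' @param ds a [domain_set()].
#' @param loops a (filtered) loops data.frame.
#' @param tol_bp absolute tolerance cap in bp (default 50 kb).
#' @param tol_frac fractional tolerance (default 0.2 of domain length).
#' @return the [domain_set()] with a logical `loop_domain` column.
#' @export
annotate_loop_domains <- function(ds, loops, tol_bp = 50000,
                                  tol_frac = 0.2) {
  df <- as.data.frame(ds)
  if (!nrow(df)) {
    df$loop_domain <- logical(0)
    return(domain_set(df, attr(ds, "bin_size")))
  }
  flag <- rep(FALSE, nrow(df))
  if (!is.null(loops) && nrow(loops)) {
    mid1 <- (loops$start1 + loops$end1) / 2
    mid2 <- (loops$start2 + loops$end2) / 2
    for (k in seq_len(nrow(df))) {
      tol <- min(tol_bp, tol_frac * (df$end[k] - df$start[k]))
      flag[k] <- any(loops$chrom == df$chrom[k] &
                       abs(mid1 - df$start[k]) <= tol &
                       abs(mid2 - df$end[k]) <= tol)
    }
  }
  df$loop_domain <- flag
  out <- domain_set(df, attr(ds, "bin_size"))
  attr(out, "removed") <- attr(ds, "removed")
  out
}
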
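#' Directionality-index vectors at domain borders
#'
#' One row per domain: the DI values of the `2 * flank_bins` bins
#' centred on the 5' border followed by the same around the 3' border
#' (`4 * flank_bins` columns).  Domains with any required bin outside
#' the defined DI range are masked out (row of zeros, `mask = TRUE`).
#'
#' @param ds a [domain_set()].
#' @param di a [directionality_index()] track on the same grid.
#' @param flank_bins bins on each side of a border (default 5, i.e. 20
#'   columns).
#' @return a `border_di_matrix`: numeric matrix with attributes `mask`
#'   (logical, `TRUE` = masked row) and `flank_bins`; row order follows
#'   the domain set.
#' @export
border_di_vectors <- function(ds, di, flank_bins = 5L) {
  if (flank_bins < 1L) stop("flank_bins must be >= 1")
  df <- as.data.frame(ds)
  bs <- attr(ds, "bin_size")
  v <- as.numeric(di)
  n <- length(v)
  ncol_out <- 4L * flank_bins
  X <- matrix(0, nrow(df), ncol_out)
  mask <- rep(FALSE, nrow(df))
  offs <- c(-flank_bins:-1L, 0L:(flank_bins - 1L))
  for (k in seq_len(nrow(df))) {
    b5 <- df$start[k] %/% bs   # 0-based border position
    b3 <- df$end[k] %/% bs
    idx <- c(b5 + offs, b3 + offs) + 1L
    if (any(idx < 1L | idx > n) || any(is.na(v[idx]))) {
      mask[k] <- TRUE
      next
    }
    X[k, ] <- v[idx]
  }
  structure(X, mask = mask, flank_bins = as.integer(flank_bins),
            class = c("border_di_matrix", "matrix", "array"))
}

#' k-means clustering of borders into asymmetry classes
#'
#' Lloyd's algorithm on the raw border DI vectors (Euclidean distance,
#' best of `n_restarts` by total within-cluster sum of squares).  With
#' `k = 3` clusters are relabeled canonically: cluster 1 has the
#' 5'-dominant centroid (largest mean |DI| excess at the 5' border
#' columns), cluster 3 the 3'-dominant one, cluster 2 the remainder,
#' mirroring the convention that clusters 1/3 are the one-sided
#' classes.  Masked rows get label `NA`.
#'
#' @param X a [border_di_vectors()] matrix.
#' @param k number of clusters (default 3).
#' @param seed integer seed.
#' @param n_restarts random restarts (default 100; Lloyd's algorithm on
#'   a dozen points in 20 dimensions traps easily, and restarts are
#'   cheap at this scale).
#' @return a `cluster_assignment` list: `labels` (per domain, `NA` for
#'   masked), `centroids`, `withinss`, `degenerate`, `seed`.
#' @export
kmeans_border_clusters <- function(X, k = 3L, seed = 1L, n_restarts = 100L) {
  mask <- attr(X, "mask")
  if (is.null(mask)) mask <- rep(FALSE, nrow(X))
  f <- attr(X, "flank_bins")
  if (is.null(f)) f <- ncol(X) %/% 4L
  rows <- which(!mask)
  if (length(rows) < k) stop("fewer unmasked rows than clusters")
  Xu <- X[rows, , drop = FALSE]
  labels <- rep(NA_integer_, nrow(X))
  if (nrow(unique(Xu)) < k) {
    labels[rows] <- 2L
    return(structure(list(labels = labels, centroids = NULL,
                          withinss = 0, degenerate = TRUE, seed = seed),
                     class = "cluster_assignment"))
  }
  set.seed(seed)
  km <- stats::kmeans(Xu, centers = k, nstart = n_restarts,
                      algorithm = "Lloyd", iter.max = 200L)
  cl <- km$cluster
  cent <- km$centers
  if (k == 3L) {
    ## centroid asymmetry judged on the border-proximal inside bins,
    ## where one-sided extrusion shows; outside bins mostly carry
    ## neighbor/background signal
    i5 <- f + seq_len(f); i3 <- 2L * f + seq_len(f)
    asym <- rowMeans(abs(cent[, i5, drop = FALSE])) -
      rowMeans(abs(cent[, i3, drop = FALSE]))
    ord <- order(asym, decreasing = TRUE)   # 5'-dominant, middle, 3'-dominant
    relabel <- integer(3L)
    relabel[ord] <- 1:3
    cl <- relabel[cl]
    cent <- cent[ord, , drop = FALSE]
  }
  labels[rows] <- cl
  structure(list(labels = labels, centroids = cent,
                 withinss = km$tot.withinss, degenerate = FALSE,
                 seed = seed),
            class = "cluster_assignment")
}

#' DI bias of a domain
#'
#' `log2(|mean DI of the 3 bins just inside the 5' border| / |mean DI
#' of the 3 bins just inside the 3' border|)`: positive when the 5'
#' border dominates.  `NA` (with the reason recorded) when any window
#' bin has undefined DI or either mean is 0.
#'
#' @param start,end domain coordinates in bp on the bin grid.
#' @param di a [directionality_index()] track.
#' @param bin_size bp per bin.
#' @param window bins per window (default 3).
#' @param inset fractional offset of the windows into the domain
#'   (default 0 = flush with the borders; e.g. 0.25 measures interior
#'   DI bias with the same formula).
#' @return a single numeric value or `NA`.
#' @export
di_bias <- function(start, end, di, bin_size, window = 3L, inset = 0) {
  v <- as.numeric(di)
  b5 <- start %/% bin_size
  b3 <- end %/% bin_size
  L <- b3 - b5
  sh <- as.integer(round(inset * L))
  w5 <- (b5 + sh) + seq_len(window)            # right of the 5' border
  w3 <- (b3 - sh) - seq_len(window) + 1L       # left of the 3' border
  if (any(w5 < 1L | w5 > length(v)) || any(w3 < 1L | w3 > length(v)))
    return(NA_real_)
  m5 <- mean(v[w5]); m3 <- mean(v[w3])
  if (is.na(m5) || is.na(m3) || m5 == 0 || m3 == 0) return(NA_real_)
  log2(abs(m5 / m3))
}

#' Split cluster-2 domains into equal subclusters by DI bias
#'
#' Members are ranked by signed DI bias (descending, i.e. most
#' 5'-dominant first; ties broken by domain start) and split into
#' `n_sub` contiguous rank groups whose sizes differ by at most one.
#'
#' @param di_bias_values per-member DI-bias values.
#' @param starts per-member domain start coordinates (tie-break).
#' @param n_sub number of subclusters (default 5).
#' @return integer subcluster labels (1 = most 5'-dominant group) in
#'   the input order.
#' @export
subcluster_by_di_strength <- function(di_bias_values, starts, n_sub = 5L) {
  n <- length(di_bias_values)
  if (n < n_sub) stop("fewer members than subclusters")
  ord <- order(-di_bias_values, starts)
  sizes <- rep(n %/% n_sub, n_sub)
  extra <- n %% n_sub
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- integer(n)
  labels[ord] <- rep(seq_len(n_sub), sizes)
  labels
}

#' Signal profiles across grouped borders
#'
#' Mean and standard error of a per-bin track at each offset in
#' `[-flank_bins, +flank_bins]` around a set of borders, separately per
#' group and border side.
#'
#' @param track numeric per-bin signal.
#' @param borders data.frame with `bin` (0-based border position),
#'   `side` (`"5p"`/`"3p"`), and `group` labels.
#' @param flank_bins profile half-width (default 5).
#' @return data.frame with `group`, `side`, `offset`, `mean`, `sem`,
#'   `n`.
#' @export
profile_signal_over_borders <- function(track, borders, flank_bins = 5L) {
  stopifnot(all(c("bin", "side", "group") %in% names(borders)))
  if (!nrow(borders)) {
    warning("empty border table: empty profile")
    return(data.frame(group = character(), side = character(),
                      offset = integer(), mean = numeric(),
                      sem = numeric(), n = integer()))
  }
  offs <- -flank_bins:flank_bins
  res <- list()
  for (g in unique(borders$group)) {
    for (sd_ in unique(borders$side)) {
      bb <- borders$bin[borders$group == g & borders$side == sd_]
      if (!length(bb)) next
      for (o in offs) {
        idx <- bb + o + 1L
        vals <- track[idx[idx >= 1L & idx <= length(track)]]
        res[[length(res) + 1L]] <- data.frame(
          group = g, side = sd_, offset = o,
          mean = mean(vals),
          sem = if (length(vals) > 1L)
            stats::sd(vals) / sqrt(length(vals)) else NA_real_,
          n = length(vals))
      }
    }
  }
  do.call(rbind, res)
}
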
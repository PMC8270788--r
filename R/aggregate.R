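## area-weighted resampling matrix: grid rows x window bins, each row
## the overlap fractions of one grid cell with the (continuous,
## 0-based) bin interval [w0, w1); rows sum to 1 over in-range bins
.resample_weights <- function(w0, w1, grid, n) {
  cellw <- (w1 - w0) / grid
  k0 <- floor(w0)
  k1 <- ceiling(w1) - 1
  bins <- k0:k1
  W <- matrix(0, grid, length(bins))
  for (g in seq_len(grid)) {
    lo <- w0 + (g - 1) * cellw
    hi <- w0 + g * cellw
    ov <- pmin(hi, bins + 1) - pmax(lo, bins)
    W[g, ] <- pmax(ov, 0) / cellw
  }
  inside <- bins >= 0 & bins <= n - 1
  list(W = W[, inside, drop = FALSE], bins = bins[inside] + 1L)
}

#' Rescaled aggregate-TAD map
#'
#' Each domain's window (the domain plus `flank_fraction` of its length
#' on both sides) is resampled to a `grid x grid` square by
#' area-weighted averaging, the squares are averaged element-wise over
#' domains (missing pixels excluded), and the result is divided by its
#' grand mean, so a featureless matrix aggregates to all ones and
#' corner-interacting borders show up as > 1 corner pixels.
#'
#' @param cm a normalized `contact_matrix`.
#' @param ds a non-empty [domain_set()].
#' @param grid output grid size (default 90; with the default flank the
#'   domain occupies the central third, cells 31-60).
#' @param flank_fraction flank length as a fraction of domain length
#'   (default 0.5).
#' @return an `aggregate_map`: `grid x grid` matrix with attributes
#'   `n_domains` and `normalization_tag`.
#' @export
aggregate_domains <- function(cm, ds, grid = 90L, flank_fraction = 0.5) {
  df <- as.data.frame(ds)
  if (!nrow(df)) stop("empty domain set")
  bs <- bin_size(cm)
  n <- n_bins(cm)
  m <- as_dense(cm, na_missing = TRUE)
  acc <- matrix(0, grid, grid)
  cnt <- matrix(0, grid, grid)
  for (k in seq_len(nrow(df))) {
    a <- df$start[k] / bs; b <- df$end[k] / bs   # continuous bin coords
    L <- b - a
    rw <- .resample_weights(a - flank_fraction * L, b + flank_fraction * L,
                            grid, n)
    sub <- m[rw$bins, rw$bins, drop = FALSE]
    ok <- is.finite(sub)
    sub0 <- sub; sub0[!ok] <- 0
    num <- rw$W %*% sub0 %*% t(rw$W)
    den <- rw$W %*% (ok + 0) %*% t(rw$W)
    ## den also accounts for window parts off the chromosome edge
    full <- rowSums(rw$W)
    den_full <- outer(full, full)
    val <- ifelse(den > 1e-12, num / den, NA)
    use <- den > 1e-12 & den_full > 1e-12
    acc[use] <- acc[use] + val[use]
    cnt[use] <- cnt[use] + 1
  }
  out <- ifelse(cnt > 0, acc / cnt, NA)
  gm <- mean(out, na.rm = TRUE)
  if (is.finite(gm) && gm > 0) out <- out / gm
  structure(out, n_domains = nrow(df), normalization_tag = cm$tag,
            class = c("aggregate_map", "matrix", "array"))
}

#' Condition-versus-reference ratio of aggregate maps
#'
#' Element-wise `map_a / map_b`; pixels with a zero or missing
#' denominator become `NA`, never infinity.
#'
#' @param map_a,map_b [aggregate_domains()] maps on the same grid.
#' @return a ratio matrix of the same dimensions.
#' @export
ratio_aggregate <- function(map_a, map_b) {
  if (!all(dim(map_a) == dim(map_b))) stop("grid mismatch")
  out <- ifelse(!is.na(map_b) & map_b != 0, map_a / map_b, NA)
  structure(out, class = c("aggregate_map", "matrix", "array"))
}

#' Aggregate a condition matrix on a reference (control) domain set
#'
#' For knockdown-style comparisons the aggregation windows come from
#' the control condition's domain calls, so the condition and control
#' maps are computed over identical genomic windows and their ratio
#' isolates the change in contact structure.
#'
#' @param condition_cm the condition's normalized `contact_matrix`.
#' @param control_ds the control [domain_set()].
#' @inheritParams aggregate_domains
#' @return an `aggregate_map`.
#' @export
aggregate_on_reference_set <- function(condition_cm, control_ds,
                                       grid = 90L, flank_fraction = 0.5) {
  aggregate_domains(condition_cm, control_ds, grid = grid,
                    flank_fraction = flank_fraction)
}

#' PCA of per-stage tracks
#'
#' Standard principal component analysis (centred, unscaled) of a
#' stage-by-bin matrix of DI or compartment scores, after masking out
#' bins undefined in any stage.
#'
#' @param tracks named list of numeric per-bin vectors (>= 2) on a
#'   common grid.
#' @return list with `coordinates` (stages x components), `explained`
#'   (variance fractions, summing to 1 when total variance > 0) and
#'   `n_bins_used`.
#' @export
pca_tracks <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  len <- unique(lengths(tracks))
  if (length(len) != 1L) stop("tracks differ in length")
  X <- do.call(rbind, tracks)
  keep <- colSums(is.na(X)) == 0L
  X <- X[, keep, drop = FALSE]
  if (!ncol(X)) stop("no bin is defined in every track")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  expl <- if (sum(v) > 0) v / sum(v) else rep(NA_real_, length(v))
  list(coordinates = pc$x, explained = expl, n_bins_used = ncol(X))
}
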
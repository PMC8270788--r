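#' Directionality index
#'
#' For each bin, `A` is the total contact with the `block_bins`
#' upstream bins and `B` with the `block_bins` downstream bins; the
#' directionality index is the signed chi-square-like statistic
#' `sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)` with `E = (A + B) / 2`.
#' It is 0 where `A == B`, and `NA` where `A + B == 0` or a full flank
#' does not fit on the chromosome.
#'
#' @param cm a normalized cis `contact_matrix`.
#' @param block_bins flank size in bins (default 40, i.e. 400 kb at
#'   10-kb resolution).
#' @return a `di_track`: numeric per-bin vector with attribute
#'   `block_bins`.
#' @export
directionality_index <- function(cm, block_bins = 40L) {
  if (block_bins < 1L) stop("block_bins must be >= 1")
  n <- n_bins(cm)
  m <- as_dense(cm)
  di <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    if (b - block_bins < 1L || b + block_bins > n) next
    A <- sum(m[b, (b - block_bins):(b - 1L)])
    B <- sum(m[b, (b + 1L):(b + block_bins)])
    if (A + B == 0) next
    E <- (A + B) / 2
    di[b] <- sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  structure(di, block_bins = as.integer(block_bins), class = "di_track")
}

#' Insulation score
#'
#' The raw score of bin `b` is the mean contact in the `block_bins x
#' block_bins` square spanning the `block_bins` bins upstream of `b`
#' against the `block_bins` bins from `b` downstream; the reported
#' value is `log2(raw / chromosome mean raw)`, so local minima mark
#' insulating boundaries and the track is invariant to global scaling.
#' Bins within `block_bins` of either chromosome edge are `NA`.
#'
#' @inheritParams directionality_index
#' @return an `insulation_track`: numeric per-bin vector with
#'   attributes `block_bins` and `raw` (the unnormalized diamond
#'   means).
#' @export
insulation_score <- function(cm, block_bins = 40L) {
  if (block_bins < 1L) stop("block_bins must be >= 1")
  n <- n_bins(cm)
  if (n < 2L * block_bins) {
    warning("chromosome shorter than 2 * block_bins: all values missing")
    return(structure(rep(NA_real_, n), block_bins = as.integer(block_bins),
                     raw = rep(NA_real_, n), class = "insulation_track"))
  }
  m <- as_dense(cm)
  raw <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    if (b - block_bins < 1L || b + block_bins - 1L > n) next
    raw[b] <- mean(m[(b - block_bins):(b - 1L), b:(b + block_bins - 1L)])
  }
  mu <- mean(raw, na.rm = TRUE)
  val <- if (mu > 0) log2(raw / mu) else rep(NA_real_, n)
  structure(val, block_bins = as.integer(block_bins), raw = raw,
            class = "insulation_track")
}

## 1-based inclusive bin span of a domain (start/end in bp)
.domain_bins <- function(start, end, bs) {
  c(first = as.integer(start %/% bs) + 1L, last = as.integer(end %/% bs))
}

#' Diamond score of a domain
#'
#' Measures domain strength as `middle / (upstream + middle)` where
#' `middle` is the contact sum of the full intra-domain square and
#' `upstream` the sum of the rectangle between the domain and an
#' upstream flank of equal length (0.5 on a featureless matrix, ->1 for
#' a strongly enriched domain).  Flanks truncated by the chromosome
#' edge are rescaled by full-area/available-area; if less than 25% of
#' the upstream flank is available the downstream flank is used
#' instead, and if that is also unavailable the domain is unscorable
#' (`NA`).
#'
#' @param cm a `contact_matrix` (raw or normalized).
#' @param start,end domain coordinates in bp (0-based half-open, on the
#'   bin grid).
#' @param variant `"upstream"` (the default, ratio over upstream flank
#'   + middle) or `"symmetric"` (`middle / (up + down + middle)`).
#' @return a `diamond_score` list: `value`, `middle`, `upstream`,
#'   `downstream`, `flank_used`, `start`, `end`.
#' @export
diamond_score <- function(cm, start, end,
                          variant = c("upstream", "symmetric")) {
  variant <- match.arg(variant)
  bs <- bin_size(cm)
  n <- n_bins(cm)
  sp <- .domain_bins(start, end, bs)
  a <- sp[["first"]]; b <- sp[["last"]]
  if (a < 1L || b > n || b < a) stop("domain does not lie on the matrix")
  L <- b - a + 1L
  m <- as_dense(cm)
  middle <- sum(m[a:b, a:b])
  flank_sum <- function(lo, hi) {
    lo2 <- max(lo, 1L); hi2 <- min(hi, n)
    avail <- hi2 - lo2 + 1L
    if (avail < 1L) return(c(sum = NA_real_, avail = 0))
    s <- sum(m[lo2:hi2, a:b])
    c(sum = s * (L / avail), avail = avail)   # area-ratio correction
  }
  up <- flank_sum(a - L, a - 1L)
  dn <- flank_sum(b + 1L, b + L)
  value <- NA_real_; flank_used <- NA_character_
  if (variant == "symmetric") {
    if (up[["avail"]] >= 0.25 * L && dn[["avail"]] >= 0.25 * L) {
      den <- up[["sum"]] + dn[["sum"]] + middle
      if (den > 0) { value <- middle / den; flank_used <- "both" }
    }
  } else {
    if (up[["avail"]] >= 0.25 * L) {
      den <- up[["sum"]] + middle
      if (den > 0) { value <- middle / den; flank_used <- "upstream" }
    } else if (dn[["avail"]] >= 0.25 * L) {
      den <- dn[["sum"]] + middle
      if (den > 0) { value <- middle / den; flank_used <- "downstream" }
    }
  }
  structure(list(value = value, middle = middle,
                 upstream = unname(up[["sum"]]),
                 downstream = unname(dn[["sum"]]),
                 flank_used = flank_used, start = start, end = end),
            class = "diamond_score")
}

## vectorized diamond-score values for a domain set
.diamond_values <- function(cm, ds, variant = "upstream") {
  df <- as.data.frame(ds)
  vapply(seq_len(nrow(df)), function(k)
    diamond_score(cm, df$start[k], df$end[k], variant = variant)$value,
    numeric(1))
}

## arrowhead transform values for pixel vectors (1-based i < j);
## NA outside range or when the denominator is 0
.arrowhead_T <- function(m, i, j) {
  n <- nrow(m)
  up_col <- 2L * i - j
  ok <- up_col >= 1L & j <= n & i >= 1L
  out <- rep(NA_real_, length(i))
  if (any(ok)) {
    up <- m[cbind(i[ok], up_col[ok])]
    dn <- m[cbind(i[ok], j[ok])]
    den <- up + dn
    out[ok] <- ifelse(den > 0, (up - dn) / den, NA_real_)
  }
  out
}

## pixels past the 3' border whose upstream mirror is intra-domain
## (T > 0 over a real corner) and the intra-domain control triangle
.corner_sets <- function(a, b, h) {
  C <- do.call(rbind, lapply(seq_len(h), function(k) {
    j <- b + k
    i0 <- as.integer(ceiling((a + j) / 2))
    if (i0 > b) return(NULL)
    cbind(i = i0:b, j = j)
  }))
  F <- do.call(rbind, lapply(seq_len(h), function(k) {
    j <- b - k + 1L
    i0 <- as.integer(ceiling((a + j) / 2))
    i1 <- j - 1L
    if (i0 > i1) return(NULL)
    cbind(i = i0:i1, j = j)
  }))
  list(C = C, F = F)
}

#' Arrowhead-style corner score of a domain
#'
#' From the arrowhead transform
#' `T[i, i+d] = (M[i, i-d] - M[i, i+d]) / (M[i, i-d] + M[i, i+d])`,
#' the score contrasts the mean of `T` over the triangle of pixels just
#' outside each border whose mirror pixel is intra-domain (positive at
#' a true corner) against the mean over the equal-height triangle just
#' inside the border (near zero); the two borders' contrasts are
#' averaged.  The triangle height is `min(domain length - 1, cap)`.
#' Higher means more corner-like; a featureless matrix scores 0.
#'
#' @inheritParams diamond_score
#' @param cap maximum triangle height in bins (default 20).
#' @return a single numeric value, `NA` when the corner lies within the
#'   triangle height of a chromosome edge.
#' @export
arrowhead_corner_score <- function(cm, start, end, cap = 20L) {
  bs <- bin_size(cm)
  n <- n_bins(cm)
  sp <- .domain_bins(start, end, bs)
  a <- sp[["first"]]; b <- sp[["last"]]
  L <- b - a + 1L
  h <- min(L - 1L, as.integer(cap))
  if (h < 1L || b + h > n || a - h < 1L) return(NA_real_)
  m <- as_dense(cm)
  one_side <- function(mm, aa, bb) {
    st <- .corner_sets(aa, bb, h)
    tc <- .arrowhead_T(mm, st$C[, "i"], st$C[, "j"])
    tf <- .arrowhead_T(mm, st$F[, "i"], st$F[, "j"])
    if (all(is.na(tc)) || all(is.na(tf))) return(NA_real_)
    mean(tc, na.rm = TRUE) - mean(tf, na.rm = TRUE)
  }
  s3 <- one_side(m, a, b)
  ## 5' border scored on the coordinate-reversed matrix
  mr <- m[n:1, n:1]
  s5 <- one_side(mr, n - b + 1L, n - a + 1L)
  mean(c(s3, s5), na.rm = FALSE)
}
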
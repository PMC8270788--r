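#' Construct a domain set
#'
#' The package's central record: an ordered per-chromosome collection
#' of candidate TADs with optional diamond score, source label(s),
#' loop-domain flag and cluster label.  Coordinates are 0-based
#' half-open bp on the bin grid; nested domains are permitted, exact
#' duplicates are not.
#'
#' @param df data.frame with at least `chrom`, `start`, `end`;
#'   optional `source`, `diamond`, `loop_domain`, `cluster`.
#' @param bin_size bp per bin of the underlying grid.
#' @return a `domain_set` (a sorted data.frame with attribute
#'   `bin_size`).
#' @export
domain_set <- function(df, bin_size) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df)) {
    if (any(df$end - df$start < bin_size))
      stop("domains must span at least one bin")
    if (any(df$start %% bin_size != 0) || any(df$end %% bin_size != 0))
      stop("domain coordinates must lie on the bin grid")
    df <- df[order(df$start, df$end), , drop = FALSE]
    if (anyDuplicated(df[, c("chrom", "start", "end")]))
      stop("identical duplicate domains are forbidden")
  }
  if (!"source" %in% names(df)) df$source <- rep("unknown", nrow(df))
  rownames(df) <- NULL
  attr(df, "bin_size") <- as.integer(bin_size)
  class(df) <- c("domain_set", "data.frame")
  df
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("domain_set: %d domains @ %d bp bins\n", nrow(x),
              attr(x, "bin_size")))
  if (nrow(x)) print(utils::head(as.data.frame(x)))
  invisible(x)
}

.ds_granges <- function(ds) {
  df <- as.data.frame(ds)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Call domains from insulation minima
#'
#' A deliberately simple internal caller used to make the pipeline
#' self-contained: borders are local minima of the insulation track
#' with topographic prominence at least `min_depth` (log2 units);
#' domains are the intervals between consecutive borders of length at
#' least `min_size_bins`.
#'
#' @param insulation an [insulation_score()] track.
#' @param bt the [bin_table()] the track was computed on.
#' @param min_depth minimum prominence of a minimum (default 0.2, calibrated on the default fixture so compartment-scale insulation wobble does not split large domains).
#' @param min_size_bins minimum domain length in bins (default 2).
#' @param source source label for the resulting set.
#' @return a [domain_set()]; empty (with a warning) when no minima
#'   qualify.
#' @export
call_domains_insulation <- function(insulation, bt, min_depth = 0.2,
                                    min_size_bins = 2L,
                                    source = "insulation") {
  bs <- attr(bt, "bin_size")
  v <- as.numeric(insulation)
  borders <- .prominent_minima(v, min_depth)
  if (length(borders) < 2L) {
    warning("fewer than two qualifying insulation minima: empty domain set")
    return(domain_set(data.frame(chrom = character(), start = integer(),
                                 end = integer(), source = character()),
                      bs))
  }
  st <- borders[-length(borders)] - 1L   # 0-based bin position
  en <- borders[-1] - 1L
  keep <- en - st >= min_size_bins
  domain_set(data.frame(chrom = bt$chrom[1], start = st[keep] * bs,
                        end = en[keep] * bs,
                        source = source), bs)
}

## local minima of v with prominence >= depth; returns 1-based indices
.prominent_minima <- function(v, depth) {
  n <- length(v)
  idx <- which(!is.na(v))
  if (length(idx) < 3L) return(integer())
  x <- v[idx]
  cand <- which(diff(sign(diff(x))) > 0) + 1L
  ## treat flat minima: keep leftmost bin of a tie plateau
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    c0 <- cand[k]
    ## climb left/right to the nearest strictly lower point or track end
    lmax <- -Inf
    i <- c0 - 1L
    while (i >= 1L) {
      if (x[i] < x[c0]) break
      lmax <- max(lmax, x[i]); i <- i - 1L
    }
    if (i < 1L) lmax <- max(lmax, max(x[seq_len(c0 - 1L)]))
    rmax <- -Inf
    i <- c0 + 1L
    while (i <= length(x)) {
      if (x[i] < x[c0]) break
      rmax <- max(rmax, x[i]); i <- i + 1L
    }
    if (i > length(x)) rmax <- max(rmax, max(x[c0:length(x)]))
    keep[k] <- min(lmax, rmax) - x[c0] >= depth
  }
  idx[cand[keep]]
}

#' Merge candidate domain sets and align their borders
#'
#' Takes the union of all domains, clusters boundary bins greedily
#' left-to-right (a border joins the current group when within
#' `window_bins`, inclusive, of the group's last member), replaces each
#' group by its member with the lowest insulation score (leftmost on
#' ties), rewrites all domains onto the merged boundaries, and
#' collapses exact duplicates with source labels concatenated.
#' Idempotent: merging a merged set with itself returns it unchanged.
#'
#' @param sets list of [domain_set()] objects on the same bin grid.
#' @param insulation the [insulation_score()] track used to pick group
#'   representatives.
#' @param window_bins merge window (default 4).
#' @return a merged [domain_set()].
#' @export
merge_domain_sets <- function(sets, insulation, window_bins = 4L) {
  if (inherits(sets, "domain_set")) sets <- list(sets)
  bs <- unique(vapply(sets, function(s) attr(s, "bin_size"), integer(1)))
  if (length(bs) != 1L) stop("domain sets are on different bin grids")
  all_df <- do.call(rbind, lapply(sets, as.data.frame))
  if (!nrow(all_df)) return(domain_set(all_df, bs))
  b_start <- all_df$start %/% bs
  b_end <- all_df$end %/% bs
  borders <- sort(unique(c(b_start, b_end)))
  ## greedy left-to-right chaining
  grp <- integer(length(borders))
  g <- 1L
  grp[1] <- g
  for (k in seq_along(borders)[-1]) {
    if (borders[k] - borders[k - 1L] > window_bins) g <- g + 1L
    grp[k] <- g
  }
  ins <- as.numeric(insulation)
  rep_of <- vapply(split(borders, grp), function(bb) {
    vals <- ins[bb + 1L]
    vals[is.na(vals)] <- Inf
    bb[which.min(vals)]   # which.min takes the leftmost on ties
  }, numeric(1))
  remap_start <- rep_of[grp[match(b_start, borders)]]
  remap_end <- rep_of[grp[match(b_end, borders)]]
  keep <- remap_end > remap_start
  out <- data.frame(chrom = all_df$chrom[keep],
                    start = as.integer(remap_start[keep] * bs),
                    end = as.integer(remap_end[keep] * bs),
                    source = all_df$source[keep])
  ## collapse duplicates, concatenating sources
  key <- paste(out$chrom, out$start, out$end)
  src <- vapply(split(out$source, key), function(s)
    paste(sort(unique(unlist(strsplit(s, ",")))), collapse = ","), "")
  out <- out[!duplicated(key), , drop = FALSE]
  out$source <- src[paste(out$chrom, out$start, out$end)]
  domain_set(out, bs)
}

#' Filter domains by diamond score and size
#'
#' Retains domains with diamond score at least `ds_min` and size at
#' least `min_size` bp; unscorable domains are removed.  Removal
#' reasons are logged in the `removed` attribute of the result.
#'
#' @param ds a [domain_set()].
#' @param cm the `contact_matrix` used for diamond scoring.
#' @param ds_min minimum diamond score (default 0.6).
#' @param min_size minimum size in bp (default 100 kb).
#' @return the filtered [domain_set()] with a `diamond` column and a
#'   `removed` attribute (data.frame `chrom`, `start`, `end`,
#'   `reason`).
#' @export
filter_domains <- function(ds, cm, ds_min = 0.6, min_size = 100000) {
  df <- as.data.frame(ds)
  bs <- attr(ds, "bin_size")
  if (!nrow(df)) {
    out <- domain_set(df, bs)
    attr(out, "removed") <- data.frame(chrom = character(),
                                       start = integer(), end = integer(),
                                       reason = character())
    return(out)
  }
  diam <- .diamond_values(cm, ds)
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(diam)] <- "unscorable"
  reason[!is.na(diam) & diam < ds_min] <- "diamond_score"
  small <- df$end - df$start < min_size
  reason[small & is.na(reason)] <- "size"
  reason[small & !is.na(reason) & reason == "diamond_score"] <-
    "diamond_score;size"
  keep <- is.na(reason)
  df$diamond <- diam
  out <- domain_set(df[keep, , drop = FALSE], bs)
  attr(out, "removed") <-
    data.frame(chrom = df$chrom[!keep], start = df$start[!keep],
               end = df$end[!keep], reason = reason[!keep])
  out
}

#' Exclude domains in low contact-density areas
#'
#' Removes domains whose mean intra-domain contact density falls
#' strictly below the `floor_quantile` quantile of all candidate
#' domains' densities.  Density is measured relative to the
#' distance-decay expectation (mean observed/expected inside the
#' domain), so large domains are not penalized for the decay of their
#' long-range pixels and the floor catches genuinely sparse or masked
#' areas.
#'
#' @param ds a [domain_set()].
#' @param cm the raw `contact_matrix`.
#' @param floor_quantile quantile floor (default 0.05; 0 disables).
#' @return the filtered [domain_set()].
#' @export
low_density_filter <- function(ds, cm, floor_quantile = 0.05) {
  df <- as.data.frame(ds)
  if (!nrow(df)) return(ds)
  bs <- attr(ds, "bin_size")
  m <- as_dense(observed_over_expected(cm))
  dens <- vapply(seq_len(nrow(df)), function(k) {
    sp <- .domain_bins(df$start[k], df$end[k], bs)
    mean(m[sp[["first"]]:sp[["last"]], sp[["first"]]:sp[["last"]]])
  }, numeric(1))
  thr <- stats::quantile(dens, floor_quantile, names = FALSE)
  out <- domain_set(df[dens >= thr, , drop = FALSE], bs)
  attr(out, "removed") <- attr(ds, "removed")
  out
}

#' Compare two domain sets by reciprocal overlap
#'
#' A pair matches when the overlap covers at least `min_fraction` of
#' both domains (the `bedtools intersect -f X -r` rule).
#'
#' @param a,b [domain_set()] objects on the same genome.
#' @param min_fraction reciprocal overlap fraction (0.9 for same-domain
#'   judgement, 0.7 for cross-experiment comparison).
#' @return list with `matched` (matched pair count), `n_a`, `n_b`,
#'   `unique_a`, `unique_b`, and `jaccard` (mean intersection/union of
#'   matched pairs, `NA` when none).
#' @export
compare_domain_sets <- function(a, b, min_fraction = 0.9) {
  ga <- .ds_granges(a); gb <- .ds_granges(b)
  if (!length(ga) || !length(gb)) {
    return(list(matched = 0L, n_a = length(ga), n_b = length(gb),
                unique_a = length(ga), unique_b = length(gb),
                jaccard = NA_real_))
  }
  hits <- GenomicRanges::findOverlaps(ga, gb)
  qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(ga)[qa],
                                           IRanges::ranges(gb)[qb]))
  wa <- IRanges::width(ga)[qa]; wb <- IRanges::width(gb)[qb]
  good <- ov >= min_fraction * wa & ov >= min_fraction * wb
  matched_a <- unique(qa[good]); matched_b <- unique(qb[good])
  jac <- if (any(good)) mean(ov[good] / (wa[good] + wb[good] - ov[good]))
         else NA_real_
  list(matched = sum(good), n_a = length(ga), n_b = length(gb),
       unique_a = length(ga) - length(matched_a),
       unique_b = length(gb) - length(matched_b),
       jaccard = jac)
}
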
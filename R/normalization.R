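#' Compute a per-bin normalization vector
#'
#' Vanilla coverage (`VC`) sets `w_i = c / rowsum_i`, square-root
#' vanilla coverage (`VC_SQRT`) sets `w_i = c / sqrt(rowsum_i)`, with
#' `c` chosen so the weighted matrix total equals the raw total.
#' `balanced` runs iterative proportional fitting until the relative
#' standard deviation of the non-missing weighted row sums falls below
#' `tol` (matrix balancing to equal row sums, the same contract as
#' Knight-Ruiz).  Before any method is applied, bins whose marginal is
#' below `coverage_floor` times the median non-zero marginal are
#' flagged missing; missing weights propagate as entry deletion, never
#' as zeros.
#'
#' @param cm a raw `contact_matrix`.
#' @param method one of `"VC"`, `"VC_SQRT"`, `"balanced"`.
#' @param coverage_floor fraction of the median non-zero marginal below
#'   which a bin is masked (default 0.02).
#' @param tol convergence tolerance on the relative SD of row sums.
#' @param max_iter balancing iteration cap.
#' @return a `norm_vector`: list with `weights` (NA = missing),
#'   `method`, `convergence_stat` (relative SD of balanced row sums),
#'   `coverage` (marginal / mean non-missing marginal, the
#'   vanilla-coverage value used by [filter_loops()]), and `n_bins`.
#' @export
compute_normalization <- function(cm, method = c("VC", "VC_SQRT", "balanced"),
                                  coverage_floor = 0.02,
                                  tol = 1e-6, max_iter = 500L) {
  method <- match.arg(method)
  n <- n_bins(cm)
  m <- as_dense(cm)
  marg <- rowSums(m)
  nz <- marg[marg > 0]
  if (!length(nz)) {
    warning("all-zero matrix: every bin flagged missing")
    return(structure(list(weights = rep(NA_real_, n), method = method,
                          convergence_stat = NA_real_,
                          coverage = rep(NA_real_, n), n_bins = n),
                     class = "norm_vector"))
  }
  miss <- marg < coverage_floor * stats::median(nz)
  coverage <- marg / mean(marg[!miss])
  coverage[miss] <- NA_real_
  w <- rep(NA_real_, n)
  conv <- NA_real_
  keep <- which(!miss)
  mk <- m[keep, keep, drop = FALSE]
  raw_sum <- sum(mk)
  if (method == "VC" || method == "VC_SQRT") {
    r <- rowSums(mk)
    wk <- if (method == "VC") 1 / r else 1 / sqrt(r)
    s1 <- sum(mk * outer(wk, wk))
    wk <- wk * sqrt(raw_sum / s1)
    w[keep] <- wk
  } else {
    wk <- rep(1, length(keep))
    for (it in seq_len(max_iter)) {
      rs <- rowSums(mk * outer(wk, wk))
      conv <- stats::sd(rs) / mean(rs)
      if (is.na(conv) || conv < tol) break
      wk <- wk / sqrt(rs / mean(rs))
    }
    rs <- rowSums(mk * outer(wk, wk))
    conv <- stats::sd(rs) / mean(rs)
    if (is.na(conv)) conv <- 0
    if (conv >= tol)
      warning(sprintf("balancing did not converge (rel SD %.3g)", conv))
    ## rescale so the balanced total matches the raw total
    wk <- wk * sqrt(raw_sum / sum(mk * outer(wk, wk)))
    w[keep] <- wk
  }
  structure(list(weights = w, method = method, convergence_stat = conv,
                 coverage = coverage, n_bins = n),
            class = "norm_vector")
}

#' Apply a normalization vector to a contact matrix
#'
#' Rescales every pixel by `w_i * w_j`; pixels touching a missing bin
#' are dropped (missingness is deletion, not zero).  The vector is
#' attached to the result so downstream code can recover the mask and
#' the vanilla-coverage values.
#'
#' @param cm a `contact_matrix`.
#' @param nv a `norm_vector` built on the same bin grid.
#' @return a normalized `contact_matrix` with `tag = nv$method`.
#' @export
apply_normalization <- function(cm, nv) {
  stopifnot(inherits(nv, "norm_vector"))
  if (nv$n_bins != n_bins(cm))
    stop("normalization vector built on a different bin table")
  e <- cm$entries
  w <- nv$weights
  keep <- !is.na(w[e$i + 1L]) & !is.na(w[e$j + 1L])
  e <- e[keep, , drop = FALSE]
  e$value <- e$value * w[e$i + 1L] * w[e$j + 1L]
  out <- cm
  out$entries <- e
  rownames(out$entries) <- NULL
  out$tag <- nv$method
  out$norm <- nv
  out
}

#' Distance-decay expected profile
#'
#' Mean contact value at each genomic separation `d` (in bins) over all
#' pairs of non-missing bins, with zero-valued pairs included in the
#' denominator.
#'
#' @param cm a `contact_matrix` (any tag) on a single chromosome.
#' @return an `expected_profile`: data.frame with `distance` (bins) and
#'   `expected`.
#' @export
expected_by_distance <- function(cm) {
  n <- n_bins(cm)
  mask <- !missing_bins(cm)
  e <- cm$entries
  d <- e$j - e$i
  sums <- numeric(n)
  if (nrow(e)) {
    agg <- rowsum(e$value, d)
    sums[as.integer(rownames(agg)) + 1L] <- agg
  }
  npairs <- vapply(0:(n - 1L), function(dd) {
    if (dd == 0L) sum(mask)
    else sum(mask[seq_len(n - dd)] & mask[seq_len(n - dd) + dd])
  }, numeric(1))
  expected <- ifelse(npairs > 0, sums / npairs, 0)
  structure(data.frame(distance = 0:(n - 1L), expected = expected),
            class = c("expected_profile", "data.frame"))
}

#' Observed/expected transform
#'
#' Divides every pixel by the expected value at its separation;
#' separations with expected 0 are dropped.
#'
#' @param cm a `contact_matrix`.
#' @param profile an [expected_by_distance()] profile from the same
#'   matrix or a designated reference.
#' @return a `contact_matrix` with `"_oe"` appended to its tag.
#' @export
observed_over_expected <- function(cm, profile = expected_by_distance(cm)) {
  e <- cm$entries
  exp_d <- profile$expected[e$j - e$i + 1L]
  keep <- !is.na(exp_d) & exp_d > 0
  e <- e[keep, , drop = FALSE]
  e$value <- e$value / exp_d[keep]
  out <- cm
  out$entries <- e
  rownames(out$entries) <- NULL
  out$tag <- paste0(sub("_oe$", "", cm$tag), "_oe")
  out
}
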
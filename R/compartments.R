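#' Reference compartment vector from an observed/expected matrix
#'
#' The leading eigenvector of the Pearson correlation matrix of the
#' O/E columns over unmasked bins: the classical two-state compartment
#' caller.  The sign is arbitrary at this stage — orient it with
#' [orient_by_signal()] before projecting other stages onto it.
#'
#' @param oe_cm an observed/expected `contact_matrix` (see
#'   [observed_over_expected()]).
#' @param min_separation separations (in bins) below this are replaced
#'   by the neutral value 1 before correlating, so domain-scale
#'   near-diagonal structure does not leak into the compartment
#'   signal (default 40, the TAD-calling block).
#' @return numeric per-bin raw vector (`NA` at masked or zero-variance
#'   bins), with attributes `degenerate` (logical: leading eigenvalue
#'   explains < 5% of total variance) and `explained`.
#' @export
reference_compartment_vector <- function(oe_cm, min_separation = 40L) {
  n <- n_bins(oe_cm)
  m <- as_dense(oe_cm)
  mask <- !missing_bins(oe_cm)
  mask <- mask & rowSums(m != 0) > 0
  if (sum(mask) < 10L) stop("fewer than 10 unmasked bins")
  if (min_separation > 0L) {
    idx <- which(abs(row(m) - col(m)) < min_separation)
    m[idx] <- 1
  }
  sub <- m[mask, mask, drop = FALSE]
  keep <- apply(sub, 2L, stats::sd) > 0
  sub <- sub[keep, keep, drop = FALSE]
  if (ncol(sub) < 10L) stop("fewer than 10 informative bins")
  cc <- stats::cor(sub)
  eg <- eigen(cc, symmetric = TRUE)
  v <- rep(NA_real_, n)
  v[which(mask)[keep]] <- eg$vectors[, 1L]
  expl <- eg$values[1L] / sum(pmax(eg$values, 0))
  ## a real two-state mode stands clear of the eigenvalue bulk; when the
  ## leading value sits on the bulk edge there is no compartment signal
  attr(v, "degenerate") <- eg$values[1L] < 1.2 * eg$values[2L]
  attr(v, "explained") <- expl
  v
}

#' Orient a compartment vector by an active chromatin mark
#'
#' If the correlation between the vector and an active-mark coverage
#' track (e.g. H3K4me3) is negative, the vector is negated so that
#' positive scores mark the active (A) state.
#'
#' @param raw_vector a per-bin compartment vector.
#' @param active_mark_track per-bin active-mark coverage on the same
#'   grid.
#' @return the oriented vector.
#' @export
orient_by_signal <- function(raw_vector, active_mark_track) {
  if (length(raw_vector) != length(active_mark_track))
    stop("vector and mark track differ in length")
  ok <- !is.na(raw_vector) & !is.na(active_mark_track)
  if (stats::sd(active_mark_track[ok]) == 0 || stats::sd(raw_vector[ok]) == 0)
    stop("orientation unresolved: zero-variance input")
  r <- stats::cor(raw_vector[ok], active_mark_track[ok])
  if (r < 0) -raw_vector else raw_vector
}

#' Project a stage's O/E matrix onto a reference compartment vector
#'
#' `score_i = sum_j OE[i, j] * ref_j` over bins where the reference is
#' defined — the matrix-vector product that transfers one stage's
#' compartment orientation onto another stage's contacts.
#'
#' @param oe_cm the stage's observed/expected `contact_matrix`.
#' @param reference_vector an oriented per-bin vector on the same grid.
#' @param min_separation separations (in bins) below this are excluded
#'   from the product, mirroring [reference_compartment_vector()].
#' @return raw per-bin stage scores (`NA` at bins masked in the stage
#'   matrix).
#' @export
project_compartment_score <- function(oe_cm, reference_vector,
                                      min_separation = 40L) {
  n <- n_bins(oe_cm)
  if (length(reference_vector) != n)
    stop("reference vector on a different bin grid")
  m <- as_dense(oe_cm)
  dead <- missing_bins(oe_cm) | rowSums(m != 0) == 0L
  if (min_separation > 0L)
    m[abs(row(m) - col(m)) < min_separation] <- 0
  ref <- ifelse(is.na(reference_vector), 0, reference_vector)
  score <- as.numeric(m %*% ref)
  score[dead] <- NA_real_
  score
}

#' Normalize compartment scores to [-1, 1] and assign A/B
#'
#' Subtracts the mean over defined bins, then divides by the maximum
#' absolute value (preserving zero as the A/B boundary).  Labels: A for
#' positive, B for negative.  Idempotent.
#'
#' @param raw_scores per-bin raw scores.
#' @param id optional stage/condition identity stored on the result.
#' @return a `compartment_track` data.frame with `score` in `[-1, 1]`
#'   and `label` in `{"A", "B", NA}`.
#' @export
normalize_scores <- function(raw_scores, id = NA_character_) {
  s <- raw_scores
  ok <- !is.na(s)
  if (!any(ok)) stop("no defined score")
  s[ok] <- s[ok] - mean(s[ok])
  mx <- max(abs(s[ok]))
  if (mx == 0) {
    warning("all scores equal: zero track, no A/B labels")
    lab <- rep(NA_character_, length(s))
  } else {
    s[ok] <- s[ok] / mx
    lab <- ifelse(is.na(s), NA_character_,
                  ifelse(s > 0, "A", ifelse(s < 0, "B", NA_character_)))
  }
  structure(data.frame(score = s, label = lab),
            id = id, class = c("compartment_track", "data.frame"))
}

#' Track A/B switching across an ordered series of stages
#'
#' Classifies every bin at each consecutive stage pair as stable-A,
#' stable-B, A->B or B->A; bins unlabeled in either stage are excluded.
#'
#' @param tracks ordered list of `compartment_track` objects (>= 2) on
#'   a common grid.
#' @return data.frame with one row per transition: `from`, `to`,
#'   `stable_A`, `stable_B`, `A_to_B`, `B_to_A`, `n`,
#'   `switch_fraction`.
#' @export
switch_tracking <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  len <- unique(vapply(tracks, nrow, integer(1)))
  if (length(len) != 1L) stop("tracks on different grids")
  ids <- vapply(seq_along(tracks), function(k) {
    id <- attr(tracks[[k]], "id")
    if (is.na(id)) as.character(k) else id
  }, "")
  res <- list()
  for (k in seq_len(length(tracks) - 1L)) {
    l1 <- tracks[[k]]$label; l2 <- tracks[[k + 1L]]$label
    ok <- !is.na(l1) & !is.na(l2)
    res[[k]] <- data.frame(
      from = ids[k], to = ids[k + 1L],
      stable_A = sum(l1 == "A" & l2 == "A" & ok),
      stable_B = sum(l1 == "B" & l2 == "B" & ok),
      A_to_B = sum(l1 == "A" & l2 == "B" & ok),
      B_to_A = sum(l1 == "B" & l2 == "A" & ok),
      n = sum(ok))
  }
  out <- do.call(rbind, res)
  out$switch_fraction <- (out$A_to_B + out$B_to_A) / out$n
  out
}
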
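#' Specify a synthetic chromosome
#'
#' A `synthetic_spec` is the planted "world" from which
#' [simulate_contact_matrix()] draws: a power-law distance decay,
#' block-enriched TADs of stated strength, corner loops, a two-state
#' compartment profile, an optional one-border (stripe-like) asymmetry
#' per domain, and Poisson count noise at a stated depth.  All borders
#' and anchors are 0-based bin positions.
#'
#' @param n_bins chromosome length in bins.
#' @param bin_size bin width in bp.
#' @param decay_exponent power-law slope `alpha` of the contact decay
#'   `depth * (1 + d)^-alpha`.
#' @param depth mean count at separation 1 bin (and at separation 0
#'   before structural factors).
#' @param tad_borders strictly increasing 0-based bin positions; `k`
#'   borders define `k - 1` contiguous domains (empty = no TADs).
#' @param tad_strength per-domain intra/inter contact fold enrichment
#'   (>= 1), recycled.
#' @param loop_list data.frame with columns `a1`, `a2` (0-based anchor
#'   bins) and `fold` (>= 1); `NULL` for none.
#' @param compartment_vector per-bin signed compartment value (sign =
#'   state, magnitude = strength); pairs are modulated by
#'   `exp(v_i * v_j)`.  `NULL` or all-zero disables compartments.
#' @param asymmetry per-domain signed factor: `+a` (a > 1) biases
#'   intra-domain contacts and border signal toward the 5' border,
#'   `-a` toward the 3' border, `0` or `1` = symmetric.  Recycled.
#' @param boundary_insulation multiplicative depletion of contacts
#'   crossing a planted domain boundary (extrusion blocking by
#'   boundary elements); applied once per crossed boundary up to two
#'   crossings, so long-range (compartment-driven) contacts keep their
#'   relative structure.  1 disables; default 0.7.
#' @param seed integer seed; the same spec is bit-reproducible.
#' @param chrom chromosome name for the bin table.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_bins, bin_size = 10000L, decay_exponent = 1.0,
                           depth = 30, tad_borders = integer(),
                           tad_strength = numeric(), loop_list = NULL,
                           compartment_vector = NULL, asymmetry = 0,
                           boundary_insulation = 0.7,
                           seed = 1L, chrom = "chrS") {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins > 0, depth > 0, decay_exponent >= 0)
  tad_borders <- as.integer(tad_borders)
  if (length(tad_borders)) {
    if (any(diff(tad_borders) <= 0L) ||
        tad_borders[1] < 0L || tad_borders[length(tad_borders)] > n_bins)
      stop("tad_borders must be strictly increasing within [0, n_bins]")
  }
  n_dom <- max(length(tad_borders) - 1L, 0L)
  if (n_dom > 0L) {
    tad_strength <- rep_len(as.numeric(tad_strength), n_dom)
    if (any(tad_strength < 1)) stop("tad_strength must be >= 1")
    asymmetry <- rep_len(as.numeric(asymmetry), n_dom)
    if (any(abs(asymmetry) < 1 & asymmetry != 0))
      stop("asymmetry magnitudes must be >= 1 (or 0 for symmetric)")
  } else {
    tad_strength <- numeric()
    asymmetry <- numeric()
  }
  if (!is.null(loop_list)) {
    stopifnot(all(c("a1", "a2", "fold") %in% names(loop_list)))
    if (any(loop_list$a1 < 0) || any(loop_list$a2 >= n_bins) ||
        any(loop_list$a1 >= loop_list$a2))
      stop("loop anchors out of bounds or misordered")
    if (any(loop_list$fold < 1)) stop("loop fold must be >= 1")
  }
  if (!is.null(compartment_vector) && length(compartment_vector) != n_bins)
    stop("compartment_vector must have one value per bin")
  stopifnot(boundary_insulation > 0, boundary_insulation <= 1)
  structure(list(n_bins = n_bins, bin_size = as.integer(bin_size),
                 decay_exponent = decay_exponent, depth = depth,
                 tad_borders = tad_borders, tad_strength = tad_strength,
                 loop_list = loop_list,
                 compartment_vector = compartment_vector,
                 asymmetry = asymmetry,
                 boundary_insulation = boundary_insulation,
                 seed = as.integer(seed), chrom = chrom),
            class = "synthetic_spec")
}

#' Default desk-scale fixture specification
#'
#' 1,000 bins of 10 kb (a 10-Mb chromosome), decay exponent 1, depth 30
#' counts at 1-bin separation, 12 domains of 40-120 bins with fold
#' enrichment 2-3 separated by 4-bin unorganized spacers, 4 of them
#' loop domains (corner fold 8), a 50-bin alternating compartment
#' profile of amplitude 0.3, and a 3 / 6 / 3 split of 5'-biased /
#' symmetric / 3'-biased domains with asymmetry factor 4.  The domain
#' block sits in the chromosome interior where the 40-bin block
#' metrics are defined.  Spacers are encoded as strength-1 segments,
#' so the planted `domains` in the ground truth are the enriched
#' segments; `territories` extend each to the spacer midpoints.
#'
#' @param seed integer seed controlling both the layout draw and the
#'   Poisson sampling.
#' @return a `synthetic_spec`.
#' @export
default_fixture_spec <- function(seed = 1L) {
  set.seed(seed)
  n <- 1000L
  gap <- 4L   # unorganized spacer between adjacent domains (40 kb)
  repeat {
    sizes <- sample(40:120, 12L, replace = TRUE)
    if (sum(sizes) + 11L * gap <= n - 100L) break
  }
  first <- sample(50:(n - sum(sizes) - 11L * gap - 50L), 1L)
  ## interleave domain and gap segments on one border list
  seg_len <- as.integer(rbind(sizes, c(rep(gap, 11L), NA))[-24L])
  borders <- as.integer(first + c(0L, cumsum(seg_len)))
  dom_idx <- seq(1L, 23L, by = 2L)
  strength <- rep(1, 23L)
  strength[dom_idx] <- stats::runif(12L, 2, 3)
  asym <- rep(0, 23L)
  asym[dom_idx] <- sample(rep(c(4, 0, -4), c(3L, 6L, 3L)))
  loop_dom <- sort(sample(dom_idx, 4L))
  loops <- data.frame(a1 = borders[loop_dom],
                      a2 = borders[loop_dom + 1L] - 1L,
                      fold = 8)
  comp <- 0.3 * rep_len(rep(c(1, -1), each = 50L), n)
  synthetic_spec(n_bins = n, bin_size = 10000L, decay_exponent = 1.0,
                 depth = 30, tad_borders = borders, tad_strength = strength,
                 loop_list = loops, compartment_vector = comp,
                 asymmetry = asym, seed = seed)
}

## planted domain segments (strength-enriched or asymmetric) in bin
## units, plus the boundary positions (outer domain edges and
## spacer midpoints) that carry insulating elements
.spec_domains <- function(spec) {
  nb <- length(spec$tad_borders)
  if (nb < 2L)
    return(list(start = integer(), end = integer(), idx = integer(),
                boundary_mid = numeric()))
  starts <- spec$tad_borders[-nb]; ends <- spec$tad_borders[-1]
  keep <- spec$tad_strength > 1 | spec$asymmetry != 0
  starts <- starts[keep]; ends <- ends[keep]
  bm <- numeric()
  if (length(starts)) {
    inner <- if (length(starts) > 1L)
      (ends[-length(ends)] + starts[-1]) / 2 else numeric()
    bm <- c(starts[1], inner, ends[length(ends)])
  }
  list(start = starts, end = ends, idx = which(keep), boundary_mid = bm)
}

#' Compartment-focused fixture specification
#'
#' A checkerboard world for compartment-analysis validation: 1,000
#' bins of 25 kb (the compartment-calling resolution), no TADs or
#' loops, and a two-state compartment profile in 50-bin (1.25-Mb)
#' blocks at amplitude 0.6 — the plaid contrast of differentiated
#' tissue (same-state vs cross-state contact fold about 1.8) — at
#' depth 100 (a deeply sequenced 25-kb map).  A
#' fraction of block signs can be flipped to emulate a later stage for
#' switch tracking.
#'
#' @param seed integer seed.
#' @param flip_fraction approximate fraction of bins whose compartment
#'   state is flipped (block-wise) relative to the unflipped layout.
#' @param amplitude compartment strength (default 0.6).
#' @return a `synthetic_spec`.
#' @export
compartment_fixture_spec <- function(seed = 1L, flip_fraction = 0,
                                     amplitude = 0.6) {
  n <- 1000L
  block <- 50L
  states <- rep_len(c(1, -1), n %/% block)
  if (flip_fraction > 0) {
    set.seed(seed + 7L)
    nflip <- max(1L, round(flip_fraction * length(states)))
    flip <- sample(seq_along(states), nflip)
    states[flip] <- -states[flip]
  }
  comp <- amplitude * rep(states, each = block)
  synthetic_spec(n_bins = n, bin_size = 25000L, decay_exponent = 1.0,
                 depth = 100, compartment_vector = comp, seed = seed)
}

#' Staged compartment series with planted per-step switching
#'
#' Builds an ordered list of [compartment_fixture_spec()]-style worlds
#' in which each stage equals the previous one with a stated fraction
#' of bins (whole blocks) flipped between A and B — the substrate for
#' validating [switch_tracking()].
#'
#' @param seed integer seed.
#' @param n_stages number of stages (>= 2).
#' @param flip_per_step fraction of bins switched at each step
#'   (default 0.1).
#' @param amplitude compartment strength.
#' @return list of `synthetic_spec` objects; each carries the evolving
#'   compartment vector.
#' @export
compartment_stage_series <- function(seed = 1L, n_stages = 4L,
                                     flip_per_step = 0.1,
                                     amplitude = 0.6) {
  n <- 1000L; block <- 50L
  set.seed(seed)
  states <- rep_len(c(1, -1), n %/% block)
  nflip <- max(1L, round(flip_per_step * length(states)))
  out <- vector("list", n_stages)
  for (st in seq_len(n_stages)) {
    if (st > 1L) {
      flip <- sample(seq_along(states), nflip)
      states[flip] <- -states[flip]
    }
    out[[st]] <- synthetic_spec(n_bins = n, bin_size = 25000L,
                                decay_exponent = 1.0, depth = 100,
                                compartment_vector =
                                  amplitude * rep(states, each = block),
                                seed = seed * 97L + st)
  }
  out
}

## expected (noise-free) intensity model over the upper triangle,
## returned alongside the pair index vectors
.lambda_model <- function(spec) {
  n <- spec$n_bins
  i <- rep.int(seq_len(n), rev(seq_len(n)))
  j <- sequence(rev(seq_len(n))) + i - 1L
  d <- j - i
  lam <- spec$depth * (1 + d)^(-spec$decay_exponent)
  nb <- length(spec$tad_borders)
  if (nb >= 2L) {
    dom_of <- rep(0L, n)
    for (k in seq_len(nb - 1L)) {
      dom_of[(spec$tad_borders[k] + 1L):spec$tad_borders[k + 1L]] <- k
    }
    di <- dom_of[i]; dj <- dom_of[j]
    intra <- di > 0L & di == dj
    if (any(intra)) {
      k <- di[intra]
      str <- spec$tad_strength[k]
      a <- spec$asymmetry[k]
      biased <- a != 0 & abs(a) > 1
      if (any(biased)) {
        ## stripe-like gradient: in a 5'-biased domain the contacts of
        ## bins nearest the 5' border are elevated across the whole
        ## domain, declining linearly toward the 3' border (and
        ## mirrored for 3'-biased domains) -- the intra-domain
        ## signature of one-sided loop extrusion
        s <- spec$tad_borders[k] ; L <- diff(spec$tad_borders)[k]
        d5 <- i[intra] - 1L - s + 0.5             # bins inside the 5' border
        d3 <- s + L - j[intra] + 1L - 0.5         # bins inside the 3' border
        t5 <- d5 / L ; t3 <- d3 / L
        ## 1-bin onset: the border bin itself stays unstriped (the
        ## extrusion anchor sits just inside the boundary element)
        fac <- ifelse(a > 0,
                      1 + (abs(a) - 1) * (1 - t5) * pmin(1, pmax(0, d5 - 0.5)),
                      1 + (abs(a) - 1) * (1 - t3) * pmin(1, pmax(0, d3 - 0.5)))
        fac[!biased] <- 1
        str <- str * fac
      }
      lam[intra] <- lam[intra] * str
    }
  }
  if (!is.null(spec$loop_list) && nrow(spec$loop_list)) {
    for (k in seq_len(nrow(spec$loop_list))) {
      hit <- abs(i - 1L - spec$loop_list$a1[k]) <= 1L &
        abs(j - 1L - spec$loop_list$a2[k]) <= 1L
      lam[hit] <- lam[hit] * spec$loop_list$fold[k]
    }
  }
  v <- spec$compartment_vector
  if (!is.null(v) && any(v != 0)) lam <- lam * exp(v[i] * v[j])
  ## insulating boundary elements: contacts crossing a planted domain
  ## boundary are depleted per crossing, saturating at two crossings
  if (spec$boundary_insulation < 1) {
    bm <- .spec_domains(spec)$boundary_mid
    if (length(bm)) {
      cum <- findInterval(seq_len(n) - 0.5, bm)
      ncross <- pmin(cum[j] - cum[i], 2L)
      lam <- lam * spec$boundary_insulation^ncross
    }
  }
  list(i = i, j = j, lambda = lam)
}

#' Simulate a contact matrix with planted structure
#'
#' Draws `Poisson(lambda_ij)` independently over the upper triangle of
#' the mean model `depth * (1+d)^-alpha * tad * loop * compartment *
#' asymmetry` and mirrors it.  Identical seeds give identical matrices.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (a raw `contact_matrix`) and `truth` (a
#'   `ground_truth` list: `borders`, `domains` data.frame in bp with
#'   `strength`, `asymmetry`, `loop_domain`, `loops` data.frame, and
#'   per-bin `compartment` labels).
#' @export
simulate_contact_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  mod <- .lambda_model(spec)
  counts <- stats::rpois(length(mod$lambda), mod$lambda)
  keep <- counts > 0L
  bt <- bin_table(spec$chrom, spec$n_bins * spec$bin_size, spec$bin_size)
  cm <- contact_matrix(bt, mod$i[keep] - 1L, mod$j[keep] - 1L,
                       as.numeric(counts[keep]))
  truth <- .ground_truth(spec)
  list(matrix = cm, truth = truth)
}

.ground_truth <- function(spec) {
  nb <- length(spec$tad_borders)
  bs <- spec$bin_size
  if (nb >= 2L) {
    starts <- spec$tad_borders[-nb] ; ends <- spec$tad_borders[-1]
    loop_flag <- rep(FALSE, nb - 1L)
    if (!is.null(spec$loop_list) && nrow(spec$loop_list)) {
      for (k in seq_len(nb - 1L)) {
        loop_flag[k] <- any(abs(spec$loop_list$a1 - starts[k]) <= 1L &
                              abs(spec$loop_list$a2 - (ends[k] - 1L)) <= 1L)
      }
    }
    domains <- data.frame(chrom = spec$chrom, start = starts * bs,
                          end = ends * bs,
                          strength = spec$tad_strength,
                          asymmetry = spec$asymmetry,
                          loop_domain = loop_flag)
    ## strength-1 symmetric segments are unorganized gaps, not domains
    domains <- domains[domains$strength > 1 | domains$asymmetry != 0, ,
                       drop = FALSE]
    rownames(domains) <- NULL
  } else {
    domains <- data.frame(chrom = character(), start = integer(),
                          end = integer(), strength = numeric(),
                          asymmetry = numeric(), loop_domain = logical())
  }
  ## planted TAD-boundary positions in bin units: the outer domain
  ## edges plus, between consecutive domains, the junction bin or the
  ## midpoint of the unorganized spacer separating them
  boundary_mid <- numeric()
  if (nrow(domains)) {
    sb <- domains$start / bs; eb <- domains$end / bs
    inner <- if (nrow(domains) > 1L)
      (eb[-nrow(domains)] + sb[-1]) / 2 else numeric()
    boundary_mid <- c(sb[1], inner, eb[nrow(domains)])
  }
  ## TAD territories: boundary-to-boundary records (each domain plus
  ## half of each flanking unorganized spacer, snapped to the grid) --
  ## the footprint a caller can actually delimit, since any position
  ## within a featureless spacer is an equally true border
  territories <- domains[, c("chrom", "start", "end"), drop = FALSE]
  if (nrow(domains)) {
    mids <- floor(boundary_mid)
    territories$start <- as.integer(mids[-length(mids)] * bs)
    territories$end <- as.integer(mids[-1] * bs)
  }
  comp <- spec$compartment_vector
  structure(list(borders = spec$tad_borders, boundary_mid = boundary_mid,
                 territories = territories,
                 domains = domains,
                 loops = spec$loop_list,
                 compartment = if (is.null(comp)) NULL else
                   ifelse(comp > 0, "A", ifelse(comp < 0, "B", NA)),
                 compartment_value = comp, seed = spec$seed),
            class = "ground_truth")
}

#' Simulate a border-enriched signal track
#'
#' Baseline Poisson coverage plus Gaussian-shaped peaks (sd 1 bin) at
#' every planted domain border.  With `asymmetric = TRUE`, the border
#' designated by each domain's asymmetry sign (5' for positive, 3' for
#' negative) has its enrichment multiplied by the asymmetry magnitude,
#' emulating one-sided CTCF/cohesin enrichment.
#'
#' @param spec a [synthetic_spec()].
#' @param truth the matching `ground_truth`.
#' @param enrichment_at_borders peak fold over baseline (1 = flat).
#' @param asymmetric apply the per-domain asymmetry factor.
#' @param baseline mean background coverage per bin.
#' @return numeric per-bin track of length `spec$n_bins`.
#' @export
simulate_signal_track <- function(spec, truth, enrichment_at_borders = 5,
                                  asymmetric = FALSE, baseline = 10) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 7919L)
  n <- spec$n_bins
  mu <- rep(baseline, n)
  if (baseline == 0 && enrichment_at_borders <= 1) return(rep(0, n))
  doms <- truth$domains
  if (nrow(doms)) {
    bs <- spec$bin_size
    for (k in seq_len(nrow(doms))) {
      for (side in c(5, 3)) {
        b <- if (side == 5) doms$start[k] / bs else doms$end[k] / bs
        enr <- enrichment_at_borders
        if (asymmetric) {
          a <- doms$asymmetry[k]
          if ((side == 5 && a > 1) || (side == 3 && a < -1))
            enr <- enr * abs(a)
        }
        if (enr > 1) {
          off <- -4:4
          pos <- b + off + 1L   # border sits between bins b and b+1
          ok <- pos >= 1L & pos <= n
          mu[pos[ok]] <- mu[pos[ok]] +
            baseline * (enr - 1) * exp(-off[ok]^2 / 2)
        }
      }
    }
  }
  stats::rpois(n, mu)
}

#' Simulate spike-in read counts
#'
#' Splits `total_reads` binomially between the target and spike-in
#' genomes so that `E[N_target / N_spike] = true_ratio`.
#'
#' @param true_ratio expected target/spike read ratio (> 0).
#' @param total_reads total mapped reads.
#' @param seed integer seed.
#' @return list with `n_target` and `n_spike`.
#' @export
simulate_spike_in_counts <- function(true_ratio, total_reads, seed = 1L) {
  stopifnot(true_ratio > 0, total_reads >= 0)
  set.seed(seed)
  if (total_reads == 0) return(list(n_target = 0L, n_spike = 0L))
  nt <- stats::rbinom(1L, total_reads, true_ratio / (1 + true_ratio))
  list(n_target = nt, n_spike = total_reads - nt)
}

#' Write ground truth to plain-text files
#'
#' Emits borders and domains as BED, loops as BEDPE and the compartment
#' vector as bedGraph under `dir` with the given prefix.
#'
#' @param truth a `ground_truth`.
#' @param spec the `synthetic_spec` that produced it.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the files written, invisibly.
#' @export
write_ground_truth <- function(truth, spec, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bs <- spec$bin_size
  files <- c()
  f <- file.path(dir, paste0(prefix, "_domains.bed"))
  utils::write.table(truth$domains[, c("chrom", "start", "end")], f,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  files["domains"] <- f
  if (!is.null(truth$loops) && nrow(truth$loops)) {
    f <- file.path(dir, paste0(prefix, "_loops.bedpe"))
    lp <- truth$loops
    utils::write.table(data.frame(spec$chrom, lp$a1 * bs, (lp$a1 + 1L) * bs,
                                  spec$chrom, lp$a2 * bs, (lp$a2 + 1L) * bs,
                                  lp$fold), f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files["loops"] <- f
  }
  if (!is.null(truth$compartment_value)) {
    f <- file.path(dir, paste0(prefix, "_compartment.bedgraph"))
    write_bedgraph(bin_table(spec$chrom, spec$n_bins * bs, bs),
                   truth$compartment_value, f)
    files["compartment"] <- f
  }
  f <- file.path(dir, paste0(prefix, "_spec.txt"))
  keys <- c("n_bins", "bin_size", "decay_exponent", "depth", "seed", "chrom")
  writeLines(paste0(keys, "\t", vapply(spec[keys], as.character, "")), f)
  files["spec"] <- f
  invisible(files)
}
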
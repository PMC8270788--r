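test_that("border DI vectors have the stated layout and masking", {
  di <- structure(c(rep(NA, 5), seq_len(90), rep(NA, 5)),
                  block_bins = 5L, class = "di_track")
  bs <- 1e4
  ds <- domain_set(data.frame(chrom = "chrS",
                              start = c(20, 2) * bs, end = c(40, 12) * bs),
                   bs)
  X <- border_di_vectors(ds, di, flank_bins = 5L)
  expect_equal(ncol(X), 20L)
  expect_true(attr(X, "mask")[1])        # domain starting at bin 2: edge DI NA
  expect_false(attr(X, "mask")[2])
  # row layout: bins 15..24 then 35..44 (0-based); track value = bin - 4
  expect_equal(X[2, ], c(15:24, 35:44) - 4)
  expect_error(border_di_vectors(ds, di, 0L), "flank_bins")
})

test_that("a mirrored symmetric domain has sign-mirrored DI halves", {
  spec <- synthetic_spec(300, tad_borders = c(120, 180), tad_strength = 3,
                         seed = 9)
  sim <- simulate_contact_matrix(spec)
  di <- directionality_index(sim$matrix, 40L)
  ds <- domain_set(data.frame(chrom = "chrS", start = 120e4, end = 180e4), 1e4)
  X <- border_di_vectors(ds, di)
  # 5' half vs reversed negated 3' half agree in sign pattern on average
  expect_gt(cor(X[1, 1:10], -rev(X[1, 11:20])), 0.5)
})

test_that("k-means separates planted asymmetry classes across 20 seeds", {
  ok_all <- c()
  for (s in 1:20) {
    spec <- default_fixture_spec(s)
    sim <- simulate_contact_matrix(spec)
    bal <- compute_normalization(sim$matrix, "balanced")
    cmb <- apply_normalization(sim$matrix, bal)
    di <- directionality_index(cmb, 40L)
    doms <- sim$truth$domains
    X <- border_di_vectors(domain_set(doms[, 1:3], 1e4), di)
    cl <- suppressWarnings(kmeans_border_clusters(X, 3L, seed = s))
    tru <- truth_cluster_labels(doms)
    ok <- !attr(X, "mask")
    ok_all <- c(ok_all, cl$labels[ok] == tru[ok])
  }
  expect_gte(mean(ok_all), 0.95)
})

test_that("k-means is deterministic under seed and flags degenerate input", {
  X <- structure(matrix(rnorm(240, sd = 5), 12, 20),
                 mask = rep(FALSE, 12), flank_bins = 5L,
                 class = c("border_di_matrix", "matrix", "array"))
  a <- kmeans_border_clusters(X, 3L, seed = 42)
  b <- kmeans_border_clusters(X, 3L, seed = 42)
  expect_identical(a$labels, b$labels)
  Xd <- structure(matrix(1, 10, 20), mask = rep(FALSE, 10), flank_bins = 5L,
                  class = c("border_di_matrix", "matrix", "array"))
  d <- kmeans_border_clusters(Xd, 3L, seed = 1)
  expect_true(d$degenerate)
  expect_true(all(d$labels == 2L))
  expect_error(kmeans_border_clusters(Xd[1:2, , drop = FALSE], 3L),
               "fewer")
})

test_that("DI bias reproduces the log2 formula", {
  bs <- 1e4
  # domain bins 10..19 (0-based): right of 5' border = bins 10..12,
  # left of 3' border = bins 17..19
  v <- rep(NA_real_, 40)
  v[11:13] <- 4; v[18:20] <- -1
  expect_equal(di_bias(10 * bs, 20 * bs, v, bs), 2)     # log2(4/1)
  v[11:13] <- 1; v[18:20] <- -8
  expect_equal(di_bias(10 * bs, 20 * bs, v, bs), -3)    # log2(1/8)
  v[11:13] <- 4; v[18:20] <- -4
  expect_equal(di_bias(10 * bs, 20 * bs, v, bs), 0)
  v[12] <- NA
  expect_true(is.na(di_bias(10 * bs, 20 * bs, v, bs)))
  v[11:13] <- c(-1, 0, 1)  # zero mean -> undefined
  expect_true(is.na(di_bias(10 * bs, 20 * bs, v, bs)))
})

test_that("DI bias negates under 5'/3' mirror", {
  spec <- default_fixture_spec(6)
  sim <- simulate_contact_matrix(spec)
  di <- directionality_index(sim$matrix, 40L)
  n <- 1000L; bs <- 1e4
  dom <- sim$truth$domains[2, ]
  fwd <- di_bias(dom$start, dom$end, di, bs)
  # mirror the matrix and the domain
  m <- as_dense(sim$matrix)[n:1, n:1]
  dir_ <- directionality_index(cm_from_dense(m), 40L)
  mstart <- n * bs - dom$end; mend <- n * bs - dom$start
  rev_ <- di_bias(mstart, mend, dir_, bs)
  expect_equal(rev_, -fwd, tolerance = 1e-9)
})

test_that("subclustering splits by rank into near-equal groups", {
  set.seed(1)
  bias <- rnorm(102)
  lab <- subcluster_by_di_strength(bias, seq_along(bias), 5L)
  expect_equal(as.integer(table(lab)), c(21L, 21L, 20L, 20L, 20L))
  expect_equal(as.integer(table(subcluster_by_di_strength(rnorm(100),
                                                          1:100, 5L))),
               rep(20L, 5))
  # group 1 holds the most 5'-dominant members
  expect_true(min(bias[lab == 1]) >= max(bias[lab == 5]))
  # ties broken by start coordinate
  lab2 <- subcluster_by_di_strength(rep(0, 10), 10:1, 5L)
  expect_equal(lab2, rep(5:1, each = 2))
  expect_error(subcluster_by_di_strength(1:3, 1:3, 5L), "fewer")
})

test_that("signal profiles report mean and s.e.m. per group and side", {
  track <- rep(2, 100)
  borders <- data.frame(bin = c(20, 40, 60), side = c("5p", "3p", "5p"),
                        group = c(1, 1, 1))
  pr <- profile_signal_over_borders(track, borders, flank_bins = 2L)
  expect_true(all(pr$mean == 2))
  expect_true(all(pr$sem[pr$side == "5p"] == 0))
  expect_true(all(is.na(pr$sem[pr$side == "3p"])))   # single border
  expect_warning(profile_signal_over_borders(track, borders[0, ], 2L),
                 "empty")
})

test_that("cluster-1 domains carry the planted 5' signal and DI dominance", {
  di5 <- c(); di3 <- c(); sig5 <- c(); sig3 <- c()
  for (s in 1:8) {
    spec <- default_fixture_spec(s)
    sim <- simulate_contact_matrix(spec)
    di <- directionality_index(sim$matrix, 40L)
    doms <- sim$truth$domains
    c1 <- doms[doms$asymmetry > 1, ]
    X <- border_di_vectors(domain_set(c1[, 1:3], 1e4), di)
    ok <- !attr(X, "mask")
    di5 <- c(di5, rowMeans(abs(X[ok, 6:10, drop = FALSE])))
    di3 <- c(di3, rowMeans(abs(X[ok, 11:15, drop = FALSE])))
    tr <- simulate_signal_track(spec, sim$truth, 5, asymmetric = TRUE)
    b5 <- c1$start / 1e4; b3 <- c1$end / 1e4
    sig5 <- c(sig5, vapply(b5, function(b) max(tr[(b - 1):(b + 3)]),
                           numeric(1)))
    sig3 <- c(sig3, vapply(b3, function(b) max(tr[(b - 1):(b + 3)]),
                           numeric(1)))
  }
  expect_gt(mean(di5), mean(di3))
  expect_gt(mean(sig5), mean(sig3))
})
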
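test_that("the insulation caller finds nothing on a monotone track", {
  ins <- structure(seq(-1, 1, length.out = 50), block_bins = 5L,
                   class = "insulation_track")
  bt <- bin_table("chrS", 50e4, 1e4)
  expect_warning(out <- call_domains_insulation(ins, bt), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("nearby minima are both reported; merging is the merge step's job", {
  v <- rep(0, 40)
  v[15] <- -1; v[18] <- -0.9
  ins <- structure(v, block_bins = 5L, class = "insulation_track")
  out <- call_domains_insulation(ins, bin_table("chrS", 40e4, 1e4),
                                 min_depth = 0.5, min_size_bins = 1L)
  expect_equal(sort(unique(c(out$start, out$end)) / 1e4), c(14, 17))
})

test_that("border merging follows the lowest-insulation rule", {
  v <- rep(0, 200)
  v[101] <- -0.2; v[104] <- 0.1   # borders at bins 100 and 103 (0-based)
  ins <- structure(v, block_bins = 5L, class = "insulation_track")
  bs <- 1e4
  a <- domain_set(data.frame(chrom = "chrS", start = 50 * bs, end = 100 * bs,
                             source = "x"), bs)
  b <- domain_set(data.frame(chrom = "chrS", start = 50 * bs, end = 103 * bs,
                             source = "y"), bs)
  merged <- merge_domain_sets(list(a, b), ins, 4L)
  expect_equal(unique(merged$end), 100 * bs)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$source, "x,y")
})

test_that("three callers reporting the same domain +/-1 bin merge to one", {
  run <- run_consensus(4)
  # every merged domain carries a single aligned border set
  expect_false(any(duplicated(run$merged[, c("start", "end")])))
  # merging is idempotent
  again <- merge_domain_sets(list(run$merged), run$ins, 4L)
  expect_equal(as.data.frame(again)[, c("chrom", "start", "end")],
               as.data.frame(run$merged)[, c("chrom", "start", "end")])
})

test_that("grid mismatch between sets is a hard error", {
  a <- domain_set(data.frame(chrom = "c", start = 0, end = 2e4), 1e4)
  b <- domain_set(data.frame(chrom = "c", start = 0, end = 2e4), 2e4)
  ins <- structure(rep(0, 10), class = "insulation_track")
  expect_error(merge_domain_sets(list(a, b), ins), "grids")
})

test_that("diamond/size filtering removes exactly the stated classes", {
  # constant matrix: every domain scores 0.5 < 0.6 -> removed as diamond_score
  cmc <- cm_from_dense(matrix(2, 80, 80))
  ds <- domain_set(data.frame(chrom = "chrT", start = 20e4, end = 40e4), 1e4)
  out <- filter_domains(ds, cmc)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "removed")$reason, "diamond_score")

  # strong domain but 90 kb: removed for size; 150 kb twin is retained
  m <- matrix(1, 80, 80)
  m[31:39, 31:39] <- 8   # 90 kb
  m[51:65, 51:65] <- 8   # 150 kb
  cm <- cm_from_dense(m)
  ds2 <- domain_set(data.frame(chrom = "chrT",
                               start = c(30e4, 50e4), end = c(39e4, 65e4)),
                    1e4)
  out2 <- filter_domains(ds2, cm)
  expect_equal(out2$start, 50e4)
  expect_equal(attr(out2, "removed")$reason, "size")
  expect_true(all(out2$diamond >= 0.6))
})

test_that("filtering returns subsets and logs unscorable domains", {
  run <- run_consensus(2)
  merged_keys <- paste(run$merged$start, run$merged$end)
  filt_keys <- paste(run$filtered$start, run$filtered$end)
  expect_true(all(filt_keys %in% merged_keys))
  zero <- cm_from_dense(matrix(0, 40, 40))
  ds <- domain_set(data.frame(chrom = "chrT", start = 10e4, end = 25e4), 1e4)
  out <- filter_domains(ds, zero)
  expect_equal(attr(out, "removed")$reason, "unscorable")
})

test_that("low-density filter honors its degenerate contracts", {
  cm <- cm_from_dense(matrix(3, 60, 60))
  ds <- domain_set(data.frame(chrom = "chrT",
                              start = c(0, 20e4, 40e4),
                              end = c(20e4, 40e4, 60e4)), 1e4)
  expect_equal(nrow(low_density_filter(ds, cm, 0.05)), 3L)   # uniform: none
  expect_equal(nrow(low_density_filter(ds, cm, 0)), 3L)      # 0 disables
  # a domain over a masked (all-zero) region is removed
  m <- matrix(3, 60, 60); m[21:40, ] <- 0; m[, 21:40] <- 0
  out <- low_density_filter(ds, cm_from_dense(m), 0.05)
  expect_false(any(out$start == 20e4))
})

test_that("reciprocal overlap comparison matches the bedtools -f/-r rule", {
  bs <- 1e4
  a <- domain_set(data.frame(chrom = "chrS", start = 100 * bs,
                             end = 200 * bs), bs)
  b_shift <- domain_set(data.frame(chrom = "chrS", start = 115 * bs,
                                   end = 215 * bs), bs)
  expect_equal(compare_domain_sets(a, a, 0.9)$matched, 1L)
  expect_equal(compare_domain_sets(a, b_shift, 0.9)$matched, 0L)  # 85% overlap
  expect_equal(compare_domain_sets(a, b_shift, 0.7)$matched, 1L)
  r <- compare_domain_sets(a, b_shift, 0.7)
  expect_equal(r$jaccard, 85 / 115, tolerance = 1e-9)
})

test_that("end-to-end consensus recovers planted domains across 20 seeds", {
  hits <- c(); totals <- c()
  for (s in 1:20) {
    run <- run_consensus(s)
    terr <- domain_set(run$sim$truth$territories, 1e4)
    r <- compare_domain_sets(terr, run$filtered, 0.9)
    hits <- c(hits, r$matched); totals <- c(totals, r$n_a)
  }
  expect_gte(sum(hits) / sum(totals), 0.9)
})
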
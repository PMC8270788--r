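test_that("spec invariants are enforced before sampling", {
  expect_error(synthetic_spec(100, tad_borders = c(10, 5)), "increasing")
  expect_error(synthetic_spec(100, tad_borders = c(10, 120)), "increasing")
  expect_error(synthetic_spec(100, tad_borders = c(10, 50), tad_strength = 0.5),
               ">= 1")
  expect_error(synthetic_spec(100, loop_list = data.frame(a1 = 50, a2 = 20,
                                                          fold = 2)),
               "misordered")
  expect_error(synthetic_spec(100, compartment_vector = 1:5), "per bin")
})

test_that("same seed gives identical matrices, different seeds differ", {
  spec <- synthetic_spec(150, seed = 7, tad_borders = c(30, 80),
                         tad_strength = 2.5)
  a <- simulate_contact_matrix(spec)
  b <- simulate_contact_matrix(spec)
  expect_identical(a$matrix$entries, b$matrix$entries)
  spec2 <- spec; spec2$seed <- 8L
  expect_false(identical(simulate_contact_matrix(spec2)$matrix$entries,
                         a$matrix$entries))
})

test_that("a structureless spec recovers the pure power law", {
  spec <- synthetic_spec(400, decay_exponent = 1, depth = 50, seed = 3)
  sim <- simulate_contact_matrix(spec)
  prof <- expected_by_distance(sim$matrix)
  d <- 0:80
  planted <- 50 * (1 + d)^-1
  expect_lt(max(abs(prof$expected[d + 1] - planted) / planted), 0.15)
})

test_that("strength-1 domains are indistinguishable from a no-TAD world", {
  ds_null <- c(); ds_flat <- c()
  borders <- c(60, 110, 170, 230)
  for (s in 1:8) {
    flat <- synthetic_spec(300, tad_borders = borders,
                           tad_strength = 1, seed = s,
                           boundary_insulation = 1)
    none <- synthetic_spec(300, seed = s + 100)
    mf <- simulate_contact_matrix(flat)$matrix
    mn <- simulate_contact_matrix(none)$matrix
    for (k in seq_len(3)) {
      ds_flat <- c(ds_flat, diamond_score(mf, borders[k] * 1e4,
                                          borders[k + 1] * 1e4)$value)
      ds_null <- c(ds_null, diamond_score(mn, borders[k] * 1e4,
                                          borders[k + 1] * 1e4)$value)
    }
  }
  expect_gt(wilcox.test(ds_flat, ds_null)$p.value, 0.01)
})

test_that("diamond score increases monotonically with planted strength", {
  grid <- c(1.5, 2, 3, 5)
  means <- vapply(grid, function(st) {
    v <- vapply(1:20, function(s) {
      spec <- synthetic_spec(300, tad_borders = c(100, 160),
                            tad_strength = st, seed = s)
      diamond_score(simulate_contact_matrix(spec)$matrix,
                    100e4, 160e4)$value
    }, numeric(1))
    mean(v)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("planted loops are O/E local maxima in the deep-coverage limit", {
  spec <- synthetic_spec(200, depth = 500, tad_borders = c(50, 120),
                         tad_strength = 2,
                         loop_list = data.frame(a1 = 50, a2 = 119, fold = 8),
                         seed = 5)
  sim <- simulate_contact_matrix(spec)
  oe <- as_dense(observed_over_expected(sim$matrix))
  anchor <- oe[51, 120]
  neigh <- oe[48:54, 117:123]
  neigh[3:5, 3:5] <- NA  # the planted 3x3 loop block
  expect_gt(anchor, max(neigh, na.rm = TRUE))
})

test_that("signal tracks reflect border enrichment and asymmetry", {
  spec <- default_fixture_spec(2)
  sim <- simulate_contact_matrix(spec)
  flat <- simulate_signal_track(spec, sim$truth, enrichment_at_borders = 1)
  doms <- sim$truth$domains
  border_bins <- unique(c(doms$start, doms$end)) / 1e4
  expect_lt(abs(mean(flat[border_bins + 1L]) - mean(flat)), 1.5)

  expect_identical(simulate_signal_track(spec, sim$truth, 1, baseline = 0),
                   rep(0, 1000L))

  # asymmetric: designated borders beat opposite borders by roughly the factor
  tr <- simulate_signal_track(spec, sim$truth, enrichment_at_borders = 5,
                              asymmetric = TRUE)
  peak_at <- function(b) max(tr[(b - 1):(b + 3)])
  biased5 <- doms$start[doms$asymmetry > 1] / 1e4
  opp3 <- doms$end[doms$asymmetry > 1] / 1e4
  expect_gt(mean(vapply(biased5, peak_at, numeric(1))) /
              mean(vapply(opp3, peak_at, numeric(1))), 2)
})

test_that("spike-in counts split binomially around the true ratio", {
  r1 <- simulate_spike_in_counts(1, 4e6, seed = 1)
  expect_lt(abs(r1$n_target / r1$n_spike - 1), 0.01)
  r2 <- simulate_spike_in_counts(2, 3e6, seed = 2)
  expect_lt(abs(r2$n_target / r2$n_spike - 2) / 2, 0.01)
  r0 <- simulate_spike_in_counts(1, 0)
  expect_identical(c(r0$n_target, r0$n_spike), c(0L, 0L))
})

test_that("ground truth is written as plain-text artifacts", {
  spec <- default_fixture_spec(1)
  sim <- simulate_contact_matrix(spec)
  dir <- withr::local_tempdir()
  files <- write_ground_truth(sim$truth, spec, dir)
  expect_true(all(file.exists(files)))
  doms <- read_domains_bed(files[["domains"]], 1e4)
  expect_equal(nrow(doms), nrow(sim$truth$domains))
  loops <- read_loops_bedpe(files[["loops"]])
  expect_equal(nrow(loops), nrow(sim$truth$loops))
})
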
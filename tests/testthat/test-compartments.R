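comp_oe <- function(spec) {
  sim <- simulate_contact_matrix(spec)
  bal <- compute_normalization(sim$matrix, "balanced")
  observed_over_expected(apply_normalization(sim$matrix, bal))
}

test_that("the reference vector recovers a planted checkerboard", {
  agr <- c()
  for (s in 1:3) {
    spec <- compartment_fixture_spec(s)
    oe <- comp_oe(spec)
    ref <- reference_compartment_vector(oe, min_separation = 0)
    tr <- sign(spec$compartment_vector)
    agr <- c(agr, max(mean(sign(ref) == tr, na.rm = TRUE),
                      mean(sign(-ref) == tr, na.rm = TRUE)))
    expect_false(attr(ref, "degenerate"))
  }
  expect_gte(mean(agr), 0.95)
})

test_that("a structureless matrix yields a degenerate flag", {
  spec <- synthetic_spec(300, 25000, 1, depth = 100, seed = 4)
  oe <- comp_oe(spec)
  ref <- reference_compartment_vector(oe, min_separation = 0)
  expect_true(attr(ref, "degenerate"))
  expect_error(reference_compartment_vector(
    contact_matrix(bin_table("c", 1e5, 1e4))), "unmasked")
})

test_that("orientation flips anticorrelated vectors and rejects flat marks", {
  v <- c(rep(1, 50), rep(-1, 50)) + rnorm(100, sd = 0.01)
  mark <- c(rep(10, 50), rep(1, 50))
  expect_equal(orient_by_signal(v, mark), v)
  expect_equal(orient_by_signal(-v, mark), v)
  expect_error(orient_by_signal(v, rep(2, 100)), "zero-variance")
  expect_error(orient_by_signal(v, mark[1:50]), "length")
})

test_that("global sign flips do not change |projection| downstream", {
  spec <- compartment_fixture_spec(2)
  oe <- comp_oe(spec)
  ref <- reference_compartment_vector(oe, min_separation = 0)
  p1 <- project_compartment_score(oe, ref)
  p2 <- project_compartment_score(oe, -ref)
  expect_equal(abs(p1), abs(p2))
})

test_that("score normalization is centred, scaled to [-1, 1], idempotent", {
  set.seed(2)
  raw <- rnorm(200, mean = 3, sd = 2)
  raw[sample(200, 10)] <- NA
  tr <- normalize_scores(raw)
  ok <- !is.na(tr$score)
  expect_equal(mean(tr$score[ok]), 0, tolerance = 1e-12)
  expect_equal(max(abs(tr$score[ok])), 1)
  expect_true(all(tr$label[ok][tr$score[ok] > 0] == "A"))
  expect_true(all(tr$label[ok][tr$score[ok] < 0] == "B"))
  tr2 <- normalize_scores(tr$score)
  expect_equal(tr2$score, tr$score, tolerance = 1e-12)
  expect_warning(z <- normalize_scores(rep(4, 5)), "equal")
  expect_true(all(z$score == 0) && all(is.na(z$label)))
})

test_that("projection self-consistency holds on the compartment fixture", {
  agr <- c()
  for (s in 1:3) {
    spec <- compartment_fixture_spec(s)
    oe <- comp_oe(spec)
    ref <- reference_compartment_vector(oe, min_separation = 0)
    set.seed(s + 13)
    tr <- sign(spec$compartment_vector)
    mark <- rpois(1000, 5 + 10 * (tr > 0))
    oriented <- orient_by_signal(ref, mark)
    track <- normalize_scores(project_compartment_score(oe, oriented))
    ok <- !is.na(track$label) & !is.na(oriented)
    agr <- c(agr, mean(track$label[ok] == ifelse(oriented[ok] > 0, "A", "B")))
    # sign coherence: A bins carry more active mark than B bins
    expect_gt(mean(mark[track$label == "A"], na.rm = TRUE),
              mean(mark[track$label == "B"], na.rm = TRUE))
  }
  expect_gte(mean(agr), 0.95)
})

test_that("switch tracking counts transitions and excludes masked bins", {
  t1 <- normalize_scores(c(1, 1, -1, -1, NA, 2))
  t2 <- normalize_scores(c(1, -2, -1, 1.5, 1, NA))
  expect_error(switch_tracking(list(t1)), "two tracks")
  sw <- switch_tracking(list(t1, t2))
  expect_equal(sw$n, 4L)          # bins 5 and 6 masked in one of the two
  expect_equal(sw$A_to_B, 1L)     # bin 2
  expect_equal(sw$B_to_A, 1L)     # bin 4
  expect_equal(sw$stable_A + sw$stable_B, 2L)
  # identical tracks -> zero switches; inverted -> all switch
  expect_equal(switch_tracking(list(t1, t1))$switch_fraction, 0)
  t1m <- t1; t1m$label <- chartr("AB", "BA", t1$label)
  expect_equal(switch_tracking(list(t1, t1m))$switch_fraction, 1)
})

test_that("planted 10%-per-step switching is recovered across stages", {
  errs <- c()
  for (s in 1:3) {
    specs <- compartment_stage_series(s, n_stages = 3)
    orient <- NULL
    tracks <- list()
    for (k in seq_along(specs)) {
      oe <- comp_oe(specs[[k]])
      if (k == 1L) {
        ref <- reference_compartment_vector(oe, min_separation = 0)
        set.seed(s + 13)
        tr <- sign(specs[[1]]$compartment_vector)
        mark <- rpois(1000, 5 + 10 * (tr > 0))
        orient <- orient_by_signal(ref, mark)
      }
      tracks[[k]] <- normalize_scores(project_compartment_score(oe, orient),
                                      id = as.character(k))
    }
    sw <- switch_tracking(tracks)
    planted <- vapply(2:length(specs), function(k)
      mean(sign(specs[[k]]$compartment_vector) !=
             sign(specs[[k - 1]]$compartment_vector)), numeric(1))
    errs <- c(errs, abs(sw$switch_fraction - planted))
  }
  expect_lt(max(errs), 0.05)
})
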
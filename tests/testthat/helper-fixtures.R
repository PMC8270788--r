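# shared fixture builders -- everything is generated in code at test time

# a contact matrix with the given dense symmetric matrix
cm_from_dense <- function(m, bin_size = 10000L, chrom = "chrT", tag = "raw") {
  n <- nrow(m)
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  cm <- contact_matrix(bin_table(chrom, n * bin_size, bin_size),
                       idx[, 1] - 1L, idx[, 2] - 1L, m[idx], tag = tag)
  cm
}

# random symmetric non-negative count matrix
random_dense <- function(n, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n * n, lambda), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# two pseudo-callers: the internal caller's set jittered by +/- 1 bin
jittered_callers <- function(called, seed, bs, max_bp) {
  jit <- function(label, s2) {
    set.seed(s2)
    df <- as.data.frame(called)
    if (!nrow(df)) return(domain_set(df, bs))
    df$start <- pmax(df$start + sample(c(-1L, 0L, 1L), nrow(df), TRUE) * bs, 0L)
    df$end <- pmin(df$end + sample(c(-1L, 0L, 1L), nrow(df), TRUE) * bs, max_bp)
    df <- df[df$end - df$start >= bs, , drop = FALSE]
    df$source <- label
    df <- df[!duplicated(df[, c("chrom", "start", "end")]), , drop = FALSE]
    domain_set(df, bs)
  }
  list(jit("pseudoA", seed + 500L), jit("pseudoB", seed + 900L))
}

# simulate + normalize + call + merge + filter: the consensus chain used
# by several suites
run_consensus <- function(seed) {
  spec <- default_fixture_spec(seed)
  sim <- simulate_contact_matrix(spec)
  cm <- sim$matrix
  bal <- compute_normalization(cm, "balanced")
  cmb <- apply_normalization(cm, bal)
  ins <- insulation_score(cmb, 40L)
  called <- call_domains_insulation(ins, cm$bins)
  ps <- jittered_callers(called, seed, bin_size(cm), n_bins(cm) * bin_size(cm))
  merged <- merge_domain_sets(c(list(called), ps), ins, 4L)
  filtered <- filter_domains(low_density_filter(merged, cm, 0.05), cmb)
  list(spec = spec, sim = sim, cm = cm, cmb = cmb, bal = bal,
       ins = ins, called = called, merged = merged, filtered = filtered)
}

# planted truth cluster labels (1 = 5'-biased, 2 = symmetric, 3 = 3'-biased)
truth_cluster_labels <- function(domains) {
  ifelse(domains$asymmetry > 1, 1L, ifelse(domains$asymmetry < -1, 3L, 2L))
}
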
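#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults
#' matching the analysis constants used throughout the package: 40-bin
#' DI/insulation block (400 kb at 10-kb bins), 4-bin border merge
#' window, diamond-score floor 0.6, 100-kb minimum domain size, 2-Mb
#' loop distance cap with vanilla-coverage floor 1 over a +/- 5-kb
#' anchor window, min(50 kb, 0.2 L) corner tolerance, 3 border
#' clusters with 5 subclusters, and a 90 x 90 aggregate grid with 50%
#' flanks.
#'
#' @param spec a [synthetic_spec()] to simulate from, or `NULL` when
#'   file inputs are given.
#' @param matrix_path,bins_path triplet matrix and bin-table files
#'   (used when `spec` is `NULL`).
#' @param out_dir output directory.
#' @param seed master seed for every random step.
#' @param block_bins,merge_window,ds_min,min_size,prominence,
#'   low_density_quantile domain-calling knobs.
#' @param loop_max_distance,vc_floor,loop_neighborhood loop filters.
#' @param corner_tol_bp,corner_tol_frac loop-domain corner tolerance.
#' @param k,n_sub,cluster_flank border-clustering knobs.
#' @param grid,flank_fraction aggregation knobs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(spec = NULL, matrix_path = NULL,
                            bins_path = NULL, out_dir = tempfile("hicarch_"),
                            seed = 1L, block_bins = 40L, merge_window = 4L,
                            ds_min = 0.6, min_size = 100000,
                            prominence = 0.2, low_density_quantile = 0.05,
                            loop_max_distance = 2e6, vc_floor = 1,
                            loop_neighborhood = 5000,
                            corner_tol_bp = 50000, corner_tol_frac = 0.2,
                            k = 3L, n_sub = 5L, cluster_flank = 5L,
                            grid = 90L, flank_fraction = 0.5) {
  if (is.null(spec) && (is.null(matrix_path) || is.null(bins_path)))
    stop("provide either a synthetic spec or matrix + bin-table paths")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full chromosome-architecture pipeline
#'
#' Simulate-or-load -> normalize (VC + balanced) -> DI/insulation ->
#' internal caller plus two jittered pseudo-callers -> border merge ->
#' diamond/size/density filters -> loop filtering and loop-domain
#' annotation -> border DI clustering, DI bias and subclusters ->
#' aggregate map -> compartment scores and A/B labels.  Every
#' intermediate artifact is written under `config$out_dir` and a run
#' report plus a manifest (with config hash and seed) is returned and
#' serialized as JSON.  Reruns with the same config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return the run report (invisibly also written to
#'   `report.json`): per-stage counts and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  truth <- NULL
  if (!is.null(config$spec)) {
    sim <- simulate_contact_matrix(config$spec)
    cm <- sim$matrix
    truth <- sim$truth
    write_bin_table(cm$bins, file.path(config$out_dir, "bins.tsv"))
    write_contact_matrix(cm, file.path(config$out_dir, "matrix.tsv"))
    write_ground_truth(truth, config$spec, config$out_dir)
  } else {
    bt <- read_bin_table(config$bins_path)
    cm <- read_contact_matrix(config$matrix_path, bt)
  }
  bs <- bin_size(cm)

  vc <- compute_normalization(cm, "VC")
  cm_vc <- apply_normalization(cm, vc)
  bal <- compute_normalization(cm, "balanced")
  cm_bal <- apply_normalization(cm, bal)
  write_bedgraph(cm$bins, bal$weights,
                 file.path(config$out_dir, "balanced_weights.bedgraph"))

  di <- directionality_index(cm_bal, config$block_bins)
  ins <- insulation_score(cm_bal, config$block_bins)
  write_bedgraph(cm$bins, as.numeric(di),
                 file.path(config$out_dir, "di.bedgraph"))
  write_bedgraph(cm$bins, as.numeric(ins),
                 file.path(config$out_dir, "insulation.bedgraph"))

  called <- call_domains_insulation(ins, cm$bins, config$prominence,
                                    source = "insulation")
  jitter_set <- function(ds, label) {
    df <- as.data.frame(ds)
    if (!nrow(df)) return(domain_set(df, bs))
    sh <- sample(c(-1L, 0L, 1L), nrow(df), replace = TRUE) * bs
    df$start <- pmax(df$start + sh, 0L)
    sh2 <- sample(c(-1L, 0L, 1L), nrow(df), replace = TRUE) * bs
    df$end <- pmin(df$end + sh2, n_bins(cm) * bs)
    df <- df[df$end - df$start >= bs, , drop = FALSE]
    df$source <- label
    df <- df[!duplicated(df[, c("chrom", "start", "end")]), , drop = FALSE]
    domain_set(df, bs)
  }
  set.seed(config$seed + 1L)   # same pseudo-callers for both input routes
  pseudo1 <- jitter_set(called, "pseudoA")
  pseudo2 <- jitter_set(called, "pseudoB")
  merged <- merge_domain_sets(list(called, pseudo1, pseudo2), ins,
                              config$merge_window)
  ## density floor first, while the candidate pool still contains the
  ## weak calls that anchor the quantile; then the diamond/size filter
  filtered <- low_density_filter(merged, cm, config$low_density_quantile)
  filtered <- filter_domains(filtered, cm_bal, config$ds_min, config$min_size)
  write_domains_bed(filtered, file.path(config$out_dir, "domains.bed"))

  ## candidate loops: planted anchors (when simulating) plus random decoys
  loops <- NULL
  if (!is.null(truth) && !is.null(truth$loops) && nrow(truth$loops)) {
    lp <- truth$loops
    cand <- data.frame(chrom = cm$bins$chrom[1],
                       start1 = lp$a1 * bs, end1 = (lp$a1 + 1L) * bs,
                       start2 = lp$a2 * bs, end2 = (lp$a2 + 1L) * bs,
                       strength = lp$fold)
    n_decoy <- max(2L, nrow(lp))
    da <- sort(sample.int(n_bins(cm) - 10L, n_decoy))
    dlen <- sample(150:400, n_decoy, replace = TRUE)  # some beyond 2 Mb
    db <- pmin(da + dlen, n_bins(cm) - 1L)
    cand <- rbind(cand, data.frame(chrom = cm$bins$chrom[1],
                                   start1 = da * bs, end1 = (da + 1L) * bs,
                                   start2 = db * bs, end2 = (db + 1L) * bs,
                                   strength = NA_real_))
    loops <- filter_loops(cand, cm_vc, config$loop_max_distance,
                          config$vc_floor, config$loop_neighborhood)
    write_loops_bedpe(loops, file.path(config$out_dir, "loops.bedpe"))
  }
  annotated <- annotate_loop_domains(filtered, loops,
                                     config$corner_tol_bp,
                                     config$corner_tol_frac)
  adf <- as.data.frame(annotated)
  write_domains_bed(annotated, file.path(config$out_dir,
                                         "domains_annotated.bed"))
  if (nrow(adf)) {
    write_domains_bed(domain_set(adf[adf$loop_domain, , drop = FALSE], bs),
                      file.path(config$out_dir, "loop_domains.bed"))
    write_domains_bed(domain_set(adf[!adf$loop_domain, , drop = FALSE], bs),
                      file.path(config$out_dir, "ordinary_domains.bed"))
  }

  ## border clustering
  X <- border_di_vectors(annotated, di, config$cluster_flank)
  clus <- if (sum(!attr(X, "mask")) >= config$k)
    kmeans_border_clusters(X, config$k, seed = config$seed)
  else list(labels = rep(NA_integer_, nrow(X)), degenerate = TRUE)
  bias <- vapply(seq_len(nrow(adf)), function(kk)
    di_bias(adf$start[kk], adf$end[kk], di, bs), numeric(1))
  sub_labels <- rep(NA_integer_, nrow(adf))
  in2 <- which(!is.na(clus$labels) & clus$labels == 2L & !is.na(bias))
  if (length(in2) >= config$n_sub)
    sub_labels[in2] <- subcluster_by_di_strength(bias[in2], adf$start[in2],
                                                 config$n_sub)
  clus_df <- data.frame(chrom = adf$chrom, start = adf$start,
                        end = adf$end, cluster = clus$labels,
                        di_bias = bias, subcluster = sub_labels)
  utils::write.table(clus_df, file.path(config$out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## aggregation
  agg <- if (nrow(adf)) aggregate_domains(cm_bal, annotated, config$grid,
                                          config$flank_fraction) else NULL
  if (!is.null(agg))
    utils::write.table(unclass(agg),
                       file.path(config$out_dir, "aggregate.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)

  ## compartments at the native resolution of the input matrix
  oe <- observed_over_expected(cm_bal)
  comp <- tryCatch({
    ref <- reference_compartment_vector(oe)
    mark <- if (!is.null(truth) && !is.null(truth$compartment_value)) {
      set.seed(config$seed + 13L)
      stats::rpois(length(truth$compartment_value),
                   5 + 10 * (truth$compartment_value > 0))
    } else NULL
    oriented <- if (!is.null(mark)) orient_by_signal(ref, mark) else ref
    normalize_scores(project_compartment_score(oe, oriented), id = "run")
  }, error = function(e) NULL)
  if (!is.null(comp))
    write_bedgraph(cm$bins, comp$score,
                   file.path(config$out_dir, "compartment.bedgraph"))

  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_ser <- config
  cfg_ser$spec <- if (is.null(config$spec)) NULL else
    lapply(config$spec[c("n_bins", "bin_size", "decay_exponent", "depth",
                         "seed", "chrom")], identity)
  jsonlite::write_json(cfg_ser[!vapply(cfg_ser, is.null, logical(1))],
                       cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- list(
    seed = config$seed,
    n_bins = n_bins(cm),
    pixels = nrow(cm$entries),
    balancing_rel_sd = bal$convergence_stat,
    domains_called = nrow(as.data.frame(called)),
    domains_merged = nrow(as.data.frame(merged)),
    domains_filtered = nrow(adf),
    loops_kept = if (is.null(loops)) 0L else nrow(loops),
    loop_domain_fraction = if (nrow(adf)) mean(adf$loop_domain) else NA,
    cluster_sizes = as.list(table(factor(clus$labels, levels = 1:config$k))),
    compartment_A_fraction = if (is.null(comp)) NA else
      mean(comp$label == "A", na.rm = TRUE),
    config_hash = unname(tools::md5sum(cfg_path)),
    outputs = list.files(config$out_dir)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
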
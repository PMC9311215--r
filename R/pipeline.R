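#' Run the full candidate-locus pipeline
#'
#' Orchestrates filtering, demographic statistics, the genome scan for
#' outliers, genotype-environment association with the random-variable null
#' control, geometric-mean combination and confidence classification, and
#' writes per-stage TSVs plus a run log. External q-value tables (e.g. from
#' Bayesian scans) can substitute for, or be combined with, the in-house
#' methods via the adapter arguments.
#'
#' The single `seed` is fanned out to per-stage seeds by fixed offsets
#' (tag thinning +1, scan +2, random variables +3, permutations +4), so any
#' stage can be reproduced in isolation.
#'
#' @param g A [genotype_matrix()]; or `NULL` to simulate from `sim`.
#' @param pm A [population_map()] (ignored when simulating).
#' @param env Environment table (ignored when simulating).
#' @param sim Optional [sim_config()] used when `g` is `NULL`.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param filter Apply [apply_filters()] first (default `TRUE`).
#' @param filter_cfg A [filter_config()].
#' @param k Number of scan axes, or `NULL` for [choose_k()].
#' @param r2_max Collinearity ceiling for [preprocess_env()].
#' @param n_perm Permutations for the RDA full-model test.
#' @param combine_cfg A [combine_config()].
#' @param external_gso,external_gea Optional paths to external q-value TSVs
#'   ([ingest_external_scan()] / [ingest_external_gea()] formats). When
#'   given, they are combined with the in-house scan; otherwise the in-house
#'   method stands alone (self-combination, which is exact for a geometric
#'   mean).
#' @param seed Master seed.
#' @return A run report: list with `gso` (classified outlier table), `gea`
#'   (classified association table), `summary` (per-method / random /
#'   combined / high-confidence counts), `diversity`, `full_model`,
#'   `filter_report`, `k`, `lambda`, `settings`, `files`.
#' @export
run_pipeline <- function(g = NULL, pm = NULL, env = NULL, sim = NULL,
                         out_dir = NULL, filter = TRUE,
                         filter_cfg = filter_config(), k = NULL,
                         r2_max = 0.7, n_perm = 999,
                         combine_cfg = combine_config(),
                         external_gso = NULL, external_gea = NULL,
                         seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(g)) {
    sim <- sim %||% sim_config(seed = seed)
    simdat <- simulate_snp_data(sim)
    g <- simdat$genotypes
    pm <- simdat$pop_map
    env <- simdat$env
  }
  if (is.null(pm) || is.null(env)) abort("pm and env are required when g is given.")

  files <- character(0)
  emit <- function(tab, name) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      path <- file.path(out_dir, paste0(name, ".tsv"))
      write_results(tab, path)
      files[[name]] <<- path
    }
  }

  # stage 1: filters -------------------------------------------------------
  filter_report <- NULL
  if (filter) {
    filter_cfg$seed <- seed + 1L
    g <- apply_filters(g, pm, filter_cfg)
    filter_report <- attr(g, "filter_report")
  }

  # stage 2: demographic statistics ---------------------------------------
  div <- diversity(g, pm)
  emit(glance(div), "diversity")

  # stage 3: genome scan for outliers --------------------------------------
  if (is.null(k)) k <- choose_k(g, max_k = min(10, n_individuals(g) - 1))$k
  scan <- with_local_seed(seed + 2L, pcadapt_scan(g, k))
  scan_b <- if (!is.null(external_gso)) {
    ingest_external_scan(external_gso, g)
  } else {
    scan
  }
  gso <- classify_gso(scan, scan_b, combine_cfg)
  gso_screen <- flag_suspect_outliers(g, pm, dplyr::filter(gso, .data$in_combined))
  emit(gso, "gso_candidates")

  # stage 4: genotype-environment association ------------------------------
  g_complete <- drop_population_missing_loci(g, pm)
  g_imp <- impute_modal(g_complete, pm)
  prep <- preprocess_env(env, r2_max = r2_max)
  full_model <- rda_full_model_test(g_imp, pm, prep$env, n_perm = n_perm,
                                    seed = seed + 4L)
  gea_real <- rda_associations(g_imp, pm, prep$env)
  gea_real_b <- if (!is.null(external_gea)) {
    ingest_external_gea(external_gea, env = env)
  } else {
    gea_real
  }
  real_combined <- combine_gea(gea_real, gea_real_b)

  ranenv <- make_random_env(unique(pm$population_id),
                            count = combine_cfg$n_random, seed = seed + 3L)
  gea_random <- rda_associations(g_imp, pm, ranenv, per_variable = TRUE)
  random_combined <- combine_gea(gea_random, gea_random)
  hits <- random_hit_counts(random_combined, combine_cfg)

  gea_class <- classify_gea(real_combined, hits, combine_cfg)
  emit(gea_class, "gea_candidates")

  # summary in the per-method / random / combined / high-confidence layout -
  alpha <- combine_cfg$alpha
  summary <- tibble(
    treatment = c("real_variables_rda", "real_variables_external",
                  "random_5pct", "combined_q", "high_confidence"),
    n_loci = c(
      length(unique(gea_real$table$locus_id[gea_real$table$q_value < alpha])),
      length(unique(gea_real_b$table$locus_id[gea_real_b$table$q_value < alpha])),
      sum(hits$n_random_hits >= combine_cfg$random_hit_max),
      length(unique(gea_class$locus_id[gea_class$significant])),
      length(unique(gea_class$locus_id[gea_class$class == "high-confidence"]))
    )
  )
  emit(summary, "summary")

  report <- list(
    gso = gso, gso_screen = gso_screen, gea = gea_class, summary = summary,
    diversity = div, full_model = full_model, hits = hits,
    filter_report = filter_report, k = k, lambda = scan$lambda,
    settings = list(alpha = alpha, r2_max = r2_max, maf_min = filter_cfg$maf_min,
                    random_hit_max = combine_cfg$random_hit_max,
                    n_random = combine_cfg$n_random, n_perm = n_perm,
                    seed = seed),
    files = files
  )
  if (!is.null(out_dir)) {
    log_lines <- c(
      paste0("adaptscan ", as.character(utils::packageVersion("adaptscan"))),
      paste0("seed: ", seed),
      paste0("alpha: ", alpha, "; r2_max: ", r2_max, "; maf_min: ",
             filter_cfg$maf_min, "; random_hit_max: ",
             combine_cfg$random_hit_max, "/", combine_cfg$n_random,
             "; n_perm: ", n_perm),
      paste0("k: ", k, "; lambda: ", signif(scan$lambda, 4)),
      if (!is.null(filter_report)) {
        paste0("filter removed: ",
               paste(filter_report$step, filter_report$removed,
                     collapse = ", "))
      }
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  report
}
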
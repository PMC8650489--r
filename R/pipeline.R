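#' Analysis configuration
#'
#' Bundles every tunable of the group-network pipeline with its standard
#' default: 50\% density target, 5\% sparse-node elimination, 0.5 mm motion
#' censoring, square-root-of-n histogram bins, 100 modularity runs, 20,000
#' permutation randomizations, alpha = 0.05 Bonferroni-corrected over
#' `m_comparisons` tests.
#'
#' @param cohort Either a [cohort_spec()] (the cohort is simulated) or a
#'   `cohort` list as returned by [simulate_cohort()] / [read_cohort_tsv()].
#' @param design Task design; required when `cohort` is not a `cohort_spec`.
#' @param n_bins Histogram bins per series for the NMI estimator; `NULL`
#'   means `ceiling(sqrt(n_retained_volumes))`.
#' @param density_target Edge density for graph thresholding.
#' @param min_node_frac Nodal-elimination fraction of possible connections.
#' @param motion_threshold_mm Censoring threshold, mm per TR.
#' @param n_mod_runs Modularity-optimization runs entering the consensus.
#' @param n_perm Permutation-test randomizations.
#' @param alpha Family-wise significance level.
#' @param m_comparisons Bonferroni divisor.
#' @param seed Master seed for consensus runs and permutation tests.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(cohort, design = NULL, n_bins = NULL,
                            density_target = 0.5, min_node_frac = 0.05,
                            motion_threshold_mm = 0.5, n_mod_runs = 100L,
                            n_perm = 20000L, alpha = 0.05,
                            m_comparisons = 20L, seed = 1L) {
  if (inherits(cohort, "cohort_spec")) {
    design <- cohort$design
  } else if (!inherits(cohort, "cohort")) {
    stop("`cohort` must be a cohort_spec or a cohort list", call. = FALSE)
  } else if (is.null(design)) {
    stop("`design` is required when passing a simulated/loaded cohort",
         call. = FALSE)
  }
  if (density_target <= 0 || density_target > 1)
    stop("`density_target` must be in (0, 1]", call. = FALSE)
  structure(list(
    cohort = cohort, design = design, n_bins = n_bins,
    density_target = density_target, min_node_frac = min_node_frac,
    motion_threshold_mm = motion_threshold_mm,
    n_mod_runs = as.integer(n_mod_runs), n_perm = as.integer(n_perm),
    alpha = alpha, m_comparisons = as.integer(m_comparisons),
    seed = as.integer(seed)
  ), class = "analysis_config")
}

# Per-subject stage: censor -> task-select -> NMI -> threshold -> eliminate.
process_subject <- function(ts, motion, design, config) {
  keep <- censor_motion(motion, config$motion_threshold_mm)
  ts_task <- select_task_volumes(ts, design, keep)
  nmi <- build_connectivity_matrix(ts_task, n_bins = config$n_bins)
  g <- brain_graph(nmi, n_original = nrow(nmi))
  g <- threshold_to_density(g, config$density_target)
  eliminate_sparse_nodes(g, config$min_node_frac)
}

#' Run the full group network analysis
#'
#' Executes the pipeline end to end. Per subject: motion censoring, task
#' volume selection, NMI connectivity, density thresholding and sparse-node
#' elimination. Per group: reduction to the common node set, group
#' averaging, re-thresholding, network metrics, consensus modular
#' decomposition, hub classification. Across each pair of groups: node-wise
#' permutation t-tests on the four metrics with a Bonferroni threshold, the
#' partition distance (on the two networks' shared nodes) with its
#' permutation test, and hub-set comparison.
#'
#' @param config An [analysis_config()].
#' @return An object of class `network_report` (see Details) with elements
#'   `groups` (per-group networks, metrics, partitions, hub tables and node
#'   counts), `comparisons` (per group pair: metric tests, pd test, hub
#'   overlap), `config` and `provenance`.
#' @export
run_group_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- if (inherits(config$cohort, "cohort_spec"))
    simulate_cohort(config$cohort) else config$cohort
  design <- config$design
  groups <- unique(vapply(cohort, `[[`, "", "group"))
  if (length(cohort) < 1) stop("empty cohort", call. = FALSE)

  subject_graphs <- lapply(cohort, function(s)
    tryCatch(process_subject(s$ts, s$motion, design, config),
             error = function(e) stop(sprintf(
               "subject-level stage failed for %s: %s", s$id,
               conditionMessage(e)), call. = FALSE)))

  group_results <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    idx <- vapply(cohort, function(s) s$group == grp, TRUE)
    graphs <- subject_graphs[idx]
    reduced <- tryCatch(reduce_to_common_nodes(graphs),
                        error = function(e) stop(sprintf(
                          "group '%s': %s", grp, conditionMessage(e)),
                          call. = FALSE))
    net <- group_average_network(reduced, config$density_target)
    metr <- network_metrics(net)
    part <- consensus_partition(net, n_runs = config$n_mod_runs,
                                seed = mix_seed(config$seed, 1000L + gi))
    hubs <- classify_nodes(net, part)
    group_results[[grp]] <- list(
      n_subjects = sum(idx),
      n_original = net$n_original,
      n_nodes = length(net$node_names),
      subject_node_counts = vapply(graphs, function(g)
        length(g$node_names), 1L),
      network = net, density = graph_density(net), metrics = metr,
      partition = part, n_modules = max(part$affiliation), hubs = hubs)
  }

  comparisons <- list()
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    metric_cols <- c("degree_norm", "strength_norm", "clustering", "efficiency")
    for (pi in seq_along(pairs)) {
      ga <- group_results[[pairs[[pi]][1L]]]
      gb <- group_results[[pairs[[pi]][2L]]]
      thr <- bonferroni_threshold(config$alpha, config$m_comparisons)
      tests <- lapply(seq_along(metric_cols), function(mi) {
        col <- metric_cols[mi]
        res <- permutation_ttest(
          ga$metrics$per_node[[col]], gb$metrics$per_node[[col]],
          n_perm = config$n_perm,
          seed = mix_seed(config$seed, 2000L + 10L * pi + mi))
        list(metric = col, statistic = res$observed, p_value = res$p_value,
             n_perm = res$n_perm, significant = res$p_value < thr)
      })
      names(tests) <- metric_cols
      common <- intersect(ga$network$node_names, gb$network$node_names)
      pd_res <- NULL
      pd <- NA_real_
      if (length(common) >= 2) {
        pa <- ga$partition$affiliation[common]
        pb <- gb$partition$affiliation[common]
        pd <- partition_distance(pa, pb)
        pd_res <- partition_distance_test(
          pa, pb, n_perm = config$n_perm,
          seed = mix_seed(config$seed, 3000L + pi))
      }
      comparisons[[paste(pairs[[pi]], collapse = "_vs_")]] <- list(
        groups = pairs[[pi]], bonferroni_threshold = thr,
        metric_tests = tests, pd = pd, pd_test = pd_res,
        n_shared_nodes = length(common),
        hub_overlap = compare_hub_tables(ga$hubs, gb$hubs))
    }
  }

  structure(list(
    groups = group_results, comparisons = comparisons, config = config,
    provenance = list(
      package_version = as.character(utils::packageVersion("nmigraph")),
      seed = config$seed,
      n_bins_policy = if (is.null(config$n_bins)) "ceiling(sqrt(n))"
                      else as.character(config$n_bins),
      permutation_unit = "node",
      pd_test_alternative = "less")
  ), class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  cat("Group network analysis report\n")
  for (grp in names(x$groups)) {
    g <- x$groups[[grp]]
    m <- g$metrics$global
    cat(sprintf(
      "  %s (n=%d): %d of %d regions in network (density %.2f)\n", grp,
      g$n_subjects, g$n_nodes, g$n_original, g$density))
    cat(sprintf(
      "    degree %.2f ± %.2f | strength %.2f ± %.2f | clustering %.2f ± %.2f | efficiency %.2f ± %.2f\n",
      m$mean_degree_norm, m$sd_degree_norm, m$mean_strength_norm,
      m$sd_strength_norm, m$mean_clustering, m$sd_clustering,
      m$global_efficiency, m$sd_efficiency))
    counts <- table(g$hubs$hub_class)
    cat(sprintf(
      "    %d modules (Q=%.3f) | hubs: %d connector, %d provincial; %d high-influence\n",
      g$n_modules, g$partition$q, counts[["connector"]],
      counts[["provincial"]], counts[["high_influence"]]))
  }
  for (nm in names(x$comparisons)) {
    cp <- x$comparisons[[nm]]
    cat(sprintf("  %s: pd = %.3f (p = %.4g over %d shared nodes)\n", nm,
                cp$pd, if (!is.null(cp$pd_test)) cp$pd_test$p_value else NA,
                cp$n_shared_nodes))
    for (t in cp$metric_tests)
      cat(sprintf("    %-13s t = %7.3f, p = %.4g%s\n", t$metric, t$statistic,
                  t$p_value, if (t$significant) " *" else ""))
    cat(sprintf("    (Bonferroni threshold p < %.4g)\n", cp$bonferroni_threshold))
  }
  invisible(x)
}

#' @export
summary.network_report <- function(object, ...) {
  rows <- lapply(names(object$groups), function(grp) {
    g <- object$groups[[grp]]
    m <- g$metrics$global
    data.frame(group = grp, n_subjects = g$n_subjects, n_nodes = g$n_nodes,
               n_original = g$n_original, density = g$density,
               mean_degree = m$mean_degree_norm,
               mean_strength = m$mean_strength_norm,
               mean_clustering = m$mean_clustering,
               global_efficiency = m$global_efficiency,
               n_modules = g$n_modules, q = g$partition$q,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize a report to JSON
#'
#' Writes every reportable number (node counts, metric summaries, module
#' counts and Q, partition distances and p-values, hub class counts,
#' configuration and provenance) as a JSON document; graph adjacency
#' matrices are left to [write_adjacency_tsv()].
#'
#' @param report A [run_group_analysis()] result.
#' @param path Output file.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "network_report"))
  slim_groups <- lapply(report$groups, function(g) {
    counts <- table(g$hubs$hub_class)
    list(n_subjects = g$n_subjects, n_nodes = g$n_nodes,
         n_original = g$n_original, density = g$density,
         subject_node_counts = unname(g$subject_node_counts),
         metrics = g$metrics$global, n_modules = g$n_modules,
         q = g$partition$q,
         hub_counts = as.list(setNames(as.integer(counts), names(counts))))
  })
  slim_cmp <- lapply(report$comparisons, function(cp) {
    list(groups = cp$groups, bonferroni_threshold = cp$bonferroni_threshold,
         metric_tests = lapply(cp$metric_tests, function(t)
           t[c("metric", "statistic", "p_value", "n_perm", "significant")]),
         pd = cp$pd,
         pd_p_value = if (!is.null(cp$pd_test)) cp$pd_test$p_value else NULL,
         n_shared_nodes = cp$n_shared_nodes)
  })
  cfg <- report$config
  cfg$cohort <- NULL; cfg$design <- NULL
  jsonlite::write_json(
    list(groups = slim_groups, comparisons = slim_cmp,
         config = unclass(cfg), provenance = report$provenance),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
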
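#' Configuration for an end-to-end pipeline run
#'
#' Validates thresholds up front so misconfigured runs fail before any stage
#' executes. Either `input_dir` (a directory of the five input files, as
#' written by [write_bundle()]) or `simulate` (a [regime_spec()]) must be
#' given.
#'
#' @param input_dir directory holding asv_table.tsv, taxonomy.tsv, tree.nwk,
#'   metadata.tsv, enzymes.tsv.
#' @param simulate a [regime_spec()] to generate inputs instead.
#' @param limitation enzyme ground-truth scenario when simulating.
#' @param stages which stages to run (structure, enzymes, assembly, network).
#' @param subsets community subsets for the assembly stage (whole, abundant,
#'   rare).
#' @param rare_cut,abund_cut abundance partition cutoffs.
#' @param n_null null draws for betaNTI / Raup-Crick.
#' @param n_perm permutations for PERMANOVA / Mantel.
#' @param prevalence occupancy filter before the network stage.
#' @param threshold fixed correlation cutoff; `NULL` (default) selects it by
#'   [rmt_threshold()].
#' @param t_grid candidate grid for the RMT threshold scan.
#' @param seed run seed; every stochastic stage derives its own child seed
#'   from it.
#' @param out_dir optional output directory for stage TSVs and the summary
#'   JSON.
#' @return a validated `crust_config` list.
#' @export
crust_config <- function(input_dir = NULL, simulate = NULL,
                         limitation = "balanced",
                         stages = c("structure", "enzymes", "assembly",
                                    "network"),
                         subsets = c("whole", "abundant", "rare"),
                         rare_cut = 0.001, abund_cut = 0.01,
                         n_null = 199, n_perm = 999, prevalence = 0.25,
                         threshold = NULL, t_grid = seq(0.30, 0.90, 0.01),
                         seed = 1, out_dir = NULL) {
  if (is.null(input_dir) && is.null(simulate))
    stopf("either input_dir or a simulate spec is required")
  if (rare_cut <= 0 || abund_cut >= 1 || rare_cut >= abund_cut)
    stopf("need 0 < rare_cut < abund_cut < 1")
  if (n_null < 1 || n_perm < 1) stopf("n_null and n_perm must be >= 1")
  if (prevalence <= 0 || prevalence > 1) stopf("prevalence must be in (0, 1]")
  stages <- match.arg(stages, several.ok = TRUE)
  subsets <- match.arg(subsets, several.ok = TRUE)
  structure(list(input_dir = input_dir, simulate = simulate,
                 limitation = limitation, stages = stages, subsets = subsets,
                 rare_cut = rare_cut, abund_cut = abund_cut,
                 n_null = as.integer(n_null), n_perm = as.integer(n_perm),
                 prevalence = prevalence, threshold = threshold,
                 t_grid = t_grid, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "crust_config")
}

#' Run the full analysis pipeline
#'
#' Loads or simulates the five inputs, validates their consistency, then
#' runs the requested stages: community structure (partition, diversity,
#' ordination, PERMANOVA by site), enzyme stoichiometry, assembly
#' (betaNTI/Raup-Crick per subset plus Mantel tests), and the co-occurrence
#' network. Identical config + seed reproduces identical numeric output.
#'
#' @param config a [crust_config()].
#' @return a `crust_summary` list with one element per stage; written as
#'   TSV/JSON under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "crust_config"))
  seeds <- stage_seeds(config$seed)
  bundle <- if (!is.null(config$input_dir)) read_bundle(config$input_dir)
            else simulate_bundle(config$simulate, limitation = config$limitation)
  report <- validate_bundle(bundle$table, bundle$taxonomy, bundle$tree,
                            bundle$metadata, bundle$enzymes)
  if (length(report$samples_not_in_metadata) ||
      length(report$samples_not_in_enzymes))
    stopf("stage 'validate': samples missing from metadata/enzymes: %s",
          paste(union(report$samples_not_in_metadata,
                      report$samples_not_in_enzymes), collapse = ", "))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  summary <- list(seed = config$seed, validation = report)
  groups <- setNames(bundle$metadata$site, bundle$metadata$sample_id)
  rel <- to_relative(bundle$table)
  partition <- partition_taxa(rel, config$rare_cut, config$abund_cut)

  if ("structure" %in% config$stages) {
    summary$structure <- run_stage("structure", {
      d <- bray_curtis(rel)
      list(partition = partition,
           shannon = shannon_diversity(bundle$table),
           copiotroph = copiotroph_ratio(rel, bundle$taxonomy),
           pcoa = pcoa_ordination(d, k = 2),
           permanova = permanova_test(d, groups[labels(d)],
                                      n_perm = config$n_perm,
                                      seed = seeds$permutation))
    })
  }
  if ("enzymes" %in% config$stages) {
    summary$enzymes <- run_stage("enzymes",
                                 enzyme_limitation(bundle$enzymes))
  }
  if ("assembly" %in% config$stages) {
    summary$assembly <- run_stage("assembly", {
      purrr::map(setNames(config$subsets, config$subsets), function(ss) {
        tryCatch({
          tab <- if (ss == "whole") bundle$table
                 else subset_partition(bundle$table, partition, ss)
          pairs <- assembly_pairs(tab, bundle$tree, n_null = config$n_null,
                                  seed = seeds$assembly)
          list(pairs = pairs,
               fractions = assembly_fractions(pairs, groups = groups),
               mantel = tryCatch(
                 mantel_env(pairs, bundle$metadata,
                            variables = c("pH", "SOC", "C_N", "C_P"),
                            n_perm = config$n_perm, seed = seeds$permutation),
                 error = function(e) NULL))
        }, error = function(e) {
          # a subset can be too sparse to analyse (e.g. no rare taxa);
          # report it as unavailable instead of aborting the whole run
          warnf("assembly subset '%s' skipped: %s", ss, conditionMessage(e))
          NULL
        })
      })
    })
  }
  if ("network" %in% config$stages) {
    summary$network <- run_stage("network", {
      filt <- prevalence_filter(bundle$table, config$prevalence)
      corr <- log_correlation(filt)
      thr <- if (is.null(config$threshold))
        rmt_threshold(corr, t_grid = config$t_grid) else config$threshold
      g <- build_conetwork(corr, thr)
      cx <- sample_complexity(g, bundle$table)
      ratios <- stoich_ratios(bundle$enzymes)
      list(threshold = as.numeric(thr),
           topology = network_topology(g, seed = seeds$network),
           modules = network_modules(g, partition = partition),
           complexity = cx,
           fit_cn = tryCatch(complexity_ratio_fit(cx, ratios, "cn"),
                             error = function(e) NULL),
           fit_cp = tryCatch(complexity_ratio_fit(cx, ratios, "cp"),
                             error = function(e) NULL))
    })
  }
  class(summary) <- "crust_summary"
  if (!is.null(config$out_dir)) write_summary(summary, bundle, config)
  invisible(summary)
}

write_summary <- function(summary, bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  if (!is.null(summary$structure)) {
    readr::write_tsv(summary$structure$partition, out("partition.tsv"))
    readr::write_tsv(summary$structure$shannon, out("shannon.tsv"))
    readr::write_tsv(summary$structure$copiotroph, out("copiotroph_ratio.tsv"))
    readr::write_tsv(summary$structure$pcoa$scores, out("pcoa_scores.tsv"))
  }
  if (!is.null(summary$enzymes))
    readr::write_tsv(summary$enzymes, out("enzyme_limitation.tsv"))
  if (!is.null(summary$assembly)) {
    for (ss in names(summary$assembly)) {
      if (is.null(summary$assembly[[ss]])) next
      readr::write_tsv(summary$assembly[[ss]]$pairs,
                       out(sprintf("assembly_pairs_%s.tsv", ss)))
      readr::write_tsv(summary$assembly[[ss]]$fractions,
                       out(sprintf("assembly_fractions_%s.tsv", ss)))
    }
  }
  if (!is.null(summary$network)) {
    readr::write_tsv(summary$network$modules$membership, out("modules.tsv"))
    readr::write_tsv(summary$network$complexity, out("complexity.tsv"))
    readr::write_tsv(summary$network$topology, out("topology.tsv"))
  }
  jsonlite::write_json(summary_json(summary), out("summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(config$out_dir)
}

# machine-readable digest of a run (scalars and small tables only)
summary_json <- function(summary) {
  js <- list(seed = summary$seed)
  if (!is.null(summary$structure)) {
    js$permanova <- unclass(glance(summary$structure$permanova))
    js$partition_sizes <- as.list(table(summary$structure$partition$category))
  }
  if (!is.null(summary$enzymes)) {
    js$enzymes <- list(
      mean_angle_deg = mean(summary$enzymes$angle_deg),
      mean_length = mean(summary$enzymes$length),
      vector_calls = as.list(table(summary$enzymes$vector_call)),
      quadrants = as.list(table(summary$enzymes$quadrant)))
  }
  if (!is.null(summary$assembly)) {
    js$assembly <- purrr::map(summary$assembly, function(a) {
      if (is.null(a)) return(NULL)
      fr <- dplyr::filter(a$fractions, .data$process != "undefined")
      split(setNames(as.list(fr$fraction), as.character(fr$process)), fr$group)
    })
  }
  if (!is.null(summary$network)) {
    js$network <- c(list(threshold = summary$network$threshold),
                    as.list(summary$network$topology))
  }
  js
}

#' @export
print.crust_summary <- function(x, ...) {
  cat("<crust_summary> stages:",
      paste(intersect(c("structure", "enzymes", "assembly", "network"),
                      names(x)), collapse = ", "), "\n")
  invisible(x)
}
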
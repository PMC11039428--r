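#' Configuration for one meta-analysis run
#'
#' @param analysis one of `host_association`, `environment`, `time`,
#'   `environment_intracellular`.
#' @param dataset path to the effect-size CSV, or a data frame.
#' @param tree path to the newick tree used as the phylogenetic random-effect
#'   structure (host or symbiont), or a `phylo` object.
#' @param tree_role which species column maps records to tips:
#'   `"symbiont"` (default, the headline runs) or `"host"`.
#' @param substitution optional substitution table (path or data frame) of
#'   `missing_species`, `stand_in` applied to the tree before matching.
#' @param moderators character vector of moderator columns to test; defaults
#'   per analysis to the moderator battery (host generation time only for the
#'   environment analyses, host life stage only for the time analysis,
#'   dependence on host not for host association).
#' @param aggregation `"none"` (default), `"per_pairing"` or `"per_symbiont"`.
#' @param population_expand expand the tree to population-level tips (one per
#'   record) at distance `epsilon` before building the correlation matrix.
#' @param epsilon inter-population distance for the expansion.
#' @param variance_mode passed to [compute_effect_sizes()].
#' @param seed integer seed recorded in the report.
#' @param out_dir optional output directory for the serialized report.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(analysis = c("host_association", "environment",
                                         "time", "environment_intracellular"),
                            dataset, tree, tree_role = c("symbiont", "host"),
                            substitution = NULL,
                            moderators = NULL,
                            aggregation = c("none", "per_pairing", "per_symbiont"),
                            population_expand = TRUE,
                            epsilon = 1e-6,
                            variance_mode = "literal",
                            seed = 1L,
                            out_dir = NULL) {
  analysis <- match.arg(analysis)
  tree_role <- match.arg(tree_role)
  aggregation <- match.arg(aggregation)
  if (is.null(moderators)) moderators <- default_moderators(analysis)
  structure(
    list(analysis = analysis, dataset = dataset, tree = tree,
         tree_role = tree_role, substitution = substitution,
         moderators = moderators, aggregation = aggregation,
         population_expand = population_expand, epsilon = epsilon,
         variance_mode = variance_mode, seed = as.integer(seed),
         out_dir = out_dir),
    class = "analysis_config"
  )
}

# Moderator battery per analysis: generation time only for the environment
# analyses, life stage only for the time analysis, dependence on host not
# tested in the host-association analysis.
default_moderators <- function(analysis) {
  base <- c("host_kingdom", "association_type", "symbiont_diversity",
            "host_reproduction", "symbiont_location", "genome_size_mb")
  switch(analysis,
    host_association = base,
    environment = c(base, "dependence_on_host"),
    environment_intracellular = c(base, "dependence_on_host",
                                  "generation_time_years"),
    time = c(base, "dependence_on_host", "host_life_stage")
  )
}

#' Subset the dataset to one analysis
#'
#' Records are matched on the `analysis` column; the intracellular variant is
#' the environment subset restricted to `symbiont_location == "intracellular"`.
#'
#' @param records effect-size data frame with an `analysis` column.
#' @param analysis analysis name.
#' @return the matching records.
#' @export
subset_dataset <- function(records, analysis) {
  stopifnot("analysis" %in% names(records))
  if (analysis == "environment_intracellular") {
    out <- records[records$analysis == "environment" &
                     records$symbiont_location == "intracellular", , drop = FALSE]
  } else {
    out <- records[records$analysis == analysis, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("empty subset for analysis '", analysis, "'")
  out
}

#' Aggregate multiple effect sizes per symbiont (or per pairing)
#'
#' Groups records by symbiont species (`per_symbiont`) or by unique
#' host-symbiont pairing (`per_pairing`) and collapses each group to one
#' record with the mean transformed effect. The aggregated sampling variance
#' is, by default, the mean of the group's variances divided by the group
#' size (the variance of a mean of independent effects); `var_rule = "mean"`
#' keeps the plain mean variance instead.
#'
#' @param records effect-size data frame with `y`, `v`, `symbiont_species`
#'   and (for `per_pairing`) `host_species`.
#' @param mode `"per_pairing"` or `"per_symbiont"`.
#' @param var_rule `"mean_over_k"` (default) or `"mean"`.
#' @return aggregated data frame, one row per group (first row's metadata is
#'   kept), with `k_aggregated` recording group sizes.
#' @export
aggregate_by_symbiont <- function(records, mode = c("per_pairing", "per_symbiont"),
                                  var_rule = c("mean_over_k", "mean")) {
  mode <- match.arg(mode)
  var_rule <- match.arg(var_rule)
  if (anyNA(records$symbiont_species) ||
      (mode == "per_pairing" && anyNA(records$host_species))) {
    stop("missing species labels: cannot aggregate")
  }
  key <- if (mode == "per_symbiont") records$symbiont_species
         else paste(records$host_species, records$symbiont_species, sep = "||")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    out <- records[i[1], , drop = FALSE]
    out$y <- mean(records$y[i])
    out$v <- if (var_rule == "mean_over_k") mean(records$v[i]) / length(i)
             else mean(records$v[i])
    out$k_aggregated <- length(i)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run one full meta-analysis
#'
#' Computes effect sizes from raw summaries where needed, subsets to the
#' requested analysis, optionally aggregates, builds the Brownian-motion
#' correlation matrix from the (substituted, population-expanded) tree, fits
#' the overall intercept-only model, fits one model per moderator with its QM
#' test, screens outliers by Cook's distance on the overall model, and
#' repeats every fit on the outlier-free records.
#'
#' @param config an [analysis_config()].
#' @return an `analysis_report`: `config` (paths replaced by hashes),
#'   `n_records`, `overall`, `moderators` (named list of fits or skip
#'   reasons), `influence`, `overall_no_outliers`, `moderators_no_outliers`,
#'   `provenance`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  records <- load_dataset(config$dataset)
  tree <- load_tree(config$tree)
  if (!is.null(config$substitution)) {
    tab <- if (is.character(config$substitution)) {
      read_substitution_table(config$substitution)
    } else config$substitution
    tree <- substitute_tips(tree, tab)
  }

  records <- compute_effect_sizes(records, variance_mode = config$variance_mode)
  records <- subset_dataset(records, config$analysis)
  if (config$aggregation != "none") {
    records <- aggregate_by_symbiont(records, config$aggregation)
  }

  species_col <- paste0(config$tree_role, "_species")
  if (!species_col %in% names(records)) {
    stop("pipeline/tree: records lack column ", species_col)
  }
  sp <- as.character(records[[species_col]])
  missing_sp <- setdiff(unique(sp), tree$tip.label)
  if (length(missing_sp)) {
    stop("pipeline/tree: species without a tip after substitution: ",
         paste(missing_sp, collapse = ", "))
  }
  tree <- prune_to(tree, unique(sp))
  if (config$population_expand) {
    mult <- split(as.character(records$effect_id), sp)
    tree <- expand_populations(tree, mult, epsilon = config$epsilon)
    tip <- as.character(records$effect_id)
  } else {
    tip <- sp
  }
  R <- bm_correlation(tree)

  make_spec <- function(rec, tp, design) {
    model_spec(rec$y, rec$v, design$X,
               study = rec$study_id, tip = tp, R = R, block = design$block)
  }

  fit_battery <- function(rec, tp) {
    overall <- fit_reml(make_spec(rec, tp, build_design(rec)))
    mods <- list()
    audit <- list()
    for (m in config$moderators) {
      if (!m %in% names(rec)) {
        mods[[m]] <- list(skipped = "column absent")
        next
      }
      x <- rec[[m]][!is.na(rec[[m]])]
      lv <- if (is.numeric(x)) NULL else sort(unique(as.character(x)))
      audit[[m]] <- if (is.null(lv)) "continuous" else lv
      if (!is.numeric(x) && length(lv) < 2L) {
        mods[[m]] <- list(skipped = paste0("single observed level: ",
                                           paste(lv, collapse = "")))
        next
      }
      d <- build_design(rec, m)
      mods[[m]] <- fit_reml(make_spec(rec[d$keep, , drop = FALSE],
                                      tp[d$keep], d))
    }
    list(overall = overall, moderators = mods, levels_audit = audit)
  }

  full <- fit_battery(records, tip)
  influence <- apply_outlier_rule(
    make_spec(records, tip, build_design(records)), full$overall
  )
  keep <- setdiff(seq_len(nrow(records)), influence$flagged)
  reduced <- fit_battery(records[keep, , drop = FALSE], tip[keep])

  report <- structure(
    list(analysis = config$analysis,
         n_records = nrow(records),
         n_records_no_outliers = length(keep),
         overall = full$overall,
         moderators = full$moderators,
         levels_audit = full$levels_audit,
         influence = influence,
         overall_no_outliers = reduced$overall,
         moderators_no_outliers = reduced$moderators,
         provenance = provenance(config)),
    class = "analysis_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(config$out_dir,
                                        paste0(config$analysis, "_report.json")))
    write_report_markdown(report, file.path(config$out_dir,
                                            paste0(config$analysis, "_report.md")))
  }
  report
}

load_dataset <- function(x) {
  if (is.data.frame(x)) return(x)
  utils::read.csv(x, stringsAsFactors = FALSE)
}

load_tree <- function(x) {
  if (inherits(x, "phylo")) return(validate_phylogeny(x))
  read_newick(x)
}

provenance <- function(config) {
  hashes <- list()
  for (f in c("dataset", "tree", "substitution")) {
    if (is.character(config[[f]]) && length(config[[f]]) == 1 &&
        file.exists(config[[f]])) {
      hashes[[f]] <- unname(tools::md5sum(config[[f]]))
    }
  }
  list(package_version = as.character(utils::packageVersion("symbmeta")),
       input_md5 = hashes, seed = config$seed,
       aggregation = config$aggregation, tree_role = config$tree_role,
       variance_mode = config$variance_mode,
       timestamp = NULL)  # deliberately NULL: reports must be byte-reproducible
}

fit_summary_row <- function(fit) {
  if (!inherits(fit, "meta_fit")) {
    return(list(skipped = fit$skipped))
  }
  out <- list(n = fit$n,
              beta = as.list(round(fit$beta, 10)),
              se = round(fit$se, 10),
              z = round(fit$zval, 10), p = round(fit$pval, 10),
              vc = as.list(round(fit$vc, 10)),
              reml_loglik = round(fit$reml_loglik, 10),
              converged = identical(fit$convergence$status, 0L) ||
                identical(fit$convergence$status, "no free components"))
  if (!is.null(fit$QM)) {
    out$QM <- round(fit$QM, 10); out$QM_df <- fit$QM_df
    out$QM_p <- round(fit$QM_p, 10)
  }
  out
}

#' Serialize an analysis report as JSON
#'
#' @param report an `analysis_report`.
#' @param file output path.
#' @export
write_report_json <- function(report, file) {
  x <- list(
    analysis = report$analysis,
    n_records = report$n_records,
    n_records_no_outliers = report$n_records_no_outliers,
    overall = fit_summary_row(report$overall),
    moderators = lapply(report$moderators, fit_summary_row),
    overall_no_outliers = fit_summary_row(report$overall_no_outliers),
    moderators_no_outliers = lapply(report$moderators_no_outliers,
                                    fit_summary_row),
    outliers = list(D = report$influence$D,
                    threshold = report$influence$threshold,
                    flagged = report$influence$flagged),
    levels_audit = report$levels_audit,
    provenance = report$provenance
  )
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Write a human-readable report table
#'
#' One row per model (overall and each moderator), with and without outliers:
#' n, estimate/z/p for the intercept, QM/df/p for the moderator block.
#'
#' @param report an `analysis_report`.
#' @param file output path (markdown).
#' @export
write_report_markdown <- function(report, file) {
  row_of <- function(name, fit, set) {
    if (!inherits(fit, "meta_fit")) {
      return(sprintf("| %s | %s | - | - | - | skipped: %s |",
                     name, set, fit$skipped))
    }
    qm <- if (is.null(fit$QM)) "-" else
      sprintf("QM = %.3f, df = %d, p = %.3f", fit$QM, fit$QM_df, fit$QM_p)
    sprintf("| %s | %s | %d | %.3f | z = %.3f, p = %.3f | %s |",
            name, set, fit$n, fit$beta[1], fit$zval[1], fit$pval[1], qm)
  }
  lines <- c(
    sprintf("# Analysis report: %s", report$analysis),
    "",
    sprintf("Records: %d (all), %d (outliers removed; %d flagged)",
            report$n_records, report$n_records_no_outliers,
            length(report$influence$flagged)),
    "",
    "| model | effect sizes | n | intercept | overall test | moderator test |",
    "|---|---|---|---|---|---|",
    row_of("overall", report$overall, "all"),
    vapply(names(report$moderators), function(m)
      row_of(m, report$moderators[[m]], "all"), character(1)),
    row_of("overall", report$overall_no_outliers, "no outliers"),
    vapply(names(report$moderators_no_outliers), function(m)
      row_of(m, report$moderators_no_outliers[[m]], "no outliers"), character(1))
  )
  writeLines(lines, file)
  invisible(file)
}
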
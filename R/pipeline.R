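#' Add threshold-exceedance outcome columns
#'
#' Adds one binary column per admixture threshold (`exceeds_1`,
#' `exceeds_10`, ...), 1 when the site's admixture metric strictly exceeds
#' the threshold. Exceedances are nested by construction: exceeding 20%
#' implies exceeding 10% implies exceeding 1%.
#'
#' @param data site table with the metric column.
#' @param metric admixture metric column (`"prta_pct"` or `"pfrt_pct"`).
#' @param thresholds strictly increasing admixture percentages in (0, 100).
#' @return `data` with the added outcome columns.
#' @export
add_exceedance <- function(data, metric = "prta_pct",
                           thresholds = c(1, 10, 20)) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0),
            all(thresholds < 100))
  data <- tibble::as_tibble(data)
  for (th in thresholds) {
    data[[paste0("exceeds_", th)]] <- as.integer(data[[metric]] > th)
  }
  data
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline: trimming rules, the covariate
#' constants defining warm and big reaches, the candidate covariates and
#' selection cutoffs, evaluation settings, the scenario list and the
#' generator configuration used when no input tables are given.
#'
#' @param reach_table,site_table paths to the delimited input tables, or
#'   `NULL` to simulate both from `generator` (simulate mode).
#' @param out_dir output directory for run artifacts, or `NULL` to skip
#'   writing.
#' @param metric admixture metric column used as the response.
#' @param thresholds admixture thresholds (%).
#' @param candidates candidate covariate columns for subset selection.
#' @param trim [trim_rules()].
#' @param warm_temp_c,big_flow_cms covariate constants (degrees C, m^3/s).
#' @param corr_cutoff,vif_cutoff,consensus_delta_aic selection cutoffs.
#' @param per_threshold_best skip the consensus rule and carry each
#'   threshold's top-ranked model forward (the treatment used for the
#'   fish-level admixture metric in the source literature).
#' @param cv_folds,stratified_cv cross-validation settings.
#' @param scenarios list of [scenario_spec()]s.
#' @param generator [generator_config()] for simulate mode.
#' @param n_sites sites to simulate in simulate mode.
#' @param seed root seed; all randomness in a run flows from it.
#' @param quantize_30m round distance covariates to 30 m multiples.
#' @param use_untrimmed compute distances on the pre-trim network.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(reach_table = NULL, site_table = NULL,
                            out_dir = NULL, metric = "prta_pct",
                            thresholds = c(1, 10, 20),
                            candidates = c("t_aug_c", "slope_pct", "cfm_day",
                                           "w95_days", "maf_cms", "df3_m",
                                           "dt13_m", "ds_m", "northing_m",
                                           "easting_m", "rt_range", "ycti"),
                            trim = trim_rules(),
                            warm_temp_c = 13, big_flow_cms = 2.83,
                            corr_cutoff = 0.80, vif_cutoff = 3.5,
                            consensus_delta_aic = 3,
                            per_threshold_best = FALSE,
                            cv_folds = 10, stratified_cv = FALSE,
                            scenarios = default_scenarios(),
                            generator = generator_config(),
                            n_sites = 500, seed = 1,
                            quantize_30m = FALSE, use_untrimmed = TRUE) {
  stopifnot(all(diff(thresholds) > 0))
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full introgression-threshold pipeline
#'
#' Executes the analysis end to end: load (or simulate) the network and
#' sites, trim marginal reaches, attach covariates, screen for
#' collinearity, run exhaustive AIC subset selection per admixture
#' threshold, apply the consensus rule, evaluate each threshold's model
#' (AUC, error-balancing cutoff, classification table, k-fold CV), project
#' the scenarios and assemble the habitat table. Sites landing on trimmed
#' reaches are an error (reported, never silently dropped); sites with
#' unreachable distance covariates are excluded from fitting with a logged
#' count. When `cfg$out_dir` is set, artifacts (model tables, rankings,
#' evaluation report, per-reach classification, habitat table, run log)
#' are written as delimited text and JSON.
#'
#' @param cfg an [analysis_config()].
#' @return a `pipeline_result` list: `network`, `sites`, `screen`,
#'   `rankings`, `consensus`, `models`, `cutoffs`, `evaluation`, `habitat`,
#'   `log`.
#' @export
run_pipeline <- function(cfg = analysis_config()) {
  stopifnot(inherits(cfg, "analysis_config"))
  hashable <- unclass(cfg)[setdiff(names(cfg), c("out_dir", "reach_table",
                                                 "site_table"))]
  log_lines <- c(sprintf("streamhyb run, seed %d", cfg$seed),
                 sprintf("config sha: %s",
                         substr(rlang::hash(hashable), 1, 12)))
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    rlang::inform(sprintf(...))
  }

  if (is.null(cfg$reach_table)) {
    gen <- cfg$generator
    gen$seed <- cfg$seed
    net0 <- generate_network(gen)
    sites <- simulate_site_samples(net0, gen, n_sites = cfg$n_sites,
                                   seed = cfg$seed + 1)
    note("simulated network (%d reaches) and %d sites", nrow(net0),
         nrow(sites))
  } else {
    net0 <- load_network(cfg$reach_table)
    sites <- readr::read_csv(cfg$site_table, show_col_types = FALSE,
                             progress = FALSE)
    note("loaded %d reaches and %d sites", nrow(net0), nrow(sites))
  }

  bad <- setdiff(cfg$candidates,
                 c("t_aug_c", "slope_pct", "cfm_day", "w95_days", "maf_cms",
                   "df3_m", "dt13_m", "ds_m", "northing_m", "easting_m",
                   "rt_range", "ycti"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown candidate covariate(s): ",
                        paste(bad, collapse = ", ")),
                 class = "streamhyb_config_error")
  }

  net <- trim_network(net0, cfg$trim)
  note("trimmed network: %d of %d reaches retained", nrow(net), nrow(net0))
  on_trimmed <- setdiff(sites$reach_id, net$reach_id)
  if (length(on_trimmed) > 0 && is.null(cfg$reach_table)) {
    keep <- !(sites$reach_id %in% on_trimmed)
    note("dropping %d simulated site(s) on trimmed reaches", sum(!keep))
    sites <- sites[keep, ]
  }
  covs <- attach_site_covariates(sites, net, cfg$warm_temp_c,
                                 cfg$big_flow_cms, cfg$use_untrimmed,
                                 cfg$quantize_30m)
  dist_cols <- intersect(c("df3_m", "dt13_m", "ds_m"), cfg$candidates)
  usable <- stats::complete.cases(covs[dist_cols])
  if (any(!usable)) {
    note("excluding %d site(s) with unreachable distance covariates",
         sum(!usable))
    covs <- covs[usable, ]
  }
  covs <- add_exceedance(covs, cfg$metric, cfg$thresholds)

  mid <- paste0("exceeds_", cfg$thresholds[ceiling(length(cfg$thresholds) / 2)])
  screen <- collinearity_screen(covs, mid, cfg$candidates,
                                cfg$corr_cutoff, cfg$vif_cutoff)
  note("collinearity screen retained %d of %d candidates",
       length(screen$retained), length(cfg$candidates))

  rankings <- lapply(cfg$thresholds, function(th) {
    all_subsets_selection(covs, paste0("exceeds_", th), screen$retained)
  })
  names(rankings) <- as.character(cfg$thresholds)

  if (cfg$per_threshold_best) {
    models <- lapply(rankings, function(r) r$fit[[1]])
    consensus <- NULL
    note("per-threshold best models selected (consensus rule skipped)")
  } else {
    consensus <- select_consensus(rankings, cfg$consensus_delta_aic)
    if (consensus$rule == "none") {
      note("no consensus model; carrying per-threshold top models forward")
      models <- lapply(rankings, function(r) r$fit[[1]])
    } else {
      note("consensus model (%s rule): %s", consensus$rule, consensus$label)
      models <- consensus$fits
    }
  }

  evaluation <- lapply(models, evaluate_model, k = cfg$cv_folds,
                       seed = cfg$seed, stratified = cfg$stratified_cv)
  cutoffs <- vapply(evaluation, function(e) e$threshold, numeric(1))
  habitat <- run_scenarios(net, models, cutoffs, cfg$scenarios,
                           cfg$warm_temp_c, cfg$big_flow_cms,
                           cfg$use_untrimmed)
  out <- structure(list(network = net, sites = covs, screen = screen,
                        rankings = rankings, consensus = consensus,
                        models = models, cutoffs = cutoffs,
                        evaluation = evaluation, habitat = habitat,
                        seed = cfg$seed, log = log_lines),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_artifacts(out, cfg)
  invisible(out)
}

write_artifacts <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(cfg$out_dir, ...)
  for (th in names(res$models)) {
    readr::write_csv(format_estimates(res$models[[th]]),
                     p(sprintf("estimates_exceeds_%s.csv", th)))
    readr::write_csv(format_ranking(res$rankings[[th]], top = 10),
                     p(sprintf("ranking_exceeds_%s.csv", th)))
    fit <- res$models[[th]]
    jsonlite::write_json(
      list(threshold = th, covariates = fit$covariates,
           coefficients = stats::setNames(fit$coefficients$estimate,
                                          fit$coefficients$term),
           aic = fit$aic, logLik = fit$logLik, n = fit$n,
           converged = fit$converged,
           cutoff = unname(res$cutoffs[[th]])),
      p(sprintf("model_exceeds_%s.json", th)), auto_unbox = TRUE,
      digits = NA)
  }
  eval_tbl <- purrr::map_dfr(names(res$evaluation), function(th) {
    dplyr::mutate(as_tibble(res$evaluation[[th]]), threshold = th,
                  .before = 1)
  })
  readr::write_csv(eval_tbl, p("evaluation.csv"))
  readr::write_csv(res$habitat, p("habitat_projection.csv"))
  flags <- classify_network(res$network, res$models[[1]], res$cutoffs[[1]],
                            cfg$warm_temp_c, cfg$big_flow_cms)
  readr::write_csv(flags, p("classification_current.csv"))
  writeLines(res$log, p("run_log.txt"))
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("streamhyb pipeline result\n")
  cat(sprintf("  %d sites on a %d-reach trimmed network (seed %d)\n",
              nrow(x$sites), nrow(x$network), x$seed))
  if (!is.null(x$consensus) && x$consensus$rule != "none") {
    cat(sprintf("  consensus model (%s): %s\n", x$consensus$rule,
                x$consensus$label))
  }
  for (th in names(x$evaluation)) {
    e <- x$evaluation[[th]]
    cat(sprintf(
      "  >%s%%: AUC %.2f, cutoff %.3f, training %.1f%%, CV %.1f%%\n",
      th, e$auc, e$threshold, e$training_accuracy_pct, e$cv_accuracy_pct))
  }
  invisible(x)
}
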
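#' Define a projection scenario
#'
#' A scenario warms every reach's mean August temperature by `delta_t_c`
#' and/or assumes introgression outside the historical rainbow-trout range
#' equilibrates at inside-range levels (`equilibrium`, encoded by setting
#' the range indicator to 1 everywhere — the only inside/outside
#' distinction the model carries). Warming by default also recomputes the
#' warm-habitat proximity covariates, since newly warm reaches become
#' springboards for rainbow-trout propagules.
#'
#' @param name scenario label.
#' @param delta_t_c degrees C added to every reach temperature (>= 0).
#' @param equilibrium treat every reach as inside the historical range.
#' @param recompute_distances recompute `dt13_m` and `ds_m` against the
#'   warmed temperatures (source flags and flows unchanged).
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(name, delta_t_c = 0, equilibrium = FALSE,
                          recompute_distances = TRUE) {
  stopifnot(delta_t_c >= 0)
  structure(list(name = name, delta_t_c = delta_t_c,
                 equilibrium = isTRUE(equilibrium),
                 recompute_distances = isTRUE(recompute_distances)),
            class = "scenario_spec")
}

#' The six standard projection scenarios
#'
#' Current conditions; equilibrium; moderate (+0.5 degrees C) and extreme
#' (+1.0 degrees C) stream warming; and each warming level combined with
#' equilibrium.
#'
#' @param recompute_distances passed to each [scenario_spec()].
#' @return list of six `scenario_spec`s.
#' @export
default_scenarios <- function(recompute_distances = TRUE) {
  list(
    scenario_spec("current", 0, FALSE, recompute_distances),
    scenario_spec("equilibrium", 0, TRUE, recompute_distances),
    scenario_spec("current+0.5C", 0.5, FALSE, recompute_distances),
    scenario_spec("equilibrium+0.5C", 0.5, TRUE, recompute_distances),
    scenario_spec("current+1.0C", 1.0, FALSE, recompute_distances),
    scenario_spec("equilibrium+1.0C", 1.0, TRUE, recompute_distances)
  )
}

#' Apply a scenario's transformations to a network
#'
#' Adds the warming increment to every reach's temperature (both the
#' working network and its pre-trim copy, so recomputed distances see the
#' warmed main stems) and, under equilibrium, sets the rainbow-trout range
#' indicator to 1 everywhere. The zero scenario is an identity.
#'
#' @param net a `stream_network`.
#' @param spec a [scenario_spec()].
#' @return the transformed `stream_network`.
#' @export
apply_scenario <- function(net, spec) {
  stopifnot(inherits(net, "stream_network"), inherits(spec, "scenario_spec"))
  warm <- function(tab) {
    tab$t_aug_c <- tab$t_aug_c + spec$delta_t_c
    if (spec$equilibrium) tab$rt_range <- rep(1, nrow(tab))
    tab
  }
  out <- warm(net)
  base <- attr(net, "untrimmed")
  if (!is.null(base)) attr(out, "untrimmed") <- warm(base)
  attr(out, "scenario") <- spec
  out
}

#' Per-reach covariate vectors for network-wide prediction
#'
#' Treats every surviving reach as a prediction point: its own attributes
#' plus the distance covariates computed (by default) on the pre-trim
#' network.
#'
#' @inheritParams attach_site_covariates
#' @param ycti value for the site-level Yellowstone-introgression indicator
#'   when the model requires it (reaches have no genotype data; 0 by
#'   default).
#' @return tibble of reach covariates.
#' @export
reach_covariates <- function(net, warm_temp_c = 13, big_flow_cms = 2.83,
                             use_untrimmed = TRUE, ycti = 0) {
  reaches <- resolve_reaches(net, use_untrimmed)
  dist <- reach_distance_covariates(reaches, net$reach_id,
                                    warm_temp_c, big_flow_cms)
  tibble::as_tibble(net) |>
    dplyr::select("reach_id", "length_m", "t_aug_c", "slope_pct", "cfm_day",
                  "w95_days", "maf_cms", "northing_m", "easting_m",
                  "rt_range") |>
    dplyr::left_join(dist, by = "reach_id") |>
    dplyr::mutate(ycti = ycti)
}

#' Classify every reach against an introgression threshold
#'
#' Predicts the exceedance probability for each reach and flags it below
#' the threshold when that probability is under the classification cutoff.
#' Reaches with unreachable (missing) distance covariates are left
#' unclassified and counted in `attr(, "n_unclassified")`.
#'
#' @param net a `stream_network` (after [apply_scenario()] if projecting).
#' @param model an `exceedance_fit`.
#' @param cutoff classification probability cutoff (from
#'   [balanced_threshold()] on training data).
#' @inheritParams reach_covariates
#' @return tibble `reach_id`, `probability`, `below` (logical; `NA` when
#'   unclassified).
#' @export
classify_network <- function(net, model, cutoff, warm_temp_c = 13,
                             big_flow_cms = 2.83, use_untrimmed = TRUE) {
  covs <- reach_covariates(net, warm_temp_c, big_flow_cms, use_untrimmed)
  need <- model$covariates
  complete <- stats::complete.cases(covs[intersect(need, names(covs))])
  prob <- rep(NA_real_, nrow(covs))
  prob[complete] <- predict_probability(model, covs[complete, ])
  out <- tibble::tibble(reach_id = covs$reach_id, probability = prob,
                        below = prob < cutoff)
  attr(out, "n_unclassified") <- sum(!complete)
  attr(out, "cutoff") <- cutoff
  out
}

#' Hydraulic-geometry constants
#'
#' Power-law scaling of channel width and depth with mean annual flow,
#' used to convert habitat length to volume: width = a * MAF^b and
#' depth = c * MAF^f, with classic downstream-hydraulic-geometry exponents
#' as defaults.
#'
#' @param a,b width coefficients (m, dimensionless).
#' @param c,f depth coefficients (m, dimensionless).
#' @return named numeric vector.
#' @export
hydraulic_geometry <- function(a = 4.3, b = 0.5, c = 0.27, f = 0.4) {
  c(a = a, b = b, c = c, f = f)
}

#' Habitat below threshold, by length and volume
#'
#' Sums stream length (km) and channel volume (m^3) of below-threshold
#' reaches, optionally stratified by the historical rainbow-trout range
#' indicator. Volume per reach is length x width x depth with
#' [hydraulic_geometry()] scaling from mean annual flow; the formula is
#' recorded in `attr(, "volume_formula")`.
#'
#' @param net the classified `stream_network`.
#' @param flags output of [classify_network()] for the same network.
#' @param stratify_by_rt_range split by inside/outside historical range.
#' @param hg [hydraulic_geometry()] constants.
#' @return tibble with `stratum`, `length_km`, `volume_m3`.
#' @export
summarize_habitat <- function(net, flags, stratify_by_rt_range = TRUE,
                              hg = hydraulic_geometry()) {
  tab <- tibble::as_tibble(net) |>
    dplyr::inner_join(flags, by = "reach_id") |>
    dplyr::mutate(
      stratum = if (stratify_by_rt_range) {
        ifelse(.data$rt_range > 0, "inside", "outside")
      } else "all",
      volume_m3 = .data$length_m * (hg[["a"]] * .data$maf_cms^hg[["b"]]) *
        (hg[["c"]] * .data$maf_cms^hg[["f"]])
    )
  out <- tab |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      length_km = sum(.data$length_m[.data$below %in% TRUE]) / 1000,
      volume_m3 = sum(.data$volume_m3[.data$below %in% TRUE]),
      .groups = "drop"
    )
  attr(out, "volume_formula") <-
    sprintf("volume = length * (%g*MAF^%g) * (%g*MAF^%g)",
            hg[["a"]], hg[["b"]], hg[["c"]], hg[["f"]])
  out
}

#' Percent change of scenario habitat relative to current conditions
#'
#' Joins matching threshold/stratum rows and reports
#' 100 * (scenario - current) / current to one decimal; `NA` (the null
#' marker) where the current amount is zero.
#'
#' @param current,scenario habitat summaries with matching `stratum` (and
#'   any shared grouping columns such as `threshold`).
#' @return scenario summary with `pct_change_length` and
#'   `pct_change_volume` columns.
#' @export
percent_change <- function(current, scenario) {
  keys <- intersect(intersect(names(current), names(scenario)),
                    c("threshold", "stratum"))
  ref <- dplyr::select(current, dplyr::all_of(keys),
                       ref_length = "length_km", ref_volume = "volume_m3")
  scenario |>
    dplyr::left_join(ref, by = keys) |>
    dplyr::mutate(
      pct_change_length = ifelse(.data$ref_length == 0, NA_real_,
        round(100 * (.data$length_km - .data$ref_length) / .data$ref_length, 1)),
      pct_change_volume = ifelse(.data$ref_volume == 0, NA_real_,
        round(100 * (.data$volume_m3 - .data$ref_volume) / .data$ref_volume, 1))
    ) |>
    dplyr::select(-"ref_length", -"ref_volume")
}

#' Run all scenarios and assemble the habitat projection table
#'
#' For each scenario and admixture threshold: transform the network,
#' classify every reach with that threshold's model and cutoff, and sum
#' below-threshold habitat by length and volume per range stratum, with
#' percent change against the current scenario.
#'
#' @param net trimmed `stream_network` under current conditions.
#' @param models named list of `exceedance_fit`, one per threshold (names
#'   like `"1"`, `"10"`, `"20"`).
#' @param cutoffs named numeric vector of classification cutoffs matching
#'   `models`.
#' @param scenarios list of [scenario_spec()]s; the first is treated as the
#'   current baseline.
#' @inheritParams reach_covariates
#' @param stratify_by_rt_range split summaries by the *current* (pre-scenario)
#'   range indicator, so equilibrium rows remain comparable across strata.
#' @param hg [hydraulic_geometry()] constants.
#' @return a `habitat_projection` tibble: scenario x threshold x stratum
#'   with `length_km`, `volume_m3`, `pct_change_length`, `pct_change_volume`.
#' @export
run_scenarios <- function(net, models, cutoffs,
                          scenarios = default_scenarios(),
                          warm_temp_c = 13, big_flow_cms = 2.83,
                          use_untrimmed = TRUE,
                          stratify_by_rt_range = TRUE,
                          hg = hydraulic_geometry()) {
  stopifnot(all(names(models) %in% names(cutoffs)) || is.null(names(models)))
  baseline_range <- net$rt_range # stratify by current range, not scenario's
  one <- function(spec) {
    snet <- apply_scenario(net, spec)
    if (!spec$recompute_distances) {
      # freeze distances at current temperatures by classifying against the
      # unwarmed pre-trim table
      attr(snet, "untrimmed") <- attr(net, "untrimmed") %||%
        tibble::as_tibble(net)[reach_columns]
      snet_dist <- snet
    }
    snet$rt_range_scenario <- snet$rt_range
    snet$rt_range <- baseline_range
    purrr::map_dfr(names(models), function(th) {
      cls_net <- snet
      cls_net$rt_range <- snet$rt_range_scenario # model sees scenario range
      flags <- classify_network(
        structure(cls_net[reach_columns],
                  class = class(net),
                  untrimmed = attr(snet, "untrimmed")),
        models[[th]], cutoffs[[th]], warm_temp_c, big_flow_cms, use_untrimmed)
      summarize_habitat(snet, flags, stratify_by_rt_range, hg) |>
        dplyr::mutate(threshold = th, .before = 1)
    }) |>
      dplyr::mutate(scenario = spec$name, .before = 1)
  }
  current <- one(scenarios[[1]])
  rest <- purrr::map(scenarios[-1], one)
  out <- dplyr::bind_rows(
    dplyr::mutate(current, pct_change_length = NA_real_,
                  pct_change_volume = NA_real_),
    purrr::map_dfr(rest, function(s) {
      percent_change(dplyr::select(current, -"scenario"),
                     dplyr::select(s, -"scenario")) |>
        dplyr::mutate(scenario = s$scenario[1], .before = 1)
    })
  )
  class(out) <- c("habitat_projection", class(out))
  out
}

#' Exceedance-probability response curves over source distance
#'
#' Probability of exceeding the threshold as a function of distance to the
#' nearest rainbow-trout source, for a grid of temperatures inside and
#' outside the historical rainbow-trout range, other model covariates held
#' at their sample medians. Curves for inside vs outside differ by a
#' constant logit offset equal to the range coefficient.
#'
#' @param model an `exceedance_fit` whose subset includes `ds_m`, `t_aug_c`
#'   and `rt_range`.
#' @param data sample data supplying medians for the remaining covariates.
#' @param ds_m grid of source distances (m).
#' @param t_values temperatures (degrees C) to trace.
#' @param rt_range range indicator values to trace.
#' @return a `response_curves` tibble: `ds_m`, `t_aug_c`, `rt_range`,
#'   `probability`. Plot with [ggplot2::autoplot()].
#' @export
response_curves <- function(model, data,
                            ds_m = seq(0, 30000, by = 250),
                            t_values = c(9, 12, 15),
                            rt_range = c(0, 1)) {
  need <- c("ds_m", "t_aug_c", "rt_range")
  absent <- setdiff(need, model$covariates)
  if (length(absent) > 0) {
    rlang::abort(paste0("model does not include covariate(s): ",
                        paste(absent, collapse = ", ")),
                 class = "streamhyb_contract_error")
  }
  others <- setdiff(model$covariates, need)
  med <- lapply(tibble::as_tibble(data)[others], stats::median, na.rm = TRUE)
  grid <- tidyr::expand_grid(ds_m = ds_m, t_aug_c = t_values,
                             rt_range = rt_range)
  grid <- dplyr::bind_cols(grid, tibble::as_tibble(med)[rep(1, nrow(grid)), ,
                                                        drop = FALSE])
  grid$probability <- predict_probability(model, grid)
  out <- grid[c("ds_m", "t_aug_c", "rt_range", "probability")]
  class(out) <- c("response_curves", class(out))
  out
}
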
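#' Predicate over reach attributes
#'
#' Describes a target set of reaches by a comparison on one reach attribute,
#' e.g. `reach_predicate("t_aug_c", ">=", 13)` for reaches at least as warm
#' as the temperature at which rainbow-trout occupancy peaks.
#'
#' @param attribute name of a reach-table column.
#' @param op one of `">="`, `">"`, `"<="`, `"<"`, `"=="`.
#' @param value threshold.
#' @return a `reach_predicate`.
#' @export
reach_predicate <- function(attribute, op = ">=", value) {
  op <- match.arg(op, c(">=", ">", "<=", "<", "=="))
  structure(list(attribute = attribute, op = op, value = value),
            class = "reach_predicate")
}

predicate_mask <- function(reaches, pred) {
  if (!pred$attribute %in% names(reaches)) {
    rlang::abort(paste0("unknown reach attribute in predicate: ",
                        pred$attribute),
                 class = "streamhyb_config_error")
  }
  x <- reaches[[pred$attribute]]
  out <- switch(pred$op,
    ">=" = x >= pred$value, ">" = x > pred$value,
    "<=" = x <= pred$value, "<" = x < pred$value,
    "==" = x == pred$value)
  out & !is.na(out)
}

# The channel network as a weighted graph of junctions and reach midpoints.
# Each reach is a segment from its upstream junction to its downstream end
# (the upstream junction of its downstream neighbour, or a basin outlet);
# a midpoint vertex splits it into two half-length edges. Distances between
# midpoint vertices are then along-channel midpoint-to-midpoint distances:
# a parent and child reach are (L_parent + L_child)/2 apart, and so are two
# sibling reaches meeting at the same junction.
#' @keywords internal
river_graph <- function(reaches) {
  id <- reaches$reach_id
  down <- reaches$downstream_id
  up_node <- paste0("J_", id)            # upstream junction of each reach
  mid_node <- paste0("M_", id)
  down_node <- ifelse(is.na(down), paste0("OUT_", id), paste0("J_", down))
  edges <- tibble::tibble(
    from = c(up_node, mid_node),
    to = c(mid_node, down_node),
    weight = rep(reaches$length_m / 2, 2)
  )
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = unique(c(up_node, mid_node, down_node)))
  )
}

# shortest along-network distance (m) from each origin reach midpoint to the
# nearest reach midpoint in `target_ids`; NA when no target is reachable
network_distance <- function(reaches, origins, target_ids) {
  if (length(target_ids) == 0) {
    return(stats::setNames(rep(NA_real_, length(origins)), origins))
  }
  g <- river_graph(reaches)
  d <- igraph::distances(g, v = paste0("M_", origins),
                         to = paste0("M_", target_ids))
  out <- apply(d, 1, min)
  out[!is.finite(out)] <- NA_real_
  stats::setNames(out, origins)
}

#' Along-network distance to the nearest reach satisfying a predicate
#'
#' Shortest along-channel path (traversal allowed both up- and downstream)
#' from the origin reach's midpoint to the midpoint of the nearest reach
#' satisfying the predicate; 0 when the origin itself satisfies it, and the
#' `NA` missing marker when no reach in the network does or none is
#' reachable. The distance between adjacent reaches is half the sum of their
#' lengths (midpoint convention); that applies equally to a parent/child
#' pair and to two tributaries meeting at the same junction.
#'
#' @param net a `stream_network`.
#' @param origin a reach id (vector allowed).
#' @param pred a [reach_predicate()].
#' @param use_untrimmed traverse and target the full pre-trim network when
#'   the network carries one (default `TRUE`): propagules move through large
#'   rivers excluded from the hybrid-zone network itself.
#' @return named numeric vector of meters (or `NA`).
#' @export
distance_to_predicate <- function(net, origin, pred, use_untrimmed = TRUE) {
  reaches <- resolve_reaches(net, use_untrimmed)
  if (!all(origin %in% reaches$reach_id)) {
    rlang::abort(paste0("unknown origin reach: ",
                        paste(setdiff(origin, reaches$reach_id), collapse = ", ")),
                 class = "streamhyb_input_error")
  }
  targets <- reaches$reach_id[predicate_mask(reaches, pred)]
  network_distance(reaches, origin, targets)
}

resolve_reaches <- function(net, use_untrimmed) {
  base <- attr(net, "untrimmed")
  if (isTRUE(use_untrimmed) && !is.null(base)) {
    tibble::as_tibble(base)
  } else {
    tibble::as_tibble(net)
  }
}

quantize_30 <- function(x) round(x / 30) * 30

#' Attach reach and distance covariates to sample sites
#'
#' Joins each genotyped site to its reach's attributes and computes the
#' three along-network propagule-proximity covariates: `df3_m`, distance to
#' the nearest reach with mean annual flow at least `big_flow_cms`;
#' `dt13_m`, distance to the nearest reach with mean August temperature at
#' least `warm_temp_c`; and `ds_m`, the shortest distance to any potential
#' rainbow-trout source (a big-flow reach, a warm reach, or a reach flagged
#' `rt_source`). Because the source set is a superset of both others,
#' `ds_m <= min(df3_m, dt13_m)` at every site.
#'
#' @param sites data frame with columns `site_id`, `reach_id`, `n_fish`,
#'   `prta_pct`, `pfrt_pct`, `ycti`.
#' @param net a `stream_network` (typically trimmed; distances traverse the
#'   pre-trim network when `use_untrimmed = TRUE`).
#' @param warm_temp_c temperature defining "warm" reaches (degrees C).
#' @param big_flow_cms flow defining "big" reaches (m^3/s).
#' @param use_untrimmed compute distances on the full pre-trim network.
#' @param quantize_30m round distances to 30 m multiples, mimicking a
#'   raster-grid implementation (off by default).
#' @return tibble of sites with the full covariate vector
#'   (`t_aug_c`, `slope_pct`, `cfm_day`, `w95_days`, `maf_cms`, `df3_m`,
#'   `dt13_m`, `ds_m`, `northing_m`, `easting_m`, `rt_range`, `ycti`).
#' @export
attach_site_covariates <- function(sites, net, warm_temp_c = 13,
                                   big_flow_cms = 2.83,
                                   use_untrimmed = TRUE,
                                   quantize_30m = FALSE) {
  sites <- tibble::as_tibble(sites)
  sites$reach_id <- as.character(sites$reach_id)
  missing_sites <- sites$site_id[!(sites$reach_id %in% net$reach_id)]
  if (length(missing_sites) > 0) {
    rlang::abort(paste0("sites on removed or unknown reaches: ",
                        paste(missing_sites, collapse = ", ")),
                 class = "streamhyb_linkage_error")
  }
  reaches <- resolve_reaches(net, use_untrimmed)
  dist <- reach_distance_covariates(reaches, unique(sites$reach_id),
                                    warm_temp_c, big_flow_cms)
  if (quantize_30m) {
    dist <- dplyr::mutate(dist, dplyr::across(c("df3_m", "dt13_m", "ds_m"),
                                              quantize_30))
  }
  attrs <- dplyr::select(tibble::as_tibble(net), "reach_id", "t_aug_c",
                         "slope_pct", "cfm_day", "w95_days", "maf_cms",
                         "northing_m", "easting_m", "rt_range")
  out <- sites |>
    dplyr::left_join(attrs, by = "reach_id") |>
    dplyr::left_join(dist, by = "reach_id")
  cols <- c("site_id", "reach_id", "n_fish", "prta_pct", "pfrt_pct",
            "t_aug_c", "slope_pct", "cfm_day", "w95_days", "maf_cms",
            "df3_m", "dt13_m", "ds_m", "northing_m", "easting_m",
            "rt_range", "ycti")
  out[intersect(cols, names(out))]
}

# distance covariates for a set of origin reaches, computed on `reaches`
reach_distance_covariates <- function(reaches, origins, warm_temp_c = 13,
                                      big_flow_cms = 2.83) {
  big <- reaches$reach_id[
    predicate_mask(reaches, reach_predicate("maf_cms", ">=", big_flow_cms))]
  warm <- reaches$reach_id[
    predicate_mask(reaches, reach_predicate("t_aug_c", ">=", warm_temp_c))]
  src <- reaches$reach_id[
    predicate_mask(reaches, reach_predicate("rt_source", ">=", 1))]
  tibble::tibble(
    reach_id = origins,
    df3_m = unname(network_distance(reaches, origins, big)),
    dt13_m = unname(network_distance(reaches, origins, warm)),
    ds_m = unname(network_distance(reaches, origins,
                                   unique(c(big, warm, src))))
  )
}
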
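#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange left_join bind_rows group_by summarise ungroup across
#' @importFrom tibble tibble as_tibble
NULL

# canonical column order of the reach-table dialect
reach_columns <- c(
  "reach_id", "downstream_id", "length_m", "slope_pct", "maf_cms",
  "t_aug_c", "w95_days", "cfm_day", "intermittent",
  "easting_m", "northing_m", "rt_range", "rt_source"
)

reach_numeric_columns <- setdiff(reach_columns, c("reach_id", "downstream_id"))

#' Short field-standard covariate names
#'
#' Named character vector mapping the package's snake_case covariate columns
#' to the short names used in the stream-introgression literature
#' (T, S, CFM, W95, MAF, DF3, DT13, DS, N, E, RTrange, YCTI). Used by the
#' report formatters so printed model tables read
#' `"T + RTrange + DS + DT13 + MAF + E"`.
#'
#' @export
covariate_aliases <- c(
  t_aug_c = "T", slope_pct = "S", cfm_day = "CFM", w95_days = "W95",
  maf_cms = "MAF", df3_m = "DF3", dt13_m = "DT13", ds_m = "DS",
  northing_m = "N", easting_m = "E", rt_range = "RTrange", ycti = "YCTI"
)

alias_terms <- function(terms) {
  out <- covariate_aliases[terms]
  out[is.na(out)] <- terms[is.na(out)]
  unname(out)
}

#' Construct a stream network from a reach table
#'
#' A stream network is a tibble with one row per reach and the class
#' `stream_network`. Each reach points to at most one downstream neighbour
#' (`downstream_id`, `NA` for an outlet), so the topology is a forest:
#' junctions are implicit where two reaches share a downstream neighbour.
#' Validation rejects duplicate ids, dangling downstream pointers, self-loops
#' and cycles.
#'
#' @param reaches data frame with the reach-table columns (`reach_id`,
#'   `downstream_id`, `length_m`, `slope_pct`, `maf_cms`, `t_aug_c`,
#'   `w95_days`, `cfm_day`, `intermittent`, `easting_m`, `northing_m`,
#'   `rt_range`, `rt_source`).
#' @return a `stream_network` tibble.
#' @export
as_stream_network <- function(reaches) {
  reaches <- as_tibble(reaches)
  missing_cols <- setdiff(reach_columns, names(reaches))
  if (length(missing_cols) > 0) {
    abort(paste0("reach table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "streamhyb_input_error")
  }
  reaches <- reaches[reach_columns]
  reaches$reach_id <- as.character(reaches$reach_id)
  reaches$downstream_id <- as.character(reaches$downstream_id)
  reaches$downstream_id[!is.na(reaches$downstream_id) &
                          reaches$downstream_id == ""] <- NA_character_
  validate_network(reaches)
  structure(reaches, class = c("stream_network", class(tibble())))
}

validate_network <- function(reaches) {
  dup <- reaches$reach_id[duplicated(reaches$reach_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate reach_id: ", paste(unique(dup), collapse = ", ")),
          class = "streamhyb_input_error")
  }
  bad <- !is.na(reaches$downstream_id) &
    !(reaches$downstream_id %in% reaches$reach_id)
  if (any(bad)) {
    abort(paste0("downstream_id not present in table: ",
                 paste(unique(reaches$downstream_id[bad]), collapse = ", ")),
          class = "streamhyb_topology_error")
  }
  if (any(!is.na(reaches$downstream_id) &
            reaches$downstream_id == reaches$reach_id)) {
    off <- reaches$reach_id[!is.na(reaches$downstream_id) &
                              reaches$downstream_id == reaches$reach_id][1]
    abort(paste0("cycle in topology involving reach ", off),
          class = "streamhyb_topology_error")
  }
  # pointer-chasing with memoised colours: detects any directed cycle
  idx <- stats::setNames(seq_len(nrow(reaches)), reaches$reach_id)
  down <- idx[reaches$downstream_id]
  state <- integer(nrow(reaches)) # 0 unvisited, 1 on stack, 2 done
  for (start in seq_len(nrow(reaches))) {
    v <- start
    path <- integer(0)
    while (!is.na(v) && state[v] == 0L) {
      state[v] <- 1L
      path <- c(path, v)
      v <- down[v]
    }
    if (!is.na(v) && state[v] == 1L) {
      abort(paste0("cycle in topology involving reach ", reaches$reach_id[v]),
            class = "streamhyb_topology_error")
    }
    state[path] <- 2L
  }
  neg <- reaches$length_m <= 0
  if (any(neg, na.rm = TRUE)) {
    abort(paste0("length_m must be > 0; offending reaches: ",
                 paste(reaches$reach_id[which(neg)], collapse = ", ")),
          class = "streamhyb_input_error")
  }
  if (any(reaches$slope_pct < 0, na.rm = TRUE) ||
        any(reaches$maf_cms < 0, na.rm = TRUE)) {
    abort("slope_pct and maf_cms must be >= 0",
          class = "streamhyb_input_error")
  }
  invisible(reaches)
}

#' Read a reach table from delimited text
#'
#' Reads the comma-delimited reach-table dialect (UTF-8, header row, empty
#' `downstream_id` marks an outlet, 0/1 indicator columns) and returns a
#' validated [as_stream_network()] object. Rows whose numeric fields fail to
#' parse are dropped with a warning naming the offending rows.
#'
#' @param path file path or connection.
#' @return a `stream_network` tibble.
#' @export
load_network <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(reach_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("reach table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "streamhyb_input_error")
  }
  bad_rows <- integer(0)
  for (col in reach_numeric_columns) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    bad_rows <- union(bad_rows, bad)
    raw[[col]] <- parsed
  }
  if (length(bad_rows) > 0) {
    warn(paste0("dropping ", length(bad_rows),
                " row(s) with malformed numeric fields (rows ",
                paste(sort(bad_rows), collapse = ", "), ")"))
    raw <- raw[-bad_rows, ]
  }
  as_stream_network(raw)
}

#' Write a reach table as delimited text
#'
#' Emits the same dialect [load_network()] reads, so a write/read cycle
#' round-trips the network exactly.
#'
#' @param net a `stream_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  out <- as_tibble(net)[reach_columns]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Trimming rules for marginal habitat
#'
#' Screening thresholds that remove reaches of marginal importance to fish
#' before modeling: intermittent channels, very small summer flows, large
#' rivers unlikely to hold cutthroat-trout spawning habitat, and steep
#' headwater chains where geological barriers are common.
#'
#' @param min_summer_flow_cms reaches with summer flow below this are
#'   removed (m^3/s). Mean annual flow is used as the screening proxy unless
#'   a dedicated summer-flow column is supplied upstream of this package.
#' @param max_maf_cms reaches with mean annual flow above this are removed
#'   (m^3/s).
#' @param max_slope_pct reaches steeper than this, together with everything
#'   upstream of them, are removed (percent).
#' @param drop_intermittent remove reaches flagged intermittent.
#' @return a `trim_rules` list.
#' @export
trim_rules <- function(min_summer_flow_cms = 0.028, max_maf_cms = 5.66,
                       max_slope_pct = 10, drop_intermittent = TRUE) {
  if (min_summer_flow_cms <= 0 || max_maf_cms <= 0 || max_slope_pct <= 0) {
    abort("trim rule thresholds must be > 0", class = "streamhyb_config_error")
  }
  structure(list(min_summer_flow_cms = min_summer_flow_cms,
                 max_maf_cms = max_maf_cms,
                 max_slope_pct = max_slope_pct,
                 drop_intermittent = isTRUE(drop_intermittent)),
            class = "trim_rules")
}

upstream_of <- function(net, ids) {
  # all reaches whose path to the outlet passes through any id in `ids`
  kids <- split(net$reach_id, net$downstream_id)
  seen <- character(0)
  frontier <- ids
  while (length(frontier) > 0) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    nxt <- setdiff(nxt, c(seen, ids))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Trim marginal reaches from a network
#'
#' Applies the four screening rules of [trim_rules()] to the original reach
#' attributes, in order: intermittent, low summer flow, high mean annual
#' flow, then slope with upstream propagation (a reach steeper than the
#' threshold is removed together with every reach upstream of it, trimming
#' the network from its upper extent). The rules do not cascade off each
#' other's removals except for the slope propagation.
#'
#' The returned network keeps the full pre-trim table in
#' `attr(, "untrimmed")` (distance covariates may traverse trimmed main
#' stems) and a removal log in `attr(, "removed")`.
#'
#' @param net a `stream_network`.
#' @param rules a [trim_rules()] object.
#' @return the trimmed `stream_network`.
#' @export
trim_network <- function(net, rules = trim_rules()) {
  stopifnot(inherits(net, "stream_network"))
  base <- attr(net, "untrimmed") %||% as_tibble(net)[reach_columns]
  tab <- as_tibble(net)
  reason <- stats::setNames(rep(NA_character_, nrow(tab)), tab$reach_id)
  if (rules$drop_intermittent) {
    hit <- tab$reach_id[tab$intermittent > 0]
    reason[hit] <- ifelse(is.na(reason[hit]), "intermittent", reason[hit])
  }
  hit <- tab$reach_id[tab$maf_cms < rules$min_summer_flow_cms]
  reason[hit] <- ifelse(is.na(reason[hit]), "low_flow", reason[hit])
  hit <- tab$reach_id[tab$maf_cms > rules$max_maf_cms]
  reason[hit] <- ifelse(is.na(reason[hit]), "high_flow", reason[hit])
  steep <- tab$reach_id[tab$slope_pct > rules$max_slope_pct]
  upstream <- upstream_of(tab, steep)
  reason[steep] <- ifelse(is.na(reason[steep]), "slope", reason[steep])
  reason[upstream] <- ifelse(is.na(reason[upstream]),
                             "upstream_of_slope", reason[upstream])
  removed <- tibble(reach_id = names(reason)[!is.na(reason)],
                    reason = unname(reason[!is.na(reason)]))
  keep <- tab[is.na(reason[tab$reach_id]), ]
  # surviving reaches whose downstream neighbour was removed become outlets
  keep$downstream_id[!(keep$downstream_id %in% keep$reach_id)] <- NA_character_
  if (nrow(keep) == 0) {
    warn("trimming removed every reach; the network is empty")
  }
  out <- structure(keep, class = c("stream_network", class(tibble())))
  attr(out, "removed") <- removed
  attr(out, "untrimmed") <- base
  out
}

#' Drop a stream network to a plain reach tibble
#'
#' Strips the network class and its bookkeeping attributes (`removed`,
#' `untrimmed`, `scenario`), returning just the reach table.
#'
#' @param x a `stream_network`.
#' @param ... unused.
#' @return a tibble.
#' @method as_tibble stream_network
#' @export
as_tibble.stream_network <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "stream_network")
  attr(out, "removed") <- NULL
  attr(out, "untrimmed") <- NULL
  attr(out, "scenario") <- NULL
  out
}

#' @export
print.stream_network <- function(x, ...) {
  n_out <- sum(is.na(x$downstream_id))
  cat(sprintf("# Stream network: %d reaches (%d outlet%s), %.1f km total\n",
              nrow(x), n_out, if (n_out == 1) "" else "s",
              sum(x$length_m) / 1000))
  removed <- attr(x, "removed")
  if (!is.null(removed) && nrow(removed) > 0) {
    cat(sprintf("# Trimmed: %d reaches removed (%s)\n", nrow(removed),
                paste(sprintf("%s %d", names(table(removed$reason)),
                              as.integer(table(removed$reason))),
                      collapse = ", ")))
  }
  print(as_tibble(x), ...)
  invisible(x)
}
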
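# Independent oracles and fixture builders. Nothing here calls the package's
# own distance, AUC or IRLS code paths.

demo_network <- function() {
  load_network(system.file("extdata", "reaches_demo.csv",
                           package = "streamhyb"))
}

demo_sites <- function() {
  readr::read_csv(system.file("extdata", "sites_demo.csv",
                              package = "streamhyb"),
                  show_col_types = FALSE)
}

# minimal reach table with every dialect column, defaults benign
make_reaches <- function(reach_id, downstream_id, length_m,
                         slope_pct = 2, maf_cms = 0.5, t_aug_c = 10,
                         w95_days = 2, cfm_day = 200, intermittent = 0,
                         easting_m = 1.4e6, northing_m = 1.8e6,
                         rt_range = 0, rt_source = 0) {
  tibble::tibble(reach_id = reach_id, downstream_id = downstream_id,
                 length_m = length_m, slope_pct = slope_pct,
                 maf_cms = maf_cms, t_aug_c = t_aug_c, w95_days = w95_days,
                 cfm_day = cfm_day, intermittent = intermittent,
                 easting_m = easting_m, northing_m = northing_m,
                 rt_range = rt_range, rt_source = rt_source)
}

# random tree network: each reach's downstream is any earlier reach
random_tree_network <- function(n, seed) {
  set.seed(seed)
  down <- c(NA_integer_, vapply(2:n, function(i) sample.int(i - 1, 1),
                                integer(1)))
  ids <- sprintf("T%03d", seq_len(n))
  make_reaches(
    reach_id = ids,
    downstream_id = ifelse(is.na(down), NA_character_, ids[down]),
    length_m = round(runif(n, 100, 3000)),
    t_aug_c = runif(n, 6, 16),
    maf_cms = runif(n, 0.05, 4)
  ) |> as_stream_network()
}

# brute-force along-network distance on a TREE. Each reach's midpoint is
# half a length from both its upstream junction (labelled by the reach
# itself) and its downstream junction (labelled by the downstream reach, or
# the outlet); walking the junction chain downstream and meeting at the
# first-reachable common junction gives the unique tree path.
oracle_tree_distance <- function(net, origin, target_ids) {
  tab <- tibble::as_tibble(net)
  len <- stats::setNames(tab$length_m, tab$reach_id)
  down <- stats::setNames(tab$downstream_id, tab$reach_id)
  chain <- function(id) {
    # junction labels and cumulative distance from the midpoint of `id`
    labs <- id                      # its own upstream junction
    d <- len[[id]] / 2
    cur <- id
    repeat {
      nxt <- down[[cur]]
      if (is.na(nxt)) {
        labs <- c(labs, "OUTLET")
        d <- c(d, d[length(d)] + if (cur == id) 0 else len[[cur]])
        break
      }
      labs <- c(labs, nxt)
      d <- c(d, d[length(d)] + if (cur == id) 0 else len[[cur]])
      cur <- nxt
    }
    stats::setNames(d, labs)
  }
  best <- Inf
  for (tg in target_ids) {
    if (tg == origin) return(0)
    cu <- chain(origin)
    ct <- chain(tg)
    common <- intersect(names(cu), names(ct))
    best <- min(best, min(cu[common] + ct[common]))
  }
  if (is.finite(best)) best else NA_real_
}

# exact pairwise-concordance AUC: counts in half-units so the comparison
# with the rank formulation is exact
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

oracle_imbalance <- function(scores, labels, cutoff) {
  pred <- scores >= cutoff
  abs(sum(!pred & labels == 1) - sum(pred & labels == 0))
}

# independent subset enumeration via stats::glm (its own IRLS + AIC)
oracle_subset_ranking <- function(data, response, candidates) {
  subsets <- unlist(lapply(0:length(candidates), function(k) {
    if (k == 0) list(character(0))
    else utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
  aics <- vapply(subsets, function(s) {
    rhs <- if (length(s) == 0) "1" else paste(s, collapse = " + ")
    stats::AIC(stats::glm(stats::reformulate(rhs, response),
                          binomial(), data))
  }, numeric(1))
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = "|"),
                 character(1))
  keys[order(aics, lengths(subsets), keys)]
}
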
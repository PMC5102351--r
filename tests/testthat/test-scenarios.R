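# published consensus coefficients for the 10% admixture threshold
consensus10 <- function() manual_model(default_true_coef(), "exceeds_10")

test_that("predict_probability is the inverse-logit of the linear predictor", {
  null_model <- manual_model(c("(Intercept)" = 0, t_aug_c = 0))
  expect_equal(predict_probability(null_model, tibble::tibble(t_aug_c = 5)),
               0.5)
  # inside-range median site: independent scalar arithmetic
  med <- tibble::tibble(t_aug_c = 11.1, rt_range = 1, ds_m = 4598,
                        dt13_m = 6231, maf_cms = 0.38, easting_m = 1390049)
  lp <- -13.4 + 0.266 * 11.1 + 1.34 * 1 + (-1.34e-4) * 4598 +
    (-6.18e-5) * 6231 + 0.512 * 0.38 + 6.75e-6 * 1390049
  expect_equal(predict_probability(consensus10(), med), 1 / (1 + exp(-lp)),
               tolerance = 1e-12)
  expect_equal(predict_probability(consensus10(), med), 0.370, tolerance = 1e-2)
  # a degree of warming multiplies the odds by exp(b_T)
  warmer <- med
  warmer$t_aug_c <- 12.1
  p0 <- predict_probability(consensus10(), med)
  p1 <- predict_probability(consensus10(), warmer)
  expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), exp(0.266),
               tolerance = 1e-9)
  expect_gt(p1, p0)
  expect_error(predict_probability(consensus10(), med[-1]),
               regexp = "t_aug_c", class = "streamhyb_contract_error")
})

test_that("the zero scenario is a fixed point and equilibrium only flips the range flag", {
  net <- generate_network(generator_config(n_reaches = 80, seed = 5))
  same <- apply_scenario(net, scenario_spec("current", 0, FALSE))
  expect_identical(tibble::as_tibble(same)[streamhyb:::reach_columns],
                   tibble::as_tibble(net)[streamhyb:::reach_columns])
  eq <- apply_scenario(net, scenario_spec("equilibrium", 0, TRUE))
  expect_true(all(eq$rt_range == 1))
  inside <- net$rt_range == 1
  expect_identical(
    tibble::as_tibble(eq)[inside, setdiff(streamhyb:::reach_columns, "rt_range")],
    tibble::as_tibble(net)[inside, setdiff(streamhyb:::reach_columns, "rt_range")])
})

test_that("warming across the 13 C line zeroes DT13 and can only shrink DS", {
  net <- make_reaches(
    reach_id = c("A", "B"), downstream_id = c(NA, "A"),
    length_m = c(1000, 800), t_aug_c = c(12.1, 10),
    maf_cms = c(1, 0.5)
  ) |> as_stream_network()
  before <- reach_covariates(net)
  warmed <- apply_scenario(net, scenario_spec("+1C", 1.0))
  after <- reach_covariates(warmed)
  expect_true(all(is.na(before$dt13_m))) # nothing warm yet, sentinel
  expect_equal(after$dt13_m[after$reach_id == "A"], 0) # 13.1 >= 13
  expect_equal(after$dt13_m[after$reach_id == "B"], 900)
  ok <- !is.na(before$ds_m)
  expect_true(all(after$ds_m[ok] <= before$ds_m[ok]))
})

test_that("fixture classification matches hand-evaluated linear predictors", {
  net <- demo_network()
  # hand-traced distance covariates (midpoint convention)
  ds <- c(R01 = 0, R02 = 0, R03 = 1250, R04 = 2350, R05 = 0, R06 = 1100,
          R07 = 2400, R08 = 3350, R09 = 4450, R10 = 3350, R11 = 2200,
          R12 = 5650)
  dt13 <- c(R01 = 0, R02 = 0, R03 = 1350, R04 = 2450, R05 = 1400,
            R06 = 2500, R07 = 2500, R08 = 3450, R09 = 4550, R10 = 3450,
            R11 = 3600, R12 = 5750)
  lp <- -13.4 + 0.266 * net$t_aug_c + 1.34 * net$rt_range -
    1.34e-4 * ds[net$reach_id] - 6.18e-5 * dt13[net$reach_id] +
    0.512 * net$maf_cms + 6.75e-6 * net$easting_m
  expected_below <- unname(1 / (1 + exp(-lp)) < 0.5)
  flags <- classify_network(net, consensus10(), cutoff = 0.5)
  expect_equal(flags$below, expected_below)
  expect_equal(sum(flags$below), 7)
  # degenerate cutoff: everything sits below 1
  all_below <- classify_network(net, consensus10(), cutoff = 1)
  expect_true(all(all_below$below))
})

test_that("habitat volume follows the hydraulic-geometry power laws on the 3-reach toy", {
  net <- make_reaches(
    reach_id = c("A", "B", "C"), downstream_id = c(NA, "A", "B"),
    length_m = c(1000, 2000, 3000), maf_cms = c(0.25, 1, 4),
    rt_range = c(1, 0, 0)
  ) |> as_stream_network()
  flags <- tibble::tibble(reach_id = c("A", "B", "C"),
                          probability = 0.1, below = TRUE)
  hab <- summarize_habitat(net, flags, stratify_by_rt_range = FALSE)
  expect_equal(hab$length_km, 6) # saturation: all below
  vol <- 1000 * (4.3 * 0.25^0.5) * (0.27 * 0.25^0.4) +
    2000 * (4.3 * 1^0.5) * (0.27 * 1^0.4) +
    3000 * (4.3 * 4^0.5) * (0.27 * 4^0.4)
  expect_equal(hab$volume_m3, vol, tolerance = 1e-12)
  strat <- summarize_habitat(net, flags, stratify_by_rt_range = TRUE)
  expect_setequal(strat$stratum, c("inside", "outside"))
  expect_equal(strat$length_km[strat$stratum == "inside"], 1)
})

test_that("percent change reproduces its arithmetic and round-trips", {
  cur <- tibble::tibble(stratum = "outside", length_km = 16186,
                        volume_m3 = 4117)
  sce <- tibble::tibble(stratum = "outside", length_km = 9472,
                        volume_m3 = 1043)
  out <- percent_change(cur, sce)
  expect_equal(out$pct_change_length, -41.5)
  expect_equal(out$pct_change_volume, -74.7)
  expect_equal(percent_change(cur, cur)$pct_change_length, 0)
  # -x% applied to current recovers -x to one decimal
  shrunk <- dplyr::mutate(cur, length_km = length_km * (1 - 0.237),
                          volume_m3 = volume_m3 * (1 - 0.237))
  expect_equal(percent_change(cur, shrunk)$pct_change_length, -23.7)
  zero <- dplyr::mutate(cur, length_km = 0, volume_m3 = 0)
  expect_true(is.na(percent_change(zero, sce)$pct_change_length))
})

test_that("warming nests the below-threshold habitat sets and equilibrium spares inside range", {
  net <- trim_network(generate_network(generator_config(n_reaches = 250,
                                                        seed = 13)))
  models <- list(`10` = consensus10())
  cutoffs <- c(`10` = 0.384)
  hab <- run_scenarios(net, models, cutoffs)
  below_set <- function(delta) {
    spec <- scenario_spec("s", delta)
    flags <- classify_network(apply_scenario(net, spec), consensus10(), 0.384)
    flags$reach_id[flags$below %in% TRUE]
  }
  b0 <- below_set(0); b05 <- below_set(0.5); b10 <- below_set(1.0)
  expect_true(all(b10 %in% b05))
  expect_true(all(b05 %in% b0))
  # equilibrium rows for the inside stratum equal the current scenario's
  inside <- dplyr::filter(hab, stratum == "inside")
  cur <- dplyr::filter(inside, scenario == "current")
  eqm <- dplyr::filter(inside, scenario == "equilibrium")
  expect_equal(eqm$length_km, cur$length_km)
  expect_equal(eqm$volume_m3, cur$volume_m3)
  # warming never grows habitat below threshold
  tab <- tidyr::pivot_wider(hab, id_cols = "stratum",
                            names_from = "scenario",
                            values_from = "length_km")
  expect_true(all(tab[["current+1.0C"]] <= tab[["current+0.5C"]] + 1e-9))
  expect_true(all(tab[["current+0.5C"]] <= tab[["current"]] + 1e-9))
})

test_that("response curves carry the range offset and decay with source distance", {
  med <- tibble::tibble(dt13_m = 6231, maf_cms = 0.38, easting_m = 1390049)
  rc <- response_curves(consensus10(), med, ds_m = seq(0, 30000, 500),
                        t_values = c(9, 12, 15))
  expect_true(all(rc$probability >= 0 & rc$probability <= 1))
  # strictly decreasing in DS (negative coefficient)
  one <- dplyr::filter(rc, t_aug_c == 12, rt_range == 1)
  expect_true(all(diff(one$probability) < 0))
  # inside/outside differ by a constant logit offset b_RTrange
  wide <- tidyr::pivot_wider(rc, names_from = "rt_range",
                             values_from = "probability")
  offset <- qlogis(wide$`1`) - qlogis(wide$`0`)
  expect_equal(offset, rep(1.34, nrow(wide)), tolerance = 1e-9)
  # published-coefficient decay: near zero a few tens of km from a source
  far <- dplyr::filter(rc, ds_m == 30000, t_aug_c == 12, rt_range == 1)
  expect_equal(far$probability, 0.02423, tolerance = 1e-3)
  expect_error(response_curves(manual_model(c("(Intercept)" = 0, x = 1)),
                               med),
               class = "streamhyb_contract_error")
})
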
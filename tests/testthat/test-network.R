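test_that("a minimal chain loads and simple topology errors are caught", {
  chain <- make_reaches(c("A", "B", "C"), c("B", "C", NA), c(500, 700, 900))
  net <- as_stream_network(chain)
  expect_s3_class(net, "stream_network")
  expect_equal(sum(!is.na(net$downstream_id)), 2)

  self_loop <- make_reaches("X", "X", 100)
  expect_error(as_stream_network(self_loop), class = "streamhyb_topology_error")

  cyc <- make_reaches(c("A", "B"), c("B", "A"), c(100, 100))
  expect_error(as_stream_network(cyc), class = "streamhyb_topology_error")

  dup <- make_reaches(c("A", "A"), c(NA, NA), c(100, 100))
  expect_error(as_stream_network(dup), class = "streamhyb_input_error")

  neg <- make_reaches("A", NA, -5)
  expect_error(as_stream_network(neg), class = "streamhyb_input_error")
})

test_that("the packaged 12-reach fixture loads with its hand-summed length", {
  net <- demo_network()
  expect_equal(nrow(net), 12)
  expect_equal(sum(net$length_m), 14500)
})

test_that("malformed numeric rows are dropped with row diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- make_reaches(c("A", "B", "C"), c("B", "C", NA), c(500, 700, 900))
  readr::write_csv(tab, path)
  txt <- readLines(path)
  txt[2] <- sub("500", "oops", txt[2])
  writeLines(txt, path)
  expect_warning(net <- load_network(path), "malformed")
  expect_equal(nrow(net), 2)
})

test_that("write_network round-trips the fixture exactly", {
  net <- demo_network()
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path)
  again <- load_network(path)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(net))
  # byte determinism of the writer
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_network(again, path2)
  expect_identical(readLines(path), readLines(path2))
})

toy_trim_network <- function() {
  # A(out, MAF 6.0) <- B <- C(intermittent) <- D <- E(11%) <- F(12%)
  make_reaches(
    reach_id = c("A", "B", "C", "D", "E", "F"),
    downstream_id = c(NA, "A", "B", "C", "D", "E"),
    length_m = rep(1000, 6),
    maf_cms = c(6.0, 2.0, 1.0, 0.6, 0.3, 0.1),
    slope_pct = c(1, 2, 3, 4, 11, 12),
    intermittent = c(0, 0, 1, 0, 0, 0)
  ) |> as_stream_network()
}

test_that("trimming applies all four rules as hand-traced on the toy network", {
  trimmed <- trim_network(toy_trim_network())
  expect_setequal(trimmed$reach_id, c("B", "D"))
  removed <- attr(trimmed, "removed")
  reasons <- stats::setNames(removed$reason, removed$reach_id)
  expect_equal(reasons[["A"]], "high_flow")
  expect_equal(reasons[["C"]], "intermittent")
  expect_equal(reasons[["E"]], "slope")
  expect_equal(reasons[["F"]], "slope")
  # survivors whose downstream was removed become outlets
  expect_true(all(is.na(trimmed$downstream_id)))
})

test_that("no-op rules leave the network unchanged and trimming is idempotent", {
  net <- toy_trim_network()
  lax <- trim_rules(min_summer_flow_cms = 1e-9, max_maf_cms = Inf,
                    max_slope_pct = Inf, drop_intermittent = FALSE)
  expect_equal(tibble::as_tibble(trim_network(net, lax))[streamhyb:::reach_columns],
               tibble::as_tibble(net)[streamhyb:::reach_columns])
  once <- trim_network(net)
  twice <- trim_network(once)
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(once))
  # output is a sub-network of the input
  expect_true(all(once$reach_id %in% net$reach_id))
})

test_that("a mid-chain slope violation removes that reach and everything upstream", {
  net <- make_reaches(
    reach_id = c("G1", "G2", "G3", "G4"),
    downstream_id = c(NA, "G1", "G2", "G3"),
    length_m = rep(500, 4),
    slope_pct = c(2, 12, 3, 4)
  ) |> as_stream_network()
  trimmed <- trim_network(net)
  expect_equal(trimmed$reach_id, "G1")
  removed <- attr(trimmed, "removed")
  expect_setequal(removed$reach_id, c("G2", "G3", "G4"))
  expect_equal(removed$reason[removed$reach_id == "G3"], "upstream_of_slope")
})

test_that("after trimming no survivor violates any rule", {
  net <- random_tree_network(60, seed = 11)
  tab <- tibble::as_tibble(net)
  tab$slope_pct <- runif(60, 0, 9)
  tab$slope_pct[c(10, 25)] <- 13 # two mid-network violators
  tab$intermittent <- rbinom(60, 1, 0.1)
  net <- as_stream_network(tab)
  trimmed <- trim_network(net)
  expect_true(all(trimmed$intermittent == 0))
  expect_true(all(trimmed$maf_cms <= 5.66))
  expect_true(all(trimmed$maf_cms >= 0.028))
  expect_true(all(trimmed$slope_pct <= 10))
  # nothing surviving sits upstream of a slope violator
  removed <- attr(trimmed, "removed")
  steep <- removed$reach_id[removed$reason == "slope"]
  up <- streamhyb:::upstream_of(tibble::as_tibble(net), steep)
  expect_length(intersect(trimmed$reach_id, up), 0)
})
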
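test_that("closed-form fits are recovered exactly", {
  # intercept-only: logit of the observed fraction
  d <- tibble::tibble(y = rep(c(1, 0), c(5, 15)))
  f <- fit_logistic(d, "y")
  expect_equal(f$coefficients$estimate, log(5 / 15), tolerance = 1e-6)
  # 2x2 design: slope is the log odds ratio, SE by the Woolf formula
  d2 <- tibble::tibble(
    x = rep(c(0, 0, 1, 1), c(30, 10, 10, 30)),
    y = rep(c(0, 1, 0, 1), c(30, 10, 10, 30))
  )
  f2 <- fit_logistic(d2, "y", "x")
  est <- stats::setNames(f2$coefficients$estimate, f2$coefficients$term)
  se <- stats::setNames(f2$coefficients$std.error, f2$coefficients$term)
  expect_equal(est[["x"]], log(9), tolerance = 1e-6)
  expect_equal(se[["x"]], sqrt(1 / 30 + 1 / 10 + 1 / 10 + 1 / 30),
               tolerance = 1e-6)
})

test_that("IRLS agrees with an independent optimizer on random data", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- 80
    d <- tibble::tibble(a = rnorm(n), b = runif(n, -2, 2))
    eta <- -0.3 + 0.8 * d$a - 1.1 * d$b
    d$y <- rbinom(n, 1, plogis(eta))
    if (length(unique(d$y)) < 2) next
    f <- fit_logistic(d, "y", c("a", "b"), tol = 1e-13)
    # general-purpose BFGS on the same likelihood
    nll <- function(beta) {
      p <- plogis(beta[1] + beta[2] * d$a + beta[3] * d$b)
      -sum(d$y * log(p) + (1 - d$y) * log(1 - p))
    }
    opt <- optim(c(0, 0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    expect_equal(f$coefficients$estimate, opt$par, tolerance = 1e-6)
    # and with the reference GLM implementation, including SEs and AIC
    g <- stats::glm(y ~ a + b, binomial(), d,
                    control = list(epsilon = 1e-13))
    expect_equal(f$coefficients$estimate, unname(coef(g)), tolerance = 1e-6)
    expect_equal(f$coefficients$std.error,
                 unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
    expect_equal(f$aic, AIC(g), tolerance = 1e-6)
  }
})

test_that("the score-equation identity holds: mean fitted equals prevalence", {
  set.seed(4)
  d <- simulate_site_covariates(300, seed = 4)
  d$y <- simulate_bernoulli_outcomes(d, seed = 5)
  f <- fit_logistic(d, "y", c("t_aug_c", "ds_m", "rt_range"))
  expect_equal(mean(f$fitted), mean(f$y), tolerance = 1e-10)
})

test_that("degenerate and ill-posed designs raise typed errors", {
  d <- tibble::tibble(y = rep(1, 10), x = rnorm(10))
  expect_error(fit_logistic(d, "y", "x"),
               class = "streamhyb_degenerate_outcome")
  set.seed(1)
  d2 <- tibble::tibble(x1 = rnorm(30))
  d2$x2 <- 2 * d2$x1
  d2$y <- rep(c(0, 1), 15)
  expect_error(fit_logistic(d2, "y", c("x1", "x2")),
               regexp = "x2", class = "streamhyb_collinearity_error")
})

test_that("complete separation trips the guard instead of exploding", {
  d <- tibble::tibble(x = c(-(10:1), 1:10) / 3,
                      y = rep(c(0, 1), each = 10))
  f <- fit_logistic(d, "y", "x")
  expect_false(f$converged)
})

test_that("standardization is invisible: scaling a covariate rescales its coefficient", {
  set.seed(8)
  d <- simulate_site_covariates(400, seed = 8)
  d$y <- simulate_bernoulli_outcomes(d, seed = 9)
  f1 <- fit_logistic(d, "y", c("t_aug_c", "ds_m"))
  d$ds_km <- d$ds_m / 1000
  f2 <- fit_logistic(d, "y", c("t_aug_c", "ds_km"))
  expect_equal(f2$coefficients$estimate[3], f1$coefficients$estimate[3] * 1000,
               tolerance = 1e-6)
  expect_equal(f2$logLik, f1$logLik, tolerance = 1e-8)
})

test_that("tidy and glance expose the broom-style surfaces", {
  d <- tibble::tibble(x = rnorm(50), y = rbinom(50, 1, 0.4))
  f <- fit_logistic(d, "y", "x")
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "conf.low", "conf.high"))
  gl <- glance(f)
  expect_equal(gl$nobs, 50)
  expect_equal(gl$AIC, -2 * f$logLik + 2 * 2)
  # Wald interval spans the estimate
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("collinearity screening removes the weaker member of a correlated pair", {
  set.seed(21)
  n <- 400
  w95 <- abs(rnorm(n, 2.5, 2))
  d <- tibble::tibble(
    w95_days = w95,
    cfm_day = 228 - 9 * w95 + rnorm(n, 0, 3), # |r| ~ 0.97 with w95
    t_aug_c = rnorm(n, 11, 2)
  )
  d$y <- rbinom(n, 1, plogis(-2 + 0.5 * w95)) # w95 is the informative one
  scr <- collinearity_screen(d, "y", c("w95_days", "cfm_day", "t_aug_c"))
  expect_true("w95_days" %in% scr$retained)
  expect_false("cfm_day" %in% scr$retained)
  expect_true(all(scr$vifs$vif[!is.na(scr$vifs$vif)] < 3.5))
})

test_that("orthogonal covariates all survive screening with unit VIFs", {
  d <- tibble::tibble(a = rep(c(-1, 1), 50), b = rep(c(-1, -1, 1, 1), 25))
  d$y <- rep(c(0, 1), each = 50)
  scr <- collinearity_screen(d, "y", c("a", "b"))
  expect_setequal(scr$retained, c("a", "b"))
  expect_equal(scr$vifs$vif, c(1, 1), tolerance = 1e-10)
})

test_that("a duplicated column is perfectly correlated and one copy is removed", {
  set.seed(3)
  d <- tibble::tibble(a = rnorm(100))
  d$b <- d$a
  d$y <- rbinom(100, 1, plogis(d$a))
  scr <- collinearity_screen(d, "y", c("a", "b"))
  expect_length(scr$retained, 1)
  expect_equal(max(abs(scr$correlations$r)), 1)
})

test_that("constant covariates are dropped with a warning", {
  d <- tibble::tibble(a = rnorm(60), c0 = 1, y = rbinom(60, 1, 0.5))
  expect_warning(scr <- collinearity_screen(d, "y", c("a", "c0")),
                 "constant")
  expect_equal(scr$retained, "a")
})

test_that("subset enumeration counts 2^k models and matches an independent ranking", {
  set.seed(31)
  d <- simulate_site_covariates(300, seed = 31)
  d$y <- simulate_bernoulli_outcomes(
    d, c("(Intercept)" = -0.5, t_aug_c = 0.2, rt_range = 1), seed = 32)
  one <- all_subsets_selection(d, "y", "t_aug_c")
  expect_equal(nrow(one), 2)
  cands <- c("t_aug_c", "rt_range", "ds_m", "maf_cms")
  rk <- all_subsets_selection(d, "y", cands)
  expect_equal(nrow(rk), 16)
  got <- vapply(rk$covariates, function(s) paste(sort(s), collapse = "|"),
                character(1))
  expect_equal(got, oracle_subset_ranking(d, "y", cands))
  expect_error(all_subsets_selection(d, "y", sprintf("c%02d", 1:13)),
               class = "streamhyb_config_error")
})

test_that("rankings render in the published four-row format", {
  set.seed(41)
  d <- simulate_site_covariates(250, seed = 41)
  d$y <- simulate_bernoulli_outcomes(d, seed = 42)
  rk <- all_subsets_selection(d, "y", c("t_aug_c", "rt_range", "ds_m"))
  out <- format_ranking(rk)
  expect_equal(nrow(out), 4)
  expect_named(out, c("Model", "AIC"))
  expect_match(out$Model, "^(\\(intercept only\\)|[A-Za-z0-9+ ]+)$")
  expect_true(any(grepl("RTrange", out$Model)))
})

mock_ranking <- function(subsets, aics) {
  # hand-built ranking shaped like all_subsets_selection output
  ord <- order(aics, lengths(subsets))
  tibble::tibble(
    rank = seq_along(subsets),
    label = vapply(subsets[ord], paste, character(1), collapse = " + "),
    covariates = subsets[ord],
    k = lengths(subsets[ord]),
    logLik = NA_real_,
    aic = aics[ord],
    delta_aic = aics[ord] - min(aics),
    converged = TRUE,
    fit = lapply(subsets[ord], function(s)
      manual_model(stats::setNames(rep(0, length(s) + 1),
                                   c("(Intercept)", s))))
  )
}

test_that("the consensus rule adopts a unanimous top model", {
  subs <- list(c("a", "b"), c("a"), c("b"))
  r <- mock_ranking(subs, c(100, 101, 102))
  cons <- select_consensus(list(`1` = r, `10` = r, `20` = r))
  expect_equal(cons$rule, "shared-top")
  expect_equal(cons$subset, c("a", "b"))
})

test_that("a shared 10/20 top more than delta-AIC above the 1% best is rejected", {
  subs <- list(c("a", "b"), c("a"), c("b"))
  top_ab <- mock_ranking(subs, c(100, 104, 105))
  one_pct <- mock_ranking(subs, c(103.1, 100, 105)) # {a,b} sits 3.1 above best
  cons <- select_consensus(list(`1` = one_pct, `10` = top_ab, `20` = top_ab))
  expect_equal(cons$rule, "none")
  expect_null(cons$subset)
})

test_that("a shared top within the window at 1% becomes the consensus model", {
  subs <- list(c("a", "b"), c("a"), c("b"))
  top_ab <- mock_ranking(subs, c(100, 104, 105))
  one_pct <- mock_ranking(subs, c(100.9, 100, 105)) # within 3 of the 1% best
  cons <- select_consensus(list(`1` = one_pct, `10` = top_ab, `20` = top_ab))
  expect_equal(cons$rule, "shared-top")
  expect_equal(cons$subset, c("a", "b"))
  expect_length(cons$fits, 3)
})

test_that("disagreeing 10/20 tops fall back to the labelled rank-sum extension", {
  subs <- list(c("a"), c("b"), c("a", "b"))
  r10 <- mock_ranking(subs, c(100, 100.5, 101))   # top: a
  r20 <- mock_ranking(subs, c(100.5, 100, 101))   # top: b
  r1 <- mock_ranking(subs, c(100, 100.2, 101))
  cons <- select_consensus(list(`1` = r1, `10` = r10, `20` = r20))
  expect_equal(cons$rule, "rank-sum")
  expect_true(!is.null(cons$subset))
})
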
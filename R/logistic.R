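#' Logistic regression by iteratively reweighted least squares
#'
#' Fits a binomial GLM with logit link by IRLS. Covariates are standardized
#' internally (centred, scaled to unit SD) for numerical stability — the
#' easting covariate is of order 1e6 m while distance coefficients are of
#' order 1e-4 per m — and estimates, standard errors and the covariance are
#' back-transformed so everything is reported in raw units (per degree C,
#' per meter, per m^3/s). Standard errors come from the inverse Fisher
#' information; p-values from the two-sided normal tail of z = b/SE.
#'
#' A fit is flagged non-converged when the iteration cap is reached or when
#' any standardized coefficient exceeds the separation guard (|b| > 15 on
#' the per-SD logit scale), rather than returning astronomically scaled
#' standard errors under complete separation.
#'
#' @param data data frame containing the response and covariates.
#' @param response name of the binary (0/1) outcome column.
#' @param covariates character vector of covariate column names (may be
#'   empty for an intercept-only model).
#' @param tol convergence tolerance on the deviance change.
#' @param max_iter iteration cap.
#' @param guard separation guard on the standardized logit scale.
#' @return an `exceedance_fit` object; see [tidy.exceedance_fit()] and
#'   [glance.exceedance_fit()].
#' @export
fit_logistic <- function(data, response, covariates = character(0),
                         tol = 1e-8, max_iter = 100, guard = 15) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) {
    rlang::abort(paste0("response column not found: ", response),
                 class = "streamhyb_input_error")
  }
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    rlang::abort(paste0("covariate column(s) not found: ",
                        paste(missing_cov, collapse = ", ")),
                 class = "streamhyb_input_error")
  }
  y <- as.numeric(data[[response]])
  X <- as.matrix(data[covariates])
  if (anyNA(y) || anyNA(X)) {
    rlang::abort("missing values in response or covariates",
                 class = "streamhyb_input_error")
  }
  if (!all(y %in% c(0, 1))) {
    rlang::abort("response must be binary 0/1",
                 class = "streamhyb_input_error")
  }
  if (length(unique(y)) < 2) {
    rlang::abort("outcome has a single class; logistic fit is degenerate",
                 class = "streamhyb_degenerate_outcome")
  }
  n <- length(y)
  k <- length(covariates)

  ctr <- rep(0, k); scl <- rep(1, k)
  if (k > 0) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    if (any(scl == 0)) {
      rlang::abort(paste0("constant covariate column(s): ",
                          paste(covariates[scl == 0], collapse = ", ")),
                   class = "streamhyb_collinearity_error")
    }
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    dep <- colnames(Xd)[qrd$pivot[(qrd$rank + 1):ncol(Xd)]]
    rlang::abort(paste0("rank-deficient design; dependent column(s): ",
                        paste(dep, collapse = ", ")),
                 class = "streamhyb_collinearity_error")
  }

  beta <- rep(0, ncol(Xd))
  dev_old <- Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    xtw <- crossprod(Xd, Xd * w)
    beta <- drop(solve(xtw, crossprod(Xd, w * z)))
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (any(abs(beta) > guard)) converged <- FALSE

  eta <- drop(Xd %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  loglik <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  w <- mu * (1 - mu)
  cov_std <- solve(crossprod(Xd, Xd * w))

  # back-transform: raw = A %*% standardized
  A <- diag(c(1, if (k > 0) 1 / scl else NULL), nrow = k + 1)
  if (k > 0) A[1, 2:(k + 1)] <- -ctr / scl
  beta_raw <- drop(A %*% beta)
  cov_raw <- A %*% cov_std %*% t(A)
  se <- sqrt(pmax(diag(cov_raw), 0))
  zstat <- beta_raw / se
  terms <- c("(Intercept)", covariates)
  coef_tbl <- tibble::tibble(
    term = terms,
    estimate = unname(beta_raw),
    std.error = unname(se),
    statistic = unname(zstat),
    p.value = 2 * stats::pnorm(-abs(unname(zstat))),
    conf.low = unname(beta_raw - 1.96 * se),
    conf.high = unname(beta_raw + 1.96 * se)
  )
  structure(list(
    coefficients = coef_tbl,
    vcov = structure(cov_raw, dimnames = list(terms, terms)),
    logLik = loglik,
    aic = -2 * loglik + 2 * (k + 1),
    n = n,
    converged = converged,
    iterations = iter,
    response = response,
    covariates = covariates,
    fitted = stats::plogis(drop(Xd %*% beta)),
    y = y,
    model_frame = data[c(response, covariates)]
  ), class = "exceedance_fit")
}

#' Build a fit object from known coefficients
#'
#' Wraps a named coefficient vector (first element the intercept) as an
#' `exceedance_fit` usable by [predict_probability()], [classify_network()]
#' and [response_curves()] — e.g. published parameter estimates applied to a
#' new network.
#'
#' @param coef named numeric vector; names after the first are covariate
#'   column names, the first element is the intercept.
#' @param response label for the response the model predicts.
#' @return an `exceedance_fit` (no inference fields).
#' @export
manual_model <- function(coef, response = "exceeds") {
  covariates <- names(coef)[-1]
  structure(list(
    coefficients = tibble::tibble(
      term = c("(Intercept)", covariates),
      estimate = unname(coef),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_,
      conf.low = NA_real_, conf.high = NA_real_),
    logLik = NA_real_, aic = NA_real_, n = NA_integer_,
    converged = TRUE, response = response, covariates = covariates
  ), class = "exceedance_fit")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table of a logistic fit
#'
#' @param x an `exceedance_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @method tidy exceedance_fit
#' @export
tidy.exceedance_fit <- function(x, ...) x$coefficients

#' One-row model summary of a logistic fit
#'
#' @param x an `exceedance_fit`.
#' @param ... unused.
#' @return one-row tibble with `logLik`, `AIC`, `nobs`, `df`, `converged`.
#' @method glance exceedance_fit
#' @export
glance.exceedance_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, AIC = x$aic, nobs = x$n,
                 df = length(x$covariates) + 1, converged = x$converged)
}

#' @export
print.exceedance_fit <- function(x, ...) {
  cat(sprintf("Logistic exceedance model: %s ~ %s\n", x$response,
              if (length(x$covariates) == 0) "1"
              else paste(alias_terms(x$covariates), collapse = " + ")))
  if (!is.na(x$aic)) {
    cat(sprintf("n = %d, logLik = %.2f, AIC = %.2f%s\n", x$n, x$logLik,
                x$aic, if (x$converged) "" else " [NOT CONVERGED]"))
  }
  print(x$coefficients)
  invisible(x)
}

#' Predicted exceedance probability
#'
#' Inverse-logit of the model's linear predictor evaluated on new data.
#'
#' @param model an `exceedance_fit`.
#' @param newdata data frame supplying every covariate in the model.
#' @return numeric vector of probabilities.
#' @export
predict_probability <- function(model, newdata) {
  newdata <- tibble::as_tibble(newdata)
  missing_cov <- setdiff(model$covariates, names(newdata))
  if (length(missing_cov) > 0) {
    rlang::abort(paste0("newdata is missing model covariate(s): ",
                        paste(missing_cov, collapse = ", ")),
                 class = "streamhyb_contract_error")
  }
  b <- model$coefficients$estimate
  X <- cbind(1, as.matrix(newdata[model$covariates]))
  stats::plogis(drop(X %*% b))
}

#' Screen candidate covariates for collinearity
#'
#' Removes, for each covariate pair correlated at `|r| >= corr_cutoff`, the
#' member with the weaker univariate association with the response
#' (higher single-covariate AIC; ties retain the alphabetically earlier
#' name), and reports variance inflation factors (1/(1-R^2) from regressing
#' each retained covariate on the others), flagging any at or above
#' `vif_cutoff`. Constant covariates are removed with a warning.
#'
#' @param data data frame with response and candidate columns.
#' @param response binary outcome column used for the univariate tie-break.
#' @param candidates character vector of candidate covariate names.
#' @param corr_cutoff absolute pairwise correlation triggering removal.
#' @param vif_cutoff VIF flag level.
#' @return a `collinearity_screen` list: `retained`, `removed` (tibble with
#'   reasons), `correlations`, `vifs`.
#' @export
collinearity_screen <- function(data, response, candidates,
                                corr_cutoff = 0.80, vif_cutoff = 3.5) {
  data <- tibble::as_tibble(data)
  if (length(candidates) < 2) {
    rlang::abort("need at least 2 candidate covariates",
                 class = "streamhyb_config_error")
  }
  removed <- tibble::tibble(term = character(0), reason = character(0))
  const <- candidates[vapply(candidates,
                             function(v) stats::sd(data[[v]]) == 0, logical(1))]
  if (length(const) > 0) {
    rlang::warn(paste0("removing constant covariate(s): ",
                       paste(const, collapse = ", ")))
    removed <- dplyr::bind_rows(removed,
      tibble::tibble(term = const, reason = "constant"))
    candidates <- setdiff(candidates, const)
  }
  cmat <- stats::cor(as.matrix(data[candidates]))
  pairs <- which(upper.tri(cmat), arr.ind = TRUE)
  cor_tbl <- tibble::tibble(
    term1 = candidates[pairs[, 1]], term2 = candidates[pairs[, 2]],
    r = cmat[pairs]
  ) |> dplyr::arrange(dplyr::desc(abs(.data$r)))

  uni_aic <- function(v) fit_logistic(data, response, v)$aic
  retained <- candidates
  flagged <- dplyr::filter(cor_tbl, abs(.data$r) >= corr_cutoff)
  for (i in seq_len(nrow(flagged))) {
    a <- flagged$term1[i]; b <- flagged$term2[i]
    if (!(a %in% retained) || !(b %in% retained)) next
    aic_a <- uni_aic(a); aic_b <- uni_aic(b)
    drop_term <- if (aic_a > aic_b) a
      else if (aic_b > aic_a) b
      else sort(c(a, b))[2]
    retained <- setdiff(retained, drop_term)
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      term = drop_term,
      reason = sprintf("|r|=%.2f with %s, weaker univariate AIC",
                       abs(flagged$r[i]), setdiff(c(a, b), drop_term))))
  }
  vifs <- tibble::tibble(term = retained, vif = NA_real_)
  if (length(retained) >= 2) {
    Xr <- as.matrix(data[retained])
    vifs$vif <- vapply(seq_along(retained), function(j) {
      r2 <- summary(stats::lm(Xr[, j] ~ Xr[, -j, drop = FALSE]))$r.squared
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  vifs$flagged <- !is.na(vifs$vif) & vifs$vif >= vif_cutoff
  structure(list(retained = retained, removed = removed,
                 correlations = cor_tbl, vifs = vifs,
                 corr_cutoff = corr_cutoff, vif_cutoff = vif_cutoff),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(sprintf("Collinearity screen (|r| >= %.2f, VIF >= %.1f):\n",
              x$corr_cutoff, x$vif_cutoff))
  cat("retained:", paste(alias_terms(x$retained), collapse = ", "), "\n")
  if (nrow(x$removed) > 0) {
    cat("removed:\n"); print(x$removed)
  }
  print(x$vifs)
  invisible(x)
}

subset_label <- function(covariates) {
  if (length(covariates) == 0) return("(intercept only)")
  paste(alias_terms(covariates), collapse = " + ")
}

#' Exhaustive AIC subset selection
#'
#' Fits every subset of the candidate covariates (intercept always
#' included; 2^k models, hard-capped at k = 12) and ranks them ascending by
#' AIC, ties broken by fewer parameters then lexicographic covariate names.
#' Non-converged fits are retained but flagged.
#'
#' @param data data frame with response and candidates.
#' @param response binary outcome column.
#' @param candidates candidate covariate names (at most 12).
#' @param ... passed to [fit_logistic()].
#' @return an `aic_ranking` tibble: `rank`, `label`, `covariates`
#'   (list-column), `k`, `logLik`, `aic`, `delta_aic`, `converged`, `fit`
#'   (list-column of `exceedance_fit`).
#' @export
all_subsets_selection <- function(data, response, candidates, ...) {
  if (length(candidates) > 12) {
    rlang::abort("exhaustive enumeration capped at 12 candidates",
                 class = "streamhyb_config_error")
  }
  subsets <- unlist(lapply(0:length(candidates), function(k) {
    if (k == 0) list(character(0))
    else utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
  fits <- lapply(subsets, function(s) fit_logistic(data, response, s, ...))
  tbl <- tibble::tibble(
    label = vapply(subsets, subset_label, character(1)),
    covariates = subsets,
    k = lengths(subsets),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    fit = fits
  )
  sort_key <- vapply(subsets, function(s) paste(sort(s), collapse = "|"),
                     character(1))
  ord <- order(tbl$aic, tbl$k, sort_key)
  tbl <- tbl[ord, ]
  tbl$rank <- seq_len(nrow(tbl))
  tbl$delta_aic <- tbl$aic - tbl$aic[1]
  out <- tbl[c("rank", "label", "covariates", "k", "logLik", "aic",
               "delta_aic", "converged", "fit")]
  class(out) <- c("aic_ranking", class(out))
  out
}

subset_key <- function(covariates) paste(sort(covariates), collapse = "|")

#' Consensus model across introgression thresholds
#'
#' Applies the cross-threshold consensus rule: the covariate subset
#' top-ranked for the 10% and 20% admixture thresholds is adopted provided
#' its AIC in the 1% ranking is within `delta_aic` of that ranking's best.
#' The chosen subset keeps threshold-specific coefficients (the per-threshold
#' fits from the rankings). When the 10% and 20% tops differ — a case the
#' rule itself does not cover — an extension picks the subset minimizing the
#' summed AIC rank across thresholds subject to the delta-AIC condition in
#' every ranking, and records that this fallback fired. When no subset
#' qualifies, an explicit no-consensus result is returned (never a silent
#' pick).
#'
#' @param rankings named list of [all_subsets_selection()] results, in
#'   increasing threshold order (e.g. names `"1"`, `"10"`, `"20"`).
#' @param delta_aic AIC window around each ranking's best model.
#' @return a `consensus_model`: `subset`, `rule` (one of `"shared-top"`,
#'   `"rank-sum"`, `"none"`), `fits` (per-threshold `exceedance_fit`),
#'   `table` (per-threshold rank/AIC of the subset).
#' @export
select_consensus <- function(rankings, delta_aic = 3) {
  stopifnot(length(rankings) == 3)
  if (is.null(names(rankings))) names(rankings) <- c("1", "10", "20")
  keys <- lapply(rankings, function(r)
    vapply(r$covariates, subset_key, character(1)))
  top <- vapply(rankings, function(r) subset_key(r$covariates[[1]]),
                character(1))
  result <- function(subset_idx_key, rule) {
    rows <- lapply(names(rankings), function(th) {
      i <- match(subset_idx_key, keys[[th]])
      rankings[[th]][i, c("rank", "label", "aic", "delta_aic", "converged")] |>
        dplyr::mutate(threshold = th, .before = 1)
    })
    i1 <- match(subset_idx_key, keys[[1]])
    structure(list(
      subset = sort(rankings[[1]]$covariates[[i1]]),
      label = rankings[[1]]$label[[i1]],
      rule = rule,
      fits = stats::setNames(lapply(names(rankings), function(th) {
        rankings[[th]]$fit[[match(subset_idx_key, keys[[th]])]]
      }), names(rankings)),
      table = dplyr::bind_rows(rows),
      delta_aic = delta_aic
    ), class = "consensus_model")
  }
  if (top[2] == top[3]) {
    i1 <- match(top[2], keys[[1]])
    if (rankings[[1]]$delta_aic[i1] <= delta_aic) {
      return(result(top[2], "shared-top"))
    }
    return(structure(list(subset = NULL, rule = "none",
                          delta_aic = delta_aic),
                     class = "consensus_model"))
  }
  # extension: 10% and 20% tops disagree -> summed-rank fallback
  common <- Reduce(intersect, keys)
  ok <- common[vapply(common, function(kk) {
    all(vapply(names(rankings), function(th) {
      rankings[[th]]$delta_aic[match(kk, keys[[th]])] <= delta_aic
    }, logical(1)))
  }, logical(1))]
  if (length(ok) == 0) {
    return(structure(list(subset = NULL, rule = "none",
                          delta_aic = delta_aic),
                     class = "consensus_model"))
  }
  rank_sum <- vapply(ok, function(kk) {
    sum(vapply(names(rankings), function(th) {
      rankings[[th]]$rank[match(kk, keys[[th]])]
    }, numeric(1)))
  }, numeric(1))
  nk <- lengths(strsplit(ok, "|", fixed = TRUE))
  best <- ok[order(rank_sum, nk, ok)][1]
  result(best, "rank-sum")
}

#' @export
print.consensus_model <- function(x, ...) {
  if (x$rule == "none") {
    cat(sprintf("No consensus: no subset within %.1f AIC of best at every threshold\n",
                x$delta_aic))
    return(invisible(x))
  }
  cat(sprintf("Consensus model (%s rule%s): %s\n", x$rule,
              if (x$rule == "rank-sum") ", extension" else "", x$label))
  print(x$table)
  invisible(x)
}

#' Format a ranking like a published model-selection table
#'
#' @param ranking an `aic_ranking`.
#' @param top number of rows to keep.
#' @return tibble with `Model` and `AIC` columns using field-standard
#'   covariate names.
#' @export
format_ranking <- function(ranking, top = 4) {
  utils::head(tibble::tibble(Model = ranking$label,
                             AIC = round(ranking$aic, 2)), top)
}

#' Format a fit like a published parameter-estimate table
#'
#' @param fit an `exceedance_fit`.
#' @return tibble with `Predictor`, `b`, `SE`, `z`, `p` columns.
#' @export
format_estimates <- function(fit) {
  tb <- fit$coefficients
  tibble::tibble(
    Predictor = c("Intercept", alias_terms(fit$covariates)),
    b = signif(tb$estimate, 3),
    SE = signif(tb$std.error, 3),
    z = round(tb$statistic, 2),
    p = ifelse(tb$p.value < 0.01, "<0.01", sprintf("%.2f", tb$p.value))
  )
}
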
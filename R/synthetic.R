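#' Default true exceedance coefficients for the latent admixture model
#'
#' Published consensus-model parameter estimates for the 10% admixture
#' threshold (intercept, then per-covariate slopes in raw units), used as
#' the generator's default truth: warmer, larger, closer-to-source,
#' inside-range and more easterly sites are more admixed.
#'
#' @return named numeric vector (first element `"(Intercept)"`).
#' @export
default_true_coef <- function() {
  c("(Intercept)" = -13.4, t_aug_c = 0.266, rt_range = 1.34,
    ds_m = -1.34e-4, dt13_m = -6.18e-5, maf_cms = 0.512,
    easting_m = 6.75e-6)
}

#' Configuration for the synthetic riverscape generator
#'
#' Parameters of the seeded generator emulating the study system: a
#' dendritic network whose flow, temperature and slope follow main-stem to
#' headwater gradients; an inside/outside historical-range partition
#' assigned by subtree; rainbow-trout sources at warm or large reaches and
#' stocked headwaters; and per-fish diagnostic-marker genotypes at sites
#' whose latent admixture follows a logistic function of the covariates.
#'
#' @param n_reaches number of reaches (>= 3).
#' @param seed integer seed; every generator call is deterministic in it.
#' @param headwater_flow_meanlog,headwater_flow_sdlog lognormal base flow
#'   of headwater reaches (m^3/s).
#' @param lateral_flow_meanlog,lateral_flow_sdlog lognormal lateral inflow
#'   added per reach (m^3/s).
#' @param length_meanlog,length_sdlog lognormal reach length (m).
#' @param temp_intercept_c,temp_flow_slope,temp_sd_c temperature model
#'   T = intercept + slope * ln(MAF) + N(0, sd), floored at 4 C.
#' @param slope_ref_pct,slope_flow_exp,slope_sdlog slope model
#'   slope = ref * (MAF / 0.3)^exp * lognormal noise (decreases downstream).
#' @param w95_mean,w95_sd winter-high-flow days, |N(mean, sd)|.
#' @param cfm_intercept,cfm_w95_slope,cfm_sd flow-mass timing
#'   CFM = intercept + slope * W95 + N(0, sd) (strongly anticorrelated with
#'   W95, as in the study region).
#' @param intermittent_maf_cms,intermittent_rate small reaches below this
#'   flow are intermittent at this rate.
#' @param rt_range_fraction target fraction of reaches inside the
#'   historical rainbow-trout range (assigned per subtree, so the range is
#'   spatially contiguous).
#' @param stocked_headwater_rate fraction of headwater reaches flagged as
#'   stocked rainbow-trout sources.
#' @param true_coef named truth vector for the latent admixture logit
#'   ([default_true_coef()]).
#' @param site_noise_sd Gaussian noise SD added to the latent site logit.
#' @param n_fish_mean mean fish genotyped per site (1 + Poisson(mean - 1)).
#' @param n_markers diagnostic markers scored per fish (2 alleles each).
#' @param beta_concentration concentration of the Beta ancestry
#'   distribution among admixed fish.
#' @param genotyping_error_rate per-allele probability of misreading a
#'   cutthroat allele as a rainbow-trout allele (0 = fully diagnostic
#'   markers).
#' @return a `generator_config` list.
#' @export
generator_config <- function(
    n_reaches = 400, seed = 1,
    headwater_flow_meanlog = log(0.04), headwater_flow_sdlog = 0.9,
    lateral_flow_meanlog = log(0.05), lateral_flow_sdlog = 0.7,
    length_meanlog = log(2400), length_sdlog = 0.45,
    temp_intercept_c = 12.3, temp_flow_slope = 1.1, temp_sd_c = 0.7,
    slope_ref_pct = 4.2, slope_flow_exp = -0.3, slope_sdlog = 0.35,
    w95_mean = 2.2, w95_sd = 2.2,
    cfm_intercept = 228, cfm_w95_slope = -9, cfm_sd = 5,
    intermittent_maf_cms = 0.03, intermittent_rate = 0.3,
    rt_range_fraction = 0.4, stocked_headwater_rate = 0.05,
    true_coef = default_true_coef(), site_noise_sd = 0.8,
    n_fish_mean = 24, n_markers = 20, beta_concentration = 4,
    genotyping_error_rate = 0) {
  stopifnot(n_reaches >= 3, rt_range_fraction >= 0, rt_range_fraction <= 1,
            stocked_headwater_rate >= 0, stocked_headwater_rate <= 1,
            genotyping_error_rate >= 0, genotyping_error_rate <= 1)
  structure(as.list(environment()), class = "generator_config")
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic dendritic stream network
#'
#' Grows a random bifurcating tree from a single outlet; flow accumulates
#' downstream (each reach's mean annual flow is the sum of its children's
#' plus a lateral increment, so conservation holds by construction),
#' temperature increases and slope decreases downstream, winter-flow and
#' flow-timing covariates are strongly anticorrelated, and coordinates come
#' from a planar embedding. Deterministic for a fixed seed.
#'
#' @param cfg a [generator_config()].
#' @return a `stream_network`.
#' @export
generate_network <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_reaches
    down <- rep(NA_integer_, n)
    n_child <- integer(n)
    for (i in 2:n) {
      open <- which(n_child < 2 & seq_len(n) < i)
      parent <- if (length(open) == 1) open else sample(open, 1)
      down[i] <- parent
      n_child[parent] <- n_child[parent] + 1L
    }
    length_m <- stats::rlnorm(n, cfg$length_meanlog, cfg$length_sdlog)
    lateral <- stats::rlnorm(n, cfg$lateral_flow_meanlog,
                             cfg$lateral_flow_sdlog)
    headwater <- n_child == 0
    maf <- lateral
    maf[headwater] <- maf[headwater] +
      stats::rlnorm(sum(headwater), cfg$headwater_flow_meanlog,
                    cfg$headwater_flow_sdlog)
    for (i in n:2) maf[down[i]] <- maf[down[i]] + maf[i] # children precede parents
    t_aug <- pmax(4, cfg$temp_intercept_c + cfg$temp_flow_slope * log(maf) +
                    stats::rnorm(n, 0, cfg$temp_sd_c))
    slope <- pmin(30, cfg$slope_ref_pct * (maf / 0.3)^cfg$slope_flow_exp *
                    stats::rlnorm(n, 0, cfg$slope_sdlog))
    w95 <- abs(stats::rnorm(n, cfg$w95_mean, cfg$w95_sd))
    cfm <- cfg$cfm_intercept + cfg$cfm_w95_slope * w95 +
      stats::rnorm(n, 0, cfg$cfm_sd)
    intermittent <- as.integer(maf < cfg$intermittent_maf_cms &
                                 stats::runif(n) < cfg$intermittent_rate)
    # planar embedding: walk upstream with a persistent per-branch heading
    east <- numeric(n); north <- numeric(n); heading <- numeric(n)
    east[1] <- 1.43e6; north[1] <- 1.78e6
    heading[1] <- pi / 2
    for (i in 2:n) {
      p <- down[i]
      heading[i] <- heading[p] + stats::runif(1, -0.7, 0.7)
      east[i] <- east[p] + length_m[i] * cos(heading[i])
      north[i] <- north[p] + length_m[i] * sin(heading[i])
    }
    # contiguous historical range: accumulate random subtrees until the
    # target fraction of reaches is covered
    kids <- split(seq_len(n), factor(down, levels = seq_len(n)))
    subtree <- function(root) {
      out <- integer(0); frontier <- root
      while (length(frontier) > 0) {
        out <- c(out, frontier)
        frontier <- unlist(kids[as.character(frontier)], use.names = FALSE)
      }
      out
    }
    rt_range <- integer(n)
    for (root in sample(n)) {
      if (sum(rt_range) >= cfg$rt_range_fraction * n) break
      rt_range[subtree(root)] <- 1L
    }
    rt_source <- integer(n)
    rt_source[maf >= 2.83 & rt_range == 1] <- 1L # naturalized populations
    hw <- which(headwater)
    stocked <- hw[stats::runif(length(hw)) < cfg$stocked_headwater_rate]
    rt_source[stocked] <- 1L
    ids <- sprintf("R%04d", seq_len(n))
    as_stream_network(tibble::tibble(
      reach_id = ids,
      downstream_id = ifelse(is.na(down), NA_character_, ids[down]),
      length_m = length_m, slope_pct = slope, maf_cms = maf,
      t_aug_c = t_aug, w95_days = w95, cfm_day = cfm,
      intermittent = intermittent, easting_m = east, northing_m = north,
      rt_range = rt_range, rt_source = rt_source
    ))
  })
}

#' Simulate genotyped sample sites on a network
#'
#' Places sites on randomly chosen non-intermittent reaches, attaches their
#' covariate vectors, and simulates per-fish diagnostic-marker genotypes
#' from a latent site admixture proportion
#' A = inverse-logit(truth linear predictor + Gaussian site noise). Each
#' fish is nonadmixed with probability q(A) = (1 - A)^2 (admixed
#' populations retain substantial numbers of nonadmixed individuals);
#' otherwise its individual ancestry is Beta-distributed with mean chosen
#' so the site's expected ancestry equals A. Each fish is scored at
#' `n_markers` codominant diagnostic markers (two alleles each, binomial in
#' its ancestry). PRTA (% rainbow-trout alleles among all scored alleles)
#' and PFRT (% of fish carrying at least one rainbow-trout allele) are
#' computed from the simulated genotypes, so PRTA <= PFRT always and the
#' two are highly correlated, and threshold exceedances are nested across
#' 1%/10%/20% by construction.
#'
#' @param net a `stream_network` from [generate_network()].
#' @param cfg the [generator_config()] used to build it.
#' @param n_sites number of sites to simulate.
#' @param seed site-level seed (defaults to `cfg$seed + 1`).
#' @return tibble of sites (`site_id`, `reach_id`, `n_fish`, `prta_pct`,
#'   `pfrt_pct`, `ycti`) with the latent admixture in `attr(, "latent")`;
#'   sites on reaches with unreachable covariates are skipped with a
#'   message and counted in `attr(, "n_skipped")`.
#' @export
simulate_site_samples <- function(net, cfg = generator_config(),
                                  n_sites = 500, seed = cfg$seed + 1) {
  with_seed(seed, {
    eligible <- net$reach_id[net$intermittent == 0]
    reach <- sample(eligible, n_sites, replace = n_sites > length(eligible))
    sites <- tibble::tibble(
      site_id = sprintf("S%05d", seq_len(n_sites)),
      reach_id = reach, n_fish = NA_integer_,
      prta_pct = NA_real_, pfrt_pct = NA_real_,
      ycti = stats::rbinom(n_sites, 1, 0.06)
    )
    covs <- attach_site_covariates(sites, net)
    b <- cfg$true_coef
    need <- names(b)[-1]
    usable <- stats::complete.cases(covs[need])
    if (any(!usable)) {
      rlang::inform(paste0("skipping ", sum(!usable),
                           " site(s) with unreachable distance covariates"))
    }
    covs <- covs[usable, ]
    m <- nrow(covs)
    lp <- drop(cbind(1, as.matrix(covs[need])) %*% b) +
      stats::rnorm(m, 0, cfg$site_noise_sd)
    A <- stats::plogis(lp)
    n_fish <- 1L + stats::rpois(m, cfg$n_fish_mean - 1)
    nm <- cfg$n_markers
    prta <- numeric(m); pfrt <- numeric(m)
    for (i in seq_len(m)) {
      nf <- n_fish[i]
      admixed <- stats::runif(nf) >= (1 - A[i])^2
      anc <- numeric(nf)
      if (any(admixed)) {
        mu <- 1 / (2 - A[i])
        anc[admixed] <- stats::rbeta(sum(admixed),
                                     mu * cfg$beta_concentration,
                                     (1 - mu) * cfg$beta_concentration)
      }
      alleles <- stats::rbinom(nf, 2 * nm, anc)
      if (cfg$genotyping_error_rate > 0) {
        alleles <- alleles + stats::rbinom(nf, 2 * nm - alleles,
                                           cfg$genotyping_error_rate)
      }
      prta[i] <- 100 * sum(alleles) / (2 * nm * nf)
      pfrt[i] <- 100 * mean(alleles > 0)
    }
    out <- covs[c("site_id", "reach_id")]
    out$n_fish <- n_fish
    out$prta_pct <- prta
    out$pfrt_pct <- pfrt
    out$ycti <- sites$ycti[usable]
    attr(out, "latent") <- A
    attr(out, "n_skipped") <- sum(!usable)
    out
  })
}

#' Simulate Bernoulli outcomes from a known exceedance logit
#'
#' Direct test harness for the estimator: y ~ Bernoulli(inverse-logit(X b))
#' with the design taken from `data`. Unlike the genotype-level simulator,
#' this is exactly matched to the fitting likelihood.
#'
#' @param data data frame supplying every covariate named in `coef`.
#' @param coef named truth (first element the intercept).
#' @param seed integer seed.
#' @return integer 0/1 vector.
#' @export
simulate_bernoulli_outcomes <- function(data, coef = default_true_coef(),
                                        seed = 1) {
  with_seed(seed, {
    need <- names(coef)[-1]
    X <- cbind(1, as.matrix(tibble::as_tibble(data)[need]))
    stats::rbinom(nrow(X), 1, stats::plogis(drop(X %*% coef)))
  })
}

#' Simulate site covariate vectors without a network
#'
#' Draws covariate vectors from marginal distributions matching the study
#' region's site statistics (temperature around 11 C, exponential-tailed
#' source distances with medians near 4.6-8 km, lognormal flows with
#' median near 0.3 m^3/s, roughly 40% of sites inside the historical
#' rainbow-trout range). Used by estimator-recovery experiments where the
#' spatial substrate is irrelevant.
#'
#' @param n number of sites.
#' @param seed integer seed.
#' @return tibble of covariate columns.
#' @export
simulate_site_covariates <- function(n, seed = 1) {
  with_seed(seed, {
    w95 <- abs(stats::rnorm(n, 2.5, 2.7))
    tibble::tibble(
      t_aug_c = pmin(pmax(stats::rnorm(n, 11, 1.9), 5), 18),
      slope_pct = abs(stats::rnorm(n, 4.5, 3.6)),
      w95_days = w95,
      cfm_day = 228 - 9 * w95 + stats::rnorm(n, 0, 5),
      maf_cms = pmin(stats::rlnorm(n, log(0.32), 0.9), 5.5),
      df3_m = stats::rexp(n, 1 / 8200),
      dt13_m = stats::rexp(n, 1 / 9000),
      ds_m = stats::rexp(n, 1 / 5500),
      northing_m = stats::rnorm(n, 1.87e6, 1.3e5),
      easting_m = stats::rnorm(n, 1.43e6, 8e4),
      rt_range = stats::rbinom(n, 1, 0.41),
      ycti = stats::rbinom(n, 1, 0.066)
    )
  })
}
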
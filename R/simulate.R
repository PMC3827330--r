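#' Simplex correlation matrix from lag-1 correlations
#'
#' The stage-wise causal chain implies a simplex structure:
#' `corr(i, j)` is the product of the lag-1 correlations between the
#' intervening stages, so correlations decay multiplicatively with causal
#' distance.
#'
#' @param lag1 vector of adjacent-stage correlations, each in (-1, 1).
#' @return correlation matrix of dimension `length(lag1) + 1`.
#' @export
#' @examples
#' simplex_corr(c(0.6, 0.5))[1, 3]   # 0.30
simplex_corr <- function(lag1) {
  if (any(abs(lag1) >= 1)) stop("lag-1 correlations must lie in (-1, 1)",
                                call. = FALSE)
  k <- length(lag1) + 1L
  R <- diag(k)
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      R[i, j] <- R[j, i] <- prod(lag1[i:(j - 1L)])
  R
}

#' Configuration for a synthetic longitudinal cohort
#'
#' Describes the generating process the cohort analyses assume: correlated
#' latent attainment scores across ordered stages (simplex or arbitrary
#' positive-definite correlation matrix), selection of entrants on an early
#' stage (restriction of range), per-stage measurement (exact, grade
#' ceiling, ordinal grouping, or binary), and outcome-dependent uptake of
#' later examinations.
#'
#' @param n_applicants number of applicants simulated before selection.
#' @param stages character vector of ordered stage labels.
#' @param lag1 lag-1 latent correlations (length `length(stages) - 1`);
#'   ignored if `corr` is supplied.
#' @param corr optional full positive-definite latent correlation matrix.
#' @param selection `NULL`, or a list with `stage`, `fraction` in (0, 1],
#'   and `type` (`"truncation"` for deterministic top-fraction selection,
#'   `"logistic"` for probabilistic selection with elements `slope`).
#' @param observe named list (by stage) of observation specs, each a list
#'   with `mode` (`"continuous"`, `"ceiling"`, `"ordinal"`, `"binary"`),
#'   plus `ceiling_q` (quantile above which values are recorded at the
#'   ceiling), `proportions` (ordinal category proportions, category 1 =
#'   lowest latent score), `prevalence` (binary), and optional
#'   `reliability` in (0, 1] (Gaussian measurement noise keeping unit
#'   variance; 1 = noise-free). Stages without an entry are observed
#'   exactly.
#' @param uptake `NULL`, or a list of entries each with `stage` (the exam
#'   whose results are masked for non-attempters), `on` (the causally prior
#'   stage whose latent score drives the attempt), `slope`, and either
#'   `intercept` or `rate` (a target attempt fraction; the intercept is then
#'   calibrated on the realized entrant scores).
#' @param covariate optional list with `name`, `prevalence`, and `shift`
#'   (named vector of latent mean shifts per stage for the positive group).
#' @param seed integer; the single source of randomness for the whole
#'   generator.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_applicants, stages, lag1 = NULL, corr = NULL,
                             selection = NULL, observe = list(),
                             uptake = NULL, covariate = NULL, seed = 1L) {
  k <- length(stages)
  if (is.null(corr)) {
    if (is.null(lag1) || length(lag1) != k - 1L)
      stop("supply either 'corr' or 'lag1' of length length(stages) - 1",
           call. = FALSE)
    corr <- simplex_corr(lag1)
  }
  ch <- tryCatch(chol(corr), error = function(e) NULL)
  if (is.null(ch))
    stop("latent correlation matrix is not positive definite", call. = FALSE)
  if (!is.null(selection)) {
    if (!selection$stage %in% stages)
      stop("selection stage not among stages", call. = FALSE)
    if (is.null(selection$fraction) || selection$fraction <= 0 ||
        selection$fraction > 1)
      stop("selection fraction must lie in (0, 1]", call. = FALSE)
    if (is.null(selection$type)) selection$type <- "truncation"
  }
  for (nm in names(observe)) {
    o <- observe[[nm]]
    if (identical(o$mode, "ordinal")) {
      if (abs(sum(o$proportions) - 1) > 1e-8)
        stop(sprintf("ordinal proportions for '%s' must sum to 1", nm),
             call. = FALSE)
    }
  }
  structure(list(n_applicants = as.integer(n_applicants), stages = stages,
                 corr = corr, lag1 = lag1, selection = selection,
                 observe = observe, uptake = uptake, covariate = covariate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Draw latent stage scores
#'
#' Multivariate standard normal applicants with the configured population
#' correlation matrix. Seeded from the config, so identical configs give
#' identical draws.
#'
#' @param config a [synthetic_config()].
#' @return numeric matrix `n_applicants` x stages (column names = stage
#'   labels).
#' @export
generate_latent <- function(config) {
  set.seed(config$seed)
  k <- length(config$stages)
  z <- matrix(stats::rnorm(config$n_applicants * k), ncol = k)
  lat <- z %*% chol(config$corr)
  colnames(lat) <- config$stages
  if (!is.null(config$covariate)) {
    grp <- stats::rbinom(config$n_applicants, 1L, config$covariate$prevalence)
    sh <- config$covariate$shift
    for (nm in names(sh)) lat[, nm] <- lat[, nm] + grp * sh[[nm]]
    attr(lat, "covariate") <- grp
  }
  lat
}

#' Select entrants on an early-stage score
#'
#' Deterministic truncation keeps the top fraction on the selection stage
#' (the cleanest restriction-of-range testbed); logistic selection admits
#' probabilistically with probability increasing in the score, at the same
#' expected fraction. Either way the entrants' spread on the selection
#' variable shrinks, attenuating their correlations.
#'
#' @param latent matrix from [generate_latent()].
#' @param config a [synthetic_config()] with a non-`NULL` `selection`.
#' @return list with `entrants` (latent rows of those admitted), `selected`
#'   (logical applicant flag), and `cutoff` (truncation threshold, or `NA`
#'   for logistic selection).
#' @export
apply_selection <- function(latent, config) {
  sel <- config$selection
  if (is.null(sel))
    return(list(entrants = latent, selected = rep(TRUE, nrow(latent)),
                cutoff = NA_real_))
  score <- latent[, sel$stage]
  if (identical(sel$type, "logistic")) {
    slope <- if (is.null(sel$slope)) 2 else sel$slope
    ## intercept chosen so the realized admission probability averages to
    ## the target fraction
    f <- function(a) mean(stats::plogis(a + slope * score)) - sel$fraction
    a <- stats::uniroot(f, c(-50, 50))$root
    keep <- stats::runif(length(score)) < stats::plogis(a + slope * score)
    cutoff <- NA_real_
  } else {
    cutoff <- stats::quantile(score, 1 - sel$fraction, type = 7, names = FALSE)
    keep <- score >= cutoff
  }
  out <- latent[keep, , drop = FALSE]
  attr(out, "covariate") <- attr(latent, "covariate")[keep]
  list(entrants = out, selected = keep, cutoff = cutoff)
}

#' Observe one latent stage under a measurement model
#'
#' Applies optional Gaussian measurement noise (parameterized by a
#' reliability, so the observed score keeps unit variance), then records the
#' score exactly, at a grade ceiling, as ordinal categories cut at the
#' cumulative-proportion quantiles, or as a binary indicator.
#'
#' @param z numeric latent column.
#' @param stage_spec observation spec (see [synthetic_config()]); `NULL` or
#'   missing mode means exact observation.
#' @param name variable name for the returned [var_spec()].
#' @return list with `observed`, `spec` (a [var_spec()]), and `truth`
#'   (censor point / thresholds actually used).
#' @export
observe_stage <- function(z, stage_spec = NULL, name = "x") {
  rel <- if (!is.null(stage_spec$reliability)) stage_spec$reliability else 1
  if (rel < 1) z <- sqrt(rel) * z + sqrt(1 - rel) * stats::rnorm(length(z))
  mode <- if (is.null(stage_spec$mode)) "continuous" else stage_spec$mode
  if (mode == "continuous") {
    list(observed = z, spec = var_spec(name, "continuous"),
         truth = list(mode = mode, reliability = rel))
  } else if (mode == "ceiling") {
    cpoint <- stats::quantile(z, stage_spec$ceiling_q, type = 7, names = FALSE)
    obs <- ifelse(z >= cpoint, cpoint, z)
    list(observed = obs,
         spec = var_spec(name, "censored_continuous", ceiling = cpoint),
         truth = list(mode = mode, ceiling = cpoint,
                      ceiling_mass = mean(z >= cpoint), reliability = rel))
  } else if (mode == "ordinal") {
    p <- stage_spec$proportions
    if (abs(sum(p) - 1) > 1e-8)
      stop("ordinal proportions must sum to 1", call. = FALSE)
    cuts <- stats::quantile(z, cumsum(p)[-length(p)], type = 7, names = FALSE)
    obs <- findInterval(z, cuts, left.open = TRUE) + 1L
    list(observed = obs,
         spec = var_spec(name, "ordinal", n_categories = length(p)),
         truth = list(mode = mode, thresholds = cuts, proportions = p,
                      reliability = rel))
  } else if (mode == "binary") {
    thr <- stats::quantile(z, 1 - stage_spec$prevalence, type = 7,
                           names = FALSE)
    obs <- as.integer(z > thr)
    list(observed = obs, spec = var_spec(name, "binary"),
         truth = list(mode = mode, threshold = thr,
                      prevalence = stage_spec$prevalence, reliability = rel))
  } else stop("unknown observation mode: ", mode, call. = FALSE)
}

#' Mask later-exam results for non-attempters
#'
#' Doctors choose whether to sit post-graduate examinations, and stronger
#' performers are more likely to attempt them. Attempt probability is
#' `plogis(intercept + slope * prior latent score)`; results of
#' non-attempters are set missing and an `attempted_<stage>` flag is kept.
#'
#' @param table data frame of observed columns (entrants).
#' @param latent latent matrix of the same rows.
#' @param config a [synthetic_config()] with non-`NULL` `uptake`.
#' @return `table` with masked values, attempt-flag columns appended, and
#'   an attribute `uptake_truth` holding the coefficients used.
#' @export
apply_uptake <- function(table, latent, config) {
  truth <- list()
  for (u in config$uptake) {
    score <- latent[, u$on]
    slope <- if (is.null(u$slope)) 0 else u$slope
    if (!is.null(u$intercept)) {
      a <- u$intercept
    } else {
      f <- function(a) mean(stats::plogis(a + slope * score)) - u$rate
      a <- stats::uniroot(f, c(-50, 50))$root
    }
    p <- stats::plogis(a + slope * score)
    attempted <- stats::runif(length(p)) < p
    table[[u$stage]][!attempted] <- NA
    table[[paste0("attempted_", u$stage)]] <- attempted
    truth[[u$stage]] <- list(on = u$on, intercept = a, slope = slope)
  }
  attr(table, "uptake_truth") <- truth
  table
}

#' Generate a full synthetic cohort
#'
#' Composition of the generator stages: latent simplex scores for the
#' applicant pool, selection of entrants, per-stage observation (noise,
#' ceilings, grouping), and outcome-dependent exam uptake. The generating
#' truth — population correlation matrix, selection rule, censoring points,
#' thresholds, uptake coefficients, and seed — is retained so estimators
#' can be checked against it.
#'
#' @param config a [synthetic_config()] (see also [cohort_preset()]).
#' @return object of class `cohort_sim`: a list with `table` (entrant data
#'   frame, one observed column per stage plus attempt flags), `specs`
#'   (list of [var_spec()] per stage), `latent` (entrant latent scores),
#'   `truth` (generating parameters), and `config`.
#' @export
#' @examples
#' cfg <- synthetic_config(500, c("s1", "s2"), lag1 = 0.6, seed = 3)
#' sim <- generate_cohort(cfg)
#' cor(sim$table$s1, sim$table$s2)
generate_cohort <- function(config) {
  lat_all <- generate_latent(config)          # seeds the generator
  sel <- apply_selection(lat_all, config)
  lat <- sel$entrants
  tab <- data.frame(row.names = seq_len(nrow(lat)))
  specs <- list(); obs_truth <- list()
  for (i in seq_along(config$stages)) {
    nm <- config$stages[i]
    o <- observe_stage(lat[, nm], config$observe[[nm]], name = nm)
    tab[[nm]] <- o$observed
    specs[[nm]] <- o$spec
    specs[[nm]]$causal_order <- i
    obs_truth[[nm]] <- o$truth
  }
  uptake_truth <- NULL
  if (!is.null(config$uptake)) {
    tab <- apply_uptake(tab, lat, config)
    uptake_truth <- attr(tab, "uptake_truth")
    attr(tab, "uptake_truth") <- NULL
  }
  if (!is.null(config$covariate))
    tab[[config$covariate$name]] <- attr(lat, "covariate")
  truth <- list(corr = config$corr, selection = config$selection,
                selection_cutoff = sel$cutoff, observation = obs_truth,
                uptake = uptake_truth, seed = config$seed,
                n_applicants = config$n_applicants, n_entrants = nrow(lat))
  structure(list(table = tab, specs = specs, latent = lat,
                 selected = sel$selected, truth = truth, config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d entrants of %d applicants, %d stages (seed %d)\n",
              x$truth$n_entrants, x$truth$n_applicants,
              length(x$config$stages), x$truth$seed))
  cat("  stages:", paste(x$config$stages, collapse = ", "), "\n")
  invisible(x)
}

#' Preset cohort configurations
#'
#' Two ready-made generating processes emulating the observable structure of
#' the studied cohorts. `"uclms"`: ~2,916 applicants selected to ~729
#' entrants on A-level score, a grade ceiling holding 62.5% of entrants at
#' the maximum, five correlated stages, and post-graduate exam uptake of
#' 34.6% that increases with clinical performance. `"cohort1985"`: ~2,399
#' applicants selected at 36.3%, an 18.7% A-level ceiling mass, a 4-category
#' ordinal pre-clinical outcome with proportions 6.7/28.3/53.3/11.7% (fail
#' to distinction), and a binary specialist-register end state. Lag-1
#' latent correlations (0.5–0.7) and uptake slopes are calibration choices
#' of the generator, documented in the package vignette.
#'
#' @param name `"uclms"` or `"cohort1985"`.
#' @param n_applicants override the preset applicant-pool size (entrants
#'   scale proportionally).
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
cohort_preset <- function(name = c("uclms", "cohort1985"),
                          n_applicants = NULL, seed = 1L) {
  name <- match.arg(name)
  if (name == "uclms") {
    if (is.null(n_applicants)) n_applicants <- 2916L
    synthetic_config(
      n_applicants = n_applicants,
      stages = c("gcse", "alevel", "bms", "clinical", "mrcp1"),
      lag1 = c(0.7, 0.55, 0.65, 0.7),
      selection = list(stage = "alevel", fraction = 0.25,
                       type = "truncation"),
      observe = list(
        gcse = list(mode = "ceiling", ceiling_q = 0.90),
        alevel = list(mode = "ceiling", ceiling_q = 0.375),
        bms = list(mode = "continuous", reliability = 0.8),
        clinical = list(mode = "continuous", reliability = 0.8),
        mrcp1 = list(mode = "continuous", reliability = 0.8)),
      uptake = list(list(stage = "mrcp1", on = "clinical",
                         slope = 1.5, rate = 0.346)),
      seed = seed)
  } else {
    if (is.null(n_applicants)) n_applicants <- 2399L
    synthetic_config(
      n_applicants = n_applicants,
      stages = c("olevel", "alevel", "bms", "finals", "register"),
      lag1 = c(0.7, 0.55, 0.6, 0.5),
      selection = list(stage = "alevel", fraction = 0.363,
                       type = "truncation"),
      observe = list(
        olevel = list(mode = "ceiling", ceiling_q = 0.90),
        alevel = list(mode = "ceiling", ceiling_q = 0.813),
        bms = list(mode = "ordinal",
                   proportions = c(0.067, 0.283, 0.533, 0.117)),
        finals = list(mode = "continuous", reliability = 0.9),
        register = list(mode = "binary", prevalence = 0.554)),
      seed = seed)
  }
}
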
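## Classed conditions so that configuration, data, and estimation failures
## are programmatically distinguishable (and map to distinct exit codes in
## any script wrapper).
lp_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "lp_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

#' Pairwise Pearson correlations
#'
#' Conventional product-moment correlations with two-sided p-values from the
#' t transform and per-pair n under pairwise deletion — the upper triangle
#' of the report layout. Pairs with fewer than `min_n` complete
#' observations are marked unavailable (`NA`), not zero.
#'
#' @param table data frame of numeric columns.
#' @param min_n minimum pairwise n to report (default 10).
#' @return data frame with `var1`, `var2`, `r`, `p`, `n`, `available`.
#' @export
pearson_pairwise <- function(table, min_n = 10L) {
  vars <- names(table)
  res <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i >= j) next
    x <- table[[i]]; y <- table[[j]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n >= max(3L, min_n) && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      ct <- stats::cor.test(x[ok], y[ok])
      res[[length(res) + 1L]] <- data.frame(
        var1 = vars[i], var2 = vars[j], r = unname(ct$estimate),
        p = ct$p.value, n = n, available = TRUE)
    } else {
      res[[length(res) + 1L]] <- data.frame(
        var1 = vars[i], var2 = vars[j], r = NA_real_, p = NA_real_,
        n = n, available = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Two-triangle correlation-matrix report
#'
#' For every variable pair: the conventional Pearson r with p and pairwise n
#' (upper triangle), and the latent correlation corrected for censoring and
#' grouping with SE and 95% percentile CI (lower triangle). The corrected
#' estimator is dispatched purely by the two variables' measurement kinds —
#' censored-normal, biserial/polyserial, tetrachoric, or polychoric — all
#' through the same interval-likelihood sampler. A pair whose estimation
#' fails is flagged and the run continues.
#'
#' @param table data frame of observed columns.
#' @param specs named list of [var_spec()] (one per column of interest).
#' @param config an [mcmc_config()]; each pair gets a deterministic seed
#'   derived from `config$seed`.
#' @param min_n minimum pairwise n (default 10).
#' @return object of class `matrix_report` with elements `variables`,
#'   `upper` (Pearson entries), `lower` (corrected entries), `kinds`.
#' @export
build_matrix_report <- function(table, specs, config = mcmc_config(),
                                min_n = 10L) {
  vars <- names(specs)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    lp_error("lp_data_error", "columns absent from table: %s",
             paste(missing_cols, collapse = ", "))
  upper <- pearson_pairwise(table[vars], min_n = min_n)
  lower <- list()
  pair_id <- 0L
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i >= j) next
    pair_id <- pair_id + 1L
    x <- table[[vars[i]]]; y <- table[[vars[j]]]
    n <- sum(!is.na(x) & !is.na(y))
    row <- data.frame(var1 = vars[i], var2 = vars[j], estimate = NA_real_,
                      se = NA_real_, lo = NA_real_, hi = NA_real_,
                      n = n, method = NA_character_, ok = FALSE)
    if (n >= min_n) {
      cfg <- config
      cfg$seed <- (config$seed + 7919L * pair_id) %% 2147483647L
      fit <- tryCatch(
        latent_cor(x, y, list(specs[[vars[i]]], specs[[vars[j]]]), cfg),
        error = function(e) e)
      if (!inherits(fit, "error")) {
        row$estimate <- fit$estimate; row$se <- fit$se
        row$lo <- fit$ci[1]; row$hi <- fit$ci[2]
        row$method <- fit$method; row$ok <- TRUE
      } else {
        row$method <- paste("failed:", conditionMessage(fit))
      }
    } else {
      row$method <- "insufficient n"
    }
    lower[[pair_id]] <- row
  }
  lower <- do.call(rbind, lower)
  rownames(lower) <- NULL
  structure(list(variables = vars, upper = upper, lower = lower,
                 kinds = vapply(specs, `[[`, character(1), "kind"),
                 min_n = min_n),
            class = "matrix_report")
}

#' @export
print.matrix_report <- function(x, digits = 3, ...) {
  k <- length(x$variables)
  m <- matrix("", k, k, dimnames = list(x$variables, x$variables))
  diag(m) <- "1"
  for (r in seq_len(nrow(x$upper))) {
    e <- x$upper[r, ]
    m[e$var1, e$var2] <- if (e$available)
      sprintf("%.*f (p=%.3g, n=%d)", digits, e$r, e$p, e$n) else "-"
  }
  for (r in seq_len(nrow(x$lower))) {
    e <- x$lower[r, ]
    m[e$var2, e$var1] <- if (e$ok)
      format_estimate(list(estimate = e$estimate, se = e$se,
                           ci = c(e$lo, e$hi)), digits) else "-"
  }
  cat("Correlation matrix report",
      "(upper: Pearson r; lower: corrected for censoring/grouping)\n")
  print(m, quote = FALSE)
  cat("Variable kinds:",
      paste(sprintf("%s=%s", x$variables, x$kinds), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a matrix report
#'
#' Lossless JSON round trip of a [build_matrix_report()] result.
#'
#' @param report a `matrix_report`.
#' @param path file path.
#' @return `report_to_json` invisibly returns the path;
#'   `report_from_json` returns the restored `matrix_report`.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$upper <- as.data.frame(raw$upper)
  raw$lower <- as.data.frame(raw$lower)
  raw$kinds <- unlist(raw$kinds)
  raw$variables <- unlist(raw$variables)
  structure(raw, class = "matrix_report")
}

#' Write the two triangles of a report as CSV files
#'
#' @param report a `matrix_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_report_csv <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  up <- file.path(dir, "matrix_pearson.csv")
  lo <- file.path(dir, "matrix_corrected.csv")
  utils::write.csv(report$upper, up, row.names = FALSE)
  utils::write.csv(report$lower, lo, row.names = FALSE)
  invisible(c(up, lo))
}

validate_run_config <- function(cfg) {
  if (!is.null(cfg$preset)) return(invisible(cfg))
  need <- c("n_applicants", "stages", "lag1", "seed")
  miss <- need[vapply(need, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(miss))
    lp_error("lp_config_error", "config is missing required key(s): %s",
             paste(miss, collapse = ", "))
  invisible(cfg)
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      lp_error("lp_config_error", "config file not found: %s", config)
    cfg <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  } else cfg <- config
  validate_run_config(cfg)
}

#' Run the full synthetic pipeline end to end
#'
#' Simulate a cohort, build the two-triangle correlation report, fit the
#' backwards-elimination path model, and write the output bundle:
#' `cohort.csv`, `matrix_pearson.csv`, `matrix_corrected.csv`, `edges.csv`,
#' `model.dot`, and `truth_vs_estimate.json` (true latent correlations next
#' to the corrected estimates, with CI-coverage flags). All randomness
#' flows from the single seed, so identical configs give byte-identical
#' bundles.
#'
#' @param config a [synthetic_config()], a [cohort_preset()] name given as
#'   `list(preset = "uclms", ...)`, or a path to a YAML/JSON file with the
#'   [synthetic_config()] fields (plus optional `mcmc` and `path` blocks).
#' @param out_dir output directory.
#' @param mcmc an [mcmc_config()] for the correlation report.
#' @param path_threshold retention threshold for the path model.
#' @return invisibly, a list with `sim`, `report`, `model`, and `files`.
#' @export
run_end_to_end <- function(config, out_dir, mcmc = mcmc_config(),
                           path_threshold = 0.05) {
  cfg <- load_run_config(config)
  if (inherits(cfg, "synthetic_config")) {
    sim_cfg <- cfg
  } else if (!is.null(cfg$preset)) {
    sim_cfg <- cohort_preset(cfg$preset,
                             n_applicants = cfg$n_applicants,
                             seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  } else {
    sim_cfg <- synthetic_config(
      n_applicants = cfg$n_applicants, stages = unlist(cfg$stages),
      lag1 = unlist(cfg$lag1), selection = cfg$selection,
      observe = cfg$observe, uptake = cfg$uptake, seed = cfg$seed)
    if (!is.null(cfg$mcmc))
      mcmc <- mcmc_config(chain_length = cfg$mcmc$chain_length,
                          estimate_window = cfg$mcmc$estimate_window,
                          seed = cfg$seed)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- generate_cohort(sim_cfg)
  obs_cols <- sim_cfg$stages
  tab <- sim$table[obs_cols]
  report <- tryCatch(
    build_matrix_report(tab, sim$specs, mcmc),
    lp_error = function(e) stop(e),
    error = function(e) lp_error("lp_estimation_error",
                                 "correlation report failed: %s",
                                 conditionMessage(e)))
  model <- fit_backbone(tab, order = obs_cols, threshold = path_threshold)

  files <- c(cohort = file.path(out_dir, "cohort.csv"),
             edges = file.path(out_dir, "edges.csv"),
             dot = file.path(out_dir, "model.dot"),
             truth = file.path(out_dir, "truth_vs_estimate.json"))
  utils::write.csv(sim$table, files["cohort"], row.names = FALSE)
  mats <- write_report_csv(report, out_dir)
  utils::write.csv(model$edges, files["edges"], row.names = FALSE)
  export_dot(model, files["dot"])
  cmp <- report$lower
  iu <- match(paste(cmp$var1, cmp$var2),
              paste(report$upper$var1, report$upper$var2))
  cmp$pearson_r <- report$upper$r[iu]
  cmp$true_rho <- mapply(function(a, b) {
    sim_cfg$corr[match(a, obs_cols), match(b, obs_cols)]
  }, cmp$var1, cmp$var2)
  cmp$ci_covers_truth <- cmp$ok & cmp$lo <= cmp$true_rho &
    cmp$true_rho <= cmp$hi
  jsonlite::write_json(cmp, files["truth"], digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(list(sim = sim, report = report, model = model,
                 files = c(files, mats)))
}
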
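# End-to-end analysis over an input bundle: features -> sample -> screen ->
# fit -> odds-ratio table, plus the report surfaces (mean-comparison table,
# list-overlap counts) and the run manifest.

#' Normalize, screen and fit one comparison sample
#'
#' Applies [normalize_features()] to the sample's covariates, removes highly
#' correlated covariates with [correlation_screen()], fits the logistic model
#' and attaches per-variable likelihood-ratio tests. The odds-ratio table is
#' the forest-plot data: one row per covariate with estimate, SE, odds ratio,
#' Wald 95% CI and LR p-value.
#'
#' @param sample a `comparison_sample` with raw features.
#' @param screen_threshold maximum tolerated absolute pairwise correlation.
#' @return list of class `sample_analysis`: `fit` (a `logistic_fit`),
#'   `or_table` (data.frame), `screen`, `normalization` (constants used),
#'   `sample_label`, `n`, `n_dropped`.
#' @export
analyze_sample <- function(sample, screen_threshold = 0.8) {
  norm <- normalize_features(sample$features)
  screen <- correlation_screen(norm, threshold = screen_threshold)
  nsample <- list(outcome = sample$outcome,
                  features = norm[screen$retained],
                  sample_label = sample$sample_label)
  fit <- fit_logistic(nsample)
  lr <- lapply(screen$retained, function(v) lr_test_variable(nsample, v))
  lr_p <- vapply(lr, function(t) t$p_value, numeric(1))
  names(lr_p) <- screen$retained
  vars <- screen$retained
  or_table <- data.frame(
    variable = vars,
    estimate = unname(fit$coefficients[vars]),
    se = unname(fit$se[vars]),
    odds_ratio = unname(fit$odds_ratios[vars]),
    ci_low = unname(fit$ci95[vars, "lower"]),
    ci_high = unname(fit$ci95[vars, "upper"]),
    lr_p = unname(lr_p[vars]),
    stars = significance_stars(unname(lr_p[vars])),
    stringsAsFactors = FALSE
  )
  structure(list(
    fit = fit,
    or_table = or_table,
    screen = screen,
    normalization = attr(norm, "normalization"),
    sample_label = sample$sample_label,
    n = length(sample$outcome),
    n_dropped = sample$n_dropped %||% NA_integer_
  ), class = "sample_analysis")
}

#' Run one focal-vs-reference analysis over an input bundle
#'
#' Chains [build_features()], [build_sample()] and [analyze_sample()] for a
#' bundle of validated input tables (as returned by [simulate_registry()] or
#' [read_bundle()]), and attaches a run manifest sufficient to reproduce the
#' run (config hash of the inputs' dimensions, seed if known, sample sizes,
#' dropped counts, normalization constants).
#'
#' @param bundle list with `registry`, `notifications`, `membership`, and
#'   either `substances` + `corpus` or a precomputed `pub_counts`.
#' @param focal,reference list names, as in [build_sample()].
#' @param model `"aggregate"` (CMR + environmental score) or
#'   `"disaggregated"` (eight individual hazard variables).
#' @param screen_threshold correlation-screen threshold.
#' @param pub_counts optional named publication-count vector overriding
#'   corpus matching.
#' @param seed recorded in the manifest (no randomness is consumed here).
#' @return a `sample_analysis` with an additional `manifest` element.
#' @export
run_analysis <- function(bundle, focal = "cl", reference = "reach",
                         model = c("aggregate", "disaggregated"),
                         screen_threshold = 0.8, pub_counts = NULL,
                         seed = NULL) {
  model <- match.arg(model)
  features <- build_features(bundle$registry, bundle$notifications,
                             substances = bundle$substances,
                             corpus = bundle$corpus,
                             model = model, pub_counts = pub_counts)
  sample <- build_sample(bundle$membership, features, focal, reference)
  res <- analyze_sample(sample, screen_threshold = screen_threshold)
  res$model <- model
  res$manifest <- list(
    sample_label = res$sample_label,
    model = model,
    n = res$n,
    k = res$fit$k,
    n_dropped = res$n_dropped,
    loglik_model = res$fit$loglik_model,
    loglik_null = res$fit$loglik_null,
    adjusted_mcfadden = res$fit$adjusted_mcfadden,
    converged = res$fit$converged,
    screen_threshold = screen_threshold,
    screened_out = res$screen$dropped,
    normalization = res$normalization,
    seed = seed,
    config_hash = config_hash(list(dim(bundle$registry), dim(bundle$membership),
                                   model, focal, reference, screen_threshold)),
    version = as.character(utils::packageVersion("svhcdrivers"))
  )
  res
}

#' Write a sample analysis to CSV + JSON
#'
#' Emits the odds-ratio table as CSV (fixed column order, stars in their own
#' column so numeric columns stay parseable) and the manifest as JSON.
#'
#' @param analysis a `sample_analysis` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, defaults to the sample label.
#' @return invisibly, the written paths.
#' @export
write_analysis <- function(analysis, dir, prefix = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- prefix %||% tolower(analysis$sample_label %||% "analysis")
  or_path <- file.path(dir, paste0(prefix, "_odds_ratios.csv"))
  man_path <- file.path(dir, paste0(prefix, "_manifest.json"))
  utils::write.csv(analysis$or_table, or_path, row.names = FALSE)
  jsonlite::write_json(analysis$manifest, man_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(odds_ratios = or_path, manifest = man_path))
}
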
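# Logistic models, odds ratios, adjusted McFadden pseudo-R2, per-variable
# likelihood-ratio tests, correlation screening and Welch mean comparisons.

check_separation <- function(y, X) {
  for (v in colnames(X)) {
    x <- X[, v]
    if (min(x[y == 1]) > max(x[y == 0]) || max(x[y == 1]) < min(x[y == 0])) {
      stop(sprintf("perfect separation on covariate '%s'", v), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Fit a logistic regression to a comparison sample
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm`) of the binary list-membership outcome on the normalized
#' covariates. Reports coefficients, Wald standard errors, odds ratios
#' `exp(beta)` and Wald 95% confidence intervals `exp(beta +/- 1.96 SE)`; the
#' odds ratio of a \[0, 1\]-normalized covariate is the odds fold-change from
#' the covariate's minimum to its maximum. Also computes the adjusted
#' McFadden pseudo-R2 (see [adjusted_mcfadden()]).
#'
#' Degenerate designs fail loudly: a constant covariate or rank-deficient
#' design is an error, and a covariate that perfectly separates the classes
#' raises an error naming it. Quasi-separation (fitted probabilities pinned
#' at 0/1) and non-convergence are flagged, not hidden.
#'
#' @param sample a `comparison_sample` (see [build_sample()]) whose features
#'   are already normalized to \[0, 1\] (see [normalize_features()]), or a
#'   list with `outcome` and `features`.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum IRLS iterations.
#' @return object of class `logistic_fit`: coefficients, `se`, `odds_ratios`,
#'   `ci95` (matrix with `lower`/`upper`), `loglik_model`, `loglik_null`,
#'   `n`, `k`, `adjusted_mcfadden`, `converged`, `quasi_separation`,
#'   `variables`, `sample_label`.
#' @export
fit_logistic <- function(sample, tol = 1e-8, max_iter = 100) {
  y <- sample$outcome
  feat <- as.data.frame(sample$features)
  feat <- feat[setdiff(names(feat), "substance_id")]
  X <- as.matrix(feat)
  storage.mode(X) <- "double"
  if (length(unique(y)) < 2) stop("outcome must contain both classes", call. = FALSE)
  if (anyNA(X)) stop("missing covariate values; build the sample with drop_incomplete = TRUE",
                     call. = FALSE)
  const <- apply(X, 2, function(x) length(unique(x)) == 1)
  if (any(const)) {
    stop(sprintf("degenerate design: covariate '%s' is constant",
                 colnames(X)[const][1]), call. = FALSE)
  }
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("singular design: covariates are linearly dependent", call. = FALSE)
  }
  check_separation(y, X)
  dat <- data.frame(.y = y, feat, check.names = TRUE)
  vars <- setdiff(names(dat), ".y")
  fit <- stats::glm(stats::reformulate(vars, ".y"), data = dat,
                    family = stats::binomial(),
                    control = stats::glm.control(epsilon = tol, maxit = max_iter))
  null <- stats::glm(.y ~ 1, data = dat, family = stats::binomial(),
                     control = stats::glm.control(epsilon = tol, maxit = max_iter))
  sm <- summary(fit)$coefficients
  beta <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  names(beta) <- names(se) <- c("(Intercept)", colnames(X))
  ll_m <- as.numeric(stats::logLik(fit))
  ll_0 <- as.numeric(stats::logLik(null))
  k <- ncol(X)
  quasi <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
  if (quasi) warning("quasi-separation: some fitted probabilities are numerically 0 or 1",
                     call. = FALSE)
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  structure(list(
    coefficients = beta,
    se = se,
    odds_ratios = exp(beta),
    ci95 = ci,
    loglik_model = ll_m,
    loglik_null = ll_0,
    n = length(y),
    k = k,
    adjusted_mcfadden = adjusted_mcfadden(ll_m, ll_0, k),
    converged = fit$converged,
    quasi_separation = quasi,
    variables = colnames(X),
    sample_label = sample$sample_label %||% NA_character_
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit%s: n = %d, k = %d, adjusted McFadden R2 = %.4f\n",
              if (is.na(x$sample_label)) "" else paste0(" [", x$sample_label, "]"),
              x$n, x$k, x$adjusted_mcfadden))
  tab <- data.frame(
    estimate = x$coefficients,
    se = x$se,
    odds_ratio = x$odds_ratios,
    ci_low = x$ci95[, "lower"],
    ci_high = x$ci95[, "upper"]
  )
  print(round(tab, 4))
  invisible(x)
}

#' Adjusted McFadden pseudo-R2
#'
#' McFadden's pseudo-R2 with an overfitting penalty: the model log-likelihood
#' is charged one unit per covariate (intercept excluded) before comparison
#' with the null model,
#' \deqn{R^2_{adj} = 1 - \frac{\ell_{model} - k}{\ell_{null}}.}
#' A model whose likelihood gain does not exceed its parameter count scores
#' at or below zero.
#'
#' @param loglik_model model log-likelihood, or a `logistic_fit` object (then
#'   the other arguments are taken from it).
#' @param loglik_null intercept-only log-likelihood.
#' @param k number of covariates excluding the intercept.
#' @return dimensionless value (at most 1; negative when the penalty exceeds
#'   the likelihood gain).
#' @export
adjusted_mcfadden <- function(loglik_model, loglik_null = NULL, k = NULL) {
  if (inherits(loglik_model, "logistic_fit")) {
    fit <- loglik_model
    loglik_null <- fit$loglik_null
    k <- fit$k
    loglik_model <- fit$loglik_model
  }
  if (loglik_null == 0) {
    stop("null log-likelihood is zero (single-class outcome); adjusted McFadden undefined",
         call. = FALSE)
  }
  1 - (loglik_model - k) / loglik_null
}

#' Likelihood-ratio significance test for one variable
#'
#' Fits the single-variable logistic model and compares it to the null
#' (intercept-only) model: deviance `D = 2 (loglik_single - loglik_null)`,
#' p-value from the chi-square distribution with 1 degree of freedom.
#'
#' @param sample a `comparison_sample` with normalized features.
#' @param variable name of the covariate to test.
#' @return list of class `variable_test`: `variable`, `deviance`, `df`,
#'   `p_value`.
#' @export
lr_test_variable <- function(sample, variable) {
  if (!variable %in% names(sample$features)) {
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  }
  sub <- list(outcome = sample$outcome,
              features = sample$features[variable],
              sample_label = sample$sample_label %||% NA_character_)
  fit <- fit_logistic(sub)
  D <- 2 * (fit$loglik_model - fit$loglik_null)
  structure(list(
    variable = variable,
    deviance = D,
    df = 1L,
    p_value = stats::pchisq(D, df = 1, lower.tail = FALSE)
  ), class = "variable_test")
}

#' Screen out highly correlated covariates
#'
#' Computes pairwise Pearson correlations and, while any pair exceeds the
#' threshold in absolute value, greedily drops from the worst-offending pair
#' the variable with the larger mean absolute correlation to all retained
#' variables (alphabetical tie-break: the later name is dropped). Highly
#' collinear covariates make the odds ratios uninterpretable, hence the
#' screen before fitting.
#'
#' @param features data.frame of numeric covariates (a `substance_id` column
#'   is ignored).
#' @param threshold maximum tolerated absolute pairwise correlation.
#' @return list: `retained` (character), `dropped` (character), `report`
#'   (data.frame of offending pairs: var_a, var_b, r, dropped).
#' @export
correlation_screen <- function(features, threshold = 0.8) {
  vars <- setdiff(names(features), "substance_id")
  if (length(vars) < 2) {
    return(list(retained = vars, dropped = character(0),
                report = data.frame(var_a = character(0), var_b = character(0),
                                    r = numeric(0), dropped = character(0))))
  }
  X <- as.matrix(features[vars])
  storage.mode(X) <- "double"
  retained <- vars
  report <- list()
  repeat {
    C <- abs(stats::cor(X[, retained, drop = FALSE],
                        use = "pairwise.complete.obs"))
    diag(C) <- 0
    C[is.na(C)] <- 0
    if (max(C) <= threshold) break
    pos <- which(C == max(C), arr.ind = TRUE)
    pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE][1, ]
    a <- retained[min(pos)]
    b <- retained[max(pos)]
    mean_r <- rowMeans(C)
    drop <- if (mean_r[a] > mean_r[b]) a
            else if (mean_r[b] > mean_r[a]) b
            else sort(c(a, b))[2]
    report[[length(report) + 1L]] <- data.frame(
      var_a = a, var_b = b, r = stats::cor(X[, a], X[, b], use = "pairwise.complete.obs"),
      dropped = drop, stringsAsFactors = FALSE
    )
    retained <- setdiff(retained, drop)
  }
  list(
    retained = retained,
    dropped = setdiff(vars, retained),
    report = if (length(report) > 0) do.call(rbind, report)
             else data.frame(var_a = character(0), var_b = character(0),
                             r = numeric(0), dropped = character(0))
  )
}

#' Two-sided Welch t-test between two list samples
#'
#' Unequal-variance (Welch) two-sample t-test, the reading of the study's
#' "two-way t-test" mean comparisons given the very different group sizes and
#' variances across lists. Identical degenerate samples (zero variance in
#' both groups, equal means) get `t = 0`, `p = 1` by convention; zero
#' variance with differing means gives `p = 0`.
#'
#' @param sample_a,sample_b numeric vectors (each of length >= 2).
#' @return list of class `mean_comparison`: group means, SDs and sizes, `t`,
#'   `df`, `p_value` and significance `stars` (`***` at 0.01, `**` at 0.05,
#'   `*` at 0.1).
#' @export
welch_t <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 non-missing values", call. = FALSE)
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      t_stat <- 0; df <- length(a) + length(b) - 2; p <- 1
      sv_msg("welch_t: zero variance in both samples with equal means; p = 1 by convention")
    } else {
      t_stat <- sign(mean(a) - mean(b)) * Inf; df <- length(a) + length(b) - 2; p <- 0
      warning("zero variance in both samples with differing means", call. = FALSE)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    t = t_stat, df = df, p_value = p,
    stars = significance_stars(p)
  ), class = "mean_comparison")
}

#' Significance stars at the 0.1 / 0.05 / 0.01 thresholds
#'
#' @param p numeric vector of p-values.
#' @return character vector: `"***"` below 0.01, `"**"` below 0.05, `"*"`
#'   below 0.1, `""` otherwise.
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  ok <- !is.na(p)
  out[ok & p < 0.1] <- "*"
  out[ok & p < 0.05] <- "**"
  out[ok & p < 0.01] <- "***"
  out
}

#' Per-variable mean comparison table across lists
#'
#' Builds the per-list means/SDs of every feature together with Welch t-test
#' p-values comparing each non-focal list to the focal list. List samples are
#' the full (overlapping) memberships, e.g. Candidate List substances are also
#' part of the REACH column.
#'
#' @param features raw (untransformed beyond the variance-stabilizing
#'   transforms) feature table with `substance_id`.
#' @param membership validated membership table.
#' @param focal focal list name (default `"cl"`).
#' @param others lists to compare against the focal list.
#' @return data.frame: one row per (variable, list) with mean, sd, n, and for
#'   non-focal lists the Welch p-value and stars versus the focal list.
#' @export
mean_comparison_table <- function(features, membership, focal = "cl",
                                  others = c("reach", "al", "sin", "prio")) {
  focal <- resolve_list(focal)
  others <- vapply(others, resolve_list, character(1))
  vars <- setdiff(names(features), "substance_id")
  idx <- match(membership$substance_id, features$substance_id)
  rows <- list()
  for (v in vars) {
    x <- features[[v]][idx]
    xf <- x[membership[[MEMBERSHIP_COLS[[focal]]]]]
    for (lst in c(focal, unname(others))) {
      xl <- x[membership[[MEMBERSHIP_COLS[[lst]]]]]
      xl_ok <- xl[!is.na(xl)]
      if (lst == focal) {
        p <- NA_real_
      } else {
        p <- welch_t(xl, xf)$p_value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, list = toupper(lst),
        mean = mean(xl_ok), sd = stats::sd(xl_ok), n = length(xl_ok),
        p_vs_focal = p, stars = significance_stars(p %||% NA_real_),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
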
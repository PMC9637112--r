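test_that("fit_logistic matches the closed-form 2x2 odds ratio", {
  # x = 1: 10 of 100 positive; x = 0: 5 of 100 positive
  y <- c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95))
  x <- c(rep(1, 100), rep(0, 100))
  fit <- fit_logistic(list(outcome = y, features = data.frame(exposed = x)))
  or_oracle <- (10 * 95) / (90 * 5)
  expect_equal(unname(fit$odds_ratios["exposed"]), or_oracle, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n, 200)
  expect_equal(fit$k, 1)
  # exp/log consistency is exact
  expect_identical(fit$odds_ratios, exp(fit$coefficients))
  expect_true(all(fit$ci95[, "lower"] < fit$odds_ratios))
  expect_true(all(fit$ci95[, "upper"] > fit$odds_ratios))
})

test_that("log-likelihood on tiny samples matches a grid/brute-force maximizer", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    x <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    # skip draws the model cannot fit (complete separation)
    sep <- min(x[y == 1]) > max(x[y == 0]) || max(x[y == 1]) < min(x[y == 0])
    if (sep) next
    fit <- fit_logistic(list(outcome = y, features = data.frame(x = x)))
    oracle <- grid_loglik_oracle(y, x)
    expect_equal(fit$loglik_model, oracle$loglik, tolerance = 1e-4)
    expect_gte(fit$loglik_model, oracle$loglik - 1e-6)
  }
})

test_that("degenerate and separated designs fail loudly", {
  y <- rep(c(0, 1), 20)
  expect_error(fit_logistic(list(outcome = y, features = data.frame(z = rep(0, 40)))),
               "constant")
  expect_error(fit_logistic(list(outcome = y,
                                 features = data.frame(a = 1:40, b = 2 * (1:40)))),
               "singular")
  # covariate equal to the outcome: perfect separation, named
  expect_error(fit_logistic(list(outcome = y, features = data.frame(leak = y))),
               "perfect separation on covariate 'leak'")
  expect_error(fit_logistic(list(outcome = rep(1, 10),
                                 features = data.frame(x = runif(10)))),
               "both classes")
})

test_that("likelihood never decreases from null to fitted model", {
  set.seed(17)
  for (i in 1:10) {
    n <- 80
    x <- runif(n)
    y <- rbinom(n, 1, plogis(-0.5 + runif(1, -2, 2) * x))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(list(outcome = y, features = data.frame(x = x)))
    expect_gte(fit$loglik_model, fit$loglik_null - 1e-10)
  }
})

test_that("adjusted McFadden penalizes the covariate count as specified", {
  # null self-comparison: k = 0, equal likelihoods
  expect_equal(adjusted_mcfadden(-100, -100, k = 0), 0)
  # hand evaluation: equal likelihoods with k > 0 go negative by k/|ll0|
  expect_equal(adjusted_mcfadden(-100, -100, k = 3), -3 / 100)
  expect_equal(adjusted_mcfadden(-90, -100, k = 2), 1 - (-92 / -100))
  expect_error(adjusted_mcfadden(0, 0, k = 1), "zero")

  # adding a covariate with a real effect increases the adjusted value at large n
  set.seed(29)
  n <- 4000
  x1 <- runif(n); x2 <- runif(n)
  y <- rbinom(n, 1, plogis(-1 + 2.5 * x1))
  f1 <- fit_logistic(list(outcome = y, features = data.frame(x2 = x2)))
  f2 <- fit_logistic(list(outcome = y, features = data.frame(x2 = x2, x1 = x1)))
  expect_gt(f2$adjusted_mcfadden, f1$adjusted_mcfadden)
})

test_that("likelihood-ratio variable test detects strong effects and rejects leaks", {
  set.seed(53)
  n <- 2000
  reject <- logical(20)
  for (i in seq_len(20)) {
    x <- runif(n)
    y <- rbinom(n, 1, plogis(-1.5 + 3 * x))
    s <- list(outcome = y, features = data.frame(x = x, noise = runif(n)))
    tt <- lr_test_variable(s, "x")
    expect_s3_class(tt, "variable_test")
    expect_equal(tt$df, 1)
    reject[i] <- tt$p_value < 1e-6
  }
  expect_gte(mean(reject), 0.99)
  # covariate identical to the outcome is a separation error
  y <- rep(c(0, 1), 50)
  expect_error(lr_test_variable(list(outcome = y, features = data.frame(v = y)), "v"),
               "perfect separation")
  expect_error(lr_test_variable(list(outcome = y, features = data.frame(v = y)), "w"),
               "unknown variable")
})

test_that("correlation screen drops greedily and deterministically", {
  set.seed(61)
  n <- 500
  a <- runif(n)
  f <- data.frame(a = a, b = a, c = runif(n))  # identical pair: drop one
  sc <- correlation_screen(f, threshold = 0.8)
  expect_length(sc$dropped, 1)
  expect_true(sc$dropped %in% c("a", "b"))
  expect_equal(sc$dropped, "b")  # alphabetical tie-break drops the later name

  # hand-checked greedy rule: r(A,B) = 0.95; B also correlates with C more
  # than A does, so B has the larger mean |r| and is dropped
  z <- rnorm(n)
  A <- z + rnorm(n, sd = 0.33)
  B <- z + rnorm(n, sd = 0.30)
  C <- 0.4 * B + rnorm(n)
  f2 <- data.frame(A = A, B = B, C = C)
  r_ab <- cor(A, B)
  expect_gt(r_ab, 0.8)  # the construction must exceed the threshold
  mean_r <- colMeans(abs(cor(f2)) - diag(3))
  sc2 <- correlation_screen(f2, threshold = 0.8)
  expect_equal(sc2$dropped, names(which.max(mean_r[c("A", "B")])))
  expect_equal(nrow(sc2$report), 1)

  # independent columns survive at the default threshold
  none_dropped <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    f3 <- as.data.frame(matrix(runif(1000 * 4), 1000))
    length(correlation_screen(f3, threshold = 0.8)$dropped) == 0
  }, logical(1))
  expect_gte(mean(none_dropped), 0.99)
})

test_that("welch_t matches the closed form and handles degenerate samples", {
  # identical samples: t = 0, p = 1
  x <- c(1.2, 3.4, 2.2, 5.0)
  w <- welch_t(x, x)
  expect_equal(w$t, 0)
  expect_equal(w$p_value, 1)
  # zero variance in both groups with equal means: convention p = 1
  w0 <- welch_t(rep(2, 5), rep(2, 7))
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)
  # textbook two-sample case against the hand-computed statistic
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.1)
  w2 <- welch_t(a, b)
  oracle <- welch_oracle(a, b)
  expect_equal(w2$t, oracle$t, tolerance = 1e-12)
  expect_equal(w2$df, oracle$df, tolerance = 1e-12)
  expect_equal(w2$p_value, oracle$p, tolerance = 1e-12)
  expect_error(welch_t(1, c(2, 3)), "at least 2")
})

test_that("welch_t rejects at the nominal rate under the null", {
  set.seed(71)
  rej <- vapply(1:2000, function(i) {
    welch_t(rnorm(50), rnorm(50))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("significance stars follow the 0.1/0.05/0.01 legend", {
  expect_identical(significance_stars(c(0.005, 0.03, 0.07, 0.5, NA)),
                   c("***", "**", "*", "", ""))
})

test_that("mean comparison table reports per-list means and Welch p-values", {
  ids <- sprintf("EC-%02d", 1:40)
  set.seed(9)
  m <- make_membership(ids, cl = ids[1:10], sin = ids[5:20], prio = ids[21:30],
                       al = ids[1:4])
  f <- make_features(ids, cmr_score = c(runif(10, 0.5, 1), runif(30, 0, 0.3)))
  tab <- mean_comparison_table(f, m, focal = "cl")
  cl_row <- tab[tab$list == "CL" & tab$variable == "cmr_score", ]
  expect_equal(cl_row$mean, mean(f$cmr_score[1:10]))
  expect_equal(cl_row$n, 10)
  expect_true(is.na(cl_row$p_vs_focal))
  reach_row <- tab[tab$list == "REACH" & tab$variable == "cmr_score", ]
  oracle <- welch_oracle(f$cmr_score, f$cmr_score[1:10])
  expect_equal(reach_row$p_vs_focal, oracle$p, tolerance = 1e-12)
})
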
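test_that("aquatic hazard classification follows the GHS threshold ladder", {
  # rapidly degradable, non-bioaccumulative: threshold 0.01 mg/L
  expect_true(classify_aquatic(TRUE, FALSE, 0.005))
  expect_false(classify_aquatic(TRUE, FALSE, 0.05))
  # not rapidly degradable: threshold 0.1 mg/L
  expect_true(classify_aquatic(FALSE, FALSE, 0.05))
  expect_false(classify_aquatic(FALSE, FALSE, 0.5))
  # not rapidly degradable and bioaccumulative: threshold 1 mg/L
  expect_true(classify_aquatic(FALSE, TRUE, 0.5))
  expect_false(classify_aquatic(FALSE, TRUE, 2))
  expect_error(classify_aquatic(TRUE, FALSE, 0), "positive")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_substances = 300, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_registry(cfg, dir = d1)
  simulate_registry(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # a different seed changes the draw
  d3 <- withr::local_tempdir()
  simulate_registry(sim_config(n_substances = 300, seed = 78), dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "membership.csv"))),
                         unname(tools::md5sum(file.path(d3, "membership.csv")))))
  # and the generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_registry(sim_config(n_substances = 50, seed = 5)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("generated bundles satisfy the membership geometry and validators", {
  for (seed in c(2, 4, 6)) {
    b <- simulate_registry(sim_config(n_substances = 600, seed = seed))
    m <- b$membership
    expect_true(all(m$in_reach))
    expect_true(all(m$in_cl[m$in_al]))  # AL subset of CL on every draw
    # outputs re-validate
    expect_silent(validate_table(as.data.frame(b$registry), "registry"))
    expect_silent(validate_table(as.data.frame(b$membership)[
      c("substance_id", "in_reach", "in_cl", "in_al", "in_sin", "in_prio")],
      "membership"))
    # fractions in range wherever present
    fr <- as.matrix(b$notifications[grep("^frac_", names(b$notifications))])
    expect_true(all(fr >= 0 & fr <= 1, na.rm = TRUE))
  }
})

test_that("an intercept-only configuration reproduces its prevalence", {
  cfg <- sim_config(n_substances = 10000, seed = 19,
                    beta = c(cmr_score = 0, env_score = 0, tonnage_log = 0,
                             countries_sqrt = 0, publication_rank = 0),
                    intercept = qlogis(0.3))
  b <- simulate_registry(cfg)
  prev <- mean(b$membership$in_cl)
  mc_se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(prev - 0.3), 3 * mc_se)
})

test_that("covariate marginals are skewed as configured", {
  b <- simulate_registry(sim_config(n_substances = 4000, seed = 23))
  pubs <- b$truth$pub_count
  skew <- mean((pubs - mean(pubs))^3) / sd(pubs)^3
  expect_gt(skew, 1)
  # tonnage and country marginals near the configured study magnitudes
  f <- build_features(b$registry, b$notifications, model = "aggregate",
                      pub_counts = pubs)
  expect_gt(mean(f$tonnage_log, na.rm = TRUE), 1)
  expect_lt(mean(f$tonnage_log, na.rm = TRUE), 2.2)
  expect_gt(mean(f$countries_sqrt), 1)
  expect_lt(mean(f$countries_sqrt), 2)
})

test_that("a negative country coefficient is recovered as an odds ratio below 1", {
  b <- simulate_registry(sim_config(n_substances = 6000, seed = 37,
                                    target_prevalence = 0.05))
  res <- run_analysis(b, "cl", "reach", "aggregate",
                      pub_counts = b$truth$pub_count)
  expect_lt(res$or_table$odds_ratio[res$or_table$variable == "countries_sqrt"], 1)
  expect_gt(res$or_table$odds_ratio[res$or_table$variable == "cmr_score"], 1)
})

test_that("with all coefficients zero the adjusted McFadden averages below zero", {
  vals <- vapply(1:8, function(s) {
    b <- simulate_registry(sim_config(
      n_substances = 1500, seed = 100 + s,
      beta = c(cmr_score = 0, env_score = 0, tonnage_log = 0,
               countries_sqrt = 0, publication_rank = 0),
      target_prevalence = 0.2))
    res <- run_analysis(b, "cl", "reach", "aggregate",
                        pub_counts = b$truth$pub_count)
    res$fit$adjusted_mcfadden
  }, numeric(1))
  expect_lt(mean(vals), 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(al_rate = 1.2), "al_rate")
  expect_error(sim_config(band_probs = c(0.5, 0.6)), "band_probs")
  expect_error(sim_config(p_cl_entry = -0.1), "probabilities")
})

test_that("corpus construction reproduces the drawn publication counts exactly", {
  b <- simulate_registry(sim_config(n_substances = 400, seed = 41))
  counts <- match_corpus(b$substances, b$corpus)
  expect_identical(as.integer(counts), as.integer(b$truth$pub_count))
})
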
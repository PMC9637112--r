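test_that("tonnage transform applies the band, largest-entry and sentinel rules", {
  expect_equal(tonnage_transform(100), 2)            # band 10-100 tonnes
  expect_equal(tonnage_transform(c(10, 1000, "confidential")), 3)
  expect_true(is.na(tonnage_transform("confidential")))
  expect_equal(tonnage_transform("none_or_intermediate"), 0)
  # confidential entries are dropped before the largest-entry rule, so a
  # substance with both sentinels still resolves to zero tonnage
  expect_equal(tonnage_transform(c("confidential", "none_or_intermediate")), 0)
  expect_error(tonnage_transform(c(-5)), "non-positive")
  expect_error(tonnage_transform("ten"), "sentinel")
  expect_error(tonnage_transform(character(0)), "empty")
})

test_that("tonnage transform ignores entry order and duplication", {
  entries <- c("10", "100000", "confidential", "none_or_intermediate", "100")
  base <- tonnage_transform(entries)
  set.seed(5)
  for (i in 1:10) {
    expect_equal(tonnage_transform(sample(entries)), base)
  }
  expect_equal(tonnage_transform(rep(entries, 3)), base)
})

test_that("country transform is the square root of the combined count", {
  expect_equal(country_transform(0, 0), 0)
  expect_equal(country_transform(3, 1), 2)
  expect_equal(country_transform(c(1, 4), c(0, 5)), c(1, 3))
  expect_error(country_transform(-1, 0), "negative")
})

test_that("publication rank bins reproduce exactly at every boundary", {
  n <- c(0, 1, 10, 11, 100, 101, 1000, 1001, 1500)
  expect_identical(publication_rank(n), as.integer(c(0, 1, 1, 2, 2, 3, 3, 4, 4)))
  expect_true(is.na(publication_rank(NA)))
  expect_error(publication_rank(-1), "negative")
  # non-decreasing in the count
  set.seed(13)
  counts <- sort(sample(0:5000, 200))
  expect_true(all(diff(publication_rank(counts)) >= 0))
})

test_that("publication counting deduplicates per publication", {
  corpus <- make_corpus(c(
    "benzene exposure in workers",          # one synonym in title
    "no chemicals here at all",
    "phenylbenzene and benzene together",   # two synonyms, counts once
    "the benzenesque compound",             # no word-boundary match
    "BENZENE in upper case"
  ))
  expect_equal(count_publications(c("benzene", "phenylbenzene"), corpus), 3)
  expect_equal(count_publications("toluene", corpus), 0)
  expect_true(is.na(count_publications(character(0), corpus)))
  expect_true(is.na(count_publications("  ;; ", corpus)))
})

test_that("multi-word and punctuated names match across fields", {
  corpus <- list(
    list(id = "p1", title = "Effects of lead oxide nanoparticles",
         abstract = "", keywords = list(), chemicals = list()),
    list(id = "p2", title = "Tinted glass and tin alloys",
         abstract = "", keywords = list("1,2-dichloroethane"), chemicals = list()),
    list(id = "p3", title = "misc", abstract = "",
         keywords = list(), chemicals = list("lead(II) oxide"))
  )
  class(corpus) <- "svhc_corpus"
  expect_equal(count_publications("lead oxide", corpus), 1)
  expect_equal(count_publications("1,2-dichloroethane", corpus), 1)
  expect_equal(count_publications("tin", corpus), 1)  # not "tinted"
  expect_equal(count_publications("lead ii oxide", corpus), 1)
})

test_that("indexed whole-table matching equals the naive full scan", {
  set.seed(23)
  words <- c("alpha", "beta", "gamma", "delta", "chloride", "oxide", "acid")
  subs <- validate_table(data.frame(
    substance_id = sprintf("EC-%02d", 1:12),
    name = sprintf("chem%02d", 1:12),
    synonyms = replicate(12, paste(sample(words, 2), collapse = " ")),
    stringsAsFactors = FALSE
  ), "substances")
  texts <- replicate(40, paste(sample(c(words, sprintf("chem%02d", 1:12), "filler"),
                                      8, replace = TRUE), collapse = " "))
  corpus <- make_corpus(texts)
  expect_identical(match_corpus(subs, corpus), naive_pub_scan(subs, corpus))
  # and agrees with per-substance counting
  for (i in c(1, 5, 12)) {
    syn <- c(subs$name[i], strsplit(subs$synonyms[i], ";")[[1]])
    expect_equal(unname(match_corpus(subs, corpus)[i]),
                 count_publications(syn, corpus))
  }
})

test_that("feature normalization uses fixed or in-sample constants as appropriate", {
  f <- data.frame(publication_rank = c(4, 0, 2),
                  tonnage_log = c(0, 2, 4),
                  cmr_score = c(0.2, 0.5, 1))
  nf <- normalize_features(f)
  expect_equal(nf$publication_rank, c(1, 0, 0.5))
  expect_equal(nf$tonnage_log, c(0, 0.5, 1))
  expect_equal(nf$cmr_score, f$cmr_score)  # already unit range
  consts <- attr(nf, "normalization")
  expect_equal(consts$max[consts$variable == "tonnage_log"], 4)
  # idempotent: a second pass is a no-op
  expect_identical(normalize_features(nf), nf)
  # zero-range variable is an error naming the variable
  f$countries_sqrt <- 1
  expect_error(normalize_features(f), "countries_sqrt")
  # unit-range violation is caught
  expect_error(normalize_features(data.frame(cmr_score = c(0.5, 1.2))), "cmr_score")
})

test_that("registry aggregation computes per-substance covariates", {
  reg <- validate_table(data.frame(
    substance_id = c("A", "A", "A", "B", "C"),
    tonnage_upper = c("10", "1000", "confidential", "none_or_intermediate", "confidential"),
    country = c("SE", "DE", "FR", "", "NO"),
    active = c(1, 0, 1, 0, 1),
    stringsAsFactors = FALSE
  ), "registry")
  rc <- registry_covariates(reg)
  a <- rc[rc$substance_id == "A", ]
  expect_equal(a$tonnage_log, 3)
  expect_equal(a$n_countries_active, 2)
  expect_equal(a$n_countries_inactive, 1)
  expect_equal(a$countries_sqrt, sqrt(3))
  expect_equal(rc$tonnage_log[rc$substance_id == "B"], 0)
  expect_equal(rc$countries_sqrt[rc$substance_id == "B"], 0)
  expect_true(is.na(rc$tonnage_log[rc$substance_id == "C"]))
  expect_error(registry_covariates(reg, eea_max = 2), "eea_max")
})
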
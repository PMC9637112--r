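# Fixtures built in code and independent oracles used across test files.

# a complete notification profile with every fraction zero unless overridden
make_profile <- function(...) {
  base <- stats::setNames(as.list(rep(0, 8)), c(
    "frac_c_warning", "frac_c_danger", "frac_m_warning", "frac_m_danger",
    "frac_r_warning", "frac_r_danger", "frac_env_acute", "frac_env_chronic"
  ))
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base)
}

make_membership <- function(ids, cl = character(0), al = character(0),
                            sin = character(0), prio = character(0),
                            reach = ids) {
  validate_table(data.frame(
    substance_id = ids,
    in_reach = as.integer(ids %in% reach),
    in_cl = as.integer(ids %in% cl),
    in_al = as.integer(ids %in% al),
    in_sin = as.integer(ids %in% sin),
    in_prio = as.integer(ids %in% prio),
    stringsAsFactors = FALSE
  ), "membership")
}

make_features <- function(ids, ...) {
  data.frame(substance_id = ids, ..., stringsAsFactors = FALSE)
}

make_corpus <- function(texts, chemicals = NULL) {
  recs <- lapply(seq_along(texts), function(i) list(
    id = sprintf("pub-%03d", i),
    title = texts[i],
    abstract = "",
    keywords = list(),
    chemicals = if (is.null(chemicals)) list() else as.list(chemicals[[i]])
  ))
  structure(recs, class = "svhc_corpus")
}

# brute-force Venn oracle: counts by explicit set algebra over ids
venn_oracle <- function(membership) {
  sets <- list(
    reach = membership$substance_id[membership$in_reach],
    cl = membership$substance_id[membership$in_cl],
    sin = membership$substance_id[membership$in_sin],
    prio = membership$substance_id[membership$in_prio]
  )
  grid <- expand.grid(reach = c(FALSE, TRUE), cl = c(FALSE, TRUE),
                      sin = c(FALSE, TRUE), prio = c(FALSE, TRUE))
  counts <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ids <- membership$substance_id
    for (s in names(sets)) {
      ids <- if (grid[[s]][g]) intersect(ids, sets[[s]]) else setdiff(ids, sets[[s]])
    }
    counts[g] <- length(ids)
  }
  cbind(grid, count = counts)
}

# independent log-likelihood maximizer for a single-covariate logistic model:
# coarse grid then iterative refinement, no glm anywhere
grid_loglik_oracle <- function(y, x, span = 20, steps = 6) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0)
  width <- span
  best <- c(NA, NA, -Inf)
  for (s in seq_len(steps)) {
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    for (b0 in b0s) for (b1 in b1s) {
      v <- ll(b0, b1)
      if (v > best[3]) best <- c(b0, b1, v)
    }
    centre <- best[1:2]
    width <- width / 8
  }
  list(b0 = best[1], b1 = best[2], loglik = best[3])
}

# hand-computed Welch statistic (closed form)
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

# naive O(records x synonyms) corpus scan with the package's token semantics,
# implemented independently (regex on padded normalized strings)
naive_pub_scan <- function(substances, corpus) {
  out <- integer(nrow(substances))
  for (i in seq_len(nrow(substances))) {
    syn <- c(substances$name[i],
             strsplit(substances$synonyms[i], ";", fixed = TRUE)[[1]])
    syn <- unique(normalize_text(syn))
    syn <- syn[nzchar(syn)]
    if (length(syn) == 0) { out[i] <- NA_integer_; next }
    n_hit <- 0L
    for (rec in corpus) {
      txt <- paste(rec$title, rec$abstract,
                   paste(unlist(rec$keywords), collapse = " "),
                   paste(unlist(rec$chemicals), collapse = " "))
      txt <- paste0(" ", normalize_text(txt), " ")
      hit <- FALSE
      for (s in syn) {
        if (grepl(paste0(" ", s, " "), txt, fixed = TRUE)) { hit <- TRUE; break }
      }
      if (hit) n_hit <- n_hit + 1L
    }
    out[i] <- n_hit
  }
  names(out) <- substances$substance_id
  out
}

# small random membership table for property tests
random_membership <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))
  cl <- ids[runif(n) < 0.2]
  make_membership(
    ids,
    cl = cl,
    al = sample(cl, size = floor(length(cl) / 3)),
    sin = ids[runif(n) < 0.3],
    prio = ids[runif(n) < 0.25],
    reach = ids[runif(n) < 0.9 | ids %in% cl]
  )
}
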
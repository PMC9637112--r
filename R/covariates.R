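# Economic and knowledge covariates: tonnage band, registrant-country count,
# grouped publication rank, and feature normalization.

#' Log10 tonnage from the registry entries of one substance
#'
#' Applies the study's tonnage rules to the (possibly multiple) registry
#' entries of a single substance: confidential entries are discarded first;
#' if any numeric upper tonnage bound remains, the result is log10 of the
#' largest one (a band of 10-100 tonnes, upper bound 100, maps to 2); if only
#' `none_or_intermediate` entries remain (no production, or intermediate use
#' only) the tonnage is zero; if every entry was confidential there is no
#' data and the result is missing.
#'
#' @param entries vector of upper tonnage bounds: positive numbers (tonnes) or
#'   the sentinels `"none_or_intermediate"` / `"confidential"`. Order and
#'   duplication are irrelevant.
#' @return a single numeric value (log10 tonnes), 0, or `NA`.
#' @examples
#' tonnage_transform(100)                       # 2
#' tonnage_transform(c(10, 1000, "confidential"))  # 3
#' tonnage_transform("confidential")            # NA
#' @export
tonnage_transform <- function(entries) {
  if (length(entries) == 0) stop("tonnage_transform: empty entry list", call. = FALSE)
  e <- trimws(as.character(entries))
  is_conf <- e == "confidential"
  is_none <- e == "none_or_intermediate"
  num <- suppressWarnings(as.numeric(e))
  is_num <- !is_conf & !is_none & !is.na(num)
  if (any(!is_conf & !is_none & !is_num)) {
    bad <- e[!is_conf & !is_none & !is_num][1]
    stop(sprintf("validation error: tonnage entry '%s' is neither numeric nor a known sentinel", bad),
         call. = FALSE)
  }
  if (any(is_num & num <= 0)) {
    stop("validation error: non-positive tonnage upper bound", call. = FALSE)
  }
  if (any(is_num)) return(log10(max(num[is_num])))
  if (any(is_none)) return(0)
  NA_real_
}

#' Square-root transformed registrant-country count
#'
#' A country counts as producing/importing a substance when it has active or
#' inactive registrants; the transform is the square root of the total count,
#' which stabilizes the variance of the skewed country distribution.
#'
#' @param n_active,n_inactive non-negative integer counts (vectorized).
#' @return numeric vector, `sqrt(n_active + n_inactive)`.
#' @export
country_transform <- function(n_active, n_inactive = 0) {
  if (any(n_active < 0, na.rm = TRUE) || any(n_inactive < 0, na.rm = TRUE)) {
    stop("validation error: negative country count", call. = FALSE)
  }
  sqrt(n_active + n_inactive)
}

#' Grouped publication rank
#'
#' Bins a publication count into the five-level knowledge rank: 0 for no
#' publications ("no information"), 1 for 1-10, 2 for 11-100, 3 for 101-1000
#' and 4 for more than 1000 publications. Boundaries are inclusive on the
#' upper end as listed (exactly 1000 publications is still rank 3). Missing
#' counts stay missing.
#'
#' @param n_publications non-negative integer vector (or `NA`).
#' @return integer rank vector in 0-4 (or `NA`).
#' @export
publication_rank <- function(n_publications) {
  n <- as.numeric(n_publications)
  if (any(n < 0, na.rm = TRUE)) {
    stop("validation error: negative publication count", call. = FALSE)
  }
  r <- findInterval(n, c(1, 11, 101, 1001))
  r[is.na(n)] <- NA_integer_
  as.integer(r)
}

#' Economic covariates aggregated from a registry table
#'
#' Groups the per-entry registry rows by substance and applies
#' [tonnage_transform()] (largest-entry rule with the sentinel conventions)
#' and [country_transform()] (distinct countries with at least one active or
#' inactive registrant).
#'
#' @param registry validated registry table.
#' @param eea_max maximum plausible number of EEA countries (validation bound).
#' @return data.frame: `substance_id`, `tonnage_log`, `n_countries_active`,
#'   `n_countries_inactive`, `countries_sqrt`.
#' @export
registry_covariates <- function(registry, eea_max = 30) {
  idx <- split(seq_len(nrow(registry)), registry$substance_id)
  ids <- names(idx)
  tonnage_log <- vapply(idx, function(i) tonnage_transform(registry$tonnage_upper[i]),
                        numeric(1))
  n_act <- vapply(idx, function(i) {
    length(unique(registry$country[i][registry$active[i] & nzchar(registry$country[i])]))
  }, integer(1))
  n_any <- vapply(idx, function(i) {
    length(unique(registry$country[i][nzchar(registry$country[i])]))
  }, integer(1))
  n_inact <- n_any - n_act
  if (any(n_any > eea_max)) {
    stop(sprintf("validation error: substance '%s' has registrants in %d countries (> eea_max = %d)",
                 ids[which.max(n_any)], max(n_any), eea_max), call. = FALSE)
  }
  data.frame(
    substance_id = ids,
    tonnage_log = unname(tonnage_log),
    n_countries_active = unname(n_act),
    n_countries_inactive = unname(n_inact),
    countries_sqrt = country_transform(unname(n_act), unname(n_inact)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Normalize model covariates to \[0, 1\]
#'
#' Applies the per-variable normalization the regression models expect:
#' hazard scores and disaggregated fractions are already in \[0, 1\] and pass
#' through (`"unit"`); the publication rank is divided by its fixed
#' theoretical maximum of 4 (`"rank4"`); `tonnage_log` and `countries_sqrt`
#' have no theoretical range and are min-max scaled over the comparison
#' sample (`"minmax"`). The constants used are recorded in the
#' `"normalization"` attribute (and belong in the run manifest). A table that
#' already carries that attribute is returned unchanged, so normalizing twice
#' is idempotent.
#'
#' @param features data.frame of numeric covariates (a `substance_id` column,
#'   if present, is carried through untouched).
#' @param scheme optional named character vector overriding the per-variable
#'   scheme (`"unit"`, `"rank4"`, `"minmax"`).
#' @return data.frame of the same shape with normalized columns and a
#'   `"normalization"` attribute (data.frame: variable, scheme, min, max).
#' @export
normalize_features <- function(features, scheme = NULL) {
  if (!is.null(attr(features, "normalization"))) return(features)
  vars <- setdiff(names(features), "substance_id")
  default_scheme <- function(v) {
    if (v %in% c("cmr_score", "env_score", names(DISAGGREGATED_VARS))) "unit"
    else if (v == "publication_rank") "rank4"
    else "minmax"
  }
  sch <- vapply(vars, function(v) scheme[v] %||% default_scheme(v), character(1))
  sch[is.na(sch)] <- vapply(vars[is.na(sch)], default_scheme, character(1))
  consts <- data.frame(variable = vars, scheme = unname(sch),
                       min = NA_real_, max = NA_real_, stringsAsFactors = FALSE)
  out <- features
  for (j in seq_along(vars)) {
    v <- vars[j]
    x <- as.numeric(features[[v]])
    switch(sch[[j]],
      unit = {
        if (any(x < 0 | x > 1, na.rm = TRUE)) {
          stop(sprintf("variable '%s' marked unit-range but lies outside [0, 1]", v),
               call. = FALSE)
        }
        consts$min[j] <- 0; consts$max[j] <- 1
      },
      rank4 = {
        x <- x / 4
        consts$min[j] <- 0; consts$max[j] <- 4
      },
      minmax = {
        rng <- range(x, na.rm = TRUE)
        if (!all(is.finite(rng)) || rng[1] == rng[2]) {
          stop(sprintf("variable '%s' has zero range; min-max normalization undefined", v),
               call. = FALSE)
        }
        x <- (x - rng[1]) / (rng[2] - rng[1])
        consts$min[j] <- rng[1]; consts$max[j] <- rng[2]
      }
    )
    out[[v]] <- x
  }
  attr(out, "normalization") <- consts
  out
}

#' Assemble the model feature table from the input tables
#'
#' Joins hazard scores, economic covariates and the publication rank into one
#' raw (unnormalized) feature table over the registry universe. Publication
#' counts come either from corpus matching (`substances` + `corpus`) or from a
#' precomputed named vector `pub_counts`; substances whose names never match
#' the corpus get a count of 0 ("no information"), while substances with no
#' usable synonyms get a missing count.
#'
#' @param registry validated registry table.
#' @param notifications validated notifications table.
#' @param substances substances table (ids, names, synonyms); optional when
#'   `pub_counts` is supplied.
#' @param corpus corpus record list; optional when `pub_counts` is supplied.
#' @param model `"aggregate"` for the CMR + environmental scores,
#'   `"disaggregated"` for the eight individual hazard variables.
#' @param pub_counts optional named (by substance_id) publication-count vector.
#' @param eea_max passed to [registry_covariates()].
#' @return data.frame: `substance_id`, hazard variables per `model`,
#'   `tonnage_log`, `countries_sqrt`, `publication_rank` (raw scales).
#' @export
build_features <- function(registry, notifications, substances = NULL,
                           corpus = NULL, model = c("aggregate", "disaggregated"),
                           pub_counts = NULL, eea_max = 30) {
  model <- match.arg(model)
  econ <- registry_covariates(registry, eea_max = eea_max)
  haz <- hazard_scores(notifications)
  if (is.null(pub_counts)) {
    if (is.null(substances) || is.null(corpus)) {
      stop("either pub_counts or both substances and corpus must be supplied",
           call. = FALSE)
    }
    pub_counts <- match_corpus(substances, corpus)
  }
  ids <- econ$substance_id
  hz <- haz[match(ids, haz$substance_id), , drop = FALSE]
  hazard_cols <- if (model == "aggregate") c("cmr_score", "env_score")
                 else names(DISAGGREGATED_VARS)
  out <- data.frame(substance_id = ids, stringsAsFactors = FALSE)
  for (col in hazard_cols) out[[col]] <- hz[[col]]
  out$tonnage_log <- econ$tonnage_log
  out$countries_sqrt <- econ$countries_sqrt
  out$publication_rank <- publication_rank(unname(pub_counts[ids]))
  rownames(out) <- NULL
  out
}
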
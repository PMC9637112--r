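# Hazard scores from GHS classification-and-labelling notification fractions.
#
# Each substance carries, for the three CMR properties (carcinogenicity C,
# mutagenicity M, reproductive toxicity R) crossed with the GHS signal words
# ("warning", "danger"), the fraction of notifying firms labelling it with the
# corresponding hazard codes, plus acute and chronic aquatic-hazard fractions.

CMR_COLS <- c("frac_c_warning", "frac_c_danger",
              "frac_m_warning", "frac_m_danger",
              "frac_r_warning", "frac_r_danger")
CMR_WARNING_COLS <- c("frac_c_warning", "frac_m_warning", "frac_r_warning")
CMR_DANGER_COLS  <- c("frac_c_danger", "frac_m_danger", "frac_r_danger")
ENV_COLS <- c("frac_env_acute", "frac_env_chronic")

DISAGGREGATED_VARS <- c(
  c_warning = "frac_c_warning", c_danger = "frac_c_danger",
  m_warning = "frac_m_warning", m_danger = "frac_m_danger",
  r_warning = "frac_r_warning", r_danger = "frac_r_danger",
  env_acute = "frac_env_acute", env_chronic = "frac_env_chronic"
)

profile_matrix <- function(profile, cols) {
  if (is.numeric(profile) && !is.null(names(profile))) {
    profile <- as.data.frame(as.list(profile))
  }
  miss <- setdiff(cols, names(profile))
  if (length(miss) > 0) {
    stop(sprintf("notification profile lacks column '%s'", miss[1]), call. = FALSE)
  }
  m <- as.matrix(as.data.frame(profile)[cols])
  storage.mode(m) <- "double"
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("validation error: notification fraction outside [0, 1]", call. = FALSE)
  }
  m
}

#' CMR hazard score
#'
#' Sums the six CMR notification fractions with "danger" fractions weighted
#' twice ("danger" flags the more severe GHS hazard categories) and divides by
#' the score's attainable maximum so the result lies in \[0, 1\]:
#' \deqn{\mathrm{CMR} = \frac{\sum_{p \in \{C,M,R\}} f_{p,\mathrm{warning}} + 2 f_{p,\mathrm{danger}}}{6}.}
#' With the default theoretical normalizer the maximum is 6 (three properties,
#' maximal weighted contribution 2 each); `normalizer = "empirical"` instead
#' divides by the largest weighted sum observed in the supplied profiles.
#'
#' A missing fraction makes the score missing (it propagates to listwise
#' deletion downstream); substances absent from the classification and
#' labelling inventory therefore get a missing, not zero, score.
#'
#' @param profile data.frame (or named numeric vector for a single substance)
#'   with the six columns `frac_c_warning`, `frac_c_danger`, `frac_m_warning`,
#'   `frac_m_danger`, `frac_r_warning`, `frac_r_danger`, values in \[0, 1\].
#' @param normalizer `"theoretical"` (default) or `"empirical"`.
#' @return numeric vector of scores in \[0, 1\].
#' @examples
#' cmr_score(c(frac_c_warning = 0, frac_c_danger = 0.5,
#'             frac_m_warning = 0.5, frac_m_danger = 0,
#'             frac_r_warning = 0, frac_r_danger = 0))  # (2*0.5 + 0.5)/6
#' @export
cmr_score <- function(profile, normalizer = c("theoretical", "empirical")) {
  normalizer <- match.arg(normalizer)
  w <- profile_matrix(profile, CMR_WARNING_COLS)
  d <- profile_matrix(profile, CMR_DANGER_COLS)
  weighted <- rowSums(w) + 2 * rowSums(d)
  denom <- if (normalizer == "theoretical") 6
           else max(weighted, na.rm = TRUE)
  if (!is.finite(denom) || denom == 0) denom <- 6
  unname(weighted / denom)
}

#' Environmental hazard score
#'
#' Mean of the acute and chronic aquatic-hazard notification fractions; the
#' two enter unweighted because the underlying GHS aquatic codes share the
#' same signal word. Range \[0, 1\]; missingness propagates as for
#' [cmr_score()].
#'
#' @inheritParams cmr_score
#' @param profile data.frame or named numeric vector with `frac_env_acute`
#'   and `frac_env_chronic`.
#' @return numeric vector of scores in \[0, 1\].
#' @export
env_score <- function(profile, normalizer = c("theoretical", "empirical")) {
  normalizer <- match.arg(normalizer)
  m <- profile_matrix(profile, ENV_COLS)
  s <- rowSums(m)
  denom <- if (normalizer == "theoretical") 2 else max(s, na.rm = TRUE)
  if (!is.finite(denom) || denom == 0) denom <- 2
  unname(s / denom)
}

#' Disaggregated hazard variables
#'
#' Passes the eight individual notification fractions through as model
#' variables (C/M/R crossed with warning/danger, plus acute and chronic
#' environmental hazard), renamed to the analysis variable names
#' (`c_warning`, ..., `env_chronic`). Missingness is per variable.
#'
#' @param profile data.frame with the eight fraction columns.
#' @return data.frame with eight columns, one row per substance.
#' @export
disaggregated_scores <- function(profile) {
  m <- profile_matrix(profile, unname(DISAGGREGATED_VARS))
  out <- as.data.frame(m)
  names(out) <- names(DISAGGREGATED_VARS)
  rownames(out) <- NULL
  out
}

#' Hazard score table for a notifications table
#'
#' Convenience wrapper computing [cmr_score()], [env_score()] and
#' [disaggregated_scores()] for every substance in a validated notifications
#' table.
#'
#' @param notifications validated notifications table.
#' @param normalizer passed to the score functions.
#' @return data.frame: `substance_id`, `cmr_score`, `env_score`, and the
#'   eight disaggregated variables.
#' @export
hazard_scores <- function(notifications, normalizer = "theoretical") {
  out <- data.frame(
    substance_id = notifications$substance_id,
    cmr_score = cmr_score(notifications, normalizer),
    env_score = env_score(notifications, normalizer),
    stringsAsFactors = FALSE
  )
  cbind(out, disaggregated_scores(notifications))
}
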
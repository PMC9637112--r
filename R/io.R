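# Input tables, validation, sample construction and list-overlap counts.
#
# All tables are plain data.frames keyed by `substance_id` (an EC-number-like
# opaque string). File dialect: UTF-8 CSV or TSV with a mandatory header row,
# "" = missing, booleans as 0/1.

MEMBERSHIP_COLS <- c(
  reach = "in_reach", cl = "in_cl", al = "in_al", sin = "in_sin", prio = "in_prio"
)

FRACTION_COLS <- c(
  "frac_c_warning", "frac_c_danger",
  "frac_m_warning", "frac_m_danger",
  "frac_r_warning", "frac_r_danger",
  "frac_env_acute", "frac_env_chronic"
)

TONNAGE_SENTINELS <- c("none_or_intermediate", "confidential")

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

require_columns <- function(df, cols, schema) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("schema '%s': missing mandatory column '%s'", schema, miss[1]),
         call. = FALSE)
  }
  invisible(df)
}

check_unique_ids <- function(ids, schema) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("validation error: duplicate substance_id in %s table: '%s'",
                 schema, dup[1]), call. = FALSE)
  }
  if (any(is.na(ids) | !nzchar(ids))) {
    stop(sprintf("validation error: empty substance_id in %s table", schema),
         call. = FALSE)
  }
  invisible(ids)
}

as_flag <- function(x, col) {
  if (is.logical(x)) {
    if (anyNA(x)) {
      stop(sprintf("validation error: column '%s' must be 0/1 with no missing values", col),
           call. = FALSE)
    }
    return(x)
  }
  v <- suppressWarnings(as.integer(as.character(x)))
  if (any(is.na(v)) || !all(v %in% c(0L, 1L))) {
    stop(sprintf("validation error: column '%s' must be 0/1 with no missing values", col),
         call. = FALSE)
  }
  as.logical(v)
}

as_fraction <- function(x, col) {
  v <- suppressWarnings(as.numeric(as.character(x)))
  bad_parse <- !is.na(as.character(x)) & nzchar(as.character(x)) & is.na(v)
  if (any(bad_parse)) {
    stop(sprintf("validation error: column '%s' contains non-numeric values", col),
         call. = FALSE)
  }
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    stop(sprintf("validation error: column '%s' has fractions outside [0, 1]", col),
         call. = FALSE)
  }
  v
}

#' Read and validate an input table
#'
#' Reads one of the pipeline's input tables and enforces its schema. Unknown
#' columns are preserved but ignored by downstream operations. The delimiter
#' (comma or tab) is sniffed from the header line unless given.
#'
#' Schemas:
#' \describe{
#'   \item{registry}{one row per REACH registry entry: `substance_id`,
#'     `tonnage_upper` (positive number, or sentinel `none_or_intermediate` /
#'     `confidential`), `country` (may be empty), `active` (0/1). Repeated
#'     `substance_id` is expected (multiple entries per substance); exactly
#'     duplicated rows are rejected.}
#'   \item{notifications}{`substance_id` plus the eight GHS notification
#'     fraction columns (`frac_c_warning`, ..., `frac_env_chronic`), each in
#'     \[0, 1\] or missing. A substance absent from the classification and
#'     labelling inventory has all eight missing; a logical `has_cl_entry`
#'     column is derived.}
#'   \item{membership}{`substance_id` plus 0/1 flags `in_reach`, `in_cl`,
#'     `in_al`, `in_sin`, `in_prio`. The Authorization List must be a subset
#'     of the Candidate List (validation error otherwise); a Candidate List
#'     substance not registered under REACH only raises a warning.}
#'   \item{substances}{`substance_id`, `name`, `synonyms`
#'     (semicolon-separated chemical names used for corpus matching).}
#'   \item{corpus}{JSON-lines publication records with fields `id`, `title`,
#'     `abstract`, `keywords` (array), `chemicals` (array).}
#' }
#'
#' @param path file path.
#' @param schema one of `"registry"`, `"notifications"`, `"membership"`,
#'   `"substances"`, `"corpus"`.
#' @param delim optional delimiter override (`","` or `"\t"`).
#' @return validated data.frame (or, for `corpus`, a list of records).
#' @export
read_table <- function(path,
                       schema = c("registry", "notifications", "membership",
                                  "substances", "corpus"),
                       delim = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (schema == "corpus") return(read_corpus(path))
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          na.strings = "", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", fileEncoding = "UTF-8")
  out <- validate_table(df, schema)
  sv_msg("read %d rows from %s (schema %s)", nrow(out), path, schema)
  out
}

#' Validate an in-memory input table against a schema
#'
#' Same checks as [read_table()] applies after parsing; usable directly on
#' tables built in code (e.g. by [simulate_registry()]).
#'
#' @param df data.frame.
#' @param schema schema name, as in [read_table()].
#' @return the validated, type-coerced data.frame.
#' @export
validate_table <- function(df, schema) {
  switch(schema,
    registry = validate_registry(df),
    notifications = validate_notifications(df),
    membership = validate_membership(df),
    substances = validate_substances(df),
    stop(sprintf("unknown schema '%s'", schema), call. = FALSE)
  )
}

validate_registry <- function(df) {
  require_columns(df, c("substance_id", "tonnage_upper", "country", "active"), "registry")
  df$substance_id <- as.character(df$substance_id)
  if (any(is.na(df$substance_id) | !nzchar(df$substance_id))) {
    stop("validation error: empty substance_id in registry table", call. = FALSE)
  }
  ton <- as.character(df$tonnage_upper)
  is_sent <- ton %in% TONNAGE_SENTINELS
  num <- suppressWarnings(as.numeric(ton))
  bad <- !is_sent & (is.na(ton) | is.na(num))
  if (any(bad)) {
    stop(sprintf("validation error: tonnage_upper value '%s' is neither numeric nor a known sentinel",
                 ton[bad][1]), call. = FALSE)
  }
  if (any(!is_sent & num <= 0)) {
    stop("validation error: non-positive numeric tonnage_upper", call. = FALSE)
  }
  df$tonnage_upper <- ton
  df$country <- ifelse(is.na(df$country), "", as.character(df$country))
  act <- df$active
  if (!is.logical(act)) {
    act <- as.character(act)
    act[is.na(act)] <- "0"
  }
  df$active <- as_flag(act, "active")
  key <- do.call(paste, c(df[c("substance_id", "tonnage_upper", "country", "active")],
                          sep = "\r"))
  if (anyDuplicated(key) > 0) {
    stop("validation error: exactly duplicated registry rows", call. = FALSE)
  }
  attr(df, "schema") <- "registry"
  df
}

validate_notifications <- function(df) {
  require_columns(df, c("substance_id", FRACTION_COLS), "notifications")
  df$substance_id <- as.character(df$substance_id)
  check_unique_ids(df$substance_id, "notifications")
  for (col in FRACTION_COLS) df[[col]] <- as_fraction(df[[col]], col)
  df$has_cl_entry <- rowSums(!is.na(as.matrix(df[FRACTION_COLS]))) > 0
  attr(df, "schema") <- "notifications"
  df
}

validate_membership <- function(df) {
  require_columns(df, c("substance_id", unname(MEMBERSHIP_COLS)), "membership")
  df$substance_id <- as.character(df$substance_id)
  check_unique_ids(df$substance_id, "membership")
  for (col in MEMBERSHIP_COLS) df[[col]] <- as_flag(df[[col]], col)
  if (any(df$in_al & !df$in_cl)) {
    bad <- df$substance_id[df$in_al & !df$in_cl][1]
    stop(sprintf("validation error: substance '%s' is on the Authorization List but not the Candidate List (AL must be a subset of CL)",
                 bad), call. = FALSE)
  }
  if (any(df$in_cl & !df$in_reach)) {
    warning(sprintf("%d Candidate List substance(s) not registered under REACH",
                    sum(df$in_cl & !df$in_reach)), call. = FALSE)
  }
  attr(df, "schema") <- "membership"
  df
}

validate_substances <- function(df) {
  require_columns(df, c("substance_id", "name", "synonyms"), "substances")
  df$substance_id <- as.character(df$substance_id)
  check_unique_ids(df$substance_id, "substances")
  df$name <- as.character(df$name)
  df$synonyms <- ifelse(is.na(df$synonyms), "", as.character(df$synonyms))
  attr(df, "schema") <- "substances"
  df
}

read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    miss <- setdiff(c("id", "title", "abstract", "keywords", "chemicals"), names(r))
    if (length(miss) > 0) {
      stop(sprintf("schema 'corpus': record %d missing mandatory field '%s'", i, miss[1]),
           call. = FALSE)
    }
  }
  sv_msg("read %d corpus records from %s", length(recs), path)
  structure(recs, class = "svhc_corpus")
}

resolve_list <- function(name) {
  name <- tolower(as.character(name))
  if (!name %in% names(MEMBERSHIP_COLS)) {
    stop(sprintf("unknown list '%s' (known: %s)", name,
                 paste(names(MEMBERSHIP_COLS), collapse = ", ")), call. = FALSE)
  }
  name
}

#' Construct a comparison sample for a focal-vs-reference list analysis
#'
#' Builds the binary-outcome sample used by the logistic models. The sample
#' universe is every member of the reference list when the reference is
#' `"reach"` (so e.g. CL vs REACH uses all REACH substances with the Candidate
#' List flag as the outcome); for the expert lists (SIN, PRIO) the universe is
#' the union of the reference and focal lists, so focal substances absent from
#' the reference list are positives and reference substances absent from the
#' focal list are negatives.
#'
#' @param membership validated membership table.
#' @param features feature table with a `substance_id` column plus numeric
#'   covariates (see [build_features()]).
#' @param focal focal list name (`"cl"`, `"al"`, ...); outcome = 1 for members.
#' @param reference reference list name; must differ from `focal`.
#' @param drop_incomplete drop rows with any missing covariate (listwise
#'   deletion); the dropped count is kept in `$n_dropped`.
#' @return an object of class `comparison_sample`: a list with `outcome`
#'   (integer 0/1), `features` (covariate data.frame, no id column),
#'   `substance_id`, `sample_label`, `n_dropped`.
#' @export
build_sample <- function(membership, features, focal, reference,
                         drop_incomplete = TRUE) {
  focal <- resolve_list(focal)
  reference <- resolve_list(reference)
  if (identical(focal, reference)) {
    stop("focal and reference lists must differ", call. = FALSE)
  }
  fcol <- MEMBERSHIP_COLS[[focal]]
  rcol <- MEMBERSHIP_COLS[[reference]]
  keep <- if (reference == "reach") membership[[rcol]]
          else membership[[rcol]] | membership[[fcol]]
  m <- membership[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("empty comparison sample", call. = FALSE)
  if (anyDuplicated(m$substance_id) > 0) {
    stop("validation error: duplicate substance_id in comparison sample", call. = FALSE)
  }
  fcols <- setdiff(names(features), "substance_id")
  idx <- match(m$substance_id, features$substance_id)
  feat <- features[idx, fcols, drop = FALSE]
  outcome <- as.integer(m[[fcol]])
  n_dropped <- 0L
  if (drop_incomplete) {
    cc <- stats::complete.cases(feat)
    n_dropped <- sum(!cc)
    feat <- feat[cc, , drop = FALSE]
    outcome <- outcome[cc]
    m <- m[cc, , drop = FALSE]
  }
  if (sum(outcome == 1L) == 0) stop("empty focal class in comparison sample", call. = FALSE)
  if (sum(outcome == 0L) == 0) stop("empty reference class in comparison sample", call. = FALSE)
  rownames(feat) <- NULL
  sv_msg("sample %s_vs_%s: n = %d (%d positives, %d rows dropped as incomplete)",
         focal, reference, length(outcome), sum(outcome), n_dropped)
  structure(list(
    outcome = outcome,
    features = feat,
    substance_id = m$substance_id,
    sample_label = paste0(toupper(focal), "_vs_", toupper(reference)),
    n_dropped = n_dropped
  ), class = "comparison_sample")
}

#' Counts for every region of the four-list Venn diagram
#'
#' Tabulates the 16 regions of the REACH / Candidate List / SIN / PRIO
#' membership Venn diagram plus the derived counts the study design cares
#' about (substances on all four lists, Candidate List substances off both
#' expert lists, REACH substances on no hazard list).
#'
#' @param membership validated membership table.
#' @return list with `regions` (data.frame of the 16 combinations and their
#'   counts, summing to the number of substances), `total`, `on_all_lists`,
#'   `cl_not_sin_prio`, `reach_unlisted`.
#' @export
overlap_counts <- function(membership) {
  flags <- data.frame(
    reach = membership$in_reach,
    cl = membership$in_cl,
    sin = membership$in_sin,
    prio = membership$in_prio
  )
  grid <- expand.grid(reach = c(FALSE, TRUE), cl = c(FALSE, TRUE),
                      sin = c(FALSE, TRUE), prio = c(FALSE, TRUE))
  key <- function(d) paste(as.integer(d$reach), as.integer(d$cl),
                           as.integer(d$sin), as.integer(d$prio))
  tab <- table(factor(key(flags), levels = key(grid)))
  regions <- cbind(grid, count = as.integer(tab))
  stopifnot(sum(regions$count) == nrow(membership))
  list(
    regions = regions,
    total = nrow(membership),
    on_all_lists = sum(flags$reach & flags$cl & flags$sin & flags$prio),
    cl_not_sin_prio = sum(flags$cl & !flags$sin & !flags$prio),
    reach_unlisted = sum(flags$reach & !flags$cl & !flags$sin & !flags$prio)
  )
}
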
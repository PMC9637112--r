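`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize free text for chemical-name matching
#'
#' Lowercases, replaces every run of non-alphanumeric characters by a single
#' space and trims. After this transform, "word boundaries" are exactly the
#' spaces, so name matching reduces to contiguous token-sequence search.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Fingerprint an R object for run manifests
#'
#' Small rolling hash over the serialized object; enough to detect that two
#' runs used different configurations, not a cryptographic digest.
#'
#' @param x any serializable R object.
#' @return 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  # skip the serialization header (R version bytes vary across interpreters)
  raw <- raw[-seq_len(min(14L, length(raw)))]
  b <- as.integer(raw)
  h <- 5381
  for (i in seq_along(b)) h <- (h * 33 + b[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}

sv_verbose <- function() isTRUE(getOption("svhcdrivers.verbose", FALSE))

sv_msg <- function(...) if (sv_verbose()) message(sprintf(...))

# run RNG-consuming code under a seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
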
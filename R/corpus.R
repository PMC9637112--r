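# Chemical-name matching against a publication corpus.
#
# Matching semantics: texts and names are passed through normalize_text()
# (lowercase, non-alphanumeric runs -> single space), and a name matches a
# publication when its token sequence occurs contiguously among the
# publication's tokens. This is a case-insensitive, whitespace-normalized,
# word-boundary-delimited substring match, so "tin" never matches "tinted".

corpus_record_text <- function(rec) {
  paste(rec$title %||% "", rec$abstract %||% "",
        paste(unlist(rec$keywords), collapse = " "),
        paste(unlist(rec$chemicals), collapse = " "))
}

corpus_search_strings <- function(corpus) {
  texts <- vapply(corpus, corpus_record_text, character(1))
  paste0(" ", normalize_text(texts), " ")
}

split_synonyms <- function(name, synonyms) {
  syn <- c(name, strsplit(synonyms %||% "", ";", fixed = TRUE)[[1]])
  syn <- normalize_text(syn)
  unique(syn[nzchar(syn)])
}

#' Count publications mentioning a substance
#'
#' Scans every corpus record for an occurrence of any of the substance's
#' names in the searched fields (title, abstract, keywords, chemical lists).
#' A publication counts once no matter how many names match or how often they
#' occur. This is the straightforward record-by-record scan; for whole-table
#' matching use [match_corpus()], which is index-based but returns identical
#' counts.
#'
#' @param synonyms character vector of chemical names for one substance.
#' @param corpus corpus record list (see [read_table()], schema `"corpus"`).
#' @return integer count of distinct matching publications; `NA` if no usable
#'   (non-empty after normalization) synonym remains.
#' @export
count_publications <- function(synonyms, corpus) {
  syn <- unique(normalize_text(synonyms))
  syn <- syn[nzchar(syn)]
  if (length(syn) == 0) return(NA_integer_)
  texts <- corpus_search_strings(corpus)
  hit <- rep(FALSE, length(texts))
  for (s in syn) {
    hit <- hit | grepl(paste0(" ", s, " "), texts, fixed = TRUE)
  }
  sum(hit)
}

#' Publication counts for a whole substances table
#'
#' Token n-gram index over the corpus: every record is tokenized once, and
#' names are matched by hashing their token sequences against the record's
#' n-grams, so the cost grows with corpus size rather than with
#' substances x records. Counts are identical to applying
#' [count_publications()] per substance.
#'
#' @param substances validated substances table (`substance_id`, `name`,
#'   `synonyms`).
#' @param corpus corpus record list.
#' @return named integer vector of publication counts keyed by substance_id;
#'   `NA` for substances without usable names.
#' @export
match_corpus <- function(substances, corpus) {
  syn_list <- mapply(split_synonyms, substances$name, substances$synonyms,
                     SIMPLIFY = FALSE)
  names(syn_list) <- substances$substance_id
  dict <- data.frame(
    syn = unlist(syn_list, use.names = FALSE),
    sub = rep(seq_along(syn_list), lengths(syn_list)),
    stringsAsFactors = FALSE
  )
  counts <- integer(nrow(substances))
  counts[lengths(syn_list) == 0] <- NA_integer_
  if (nrow(dict) == 0 || length(corpus) == 0) {
    names(counts) <- substances$substance_id
    return(counts)
  }
  dict$len <- lengths(strsplit(dict$syn, " ", fixed = TRUE))
  toks <- strsplit(normalize_text(vapply(corpus, corpus_record_text, character(1))),
                   " ", fixed = TRUE)
  flat <- unlist(toks, use.names = FALSE)
  rec_of <- rep.int(seq_along(toks), lengths(toks))
  pair_rec <- list()
  pair_sub <- list()
  for (n in sort(unique(dict$len))) {
    dn <- dict[dict$len == n, , drop = FALSE]
    m <- length(flat) - n + 1L
    if (m < 1L) next
    start <- seq_len(m)
    # n-gram stays within one record iff its first and last token share it
    ok <- rec_of[start] == rec_of[start + n - 1L]
    grams <- flat[start]
    if (n > 1L) {
      for (k in seq_len(n - 1L)) grams <- paste(grams, flat[start + k])
    }
    hit <- match(grams[ok], dn$syn)
    keep <- !is.na(hit)
    pair_rec[[length(pair_rec) + 1L]] <- rec_of[start][ok][keep]
    pair_sub[[length(pair_sub) + 1L]] <- dn$sub[hit[keep]]
  }
  pair_rec <- unlist(pair_rec, use.names = FALSE) %||% integer(0)
  pair_sub <- unlist(pair_sub, use.names = FALSE) %||% integer(0)
  if (length(pair_sub) > 0) {
    key <- !duplicated(paste(pair_rec, pair_sub))
    tab <- tabulate(pair_sub[key], nbins = nrow(substances))
    ok <- lengths(syn_list) > 0
    counts[ok] <- tab[ok]
  }
  names(counts) <- substances$substance_id
  counts
}
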
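# Semi-automated literature screening and eligibility scoring.
#
# Screening assigns each record (title + abstract) a relevance score from a
# keyword-to-weight map over word n-grams (n = 1..3); eligibility scans full
# texts for sentences that mention a feature synonym together with a numeric
# value and a unit of measurement. The shipped default lexicons cover the
# eight hyperthermia features (H, f, C_SPION, T, d_TEM, Ms, Hc, Mr) plus SAR;
# both maps are user-replaceable YAML/JSON because real screening vocabularies
# are corpus-specific.

#' Keyword-to-weight map for screening
#'
#' @param entries Named numeric vector: names are lowercase word n-grams
#'   (n = 1..3), values are nonnegative weights.
#' @return An object of class `keyword_map`.
#' @export
keyword_map <- function(entries) {
  if (!is.numeric(entries) || length(entries) == 0L || is.null(names(entries))) {
    stopf("entries must be a nonempty named numeric vector")
  }
  if (any(entries < 0) || anyNA(entries)) stopf("keyword weights must be >= 0")
  ngram_len <- lengths(strsplit(names(entries), "\\s+"))
  if (any(ngram_len < 1L | ngram_len > 3L)) {
    stopf("keywords must be 1-, 2- or 3-grams")
  }
  names(entries) <- tolower(names(entries))
  structure(entries, class = "keyword_map")
}

# Lowercase, map unicode minus/dashes to ascii, split into word-token runs;
# n-grams never cross punctuation boundaries, which keeps scoring additive
# over punctuation-separated concatenation.
tokenize_runs <- function(text) {
  text <- tolower(text)
  text <- gsub("−|–|—", "-", text)
  runs <- strsplit(text, "[^a-z0-9.+-]*[,;:()!?\"]+[^a-z0-9.+-]*|\\.\\s+", perl = TRUE)[[1]]
  lapply(runs, function(r) {
    toks <- strsplit(trimws(r), "\\s+")[[1]]
    toks[nzchar(toks)]
  })
}

count_ngram <- function(token_runs, ngram_tokens) {
  k <- length(ngram_tokens)
  total <- 0L
  for (toks in token_runs) {
    n <- length(toks)
    if (n < k) next
    if (k == 1L) {
      total <- total + sum(toks == ngram_tokens)
    } else {
      for (i in seq_len(n - k + 1L)) {
        if (all(toks[i:(i + k - 1L)] == ngram_tokens)) total <- total + 1L
      }
    }
  }
  total
}

#' Relevance score of a record under a keyword map
#'
#' The score is the weight-sum over every occurrence of every mapped n-gram in
#' the text (case-insensitive; occurrences, not distinct keywords, are
#' counted). Overlapping n-grams all count: a trigram occurrence also scores
#' any contained bigram that is separately present in the map.
#'
#' @param title_abstract Text of the record (title and abstract pasted).
#' @param map A [keyword_map()].
#' @return Nonnegative numeric score; 0 for empty text.
#' @examples
#' m <- keyword_map(c("hyperthermia" = 2, "iron oxide" = 3))
#' score_record("Iron oxide particles for hyperthermia", m)
#' @export
score_record <- function(title_abstract, map) {
  stopifnot(inherits(map, "keyword_map"))
  if (length(title_abstract) != 1L) stopf("title_abstract must be a single string")
  if (is.na(title_abstract) || !nzchar(trimws(title_abstract))) return(0)
  runs <- tokenize_runs(title_abstract)
  grams <- strsplit(names(map), "\\s+")
  sum(vapply(seq_along(map), function(i) {
    count_ngram(runs, grams[[i]]) * unclass(map)[i]
  }, numeric(1)))
}

#' Rank records by screening score and keep the top k
#'
#' @param records Data frame with columns `id`, `title`, `abstract` (or
#'   `id` and `text`).
#' @param map A [keyword_map()].
#' @param k Number of records to keep (>= 0).
#' @return The `id`s of the top-`k` records, in descending score order; ties
#'   are broken by input order (stable).
#' @export
rank_and_select <- function(records, map, k) {
  stopifnot(is.data.frame(records), is_number(k), k >= 0)
  text <- if ("text" %in% names(records)) {
    records$text
  } else {
    paste(records$title, records$abstract)
  }
  scores <- vapply(text, score_record, numeric(1), map = map, USE.NAMES = FALSE)
  ord <- order(-scores) # order() is stable: ties keep input order
  records$id[ord][seq_len(min(k, nrow(records)))]
}

number_pattern <- "[-+]?[0-9]+(?:\\.[0-9]+)?(?:[eE][-+]?[0-9]+)?"

#' Detect feature-reporting sentences in a full text
#'
#' A hit is emitted for every sentence that contains a feature synonym and a
#' numeric value immediately followed by one of that feature's units. Numbers
#' are parsed with decimal points and scientific notation; unicode minus signs
#' are normalized. Units that serve as unambiguous synonyms (e.g. kHz for the
#' field frequency) may be listed among a feature's synonyms.
#'
#' @param fulltext A single string; sentences are split on `.`, `?`, `!`
#'   followed by whitespace.
#' @param feature_lexicon Named list: feature id -> character vector of
#'   lowercase synonyms.
#' @param unit_lexicon Named list: feature id -> named character vector
#'   mapping lowercase unit surface forms to the canonical unit string.
#' @return A data frame of hits: `feature_name`, `value`, `unit`,
#'   `sentence_index`. Zero rows when nothing is found.
#' @export
detect_feature_sentences <- function(fulltext, feature_lexicon, unit_lexicon) {
  if (length(feature_lexicon) == 0L || length(unit_lexicon) == 0L) {
    stopf("lexicons must be nonempty")
  }
  txt <- gsub("−|–|—", "-", tolower(fulltext))
  sentences <- strsplit(txt, "(?<=[.?!])\\s+", perl = TRUE)[[1]]
  hits <- list()
  for (si in seq_along(sentences)) {
    sent <- sentences[si]
    for (feat in names(feature_lexicon)) {
      syns <- tolower(feature_lexicon[[feat]])
      if (!any(vapply(syns, function(s) grepl(s, sent, fixed = TRUE), logical(1)))) next
      units <- unit_lexicon[[feat]]
      if (is.null(units)) next
      for (uidx in seq_along(units)) {
        surface <- tolower(names(units)[uidx])
        pat <- paste0("(", number_pattern, ")\\s*", escape_regex(surface))
        m <- gregexpr(pat, sent, perl = TRUE)[[1]]
        if (m[1] == -1L) next
        starts <- attr(m, "capture.start")
        lens <- attr(m, "capture.length")
        for (j in seq_along(m)) {
          val <- as.numeric(substr(sent, starts[j, 1], starts[j, 1] + lens[j, 1] - 1L))
          hits[[length(hits) + 1L]] <- data.frame(
            feature_name = feat, value = val, unit = unname(units[uidx]),
            sentence_index = si, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(feature_name = character(0), value = numeric(0),
                      unit = character(0), sentence_index = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  # a (sentence, feature, value) reported with two surface forms of the same
  # canonical unit is one observation
  unique(out)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Article-by-feature occurrence matrix
#'
#' Counts, for each full text, the number of eligibility hits per feature -
#' the matrix behind a screening heatmap.
#'
#' @param fulltexts Character vector of full texts.
#' @param feature_lexicon,unit_lexicon As in [detect_feature_sentences()].
#' @return Integer matrix, articles x features.
#' @export
eligibility_matrix <- function(fulltexts, feature_lexicon, unit_lexicon) {
  feats <- names(feature_lexicon)
  out <- matrix(0L, nrow = length(fulltexts), ncol = length(feats),
                dimnames = list(NULL, feats))
  for (i in seq_along(fulltexts)) {
    h <- detect_feature_sentences(fulltexts[i], feature_lexicon, unit_lexicon)
    if (nrow(h) > 0L) {
      tab <- table(h$feature_name)
      out[i, names(tab)] <- as.integer(tab)
    }
  }
  out
}

#' Default screening lexicons
#'
#' Loads the keyword map, feature synonym lexicon and unit lexicon shipped
#' with the package (YAML under `extdata/screening/`). These cover the eight
#' predictive hyperthermia features plus SAR and are intended as replaceable
#' defaults.
#'
#' @return A list with elements `keyword_map` (a [keyword_map()]),
#'   `feature_lexicon` and `unit_lexicon`.
#' @export
default_screening_lexicons <- function() {
  dir <- system.file("extdata", "screening", package = "sarqspr")
  km <- yaml::read_yaml(file.path(dir, "keyword_map.yaml"))
  fl <- yaml::read_yaml(file.path(dir, "feature_lexicon.yaml"))
  ul_raw <- yaml::read_yaml(file.path(dir, "unit_lexicon.yaml"))
  ul <- lapply(ul_raw, function(x) unlist(x))
  list(
    keyword_map = keyword_map(unlist(km)),
    feature_lexicon = lapply(fl, unlist),
    unit_lexicon = ul
  )
}
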
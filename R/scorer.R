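#' Load a scoring dictionary
#'
#' Loads a LIWC-style category dictionary (`.dic` dialect, see [read_dic()])
#' together with composite-category rules. The default composite follows the
#' established convention that `biology` combines the `body`, `health`,
#' `sexual`, and `ingestion` word categories.
#'
#' The packaged fixture dictionary (`liwc_like.dic`) provides small open
#' word lists for `i`, `we`, `posemo`, `negemo`, `sadness`, `body`, `health`,
#' `sexual`, and `ingestion`. These are not the proprietary LIWC 2015 lists;
#' absolute scores are not LIWC-equivalent, but relative and longitudinal
#' behavior — what the analyses here use — is preserved.
#'
#' @param path Path to a `.dic` file; defaults to the packaged fixture.
#' @param composites Named list mapping composite category names to member
#'   category names.
#' @return An object of class `ba_dictionary`: `categories` (named list of
#'   term sets) and `composites`.
#' @export
load_dictionary <- function(path = system.file("extdata", "liwc_like.dic",
                                               package = "balex"),
                            composites = list(
                              biology = c("body", "health", "sexual", "ingestion"))) {
  categories <- read_dic(path)
  for (comp in names(composites)) {
    missing <- setdiff(composites[[comp]], names(categories))
    if (length(missing) > 0L) {
      stop("composite '", comp, "' references missing categories: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(categories = categories, composites = composites),
            class = "ba_dictionary")
}

#' @export
print.ba_dictionary <- function(x, ...) {
  cat("<ba_dictionary>", length(x$categories), "categories")
  if (length(x$composites)) {
    cat(";", length(x$composites), "composite(s):",
        paste(names(x$composites), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

# Resolve a category (base or composite) to its full term set.
category_terms <- function(dictionary, category) {
  if (category %in% names(dictionary$composites)) {
    members <- dictionary$composites[[category]]
    return(sort(unique(unlist(dictionary$categories[members], use.names = FALSE))))
  }
  if (!category %in% names(dictionary$categories)) {
    stop("unknown dictionary category: '", category, "'")
  }
  dictionary$categories[[category]]
}

# Count matches of a term set in a token sequence. Multiword phrases count
# as one match; a token consumed by a phrase match does not also match the
# same category as a single word (longest match wins, scanning left to
# right). Each token/phrase occurrence counts at most once per category.
count_matches <- function(tokens, terms) {
  n <- length(tokens)
  if (n == 0L || length(terms) == 0L) return(0L)
  has_phrase <- any(grepl(" ", terms, fixed = TRUE))
  if (!has_phrase) {
    return(sum(tokens %in% terms))
  }
  phrases <- strsplit(terms[grepl(" ", terms, fixed = TRUE)], " ", fixed = TRUE)
  singles <- terms[!grepl(" ", terms, fixed = TRUE)]
  max_len <- max(vapply(phrases, length, 1L))
  phrase_keys <- vapply(phrases, paste, "", collapse = " ")
  matches <- 0L
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    top <- min(max_len, n - i + 1L)
    if (top >= 2L) {
      for (len in seq(top, 2L, by = -1L)) {
        cand <- paste(tokens[i:(i + len - 1L)], collapse = " ")
        if (cand %in% phrase_keys) { hit_len <- len; break }
      }
    }
    if (hit_len > 0L) {
      matches <- matches + 1L
      i <- i + hit_len
    } else {
      if (tokens[i] %in% singles) matches <- matches + 1L
      i <- i + 1L
    }
  }
  matches
}

#' Score one document against one dictionary category
#'
#' Returns the percent of tokens in the document that match the category:
#' `100 * matches / token_count`. Single-word entries match exactly
#' (case-insensitively; documents are already lowercase); a multiword phrase
#' entry counts as one match. A 40-word document with 4 category hits scores
#' 10%.
#'
#' @param doc One pooled-document row (or a list with `tokens`,
#'   `token_count`), or a plain character vector of tokens.
#' @param dictionary A `ba_dictionary`, `ba_lexicon`, or named list of term
#'   sets.
#' @param category Category name (base or composite).
#' @return Percent in \[0, 100\]; `NA_real_` (with a warning) for an empty
#'   document, where the score is undefined.
#' @export
score_document <- function(doc, dictionary, category) {
  tokens <- doc_tokens(doc)
  if (length(tokens) == 0L) {
    warning("score is undefined for an empty document")
    return(NA_real_)
  }
  terms <- resolve_terms(dictionary, category)
  100 * count_matches(tokens, terms) / length(tokens)
}

doc_tokens <- function(doc) {
  if (is.character(doc)) return(doc)
  tk <- doc$tokens
  if (is.list(tk) && !is.character(tk)) tk <- tk[[1L]]
  tk
}

resolve_terms <- function(dictionary, category) {
  if (inherits(dictionary, "ba_dictionary")) {
    category_terms(dictionary, category)
  } else if (inherits(dictionary, "ba_lexicon")) {
    if (!category %in% names(dictionary$categories)) {
      stop("unknown lexicon category: '", category, "'")
    }
    dictionary$categories[[category]]
  } else {
    if (!category %in% names(dictionary)) {
      stop("unknown category: '", category, "'")
    }
    dictionary[[category]]
  }
}

#' Composite emotional tone
#'
#' Combines the positive- and negative-emotion percent scores into one tone
#' variable on \[0, 100\]: `100 * pos / (pos + neg)`. A score of 50 indicates
#' a balance between positive and negative affect; high values indicate a
#' predominance of positive over negative emotion words. When both inputs
#' are 0 the balance convention (50) applies.
#'
#' @param pos_pct,neg_pct Nonnegative percent scores.
#' @return Tone score in \[0, 100\] (vectorised).
#' @export
tone_score <- function(pos_pct, neg_pct) {
  if (any(pos_pct < 0, na.rm = TRUE) || any(neg_pct < 0, na.rm = TRUE)) {
    stop("tone inputs must be nonnegative percents")
  }
  total <- pos_pct + neg_pct
  out <- ifelse(total > 0, 100 * pos_pct / total, 50)
  ifelse(is.na(pos_pct) | is.na(neg_pct), NA_real_, out)
}

#' Score all documents against the standard categories and a BA lexicon
#'
#' Produces one row per pooled document with percent scores for the
#' established marker categories (`i`, `we`, `sadness`, `health`, the
#' composite `biology`), the composite emotional `tone` (from `posemo` and
#' `negemo`), and — when a lexicon is supplied — the overall `activation`
#' category and each of its 7 subconstructs. Empty documents (token_count 0)
#' get `NA` scores and keep their `is_empty` flag.
#'
#' @param docs Pooled-document tibble ([pool_by_week()] /
#'   [pool_by_assessment()]).
#' @param dictionary A `ba_dictionary` (or `NULL` to skip the established
#'   categories).
#' @param lexicon A `ba_lexicon` (or `NULL` to skip BA scoring).
#' @return A tibble: identifier columns from `docs` (all except `tokens`)
#'   plus one numeric percent column per category.
#' @export
score_all <- function(docs, dictionary = load_dictionary(), lexicon = NULL) {
  stopifnot(is.data.frame(docs), "tokens" %in% names(docs))
  out <- docs[, setdiff(names(docs), "tokens"), drop = FALSE]
  cats <- list()
  if (!is.null(dictionary)) {
    stopifnot(inherits(dictionary, "ba_dictionary"))
    base_names <- c("i", "we", "sadness", "health", "posemo", "negemo")
    for (nm in base_names) cats[[nm]] <- category_terms(dictionary, nm)
    for (nm in names(dictionary$composites)) {
      cats[[nm]] <- category_terms(dictionary, nm)
    }
  }
  if (!is.null(lexicon)) {
    stopifnot(inherits(lexicon, "ba_lexicon"))
    for (nm in names(lexicon$categories)) cats[[nm]] <- lexicon$categories[[nm]]
  }
  counts <- count_matches_bulk(docs$tokens, cats)
  n_tok <- docs$token_count
  for (nm in names(cats)) {
    pct <- 100 * counts[[nm]] / n_tok
    pct[n_tok == 0L] <- NA_real_
    out[[nm]] <- pct
  }
  if (all(c("posemo", "negemo") %in% names(out))) {
    out$tone <- tone_score(out$posemo, out$negemo)
  }
  out
}

# Vectorised bulk counting across documents: one pass over the concatenated
# token stream per run, per-document tallies via rowsum. Categories with
# phrases fall back to the per-document scanner.
count_matches_bulk <- function(token_list, cats) {
  n_doc <- length(token_list)
  lens <- vapply(token_list, length, 1L)
  flat <- unlist(token_list, use.names = FALSE)
  doc_id <- rep.int(seq_len(n_doc), lens)
  res <- list()
  for (nm in names(cats)) {
    terms <- cats[[nm]]
    if (length(terms) > 0L && any(grepl(" ", terms, fixed = TRUE))) {
      res[[nm]] <- vapply(token_list, count_matches, 1L, terms = terms)
    } else if (length(flat) == 0L || length(terms) == 0L) {
      res[[nm]] <- rep.int(0L, n_doc)
    } else {
      hit <- flat %in% terms
      tallied <- rowsum(as.integer(hit), doc_id)
      counts <- rep.int(0L, n_doc)
      counts[as.integer(rownames(tallied))] <- tallied[, 1L]
      res[[nm]] <- counts
    }
  }
  res
}
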
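ba_subconstructs <- function() {
  c("satisfaction", "breadth", "decisions", "accomplishment",
    "long-term", "effort", "structure")
}

#' Read a BADS seed-term table
#'
#' Reads the seed-term table derived from the 7 items of the Activation
#' subscale of the Behavioral Activation for Depression Scale (BADS). Each of
#' the 7 items (satisfaction, breadth, decisions, accomplishment, long-term,
#' effort, structure) carries a clinician-curated list of seed terms; terms
#' may repeat across items ("goals" seeds accomplishment, long-term, and
#' structure). The packaged table carries 104 seed tokens in total, 66 unique
#' terms case-insensitively.
#'
#' @param path CSV with columns `item`, `seed_term`; defaults to the packaged
#'   table.
#' @return A tibble with columns `item` and `seed_term` (lowercase).
#' @export
read_seed_table <- function(path = system.file("extdata", "bads_seed_terms.csv",
                                               package = "balex")) {
  raw <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  missing_cols <- setdiff(c("item", "seed_term"), names(raw))
  if (length(missing_cols) > 0L) {
    stop("seed table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::tibble(item = tolower(trimws(raw$item)),
                        seed_term = tolower(trimws(raw$seed_term)))
  bad <- setdiff(unique(out$item), ba_subconstructs())
  if (length(bad) > 0L) {
    stop("seed table contains unknown item(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Read a term blocklist
#'
#' One term per line; `#` starts a comment; blank lines ignored; terms are
#' lowercased. The blocklist is the reproducible record of the manual
#' pruning step that removes irrelevant or inaccurate expansion terms.
#'
#' @param path Path to the blocklist file.
#' @return A character vector of lowercase terms.
#' @export
read_blocklist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- tolower(trimws(lines))
  unique(lines[nzchar(lines)])
}

#' Expand one seed term via embedding nearest neighbors
#'
#' Returns the seed plus its `k` most cosine-similar vocabulary terms, minus
#' any blocklisted terms. Multiword seeds first try an underscore-joined
#' phrase token; if that is absent from the vocabulary, each constituent word
#' is expanded and the results are unioned. A seed absent from the vocabulary
#' is skipped with a warning (returning the empty set) rather than failing
#' the build. With `k = 0` the expansion step is disabled and the seed itself
#' is returned (minus blocklist).
#'
#' @param embeddings A `ba_embeddings` object.
#' @param seed Seed term (may be multiword).
#' @param k Number of neighbors to add per seed.
#' @param blocklist Character vector of terms to exclude.
#' @return A character set (vector) of lowercase terms.
#' @export
expand_seed <- function(embeddings, seed, k = 30L, blocklist = character(0)) {
  seed <- tolower(trimws(seed))
  blocklist <- tolower(blocklist)
  if (k == 0L) return(setdiff(seed, blocklist))
  words <- strsplit(seed, "\\s+")[[1]]
  if (length(words) > 1L) {
    phrase <- paste(words, collapse = "_")
    if (phrase %in% embeddings$vocabulary) {
      words <- phrase
    }
  }
  out <- character(0)
  for (w in words) {
    if (!(w %in% embeddings$vocabulary)) {
      warning("seed term OOV, skipped: '", w, "'", call. = FALSE)
      next
    }
    nn <- nearest_neighbors(embeddings, w, k = k)
    out <- union(out, c(w, nn$term))
  }
  setdiff(tolower(out), blocklist)
}

#' Build one BA subconstruct category
#'
#' Unions the per-seed expansions ([expand_seed()]) of all seed terms of one
#' BADS item into a deduplicated category term set.
#'
#' @param item_name Name of the subconstruct.
#' @param seed_list Character vector of seed terms for the item.
#' @param embeddings A `ba_embeddings` object.
#' @param k Neighbors per seed (`k = 0` disables expansion).
#' @param blocklist Terms to exclude.
#' @return A character vector of unique lowercase terms.
#' @export
build_subconstruct <- function(item_name, seed_list, embeddings, k = 30L,
                               blocklist = character(0)) {
  stopifnot(length(seed_list) > 0L)
  sets <- lapply(seed_list, function(s) expand_seed(embeddings, s, k, blocklist))
  sort(unique(unlist(sets, use.names = FALSE)))
}

#' Deduplicated overall activation category
#'
#' The overarching activation category is the union of the 7 subconstruct
#' categories with duplicate terms removed, so that overlapping subconstructs
#' ("goals" belongs to several) are not double counted.
#'
#' @param subconstructs A named list of exactly 7 category term sets.
#' @return A character vector of unique terms.
#' @export
build_overall <- function(subconstructs) {
  stopifnot(length(subconstructs) == 7L)
  sort(unique(unlist(subconstructs, use.names = FALSE)))
}

#' Build the full BA lexicon from a seed table
#'
#' Expands every seed of every BADS item ([expand_seed()]), combines the
#' expansions into the 7 partially overlapping subconstruct categories, and
#' adds the deduplicated `activation` (overall) category. Records per-term
#' provenance (`seed` or `neighbor-of:<seed>`) and build metadata.
#'
#' @param embeddings A `ba_embeddings` object.
#' @param seed_table Tibble from [read_seed_table()].
#' @param k Neighbors per seed.
#' @param blocklist Terms to exclude (vector, or path to a blocklist file).
#' @return An object of class `ba_lexicon`: `categories` (named list;
#'   `activation` plus 7 subconstructs), `provenance`, `metadata`.
#' @export
build_ba_lexicon <- function(embeddings, seed_table = read_seed_table(),
                             k = 30L, blocklist = character(0)) {
  blocklist_version <- "inline"
  if (length(blocklist) == 1L && file.exists(blocklist)) {
    blocklist_version <- basename(blocklist)
    blocklist <- read_blocklist(blocklist)
  }
  blocklist <- tolower(blocklist)
  items <- split(seed_table$seed_term, seed_table$item)
  items <- items[intersect(ba_subconstructs(), names(items))]
  provenance <- list()
  categories <- lapply(names(items), function(item) {
    sets <- lapply(items[[item]], function(s) expand_seed(embeddings, s, k, blocklist))
    for (j in seq_along(sets)) {
      seed <- tolower(items[[item]][j])
      for (term in sets[[j]]) {
        if (is.null(provenance[[term]])) {
          provenance[[term]] <<- if (term %in% tolower(items[[item]])) "seed" else
            paste0("neighbor-of:", seed)
        }
      }
    }
    sort(unique(unlist(sets, use.names = FALSE)))
  })
  names(categories) <- names(items)
  categories <- c(list(activation = build_overall(categories)), categories)
  structure(
    list(categories = categories,
         provenance = provenance,
         metadata = list(k = as.integer(k),
                         blocklist_version = blocklist_version,
                         n_blocklist = length(blocklist),
                         embedding_dim = ncol(embeddings$vectors),
                         embedding_config = embeddings$config,
                         built = format(Sys.time(), "%Y-%m-%d"))),
    class = "ba_lexicon"
  )
}

#' @export
print.ba_lexicon <- function(x, ...) {
  sizes <- vapply(x$categories, length, 1L)
  cat("<ba_lexicon>", sizes[["activation"]], "unique activation terms\n")
  for (nm in setdiff(names(sizes), "activation")) {
    cat(sprintf("  %-15s %d terms\n", nm, sizes[[nm]]))
  }
  invisible(x)
}

#' Apply a blocklist to an existing lexicon
#'
#' Removes every blocklisted term from every category (and from the overall
#' activation set), recording the blocklist version in the metadata.
#' Idempotent: applying the same blocklist twice equals applying it once.
#' Blocklisted terms not present in the lexicon are ignored.
#'
#' @param lexicon A `ba_lexicon`.
#' @param blocklist Character vector of terms, or path to a blocklist file.
#' @return The pruned `ba_lexicon`.
#' @export
apply_blocklist <- function(lexicon, blocklist) {
  version <- "inline"
  if (length(blocklist) == 1L && file.exists(blocklist)) {
    version <- basename(blocklist)
    blocklist <- read_blocklist(blocklist)
  }
  blocklist <- tolower(blocklist)
  lexicon$categories <- lapply(lexicon$categories, setdiff, y = blocklist)
  lexicon$provenance <- lexicon$provenance[
    setdiff(names(lexicon$provenance), blocklist)]
  lexicon$metadata$blocklist_version <- version
  lexicon$metadata$n_blocklist <- length(blocklist)
  lexicon
}

#' Write a lexicon or dictionary in LIWC-style .dic format
#'
#' Format: a `%`-delimited header block mapping numeric category ids to
#' names, followed by one line per term: `term<TAB>id[<TAB>id...]`. Multiword
#' terms are written as-is (spaces preserved).
#'
#' @param x A `ba_lexicon` or a named list of category term sets.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dic <- function(x, path) {
  categories <- if (inherits(x, "ba_lexicon")) x$categories else x
  stopifnot(is.list(categories), !is.null(names(categories)))
  ids <- seq_along(categories)
  header <- c("%", paste0(ids, "\t", names(categories)), "%")
  terms <- sort(unique(unlist(categories, use.names = FALSE)))
  body <- vapply(terms, function(tm) {
    in_cat <- ids[vapply(categories, function(set) tm %in% set, TRUE)]
    paste(c(tm, in_cat), collapse = "\t")
  }, "")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a LIWC-style .dic file
#'
#' @param path Path to a `.dic` file in the dialect written by [write_dic()].
#' @return A named list of category term sets (lowercase).
#' @export
read_dic <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2L) stop("malformed .dic file (missing % header block): ", path)
  header <- lines[(pct[1] + 1L):(pct[2] - 1L)]
  hp <- strsplit(header, "\t", fixed = TRUE)
  cat_names <- vapply(hp, `[`, "", 2L)
  names(cat_names) <- vapply(hp, `[`, "", 1L)
  categories <- stats::setNames(vector("list", length(cat_names)),
                                unname(cat_names))
  body <- lines[-seq_len(pct[2])]
  for (line in body) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    term <- tolower(parts[1])
    for (id in parts[-1]) {
      nm <- cat_names[[id]]
      categories[[nm]] <- c(categories[[nm]], term)
    }
  }
  lapply(categories, function(x) sort(unique(x)))
}

#' Read a BA lexicon from a .dic file
#'
#' Loads a `.dic` file written by [write_dic()] back into a `ba_lexicon`.
#' The `activation` category is recomputed as the deduplicated union of the
#' other categories if absent.
#'
#' @param path Path to the `.dic` file.
#' @return A `ba_lexicon` (provenance empty; metadata records the source).
#' @export
read_lexicon <- function(path) {
  categories <- read_dic(path)
  subs <- categories[setdiff(names(categories), "activation")]
  if (!"activation" %in% names(categories)) {
    categories <- c(list(activation = sort(unique(unlist(subs, use.names = FALSE)))),
                    subs)
  }
  structure(list(categories = categories, provenance = list(),
                 metadata = list(source = basename(path))),
            class = "ba_lexicon")
}

#' Write lexicon provenance and metadata sidecar
#'
#' @param lexicon A `ba_lexicon`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_lexicon_meta <- function(lexicon, path) {
  jsonlite::write_json(
    list(provenance = lexicon$provenance, metadata = lexicon$metadata),
    path, auto_unbox = TRUE, pretty = TRUE, force = TRUE
  )
  invisible(path)
}
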
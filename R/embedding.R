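#' Embedding training configuration
#'
#' Defaults follow the training setup used to build the BA lexicon:
#' 100-dimensional skip-gram-with-negative-sampling vectors trained for 10
#' epochs with a sliding window radius of 2, a frequency subsampling threshold
#' of 1e-5, and a minimum corpus frequency of 5 (rarer words are excluded from
#' training). The number of negative samples (5) and the initial learning rate
#' (0.025, decaying linearly) are the canonical defaults of the algorithm.
#'
#' @param dim Vector dimensionality.
#' @param window_radius Sliding context window radius.
#' @param subsample_threshold Frequency subsampling threshold.
#' @param min_count Minimum corpus frequency for inclusion in the vocabulary.
#' @param epochs Number of training passes over the corpus.
#' @param negative_samples Negative samples per positive example.
#' @param alpha Initial learning rate (linear decay to `alpha_min`).
#' @param alpha_min Learning-rate floor.
#' @param seed Integer RNG seed; training is single-threaded and
#'   bit-reproducible for a fixed seed.
#' @return A list of class `ba_embedding_config`.
#' @export
embedding_config <- function(dim = 100L, window_radius = 2L,
                             subsample_threshold = 1e-5, min_count = 5L,
                             epochs = 10L, negative_samples = 5L,
                             alpha = 0.025, alpha_min = 1e-4, seed = 1L) {
  stopifnot(dim > 0, window_radius >= 1, min_count >= 1, epochs >= 1,
            negative_samples >= 0, alpha > 0)
  structure(
    list(dim = as.integer(dim), window_radius = as.integer(window_radius),
         subsample_threshold = subsample_threshold,
         min_count = as.integer(min_count), epochs = as.integer(epochs),
         negative_samples = as.integer(negative_samples),
         alpha = alpha, alpha_min = alpha_min, seed = as.integer(seed)),
    class = "ba_embedding_config"
  )
}

#' Train word embeddings on a pooled-document corpus
#'
#' Trains skip-gram-with-negative-sampling word vectors on the token streams
#' of a pooled-document corpus (each document is one training "sentence").
#'
#' @param corpus A pooled-document tibble (see [pool_by_week()]) or a list of
#'   token character vectors.
#' @param config An [embedding_config()].
#' @return An object of class `ba_embeddings` with elements `vocabulary`
#'   (terms ordered by decreasing corpus frequency), `vectors` (terms x dim
#'   matrix, rownames = vocabulary), `counts`, and `config`.
#' @export
train_embeddings <- function(corpus, config = embedding_config()) {
  sentences <- if (is.data.frame(corpus)) corpus$tokens else corpus
  stopifnot(is.list(sentences))
  if (length(sentences) == 0L) stop("corpus is empty")
  all_tokens <- unlist(sentences, use.names = FALSE)
  if (length(all_tokens) == 0L) stop("corpus contains no tokens")
  freq <- sort(table(all_tokens), decreasing = TRUE)
  keep <- freq[freq >= config$min_count]
  if (length(keep) == 0L) {
    stop("vocabulary is empty after applying min_count = ", config$min_count)
  }
  # decreasing frequency, ties broken lexicographically, for a stable ordering
  ord <- order(-as.integer(keep), names(keep), method = "radix")
  vocab <- names(keep)[ord]
  counts <- as.integer(keep)[ord]
  idx <- lapply(sentences, function(s) {
    m <- match(s, vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  idx <- idx[vapply(idx, length, 1L) > 0L]
  vec <- .sgns_train(idx, counts, config$dim, config$window_radius,
                     config$subsample_threshold, config$negative_samples,
                     config$epochs, config$alpha, config$alpha_min,
                     config$seed)
  rownames(vec) <- vocab
  structure(list(vocabulary = vocab, vectors = vec, counts = counts,
                 config = config),
            class = "ba_embeddings")
}

#' @export
print.ba_embeddings <- function(x, ...) {
  cat("<ba_embeddings>", length(x$vocabulary), "terms x", ncol(x$vectors),
      "dimensions\n")
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length; both must be nonzero.
#' @return The cosine similarity, in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Nearest neighbors of a term by cosine similarity
#'
#' Returns the `k` vocabulary terms most cosine-similar to the query term
#' (excluding the query itself), in decreasing similarity with ties broken
#' lexicographically. If the vocabulary holds fewer than `k + 1` terms, all
#' other terms are returned.
#'
#' @param embeddings A `ba_embeddings` object.
#' @param term Query term (must be in the vocabulary).
#' @param k Number of neighbors.
#' @return A tibble with columns `term` and `similarity`.
#' @export
nearest_neighbors <- function(embeddings, term, k = 30L) {
  stopifnot(inherits(embeddings, "ba_embeddings"), k >= 1)
  i <- match(term, embeddings$vocabulary)
  if (is.na(i)) {
    stop("term not in embedding vocabulary (OOV): '", term, "'",
         call. = FALSE)
  }
  V <- embeddings$vectors
  q <- V[i, ]
  qn <- sqrt(sum(q^2))
  norms <- sqrt(rowSums(V^2))
  sims <- unname(as.numeric(V %*% q) / (norms * qn))
  sims[i] <- -Inf
  ord <- order(-sims, embeddings$vocabulary, method = "radix")
  ord <- ord[seq_len(min(k, length(ord) - 1L))]
  tibble::tibble(term = embeddings$vocabulary[ord], similarity = sims[ord])
}

#' Write embeddings in word2vec text format
#'
#' First line "V D" (vocabulary size and dimensionality), then one line per
#' term: the term followed by D space-separated coordinates.
#'
#' @param embeddings A `ba_embeddings` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(length(embeddings$vocabulary), ncol(embeddings$vectors)), con)
  body <- vapply(seq_along(embeddings$vocabulary), function(i) {
    paste(embeddings$vocabulary[i],
          paste(formatC(embeddings$vectors[i, ], format = "g", digits = 9),
                collapse = " "))
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read embeddings from word2vec text format
#'
#' @param path Path to a file written by [write_embeddings()] (or any
#'   word2vec-style text embedding file).
#' @return A `ba_embeddings` object (without training counts/config).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  v <- hdr[1]; d <- hdr[2]
  parts <- strsplit(lines[1 + seq_len(v)], " ", fixed = TRUE)
  vocab <- vapply(parts, `[`, "", 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(vec) <- vocab
  structure(list(vocabulary = vocab, vectors = vec, counts = NULL,
                 config = NULL),
            class = "ba_embeddings")
}
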
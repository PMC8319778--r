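# Shared fixtures and independent oracles for the test suite.

# The 40-word interview excerpt used as the worked scoring example.
worked_excerpt <- function() {
  paste(
    "When I speak of depression, I speak of a clinical depression that is",
    "the background of your entire life, a background of anguish and",
    "anxiety, a sense that nothing goes well, that pleasure is unavailable",
    "and all your strategies collapse."
  )
}

# A small chat-log tibble for pooling tests.
toy_messages <- function() {
  tibble::tibble(
    patient_id = c("p1", "p1", "p1", "p2", "p2"),
    week = c(1L, 2L, 4L, 1L, 4L),
    text = c("plan the day", "goals and progress", "more goals",
             "quiet week", "went to a restaurant")
  )
}

toy_assessments <- function() {
  tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    week = c(0L, 3L, 3L),
    phq9 = c(12L, 9L, 15L)
  )
}

# Independent brute-force cosine-kNN oracle: full pairwise sort.
oracle_knn <- function(vectors, term, k) {
  vocab <- rownames(vectors)
  q <- vectors[term, ]
  sims <- apply(vectors, 1, function(v) {
    sum(q * v) / (sqrt(sum(q^2)) * sqrt(sum(v^2)))
  })
  sims <- sims[names(sims) != term]
  ord <- order(-sims, names(sims), method = "radix")
  head(data.frame(term = names(sims)[ord], similarity = unname(sims)[ord],
                  stringsAsFactors = FALSE), k)
}

# Independent per-token scoring oracle: scans the token stream one position
# at a time, consuming greedy longest phrase matches first.
oracle_count <- function(tokens, terms) {
  singles <- terms[!grepl(" ", terms, fixed = TRUE)]
  phrase_toks <- lapply(terms[grepl(" ", terms, fixed = TRUE)],
                        function(p) strsplit(p, " ", fixed = TRUE)[[1]])
  n <- length(tokens)
  hits <- 0L
  i <- 1L
  while (i <= n) {
    consumed <- 0L
    if (length(phrase_toks) > 0L) {
      lens <- sort(unique(vapply(phrase_toks, length, 1L)), decreasing = TRUE)
      for (L in lens) {
        if (i + L - 1L > n) next
        window <- tokens[i:(i + L - 1L)]
        for (p in phrase_toks) {
          if (length(p) == L && all(p == window)) { consumed <- L; break }
        }
        if (consumed > 0L) break
      }
    }
    if (consumed > 0L) {
      hits <- hits + 1L
      i <- i + consumed
    } else {
      if (tokens[i] %in% singles) hits <- hits + 1L
      i <- i + 1L
    }
  }
  hits
}

# A tiny trained embedding table shared across lexicon tests: words co-occur
# within three context "themes" so neighborhoods are nontrivial.
themed_embeddings <- function(seed = 11L) {
  set.seed(seed)
  themes <- list(
    c("plan", "planning", "goal", "goals", "schedule", "routine"),
    c("run", "running", "exercise", "sport", "gym", "training"),
    c("sad", "tired", "sleep", "awake", "night", "morning")
  )
  sentences <- replicate(400, {
    th <- themes[[sample(3, 1)]]
    sample(th, 8, replace = TRUE)
  }, simplify = FALSE)
  train_embeddings(sentences,
                   embedding_config(dim = 16, min_count = 5, epochs = 3,
                                    seed = 99L))
}
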
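test_that("packaged seed table carries 104 seed tokens over 7 items, 66 unique", {
  seeds <- read_seed_table()
  expect_equal(nrow(seeds), 104L)
  expect_equal(length(unique(seeds$seed_term)), 66L)
  expect_setequal(unique(seeds$item),
                  c("satisfaction", "breadth", "decisions", "accomplishment",
                    "long-term", "effort", "structure"))
  # overlap across items is real: "goals" seeds three subconstructs
  expect_equal(sum(seeds$seed_term == "goals"), 3L)
})

test_that("seed expansion composes the seed with its neighbor set", {
  emb <- themed_embeddings()
  nn <- nearest_neighbors(emb, "plan", k = 3)
  got <- expand_seed(emb, "plan", k = 3)
  expect_setequal(got, c("plan", nn$term))
  # blocklisting every neighbor leaves just the seed
  expect_identical(expand_seed(emb, "plan", k = 3, blocklist = nn$term), "plan")
  # k = 0 disables expansion
  expect_identical(expand_seed(emb, "plan", k = 0), "plan")
  # OOV seed is skipped with a warning, not an error
  expect_warning(out <- expand_seed(emb, "zzzunknown", k = 3), "OOV")
  expect_length(out, 0L)
})

test_that("multiword seeds fall back to constituent-word expansion", {
  emb <- themed_embeddings()
  # no "plan_schedule" phrase token exists, so constituents are unioned
  both <- expand_seed(emb, "plan schedule", k = 2)
  expect_true(all(c("plan", "schedule") %in% both))
  expect_true(length(both) >= length(expand_seed(emb, "plan", k = 2)))
})

test_that("subconstruct building unions and deduplicates per-seed expansions", {
  emb <- themed_embeddings()
  one <- build_subconstruct("demo", c("plan", "plan"), emb, k = 3)
  expect_identical(one, sort(expand_seed(emb, "plan", k = 3)))
  two <- build_subconstruct("demo", c("plan", "run"), emb, k = 3)
  expect_setequal(two, union(expand_seed(emb, "plan", k = 3),
                             expand_seed(emb, "run", k = 3)))
  expect_false(any(duplicated(two)))
})

test_that("with expansion disabled the full seed table collapses to 66 terms", {
  emb <- themed_embeddings()
  seeds <- read_seed_table()
  cats <- lapply(split(seeds$seed_term, seeds$item), function(s) {
    build_subconstruct("item", s, emb, k = 0)
  })
  expect_length(build_overall(cats), 66L)
})

test_that("the overall category is the deduplicated union of the seven", {
  expect_setequal(build_overall(list(c("a", "b"), c("b", "c"),
                                     "a", "a", "a", "a", "a")),
                  c("a", "b", "c"))
  same <- replicate(7, c("x", "y"), simplify = FALSE)
  expect_setequal(build_overall(same), c("x", "y"))
  expect_error(build_overall(list(c("a"), c("b"))))
})

test_that("full lexicon build keeps overall == union and tracks provenance", {
  emb <- themed_embeddings()
  seeds <- tibble::tibble(
    item = rep(c("satisfaction", "breadth", "decisions", "accomplishment",
                 "long-term", "effort", "structure"), each = 1),
    seed_term = c("plan", "run", "goal", "goals", "schedule", "exercise",
                  "routine")
  )
  lex <- build_ba_lexicon(emb, seeds, k = 5)
  subs <- lex$categories[setdiff(names(lex$categories), "activation")]
  expect_identical(lex$categories$activation,
                   sort(unique(unlist(subs, use.names = FALSE))))
  # every non-seed term's provenance names a seed whose neighbor list holds it
  for (term in names(lex$provenance)) {
    prov <- lex$provenance[[term]]
    if (prov == "seed") {
      expect_true(term %in% seeds$seed_term)
    } else {
      seed <- sub("^neighbor-of:", "", prov)
      expect_true(term %in% nearest_neighbors(emb, seed, k = 5)$term)
    }
  }
  # rebuild is deterministic
  lex2 <- build_ba_lexicon(emb, seeds, k = 5)
  expect_identical(lex$categories, lex2$categories)
})

test_that("blocklist application removes terms everywhere and is idempotent", {
  emb <- themed_embeddings()
  seeds <- tibble::tibble(
    item = c("satisfaction", "breadth", "decisions", "accomplishment",
             "long-term", "effort", "structure"),
    seed_term = c("plan", "plan", "plan", "goal", "goal", "run", "run")
  )
  lex <- build_ba_lexicon(emb, seeds, k = 5)
  identity <- apply_blocklist(lex, character(0))
  expect_identical(identity$categories, lex$categories)

  victim <- lex$categories$activation[1]
  pruned <- apply_blocklist(lex, victim)
  expect_false(any(vapply(pruned$categories, function(s) victim %in% s, TRUE)))
  twice <- apply_blocklist(pruned, victim)
  expect_identical(twice$categories, pruned$categories)
  # overall stays the exact union after pruning
  subs <- pruned$categories[setdiff(names(pruned$categories), "activation")]
  expect_identical(pruned$categories$activation,
                   sort(unique(unlist(subs, use.names = FALSE))))
})

test_that("packaged blocklist file parses and feeds the build", {
  bl <- read_blocklist(system.file("extdata", "blocklist.txt", package = "balex"))
  expect_true("sucide" %in% bl)
  expect_false(any(grepl("#", bl)))
  emb <- themed_embeddings()
  # a blocklisted term never survives into any category
  seeds <- tibble::tibble(
    item = c("satisfaction", "breadth", "decisions", "accomplishment",
             "long-term", "effort", "structure"),
    seed_term = rep("plan", 7)
  )
  lex <- build_ba_lexicon(emb, seeds, k = 5,
                          blocklist = system.file("extdata", "blocklist.txt",
                                                  package = "balex"))
  expect_false(any(vapply(lex$categories, function(s) "sucide" %in% s, TRUE)))
  expect_equal(lex$metadata$blocklist_version, "blocklist.txt")
})

test_that(".dic serialization round-trips categories including phrases", {
  cats <- list(alpha = c("plan", "water coloring", "goal"),
               beta = c("goal", "run"))
  path <- withr::local_tempfile(fileext = ".dic")
  write_dic(cats, path)
  back <- read_dic(path)
  expect_setequal(back$alpha, cats$alpha)
  expect_setequal(back$beta, cats$beta)
  # packaged dictionary file parses with its nine categories
  fixture <- read_dic(system.file("extdata", "liwc_like.dic", package = "balex"))
  expect_setequal(names(fixture),
                  c("i", "we", "posemo", "negemo", "sadness", "body",
                    "health", "sexual", "ingestion"))
})
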
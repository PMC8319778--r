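#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the analyses assume: weekly message
#' streams over study weeks -3..11; a mean of 770 word tokens written per
#' patient-week; PHQ-9 assessed at weeks 0, 3, 6, 9, 12 on the 0-27 integer
#' scale; and group-level activation-percent trends of
#' `3.837 + 0.039 * week` (improving) and `3.598 + 0.006 * week`
#' (nonimproving) around which patients vary with random intercepts and
#' slopes. The random-effect and residual SDs (0.8 / 0.05 / 0.6, correlation
#' 0) are calibration choices that put the simulated dispersion on the order
#' of the observed baseline SD of the overall activation score (0.89); they
#' are not reported quantities. PHQ trajectories share a latent severity with
#' the non-activation token categories, so marker-vs-PHQ associations exist
#' by construction.
#'
#' @param n_patients Named integer vector: patients per trajectory group.
#' @param weeks Integer study weeks with messages.
#' @param fixed_effects Per-group `c(intercept, slope)` of the activation
#'   percent process.
#' @param sd_intercept,sd_slope,re_correlation,sd_resid Random-effect SDs,
#'   intercept-slope correlation, and residual SD of the activation process.
#' @param tokens_mean,tokens_size Negative-binomial mean and size of tokens
#'   per patient-week (size controls overdispersion).
#' @param phq PHQ-9 process parameters: baseline mean/SD, per-group weekly
#'   slope, and observation residual SD.
#' @param rates Baseline emission probability and per-severity-unit linkage
#'   slope for each non-activation token category (probability =
#'   `base + link * (severity - 13)`).
#' @param seed Default RNG seed for [simulate_cohort()].
#' @return A list of class `ba_cohort_config`.
#' @export
cohort_config <- function(
    n_patients = c(improving = 100L, nonimproving = 100L),
    weeks = -3:11,
    fixed_effects = list(improving = c(intercept = 3.837, slope = 0.039),
                         nonimproving = c(intercept = 3.598, slope = 0.006)),
    sd_intercept = 0.8, sd_slope = 0.05, re_correlation = 0, sd_resid = 0.6,
    tokens_mean = 770, tokens_size = 5,
    phq = list(baseline_mean = 13.4, baseline_sd = 4.9,
               slope = c(improving = -0.75, nonimproving = -0.10),
               resid_sd = 2),
    rates = list(
      i = c(base = 0.055, link = 0.0012),
      we = c(base = 0.010, link = -0.0003),
      posemo = c(base = 0.020, link = -0.0006),
      negemo = c(base = 0.022, link = 0.0009),
      sadness = c(base = 0.008, link = 0.0004),
      body = c(base = 0.006, link = 0.0002),
      health = c(base = 0.007, link = 0.0003),
      sexual = c(base = 0.0015, link = 0),
      ingestion = c(base = 0.004, link = 0)),
    seed = 1L) {
  stopifnot(all(n_patients >= 0), sd_intercept >= 0, sd_slope >= 0,
            sd_resid >= 0, abs(re_correlation) <= 1,
            tokens_mean > 0, tokens_size > 0,
            all(names(n_patients) %in% names(fixed_effects)),
            all(weeks >= -3), all(weeks <= 11))
  structure(
    list(n_patients = n_patients, weeks = as.integer(weeks),
         fixed_effects = fixed_effects, sd_intercept = sd_intercept,
         sd_slope = sd_slope, re_correlation = re_correlation,
         sd_resid = sd_resid, tokens_mean = tokens_mean,
         tokens_size = tokens_size, phq = phq, rates = rates,
         seed = as.integer(seed)),
    class = "ba_cohort_config"
  )
}

# Emission vocabulary: activation terms are the single-word BADS seeds; the
# other categories reuse the packaged fixture dictionary with any activation
# terms removed; filler is a neutral vocabulary disjoint from every category.
# Disjointness makes the scored activation percent an unbiased estimate of
# the generating mu_ij.
generator_term_sets <- function() {
  seeds <- read_seed_table()
  activation <- sort(unique(seeds$seed_term[!grepl(" ", seeds$seed_term)]))
  dict <- load_dictionary()
  others <- lapply(dict$categories, setdiff, y = activation)
  used <- c(activation, unlist(others, use.names = FALSE))
  filler <- c(
    "the", "and", "to", "a", "of", "in", "it", "that", "was", "is", "for",
    "on", "with", "as", "at", "this", "but", "not", "they", "be", "have",
    "had", "has", "so", "just", "about", "week", "today", "yesterday",
    "time", "day", "work", "home", "think", "thought", "know", "really",
    "been", "being", "going", "went", "got", "get", "like", "feel", "felt",
    "feeling", "when", "then", "than", "there", "here", "what", "how",
    "because", "would", "could", "should", "much", "more", "some", "any",
    "also", "back", "out", "over", "again", "still", "even", "only",
    "talked", "said", "told", "asked", "trying", "tried", "things", "thing",
    "stuff", "people", "friend", "family", "sister", "brother", "mother",
    "father", "job", "house", "weekend", "morning", "evening", "night",
    "maybe", "probably", "pretty", "very", "quite", "bit", "lot", "while",
    "during", "after", "before", "since", "around", "little", "big", "new",
    "old", "last", "next", "first", "two", "three", "few", "many", "most",
    "other", "another", "same", "different", "own", "way", "part", "kind",
    "sort", "moment", "place", "year", "month", "hour", "minute")
  filler <- setdiff(filler, used)
  c(list(activation = activation), others, list(filler = filler))
}

#' The generator's own BA lexicon
#'
#' The lexicon over the generator's emission vocabulary: the 7 subconstruct
#' categories are the per-item single-word seed sets and `activation` is
#' their deduplicated union. Scoring simulated documents with this lexicon
#' closes the loop between the simulator and the scorer.
#'
#' @return A `ba_lexicon`.
#' @export
generator_lexicon <- function() {
  seeds <- read_seed_table()
  seeds <- seeds[!grepl(" ", seeds$seed_term), ]
  items <- split(seeds$seed_term, seeds$item)
  items <- items[ba_subconstructs()]
  categories <- lapply(items, function(x) sort(unique(x)))
  provenance <- stats::setNames(
    as.list(rep("seed", length(unique(seeds$seed_term)))),
    sort(unique(seeds$seed_term)))
  structure(
    list(categories = c(list(activation = build_overall(categories)), categories),
         provenance = provenance,
         metadata = list(k = 0L, blocklist_version = "none", n_blocklist = 0L,
                         source = "synthetic-generator emission vocabulary")),
    class = "ba_lexicon"
  )
}

#' Simulate a synthetic chat cohort
#'
#' Generates per-patient weekly message streams and PHQ-9 assessments with
#' the statistical structure the longitudinal analyses assume. For patient
#' `i` in group `g` at week `j`, the target activation percent is
#' `mu_ij = b0_g + b1_g j + g0_i + g1_i j + e_ij` (clamped to \[0, 100\]);
#' the week's token counts are multinomial with activation-cell probability
#' `mu_ij / 100`, the other category probabilities linked linearly to the
#' patient's latent severity, and the remainder emitted as filler tokens.
#' PHQ-9 scores are the latent severity observed with noise at the scheduled
#' weeks, rounded and truncated to 0-27. Fully reproducible for a fixed
#' seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of class `ba_cohort`: `messages` (tibble `patient_id`,
#'   `week`, `text`), `assessments` (tibble `patient_id`, `week`, `phq9`),
#'   `truth` (per-patient latent parameters and group labels), `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "ba_cohort_config"))
  set.seed(seed)
  term_sets <- generator_term_sets()
  other_names <- names(config$rates)
  missing_sets <- setdiff(other_names, names(term_sets))
  if (length(missing_sets) > 0L) {
    stop("no emission term set for category: ", paste(missing_sets, collapse = ", "))
  }
  groups <- names(config$n_patients)[config$n_patients > 0]
  msg_list <- list(); phq_list <- list(); truth_list <- list()
  for (g in groups) {
    n <- config$n_patients[[g]]
    fe <- config$fixed_effects[[g]]
    ids <- sprintf("P-%s-%05d", substr(g, 1, 3), seq_len(n))
    # correlated random effects via Cholesky of the 2x2 covariance
    z <- matrix(rnorm(2L * n), ncol = 2L)
    rho <- config$re_correlation
    g0 <- config$sd_intercept * z[, 1L]
    g1 <- config$sd_slope * (rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L])
    phq_base <- rnorm(n, config$phq$baseline_mean, config$phq$baseline_sd)
    phq_slope <- config$phq$slope[[g]]

    weeks <- config$weeks
    n_wk <- length(weeks)
    pid <- rep(ids, each = n_wk)
    wk <- rep(weeks, n)
    mu <- fe[["intercept"]] + fe[["slope"]] * wk +
      rep(g0, each = n_wk) + rep(g1, each = n_wk) * wk +
      rnorm(n * n_wk, 0, config$sd_resid)
    mu <- pmin(pmax(mu, 0), 100)
    sev <- rep(phq_base, each = n_wk) + phq_slope * pmax(wk, 0)
    sev <- pmin(pmax(sev, 0), 27)

    n_tok <- pmax(1L, rnbinom(n * n_wk, mu = config$tokens_mean,
                              size = config$tokens_size))
    p <- matrix(0, nrow = n * n_wk, ncol = length(other_names) + 2L,
                dimnames = list(NULL, c("activation", other_names, "filler")))
    p[, "activation"] <- mu / 100
    for (nm in other_names) {
      r <- config$rates[[nm]]
      p[, nm] <- pmax(r[["base"]] + r[["link"]] * (sev - 13), 0)
    }
    p[, "filler"] <- 1 - rowSums(p[, -ncol(p), drop = FALSE])
    if (any(p[, "filler"] < 0)) {
      stop("configured category rates exceed probability 1; reduce base/link rates")
    }
    n_doc <- n * n_wk
    counts <- matrix(0L, nrow = ncol(p), ncol = n_doc)
    for (d in seq_len(n_doc)) {
      counts[, d] <- rmultinom(1L, n_tok[d], p[d, ])
    }
    # batch-draw tokens per category, then reassemble per document
    tok_all <- vector("list", nrow(counts))
    doc_all <- vector("list", nrow(counts))
    for (k in seq_len(nrow(counts))) {
      total <- sum(counts[k, ])
      if (total == 0L) next
      terms <- term_sets[[colnames(p)[k]]]
      tok_all[[k]] <- sample(terms, total, replace = TRUE)
      doc_all[[k]] <- rep.int(seq_len(n_doc), counts[k, ])
    }
    tok_all <- unlist(tok_all, use.names = FALSE)
    doc_all <- unlist(doc_all, use.names = FALSE)
    ord <- order(doc_all, method = "radix")
    tok_sorted <- tok_all[ord]
    cnt <- tabulate(doc_all, nbins = n_doc)
    ends <- cumsum(cnt); starts <- ends - cnt + 1L
    text <- vapply(seq_len(n_doc), function(d) {
      stringi::stri_flatten(tok_sorted[starts[d]:ends[d]], collapse = " ")
    }, "")
    msg_list[[g]] <- tibble::tibble(patient_id = pid, week = wk, text = text)

    sched <- phq_schedule()
    phq_sev <- rep(phq_base, each = length(sched)) +
      phq_slope * rep(sched, n)
    phq_obs <- round(phq_sev + rnorm(n * length(sched), 0, config$phq$resid_sd))
    phq_list[[g]] <- tibble::tibble(
      patient_id = rep(ids, each = length(sched)),
      week = rep(sched, n),
      phq9 = as.integer(pmin(pmax(phq_obs, 0), 27))
    )
    truth_list[[g]] <- tibble::tibble(
      patient_id = ids, group = g, gamma0 = g0, gamma1 = g1,
      phq_baseline = phq_base,
      intercept = fe[["intercept"]], slope = fe[["slope"]]
    )
  }
  structure(
    list(messages = dplyr::bind_rows(msg_list),
         assessments = dplyr::bind_rows(phq_list),
         truth = dplyr::bind_rows(truth_list),
         config = config, seed = as.integer(seed)),
    class = "ba_cohort"
  )
}

#' @export
print.ba_cohort <- function(x, ...) {
  cat("<ba_cohort>", nrow(x$truth), "patients,", nrow(x$messages),
      "weekly messages,", nrow(x$assessments), "PHQ assessments\n")
  invisible(x)
}

#' Export a cohort as plain-text fixture files
#'
#' Writes `chats.csv` (patient_id, week, text), `phq.csv` (patient_id, week,
#' phq9), and `truth.json` (per-patient latent parameters, group labels, and
#' the generating configuration) into a directory. The files round-trip
#' through [read_chat_log()] and [read_phq()].
#'
#' @param cohort A `ba_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
export_fixture <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "ba_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chats <- file.path(out_dir, "chats.csv")
  phq <- file.path(out_dir, "phq.csv")
  truth <- file.path(out_dir, "truth.json")
  write_chat_log(cohort$messages, chats)
  readr::write_csv(cohort$assessments, phq, progress = FALSE)
  jsonlite::write_json(
    list(seed = cohort$seed,
         config = unclass(cohort$config),
         patients = cohort$truth),
    truth, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
  )
  invisible(c(chats = chats, phq = phq, truth = truth))
}
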
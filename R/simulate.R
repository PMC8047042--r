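#' Simulation configuration
#'
#' Defines one emulated longitudinal checklist dataset: cohort size and
#' low-language (LL) prevalence, a synthetic feature-norm lexicon, per-band
#' vocabulary-size distributions with an LL deficit, a structure bias making
#' LL children prefer low-connectivity nouns, demographic category
#' probabilities with missingness, and logistic links from vocabulary size
#' to the grammar items.
#'
#' The LL signal is injected through vocabulary size (`ll_vocab_shift`, a
#' shift on the lognormal log-mean) and through word selection, and the
#' dials are independent so size-only, structure-only and combined signals
#' can be generated. Word-selection has two distinct mechanisms:
#' hub-avoidance (`structure_bias` >= 0; sampling weight proportional to
#' (1 + connectivity)^-bias, thinning the network) and thematic sampling
#' (`theme_bias` >= 0; a randomly chosen lexicon word's graph neighbourhood
#' is boosted, producing one dense cluster and a sparse periphery). Each LL
#' child draws one dominant mechanism (size deficit, hub-avoidance, or
#' thematic vocabulary) plus a mild common size deficit, so the low-language
#' group is heterogeneous: different children are detectable through
#' different measures, as in clinically mixed cohorts.
#'
#' @param n_children cohort size
#' @param prevalence probability of an LL outcome, in (0, 1)
#' @param dataset_id dataset label, also keyed into the band map
#' @param bands data.frame (age_months, n_records): checklist waves and how
#'   many of the children contribute a record at each
#' @param lexicon_size number of nouns in the synthetic lexicon
#' @param n_features size of the semantic feature inventory
#' @param features_per_word integer range (min, max) of features per noun
#' @param n_nonnouns checklist words with no lexicon entry (count toward raw
#'   vocabulary size, excluded from networks)
#' @param vocab_meanlog,vocab_sdlog named per-band lognormal parameters of
#'   typically-developing raw vocabulary size
#' @param ll_vocab_shift additive shift of meanlog for size-deficit LL
#'   children (<= 0); other LL children receive a quarter of it
#' @param structure_bias hub-avoidance sampling bias of structure-mechanism
#'   LL children (0 = none)
#' @param theme_bias multiplicative boost of one random lexicon
#'   neighbourhood for theme-mechanism LL children (0 = none)
#' @param demographic_spec named list: per variable, `levels`, `prob`, `miss`
#' @param grammar_spec logistic-link coefficients from log1p(raw size) to
#'   the combining item and the complexity count, plus a missingness rate
#' @param band_map dataset/age to band map (see [ll_band_map()])
#' @param seed master seed; every component draws from its own derived stream
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_children = 400,
                       prevalence = 0.1,
                       dataset_id = "EIRLI-like",
                       bands = data.frame(age_months = c(16L, 28L),
                                          n_records = c(400L, 400L)),
                       lexicon_size = 160,
                       n_features = 120,
                       features_per_word = c(2L, 4L),
                       n_nonnouns = 60,
                       vocab_meanlog = c(younger = log(55), older = log(120)),
                       vocab_sdlog = c(younger = 0.60, older = 0.45),
                       ll_vocab_shift = -1.3,
                       structure_bias = 3.5,
                       theme_bias = 60,
                       demographic_spec = default_demographic_spec(),
                       grammar_spec = list(comb_a = -0.2, comb_b = 0.15,
                                           cplx_items = 37, cplx_a = -0.6,
                                           cplx_b = 0.15, miss = 0.05),
                       band_map = ll_band_map(),
                       seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1,
            all(bands$n_records <= n_children),
            n_features >= max(features_per_word),
            lexicon_size >= 1, structure_bias >= 0, theme_bias >= 0)
  bands$age_band <- assign_age_band(rep(dataset_id, nrow(bands)),
                                    bands$age_months, band_map)
  stopifnot(all(bands$age_band %in% names(vocab_meanlog)))
  cfg <- list(n_children = n_children, prevalence = prevalence,
              dataset_id = dataset_id, bands = bands,
              lexicon_size = lexicon_size, n_features = n_features,
              features_per_word = features_per_word, n_nonnouns = n_nonnouns,
              vocab_meanlog = vocab_meanlog, vocab_sdlog = vocab_sdlog,
              ll_vocab_shift = ll_vocab_shift,
              structure_bias = structure_bias, theme_bias = theme_bias,
              demographic_spec = demographic_spec, grammar_spec = grammar_spec,
              band_map = band_map, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

default_demographic_spec <- function() {
  list(
    gender = list(levels = c("F", "M"), prob = c(.5, .5), miss = .01),
    race = list(levels = c("white", "hispanic", "black", "asian", "other"),
                prob = c(.60, .18, .10, .07, .05), miss = .05),
    family_history = list(levels = c("no", "yes"), prob = c(.8, .2),
                          miss = .08),
    income = list(levels = c("low", "mid", "high"), prob = c(.2, .5, .3),
                  miss = .10),
    maternal_education = list(
      levels = c("hs", "some_college", "college", "graduate"),
      prob = c(.20, .30, .35, .15), miss = .03),
    paternal_education = list(
      levels = c("hs", "some_college", "college", "graduate"),
      prob = c(.20, .30, .35, .15), miss = .06)
  )
}

#' Preset configurations emulating the two study cohorts
#'
#' `"eirli"`: 391 children, 4.3% LL prevalence, checklist waves at 16 months
#' (314 records) and 28 months (390 records). `"laser"`: 85 children, 14%
#' prevalence, waves at 18 and 27 months (85 records each).
#'
#' @param preset `"eirli"` or `"laser"`
#' @param seed master seed
#' @param ... overrides passed on to [sim_config()]
#' @return a `sim_config`
#' @export
sim_preset <- function(preset = c("eirli", "laser"), seed = 1, ...) {
  preset <- match.arg(preset)
  args <- if (preset == "eirli") {
    list(n_children = 391, prevalence = 17 / 391, dataset_id = "EIRLI-like",
         bands = data.frame(age_months = c(16L, 28L),
                            n_records = c(314L, 390L)))
  } else {
    list(n_children = 85, prevalence = 12 / 85, dataset_id = "LASER-like",
         bands = data.frame(age_months = c(18L, 27L),
                            n_records = c(85L, 85L)))
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, c(args, list(seed = seed)))
}

#' Generate a synthetic semantic-feature lexicon
#'
#' Each of `W` nouns receives a feature set drawn without replacement from a
#' skewed (Zipf-like) feature-frequency distribution, so a few features are
#' shared widely and some nouns become connectivity hubs in the
#' >= 2-shared-feature graph. Deterministic given the seed.
#'
#' @param W number of nouns
#' @param F_n feature inventory size
#' @param features_per_word integer range (min, max) of features per noun
#' @param seed RNG seed
#' @return named list word -> character feature vector
#' @export
generate_lexicon <- function(W, F_n, features_per_word = c(3L, 6L), seed = 1) {
  stopifnot(W >= 1, F_n >= max(features_per_word),
            min(features_per_word) >= 1)
  with_seed(seed, {
    feats <- sprintf("feat%03d", seq_len(F_n))
    wts <- 1 / seq_len(F_n)^0.9
    lex <- lapply(seq_len(W), function(i) {
      k <- sample(seq(features_per_word[1], features_per_word[2]), 1)
      sort(sample(feats, k, prob = wts))
    })
    names(lex) <- sprintf("noun%03d", seq_len(W))
    lex
  })
}

#' Connectivity of each lexicon word in the full-lexicon graph
#'
#' Degree each word would have if every lexicon noun were produced: the
#' number of other nouns sharing at least `min_shared` features. Used as the
#' hub measure that the LL sampling bias avoids.
#'
#' @param lexicon named feature list
#' @param min_shared edge threshold
#' @return named integer vector
#' @export
lexicon_connectivity <- function(lexicon, min_shared = 2) {
  words <- names(lexicon)
  if (length(words) < 2) {
    return(stats::setNames(integer(length(words)), words))
  }
  feats <- unique(unlist(lexicon, use.names = FALSE))
  inc <- vapply(words, function(w) as.integer(feats %in% lexicon[[w]]),
                integer(length(feats)))
  ov <- crossprod(inc)
  diag(ov) <- 0
  stats::setNames(as.integer(colSums(ov >= min_shared)), words)
}

# 0/1 adjacency of the full lexicon graph (>= min_shared shared features)
lexicon_adjacency <- function(lexicon, min_shared = 2) {
  words <- names(lexicon)
  n <- length(words)
  if (n < 2) return(matrix(0L, n, n, dimnames = list(words, words)))
  feats <- unique(unlist(lexicon, use.names = FALSE))
  inc <- vapply(words, function(w) as.integer(feats %in% lexicon[[w]]),
                integer(length(feats)))
  ov <- crossprod(inc)
  diag(ov) <- 0
  a <- (ov >= min_shared) * 1L
  dimnames(a) <- list(words, words)
  a
}

#' Generate a synthetic dataset bundle
#'
#' Draws outcomes, per-band vocabulary sizes, word selections, grammar items
#' and demographics per [sim_config()], and builds the norms table from the
#' empirical typically-developing raw-score quantiles at each age (so the TD
#' median maps to the 50th percentile up to lookup granularity). Each
#' logical component uses its own RNG stream derived from the master seed.
#'
#' @param cfg a `sim_config`
#' @param lexicon optional pre-built lexicon (generated from `cfg` if NULL)
#' @return an `ll_bundle`
#' @export
generate_children <- function(cfg, lexicon = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(lexicon)) {
    lexicon <- generate_lexicon(cfg$lexicon_size, cfg$n_features,
                                cfg$features_per_word,
                                seed = seed_stream(cfg$seed, 11))
  }
  nouns <- names(lexicon)
  nonnouns <- if (cfg$n_nonnouns > 0) {
    sprintf("word%03d", seq_len(cfg$n_nonnouns))
  } else character(0)
  pool <- c(nouns, nonnouns)
  base_freq <- 1 / seq_along(pool)^0.7
  conn <- lexicon_connectivity(lexicon)
  adj <- lexicon_adjacency(lexicon)
  hub_weights <- function(bias) {
    w <- base_freq
    w[seq_along(nouns)] <- w[seq_along(nouns)] * (1 + conn)^(-bias)
    w
  }
  theme_weights <- function(anchor, boost) {
    w <- base_freq
    hood <- c(anchor, which(adj[, anchor] > 0))
    w[hood] <- w[hood] * (1 + boost)
    w
  }

  ids <- sprintf("%s-%04d", sub("-like$", "", cfg$dataset_id),
                 seq_len(cfg$n_children))
  outcome <- with_seed(seed_stream(cfg$seed, 22),
                       stats::rbinom(cfg$n_children, 1, cfg$prevalence))
  # Heterogeneous LL profiles: each LL child draws one dominant mechanism
  # (1 = vocabulary-size deficit, 2 = hub-avoidance, 3 = thematic
  # vocabulary), plus a mild common size deficit. Theme children also get a
  # random anchor word whose lexicon neighbourhood they over-sample.
  mech <- with_seed(seed_stream(cfg$seed, 88), {
    list(kind = sample.int(3, cfg$n_children, replace = TRUE),
         anchor = sample(seq_along(nouns), cfg$n_children, replace = TRUE,
                         prob = (1 + conn)^2))
  })

  # band membership: requested record counts, every child in >= 1 band
  members <- with_seed(seed_stream(cfg$seed, 66), {
    out <- vector("list", nrow(cfg$bands))
    first <- order(cfg$bands$n_records)[nrow(cfg$bands)]
    in_first <- sort(sample.int(cfg$n_children, cfg$bands$n_records[first]))
    out[[first]] <- in_first
    for (b in setdiff(seq_len(nrow(cfg$bands)), first)) {
      need <- cfg$bands$n_records[b]
      must <- setdiff(seq_len(cfg$n_children), in_first)
      stopifnot(length(must) <= need)
      extra <- sample(in_first, need - length(must))
      out[[b]] <- sort(c(must, extra))
    }
    out
  })

  vocab_seed <- seed_stream(cfg$seed, 33)
  word_seed <- seed_stream(cfg$seed, 44)
  gram_seed <- seed_stream(cfg$seed, 55)
  demo_seed <- seed_stream(cfg$seed, 77)

  rec <- list(); wrd <- list()
  for (b in seq_len(nrow(cfg$bands))) {
    idx <- members[[b]]
    band <- cfg$bands$age_band[b]
    age <- cfg$bands$age_months[b]
    size_mult <- ifelse(mech$kind == 1, 1.6, 0.4)  # dominant vs mild deficit
    mlog <- cfg$vocab_meanlog[[band]] +
      outcome[idx] * cfg$ll_vocab_shift * size_mult[idx]
    sizes <- with_seed(seed_stream(vocab_seed, b), {
      pmin(pmax(round(stats::rlnorm(length(idx), mlog,
                                    cfg$vocab_sdlog[[band]])), 1L),
           length(pool))
    })
    words_b <- with_seed(seed_stream(word_seed, b), {
      lapply(seq_along(idx), function(i) {
        ch <- idx[i]
        w <- if (outcome[ch] != 1) base_freq
        else switch(mech$kind[ch],
                    base_freq,                                  # size deficit
                    hub_weights(cfg$structure_bias * 1.6),      # hub-avoidance
                    theme_weights(mech$anchor[ch], cfg$theme_bias))
        sample(pool, sizes[i], prob = w)
      })
    })
    gs <- cfg$grammar_spec
    gram <- with_seed(seed_stream(gram_seed, b), {
      comb <- stats::rbinom(length(idx), 1,
                            stats::plogis(gs$comb_a + gs$comb_b * log1p(sizes)))
      lam <- gs$cplx_items * stats::plogis(gs$cplx_a + gs$cplx_b * log1p(sizes))
      cplx <- pmin(stats::rpois(length(idx), lam), gs$cplx_items)
      comb[stats::runif(length(idx)) < gs$miss] <- NA
      cplx[stats::runif(length(idx)) < gs$miss] <- NA
      list(comb = comb, cplx = cplx)
    })
    rec[[b]] <- data.frame(
      child_id = ids[idx], dataset_id = cfg$dataset_id, age_months = age,
      age_band = band, combines_words = gram$comb,
      complexity_score = gram$cplx, outcome_LL = outcome[idx],
      stringsAsFactors = FALSE
    )
    wrd[[b]] <- data.frame(
      child_id = rep(ids[idx], lengths(words_b)),
      dataset_id = cfg$dataset_id, age_months = age, age_band = band,
      word = unlist(words_b), stringsAsFactors = FALSE
    )
  }
  children <- do.call(rbind, rec)
  words <- do.call(rbind, wrd)

  demo <- with_seed(demo_seed, {
    out <- data.frame(child_id = ids, stringsAsFactors = FALSE)
    for (v in names(cfg$demographic_spec)) {
      sp <- cfg$demographic_spec[[v]]
      x <- sample(sp$levels, cfg$n_children, replace = TRUE, prob = sp$prob)
      x[stats::runif(cfg$n_children) < sp$miss] <- NA
      out[[v]] <- x
    }
    out
  })
  children <- merge(children, demo, by = "child_id", sort = FALSE)
  children <- children[order(children$age_months, children$child_id), ]
  rownames(children) <- NULL

  norms <- td_norms(children, words)
  new_bundle(children, words, lexicon, norms,
             provenance = paste0("synthetic ", cfg$dataset_id,
                                 " seed=", cfg$seed))
}

# Norms table from empirical TD raw-score quantiles at each checklist age.
td_norms <- function(children, words) {
  raw <- table(paste(words$child_id, words$age_months))
  out <- list()
  for (a in unique(children$age_months)) {
    ch <- children[children$age_months == a, ]
    td <- ch[ch$outcome_LL == 0, ]
    if (nrow(td) < 5) td <- ch  # tiny cohorts: fall back to all children
    sizes <- as.integer(raw[paste(td$child_id, a)])
    sizes[is.na(sizes)] <- 0L
    p <- seq(1, 99, by = 2)
    q <- as.integer(stats::quantile(sizes, p / 100, type = 1))
    keep <- !duplicated(q, fromLast = TRUE)  # max percentile per raw score
    out[[length(out) + 1]] <- data.frame(age_months = a, raw_score = q[keep],
                                         percentile = p[keep])
  }
  do.call(rbind, out)
}

#' Permute outcome labels of a bundle
#'
#' Uniform random permutation of the per-child outcome; predictors and the
#' label multiset (hence prevalence) are untouched. Used for null-model
#' checks of the classification pipeline.
#'
#' @param bundle an `ll_bundle`
#' @param seed RNG seed
#' @return the bundle with permuted `outcome_LL`
#' @export
shuffle_labels <- function(bundle, seed = 1) {
  ch <- unique(bundle$children[c("child_id", "outcome_LL")])
  perm <- with_seed(seed, sample(ch$outcome_LL))
  bundle$children$outcome_LL <-
    perm[match(bundle$children$child_id, ch$child_id)]
  bundle
}
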
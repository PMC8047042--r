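# Small shared fixtures, all built in code at test time.

toy_lexicon <- function() {
  list(w1 = c("f1", "f2", "f3"), w2 = c("f1", "f2"), w3 = "f3")
}

# minimal bundle: four children at one age, deterministic content
toy_bundle <- function() {
  children <- data.frame(
    child_id = c("c1", "c2", "c3", "c4"),
    dataset_id = "EIRLI-like", age_months = 16L, age_band = "younger",
    combines_words = c(0, 1, NA, 1), complexity_score = c(0L, 2L, 1L, NA),
    gender = c("F", "M", NA, "F"),
    race = c("white", "white", "black", NA),
    family_history = c("no", "yes", "no", "no"),
    income = rep(NA_character_, 4),
    maternal_education = c("hs", "college", "college", "graduate"),
    paternal_education = c("hs", "college", NA, "graduate"),
    outcome_LL = c(0L, 0L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  words <- data.frame(
    child_id = c("c1", "c1", "c2", "c2", "c2", "c3", "c4", "c4"),
    dataset_id = "EIRLI-like", age_months = 16L, age_band = "younger",
    word = c("apple", "eye", "apple", "ball", "zork", "zork", "balloon",
             "eye"),
    stringsAsFactors = FALSE
  )
  norms <- data.frame(age_months = 16L, raw_score = c(0L, 1L, 2L, 3L),
                      percentile = c(10, 25, 50, 75))
  new_bundle(children, words, example_lexicon(), norms, "toy")
}

toy_norms <- function() {
  data.frame(age_months = 18L, raw_score = c(10L, 50L, 100L),
             percentile = c(25, 50, 75))
}

# feature table with a controllable number of informative numeric features;
# remaining predictors are noise. Used for model-layer unit tests.
toy_feature_table <- function(n = 120, prevalence = 0.25, seed = 1,
                              signal = 2.5) {
  set.seed(seed)
  y <- rbinom(n, 1, prevalence)
  num <- function(eff) rnorm(n, mean = eff * y)
  df <- data.frame(
    child_id = sprintf("t%03d", seq_len(n)),
    dataset_id = "other", age_band = "younger", quality_flag = "ok",
    meanBC = num(signal), MD = num(signal), meanHC = num(0), MPL = num(0),
    GCC = num(0), vocab_percentile = runif(n, 0, 100),
    combines_words = rbinom(n, 1, 0.6), complexity_score = rpois(n, 3),
    stringsAsFactors = FALSE
  )
  for (v in ll_demographics()) {
    df[[v]] <- factor(sample(c("a", "b", "missing"), n, replace = TRUE,
                             prob = c(.45, .45, .1)),
                      levels = c("a", "b", "missing"))
  }
  df$outcome_LL <- y
  class(df) <- c("ll_features", "data.frame")
  df
}

quiet_features <- function(...) suppressMessages(assemble_features(...))
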
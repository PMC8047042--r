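# reduced forests keep these unit tests fast; the full-scale protocol is
# exercised by the acceptance suite
fast_cfg <- function(...) {
  args <- list(ntree = 100, inner_repeats = 1, outer_repeats = 1, n_runs = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(rf_config, args)
}
net6 <- c("meanBC", "MD", "meanHC", "MPL", "GCC", "vocab_percentile")

single_signal_table <- function(n = 150, seed = 1, eff = 3) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.3)
  df <- data.frame(child_id = sprintf("c%03d", 1:n),
                   meanBC = rnorm(n, eff * y), MD = rnorm(n),
                   meanHC = rnorm(n), MPL = rnorm(n), GCC = rnorm(n),
                   vocab_percentile = runif(n, 0, 100), outcome_LL = y)
  df
}

test_that("a single predictive feature ranks first with positive importance", {
  wins <- 0
  for (s in 1:10) {
    imp <- drop_one_importance(single_signal_table(seed = s), net6,
                               fast_cfg(), seed = 100 + s)
    if (imp$feature[1] == "meanBC" && imp$importance[1] > 0) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("an exact duplicate column scores at most the unique signal", {
  diffs <- vapply(1:3, function(s) {
    d <- single_signal_table(seed = 20 + s)
    d$MD <- d$meanBC            # redundant twin of the informative feature
    d$MPL <- rnorm(nrow(d), 1.5 * d$outcome_LL)  # unique second signal
    imp <- drop_one_importance(d, net6, fast_cfg(inner_repeats = 2),
                               seed = 200 + s)
    v <- stats::setNames(imp$importance, imp$feature)
    v["MPL"] - max(v["meanBC"], v["MD"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("pure-noise features have importances near zero", {
  d <- single_signal_table(seed = 31, eff = 0)
  imp <- drop_one_importance(d, net6, fast_cfg(inner_repeats = 2), seed = 300)
  expect_lt(max(abs(imp$importance)), 6)       # percentage points
  expect_lt(abs(mean(imp$importance)), 2.5)
})

test_that("importance ties break alphabetically and ranks are a permutation", {
  d <- single_signal_table(seed = 32)
  imp <- drop_one_importance(d, net6, fast_cfg(), seed = 301)
  expect_setequal(imp$rank, seq_along(net6))
  ties <- split(imp$feature, imp$importance)
  for (g in ties) expect_identical(g, sort(g))
})

test_that("tuned mtry comes from the grid", {
  d <- single_signal_table(seed = 33)
  m <- tune_mtry(d, net6, grid = c(2, 4, 6), rf_cfg = fast_cfg(), seed = 5)
  expect_true(m %in% c(2, 4, 6))
})

test_that("nested CV keeps outer-test rows out of every inner computation", {
  ft <- toy_feature_table(n = 120, seed = 2)
  fit <- nested_cv_fit(ft, fast_cfg(n_select = 5), seed = 11)
  expect_equal(fit$audit$max_test_train_overlap, 0)
  # each child scored exactly once per (run, repeat)
  expect_equal(nrow(fit$predictions), 120)
  expect_setequal(fit$predictions$child_id, ft$child_id)
})

test_that("nested CV is reproducible and honours degenerate selection", {
  ft <- toy_feature_table(n = 100, seed = 3)
  f1 <- nested_cv_fit(ft, fast_cfg(), seed = 12)
  f2 <- nested_cv_fit(ft, fast_cfg(), seed = 12)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$run_balacc, f2$run_balacc)

  all_p <- nested_cv_fit(ft, fast_cfg(n_select = 14), seed = 13)
  for (fi in all_p$fold_info) {
    expect_setequal(fi$selected, intersect(ll_predictor_names(), names(ft)))
  }
})

test_that("nested CV rejects tables it cannot stratify", {
  ft <- toy_feature_table(n = 60, seed = 4)
  ft$outcome_LL <- 0L
  expect_error(nested_cv_fit(ft, fast_cfg(), seed = 1))
  ft$outcome_LL <- c(1L, rep(0L, 59))
  expect_error(nested_cv_fit(ft, fast_cfg(), seed = 1), "too few minority")
})

test_that("a strong signal is recovered with high out-of-fold accuracy", {
  ft <- toy_feature_table(n = 150, seed = 5, signal = 3)
  fit <- nested_cv_fit(ft, fast_cfg(n_select = 5), seed = 14)
  expect_gt(mean(fit$run_balacc), 0.8)
  expect_gt(fit$selection[["meanBC"]], 0.5)
})

test_that("final models score external tables and detect schema mismatch", {
  ft_a <- toy_feature_table(n = 140, seed = 6, signal = 3)
  ft_b <- toy_feature_table(n = 140, seed = 7, signal = 3)
  model <- fit_final_model(ft_a, fast_cfg(n_select = 5), seed = 15)
  expect_length(model$features, 5)

  # resubstitution consistency: repeated scoring of the source is identical
  p1 <- predict(model, ft_a)
  p2 <- predict(model, ft_a)
  expect_identical(p1, p2)

  pb <- external_validate(model, ft_b)
  expect_equal(nrow(pb), 140)
  m <- screening_metrics(confusion(pb$label, pb$pred))
  expect_gt(m$balanced_accuracy, 0.7)

  # unseen factor levels fold into the missing level rather than erroring
  ft_c <- ft_b
  levels(ft_c$gender) <- c("x", "y", "missing")
  expect_silent(external_validate(model, ft_c))

  ft_d <- ft_b[setdiff(names(ft_b), model$features[1])]
  expect_error(external_validate(model, ft_d), model$features[1])
})

test_that("SMOTE inside training uses only training rows (convexity audit)", {
  ft <- toy_feature_table(n = 90, seed = 8)
  num <- c("meanBC", "MD", "meanHC", "MPL", "GCC", "vocab_percentile",
           "combines_words", "complexity_score")
  out <- smote_oversample(ft, intersect(ll_predictor_names(), names(ft)),
                          smote_config(), seed = 16)
  syn <- out[attr(out, "synthetic"), ]
  mino <- ft[ft$outcome_LL == 1, ]
  for (v in num) {
    expect_true(all(syn[[v]] >= min(mino[[v]]) - 1e-9))
    expect_true(all(syn[[v]] <= max(mino[[v]]) + 1e-9))
  }
})
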
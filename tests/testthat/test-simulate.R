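test_that("lexicon generation is deterministic and validates parameters", {
  l1 <- generate_lexicon(30, 20, c(2, 5), seed = 9)
  l2 <- generate_lexicon(30, 20, c(2, 5), seed = 9)
  expect_identical(l1, l2)
  expect_length(l1, 30)
  expect_true(all(lengths(l1) >= 2 & lengths(l1) <= 5))
  expect_length(generate_lexicon(1, 5, c(2, 3), seed = 1), 1)
  expect_error(generate_lexicon(10, 3, c(2, 5)), "F_n")
})

test_that("bundle generation is deterministic given the seed", {
  cfg <- sim_preset("laser", seed = 4)
  b1 <- generate_children(cfg)
  b2 <- generate_children(cfg)
  expect_identical(b1$children, b2$children)
  expect_identical(b1$words, b2$words)
  expect_identical(b1$lexicon, b2$lexicon)
})

test_that("presets reproduce the two cohort designs", {
  e <- generate_children(sim_preset("eirli", seed = 2))
  se <- dataset_summary(e)
  expect_equal(se$n_children, 391)
  expect_equal(as.vector(se$records_per_band[c("younger", "older")]),
               c(314, 390))
  l <- generate_children(sim_preset("laser", seed = 2))
  sl <- dataset_summary(l)
  expect_equal(sl$n_children, 85)
  expect_equal(as.vector(sl$records_per_band[c("younger", "older")]),
               c(85, 85))
  # every child appears in at least one band
  expect_setequal(unique(e$children$child_id), sprintf("EIRLI-%04d", 1:391))
})

test_that("positive counts match the configured prevalence in expectation", {
  pos <- vapply(1:10, function(s) {
    dataset_summary(generate_children(sim_preset("eirli", seed = s)))$n_positive
  }, numeric(1))
  # Binomial(391, 17/391): mean 17, sd of the 10-seed mean ~ 1.3
  expect_gt(mean(pos), 12)
  expect_lt(mean(pos), 22)
})

test_that("with all group dials at zero the groups are exchangeable", {
  sizes_td <- c(); sizes_ll <- c(); md_td <- c(); md_ll <- c()
  for (s in 1:5) {
    cfg <- sim_config(n_children = 200, prevalence = 0.2,
                      ll_vocab_shift = 0, structure_bias = 0, theme_bias = 0,
                      bands = data.frame(age_months = 16L, n_records = 200L),
                      seed = s)
    b <- generate_children(cfg)
    ft <- quiet_features(b, band = "younger")
    sizes_td <- c(sizes_td, ft$vocab_percentile[ft$outcome_LL == 0])
    sizes_ll <- c(sizes_ll, ft$vocab_percentile[ft$outcome_LL == 1])
    md_td <- c(md_td, ft$MD[ft$outcome_LL == 0])
    md_ll <- c(md_ll, ft$MD[ft$outcome_LL == 1])
  }
  expect_gt(suppressWarnings(stats::ks.test(sizes_td, sizes_ll))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(md_td, md_ll))$p.value, 0.01)
})

test_that("the structure-bias dial moves the group gap monotonically", {
  gap <- function(bias) {
    g_md <- 0; g_gcc <- 0
    for (s in 1:4) {
      cfg <- sim_config(n_children = 300, prevalence = 0.2,
                        ll_vocab_shift = 0, structure_bias = bias,
                        bands = data.frame(age_months = 16L, n_records = 300L),
                        seed = 100 + s)
      ft <- quiet_features(generate_children(cfg), band = "younger")
      g_md <- g_md + mean(ft$MD[ft$outcome_LL == 0]) -
        mean(ft$MD[ft$outcome_LL == 1])
      g_gcc <- g_gcc + mean(ft$GCC[ft$outcome_LL == 0]) -
        mean(ft$GCC[ft$outcome_LL == 1])
    }
    c(md = g_md, gcc = g_gcc) / 4
  }
  g0 <- gap(0); g1 <- gap(1.2); g2 <- gap(2.5)
  expect_lt(g0["md"], g1["md"]); expect_lt(g1["md"], g2["md"])
  expect_lt(g0["gcc"], g1["gcc"]); expect_lt(g1["gcc"], g2["gcc"])
})

test_that("generated norms map the TD median near the 50th percentile", {
  cfg <- sim_config(n_children = 300, prevalence = 0.1,
                    bands = data.frame(age_months = 16L, n_records = 300L),
                    seed = 6)
  b <- generate_children(cfg)
  td <- b$children$child_id[b$children$outcome_LL == 0]
  raw <- table(b$words$child_id[b$words$child_id %in% td])
  med <- stats::median(as.integer(raw))
  p <- vocabulary_percentile(med, 16, b$norms)
  expect_gte(p, 45); expect_lte(p, 55)
})

test_that("label shuffling permutes outcomes without touching predictors", {
  b <- generate_children(sim_preset("laser", seed = 3))
  sh <- shuffle_labels(b, seed = 10)
  expect_identical(sh$words, b$words)
  expect_equal(sort(unique(sh$children[c("child_id", "outcome_LL")])$outcome_LL),
               sort(unique(b$children[c("child_id", "outcome_LL")])$outcome_LL))
  expect_identical(shuffle_labels(b, seed = 10)$children, sh$children)
  # per-child consistency across bands
  per <- unique(sh$children[c("child_id", "outcome_LL")])
  expect_equal(nrow(per), 85)
})

test_that("two-row shuffle yields one of the two permutations", {
  b <- toy_bundle()
  b$children <- b$children[1:2, ]
  b$children$outcome_LL <- c(0L, 1L)
  b$words <- b$words[b$words$child_id %in% c("c1", "c2"), ]
  sh <- shuffle_labels(b, seed = 2)
  expect_setequal(sh$children$outcome_LL, c(0L, 1L))
})
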
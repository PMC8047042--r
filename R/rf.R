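#' Random-forest pipeline configuration
#'
#' Defaults mirror the full study protocol: 500-tree forests, mtry tuned
#' from 2 up to the number of retained features, 3-fold x 10-repeat outer
#' cross-validation, 5-fold x 10-repeat inner feature-selection loop,
#' 100 training runs, and pruning to the top 7 of the 14 predictors.
#' `desk_scale()` returns the reduced preset used for interactive work and
#' tests (5 runs, 3x2 outer, 5x2 inner).
#'
#' @param ntree trees per forest
#' @param mtry_grid candidate mtry values (NULL = 2..#selected features)
#' @param outer_folds,outer_repeats outer CV shape
#' @param inner_folds,inner_repeats inner (feature selection / tuning) shape
#' @param n_runs independent training runs
#' @param n_select features kept after importance pruning
#' @return list of class `rf_config`
#' @export
rf_config <- function(ntree = 500, mtry_grid = NULL,
                      outer_folds = 3, outer_repeats = 10,
                      inner_folds = 5, inner_repeats = 10,
                      n_runs = 100, n_select = 7) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, n_select >= 1, ntree >= 1)
  structure(list(ntree = ntree, mtry_grid = mtry_grid,
                 outer_folds = outer_folds, outer_repeats = outer_repeats,
                 inner_folds = inner_folds, inner_repeats = inner_repeats,
                 n_runs = n_runs, n_select = n_select),
            class = "rf_config")
}

#' @rdname rf_config
#' @param ... overrides applied on top of the desk-scale preset
#' @export
desk_scale <- function(...) {
  args <- list(outer_repeats = 2, inner_repeats = 2, n_runs = 5)
  over <- list(...)
  args[names(over)] <- over
  do.call(rf_config, args)
}

fit_forest <- function(data, predictors, label = "outcome_LL",
                       mtry = NULL, ntree = 500, seed = 1,
                       probability = FALSE) {
  y <- factor(data[[label]], levels = c(0, 1))
  p <- length(predictors)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(p)))
  ranger::ranger(x = data[predictors], y = y,
                 num.trees = ntree, mtry = min(mtry, p),
                 probability = probability,
                 num.threads = 1, seed = seed,
                 respect.unordered.factors = "ignore")
}

forest_scores <- function(model, data, predictors) {
  # fixed predict seed: vote ties must not read (or advance) the global RNG
  pr <- stats::predict(model, data = data[predictors], num.threads = 1,
                       seed = 1L)
  if (model$treetype == "Probability estimation") {
    as.numeric(pr$predictions[, "1"])
  } else {
    as.numeric(as.character(pr$predictions))
  }
}

# plain accuracy (fraction correct), the importance criterion
fold_accuracy <- function(model, test, predictors, label = "outcome_LL") {
  pred <- forest_scores(model, test, predictors)
  mean((pred >= 0.5) == (test[[label]] == 1))
}

fold_balacc <- function(model, test, predictors, label = "outcome_LL") {
  pred <- as.integer(forest_scores(model, test, predictors) >= 0.5)
  screening_metrics(confusion(test[[label]], pred))$balanced_accuracy
}

numeric_predictors <- function(data, predictors) {
  predictors[vapply(data[predictors], is.numeric, logical(1))]
}

# One inner CV pass shared by importance ranking and mtry tuning:
# stratified folds, train-fold median imputation, SMOTE on the training
# partition only, candidate models scored on the untouched held-out fold.
inner_cv <- function(data, predictors, rf_cfg, smote_cfg, seed, score_fun) {
  y <- data$outcome_LL
  scores <- NULL
  cnt <- 0
  for (rep in seq_len(rf_cfg$inner_repeats)) {
    folds <- stratified_folds(y, rf_cfg$inner_folds, seed_stream(seed, rep))
    for (f in seq_len(rf_cfg$inner_folds)) {
      tr <- data[folds != f, , drop = FALSE]
      te <- data[folds == f, , drop = FALSE]
      if (length(unique(tr$outcome_LL)) < 2 || nrow(te) == 0) next
      imp <- impute_median(tr, te, numeric_predictors(data, predictors))
      tr_s <- smote_oversample(imp$train, predictors, smote_cfg,
                               seed = seed_stream(seed, 100 * rep + f))
      s <- score_fun(tr_s, imp$test, seed_stream(seed, 1000 + 100 * rep + f))
      scores <- if (is.null(scores)) s else scores + s
      cnt <- cnt + 1
    }
  }
  if (cnt == 0) stop("no usable inner fold (a training partition was single-class)")
  scores / cnt
}

#' Drop-one retraining feature importance
#'
#' For each feature, importance is the percentage-point difference in
#' classification accuracy between the full model and a model retrained
#' without that feature, both evaluated on inner cross-validation held-out
#' folds (SMOTE applied to each inner training partition first) and averaged
#' over folds and repeats. Ties in rank are broken alphabetically.
#'
#' @param data feature table rows (training partition)
#' @param predictors features to rank
#' @param rf_cfg an [rf_config()] (inner_* fields and ntree are used)
#' @param smote_cfg a [smote_config()]
#' @param seed RNG seed
#' @return data.frame of class `importance_report`: feature, importance
#'   (accuracy percentage points), rank
#' @export
drop_one_importance <- function(data, predictors, rf_cfg = desk_scale(),
                                smote_cfg = smote_config(), seed = 1) {
  stopifnot(length(predictors) >= 2)
  score_fun <- function(train, test, s) {
    full <- fit_forest(train, predictors, ntree = rf_cfg$ntree, seed = s)
    acc_full <- fold_accuracy(full, test, predictors)
    vapply(seq_along(predictors), function(j) {
      drop <- predictors[-j]
      m <- fit_forest(train, drop, ntree = rf_cfg$ntree,
                      seed = seed_stream(s, j))
      acc_full - fold_accuracy(m, test, drop)
    }, numeric(1))
  }
  imp <- inner_cv(data, predictors, rf_cfg, smote_cfg, seed, score_fun) * 100
  ord <- order(-imp, predictors)
  out <- data.frame(feature = predictors, importance = imp,
                    rank = match(seq_along(predictors), ord))
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Tune mtry by inner cross-validated balanced accuracy
#'
#' Evaluates each candidate mtry on the same inner-CV scheme as
#' [drop_one_importance()]; ties go to the smaller mtry (balanced accuracy
#' is used because SMOTE-balanced folds make it nearly identical to plain
#' accuracy while staying defined under residual imbalance).
#'
#' @inheritParams drop_one_importance
#' @param grid candidate mtry values (default 2..length(predictors))
#' @return the selected mtry (integer)
#' @export
tune_mtry <- function(data, predictors, grid = NULL, rf_cfg = desk_scale(),
                      smote_cfg = smote_config(), seed = 1) {
  p <- length(predictors)
  if (is.null(grid)) grid <- seq(min(2, p), p)
  grid <- grid[grid <= p]
  score_fun <- function(train, test, s) {
    vapply(seq_along(grid), function(g) {
      m <- fit_forest(train, predictors, mtry = grid[g],
                      ntree = rf_cfg$ntree, seed = seed_stream(s, g))
      fold_balacc(m, test, predictors)
    }, numeric(1))
  }
  ba <- inner_cv(data, predictors, rf_cfg, smote_cfg, seed, score_fun)
  grid[which.max(ba)]  # which.max takes the first (smallest) on ties
}

row_fingerprint <- function(data, predictors) {
  apply(cbind(id = data$child_id, data[predictors]), 1, paste, collapse = "|")
}

#' Nested cross-validated random-forest fit
#'
#' For every training run, outer repeat and outer fold: the inner loop
#' (SMOTE balancing, drop-one importance ranking, pruning to the top
#' `n_select` features, mtry tuning) runs on the outer-training partition
#' only; a final forest is then trained on that partition with the selected
#' features and SMOTE, and scored on the untouched outer-test fold.
#' Out-of-fold predictions, per-(run, repeat) balanced accuracies, feature
#' selection frequencies and a leakage audit (outer-test row fingerprints
#' are checked against every inner-loop input) are returned.
#'
#' @param table an `ll_features` table (both classes present; at least
#'   `outer_folds` positive cases so folds can be stratified)
#' @param rf_cfg an [rf_config()]
#' @param smote_cfg a [smote_config()]
#' @param seed master seed
#' @return object of class `ll_fit`: list with `predictions` (child_id, run,
#'   rep, fold, score, pred, label), `run_balacc`, `selection` (per-feature
#'   selection frequency), `fold_info`, `audit`, `config`, `seed`
#' @export
nested_cv_fit <- function(table, rf_cfg = desk_scale(),
                          smote_cfg = smote_config(), seed = 1) {
  predictors <- intersect(ll_predictor_names(), names(table))
  y <- table$outcome_LL
  stopifnot(length(unique(y)) == 2, nrow(table) >= 2 * rf_cfg$outer_folds)
  if (min(table(y)) < rf_cfg$outer_folds) {
    stop("too few minority cases to stratify ", rf_cfg$outer_folds,
         " outer folds")
  }
  num <- numeric_predictors(table, predictors)
  preds <- list(); fold_info <- list(); balacc <- c()
  sel_count <- stats::setNames(numeric(length(predictors)), predictors)
  n_folds_total <- 0
  max_overlap <- 0L

  for (run in seq_len(rf_cfg$n_runs)) {
    run_seed <- seed_stream(seed, 7000 + run)
    for (rep in seq_len(rf_cfg$outer_repeats)) {
      folds <- stratified_folds(y, rf_cfg$outer_folds,
                                seed_stream(run_seed, rep))
      rep_pred <- list()
      for (f in seq_len(rf_cfg$outer_folds)) {
        tr <- table[folds != f, , drop = FALSE]
        te <- table[folds == f, , drop = FALSE]
        if (length(unique(tr$outcome_LL)) < 2) {
          stop("single-class outer training fold; reduce outer_folds")
        }
        fseed <- seed_stream(run_seed, 100 * rep + f)
        te_hash <- row_fingerprint(te, predictors)

        imp <- drop_one_importance(tr, predictors, rf_cfg, smote_cfg,
                                   seed = fseed)
        sel <- imp$feature[seq_len(min(rf_cfg$n_select, nrow(imp)))]
        mtry <- tune_mtry(tr, sel, rf_cfg$mtry_grid, rf_cfg, smote_cfg,
                          seed = seed_stream(fseed, 2))

        im <- impute_median(tr, te, num)
        tr_s <- smote_oversample(im$train, predictors, smote_cfg,
                                 seed = seed_stream(fseed, 3))
        max_overlap <- max(max_overlap, length(intersect(
          te_hash, row_fingerprint(tr_s[!attr(tr_s, "synthetic"), ],
                                   predictors))))
        model <- fit_forest(tr_s, sel, mtry = mtry, ntree = rf_cfg$ntree,
                            seed = seed_stream(fseed, 4), probability = TRUE)
        score <- forest_scores(model, im$test, sel)
        rep_pred[[f]] <- data.frame(
          child_id = te$child_id, run = run, rep = rep, fold = f,
          score = score, pred = as.integer(score >= 0.5),
          label = te$outcome_LL, stringsAsFactors = FALSE
        )
        sel_count[sel] <- sel_count[sel] + 1
        n_folds_total <- n_folds_total + 1
        fold_info[[length(fold_info) + 1]] <- list(
          run = run, rep = rep, fold = f, selected = sel, mtry = mtry,
          importance = imp
        )
      }
      rp <- do.call(rbind, rep_pred)
      preds[[length(preds) + 1]] <- rp
      balacc <- c(balacc, screening_metrics(
        confusion(rp$label, rp$pred))$balanced_accuracy)
    }
  }
  out <- list(
    predictions = do.call(rbind, preds),
    run_balacc = balacc,
    selection = sel_count / n_folds_total,
    fold_info = fold_info,
    audit = list(max_test_train_overlap = max_overlap),
    config = rf_cfg, smote = smote_cfg, seed = seed
  )
  class(out) <- "ll_fit"
  out
}

#' @export
print.ll_fit <- function(x, ...) {
  cm <- confusion(x$predictions$label, x$predictions$pred)
  sm <- screening_metrics(cm)
  cat(sprintf(
    "nested-CV fit: %d runs x %d repeats x %d folds; pooled balanced accuracy %.3f\n",
    x$config$n_runs, x$config$outer_repeats, x$config$outer_folds,
    sm$balanced_accuracy))
  top <- sort(x$selection, decreasing = TRUE)
  cat("selection frequency:",
      paste0(names(top)[1:min(7, length(top))], "=",
             round(top[1:min(7, length(top))], 2), collapse = ", "), "\n")
  invisible(x)
}

#' Train a single deployable model on a whole dataset
#'
#' Runs the inner feature-selection loop (drop-one importance, top
#' `n_select` pruning, mtry tuning) on the full table, then fits one
#' SMOTE-balanced probability forest. Training factor levels and imputation
#' medians are stored so the model can score external datasets.
#'
#' @inheritParams nested_cv_fit
#' @return object of class `ll_model`
#' @export
fit_final_model <- function(table, rf_cfg = desk_scale(),
                            smote_cfg = smote_config(), seed = 1) {
  predictors <- intersect(ll_predictor_names(), names(table))
  imp <- drop_one_importance(table, predictors, rf_cfg, smote_cfg,
                             seed = seed_stream(seed, 1))
  sel <- imp$feature[seq_len(min(rf_cfg$n_select, nrow(imp)))]
  mtry <- tune_mtry(table, sel, rf_cfg$mtry_grid, rf_cfg, smote_cfg,
                    seed = seed_stream(seed, 2))
  num <- numeric_predictors(table, predictors)
  medians <- vapply(table[num], function(x) {
    m <- stats::median(x, na.rm = TRUE); if (is.na(m)) 0 else m
  }, numeric(1))
  tr <- table
  for (v in num) tr[[v]][is.na(tr[[v]])] <- medians[[v]]
  tr_s <- smote_oversample(tr, predictors, smote_cfg,
                           seed = seed_stream(seed, 3))
  forest <- fit_forest(tr_s, sel, mtry = mtry, ntree = rf_cfg$ntree,
                       seed = seed_stream(seed, 4), probability = TRUE)
  levels_map <- lapply(table[predictors[vapply(table[predictors], is.factor,
                                               logical(1))]], levels)
  structure(list(forest = forest, features = sel, mtry = mtry,
                 importance = imp, medians = medians,
                 levels = levels_map, threshold = 0.5),
            class = "ll_model")
}

#' @export
print.ll_model <- function(x, ...) {
  cat("screening model:", length(x$features), "features (",
      paste(x$features, collapse = ", "), "), mtry =", x$mtry, "\n")
  invisible(x)
}

#' Score new data with a trained model
#'
#' Factor levels unseen in training are mapped to the `"missing"` level;
#' missing numerics are imputed with the training medians. No row of
#' `newdata` influences the model.
#'
#' @param object an `ll_model`
#' @param newdata a compatible feature table
#' @param ... unused
#' @return data.frame (child_id, score, pred, label)
#' @export
predict.ll_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss) > 0) {
    stop("newdata lacks model feature(s): ", paste(miss, collapse = ", "))
  }
  for (v in names(object$levels)) {
    if (!v %in% names(newdata)) next
    x <- as.character(newdata[[v]])
    x[!x %in% object$levels[[v]]] <- "missing"
    newdata[[v]] <- factor(x, levels = object$levels[[v]])
  }
  for (v in names(object$medians)) {
    if (!v %in% names(newdata)) next
    newdata[[v]][is.na(newdata[[v]])] <- object$medians[[v]]
  }
  score <- forest_scores(object$forest, newdata, object$features)
  data.frame(child_id = newdata$child_id %||% seq_len(nrow(newdata)),
             score = score,
             pred = as.integer(score >= object$threshold),
             label = newdata$outcome_LL %||% NA_integer_,
             stringsAsFactors = FALSE)
}

#' External validation: score dataset B with a model trained on dataset A
#'
#' @param model an `ll_model` trained on the source dataset
#' @param table_b feature table of the target dataset (same predictor schema)
#' @return data.frame of predictions (see [predict.ll_model()])
#' @export
external_validate <- function(model, table_b) {
  predict(model, table_b)
}
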
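#' Names of the 14 model predictors
#'
#' Five vocabulary-structure measures, vocabulary-size percentile, two early
#' grammar items and six demographic variables.
#' @return character vector of length 14, in the fixed column order used by
#'   [assemble_features()]
#' @export
ll_predictor_names <- function() {
  c("meanBC", "MD", "meanHC", "MPL", "GCC",
    "vocab_percentile", "combines_words", "complexity_score",
    ll_demographics())
}

# Word-combining checklist item: "Not Yet" scores 0, "Sometimes" and
# "Often" both score 1. Numeric 0/1 passes through; NA propagates.
encode_combines <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x))) {
      stop("numeric combines_words values must be 0, 1 or NA")
    }
    return(as.numeric(x))
  }
  key <- gsub("[ _]", "", tolower(trimws(as.character(x))))
  out <- rep(NA_real_, length(key))
  out[key %in% c("notyet", "0")] <- 0
  out[key %in% c("sometimes", "often", "1")] <- 1
  bad <- !is.na(key) & key != "" & key != "na" & is.na(out)
  if (any(bad)) {
    stop("unrecognized combines_words response(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Encode a record's two grammar items
#'
#' @param combines_words raw word-combining response ("Not Yet" /
#'   "Sometimes" / "Often", or 0/1)
#' @param complexity_score non-negative integer count of morpho-syntactic
#'   items endorsed
#' @return list with numeric `combines_words` (0/1/NA) and integer
#'   `complexity_score` (NA allowed; imputed downstream within training
#'   folds)
#' @export
encode_grammar <- function(combines_words, complexity_score) {
  cs <- suppressWarnings(as.integer(complexity_score))
  if (any(!is.na(cs) & cs < 0)) stop("complexity_score must be >= 0")
  list(combines_words = encode_combines(combines_words),
       complexity_score = cs)
}

#' Vocabulary-size percentile lookup
#'
#' Step-function lookup against a norms table: the percentile of the largest
#' tabulated raw score not exceeding the input, clamped to the table's range
#' (a raw score below the smallest row returns that age's minimum
#' percentile). For fixed age the result is non-decreasing in raw score.
#'
#' @param raw_score non-negative integer total productive vocabulary
#' @param age_months checklist age; must be covered by the norms
#' @param norms norms table (age_months, raw_score, percentile)
#' @return percentile in \[0, 100\] (vectorized over raw_score/age_months)
#' @export
vocabulary_percentile <- function(raw_score, age_months, norms) {
  stopifnot(all(raw_score >= 0))
  n <- max(length(raw_score), length(age_months))
  raw_score <- rep_len(raw_score, n)
  age_months <- rep_len(age_months, n)
  out <- numeric(n)
  for (a in unique(age_months)) {
    sub <- norms[norms$age_months == a, ]
    if (nrow(sub) == 0) stop("norms table does not cover age ", a, " months")
    sub <- sub[order(sub$raw_score), ]
    i <- which(age_months == a)
    pos <- findInterval(raw_score[i], sub$raw_score)
    out[i] <- sub$percentile[pmax(pos, 1)]
  }
  pmin(pmax(out, 0), 100)
}

#' Per-record network metrics for a whole bundle
#'
#' Builds each (child, age) record's noun-feature network from its produced
#' words and the bundle lexicon, and computes the five structure measures.
#'
#' @param bundle an `ll_bundle`
#' @param min_shared edge threshold passed to [build_network()]
#' @param variant,normalized passed to [compute_all_metrics()]
#' @return data.frame keyed by (child_id, age_months) with age_band,
#'   n_nodes, n_edges, MPL, GCC, MD, meanBC, meanHC, quality_flag
#' @export
metrics_for_bundle <- function(bundle, min_shared = 2,
                               variant = c("mean-local", "transitivity"),
                               normalized = FALSE) {
  variant <- match.arg(variant)
  keys <- unique(bundle$children[c("child_id", "age_months", "age_band")])
  wkey <- paste(bundle$words$child_id, bundle$words$age_months)
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    w <- bundle$words$word[wkey == paste(keys$child_id[i], keys$age_months[i])]
    net <- suppressWarnings(build_network(w, bundle$lexicon, min_shared))
    m <- compute_all_metrics(net, variant, normalized)
    rows[[i]] <- data.frame(
      child_id = keys$child_id[i], age_months = keys$age_months[i],
      age_band = keys$age_band[i], n_nodes = m$n_nodes, n_edges = m$n_edges,
      MPL = m$MPL, GCC = m$GCC, MD = m$MD, meanBC = m$meanBC,
      meanHC = m$meanHC, quality_flag = m$quality_flag,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Assemble the 14-predictor modeling table
#'
#' Joins per-record network metrics, the vocabulary-size percentile (raw
#' size = count of ALL produced checklist words, lexicon nouns or not), the
#' two grammar items and the six demographics into one row per record, then
#' attaches the binary outcome. Demographic missingness becomes an explicit
#' `"missing"` factor level so models see it; numeric missingness is left as
#' NA for within-fold imputation. Predictors are computed before the label
#' is joined, so no predictor can read the outcome.
#'
#' @param bundle an `ll_bundle`
#' @param metrics output of [metrics_for_bundle()] (computed if NULL)
#' @param band optional band filter (`"younger"` / `"older"`)
#' @param min_shared edge threshold if metrics are computed here
#' @return data.frame of class `ll_features`: metadata columns (child_id,
#'   dataset_id, age_band, quality_flag), the 14 predictors in
#'   [ll_predictor_names()] order, then `outcome_LL`
#' @export
assemble_features <- function(bundle, metrics = NULL, band = NULL,
                              min_shared = 2) {
  ch <- bundle$children
  if (!is.null(band)) ch <- ch[ch$age_band == band, ]
  if (is.null(metrics)) metrics <- metrics_for_bundle(bundle, min_shared)
  key <- paste(ch$child_id, ch$age_months)
  mi <- match(key, paste(metrics$child_id, metrics$age_months))
  if (anyNA(mi)) {
    stop("records without network metrics: ",
         paste(unique(ch$child_id[is.na(mi)]), collapse = ", "))
  }
  m <- metrics[mi, ]

  raw <- table(paste(bundle$words$child_id, bundle$words$age_months))
  raw_score <- as.integer(raw[key])
  raw_score[is.na(raw_score)] <- 0L

  pred <- data.frame(
    meanBC = m$meanBC, MD = m$MD, meanHC = m$meanHC, MPL = m$MPL, GCC = m$GCC,
    vocab_percentile = vocabulary_percentile(raw_score, ch$age_months,
                                             bundle$norms),
    combines_words = encode_combines(ch$combines_words),
    complexity_score = as.numeric(ch$complexity_score)
  )
  for (v in ll_demographics()) {
    x <- as.character(ch[[v]])
    x[is.na(x) | x == ""] <- "missing"
    levs <- sort(unique(x))
    pred[[v]] <- factor(x, levels = union(levs, "missing"))
  }
  out <- cbind(
    data.frame(child_id = ch$child_id, dataset_id = ch$dataset_id,
               age_band = ch$age_band, quality_flag = m$quality_flag,
               stringsAsFactors = FALSE),
    pred,
    data.frame(outcome_LL = as.integer(ch$outcome_LL))
  )
  rownames(out) <- NULL
  miss <- vapply(out[ll_predictor_names()], function(x) {
    mean(is.na(x) | (is.factor(x) & x == "missing"))
  }, numeric(1))
  message("assembled ", nrow(out), " x 14 feature table; missingness: ",
          paste0(names(miss)[miss > 0], "=",
                 round(100 * miss[miss > 0]), "%", collapse = ", "))
  class(out) <- c("ll_features", "data.frame")
  out
}
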
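#' Demographic variable names used throughout the pipeline
#'
#' The six demographic predictors collected in both emulated datasets.
#' @return character vector of column names
#' @export
ll_demographics <- function() {
  c("gender", "race", "family_history", "income",
    "maternal_education", "paternal_education")
}

#' Default dataset/age to age-band map
#'
#' The two emulated longitudinal datasets contribute checklist records at
#' two ages each; records are harmonized into a younger band (EIRLI-like 16
#' months, LASER-like 18 months) and an older band (EIRLI-like 28 months,
#' LASER-like 27 months).
#'
#' @return data.frame with columns dataset_id, age_months, age_band
#' @export
ll_band_map <- function() {
  data.frame(
    dataset_id = c("EIRLI-like", "EIRLI-like", "LASER-like", "LASER-like"),
    age_months = c(16L, 28L, 18L, 27L),
    age_band   = c("younger", "older", "younger", "older"),
    stringsAsFactors = FALSE
  )
}

#' Assign an age band to (dataset, age) pairs
#'
#' @param dataset_id character vector of dataset identifiers
#' @param age_months integer vector of checklist ages
#' @param band_map a band map data.frame like [ll_band_map()] (user-supplied
#'   maps may cover additional datasets or ages)
#' @return character vector of bands (`"younger"` / `"older"`)
#' @export
assign_age_band <- function(dataset_id, age_months, band_map = ll_band_map()) {
  key <- paste(dataset_id, age_months)
  idx <- match(key, paste(band_map$dataset_id, band_map$age_months))
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("no age-band mapping for: ", paste(bad, collapse = ", "),
         "; supply a band_map covering these (dataset, age) pairs")
  }
  band_map$age_band[idx]
}

#' Read a long-format vocabulary checklist
#'
#' One row per (child, age, produced word). Words are case-folded and
#' trimmed; duplicated (child_id, age_months, word) rows are collapsed with
#' a warning. Row counts and unknown columns are reported via `message()`.
#'
#' @param path CSV file with columns child_id, age_months, word
#' @param dataset_id dataset identifier attached to every record
#' @param band_map see [assign_age_band()]
#' @return data.frame (child_id, dataset_id, age_months, age_band, word)
#' @export
read_checklist <- function(path, dataset_id, band_map = ll_band_map()) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("child_id", "age_months", "word")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("checklist ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(df), req)
  if (length(extra) > 0) {
    message("checklist ", basename(path), ": ignoring column(s) ",
            paste(extra, collapse = ", "))
  }
  df <- df[req]
  df$child_id <- as.character(df$child_id)
  df$age_months <- as.integer(df$age_months)
  df$word <- normalize_words(df$word)
  n0 <- nrow(df)
  df <- unique(df)
  if (nrow(df) < n0) {
    warning("checklist ", basename(path), ": removed ", n0 - nrow(df),
            " duplicated (child_id, age, word) row(s)")
  }
  df$dataset_id <- dataset_id
  df$age_band <- assign_age_band(df$dataset_id, df$age_months, band_map)
  message("checklist ", basename(path), ": ", nrow(df), " item rows, ",
          nrow(unique(df[c("child_id", "age_months")])), " child-age records")
  df[c("child_id", "dataset_id", "age_months", "age_band", "word")]
}

#' Read the wide per-child table (grammar, demographics, outcome)
#'
#' One row per (child_id, age_months) with the word-combining item, the
#' grammatical-complexity count, the six demographic variables and the
#' binary low-language outcome.
#'
#' @param path CSV file
#' @param dataset_id dataset identifier
#' @param band_map see [assign_age_band()]
#' @return data.frame keyed by (child_id, age_months)
#' @export
read_child_table <- function(path, dataset_id, band_map = ll_band_map()) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("child_id", "age_months", "combines_words", "complexity_score",
           ll_demographics(), "outcome_LL")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("child table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df <- df[req]
  df$child_id <- as.character(df$child_id)
  df$age_months <- as.integer(df$age_months)
  if (anyDuplicated(df[c("child_id", "age_months")]) > 0) {
    stop("child table ", path, ": duplicated (child_id, age_months) rows")
  }
  if (anyNA(df$outcome_LL) || !all(df$outcome_LL %in% c(0, 1))) {
    stop("child table ", path, ": outcome_LL must be 0/1 and non-missing")
  }
  df$combines_words <- encode_combines(df$combines_words)
  df$complexity_score <- as.integer(df$complexity_score)
  df$dataset_id <- dataset_id
  df$age_band <- assign_age_band(df$dataset_id, df$age_months, band_map)
  message("child table ", basename(path), ": ", nrow(df), " records, ",
          sum(df$outcome_LL), " LL-positive")
  df
}

#' Read a semantic-feature lexicon
#'
#' Accepts either a long CSV (columns word, feature) or a JSON object
#' mapping each word to an array of features. Word identifiers are
#' case-folded and trimmed; every feature set must be non-empty.
#'
#' @param path CSV or JSON file
#' @return named list word -> character vector of features
#' @export
read_lexicon <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    lex <- lapply(raw, as.character)
    names(lex) <- normalize_words(names(lex))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("word", "feature") %in% names(df))) {
      stop("lexicon CSV must have columns word, feature")
    }
    df$word <- normalize_words(df$word)
    lex <- split(as.character(df$feature), df$word)
    lex <- lapply(lex, unique)
  }
  if (anyDuplicated(names(lex)) > 0) stop("lexicon has duplicated words")
  if (any(lengths(lex) == 0)) stop("lexicon has words with empty feature sets")
  lex
}

#' Read a vocabulary-size norms table
#'
#' Rows of (age_months, raw_score, percentile). Within each age the
#' percentile must be non-decreasing in raw score.
#'
#' @param path CSV file
#' @return data.frame (age_months, raw_score, percentile)
#' @export
read_norms <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_months", "raw_score", "percentile") %in% names(df))) {
    stop("norms CSV must have columns age_months, raw_score, percentile")
  }
  validate_norms(df)
  df
}

validate_norms <- function(norms) {
  stopifnot(all(norms$percentile >= 0 & norms$percentile <= 100))
  for (a in unique(norms$age_months)) {
    sub <- norms[norms$age_months == a, ]
    sub <- sub[order(sub$raw_score), ]
    if (is.unsorted(sub$percentile)) {
      stop("norms: percentile not non-decreasing in raw_score at age ", a)
    }
  }
  invisible(norms)
}

#' Bundle the four inputs of one dataset
#'
#' @param children wide per-child table (see [read_child_table()])
#' @param words long checklist table (see [read_checklist()])
#' @param lexicon named feature list
#' @param norms norms table
#' @param provenance free-text metadata
#' @return object of class `ll_bundle`
#' @export
new_bundle <- function(children, words, lexicon, norms, provenance = "") {
  validate_norms(norms)
  stopifnot(all(words$child_id %in% children$child_id))
  uncovered <- setdiff(unique(children$age_months), unique(norms$age_months))
  if (length(uncovered) > 0) {
    stop("norms table does not cover age(s): ", paste(uncovered, collapse = ", "))
  }
  structure(list(children = children, words = words, lexicon = lexicon,
                 norms = norms, provenance = provenance),
            class = "ll_bundle")
}

#' @export
print.ll_bundle <- function(x, ...) {
  s <- dataset_summary(x)
  cat(sprintf(
    "dataset bundle: %d children, %d records, %d LL-positive children (%.1f%%)\n",
    s$n_children, s$n_records, s$n_positive, s$prevalence_pct))
  invisible(x)
}

#' Summarise a dataset bundle
#'
#' Counts children, records and positive outcomes; prevalence is reported
#' as a percentage rounded to one decimal (17 positives of 391 children
#' reports 4.3).
#'
#' @param bundle an `ll_bundle`
#' @return list with n_children, n_records, n_positive, prevalence_pct and
#'   a per-band record count table
#' @export
dataset_summary <- function(bundle) {
  ch <- unique(bundle$children[c("child_id", "dataset_id", "outcome_LL")])
  list(
    n_children = nrow(ch),
    n_records = nrow(bundle$children),
    n_positive = sum(ch$outcome_LL),
    prevalence_pct = round_half_up(100 * sum(ch$outcome_LL) / nrow(ch), 1),
    records_per_band = table(bundle$children$age_band)
  )
}

#' Write / read a bundle as plain-text files
#'
#' Serializes to `children.csv`, `words.csv`, `lexicon.json`, `norms.csv`
#' and `provenance.json` under `dir`; `read_bundle()` reverses it exactly
#' (word sets compare equal as sets, everything else exactly).
#'
#' @param bundle an `ll_bundle`
#' @param dir directory (created if needed)
#' @return `write_bundle()` the directory invisibly; `read_bundle()` an
#'   `ll_bundle`
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$children, file.path(dir, "children.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$words, file.path(dir, "words.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$lexicon, file.path(dir, "lexicon.json"))
  utils::write.csv(bundle$norms, file.path(dir, "norms.csv"), row.names = FALSE)
  jsonlite::write_json(list(provenance = bundle$provenance),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  children <- utils::read.csv(file.path(dir, "children.csv"),
                              stringsAsFactors = FALSE)
  children$child_id <- as.character(children$child_id)
  for (v in ll_demographics()) children[[v]] <- as.character(children[[v]])
  words <- utils::read.csv(file.path(dir, "words.csv"), stringsAsFactors = FALSE)
  words$child_id <- as.character(words$child_id)
  lexicon <- read_lexicon(file.path(dir, "lexicon.json"))
  norms <- read_norms(file.path(dir, "norms.csv"))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))$provenance
  new_bundle(children, words, lexicon, norms, prov %||% "")
}

#' Aggregate several bundles into one age band
#'
#' Concatenates the requested band's records across bundles into a single
#' dataset with one binary outcome column; `dataset_id` is preserved as a
#' column. Child ids are namespaced by dataset when they collide across
#' bundles. All bundles must share the same child-table schema; the first
#' bundle's lexicon and the row-bound norms are carried along.
#'
#' @param bundles list of `ll_bundle` objects
#' @param band `"younger"` or `"older"`
#' @return an `ll_bundle` restricted to the requested band
#' @export
aggregate_datasets <- function(bundles, band = c("younger", "older")) {
  band <- match.arg(band)
  stopifnot(length(bundles) >= 1)
  schemas <- lapply(bundles, function(b) sort(names(b$children)))
  if (!all(vapply(schemas, identical, logical(1), y = schemas[[1]]))) {
    stop("bundles have different child-table schemas; cannot aggregate")
  }
  if (length(bundles) == 1) {
    b <- bundles[[1]]
    keep <- b$children$age_band == band
    kept <- b$children[keep, ]
    w <- b$words[paste(b$words$child_id, b$words$age_months) %in%
                   paste(kept$child_id, kept$age_months), ]
    return(new_bundle(kept, w, b$lexicon, b$norms, b$provenance))
  }
  ids <- lapply(bundles, function(b) unique(b$children$child_id))
  collide <- length(unlist(ids)) != length(unique(unlist(ids)))
  parts_c <- list(); parts_w <- list(); parts_n <- list()
  for (b in bundles) {
    ch <- b$children[b$children$age_band == band, ]
    w <- b$words[paste(b$words$child_id, b$words$age_months) %in%
                   paste(ch$child_id, ch$age_months), ]
    if (collide) {
      ch$child_id <- paste(ch$dataset_id, ch$child_id, sep = ":")
      w$child_id <- paste(w$dataset_id, w$child_id, sep = ":")
    }
    parts_c[[length(parts_c) + 1]] <- ch
    parts_w[[length(parts_w) + 1]] <- w
    parts_n[[length(parts_n) + 1]] <- b$norms
  }
  children <- do.call(rbind, parts_c)
  words <- do.call(rbind, parts_w)
  norms <- unique(do.call(rbind, parts_n))
  new_bundle(children, words, bundles[[1]]$lexicon, norms,
             paste0("aggregated-", band))
}
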
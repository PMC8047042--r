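#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Display rounding for report tables: exact halves round up (2.345 -> 2.35),
#' unlike [round()]'s round-half-even. Machine-readable outputs keep full
#' precision; this is applied only when formatting.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Independent RNG streams derived from one master seed, so regenerating one
# simulation component does not perturb the others. Kept below 2^31 - 1.
seed_stream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483587L)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin across k folds, so class counts per fold differ by at most 1.
stratified_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run code under a local RNG state (seeded), restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  code
}

# Median imputation of numeric columns, train statistics applied to both
# partitions (never computed on test rows).
impute_median <- function(train, test = NULL, cols) {
  for (cl in cols) {
    med <- stats::median(train[[cl]], na.rm = TRUE)
    if (is.na(med)) med <- 0
    train[[cl]][is.na(train[[cl]])] <- med
    if (!is.null(test)) test[[cl]][is.na(test[[cl]])] <- med
  }
  list(train = train, test = test)
}

# Word identifiers are case-folded and whitespace-trimmed before any
# lexicon lookup or join.
normalize_words <- function(x) tolower(trimws(as.character(x)))
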
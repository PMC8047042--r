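#' SMOTE configuration
#'
#' @param k_neighbors minority nearest neighbours considered per synthetic
#'   sample (default 5; reduced automatically when fewer minority rows exist)
#' @param target_ratio minority:majority ratio after oversampling (default 1,
#'   i.e. fully balanced)
#' @return list of class `smote_config`
#' @export
smote_config <- function(k_neighbors = 5, target_ratio = 1) {
  stopifnot(k_neighbors >= 1, target_ratio > 0)
  structure(list(k_neighbors = k_neighbors, target_ratio = target_ratio),
            class = "smote_config")
}

#' Synthetic minority oversampling (SMOTE) for mixed-type training data
#'
#' Raises the minority-class count to `target_ratio` times the majority
#' count. Each synthetic row is a convex combination of a real minority row
#' (the anchor) and one of its k nearest minority neighbours: numeric
#' predictors are interpolated at a uniform random gap, categorical
#' predictors are copied from the anchor. Neighbour search uses Euclidean
#' distance over numeric predictors standardized by median/MAD (so no
#' variable dominates); numeric predictors must be imputed beforehand.
#' Applied to training partitions only — never to held-out data.
#'
#' With fewer than 2 minority rows interpolation is impossible; the single
#' row is duplicated with a warning (never silently).
#'
#' @param data data.frame containing `predictors` and the label column
#' @param predictors character vector of predictor columns
#' @param cfg a [smote_config()]
#' @param seed RNG seed
#' @param label label column name (default `"outcome_LL"`)
#' @return data.frame with original rows first, synthetic rows appended;
#'   attribute `"synthetic"` is a logical vector marking them
#' @export
smote_oversample <- function(data, predictors, cfg = smote_config(), seed = 1,
                             label = "outcome_LL") {
  y <- data[[label]]
  stopifnot(!anyNA(y), length(unique(y)) == 2)
  num <- predictors[vapply(data[predictors], is.numeric, logical(1))]
  if (anyNA(data[num])) {
    stop("numeric predictors must be imputed before SMOTE")
  }
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  m <- sum(y == minority)
  target <- floor(cfg$target_ratio * max(tab))
  n_syn <- target - m
  mark <- function(d, syn) { attr(d, "synthetic") <- syn; d }
  if (n_syn <= 0) return(mark(data, rep(FALSE, nrow(data))))

  mino <- data[y == minority, , drop = FALSE]
  if (m < 2) {
    warning("fewer than 2 minority rows; falling back to duplication")
    dup <- mino[rep(1, n_syn), , drop = FALSE]
    out <- rbind(data, dup)
    rownames(out) <- NULL
    return(mark(out, c(rep(FALSE, nrow(data)), rep(TRUE, n_syn))))
  }

  z <- scale_mad(mino[num])
  d2 <- as.matrix(stats::dist(z))
  diag(d2) <- Inf
  k <- min(cfg$k_neighbors, m - 1)
  nn <- matrix(apply(d2, 1, function(r) order(r)[seq_len(k)]),
               nrow = m, ncol = k, byrow = TRUE)

  syn <- with_seed(seed, {
    anchors <- rep_len(seq_len(m), n_syn)
    rows <- vector("list", n_syn)
    for (s in seq_len(n_syn)) {
      a <- anchors[s]
      b <- nn[a, sample.int(k, 1)]
      gap <- stats::runif(1)
      row <- mino[a, , drop = FALSE]
      row[num] <- mino[a, num] + gap * (mino[b, num] - mino[a, num])
      rows[[s]] <- row
    }
    do.call(rbind, rows)
  })
  out <- rbind(data, syn)
  rownames(out) <- NULL
  mark(out, c(rep(FALSE, nrow(data)), rep(TRUE, n_syn)))
}

# Median/MAD standardization; zero-MAD columns are left centred only.
scale_mad <- function(df) {
  z <- as.matrix(df)
  if (ncol(z) == 0) return(matrix(0, nrow(df), 1))
  for (j in seq_len(ncol(z))) {
    med <- stats::median(z[, j])
    s <- stats::mad(z[, j])
    if (s == 0) s <- 1
    z[, j] <- (z[, j] - med) / s
  }
  z
}
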
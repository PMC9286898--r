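#' SVM recursive feature elimination
#'
#' Ranks features by backward elimination with a linear support-vector
#' machine: fit the SVM on the surviving features, score each feature by the
#' square of its weight (`F_i = w_i^2`), remove the single feature with the
#' smallest score (ties broken by column order, first wins), and repeat until
#' the feature set is empty.  The final ranking is the reverse elimination
#' order; the importance reported for each feature is its squared weight at
#' the time it was eliminated (once removed, a feature has no later weight).
#'
#' Features are z-score standardized before the loop (a linear-SVM weight is
#' only comparable across features on a common scale); the SVM uses a linear
#' kernel with cost `cost` and no further preprocessing.
#'
#' @param x numeric matrix or data frame, rows = compounds, columns = named
#'   features; no missing values.
#' @param y binary labels (factor, 0/1, or two-level character), at least two
#'   rows per class.
#' @param cost SVM regularization constant.
#' @param standardize z-score columns before the loop (recommended).
#' @param step number of features removed per iteration; values above 1
#'   accelerate very wide matrices but deviate from strict one-at-a-time
#'   elimination and emit a warning.
#' @param class_weights optional named class weights passed to the SVM (e.g.
#'   `c(a = 1, b = 4)` or `"inverse"`); default is unweighted.
#' @return an object of class `svm_rfe`: a ranking data frame (`rank`,
#'   `feature`, `score`, `eliminated_at`) plus call metadata.
#' @export
svm_rfe <- function(x, y, cost = 1, standardize = TRUE, step = 1L,
                    class_weights = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty feature matrix")
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  }
  y <- factor(y)
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  if (any(table(y) < 2L)) stop("need at least 2 rows per class")
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)")
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  if (step > 1L) {
    warning("step > 1 removes features in chunks; ",
            "strict RFE eliminates one feature per iteration")
  }
  if (standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    x <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  }
  p <- ncol(x)
  surviving <- seq_len(p)
  elim_order <- integer(0)
  elim_score <- numeric(0)
  it <- 0L
  while (length(surviving) > 0L) {
    it <- it + 1L
    fit <- e1071::svm(x[, surviving, drop = FALSE], y, kernel = "linear",
                      cost = cost, scale = FALSE,
                      class.weights = class_weights)
    w <- drop(t(fit$coefs) %*% fit$SV)
    scores <- w^2
    n_drop <- min(step, length(surviving))
    if (length(surviving) == 1L) n_drop <- 1L
    # ascending score; ties resolved by column order (first column wins)
    drop_local <- order(scores, seq_along(scores))[seq_len(n_drop)]
    elim_order <- c(elim_order, surviving[drop_local])
    elim_score <- c(elim_score, scores[drop_local])
    surviving <- surviving[-drop_local]
  }
  ranking <- data.frame(
    rank = seq_len(p),
    feature = colnames(x)[rev(elim_order)],
    score = rev(elim_score),
    eliminated_at = rev(seq_len(p)),
    stringsAsFactors = FALSE)
  structure(list(ranking = ranking, n_features = p, cost = cost,
                 standardize = standardize, step = step,
                 iterations = it, classes = levels(y)),
            class = "svm_rfe")
}

#' @export
print.svm_rfe <- function(x, n = 10L, ...) {
  cat("<svm_rfe>", x$n_features, "features ranked over", x$iterations,
      "eliminations (classes:", paste(x$classes, collapse = " vs "), ")\n")
  print(utils::head(x$ranking, n), row.names = FALSE)
  if (x$n_features > n) cat("  ...", x$n_features - n, "more\n")
  invisible(x)
}

#' @export
plot.svm_rfe <- function(x, n = 20L, ...) {
  top <- utils::head(x$ranking, n)
  graphics::barplot(rev(top$score), names.arg = rev(top$feature),
                    horiz = TRUE, las = 1,
                    xlab = "importance (squared SVM weight at elimination)",
                    ...)
  invisible(x)
}

#' Group a feature ranking by descriptor category
#'
#' Summarises an [svm_rfe()] ranking by descriptor category (e.g. basic
#' descriptors, 2D autocorrelations, lipophilicity, water solubility),
#' reporting per-category counts, the best rank achieved and the top-ranked
#' member.
#'
#' @param ranking an `svm_rfe` object or its ranking data frame.
#' @param category_map named character vector (`feature -> category`) or a
#'   two-column data frame `(feature, category)`.
#' @return list with `summary` (one row per category, ordered by best rank)
#'   and `ranking` (the input ranking with a `category` column).
#' @export
categorize_features <- function(ranking, category_map) {
  rk <- if (inherits(ranking, "svm_rfe")) ranking$ranking else ranking
  if (is.data.frame(category_map)) {
    category_map <- stats::setNames(as.character(category_map[[2L]]),
                                    as.character(category_map[[1L]]))
  }
  unmapped <- setdiff(rk$feature, names(category_map))
  if (length(unmapped)) {
    stop("features missing from category map: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  rk$category <- unname(category_map[rk$feature])
  agg <- do.call(rbind, lapply(split(rk, rk$category), function(g) {
    data.frame(category = g$category[1L], n = nrow(g),
               best_rank = min(g$rank),
               top_feature = g$feature[which.min(g$rank)],
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$best_rank), , drop = FALSE]
  rownames(agg) <- NULL
  list(summary = agg, ranking = rk)
}

#' Select the top of an RFE ranking
#'
#' Returns the first `k` ranked features, or all features whose elimination
#' score exceeds `threshold`.  The selected set is always a prefix of the
#' ranking when `k` is used.
#'
#' @param ranking an `svm_rfe` object or its ranking data frame.
#' @param k number of features to keep (1..total).
#' @param threshold alternative score cutoff (features with
#'   `score > threshold`).
#' @return character vector of selected feature names.
#' @export
select_top_k <- function(ranking, k = NULL, threshold = NULL) {
  rk <- if (inherits(ranking, "svm_rfe")) ranking$ranking else ranking
  if (is.null(k) == is.null(threshold)) {
    stop("give exactly one of k or threshold")
  }
  if (!is.null(k)) {
    if (k < 1 || k > nrow(rk)) {
      stop("k must be between 1 and ", nrow(rk))
    }
    return(rk$feature[seq_len(k)])
  }
  rk$feature[rk$score > threshold]
}
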
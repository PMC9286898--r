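#' Labeled compound-disease pairs
#'
#' Constructs and validates a pair-label table.  Labels are `"positive"`
#' (a curated relationship, e.g. a direct-evidence marker/mechanism/treatment
#' annotation), `"negative"` (a sampled unknown pair used as a negative), or
#' `"unknown"`.
#'
#' @param compound_id,disease_id character vectors.
#' @param label label per pair.
#' @param evidence optional evidence string per pair.
#' @return a data frame with one row per pair.
#' @export
pair_labels <- function(compound_id, disease_id,
                        label = "positive", evidence = NA_character_) {
  df <- data.frame(compound_id = as.character(compound_id),
                   disease_id = as.character(disease_id),
                   label = as.character(label),
                   evidence = as.character(evidence),
                   stringsAsFactors = FALSE)
  if (!all(df$label %in% c("positive", "negative", "unknown"))) {
    stop("labels must be positive/negative/unknown")
  }
  if (anyDuplicated(pair_key(df$compound_id, df$disease_id))) {
    stop("duplicate (compound_id, disease_id) pairs")
  }
  df
}

#' Read / write a pairs file
#'
#' CSV with columns `compound_id`, `disease_id`, `label` and optionally
#' `evidence`.
#'
#' @param path file path.
#' @param pairs a pairs data frame.
#' @return the pairs data frame (read) or `path` (write).
#' @export
read_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "disease_id", "label")
  if (!all(need %in% names(df))) {
    stop("pairs file must have columns: ", paste(need, collapse = ", "))
  }
  pair_labels(df$compound_id, df$disease_id, df$label,
              if ("evidence" %in% names(df)) df$evidence else NA_character_)
}

#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Enumerate the unlabeled complement of the positive set
#'
#' All compound x disease pairs not present among the positives; these
#' unknown pairs form the pool that negatives are sampled from.  With the
#' benchmark dimensions (4770 compounds, 40 diseases, 13981 positives) the
#' pool has 176819 pairs.
#'
#' @param compound_ids,disease_ids id vectors spanning the grid.
#' @param positives data frame of positive pairs.
#' @return data frame of unknown pairs (`label = "unknown"`).
#' @export
complement_pool <- function(compound_ids, disease_ids, positives) {
  compound_ids <- as.character(compound_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(compound_ids) || anyDuplicated(disease_ids)) {
    stop("duplicated ids in the grid definition")
  }
  pos_key <- pair_key(positives$compound_id, positives$disease_id)
  bad_c <- setdiff(positives$compound_id, compound_ids)
  bad_d <- setdiff(positives$disease_id, disease_ids)
  if (length(bad_c) || length(bad_d)) {
    stop("positive pairs reference unknown ids: ",
         paste(utils::head(c(bad_c, bad_d), 5L), collapse = ", "))
  }
  grid <- expand.grid(compound_id = compound_ids, disease_id = disease_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- !(pair_key(grid$compound_id, grid$disease_id) %in% pos_key)
  pool <- grid[keep, , drop = FALSE]
  rownames(pool) <- NULL
  pool$label <- "unknown"
  pool
}

#' Sample negative pairs from the unknown pool
#'
#' Uniform sampling without replacement; deterministic for a fixed seed.
#'
#' @param pool data frame of unknown pairs (see [complement_pool()]).
#' @param n number of negatives to draw.
#' @param seed integer seed.
#' @return data frame of `n` pairs with `label = "negative"`.
#' @export
sample_negatives <- function(pool, n, seed = 1L) {
  if (n > nrow(pool)) {
    stop("requested ", n, " negatives but the pool has only ",
         nrow(pool), " pairs")
  }
  idx <- with_seed(seed, sample.int(nrow(pool), n))
  neg <- pool[idx, , drop = FALSE]
  rownames(neg) <- NULL
  neg$label <- "negative"
  neg
}

#' Specification of a benchmark split
#'
#' @param mode `"random"` (stratified random split), `"disease_held_out"` or
#'   `"compound_held_out"` (no test disease/compound appears in training).
#' @param train_fraction fraction of sampled pairs used for training
#'   (benchmark setting: 0.75).
#' @param ratio_neg_per_pos negatives per positive (benchmark series: 1..5).
#' @param sample_size pairs drawn per dataset (benchmark setting: 20000).
#' @param repeats number of repetitions with derived seeds (benchmark: 3).
#' @param seed master seed; repeat `i` uses `seed + i`.
#' @return a `split_spec` object.
#' @export
split_spec <- function(mode = c("random", "disease_held_out",
                                "compound_held_out"),
                       train_fraction = 0.75, ratio_neg_per_pos = 1L,
                       sample_size = 20000L, repeats = 3L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(train_fraction > 0, train_fraction < 1, ratio_neg_per_pos >= 1,
            sample_size >= 2, repeats >= 1)
  structure(list(mode = mode, train_fraction = train_fraction,
                 ratio_neg_per_pos = as.integer(ratio_neg_per_pos),
                 sample_size = as.integer(sample_size),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "split_spec")
}

new_split <- function(train, test, provenance) {
  rownames(train) <- NULL
  rownames(test) <- NULL
  structure(list(train = train, test = test, provenance = provenance),
            class = "cdr_split")
}

#' @export
print.cdr_split <- function(x, ...) {
  p <- x$provenance
  cat("<cdr_split>", p$mode %||% "random", "- train",
      nrow(x$train), "(", sum(x$train$label == "positive"), "pos ) / test",
      nrow(x$test), "(", sum(x$test$label == "positive"), "pos )\n")
  invisible(x)
}

# stratified random split preserving the class ratio
stratified_split <- function(pairs, train_fraction) {
  take <- logical(nrow(pairs))
  for (lab in unique(pairs$label)) {
    idx <- which(pairs$label == lab)
    n_tr <- floor(train_fraction * length(idx))
    take[sample(idx, n_tr)] <- TRUE
  }
  list(train = pairs[take, , drop = FALSE],
       test = pairs[!take, , drop = FALSE])
}

#' Build the positive:negative ratio dataset series
#'
#' For each requested ratio `1:r`, draws `sample_size` pairs (positives
#' `floor(sample_size / (1 + r))`, the remainder negatives sampled from the
#' unknown pool), splits them `train_fraction` / rest preserving the class
#' ratio in both partitions, and repeats with derived seeds
#' (`spec$seed + repeat`).  The benchmark series uses 20000 samples, ratios
#' 1:1 through 1:5 and 3 repeats.
#'
#' @param positives data frame of positive pairs.
#' @param pool unknown-pair pool from [complement_pool()].
#' @param spec a [split_spec()].
#' @param ratios integer vector of negative:positive ratios; defaults to the
#'   single ratio in `spec`.
#' @return nested list: `result[[as.character(r)]][[repeat]]` is a
#'   `cdr_split`.
#' @export
make_ratio_datasets <- function(positives, pool, spec = split_spec(),
                                ratios = spec$ratio_neg_per_pos) {
  out <- list()
  for (r in ratios) {
    n_pos <- spec$sample_size %/% (1L + r)
    n_neg <- spec$sample_size - n_pos
    if (n_pos < 1L) stop("ratio 1:", r, " leaves no positives at sample size ",
                         spec$sample_size)
    if (n_pos > nrow(positives)) {
      stop("need ", n_pos, " positives but only ", nrow(positives),
           " are available")
    }
    if (n_neg > nrow(pool)) {
      stop("need ", n_neg, " negatives but the pool has ", nrow(pool))
    }
    reps <- vector("list", spec$repeats)
    for (i in seq_len(spec$repeats)) {
      rep_seed <- spec$seed + i
      reps[[i]] <- with_seed(rep_seed, {
        pos <- positives[sample.int(nrow(positives), n_pos), , drop = FALSE]
        pos$label <- "positive"
        neg <- pool[sample.int(nrow(pool), n_neg), , drop = FALSE]
        neg$label <- "negative"
        parts <- stratified_split(rbind(pos[, c("compound_id", "disease_id",
                                                "label")],
                                        neg[, c("compound_id", "disease_id",
                                                "label")]),
                                  spec$train_fraction)
        new_split(parts$train, parts$test,
                  list(mode = "random", ratio = r, repeat_index = i,
                       seed = rep_seed, n_pos = n_pos, n_neg = n_neg,
                       train_fraction = spec$train_fraction))
      })
    }
    out[[as.character(r)]] <- reps
  }
  out
}

# grouped held-out construction for one label class: move whole groups
# (all pairs of one disease or compound) into training until the target is
# reached, then sample the test pairs from the untouched groups
held_out_one_class <- function(pairs, group_col, n_train, n_test) {
  groups <- unique(pairs[[group_col]])
  if (length(groups) < 2L) {
    stop("cannot build a held-out split: data spans a single ", group_col)
  }
  ord <- sample(groups)
  sizes <- table(pairs[[group_col]])[ord]
  cum <- cumsum(as.integer(sizes))
  k <- match(TRUE, cum >= n_train)
  if (is.na(k)) {
    stop("cannot reach ", n_train, " training pairs: only ",
         sum(sizes), " available")
  }
  train_groups <- ord[seq_len(k)]
  train <- pairs[pairs[[group_col]] %in% train_groups, , drop = FALSE]
  remaining <- pairs[!(pairs[[group_col]] %in% train_groups), , drop = FALSE]
  if (nrow(remaining) < n_test) {
    stop("only ", nrow(remaining), " pairs left for testing; need ", n_test,
         " (training consumed ", length(train_groups), " of ",
         length(groups), " groups)")
  }
  test <- remaining[sample.int(nrow(remaining), n_test), , drop = FALSE]
  list(train = train, test = test, groups = train_groups)
}

held_out_split <- function(positives, negatives, n_train_pos, n_test_pos,
                           group_col, seed,
                           n_train_neg = n_train_pos,
                           n_test_neg = n_test_pos) {
  positives$label <- "positive"
  negatives$label <- "negative"
  with_seed(seed, {
    pos <- held_out_one_class(positives, group_col, n_train_pos, n_test_pos)
    neg <- held_out_one_class(negatives, group_col, n_train_neg, n_test_neg)
    cols <- c("compound_id", "disease_id", "label")
    train <- rbind(pos$train[, cols], neg$train[, cols])
    test <- rbind(pos$test[, cols], neg$test[, cols])
    cross_overlap <- union(
      intersect(unique(pos$train[[group_col]]), unique(neg$test[[group_col]])),
      intersect(unique(neg$train[[group_col]]), unique(pos$test[[group_col]])))
    new_split(train, test, list(
      mode = paste0(sub("_id$", "", group_col), "_held_out"),
      seed = seed,
      n_train_pos_target = n_train_pos, n_test_pos = n_test_pos,
      n_train_neg_target = n_train_neg, n_test_neg = n_test_neg,
      realized_train_pos = nrow(pos$train),
      realized_train_neg = nrow(neg$train),
      cross_class_group_overlap = cross_overlap))
  })
}

#' Disease-held-out and compound-held-out splits
#'
#' Builds the cold-start evaluation splits: randomly picked diseases (or
#' compounds) contribute *all* of their positive pairs to the training set
#' until the training-positive target is reached (the first whole group that
#' crosses the target is kept, so realized counts can overshoot slightly);
#' `n_test_pos` pairs are then sampled from the untouched groups.  The same
#' grouped procedure is applied independently to the negatives.  By
#' construction no test disease (or compound) id occurs in the training set
#' within either label class; any cross-class overlap is reported in the
#' provenance.  The benchmark setting is 7500 training and 2500 test pairs
#' per class (15000 train / 5000 test).
#'
#' @param positives,negatives pair data frames.
#' @param n_train_pos training-positive target count.
#' @param n_test_pos test positives sampled from held-out groups.
#' @param seed integer seed.
#' @param n_train_neg,n_test_neg negative-class targets (default: same as
#'   positives).
#' @return a `cdr_split` with realized counts in `provenance`.
#' @export
disease_held_out_split <- function(positives, negatives,
                                   n_train_pos = 7500L, n_test_pos = 2500L,
                                   seed = 1L,
                                   n_train_neg = n_train_pos,
                                   n_test_neg = n_test_pos) {
  held_out_split(positives, negatives, n_train_pos, n_test_pos,
                 "disease_id", seed, n_train_neg, n_test_neg)
}

#' @rdname disease_held_out_split
#' @export
compound_held_out_split <- function(positives, negatives,
                                    n_train_pos = 7500L, n_test_pos = 2500L,
                                    seed = 1L,
                                    n_train_neg = n_train_pos,
                                    n_test_neg = n_test_pos) {
  held_out_split(positives, negatives, n_train_pos, n_test_pos,
                 "compound_id", seed, n_train_neg, n_test_neg)
}

#' Write a split manifest (ids only) as JSON
#'
#' @param split a `cdr_split`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(
    list(provenance = split$provenance,
         train = split$train, test = split$test),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
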
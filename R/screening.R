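#' Screening configuration
#'
#' Compound admission rules and the high-confidence probability cut used
#' when screening a library.  The reference screen admits QC compounds,
#' blood compounds and compounds with oral bioavailability strictly above
#' 30%, and flags predicted pairs with probability above 0.9 as candidates.
#'
#' @param ob_threshold oral-bioavailability threshold in percent (strict
#'   `>`; a compound at exactly the threshold does not pass this clause, and
#'   a missing OB value never passes it).
#' @param candidate_cut probability above which a predicted pair is flagged
#'   as a high-confidence candidate (strict `>`).
#' @param combine `"any"` admits a compound satisfying at least one of the
#'   three clauses (the reference reading: a union of admissible classes);
#'   `"all"` requires all three, for sensitivity analysis.
#' @return a `screen_config` object.
#' @export
screen_config <- function(ob_threshold = 30, candidate_cut = 0.9,
                          combine = c("any", "all")) {
  combine <- match.arg(combine)
  stopifnot(ob_threshold >= 0, candidate_cut > 0, candidate_cut < 1)
  structure(list(ob_threshold = ob_threshold, candidate_cut = candidate_cut,
                 combine = combine),
            class = "screen_config")
}

#' Filter a compound library by annotation rules
#'
#' Keeps a compound iff `is_qc` OR `is_blood` OR `ob_percent >
#' config$ob_threshold` (strict).  Missing flags count as `FALSE`; a missing
#' OB value fails the OB clause.  With `combine = "all"` the clauses are
#' conjoined instead.
#'
#' @param compounds a compound `descriptor_table` with annotations.
#' @param config a [screen_config()].
#' @return the filtered `descriptor_table`.
#' @export
filter_compounds <- function(compounds, config = screen_config()) {
  stopifnot(inherits(compounds, "descriptor_table"),
            compounds$entity == "compound")
  ann <- compounds$annotations
  if (is.null(ann)) {
    stop("compound table carries no annotations (is_qc/is_blood/ob_percent)")
  }
  qc <- !is.na(ann$is_qc) & ann$is_qc
  blood <- !is.na(ann$is_blood) & ann$is_blood
  ob <- !is.na(ann$ob_percent) & ann$ob_percent > config$ob_threshold
  keep <- if (config$combine == "any") qc | blood | ob else qc & blood & ob
  subset_records(compounds, which(keep))
}

#' Enumerate unknown pairs for screening
#'
#' All compound x disease pairs except those already labeled in the
#' benchmark (a pair with curated evidence is not "unknown").  The reference
#' screen pairs 437 filtered compounds with 40 diseases: 17480 pairs.
#'
#' @param compound_ids,disease_ids id vectors (typically the filtered
#'   library and the disease panel).
#' @param known_pairs optional data frame of already-labeled pairs to
#'   exclude.
#' @return data frame of pairs; attribute `n_excluded_known` records how
#'   many grid pairs were removed as already known.
#' @export
enumerate_unknown_pairs <- function(compound_ids, disease_ids,
                                    known_pairs = NULL) {
  compound_ids <- as.character(compound_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(compound_ids)) {
    stop("id collision: duplicated compound ids: ",
         paste(utils::head(unique(
           compound_ids[duplicated(compound_ids)]), 5L), collapse = ", "))
  }
  if (anyDuplicated(disease_ids)) {
    stop("id collision: duplicated disease ids")
  }
  grid <- expand.grid(compound_id = compound_ids, disease_id = disease_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_excluded <- 0L
  if (!is.null(known_pairs) && nrow(known_pairs)) {
    known <- pair_key(known_pairs$compound_id, known_pairs$disease_id)
    drop <- pair_key(grid$compound_id, grid$disease_id) %in% known
    n_excluded <- sum(drop)
    grid <- grid[!drop, , drop = FALSE]
    rownames(grid) <- NULL
  }
  attr(grid, "n_excluded_known") <- n_excluded
  grid
}

#' Screen a compound library against the disease panel
#'
#' Runs the full screening pipeline: filter the library by annotation rules,
#' enumerate unknown pairs against the disease panel, encode every pair as a
#' fused grayscale image, predict with the trained classifier, and rank.
#' Pairs are sorted by probability in descending order (ties broken stably
#' by compound id, then disease id); `predicted_positive` uses the model's
#' 0.5 threshold while `candidate` uses the high-confidence cut
#' (`config$candidate_cut`, default 0.9) — two distinct counts.
#'
#' @param model a fitted [cdr_cnn()].
#' @param compounds compound library `descriptor_table`, already normalized
#'   on the training scale (see [apply_normalization()]).
#' @param diseases normalized disease `descriptor_table`.
#' @param config a [screen_config()] (the filtering rules must match the
#'   annotations present).
#' @param known_pairs benchmark pairs to exclude from enumeration.
#' @param target optional image resize passed to [encode_images()].
#' @return a `cdr_screen` object: `results` (ranked data frame with
#'   `compound_id`, `disease_id`, `probability`, `predicted_positive`,
#'   `candidate`) and `summary` counts.
#' @export
screen_compounds <- function(model, compounds, diseases,
                             config = screen_config(), known_pairs = NULL,
                             target = NULL) {
  stopifnot(inherits(model, "cdr_cnn"))
  kept <- filter_compounds(compounds, config)
  if (length(kept$ids) == 0L) stop("no compounds pass the screening filter")
  if (anyNA(kept$features)) {
    bad <- kept$ids[rowSums(is.na(kept$features)) > 0]
    stop("missing descriptor vectors for: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  pairs <- enumerate_unknown_pairs(kept$ids, diseases$ids, known_pairs)
  if (nrow(pairs) == 0L) {
    stop("no unknown pairs to screen: every enumerated pair is already ",
         "labeled in known_pairs")
  }
  stack <- encode_images(kept, diseases, pairs, target = target)
  prob <- predict(model, stack, type = "prob")
  ord <- order(-prob, pairs$compound_id, pairs$disease_id, method = "radix")
  results <- data.frame(compound_id = pairs$compound_id[ord],
                        disease_id = pairs$disease_id[ord],
                        probability = prob[ord],
                        stringsAsFactors = FALSE)
  results$predicted_positive <- results$probability > 0.5
  results$candidate <- results$probability > config$candidate_cut
  structure(list(
    results = results,
    summary = list(n_compounds_kept = length(kept$ids),
                   n_pairs = nrow(results),
                   n_excluded_known = attr(pairs, "n_excluded_known"),
                   n_predicted_positive = sum(results$predicted_positive),
                   n_candidates = sum(results$candidate)),
    config = config), class = "cdr_screen")
}

#' @export
print.cdr_screen <- function(x, ...) {
  s <- x$summary
  cat("<cdr_screen>", s$n_compounds_kept, "compounds ->", s$n_pairs,
      "unknown pairs (", s$n_excluded_known, "known excluded )\n")
  cat("  predicted positive (p > 0.5):", s$n_predicted_positive,
      "; candidates (p >", x$config$candidate_cut, "):", s$n_candidates, "\n")
  invisible(x)
}

#' Write screening results
#'
#' Ranked pairs as CSV plus a JSON summary.
#'
#' @param screen a `cdr_screen` object.
#' @param csv_path,json_path output paths (`NULL` skips either output).
#' @return invisibly, the paths written.
#' @export
write_screen_results <- function(screen, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(screen, "cdr_screen"))
  if (!is.null(csv_path)) {
    utils::write.csv(screen$results, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(screen$summary, json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(c(csv_path, json_path))
}
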
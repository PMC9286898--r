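#' Descriptor tables for compounds and diseases
#'
#' A descriptor table holds one numeric feature vector per entity: molecular
#' descriptors for compounds (the reference pipeline uses 5270 Dragon
#' descriptors) or symptom descriptors for diseases (322 weights from the
#' human symptom-disease network).  Compound tables additionally carry the
#' screening annotations `is_qc`, `is_blood` and `ob_percent` (oral
#' bioavailability, in percent).
#'
#' @param ids character vector of unique entity ids.
#' @param features numeric matrix, one row per entity; column names are the
#'   feature names.
#' @param entity `"compound"` or `"disease"`.
#' @param name optional character vector of display names.
#' @param is_qc,is_blood optional logical annotation flags (compounds only).
#' @param ob_percent optional numeric oral-bioavailability percentages;
#'   `NA` = unknown.
#' @return an object of class `descriptor_table`.
#' @export
descriptor_table <- function(ids, features, entity = c("compound", "disease"),
                             name = NULL, is_qc = NULL, is_blood = NULL,
                             ob_percent = NULL) {
  entity <- match.arg(entity)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate ", entity, " ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) != length(ids)) stop("features rows != number of ids")
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  }
  ann <- NULL
  if (entity == "compound" &&
      (!is.null(is_qc) || !is.null(is_blood) || !is.null(ob_percent))) {
    n <- length(ids)
    ann <- data.frame(
      is_qc = as.logical(is_qc %||% rep(FALSE, n)),
      is_blood = as.logical(is_blood %||% rep(FALSE, n)),
      ob_percent = as.numeric(ob_percent %||% rep(NA_real_, n)))
    if (any(ann$ob_percent < 0, na.rm = TRUE)) stop("ob_percent must be >= 0")
  }
  structure(list(entity = entity, ids = ids, name = name,
                 features = features, annotations = ann,
                 normalized = FALSE, norm_params = NULL),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table>", length(x$ids), x$entity, "records x",
      ncol(x$features), "features;",
      if (x$normalized) "normalized [0,1]" else "raw", "\n")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$features)

# row subset preserving all metadata
subset_records <- function(table, idx) {
  table$ids <- table$ids[idx]
  table$features <- table$features[idx, , drop = FALSE]
  if (!is.null(table$name)) table$name <- table$name[idx]
  if (!is.null(table$annotations)) {
    table$annotations <- table$annotations[idx, , drop = FALSE]
    rownames(table$annotations) <- NULL
  }
  table
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

ANNOTATION_COLS <- c("is_qc", "is_blood", "ob_percent")

#' Read a descriptor table from delimited text
#'
#' The file must have a header row; the first column is the entity id and the
#' remaining numeric columns are features.  For compound tables, columns named
#' `name`, `is_qc`, `is_blood` and `ob_percent` are treated as annotations,
#' not features.  Missing numeric cells become `NA` (never silently zero).
#'
#' @param path file path.
#' @param entity `"compound"` or `"disease"`.
#' @param delimiter field delimiter; `NULL` auto-detects tab vs comma from
#'   the header line.
#' @return a `descriptor_table`.
#' @export
read_descriptor_table <- function(path, entity = c("compound", "disease"),
                                  delimiter = NULL) {
  entity <- match.arg(entity)
  if (!file.exists(path)) stop("no such file: ", path)
  delimiter <- delimiter %||% detect_delimiter(path)
  nf <- utils::count.fields(path, sep = delimiter, quote = "\"",
                            blank.lines.skip = FALSE)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row in ", path, ": line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  name <- NULL
  if ("name" %in% names(df)) {
    name <- as.character(df[["name"]])
    df[["name"]] <- NULL
  }
  ann <- list(is_qc = NULL, is_blood = NULL, ob_percent = NULL)
  if (entity == "compound") {
    for (col in ANNOTATION_COLS) {
      if (col %in% names(df)) {
        ann[[col]] <- df[[col]]
        df[[col]] <- NULL
      }
    }
    if (!is.null(ann$is_qc)) ann$is_qc <- as.logical(ann$is_qc)
    if (!is.null(ann$is_blood)) ann$is_blood <- as.logical(ann$is_blood)
    if (!is.null(ann$ob_percent)) ann$ob_percent <- as.numeric(ann$ob_percent)
  }
  feats <- as.matrix(df)
  storage.mode(feats) <- "double"
  descriptor_table(ids, feats, entity, name = name, is_qc = ann$is_qc,
                   is_blood = ann$is_blood, ob_percent = ann$ob_percent)
}

#' Write a descriptor table as delimited text
#'
#' Numeric values are written with 17 significant digits so that a
#' write/read round-trip reproduces every double bit-exactly.
#'
#' @param table a `descriptor_table`.
#' @param path output path.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "descriptor_table"))
  id_col <- paste0(table$entity, "_id")
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    setNames(list(table$ids), id_col))
  if (!is.null(table$name)) out$name <- table$name
  if (!is.null(table$annotations)) {
    out$is_qc <- table$annotations$is_qc
    out$is_blood <- table$annotations$is_blood
    out$ob_percent <- format_full(table$annotations$ob_percent)
  }
  feat <- apply(table$features, 2L, format_full)
  if (!is.matrix(feat)) feat <- matrix(feat, nrow = nrow(table$features),
                                       dimnames = dimnames(table$features))
  out <- cbind(out, as.data.frame(feat, check.names = FALSE))
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Min-max normalize a descriptor table
#'
#' Each feature column is independently rescaled to `[0, 1]` by
#' `(x - min) / (max - min)`; constant columns map to 0 (and are kept, so the
#' feature count and hence the fused-image geometry never changes).  Compound
#' and disease tables are normalized separately, each over its own records.
#' The per-feature `(min, max)` pairs are stored on the result so the same
#' transform can be applied to new records with [apply_normalization()] —
#' e.g. screened library compounds must be encoded on the training scale.
#' Normalizing an already-normalized table returns it unchanged (the
#' transform is idempotent).
#'
#' @param table a `descriptor_table`.
#' @param method `"feature"` (per-column min-max, the default) or `"vector"`
#'   (per-record min-max across its own features; provided because the
#'   normalization granularity is a modelling choice, but untested against
#'   any reference pipeline).
#' @param na_action `"error"` rejects missing values; `"median"` fills each
#'   missing cell with its column median before normalizing.
#' @return a normalized `descriptor_table` with `norm_params` set.
#' @export
normalize_descriptors <- function(table, method = c("feature", "vector"),
                                  na_action = c("error", "median")) {
  stopifnot(inherits(table, "descriptor_table"))
  method <- match.arg(method)
  na_action <- match.arg(na_action)
  if (table$normalized) return(table)
  x <- table$features
  if (anyNA(x)) {
    if (na_action == "error") {
      bad <- colnames(x)[colSums(is.na(x)) > 0]
      stop("missing descriptor values in feature(s): ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) ", ..." else "",
           " (set na_action = \"median\" to fill)")
    }
    for (j in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, j]), j] <- stats::median(x[, j], na.rm = TRUE)
    }
  }
  if (method == "vector") {
    rng <- t(apply(x, 1L, range))
    den <- rng[, 2L] - rng[, 1L]
    den[den == 0] <- 1
    table$features <- (x - rng[, 1L]) / den
    table$normalized <- TRUE
    table$norm_params <- NULL
    table$norm_method <- "vector"
    return(table)
  }
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  den <- maxs - mins
  den[den == 0] <- 1            # constant columns -> 0
  table$features <- sweep(sweep(x, 2L, mins), 2L, den, "/")
  table$normalized <- TRUE
  table$norm_method <- "feature"
  table$norm_params <- rbind(min = mins, max = maxs)
  table
}

#' Apply stored normalization parameters to a table
#'
#' Transforms each feature with the `(min, max)` pair fitted on another
#' table (typically the benchmark training set) and clips the result to
#' `[0, 1]`, so out-of-range values in new records cannot break the grayscale
#' rendering contract.
#'
#' @param table an unnormalized `descriptor_table`.
#' @param params a 2 x D matrix with rows `min`, `max` and feature column
#'   names, as stored in `norm_params` by [normalize_descriptors()] or read
#'   back by [read_norm_params()].
#' @return a normalized `descriptor_table`.
#' @export
apply_normalization <- function(table, params) {
  stopifnot(inherits(table, "descriptor_table"))
  if (ncol(params) != ncol(table$features)) {
    stop("normalization params have ", ncol(params), " features, table has ",
         ncol(table$features))
  }
  if (!is.null(colnames(params)) &&
      !identical(colnames(params), colnames(table$features))) {
    stop("feature names of params and table disagree")
  }
  den <- params["max", ] - params["min", ]
  den[den == 0] <- 1
  x <- sweep(sweep(table$features, 2L, params["min", ]), 2L, den, "/")
  table$features <- pmin(pmax(x, 0), 1)
  table$normalized <- TRUE
  table$norm_method <- "feature"
  table$norm_params <- params
  table
}

#' Serialize normalization parameters as JSON
#'
#' Written as `{feature_name: [min, max], ...}` with full precision.
#'
#' @param params 2 x D `norm_params` matrix.
#' @param path JSON file path.
#' @return `path` (write) or the params matrix (read).
#' @export
write_norm_params <- function(params, path) {
  obj <- lapply(seq_len(ncol(params)), function(j) unname(params[, j]))
  names(obj) <- colnames(params)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_norm_params
#' @export
read_norm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- vapply(obj, function(v) c(min = v[1L], max = v[2L]), numeric(2))
  rownames(params) <- c("min", "max")
  params
}
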
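#' Build the fused compound-disease matrix
#'
#' Fuses one normalized compound descriptor vector `b` (length `D_c`) and one
#' normalized disease symptom vector `a` (length `D_d`) into the additive
#' two-dimensional relationship matrix whose entry for compound feature `r`
#' and disease feature `c` is `(b_r + a_c) / 2`.  With the reference
#' dimensions (5270 molecular descriptors, 322 symptom descriptors) this is a
#' 5270 x 322 matrix.  Rows index compound features and columns disease
#' features by default; `transpose = TRUE` exposes the other orientation
#' (disease features as rows), since either reading renders the same
#' information.
#'
#' @param compound numeric vector in `[0, 1]` (normalized descriptors).
#' @param disease numeric vector in `[0, 1]` (normalized symptom weights).
#' @param compound_id,disease_id identifiers carried on the result.
#' @param transpose if `TRUE`, return the disease-rows orientation.
#' @return a `cdr_matrix`: a numeric matrix with `compound_id`/`disease_id`
#'   attributes; every entry lies in `[0, 1]`.
#' @export
build_cdr_matrix <- function(compound, disease, compound_id = "",
                             disease_id = "", transpose = FALSE) {
  compound <- as.numeric(compound)
  disease <- as.numeric(disease)
  if (anyNA(compound) || anyNA(disease)) stop("descriptor vectors contain NA")
  if (any(compound < 0 | compound > 1) || any(disease < 0 | disease > 1)) {
    stop("input vectors must be normalized to [0, 1]; got range [",
         format(min(compound, disease)), ", ",
         format(max(compound, disease)), "]")
  }
  m <- outer(compound, disease, "+") / 2
  if (transpose) m <- t(m)
  structure(m, compound_id = compound_id, disease_id = disease_id,
            class = c("cdr_matrix", class(m)))
}

# round half away from zero (all fused values are >= 0)
round_half_up <- function(x) floor(x + 0.5)

#' Render a fused matrix as an 8-bit grayscale image
#'
#' Pixels are `round(255 * value)` with halves rounded away from zero
#' (so a fused value of exactly 0.5, i.e. 127.5 gray, becomes 128), clamped
#' to `0..255`.  Quantization error is at most 1/510 per entry.
#'
#' @param matrix a `cdr_matrix` (entries in `[0, 1]`).
#' @return a `cdr_image`: an integer matrix with values in `0..255`, carrying
#'   the source pair ids.
#' @export
to_grayscale <- function(matrix) {
  if (any(matrix < 0 | matrix > 1)) stop("matrix entries must lie in [0, 1]")
  px <- round_half_up(255 * unclass(matrix))
  px <- pmin(pmax(px, 0), 255)
  storage.mode(px) <- "integer"
  structure(px,
            compound_id = attr(matrix, "compound_id") %||% "",
            disease_id = attr(matrix, "disease_id") %||% "",
            class = c("cdr_image", "matrix", "array"))
}

#' Resize a grayscale image for network input
#'
#' Deterministic bilinear interpolation of the pixel grid (corner-aligned
#' sampling: the four image corners map exactly to the target corners, so
#' resizing to the image's own shape is the identity).  The reference
#' pipeline's network input geometry is not fixed by the method; any target
#' works, e.g. 224 x 224 for the full-scale architectures, or no resize at
#' all for the desk-scale network.
#'
#' @param image a `cdr_image`.
#' @param target integer `(height, width)`, both >= 1.
#' @return a `cdr_image` of the target shape.
#' @export
resize_image <- function(image, target) {
  stopifnot(length(target) == 2L, all(target >= 1))
  H <- nrow(image); W <- ncol(image)
  if (H == 0L || W == 0L) stop("cannot resize an empty image")
  src <- function(n_out, n_in) {
    if (n_out == 1L) return((n_in + 1) / 2)
    (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1) + 1
  }
  sy <- src(target[1L], H)
  sx <- src(target[2L], W)
  y0 <- pmin(floor(sy), H - 1L); y0 <- pmax(y0, 1L); fy <- sy - y0
  x0 <- pmin(floor(sx), W - 1L); x0 <- pmax(x0, 1L); fx <- sx - x0
  if (H == 1L) { y0 <- rep(1L, length(sy)); fy <- rep(0, length(sy)) }
  if (W == 1L) { x0 <- rep(1L, length(sx)); fx <- rep(0, length(sx)) }
  P <- unclass(image)
  y1 <- pmin(y0 + 1L, H); x1 <- pmin(x0 + 1L, W)
  R <- P[y0, , drop = FALSE] * (1 - fy) + P[y1, , drop = FALSE] * fy
  out <- sweep(R[, x0, drop = FALSE], 2L, 1 - fx, "*") +
         sweep(R[, x1, drop = FALSE], 2L, fx, "*")
  px <- pmin(pmax(round_half_up(out), 0), 255)
  storage.mode(px) <- "integer"
  structure(px,
            compound_id = attr(image, "compound_id") %||% "",
            disease_id = attr(image, "disease_id") %||% "",
            class = c("cdr_image", "matrix", "array"))
}

#' @export
print.cdr_image <- function(x, ...) {
  cat("<cdr_image>", nrow(x), "x", ncol(x), "8-bit grayscale",
      paste0("(", attr(x, "compound_id"), " / ", attr(x, "disease_id"), ")"),
      "\n")
  invisible(x)
}

#' Write / read a CDR image as 8-bit grayscale PNG
#'
#' The write/read round-trip is pixel-exact.  By convention files are named
#' `<compound_id>__<disease_id>.png`.
#'
#' @param image a `cdr_image`.
#' @param path PNG file path.
#' @param rgb how [read_cdr_png()] treats multi-channel PNGs: `"error"`
#'   (default) or `"luminance"` (Rec. 601 weights 0.299/0.587/0.114).
#' @return `path` (write); a `cdr_image` (read).
#' @export
write_cdr_png <- function(image, path) {
  ok <- try(png::writePNG(unclass(image) / 255, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed to write PNG at ", path, ": ", attr(ok, "condition")$message)
  }
  invisible(path)
}

#' @rdname write_cdr_png
#' @export
read_cdr_png <- function(path, rgb = c("error", "luminance")) {
  rgb <- match.arg(rgb)
  if (!file.exists(path)) stop("no such PNG: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    if (rgb == "error") {
      stop("PNG at ", path, " has ", dim(x)[3L],
           " channels; expected single-channel grayscale ",
           "(use rgb = \"luminance\" to convert)")
    }
    x <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
  }
  px <- round_half_up(255 * x)
  storage.mode(px) <- "integer"
  structure(px, compound_id = "", disease_id = "",
            class = c("cdr_image", "matrix", "array"))
}

#' Encode a batch of compound-disease pairs as network-ready images
#'
#' Builds the fused matrix for every pair, quantizes it to 8-bit gray and
#' returns the stack as a single `(D_c * D_d) x N` matrix of pixel
#' intensities rescaled to `[0, 1]` — the input format of [cdr_cnn()] and
#' [predict.cdr_cnn()].  Both tables must already be normalized (screened
#' libraries via [apply_normalization()] with the training-set parameters).
#'
#' @param compounds,diseases normalized `descriptor_table`s.
#' @param pairs data frame with `compound_id` and `disease_id` columns.
#' @param target optional `(height, width)`; when given, every image is
#'   bilinearly resized with [resize_image()] before stacking.
#' @return a `cdr_image_stack`: list with `x` (pixel matrix), `shape`
#'   (`c(height, width)`) and `pairs`.
#' @export
encode_images <- function(compounds, diseases, pairs, target = NULL) {
  stopifnot(inherits(compounds, "descriptor_table"),
            inherits(diseases, "descriptor_table"))
  if (!compounds$normalized || !diseases$normalized) {
    stop("both tables must be normalized before encoding")
  }
  ci <- match(as.character(pairs$compound_id), compounds$ids)
  di <- match(as.character(pairs$disease_id), diseases$ids)
  if (anyNA(ci) || anyNA(di)) {
    missing <- c(unique(pairs$compound_id[is.na(ci)]),
                 unique(pairs$disease_id[is.na(di)]))
    stop("pairs reference ids with no descriptor vector: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  dc <- ncol(compounds$features)
  dd <- ncol(diseases$features)
  B <- t(compounds$features)[, ci, drop = FALSE]   # dc x N
  A <- t(diseases$features)[, di, drop = FALSE]    # dd x N
  vals <- 0.5 * (B[rep(seq_len(dc), dd), , drop = FALSE] +
                 A[rep(seq_len(dd), each = dc), , drop = FALSE])
  dimnames(vals) <- NULL
  px <- pmin(pmax(round_half_up(255 * vals), 0), 255)
  shape <- c(dc, dd)
  if (!is.null(target) && !all(target == shape)) {
    n <- ncol(px)
    res <- matrix(0, target[1L] * target[2L], n)
    for (k in seq_len(n)) {
      img <- matrix(as.integer(px[, k]), dc, dd)
      class(img) <- c("cdr_image", "matrix", "array")
      res[, k] <- as.numeric(resize_image(img, target))
    }
    px <- res
    shape <- as.integer(target)
  }
  structure(list(x = px / 255, shape = shape,
                 pairs = pairs[, c("compound_id", "disease_id")]),
            class = "cdr_image_stack")
}

#' @export
print.cdr_image_stack <- function(x, ...) {
  cat("<cdr_image_stack>", ncol(x$x), "images of",
      paste(x$shape, collapse = " x "), "\n")
  invisible(x)
}
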
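#' Construct an omics matrix
#'
#' The common currency of the pipeline: a numeric feature-by-sample matrix
#' tagged with the kind of measurement it holds. Rows are features (genes or
#' probes), columns are samples; \code{NA} marks missing entries.
#'
#' @param values Numeric matrix with rownames (features) and colnames
#'   (samples).
#' @param kind One of \code{"cnv_logratio"}, \code{"beta"}, \code{"fpkm"},
#'   \code{"counts"}.
#' @return An \code{omics_matrix}: the matrix with a \code{kind} attribute.
#' @examples
#' m <- matrix(runif(6), 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' om <- omics_matrix(m, "beta")
#' omics_kind(om)
#' @export
omics_matrix <- function(values, kind = c("cnv_logratio", "beta", "fpkm", "counts")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (features) and colnames (samples)", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("feature and sample names must be unique", call. = FALSE)
  }
  obs <- values[!is.na(values)]
  if (kind == "beta" && length(obs) && (min(obs) < 0 || max(obs) > 1)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "counts" && length(obs) && (min(obs) < 0 || any(obs != round(obs)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (kind == "fpkm" && length(obs) && min(obs) < 0) {
    stop("fpkm values must be non-negative", call. = FALSE)
  }
  structure(values, kind = kind, class = c("omics_matrix", "matrix", "array"))
}

#' @rdname omics_matrix
#' @param x An \code{omics_matrix}.
#' @export
omics_kind <- function(x) {
  k <- attr(x, "kind")
  if (is.null(k)) stop("not an omics_matrix: no kind attribute", call. = FALSE)
  k
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix kind=%s: %d features x %d samples, %.1f%% missing>\n",
    omics_kind(x), nrow(x), ncol(x), 100 * mean(is.na(x))
  ))
  invisible(x)
}

# Subsetting keeps the class and kind when the result is still a matrix.
#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    attr(out, "kind") <- attr(x, "kind")
    class(out) <- class(x)
  }
  out
}

# Align two omics matrices on their shared samples (and optionally genes),
# preserving the order of the first argument. Errors when nothing is shared.
align_samples <- function(a, b, what = "matrices") {
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) == 0) {
    stop(sprintf("%s share no samples", what), call. = FALSE)
  }
  list(a = a[, shared, drop = FALSE], b = b[, shared, drop = FALSE], samples = shared)
}
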
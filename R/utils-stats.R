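#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples.
#' 1 means identical partitions (up to label names), 0 is the expected value
#' under independent random labellings.
#'
#' @param a,b Cluster label vectors of equal length (any atomic type).
#' @return A single number in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Mean silhouette width of a clustering
#'
#' Silhouette widths computed from a full distance matrix; singleton-cluster
#' samples get width 0 by convention.
#'
#' @param labels Cluster labels, length n.
#' @param dmat n x n symmetric distance matrix (or a `dist`).
#' @return List with `widths` (per sample) and `mean`.
#' @export
silhouette_widths <- function(labels, dmat) {
  if (inherits(dmat, "dist")) dmat <- as.matrix(dmat)
  n <- length(labels)
  stopifnot(nrow(dmat) == n, ncol(dmat) == n)
  labels <- as.character(labels)
  cl <- unique(labels)
  if (length(cl) < 2) stop("silhouette needs >= 2 clusters", call. = FALSE)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own == 1) { widths[i] <- 0; next }
    a_i <- sum(dmat[i, own]) / (n_own - 1)
    b_i <- min(vapply(setdiff(cl, labels[i]), function(g) {
      mean(dmat[i, labels == g])
    }, numeric(1)))
    widths[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  list(widths = widths, mean = mean(widths))
}

# Two-sided p-value for a Pearson correlation via the t transform with
# n - 2 degrees of freedom. |r| = 1 maps to p = 0.
cor_t_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  edge <- ok & abs(r) >= 1
  p[edge] <- 0
  mid <- ok & !edge
  tstat <- r[mid] * sqrt((n[mid] - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tstat), df = n[mid] - 2)
  p
}

# Deterministic seed streams: derive child seeds below 2^31 from a base seed.
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000000L) * 2039L + as.integer(index) * 7L + 13L
}
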
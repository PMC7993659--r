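#' Event-calling thresholds
#'
#' Per-entry event definitions: copy-number gain for values strictly above
#' `cnv_gain`, loss strictly below `cnv_loss`, hypermethylation for beta
#' strictly above `beta_hyper`, hypomethylation strictly below `beta_hypo`.
#' Boundary values are non-events.
#'
#' @param cnv_gain,cnv_loss,beta_hyper,beta_hypo Thresholds; defaults
#'   0.3, -0.3, 0.8, 0.2.
#' @return An `event_thresholds` list.
#' @export
event_thresholds <- function(cnv_gain = 0.3, cnv_loss = -0.3,
                             beta_hyper = 0.8, beta_hypo = 0.2) {
  if (!(cnv_loss < cnv_gain)) stop("cnv_loss must be < cnv_gain", call. = FALSE)
  if (!(beta_hypo < beta_hyper)) stop("beta_hypo must be < beta_hyper", call. = FALSE)
  if (beta_hyper > 1 || beta_hypo < 0) stop("beta thresholds must lie in [0,1]", call. = FALSE)
  structure(list(
    cnv_gain = cnv_gain, cnv_loss = cnv_loss,
    beta_hyper = beta_hyper, beta_hypo = beta_hypo
  ), class = "event_thresholds")
}

#' Count copy-number and methylation events per sample
#'
#' @param cnv `omics_matrix` of kind `cnv_logratio`.
#' @param beta `omics_matrix` of kind `beta` (probe or gene level).
#' @param thresholds An [event_thresholds()].
#' @return data.frame: sample, n_gain, n_loss, n_hyper, n_hypo. Missing
#'   entries are never counted. Only samples shared by both matrices are
#'   reported; disjoint sample sets are an error.
#' @export
classify_events <- function(cnv, beta, thresholds = event_thresholds()) {
  stopifnot(omics_kind(cnv) == "cnv_logratio", omics_kind(beta) == "beta")
  shared <- intersect(colnames(cnv), colnames(beta))
  if (!length(shared)) stop("cnv and beta matrices share no samples", call. = FALSE)
  cm <- unclass(cnv)[, shared, drop = FALSE]
  bm <- unclass(beta)[, shared, drop = FALSE]
  count_col <- function(m, f) colSums(f(m), na.rm = TRUE)
  data.frame(
    sample = shared,
    n_gain = as.integer(count_col(cm, function(x) x > thresholds$cnv_gain)),
    n_loss = as.integer(count_col(cm, function(x) x < thresholds$cnv_loss)),
    n_hyper = as.integer(count_col(bm, function(x) x > thresholds$beta_hyper)),
    n_hypo = as.integer(count_col(bm, function(x) x < thresholds$beta_hypo)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Pairwise concordance of per-sample event frequencies
#'
#' Pearson correlation, for every unordered pair among {gain, loss, hyper,
#' hypo}, of the per-sample event counts, with a two-sided p-value from the
#' t transform (n - 2 df). A pair with a constant member gets `NA` with a
#' warning rather than an error. Significance labels follow the r-sign +
#' p < 0.01 rule: `positive` (r > 0, p < 0.01), `negative` (r < 0,
#' p < 0.01), otherwise `ns`.
#'
#' @param counts data.frame from [classify_events()].
#' @param alpha Significance level for the labels; default 0.01.
#' @return data.frame: pair, r, p, n, label (6 rows).
#' @export
event_frequency_correlations <- function(counts, alpha = 0.01) {
  if (nrow(counts) < 3) stop("need >= 3 samples for event correlations", call. = FALSE)
  vars <- c(gain = "n_gain", loss = "n_loss", hyper = "n_hyper", hypo = "n_hypo")
  combos <- utils::combn(names(vars), 2)
  n <- nrow(counts)
  res <- apply(combos, 2, function(pr) {
    x <- counts[[vars[pr[1]]]]
    y <- counts[[vars[pr[2]]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("constant event counts in pair %s~%s; r undefined", pr[1], pr[2]), call. = FALSE)
      return(data.frame(
        pair = paste0(pr[1], "~", pr[2]), r = NA_real_, p = NA_real_,
        n = n, label = "undefined", stringsAsFactors = FALSE
      ))
    }
    r <- stats::cor(x, y)
    p <- cor_t_pvalue(r, n)
    lab <- if (is.na(p) || p >= alpha) "ns" else if (r > 0) "positive" else "negative"
    data.frame(
      pair = paste0(pr[1], "~", pr[2]), r = r, p = p, n = n, label = lab,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
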
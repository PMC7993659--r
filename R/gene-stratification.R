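#' Correlate an omics layer with expression, gene by gene
#'
#' For every gene present in both matrices, computes the Pearson correlation
#' r between the omics value and log2(FPKM + 1) expression over complete
#' sample pairs, the Fisher z transform `z = ln((1 + r) / (1 - r))`, and a
#' two-sided p-value from the t transform with n - 2 degrees of freedom.
#' |r| = 1 yields infinite z and p = 0.
#'
#' @param omics `omics_matrix` (cnv_logratio or beta, gene level).
#' @param expression `omics_matrix` of kind `fpkm` (log2(x+1) applied
#'   internally) or any matrix already on a linear-model-friendly scale
#'   (used as-is when kind is not `fpkm`).
#' @param layer Label `"cnv"` or `"met"` carried into the result.
#' @return data.frame: gene, layer, r, z, p, n (complete pairs). Genes with
#'   fewer than 3 complete pairs or zero variance are dropped.
#' @export
correlate_omics_expression <- function(omics, expression, layer = c("cnv", "met")) {
  layer <- match.arg(layer)
  shared_g <- intersect(rownames(omics), rownames(expression))
  if (!length(shared_g)) stop("omics and expression share no genes", call. = FALSE)
  al <- align_samples(omics, expression, "omics and expression")
  om <- unclass(al$a)[shared_g, , drop = FALSE]
  ex <- unclass(al$b)[shared_g, , drop = FALSE]
  if (omics_kind(expression) == "fpkm") ex <- log2(ex + 1)

  res <- lapply(seq_along(shared_g), function(i) {
    ok <- !is.na(om[i, ]) & !is.na(ex[i, ])
    n <- sum(ok)
    if (n < 3) return(NULL)
    x <- om[i, ok]; y <- ex[i, ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
    r <- stats::cor(x, y)
    data.frame(
      gene = shared_g[i], layer = layer, r = r, z = fisher_z(r),
      p = cor_t_pvalue(r, n), n = n, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(
      gene = character(0), layer = character(0), r = numeric(0),
      z = numeric(0), p = numeric(0), n = integer(0), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Fisher z transform of a correlation coefficient
#'
#' `z = ln((1 + r) / (1 - r))`, i.e. `2 * artanh(r)`; r = 1 maps to `Inf`,
#' r = -1 to `-Inf`.
#' @param r Correlation value(s) in [-1, 1].
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) log((1 + r) / (1 - r))

#' Select significantly correlated genes
#'
#' Keeps genes with correlation p strictly below `alpha`, any sign of r.
#' The returned set is labelled CNV-G or MET-G according to the layer.
#'
#' @param records data.frame from [correlate_omics_expression()].
#' @param alpha Default 1e-5.
#' @return Character vector of gene ids with attribute `set_label`.
#' @export
select_correlated_genes <- function(records, alpha = 1e-5) {
  if (nrow(records) == 0) {
    return(structure(character(0), set_label = "empty"))
  }
  sel <- records$gene[!is.na(records$p) & records$p < alpha]
  label <- if (all(records$layer == "met")) "MET-G" else if (all(records$layer == "cnv")) "CNV-G" else "mixed"
  structure(sort(unique(sel)), set_label = label)
}

#' Univariate prognostic screen by median expression split
#'
#' Per gene, samples are split at the median of log2(FPKM + 1) expression
#' (ties at the median go to the low group) and the two groups are compared
#' by a log-rank test. Genes whose split is degenerate (constant expression,
#' empty group) are skipped with a warning.
#'
#' @param expression `omics_matrix` (fpkm kind is log-transformed
#'   internally).
#' @param clinical data.frame with sample, OS_time, OS_event.
#' @param genes Genes to screen; default all rows.
#' @param alpha Significance threshold for the `prognostic` flag; default
#'   0.05.
#' @return data.frame: gene, logrank_statistic, p, direction (adverse if the
#'   high-expression group has worse survival), prognostic.
#' @export
prognostic_screen <- function(expression, clinical, genes = rownames(expression),
                              alpha = 0.05) {
  stopifnot(all(c("sample", "OS_time", "OS_event") %in% colnames(clinical)))
  shared <- intersect(colnames(expression), clinical$sample)
  if (length(shared) < 4) stop("too few samples shared with the clinical table", call. = FALSE)
  cl <- clinical[match(shared, clinical$sample), ]
  ex <- unclass(expression)[, shared, drop = FALSE]
  if (omics_kind(expression) == "fpkm") ex <- log2(ex + 1)
  genes <- intersect(genes, rownames(ex))

  skipped <- character(0)
  res <- lapply(genes, function(g) {
    x <- ex[g, ]
    med <- stats::median(x, na.rm = TRUE)
    grp <- ifelse(x <= med, "low", "high")  # ties at the median go low
    if (length(unique(grp[!is.na(grp)])) < 2 || sum(cl$OS_event) == 0) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    sd <- safe_survdiff(cl$OS_time, cl$OS_event, grp)
    pval <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    # adverse if the high-expression group observes more events than expected
    hi <- which(sort(unique(grp)) == "high")
    direction <- if (sd$obs[hi] > sd$exp[hi]) "adverse" else "favorable"
    data.frame(
      gene = g, logrank_statistic = unname(sd$chisq), p = pval,
      direction = direction, prognostic = pval < alpha,
      stringsAsFactors = FALSE
    )
  })
  if (length(skipped)) {
    warning(sprintf(
      "%d gene(s) skipped (constant expression or no events): %s%s",
      length(skipped), paste(utils::head(skipped, 5), collapse = ", "),
      if (length(skipped) > 5) ", ..." else ""
    ), call. = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(
      gene = character(0), logrank_statistic = numeric(0), p = numeric(0),
      direction = character(0), prognostic = logical(0), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Intersect two gene sets
#'
#' @param a,b Character vectors of gene ids.
#' @return Sorted intersection.
#' @export
intersect_gene_sets <- function(a, b) sort(intersect(unique(a), unique(b)))
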
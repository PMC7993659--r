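#' Merge copy-number segments by reciprocal overlap
#'
#' Within each sample and chromosome, segments with fewer than `min_probes`
#' supporting probes are dropped, and the remaining segments are merged when
#' their reciprocal overlap (overlap length divided by the length of EACH
#' interval, both must reach the threshold) is at least
#' `reciprocal_overlap`. Merging is transitive: connected components under
#' the pairwise overlap relation collapse to their union interval, with a
#' probe-count-weighted mean value and summed probe count. Coordinates are
#' 1-based inclusive.
#'
#' @param segments data.frame with columns sample, chrom, start, end,
#'   num_probes, value (as returned by [read_seg_file()]).
#' @param reciprocal_overlap Fraction in (0, 1]; default 0.5.
#' @param min_probes Segments with fewer probes are removed first; default 5.
#' @return data.frame of merged segments, same columns.
#' @export
merge_cnv_segments <- function(segments, reciprocal_overlap = 0.5, min_probes = 5L) {
  req <- c("sample", "chrom", "start", "end", "num_probes", "value")
  if (!all(req %in% colnames(segments))) {
    stop("segments must have columns sample, chrom, start, end, num_probes, value", call. = FALSE)
  }
  if (any(segments$start > segments$end)) {
    stop("malformed segment: start > end", call. = FALSE)
  }
  seg <- segments[segments$num_probes >= min_probes, , drop = FALSE]
  if (nrow(seg) == 0) return(seg)

  pieces <- split(seg, list(seg$sample, seg$chrom), drop = TRUE)
  merged <- lapply(pieces, function(s) {
    s <- s[order(s$start, s$end), , drop = FALSE]
    n <- nrow(s)
    if (n == 1) return(s)
    # Union-find over the reciprocal-overlap relation.
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    len <- s$end - s$start + 1
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (s$start[j] > s$end[i]) break  # sorted by start: no further overlap with i
        ov <- min(s$end[i], s$end[j]) - max(s$start[i], s$start[j]) + 1
        if (ov >= reciprocal_overlap * len[i] && ov >= reciprocal_overlap * len[j]) {
          parent[find(j)] <- find(i)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    out <- lapply(unique(comp), function(cid) {
      grp <- s[comp == cid, , drop = FALSE]
      data.frame(
        sample = grp$sample[1], chrom = grp$chrom[1],
        start = min(grp$start), end = max(grp$end),
        num_probes = sum(grp$num_probes),
        value = sum(grp$value * grp$num_probes) / sum(grp$num_probes),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$sample, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map merged segments to gene-level copy-number values
#'
#' Per gene and sample, the value is the unweighted mean of all merged
#' segments overlapping the gene body `[gene_start, gene_end]`; genes with
#' no overlapping segment in a sample are missing there.
#'
#' @param segments Merged segment data.frame.
#' @param annotation Gene annotation data.frame (gene, chrom, gene_start,
#'   gene_end, ...).
#' @return An `omics_matrix` of kind `cnv_logratio`.
#' @export
map_cnv_to_genes <- function(segments, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0) {
    stop("empty gene annotation", call. = FALSE)
  }
  genes <- annotation$gene
  samples <- sort(unique(segments$sample))
  m <- matrix(NA_real_, length(genes), length(samples),
    dimnames = list(genes, samples)
  )
  cnt <- matrix(0L, length(genes), length(samples))
  seg_by_chrom <- split(segments, segments$chrom)
  for (ci in unique(annotation$chrom)) {
    s <- seg_by_chrom[[ci]]
    if (is.null(s)) next
    ann <- annotation[annotation$chrom == ci, , drop = FALSE]
    sj <- match(s$sample, samples)
    for (gi in seq_len(nrow(ann))) {
      hit <- which(s$start <= ann$gene_end[gi] & s$end >= ann$gene_start[gi])
      if (!length(hit)) next
      ri <- match(ann$gene[gi], genes)
      for (h in hit) {
        j <- sj[h]
        k <- cnt[ri, j]
        m[ri, j] <- if (k == 0) s$value[h] else (m[ri, j] * k + s$value[h]) / (k + 1)
        cnt[ri, j] <- k + 1L
      }
    }
  }
  omics_matrix(m, "cnv_logratio")
}

#' Filter and KNN-impute a probe-level methylation matrix
#'
#' Probes missing in more than `max_missing_fraction` of samples are
#' dropped. Remaining missing entries are imputed as the mean, over the
#' `k_neighbors` nearest probes, of their values in that sample; nearness is
#' Euclidean distance over the samples both probes observe, normalized by the
#' number of shared samples. Ties at the neighbourhood boundary are broken by
#' probe id (lowest first) for determinism. Imputed values are clipped to
#' [0, 1]; observed entries are never altered.
#'
#' @param beta An `omics_matrix` of kind `beta` at probe level.
#' @param max_missing_fraction Drop probes missing in strictly more than this
#'   fraction of samples; default 0.7.
#' @param k_neighbors Neighbourhood size; default 10.
#' @return A complete probe-level `omics_matrix`.
#' @export
filter_impute_methylation <- function(beta, max_missing_fraction = 0.7, k_neighbors = 10L) {
  stopifnot(omics_kind(beta) == "beta")
  miss_frac <- rowMeans(is.na(beta))
  keep <- miss_frac <= max_missing_fraction
  if (!any(keep)) {
    stop(sprintf(
      "all %d probes dropped: every probe missing in > %.0f%% of samples",
      nrow(beta), 100 * max_missing_fraction
    ), call. = FALSE)
  }
  m <- unclass(beta)[keep, , drop = FALSE]
  if (!anyNA(m)) return(omics_matrix(m, "beta"))

  need <- which(rowSums(is.na(m)) > 0)
  obs <- !is.na(m)
  filled <- m
  for (i in need) {
    # mean squared difference over shared observed samples, per candidate row
    shared <- obs & rep(obs[i, ], each = nrow(m))
    n_shared <- rowSums(shared)
    diff2 <- (m - rep(m[i, ], each = nrow(m)))^2
    diff2[!shared] <- 0
    d2 <- ifelse(n_shared > 0, rowSums(diff2) / n_shared, Inf)
    d2[i] <- Inf
    ord <- order(d2, rownames(m))  # probe-id tie-break, deterministic
    for (j in which(is.na(m[i, ]))) {
      cand <- ord[obs[ord, j] & is.finite(d2[ord])]
      if (!length(cand)) {
        filled[i, j] <- mean(m[i, ], na.rm = TRUE)  # fallback: row mean
        next
      }
      nb <- cand[seq_len(min(k_neighbors, length(cand)))]
      filled[i, j] <- mean(m[nb, j])
    }
  }
  filled[filled < 0] <- 0
  filled[filled > 1] <- 1
  omics_matrix(filled, "beta")
}

#' Aggregate promoter probes to gene-level methylation
#'
#' A probe is assigned to a gene when it falls in the strand-aware promoter
#' window `[tss - upstream, tss + downstream]` (positions upstream of the
#' TSS count against `upstream` on both strands). Multiple probes per gene
#' are averaged per sample. Probes on chromosomes absent from the annotation
#' are skipped with a warning.
#'
#' @param beta Complete probe-level `omics_matrix` of kind `beta`.
#' @param probes Probe annotation data.frame (probe, chrom, position, ...).
#' @param annotation Gene annotation data.frame (gene, chrom, strand, tss, ...).
#' @param upstream,downstream Promoter window in bp; defaults 2000 and 200.
#' @return Gene-level `omics_matrix` of kind `beta`.
#' @export
map_probes_to_promoters <- function(beta, probes, annotation,
                                    upstream = 2000L, downstream = 200L) {
  stopifnot(omics_kind(beta) == "beta")
  probes <- probes[probes$probe %in% rownames(beta), , drop = FALSE]
  unknown <- !probes$chrom %in% annotation$chrom
  if (any(unknown)) {
    warning(sprintf(
      "%d probe(s) on chromosomes absent from the gene annotation were skipped",
      sum(unknown)
    ), call. = FALSE)
    probes <- probes[!unknown, , drop = FALSE]
  }
  acc <- list()
  for (ci in unique(annotation$chrom)) {
    ann <- annotation[annotation$chrom == ci, , drop = FALSE]
    pr <- probes[probes$chrom == ci, , drop = FALSE]
    if (nrow(pr) == 0) next
    for (gi in seq_len(nrow(ann))) {
      tss <- ann$tss[gi]
      if (ann$strand[gi] == "+") {
        lo <- tss - upstream; hi <- tss + downstream
      } else {
        lo <- tss - downstream; hi <- tss + upstream
      }
      hit <- pr$probe[pr$position >= lo & pr$position <= hi]
      if (length(hit)) acc[[ann$gene[gi]]] <- hit
    }
  }
  if (!length(acc)) {
    warning("no probe fell in any promoter window; empty matrix returned", call. = FALSE)
    return(omics_matrix(
      matrix(numeric(0), 0, ncol(beta),
        dimnames = list(character(0), colnames(beta))
      ), "beta"
    ))
  }
  vals <- t(vapply(acc, function(ids) {
    colMeans(unclass(beta)[ids, , drop = FALSE])
  }, numeric(ncol(beta))))
  rownames(vals) <- names(acc)
  colnames(vals) <- colnames(beta)
  omics_matrix(vals[order(rownames(vals)), , drop = FALSE], "beta")
}

#' Drop low-expressed genes from an FPKM matrix
#'
#' Genes are retained only when the fraction of samples with FPKM exactly 0
#' is strictly below `max_zero_fraction`; the boundary case (zero fraction
#' equal to the threshold) is removed.
#'
#' @param fpkm An `omics_matrix` of kind `fpkm`.
#' @param max_zero_fraction Default 0.5.
#' @return Filtered `omics_matrix`.
#' @export
filter_expression <- function(fpkm, max_zero_fraction = 0.5) {
  stopifnot(omics_kind(fpkm) == "fpkm")
  zero_frac <- rowMeans(unclass(fpkm) == 0, na.rm = TRUE)
  keep <- zero_frac < max_zero_fraction
  if (!any(keep)) warning("all genes removed by the expression filter", call. = FALSE)
  fpkm[keep, , drop = FALSE]
}

#' Remove intronic and silent mutation calls
#'
#' @param records data.frame with columns gene, sample, classification.
#' @param drop_classes Classifications removed, case-insensitively; defaults
#'   to Intron and Silent (with the common synonyms "Silence" and "IGR"
#'   excluded from the default on purpose — pass your own list to widen it).
#' @return Filtered records.
#' @export
filter_mutations <- function(records, drop_classes = c("Intron", "Silent")) {
  if (nrow(records) == 0) return(records)
  if (!"classification" %in% colnames(records) ||
      any(is.na(records$classification)) || any(!nzchar(records$classification))) {
    stop("malformed mutation record: missing classification", call. = FALSE)
  }
  keep <- !(tolower(records$classification) %in% tolower(drop_classes))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
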
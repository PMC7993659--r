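#' Non-negative matrix factorization by KL multiplicative updates
#'
#' The classical "brunet" variant: starting from uniform-random positive
#' factors, W and H are updated multiplicatively to decrease the
#' Kullback-Leibler divergence D(V || WH); the update sequence is
#' non-increasing in D. Iteration stops when the relative change of the
#' divergence falls below `tol` or after `max_iter` updates.
#'
#' @param V Non-negative feature-by-sample matrix, no missing values.
#' @param rank Factorization rank, strictly less than both dimensions.
#' @param seed Seed for the random initialization.
#' @param max_iter,tol Stopping rule; defaults 2000 and 1e-6.
#' @param n_init Number of seeded random initializations screened with
#'   `init_iter` burn-in updates each; the candidate with the lowest KL
#'   divergence is continued to convergence. Guards against the dead-basis
#'   local minima multiplicative updates cannot leave; default 3.
#' @param init_iter Burn-in updates per candidate; default 30.
#' @return An `nmf_model`: W (feature x rank), H (rank x sample), rank,
#'   divergence (final KL value), divergence_trace, n_iter, converged.
#' @export
nmf_factorize <- function(V, rank, seed = 1L, max_iter = 2000L, tol = 1e-6,
                          n_init = 3L, init_iter = 30L) {
  V <- unclass(V)
  if (anyNA(V)) stop("V must not contain missing values", call. = FALSE)
  if (any(V < 0)) stop("V must be non-negative", call. = FALSE)
  if (rank >= min(dim(V))) stop("rank must be < min(dim(V))", call. = FALSE)
  if (rank < 1) stop("rank must be >= 1", call. = FALSE)
  p <- nrow(V); n <- ncol(V)
  eps <- .Machine$double.eps
  pos <- V > 0
  kl_div <- function(WH) {
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }
  update_steps <- function(st, iters, tol_stop) {
    W <- st$W; H <- st$H
    WH <- W %*% H
    d_prev <- if (is.null(st$d)) kl_div(WH) else st$d
    trace <- st$trace
    if (is.null(trace)) trace <- d_prev
    converged <- FALSE
    done <- 0L
    while (done < iters) {
      done <- done + 1L
      R <- V / pmax(WH, eps)
      H <- H * (t(W) %*% R) / pmax(colSums(W), eps)
      WH <- W %*% H
      R <- V / pmax(WH, eps)
      W <- W * (R %*% t(H)) / pmax(rep(rowSums(H), each = p), eps)
      WH <- W %*% H
      d <- kl_div(WH)
      trace <- c(trace, d)
      if (!is.null(tol_stop) && abs(d_prev - d) <= tol_stop * max(abs(d_prev), eps)) {
        converged <- TRUE
        d_prev <- d
        break
      }
      d_prev <- d
    }
    list(W = W, H = H, d = d_prev, trace = trace, converged = converged, n_iter = done)
  }

  burn <- min(init_iter, max_iter)
  candidates <- lapply(seq_len(max(1L, n_init)), function(ci) {
    set.seed(derive_seed(seed, ci))
    st <- list(
      W = matrix(stats::runif(p * rank, 0.1, 1), p, rank),
      H = matrix(stats::runif(rank * n, 0.1, 1), rank, n)
    )
    update_steps(st, burn, tol_stop = NULL)
  })
  best <- candidates[[which.min(vapply(candidates, `[[`, numeric(1), "d"))]]
  fin <- update_steps(best, max_iter - best$n_iter, tol_stop = tol)
  structure(list(
    W = fin$W, H = fin$H, rank = rank, divergence = fin$d,
    divergence_trace = fin$trace, n_iter = best$n_iter + fin$n_iter,
    converged = fin$converged || fin$n_iter == 0L
  ), class = "nmf_model")
}

#' Hard column clustering from an NMF model
#'
#' Each sample is assigned to the row of H with the largest coefficient.
#' @param model An `nmf_model`.
#' @return Integer vector of cluster ids, one per sample.
#' @export
nmf_cluster <- function(model) apply(model$H, 2, which.max)

#' Consensus clustering over repeated NMF runs
#'
#' Runs `n_runs` factorizations from distinct seeded random initializations,
#' assigns samples by dominant H row per run, and accumulates the
#' co-assignment frequency into a consensus matrix. The final assignment is
#' average-linkage hierarchical clustering of 1 - consensus cut at `rank`
#' clusters. Reported metrics: cophenetic correlation (CPCC) between the
#' dendrogram's cophenetic distances and 1 - consensus, the dispersion index
#' mean((2 (C - 1/2))^2), and the mean silhouette width on 1 - consensus.
#' A rank whose smallest cluster is below `min_cluster_size` is flagged
#' inadmissible rather than erroring.
#'
#' @param V Non-negative matrix with sample columns (colnames required).
#' @param rank Number of clusters.
#' @param n_runs Number of random restarts; default 50.
#' @param seed Base seed; run r uses a seed derived from it.
#' @param max_iter,tol Per-run stopping rule passed to [nmf_factorize()].
#' @param min_cluster_size Admissibility floor; default 10.
#' @return A `consensus_result`: rank, consensus matrix, cophenetic,
#'   dispersion, mean_silhouette, assignment ([subtype_assignment()]),
#'   admissible flag.
#' @export
consensus_cluster <- function(V, rank, n_runs = 50L, seed = 1L,
                              max_iter = 2000L, tol = 1e-6,
                              min_cluster_size = 10L) {
  V <- unclass(V)
  if (is.null(colnames(V))) stop("V must have sample colnames", call. = FALSE)
  n <- ncol(V)
  C <- matrix(0, n, n, dimnames = list(colnames(V), colnames(V)))
  for (r in seq_len(n_runs)) {
    fit <- nmf_factorize(V, rank,
      seed = derive_seed(seed, r),
      max_iter = max_iter, tol = tol
    )
    lab <- nmf_cluster(fit)
    C <- C + outer(lab, lab, `==`)
  }
  C <- C / n_runs
  consensus_metrics(C, rank, min_cluster_size)
}

#' Stability metrics of a consensus matrix
#'
#' Average-linkage clustering of 1 - consensus cut at `rank` clusters, with
#' the cophenetic correlation, dispersion index and mean silhouette. A
#' constant off-diagonal consensus has no defined dendrogram agreement and
#' yields `NA` cophenetic with a warning.
#'
#' @param C Symmetric sample-by-sample consensus matrix in [0,1] with unit
#'   diagonal.
#' @param rank Number of clusters to cut.
#' @param min_cluster_size Admissibility floor; default 10.
#' @return A `consensus_result`; see [consensus_cluster()].
#' @export
consensus_metrics <- function(C, rank, min_cluster_size = 10L) {
  d <- stats::as.dist(1 - C)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = rank)
  coph_d <- stats::cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(coph_d) == 0) {
    warning("degenerate consensus matrix: cophenetic correlation undefined", call. = FALSE)
    cpcc <- NA_real_
  } else {
    cpcc <- stats::cor(as.vector(d), as.vector(coph_d))
  }
  dispersion <- mean((2 * (C - 0.5))^2)
  sil <- if (length(unique(labels)) >= 2) {
    silhouette_widths(labels, as.matrix(1 - C))$mean
  } else NA_real_
  admissible <- min(table(labels)) >= min_cluster_size
  structure(list(
    rank = rank, consensus = C, cophenetic = cpcc, dispersion = dispersion,
    mean_silhouette = sil,
    assignment = subtype_assignment(labels, method = sprintf("NMF-k%d", rank)),
    admissible = admissible, min_cluster_size = min_cluster_size
  ), class = "consensus_result")
}

#' Subtype assignment container
#'
#' @param labels Named vector (names = samples) of cluster ids.
#' @param method Provenance label, e.g. "NMF-CNVCor" or "integrative".
#' @return A `subtype_assignment`: method, labels (named integer-coded), k.
#' @export
subtype_assignment <- function(labels, method = "unknown") {
  if (is.null(names(labels))) stop("labels must be named by sample", call. = FALSE)
  coded <- as.integer(factor(labels))
  names(coded) <- names(labels)
  structure(list(method = method, labels = coded, k = length(unique(coded))),
    class = "subtype_assignment"
  )
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("<subtype_assignment method=%s, k=%d, n=%d>\n", x$method, x$k, length(x$labels)))
  print(table(x$labels))
  invisible(x)
}

#' Select the factorization rank from consensus metrics
#'
#' Among admissible ranks (smallest cluster >= `min_cluster_size`), picks
#' the maximal cophenetic correlation; ties go to the higher mean
#' silhouette, then to the smaller rank.
#'
#' @param results List of `consensus_result` objects over candidate ranks.
#' @param min_cluster_size Re-checked here; default 10.
#' @return The chosen rank (integer).
#' @export
select_rank <- function(results, min_cluster_size = 10L) {
  ok <- vapply(results, function(r) {
    min(table(r$assignment$labels)) >= min_cluster_size && !is.na(r$cophenetic)
  }, logical(1))
  if (!any(ok)) stop("no admissible rank: every candidate has a cluster below the size floor", call. = FALSE)
  cand <- results[ok]
  coph <- vapply(cand, `[[`, numeric(1), "cophenetic")
  sil <- vapply(cand, `[[`, numeric(1), "mean_silhouette")
  rk <- vapply(cand, `[[`, numeric(1), "rank")
  ord <- order(-coph, -sil, rk)
  as.integer(rk[ord[1]])
}

#' Cross-tabulate two subtype assignments
#'
#' Contingency table over shared samples with a chi-square test of
#' independence and row-normalized overlap fractions. For tables with any
#' expected count below 5 the p-value is a seeded Monte-Carlo estimate
#' (1e5 tables); 2x2 tables use continuity correction otherwise.
#'
#' @param a,b `subtype_assignment` objects.
#' @param seed Seed for the Monte-Carlo branch.
#' @return List: table, p, fractions (rows of a), method.
#' @export
subtype_overlap <- function(a, b, seed = 1L) {
  shared <- intersect(names(a$labels), names(b$labels))
  if (!length(shared)) stop("assignments share no samples", call. = FALSE)
  tab <- table(a = a$labels[shared], b = b$labels[shared])
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    set.seed(seed)
    ct <- suppressWarnings(stats::chisq.test(tab, simulate.p.value = TRUE, B = 1e5))
    method <- "chisq_montecarlo"
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = all(dim(tab) == 2)))
    method <- "chisq"
  }
  list(
    table = tab, p = unname(ct$p.value),
    fractions = sweep(unclass(tab), 1, rowSums(tab), `/`),
    method = method
  )
}
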
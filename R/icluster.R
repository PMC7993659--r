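#' Configuration for the integrative latent-variable clustering
#'
#' The model couples T data types through shared latent positions:
#' `X_t = W_t Z + eps_t`, with `Z` a (k-1)-dimensional standard Gaussian and
#' diagonal type-specific noise. One lasso penalty per data type, each in
#' [0, 1], sparsifies the loadings.
#'
#' The lambda vectors printed by the reference analysis are available as
#' documented presets: `icluster_lambda_presets()` returns the K=2 vector
#' (0.26756757, 0.02432432, 0.29459459) and the K=3 vector
#' (0.95945946, 0.01351351, 0.57567568) for (CNV, methylation, expression).
#' They are presets, not defaults: lambda tuning is data-dependent.
#'
#' @param k Number of clusters (latent dimension is k - 1); >= 2.
#' @param lambda Numeric vector, one penalty in [0,1] per data type.
#' @param n_lambda_points Size of the tuning design; default 101.
#' @param n_repeats Refits for stability assessment; default 20.
#' @param max_iter,tol EM stopping rule; defaults 2000 and 1e-6 (EM can
#'   need many cheap iterations at high signal-to-noise).
#' @param seed Integer seed.
#' @return An `icluster_config` list.
#' @export
icluster_config <- function(k = 3L, lambda = c(0.2, 0.2, 0.2),
                            n_lambda_points = 101L, n_repeats = 20L,
                            max_iter = 2000L, tol = 1e-6, seed = 1L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (any(lambda < 0 | lambda > 1)) stop("all lambda must lie in [0,1]", call. = FALSE)
  structure(list(
    k = as.integer(k), lambda = as.numeric(lambda),
    n_lambda_points = as.integer(n_lambda_points),
    n_repeats = as.integer(n_repeats),
    max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed)
  ), class = "icluster_config")
}

#' @rdname icluster_config
#' @export
icluster_lambda_presets <- function() {
  list(
    k2 = c(cnv = 0.26756757, met = 0.02432432, expr = 0.29459459),
    k3 = c(cnv = 0.95945946, met = 0.01351351, expr = 0.57567568)
  )
}

#' Prepare omics matrices for integrative clustering
#'
#' Beta matrices are logit-transformed after clipping to [0.001, 0.999],
#' FPKM is log2(x + 1) transformed; every matrix is then row-standardized
#' (mean 0, sd 1; zero-variance rows dropped) and restricted to the given
#' gene set and the samples shared by all types.
#'
#' @param data Named list of `omics_matrix` objects.
#' @param gene_sets Optional named list (same names) of gene ids to keep.
#' @return Named list of standardized plain matrices on shared samples.
#' @export
prepare_icluster_inputs <- function(data, gene_sets = NULL) {
  shared <- Reduce(intersect, lapply(data, colnames))
  if (length(shared) < 2) stop("data types share fewer than 2 samples", call. = FALSE)
  out <- lapply(names(data), function(nm) {
    m <- data[[nm]]
    kind <- omics_kind(m)
    x <- unclass(m)[, shared, drop = FALSE]
    if (!is.null(gene_sets) && !is.null(gene_sets[[nm]])) {
      x <- x[intersect(rownames(x), gene_sets[[nm]]), , drop = FALSE]
    }
    if (kind == "beta") x <- stats::qlogis(pmin(pmax(x, 0.001), 0.999))
    if (kind == "fpkm") x <- log2(x + 1)
    mu <- rowMeans(x, na.rm = TRUE)
    sd <- apply(x, 1, stats::sd, na.rm = TRUE)
    keep <- is.finite(sd) & sd > 0
    x <- (x - mu) / ifelse(keep, sd, 1)
    x[keep, , drop = FALSE]
  })
  names(out) <- names(data)
  out
}

#' Fit the lasso-penalized Gaussian latent-variable model
#'
#' EM on the joint model `X_t = W_t Z + eps_t` with diagonal noise and
#' standard-Gaussian latent columns. The E-step computes the posterior mean
#' and covariance of Z given the stacked data; the M-step updates the
#' loadings with per-type soft-thresholding at
#' `lambda_t * max |unpenalized loading of type t|` and the noise variances
#' from residual moments. Final clusters come from seeded k-means (20
#' restarts) on the posterior latent positions. At lambda = 0 the iteration
#' is a plain EM and the observed-data log-likelihood is non-decreasing.
#'
#' @param data List of row-standardized feature-by-sample matrices sharing
#'   sample columns (see [prepare_icluster_inputs()]).
#' @param config An [icluster_config()]; `config$lambda` is recycled to the
#'   number of data types.
#' @return An `icluster_model`: loadings `W` (per type), latent `Z`
#'   ((k-1) x n posterior means), `psi` (per type), `loglik_trace`,
#'   `converged`, `degenerate`, `assignment`.
#' @export
fit_icluster <- function(data, config = icluster_config()) {
  if (!is.list(data) || !length(data)) stop("data must be a non-empty list of matrices", call. = FALSE)
  ns <- vapply(data, ncol, integer(1))
  cols <- lapply(data, colnames)
  if (length(unique(ns)) != 1 || (!is.null(cols[[1]]) &&
      !all(vapply(cols, identical, logical(1), cols[[1]])))) {
    stop("data types must share identical sample columns", call. = FALSE)
  }
  if (any(vapply(data, function(m) any(!is.finite(m)), logical(1)))) {
    stop("non-finite values in input matrices", call. = FALSE)
  }
  k <- config$k
  q <- k - 1L
  lambda <- rep_len(config$lambda, length(data))
  X <- do.call(rbind, lapply(data, unclass))
  p <- nrow(X); n <- ncol(X)
  type_of <- rep(seq_along(data), vapply(data, nrow, integer(1)))
  if (q >= min(p, n)) stop("k too large for the data dimensions", call. = FALSE)

  set.seed(config$seed)
  W <- matrix(stats::rnorm(p * q, 0, 0.3), p, q)
  psi <- rep(1, p)
  xx_row <- rowSums(X^2)

  loglik <- function(W, psi) {
    pinv <- 1 / psi
    M <- crossprod(W * pinv, W)          # q x q
    IM <- diag(q) + M
    A <- crossprod(W * pinv, X)          # q x n
    quad <- colSums(X^2 * pinv) - colSums(A * solve(IM, A))
    logdet <- sum(log(psi)) + determinant(IM, logarithm = TRUE)$modulus[1]
    -0.5 * (n * p * log(2 * pi) + n * logdet + sum(quad))
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  EZ <- NULL
  for (it in seq_len(config$max_iter)) {
    # E-step
    pinv <- 1 / psi
    M <- crossprod(W * pinv, W)
    Sig <- solve(diag(q) + M)            # posterior covariance of Z
    EZ <- Sig %*% crossprod(W * pinv, X) # q x n posterior means
    EZZ <- n * Sig + tcrossprod(EZ)

    # M-step
    Cc <- tcrossprod(X, EZ)              # p x q, X %*% t(EZ)
    W_unpen <- Cc %*% solve(EZZ)
    W_new <- W_unpen
    for (t in seq_along(data)) {
      rows <- type_of == t
      if (lambda[t] > 0) {
        thr <- lambda[t] * max(abs(W_unpen[rows, , drop = FALSE]))
        wt <- W_unpen[rows, , drop = FALSE]
        W_new[rows, ] <- sign(wt) * pmax(abs(wt) - thr, 0)
      }
    }
    psi_new <- (xx_row - 2 * rowSums(W_new * Cc) + rowSums((W_new %*% EZZ) * W_new)) / n
    psi_new <- pmax(psi_new, 1e-3)  # Heywood-case floor (inputs are row-standardized)

    W <- W_new
    psi <- psi_new
    ll <- loglik(W, psi)
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <= config$tol * (abs(ll_trace[it - 1]) + 1e-3)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("EM did not converge within max_iter", call. = FALSE)

  degenerate <- all(W == 0)
  if (degenerate) {
    warning("all loadings shrunk to zero: degenerate model, assignment undefined", call. = FALSE)
    assignment <- NULL
  } else {
    pinv <- 1 / psi
    Sig <- solve(diag(q) + crossprod(W * pinv, W))
    EZ <- Sig %*% crossprod(W * pinv, X)
    set.seed(derive_seed(config$seed, 999L))
    km <- stats::kmeans(t(EZ), centers = k, nstart = 20, iter.max = 100)
    labs <- km$cluster
    names(labs) <- colnames(data[[1]])
    assignment <- subtype_assignment(labs, method = "integrative")
  }
  Wsplit <- split.data.frame(W, type_of)
  names(Wsplit) <- names(data)
  structure(list(
    W = Wsplit, Z = EZ, psi = split(psi, type_of), lambda = lambda,
    k = k, loglik_trace = ll_trace, converged = converged,
    degenerate = degenerate, assignment = assignment,
    n_nonzero = sum(W != 0)
  ), class = "icluster_model")
}

# Low-discrepancy design over [0,1]^d: Halton sequence (bases 2,3,5,7,...)
# with a seeded random shift modulo 1.
halton_design <- function(n, d, seed) {
  vdc <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  bases <- c(2, 3, 5, 7, 11, 13)[seq_len(d)]
  pts <- sapply(seq_len(d), function(j) vapply(seq_len(n), vdc, numeric(1), base = bases[j]))
  pts <- matrix(pts, n, d)
  set.seed(seed)
  shift <- stats::runif(d)
  (pts + rep(shift, each = n)) %% 1
}

#' Tune the per-type lasso penalties
#'
#' Evaluates `n_points` lambda vectors from a seeded low-discrepancy
#' (shifted Halton) design over `[0,1]^T`, fits the model at each, and
#' selects the vector maximizing the mean silhouette width of the k-cluster
#' assignment in latent space; ties break to the smaller L1 norm of lambda.
#' Degenerate fits (all loadings zero) get silhouette `NA`.
#'
#' @param data As for [fit_icluster()].
#' @param k Cluster count.
#' @param n_points Design size; default 101.
#' @param seed Seed for the design shift and the fits.
#' @param max_iter,tol EM stopping rule for the tuning fits.
#' @return List: `best_lambda`, `best_model`, `diagnostics` (one row per
#'   design point: lambda columns, silhouette, n_nonzero, converged,
#'   degenerate).
#' @export
tune_lambda <- function(data, k, n_points = 101L, seed = 1L,
                        max_iter = 60L, tol = 1e-5) {
  d <- length(data)
  design <- halton_design(n_points, d, seed)
  rows <- vector("list", n_points)
  models <- vector("list", n_points)
  for (i in seq_len(n_points)) {
    cfg <- icluster_config(
      k = k, lambda = design[i, ], max_iter = max_iter, tol = tol,
      seed = derive_seed(seed, i)
    )
    fit <- suppressWarnings(fit_icluster(data, cfg))
    sil <- NA_real_
    if (!fit$degenerate) {
      dz <- stats::dist(t(fit$Z))
      labs <- fit$assignment$labels
      if (length(unique(labs)) >= 2) sil <- silhouette_widths(labs, dz)$mean
    }
    models[[i]] <- fit
    rows[[i]] <- data.frame(
      point = i, t(design[i, ]), silhouette = sil,
      n_nonzero = fit$n_nonzero, converged = fit$converged,
      degenerate = fit$degenerate
    )
  }
  diag_tab <- do.call(rbind, rows)
  colnames(diag_tab)[2:(1 + d)] <- paste0("lambda_", seq_len(d))
  if (all(is.na(diag_tab$silhouette))) {
    stop("all lambda design points degenerate; see diagnostics", call. = FALSE)
  }
  l1 <- rowSums(design)
  ord <- order(-diag_tab$silhouette, l1, na.last = TRUE)
  best <- ord[1]
  list(
    best_lambda = design[best, ], best_model = models[[best]],
    diagnostics = diag_tab
  )
}

#' Stability of the integrative clustering across refits
#'
#' For each candidate k, refits the model `n_repeats` times with distinct
#' seeds and reports the mean pairwise adjusted Rand index between the
#' resulting assignments, plus (when clinical data are supplied) the global
#' log-rank p-value of the medoid assignment — the refit with highest mean
#' agreement with the others. The report ranks k; the final choice stays
#' with the caller.
#'
#' @param data As for [fit_icluster()].
#' @param k_values Candidate cluster counts; default c(2, 3, 4).
#' @param config Base [icluster_config()] (lambda, stopping rule, seed).
#' @param clinical Optional clinical table (sample, OS_time, OS_event).
#' @param n_repeats Refits per k; default `config$n_repeats` (20).
#' @return List: `report` (data.frame k, stability, logrank_p),
#'   `assignments` (medoid assignment per k).
#' @export
stability_repeats <- function(data, k_values = c(2L, 3L, 4L),
                              config = icluster_config(), clinical = NULL,
                              n_repeats = config$n_repeats) {
  report <- list()
  assignments <- list()
  for (k in k_values) {
    labs <- list()
    for (r in seq_len(n_repeats)) {
      cfg <- icluster_config(
        k = k, lambda = config$lambda, max_iter = config$max_iter,
        tol = config$tol, seed = derive_seed(config$seed, k * 1000L + r)
      )
      fit <- suppressWarnings(fit_icluster(data, cfg))
      if (!fit$degenerate) labs[[length(labs) + 1]] <- fit$assignment$labels
    }
    if (length(labs) < 2) {
      report[[as.character(k)]] <- data.frame(
        k = k, stability = NA_real_, logrank_p = NA_real_
      )
      next
    }
    pairs <- utils::combn(length(labs), 2)
    aris <- apply(pairs, 2, function(ij) adjusted_rand_index(labs[[ij[1]]], labs[[ij[2]]]))
    # medoid refit: highest mean agreement with the others
    agree <- vapply(seq_along(labs), function(i) {
      mean(vapply(seq_along(labs)[-i], function(j) adjusted_rand_index(labs[[i]], labs[[j]]), numeric(1)))
    }, numeric(1))
    medoid <- subtype_assignment(labs[[which.max(agree)]],
      method = sprintf("integrative-k%d", k)
    )
    assignments[[as.character(k)]] <- medoid
    lr_p <- NA_real_
    if (!is.null(clinical)) {
      lr <- try(km_logrank(clinical, medoid), silent = TRUE)
      if (!inherits(lr, "try-error")) lr_p <- lr$global_p
    }
    report[[as.character(k)]] <- data.frame(
      k = k, stability = mean(aris), logrank_p = lr_p
    )
  }
  list(report = do.call(rbind, c(report, make.row.names = FALSE)), assignments = assignments)
}
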
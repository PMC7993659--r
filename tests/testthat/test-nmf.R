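# block-diagonal non-negative matrix with known column membership
block_matrix <- function(n_blocks = 3, rows_per = 12, cols_per = 7, noise = 0, seed = 1) {
  set.seed(seed)
  p <- n_blocks * rows_per
  n <- n_blocks * cols_per
  V <- matrix(noise * abs(rnorm(p * n)), p, n)
  for (b in seq_len(n_blocks)) {
    ri <- (b - 1) * rows_per + seq_len(rows_per)
    ci <- (b - 1) * cols_per + seq_len(cols_per)
    V[ri, ci] <- V[ri, ci] + matrix(runif(rows_per * cols_per, 5, 10), rows_per, cols_per)
  }
  dimnames(V) <- list(sprintf("g%02d", 1:p), sprintf("s%02d", 1:n))
  list(V = V, labels = rep(seq_len(n_blocks), each = cols_per))
}

test_that("factorizing an exact rank-1 matrix drives the divergence to ~0", {
  set.seed(4)
  V <- outer(runif(15, 1, 3), runif(9, 1, 3))
  dimnames(V) <- list(sprintf("g%d", 1:15), sprintf("s%d", 1:9))
  fit <- nmf_factorize(V, 1, seed = 2, max_iter = 2000, tol = 1e-12)
  expect_lt(fit$divergence, 1e-8)
})

test_that("the KL objective is non-increasing and inputs are validated", {
  bm <- block_matrix(noise = 0.5, seed = 9)
  fit <- nmf_factorize(bm$V, 3, seed = 5, max_iter = 150)
  expect_true(all(diff(fit$divergence_trace) <= 1e-9 * max(1, fit$divergence_trace[1])))
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))

  Vneg <- bm$V; Vneg[1, 1] <- -1
  expect_error(nmf_factorize(Vneg, 2), "non-negative")
  expect_error(nmf_factorize(bm$V, min(dim(bm$V))), "rank")
})

test_that("factor scale indeterminacy leaves the divergence unchanged", {
  bm <- block_matrix(noise = 0.5, seed = 10)
  fit <- nmf_factorize(bm$V, 3, seed = 6, max_iter = 100)
  kl <- function(W, H) {
    WH <- W %*% H
    pos <- bm$V > 0
    sum(bm$V[pos] * log(bm$V[pos] / WH[pos])) - sum(bm$V) + sum(WH)
  }
  W2 <- fit$W; H2 <- fit$H
  W2[, 1] <- W2[, 1] * 3.7
  H2[1, ] <- H2[1, ] / 3.7
  expect_equal(kl(fit$W, fit$H), kl(W2, H2), tolerance = 1e-10)
})

test_that("3-block matrices are clustered exactly and consensus is ideal", {
  bm <- block_matrix(noise = 0, seed = 11)
  fit <- nmf_factorize(bm$V, 3, seed = 3, max_iter = 500)
  expect_equal(adjusted_rand_index(nmf_cluster(fit), bm$labels), 1)

  cr <- consensus_cluster(bm$V, 3, n_runs = 10, seed = 21, max_iter = 500, min_cluster_size = 5)
  expect_true(all(cr$consensus %in% c(0, 1)))
  expect_equal(cr$cophenetic, 1, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(cr$assignment$labels, bm$labels), 1)
  # symmetry and unit diagonal
  expect_equal(cr$consensus, t(cr$consensus))
  expect_equal(unname(diag(cr$consensus)), rep(1, ncol(bm$V)))
})

test_that("consensus is deterministic given seeds", {
  bm <- block_matrix(noise = 1, seed = 12)
  a <- consensus_cluster(bm$V, 2, n_runs = 5, seed = 7, max_iter = 100, min_cluster_size = 2)
  b <- consensus_cluster(bm$V, 2, n_runs = 5, seed = 7, max_iter = 100, min_cluster_size = 2)
  expect_identical(a$consensus, b$consensus)
})

test_that("a constant off-diagonal consensus is flagged undefined", {
  C <- matrix(0.5, 8, 8, dimnames = list(sprintf("s%d", 1:8), sprintf("s%d", 1:8)))
  diag(C) <- 1
  expect_warning(res <- consensus_metrics(C, 2, min_cluster_size = 1), "degenerate")
  expect_true(is.na(res$cophenetic))
})

test_that("rank selection maximizes CPCC with the stated tie-breaks", {
  mk <- function(rank, coph, sil, sizes) {
    labels <- rep(seq_along(sizes), sizes)
    names(labels) <- sprintf("s%03d", seq_along(labels))
    structure(list(
      rank = rank, cophenetic = coph, mean_silhouette = sil,
      assignment = subtype_assignment(labels)
    ), class = "consensus_result")
  }
  expect_equal(select_rank(list(mk(2, 1.0, 0.5, c(20, 20)), mk(3, 0.8, 0.9, c(14, 13, 13)))), 2)
  # a rank with a 9-member cluster is excluded
  expect_equal(select_rank(list(mk(2, 0.7, 0.5, c(31, 9)), mk(3, 0.6, 0.5, c(14, 13, 13)))), 3)
  # cophenetic tie: higher silhouette wins
  expect_equal(select_rank(list(mk(2, 0.9, 0.4, c(20, 20)), mk(3, 0.9, 0.6, c(14, 13, 13)))), 3)
  # full tie: smaller rank
  expect_equal(select_rank(list(mk(3, 0.9, 0.5, c(14, 13, 13)), mk(2, 0.9, 0.5, c(20, 20)))), 2)
  expect_error(select_rank(list(mk(2, 0.9, 0.5, c(39, 1)))), "no admissible rank")
})

test_that("subtype overlap recovers identity, nesting and the null", {
  labs <- rep(1:3, each = 12)
  names(labs) <- sprintf("s%03d", 1:36)
  a <- subtype_assignment(labs, "x")
  self <- subtype_overlap(a, a)
  expect_true(all(self$table[row(self$table) != col(self$table)] == 0))

  # nested: every a-cluster inside one b-cluster -> row fractions 1
  coarse <- subtype_assignment(stats::setNames(rep(1:2, c(12, 24)), names(labs)), "y")
  nest <- subtype_overlap(a, coarse)
  expect_true(all(apply(nest$fractions, 1, max) == 1))

  # independent labels: reject at 0.05 in <= 10% of seeds
  n_reject <- 0L
  for (s in 1:100) {
    set.seed(5000 + s)
    l1 <- stats::setNames(sample(1:2, 200, replace = TRUE), sprintf("s%d", 1:200))
    l2 <- stats::setNames(sample(1:2, 200, replace = TRUE), sprintf("s%d", 1:200))
    ov <- subtype_overlap(subtype_assignment(l1), subtype_assignment(l2))
    if (ov$p < 0.05) n_reject <- n_reject + 1L
  }
  expect_lte(n_reject, 10)
})

test_that("planted subtypes are recovered from coupled-gene expression", {
  b <- small_bundle()
  tg <- b$truth$genes
  genes <- tg$gene[tg$coupled_cnv | tg$coupled_met]
  V <- log2(unclass(b$expression_fpkm)[genes, ] + 1)
  cr <- consensus_cluster(V, 3, n_runs = 10, seed = 31, max_iter = 300, tol = 1e-5)
  truth <- b$truth$samples$subtype
  names(truth) <- b$truth$samples$sample
  ari <- adjusted_rand_index(cr$assignment$labels[names(truth)], truth)
  expect_gte(ari, 0.95)
})
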
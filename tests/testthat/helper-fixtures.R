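# Shared fixtures built in code. Everything is seeded; nothing touches disk
# except through tempdir().

named_matrix <- function(x, nr, nc, kind = NULL, prefix_r = "f", prefix_c = "s") {
  m <- matrix(x, nr, nc, dimnames = list(
    sprintf("%s%03d", prefix_r, seq_len(nr)),
    sprintf("%s%03d", prefix_c, seq_len(nc))
  ))
  if (is.null(kind)) m else omics_matrix(m, kind)
}

# negative-binomial count matrix with optional planted fold change in the
# second half of the samples
nb_counts <- function(p, n, seed, dispersion = 0.1, lfc = 0, frac_de = 0,
                      meanlog = 4, sdlog = 1) {
  set.seed(seed)
  base <- exp(stats::rnorm(p, meanlog, sdlog))
  mu <- outer(base, rep(1, n))
  n_de <- round(frac_de * p)
  if (n_de > 0) mu[seq_len(n_de), (n %/% 2 + 1):n] <- mu[seq_len(n_de), (n %/% 2 + 1):n] * 2^lfc
  named_matrix(
    stats::rnbinom(p * n, mu = as.vector(mu), size = 1 / dispersion),
    p, n, "counts", prefix_r = "g"
  )
}

# small default bundle reused across files (scaled-down stated world)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_multiomics(
        simulation_config(n_samples = 90, n_genes = 600, seed = 424)
      )
    }
    cache
  }
})

# brute-force O(n^2) union-find oracle for segment merging (independent of
# the implementation's sorted sweep)
oracle_merge_segments <- function(segments, reciprocal_overlap = 0.5, min_probes = 5L) {
  seg <- segments[segments$num_probes >= min_probes, , drop = FALSE]
  if (nrow(seg) == 0) return(seg)
  out <- list()
  for (key in unique(paste(seg$sample, seg$chrom))) {
    s <- seg[paste(seg$sample, seg$chrom) == key, , drop = FALSE]
    n <- nrow(s)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (comp[i] == comp[j]) next
          ov <- min(s$end[i], s$end[j]) - max(s$start[i], s$start[j]) + 1
          li <- s$end[i] - s$start[i] + 1
          lj <- s$end[j] - s$start[j] + 1
          if (ov >= reciprocal_overlap * li && ov >= reciprocal_overlap * lj) {
            comp[comp == comp[j]] <- comp[i]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    for (cid in unique(comp)) {
      grp <- s[comp == cid, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        sample = grp$sample[1], chrom = grp$chrom[1],
        start = min(grp$start), end = max(grp$end),
        num_probes = sum(grp$num_probes),
        value = sum(grp$value * grp$num_probes) / sum(grp$num_probes),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  out[order(out$sample, out$chrom, out$start), , drop = FALSE]
}

random_segments <- function(n, seed) {
  set.seed(seed)
  start <- sample(1:500, n, replace = TRUE)
  data.frame(
    sample = sample(c("A", "B"), n, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start,
    end = start + sample(1:120, n, replace = TRUE),
    num_probes = sample(0:30, n, replace = TRUE),
    value = round(stats::rnorm(n), 3),
    stringsAsFactors = FALSE
  )
}

# scaled-down pipeline config used by the pipeline and acceptance tests: a
# 60-sample, 500-gene world with lighter NMF/icluster settings so the
# end-to-end run stays fast; thresholds and alphas are the defaults.
small_pipeline_config <- function(out_dir, seed = 11) {
  pipeline_config(
    out_dir = out_dir, seed = seed,
    simulate = list(n_samples = 60, n_genes = 500),
    nmf = list(kmin = 2L, kmax = 3L, n_runs = 10L, max_iter = 150L, tol = 1e-5),
    icluster = list(
      k = 3L, lambda = c(0.1, 0.1, 0.1), k_values = c(2L, 3L),
      n_repeats = 4L, max_iter = 60L, tol = 1e-5
    )
  )
}

expect_same_segments <- function(a, b) {
  # canonical order: merge output order is unspecified for start ties
  a <- a[order(a$sample, a$chrom, a$start, a$end), , drop = FALSE]
  b <- b[order(b$sample, b$chrom, b$start, b$end), , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$num_probes, b$num_probes)
  expect_equal(a$value, b$value, tolerance = 1e-12)
}
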
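test_that("state calling maps thresholds to the three-state alphabet", {
  cnv <- named_matrix(c(0.5, -0.5, 0, NA), 4, 1, "cnv_logratio", prefix_r = "g")
  st <- call_states(cnv)
  expect_equal(unname(st[, 1]), c("Gain", "Loss", "Normal", NA))
  beta <- named_matrix(c(0.9, 0.1, 0.5), 3, 1, "beta", prefix_r = "cg")
  expect_equal(unname(call_states(beta)[, 1]), c("HyperMethy", "HypoMethy", "Normal"))
  expect_error(call_states(named_matrix(1, 2, 2, "counts", prefix_r = "g")), "states")
})

test_that("the exact 2xC test matches stats::fisher.test on small random tables", {
  set.seed(55)
  for (rep in 1:40) {
    nc <- sample(2:3, 1)
    tab <- matrix(sample(0:6, 2 * nc, replace = TRUE), 2, nc)
    if (any(rowSums(tab) == 0) || sum(tab) == 0) next
    keep <- colSums(tab) > 0
    if (sum(keep) < 2) next
    mine <- omicstrata:::exact_2xc_test(tab)
    oracle <- stats::fisher.test(tab[, keep, drop = FALSE])
    expect_equal(mine$p, oracle$p.value, tolerance = 1e-7)
    expect_equal(mine$method, "enumeration")
  }
})

test_that("the 2x2 worked example gives p = 2 / C(20,10)", {
  tab <- rbind(c(10, 0), c(0, 10))
  res <- omicstrata:::exact_2xc_test(tab)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("fisher_state_test runs per feature with BH and a null identity", {
  # identical state distributions in both groups -> p = 1
  states <- matrix(
    rep(c("Gain", "Loss", "Normal", "Normal"), 4), 2, 8,
    dimnames = list(c("f1", "f2"), sprintf("s%d", 1:8))
  )
  res <- fisher_state_test(states, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_equal(res$p, c(1, 1))
  expect_true(all(res$fdr >= res$p))
  expect_error(fisher_state_test(states, character(0), "s1"), "non-empty")
  expect_error(fisher_state_test(states, "s1", "s1"), "disjoint")

  # a strongly separated feature through the public interface:
  # 6 Gain in group A vs 6 Normal in group B -> p = 2 / C(12,6)
  st2 <- matrix(
    c(rep("Gain", 6), rep("Normal", 6)), 1, 12,
    dimnames = list("f1", sprintf("s%d", 1:12))
  )
  res2 <- fisher_state_test(st2, sprintf("s%d", 1:6), sprintf("s%d", 7:12))
  expect_equal(res2$p, 2 / choose(12, 6), tolerance = 1e-12)
})

test_that("NB differential expression: null lfc, exact fold recovery, BH ordering", {
  # identical columns duplicated into two groups -> log2FC = 0
  k <- named_matrix(rep(c(10, 50, 200), 4), 3, 4, "counts", prefix_r = "g")
  res <- nb_differential_expression(k, c("s001", "s002"), c("s003", "s004"))
  expect_equal(res$log2fc, rep(0, 3))

  # noise-free 4-fold planted gene with equal size factors -> log2FC = 2 exactly
  kk <- named_matrix(100, 50, 6, NULL, prefix_r = "g")
  kk["g001", 4:6] <- 400
  res2 <- nb_differential_expression(omics_matrix(kk, "counts"),
    sprintf("s%03d", 1:3), sprintf("s%03d", 4:6)
  )
  expect_equal(res2$log2fc[res2$feature == "g001"], 2)

  # BH monotone: fdr ordering preserves p ordering
  kx <- nb_counts(300, 20, seed = 61, lfc = 1.5, frac_de = 0.2)
  rx <- nb_differential_expression(kx, sprintf("s%03d", 1:10), sprintf("s%03d", 11:20))
  ord <- order(rx$p)
  expect_true(all(diff(rx$fdr[ord]) >= -1e-12))
  expect_true(all(rx$fdr >= rx$p - 1e-12))
})

test_that("mutation frequency test matches the enumeration oracle", {
  muts <- data.frame(
    gene = rep("TP53", 10), sample = sprintf("a%d", 1:10),
    classification = "Missense_Mutation", stringsAsFactors = FALSE
  )
  res <- mutation_frequency_test(muts, sprintf("a%d", 1:10), sprintf("b%d", 1:10))
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)

  # equal mutation counts in both groups -> p = 1
  muts2 <- data.frame(
    gene = "KRAS", sample = c("a1", "a2", "b1", "b2"),
    classification = "Missense_Mutation", stringsAsFactors = FALSE
  )
  res2 <- mutation_frequency_test(muts2, sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  expect_equal(res2$p, 1)

  empty <- mutation_frequency_test(muts2[0, ], "a1", "b1")
  expect_equal(nrow(empty), 0)
})

test_that("log-rank: null identity, hand-computed 6-subject oracle, 2-group equality", {
  # identical survival data in two groups
  clin <- data.frame(
    sample = sprintf("s%d", 1:8),
    OS_time = rep(c(3, 6, 9, 12), 2), OS_event = 1
  )
  lab <- stats::setNames(rep(1:2, each = 4), c(sprintf("s%d", 1:4), sprintf("s%d", 5:8)))
  res <- km_logrank(clin, lab)
  expect_lt(res$global_statistic, 1e-10)
  expect_equal(res$global_p, 1, tolerance = 1e-9)

  # 6 subjects, times 1..6 all events, groups ABABAB: independent
  # observed-minus-expected tabulation
  clin6 <- data.frame(sample = sprintf("s%d", 1:6), OS_time = 1:6, OS_event = 1)
  lab6 <- stats::setNames(rep(c("A", "B"), 3), sprintf("s%d", 1:6))
  res6 <- km_logrank(clin6, lab6)
  at_risk_A <- c(3, 2, 2, 1, 1, 0)  # A dies at t=1,3,5
  at_risk <- 6:1
  died_A <- c(1, 0, 1, 0, 1, 0)
  e_A <- at_risk_A / at_risk          # one death per time
  v_A <- e_A * (1 - e_A)              # hypergeometric variance, single death
  stat_oracle <- (sum(died_A) - sum(e_A))^2 / sum(v_A)
  expect_equal(res6$global_statistic, stat_oracle, tolerance = 1e-10)
  # with 2 groups the global statistic equals the pairwise statistic
  expect_equal(res6$global_statistic, res6$pairwise$statistic, tolerance = 1e-12)

  expect_error(km_logrank(clin6, stats::setNames(rep(1, 6), sprintf("s%d", 1:6))), ">= 2 groups")
  # KM table covers both groups
  expect_setequal(unique(res6$km$group), c("A", "B"))
})

test_that("marker tertile stratification splits 3/3/3 and detects trends", {
  clin <- data.frame(
    sample = sprintf("s%d", 1:9), OS_time = rep(5, 9), OS_event = 1
  )
  ex <- named_matrix(1:9, 1, 9, NULL, prefix_r = "g")
  colnames(ex) <- sprintf("s%d", 1:9)
  m <- omics_matrix(ex, "fpkm")
  st <- stratify_marker_expression(m, "g001", clin)
  expect_equal(unname(table(st$tiers)), c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(st$logrank$p, 1, tolerance = 1e-9)  # identical survival per tier

  # planted monotone hazard over tiers (1/2/4) -> adverse
  set.seed(71)
  n <- 120
  x <- stats::rnorm(n)
  tier_rate <- 0.2 * 2^(findInterval(rank(x), c(n / 3, 2 * n / 3) + 0.5))
  clin2 <- data.frame(
    sample = sprintf("t%03d", 1:n),
    OS_time = stats::rexp(n, rate = tier_rate), OS_event = 1
  )
  ex2 <- matrix(x, 1, n, dimnames = list("g1", sprintf("t%03d", 1:n)))
  st2 <- stratify_marker_expression(omics_matrix(2^ex2, "fpkm"), "g1", clin2)
  expect_equal(st2$direction, "adverse")
  expect_lt(st2$logrank$p, 0.01)

  # heavy ties fall back to seeded jitter with a warning
  exT <- named_matrix(rep(1, 9), 1, 9, NULL, prefix_r = "g")
  colnames(exT) <- sprintf("s%d", 1:9)
  expect_warning(
    stT <- stratify_marker_expression(omics_matrix(exT, "fpkm"), "g001", clin),
    "ties"
  )
  expect_equal(unname(table(stT$tiers)), c(3L, 3L, 3L), ignore_attr = TRUE)
})

test_that("rank tests across subtypes: identity, exact 3v3 oracle, shift detection", {
  labs <- stats::setNames(rep(1:2, each = 3), sprintf("s%d", 1:6))
  # same multiset per group -> H ~ 0
  sc <- stats::setNames(c(1, 2, 3, 1, 2, 3), sprintf("s%d", 1:6))
  r0 <- compare_scores_across_subtypes(sc, labs)
  expect_lt(r0$global_statistic, 1e-10)

  # exact p for 3 vs 3 all distinct equals enumeration over all 20 splits
  sc2 <- stats::setNames(c(1.3, 2.1, 9.5, 3.2, 4.4, 5.0), sprintf("s%d", 1:6))
  r2 <- compare_scores_across_subtypes(sc2, labs)
  splits <- utils::combn(6, 3)
  w_obs <- sum(rank(sc2)[1:3])
  w_all <- apply(splits, 2, function(ix) sum(rank(sc2)[ix]))
  mu <- mean(w_all)
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(r2$pairwise$p, p_exact, tolerance = 1e-12)

  # one group shifted +10 is detected at n = 10 per group
  set.seed(81)
  sc3 <- stats::setNames(c(rnorm(10), rnorm(10) + 10), sprintf("s%d", 1:20))
  labs3 <- stats::setNames(rep(1:2, each = 10), sprintf("s%d", 1:20))
  r3 <- compare_scores_across_subtypes(sc3, labs3)
  expect_lt(r3$global_p, 0.05)

  # constant scores
  sc4 <- stats::setNames(rep(2, 6), sprintf("s%d", 1:6))
  expect_warning(r4 <- compare_scores_across_subtypes(sc4, labs), "constant")
  expect_equal(r4$global_p, 1)
})

test_that("hypergeometric enrichment evaluates the closed-form cases", {
  universe <- sprintf("G%02d", 1:20)
  hits <- universe[1:5]
  sets <- list(
    exact = universe[1:5],
    disjoint = universe[10:14],
    everything = universe
  )
  res <- hypergeometric_enrichment(hits, universe, sets)
  expect_equal(res$p[res$term == "exact"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p[res$term == "disjoint"], 1)
  expect_equal(res$p[res$term == "everything"], 1)
  expect_error(hypergeometric_enrichment(hits, character(0), sets), "universe")
  expect_error(hypergeometric_enrichment(c(hits, "ZZ"), universe, sets), "subset")
})
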
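# survdiff with a guard for the fully degenerate case (a single distinct
# event time, or no events): observed equals expected there, so the log-rank
# statistic is 0 by definition while survdiff's variance matrix is singular.
safe_survdiff <- function(time, event, group) {
  out <- try(survival::survdiff(survival::Surv(time, event) ~ group), silent = TRUE)
  if (!inherits(out, "try-error")) return(out)
  if (length(unique(time[event == 1])) <= 1) {
    g <- table(group)
    return(list(chisq = 0, obs = as.vector(g) * mean(event), exp = as.vector(g) * mean(event)))
  }
  stop(attr(out, "condition"))
}

#' Call per-entry CNV and methylation states
#'
#' Maps numeric matrices to categorical state matrices using the event
#' thresholds: CNV to Gain/Loss/Normal, methylation to
#' HyperMethy/HypoMethy/Normal. Missing entries stay `NA`.
#'
#' @param m An `omics_matrix` of kind `cnv_logratio` or `beta`.
#' @param thresholds An [event_thresholds()].
#' @return Character matrix of states, same dimnames.
#' @export
call_states <- function(m, thresholds = event_thresholds()) {
  kind <- omics_kind(m)
  x <- unclass(m)
  out <- matrix(NA_character_, nrow(x), ncol(x), dimnames = dimnames(x))
  if (kind == "cnv_logratio") {
    out[!is.na(x)] <- "Normal"
    out[!is.na(x) & x > thresholds$cnv_gain] <- "Gain"
    out[!is.na(x) & x < thresholds$cnv_loss] <- "Loss"
  } else if (kind == "beta") {
    out[!is.na(x)] <- "Normal"
    out[!is.na(x) & x > thresholds$beta_hyper] <- "HyperMethy"
    out[!is.na(x) & x < thresholds$beta_hypo] <- "HypoMethy"
  } else {
    stop("states are defined for cnv_logratio or beta matrices", call. = FALSE)
  }
  out
}

# Exact two-sided probability test for a 2 x C contingency table
# (Freeman-Halton): enumerate all tables with the observed margins when the
# total is at most `enum_limit`, otherwise estimate by seeded Monte-Carlo
# sampling from the margin-conditional null (Patefield's algorithm via
# r2dtable). Two-sided p sums the probabilities of tables no more probable
# than the observed one (with a 1e-7 relative tolerance for float ties).
exact_2xc_test <- function(tab, enum_limit = 200L, mc_tables = 1e5, seed = 1L) {
  stopifnot(nrow(tab) == 2)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2) return(list(p = 1, method = "degenerate"))
  N <- sum(tab)
  r1 <- sum(tab[1, ])
  cs <- colSums(tab)
  # unnormalized log-probability of a first row `a`: log prod C(cs, a);
  # the common factor 1/C(N, r1) cancels in the probability-ordering rule
  logp_row <- function(a) sum(lchoose(cs, a))
  lp_obs <- logp_row(tab[1, ])
  if (N <= enum_limit) {
    C <- length(cs)
    # enumerate compositions of r1 over C cells with a_c <= cs_c
    total <- 0
    lnorm <- lchoose(N, r1)
    rec <- function(idx, remaining, acc_lp) {
      if (idx == C) {
        if (remaining <= cs[C]) {
          lp <- acc_lp + lchoose(cs[C], remaining)
          if (lp <= lp_obs + 1e-7) total <<- total + exp(lp - lnorm)
        }
        return(invisible())
      }
      for (a in 0:min(cs[idx], remaining)) {
        rec(idx + 1, remaining - a, acc_lp + lchoose(cs[idx], a))
      }
    }
    rec(1L, r1, 0)
    list(p = min(1, total), method = "enumeration")
  } else {
    set.seed(seed)
    sims <- stats::r2dtable(mc_tables, c(r1, N - r1), cs)
    lp_sim <- vapply(sims, function(s) logp_row(s[1, ]), numeric(1))
    p <- (1 + sum(lp_sim <= lp_obs + 1e-7)) / (mc_tables + 1)
    list(p = p, method = "montecarlo")
  }
}

#' Per-feature exact test of state distributions between two groups
#'
#' For each feature, builds the 2 x {states} table of state counts in the
#' two sample groups and applies the exact probability test (full
#' enumeration up to 200 observations, seeded Monte-Carlo above), then BH
#' adjustment across features.
#'
#' @param states Character state matrix from [call_states()].
#' @param group_a,group_b Disjoint, non-empty sample id vectors.
#' @param seed Seed for the Monte-Carlo branch.
#' @return data.frame: feature, test, p, fdr.
#' @export
fisher_state_test <- function(states, group_a, group_b, seed = 1L) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty", call. = FALSE)
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint", call. = FALSE)
  group_a <- intersect(group_a, colnames(states))
  group_b <- intersect(group_b, colnames(states))
  if (!length(group_a) || !length(group_b)) stop("groups not found among samples", call. = FALSE)
  levels_all <- c("Gain", "Loss", "HyperMethy", "HypoMethy", "Normal")
  p <- vapply(seq_len(nrow(states)), function(i) {
    sa <- factor(states[i, group_a], levels = levels_all)
    sb <- factor(states[i, group_b], levels = levels_all)
    tab <- rbind(table(sa), table(sb))
    exact_2xc_test(tab, seed = derive_seed(seed, i))$p
  }, numeric(1))
  data.frame(
    feature = rownames(states), test = "fisher_state", p = p,
    fdr = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE
  )
}

#' Negative-binomial Wald test for differential expression
#'
#' A documented, self-contained replacement for a full shrinkage-based NB
#' pipeline: median-of-ratios size factors; per-gene method-of-moments NB
#' dispersion pooled within groups (floored at 1e-8); Wald test on the log2
#' fold change of normalized group means with a delta-method standard error
#' and a t reference with n_A + n_B - 2 degrees of freedom; BH across genes.
#' Genes with zero counts throughout are skipped.
#'
#' @param counts `omics_matrix` of kind `counts`.
#' @param group_a,group_b Disjoint sample id vectors, each of size >= 2.
#' @param lfc_threshold Absolute log2 fold-change cut for the `significant`
#'   flag; default 1 (two-fold).
#' @param fdr_threshold Default 0.05.
#' @return data.frame: feature, test, base_mean, log2fc, se, p, fdr,
#'   significant.
#' @export
nb_differential_expression <- function(counts, group_a, group_b,
                                       lfc_threshold = 1.0, fdr_threshold = 0.05) {
  stopifnot(omics_kind(counts) == "counts")
  group_a <- intersect(group_a, colnames(counts))
  group_b <- intersect(group_b, colnames(counts))
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint", call. = FALSE)
  k <- unclass(counts)[, c(group_a, group_b), drop = FALSE]
  sf <- size_factors(k)
  q <- sweep(k, 2, sf, `/`)
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)

  keep <- rowSums(k) > 0
  if (any(!keep)) {
    message(sprintf("%d all-zero gene(s) skipped", sum(!keep)))
  }
  qa <- q[keep, ia, drop = FALSE]
  qb <- q[keep, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  mu_a <- rowMeans(qa)
  mu_b <- rowMeans(qb)
  var_a <- apply(qa, 1, stats::var)
  var_b <- apply(qb, 1, stats::var)
  s1_a <- sum(1 / sf[ia]); s1_b <- sum(1 / sf[ib])

  # method-of-moments dispersion, pooled across the two groups
  excess <- function(v, mu, s1, n) (v - mu * s1 / n) / pmax(mu^2, 1e-12)
  alpha <- ((na - 1) * excess(var_a, mu_a, s1_a, na) +
            (nb - 1) * excess(var_b, mu_b, s1_b, nb)) / (na + nb - 2)
  alpha <- pmax(alpha, 1e-8)

  pseudo <- ifelse(mu_a == 0 | mu_b == 0, 0.5, 0)
  lfc <- log2((mu_b + pseudo) / (mu_a + pseudo))
  var_mu <- function(mu, s1, n) (mu * s1 / n^2 + alpha * mu^2 / n)
  se_log <- sqrt(
    var_mu(mu_a + pseudo, s1_a, na) / (mu_a + pseudo)^2 +
    var_mu(mu_b + pseudo, s1_b, nb) / (mu_b + pseudo)^2
  )
  se_lfc <- se_log / log(2)
  stat <- lfc / se_lfc
  p <- 2 * stats::pt(-abs(stat), df = na + nb - 2)
  p[se_lfc == 0] <- ifelse(lfc[se_lfc == 0] == 0, 1, 0)
  fdr <- stats::p.adjust(p, "BH")
  data.frame(
    feature = rownames(k)[keep], test = "nb_wald",
    base_mean = (mu_a + mu_b) / 2, log2fc = lfc, se = se_lfc,
    p = p, fdr = fdr,
    significant = abs(lfc) >= lfc_threshold & fdr < fdr_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Median-of-ratios size factors
#'
#' @param k Count matrix (features x samples).
#' @return Numeric vector of per-sample size factors (geometric-mean
#'   reference, median ratio), normalized only by the genes with nonzero
#'   counts in every sample.
#' @export
size_factors <- function(k) {
  k <- unclass(k)
  logk <- log(k)
  logk[!is.finite(logk)] <- NA
  ref <- rowMeans(logk)  # NA when any sample has zero counts
  use <- is.finite(ref)
  if (!any(use)) {
    warning("no gene expressed in all samples; size factors set to 1", call. = FALSE)
    return(stats::setNames(rep(1, ncol(k)), colnames(k)))
  }
  sf <- apply(logk[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(col - ref[use], na.rm = TRUE))
  })
  stats::setNames(sf, colnames(k))
}

#' Per-gene mutation frequency contrast between two groups
#'
#' For each mutated gene, a 2 x 2 exact test (mutated vs not, by group);
#' raw p below `alpha` flags the gene, BH also reported.
#'
#' @param mutations data.frame with columns gene, sample (already filtered
#'   of Silent/Intron calls).
#' @param group_a,group_b Disjoint sample id vectors.
#' @param alpha Default 0.05.
#' @return data.frame: feature, test, n_mut_a, n_mut_b, odds_ratio, p, fdr,
#'   significant.
#' @export
mutation_frequency_test <- function(mutations, group_a, group_b, alpha = 0.05) {
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint", call. = FALSE)
  if (nrow(mutations) == 0) {
    return(data.frame(
      feature = character(0), test = character(0), n_mut_a = integer(0),
      n_mut_b = integer(0), odds_ratio = numeric(0), p = numeric(0),
      fdr = numeric(0), significant = logical(0), stringsAsFactors = FALSE
    ))
  }
  rel <- mutations[mutations$sample %in% c(group_a, group_b), , drop = FALSE]
  genes <- sort(unique(rel$gene))
  na <- length(group_a); nb <- length(group_b)
  rows <- lapply(genes, function(g) {
    mut_samples <- unique(rel$sample[rel$gene == g])
    a1 <- sum(group_a %in% mut_samples); b1 <- sum(group_b %in% mut_samples)
    if (a1 + b1 == 0) return(NULL)  # absent from both groups
    tab <- rbind(c(a1, na - a1), c(b1, nb - b1))
    p <- exact_2xc_test(t(tab), enum_limit = 1e9)$p  # 2x2: enumeration always
    or <- ((a1 + 0.5) * (nb - b1 + 0.5)) / ((na - a1 + 0.5) * (b1 + 0.5))
    data.frame(
      feature = g, test = "fisher_mutation", n_mut_a = a1, n_mut_b = b1,
      odds_ratio = or, p = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(
      feature = character(0), test = character(0), n_mut_a = integer(0),
      n_mut_b = integer(0), odds_ratio = numeric(0), p = numeric(0),
      fdr = numeric(0), significant = logical(0), stringsAsFactors = FALSE
    ))
  }
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curves and log-rank tests across subtypes
#'
#' Global log-rank across all groups, pairwise log-rank per group pair, and
#' the KM estimator per group as a step-function table. Groups with zero
#' events are kept with a warning; a single group is an error.
#'
#' @param clinical data.frame with sample, OS_time, OS_event.
#' @param assignment A [subtype_assignment()] (or named label vector).
#' @param alpha Flagging threshold; default 0.05.
#' @return List: global_statistic, global_df, global_p, significant,
#'   pairwise (data.frame), km (data.frame: group, time, n_risk, n_event,
#'   surv).
#' @export
km_logrank <- function(clinical, assignment, alpha = 0.05) {
  labels <- if (inherits(assignment, "subtype_assignment")) assignment$labels else assignment
  if (is.null(names(labels))) stop("assignment labels must be named by sample", call. = FALSE)
  shared <- intersect(clinical$sample, names(labels))
  if (length(shared) < 2) stop("clinical table and assignment share too few samples", call. = FALSE)
  cl <- clinical[match(shared, clinical$sample), ]
  grp <- factor(labels[shared])
  if (nlevels(grp) < 2) stop("need >= 2 groups for a log-rank test", call. = FALSE)
  ev_by_grp <- tapply(cl$OS_event, grp, sum)
  if (any(ev_by_grp == 0)) {
    warning(sprintf(
      "group(s) with zero events: %s",
      paste(names(ev_by_grp)[ev_by_grp == 0], collapse = ", ")
    ), call. = FALSE)
  }
  surv <- survival::Surv(cl$OS_time, cl$OS_event)
  sd_all <- safe_survdiff(cl$OS_time, cl$OS_event, grp)
  gdf <- nlevels(grp) - 1
  gp <- stats::pchisq(sd_all$chisq, df = gdf, lower.tail = FALSE)

  prs <- utils::combn(levels(grp), 2)
  pairwise <- apply(prs, 2, function(pr) {
    sel <- grp %in% pr
    sdp <- safe_survdiff(cl$OS_time[sel], cl$OS_event[sel], droplevels(grp[sel]))
    data.frame(
      group_a = pr[1], group_b = pr[2],
      statistic = unname(sdp$chisq),
      p = stats::pchisq(sdp$chisq, df = 1, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  pairwise <- do.call(rbind, pairwise)

  fit <- survival::survfit(surv ~ grp)
  strata_names <- sub("^grp=", "", rep(names(fit$strata), fit$strata))
  km <- data.frame(
    group = strata_names, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, surv = fit$surv, stringsAsFactors = FALSE
  )
  list(
    global_statistic = unname(sd_all$chisq), global_df = gdf, global_p = gp,
    significant = gp < alpha, pairwise = pairwise, km = km
  )
}

#' Tertile expression cascade for a marker gene
#'
#' Splits samples into low/middle/high expression tiers (L1/L2/L3) by
#' expression rank (near-equal sizes; heavy ties are broken by a seeded
#' jitter with a warning), runs the log-rank test across tiers, and calls
#' the trend adverse when the per-tier observed/expected event ratio rises
#' monotonically from L1 to L3, favorable when it falls monotonically,
#' otherwise mixed.
#'
#' @param expression `omics_matrix` (fpkm is log-transformed internally).
#' @param gene Gene id present in the matrix.
#' @param clinical data.frame with sample, OS_time, OS_event.
#' @param seed Seed for the tie-break jitter.
#' @return List: gene, tiers (named factor L1/L2/L3), logrank (global test
#'   list), direction.
#' @export
stratify_marker_expression <- function(expression, gene, clinical, seed = 1L) {
  if (!gene %in% rownames(expression)) stop(sprintf("gene '%s' not in expression matrix", gene), call. = FALSE)
  shared <- intersect(colnames(expression), clinical$sample)
  if (length(shared) < 6) stop("need >= 6 samples for a tertile split", call. = FALSE)
  x <- unclass(expression)[gene, shared]
  if (omics_kind(expression) == "fpkm") x <- log2(x + 1)
  if (max(table(x)) > length(x) / 3) {
    warning("heavy ties in expression; tertiles use a seeded jitter", call. = FALSE)
    set.seed(derive_seed(seed, 1L))
    x <- x + stats::runif(length(x), -1e-9, 1e-9) * (1 + abs(x))
  }
  rk <- rank(x, ties.method = "first")
  n <- length(rk)
  cut1 <- floor(n / 3)
  cut2 <- floor(2 * n / 3)
  tier <- factor(ifelse(rk <= cut1, "L1", ifelse(rk <= cut2, "L2", "L3")),
    levels = c("L1", "L2", "L3")
  )
  names(tier) <- shared
  cl <- clinical[match(shared, clinical$sample), ]
  sd3 <- safe_survdiff(cl$OS_time, cl$OS_event, tier)
  gp <- stats::pchisq(sd3$chisq, df = 2, lower.tail = FALSE)
  oe <- sd3$obs / pmax(sd3$exp, 1e-12)
  direction <- if (all(diff(oe) > 0)) "adverse" else if (all(diff(oe) < 0)) "favorable" else "mixed"
  list(
    gene = gene, tiers = tier,
    logrank = list(statistic = unname(sd3$chisq), df = 2, p = gp),
    direction = direction
  )
}

#' Rank tests of a per-sample score across subtypes
#'
#' Kruskal-Wallis across all groups plus pairwise Wilcoxon rank-sum tests
#' with BH adjustment; per-group medians reported. Constant scores give
#' p = 1 with a warning.
#'
#' @param scores Named numeric vector (names = samples).
#' @param assignment A [subtype_assignment()] (or named label vector).
#' @return List: global_p, medians, pairwise (data.frame with BH-adjusted
#'   p).
#' @export
compare_scores_across_subtypes <- function(scores, assignment) {
  labels <- if (inherits(assignment, "subtype_assignment")) assignment$labels else assignment
  shared <- intersect(names(scores), names(labels))
  grp <- factor(labels[shared])
  x <- scores[shared]
  if (nlevels(grp) < 2 || any(table(grp) < 2)) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    warning("constant scores: no rank test possible, p = 1", call. = FALSE)
    return(list(
      global_p = 1, medians = tapply(x, grp, stats::median),
      pairwise = data.frame(
        group_a = character(0), group_b = character(0), p = numeric(0),
        fdr = numeric(0), stringsAsFactors = FALSE
      )
    ))
  }
  kw <- stats::kruskal.test(x ~ grp)
  prs <- utils::combn(levels(grp), 2)
  pw <- apply(prs, 2, function(pr) {
    sel <- grp %in% pr
    w <- suppressWarnings(stats::wilcox.test(x[sel] ~ droplevels(grp[sel])))
    data.frame(group_a = pr[1], group_b = pr[2], p = w$p.value, stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$fdr <- stats::p.adjust(pw$p, "BH")
  list(
    global_statistic = unname(kw$statistic), global_p = kw$p.value,
    medians = tapply(x, grp, stats::median), pairwise = pw
  )
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric p per term (terms intersected with the
#' universe first), BH across terms.
#'
#' @param hits Gene set of interest; must be a subset of `universe`.
#' @param universe Background gene set.
#' @param collections Named list of gene sets (e.g. from [read_gmt()]).
#' @return data.frame: term, n_term, n_hits, overlap, p, fdr.
#' @export
hypergeometric_enrichment <- function(hits, universe, collections) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe", call. = FALSE)
  N <- length(universe)
  n_h <- length(hits)
  rows <- lapply(names(collections), function(nm) {
    term <- intersect(collections[[nm]], universe)
    m <- length(term)
    k <- length(intersect(term, hits))
    p <- if (m == 0) 1 else stats::phyper(k - 1, m, N - m, n_h, lower.tail = FALSE)
    data.frame(
      term = nm, n_term = m, n_hits = n_h, overlap = k, p = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
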
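#' Simulation configuration for the coupled multi-omics generator
#'
#' Describes a cohort with planted molecular subtypes and the statistical
#' couplings the downstream analysis assumes: positive copy-number-to-
#' expression coupling, negative promoter-methylation-to-expression coupling,
#' a shared per-sample "burden" factor that correlates event frequencies
#' across layers, and subtype-dependent survival hazards.
#'
#' Defaults mirror the cohort the pipeline targets: 159 samples, 3 subtypes,
#' 2000 genes of which 10% are copy-number-coupled at r = 0.6 and 10%
#' methylation-coupled at r = -0.6, exponential survival with hazard ratios
#' 3 / 1.7 / 1 and ~30% independent censoring.
#'
#' @param n_samples,n_genes,n_subtypes Cohort dimensions; `n_subtypes` is the
#'   planted K.
#' @param frac_coupled_cnv,frac_coupled_met Fractions in [0,1] of genes whose
#'   expression is driven by copy number / promoter methylation. The two gene
#'   sets are disjoint.
#' @param coupling_r_cnv Target Pearson correlation in (0,1) between gene
#'   copy-number value and log expression for coupled genes.
#' @param coupling_r_met Target correlation in (-1,0) between promoter
#'   methylation (logit scale) and log expression for coupled genes.
#' @param block_effect Subtype mean shift: CNV log-ratio units for
#'   copy-number blocks; for methylation blocks the shift is applied on the
#'   logit scale as `4 * block_effect` so the beta-scale shift near 0.5 is
#'   approximately `block_effect`.
#' @param hazard_ratios Per-subtype hazard multipliers, length `n_subtypes`.
#' @param censor_rate Expected fraction of censored samples (independent
#'   exponential censoring).
#' @param mutation_rate_per_gene Per gene, per sample mutation probability.
#' @param seed Integer seed; identical config + seed gives identical bundles.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 159L, n_genes = 2000L, n_subtypes = 3L,
                              frac_coupled_cnv = 0.1, frac_coupled_met = 0.1,
                              coupling_r_cnv = 0.6, coupling_r_met = -0.6,
                              block_effect = 0.8,
                              hazard_ratios = NULL,
                              censor_rate = 0.3,
                              mutation_rate_per_gene = 0.01,
                              seed = 1L) {
  if (is.null(hazard_ratios)) {
    hazard_ratios <- switch(as.character(n_subtypes),
      "1" = 1, "2" = c(3, 1), "3" = c(3, 1.7, 1),
      seq(3, 1, length.out = n_subtypes)
    )
  }
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_subtypes = as.integer(n_subtypes),
    frac_coupled_cnv = frac_coupled_cnv, frac_coupled_met = frac_coupled_met,
    coupling_r_cnv = coupling_r_cnv, coupling_r_met = coupling_r_met,
    block_effect = block_effect, hazard_ratios = as.numeric(hazard_ratios),
    censor_rate = censor_rate,
    mutation_rate_per_gene = mutation_rate_per_gene, seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  num <- unlist(cfg[c(
    "n_samples", "n_genes", "n_subtypes", "frac_coupled_cnv",
    "frac_coupled_met", "coupling_r_cnv", "coupling_r_met", "block_effect",
    "hazard_ratios", "censor_rate", "mutation_rate_per_gene", "seed"
  )])
  if (any(!is.finite(num))) stop("invalid config: non-finite values", call. = FALSE)
  with(cfg, {
    if (n_samples < 1 || n_genes < 1) stop("invalid config: empty cohort", call. = FALSE)
    if (n_subtypes < 1) stop("invalid config: n_subtypes must be >= 1", call. = FALSE)
    if (n_subtypes > n_samples) stop("invalid config: n_subtypes > n_samples", call. = FALSE)
    for (f in c(frac_coupled_cnv, frac_coupled_met, censor_rate, mutation_rate_per_gene)) {
      if (f < 0 || f > 1) stop("invalid config: fractions must lie in [0,1]", call. = FALSE)
    }
    if (frac_coupled_cnv + frac_coupled_met > 1) {
      stop("invalid config: coupled fractions overlap (sum > 1)", call. = FALSE)
    }
    if (coupling_r_cnv <= 0 || coupling_r_cnv >= 1) stop("invalid config: coupling_r_cnv must be in (0,1)", call. = FALSE)
    if (coupling_r_met >= 0 || coupling_r_met <= -1) stop("invalid config: coupling_r_met must be in (-1,0)", call. = FALSE)
    if (length(hazard_ratios) != n_subtypes) stop("invalid config: hazard_ratios length != n_subtypes", call. = FALSE)
    if (any(hazard_ratios <= 0)) stop("invalid config: hazard_ratios must be positive", call. = FALSE)
  })
  invisible(cfg)
}

#' Generate a coupled multi-omics bundle
#'
#' Draws one synthetic cohort under `config`. The generative model, in order:
#' samples are assigned to `n_subtypes` balanced subtypes; each sample gets a
#' lognormal burden factor shared by the CNV and methylation layers (this is
#' what makes per-sample event frequencies mutually correlated); coupled
#' copy-number genes get a per-subtype block shift of `block_effect` on their
#' segment value and expression built as
#' `r * scale(cnv) + sqrt(1-r^2) * noise` so the planted correlation equals
#' `coupling_r_cnv` by construction; coupled methylation genes get promoter
#' probes whose logit-beta carries the block shift and drives expression
#' with correlation `coupling_r_met`; counts are negative binomial
#' (dispersion 0.1) around the log-linear mean with lognormal library sizes,
#' and FPKM is counts rescaled by fixed gene lengths and library size;
#' survival is exponential with per-subtype hazard ratios raced against an
#' independent exponential censoring time calibrated to `censor_rate`.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_bundle` list: `cnv_segments`, `cnv_gene` (gene-level
#'   convenience matrix), `beta_matrix` (probe level, with missing values),
#'   `probe_annotation`, `gene_annotation`, `expression_fpkm`,
#'   `expression_counts`, `mutations`, `clinical`, `gene_sets` (GMT-style
#'   list), and `truth` (`samples` and `genes` tables).
#' @export
generate_multiomics <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_genes
  K <- config$n_subtypes

  samples <- sprintf("S%03d", seq_len(n))
  genes <- sprintf("G%04d", seq_len(p))
  subtype <- sample(rep_len(seq_len(K), n))

  # Gene layout: non-overlapping 10 kb genes with 40 kb gaps over 22 chromosomes.
  chrom_of <- paste0("chr", rep_len(1:22, p))
  idx_on_chrom <- stats::ave(seq_len(p), chrom_of, FUN = seq_along)
  gene_start <- 1L + (idx_on_chrom - 1L) * 50000L
  gene_end <- gene_start + 9999L
  strand <- sample(c("+", "-"), p, replace = TRUE)
  tss <- ifelse(strand == "+", gene_start, gene_end)
  gene_len <- stats::rnbinom(p, mu = 2000, size = 4) + 300  # transcript length, bp
  gene_annotation <- data.frame(
    gene = genes, chrom = chrom_of, strand = strand, tss = tss,
    gene_start = gene_start, gene_end = gene_end, stringsAsFactors = FALSE
  )

  # Coupled gene sets (disjoint) and their subtype block assignment.
  n_cnv <- round(config$frac_coupled_cnv * p)
  n_met <- round(config$frac_coupled_met * p)
  perm <- sample(p)
  coupled_cnv <- sort(perm[seq_len(n_cnv)])
  coupled_met <- sort(perm[n_cnv + seq_len(n_met)])
  block_of <- rep(NA_integer_, p)
  block_of[coupled_cnv] <- rep_len(seq_len(K), n_cnv)
  block_of[coupled_met] <- rep_len(seq_len(K), n_met)

  # Shared per-sample burden factor: correlates event frequencies across layers.
  burden <- exp(stats::rnorm(n, 0, 0.3))

  # --- CNV layer -----------------------------------------------------------
  # Quiet baseline plus burden-driven focal events: each gene/sample pair
  # gains (or loses) a large segment value with probability proportional to
  # the sample's burden factor, so per-sample gain and loss frequencies are
  # mutually correlated through the shared burden.
  cnv <- matrix(stats::rnorm(p * n, 0, 0.12), p, n,
    dimnames = list(genes, samples)
  )
  ev_rate <- pmin(0.04 * rep(burden, each = p), 0.45)
  gain_ev <- matrix(stats::runif(p * n) < ev_rate, p, n)
  loss_ev <- matrix(stats::runif(p * n) < ev_rate, p, n) & !gain_ev
  cnv[gain_ev] <- cnv[gain_ev] + stats::runif(sum(gain_ev), 0.4, 1.0)
  cnv[loss_ev] <- cnv[loss_ev] - stats::runif(sum(loss_ev), 0.4, 1.0)
  for (g in coupled_cnv) {
    hit <- subtype == block_of[g]
    cnv[g, hit] <- cnv[g, hit] + config$block_effect
  }

  # --- Methylation layer (logit scale), promoter probes --------------------
  # Mid-range baseline so both methylation tails are reachable; the same
  # burden factor drives hyper- and hypomethylation events, and coupled
  # genes carry a hypermethylation block shift (4 * block_effect on the
  # logit scale, approximately block_effect on the beta scale near 0.5).
  logit_base <- stats::rnorm(p, -0.8, 0.5)
  met_logit <- logit_base + matrix(stats::rnorm(p * n, 0, 0.4), p, n,
    dimnames = list(genes, samples)
  )
  hyper_ev <- matrix(stats::runif(p * n) < ev_rate, p, n)
  hypo_ev <- matrix(stats::runif(p * n) < ev_rate, p, n) & !hyper_ev
  met_logit[hyper_ev] <- met_logit[hyper_ev] + stats::runif(sum(hyper_ev), 2.2, 4.0)
  met_logit[hypo_ev] <- met_logit[hypo_ev] - stats::runif(sum(hypo_ev), 1.6, 3.0)
  for (g in coupled_met) {
    hit <- subtype == block_of[g]
    met_logit[g, hit] <- met_logit[g, hit] + 4 * config$block_effect
  }

  # --- Expression ----------------------------------------------------------
  # Signal on the log scale: coupled genes are built from the standardized
  # driver (cnv value or logit-beta) so the planted correlation is exact.
  row_std <- function(m) {
    mu <- rowMeans(m)
    sd <- apply(m, 1, stats::sd)
    sd[sd == 0] <- 1
    (m - mu) / sd
  }
  esig <- matrix(stats::rnorm(p * n), p, n, dimnames = list(genes, samples))
  z_cnv <- row_std(cnv[coupled_cnv, , drop = FALSE])
  r1 <- config$coupling_r_cnv
  esig[coupled_cnv, ] <- r1 * z_cnv + sqrt(1 - r1^2) * esig[coupled_cnv, , drop = FALSE]
  z_met <- row_std(met_logit[coupled_met, , drop = FALSE])
  r2 <- config$coupling_r_met
  esig[coupled_met, ] <- r2 * z_met + sqrt(1 - r2^2) * esig[coupled_met, , drop = FALSE]

  base_mu <- exp(stats::rnorm(p, 4, 1.2))
  low_expressed <- rep(FALSE, p)
  free <- setdiff(seq_len(p), c(coupled_cnv, coupled_met))
  n_low <- min(length(free), round(0.05 * p))
  if (n_low > 0) {
    low_idx <- sort(sample(free, n_low))
    base_mu[low_idx] <- 0.25  # mostly-zero genes, exercise the FPKM filter
    low_expressed[low_idx] <- TRUE
  }
  lib_factor <- exp(stats::rnorm(n, 0, 0.15))
  mu <- base_mu * exp(0.9 * esig)
  mu <- sweep(mu, 2, lib_factor, `*`)
  counts <- matrix(
    stats::rnbinom(p * n, mu = as.vector(mu), size = 1 / 0.1), p, n,
    dimnames = list(genes, samples)
  )
  total_frag <- colSums(counts)
  fpkm <- counts * 1e9 / outer(gene_len, total_frag)

  # --- Segment table: one true segment per gene/sample plus low-probe decoys.
  n_probes_seg <- 10L + stats::rpois(p, 20)
  cnv_segments <- data.frame(
    sample = rep(samples, each = p),
    chrom = rep(chrom_of, n),
    start = rep(gene_start, n),
    end = rep(gene_end, n),
    num_probes = rep(n_probes_seg, n),
    value = as.vector(cnv),
    stringsAsFactors = FALSE
  )
  n_decoy <- 3L * n
  decoy_chrom <- paste0("chr", sample(1:22, n_decoy, replace = TRUE))
  decoy_start <- sample(gene_end) [rep_len(seq_len(p), n_decoy)] + 15000L
  decoys <- data.frame(
    sample = rep(samples, each = 3L),
    chrom = decoy_chrom,
    start = decoy_start,
    end = decoy_start + 4999L,
    num_probes = sample(0:4, n_decoy, replace = TRUE),
    value = stats::rnorm(n_decoy, 0, 0.5),
    stringsAsFactors = FALSE
  )
  cnv_segments <- rbind(cnv_segments, decoys)
  cnv_segments <- cnv_segments[order(cnv_segments$sample, cnv_segments$chrom, cnv_segments$start), ]
  rownames(cnv_segments) <- NULL

  # --- Probe table: two promoter probes per gene + decoys outside promoters.
  probe_beta_of <- function(offset_lo, offset_hi, jitter_sd) {
    off <- sample(offset_lo:offset_hi, p, replace = TRUE)
    pos <- ifelse(strand == "+", tss + off, tss - off)
    b <- stats::plogis(met_logit + stats::rnorm(p * n, 0, jitter_sd))
    list(pos = pos, beta = b)
  }
  pr1 <- probe_beta_of(-1500L, 100L, 0.2)   # in-promoter probe near TSS
  pr2 <- probe_beta_of(-1990L, 190L, 0.3)   # second in-promoter probe
  off3 <- sample(4000:8000, p, replace = TRUE)
  pos3 <- ifelse(strand == "+", tss + off3, tss - off3)
  beta3 <- stats::plogis(matrix(stats::rnorm(p * n, 0, 1.5), p, n))

  probe_ids <- c(sprintf("cg%05d", seq_len(p)), sprintf("cg%05d", p + seq_len(p)),
                 sprintf("cg%05d", 2L * p + seq_len(p)))
  beta_matrix <- rbind(pr1$beta, pr2$beta, beta3)
  dimnames(beta_matrix) <- list(probe_ids, samples)
  probe_annotation <- data.frame(
    probe = probe_ids,
    chrom = rep(chrom_of, 3L),
    position = pmax(1L, as.integer(c(pr1$pos, pr2$pos, pos3))),
    gene = rep(genes, 3L),
    region_class = c(
      rep("Island", p), rep("N_Shore", p),
      sample(c("OpenSea", "S_Shelf"), p, replace = TRUE)
    ),
    stringsAsFactors = FALSE
  )

  # Missingness: 2% scattered entries, plus 1% of probes missing in 75% of
  # samples (these should be dropped by the >70% filter downstream).
  n_probe <- nrow(beta_matrix)
  miss <- matrix(stats::runif(n_probe * n) < 0.02, n_probe, n)
  heavy <- sample(n_probe, max(1L, round(0.01 * n_probe)))
  for (pr in heavy) miss[pr, sample(n, ceiling(0.75 * n))] <- TRUE
  beta_matrix[miss] <- NA_real_

  # --- Mutations -----------------------------------------------------------
  mut_rate <- matrix(config$mutation_rate_per_gene, p, n)
  driver <- integer(0)
  if (K >= 2 && p >= 50 && config$mutation_rate_per_gene > 0) {
    driver <- sort(sample(free, min(5L, length(free))))
    mut_rate[driver, subtype == 1L] <- pmin(1, config$mutation_rate_per_gene * 8)
  }
  hitmat <- matrix(stats::runif(p * n) < mut_rate, p, n)
  hit_idx <- which(hitmat, arr.ind = TRUE)
  classes <- c(
    "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Splice_Site", "Silent", "Intron"
  )
  mutations <- data.frame(
    gene = genes[hit_idx[, 1]],
    sample = samples[hit_idx[, 2]],
    classification = sample(classes, nrow(hit_idx),
      replace = TRUE, prob = c(0.45, 0.1, 0.1, 0.05, 0.2, 0.1)
    ),
    stringsAsFactors = FALSE
  )
  mutations <- mutations[order(mutations$sample, mutations$gene), ]
  rownames(mutations) <- NULL

  # --- Clinical ------------------------------------------------------------
  base_hazard <- 0.35  # events per year at hazard ratio 1
  haz <- base_hazard * config$hazard_ratios[subtype]
  t_event <- stats::rexp(n, rate = haz)
  cr <- config$censor_rate
  if (cr > 0 && cr < 1) {
    t_cens <- stats::rexp(n, rate = haz * cr / (1 - cr))
  } else if (cr == 0) {
    t_cens <- rep(Inf, n)
  } else {
    t_cens <- rep(0, n)
  }
  os_time <- pmax(pmin(t_event, t_cens), 1 / 365)
  os_event <- as.integer(t_event <= t_cens)
  stage_prob <- function(k) {
    w <- c(1, 1, 1, 1) + c(-0.5, 0, 0.3, 0.6) * (k - (K + 1) / 2) / max(1, K - 1)
    pmax(w, 0.1)
  }
  stage <- vapply(subtype, function(k) sample(paste0("Stage", c("I", "II", "III", "IV")), 1, prob = stage_prob(K + 1 - k)), character(1))
  clinical <- data.frame(
    sample = samples,
    OS_time = round(os_time * 365.25, 1),  # days
    OS_event = os_event,
    T_stage = sample(paste0("T", 1:4), n, replace = TRUE),
    N_stage = sample(paste0("N", 0:3), n, replace = TRUE),
    M_stage = sample(paste0("M", 0:1), n, replace = TRUE, prob = c(0.85, 0.15)),
    stage = stage,
    age = round(stats::rnorm(n, 62, 9)),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.75, 0.25)),
    histology = sample(c("squamous", "adenocarcinoma"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  # --- Synthetic gene sets: one per subtype block + random terms -----------
  gene_sets <- list()
  for (k in seq_len(K)) {
    members <- genes[which(block_of == k)]
    if (length(members)) {
      gene_sets[[sprintf("BLOCK_SUBTYPE_%d", k)]] <-
        sort(unique(c(members, sample(genes, 10))))
    }
  }
  for (j in 1:5) {
    gene_sets[[sprintf("RANDOM_SET_%02d", j)]] <- sort(sample(genes, min(50L, p)))
  }

  truth_samples <- data.frame(sample = samples, subtype = subtype, stringsAsFactors = FALSE)
  truth_genes <- data.frame(
    gene = genes,
    coupled_cnv = seq_len(p) %in% coupled_cnv,
    coupled_met = seq_len(p) %in% coupled_met,
    block_subtype = block_of,
    driver_mutation = seq_len(p) %in% driver,
    low_expressed = low_expressed,
    gene_length = gene_len,
    stringsAsFactors = FALSE
  )

  structure(list(
    cnv_segments = cnv_segments,
    cnv_gene = omics_matrix(cnv, "cnv_logratio"),
    beta_matrix = omics_matrix(beta_matrix, "beta"),
    probe_annotation = probe_annotation,
    gene_annotation = gene_annotation,
    expression_fpkm = omics_matrix(fpkm, "fpkm"),
    expression_counts = omics_matrix(counts, "counts"),
    mutations = mutations,
    clinical = clinical,
    gene_sets = gene_sets,
    truth = list(samples = truth_samples, genes = truth_genes),
    config = config
  ), class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle: %d samples, %d genes, %d probes, K=%d planted subtypes>\n",
    ncol(x$expression_counts), nrow(x$expression_counts),
    nrow(x$beta_matrix), x$config$n_subtypes
  ))
  invisible(x)
}

# Full-precision numeric formatting so a written bundle round-trips exactly.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- cbind(rownames(m), apply(unclass(m), 2, fmt_num))
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
}

#' Write a synthetic bundle to disk
#'
#' Emits the bundle in the pipeline's on-disk interchange formats: a SEG-like
#' segment table, probe/gene annotation TSVs, probe-level beta and gene-level
#' FPKM/count matrices, a MAF-like mutation table, a clinical table, truth
#' tables, and a GMT file of the synthetic gene sets. Numeric values are
#' written with 17 significant digits so reading the files back reproduces
#' the matrices exactly.
#'
#' @param bundle A `synthetic_bundle` from [generate_multiomics()].
#' @param directory Output directory (created if absent).
#' @return Invisibly, a manifest data.frame: file, rows, cols.
#' @export
write_bundle <- function(bundle, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
  }
  if (file.access(directory, mode = 2) != 0) {
    stop(sprintf("directory '%s' is not writable", directory), call. = FALSE)
  }
  p <- function(f) file.path(directory, f)

  seg <- bundle$cnv_segments
  seg_out <- data.frame(
    Sample = seg$sample, Chromosome = seg$chrom, Start = seg$start,
    End = seg$end, Num_Probes = seg$num_probes,
    Segment_Mean = fmt_num(seg$value), stringsAsFactors = FALSE
  )
  utils::write.table(seg_out, p("cnv_segments.seg"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_matrix_tsv(bundle$beta_matrix, p("methylation_beta.tsv"), "probe")
  write_matrix_tsv(bundle$expression_fpkm, p("expression_fpkm.tsv"), "gene")
  write_matrix_tsv(bundle$expression_counts, p("expression_counts.tsv"), "gene")
  utils::write.table(bundle$probe_annotation, p("probe_annotation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(bundle$gene_annotation, p("gene_annotation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  maf <- data.frame(
    Hugo_Symbol = bundle$mutations$gene,
    Tumor_Sample_Barcode = bundle$mutations$sample,
    Variant_Classification = bundle$mutations$classification,
    stringsAsFactors = FALSE
  )
  utils::write.table(maf, p("mutations.maf"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(bundle$clinical, p("clinical.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(bundle$truth$samples, p("truth_samples.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(bundle$truth$genes, p("truth_genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  gmt_lines <- vapply(names(bundle$gene_sets), function(nm) {
    paste(c(nm, "synthetic", bundle$gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, p("gene_sets.gmt"))

  files <- c(
    "cnv_segments.seg", "methylation_beta.tsv", "expression_fpkm.tsv",
    "expression_counts.tsv", "probe_annotation.tsv", "gene_annotation.tsv",
    "mutations.maf", "clinical.tsv", "truth_samples.tsv", "truth_genes.tsv",
    "gene_sets.gmt"
  )
  rows <- c(
    nrow(seg), nrow(bundle$beta_matrix), nrow(bundle$expression_fpkm),
    nrow(bundle$expression_counts), nrow(bundle$probe_annotation),
    nrow(bundle$gene_annotation), nrow(maf), nrow(bundle$clinical),
    nrow(bundle$truth$samples), nrow(bundle$truth$genes),
    length(bundle$gene_sets)
  )
  cols <- c(
    6L, ncol(bundle$beta_matrix), ncol(bundle$expression_fpkm),
    ncol(bundle$expression_counts), 5L, 6L, 3L, ncol(bundle$clinical),
    2L, ncol(bundle$truth$genes), NA_integer_
  )
  manifest <- data.frame(
    file = file.path(directory, files), rows = rows, cols = cols,
    stringsAsFactors = FALSE
  )
  invisible(manifest)
}
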
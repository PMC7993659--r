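#' Pipeline configuration
#'
#' A single configuration object driving the stage sequence
#' simulate -> preprocess -> events -> stratify -> nmf -> icluster ->
#' characterize. Can be built in code or loaded from a JSON file with
#' [read_pipeline_config()]; unknown fields are rejected so typos fail
#' loudly.
#'
#' @param out_dir Output directory; each stage writes under
#'   `out_dir/<stage>/`.
#' @param seed Master seed; stage seeds are derived from it.
#' @param stages Character vector of enabled stages, in any order (executed
#'   in dependency order).
#' @param simulate List of [simulation_config()] overrides.
#' @param preprocess List: reciprocal_overlap, min_probes,
#'   max_missing_fraction, k_neighbors, upstream, downstream,
#'   max_zero_fraction.
#' @param stratify List: alpha_corr, alpha_surv.
#' @param nmf List: kmin, kmax, n_runs, max_iter, tol, min_cluster_size.
#' @param icluster List: k, lambda, tune (logical), n_points, k_values,
#'   n_repeats, max_iter, tol.
#' @param characterize List: lfc_threshold, fdr_threshold, alpha.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c(
                              "simulate", "preprocess", "events", "stratify",
                              "nmf", "icluster", "characterize"
                            ),
                            simulate = list(), preprocess = list(),
                            stratify = list(), nmf = list(),
                            icluster = list(), characterize = list()) {
  known <- c(
    "simulate", "preprocess", "events", "stratify", "nmf", "icluster",
    "characterize"
  )
  bad <- setdiff(stages, known)
  if (length(bad)) stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    simulate = simulate, preprocess = preprocess, stratify = stratify,
    nmf = nmf, icluster = icluster, characterize = characterize
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a JSON config file.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

with_defaults <- function(user, defaults) {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop(sprintf("unknown parameter(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  utils::modifyList(defaults, user)
}

write_df <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs as TSV under `out_dir/<stage>/` and logging filter counts to
#' stderr. All randomness flows from `config$seed`. Any stage failure stops
#' the run; the manifest returned so far records the failure point.
#'
#' @param config A [pipeline_config()].
#' @return A run manifest data.frame: stage, status, elapsed_s, outputs
#'   (";"-separated), md5 (";"-separated, aligned with outputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  order_all <- c(
    "simulate", "preprocess", "events", "stratify", "nmf", "icluster",
    "characterize"
  )
  stages <- order_all[order_all %in% config$stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  manifest <- list()

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    outputs <- character(0)
    status <- "ok"
    res <- try(
      {
        outputs <- switch(stage,
          simulate = stage_simulate(config, state),
          preprocess = stage_preprocess(config, state),
          events = stage_events(config, state),
          stratify = stage_stratify(config, state),
          nmf = stage_nmf(config, state),
          icluster = stage_icluster(config, state),
          characterize = stage_characterize(config, state)
        )
      },
      silent = TRUE
    )
    if (inherits(res, "try-error")) {
      status <- paste("failed:", trimws(attr(res, "condition")$message))
      log_stage(stage, status)
    }
    manifest[[stage]] <- data.frame(
      stage = stage, status = status,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
      outputs = paste(outputs, collapse = ";"),
      md5 = paste(unname(tools::md5sum(outputs)), collapse = ";"),
      stringsAsFactors = FALSE
    )
    if (status != "ok") break
  }
  out <- do.call(rbind, c(manifest, make.row.names = FALSE))
  write_df(out, file.path(config$out_dir, "run_manifest.tsv"))
  out
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

stage_simulate <- function(config, state) {
  prm <- with_defaults(config$simulate, formals_defaults(simulation_config))
  if (!"seed" %in% names(config$simulate)) prm$seed <- config$seed
  cfg <- do.call(simulation_config, prm)
  bundle <- generate_multiomics(cfg)
  state$bundle <- bundle
  d <- stage_dir(config, "simulate")
  manifest <- write_bundle(bundle, d)
  log_stage("simulate", sprintf(
    "%d samples, %d genes, K=%d", cfg$n_samples, cfg$n_genes, cfg$n_subtypes
  ))
  manifest$file
}

formals_defaults <- function(f) {
  lapply(as.list(formals(f)), eval, envir = baseenv())
}

stage_preprocess <- function(config, state) {
  if (is.null(state$bundle)) {
    sim_dir <- file.path(config$out_dir, "simulate")
    if (!dir.exists(sim_dir)) stop("preprocess: missing upstream stage 'simulate'", call. = FALSE)
    state$bundle <- list(
      cnv_segments = read_seg_file(file.path(sim_dir, "cnv_segments.seg")),
      beta_matrix = read_matrix_tsv(file.path(sim_dir, "methylation_beta.tsv"), "beta"),
      probe_annotation = read_probe_annotation(file.path(sim_dir, "probe_annotation.tsv")),
      gene_annotation = read_gene_annotation(file.path(sim_dir, "gene_annotation.tsv")),
      expression_fpkm = read_matrix_tsv(file.path(sim_dir, "expression_fpkm.tsv"), "fpkm"),
      expression_counts = read_matrix_tsv(file.path(sim_dir, "expression_counts.tsv"), "counts"),
      mutations = read_maf_file(file.path(sim_dir, "mutations.maf")),
      clinical = read_clinical(file.path(sim_dir, "clinical.tsv")),
      gene_sets = read_gmt(file.path(sim_dir, "gene_sets.gmt"))
    )
  }
  prm <- with_defaults(config$preprocess, list(
    reciprocal_overlap = 0.5, min_probes = 5L, max_missing_fraction = 0.7,
    k_neighbors = 10L, upstream = 2000L, downstream = 200L,
    max_zero_fraction = 0.5
  ))
  b <- state$bundle
  seg0 <- nrow(b$cnv_segments)
  merged <- merge_cnv_segments(b$cnv_segments, prm$reciprocal_overlap, prm$min_probes)
  log_stage("preprocess", sprintf("segments %d -> %d after probe filter + merge", seg0, nrow(merged)))
  cnv_gene <- map_cnv_to_genes(merged, b$gene_annotation)
  n0 <- nrow(b$beta_matrix)
  beta_imp <- filter_impute_methylation(b$beta_matrix, prm$max_missing_fraction, prm$k_neighbors)
  log_stage("preprocess", sprintf("probes %d -> %d after missingness filter", n0, nrow(beta_imp)))
  beta_gene <- map_probes_to_promoters(
    beta_imp, b$probe_annotation, b$gene_annotation, prm$upstream, prm$downstream
  )
  e0 <- nrow(b$expression_fpkm)
  fpkm <- filter_expression(b$expression_fpkm, prm$max_zero_fraction)
  log_stage("preprocess", sprintf("genes %d -> %d after expression filter", e0, nrow(fpkm)))
  counts <- b$expression_counts[rownames(fpkm), , drop = FALSE]
  m0 <- nrow(b$mutations)
  muts <- filter_mutations(b$mutations)
  log_stage("preprocess", sprintf("mutation records %d -> %d after class filter", m0, nrow(muts)))

  state$cnv_gene <- cnv_gene
  state$beta_gene <- beta_gene
  state$fpkm <- fpkm
  state$counts <- counts
  state$mutations <- muts
  d <- stage_dir(config, "preprocess")
  c(
    write_matrix_stage(cnv_gene, file.path(d, "cnv_gene.tsv"), "gene"),
    write_matrix_stage(beta_gene, file.path(d, "methylation_gene.tsv"), "gene"),
    write_matrix_stage(fpkm, file.path(d, "expression_fpkm_filtered.tsv"), "gene"),
    write_matrix_stage(counts, file.path(d, "expression_counts_filtered.tsv"), "gene"),
    write_df(muts, file.path(d, "mutations_filtered.tsv"))
  )
}

write_matrix_stage <- function(m, path, id_col) {
  write_matrix_tsv(m, path, id_col)
  path
}

needs <- function(state, what, stage) {
  for (w in what) {
    if (is.null(state[[w]])) {
      stop(sprintf("%s: missing upstream output '%s' (run preprocess first)", stage, w), call. = FALSE)
    }
  }
}

stage_events <- function(config, state) {
  needs(state, c("cnv_gene", "beta_gene"), "events")
  counts <- classify_events(state$cnv_gene, state$beta_gene)
  cors <- event_frequency_correlations(counts)
  state$event_counts <- counts
  d <- stage_dir(config, "events")
  log_stage("events", sprintf(
    "6 pair correlations; %d significant at p<0.01", sum(cors$label != "ns", na.rm = TRUE)
  ))
  c(
    write_df(counts, file.path(d, "event_counts.tsv")),
    write_df(cors, file.path(d, "event_correlations.tsv"))
  )
}

stage_stratify <- function(config, state) {
  needs(state, c("cnv_gene", "beta_gene", "fpkm"), "stratify")
  prm <- with_defaults(config$stratify, list(alpha_corr = 1e-5, alpha_surv = 0.05))
  cnv_cor <- correlate_omics_expression(state$cnv_gene, state$fpkm, "cnv")
  met_cor <- correlate_omics_expression(state$beta_gene, state$fpkm, "met")
  cnv_g <- select_correlated_genes(cnv_cor, prm$alpha_corr)
  met_g <- select_correlated_genes(met_cor, prm$alpha_corr)
  log_stage("stratify", sprintf("CNV-G: %d genes, MET-G: %d genes", length(cnv_g), length(met_g)))
  state$cnv_g <- cnv_g
  state$met_g <- met_g
  d <- stage_dir(config, "stratify")
  outputs <- c(
    write_df(cnv_cor, file.path(d, "cnv_expression_correlation.tsv")),
    write_df(met_cor, file.path(d, "met_expression_correlation.tsv"))
  )
  writeLines(cnv_g, file.path(d, "cnv_g.txt"))
  writeLines(met_g, file.path(d, "met_g.txt"))
  outputs <- c(outputs, file.path(d, c("cnv_g.txt", "met_g.txt")))
  if (!is.null(state$bundle$clinical)) {
    screen_genes <- union(cnv_g, met_g)
    if (length(screen_genes)) {
      prog <- suppressWarnings(prognostic_screen(
        state$fpkm, state$bundle$clinical, screen_genes, prm$alpha_surv
      ))
      prog_cnv <- prog$gene[prog$prognostic & prog$gene %in% cnv_g]
      prog_met <- prog$gene[prog$prognostic & prog$gene %in% met_g]
      inter <- intersect_gene_sets(prog_cnv, prog_met)
      log_stage("stratify", sprintf(
        "prognostic: %d CNV-G, %d MET-G, intersection %d",
        length(prog_cnv), length(prog_met), length(inter)
      ))
      outputs <- c(outputs, write_df(prog, file.path(d, "prognostic_screen.tsv")))
      writeLines(inter, file.path(d, "prognostic_intersection.txt"))
      outputs <- c(outputs, file.path(d, "prognostic_intersection.txt"))
    }
  }
  outputs
}

stage_nmf <- function(config, state) {
  needs(state, c("fpkm", "cnv_g", "met_g"), "nmf")
  prm <- with_defaults(config$nmf, list(
    kmin = 2L, kmax = 4L, n_runs = 30L, max_iter = 500L, tol = 1e-5,
    min_cluster_size = 10L
  ))
  d <- stage_dir(config, "nmf")
  outputs <- character(0)
  for (set_name in c("cnv_g", "met_g")) {
    genes <- intersect(state[[set_name]], rownames(state$fpkm))
    if (length(genes) < prm$kmax + 1) {
      log_stage("nmf", sprintf("%s: too few genes (%d), skipped", set_name, length(genes)))
      next
    }
    V <- log2(unclass(state$fpkm)[genes, , drop = FALSE] + 1)
    results <- list()
    metrics <- list()
    for (k in prm$kmin:prm$kmax) {
      cr <- suppressWarnings(consensus_cluster(
        V, k, n_runs = prm$n_runs, seed = derive_seed(config$seed, k),
        max_iter = prm$max_iter, tol = prm$tol,
        min_cluster_size = prm$min_cluster_size
      ))
      results[[as.character(k)]] <- cr
      metrics[[as.character(k)]] <- data.frame(
        rank = k, cophenetic = cr$cophenetic, dispersion = cr$dispersion,
        mean_silhouette = cr$mean_silhouette, admissible = cr$admissible,
        min_cluster = min(table(cr$assignment$labels))
      )
    }
    metrics <- do.call(rbind, c(metrics, make.row.names = FALSE))
    chosen <- try(select_rank(results, prm$min_cluster_size), silent = TRUE)
    if (inherits(chosen, "try-error")) {
      log_stage("nmf", sprintf("%s: no admissible rank", set_name))
      next
    }
    best <- results[[as.character(chosen)]]
    method_label <- if (set_name == "cnv_g") "NMF-CNVCor" else "NMF-METCor"
    best$assignment$method <- method_label
    state[[paste0("nmf_", set_name)]] <- best$assignment
    log_stage("nmf", sprintf("%s: chose k=%d (CPCC=%.3f)", set_name, chosen, best$cophenetic))
    assign_df <- data.frame(
      sample = names(best$assignment$labels),
      cluster = as.integer(best$assignment$labels),
      method = method_label, stringsAsFactors = FALSE
    )
    outputs <- c(
      outputs,
      write_df(metrics, file.path(d, paste0(set_name, "_metrics.tsv"))),
      write_df(assign_df, file.path(d, paste0(set_name, "_assignment.tsv"))),
      write_matrix_stage(
        omics_matrix(best$consensus, "cnv_logratio"),
        file.path(d, paste0(set_name, "_consensus.tsv")), "sample"
      )
    )
  }
  outputs
}

stage_icluster <- function(config, state) {
  needs(state, c("cnv_gene", "beta_gene", "fpkm", "cnv_g", "met_g"), "icluster")
  prm <- with_defaults(config$icluster, list(
    k = 3L, lambda = c(0.2, 0.2, 0.2), tune = FALSE, n_points = 101L,
    k_values = c(2L, 3L, 4L), n_repeats = 10L, max_iter = 100L, tol = 1e-5
  ))
  sets <- list(
    cnv = state$cnv_g, met = state$met_g,
    expr = union(state$cnv_g, state$met_g)
  )
  data <- prepare_icluster_inputs(
    list(cnv = state$cnv_gene, met = state$beta_gene, expr = state$fpkm),
    sets
  )
  data <- data[vapply(data, nrow, integer(1)) > 0]
  if (length(data) < 2) stop("icluster: fewer than 2 usable data types", call. = FALSE)
  lambda <- rep_len(prm$lambda, length(data))
  if (isTRUE(prm$tune)) {
    tuned <- tune_lambda(data, prm$k, n_points = prm$n_points, seed = config$seed)
    lambda <- tuned$best_lambda
    log_stage("icluster", sprintf("tuned lambda = %s", paste(round(lambda, 4), collapse = ", ")))
  }
  cfg <- icluster_config(
    k = prm$k, lambda = lambda, max_iter = prm$max_iter, tol = prm$tol,
    seed = config$seed, n_repeats = prm$n_repeats
  )
  stab <- stability_repeats(data, prm$k_values, cfg,
    clinical = state$bundle$clinical, n_repeats = prm$n_repeats
  )
  fit <- suppressWarnings(fit_icluster(data, cfg))
  if (fit$degenerate) stop("icluster: degenerate model at the chosen lambda", call. = FALSE)
  state$icluster_assignment <- fit$assignment
  d <- stage_dir(config, "icluster")
  log_stage("icluster", sprintf(
    "k=%d assignment; stability: %s", prm$k,
    paste(sprintf("k%d=%.2f", stab$report$k, stab$report$stability), collapse = " ")
  ))
  assign_df <- data.frame(
    sample = names(fit$assignment$labels),
    cluster = as.integer(fit$assignment$labels),
    method = "integrative", stringsAsFactors = FALSE
  )
  outputs <- c(
    write_df(assign_df, file.path(d, "assignment.tsv")),
    write_df(stab$report, file.path(d, "stability_report.tsv"))
  )
  summary <- list(
    k = prm$k, lambda = as.numeric(lambda), converged = fit$converged,
    n_nonzero = fit$n_nonzero,
    loglik = fit$loglik_trace[length(fit$loglik_trace)]
  )
  jsonlite::write_json(summary, file.path(d, "model_summary.json"), auto_unbox = TRUE, digits = NA)
  c(outputs, file.path(d, "model_summary.json"))
}

stage_characterize <- function(config, state) {
  needs(state, c("icluster_assignment", "cnv_gene", "beta_gene", "counts", "mutations"), "characterize")
  prm <- with_defaults(config$characterize, list(
    lfc_threshold = 1.0, fdr_threshold = 0.05, alpha = 0.05
  ))
  assign <- state$icluster_assignment
  clinical <- state$bundle$clinical
  d <- stage_dir(config, "characterize")
  outputs <- character(0)

  lr <- suppressWarnings(km_logrank(clinical, assign, prm$alpha))
  log_stage("characterize", sprintf("global log-rank p = %.3g", lr$global_p))
  outputs <- c(
    outputs,
    write_df(lr$pairwise, file.path(d, "logrank_pairwise.tsv")),
    write_df(lr$km, file.path(d, "km_curves.tsv"))
  )
  global_df <- data.frame(statistic = lr$global_statistic, df = lr$global_df, p = lr$global_p)
  outputs <- c(outputs, write_df(global_df, file.path(d, "logrank_global.tsv")))

  # contrast the two extreme-survival subtypes
  km_med <- tapply(
    clinical$OS_time[match(names(assign$labels), clinical$sample)],
    assign$labels, stats::median
  )
  worst <- names(which.min(km_med))
  best <- names(which.max(km_med))
  grp_a <- names(assign$labels)[assign$labels == worst]
  grp_b <- names(assign$labels)[assign$labels == best]

  cnv_states <- call_states(state$cnv_gene)
  de_cnv <- fisher_state_test(cnv_states, grp_a, grp_b, seed = config$seed)
  met_states <- call_states(state$beta_gene)
  de_met <- fisher_state_test(met_states, grp_a, grp_b, seed = config$seed)
  de_expr <- nb_differential_expression(
    state$counts, grp_a, grp_b, prm$lfc_threshold, prm$fdr_threshold
  )
  de_mut <- mutation_frequency_test(state$mutations, grp_a, grp_b, prm$alpha)
  log_stage("characterize", sprintf(
    "differential features (fdr<%.2g): cnv %d, met %d, expr %d, mutation %d",
    prm$fdr_threshold, sum(de_cnv$fdr < prm$fdr_threshold),
    sum(de_met$fdr < prm$fdr_threshold), sum(de_expr$significant),
    sum(de_mut$significant)
  ))
  outputs <- c(
    outputs,
    write_df(de_cnv, file.path(d, "differential_cnv_states.tsv")),
    write_df(de_met, file.path(d, "differential_met_states.tsv")),
    write_df(de_expr, file.path(d, "differential_expression.tsv")),
    write_df(de_mut, file.path(d, "differential_mutations.tsv"))
  )

  # enrichment of the significant expression genes against the bundle's GMT
  if (!is.null(state$bundle$gene_sets) && any(de_expr$significant)) {
    ora <- hypergeometric_enrichment(
      de_expr$feature[de_expr$significant], de_expr$feature,
      state$bundle$gene_sets
    )
    outputs <- c(outputs, write_df(ora, file.path(d, "enrichment.tsv")))
  }
  outputs
}
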
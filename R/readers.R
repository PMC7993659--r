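# Readers for the pipeline's on-disk formats. All are thin wrappers over
# read.delim with header validation that reports the offending file and,
# where detectable, the line number.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop(sprintf(
      "%s '%s': missing required column(s) %s (line 1)",
      what, path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  df
}

#' Read a SEG-like copy-number segment table
#'
#' Expects columns Sample, Chromosome, Start, End, Num_Probes, Segment_Mean
#' with 1-based inclusive coordinates.
#'
#' @param path Path to a tab-separated segment file.
#' @return data.frame with columns sample, chrom, start, end, num_probes,
#'   value.
#' @export
read_seg_file <- function(path) {
  df <- read_tsv_checked(
    path, c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean"),
    "segment file"
  )
  bad <- which(df$Start > df$End)
  if (length(bad)) {
    stop(sprintf(
      "segment file '%s': start > end at data line %d", path, bad[1]
    ), call. = FALSE)
  }
  data.frame(
    sample = as.character(df$Sample), chrom = as.character(df$Chromosome),
    start = as.integer(df$Start), end = as.integer(df$End),
    num_probes = as.integer(df$Num_Probes), value = as.numeric(df$Segment_Mean),
    stringsAsFactors = FALSE
  )
}

#' Read a feature-by-sample matrix TSV
#'
#' First column is the feature id, remaining columns are samples.
#'
#' @param path Path to the TSV.
#' @param kind Omics kind tag, see [omics_matrix()].
#' @return An `omics_matrix`.
#' @export
read_matrix_tsv <- function(path, kind) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop(sprintf("matrix file '%s': needs id column + >=1 sample", path), call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(df[, -1, drop = FALSE], 1, function(r) any(is.na(suppressWarnings(as.numeric(r))) & !is.na(r) & r != "NA")))
    stop(sprintf(
      "matrix file '%s': non-numeric entries (data line %s)",
      path, if (length(bad)) bad[1] else "?"
    ), call. = FALSE)
  }
  rownames(m) <- ids
  omics_matrix(m, kind)
}

#' Read a methylation probe annotation table
#'
#' Expects columns probe, chrom, position, gene, region_class.
#' @param path Path to the TSV.
#' @return data.frame of probe records.
#' @export
read_probe_annotation <- function(path) {
  df <- read_tsv_checked(
    path, c("probe", "chrom", "position", "gene", "region_class"),
    "probe annotation"
  )
  if (any(df$position < 1)) {
    stop(sprintf(
      "probe annotation '%s': position < 1 at data line %d",
      path, which(df$position < 1)[1]
    ), call. = FALSE)
  }
  df
}

#' Read a gene annotation table
#'
#' Expects columns gene, chrom, strand, tss, gene_start, gene_end
#' (1-based inclusive).
#' @param path Path to the TSV.
#' @return data.frame of gene records.
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv_checked(
    path, c("gene", "chrom", "strand", "tss", "gene_start", "gene_end"),
    "gene annotation"
  )
  bad <- which(df$gene_start > df$gene_end)
  if (length(bad)) {
    stop(sprintf(
      "gene annotation '%s': gene_start > gene_end at data line %d",
      path, bad[1]
    ), call. = FALSE)
  }
  df
}

#' Read a MAF-like mutation table
#'
#' Expects columns Hugo_Symbol, Tumor_Sample_Barcode, Variant_Classification.
#' @param path Path to the TSV.
#' @return data.frame with columns gene, sample, classification.
#' @export
read_maf_file <- function(path) {
  df <- read_tsv_checked(
    path, c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification"),
    "MAF file"
  )
  data.frame(
    gene = as.character(df$Hugo_Symbol),
    sample = as.character(df$Tumor_Sample_Barcode),
    classification = as.character(df$Variant_Classification),
    stringsAsFactors = FALSE
  )
}

#' Read a clinical table
#'
#' Expects at least sample, OS_time, OS_event; other columns pass through.
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_checked(path, c("sample", "OS_time", "OS_event"), "clinical table")
  if (any(df$OS_time <= 0, na.rm = TRUE)) {
    stop(sprintf(
      "clinical table '%s': OS_time must be > 0 (data line %d)",
      path, which(df$OS_time <= 0)[1]
    ), call. = FALSE)
  }
  if (!all(df$OS_event %in% c(0, 1))) {
    stop(sprintf(
      "clinical table '%s': OS_event must be 0/1 (data line %d)",
      path, which(!df$OS_event %in% c(0, 1))[1]
    ), call. = FALSE)
  }
  df
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (term, description, members...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("GMT '%s': line %d has < 3 fields", path, i), call. = FALSE)
    }
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}
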
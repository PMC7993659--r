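seg_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      sample = r[[1]], chrom = r[[2]], start = r[[3]], end = r[[4]],
      num_probes = r[[5]], value = r[[6]], stringsAsFactors = FALSE
    )
  }))
}

test_that("segment merging applies the probe filter and the reciprocal-overlap rule", {
  # < 5 probes: removed
  low <- seg_df(list("A", "chr1", 100, 200, 4, 0.5))
  expect_equal(nrow(merge_cnv_segments(low)), 0)

  # disjoint segments pass through unchanged
  disj <- seg_df(
    list("A", "chr1", 100, 200, 10, 0.4),
    list("A", "chr1", 500, 600, 10, -0.2)
  )
  expect_same_segments(merge_cnv_segments(disj), disj)

  # the worked overlap case: union [100,250], probe-weighted mean 0.3
  ov <- seg_df(
    list("A", "chr1", 100, 200, 10, 0.4),
    list("A", "chr1", 150, 250, 10, 0.2)
  )
  m <- merge_cnv_segments(ov)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100)
  expect_equal(m$end, 250)
  expect_equal(m$value, 0.3)
  expect_equal(m$num_probes, 20)

  # reciprocal rule: overlap must reach the threshold for BOTH intervals
  asym <- seg_df(
    list("A", "chr1", 100, 1000, 10, 0.4),  # long
    list("A", "chr1", 100, 200, 10, 0.0)    # short, fully inside
  )
  expect_equal(nrow(merge_cnv_segments(asym)), 2)

  expect_error(
    merge_cnv_segments(seg_df(list("A", "chr1", 300, 200, 10, 0))),
    "malformed"
  )
})

test_that("segment merging matches the brute-force union-find oracle", {
  for (s in 1:25) {
    seg <- random_segments(sample(2:50, 1), seed = 7000 + s)
    got <- merge_cnv_segments(seg)
    want <- oracle_merge_segments(seg)
    expect_same_segments(got, want)
  }
})

test_that("segment merging is invariant to input row order", {
  seg <- random_segments(40, seed = 88)
  shuffled <- seg[sample(nrow(seg)), ]
  expect_same_segments(merge_cnv_segments(seg), merge_cnv_segments(shuffled))
})

test_that("gene-level CNV mapping averages overlapping segments, unweighted", {
  ann <- data.frame(
    gene = c("G1", "G2"), chrom = "chr1", strand = "+",
    tss = c(150, 5000), gene_start = c(150, 5000), gene_end = c(260, 5100),
    stringsAsFactors = FALSE
  )
  segs <- seg_df(
    list("A", "chr1", 100, 200, 10, 0.2),
    list("A", "chr1", 201, 300, 30, 0.4)   # different probe counts: mean is unweighted
  )
  m <- map_cnv_to_genes(segs, ann)
  expect_equal(unclass(m)["G1", "A"], 0.3)
  expect_true(is.na(unclass(m)["G2", "A"]))

  inside <- seg_df(list("B", "chr1", 1, 1000, 10, -0.7))
  m2 <- map_cnv_to_genes(inside, ann[1, ])
  expect_equal(unclass(m2)["G1", "B"], -0.7)

  expect_error(map_cnv_to_genes(segs, ann[0, ]), "empty")
})

test_that("methylation filter drops >70%-missing probes and imputation is exact on duplicates", {
  set.seed(31)
  m <- named_matrix(runif(10 * 100), 10, 100, prefix_r = "cg")
  m["cg001", 1:71] <- NA  # missing in 71% of samples
  om <- omics_matrix(m, "beta")
  out <- filter_impute_methylation(om)
  expect_false("cg001" %in% rownames(out))

  # fully observed input is returned unchanged
  full <- omics_matrix(m[-1, ], "beta")
  got <- unclass(filter_impute_methylation(full))
  attr(got, "kind") <- NULL
  expect_identical(got, m[-1, ])

  # duplicated row, one masked entry: nearest neighbour at distance 0 dominates
  dup <- m[-1, ]
  dup["cg002", ] <- dup["cg003", ]
  dup["cg002", 5] <- NA
  imp <- filter_impute_methylation(omics_matrix(dup, "beta"), k_neighbors = 1)
  expect_equal(unclass(imp)["cg002", 5], dup["cg003", 5])
  # observed entries are never altered
  obs <- !is.na(dup)
  expect_identical(unclass(imp)[obs], dup[obs])

  expect_error(
    filter_impute_methylation(omics_matrix(
      named_matrix(NA_real_, 3, 10, prefix_r = "cg"), "beta"
    )),
    "dropped"
  )
})

test_that("promoter mapping is strand-aware and averages probes per gene", {
  ann <- data.frame(
    gene = c("GP", "GM"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10000, 50000), gene_start = c(10000, 40000),
    gene_end = c(20000, 50000), stringsAsFactors = FALSE
  )
  probes <- data.frame(
    probe = c("p1", "p2", "p3", "p4", "p5"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chrUn"),
    position = c(10150, 15000, 9900, 50150, 100),
    gene = NA, region_class = "Island", stringsAsFactors = FALSE
  )
  # p1 at tss+150 (+): in window; p2 at tss+5000: out; p3 at tss-100: in
  # p4 at tss+150 genomically on the minus strand = 150 bp UPSTREAM in
  # transcript orientation: inside the 2 kb upstream window
  beta <- named_matrix(0, 5, 2, prefix_r = "q")
  rownames(beta) <- probes$probe
  beta["p1", ] <- c(0.2, 0.6)
  beta["p3", ] <- c(0.4, 0.8)
  beta["p4", ] <- c(0.9, 0.1)
  om <- omics_matrix(beta, "beta")
  expect_warning(
    g <- map_probes_to_promoters(om, probes, ann),
    "skipped"
  )
  expect_equal(unclass(g)["GP", ], c(s001 = 0.3, s002 = 0.7))
  expect_equal(unclass(g)["GM", ], c(s001 = 0.9, s002 = 0.1))
})

test_that("expression filter treats the 50% boundary as removed", {
  f <- named_matrix(1, 3, 10, prefix_r = "g")
  f["g001", 1:6] <- 0  # 60% zeros: removed
  f["g002", 1:5] <- 0  # exactly 50%: removed (not < 0.5)
  out <- filter_expression(omics_matrix(f, "fpkm"))
  expect_identical(rownames(out), "g003")
})

test_that("mutation filter removes Intron and Silent case-insensitively", {
  rec <- data.frame(
    gene = c("A", "B", "C", "D"), sample = "s1",
    classification = c("Silent", "silent", "Intron", "Missense_Mutation"),
    stringsAsFactors = FALSE
  )
  out <- filter_mutations(rec)
  expect_identical(out$gene, "D")
  expect_equal(nrow(filter_mutations(rec[0, ])), 0)
  rec$classification[1] <- ""
  expect_error(filter_mutations(rec), "malformed")
})

test_that("readers validate headers and coordinates", {
  d <- withr::local_tempdir()
  writeLines("a\tb\tc", file.path(d, "bad.seg"))
  expect_error(read_seg_file(file.path(d, "bad.seg")), "missing required column")
  writeLines(
    c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean", "A\tchr1\t50\t10\t6\t0.1"),
    file.path(d, "rev.seg")
  )
  expect_error(read_seg_file(file.path(d, "rev.seg")), "start > end at data line 1")
  writeLines(c("sample\tOS_time\tOS_event", "s1\t-3\t1"), file.path(d, "clin.tsv"))
  expect_error(read_clinical(file.path(d, "clin.tsv")), "OS_time")
})
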
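test_that("fixture bundle round-trips through the TSV readers", {
  b <- generate_cohorts(small_sim_config(seed = 11))
  dir <- withr::local_tempdir()
  paths <- suppressMessages(write_fixture_bundle(b, dir))
  bundle <- suppressMessages(read_cohort(
    expression_paths = stats::setNames(
      file.path(dir, paste0("expr_", c("D1", "D2", "D3", "VAL"), ".tsv")),
      c("D1", "D2", "D3", "VAL")),
    sample_sheet_path = file.path(dir, "samples.tsv"),
    annotation_path = file.path(dir, "annotation.tsv"),
    tf_map_path = file.path(dir, "tf_targets.tsv"),
    cn_path = file.path(dir, "cn_VAL.tsv"), cn_dataset_id = "VAL"))
  expect_length(bundle$datasets, 4L)
  expect_equal(bundle$datasets$D1$values, b$datasets$D1$values)
  expect_equal(bundle$datasets$D1$groups, b$datasets$D1$groups)
  expect_equal(bundle$cn$values, b$cn$values)
  expect_equal(sort(names(bundle$tf_map)), sort(names(b$tf_map)))
  expect_equal(bundle$annotation$cytoband, b$annotation$cytoband)
})

test_that("readers report malformed inputs precisely", {
  dir <- withr::local_tempdir()
  # sample sheet that misses one sample
  mat <- matrix(1:6, 2, 3,
                dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_error(
    expression_dataset("d", mat, c(s1 = "FN", s2 = "FP")),
    "s3")
  # duplicate gene row
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"),
             file.path(dir, "dup.tsv"))
  expect_error(read_expression_matrix(file.path(dir, "dup.tsv")), "g1")
  # non-numeric cell names the row and column
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\toops\t4"),
             file.path(dir, "bad.tsv"))
  expect_error(read_expression_matrix(file.path(dir, "bad.tsv")),
               "g2.*'s1'")
})

test_that("GCT 1.2 matrices are read with the Description column dropped", {
  dir <- withr::local_tempdir()
  writeLines(c("#1.2", "2\t2",
               "Name\tDescription\ts1\ts2",
               "g1\tfoo\t1.5\t2", "g2\tbar\t3\t4"),
             file.path(dir, "m.gct"))
  m <- read_gct(file.path(dir, "m.gct"))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["g1", "s2"], 2)
  expect_equal(colnames(m), c("s1", "s2"))
})

test_that("zero-fraction filter is strict at the boundary", {
  vals <- rbind(
    mostly_zero = c(rep(0, 6), rep(2, 4)),   # 0.6 > 0.5 -> removed
    half_zero   = c(rep(0, 5), rep(2, 5)),   # exactly 0.5 -> retained
    positive    = rep(3, 10))
  colnames(vals) <- paste0("s", 1:10)
  ds <- expression_dataset("d", vals,
                           stats::setNames(rep(c("FN", "FP"), 5),
                                           colnames(vals)))
  out <- filter_genes(ds, protein_coding_only = FALSE)
  expect_equal(rownames(out$values), c("half_zero", "positive"))
  # idempotent, sample set and order unchanged
  out2 <- filter_genes(out, protein_coding_only = FALSE)
  expect_identical(out2$values, out$values)
  expect_identical(colnames(out$values), colnames(ds$values))
})

test_that("coding filter uses the annotation and errors when all genes die", {
  vals <- matrix(1, 3, 4, dimnames = list(c("gA", "gB", "gX"),
                                          paste0("s", 1:4)))
  ds <- expression_dataset("d", vals,
                           stats::setNames(rep("FN", 4), paste0("s", 1:4)))
  ann <- gene_annotation(data.frame(
    gene_id = c("gA", "gB"), chromosome = "chr1", start = 1, end = 10,
    cytoband = "1q1", gene_type = c("protein_coding", "other"),
    is_tf = 0L))
  out <- filter_genes(ds, annotation = ann)
  # gB is non-coding, gX unannotated: both dropped under coding-only
  expect_equal(rownames(out$values), "gA")
  zero_ds <- expression_dataset(
    "d", matrix(0, 1, 4, dimnames = list("gA", paste0("s", 1:4))),
    stats::setNames(rep("FN", 4), paste0("s", 1:4)), scale = "linear")
  expect_error(filter_genes(zero_ds, annotation = ann),
               "no genes survive")
})

test_that("comparison sample selection applies the exclusion rules", {
  vals <- matrix(1, 1, 8, dimnames = list("g", paste0("s", 1:8)))
  groups <- stats::setNames(
    c("FP", "FP", "FP", "FN", "FN", "FN", "FN", "OTHER"), paste0("s", 1:8))
  ds <- expression_dataset("d", vals, groups)
  sel <- select_comparison_samples(ds, "FN_vs_FP")
  expect_length(sel$a, 4L)
  expect_length(sel$b, 3L)
  expect_false("s8" %in% c(sel$a, sel$b))  # OTHER always excluded

  groups2 <- stats::setNames(rep(c("FN", "NORMAL"), each = 4),
                             paste0("s", 1:8))
  ds2 <- expression_dataset("d", vals, groups2)
  sel2 <- select_comparison_samples(ds2, "FN_vs_NORMAL")
  expect_length(sel2$a, 4L)
  expect_length(sel2$b, 4L)

  groups3 <- stats::setNames(rep("FN", 8), paste0("s", 1:8))
  ds3 <- expression_dataset("d", vals, groups3)
  expect_error(select_comparison_samples(ds3, "FN_vs_FP"), "FP")
})
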
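test_that("Welch t handles identical and degenerate groups by convention", {
  expect_equal(welch_t_two_group(c(5, 5, 5), c(5, 5, 5))$p, 1)
  r <- welch_t_two_group(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_lt(welch_t_two_group(c(10, 11, 12, 13), c(1, 2, 3, 4))$p, 0.01)
  # constant but different: variance floor keeps the direction testable
  expect_message(r2 <- fgcnminer:::welch_rows(matrix(2, 1, 3),
                                              matrix(1, 1, 3)),
                 "floored")
  expect_lt(r2$p, 0.001)
  expect_error(welch_t_two_group(1, c(1, 2)), "2 values")
})

test_that("Welch t agrees with stats::t.test across random cases", {
  set.seed(5)
  for (i in 1:50) {
    xs <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    ys <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    got <- welch_t_two_group(xs, ys)
    ref <- t.test(xs, ys)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_equal(benjamini_hochberg(rep(0, 5)), rep(0, 5))
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_enum(p))
    expect_true(all(q >= p))
    perm <- sample(seq_along(p))
    expect_equal(benjamini_hochberg(p[perm]), q[perm])
  }
})

sim_de_ds <- function(seed = 1, n_genes = 50, shift_gene = NULL,
                      shift = 0, n_a = 20, n_b = 20, sd = 0.3) {
  set.seed(seed)
  samples <- c(sprintf("a%02d", 1:n_a), sprintf("b%02d", 1:n_b))
  x <- matrix(rnorm(n_genes * (n_a + n_b), mean = 6, sd = sd),
              n_genes, n_a + n_b,
              dimnames = list(sprintf("g%03d", 1:n_genes), samples))
  if (!is.null(shift_gene)) x[shift_gene, 1:n_a] <- x[shift_gene, 1:n_a] + shift
  expression_dataset("d", x,
                     stats::setNames(rep(c("FN", "FP"), c(n_a, n_b)),
                                     samples), scale = "log2")
}

test_that("a planted four-fold shift is called up and nulls stay ns", {
  ds <- sim_de_ds(seed = 3, shift_gene = "g001", shift = 2)  # 4-fold
  deg <- de_two_group(ds, "FN_vs_FP", de_params(transform = "none"))
  expect_equal(deg$status[deg$gene_id == "g001"], "up")
  expect_gt(mean(deg$status[deg$gene_id != "g001"] == "ns"), 0.9)
  expect_true(all(deg$q >= deg$p))
})

test_that("label swap flips sign and up/down but not p", {
  ds <- sim_de_ds(seed = 4, shift_gene = "g002", shift = 1.5)
  flipped <- ds
  flipped$groups <- stats::setNames(
    ifelse(ds$groups == "FN", "FP", "FN"), names(ds$groups))
  d1 <- de_two_group(ds, "FN_vs_FP", de_params(transform = "none"))
  d2 <- de_two_group(flipped, "FN_vs_FP", de_params(transform = "none"))
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
  expect_equal(d1$status == "up", d2$status == "down")
})

test_that("fold-change gate is strict at |log2fc| == log2(1.5)", {
  n <- 10
  d <- 1e-3
  xa <- log2(1.5) + rep(c(-d, d), n / 2)   # mean exactly log2(1.5)
  xb <- rep(c(-d, d), n / 2)               # mean exactly 0
  samples <- sprintf("s%02d", 1:(2 * n))
  x <- rbind(gene = c(xa, xb))
  colnames(x) <- samples
  ds <- expression_dataset("d", x,
                           stats::setNames(rep(c("FN", "FP"), each = n),
                                           samples), scale = "log2")
  deg <- de_two_group(ds, "FN_vs_FP", de_params(transform = "none"))
  expect_equal(deg$log2fc, log2(1.5))
  expect_lt(deg$q, 0.05)
  expect_equal(deg$status, "ns")           # boundary excluded
})

test_that("target summaries use the full target list as denominator", {
  deg <- data.frame(gene_id = sprintf("t%02d", 1:20),
                    log2fc = 0, p = 1, q = 1,
                    status = c(rep("up", 3), rep("down", 2), rep("ns", 15)),
                    stringsAsFactors = FALSE)
  s <- target_de_summary("TF1", sprintf("t%02d", 1:20), deg,
                         n_targets_total = 40)
  expect_equal(s$n_de, 5)
  expect_equal(s$pct_de, 100 * 5 / 40)
  expect_warning(
    s0 <- target_de_summary("TF2", c("zz1", "zz2"), deg),
    "no target")
  expect_equal(s0$n_de, 0)
  expect_equal(s0$pct_de, 0)
})
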
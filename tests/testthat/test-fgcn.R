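make_ds <- function(mat) {
  expression_dataset("d", mat,
                     stats::setNames(rep("FN", ncol(mat)), colnames(mat)))
}

test_that("pairwise |PCC| matches hand-computed correlations", {
  mat <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
               c = c(4, 3, 2, 1), d = c(1, 3, 2, 4))
  colnames(mat) <- paste0("s", 1:4)
  r <- pairwise_abs_pcc(make_ds(mat))
  expect_equal(r["a", "b"], 1.0)        # exact linear dependence
  expect_equal(r["a", "c"], 1.0)        # anti-correlation, absolute value
  expect_equal(r["a", "d"], 0.8)        # direct PCC formula
  expect_true(all(is.na(diag(r))))
})

test_that("zero-variance genes are excluded and small inputs rejected", {
  mat <- rbind(a = c(1, 2, 3), flat = c(5, 5, 5), b = c(3, 1, 2))
  colnames(mat) <- paste0("s", 1:3)
  expect_warning(r <- pairwise_abs_pcc(make_ds(mat)), "zero-variance")
  expect_equal(sort(rownames(r)), c("a", "b"))
  expect_error(pairwise_abs_pcc(make_ds(mat[, 1:2])), "3 samples")
})

test_that("nearest-rank percentile keeps the stated top fraction", {
  vals <- seq(0.01, 1.00, by = 0.01)
  expect_equal(percentile_threshold(vals, 0.05), 0.96)
  expect_equal(sum(vals >= percentile_threshold(vals, 0.05)), 5L)
  expect_equal(percentile_threshold(vals, 1.0), 0.01)   # q = 1 keeps all
  expect_equal(percentile_threshold(rep(0.5, 40), 0.05), 0.5)
})

test_that("top-percentile edge selection includes threshold ties", {
  g <- c("a", "b", "c", "d", "e", "f", "g")
  corr <- matrix(0, 7, 7, dimnames = list(g, g))
  vals <- c(0.9, 0.8, 0.8, seq(0.05, 0.70, length.out = 18))
  corr[upper.tri(corr)] <- vals
  corr <- pmax(corr, t(corr))
  diag(corr) <- NA
  es <- top_percentile_edges(corr, q = 0.10)
  # 21 pairs, k = ceiling(2.1) = 3 -> threshold 0.8, tie at 0.8 included
  expect_equal(es$threshold, 0.8)
  expect_equal(nrow(es$edges), 3L)
  es_all <- suppressWarnings(
    top_percentile_edges(matrix(c(NA, 0.5, 0.5, NA), 2, 2,
                                dimnames = list(c("a", "b"),
                                                c("a", "b"))), q = 0.05))
  expect_equal(nrow(es_all$edges), 1L)  # total tie selects everything
})

test_that("frequency weights count occurrences across edge sets", {
  mk <- function(pairs) {
    structure(list(dataset_id = "x", genes = c("a", "b", "c", "d"),
                   edges = data.frame(gene_a = pairs[[1]],
                                      gene_b = pairs[[2]],
                                      pcc = 1)),
              class = "correlation_edge_set")
  }
  es <- list(mk(list(c("a", "a"), c("b", "c"))),
             mk(list(c("a", "b"), c("b", "c"))),
             mk(list(c("a", "b"), c("b", "c"))))
  net <- build_frequency_network(es)
  w <- net$edges
  expect_equal(w$weight[w$gene_a == "a" & w$gene_b == "b"], 1.0)
  expect_equal(w$weight[w$gene_a == "a" & w$gene_b == "c"], 1 / 3)
  expect_equal(w$weight[w$gene_a == "b" & w$gene_b == "c"], 2 / 3)
  expect_false(any(w$gene_a == "c" & w$gene_b == "d"))  # never seen: absent
  expect_true(all(w$weight > 0 & w$weight <= 1))
  # disjoint universes are a hard error
  es2 <- es
  es2[[2]]$genes <- c("x", "y")
  expect_error(build_frequency_network(es2), "intersection")
})

test_that("a full clique is mined as one module and isolates are ignored", {
  clique <- c("a", "b", "c", "d", "e")
  net <- make_network(clique_edges(clique), genes = c(clique, "x", "y", "z"))
  mods <- lmqcm_mine(net, lmqcm_params(min_size = 5))
  expect_length(mods, 1L)
  expect_setequal(mods[[1]]$genes, clique)
  expect_equal(mods[[1]]$density, 1.0)
  expect_equal(lmqcm_mine(make_network(clique_edges(clique)[0, ]),
                          lmqcm_params()), list())
})

test_that("seeding requires gamma times the maximum weight", {
  # one strong clique (w_max = 1) plus an isolated weak edge at 0.65:
  # 0.65 < 0.7 * 1.0, so the weak edge cannot seed a module
  e <- rbind(clique_edges(c("a", "b", "c", "d", "e")),
             edge_df("y", "z", 0.65))
  net <- make_network(e)
  mods <- lmqcm_mine(net, lmqcm_params(min_size = 2))
  expect_length(mods, 1L)
  expect_setequal(mods[[1]]$genes, c("a", "b", "c", "d", "e"))
})

test_that("grown clusters merge when overlap exceeds beta", {
  w <- matrix(0.5, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(w) <- 0
  merged <- fgcnminer:::merge_clusters(
    list(c("a", "b", "c", "d", "e"), c("a", "b", "c", "d", "f")),
    beta = 0.4, w = w)
  expect_length(merged, 1L)
  expect_setequal(merged[[1]], letters[1:6])
  # overlap below beta stays separate
  kept <- fgcnminer:::merge_clusters(
    list(c("a", "b", "c", "d", "e"), c("e", "f", "g", "h", "i")),
    beta = 0.4,
    w = matrix(0.5, 9, 9, dimnames = list(letters[1:9], letters[1:9])))
  expect_length(kept, 2L)
})

test_that("mining is deterministic and invariant to weight scale", {
  set.seed(42)
  g <- random_graph(10)
  p <- lmqcm_params(min_size = 3)
  m1 <- lmqcm_mine(g$net, p)
  m2 <- lmqcm_mine(g$net, p)
  expect_identical(m1, m2)
  # multiplying all weights by a constant (raw counts vs frequencies)
  # changes nothing: gamma is relative to w_max
  scaled <- g$net
  scaled$edges$weight <- scaled$edges$weight * 3
  m3 <- lmqcm_mine(scaled, p)
  expect_identical(lapply(m1, `[[`, "genes"), lapply(m3, `[[`, "genes"))
})

test_that("output modules respect the merge and seed invariants", {
  set.seed(7)
  for (rep in 1:10) {
    g <- random_graph(sample(6:12, 1))
    p <- lmqcm_params(min_size = 2)
    mods <- lmqcm_mine(g$net, p)
    if (length(mods) < 2) next
    for (i in seq_along(mods))
      for (j in seq_along(mods))
        if (i < j) {
          ov <- length(intersect(mods[[i]]$genes, mods[[j]]$genes)) /
            min(length(mods[[i]]$genes), length(mods[[j]]$genes))
          expect_lte(ov, p$beta)
        }
  }
})

test_that("mining agrees with a naive loop-based implementation", {
  set.seed(99)
  for (rep in 1:30) {
    g <- random_graph(sample(4:12, 1))
    p <- lmqcm_params(min_size = 2)
    mods <- lmqcm_mine(g$net, p)
    w <- fgcnminer:::weight_matrix(g$net)
    oracle <- naive_mine(w, p$gamma, p$lam, p$t, p$beta, p$min_size)
    got <- lapply(mods, function(m) sort(m$genes))
    key <- function(x) paste(x, collapse = "|")
    expect_setequal(vapply(got, key, ""), vapply(oracle, key, ""))
  }
})

test_that("module tables carry rank, size, density and seed", {
  net <- make_network(clique_edges(c("a", "b", "c")))
  mods <- lmqcm_mine(net, lmqcm_params(min_size = 2))
  tabs <- modules_to_tables(mods)
  expect_equal(tabs$summary$size, 3L)
  expect_equal(tabs$summary$density, 1.0)
  expect_equal(nrow(tabs$members), 3L)
  expect_equal(tabs$members$rank_in_module, 1:3)
})
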
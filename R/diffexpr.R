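#' Differential-expression parameters
#'
#' @param q_thresh BH-adjusted significance level (default 0.05).
#' @param fc_thresh Linear fold-change bound; a gene is up/down only when
#'   `|log2fc| > log2(fc_thresh)` (strict; default 1.5).
#' @param transform `"log2p1"` to test on `log2(x + 1)` (applied only to
#'   linear-scale data), or `"none"`.
#' @return List of class `de_params`.
#' @export
de_params <- function(q_thresh = 0.05, fc_thresh = 1.5,
                      transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  stopifnot(q_thresh > 0, q_thresh < 1, fc_thresh > 1)
  structure(list(q_thresh = q_thresh, fc_thresh = fc_thresh,
                 transform = transform),
            class = "de_params")
}

## vectorized Welch t over rows of two matrices; returns statistic, df, p.
## Degenerate rows: both groups constant and equal -> p = 1; constant but
## different -> variance floored at eps so the direction still registers.
welch_rows <- function(xa, xb, eps = 1e-12) {
  na <- ncol(xa); nb <- ncol(xb)
  stopifnot(na >= 2L, nb >= 2L)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  zero_both <- va == 0 & vb == 0
  flat <- zero_both & ma == mb
  floored <- zero_both & ma != mb
  if (any(floored))
    message(sum(floored), " gene(s) constant within both groups but ",
            "different between them: variance floored at ", eps)
  va[zero_both] <- eps
  vb[zero_both] <- eps
  se2 <- va / na + vb / nb
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  stat[flat] <- 0
  p[flat] <- 1
  list(statistic = stat, df = df, p = p)
}

#' Welch's unequal-variance t-test for two groups
#'
#' Two-sided test with Welch-Satterthwaite degrees of freedom. Two identical
#' constant groups give p = 1 by convention; constant-but-different groups
#' are tested with a variance floor of 1e-12.
#'
#' @param xs Numeric vector, group A (at least 2 finite values).
#' @param ys Numeric vector, group B.
#' @return List with `statistic` and two-sided `p`.
#' @export
welch_t_two_group <- function(xs, ys) {
  if (length(xs) < 2L || length(ys) < 2L)
    stop("at least 2 values per group required")
  if (!all(is.finite(xs)) || !all(is.finite(ys)))
    stop("values must be finite")
  r <- welch_rows(matrix(xs, nrow = 1L), matrix(ys, nrow = 1L))
  list(statistic = unname(r$statistic), p = unname(r$p))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1 and mapped back to the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Two-group differential expression for one dataset
#'
#' Welch's t per gene on log2-scale values (group A is FN by convention),
#' BH correction across all tested genes of the dataset, and status calling
#' with strict q and fold-change gates:
#' up iff `q < q_thresh` and `log2fc > log2(fc_thresh)`; down symmetric;
#' otherwise ns. The fold change is the difference of group means on the
#' log2 scale.
#'
#' @param ds An [expression_dataset()].
#' @param comparison `"FN_vs_FP"` or `"FN_vs_NORMAL"`.
#' @param params A [de_params()] object.
#' @return data.frame of class `deg_table`: `gene_id`, `log2fc`, `p`, `q`,
#'   `status`; attribute `"comparison"`.
#' @export
de_two_group <- function(ds, comparison = "FN_vs_FP", params = de_params()) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(params, "de_params"))
  sel <- select_comparison_samples(ds, comparison)
  x <- ds$values
  if (params$transform == "log2p1" && ds$scale == "linear") x <- log2(x + 1)
  r <- welch_rows(x[, sel$a, drop = FALSE], x[, sel$b, drop = FALSE])
  log2fc <- rowMeans(x[, sel$a, drop = FALSE]) -
    rowMeans(x[, sel$b, drop = FALSE])
  q <- benjamini_hochberg(r$p)
  lfc_gate <- log2(params$fc_thresh)
  status <- rep("ns", nrow(x))
  status[q < params$q_thresh & log2fc > lfc_gate] <- "up"
  status[q < params$q_thresh & log2fc < -lfc_gate] <- "down"
  out <- data.frame(gene_id = rownames(x), log2fc = unname(log2fc),
                    p = unname(r$p), q = unname(q), status = status,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Summarize differential expression of a regulator's targets
#'
#' Counts how many of a regulator's target genes are differentially
#' expressed in a DEG table. The percentage is taken over the full target
#' list size (`n_targets_total`), not only the targets present in the
#' table, matching how target-list coverage is conventionally reported.
#'
#' @param tf_id Regulator identifier (reporting only).
#' @param targets Character vector of target gene ids (nonempty).
#' @param deg A `deg_table` from [de_two_group()].
#' @param n_targets_total Denominator for `pct_de`; defaults to
#'   `length(targets)`.
#' @return One-row data.frame: `tf_id`, `n_targets_total`,
#'   `n_targets_tested`, `n_de`, `n_up`, `n_down`, `pct_de`.
#' @export
target_de_summary <- function(tf_id, targets, deg,
                              n_targets_total = length(targets)) {
  stopifnot(length(targets) > 0L)
  hit <- deg[deg$gene_id %in% targets, , drop = FALSE]
  if (nrow(hit) == 0L)
    warning("no target of ", tf_id, " present in the DEG table")
  n_up <- sum(hit$status == "up")
  n_down <- sum(hit$status == "down")
  data.frame(tf_id = tf_id, n_targets_total = n_targets_total,
             n_targets_tested = nrow(hit), n_de = n_up + n_down,
             n_up = n_up, n_down = n_down,
             pct_de = 100 * (n_up + n_down) / n_targets_total,
             stringsAsFactors = FALSE)
}
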
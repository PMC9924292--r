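#' Construct a gene-level copy-number matrix
#'
#' Same layout as an expression matrix (genes x samples) with per-sample
#' fusion-status groups. The value scale (absolute CN or log-ratio) is
#' opaque: downstream analysis uses rank tests and mean differences, which
#' are monotone in either convention. Higher always means amplified.
#'
#' @param values Numeric genes x samples matrix with dimnames.
#' @param groups Named character vector sample -> FP/FN/OTHER/NORMAL.
#' @param scale Free-text scale tag (metadata only).
#' @return Object of class `cn_matrix`.
#' @export
cn_matrix <- function(values, groups, scale = "absolute") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene rownames and sample colnames")
  if (!all(is.finite(values))) stop("copy-number values must be finite")
  groups <- toupper(unlist(groups))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("sample(s) missing from the sample sheet: ",
         paste(missing, collapse = ", "))
  structure(list(values = values, groups = groups[colnames(values)],
                 scale = scale),
            class = "cn_matrix")
}

#' Wilcoxon rank-sum two-sided p-value
#'
#' Exact p by enumeration of the rank-sum distribution when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with midranks, tie correction and continuity correction.
#'
#' @param xs Numeric vector (nonempty).
#' @param ys Numeric vector (nonempty).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(xs, ys) {
  if (!length(xs) || !length(ys)) stop("empty group")
  ties <- anyDuplicated(c(xs, ys)) > 0L
  exact <- !ties && (length(xs) + length(ys)) <= 12L
  suppressWarnings(
    stats::wilcox.test(xs, ys, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Differential copy number between fusion groups
#'
#' Per-gene Wilcoxon rank-sum test between group A (FN) and group B, with
#' direction from the sign of the group-mean difference. A gene is called
#' amplified (or deleted) in A only when the sign agrees and the raw p is
#' below `alpha`; p-values are not multiplicity-corrected here, matching
#' the per-gene screen convention for small validation cohorts.
#'
#' @param cn A [cn_matrix()].
#' @param comparison `"FN_vs_FP"` or `"FN_vs_NORMAL"` (group A is FN).
#' @param alpha Raw-p significance cutoff (default 0.05).
#' @param location `"mean"` (default) or `"median"` for the direction call.
#' @return data.frame of class `diffcn_table`: `gene_id`, `p`, `mean_a`,
#'   `mean_b`, `mean_diff`, `significant`, `direction` in
#'   `{amp_in_FN, del_in_FN, none}`.
#' @export
differential_cn <- function(cn, comparison = "FN_vs_FP", alpha = 0.05,
                            location = c("mean", "median")) {
  stopifnot(inherits(cn, "cn_matrix"))
  location <- match.arg(location)
  b_group <- if (comparison == "FN_vs_FP") "FP" else "NORMAL"
  a <- names(cn$groups)[cn$groups == "FN"]
  b <- names(cn$groups)[cn$groups == b_group]
  if (length(a) < 2L || length(b) < 2L)
    stop("fewer than 2 samples in a comparison group")
  xa <- cn$values[, a, drop = FALSE]
  xb <- cn$values[, b, drop = FALSE]
  loc <- if (location == "mean") rowMeans else
    function(m) apply(m, 1L, stats::median)
  ma <- loc(xa); mb <- loc(xb)
  p <- vapply(seq_len(nrow(xa)), function(i)
    wilcoxon_rank_sum(xa[i, ], xb[i, ]), numeric(1L))
  sig <- p < alpha
  direction <- rep("none", nrow(xa))
  direction[sig & ma > mb] <- "amp_in_FN"
  direction[sig & ma < mb] <- "del_in_FN"
  out <- data.frame(gene_id = rownames(xa), p = p, mean_a = unname(ma),
                    mean_b = unname(mb), mean_diff = unname(ma - mb),
                    significant = sig, direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  class(out) <- c("diffcn_table", "data.frame")
  out
}

#' Module enrichment in differential copy number
#'
#' As [module_deg_enrichment()], with "significant differential CN" as the
#' marked gene set.
#'
#' @param module A `gene_module` or character vector of gene ids.
#' @param diffcn A `diffcn_table` from [differential_cn()].
#' @param universe Background gene ids.
#' @param alpha Raw-p significance cutoff (default 0.05).
#' @return One-row data.frame with the 2x2 counts, `odds_ratio`, `p`,
#'   `significant`.
#' @export
module_cnv_enrichment <- function(module, diffcn, universe, alpha = 0.05) {
  genes <- if (inherits(module, "gene_module")) module$genes else module
  id <- if (inherits(module, "gene_module")) module$module_id else NA
  genes <- intersect(genes, universe)
  cn_sig <- diffcn$gene_id[diffcn$significant]
  rec <- enrich_record(id, cn_sig, genes, universe)
  rec$significant <- rec$p < alpha
  rec
}

#' Copy-number / expression concordance of a module
#'
#' Flags each module gene for copy-number alteration and differential
#' expression in the same comparison and calls it concordant when both
#' point the same way (amplified & up, or deleted & down, in FN). Only the
#' gene intersection of the two tables is required; CN and expression may
#' come from different sample subsets of the same cohort.
#'
#' @param module A `gene_module` or character vector of gene ids.
#' @param diffcn A `diffcn_table`.
#' @param deg A `deg_table`.
#' @param annotation Optional [gene_annotation()]; when given, a `cytoband`
#'   column is attached.
#' @return data.frame, one row per module gene present in both tables:
#'   `gene_id`, `cn_p`, `cn_direction`, `log2fc`, `de_status`, `cn_amp`,
#'   `cn_del`, `mrna_up`, `mrna_down`, `concordant` (+ `cytoband`).
#'   Attribute `"summary"` holds `n_genes`, `n_cn_alt`, `n_de`,
#'   `n_concordant`.
#' @export
concordance <- function(module, diffcn, deg, annotation = NULL) {
  genes <- if (inherits(module, "gene_module")) module$genes else module
  common <- intersect(intersect(genes, diffcn$gene_id), deg$gene_id)
  if (!length(intersect(diffcn$gene_id, deg$gene_id)))
    stop("differential-CN and DEG tables share no gene identifiers")
  cn <- diffcn[match(common, diffcn$gene_id), , drop = FALSE]
  de <- deg[match(common, deg$gene_id), , drop = FALSE]
  out <- data.frame(
    gene_id = common,
    cn_p = cn$p,
    cn_direction = cn$direction,
    log2fc = de$log2fc,
    de_status = de$status,
    cn_amp = cn$direction == "amp_in_FN",
    cn_del = cn$direction == "del_in_FN",
    mrna_up = de$status == "up",
    mrna_down = de$status == "down",
    stringsAsFactors = FALSE)
  out$concordant <- (out$cn_amp & out$mrna_up) | (out$cn_del & out$mrna_down)
  if (!is.null(annotation))
    out$cytoband <- annotation$cytoband[match(out$gene_id,
                                              annotation$gene_id)]
  attr(out, "summary") <- c(
    n_genes = nrow(out),
    n_cn_alt = sum(out$cn_amp | out$cn_del),
    n_de = sum(out$mrna_up | out$mrna_down),
    n_concordant = sum(out$concordant))
  out
}
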
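#' Upper tail of the hypergeometric distribution
#'
#' `P[X >= a]` for `X ~ Hypergeom(N, K, n)`: the probability of drawing at
#' least `a` marked items when `n` items are drawn without replacement from
#' a universe of `N` containing `K` marked ones. This is the one-sided
#' (greater) Fisher exact p-value shared by all enrichment tests here.
#'
#' @param a Observed overlap (0 <= a <= min(K, n)).
#' @param K Number of marked items in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @return The exact tail probability.
#' @export
hypergeom_tail <- function(a, K, n, N) {
  if (any(a < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(a > pmin(K, n)))
    stop("inconsistent hypergeometric margins")
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

## one-sided (greater) enrichment record from set membership
## set: the "marked" genes (e.g. DEGs, band members, TF targets)
enrich_record <- function(subject, set, module_genes, universe) {
  set <- intersect(set, universe)
  module_genes <- intersect(module_genes, universe)
  a <- length(intersect(set, module_genes))
  b <- length(set) - a
  cc <- length(module_genes) - a
  d <- length(universe) - a - b - cc
  odds <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
  p <- hypergeom_tail(a, length(set), length(module_genes), length(universe))
  data.frame(subject = as.character(subject), a = a, b = b, c = cc, d = d,
             odds_ratio = odds, p = p, stringsAsFactors = FALSE)
}

#' Module enrichment in differentially expressed genes
#'
#' One-sided Fisher test of DEG membership against module membership over a
#' gene universe; significant when `p < alpha` (raw p, as is conventional
#' for a per-module screen).
#'
#' @param module A `gene_module` (or character vector of gene ids).
#' @param deg A `deg_table` from [de_two_group()].
#' @param universe Character vector of background gene ids; the module must
#'   be contained in it.
#' @param alpha Raw-p significance cutoff (default 0.05).
#' @return One-row data.frame with the 2x2 counts, `odds_ratio`, `p`,
#'   `significant`.
#' @export
module_deg_enrichment <- function(module, deg, universe, alpha = 0.05) {
  genes <- if (inherits(module, "gene_module")) module$genes else module
  id <- if (inherits(module, "gene_module")) module$module_id else NA
  if (length(setdiff(genes, universe)))
    stop("module contains genes outside the universe")
  degs <- deg$gene_id[deg$status != "ns"]
  rec <- enrich_record(id, degs, genes, universe)
  rec$significant <- rec$p < alpha
  rec
}

#' Cytoband enrichment of a module
#'
#' One cytoband at a time, a one-sided Fisher test of band membership vs
#' module membership, BH-corrected across all bands present in the
#' (annotated) universe. Genes without annotation are dropped from both
#' margins. Significant when `q < fdr`.
#'
#' @param module A `gene_module` or character vector of gene ids.
#' @param annotation A [gene_annotation()].
#' @param universe Background gene ids.
#' @param fdr BH FDR cutoff (default 0.05).
#' @return data.frame, one row per cytoband, sorted by `q` then `p` then
#'   band name: `subject` (band), 2x2 counts, `odds_ratio`, `p`, `q`,
#'   `significant`.
#' @export
cytoband_enrichment <- function(module, annotation, universe, fdr = 0.05) {
  genes <- if (inherits(module, "gene_module")) module$genes else module
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  dropped <- length(setdiff(universe, ann$gene_id))
  if (dropped)
    message("cytoband_enrichment: ", dropped,
            " unannotated gene(s) dropped from both margins")
  uni <- ann$gene_id
  mod <- intersect(genes, uni)
  bands <- sort(unique(ann$cytoband))
  recs <- do.call(rbind, lapply(bands, function(b) {
    enrich_record(b, ann$gene_id[ann$cytoband == b], mod, uni)
  }))
  recs$q <- benjamini_hochberg(recs$p)
  recs$significant <- recs$q < fdr
  recs[order(recs$q, recs$p, recs$subject), , drop = FALSE]
}

#' Upstream-regulator candidates for a module
#'
#' Screens every regulator in the TF-target map against a module using
#' three criteria: (1) the regulator is annotated as a transcription
#' factor; (2) its targets are enriched in the module by a one-sided Fisher
#' exact test at raw `p < p_thresh`; (3) its targets cover strictly more
#' than `min_coverage` of the module genes. Only regulators meeting all
#' three are flagged as candidates.
#'
#' @param module A `gene_module` or character vector of gene ids.
#' @param tf_map A [tf_target_map()].
#' @param annotation A [gene_annotation()] supplying the `is_tf` flag.
#' @param universe Background gene ids.
#' @param p_thresh Raw-p cutoff for criterion 2 (default 0.01).
#' @param min_coverage Coverage bound for criterion 3, strict (default
#'   0.10).
#' @return data.frame, one row per regulator, sorted by `p`: `subject`,
#'   `is_tf`, 2x2 counts, `odds_ratio`, `p`, `coverage`, `candidate`.
#' @export
regulator_enrichment <- function(module, tf_map, annotation, universe,
                                 p_thresh = 0.01, min_coverage = 0.10) {
  stopifnot(length(tf_map) > 0L)
  genes <- if (inherits(module, "gene_module")) module$genes else module
  mod <- intersect(genes, universe)
  tf_ids <- annotation$gene_id[annotation$is_tf]
  recs <- do.call(rbind, lapply(names(tf_map), function(reg) {
    rec <- enrich_record(reg, tf_map[[reg]], mod, universe)
    rec$is_tf <- reg %in% tf_ids
    rec$coverage <- if (length(mod)) rec$a / length(mod) else 0
    rec
  }))
  recs$candidate <- recs$is_tf & recs$p < p_thresh &
    recs$coverage > min_coverage
  recs[order(recs$p, recs$subject), , drop = FALSE]
}
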
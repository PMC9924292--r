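#' Modules significant in every discovery dataset
#'
#' Given per-dataset module-DEG enrichment tables, returns the module ids
#' whose enrichment is significant in all of them — the consensus rule used
#' to call fusion-status-associated modules.
#'
#' @param records List of data.frames with columns `subject` and
#'   `significant` (one per discovery dataset).
#' @return Sorted vector of module ids significant everywhere.
#' @export
intersect_significant_modules <- function(records) {
  stopifnot(length(records) >= 1L)
  sig <- lapply(records, function(r) r$subject[r$significant])
  out <- Reduce(intersect, sig)
  if (is.numeric(out) || !any(is.na(suppressWarnings(as.numeric(out)))))
    out <- out[order(as.numeric(out))]
  else out <- sort(out)
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one object.
#'
#' @param edge_q Top fraction of |PCC| pairs kept per dataset (default
#'   0.05).
#' @param log2_transform Correlate on `log2(x + 1)` for linear-scale
#'   datasets (default TRUE).
#' @param max_zero_frac Gene zero-fraction filter bound (default 0.5).
#' @param protein_coding_only Restrict to protein-coding genes (default
#'   TRUE).
#' @param lmqcm An [lmqcm_params()].
#' @param de A [de_params()].
#' @param module_deg_alpha Raw-p cutoff for module-DEG enrichment (default
#'   0.05).
#' @param cytoband_fdr BH FDR cutoff for cytoband enrichment (default
#'   0.05).
#' @param regulator_p Raw-p cutoff for regulator enrichment (default 0.01).
#' @param regulator_coverage Strict coverage bound for regulator candidacy
#'   (default 0.10).
#' @param cn_alpha Raw-p cutoff for differential CN (default 0.05).
#' @param comparison Two-group comparison for DE/CN (default
#'   `"FN_vs_FP"`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(edge_q = 0.05, log2_transform = TRUE,
                            max_zero_frac = 0.5, protein_coding_only = TRUE,
                            lmqcm = lmqcm_params(), de = de_params(),
                            module_deg_alpha = 0.05, cytoband_fdr = 0.05,
                            regulator_p = 0.01, regulator_coverage = 0.10,
                            cn_alpha = 0.05, comparison = "FN_vs_FP") {
  structure(list(edge_q = edge_q, log2_transform = log2_transform,
                 max_zero_frac = max_zero_frac,
                 protein_coding_only = protein_coding_only,
                 lmqcm = lmqcm, de = de,
                 module_deg_alpha = module_deg_alpha,
                 cytoband_fdr = cytoband_fdr, regulator_p = regulator_p,
                 regulator_coverage = regulator_coverage,
                 cn_alpha = cn_alpha, comparison = comparison),
            class = "pipeline_config")
}

write_tsv6 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, 6L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis
#'
#' Executes the end-to-end workflow: per-dataset gene filtering, pairwise
#' |PCC| and top-percentile edge selection, frequency-network construction,
#' lmQCM module mining, per-dataset differential expression, module-DEG
#' enrichment with consensus intersection, cytoband and upstream-regulator
#' enrichment per module, and — when a copy-number matrix is present —
#' differential CN, module CNV enrichment and CN/expression concordance on
#' the validation cohort. Every stage's table is written as TSV (numbers at
#' 6 significant digits), plus a YAML run manifest and a markdown summary.
#' Identical inputs and config give identical outputs.
#'
#' @param bundle A `cohort_bundle` or `sim_bundle`: needs `datasets`
#'   (discovery cohorts), `annotation`, and optionally `validation`,
#'   `cn`, `tf_map`.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param config A [pipeline_config()].
#' @return List of class `fgcn_result` with elements `filtered`, `network`,
#'   `modules`, `deg` (per dataset), `module_deg` (per dataset),
#'   `shared_modules`, `cytoband`, `regulators`, `diffcn`,
#'   `cnv_enrichment`, `concordance`, `universe`, `config`.
#' @export
run_full <- function(bundle, out_dir = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done (%.1fs elapsed)", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  ann <- bundle$annotation

  filtered <- stage("preprocess", lapply(bundle$datasets, filter_genes,
                                         max_zero_frac = config$max_zero_frac,
                                         protein_coding_only =
                                           config$protein_coding_only,
                                         annotation = ann))

  edge_sets <- stage("edges", lapply(filtered, function(ds) {
    corr <- suppressWarnings(
      pairwise_abs_pcc(ds, log2_transform = config$log2_transform))
    suppressWarnings(
      top_percentile_edges(corr, q = config$edge_q,
                           dataset_id = ds$dataset_id,
                           universe = rownames(ds$values)))
  }))

  network <- stage("network", build_frequency_network(edge_sets))
  modules <- stage("mine", lmqcm_mine(network, config$lmqcm))
  universe <- network$genes

  deg <- stage("diffexpr", {
    all_ds <- bundle$datasets
    if (!is.null(bundle$validation))
      all_ds <- c(all_ds,
                  stats::setNames(list(bundle$validation),
                                  bundle$validation$dataset_id))
    lapply(all_ds, function(ds) {
      ds_f <- filter_genes(ds, config$max_zero_frac,
                           config$protein_coding_only, ann)
      de_two_group(ds_f, config$comparison, config$de)
    })
  })

  module_deg <- stage("module_deg_enrichment", lapply(
    deg[names(bundle$datasets)], function(dt)
      do.call(rbind, lapply(modules, function(m) {
        rec <- module_deg_enrichment(intersect(m$genes, universe), dt,
                                     universe, config$module_deg_alpha)
        rec$subject <- m$module_id
        rec
      }))))
  shared <- if (length(modules))
    intersect_significant_modules(module_deg) else integer(0)

  cytoband <- stage("cytoband_enrichment", {
    recs <- lapply(modules, function(m) {
      r <- cytoband_enrichment(m, ann, universe, config$cytoband_fdr)
      r$module_id <- m$module_id
      r
    })
    if (length(recs)) do.call(rbind, recs) else NULL
  })

  regulators <- stage("regulator_enrichment", {
    if (is.null(bundle$tf_map) || !length(modules)) NULL
    else do.call(rbind, lapply(modules, function(m) {
      r <- regulator_enrichment(m, bundle$tf_map, ann, universe,
                                config$regulator_p,
                                config$regulator_coverage)
      r$module_id <- m$module_id
      r
    }))
  })

  diffcn <- cnv_enr <- conc <- NULL
  if (!is.null(bundle$cn)) {
    diffcn <- stage("differential_cn", {
      cn <- bundle$cn
      keep <- intersect(rownames(cn$values), universe)
      differential_cn(cn_matrix(cn$values[keep, , drop = FALSE], cn$groups,
                                cn$scale),
                      config$comparison, config$cn_alpha)
    })
    cnv_enr <- stage("module_cnv_enrichment", {
      if (!length(modules)) NULL
      else do.call(rbind, lapply(modules, function(m)
        module_cnv_enrichment(m, diffcn, universe, config$module_deg_alpha)))
    })
    val_deg <- if (!is.null(bundle$validation))
      deg[[bundle$validation$dataset_id]] else deg[[length(deg)]]
    conc <- stage("concordance", {
      out <- lapply(modules, function(m)
        concordance(m, diffcn, val_deg, ann))
      names(out) <- vapply(modules, `[[`, integer(1L), "module_id")
      out
    })
  } else {
    message("[cnv] skipped: no copy-number matrix supplied")
  }

  result <- structure(list(
    filtered = filtered, edge_sets = edge_sets, network = network,
    modules = modules, deg = deg, module_deg = module_deg,
    shared_modules = shared, cytoband = cytoband, regulators = regulators,
    diffcn = diffcn, cnv_enrichment = cnv_enr, concordance = conc,
    universe = universe, config = config), class = "fgcn_result")
  if (!is.null(out_dir)) write_result(result, bundle, out_dir)
  result
}

## write every stage table, a manifest and a markdown summary
write_result <- function(result, bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_network_tsv(result$network, file.path(out_dir, "network.tsv"))
  tabs <- modules_to_tables(result$modules)
  write_tsv6(tabs$members, file.path(out_dir, "modules.tsv"))
  write_tsv6(tabs$summary, file.path(out_dir, "module_summary.tsv"))
  for (id in names(result$deg))
    write_tsv6(result$deg[[id]],
               file.path(out_dir, paste0("deg_", id, ".tsv")))
  for (id in names(result$module_deg))
    write_tsv6(result$module_deg[[id]],
               file.path(out_dir, paste0("module_deg_", id, ".tsv")))
  if (!is.null(result$cytoband))
    write_tsv6(result$cytoband, file.path(out_dir, "cytoband_enrichment.tsv"))
  if (!is.null(result$regulators))
    write_tsv6(result$regulators,
               file.path(out_dir, "regulator_enrichment.tsv"))
  if (!is.null(result$diffcn))
    write_tsv6(result$diffcn, file.path(out_dir, "differential_cn.tsv"))
  if (!is.null(result$cnv_enrichment))
    write_tsv6(result$cnv_enrichment,
               file.path(out_dir, "module_cnv_enrichment.tsv"))
  if (!is.null(result$concordance)) {
    conc_all <- do.call(rbind, lapply(names(result$concordance), function(id) {
      df <- result$concordance[[id]]
      df$module_id <- id
      df
    }))
    write_tsv6(conc_all, file.path(out_dir, "concordance.tsv"))
  }
  manifest <- list(
    package = "fgcnminer",
    version = as.character(utils::packageVersion("fgcnminer")),
    config = rapply(unclass(result$config), unclass, how = "replace"),
    datasets = lapply(bundle$datasets, function(d)
      list(id = d$dataset_id, genes = nrow(d$values),
           samples = ncol(d$values))),
    cn_supplied = !is.null(bundle$cn),
    universe_size = length(result$universe),
    n_modules = length(result$modules))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  writeLines(summary_markdown(result), file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

summary_markdown <- function(result) {
  tabs <- modules_to_tables(result$modules)$summary
  lines <- c("# fGCN analysis summary", "",
             sprintf("- Genes in frequency network: %d",
                     length(result$universe)),
             sprintf("- Modules found: %d", length(result$modules)),
             sprintf("- Modules DEG-enriched in every discovery dataset: %s",
                     if (length(result$shared_modules))
                       paste(result$shared_modules, collapse = ", ")
                     else "none"), "")
  for (mid in result$shared_modules) {
    lines <- c(lines, sprintf("## Module %s", mid))
    sz <- tabs$size[tabs$module_id == mid]
    lines <- c(lines, sprintf("- size %d, density %.3f", sz,
                              tabs$density[tabs$module_id == mid]))
    if (!is.null(result$cytoband)) {
      cb <- result$cytoband[result$cytoband$module_id == mid &
                              result$cytoband$significant, , drop = FALSE]
      lines <- c(lines, sprintf("- enriched cytobands: %s",
                                if (nrow(cb)) paste(cb$subject,
                                                    collapse = ", ")
                                else "none"))
    }
    if (!is.null(result$regulators)) {
      rg <- result$regulators[result$regulators$module_id == mid &
                                result$regulators$candidate, , drop = FALSE]
      lines <- c(lines, sprintf("- candidate upstream regulators: %s",
                                if (nrow(rg)) paste(rg$subject,
                                                    collapse = ", ")
                                else "none"))
    }
    if (!is.null(result$concordance)) {
      s <- attr(result$concordance[[as.character(mid)]], "summary")
      lines <- c(lines, sprintf(
        "- CN-altered %d, DE %d, concordant %d of %d genes",
        s[["n_cn_alt"]], s[["n_de"]], s[["n_concordant"]], s[["n_genes"]]))
    }
    lines <- c(lines, "")
  }
  lines
}

#' @export
print.fgcn_result <- function(x, ...) {
  cat(sprintf("<fgcn_result> %d modules over %d genes; shared modules: %s\n",
              length(x$modules), length(x$universe),
              if (length(x$shared_modules))
                paste(x$shared_modules, collapse = ", ") else "none"))
  invisible(x)
}
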
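#' Construct an expression dataset
#'
#' Bundles one cohort's genes x samples expression matrix with per-sample
#' fusion-status group labels. This is the unit of input for per-cohort
#' correlation, edge selection and differential expression.
#'
#' @param dataset_id Single string identifying the cohort.
#' @param values Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). Values must be finite and
#'   non-negative on the linear scale.
#' @param groups Named character vector mapping every sample ID to one of
#'   `"FP"`, `"FN"`, `"OTHER"`, `"NORMAL"` (case-insensitive on input).
#' @param scale Either `"linear"` (e.g. normalized counts/intensities) or
#'   `"log2"` if the matrix is already log2-transformed. Metadata only: no
#'   transform is applied at construction time.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, values, groups,
                               scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifier: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifier: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale expression values must be non-negative")
  groups <- toupper(unlist(groups))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("sample(s) missing from the sample sheet: ",
         paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c("FP", "FN", "OTHER", "NORMAL"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  structure(
    list(dataset_id = dataset_id, values = values, groups = groups,
         scale = scale),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d genes x %d samples (%s scale)\n",
              x$dataset_id, nrow(x$values), ncol(x$values), x$scale))
  print(table(x$groups))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

## ---- readers -------------------------------------------------------------

#' Read a genes x samples matrix from TSV
#'
#' First column must be `gene_id`; remaining columns are samples. Decimal
#' point is '.', encoding UTF-8.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "gene_id")
    stop("expected TSV with first column 'gene_id': ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene row in ", basename(path), ": ",
         ids[duplicated(ids)][1L])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(mat), nrow(mat)))) &
                   !is.na(mat), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell in %s at row %d (gene %s), column '%s'",
                   basename(path), bad[1L, 1L], ids[bad[1L, 1L]],
                   colnames(mat)[bad[1L, 2L]]))
    stop("non-numeric values in ", path)
  }
  rownames(mat) <- ids
  mat
}

#' Read a GCT 1.2 matrix
#'
#' Skips the two GCT header lines and drops the `Description` column.
#'
#' @param path File path to a GCT 1.2 file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!grepl("^#1\\.2", header)) stop("not a GCT 1.2 file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = 2L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  drop <- c(1L, which(tolower(names(df)) == "description"))
  mat <- as.matrix(df[, -drop, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `dataset_id`, `group` (FP/FN/OTHER/NORMAL,
#' case-insensitive).
#'
#' @param path File path.
#' @return data.frame with normalized upper-case group labels.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "dataset_id", "group")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  df$group <- toupper(df$group)
  df
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `chromosome`, `start`, `end`, `cytoband`,
#' `gene_type`, `is_tf` (0/1). Cytoband strings must begin with the
#' chromosome name stripped of any "chr" prefix (e.g. chromosome `chr8`,
#' cytoband `8q24.3`).
#'
#' @param path File path.
#' @return data.frame of class `gene_annotation`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gene_annotation(df)
}

#' Validate a gene annotation data.frame
#'
#' @param df data.frame with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `cytoband`, `gene_type`, `is_tf`.
#' @return The validated data.frame, classed `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chromosome", "start", "end", "cytoband",
            "gene_type", "is_tf")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  if (any(df$start > df$end)) stop("annotation has start > end")
  arm_free <- sub("^chr", "", df$chromosome)
  if (!all(substr(df$cytoband, 1L, nchar(arm_free)) == arm_free))
    stop("cytoband strings must begin with the chromosome name (chr-free)")
  df$is_tf <- as.logical(as.integer(df$is_tf))
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a TF-target edge table
#'
#' Two-column TSV `regulator_id`, `target_id`. Returned as a named list of
#' target-gene character vectors, one element per regulator.
#'
#' @param path File path.
#' @return Named list: regulator id -> character vector of target gene ids.
#' @export
read_tf_targets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("regulator_id", "target_id") %in% names(df)))
    stop("TF-target table must have columns regulator_id, target_id")
  tf_target_map(split(df$target_id, df$regulator_id))
}

#' Validate a TF -> target mapping
#'
#' @param x Named list: regulator gene id -> character vector of targets.
#' @return The validated list, classed `tf_target_map`.
#' @export
tf_target_map <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(names(x) == ""))
    stop("tf map must be a named list of target vectors")
  x <- lapply(x, function(v) unique(as.character(v)))
  if (any(lengths(x) == 0L)) stop("tf map contains an empty target set")
  structure(x, class = "tf_target_map")
}

#' Read a full cohort bundle from disk
#'
#' Reads one or more expression matrices, a shared sample sheet, the gene
#' annotation, an optional TF-target table and an optional copy-number
#' matrix, validates everything and attaches group labels. Genes that do not
#' resolve against the annotation are logged and retained (they participate
#' in network mining but are excluded from cytoband enrichment).
#'
#' @param expression_paths Named character vector of TSV paths; names are
#'   dataset ids (unnamed paths fall back to file basenames).
#' @param sample_sheet_path Sample sheet TSV (see [read_sample_sheet()]).
#' @param annotation_path Gene annotation TSV.
#' @param tf_map_path Optional TF-target TSV.
#' @param cn_path Optional copy-number matrix TSV (same layout as expression).
#' @param cn_dataset_id Dataset id whose samples the CN matrix belongs to
#'   (defaults to the last expression dataset).
#' @return A list of class `cohort_bundle` with elements `datasets`
#'   (named list of [expression_dataset()]), `annotation`, `tf_map`, `cn`.
#' @export
read_cohort <- function(expression_paths, sample_sheet_path, annotation_path,
                        tf_map_path = NULL, cn_path = NULL,
                        cn_dataset_id = NULL) {
  sheet <- read_sample_sheet(sample_sheet_path)
  annotation <- read_gene_annotation(annotation_path)
  if (is.null(names(expression_paths)) || any(names(expression_paths) == ""))
    names(expression_paths) <- sub("\\.tsv$", "", basename(expression_paths))
  datasets <- lapply(names(expression_paths), function(id) {
    mat <- read_expression_matrix(expression_paths[[id]])
    rows <- sheet[sheet$dataset_id == id, , drop = FALSE]
    groups <- stats::setNames(rows$group, rows$sample_id)
    ds <- expression_dataset(id, mat, groups)
    message(sprintf("read_cohort: %s %d genes x %d samples [%s]",
                    id, nrow(mat), ncol(mat),
                    paste(sprintf("%s=%d", names(table(ds$groups)),
                                  table(ds$groups)), collapse = " ")))
    ds
  })
  names(datasets) <- names(expression_paths)
  unresolved <- setdiff(unique(unlist(lapply(datasets,
                                             function(d) rownames(d$values)))),
                        annotation$gene_id)
  if (length(unresolved))
    message("read_cohort: ", length(unresolved),
            " gene(s) absent from annotation (kept for network mining)")
  tf_map <- if (!is.null(tf_map_path)) read_tf_targets(tf_map_path) else NULL
  cn <- NULL
  if (!is.null(cn_path)) {
    if (is.null(cn_dataset_id))
      cn_dataset_id <- names(datasets)[length(datasets)]
    cn_mat <- read_expression_matrix(cn_path)
    rows <- sheet[sheet$dataset_id == cn_dataset_id, , drop = FALSE]
    cn <- cn_matrix(cn_mat, stats::setNames(rows$group, rows$sample_id))
  }
  structure(list(datasets = datasets, annotation = annotation,
                 tf_map = tf_map, cn = cn),
            class = "cohort_bundle")
}

## ---- filtering & comparison selection ------------------------------------

#' Filter genes by zero fraction and coding status
#'
#' Removes genes whose value is zero in more than `max_zero_frac` of the
#' samples (strictly greater; a gene zero in exactly half the samples is
#' retained) and, optionally, restricts to protein-coding genes per the
#' annotation. Genes absent from the annotation are treated as
#' non-protein-coding and therefore dropped when `protein_coding_only` is on.
#' Sample set and gene order are preserved; the operation is idempotent.
#'
#' @param ds An [expression_dataset()].
#' @param max_zero_frac Maximum tolerated zero fraction (default 0.5).
#' @param protein_coding_only Keep only `gene_type == "protein_coding"`.
#' @param annotation A [gene_annotation()]; required when
#'   `protein_coding_only` is `TRUE`.
#' @return The filtered `expression_dataset`.
#' @export
filter_genes <- function(ds, max_zero_frac = 0.5, protein_coding_only = TRUE,
                         annotation = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  zero_frac <- rowMeans(ds$values == 0)
  keep <- zero_frac <= max_zero_frac
  if (protein_coding_only) {
    if (is.null(annotation))
      stop("annotation required when protein_coding_only = TRUE")
    coding <- annotation$gene_id[annotation$gene_type == "protein_coding"]
    keep <- keep & rownames(ds$values) %in% coding
  }
  if (!any(keep)) stop("no genes survive filtering")
  out <- ds
  out$values <- ds$values[keep, , drop = FALSE]
  out
}

#' Select the samples entering a two-group comparison
#'
#' Applies the cohort-inclusion rules: samples labelled OTHER (non-canonical
#' fusions) are always excluded; NORMAL samples are excluded from the
#' FN-vs-FP comparison and FP samples from the FN-vs-normal comparison.
#'
#' @param ds An [expression_dataset()].
#' @param comparison `"FN_vs_FP"` or `"FN_vs_NORMAL"`; group A is always FN.
#' @return List with character vectors `a` and `b` of sample ids.
#' @export
select_comparison_samples <- function(ds,
                                      comparison = c("FN_vs_FP",
                                                     "FN_vs_NORMAL")) {
  comparison <- match.arg(comparison)
  b_group <- if (comparison == "FN_vs_FP") "FP" else "NORMAL"
  a <- names(ds$groups)[ds$groups == "FN"]
  b <- names(ds$groups)[ds$groups == b_group]
  if (length(a) < 2L)
    stop(sprintf("fewer than 2 FN samples in %s", ds$dataset_id))
  if (length(b) < 2L)
    stop(sprintf("fewer than 2 %s samples in %s", b_group, ds$dataset_id))
  list(a = a, b = b)
}
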
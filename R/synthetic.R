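#' Describe one planted co-expression module
#'
#' Planted modules are blocks of genes sharing a per-sample latent factor,
#' so their pairwise correlation recurs in every simulated cohort. A
#' `cnv`-driven module additionally sits on one contiguous synthetic
#' cytoband and gains copies in FN samples, with expression coupled to copy
#' number; a `tf`-driven module's genes additionally track a regulator gene
#' whose own expression is shifted between groups.
#'
#' @param module_id Short label used in the ground truth.
#' @param size Number of genes (>= 15 so mined modules clear the default
#'   minimum size with margin).
#' @param driver `"cnv"`, `"tf"` or `"neutral"`.
#' @param loading Factor loading per gene (default 1.0).
#' @param amp Copy-number gain in FN samples, cnv driver only (default +1
#'   copy).
#' @param coupling Expression shift per extra copy on the log2 scale, cnv
#'   driver only (default 0.5).
#' @param reg_strength Multiplier linking target expression to the
#'   regulator's expression deviation, tf driver only (default 1.0).
#' @param reg_shift Group shift of the regulator itself in FN, log2 units,
#'   tf driver only (default +1.5).
#' @return List of class `planted_module`.
#' @export
planted_module <- function(module_id, size, driver = c("neutral", "cnv",
                                                       "tf"),
                           loading = 1.0, amp = 1.0, coupling = 0.5,
                           reg_strength = 1.0, reg_shift = 1.5) {
  driver <- match.arg(driver)
  stopifnot(size >= 15L)
  structure(list(module_id = module_id, size = as.integer(size),
                 driver = driver, loading = loading, amp = amp,
                 coupling = coupling, reg_strength = reg_strength,
                 reg_shift = reg_shift),
            class = "planted_module")
}

#' Simulation configuration for the multi-cohort generator
#'
#' Defaults describe three discovery cohorts of 20 FN + 15 FP samples each
#' plus a smaller validation cohort of 8 FN + 4 FP samples with matched
#' copy-number data, 2000 genes, and three planted modules: one
#' copy-number-driven (30 genes on one cytoband, +1 copy in FN, 0.5 log2
#' units per copy), one TF-driven (25 genes tracking a shifted regulator),
#' and one neutral co-expression module (20 genes).
#'
#' @param n_datasets Number of discovery cohorts (default 3).
#' @param genes_total Total genes (default 2000).
#' @param samples_discovery Named vector `c(FN=, FP=)` per discovery cohort.
#' @param samples_validation Named vector `c(FN=, FP=)` for the validation
#'   cohort carrying the copy-number matrix.
#' @param modules List of [planted_module()] objects (disjoint by
#'   construction; sizes are honored in gene-index order).
#' @param noise_sd Residual log2 noise SD (default 0.5).
#' @param cn_noise_sd Copy-number measurement noise SD (default 0.05).
#' @param zero_entry_frac Fraction of entries zeroed among background genes
#'   to exercise the zero filter's tolerance (default 0.02).
#' @param n_decoy_zero_genes Background genes zeroed in >50% of samples so
#'   the zero filter provably removes them (default 40).
#' @param n_other_type_genes Background genes annotated as
#'   non-protein-coding (default 100).
#' @param n_decoy_tfs Decoy regulators with random target sets (default 5).
#' @param decoy_targets Targets per decoy regulator (default 50).
#' @param seed Integer seed; the single source of randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 3L, genes_total = 2000L,
                       samples_discovery = c(FN = 20L, FP = 15L),
                       samples_validation = c(FN = 8L, FP = 4L),
                       modules = list(
                         planted_module("M_CNV", 30L, "cnv"),
                         planted_module("M_TF", 25L, "tf"),
                         planted_module("M_NEUTRAL", 20L, "neutral")),
                       noise_sd = 0.5, cn_noise_sd = 0.05,
                       zero_entry_frac = 0.02, n_decoy_zero_genes = 40L,
                       n_other_type_genes = 100L, n_decoy_tfs = 5L,
                       decoy_targets = 50L, seed = 1L) {
  stopifnot(n_datasets >= 1L, genes_total >= 200L,
            all(samples_discovery >= 2L), all(samples_validation >= 2L),
            noise_sd >= 0, cn_noise_sd >= 0,
            zero_entry_frac >= 0, zero_entry_frac < 0.5)
  if (!all(vapply(modules, inherits, logical(1L), "planted_module")))
    stop("'modules' must be a list of planted_module objects")
  total_planted <- sum(vapply(modules, `[[`, integer(1L), "size"))
  if (total_planted + n_decoy_zero_genes + n_other_type_genes +
      n_decoy_tfs + length(modules) > genes_total / 2)
    stop("planted structure exceeds half the gene universe")
  structure(list(n_datasets = as.integer(n_datasets),
                 genes_total = as.integer(genes_total),
                 samples_discovery = samples_discovery,
                 samples_validation = samples_validation,
                 modules = modules, noise_sd = noise_sd,
                 cn_noise_sd = cn_noise_sd,
                 zero_entry_frac = zero_entry_frac,
                 n_decoy_zero_genes = as.integer(n_decoy_zero_genes),
                 n_other_type_genes = as.integer(n_other_type_genes),
                 n_decoy_tfs = as.integer(n_decoy_tfs),
                 decoy_targets = as.integer(decoy_targets),
                 seed = as.integer(seed)),
            class = "sim_config")
}

## deterministic gene layout: ids, chromosomes, cytobands, planted blocks
sim_layout <- function(config) {
  g <- config$genes_total
  width <- max(4L, nchar(as.character(g)))
  gene_id <- sprintf(paste0("G%0", width, "d"), seq_len(g))
  n_chr <- 10L
  per_chr <- ceiling(g / n_chr)
  chr_idx <- ((seq_len(g) - 1L) %/% per_chr) + 1L
  chromosome <- paste0("chr", chr_idx)
  band_size <- 40L
  within <- (seq_len(g) - 1L) %% per_chr
  cytoband <- paste0(chr_idx, "q", (within %/% band_size) + 1L)
  start <- within * 10000L + 1L
  end <- start + 9999L

  ## cnv modules are placed at the start of a fresh cytoband so the whole
  ## module is contiguous on one band; tf/neutral module genes (and
  ## regulators) are scattered evenly across the free gene indices so only
  ## copy-number-driven modules co-localize on cytobands
  assigned <- rep(NA_character_, g)
  regulator_of <- character(0)
  module_genes <- list()
  module_band <- character(0)
  band_of <- function(i) cytoband[i]
  next_free <- 1L
  for (m in config$modules) {
    if (m$driver != "cnv") next
    i <- next_free
    repeat {
      while (within[i] %% band_size != 0L) i <- i + 1L
      if (all(is.na(assigned[i:(i + m$size - 1L)])) &&
          band_of(i) == band_of(i + m$size - 1L)) break
      i <- i + band_size
    }
    idx <- i:(i + m$size - 1L)
    assigned[idx] <- m$module_id
    module_genes[[m$module_id]] <- gene_id[idx]
    module_band[m$module_id] <- band_of(idx[1L])
    next_free <- max(idx) + 1L
  }
  for (m in config$modules) {
    if (m$driver == "cnv") next
    free <- which(is.na(assigned))
    idx <- free[floor(seq(1L, length(free), length.out = m$size))]
    stopifnot(!anyDuplicated(idx))
    assigned[idx] <- m$module_id
    module_genes[[m$module_id]] <- gene_id[idx]
    if (m$driver == "tf") {
      ## regulator is a dedicated gene outside its own target module
      r <- setdiff(which(is.na(assigned)), idx)[1L]
      assigned[r] <- paste0(m$module_id, "_REG")
      regulator_of[m$module_id] <- gene_id[r]
    }
  }
  background <- which(is.na(assigned))
  decoy_zero <- gene_id[utils::tail(background, config$n_decoy_zero_genes)]
  background <- utils::head(background,
                            length(background) - config$n_decoy_zero_genes)
  other_type <- gene_id[utils::tail(background, config$n_other_type_genes)]
  background <- utils::head(background,
                            length(background) - config$n_other_type_genes)
  list(gene_id = gene_id, chromosome = chromosome, cytoband = cytoband,
       start = start, end = end, module_of = assigned,
       module_genes = module_genes, module_band = module_band,
       regulator_of = regulator_of, decoy_zero = decoy_zero,
       other_type = other_type, background = gene_id[background])
}

#' Generate a synthetic multi-cohort bundle with ground truth
#'
#' Simulates `n_datasets` discovery cohorts plus one validation cohort with
#' a matched gene-level copy-number matrix. Per cohort and sample, each
#' planted module draws a fresh latent factor shared by its genes (so
#' co-expression recurs across cohorts while the values do not); baseline
#' log2 expression is Uniform(3, 8) per gene; cnv-module genes gain `amp`
#' copies in FN samples with expression coupled at `coupling` log2 units
#' per copy; tf-module genes track their regulator's group-shifted
#' expression deviation. Matrices are emitted on the linear scale
#' (`2^log2expr`, rounded to 3 decimals) with a designated decoy gene set
#' zeroed in >50% of samples and a light sprinkle of background zeros.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_bundle`: `datasets` (named list of discovery
#'   [expression_dataset()]s), `validation` (expression_dataset), `cn`
#'   ([cn_matrix()] on the validation samples), `annotation`, `tf_map`,
#'   `truth` (list: `genes` data.frame with per-gene planted assignment,
#'   `modules` metadata incl. regulator and cytoband), `config`.
#' @export
generate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- sim_layout(config)
  g <- config$genes_total
  mu <- stats::runif(g, 3, 8)
  names(mu) <- lay$gene_id

  dataset_ids <- c(paste0("D", seq_len(config$n_datasets)), "VAL")
  sizes <- c(rep(list(config$samples_discovery), config$n_datasets),
             list(config$samples_validation))
  names(sizes) <- dataset_ids

  simulate_one <- function(id, n_fn, n_fp) {
    n_s <- n_fn + n_fp
    samples <- c(sprintf("%s_FN_%02d", id, seq_len(n_fn)),
                 sprintf("%s_FP_%02d", id, seq_len(n_fp)))
    groups <- stats::setNames(rep(c("FN", "FP"), c(n_fn, n_fp)), samples)
    is_fn <- groups == "FN"
    x <- matrix(mu, nrow = g, ncol = n_s,
                dimnames = list(lay$gene_id, samples))
    cn <- matrix(2 + stats::rnorm(g * n_s, 0, config$cn_noise_sd),
                 nrow = g, ncol = n_s,
                 dimnames = list(lay$gene_id, samples))
    for (m in config$modules) {
      idx <- lay$module_genes[[m$module_id]]
      f <- stats::rnorm(n_s)                       # fresh latent factor
      x[idx, ] <- x[idx, ] + m$loading * rep(f, each = length(idx))
      if (m$driver == "cnv") {
        cn[idx, is_fn] <- cn[idx, is_fn] + m$amp
        x[idx, ] <- x[idx, ] + m$coupling * (cn[idx, , drop = FALSE] - 2)
      } else if (m$driver == "tf") {
        reg <- lay$regulator_of[[m$module_id]]
        r_dev <- m$reg_shift * is_fn + stats::rnorm(n_s, 0, config$noise_sd)
        x[reg, ] <- mu[reg] + r_dev
        x[idx, ] <- x[idx, ] + m$reg_strength * rep(r_dev, each = length(idx))
      }
    }
    noise_rows <- setdiff(lay$gene_id,
                          unname(unlist(lay$regulator_of)))
    x[noise_rows, ] <- x[noise_rows, ] +
      stats::rnorm(length(noise_rows) * n_s, 0, config$noise_sd)
    lin <- round(2^x, 3L)
    ## designated decoys: zero in >50% of samples, deterministically many
    n_zero <- ceiling(0.6 * n_s)
    for (gene in lay$decoy_zero)
      lin[gene, sample.int(n_s, n_zero)] <- 0
    ## light zero sprinkle over background genes
    if (config$zero_entry_frac > 0 && length(lay$background)) {
      bg <- lin[lay$background, , drop = FALSE]
      hit <- stats::runif(length(bg)) < config$zero_entry_frac
      bg[hit] <- 0
      lin[lay$background, ] <- bg
    }
    list(ds = expression_dataset(id, lin, groups, scale = "linear"),
         cn = cn, groups = groups)
  }

  sims <- lapply(dataset_ids, function(id)
    simulate_one(id, sizes[[id]]["FN"], sizes[[id]]["FP"]))
  names(sims) <- dataset_ids

  annotation <- gene_annotation(data.frame(
    gene_id = lay$gene_id, chromosome = lay$chromosome,
    start = lay$start, end = lay$end, cytoband = lay$cytoband,
    gene_type = ifelse(lay$gene_id %in% lay$other_type, "other",
                       "protein_coding"),
    is_tf = as.integer(lay$gene_id %in% unname(unlist(lay$regulator_of))),
    stringsAsFactors = FALSE))

  ## TF map: planted regulators -> their module genes, plus decoys
  tf_map <- list()
  for (m in config$modules)
    if (m$driver == "tf")
      tf_map[[lay$regulator_of[[m$module_id]]]] <-
        lay$module_genes[[m$module_id]]
  decoy_pool <- setdiff(lay$background, names(tf_map))
  decoy_tfs <- utils::head(decoy_pool, config$n_decoy_tfs)
  annotation$is_tf[annotation$gene_id %in% decoy_tfs] <- TRUE
  for (tf in decoy_tfs)
    tf_map[[tf]] <- sample(setdiff(lay$gene_id, tf), config$decoy_targets)
  tf_map <- tf_target_map(tf_map)

  module_meta <- do.call(rbind, lapply(config$modules, function(m)
    data.frame(module_id = m$module_id, driver = m$driver, size = m$size,
               cytoband = if (m$driver == "cnv")
                 lay$module_band[[m$module_id]] else NA_character_,
               regulator = if (m$driver == "tf")
                 lay$regulator_of[[m$module_id]] else NA_character_,
               stringsAsFactors = FALSE)))
  target_genes <- unlist(lapply(config$modules[vapply(config$modules,
                                  `[[`, "", "driver") == "tf"],
                         function(m) lay$module_genes[[m$module_id]]))
  truth_genes <- data.frame(
    gene_id = lay$gene_id,
    module_id = ifelse(is.na(lay$module_of), "", lay$module_of),
    driver = vapply(lay$module_of, function(mid) {
      if (is.na(mid)) return("")
      hit <- module_meta$driver[module_meta$module_id == mid]
      if (length(hit)) hit else "regulator"
    }, character(1L), USE.NAMES = FALSE),
    cytoband = lay$cytoband,
    is_regulator_target = as.integer(lay$gene_id %in% target_genes),
    stringsAsFactors = FALSE)

  structure(list(
    datasets = lapply(sims[seq_len(config$n_datasets)], `[[`, "ds"),
    validation = sims$VAL$ds,
    cn = cn_matrix(round(sims$VAL$cn, 4L), sims$VAL$groups),
    annotation = annotation, tf_map = tf_map,
    truth = list(genes = truth_genes, modules = module_meta,
                 module_genes = lay$module_genes,
                 decoy_zero = lay$decoy_zero),
    config = config),
    class = "sim_bundle")
}

#' Write a simulated bundle as plain-text fixtures
#'
#' Emits one expression TSV per cohort (validation included), the sample
#' sheet, annotation, TF-target table, copy-number matrix, ground truth and
#' the generating configuration as YAML. Re-reading with [read_cohort()]
#' reproduces the objects; identical seeds give byte-identical files.
#'
#' @param bundle A `sim_bundle` from [generate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  write_mat <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  all_ds <- c(bundle$datasets, list(VAL = bundle$validation))
  for (id in names(all_ds))
    paths[paste0("expr_", id)] <-
      write_mat(all_ds[[id]]$values, file.path(dir,
                                               paste0("expr_", id, ".tsv")))
  sheet <- do.call(rbind, lapply(names(all_ds), function(id)
    data.frame(sample_id = names(all_ds[[id]]$groups), dataset_id = id,
               group = unname(all_ds[[id]]$groups),
               stringsAsFactors = FALSE)))
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["samples"] <- file.path(dir, "samples.tsv")
  paths["cn"] <- write_mat(bundle$cn$values, file.path(dir, "cn_VAL.tsv"))
  ann <- bundle$annotation
  ann$is_tf <- as.integer(ann$is_tf)
  utils::write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["annotation"] <- file.path(dir, "annotation.tsv")
  tf_df <- do.call(rbind, lapply(names(bundle$tf_map), function(reg)
    data.frame(regulator_id = reg, target_id = bundle$tf_map[[reg]],
               stringsAsFactors = FALSE)))
  utils::write.table(tf_df, file.path(dir, "tf_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["tf_map"] <- file.path(dir, "tf_targets.tsv")
  utils::write.table(bundle$truth$genes, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths["ground_truth"] <- file.path(dir, "ground_truth.tsv")
  cfg <- bundle$config
  cfg$modules <- lapply(cfg$modules, unclass)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  paths["config"] <- file.path(dir, "config.yaml")
  invisible(paths)
}
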
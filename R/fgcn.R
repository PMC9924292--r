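#' Absolute Pearson correlation between all gene pairs
#'
#' Computes |PCC| between every pair of genes across the samples of one
#' dataset. Genes with zero variance cannot be correlated and are excluded
#' from the result with a warning.
#'
#' @param ds An [expression_dataset()].
#' @param log2_transform Apply `log2(x + 1)` before correlating (only when
#'   the dataset is on the linear scale).
#' @return Symmetric numeric matrix of |PCC| with `NA` on the diagonal.
#' @export
pairwise_abs_pcc <- function(ds, log2_transform = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  x <- ds$values
  if (ncol(x) < 3L)
    stop("at least 3 samples required for pairwise correlation")
  if (log2_transform && ds$scale == "linear") x <- log2(x + 1)
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) excluded from correlation")
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2L) {
    ## degenerate input: no correlatable genes, hence no edges downstream
    return(matrix(numeric(0), 0L, 0L))
  }
  r <- abs(stats::cor(t(x)))
  diag(r) <- NA_real_
  r
}

#' Nearest-rank top-percentile threshold
#'
#' For a vector of edge strengths, returns the value at rank
#' `ceiling(q * n)` from the top: the weakest value still inside the top
#' `q` fraction. Selecting all values `>= threshold` keeps at least that
#' fraction; ties at the threshold are all included.
#'
#' @param values Numeric vector (no NAs).
#' @param q Fraction to keep from the top, in (0, 1].
#' @return The threshold value.
#' @export
percentile_threshold <- function(values, q = 0.05) {
  stopifnot(q > 0, q <= 1, length(values) > 0L, !anyNA(values))
  k <- ceiling(q * length(values))
  sort(values, decreasing = TRUE)[k]
}

#' Select the top-percentile co-expression edges of one dataset
#'
#' Keeps the gene pairs whose |PCC| lies in the top `q` fraction of all
#' off-diagonal values (nearest-rank threshold; ties included).
#'
#' @param corr Symmetric |PCC| matrix from [pairwise_abs_pcc()].
#' @param q Top fraction to keep (default 0.05, i.e. top 5 percentile).
#' @param dataset_id Optional id carried along for reporting.
#' @param universe Gene universe the edge set ranges over; defaults to the
#'   matrix's genes. Pass the dataset's full filtered gene list so that
#'   genes excluded from the correlation (zero variance) still count as
#'   nodes when universes are intersected across datasets.
#' @return List of class `correlation_edge_set` with elements `dataset_id`,
#'   `genes` (the universe), `edges` (data.frame `gene_a`, `gene_b`, `pcc`,
#'   lexicographic pair order), `threshold`, `q`.
#' @export
top_percentile_edges <- function(corr, q = 0.05, dataset_id = NA_character_,
                                 universe = rownames(corr)) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  genes <- rownames(corr)
  ut <- upper.tri(corr)
  vals <- corr[ut]
  if (length(vals) == 0L) {
    return(structure(list(dataset_id = dataset_id,
                          genes = if (is.null(universe)) character(0)
                                  else universe,
                          edges = data.frame(gene_a = character(),
                                             gene_b = character(),
                                             pcc = numeric()),
                          threshold = NA_real_, q = q),
                     class = "correlation_edge_set"))
  }
  if (length(vals) < 20L)
    warning("fewer than 20 gene pairs: percentile threshold is unstable")
  thr <- percentile_threshold(vals, q)
  idx <- which(ut & corr >= thr, arr.ind = TRUE)
  ga <- genes[idx[, 1L]]
  gb <- genes[idx[, 2L]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  ord <- order(ga, gb)
  edges <- data.frame(gene_a = ga[ord], gene_b = gb[ord],
                      pcc = corr[idx][ord], stringsAsFactors = FALSE)
  structure(list(dataset_id = dataset_id,
                 genes = if (is.null(universe)) genes else universe,
                 edges = edges, threshold = thr, q = q),
            class = "correlation_edge_set")
}

#' Build the cross-dataset frequency-weighted network
#'
#' Nodes are the intersection of the per-dataset gene universes; each pair's
#' weight is the fraction of datasets in which it was a top-percentile
#' co-expression edge. Pairs never selected are absent.
#'
#' @param edge_sets List of `correlation_edge_set` objects.
#' @param d Denominator for the frequency weight. Defaults to the total
#'   number of edge sets; set `d = "per_pair"` to divide each pair's count
#'   by the number of datasets containing both genes instead.
#' @return List of class `frequency_network` with `genes` (sorted node
#'   list), `n_datasets`, and `edges` (data.frame `gene_a`, `gene_b`,
#'   `count`, `weight`, lexicographic order).
#' @export
build_frequency_network <- function(edge_sets, d = NULL) {
  stopifnot(length(edge_sets) >= 1L)
  universes <- lapply(edge_sets, `[[`, "genes")
  genes <- sort(Reduce(intersect, universes))
  if (length(genes) == 0L)
    stop("empty intersection of gene universes across datasets")
  n_d <- length(edge_sets)
  keys <- unlist(lapply(edge_sets, function(es) {
    e <- es$edges
    keep <- e$gene_a %in% genes & e$gene_b %in% genes
    paste(e$gene_a[keep], e$gene_b[keep], sep = "\r")
  }))
  if (length(keys) == 0L) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        count = integer(), weight = numeric())
  } else {
    tab <- table(keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    ga <- vapply(parts, `[[`, "", 1L)
    gb <- vapply(parts, `[[`, "", 2L)
    count <- as.integer(tab)
    denom <- if (identical(d, "per_pair")) {
      ## number of datasets whose universe contains both endpoints
      vapply(seq_along(ga), function(i) {
        sum(vapply(universes, function(u)
          ga[i] %in% u && gb[i] %in% u, logical(1L)))
      }, integer(1L))
    } else if (is.null(d)) n_d else d
    ord <- order(ga, gb)
    edges <- data.frame(gene_a = ga[ord], gene_b = gb[ord],
                        count = count[ord],
                        weight = (count / denom)[ord],
                        stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, n_datasets = n_d, edges = edges),
            class = "frequency_network")
}

#' @export
print.frequency_network <- function(x, ...) {
  cat(sprintf("<frequency_network> %d genes, %d edges, %d datasets\n",
              length(x$genes), nrow(x$edges), x$n_datasets))
  invisible(x)
}

#' Write / read a frequency network as 3-column TSV
#'
#' @param net A `frequency_network`.
#' @param path Output TSV path (`gene_a  gene_b  weight`).
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  e <- net$edges[order(net$edges$gene_a, net$edges$gene_b), ]
  utils::write.table(
    data.frame(gene_a = e$gene_a, gene_b = e$gene_b,
               weight = signif(e$weight, 6L)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- lmQCM ---------------------------------------------------------------

#' lmQCM mining parameters
#'
#' @param gamma Seed-weight factor: an edge can seed a module only if its
#'   weight is at least `gamma * max(weight)` (default 0.7).
#' @param lam Density-decay factor lambda controlling how fast the admission
#'   threshold relaxes as the cluster grows (default 1.0).
#' @param t Size offset in the decay schedule (default 1.0).
#' @param beta Overlap ratio above which two grown clusters are merged
#'   (default 0.4).
#' @param min_size Minimum module size kept after merging (default 10).
#' @return List of class `lmqcm_params`.
#' @export
lmqcm_params <- function(gamma = 0.7, lam = 1.0, t = 1.0, beta = 0.4,
                         min_size = 10L) {
  stopifnot(gamma > 0, gamma <= 1, lam > 0, t >= 0, beta > 0, beta <= 1,
            min_size >= 2)
  structure(list(gamma = gamma, lam = lam, t = t, beta = beta,
                 min_size = as.integer(min_size)),
            class = "lmqcm_params")
}

## dense symmetric weight matrix over the network's node set
weight_matrix <- function(net) {
  n <- length(net$genes)
  w <- matrix(0, n, n, dimnames = list(net$genes, net$genes))
  if (nrow(net$edges)) {
    i <- match(net$edges$gene_a, net$genes)
    j <- match(net$edges$gene_b, net$genes)
    w[cbind(i, j)] <- net$edges$weight
    w[cbind(j, i)] <- net$edges$weight
  }
  w
}

## locally maximal seed edges: weight >= gamma * w_max and >= every edge
## sharing an endpoint (ties count as maximal); returned in descending
## weight, ties by lexicographic endpoint pair
lmqcm_seeds <- function(w, gamma) {
  node_max <- apply(w, 1L, max)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(idx[0, , drop = FALSE])
  wt <- w[idx]
  w_max <- max(wt)
  keep <- wt >= gamma * w_max &
    wt >= node_max[idx[, 1L]] & wt >= node_max[idx[, 2L]]
  idx <- idx[keep, , drop = FALSE]
  wt <- wt[keep]
  g <- rownames(w)
  a <- pmin(g[idx[, 1L]], g[idx[, 2L]])
  b <- pmax(g[idx[, 1L]], g[idx[, 2L]])
  idx[order(-wt, a, b), , drop = FALSE]
}

## grow one cluster from a seed edge; returns genes in admission order
lmqcm_grow <- function(w, seed_i, seed_j, lam, t) {
  g <- rownames(w)
  members <- c(seed_i, seed_j)
  sum_w <- w[seed_i, seed_j]
  s <- w[, seed_i] + w[, seed_j]        # connectivity of every vertex into C
  s[members] <- -Inf
  repeat {
    k <- length(members)
    m <- max(s)
    if (m <= 0) break
    cand <- which(s == m)
    v <- g[cand[order(g[cand])][1L]]    # lexicographic tie-break
    alpha <- 1 - 1 / (2 * lam * (k + t))
    dens <- 2 * sum_w / (k * (k - 1))
    if (m / k < alpha * dens) break     # first rejection stops growth
    members <- c(members, v)
    sum_w <- sum_w + m
    s <- s + w[, v]
    s[v] <- -Inf
  }
  members
}

cluster_density <- function(w, genes) {
  n <- length(genes)
  if (n < 2L) return(0)
  sub <- w[genes, genes]
  sum(sub[upper.tri(sub)]) * 2 / (n * (n - 1))
}

## order clusters by size desc, ties density desc, then first gene
order_clusters <- function(clusters, w) {
  sizes <- lengths(clusters)
  dens <- vapply(clusters, function(cl) cluster_density(w, cl), numeric(1L))
  first <- vapply(clusters, function(cl) sort(cl)[1L], character(1L))
  clusters[order(-sizes, -dens, first)]
}

## iteratively merge clusters whose overlap ratio |A.B|/min(|A|,|B|)
## exceeds beta; rescan from the largest after every merge
merge_clusters <- function(clusters, beta, w) {
  clusters <- clusters[!duplicated(lapply(clusters, sort))]
  repeat {
    clusters <- order_clusters(clusters, w)
    n <- length(clusters)
    merged <- FALSE
    for (i in seq_len(max(0L, n - 1L))) {
      for (j in seq.int(i + 1L, n)) {
        ov <- length(intersect(clusters[[i]], clusters[[j]])) /
          min(length(clusters[[i]]), length(clusters[[j]]))
        if (ov > beta) {
          clusters[[i]] <- c(clusters[[i]],
                             setdiff(clusters[[j]], clusters[[i]]))
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(clusters)
  }
}

#' Mine fGCN modules with the local maximal quasi-clique merger
#'
#' Grows dense subgraphs from locally maximal seed edges and merges
#' overlapping clusters. A vertex joins the current cluster C when its total
#' edge weight into C, divided by |C|, is at least
#' `(1 - 1/(2 * lam * (|C| + t))) * density(C)`; growth stops at the first
#' rejection. Grown clusters smaller than `min_size` are discarded, then
#' clusters whose overlap ratio exceeds `beta` are merged. All ties are
#' broken lexicographically, so output is deterministic.
#'
#' @param net A [build_frequency_network()] result (any weighted undirected
#'   network representation with `genes` and `edges` works).
#' @param params An [lmqcm_params()] object.
#' @param keep_grown Also return the pre-merge grown clusters (for
#'   diagnostics) as attribute `"grown"`.
#' @return List of `gene_module` objects, ranked by size (ties by density,
#'   then lexicographic first gene): each has `module_id`, `genes`
#'   (admission order, seed pair first where meaningful), `density`, `seed`.
#' @export
lmqcm_mine <- function(net, params = lmqcm_params(), keep_grown = FALSE) {
  stopifnot(inherits(params, "lmqcm_params"))
  if (length(net$genes) == 0L || nrow(net$edges) == 0L) return(list())
  w <- weight_matrix(net)
  seeds <- lmqcm_seeds(w, params$gamma)
  if (!nrow(seeds)) return(list())
  g <- rownames(w)
  grown <- vector("list", nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    i <- seeds[k, 1L]; j <- seeds[k, 2L]
    pair <- sort(c(g[i], g[j]))
    grown[[k]] <- lmqcm_grow(w, pair[1L], pair[2L], params$lam, params$t)
  }
  ## clusters below the minimum size are discarded before merging: tiny
  ## two-gene clusters sharing one gene with a large cluster would
  ## otherwise always exceed the overlap ratio and leak noise genes in
  candidates <- grown[lengths(grown) >= params$min_size]
  merged <- merge_clusters(candidates, params$beta, w)
  merged <- order_clusters(merged, w)
  modules <- lapply(seq_along(merged), function(r) {
    cl <- merged[[r]]
    structure(list(module_id = r, genes = cl,
                   density = cluster_density(w, cl),
                   seed = cl[1:2]),
              class = "gene_module")
  })
  if (keep_grown) attr(modules, "grown") <- grown
  modules
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("<gene_module> %d: %d genes, density %.3f (seed %s--%s)\n",
              x$module_id, length(x$genes), x$density, x$seed[1L],
              x$seed[2L]))
  invisible(x)
}

#' Tabulate mined modules
#'
#' @param modules List of `gene_module` objects from [lmqcm_mine()].
#' @return List of two data.frames: `members` (`module_id`,
#'   `rank_in_module`, `gene_id`) and `summary` (`module_id`, `size`,
#'   `density`, `seed_gene_a`, `seed_gene_b`).
#' @export
modules_to_tables <- function(modules) {
  if (!length(modules)) {
    return(list(
      members = data.frame(module_id = integer(), rank_in_module = integer(),
                           gene_id = character()),
      summary = data.frame(module_id = integer(), size = integer(),
                           density = numeric(), seed_gene_a = character(),
                           seed_gene_b = character())))
  }
  members <- do.call(rbind, lapply(modules, function(m)
    data.frame(module_id = m$module_id,
               rank_in_module = seq_along(m$genes),
               gene_id = m$genes, stringsAsFactors = FALSE)))
  summary <- do.call(rbind, lapply(modules, function(m)
    data.frame(module_id = m$module_id, size = length(m$genes),
               density = m$density, seed_gene_a = m$seed[1L],
               seed_gene_b = m$seed[2L], stringsAsFactors = FALSE)))
  list(members = members, summary = summary)
}
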
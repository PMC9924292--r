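# Independent oracles used to cross-check the package's statistics. These
# deliberately use brute-force enumeration / direct formulas, not the code
# paths under test.

# hypergeometric upper tail by direct summation of the pmf
hyper_tail_enum <- function(a, K, n, N) {
  hi <- min(K, n)
  if (a > hi) return(0)
  j <- a:hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# exact two-sided rank-sum p by enumerating all group assignments
wilcox_enum <- function(xs, ys) {
  nx <- length(xs)
  vals <- c(xs, ys)
  r <- rank(vals)
  splits <- utils::combn(length(vals), nx)
  w_all <- apply(splits, 2L, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# BH step-up by the direct formula q_(i) = min_{j>=i} p_(j) m / j
bh_enum <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

# build a frequency-network-shaped object from an explicit edge list
make_network <- function(edges, genes = sort(unique(c(edges$gene_a,
                                                      edges$gene_b)))) {
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  structure(list(genes = genes, n_datasets = NA_integer_, edges = edges),
            class = "frequency_network")
}

edge_df <- function(a, b, w) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(gene_a = a, gene_b = b, weight = w, stringsAsFactors = FALSE)
}

# a complete graph on `genes` with constant weight
clique_edges <- function(genes, w = 1) {
  idx <- utils::combn(genes, 2L)
  edge_df(idx[1L, ], idx[2L, ], rep(w, ncol(idx)))
}

# naive, loop-based quasi-clique miner used as the replay oracle: same
# pinned rules, written independently of the package implementation
naive_density <- function(w, set) {
  if (length(set) < 2L) return(0)
  tot <- 0
  for (i in seq_along(set))
    for (j in seq_along(set))
      if (i < j) tot <- tot + w[set[i], set[j]]
  2 * tot / (length(set) * (length(set) - 1))
}

naive_grow <- function(w, u, v, lam, t) {
  genes <- rownames(w)
  C <- c(u, v)
  repeat {
    outside <- setdiff(genes, C)
    S <- vapply(outside, function(x) sum(w[x, C]), numeric(1L))
    S <- S[S > 0]
    if (!length(S)) break
    best <- sort(names(S)[S == max(S)])[1L]
    k <- length(C)
    alpha <- 1 - 1 / (2 * lam * (k + t))
    if (S[[best]] / k < alpha * naive_density(w, C)) break
    C <- c(C, best)
  }
  C
}

naive_mine <- function(w, gamma, lam, t, beta, min_size) {
  genes <- rownames(w)
  wmax <- max(w)
  if (wmax <= 0) return(list())
  seeds <- list()
  for (i in seq_along(genes))
    for (j in seq_along(genes))
      if (i < j && w[i, j] > 0 && w[i, j] >= gamma * wmax &&
          w[i, j] >= max(w[i, ]) && w[i, j] >= max(w[j, ]))
        seeds[[length(seeds) + 1L]] <-
          list(u = genes[i], v = genes[j], w = w[i, j])
  if (!length(seeds)) return(list())
  ord <- order(-vapply(seeds, `[[`, numeric(1L), "w"),
               vapply(seeds, `[[`, "", "u"),
               vapply(seeds, `[[`, "", "v"))
  grown <- lapply(seeds[ord], function(s) naive_grow(w, s$u, s$v, lam, t))
  grown <- grown[!duplicated(lapply(grown, sort))]
  grown <- grown[lengths(grown) >= min_size]
  if (!length(grown)) return(list())
  repeat {
    sizes <- lengths(grown)
    dens <- vapply(grown, function(cl) naive_density(w, cl), numeric(1L))
    first <- vapply(grown, function(cl) sort(cl)[1L], character(1L))
    grown <- grown[order(-sizes, -dens, first)]
    hit <- NULL
    for (i in seq_along(grown)) {
      for (j in seq_along(grown)) {
        if (i >= j) next
        ov <- length(intersect(grown[[i]], grown[[j]])) /
          min(length(grown[[i]]), length(grown[[j]]))
        if (ov > beta) { hit <- c(i, j); break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    grown[[hit[1L]]] <- union(grown[[hit[1L]]], grown[[hit[2L]]])
    grown[[hit[2L]]] <- NULL
  }
  grown <- grown[lengths(grown) >= min_size]
  lapply(grown, sort)
}

# a random weighted graph as weight matrix + network object
random_graph <- function(n, p_edge = 0.5) {
  genes <- sprintf("n%02d", seq_len(n))
  idx <- utils::combn(n, 2L)
  on <- stats::runif(ncol(idx)) < p_edge
  if (!any(on)) on[1L] <- TRUE
  e <- edge_df(genes[idx[1L, on]], genes[idx[2L, on]],
               stats::runif(sum(on)))
  list(net = make_network(e, genes))
}

# small simulation config that keeps unit tests fast
small_sim_config <- function(seed = 1L, ...) {
  sim_config(genes_total = 600L, n_decoy_zero_genes = 10L,
             n_other_type_genes = 20L, n_decoy_tfs = 2L,
             decoy_targets = 25L, seed = seed, ...)
}

best_jaccard <- function(modules, truth_genes) {
  if (!length(modules)) return(0)
  max(vapply(modules, function(m) {
    length(intersect(m$genes, truth_genes)) /
      length(union(m$genes, truth_genes))
  }, numeric(1L)))
}
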
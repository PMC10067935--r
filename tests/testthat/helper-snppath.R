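# Shared fixtures and independent oracles used across the suite.

# small long-format SNP table builder
make_snps <- function(snp_id, chrom = "1", pos = 1000L, ancestry = "EA",
                      consequence = "intron_variant", assoc_p = 1e-5) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             ancestry = ancestry, assoc_p = assoc_p,
             consequence = consequence, stringsAsFactors = FALSE)
}

# igraph from an explicit undirected edge list over named vertices
make_graph <- function(edges, vertices = NULL) {
  if (is.null(vertices)) vertices <- sort(unique(unlist(edges)))
  igraph::graph_from_data_frame(
    data.frame(from = vapply(edges, `[[`, character(1), 1),
               to = vapply(edges, `[[`, character(1), 2)),
    directed = FALSE,
    vertices = data.frame(name = vertices))
}

clique_edges <- function(members) {
  pairs <- utils::combn(members, 2)
  lapply(seq_len(ncol(pairs)), function(i) pairs[, i])
}

# Adjusted Rand index between two label vectors (independent of any
# clustering package).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Brute-force one-sided hypergeometric upper tail via log-binomials,
# independent of phyper.
hyper_tail_oracle <- function(a, K, N, n) {
  ks <- a:min(K, n)
  ks <- ks[n - ks <= N - K]
  if (length(ks) == 0) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Brute-force MCODE vertex weight: peel the closed neighborhood by hand
# (no igraph::coreness) to find the highest k-core and its density.
mcode_weight_oracle <- function(adj_mat, v) {
  deg <- rowSums(adj_mat)
  if (deg[v] < 2) return(0)
  nbhd <- sort(unique(c(v, which(adj_mat[v, ] > 0))))
  best_k <- 0; best_density <- 0
  for (k in seq_len(length(nbhd))) {
    keep <- nbhd
    repeat {
      sub <- adj_mat[keep, keep, drop = FALSE]
      low <- rowSums(sub) < k
      if (!any(low)) break
      keep <- keep[!low]
      if (length(keep) == 0) break
    }
    if (length(keep) == 0) break
    sub <- adj_mat[keep, keep, drop = FALSE]
    nk <- length(keep)
    best_k <- k
    best_density <- if (nk < 2) 0 else sum(sub) / (nk * (nk - 1))
  }
  best_k * best_density
}

# Independent step-by-step reimplementation of the KS-like random-walk
# score from the written formulas (explicit loops, no vectorization
# shared with the package implementation).
gsva_oracle <- function(expr, set, tau = 1) {
  p <- nrow(expr); n <- ncol(expr)
  genes <- rownames(expr)
  z <- matrix(0, p, n, dimnames = dimnames(expr))
  for (i in seq_len(p)) {
    h <- max(stats::sd(expr[i, ]) / 4, 1e-8)
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) {
        acc <- acc + stats::pnorm((expr[i, j] - expr[i, k]) / h)
      }
      z[i, j] <- acc / n
    }
  }
  scores <- numeric(n)
  m <- length(set)
  for (j in seq_len(n)) {
    ord <- order(-z[, j], genes)
    rank_of <- integer(p)
    rank_of[ord] <- seq_len(p)
    r <- abs(p / 2 - rank_of)
    denom <- sum(r[match(set, genes)]^tau)
    v <- 0; vmax <- 0; vmin <- 0
    for (t in seq_len(p)) {
      g <- genes[ord[t]]
      if (g %in% set) {
        v <- v + abs(p / 2 - t)^tau / denom
      } else {
        v <- v - 1 / (p - m)
      }
      if (v > vmax) vmax <- v
      if (v < vmin) vmin <- v
    }
    scores[j] <- vmax + vmin
  }
  stats::setNames(scores, colnames(expr))
}
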
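# Protein-protein interaction subnetworks, a degree-based connectivity
# enrichment gate, MCODE molecular-complex clustering (implemented from
# scratch on top of igraph primitives), cluster metastructures, and the
# random-gene-cohort null comparison.

#' Build an induced PPI subnetwork
#'
#' Induces the subgraph of the confidence-filtered interaction network on
#' a gene set. Edges with `combined_score` below `min_score` are dropped;
#' duplicate and reciprocal rows are collapsed (keeping the maximum
#' score); self-loops are removed. Selected genes absent from the edge
#' table do not become vertices (only genes present on the interaction
#' platform enter the network).
#'
#' @param genes Character vector of gene symbols.
#' @param edge_table Data.frame with `node1`, `node2`, `combined_score`
#'   (STRING convention, scores in \[0, 1000\]), or a path readable by
#'   [read_string_edges()].
#' @param min_score Minimum combined score (default 400, the conventional
#'   "medium confidence" cut).
#' @return An undirected simple `igraph` with vertex names and a `score`
#'   edge attribute.
#' @export
build_subnetwork <- function(genes, edge_table, min_score = 400) {
  if (is.character(edge_table) && length(edge_table) == 1) {
    edge_table <- read_string_edges(edge_table)
  }
  stopifnot(all(c("node1", "node2", "combined_score") %in%
                  names(edge_table)))
  if (any(edge_table$combined_score < 0 | edge_table$combined_score > 1000)) {
    stop("combined_score outside [0, 1000]", call. = FALSE)
  }
  nodes <- unique(c(edge_table$node1, edge_table$node2))
  keep_genes <- sort(intersect(unique(genes), nodes))
  e <- edge_table[edge_table$node1 %in% keep_genes &
                    edge_table$node2 %in% keep_genes &
                    edge_table$combined_score >= min_score &
                    edge_table$node1 != edge_table$node2, , drop = FALSE]
  if (nrow(e) > 0) {
    # canonical order collapses reciprocal duplicates
    a <- pmin(e$node1, e$node2)
    b <- pmax(e$node1, e$node2)
    key <- paste(a, b, sep = "\r")
    score <- tapply(e$combined_score, key, max)
    pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
    g <- igraph::graph_from_data_frame(
      data.frame(from = pairs[, 1], to = pairs[, 2],
                 score = as.numeric(score), stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = keep_genes, stringsAsFactors = FALSE))
  } else {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(keep_genes), name = keep_genes)
  }
  g
}

#' Connectivity-enrichment p-value of a subnetwork
#'
#' Tests whether the subnetwork has more edges than expected for the same
#' genes under a degree-preserving (Chung-Lu) null derived from the
#' background network: the expected edge count is
#' \eqn{\lambda = \sum_{u<v} \min(1, k_u k_v / 2m)} over node pairs of
#' the subnetwork, with degrees and edge count taken from the background,
#' and the p-value is the upper tail of a Poisson with mean
#' \eqn{\lambda} at the observed edge count. This approximates the
#' STRING platform's (unpublished) internal null; the quality-control
#' gate keeps a subnetwork only when p is strictly below `gate`
#' (default 1e-16).
#'
#' @param sub Subnetwork (`igraph`), nodes a subset of `background`'s.
#' @param background Background interaction network (`igraph`).
#' @param gate Strict gate threshold (default `1e-16`).
#' @return List with `p`, `lambda`, `observed`, `gate`, `passes`.
#' @export
ppi_enrichment_p <- function(sub, background, gate = 1e-16) {
  sub_nodes <- igraph::V(sub)$name
  if (!all(sub_nodes %in% igraph::V(background)$name)) {
    stop("subnetwork nodes must be a subset of the background network",
         call. = FALSE)
  }
  obs <- igraph::ecount(sub)
  if (length(sub_nodes) < 2) {
    return(list(p = 1, lambda = 0, observed = obs, gate = gate,
                passes = FALSE))
  }
  deg <- igraph::degree(background)[sub_nodes]
  m <- igraph::ecount(background)
  if (m == 0) {
    lambda <- 0
  } else {
    probs <- outer(deg, deg) / (2 * m)
    probs[probs > 1] <- 1  # pmin(1, .) would drop the dim attributes
    lambda <- sum(probs[upper.tri(probs)])
  }
  p <- if (obs == 0) 1 else
    stats::ppois(obs - 1, lambda, lower.tail = FALSE)
  list(p = p, lambda = lambda, observed = obs, gate = gate,
       passes = p < gate)
}

# Highest k-core of a graph: k is the maximum coreness present; returns
# list(k, n, density) of the induced subgraph on vertices with coreness
# == k (empty graph -> k = 0).
highest_kcore <- function(g) {
  if (igraph::vcount(g) == 0) return(list(k = 0, n = 0L, density = 0))
  cores <- igraph::coreness(g)
  k <- max(cores)
  core_g <- igraph::induced_subgraph(g, which(cores == k))
  n <- igraph::vcount(core_g)
  dens <- if (n < 2) 0 else 2 * igraph::ecount(core_g) / (n * (n - 1))
  list(k = k, n = n, density = dens)
}

#' MCODE vertex weights
#'
#' For each vertex, the weight is `k * density` of the highest k-core of
#' the graph induced on the vertex's closed neighborhood (the vertex plus
#' its neighbors), with density `2e/(n(n-1))`. Vertices with degree below
#' `degree_cutoff` get weight 0.
#'
#' @param net Simple undirected `igraph` with vertex names.
#' @param degree_cutoff Minimum degree for a nonzero weight (default 2).
#' @return Named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(net, degree_cutoff = 2) {
  nv <- igraph::vcount(net)
  w <- stats::setNames(numeric(nv), igraph::V(net)$name)
  if (nv == 0) return(w)
  deg <- igraph::degree(net)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  for (i in seq_len(nv)) {
    if (deg[i] < degree_cutoff) next
    nbhd <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(net, nbhd)
    core <- highest_kcore(sub)
    w[i] <- core$k * core$density
  }
  w
}

#' MCODE molecular-complex clustering
#'
#' From-scratch implementation of the MCODE graph-clustering algorithm:
#' \enumerate{
#'   \item \emph{Vertex weighting}: weight = core number times core
#'     density of the highest k-core of each vertex's closed
#'     neighborhood ([mcode_vertex_weights()]).
#'   \item \emph{Complex prediction}: seed at the highest-weight
#'     unassigned vertex and grow breadth-first, including neighbors
#'     whose weight is at least `(1 - node_score_cutoff)` times the seed
#'     weight, up to `max_depth` steps from the seed; vertices already in
#'     a complex are never reused.
#'   \item \emph{Post-processing}: complexes lacking a `k_core`-core are
#'     discarded; with `haircut`, members outside the complex's 2-core
#'     (i.e. iteratively degree-1 members) are removed.
#' }
#' Ties in seed selection and traversal order are broken
#' lexicographically by vertex name, so the output is deterministic.
#' Complexes are scored as seed weight times member count and returned
#' in decreasing score order.
#'
#' @param net Simple undirected `igraph` with vertex names.
#' @param degree_cutoff,node_score_cutoff,k_core,max_depth,haircut,fluff
#'   MCODE parameters; defaults are the conventional plugin defaults
#'   (2, 0.2, 2, 100, TRUE, FALSE). `fluff` is accepted for interface
#'   completeness but only `FALSE` is implemented.
#' @return List of class `mcode_result`; each element is a
#'   `cluster_report` list with `id`, `members` (sorted), `seed`,
#'   `seed_weight`, `score`, `size`.
#' @export
mcode <- function(net, degree_cutoff = 2, node_score_cutoff = 0.2,
                  k_core = 2, max_depth = 100, haircut = TRUE,
                  fluff = FALSE) {
  if (fluff) stop("fluff post-processing is not implemented", call. = FALSE)
  nv <- igraph::vcount(net)
  if (nv == 0) return(structure(list(), class = "mcode_result"))
  stopifnot(!igraph::is_directed(net))
  names_v <- igraph::V(net)$name
  w <- mcode_vertex_weights(net, degree_cutoff = degree_cutoff)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  assigned <- rep(FALSE, nv)
  order_idx <- order(-w, names_v)
  complexes <- list()
  for (seed in order_idx) {
    if (assigned[seed] || w[seed] <= 0) next
    threshold <- (1 - node_score_cutoff) * w[seed]
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        nbrs <- as.integer(adj[[v]])
        nbrs <- nbrs[order(names_v[nbrs])]
        for (u in nbrs) {
          if (!assigned[u] && w[u] >= threshold) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    complexes[[length(complexes) + 1]] <-
      list(seed = seed, members = members)
  }
  # post-processing: k_core filter, then haircut (= keep the 2-core)
  reports <- list()
  for (cx in complexes) {
    sub <- igraph::induced_subgraph(net, cx$members)
    cores <- igraph::coreness(sub)
    if (max(c(0, cores)) < k_core) next
    keep <- igraph::V(sub)$name
    if (haircut) keep <- keep[cores >= 2]
    if (length(keep) == 0) next
    seed_name <- names_v[cx$seed]
    reports[[length(reports) + 1]] <- structure(
      list(id = NA_integer_, members = sort(keep), seed = seed_name,
           seed_weight = unname(w[cx$seed]),
           score = unname(w[cx$seed]) * length(keep),
           size = length(keep)),
      class = "cluster_report")
  }
  if (length(reports) > 0) {
    ord <- order(-vapply(reports, `[[`, numeric(1), "score"),
                 vapply(reports, function(r) r$members[[1]], character(1)))
    reports <- reports[ord]
    for (i in seq_along(reports)) reports[[i]]$id <- i
  }
  structure(reports, class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(length(x), "MCODE cluster(s)\n")
  for (r in x) {
    cat(sprintf("  #%d: %d genes, seed %s (weight %.3f), score %.2f\n",
                r$id, r$size, r$seed, r$seed_weight, r$score))
  }
  invisible(x)
}

#' Cluster metastructure statistics
#'
#' For each cluster: size, intra-cluster edge count, and inter-cluster
#' edge count (edges from the cluster to any other cluster). The edge
#' conservation identity (sum of intra edges + pairwise inter edges +
#' edges incident to unclustered vertices = total edges) is asserted.
#'
#' @param clusters An `mcode_result` (or list of member vectors).
#' @param net The network the clusters were derived from.
#' @return Data.frame (`cluster`, `size`, `intra`, `inter`) with the
#'   pairwise inter-cluster count matrix attached as attribute
#'   `inter_matrix` and unclustered-incident edge count as
#'   `unclustered_incident`.
#' @export
metastructure <- function(clusters, net) {
  members <- lapply(clusters, function(x) if (is.list(x)) x$members else x)
  k <- length(members)
  assign_of <- stats::setNames(
    rep(seq_len(k), lengths(members)), unlist(members))
  el <- igraph::as_edgelist(net, names = TRUE)
  c1 <- assign_of[el[, 1]]
  c2 <- assign_of[el[, 2]]
  intra <- integer(k)
  inter_mat <- matrix(0L, k, k)
  unclustered_incident <- 0L
  if (nrow(el) > 0) {
    for (e in seq_len(nrow(el))) {
      a <- c1[[e]]; b <- c2[[e]]
      if (is.na(a) || is.na(b)) {
        unclustered_incident <- unclustered_incident + 1L
      } else if (a == b) {
        intra[a] <- intra[a] + 1L
      } else {
        inter_mat[a, b] <- inter_mat[a, b] + 1L
        inter_mat[b, a] <- inter_mat[b, a] + 1L
      }
    }
  }
  stopifnot(sum(intra) + sum(inter_mat) / 2 + unclustered_incident ==
              igraph::ecount(net))
  out <- data.frame(cluster = seq_len(k),
                    size = lengths(members),
                    intra = intra,
                    inter = as.integer(rowSums(inter_mat)))
  attr(out, "inter_matrix") <- inter_mat
  attr(out, "unclustered_incident") <- unclustered_incident
  out
}

#' Compare real and random-cohort cluster metastructures
#'
#' Welch's unequal-variance t-test per metric (cluster size, intra- and
#' inter-cluster connections) between the clusters of a real gene-set
#' network and those of an equivalently sized random gene cohort, with
#' 95% confidence intervals on the mean difference. At least two
#' clusters are required on each side.
#'
#' @param real_stats,random_stats Metastructure tables from
#'   [metastructure()].
#' @param metrics Metrics to compare (default size, intra, inter).
#' @return Data.frame: `metric`, `mean_real`, `mean_random`, `t`, `df`,
#'   `p`, `ci_lo`, `ci_hi`.
#' @export
compare_to_random <- function(real_stats, random_stats,
                              metrics = c("size", "intra", "inter")) {
  rows <- lapply(metrics, function(mname) {
    a <- real_stats[[mname]]
    b <- random_stats[[mname]]
    if (length(a) < 2 || length(b) < 2) {
      stop("fewer than 2 clusters per side for metric '", mname, "'",
           call. = FALSE)
    }
    wt <- welch_t(a, b)
    data.frame(metric = mname, mean_real = mean(a), mean_random = mean(b),
               t = wt$t, df = wt$df, p = wt$p,
               ci_lo = wt$conf_int[1], ci_hi = wt$conf_int[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default category-to-overall-group map helper
#'
#' Builds a flat named vector (category -> overall group) from a list
#' grouping categories under the six conventional overall-function
#' groups.
#'
#' @param groups Named list: overall group -> character vector of
#'   category labels.
#' @return Named character vector mapping category to group.
#' @export
make_group_map <- function(groups) {
  allowed <- c("immune", "tissue repair", "metabolic", "motility",
               "cell stress", "general")
  bad <- setdiff(names(groups), allowed)
  if (length(bad) > 0) {
    stop("unknown overall group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(rep(names(groups), lengths(groups)),
                  unlist(groups))
}

#' Fraction of genes per overall functional group
#'
#' Maps each annotated gene's functional category to an overall group
#' (immune, tissue repair, metabolic, motility, cell stress, general)
#' and reports percentages over annotated genes (summing to 100 within
#' rounding).
#'
#' @param genes Character vector of gene symbols (non-empty).
#' @param library Exclusive functional [annotation_library()].
#' @param group_map Named character vector (category -> overall group)
#'   covering every category that occurs; see [make_group_map()].
#' @return Data.frame `group`, `n`, `percent` over all six groups.
#' @export
category_fractions <- function(genes, library, group_map) {
  genes <- unique(genes)
  if (length(genes) == 0) stop("empty gene list", call. = FALSE)
  memb <- library$memberships
  memb <- memb[memb$gene %in% genes, , drop = FALSE]
  if (nrow(memb) == 0) {
    stop("no query gene carries an annotation in scheme '",
         library$scheme, "'", call. = FALSE)
  }
  unmapped <- setdiff(unique(memb$category), names(group_map))
  if (length(unmapped) > 0) {
    stop("category label(s) missing from group map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  groups <- c("immune", "tissue repair", "metabolic", "motility",
              "cell stress", "general")
  gene_group <- group_map[memb$category]
  counts <- table(factor(gene_group, levels = groups))
  data.frame(group = groups, n = as.integer(counts),
             percent = 100 * as.integer(counts) / nrow(memb),
             stringsAsFactors = FALSE)
}
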
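string_df <- function(n1, n2, score) {
  data.frame(node1 = n1, node2 = n2, combined_score = score,
             stringsAsFactors = FALSE)
}

test_that("subnetwork induction filters, collapses and drops loops", {
  edges <- string_df(c("A", "B", "C", "A", "A", "D"),
                     c("B", "C", "A", "B", "A", "E"),
                     c(400, 500, 900, 700, 999, 800))
  g <- build_subnetwork(c("A", "B", "C"), edges, min_score = 401)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  # A-B collapses to max score 700; C-A 900; B-C 500; loop dropped
  expect_equal(igraph::ecount(g), 3)
  g2 <- build_subnetwork(c("A", "B", "C"), edges, min_score = 701)
  expect_equal(igraph::ecount(g2), 1)
  empty <- build_subnetwork(c("X", "Y"), edges)
  expect_equal(igraph::vcount(empty), 0)
  g0 <- build_subnetwork(c("A", "B", "C"), edges, min_score = 0)
  expect_equal(igraph::ecount(g0), 3)
})

test_that("connectivity enrichment gate follows the Poisson-tail oracle", {
  # planted 10-clique inside a sparse 500-node background
  uni <- gene_universe(500)
  clique <- uni[1:10]
  set.seed(77)
  pairs <- utils::combn(uni, 2)
  bg <- stats::runif(ncol(pairs)) < 0.005
  in_clique <- pairs[1, ] %in% clique & pairs[2, ] %in% clique
  keep <- bg | in_clique
  edges <- string_df(pairs[1, keep], pairs[2, keep], 900)
  background <- build_subnetwork(uni, edges, min_score = 0)
  sub <- build_subnetwork(clique, edges, min_score = 0)
  res <- ppi_enrichment_p(sub, background)
  expect_lt(res$p, 1e-16)
  expect_true(res$passes)
  # oracle: upper Poisson tail summed directly in log space, on induced
  # subgraphs with moderate significance
  tail_oracle <- function(obs, lam) {
    ks <- obs:(obs + 400)
    sum(exp(-lam + ks * log(lam) - lgamma(ks + 1)))
  }
  set.seed(3)
  for (i in 1:5) {
    pick <- c(sample(clique, 4), sample(uni[-(1:10)], 12))
    s <- build_subnetwork(pick, edges, min_score = 0)
    r <- ppi_enrichment_p(s, background)
    if (r$observed > 0) {
      expect_equal(r$p, tail_oracle(r$observed, r$lambda),
                   tolerance = 1e-10)
    }
  }
  # fewer observed edges -> strictly larger p at the same node set,
  # checked on an instance whose p does not underflow
  mod <- build_subnetwork(c(clique[1:3], uni[400:419]), edges,
                          min_score = 0)
  pm <- ppi_enrichment_p(mod, background)
  expect_gt(pm$p, 0)
  weak <- igraph::delete_edges(mod, 1)
  expect_gt(ppi_enrichment_p(weak, background)$p, pm$p)
  # degenerate contracts
  iso <- build_subnetwork(uni[490:500], string_df("A", "B", 500),
                          min_score = 0)
  expect_equal(ppi_enrichment_p(iso, background)$p, 1)
  one <- build_subnetwork(clique[1], edges, min_score = 0)
  expect_equal(ppi_enrichment_p(one, background)$p, 1)
})

test_that("strictly-below gate: p equal to the threshold fails", {
  res <- list(p = 1e-16)
  expect_false(res$p < 1e-16)
})

test_that("vertex weights: triangle and brute-force neighborhood oracle", {
  tri <- make_graph(clique_edges(c("A", "B", "C")))
  expect_equal(unname(mcode_vertex_weights(tri)), c(2, 2, 2))
  set.seed(5)
  for (i in 1:12) {
    n <- sample(8:30, 1)
    adj <- matrix(0L, n, n)
    pairs <- utils::combn(n, 2)
    on <- stats::runif(ncol(pairs)) < stats::runif(1, 0.1, 0.5)
    for (k in which(on)) {
      adj[pairs[1, k], pairs[2, k]] <- 1L
      adj[pairs[2, k], pairs[1, k]] <- 1L
    }
    vn <- sprintf("V%02d", 1:n)
    dimnames(adj) <- list(vn, vn)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    w <- mcode_vertex_weights(g)
    for (v in 1:n) {
      expect_equal(unname(w[vn[v]]), mcode_weight_oracle(adj, v),
                   tolerance = 1e-12)
    }
  }
})

test_that("mcode recovers disjoint cliques exactly", {
  expect_length(mcode(make_graph(list(), vertices = character(0))), 0)
  tri <- mcode(make_graph(clique_edges(c("A", "B", "C"))))
  expect_length(tri, 1)
  expect_equal(tri[[1]]$members, c("A", "B", "C"))
  cliques <- list(paste0("a", 1:4), paste0("b", 1:5), paste0("c", 1:3))
  g <- make_graph(unlist(lapply(cliques, clique_edges),
                         recursive = FALSE))
  out <- mcode(g)
  expect_length(out, 3)
  got <- lapply(out, `[[`, "members")
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(lapply(cliques, sort), paste, collapse = ","))
  # clusters sorted by score = seed weight x size: the 5-clique first
  expect_equal(out[[1]]$size, 5)
})

test_that("bridged equal-weight cliques merge; low-weight path is excluded", {
  # Under the seed-relative expansion rule, the bridge endpoint carries
  # the same weight as the seed and is always absorbed, so the two
  # cliques form a single complex; the appended path never clears the
  # 2-core filter.
  a <- paste0("a", 1:6); b <- paste0("b", 1:6); p <- paste0("p", 1:10)
  edges <- c(clique_edges(a), clique_edges(b), list(c("a1", "b1")),
             lapply(1:9, function(i) c(p[i], p[i + 1])),
             list(c("p1", "a2")))
  g <- make_graph(edges)
  out <- mcode(g)
  expect_length(out, 1)
  expect_setequal(out[[1]]$members, c(a, b))
})

test_that("mcode clusters are disjoint, contain their seed, and are stable
           under relabeling", {
  cfg <- synth_config(seed = 19,
                      ppi_spec = list(n_nodes = 60, n_modules = 3,
                                      module_size = 8, p_within = 0.9,
                                      p_background = 0.02))
  ppi <- gen_ppi(cfg)
  net <- build_subnetwork(ppi$nodes, ppi$edges, min_score = 0)
  out <- mcode(net)
  members <- unlist(lapply(out, `[[`, "members"))
  expect_false(anyDuplicated(members) > 0)
  for (cl in out) expect_true(cl$seed %in% cl$members)
  # relabel vertices by a structure-preserving bijection: same clusters
  relabel <- function(x) chartr("G", "H", x)
  edges2 <- ppi$edges
  edges2$node1 <- relabel(edges2$node1)
  edges2$node2 <- relabel(edges2$node2)
  net2 <- build_subnetwork(relabel(ppi$nodes), edges2, min_score = 0)
  out2 <- mcode(net2)
  expect_equal(lapply(out2, function(c) c$members),
               lapply(out, function(c) relabel(c$members)))
})

test_that("metastructure counts and edge conservation", {
  g <- make_graph(list(c("A", "B"), c("B", "C"), c("C", "A"),
                       c("D", "E"), c("A", "D")))
  clusters <- list(c("A", "B", "C"), c("D", "E"))
  meta <- metastructure(clusters, g)
  expect_equal(meta$size, c(3, 2))
  expect_equal(meta$intra, c(3, 1))
  expect_equal(meta$inter, c(1, 1))
  whole <- metastructure(list(igraph::V(g)$name), g)
  expect_equal(whole$intra, igraph::ecount(g))
  expect_equal(whole$inter, 0)
  # conservation on random instances with unclustered leftovers
  set.seed(8)
  for (i in 1:10) {
    n <- 20
    vn <- sprintf("N%02d", 1:n)
    pairs <- utils::combn(vn, 2)
    keep <- stats::runif(ncol(pairs)) < 0.2
    g2 <- make_graph(lapply(which(keep), function(k) pairs[, k]),
                     vertices = vn)
    cl <- list(vn[1:5], vn[6:12])
    m <- metastructure(cl, g2)  # internal stopifnot asserts the identity
    expect_equal(sum(m$intra) + sum(m$inter) / 2 +
                   attr(m, "unclustered_incident"), igraph::ecount(g2))
  }
})

test_that("random-null comparison: identical, degenerate and error cases", {
  a <- data.frame(size = c(3, 4, 5), intra = c(3, 5, 7),
                  inter = c(1, 2, 1))
  same <- compare_to_random(a, a)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))
  # zero-variance two-point samples: exact-equality fallback
  b <- data.frame(size = c(4, 4), intra = c(2, 2), inter = c(0, 0))
  d <- data.frame(size = c(4, 4), intra = c(9, 9), inter = c(0, 0))
  fb <- compare_to_random(b, d)
  expect_equal(fb$p[fb$metric == "size"], 1)
  expect_equal(fb$p[fb$metric == "intra"], 0)
  expect_error(compare_to_random(a, a[1, , drop = FALSE]), "intra|size")
})

test_that("category fractions sum to 100 and reject unmapped labels", {
  uni <- gene_universe(40)
  memb <- data.frame(gene = uni,
                     category = rep(c("imm", "rep"), each = 20),
                     stringsAsFactors = FALSE)
  lib <- annotation_library("functional", uni, memb, exclusive = TRUE)
  gm <- make_group_map(list(immune = "imm", `tissue repair` = "rep"))
  one <- category_fractions(uni[1:20], lib, gm)
  expect_equal(one$percent[one$group == "immune"], 100)
  expect_equal(sum(one$percent), 100)
  both <- category_fractions(uni[11:30], lib, gm)
  expect_equal(both$percent[both$group %in% c("immune", "tissue repair")],
               c(50, 50))
  expect_error(category_fractions(character(0), lib, gm), "empty")
  expect_error(category_fractions(uni[1:5], lib, gm["imm"][0]), "missing")
  expect_error(make_group_map(list(oddgroup = "imm")), "unknown")
})

test_that("planted 50% tissue-repair fraction is recovered", {
  # half the categories map to tissue repair; gene labels are uniform,
  # so the expected fraction is 50% with multinomial noise
  cfg <- synth_config(seed = 28, n_functional_categories = 10)
  ann <- gen_annotation_library(cfg)
  cats <- sort(unique(ann$functional$memberships$category))
  gm <- make_group_map(list(`tissue repair` = cats[1:5],
                            general = cats[6:10]))
  genes <- random_gene_cohort(ann$functional$universe, 400, seed = 3)
  fr <- category_fractions(genes, ann$functional, gm)
  got <- fr$percent[fr$group == "tissue repair"] / 100
  half <- 2.576 * sqrt(0.5 * 0.5 / 400)
  expect_lt(abs(got - 0.5), half + 1e-9)
})
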
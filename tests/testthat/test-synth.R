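test_that("SNP generator hits exact per-ancestry and shared counts", {
  cfg <- synth_config(seed = 7)
  snps <- gen_snp_table(cfg)
  expect_equal(sum(snps$ancestry == "EA"), 757)
  expect_equal(sum(snps$ancestry == "AsA"), 700)
  shared_ids <- unique(snps$snp_id[snps$shared])
  expect_length(shared_ids, 20)
  for (id in shared_ids[1:3]) {
    expect_setequal(snps$ancestry[snps$snp_id == id], c("EA", "AsA"))
  }
  # empty config
  cfg0 <- synth_config(n_snps_per_ancestry = c(EA = 0, AsA = 0),
                       shared_snp_count = 0)
  expect_equal(nrow(gen_snp_table(cfg0)), 0)
})

test_that("generators are byte-reproducible and seed-sensitive", {
  cfg <- synth_config(seed = 3, n_snps_per_ancestry = c(EA = 60, AsA = 50),
                      shared_snp_count = 4, n_genes_universe = 300,
                      ppi_spec = list(n_nodes = 60, n_modules = 2,
                                      module_size = 6, p_within = 0.9,
                                      p_background = 0.02),
                      expr_spec = list(n_genes = 120, n_case = 4,
                                       n_control = 4, n_sets = 4,
                                       set_size = 10, n_planted = 1,
                                       delta = 1, noise_sd = 1))
  s1 <- synth_generate(cfg)
  s2 <- synth_generate(cfg)
  expect_identical(s1, s2)
  cfg2 <- cfg
  cfg2$seed <- 4L
  s3 <- synth_generate(cfg2)
  expect_false(identical(s1$snps, s3$snps))
  expect_false(identical(s1$ppi$edges, s3$ppi$edges))
  # generators leave the caller's RNG stream untouched
  set.seed(99)
  before <- .Random.seed
  invisible(gen_snp_table(cfg))
  expect_identical(.Random.seed, before)
})

test_that("config invariants are enforced", {
  expect_error(synth_config(shared_snp_count = 1000), "exceeds")
  expect_error(synth_config(eqtl_hit_rate = 1.5), "hit rates")
  expect_error(synth_config(ppi_spec = list(n_nodes = 100, n_modules = 2,
                                            module_size = 10,
                                            p_within = 0.1,
                                            p_background = 0.2)),
               "exceed")
  expect_error(synth_config(ppi_spec = list(n_nodes = 10, n_modules = 3,
                                            module_size = 5,
                                            p_within = 0.9,
                                            p_background = 0.01)),
               "exceeds")
  expect_error(synth_config(expr_spec = list(n_genes = 50, n_case = 1,
                                             n_control = 5, n_sets = 2,
                                             set_size = 5, n_planted = 1,
                                             delta = 1, noise_sd = 1)),
               ">= 2")
  bad_prop <- default_category_proportions()
  bad_prop$EA[1] <- bad_prop$EA[1] + 0.1
  expect_error(synth_config(category_proportions = bad_prop), "sum")
})

test_that("category proportions are recovered within multinomial error", {
  cfg <- synth_config(seed = 15)
  snps <- categorize_snps(gen_snp_table(cfg))
  ea <- snps[snps$ancestry == "EA" & !snps$shared, ]
  props <- default_category_proportions()$EA
  noncoding <- sum(props[c("intergenic_variant", "intron_variant")])
  got <- mean(ea$group == "non-coding")
  half <- 2.576 * sqrt(noncoding * (1 - noncoding) / nrow(ea))
  expect_lt(abs(got - noncoding), half + 1e-9)
})

test_that("lookup generator respects hit rates and boundary cases", {
  cfg <- synth_config(seed = 2, n_snps_per_ancestry = c(EA = 80, AsA = 70),
                      shared_snp_count = 5, n_genes_universe = 400,
                      eqtl_hit_rate = 1.0)
  snps <- gen_snp_table(cfg)
  lk <- gen_lookup_tables(cfg, snps)
  expect_setequal(unique(lk$eqtl$snp_id), unique(snps$snp_id))
  expect_true(all(lk$eqtl$gene %in% lk$universe))
  # coordinates tile the universe without overlap, 1-based closed
  gc <- lk$gene_coords
  expect_setequal(gc$gene, lk$universe)
  expect_true(all(gc$start >= 1 & gc$end > gc$start))
  for (ch in unique(gc$chrom)) {
    g <- gc[gc$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # observed eQTL hit rate within the 99% binomial interval of 0.58
  cfg58 <- synth_config(seed = 8,
                        n_snps_per_ancestry = c(EA = 0, AsA = 700),
                        shared_snp_count = 0, eqtl_hit_rate = 0.58)
  snps58 <- gen_snp_table(cfg58)
  lk58 <- gen_lookup_tables(cfg58, snps58)
  rate <- length(unique(lk58$eqtl$snp_id)) / 700
  half <- 2.576 * sqrt(0.58 * 0.42 / 700)
  expect_lt(abs(rate - 0.58), half + 1e-9)
})

test_that("PPI generator: exact cliques, empty case, ground truth", {
  cfg <- synth_config(seed = 6, n_genes_universe = 200,
                      ppi_spec = list(n_nodes = 40, n_modules = 3,
                                      module_size = 5, p_within = 1.0,
                                      p_background = 0))
  ppi <- gen_ppi(cfg)
  expect_equal(nrow(ppi$edges), 3 * choose(5, 2))
  for (m in ppi$modules) {
    sub <- ppi$edges[ppi$edges$node1 %in% m & ppi$edges$node2 %in% m, ]
    expect_equal(nrow(sub), choose(5, 2))
  }
  expect_length(unlist(ppi$modules), 15)
  expect_equal(sum(!is.na(ppi$truth)), 15)
  cfg0 <- synth_config(seed = 6, n_genes_universe = 200,
                       ppi_spec = list(n_nodes = 30, n_modules = 0,
                                       module_size = 5, p_within = 1.0,
                                       p_background = 0))
  expect_equal(nrow(gen_ppi(cfg0)$edges), 0)
  expect_true(all(ppi$edges$combined_score >= 400 &
                    ppi$edges$combined_score <= 1000))
})

test_that("annotation generator: label counts and degenerate universe", {
  cfg <- synth_config(seed = 10)
  ann <- gen_annotation_library(cfg)
  expect_length(unique(ann$functional$memberships$category), 54)
  expect_setequal(ann$functional$memberships$gene,
                  ann$functional$universe)
  expect_false(anyDuplicated(ann$functional$memberships$gene) > 0)
  expect_lte(length(unique(ann$cell$memberships$category)), 30)
  one <- synth_config(seed = 10, n_genes_universe = 10,
                      n_functional_categories = 1,
                      planted_categories = NULL,
                      ppi_spec = list(n_nodes = 10, n_modules = 0,
                                      module_size = 2, p_within = 0.5,
                                      p_background = 0.1),
                      expr_spec = list(n_genes = 10, n_case = 2,
                                       n_control = 2, n_sets = 1,
                                       set_size = 3, n_planted = 0,
                                       delta = 0, noise_sd = 1))
  ann1 <- gen_annotation_library(one)
  expect_equal(unique(ann1$functional$memberships$category), "F01")
  expect_error(synth_config(n_functional_categories = 0), "at least one")
})

test_that("expression generator plants disjoint shifted sets and couples
           metadata to the signature activity", {
  cfg <- synth_config(seed = 21,
                      expr_spec = list(n_genes = 400, n_case = 15,
                                       n_control = 15, n_sets = 6,
                                       set_size = 25, n_planted = 2,
                                       delta = 1.2, noise_sd = 1))
  ex <- gen_expression(cfg)
  expect_equal(dim(ex$expr), c(400, 30))
  expect_length(intersect(ex$sets$SIG01, ex$sets$SIG02), 0)
  for (d in c("SIG03", "SIG04")) {
    expect_length(intersect(ex$sets[[d]],
                            c(ex$sets$SIG01, ex$sets$SIG02)), 0)
  }
  # planted genes are shifted by about delta in cases
  idx <- match(ex$sets$SIG01, rownames(ex$expr))
  case <- ex$metadata$group == "case"
  shift <- mean(ex$expr[idx, case]) - mean(ex$expr[idx, !case])
  expect_lt(abs(shift - 1.2), 0.25)
  # metadata regression on true activity recovers the configured slope
  fit <- simple_linreg(ex$true_activity, ex$metadata$sledai)
  expect_lt(abs(fit$slope - cfg$meta_spec$sledai[["slope"]]), 1.5)
  # zero-coupling contract: slope CI covers 0
  cfg0 <- cfg
  cfg0$meta_spec$sledai <- c(intercept = 5, slope = 0, sd = 1)
  ex0 <- gen_expression(cfg0)
  fit0 <- simple_linreg(ex0$true_activity, ex0$metadata$sledai)
  se <- abs(fit0$slope / stats::qt(1 - fit0$p / 2, fit0$n - 2))
  expect_lt(abs(fit0$slope), 3 * max(se, 0.05))
})

test_that("written artifacts round-trip through the readers", {
  cfg <- synth_config(seed = 31, n_snps_per_ancestry = c(EA = 30, AsA = 25),
                      shared_snp_count = 2, n_genes_universe = 150,
                      ppi_spec = list(n_nodes = 40, n_modules = 2,
                                      module_size = 5, p_within = 0.9,
                                      p_background = 0.05),
                      expr_spec = list(n_genes = 100, n_case = 3,
                                       n_control = 3, n_sets = 3,
                                       set_size = 10, n_planted = 1,
                                       delta = 1, noise_sd = 1))
  s <- synth_generate(cfg)
  dir <- withr::local_tempdir()
  write_synth_inputs(s, dir)
  snps <- read_tsv_table(file.path(dir, "snps.tsv"),
                         required_cols = c("snp_id", "ancestry"))
  expect_equal(nrow(snps), nrow(s$snps))
  edges <- read_string_edges(file.path(dir, "ppi_edges.tsv"))
  expect_equal(nrow(edges), nrow(s$ppi$edges))
  expr <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(expr, s$expression$expr, tolerance = 1e-12)
  gmt <- read_gmt(file.path(dir, "signatures.gmt"))
  expect_equal(lapply(gmt, as.character),
               lapply(s$expression$sets, as.character))
})
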
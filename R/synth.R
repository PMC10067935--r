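# Synthetic-data generators. Every pipeline input (SNP association table,
# SNP-to-gene lookup tables, gene coordinates, annotation libraries, PPI
# edge list, expression matrix with metadata and signature GMT) is
# generated with known planted structure, so each downstream stage has a
# parameter-recovery test surface. All generators are deterministic under
# the config seed and leave the caller's RNG stream untouched.

#' Deterministic synthetic gene universe
#'
#' Gene symbols are synthetic tokens (`G000001`, `G000002`, ...) so they
#' can never collide with real gene symbols.
#'
#' @param n Number of genes.
#' @return Character vector of length `n`.
#' @export
gene_universe <- function(n) {
  if (n < 1) stop("universe size must be >= 1", call. = FALSE)
  sprintf("G%06d", seq_len(n))
}

#' Synthetic-data configuration
#'
#' Collects every knob of the generators, with defaults chosen to emulate
#' the scale and structure of a two-ancestry immune-disease SNP study:
#' 757 EA and 700 AsA associated SNPs of which 20 are shared; roughly 70%
#' of SNPs non-coding and 8% coding, with the AsA cohort carrying twice
#' the EA fraction of ncRNA variants; an eQTL hit rate a bit under one
#' half, regulatory hits for about 7% of SNPs and coding-gene links for
#' (mis)sense/nonsense variants; a 2000-gene universe annotated into 54
#' functional and 30 cell-type categories with two planted enriched
#' categories; a 400-node interaction network carrying 5 planted dense
#' 12-gene modules (within-module edge probability 0.8) on a sparse
#' background whose density (0.05) mirrors a medium-confidence
#' interaction platform; and a genome-scale (full-universe), 20 vs 20
#' sample expression matrix with two planted case-shifted signatures
#' (shift 1.0 on the log2 scale, unit noise SD) plus disease-activity
#' metadata linearly coupled to the first planted signature. The
#' expression matrix deliberately spans the whole universe: per-sample
#' rank-based scoring makes unshifted "decoy" sets slightly
#' anti-enriched when a large fraction of the matrix is shifted, and the
#' effect only vanishes when planted signatures are a small fraction of
#' the profiled genes, as in real arrays.
#'
#' @param seed Integer master seed; each generator derives its own
#'   sub-seed from it.
#' @param n_snps_per_ancestry Named integer vector, ancestry -> SNP count
#'   (shared SNPs included in each count).
#' @param shared_snp_count SNPs associated in every ancestry.
#' @param category_proportions Named list, ancestry -> named numeric
#'   vector of consequence-term proportions (each summing to 1).
#' @param eqtl_hit_rate,regulatory_hit_rate Fractions in \[0,1\]: the
#'   probability that a SNP has at least one E-gene / T-gene row.
#' @param coding_hit_rate Fraction in \[0,1\] applied to SNPs whose
#'   consequence is missense or nonsense.
#' @param genes_per_hit List `(min, lambda)`: targets per lookup hit are
#'   `min + rpois(lambda)`.
#' @param n_genes_universe,n_functional_categories,n_cell_categories
#'   Universe and annotation-scheme sizes.
#' @param planted_categories Data.frame (`category`, `odds`): functional
#'   categories over-sampled (with the stated odds) into the generated
#'   signal gene sets.
#' @param ppi_spec List: `n_nodes`, `n_modules`, `module_size`,
#'   `p_within`, `p_background` (within-module probability must exceed
#'   background).
#' @param expr_spec List: `n_genes`, `n_case`, `n_control`, `n_sets`,
#'   `set_size`, `n_planted`, `delta` (log2 shift), `noise_sd`.
#' @param meta_spec List: `sledai`, `anti_dsdna`, `c3`, each
#'   `c(intercept, slope, sd)` coupling the covariate linearly to the
#'   first planted signature's true activity.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(
    seed = 1,
    n_snps_per_ancestry = c(EA = 757, AsA = 700),
    shared_snp_count = 20,
    category_proportions = default_category_proportions(),
    eqtl_hit_rate = 0.45,
    regulatory_hit_rate = 0.07,
    coding_hit_rate = 1.0,
    genes_per_hit = list(min = 1, lambda = 2),
    n_genes_universe = 2000,
    n_functional_categories = 54,
    n_cell_categories = 30,
    planted_categories = data.frame(category = c("F01", "F02"),
                                    odds = c(5, 5)),
    ppi_spec = list(n_nodes = 400, n_modules = 5, module_size = 12,
                    p_within = 0.8, p_background = 0.05),
    expr_spec = list(n_genes = 2000, n_case = 20, n_control = 20,
                     n_sets = 12, set_size = 25, n_planted = 2,
                     delta = 1.0, noise_sd = 1.0),
    meta_spec = list(sledai = c(intercept = 2, slope = 6, sd = 2),
                     anti_dsdna = c(intercept = 30, slope = 60, sd = 25),
                     c3 = c(intercept = 110, slope = -40, sd = 15))) {
  cfg <- list(seed = as.integer(seed),
              n_snps_per_ancestry = n_snps_per_ancestry,
              shared_snp_count = shared_snp_count,
              category_proportions = category_proportions,
              eqtl_hit_rate = eqtl_hit_rate,
              regulatory_hit_rate = regulatory_hit_rate,
              coding_hit_rate = coding_hit_rate,
              genes_per_hit = genes_per_hit,
              n_genes_universe = n_genes_universe,
              n_functional_categories = n_functional_categories,
              n_cell_categories = n_cell_categories,
              planted_categories = planted_categories,
              ppi_spec = ppi_spec, expr_spec = expr_spec,
              meta_spec = meta_spec)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' Default per-ancestry consequence-term proportions
#'
#' About 70% non-coding (intergenic + intronic) and 8% coding in both
#' ancestries; the AsA cohort carries twice the EA ncRNA fraction (12%
#' vs 6%) and correspondingly fewer regulatory variants, mirroring the
#' reported ancestral contrast in SNP functional categories.
#'
#' @return Named list (`EA`, `AsA`) of named proportion vectors over the
#'   default consequence vocabulary.
#' @export
default_category_proportions <- function() {
  ea <- c(intergenic_variant = 0.30, intron_variant = 0.40,
          TF_binding_site_variant = 0.03, promoter_variant = 0.03,
          enhancer_variant = 0.05, repressor_variant = 0.01,
          promoter_flanking_region_variant = 0.02,
          open_chromatin_variant = 0.02,
          lncRNA_variant = 0.05, miRNA_variant = 0.01,
          `5_prime_UTR_variant` = 0.01, `3_prime_UTR_variant` = 0.02,
          synonymous_variant = 0.02, missense_variant = 0.025,
          stop_gained = 0.005)
  asa <- c(intergenic_variant = 0.30, intron_variant = 0.40,
           TF_binding_site_variant = 0.02, promoter_variant = 0.02,
           enhancer_variant = 0.03, repressor_variant = 0.005,
           promoter_flanking_region_variant = 0.0125,
           open_chromatin_variant = 0.0125,
           lncRNA_variant = 0.10, miRNA_variant = 0.02,
           `5_prime_UTR_variant` = 0.01, `3_prime_UTR_variant` = 0.02,
           synonymous_variant = 0.02, missense_variant = 0.025,
           stop_gained = 0.005)
  list(EA = ea, AsA = asa)
}

validate_synth_config <- function(cfg) {
  frac_ok <- function(x) is.numeric(x) && x >= 0 && x <= 1
  if (!frac_ok(cfg$eqtl_hit_rate) || !frac_ok(cfg$regulatory_hit_rate) ||
      !frac_ok(cfg$coding_hit_rate)) {
    stop("hit rates must lie in [0, 1]", call. = FALSE)
  }
  n <- cfg$n_snps_per_ancestry
  if (length(n) > 0 && cfg$shared_snp_count > min(n)) {
    stop("shared_snp_count (", cfg$shared_snp_count,
         ") exceeds an ancestry's SNP count (", min(n), ")",
         call. = FALSE)
  }
  for (a in names(cfg$category_proportions)) {
    pr <- cfg$category_proportions[[a]]
    if (abs(sum(pr) - 1) > 1e-8) {
      stop("category proportions for ", a, " sum to ", sum(pr),
           ", not 1", call. = FALSE)
    }
    if (any(pr < 0)) stop("negative proportion for ", a, call. = FALSE)
  }
  ps <- cfg$ppi_spec
  if (ps$n_modules > 0 && ps$p_within <= ps$p_background) {
    stop("within-module edge probability must exceed background",
         call. = FALSE)
  }
  if (ps$n_modules * ps$module_size > ps$n_nodes) {
    stop("module_size x n_modules exceeds the network node count",
         call. = FALSE)
  }
  if (ps$n_nodes > cfg$n_genes_universe) {
    stop("network node count exceeds the gene universe", call. = FALSE)
  }
  if (cfg$n_functional_categories < 1 || cfg$n_cell_categories < 1) {
    stop("need at least one annotation category per scheme",
         call. = FALSE)
  }
  es <- cfg$expr_spec
  if (es$n_case < 2 || es$n_control < 2) {
    stop("expression generator needs >= 2 case and >= 2 control samples",
         call. = FALSE)
  }
  invisible(cfg)
}

# sub-seed offsets per generator, so stages are independently reproducible
seed_offsets <- c(snp = 11L, lookup = 23L, annot = 37L, ppi = 41L,
                  expr = 53L)
sub_seed <- function(cfg, stage) {
  (cfg$seed + seed_offsets[[stage]]) %% .Machine$integer.max
}

#' Generate a synthetic SNP association table
#'
#' Long format: one row per SNP x ancestry; a shared SNP appears once per
#' ancestry under a stable `snp_id`, so ancestry partitioning is a pure
#' group-by. Positions are sampled over a synthetic genome of 22 numbered
#' chromosomes of 40 Mb (1-based), which contains the chromosome-6 HLA
#' exclusion window so the exclusion filter is exercised. Consequence
#' terms are drawn per ancestry from the configured proportions (shared
#' SNPs use the ancestry-averaged proportions).
#'
#' @param config A [synth_config()].
#' @return Data.frame: `snp_id`, `chrom`, `pos`, `ancestry`, `assoc_p`,
#'   `consequence`, plus logical `shared`.
#' @export
gen_snp_table <- function(config) {
  validate_synth_config(config)
  n_per <- config$n_snps_per_ancestry
  s <- config$shared_snp_count
  empty <- data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), ancestry = character(),
                      assoc_p = numeric(), consequence = character(),
                      shared = logical(), stringsAsFactors = FALSE)
  if (length(n_per) == 0 || sum(n_per) == 0) return(empty)
  ancestries <- names(n_per)
  props <- config$category_proportions[ancestries]
  terms <- names(props[[1]])
  avg_prop <- Reduce(`+`, props) / length(props)
  with_seed(sub_seed(config, "snp"), {
    n_unique <- s + sum(n_per - s)
    ids <- sprintf("S%06d", seq_len(n_unique))
    chrom <- as.character(sample.int(22, n_unique, replace = TRUE))
    pos <- sample.int(40000000L, n_unique, replace = TRUE)
    assoc_p <- 10^stats::runif(n_unique, -10, -3)
    shared_ids <- ids[seq_len(s)]
    cons <- character(n_unique)
    if (s > 0) {
      cons[seq_len(s)] <- sample(terms, s, replace = TRUE,
                                 prob = avg_prop)
    }
    rows <- list()
    offset <- s
    if (s > 0) {
      for (a in ancestries) {
        rows[[length(rows) + 1]] <- data.frame(
          snp_id = shared_ids, chrom = chrom[seq_len(s)],
          pos = pos[seq_len(s)], ancestry = a,
          assoc_p = assoc_p[seq_len(s)],
          consequence = cons[seq_len(s)], shared = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    for (a in ancestries) {
      k <- n_per[[a]] - s
      if (k == 0) next
      idx <- offset + seq_len(k)
      offset <- offset + k
      cons[idx] <- sample(terms, k, replace = TRUE, prob = props[[a]])
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = ids[idx], chrom = chrom[idx], pos = pos[idx],
        ancestry = a, assoc_p = assoc_p[idx], consequence = cons[idx],
        shared = FALSE, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$snp_id, out$ancestry), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate SNP-to-gene lookup tables and gene coordinates
#'
#' Table-driven stand-ins for the external eQTL, regulatory-element and
#' coding-annotation resources. Each SNP independently receives an eQTL
#' hit (probability `eqtl_hit_rate`) and a regulatory hit
#' (`regulatory_hit_rate`) listing `min + rpois(lambda)` target genes
#' drawn from the universe; SNPs with a missense or nonsense consequence
#' receive a coding-gene link with probability `coding_hit_rate`. Gene
#' coordinates tile the universe over the synthetic genome in
#' non-overlapping 1-based closed intervals. SNPs given no hit anywhere
#' are recorded as the ground truth for proximal (P-gene) assignment.
#'
#' @param config A [synth_config()].
#' @param snps SNP table from [gen_snp_table()].
#' @return List: `eqtl`, `regulatory`, `coding` (data.frames `snp_id`,
#'   `gene`), `gene_coords`, `unhit_snps` (character), `universe`.
#' @export
gen_lookup_tables <- function(config, snps) {
  validate_synth_config(config)
  universe <- gene_universe(config$n_genes_universe)
  gene_coords <- tile_gene_coords(universe)
  usnp <- snps[!duplicated(snps$snp_id), , drop = FALSE]
  coding_terms <- c("missense_variant", "stop_gained")
  with_seed(sub_seed(config, "lookup"), {
    draw_table <- function(ids, rate) {
      hit <- ids[stats::runif(length(ids)) < rate]
      if (length(hit) == 0) {
        return(data.frame(snp_id = character(), gene = character(),
                          stringsAsFactors = FALSE))
      }
      n_targets <- config$genes_per_hit$min +
        stats::rpois(length(hit), config$genes_per_hit$lambda)
      genes <- lapply(n_targets, function(k) {
        sample(universe, min(k, length(universe)))
      })
      data.frame(snp_id = rep(hit, lengths(genes)),
                 gene = unlist(genes), stringsAsFactors = FALSE)
    }
    eqtl <- draw_table(usnp$snp_id, config$eqtl_hit_rate)
    regulatory <- draw_table(usnp$snp_id, config$regulatory_hit_rate)
    coding_ids <- usnp$snp_id[usnp$consequence %in% coding_terms]
    coding_hit <- coding_ids[stats::runif(length(coding_ids)) <
                               config$coding_hit_rate]
    coding <- data.frame(
      snp_id = coding_hit,
      gene = if (length(coding_hit)) sample(universe, length(coding_hit),
                                            replace = TRUE)
             else character(),
      stringsAsFactors = FALSE)
    hit_ids <- unique(c(eqtl$snp_id, regulatory$snp_id, coding$snp_id))
    list(eqtl = eqtl, regulatory = regulatory, coding = coding,
         gene_coords = gene_coords,
         unhit_snps = sort(setdiff(usnp$snp_id, hit_ids)),
         universe = universe)
  })
}

# Tile genes over 22 chromosomes: 20 kb genes every 50 kb, 1-based closed,
# non-overlapping by construction.
tile_gene_coords <- function(universe) {
  n <- length(universe)
  i <- seq_len(n)
  chrom <- as.character(((i - 1) %% 22) + 1)
  k <- (i - 1) %/% 22
  start <- 1 + k * 50000
  data.frame(gene = universe, chrom = chrom, start = start,
             end = start + 19999, stringsAsFactors = FALSE)
}

#' Generate functional and cell-type annotation libraries
#'
#' Every universe gene gets exactly one of `n_functional_categories`
#' functional labels (`F01`, `F02`, ...); cell-type labels (`C01`, ...)
#' are non-exclusive and cover only a fraction of genes. For each planted
#' category, a "signal" query gene set is drawn with that category's
#' genes over-sampled at the configured odds, giving downstream
#' enrichment a known positive to recover.
#'
#' @param config A [synth_config()].
#' @param n_signal Size of each signal query set (default 100).
#' @return List: `functional` and `cell` ([annotation_library()]s),
#'   `signal_sets` (named list of gene vectors, one per planted
#'   category), `planted` (the planted-category table).
#' @export
gen_annotation_library <- function(config, n_signal = 100) {
  validate_synth_config(config)
  universe <- gene_universe(config$n_genes_universe)
  fun_labels <- sprintf("F%02d", seq_len(config$n_functional_categories))
  cell_labels <- sprintf("C%02d", seq_len(config$n_cell_categories))
  with_seed(sub_seed(config, "annot"), {
    fun_cat <- sample(fun_labels, length(universe), replace = TRUE)
    functional <- annotation_library(
      "functional", universe,
      data.frame(gene = universe, category = fun_cat,
                 stringsAsFactors = FALSE),
      exclusive = TRUE)
    has_cell <- stats::runif(length(universe)) < 0.3
    n_cell <- ifelse(has_cell, 1 + (stats::runif(length(universe)) < 0.3),
                     0)
    cell_rows <- data.frame(
      gene = rep(universe, n_cell),
      category = unlist(lapply(n_cell[n_cell > 0], sample,
                               x = cell_labels)),
      stringsAsFactors = FALSE)
    cell <- annotation_library("celltype", universe, cell_rows,
                               exclusive = FALSE)
    planted <- config$planted_categories
    signal_sets <- list()
    if (!is.null(planted) && nrow(planted) > 0) {
      for (i in seq_len(nrow(planted))) {
        wt <- ifelse(fun_cat == planted$category[i], planted$odds[i], 1)
        signal_sets[[planted$category[i]]] <-
          sort(sample(universe, min(n_signal, length(universe)),
                      prob = wt))
      }
    }
    list(functional = functional, cell = cell,
         signal_sets = signal_sets, planted = planted)
  })
}

#' Generate a synthetic PPI edge table with planted modules
#'
#' Emits a STRING-dialect edge table (`node1`, `node2`,
#' `combined_score`) over `n_nodes` genes: node-disjoint planted modules
#' whose internal pairs are connected with probability `p_within`, on a
#' background where every other node pair is connected with probability
#' `p_background`. Scores are uniform over 400-1000 so the conventional
#' medium-confidence filter keeps all edges. Module membership is
#' returned as ground truth.
#'
#' @param config A [synth_config()].
#' @param universe Gene universe (defaults to the config's).
#' @param module_genes Optional character vector of genes to plant the
#'   modules on (taken in order, `n_modules * module_size` genes);
#'   default: sampled from the node set.
#' @return List: `edges` (data.frame), `nodes`, `modules` (list of
#'   member vectors), `truth` (named module id per gene, NA for
#'   background).
#' @export
gen_ppi <- function(config, universe = gene_universe(config$n_genes_universe),
                    module_genes = NULL) {
  validate_synth_config(config)
  ps <- config$ppi_spec
  n_mod_genes <- ps$n_modules * ps$module_size
  with_seed(sub_seed(config, "ppi"), {
    if (is.null(module_genes)) {
      nodes <- sort(sample(universe, ps$n_nodes))
      mod_members <- if (n_mod_genes > 0) sample(nodes, n_mod_genes)
                     else character()
    } else {
      module_genes <- unique(module_genes)
      if (length(module_genes) < n_mod_genes) {
        stop("need at least ", n_mod_genes, " module genes",
             call. = FALSE)
      }
      mod_members <- module_genes[seq_len(n_mod_genes)]
      rest <- setdiff(universe, mod_members)
      nodes <- sort(c(mod_members,
                      sample(rest, ps$n_nodes - n_mod_genes)))
    }
    modules <- if (n_mod_genes > 0) {
      split(mod_members, rep(seq_len(ps$n_modules),
                             each = ps$module_size))
    } else list()
    truth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
    for (m in seq_along(modules)) truth[modules[[m]]] <- m
    # all node pairs, then per-pair edge probability by module status
    pairs <- utils::combn(nodes, 2)
    t1 <- truth[pairs[1, ]]
    t2 <- truth[pairs[2, ]]
    same_module <- !is.na(t1) & !is.na(t2) & t1 == t2
    prob <- ifelse(same_module, ps$p_within, ps$p_background)
    keep <- stats::runif(ncol(pairs)) < prob
    edges <- data.frame(
      node1 = pairs[1, keep], node2 = pairs[2, keep],
      combined_score = round(stats::runif(sum(keep), 400, 1000)),
      stringsAsFactors = FALSE)
    rownames(edges) <- NULL
    list(edges = edges, nodes = nodes, modules = modules, truth = truth)
  })
}

#' Generate an expression matrix with planted signatures and metadata
#'
#' Control samples are gene baseline (uniform on log2 8 +/- 2) plus
#' i.i.d. Gaussian noise; case samples are additionally shifted by
#' `delta` log2 units on the genes of the planted signature sets. The
#' remaining sets are unshifted decoys. Disease-activity metadata
#' (SLEDAI-like, anti-dsDNA-like, C3-like) are linear functions of the
#' first planted signature's true activity (the per-sample mean
#' baseline-centred expression of its genes) plus Gaussian noise, with
#' the coefficients stated in `meta_spec`.
#'
#' @param config A [synth_config()].
#' @param universe Gene universe (defaults to the config's).
#' @return List: `expr` (genes x samples matrix), `metadata`
#'   (data.frame: `sample`, `group`, `sledai`, `anti_dsdna`, `c3`,
#'   `ancestry`), `sets` (named list incl. decoys), `planted_sets`
#'   (names), `true_activity` (per sample), `genes`.
#' @export
gen_expression <- function(config,
                           universe = gene_universe(config$n_genes_universe)) {
  validate_synth_config(config)
  es <- config$expr_spec
  ms <- config$meta_spec
  with_seed(sub_seed(config, "expr"), {
    genes <- sort(sample(universe, min(es$n_genes, length(universe))))
    p <- length(genes)
    n <- es$n_case + es$n_control
    samples <- c(sprintf("CASE%02d", seq_len(es$n_case)),
                 sprintf("CTRL%02d", seq_len(es$n_control)))
    group <- rep(c("case", "control"), c(es$n_case, es$n_control))
    baseline <- stats::runif(p, 6, 10)
    # planted sets are mutually disjoint and decoys are drawn from the
    # unshifted remainder, so decoy flags measure the false-positive rate
    n_planted <- min(es$n_planted, es$n_sets)
    if (n_planted * es$set_size > p) {
      stop("planted signatures (", n_planted, " x ", es$set_size,
           " genes) do not fit in the expression matrix", call. = FALSE)
    }
    planted_pool <- sample(genes, n_planted * es$set_size)
    decoy_pool <- setdiff(genes, planted_pool)
    if (es$n_sets > n_planted && length(decoy_pool) < es$set_size) {
      stop("too few genes left for decoy signatures", call. = FALSE)
    }
    sets <- lapply(seq_len(es$n_sets), function(i) {
      if (i <= n_planted) {
        sort(planted_pool[(i - 1) * es$set_size + seq_len(es$set_size)])
      } else {
        sort(sample(decoy_pool, es$set_size))
      }
    })
    names(sets) <- sprintf("SIG%02d", seq_len(es$n_sets))
    planted_sets <- names(sets)[seq_len(n_planted)]
    expr <- baseline +
      matrix(stats::rnorm(p * n, sd = es$noise_sd), p, n)
    dimnames(expr) <- list(genes, samples)
    for (ps_name in planted_sets) {
      idx <- match(sets[[ps_name]], genes)
      expr[idx, group == "case"] <- expr[idx, group == "case"] + es$delta
    }
    coupled <- if (length(planted_sets) > 0) sets[[planted_sets[1]]]
               else sets[[1]]
    act <- colMeans(expr[match(coupled, genes), , drop = FALSE] -
                      baseline[match(coupled, genes)])
    lin <- function(cf) {
      cf[["intercept"]] + cf[["slope"]] * act +
        stats::rnorm(n, sd = cf[["sd"]])
    }
    metadata <- data.frame(
      sample = samples, group = group,
      sledai = lin(ms$sledai), anti_dsdna = lin(ms$anti_dsdna),
      c3 = lin(ms$c3),
      ancestry = rep_len(c("EA", "AsA"), n),
      stringsAsFactors = FALSE)
    list(expr = expr, metadata = metadata, sets = sets,
         planted_sets = planted_sets,
         true_activity = stats::setNames(act, samples), genes = genes)
  })
}

#' Generate every pipeline input from one config
#'
#' Runs all generators and wires them together the way the pipeline
#' consumes them. The PPI modules are planted on SNP-linked genes (the
#' most frequent targets in the eQTL table), emulating the empirical
#' tendency of disease-associated genes to form dense interaction
#' modules.
#'
#' @param config A [synth_config()].
#' @return List: `config`, `snps`, `lookups`, `annotation`, `ppi`,
#'   `expression`.
#' @export
synth_generate <- function(config) {
  snps <- gen_snp_table(config)
  lookups <- gen_lookup_tables(config, snps)
  annotation <- gen_annotation_library(config)
  n_mod_genes <- config$ppi_spec$n_modules * config$ppi_spec$module_size
  linked <- unique(c(lookups$eqtl$gene, lookups$regulatory$gene,
                     lookups$coding$gene))
  module_genes <- if (length(linked) >= n_mod_genes && n_mod_genes > 0) {
    sort(linked)  # deterministic order; gen_ppi takes the first block
  } else NULL
  ppi <- gen_ppi(config, universe = lookups$universe,
                 module_genes = module_genes)
  expression <- gen_expression(config, universe = lookups$universe)
  list(config = config, snps = snps, lookups = lookups,
       annotation = annotation, ppi = ppi, expression = expression)
}

#' Write synthetic inputs to a directory as plain-text artifacts
#'
#' Emits the SNP TSV, the three lookup TSVs, gene coordinates,
#' annotation TSVs, the STRING-dialect edge TSV, expression and metadata
#' TSVs and the signature GMT.
#'
#' @param synth Output of [synth_generate()].
#' @param dir Output directory (created if needed).
#' @param header_comment Optional provenance line for every TSV.
#' @return `dir`, invisibly.
#' @export
write_synth_inputs <- function(synth, dir, header_comment = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    write_tsv_table(df, file.path(dir, name),
                    header_comment = header_comment)
  }
  w(synth$snps, "snps.tsv")
  w(synth$lookups$eqtl, "eqtl.tsv")
  w(synth$lookups$regulatory, "regulatory.tsv")
  w(synth$lookups$coding, "coding.tsv")
  w(synth$lookups$gene_coords, "gene_coords.tsv")
  w(synth$annotation$functional$memberships, "annotation_functional.tsv")
  w(synth$annotation$cell$memberships, "annotation_celltype.tsv")
  w(synth$ppi$edges, "ppi_edges.tsv")
  expr_df <- data.frame(gene = rownames(synth$expression$expr),
                        synth$expression$expr, check.names = FALSE,
                        stringsAsFactors = FALSE)
  w(expr_df, "expression.tsv")
  w(synth$expression$metadata, "metadata.tsv")
  write_gmt(synth$expression$sets, file.path(dir, "signatures.gmt"))
  invisible(dir)
}
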
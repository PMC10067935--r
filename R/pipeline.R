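# End-to-end orchestration: synthetic inputs -> HLA exclusion -> SNP
# categorization -> E/T/C/P gene mapping -> ancestry partition -> category
# enrichment -> PPI network clustering with a random-cohort null ->
# single-sample signature scoring with Welch and regression downstream.

#' Default category-to-overall-group map for generated functional labels
#'
#' Splits the generated functional categories (`F01`, `F02`, ...) evenly
#' over the six overall-function groups. Real analyses replace this with
#' a curated mapping; the pipeline only requires that the map cover every
#' category label in use.
#'
#' @param categories Character vector of functional category labels.
#' @return Named character vector (category -> overall group).
#' @export
default_group_map <- function(categories) {
  groups <- c("immune", "tissue repair", "metabolic", "motility",
              "cell stress", "general")
  stats::setNames(rep_len(rep(groups, each = ceiling(length(categories) / 6)),
                          length(categories)),
                  sort(unique(categories)))
}

#' Pipeline configuration
#'
#' Bundles the synthetic-data config with every fixed constant of the
#' analysis: the HLA exclusion window, the enrichment flag rule (OR > 1
#' and -log10 p > 1.33), the network parameters (confidence cut 400,
#' connectivity gate 1e-16, MCODE defaults) and the signature-scoring
#' parameters.
#'
#' @param synth A [synth_config()]; its seed drives every stochastic
#'   stage.
#' @param hla_window Exclusion window ([default_hla_window()]).
#' @param enrichment List: `neg_log10_p_cut`.
#' @param network List: `min_score`, `gate`, `focus_ancestry` (ancestry
#'   whose predicted genes seed the network stage; default the first),
#'   `mcode` (parameter list for [mcode()]).
#' @param signatures List: `tau`, `min_set`, `kcdf`, `active_sledai`
#'   (threshold defining the active-disease subgroup for regressions).
#' @param out_dir Output directory for artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            hla_window = default_hla_window(),
                            enrichment = list(neg_log10_p_cut = 1.33),
                            network = list(min_score = 400, gate = 1e-16,
                                           focus_ancestry = NULL,
                                           mcode = list()),
                            signatures = list(tau = 1, min_set = 2,
                                              kcdf = "gaussian",
                                              active_sledai = 6),
                            out_dir = tempfile("snppath_run_")) {
  stopifnot(inherits(synth, "synth_config"))
  if (enrichment$neg_log10_p_cut <= 0 || network$gate <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  structure(list(synth = synth, hla_window = hla_window,
                 enrichment = enrichment, network = network,
                 signatures = signatures, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `synth`, `enrichment`, `network`, `signatures`,
#' `hla_window` and `out_dir` override the corresponding
#' [pipeline_config()] defaults; `seed` (or the `seed` argument, which
#' wins) overrides the synthetic seed.
#'
#' @param path YAML file.
#' @param seed Optional integer overriding the configured seed.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  synth_args <- raw$synth %||% list()
  # YAML mappings arrive as lists; the config wants named vectors
  for (nm in c("n_snps_per_ancestry")) {
    if (is.list(synth_args[[nm]])) {
      synth_args[[nm]] <- unlist(synth_args[[nm]])
    }
  }
  if (is.list(synth_args$category_proportions)) {
    synth_args$category_proportions <-
      lapply(synth_args$category_proportions, unlist)
  }
  if (is.list(synth_args$meta_spec)) {
    synth_args$meta_spec <- lapply(synth_args$meta_spec, unlist)
  }
  if (!is.null(raw$seed)) synth_args$seed <- raw$seed
  if (!is.null(seed)) synth_args$seed <- seed
  synth <- do.call(synth_config, synth_args)
  pipeline_config(
    synth = synth,
    hla_window = utils::modifyList(defaults$hla_window,
                                   raw$hla_window %||% list()),
    enrichment = utils::modifyList(defaults$enrichment,
                                   raw$enrichment %||% list()),
    network = utils::modifyList(defaults$network, raw$network %||% list()),
    signatures = utils::modifyList(defaults$signatures,
                                   raw$signatures %||% list()),
    out_dir = raw$out_dir %||% defaults$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes the stages in order (generate -> HLA exclusion ->
#' categorize -> map -> partition -> enrich -> network with random-null
#' comparison -> signatures), writes every intermediate artifact under
#' `config$out_dir`, and returns (and writes as JSON) a machine-readable
#' run report whose counts are recomputable from the artifacts. The run
#' is deterministic under the configured seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(schema_version = "1.0",
                 seed = config$synth$seed,
                 parameters = list(
                   hla_window = config$hla_window,
                   enrichment = config$enrichment,
                   network = config$network[c("min_score", "gate")],
                   signatures = config$signatures))

  synth <- run_stage("synthetic_data", {
    s <- synth_generate(config$synth)
    write_synth_inputs(s, file.path(config$out_dir, "inputs"))
    s
  })
  report$counts <- list(snp_rows = nrow(synth$snps),
                        unique_snps = length(unique(synth$snps$snp_id)))

  snps <- run_stage("exclude_hla",
                    exclude_hla(synth$snps, config$hla_window))
  report$counts$hla_removed <- attr(snps, "n_removed")
  report$counts$snp_rows_after_hla <- nrow(snps)

  categorized <- run_stage("categorize", categorize_snps(snps))
  cat_summary <- category_summary(categorized, by = "category")
  grp_summary <- category_summary(categorized, by = "group")
  ancestries <- sort(unique(categorized$ancestry))
  prop_tests <- NULL
  if (length(ancestries) == 2) {
    prop_tests <- run_stage("categorize", compare_category_proportions(
      grp_summary[grp_summary$ancestry == ancestries[1], ],
      grp_summary[grp_summary$ancestry == ancestries[2], ]))
    write_tsv_table(prop_tests,
                    file.path(config$out_dir, "group_proportion_tests.tsv"))
  }
  write_tsv_table(cat_summary,
                  file.path(config$out_dir, "category_summary.tsv"))
  report$proportion_tests <- prop_tests

  assignments <- run_stage("gene_mapping", {
    if (nrow(snps) == 0) stop("no SNPs available for gene mapping")
    assign_genes(categorized, synth$lookups$eqtl,
                 synth$lookups$regulatory, synth$lookups$coding,
                 synth$lookups$gene_coords,
                 universe = synth$lookups$universe)
  })
  write_tsv_table(assignments,
                  file.path(config$out_dir, "gene_assignments.tsv"))
  report$counts$assignments <- nrow(assignments)
  report$counts$assignments_by_class <-
    as.list(table(assignments$evidence))

  sets <- run_stage("partition", partition_by_ancestry(assignments))
  report$counts$genes_per_ancestry <- lapply(sets$per_ancestry, length)
  report$counts$genes_shared <- length(sets$shared)
  report$counts$genes_union <- length(unique(unlist(sets$per_ancestry)))
  venn <- NULL
  if (length(sets$per_ancestry) >= 2) {
    venn <- overlap_report(sets$per_ancestry)
    write_tsv_table(venn, file.path(config$out_dir, "ancestry_venn.tsv"))
  }
  report$venn <- venn

  enr <- run_stage("enrichment", {
    queries <- c(sets$specific, list(shared = sets$shared),
                 synth$annotation$signal_sets)
    queries <- queries[lengths(queries) > 0]
    enrichment_heat_table(queries, synth$annotation$functional,
                          neg_log10_p_cut =
                            config$enrichment$neg_log10_p_cut)
  })
  for (q in names(enr$tables)) {
    write_tsv_table(enr$tables[[q]],
                    file.path(config$out_dir,
                              paste0("enrichment_", q, ".tsv")))
  }
  report$enrichment <- lapply(enr$rankings, function(r) {
    r[c("category", "odds_ratio", "p", "enriched")]
  })

  net_report <- run_stage("network", {
    focus <- config$network$focus_ancestry %||%
      names(sets$per_ancestry)[1]
    real_genes <- intersect(sets$per_ancestry[[focus]], synth$ppi$nodes)
    background <- build_subnetwork(synth$ppi$nodes, synth$ppi$edges,
                                   min_score = config$network$min_score)
    real_net <- build_subnetwork(real_genes, synth$ppi$edges,
                                 min_score = config$network$min_score)
    gate <- ppi_enrichment_p(real_net, background,
                             gate = config$network$gate)
    real_clusters <- do.call(mcode, c(list(real_net),
                                      config$network$mcode))
    real_meta <- metastructure(real_clusters, real_net)
    cohort <- random_gene_cohort(synth$ppi$nodes, length(real_genes),
                                 seed = config$synth$seed + 101)
    rand_net <- build_subnetwork(cohort, synth$ppi$edges,
                                 min_score = config$network$min_score)
    rand_clusters <- do.call(mcode, c(list(rand_net),
                                      config$network$mcode))
    rand_meta <- metastructure(rand_clusters, rand_net)
    comparison <- if (nrow(real_meta) >= 2 && nrow(rand_meta) >= 2) {
      compare_to_random(real_meta, rand_meta)
    } else NULL
    gm <- default_group_map(
      unique(synth$annotation$functional$memberships$category))
    fractions <- list(
      real = category_fractions(real_genes,
                                synth$annotation$functional, gm),
      random = category_fractions(cohort,
                                  synth$annotation$functional, gm))
    cluster_df <- if (length(real_clusters) > 0) {
      data.frame(cluster = rep(vapply(real_clusters, `[[`, integer(1),
                                      "id"),
                               vapply(real_clusters, `[[`, integer(1),
                                      "size")),
                 gene = unlist(lapply(real_clusters, `[[`, "members")),
                 stringsAsFactors = FALSE)
    } else data.frame(cluster = integer(), gene = character())
    write_tsv_table(cluster_df,
                    file.path(config$out_dir, "mcode_clusters.tsv"))
    write_tsv_table(real_meta,
                    file.path(config$out_dir, "metastructure_real.tsv"))
    write_tsv_table(rand_meta,
                    file.path(config$out_dir, "metastructure_random.tsv"))
    list(focus_ancestry = focus, n_genes = length(real_genes),
         gate = gate[c("p", "lambda", "observed", "passes")],
         n_clusters_real = nrow(real_meta),
         n_clusters_random = nrow(rand_meta),
         metastructure_real = real_meta,
         metastructure_random = rand_meta,
         comparison = comparison, category_fractions = fractions)
  })
  report$network <- net_report

  sig_report <- run_stage("signatures", {
    ex <- synth$expression
    scores <- gsva_scores(ex$expr, ex$sets,
                          tau = config$signatures$tau,
                          min_set = config$signatures$min_set,
                          kcdf = config$signatures$kcdf)
    score_df <- data.frame(sample = rownames(scores),
                           as.data.frame(unclass(scores)),
                           check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_table(score_df, file.path(config$out_dir, "gsva_scores.tsv"))
    covars <- c("sledai", "anti_dsdna", "c3")
    reg_grid <- data.frame(
      x = rep(ex$planted_sets[1], length(covars)), y = covars,
      stringsAsFactors = FALSE)
    panel <- signature_panel_report(scores, ex$metadata,
                                    regressions = reg_grid)
    active <- ex$metadata$sledai >= config$signatures$active_sledai &
      ex$metadata$group == "case"
    active_panel <- if (sum(active) >= 3) {
      signature_panel_report(scores, ex$metadata,
                             regressions = reg_grid, subset = active)
    } else NULL
    write_tsv_table(panel$welch,
                    file.path(config$out_dir, "signature_welch.tsv"))
    list(welch = panel$welch, regressions = panel$regressions,
         active_regressions = if (!is.null(active_panel))
           active_panel$regressions else NULL,
         n_case = panel$n_case, n_control = panel$n_control,
         planted_sets = ex$planted_sets)
  })
  report$signatures <- sig_report

  json_path <- file.path(config$out_dir, "run_report.json")
  jsonlite::write_json(serialize_report(report), json_path,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  report$out_dir <- config$out_dir
  structure(report, class = "run_report")
}

# flatten data.frames so the JSON report is stable and readable
serialize_report <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (is.list(x)) return(lapply(x, serialize_report))
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat("snppath run report (seed", x$seed, ")\n")
  cat("  SNP rows:", x$counts$snp_rows, "| after HLA exclusion:",
      x$counts$snp_rows_after_hla, "\n")
  cat("  gene assignments:", x$counts$assignments, "| union genes:",
      x$counts$genes_union, "| shared:", x$counts$genes_shared, "\n")
  cat("  network: ", x$network$n_genes, " genes, ",
      x$network$n_clusters_real, " clusters (gate p = ",
      format(x$network$gate$p, digits = 3), ")\n", sep = "")
  sig <- x$signatures$welch$set[x$signatures$welch$significant]
  cat("  signatures flagged:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Validate pipeline input files
#'
#' Schema and referential-integrity diagnostics for every input dialect;
#' returns a pass/fail table rather than raising conditions.
#'
#' @param paths Named list of file paths; recognized names: `snps`,
#'   `eqtl`, `regulatory`, `coding`, `gene_coords`, `annotation`,
#'   `ppi_edges`, `expression`, `metadata`, `signatures_gmt`.
#' @return Data.frame: `file`, `check`, `pass`, `message`.
#' @export
validate_inputs <- function(paths) {
  out <- list()
  note <- function(file, check, pass, msg = "") {
    out[[length(out) + 1]] <<- data.frame(
      file = file, check = check, pass = pass, message = msg,
      stringsAsFactors = FALSE)
  }
  try_read <- function(name, cols) {
    if (is.null(paths[[name]])) return(NULL)
    res <- tryCatch(read_tsv_table(paths[[name]], required_cols = cols),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      note(name, "schema", FALSE, res)
      NULL
    } else {
      note(name, "schema", TRUE)
      res
    }
  }
  snps <- try_read("snps", c("snp_id", "chrom", "pos", "ancestry",
                             "consequence"))
  eqtl <- try_read("eqtl", c("snp_id", "gene"))
  regulatory <- try_read("regulatory", c("snp_id", "gene"))
  coding <- try_read("coding", c("snp_id", "gene"))
  coords <- try_read("gene_coords", c("gene", "chrom", "start", "end"))
  annotation <- try_read("annotation", c("gene", "category"))
  edges <- NULL
  if (!is.null(paths$ppi_edges)) {
    edges <- tryCatch(read_string_edges(paths$ppi_edges),
                      error = function(e) conditionMessage(e))
    if (is.character(edges)) {
      note("ppi_edges", "schema", FALSE, edges); edges <- NULL
    } else note("ppi_edges", "schema", TRUE)
  }
  expr <- NULL
  if (!is.null(paths$expression)) {
    expr <- tryCatch(read_expression_tsv(paths$expression),
                     error = function(e) conditionMessage(e))
    if (is.character(expr)) {
      note("expression", "schema", FALSE, expr); expr <- NULL
    } else note("expression", "schema", TRUE)
  }
  meta <- try_read("metadata", c("sample", "group"))
  if (!is.null(paths$signatures_gmt)) {
    gmt <- tryCatch(read_gmt(paths$signatures_gmt),
                    error = function(e) conditionMessage(e))
    if (is.character(gmt)) note("signatures_gmt", "schema", FALSE, gmt)
    else note("signatures_gmt", "schema", TRUE)
  }
  # referential integrity across tables
  if (!is.null(coords)) {
    universe <- unique(coords$gene)
    for (nm in c("eqtl", "regulatory", "coding")) {
      tab <- get(nm)
      if (is.null(tab)) next
      bad <- which(!(tab$gene %in% universe))
      note(nm, "genes_in_universe", length(bad) == 0,
           if (length(bad) > 0)
             paste0("row(s) ", paste(utils::head(bad, 5), collapse = ", "),
                    " reference unknown gene(s)") else "")
    }
    if (!is.null(annotation)) {
      bad <- which(!(annotation$gene %in% universe))
      note("annotation", "genes_in_universe", length(bad) == 0,
           if (length(bad) > 0) paste0(length(bad), " unknown gene(s)")
           else "")
    }
  }
  if (!is.null(snps)) {
    for (nm in c("eqtl", "regulatory", "coding")) {
      tab <- get(nm)
      if (is.null(tab)) next
      bad <- which(!(tab$snp_id %in% snps$snp_id))
      note(nm, "snps_known", length(bad) == 0,
           if (length(bad) > 0)
             paste0("row(s) ", paste(utils::head(bad, 5), collapse = ", "),
                    " reference unknown SNP(s)") else "")
    }
  }
  if (!is.null(expr) && !is.null(meta)) {
    missing <- setdiff(colnames(expr), meta$sample)
    note("metadata", "samples_cover_expression", length(missing) == 0,
         if (length(missing) > 0)
           paste("sample(s) missing:",
                 paste(utils::head(missing, 5), collapse = ", ")) else "")
  }
  do.call(rbind, out)
}
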
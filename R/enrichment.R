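#' Construct an annotation library
#'
#' An annotation library maps gene symbols to category labels over a
#' declared gene universe. Two flavours are used: a functional scheme
#' (BIG-C-style; exclusive, every annotated gene carries exactly one of
#' the ~54 categories) and a cell-type scheme (I-Scope-style;
#' non-exclusive, zero or more of ~30 hematopoietic categories per gene).
#'
#' @param scheme Scheme name (e.g. `"functional"`, `"celltype"`).
#' @param universe Character vector: the library's gene universe.
#' @param memberships Data.frame with columns `gene`, `category`.
#' @param exclusive Logical; if `TRUE` a gene may carry at most one
#'   category and duplicates are an error.
#' @return An object of class `annotation_library`.
#' @export
annotation_library <- function(scheme, universe, memberships,
                               exclusive = FALSE) {
  stopifnot(all(c("gene", "category") %in% names(memberships)))
  universe <- unique(as.character(universe))
  memberships <- unique(memberships[c("gene", "category")])
  outside <- setdiff(unique(memberships$gene), universe)
  if (length(outside) > 0) {
    stop("membership gene(s) outside the declared universe: ",
         paste(utils::head(outside, 10), collapse = ", "), call. = FALSE)
  }
  if (exclusive && anyDuplicated(memberships$gene)) {
    dup <- unique(memberships$gene[duplicated(memberships$gene)])
    stop("exclusive scheme '", scheme, "' assigns multiple categories to: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  structure(list(scheme = scheme, universe = universe,
                 memberships = memberships, exclusive = exclusive),
            class = "annotation_library")
}

#' @export
print.annotation_library <- function(x, ...) {
  cat(sprintf("annotation library '%s': %d genes, %d categories (%s)\n",
              x$scheme, length(x$universe),
              length(unique(x$memberships$category)),
              if (x$exclusive) "exclusive" else "non-exclusive"))
  invisible(x)
}

#' Read an annotation library from TSV or GMT
#'
#' TSV input needs columns `gene`, `category` (an optional `scheme`
#' column is checked for consistency). GMT input treats each set as a
#' category. The universe defaults to the union of annotated genes.
#'
#' @param path File path (`.gmt` files are detected by extension).
#' @param scheme Scheme name for the resulting library.
#' @param universe Optional explicit universe.
#' @param exclusive Passed to [annotation_library()].
#' @return An `annotation_library`.
#' @export
read_annotation_library <- function(path, scheme = "functional",
                                    universe = NULL, exclusive = FALSE) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- read_gmt(path)
    memberships <- data.frame(
      gene = unlist(sets, use.names = FALSE),
      category = rep(names(sets), lengths(sets)),
      stringsAsFactors = FALSE)
  } else {
    memberships <- read_tsv_table(path, required_cols = c("gene",
                                                          "category"))
  }
  if (is.null(universe)) universe <- unique(memberships$gene)
  annotation_library(scheme, universe, memberships, exclusive = exclusive)
}

#' Category over-representation for a gene set
#'
#' For each category, builds the 2x2 table over the library universe
#' (in-query x in-category) and reports the sample odds ratio `ad/bc`
#' (`Inf` when `bc = 0` and `ad > 0`; 0 when `ad = 0`) and the one-sided
#' exact hypergeometric p-value for over-representation. A category is
#' flagged `enriched` exactly when the odds ratio exceeds 1 and
#' `-log10(p)` exceeds `neg_log10_p_cut` (default 1.33, i.e. p below
#' about 0.0468). Benjamini-Hochberg adjusted p-values are emitted for
#' information only; flags use the raw rule. Query genes outside the
#' library universe are dropped with a message.
#'
#' @param query Character vector of gene symbols.
#' @param library An [annotation_library()].
#' @param neg_log10_p_cut Threshold on `-log10(p)` for the enriched flag.
#' @return Data.frame with one row per category: `category`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `p`, `p_bh`, `neg_log10_p`, `enriched`,
#'   ordered by `p` then category label.
#' @export
enrich_categories <- function(query, library, neg_log10_p_cut = 1.33) {
  stopifnot(inherits(library, "annotation_library"))
  query <- unique(as.character(query))
  dropped <- setdiff(query, library$universe)
  if (length(dropped) > 0) {
    message(length(dropped), " query gene(s) outside the '",
            library$scheme, "' universe dropped")
  }
  query <- intersect(query, library$universe)
  if (length(query) == 0) {
    stop("query has no genes in the library universe", call. = FALSE)
  }
  N <- length(library$universe)
  nq <- length(query)
  cats <- sort(unique(library$memberships$category))
  by_cat <- split(library$memberships$gene, library$memberships$category)
  rows <- lapply(cats, function(cat) {
    members <- unique(by_cat[[cat]])
    K <- length(members)
    a <- length(intersect(query, members))
    b <- nq - a
    cc <- K - a
    d <- N - a - b - cc
    or <- if (a * d == 0) 0 else if (b * cc == 0) Inf else
      (a * d) / (b * cc)
    p <- stats::phyper(a - 1, K, N - K, nq, lower.tail = FALSE)
    data.frame(category = cat, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$neg_log10_p <- -log10(out$p)
  out$enriched <- out$odds_ratio > 1 & out$neg_log10_p > neg_log10_p_cut
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_query_dropped") <- length(dropped)
  out
}

#' Signed enrichment heat table over several queries
#'
#' Runs [enrich_categories()] for each named query and assembles a
#' categories x queries matrix of `-log10(p)` signed by the direction of
#' the odds ratio (positive when OR > 1). Also returns, per query, the
#' enriched categories ranked by ascending p with deterministic
#' label-order tie-breaks, optionally truncated to the top `k`.
#'
#' @param queries Named list of gene-symbol vectors.
#' @param library An [annotation_library()].
#' @param top_k Optional integer: keep only the `k` best-ranked enriched
#'   categories per query.
#' @inheritParams enrich_categories
#' @return List of class `enrichment_heat` with `matrix` (signed
#'   `-log10 p`), `rankings` (named list of data.frames) and `tables`
#'   (full per-query enrichment tables).
#' @export
enrichment_heat_table <- function(queries, library, top_k = NULL,
                                  neg_log10_p_cut = 1.33) {
  stopifnot(is.list(queries), length(queries) >= 1, !is.null(names(queries)))
  tables <- lapply(queries, enrich_categories, library = library,
                   neg_log10_p_cut = neg_log10_p_cut)
  cats <- sort(unique(library$memberships$category))
  mat <- vapply(tables, function(tab) {
    tab <- tab[match(cats, tab$category), ]
    sign <- ifelse(tab$odds_ratio > 1, 1, -1)
    sign * tab$neg_log10_p
  }, numeric(length(cats)))
  if (length(cats) == 1) mat <- matrix(mat, nrow = 1)
  dimnames(mat) <- list(cats, names(queries))
  rankings <- lapply(tables, function(tab) {
    r <- tab[tab$enriched, , drop = FALSE]
    r <- r[order(r$p, r$category), , drop = FALSE]
    if (!is.null(top_k)) r <- utils::head(r, top_k)
    rownames(r) <- NULL
    r
  })
  structure(list(matrix = mat, rankings = rankings, tables = tables),
            class = "enrichment_heat")
}
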
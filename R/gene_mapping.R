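# Evidence cascade linking association SNPs to candidate genes:
# E (eQTL target), T (regulatory-element target), C (coding consequence)
# are independent lookups; P (closest proximal gene) is the fallback for
# SNPs with no E/T/C evidence.

#' Default HLA exclusion window
#'
#' The chromosome-6 major-histocompatibility region is conventionally
#' dropped from SNP-to-gene mapping because its extreme linkage
#' disequilibrium makes per-SNP gene assignment meaningless.
#'
#' @return List with `chrom`, `start`, `end` (1-based, closed interval).
#' @export
default_hla_window <- function() {
  list(chrom = "6", start = 28014374, end = 33683352)
}

#' Remove SNPs inside the HLA exclusion window
#'
#' Coordinates are 1-based and the window is fully closed: a SNP exactly
#' at `start` or `end` is removed. The number of removed rows is attached
#' as the `n_removed` attribute and reported via `message()`.
#'
#' @param snps SNP table with `chrom` and `pos` columns.
#' @param window Exclusion window, defaulting to [default_hla_window()].
#' @return The filtered SNP table.
#' @export
exclude_hla <- function(snps, window = default_hla_window()) {
  stopifnot(all(c("chrom", "pos") %in% names(snps)))
  inside <- as.character(snps$chrom) == as.character(window$chrom) &
    snps$pos >= window$start & snps$pos <= window$end
  out <- snps[!inside, , drop = FALSE]
  rownames(out) <- NULL
  message(sum(inside), " SNP row(s) removed in exclusion window ",
          "chr", window$chrom, ":", window$start, "-", window$end)
  attr(out, "n_removed") <- sum(inside)
  out
}

# Collapse a long (one row per SNP x ancestry) table to one row per SNP,
# with ancestries joined into a sorted comma-separated string.
unique_snps <- function(snps) {
  stopifnot(all(c("snp_id", "ancestry") %in% names(snps)))
  anc <- vapply(split(snps$ancestry, snps$snp_id),
                function(a) paste(sort(unique(a)), collapse = ","),
                character(1))
  first <- snps[!duplicated(snps$snp_id), , drop = FALSE]
  first$ancestries <- unname(anc[first$snp_id])
  first$ancestry <- NULL
  rownames(first) <- NULL
  first
}

#' Assign E-, T- and C-genes from lookup tables
#'
#' The three evidence classes are independent lookups, not exclusive: a
#' SNP found in more than one table yields assignments in each class (and
#' is thereby ineligible for the proximal fallback). All target genes per
#' hit are emitted and weighted equally regardless of class.
#'
#' @param snps SNP table in long format (`snp_id`, `ancestry`, ...).
#' @param eqtl_table,regulatory_table,coding_table Lookup tables with
#'   columns `snp_id`, `gene`; extra columns are ignored.
#' @param universe Optional character vector of valid gene symbols; a
#'   lookup gene outside it is a referential-integrity error.
#' @return A data.frame of gene assignments: `snp_id`, `gene`, `evidence`
#'   (one of E/T/C), `source`, `ancestries`.
#' @export
assign_evidence_genes <- function(snps, eqtl_table, regulatory_table,
                                  coding_table, universe = NULL) {
  usnp <- unique_snps(snps)
  anc_of <- stats::setNames(usnp$ancestries, usnp$snp_id)
  one_class <- function(tab, evidence, source) {
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    stopifnot(all(c("snp_id", "gene") %in% names(tab)))
    tab <- tab[tab$snp_id %in% usnp$snp_id, , drop = FALSE]
    if (nrow(tab) == 0) return(NULL)
    if (!is.null(universe)) {
      bad <- setdiff(unique(tab$gene), universe)
      if (length(bad) > 0) {
        stop("referential-integrity error: ", source,
             " table references gene(s) outside the universe: ",
             paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
      }
    }
    data.frame(snp_id = tab$snp_id, gene = tab$gene, evidence = evidence,
               source = source, ancestries = unname(anc_of[tab$snp_id]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_class(eqtl_table, "E", "eqtl"),
               one_class(regulatory_table, "T", "regulatory"),
               one_class(coding_table, "C", "coding"))
  if (is.null(out)) {
    out <- data.frame(snp_id = character(), gene = character(),
                      evidence = character(), source = character(),
                      ancestries = character(), stringsAsFactors = FALSE)
  }
  # (snp_id, gene, evidence) unique: collapse duplicate rows within class
  out <- out[!duplicated(out[c("snp_id", "gene", "evidence")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign the closest proximal gene (P-gene) to unassigned SNPs
#'
#' Each SNP receives exactly one gene: distance 0 if the SNP lies inside
#' the gene interval, otherwise the gap to the nearest interval end, with
#' genes restricted to the SNP's chromosome. Ties are broken
#' lexicographically by gene symbol (documented contract). Intervals are
#' 1-based and fully closed.
#'
#' @param unassigned_snps Long-format SNP table restricted to SNPs with no
#'   E/T/C assignment.
#' @param gene_coords Gene coordinate table: `gene`, `chrom`, `start`,
#'   `end`.
#' @return A data.frame of P assignments (same shape as
#'   [assign_evidence_genes()]) plus a `distance` column.
#' @export
assign_proximal <- function(unassigned_snps, gene_coords) {
  if (is.null(gene_coords) || nrow(gene_coords) == 0) {
    stop("gene coordinate table is empty", call. = FALSE)
  }
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_coords)))
  usnp <- unique_snps(unassigned_snps)
  if (nrow(usnp) == 0) {
    return(data.frame(snp_id = character(), gene = character(),
                      evidence = character(), source = character(),
                      ancestries = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  coords_by_chrom <- split(gene_coords, as.character(gene_coords$chrom))
  pick <- function(i) {
    g <- coords_by_chrom[[as.character(usnp$chrom[i])]]
    if (is.null(g) || nrow(g) == 0) {
      stop("no genes on chromosome ", usnp$chrom[i],
           " for SNP ", usnp$snp_id[i], call. = FALSE)
    }
    pos <- usnp$pos[i]
    d <- pmax(0, pmax(g$start - pos, pos - g$end))
    ord <- order(d, g$gene)
    c(gene = g$gene[ord[1]], distance = d[ord[1]])
  }
  hits <- vapply(seq_len(nrow(usnp)), pick, c(gene = "", distance = ""))
  data.frame(snp_id = usnp$snp_id, gene = unname(hits["gene", ]),
             evidence = "P", source = "proximal",
             ancestries = usnp$ancestries,
             distance = as.numeric(hits["distance", ]),
             stringsAsFactors = FALSE)
}

#' Run the full E/T/C/P evidence cascade
#'
#' Applies [assign_evidence_genes()] then [assign_proximal()] to the SNPs
#' left without any E/T/C link, and binds the results. Cascade
#' exclusivity (no SNP holds both a P and an E/T/C assignment) holds by
#' construction.
#'
#' @inheritParams assign_evidence_genes
#' @param gene_coords Gene coordinate table for the proximal fallback.
#' @return A data.frame of GeneAssignment rows.
#' @export
assign_genes <- function(snps, eqtl_table, regulatory_table, coding_table,
                         gene_coords, universe = NULL) {
  etc <- assign_evidence_genes(snps, eqtl_table, regulatory_table,
                               coding_table, universe = universe)
  left <- snps[!(snps$snp_id %in% etc$snp_id), , drop = FALSE]
  p <- assign_proximal(left, gene_coords)
  p$distance <- NULL
  rbind(etc, p)
}

split_ancestries <- function(x) strsplit(x, ",", fixed = TRUE)

#' Partition assigned genes by ancestry
#'
#' A gene's ancestry set is the union of the ancestry labels of every SNP
#' linked to it (any evidence class). A gene is "shared"
#' (trans-ancestral) iff its ancestry set covers all ancestries present;
#' ancestry-specific sets exclude shared genes.
#'
#' @param assignments GeneAssignment table from [assign_genes()].
#' @return An object of class `ancestry_gene_sets`: list with
#'   `per_ancestry` (gene sets including shared genes), `shared`,
#'   `specific` (per-ancestry minus shared), and `per_class` (per
#'   ancestry, per evidence class gene sets, shared genes included).
#' @export
partition_by_ancestry <- function(assignments) {
  anc_lists <- split_ancestries(assignments$ancestries)
  ancestries <- sort(unique(unlist(anc_lists)))
  per_ancestry <- lapply(ancestries, function(a) {
    sort(unique(assignments$gene[vapply(anc_lists, function(x) a %in% x,
                                        logical(1))]))
  })
  names(per_ancestry) <- ancestries
  shared <- if (length(per_ancestry) == 0) character(0) else
    sort(Reduce(intersect, per_ancestry))
  specific <- lapply(per_ancestry, function(g) setdiff(g, shared))
  per_class <- lapply(ancestries, function(a) {
    in_a <- vapply(anc_lists, function(x) a %in% x, logical(1))
    sub <- assignments[in_a, , drop = FALSE]
    lapply(split(sub$gene, factor(sub$evidence,
                                  levels = c("E", "T", "C", "P"))),
           function(g) sort(unique(g)))
  })
  names(per_class) <- ancestries
  structure(list(per_ancestry = per_ancestry, shared = shared,
                 specific = specific, per_class = per_class),
            class = "ancestry_gene_sets")
}

#' @export
print.ancestry_gene_sets <- function(x, ...) {
  for (a in names(x$per_ancestry)) {
    cat(sprintf("%s: %d genes (%d specific)\n", a,
                length(x$per_ancestry[[a]]), length(x$specific[[a]])))
  }
  cat(sprintf("shared: %d genes; union: %d genes\n", length(x$shared),
              length(unique(unlist(x$per_ancestry)))))
  invisible(x)
}

#' Venn region counts for named gene sets
#'
#' Counts every region of the n-set Venn partition. Region labels join
#' member set names with `&`. Inclusion-exclusion consistency (region
#' counts sum to the union size) holds by construction and is asserted.
#'
#' @param sets Named list of >= 2 character vectors.
#' @return A data.frame with columns `region`, `degree` (number of sets in
#'   the region) and `count`, including empty regions; the union size is
#'   attached as attribute `union_size`.
#' @export
overlap_report <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL,
                                                              names(sets)))
  n <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1, function(pat) {
    if (length(universe) == 0) return(0L)
    sum(apply(member, 1, function(row) all(row == pat)))
  })
  region <- apply(patterns, 1, function(pat) {
    paste(names(sets)[as.logical(pat)], collapse = "&")
  })
  out <- data.frame(region = region, degree = rowSums(patterns),
                    count = as.integer(counts), stringsAsFactors = FALSE,
                    row.names = NULL)
  stopifnot(sum(out$count) == length(universe))
  attr(out, "union_size") <- length(universe)
  out
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Draw a random gene cohort
#'
#' Uniform sample without replacement from the gene universe,
#' reproducible under `seed`; the standard null cohort for network and
#' category-fraction comparisons.
#'
#' @param universe Character vector of gene symbols.
#' @param n Cohort size (must not exceed the universe size).
#' @param seed Integer seed.
#' @return Sorted character vector of `n` genes.
#' @export
random_gene_cohort <- function(universe, n, seed) {
  universe <- unique(universe)
  if (n > length(universe)) {
    stop("cohort size ", n, " exceeds universe size ", length(universe),
         call. = FALSE)
  }
  sort(with_seed(seed, sample(universe, n)))
}

#' Filter a differential-expression table to significant, deduplicated genes
#'
#' Retains probes with FDR strictly below the threshold, then keeps only
#' the most significant (smallest p) probe per gene. The FDR threshold is
#' deliberately permissive by default (0.2) to avoid falsely excluding
#' genes before set-overlap analyses.
#'
#' @param deg_table Data.frame with columns `probe`, `gene`, `p`, `FDR`.
#' @param fdr_threshold Strict upper bound on FDR (default 0.2).
#' @return List with `table` (one row per retained gene) and `genes`
#'   (deduplicated gene list).
#' @export
filter_deg_table <- function(deg_table, fdr_threshold = 0.2) {
  needed <- c("probe", "gene", "p", "FDR")
  missing <- setdiff(needed, names(deg_table))
  if (length(missing) > 0) {
    stop("DEG table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- deg_table[deg_table$FDR < fdr_threshold, , drop = FALSE]
  if (nrow(keep) > 0) {
    keep <- keep[order(keep$gene, keep$p, keep$FDR, keep$probe), ,
                 drop = FALSE]
    keep <- keep[!duplicated(keep$gene), , drop = FALSE]
  }
  rownames(keep) <- NULL
  list(table = keep, genes = sort(unique(keep$gene)))
}
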
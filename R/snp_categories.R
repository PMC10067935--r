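#' Default consequence-term vocabulary
#'
#' Maps each controlled-vocabulary variant-consequence term to a genomic
#' functional category and a super-group. The groups follow the usual
#' reporting convention for disease-association SNP lists:
#' \describe{
#'   \item{non-coding}{intergenic and intronic variants}
#'   \item{ncRNA}{variants in non-coding RNA genes (lncRNA, miRNA) --
#'     tracked as its own super-group because ancestral comparisons quote
#'     ncRNA fractions separately}
#'   \item{regulatory}{transcription-factor binding sites, promoters,
#'     enhancers, repressors, promoter-flanking regions, open chromatin}
#'   \item{coding}{5'/3' UTRs, synonymous, missense and nonsense variants}
#' }
#' An editable copy ships as `inst/extdata/consequence_map.yaml`; pass a
#' modified map to [categorize_snps()] to change the vocabulary.
#'
#' @return A data.frame with columns `consequence`, `category`, `group`.
#' @export
default_consequence_map <- function() {
  path <- system.file("extdata", "consequence_map.yaml", package = "snppath")
  read_consequence_map(path)
}

#' Read a consequence vocabulary from YAML
#'
#' The YAML maps each consequence term to a `category` and `group` pair.
#'
#' @param path YAML file path.
#' @return A data.frame with columns `consequence`, `category`, `group`.
#' @export
read_consequence_map <- function(path) {
  raw <- yaml::read_yaml(path)
  df <- data.frame(
    consequence = names(raw),
    category = vapply(raw, function(x) x$category, character(1)),
    group = vapply(raw, function(x) x$group, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  bad <- setdiff(unique(df$group),
                 c("non-coding", "ncRNA", "regulatory", "coding"))
  if (length(bad) > 0) {
    stop("unknown super-group(s) in vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Assign each SNP a genomic functional category
#'
#' Category and super-group are pure functions of the pre-annotated
#' consequence term; an unknown term is an error naming the offending
#' term, never a silent "other".
#'
#' @param snps SNP table in long format (one row per SNP x ancestry) with
#'   at least columns `snp_id`, `ancestry`, `consequence`.
#' @param vocabulary Consequence map as returned by
#'   [default_consequence_map()].
#' @return `snps` with `category` and `group` columns filled.
#' @seealso [category_summary()] for the per-ancestry count table.
#' @export
categorize_snps <- function(snps, vocabulary = default_consequence_map()) {
  stopifnot(all(c("snp_id", "ancestry", "consequence") %in% names(snps)))
  idx <- match(snps$consequence, vocabulary$consequence)
  if (anyNA(idx)) {
    unknown <- sort(unique(snps$consequence[is.na(idx)]))
    stop("unknown consequence term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  snps$category <- vocabulary$category[idx]
  snps$group <- vocabulary$group[idx]
  snps
}

#' Per-ancestry category count summary
#'
#' Counts unique SNPs per (ancestry, category). A SNP associated in both
#' ancestries appears once in each ancestry's counts and denominator.
#'
#' @param snps Categorized SNP table (from [categorize_snps()]).
#' @param by Count by `"category"` (default) or by super-`"group"`.
#' @return A data.frame with columns `ancestry`, `category`, `count`, `n`
#'   where `n` is the total SNP count for that ancestry.
#' @export
category_summary <- function(snps, by = c("category", "group")) {
  by <- match.arg(by)
  stopifnot(all(c("snp_id", "ancestry", by) %in% names(snps)))
  dedup <- snps[!duplicated(paste(snps$snp_id, snps$ancestry)), ]
  if (nrow(dedup) == 0) {
    return(data.frame(ancestry = character(), category = character(),
                      count = integer(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(dedup$ancestry, dedup[[by]])
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("ancestry", "category", "count")
  totals <- rowSums(tab)
  out$n <- as.integer(totals[out$ancestry])
  out[order(out$ancestry, out$category), , drop = FALSE]
}

#' Two-proportion z-test
#'
#' Pooled two-sample test of equal proportions with no continuity
#' correction, the form customarily used to compare SNP category fractions
#' between ancestral cohorts. Two-tailed p-value from the normal
#' distribution. Degenerate contract: when the pooled proportion is 0 or 1
#' (both samples all-failures or all-successes) the statistic is defined
#' as z = 0, p = 1.
#'
#' @param count_a,n_a Successes and trials in group A.
#' @param count_b,n_b Successes and trials in group B.
#' @return A list of class `prop_z_test` with fields `count_a`, `n_a`,
#'   `count_b`, `n_b`, `estimate_a`, `estimate_b`, `z`, `p`.
#' @examples
#' two_proportion_z(70, 100, 50, 100)
#' @export
two_proportion_z <- function(count_a, n_a, count_b, n_b) {
  if (n_a < 1 || n_b < 1) stop("group sizes must be >= 1", call. = FALSE)
  if (count_a < 0 || count_b < 0 || count_a > n_a || count_b > n_b) {
    stop("counts must lie in [0, n] for each group", call. = FALSE)
  }
  p_a <- count_a / n_a
  p_b <- count_b / n_b
  pooled <- (count_a + count_b) / (n_a + n_b)
  if (pooled <= 0 || pooled >= 1) {
    z <- 0
    p <- 1
  } else {
    se <- sqrt(pooled * (1 - pooled) * (1 / n_a + 1 / n_b))
    z <- (p_a - p_b) / se
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  structure(list(count_a = count_a, n_a = n_a, count_b = count_b, n_b = n_b,
                 estimate_a = p_a, estimate_b = p_b, z = z, p = p),
            class = "prop_z_test")
}

#' @export
print.prop_z_test <- function(x, ...) {
  cat(sprintf("2-proportion z-test: %d/%d vs %d/%d  z = %.4f, p = %.4g\n",
              x$count_a, x$n_a, x$count_b, x$n_b, x$z, x$p))
  invisible(x)
}

#' Compare category proportions between two ancestries
#'
#' One two-proportion z-test per category, flagged at raw two-tailed
#' p < 0.05. No multiplicity adjustment is applied to the flags (the
#' customary reporting rule for these per-category comparisons);
#' Benjamini-Hochberg adjusted p-values are emitted alongside for
#' transparency but do not drive the `significant` column.
#'
#' @param summary_a,summary_b Per-ancestry summaries from
#'   [category_summary()], restricted to one ancestry each, over the same
#'   category vocabulary.
#' @param alpha Flagging threshold on the raw p-value (default 0.05).
#' @return A data.frame with one row per category: counts, denominators,
#'   proportions, `z`, `p`, `p_bh`, `significant`.
#' @export
compare_category_proportions <- function(summary_a, summary_b, alpha = 0.05) {
  for (s in list(summary_a, summary_b)) {
    stopifnot(all(c("category", "count", "n") %in% names(s)))
  }
  if (!setequal(summary_a$category, summary_b$category)) {
    stop("category vocabularies differ between the two summaries",
         call. = FALSE)
  }
  cats <- sort(unique(summary_a$category))
  a <- summary_a[match(cats, summary_a$category), ]
  b <- summary_b[match(cats, summary_b$category), ]
  tests <- lapply(seq_along(cats), function(i) {
    two_proportion_z(a$count[i], a$n[i], b$count[i], b$n[i])
  })
  out <- data.frame(
    category = cats,
    count_a = a$count, n_a = a$n,
    count_b = b$count, n_b = b$n,
    prop_a = a$count / a$n,
    prop_b = b$count / b$n,
    z = vapply(tests, `[[`, numeric(1), "z"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out
}
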
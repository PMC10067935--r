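# Single-sample gene-set scoring with a KS-like weighted random walk over
# kernel-CDF-ranked genes, plus the downstream Welch-t and simple-linear-
# regression analyses applied to the resulting score matrix.

#' Read a log2 expression matrix from TSV
#'
#' Genes as rows (first column `gene`), samples as header columns.
#' Ingestion contract: no missing values, unique gene identifiers, at
#' least two samples.
#'
#' @param path TSV path.
#' @return Numeric matrix (genes x samples) with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_table(path, required_cols = "gene")
  genes <- df$gene
  mat <- as.matrix(df[setdiff(names(df), "gene")])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (anyNA(mat)) stop("expression matrix contains missing values",
                       call. = FALSE)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers",
                                 call. = FALSE)
  if (ncol(mat) < 2) stop("need at least two samples", call. = FALSE)
  mat
}

# Kernel CDF estimate per gene: z[i, j] = mean_k Phi((x[i,j] - x[i,k]) / h_i)
# with h_i = sd_i / 4 floored at 1e-8 (Gaussian), or the empirical CDF
# rank/n (ecdf).
kcdf_scores <- function(expr, kcdf = c("gaussian", "ecdf")) {
  kcdf <- match.arg(kcdf)
  n <- ncol(expr)
  if (kcdf == "ecdf") {
    t(apply(expr, 1, function(x) {
      rank(x, ties.method = "max") / n
    }))
  } else {
    t(apply(expr, 1, function(x) {
      h <- max(stats::sd(x) / 4, 1e-8)
      colMeans(stats::pnorm(outer(x, x, FUN = function(a, b) (b - a) / h)))
    }))
  }
}

# KS-like random walk for one ordered gene list. in_set: logical along the
# ranked list (position 1 = top). r_pos: symmetric rank statistic |p/2 - t|
# along positions. Returns max positive deviation + min negative deviation
# (magnitude difference) or the max-absolute-deviation alternative.
ks_walk <- function(in_set, r_pos, tau, summary_rule) {
  p <- length(in_set)
  m <- sum(in_set)
  denom_in <- sum(r_pos[in_set]^tau)
  step <- numeric(p)
  if (denom_in > 0) step[in_set] <- r_pos[in_set]^tau / denom_in
  step[!in_set] <- -1 / (p - m)
  v <- cumsum(step)
  if (summary_rule == "max_abs") {
    v[which.max(abs(v))]
  } else {
    max(c(0, v)) + min(c(0, v))
  }
}

#' Single-sample gene-set enrichment scores (KS-like random walk)
#'
#' Non-parametric per-sample scoring of gene-set activity from a log2
#' expression matrix, following the GSVA algorithm:
#' \enumerate{
#'   \item Per gene, an expression-level statistic is computed as the
#'     kernel CDF estimate of each observation against the gene's own
#'     sample distribution: Gaussian kernel with bandwidth `sd/4`
#'     (floored at 1e-8 for constant genes), or the empirical CDF when
#'     `kcdf = "ecdf"` (which makes scores exactly invariant to any
#'     strictly monotone per-gene transformation).
#'   \item Per sample, genes are ranked by decreasing statistic (ties
#'     broken by gene label) and the rank is symmetrized:
#'     `r = |p/2 - rank|` for `p` genes.
#'   \item A KS-like random walk runs down the ranked list: in-set steps
#'     are weighted `r^tau` normalized by the set total, out-of-set
#'     steps are `1/(p - set size)`.
#'   \item The score is the magnitude difference: maximum positive walk
#'     deviation plus minimum negative deviation (default), or the
#'     maximum absolute deviation when `summary_rule = "max_abs"`.
#' }
#' Scores lie in \[-1, 1\] under the magnitude-difference summary.
#' Degenerate contracts: a set covering all genes scores 0 for every
#' sample and is flagged; a sample whose statistics are completely tied
#' (e.g. a constant matrix) scores 0 for every set; sets with fewer than
#' `min_set` genes in the matrix are skipped with a warning.
#'
#' @param expr Numeric matrix (genes x samples, log2 scale) with
#'   dimnames, or a TSV path for [read_expression_tsv()].
#' @param sets Named list of gene-symbol vectors, or a GMT path.
#' @param tau Weighting exponent on the symmetric rank (default 1).
#' @param min_set Minimum mapped set size (default 2).
#' @param kcdf Kernel for the expression statistic: `"gaussian"`
#'   (default) or `"ecdf"`.
#' @param summary_rule `"magnitude_difference"` (default) or
#'   `"max_abs"`.
#' @return Samples x sets numeric matrix of class `score_matrix`;
#'   parameters are attached as the `params` attribute, degenerate
#'   (all-genes) sets as `degenerate_sets`.
#' @export
gsva_scores <- function(expr, sets, tau = 1, min_set = 2,
                        kcdf = c("gaussian", "ecdf"),
                        summary_rule = c("magnitude_difference",
                                         "max_abs")) {
  kcdf <- match.arg(kcdf)
  summary_rule <- match.arg(summary_rule)
  if (is.character(expr) && length(expr) == 1) {
    expr <- read_expression_tsv(expr)
  }
  if (is.character(sets) && length(sets) == 1) sets <- read_gmt(sets)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)))
  p <- nrow(expr)
  n <- ncol(expr)
  if (p < 3) stop("need at least 3 genes", call. = FALSE)
  genes <- rownames(expr)
  mapped <- lapply(sets, function(s) intersect(unique(s), genes))
  too_small <- names(sets)[lengths(mapped) < min_set]
  if (length(too_small) > 0) {
    warning("skipping set(s) with fewer than ", min_set,
            " mapped genes: ", paste(too_small, collapse = ", "),
            call. = FALSE)
    mapped <- mapped[lengths(mapped) >= min_set]
  }
  degenerate <- names(mapped)[lengths(mapped) == p]
  if (length(degenerate) > 0) {
    warning("set(s) covering all genes score 0 by contract: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  z <- kcdf_scores(expr, kcdf = kcdf)
  r_pos <- abs(p / 2 - seq_len(p))
  scores <- matrix(0, nrow = n, ncol = length(mapped),
                   dimnames = list(colnames(expr), names(mapped)))
  for (j in seq_len(n)) {
    zj <- z[, j]
    if (max(zj) - min(zj) == 0) next  # complete tie: scores stay 0
    ord <- order(-zj, genes)
    ranked_genes <- genes[ord]
    for (s in seq_along(mapped)) {
      if (names(mapped)[s] %in% degenerate) next
      in_set <- ranked_genes %in% mapped[[s]]
      scores[j, s] <- ks_walk(in_set, r_pos, tau, summary_rule)
    }
  }
  structure(scores, class = c("score_matrix", "matrix"),
            params = list(tau = tau, min_set = min_set, kcdf = kcdf,
                          summary_rule = summary_rule),
            degenerate_sets = degenerate)
}

#' Welch's unequal-variance t-test
#'
#' Two-sample location test with the Satterthwaite degrees-of-freedom
#' approximation and a two-tailed p-value. Degenerate contract: when both
#' groups have zero variance the comparison falls back to an exact
#' equality test (t = 0, p = 1 if the means are equal; otherwise t is
#' signed infinity and p = 0).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List of class `welch_test`: `t`, `df`, `p`, `mean_a`,
#'   `mean_b`, `conf_int` (95% CI on `mean(a) - mean(b)`).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  diff <- ma - mb
  if (va == 0 && vb == 0) {
    if (diff == 0) {
      res <- list(t = 0, df = NA_real_, p = 1)
    } else {
      res <- list(t = sign(diff) * Inf, df = NA_real_, p = 0)
    }
    ci <- c(diff, diff)
  } else {
    se <- sqrt(va / na + vb / nb)
    t <- diff / se
    df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    ci <- diff + c(-1, 1) * stats::qt(0.975, df) * se
    res <- list(t = t, df = df, p = p)
  }
  structure(c(res, list(mean_a = ma, mean_b = mb, conf_int = ci)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %.4g (means %.4g vs %.4g)\n",
              x$t, x$df, x$p, x$mean_a, x$mean_b))
  invisible(x)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with the slope's two-tailed
#' t-test; R-squared equals the squared Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must not be
#'   constant.
#' @return List of class `linreg`: `slope`, `intercept`, `r_squared`,
#'   `p` (slope t-test), `n`.
#' @export
simple_linreg <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p = sm$coefficients[2, 4],
                 n = length(x)),
            class = "linreg")
}

#' @export
print.linreg <- function(x, ...) {
  cat(sprintf("y = %.4g + %.4g x  (R2 = %.4f, p = %.4g, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$p, x$n))
  invisible(x)
}

#' Signature panel report: per-set Welch tests and a regression grid
#'
#' For every gene set in a score matrix, compares case against control
#' scores with Welch's t-test (flagged at p below `alpha`), then runs
#' simple linear regressions over a configured grid of (x, y) pairs
#' where each name refers to a score column or a numeric metadata
#' covariate. An optional subgroup filter (e.g. restricting to active
#' patients with SLEDAI of 6 or more) applies to the regressions, whose
#' reported `n` reflects the samples actually used.
#'
#' @param scores A `score_matrix` (samples x sets) from [gsva_scores()].
#' @param metadata Data.frame with one row per sample, a `sample` column
#'   matching the score-matrix rownames, and a `group` column.
#' @param case_label,control_label Group labels for the Welch contrast.
#' @param regressions Optional data.frame with columns `x`, `y` naming
#'   score columns or numeric metadata covariates.
#' @param subset Optional logical vector over metadata rows restricting
#'   regression samples.
#' @param alpha Flagging threshold for the Welch p-value (default 0.05).
#' @return List of class `signature_panel`: `welch` (per-set table with
#'   `significant` flag), `regressions` (one row per requested pair),
#'   `n_case`, `n_control`.
#' @export
signature_panel_report <- function(scores, metadata,
                                   case_label = "case",
                                   control_label = "control",
                                   regressions = NULL, subset = NULL,
                                   alpha = 0.05) {
  stopifnot(all(c("sample", "group") %in% names(metadata)))
  idx <- match(rownames(scores), metadata$sample)
  if (anyNA(idx)) {
    stop("score-matrix sample(s) missing from metadata: ",
         paste(utils::head(rownames(scores)[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  }
  meta <- metadata[idx, , drop = FALSE]
  is_case <- meta$group == case_label
  is_control <- meta$group == control_label
  welch_rows <- lapply(colnames(scores), function(set) {
    wt <- welch_t(scores[is_case, set], scores[is_control, set])
    data.frame(set = set, mean_case = wt$mean_a,
               mean_control = wt$mean_b, t = wt$t, df = wt$df, p = wt$p,
               significant = wt$p < alpha, stringsAsFactors = FALSE)
  })
  welch_tab <- do.call(rbind, welch_rows)
  reg_tab <- NULL
  if (!is.null(regressions) && nrow(regressions) > 0) {
    keep <- if (is.null(subset)) rep(TRUE, nrow(meta)) else subset
    stopifnot(length(keep) == nrow(meta))
    grab <- function(name) {
      if (name %in% colnames(scores)) return(scores[keep, name])
      if (name %in% names(meta) && is.numeric(meta[[name]])) {
        return(meta[[name]][keep])
      }
      stop("unknown set or covariate name: ", name, call. = FALSE)
    }
    reg_rows <- lapply(seq_len(nrow(regressions)), function(i) {
      xv <- grab(regressions$x[i])
      yv <- grab(regressions$y[i])
      fit <- simple_linreg(xv, yv)
      data.frame(x = regressions$x[i], y = regressions$y[i],
                 slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, p = fit$p, n = fit$n,
                 stringsAsFactors = FALSE)
    })
    reg_tab <- do.call(rbind, reg_rows)
  }
  structure(list(welch = welch_tab, regressions = reg_tab,
                 n_case = sum(is_case), n_control = sum(is_control)),
            class = "signature_panel")
}

#' @export
print.signature_panel <- function(x, ...) {
  cat(sprintf("signature panel: %d case vs %d control samples\n",
              x$n_case, x$n_control))
  sig <- x$welch$set[x$welch$significant]
  cat("significant sets (Welch p < 0.05):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  if (!is.null(x$regressions)) {
    cat(nrow(x$regressions), "regression(s) computed\n")
  }
  invisible(x)
}
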
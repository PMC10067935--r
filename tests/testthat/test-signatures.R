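random_expr <- function(p, n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(p * n, mean = 8), p, n)
  dimnames(m) <- list(gene_universe(p), sprintf("SMP%02d", seq_len(n)))
  m
}

test_that("scores match the step-by-step random-walk oracle to 1e-10", {
  expr <- random_expr(50, 12, seed = 101)
  set.seed(102)
  sets <- list(s8 = sample(rownames(expr), 8),
               s5 = sample(rownames(expr), 5))
  got <- gsva_scores(expr, sets)
  for (nm in names(sets)) {
    expect_equal(unname(got[, nm]),
                 unname(gsva_oracle(expr, sets[[nm]])),
                 tolerance = 1e-10)
  }
})

test_that("scores are bounded in [-1, 1] and directional", {
  expr <- random_expr(40, 10, seed = 7)
  sets <- list(a = rownames(expr)[1:6], b = rownames(expr)[20:30])
  got <- gsva_scores(expr, sets)
  expect_true(all(got >= -1 & got <= 1))
  # push set-a genes to the top of sample 1's ranking: maximal score
  expr2 <- expr
  expr2[1:6, 1] <- expr2[1:6, 1] + 50
  got2 <- gsva_scores(expr2, sets)
  expect_equal(unname(which.max(got2[, "a"])), 1)
  expect_gt(got2[1, "a"], 0)
})

test_that("degenerate contracts: all-gene sets, tiny sets, constant data", {
  expr <- random_expr(10, 6)
  expect_warning(all_set <- gsva_scores(expr, list(all = rownames(expr))),
                 "score 0")
  expect_true(all(all_set[, "all"] == 0))
  expect_warning(out <- gsva_scores(expr, list(tiny = rownames(expr)[1],
                                               ok = rownames(expr)[1:4])),
                 "skipping")
  expect_equal(colnames(out), "ok")
  const <- matrix(3, 10, 6,
                  dimnames = list(gene_universe(10), paste0("S", 1:6)))
  got <- gsva_scores(const, list(s = gene_universe(10)[1:4]))
  expect_true(all(got == 0))
  expect_error(gsva_scores(expr[1:2, ], list(s = rownames(expr)[1:2])),
               "3 genes")
})

test_that("ecdf kernel gives exact monotone-transform invariance;
           Gaussian kernel is affine-invariant", {
  expr <- random_expr(30, 8, seed = 31)
  sets <- list(s = rownames(expr)[c(2, 9, 14, 20, 28)])
  base_e <- gsva_scores(expr, sets, kcdf = "ecdf")
  base_g <- gsva_scores(expr, sets, kcdf = "gaussian")
  trans <- expr
  # different strictly monotone map per gene
  for (i in seq_len(nrow(expr))) {
    f <- switch(i %% 3 + 1, function(x) exp(x / 4),
                function(x) x^3, function(x) 5 * x - 2)
    trans[i, ] <- f(expr[i, ])
  }
  expect_equal(gsva_scores(trans, sets, kcdf = "ecdf"), base_e,
               tolerance = 1e-12)
  affine <- 3 * expr + 11
  expect_equal(gsva_scores(affine, sets, kcdf = "gaussian"), base_g,
               tolerance = 1e-10)
})

test_that("negating the matrix reverses rankings and flips score signs", {
  expr <- random_expr(50, 8, seed = 55)
  sets <- list(s = rownames(expr)[1:10])
  expr[1:10, 1:4] <- expr[1:10, 1:4] + 3  # make scores well separated
  fwd <- gsva_scores(expr, sets)
  rev <- gsva_scores(-expr, sets)
  strong <- abs(fwd[, "s"]) > 0.2
  expect_true(any(strong))
  expect_equal(sign(rev[strong, "s"]), -sign(fwd[strong, "s"]))
  expect_lt(stats::cor(fwd[, "s"], rev[, "s"]), -0.95)
})

test_that("welch_t: worked example, t.test oracle, degenerate fallback", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  wk <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(wk$t, -1.224745, tolerance = 1e-6)
  expect_equal(wk$df, 4)
  expect_equal(wk$p, 0.2878641, tolerance = 1e-6)
  set.seed(9)
  for (i in 1:40) {
    a <- rnorm(sample(2:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:30, 1), mean = runif(1, -1, 1))
    res <- welch_t(a, b)
    or <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(res$t, unname(or$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(or$parameter), tolerance = 1e-10)
    expect_equal(res$p, or$p.value, tolerance = 1e-10)
    expect_equal(res$conf_int, as.numeric(or$conf.int),
                 tolerance = 1e-10)
  }
  fb_eq <- welch_t(c(2, 2), c(2, 2, 2))
  expect_equal(fb_eq$p, 1)
  fb_ne <- welch_t(c(2, 2), c(3, 3))
  expect_equal(fb_ne$p, 0)
  expect_equal(fb_ne$t, -Inf)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("simple_linreg: exact fits, orthogonality, closed-form oracle", {
  x <- c(1, 2, 3, 4, 5)
  exact <- suppressWarnings(simple_linreg(x, 2 * x + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)
  orth <- simple_linreg(c(-1, 0, 1, 0), c(0, 1, 0, -1))
  expect_equal(orth$slope, 0)
  expect_equal(orth$r_squared, 0)
  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    res <- simple_linreg(x, y)
    # closed-form oracle
    bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    b0 <- mean(y) - bx * mean(x)
    r2 <- stats::cor(x, y)^2
    se <- sqrt(sum((y - b0 - bx * x)^2) / (n - 2) /
                 sum((x - mean(x))^2))
    p <- 2 * stats::pt(abs(bx / se), n - 2, lower.tail = FALSE)
    expect_equal(res$slope, bx, tolerance = 1e-10)
    expect_equal(res$intercept, b0, tolerance = 1e-10)
    expect_equal(res$r_squared, r2, tolerance = 1e-10)
    expect_equal(res$p, p, tolerance = 1e-10)
  }
  expect_error(simple_linreg(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(simple_linreg(1:3, 1:4), "mismatch")
  expect_error(simple_linreg(1:2, 1:2), "at least 3")
})

test_that("panel report contrasts groups, filters subgroups, guards names", {
  cfg <- synth_config(seed = 44,
                      expr_spec = list(n_genes = 300, n_case = 10,
                                       n_control = 10, n_sets = 5,
                                       set_size = 20, n_planted = 1,
                                       delta = 1.5, noise_sd = 1))
  ex <- gen_expression(cfg)
  sc <- gsva_scores(ex$expr, ex$sets)
  reg <- data.frame(x = "SIG01", y = "sledai", stringsAsFactors = FALSE)
  pan <- signature_panel_report(sc, ex$metadata, regressions = reg)
  expect_equal(pan$n_case, 10)
  expect_equal(pan$n_control, 10)
  expect_true(pan$welch$significant[pan$welch$set == "SIG01"])
  expect_equal(pan$regressions$n, 20)
  active <- ex$metadata$sledai >= stats::median(ex$metadata$sledai)
  sub <- signature_panel_report(sc, ex$metadata, regressions = reg,
                                subset = active)
  expect_equal(sub$regressions$n, sum(active))
  bad <- data.frame(x = "NOPE", y = "sledai", stringsAsFactors = FALSE)
  expect_error(signature_panel_report(sc, ex$metadata, regressions = bad),
               "NOPE")
})

test_that("null expression (delta 0) yields roughly uniform Welch p", {
  ps <- c()
  for (r in 1:10) {
    cfg <- synth_config(seed = 500 + r,
                        expr_spec = list(n_genes = 300, n_case = 10,
                                         n_control = 10, n_sets = 6,
                                         set_size = 20, n_planted = 0,
                                         delta = 0, noise_sd = 1))
    ex <- gen_expression(cfg)
    sc <- gsva_scores(ex$expr, ex$sets)
    pan <- signature_panel_report(sc, ex$metadata)
    ps <- c(ps, pan$welch$p)
  }
  # 60 null p-values: no mass pile-up near zero
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
})
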
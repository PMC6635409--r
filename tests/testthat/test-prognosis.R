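test_that("per-gene Cox recovers a planted log-hazard of 1", {
  fx <- make_expression_survival_fixture(
    seed = 71, n_genes = 3, n_tumor = 300, n_normal = 5,
    deg_genes = "G1", log2fc = 0, beta = c(G2 = 1),
    baseline_hazard = 0.02)
  stats_tab <- per_gene_cox(fx$expr, fx$clinical)
  hr <- stats_tab$hr[stats_tab$gene == "G2"]
  expect_gte(hr, exp(0.7)); expect_lte(hr, exp(1.3))
  expect_equal(sign(stats_tab$z), sign(log(stats_tab$hr)))
  expect_true(all(stats_tab$hr > 0))
})

test_that("null expression yields calibrated per-gene P values", {
  fx <- make_expression_survival_fixture(
    seed = 72, n_genes = 100, n_tumor = 300, n_normal = 5,
    deg_genes = "G1", log2fc = 0)
  stats_tab <- per_gene_cox(fx$expr, fx$clinical)
  fp <- mean(stats_tab$p < 0.05)
  expect_lt(abs(fp - 0.05), 0.05)
})

test_that("events beyond the 10-year horizon are censored", {
  expr <- expression_matrix(
    matrix(rnorm(40, 8), 2, 20,
           dimnames = list(c("g1", "g2"), sprintf("T%d", 1:20))),
    rep("tumor", 20))
  cl <- clinical_table(sprintf("T%d", 1:20),
                       time = seq(30, 220, by = 10), event = 1)
  # all events after 120 months must not count as events
  expect_error(per_gene_cox(expr, clinical_table(sprintf("T%d", 1:20),
                                                 rep(150, 20), rep(1, 20))),
               "no events")
  st <- per_gene_cox(expr, cl)
  expect_equal(nrow(st), 2L)
  # constant gene flagged
  expr2 <- expr; expr2$values[1, ] <- 5
  st2 <- per_gene_cox(expr2, cl)
  expect_true(st2$flagged[1]); expect_true(is.na(st2$hr[1]))
})

test_that("combined score applies signed weights, RC and the mixed flag", {
  vals <- matrix(c(5, 3, 2, 1, 4, 6), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("T1", "T2", "T3")))
  expr <- expression_matrix(vals, rep("tumor", 3))
  gs <- data.frame(gene = c("g1", "g2"), hr = c(1.5, 0.5),
                   stringsAsFactors = FALSE)
  cs <- combined_score(expr, gs, c("g1", "g2"))
  # w = (+1, -1): MV(T1) = 5 - 3 = 2
  expect_equal(unname(cs$mv["T1"]), 2)
  expect_equal(cs$rc, 1)
  expect_equal(cs$cs, cs$mv)
  # HR exactly 1 gets weight +1
  gs2 <- data.frame(gene = c("g1", "g2"), hr = c(1, 1))
  expect_equal(unname(combined_score(expr, gs2, c("g1", "g2"))$weights),
               c(1, 1))
  expect_error(combined_score(expr, gs, character()), "empty")
  expect_error(combined_score(expr, gs, c("g1", "gX")), "expression")
})

test_that("RC flips at >= 75% negative MV and mixed sign is flagged", {
  mk <- function(frac_neg, n = 20) {
    n_neg <- round(frac_neg * n)
    vals <- matrix(0, 1, n, dimnames = list("g1", sprintf("T%d", 1:n)))
    vals[1, ] <- c(rep(-2, n_neg), rep(2, n - n_neg))
    expr <- expression_matrix(vals, rep("tumor", n))
    combined_score(expr, data.frame(gene = "g1", hr = 2), "g1")
  }
  cs80 <- mk(0.8)
  expect_equal(cs80$rc, -1)
  expect_equal(cs80$cs, -cs80$mv)
  expect_false(cs80$mixed_sign)
  cs50 <- mk(0.5)
  expect_equal(cs50$rc, 1)
  expect_true(cs50$mixed_sign)
  expect_false(mk(0.1)$mixed_sign)
})

test_that("combined score is equivariant under weight negation", {
  set.seed(73)
  vals <- matrix(rnorm(60, 0, 2), 3, 20,
                 dimnames = list(c("g1", "g2", "g3"), sprintf("T%d", 1:20)))
  expr <- expression_matrix(vals, rep("tumor", 20))
  gs_pos <- data.frame(gene = rownames(vals), hr = c(2, 3, 1.2))
  gs_neg <- data.frame(gene = rownames(vals), hr = c(0.5, 0.3, 0.8))
  a <- combined_score(expr, gs_pos, rownames(vals))
  b <- combined_score(expr, gs_neg, rownames(vals))
  expect_equal(b$mv, -a$mv)
  # RC responds to the flipped sign so CS is reproduced up to direction
  expect_equal(abs(b$cs), abs(a$cs))
})

test_that("stratification partitions patients and finds planted separation", {
  set.seed(74)
  n <- 200
  cs <- setNames(rnorm(n), sprintf("T%d", 1:n))
  # hazard increases with the score
  times <- rexp(n, rate = 0.02 * exp(0.8 * cs))
  cl <- clinical_table(names(cs), pmax(times, 0.1),
                       rbinom(n, 1, 0.8))
  st_med <- stratify(cs, cl, policy = "median")
  expect_equal(as.integer(table(st_med$groups)), c(100L, 100L))
  expect_setequal(names(st_med$groups), names(cs))
  st_best <- stratify(cs, cl, policy = "best")
  expect_lt(st_best$logrank_p, 0.01)
  expect_gt(st_best$hr, 1)
  expect_lte(st_best$logrank_p, st_med$logrank_p + 1e-12)
  # n = 10 distinct values, median policy -> 5/5 split
  cs10 <- setNames(1:10, sprintf("T%d", 1:10))
  st10 <- stratify(cs10, cl[1:10, ], policy = "median")
  expect_equal(as.integer(table(st10$groups)), c(5L, 5L))
  expect_error(stratify(setNames(rep(1, 10), sprintf("T%d", 1:10)),
                        cl[1:10, ]), "degenerate")
})

test_that("median-policy stratification is calibrated under the null", {
  set.seed(75)
  n_rep <- 2000; n <- 50
  hits <- 0L
  base_cl <- NULL
  for (i in seq_len(n_rep)) {
    cs <- setNames(rnorm(n), sprintf("T%d", 1:n))
    cl <- clinical_table(names(cs), rexp(n, 0.02), rbinom(n, 1, 0.8))
    p <- stratify(cs, cl, policy = "median")$logrank_p
    if (!is.na(p) && p < 0.05) hits <- hits + 1L
  }
  expect_lt(abs(hits / n_rep - 0.05), 0.02)
})

test_that("the best-cutoff scan is optimistic under the null", {
  set.seed(76)
  n_rep <- 200; n <- 60
  hits <- 0L
  for (i in seq_len(n_rep)) {
    cs <- setNames(rnorm(n), sprintf("T%d", 1:n))
    cl <- clinical_table(names(cs), rexp(n, 0.02), rbinom(n, 1, 0.8))
    p <- stratify(cs, cl, policy = "best")$logrank_p
    if (!is.na(p) && p < 0.05) hits <- hits + 1L
  }
  # the reported minimum P is not multiplicity-corrected: the false
  # positive rate must sit well above the nominal 5%
  expect_gt(hits / n_rep, 0.10)
})

test_that("prognostic meta-z combines and thresholds z-scores", {
  r <- prognostic_meta_z(c(1.96, 1.96))
  expect_equal(r$meta_z, 2 * 1.96 / sqrt(2), tolerance = 1e-9)
  expect_true(r$significant)
  r0 <- prognostic_meta_z(c(2, -2))
  expect_equal(r0$meta_z, 0)
  expect_false(r0$significant)
  z <- c(0.3, -1.2, 2.5)
  expect_equal(prognostic_meta_z(z)$meta_z,
               prognostic_meta_z(rev(z))$meta_z)
  expect_error(prognostic_meta_z(numeric()), "empty")
})

test_that("Kaplan-Meier coordinates partition all patients", {
  set.seed(77)
  n <- 40
  cs <- setNames(rnorm(n), sprintf("T%d", 1:n))
  cl <- clinical_table(names(cs), rexp(n, 0.02), rbinom(n, 1, 0.7))
  st <- stratify(cs, cl, policy = "median")
  km <- km_coordinates(st$groups, cl)
  expect_setequal(unique(km$group), c("high", "low"))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  # every patient is in exactly one group
  expect_equal(sort(names(st$groups)), sort(cl$patient))
  expect_equal(sum(table(st$groups)), n)
})
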
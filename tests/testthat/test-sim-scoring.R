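test_that("component scores reproduce their closed-form values", {
  # interacting-region similarity
  expect_equal(score_irs(1.0, 100, 100), 1.0)
  expect_equal(score_irs(0.5, 50, 100), 0.5)       # sqrt(0.5 * 0.5)
  expect_equal(score_irs(0.0, 80, 100), 0.0)
  expect_equal(score_irs(1.0, 200, 100), 1.0)      # L/Q_d clipped at 1
  expect_error(score_irs(0.5, 50, 0), "positive")
  # template quality
  expect_equal(score_qul(2, 2, 2), 1.0)
  expect_equal(score_qul(0, 0, 0), 0.0)
  expect_equal(score_qul(1, 0, 5), 0.5)            # (1 + 0 + 2)/6
  # joint sequence similarity
  expect_equal(score_jss(1e-30, 1e-40, 1e-30, 1e-40), 1.0)
  expect_equal(score_jss(1e-50, 1e-20, 1e-200, 1e-80), 0.25)
  expect_equal(score_jss(1.0, 1e-20, 1e-100, 1e-80), 0.0)
  # similarity rank
  expect_equal(score_rank(1, 100), 1.0)
  expect_equal(score_rank(100, 100), 0.0)
  expect_equal(score_rank(10, 100), 0.5)
  expect_equal(score_rank(1, 1), 1.0)
  expect_error(score_rank(5, 4), "rank")
  # evolutionary conservation
  expect_equal(score_es(0.6, 1), 0.3)
  expect_equal(score_es(0.6, 2), 0.6)
  expect_equal(score_es(c(0.8, 0.9), c(2, 2)), 1.0)  # clipped
  expect_equal(score_es(numeric(), numeric()), 0.0)
  # network topology
  expect_equal(score_topo(2, 8, 1, 13913), 0.5)
  expect_equal(score_topo(0, 5, 100, 13913), 0.0)
  expect_equal(score_topo(5, 5, 1, 10), 1.0)
  expect_equal(score_topo(0, 0, 1, 10), 0.0)
  expect_error(score_topo(6, 5, 1, 10), "exceed")
})

test_that("components stay in [0,1] and are monotone on random inputs", {
  set.seed(31)
  for (i in 1:200) {
    si <- runif(1); l <- sample(1:500, 1); qd <- sample(1:500, 1)
    v <- score_irs(si, l, qd)
    expect_gte(v, 0); expect_lte(v, 1)
    # monotone in SI and L
    expect_gte(score_irs(min(1, si + 0.1), l, qd), v)
    expect_gte(score_irs(si, l + 10, qd), v - 1e-12)
    e <- 10^-runif(4, 1, 170)
    j <- score_jss(e[1], e[2], min(e[1], e[3]), min(e[2], e[4]))
    expect_gte(j, 0); expect_lte(j, 1)
    # decreasing in the cross E-value
    expect_lte(score_jss(min(1, e[1] * 10), e[2], min(e[1], e[3]),
                         min(e[2], e[4])), j + 1e-12)
    rmx <- sample(2:1000, 1); r <- sample(seq_len(rmx), 1)
    sr <- score_rank(r, rmx)
    expect_gte(sr, 0); expect_lte(sr, 1)
    if (r < rmx) expect_lte(score_rank(r + 1, rmx), sr)
    d <- runif(3); m <- sample(1:4, 3, replace = TRUE)
    se <- score_es(d, m)
    expect_gte(se, 0); expect_lte(se, 1)
    n <- sample(1:50, 1); cc <- sample(0:n, 1)
    rmax2 <- sample(10:100, 1); rb <- sample(seq_len(rmax2), 1)
    st <- score_topo(cc, n, rb, rmax2)
    expect_gte(st, 0); expect_lte(st, 1)
    if (cc < n) expect_gte(score_topo(cc + 1, n, rb, rmax2), st)
    if (rb < rmax2) expect_lte(score_topo(cc, n, rb + 1, rmax2), st + 1e-12)
  }
})

test_that("all-maximal inputs attain the component and total maxima", {
  expect_equal(score_irs(1, 120, 120) + score_qul(3, 2, 5) +
                 score_jss(1e-60, 1e-80, 1e-60, 1e-80) + score_rank(1, 50) +
                 score_es(c(0.8, 0.9), c(2, 3)) + score_topo(7, 7, 1, 100),
               6.0)
})

test_that("network construction ranks degree fractionally, hubs first", {
  nw <- ppi_network(data.frame(a = c("h", "h", "h", "x", "y"),
                               b = c("x", "y", "z", "y", "z")))
  expect_equal(unname(nw$degree[c("h", "x", "y", "z")]), c(3L, 2L, 3L, 2L))
  expect_equal(unname(nw$rank["h"]), 1.5)   # tie with y at the top
  expect_equal(nw$r_max, 3.5)
  # symmetric adjacency
  expect_true("h" %in% nw$adj[["x"]] && "x" %in% nw$adj[["h"]])
})

test_that("candidate search applies homology gates and the max combiner", {
  ix <- make_interactome_fixture(seed = 7, n_mps = 1, n_pos = 3, n_neg = 3,
                                 n_background = 8)
  tm <- exclude_self_templates("MP1", ix$templates)
  res <- predict_partners("MP1", ix$proteome, tm, ix$hits, ix$network,
                          ix$distances, threshold = 0)
  expect_true(all(res$s_sim >= 0 & res$s_sim <= 6))
  comp <- res[, c("s_irs", "s_qul", "s_jss", "s_rank", "s_es", "s_topo")]
  expect_true(all(comp >= 0 & comp <= 1))
  expect_equal(res$s_sim, unname(rowSums(comp)), tolerance = 1e-9)
  expect_false(any(duplicated(res$partner)))
  # thresholding keeps a candidate at exactly the cutoff
  thr <- res$s_sim[2]
  res3 <- predict_partners("MP1", ix$proteome, tm, ix$hits, ix$network,
                           ix$distances, threshold = thr)
  expect_true(all(res3$s_sim >= thr))
  expect_true(res$partner[2] %in% res3$partner)
  # MP without cytoplasmic region
  expect_warning(
    res4 <- predict_partners("BG1", ix$proteome, tm, ix$hits, ix$network,
                             ix$distances),
    "cytoplasmic")
  expect_equal(nrow(res4), 0L)
})

test_that("per-protein and joint E-value gates act before scoring", {
  proteome <- protein_table(c("MP1", "HB"), "Homo sapiens", c(200, 300),
                            is_mp = c(TRUE, FALSE),
                            cyto = list(rbind(c(1, 50)), NULL))
  tm <- ppi_templates("TA", "TB", "Mus musculus", "Mus musculus",
                      methods = list("MI:0114"), types = list("MI:0407"),
                      refs = list("PM1"))
  dt <- distance_table("Homo sapiens", "Mus musculus", 0.3)
  nw <- ppi_network(data.frame(a = character(), b = character()))
  mk_hits <- function(e_partner, e_mp = 1e-50) data.frame(
    query = c("TA", "TB", "MP1:cr1", "TA", "TB"),
    subject = c("TA", "TB", "TA", "MP1", "HB"),
    identity = c(1, 1, 0.9, 0.7, 0.6),
    length = c(200L, 300L, 50L, 150L, 200L),
    evalue = c(1e-120, 1e-150, 1e-30, e_mp, e_partner),
    stringsAsFactors = FALSE)
  # joint E = sqrt(1e-50 * 1e-20) = 1e-35 > 1e-40: excluded
  res_fail <- predict_partners("MP1", proteome, tm, mk_hits(1e-20), nw, dt,
                               threshold = 0)
  expect_equal(nrow(res_fail), 0L)
  # joint E = 1e-45 passes both gates
  res_ok <- predict_partners("MP1", proteome, tm, mk_hits(1e-40), nw, dt,
                             threshold = 0)
  expect_equal(res_ok$partner, "HB")
  # a per-protein E-value above 1e-10 fails even with a tiny joint E
  res_single <- predict_partners("MP1", proteome, tm, mk_hits(1e-9, 1e-120),
                                 nw, dt, threshold = 0)
  expect_equal(nrow(res_single), 0L)
})

test_that("scores agree with a brute-force triple enumeration", {
  for (seed in c(3, 9)) {
    ix <- make_interactome_fixture(seed = seed, n_mps = 1, n_pos = 3,
                                   n_neg = 2, n_background = 6)
    tm <- exclude_self_templates("MP1", ix$templates)
    res <- predict_partners("MP1", ix$proteome, tm, ix$hits, ix$network,
                            ix$distances, threshold = 0)
    brute <- brute_force_scores("MP1", ix$proteome, tm, ix$hits, ix$network,
                                ix$distances)
    expect_setequal(res$partner, names(brute))
    expect_equal(res$s_sim[match(names(brute), res$partner)],
                 as.numeric(brute), tolerance = 1e-9)
  }
})

test_that("evaluation computes AUC, F2 and the best threshold", {
  pos <- data.frame(a = "m", b = sprintf("p%d", 1:4))
  neg <- data.frame(a = "m", b = sprintf("n%d", 1:4))
  scores <- setNames(c(4, 3.8, 3.5, 3.2, 1, 0.8, 0.5, 0.2),
                     pair_key("m", c(pos$b, neg$b)))
  ev <- evaluate_predictions(scores, pos, neg)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$best_f2, 1.0)
  # precision 0.5, recall 1 => F2 = 5/6
  scores2 <- setNames(c(2, 2, 2, 2, 2, 2, 2, 2), names(scores))
  ev2 <- evaluate_predictions(scores2, pos, neg)
  expect_equal(ev2$pr_curve$f2[1], 5 / 6, tolerance = 1e-12)
  # unscored labeled pairs imputed at 0
  ev3 <- evaluate_predictions(scores[1:4], pos, neg)
  expect_equal(ev3$auc, 1.0)
  expect_error(evaluate_predictions(scores, pos, pos), "overlap")
  expect_error(evaluate_predictions(scores, pos[0, ], neg), "class")
})

test_that("random labels give chance-level AUC", {
  set.seed(41)
  sc <- runif(1000)
  keys <- pair_key("m", sprintf("x%d", 1:1000))
  lab <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  ev <- evaluate_predictions(setNames(sc, keys),
                             data.frame(a = "m", b = sprintf("x%d",
                                                             which(lab))),
                             data.frame(a = "m", b = sprintf("x%d",
                                                             which(!lab))))
  expect_lt(abs(ev$auc - 0.5), 0.05)
})

test_that("rank AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  sc <- c(rnorm(40, 1), rnorm(60))
  lab <- rep(c(1, 0), c(40, 60))
  keys <- pair_key("m", sprintf("y%d", seq_along(sc)))
  ours <- evaluate_predictions(setNames(sc, keys),
                               data.frame(a = "m",
                                          b = sprintf("y%d", which(lab == 1))),
                               data.frame(a = "m",
                                          b = sprintf("y%d", which(lab == 0))))
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours$auc, ref, tolerance = 1e-12)
})
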
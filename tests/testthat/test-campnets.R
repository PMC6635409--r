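test_that("pair counting matches the two-involved-genes worked example", {
  s <- tiny_enrichment_setting(n_coexpr = 6)
  en <- enrichment(s$community, "target", s$degs, s$coexpr, s$pathways)
  expect_equal(en$n, 44L)      # 2 involved genes x 22 pathway DEGs
  expect_equal(en$x, 6L)
  expect_false(en$unevaluable)
  expect_gte(en$p, 0); expect_lte(en$p, 1)
  # zero involved genes -> unevaluable
  empty <- enrichment(mpp_community("ZZ", "YY"), "target", s$degs,
                      s$coexpr, s$pathways)
  expect_true(empty$unevaluable)
  expect_equal(empty$p, 1)
  # x = 0 gives the full tail, P = 1
  s0 <- tiny_enrichment_setting(n_coexpr = 0)
  s0$coexpr <- s0$coexpr[0, ]
  en0 <- enrichment(s0$community, "target", s0$degs, s0$coexpr, s0$pathways)
  expect_equal(en0$p, 1)
})

test_that("enrichment P equals the exact hypergeometric tail", {
  # hand instance: x=2, n=4, M=5, N=10 -> 155/210
  expect_equal(brute_hyper_tail(2, 5, 10, 4), 155 / 210)
  expect_equal(enumerate_hyper_tail(2, 5, 10, 4), 155 / 210)
  expect_equal(hyper_tail_p(2, 4, 5, 10), 155 / 210)
  # property: for random instances with N <= 30 the pipeline P matches
  # a brute-force tail sum (and full enumeration when feasible)
  set.seed(61)
  for (i in 1:60) {
    N <- sample(2:30, 1)
    M <- sample(0:N, 1)
    n <- sample(1:N, 1)
    x <- sample(0:min(n, M), 1)
    p_pkg <- hyper_tail_p(x, n, M, N)
    expect_equal(p_pkg, brute_hyper_tail(x, M, N, n), tolerance = 1e-12)
    if (choose(N, n) <= 20000)
      expect_equal(p_pkg, enumerate_hyper_tail(x, M, N, n),
                   tolerance = 1e-12)
  }
})

test_that("empirical P follows the add-one convention and its bounds", {
  w <- null_enrichment_world(seed = 62)
  cm <- w$communities[[1]]
  ep <- empirical_p(cm, "pw1", w$communities, w$degs, w$coexpr, w$pathways,
                    B = 50, seed = 1)
  expect_gte(ep$empirical_p, 1 / 51)
  expect_lte(ep$empirical_p, 1)
  # same seed, same answer (pipeline determinism)
  ep2 <- empirical_p(cm, "pw1", w$communities, w$degs, w$coexpr, w$pathways,
                     B = 50, seed = 1)
  expect_identical(ep, ep2)
  # a community larger than the pool is an error
  big <- mpp_community("XX", sprintf("Y%d", 1:1000))
  expect_error(empirical_p(big, "pw1", w$communities, w$degs, w$coexpr,
                           w$pathways, B = 5, seed = 1), "pool")
})

test_that("an observed score beating every shuffle yields 1/(B+1)", {
  fx <- make_campnets_fixture(seed = 63)
  ep <- empirical_p(fx$communities[[1]], "planted_pathway", fx$communities,
                    fx$degs, fx$coexpr, fx$pathways, B = 100, seed = 2)
  expect_equal(ep$empirical_p, 1 / 101)
})

test_that("meta-z reproduces Stouffer closed forms", {
  expect_equal(meta_z(rep(0.05, 15)), qnorm(0.95) * sqrt(15),
               tolerance = 1e-9)
  expect_equal(meta_z(0.5), 0.0, tolerance = 1e-12)
  p <- c(0.01, 0.2, 0.6, 0.04)
  expect_equal(meta_z(p), meta_z(rev(p)))
  # floor keeps z finite for extreme P
  expect_true(is.finite(meta_z(c(1e-300, 0.5))))
  expect_error(meta_z(numeric()), "empty")
  expect_error(meta_z(c(0.5, 1.5)), "lie in")
  expect_equal(stouffer_z(c(2, -2)), 0)
})

test_that("homogeneity fractions and the paired Wilcoxon behave", {
  obs <- expand.grid(community = c("c1", "c2", "c3"),
                     pathway = "pw", cancer = c("A", "B", "C"),
                     stringsAsFactors = FALSE)
  obs$p <- 1
  # c1 regulates pw in A,B,C; c2 in A; c3 in A,B
  reg <- rbind(c("c1", "A"), c("c1", "B"), c("c1", "C"),
               c("c2", "A"), c("c3", "A"), c("c3", "B"))
  obs$p[match(paste(reg[, 1], reg[, 2]),
              paste(obs$community, obs$cancer))] <- 0.01
  h <- homogeneity(obs, shuffled = list(obs), ks = 2)
  expect_equal(h$fractions$observed, 2 / 3)
  expect_equal(h$fractions$expected, 2 / 3)
  expect_equal(h$tests$wilcoxon_p, 1)      # identical sets, no signal
  # nothing regulated -> zero fractions everywhere
  obs0 <- obs; obs0$p <- 1
  h0 <- homogeneity(obs0, list(obs0), ks = c(2, 3))
  expect_true(all(h0$fractions$observed == 0))
  expect_error(homogeneity(obs, list(obs), ks = 5), "exceeds")
})

test_that("homogeneity detects planted sharing against shuffled sets", {
  set.seed(64)
  cancers <- sprintf("K%d", 1:5)
  mk <- function(p_fun) {
    df <- expand.grid(community = sprintf("c%d", 1:10),
                      pathway = sprintf("pw%d", 1:8), cancer = cancers,
                      stringsAsFactors = FALSE)
    df$p <- p_fun(nrow(df))
    df
  }
  obs <- mk(function(n) ifelse(runif(n) < 0.6, 0.01, 1))   # much sharing
  shuf <- replicate(20, mk(function(n) ifelse(runif(n) < 0.1, 0.01, 1)),
                    simplify = FALSE)
  h <- homogeneity(obs, shuf, ks = c(2, 3))
  expect_true(all(h$fractions$observed >= h$fractions$expected))
  expect_lt(h$tests$wilcoxon_p[1], 0.05)
})

test_that("network statistics report degree, hubs and the exponent", {
  m <- rbind(c(5, 3, 0.2, 2.1), c(2, 0.5, 0.3, 0.1), c(3, 2, 2.2, 1.9))
  rownames(m) <- c("apc", "bpc", "cpc")
  ns <- network_stats(m, z_cut = 1.64)
  expect_equal(ns$stats$degree, c(3, 1, 4))
  expect_equal(ns$stats$mean_meta_z[1], mean(c(5, 3, 2.1)))
  expect_true(ns$stats$hub[3])             # top-25% degree
  expect_false(ns$stats$hub[2])
  # one community is trivially a hub
  ns1 <- network_stats(m[1, , drop = FALSE])
  expect_true(ns1$stats$hub)
  # all-zero degrees: exponent undefined
  ns0 <- network_stats(matrix(0, 2, 3))
  expect_true(is.na(ns0$gamma))
})

test_that("power-law exponent recovery on simulated degree sequences", {
  set.seed(65)
  x <- rpowerlaw(5000, gamma = 1.5)
  g <- fit_power_law_gamma(x)
  expect_lt(abs(g - 1.5), 0.15)
  x2 <- rpowerlaw(5000, gamma = 2.5)
  expect_lt(abs(fit_power_law_gamma(x2) - 2.5), 0.2)
})

test_that("meta-z profile clustering recovers planted blocks", {
  set.seed(66)
  sig1 <- rnorm(10); sig2 <- rnorm(10)
  m <- rbind(t(replicate(6, sig1 + rnorm(10, sd = 0.2))),
             t(replicate(6, sig2 + rnorm(10, sd = 0.2))))
  rownames(m) <- sprintf("c%d", 1:12)
  cl <- cluster_meta_z(m, k = 2)
  expect_equal(length(unique(cl$labels[1:6])), 1L)
  expect_equal(length(unique(cl$labels[7:12])), 1L)
  expect_false(cl$labels[1] == cl$labels[7])
  # identical rows merge first (distance 0)
  m2 <- rbind(a = sig1, b = sig1, c = -sig1)
  cl2 <- cluster_meta_z(m2, k = 2)
  expect_equal(cl2$labels[["a"]], cl2$labels[["b"]])
  expect_false(cl2$labels[["a"]] == cl2$labels[["c"]])
  # constant rows are dropped with a warning
  m3 <- rbind(m2, d = rep(1, 10))
  expect_warning(cluster_meta_z(m3, k = 2), "constant")
})
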
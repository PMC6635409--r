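## Community-regulated-pathway enrichment with permutation nulls,
## Stouffer meta-analysis across cancers, tumor-homogeneity
## quantification, and pan-cancer network structure.

#' Construct a membrane-protein partner community
#'
#' An MP together with its interaction partners (reported/direct plus
#' predicted). The MP is never its own partner.
#'
#' @param mp gene identifier of the membrane protein.
#' @param partners character vector of partner gene identifiers.
#' @return `list(mp=, partners=)` with class `"mpp_community"`.
#' @export
mpp_community <- function(mp, partners) {
  structure(list(mp = as.character(mp),
                 partners = sort(setdiff(unique(as.character(partners)), mp))),
            class = "mpp_community")
}

#' Involved genes of a community in one cancer
#'
#' The differentially expressed members of the community (MP plus
#' partners) in that cancer.
#'
#' @param community an [mpp_community()].
#' @param deg_genes character vector of DEG identifiers for the cancer.
#' @return character vector of involved genes.
#' @export
involved_genes <- function(community, deg_genes) {
  intersect(c(community$mp, community$partners), deg_genes)
}

#' Index co-expressed pairs for fast membership tests
#' @param pairs data.frame from [coexpressed_pairs()].
#' @return character vector of unordered pair keys.
#' @export
coexpr_index <- function(pairs) {
  unique(pair_key(pairs$gene_a, pairs$gene_b))
}

## ordered cross-pair counting between two gene sets: n excludes
## identical-gene pairs; x counts combos present in the co-expression
## index (a pair with both genes in both sets contributes two combos).
cross_pair_counts <- function(set_a, set_b, idx) {
  la <- length(set_a); lb <- length(set_b)
  n <- la * lb - length(intersect(set_a, set_b))
  if (n == 0L) return(c(x = 0L, n = 0L))
  keys <- pair_key(rep(set_a, each = lb), rep.int(set_b, la))
  keys <- keys[rep(set_a, each = lb) != rep.int(set_b, la)]
  c(x = sum(keys %in% idx), n = as.integer(n))
}

#' Upper hypergeometric tail probability
#'
#' `P = sum_{i=x}^{n} C(M,i) C(N-M,n-i) / C(N,n)`: the probability of
#' observing `x` or more co-expressed pairs when drawing `n` pairs from
#' a population of `N` pairs of which `M` are co-expressed.
#'
#' @param x observed successes.
#' @param n draws.
#' @param M successes in the population.
#' @param N population size.
#' @return tail probability in `[0, 1]`.
#' @export
hyper_tail_p <- function(x, n, M, N) {
  stats::phyper(x - 1, M, N - M, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a community-pathway association
#'
#' Counts the cross gene pairs between the community's involved genes
#' and the DEG members of the pathway (`n`), the co-expressed pairs
#' among them (`x`), and the analogous totals against the DEG members of
#' the full pathway collection (`N`, `M`). The enrichment P value is the
#' upper hypergeometric tail `P = sum_{i=x}^{n} C(M,i) C(N-M,n-i) /
#' C(N,n)`; the involvement score is `-log10(P)`.
#'
#' @param community an [mpp_community()].
#' @param pathway_id pathway name inside `pathways`.
#' @param degs DEG table from [call_degs()] (or any data.frame with
#'   `gene` and logical `deg`).
#' @param coexpr co-expression index from [coexpr_index()] (or a pair
#'   data.frame, converted on the fly).
#' @param pathways a [pathway_collection()]; `N` and `M` are measured
#'   against the union of all its gene sets.
#' @param p_cutoff significance cutoff on the enrichment P (default
#'   0.05).
#' @return `list(x=, n=, M=, N=, p=, involvement=, significant=,
#'   unevaluable=)`.
#' @export
enrichment <- function(community, pathway_id, degs, coexpr, pathways,
                       p_cutoff = 0.05) {
  if (!pathway_id %in% names(pathways$pathways))
    stop_campnets("unknown pathway: ", pathway_id)
  if (is.data.frame(coexpr)) coexpr <- coexpr_index(coexpr)
  deg_genes <- degs$gene[degs$deg]
  inv <- involved_genes(community, deg_genes)
  pw_deg <- intersect(pathways$pathways[[pathway_id]], deg_genes)
  if (length(inv) == 0L || length(pw_deg) == 0L) {
    return(list(x = 0L, n = 0L, M = 0L, N = 0L, p = 1,
                involvement = 0, significant = FALSE, unevaluable = TRUE))
  }
  universe <- intersect(unique(unlist(pathways$pathways, use.names = FALSE)),
                        deg_genes)
  xn <- cross_pair_counts(inv, pw_deg, coexpr)
  mn <- cross_pair_counts(inv, universe, coexpr)
  x <- xn[["x"]]; n <- xn[["n"]]; m <- mn[["x"]]; n_tot <- mn[["n"]]
  p <- if (n == 0L) 1 else hyper_tail_p(x, n, m, n_tot)
  p <- min(max(p, 0), 1)
  list(x = x, n = n, M = m, N = n_tot, p = p,
       involvement = -log10(max(p, .Machine$double.xmin)),
       significant = p <= p_cutoff, unevaluable = FALSE)
}

#' Permutation empirical P of a community-pathway involvement
#'
#' The observed involvement score is compared with that of shuffled
#' communities of the same size, whose partners are drawn without
#' replacement from the pooled partner multiset of all communities (a
#' gene-label permutation across the pool). The empirical P uses the
#' add-one convention `(1 + #{shuffled >= observed}) / (B + 1)` and is
#' never exactly zero.
#'
#' @param community an [mpp_community()].
#' @param pathway_id pathway name.
#' @param all_communities list of [mpp_community()] objects providing
#'   the partner pool.
#' @param degs,coexpr,pathways as in [enrichment()].
#' @param B number of Monte Carlo trials (default 1000).
#' @param seed integer seed for the trials (required for
#'   reproducibility).
#' @return `list(empirical_p=, observed=, B=)` where `observed` is the
#'   observed involvement score.
#' @export
empirical_p <- function(community, pathway_id, all_communities, degs,
                        coexpr, pathways, B = 1000, seed = NULL) {
  if (B < 1) stop_campnets("B must be >= 1")
  if (is.data.frame(coexpr)) coexpr <- coexpr_index(coexpr)
  if (!is.null(seed)) set.seed(seed)
  pool <- unlist(lapply(all_communities, `[[`, "partners"), use.names = FALSE)
  pool <- pool[pool != community$mp]
  size <- length(community$partners)
  if (length(pool) < size)
    stop_campnets("pooled partner multiset smaller than community size")
  obs <- enrichment(community, pathway_id, degs, coexpr, pathways)$involvement
  hits <- 0L
  for (b in seq_len(B)) {
    shuffled <- mpp_community(community$mp, sample(pool, size))
    inv_b <- enrichment(shuffled, pathway_id, degs, coexpr,
                        pathways)$involvement
    if (inv_b >= obs) hits <- hits + 1L
  }
  list(empirical_p = (1 + hits) / (B + 1), observed = obs, B = B)
}

#' Stouffer's unweighted Z combination
#'
#' @param z finite z-scores.
#' @return `sum(z) / sqrt(length(z))`.
#' @export
stouffer_z <- function(z) {
  if (length(z) == 0L) stop_campnets("empty z vector")
  if (any(!is.finite(z))) stop_campnets("non-finite z-score")
  sum(z) / sqrt(length(z))
}

#' Meta-z of one-sided P values across cancers
#'
#' Each P is floored at `p_floor`, transformed to a one-sided z-score
#' `z = qnorm(1 - p)`, and the z-scores combined with Stouffer's
#' unweighted method. A pan-cancer association is called enriched at
#' `meta_z > 1.64` (one-sided 5%).
#'
#' @param p one-sided P values in `(0, 1)`, one per cancer.
#' @param p_floor floor applied before the transform (default 1e-16),
#'   keeping z finite.
#' @return the meta-z score.
#' @export
meta_z <- function(p, p_floor = 1e-16) {
  if (length(p) == 0L) stop_campnets("empty P-value vector")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop_campnets("P values must lie in (0, 1]")
  z <- stats::qnorm(pmax(p, p_floor), lower.tail = FALSE)
  stouffer_z(z)
}

#' Tumor homogeneity of community-regulated pathways
#'
#' For each pathway, the fraction of communities regulating it
#' (enrichment P and empirical P below their cutoffs) in at least `k`
#' cancers, compared with the median fraction over shuffled community
#' sets, with a paired Wilcoxon signed-rank test across pathways.
#'
#' @param observed data.frame with columns `community`, `pathway`,
#'   `cancer`, `p` and (optionally) `empirical_p`.
#' @param shuffled list of data.frames of the same shape, one per
#'   shuffled community set.
#' @param ks sharing thresholds (default `c(2, 3, 5, 7, 9)`); each must
#'   not exceed the number of cancers.
#' @param enrich_p_cutoff enrichment-P cutoff (default 0.05).
#' @param empirical_p_cutoff empirical-P cutoff (default 0.05; ignored
#'   when the column is absent).
#' @return `list(fractions = <data.frame pathway, k, observed,
#'   expected>, tests = <data.frame k, wilcoxon_p>)`.
#' @export
homogeneity <- function(observed, shuffled, ks = c(2, 3, 5, 7, 9),
                        enrich_p_cutoff = 0.05,
                        empirical_p_cutoff = 0.05) {
  n_cancers <- length(unique(observed$cancer))
  if (any(ks > n_cancers))
    stop_campnets("sharing threshold k exceeds the number of cancers")
  pathways_ <- sort(unique(observed$pathway))
  regulated <- function(df) {
    flag <- df$p <= enrich_p_cutoff
    if (!is.null(df$empirical_p))
      flag <- flag & df$empirical_p <= empirical_p_cutoff
    df[flag, , drop = FALSE]
  }
  fractions_of <- function(df) {
    reg <- regulated(df)
    communities <- unique(df$community)
    out <- vapply(pathways_, function(pw) {
      sub <- reg[reg$pathway == pw, , drop = FALSE]
      shared <- tapply(sub$cancer, sub$community,
                       function(x) length(unique(x)))
      vapply(ks, function(k)
        sum(shared >= k) / length(communities), numeric(1))
    }, numeric(length(ks)))
    matrix(out, nrow = length(ks),
           dimnames = list(NULL, pathways_))  # ks x pathways
  }
  obs_f <- fractions_of(observed)
  shuf_f <- lapply(shuffled, fractions_of)
  exp_f <- apply(array(unlist(shuf_f), dim = c(dim(obs_f), length(shuf_f))),
                 c(1, 2), stats::median)
  dimnames(exp_f) <- dimnames(obs_f)
  fractions <- do.call(rbind, lapply(seq_along(ks), function(i) {
    data.frame(pathway = pathways_, k = ks[i],
               observed = obs_f[i, ], expected = exp_f[i, ],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  tests <- do.call(rbind, lapply(seq_along(ks), function(i) {
    d <- obs_f[i, ] - exp_f[i, ]
    p <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(obs_f[i, ], exp_f[i, ],
                                          paired = TRUE)$p.value)
    data.frame(k = ks[i], wilcoxon_p = p)
  }))
  list(fractions = fractions, tests = tests)
}

#' Structure of the pan-cancer community-pathway network
#'
#' Filters the community-by-pathway meta-z matrix at `z_cut`, reporting
#' per community its degree (number of passing pathways), its mean
#' meta-z over passing pathways, a hub flag (degree within the top 25%
#' of all communities), and the degree exponent gamma of the degree
#' distribution fitted by discrete power-law maximum likelihood.
#'
#' @param meta_z_mat numeric matrix, communities in rows, pathways in
#'   columns, of meta-z scores.
#' @param z_cut meta-z filter (default 1.64).
#' @param hub_fraction top fraction of degrees called hubs (default
#'   0.25).
#' @param gamma_method `"mle"` (discrete maximum likelihood, `x_min` =
#'   1) or `"lsq"` (log-log least squares on the degree distribution).
#' @return `list(stats = <data.frame community, degree, mean_meta_z,
#'   hub>, gamma=)`; `gamma` is `NA` when every degree is zero.
#' @export
network_stats <- function(meta_z_mat, z_cut = 1.64, hub_fraction = 0.25,
                          gamma_method = c("mle", "lsq")) {
  gamma_method <- match.arg(gamma_method)
  pass <- meta_z_mat > z_cut
  degree <- rowSums(pass)
  mean_mz <- ifelse(degree > 0, rowSums(meta_z_mat * pass) / degree, NA_real_)
  hub_cut <- stats::quantile(degree, 1 - hub_fraction, names = FALSE)
  gamma <- if (all(degree == 0)) NA_real_ else
    fit_power_law_gamma(degree[degree > 0], method = gamma_method)
  list(stats = data.frame(community = rownames(meta_z_mat) %||%
                            as.character(seq_along(degree)),
                          degree = unname(degree),
                          mean_meta_z = unname(mean_mz),
                          hub = unname(degree >= hub_cut),
                          stringsAsFactors = FALSE),
       gamma = gamma)
}

#' Fit the degree exponent of a discrete power law
#'
#' Maximum-likelihood fit of `P(k) ~ k^-gamma` on positive integer data
#' with `x_min = 1`, using the Riemann zeta normalization; the
#' log-likelihood `-n log zeta(gamma) - gamma sum(log x)` is maximized
#' numerically. The `"lsq"` alternative regresses log frequency on log
#' degree.
#'
#' @param x positive integer observations.
#' @param method `"mle"` or `"lsq"`.
#' @return estimated exponent gamma.
#' @export
fit_power_law_gamma <- function(x, method = c("mle", "lsq")) {
  method <- match.arg(method)
  x <- x[x >= 1]
  if (length(x) == 0L) return(NA_real_)
  if (method == "mle") {
    slx <- sum(log(x))
    nll <- function(g) length(x) * log(pracma::zeta(g)) + g * slx
    stats::optimize(nll, c(1.05, 10))$minimum
  } else {
    tab <- table(x)
    k <- as.numeric(names(tab))
    f <- as.numeric(tab) / length(x)
    keep <- k > 0 & f > 0
    -unname(stats::coef(stats::lm(log(f[keep]) ~ log(k[keep])))[2L])
  }
}

#' Sample from a (truncated) discrete power law
#'
#' @param n sample size.
#' @param gamma exponent (> 1).
#' @param xmax truncation point of the support `1..xmax`.
#' @return integer vector of draws.
#' @export
rpowerlaw <- function(n, gamma, xmax = 1e5) {
  k <- seq_len(xmax)
  sample(k, n, replace = TRUE, prob = k^(-gamma))
}

#' Hierarchical clustering of community meta-z profiles
#'
#' Average-linkage agglomeration with `1 - Pearson r` between community
#' rows as the distance; constant rows (undefined correlation) are
#' dropped with a warning. The tree is cut into `k` clusters.
#'
#' @param meta_z_mat communities x pathways matrix of meta-z scores with
#'   at least two non-constant rows.
#' @param k number of clusters to cut (default 4).
#' @return `list(labels = <named integer>, hclust = <hclust>)`.
#' @export
cluster_meta_z <- function(meta_z_mat, k = 4) {
  sds <- apply(meta_z_mat, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant row(s) dropped before clustering",
            call. = FALSE)
    meta_z_mat <- meta_z_mat[sds > 0, , drop = FALSE]
  }
  if (nrow(meta_z_mat) < 2L)
    stop_campnets("need at least 2 non-constant communities to cluster")
  d <- stats::as.dist(1 - stats::cor(t(meta_z_mat)))
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = min(k, nrow(meta_z_mat)))
  list(labels = labels, hclust = hc)
}
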
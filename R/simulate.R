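## Seeded synthetic-data generators with the statistical structure every
## pipeline stage assumes: planted template homology for the interolog
## scorer, planted differential expression, latent-factor co-expression
## blocks, proportional-hazards survival, and overlapping pathway
## collections with one planted community-pathway association.
## Every generator is a pure function of its arguments given the seed.

#' Generate an interactome fixture with planted homology structure
#'
#' Builds a human proteome (membrane proteins with cytoplasmic regions
#' plus background proteins), interolog templates in source organisms,
#' and alignment hits in which the true partners of each membrane
#' protein carry strong template homology (high region identity, low
#' per-protein and joint E-values, rich evidence, shared network
#' neighbors) while decoy partners pass the homology gates with weak
#' signal. E-values are generated directly as a deterministic function
#' of planted identity and length plus log-scale noise, since the
#' scorer consumes E-values rather than sequences.
#'
#' @param seed integer seed (required).
#' @param n_mps number of membrane proteins (default 3).
#' @param n_pos,n_neg true partners and decoys per membrane protein
#'   (default 5 each).
#' @param n_background background human proteins for the network
#'   (default 20).
#' @param evalue_noise_sd standard deviation of the log10 E-value noise
#'   (default 3).
#' @return list with `proteome`, `templates`, `hits`, `distances`,
#'   `network`, `positives`, `negatives` (data.frames `a`, `b`) and a
#'   `truth` record.
#' @export
make_interactome_fixture <- function(seed, n_mps = 3, n_pos = 5, n_neg = 5,
                                     n_background = 20,
                                     evalue_noise_sd = 3) {
  if (missing(seed)) stop_campnets("seed is required")
  if (n_pos + n_neg == 0) stop_campnets("need at least one planted pair")
  set.seed(seed)
  sources <- c("Mus musculus", "Drosophila melanogaster",
               "Caenorhabditis elegans")
  src_dist <- c(0.25, 0.65, 0.8)
  human <- "Homo sapiens"
  dt <- distance_table(
    org_a = c(rep(human, 3), "Mus musculus", "Mus musculus",
              "Drosophila melanogaster"),
    org_b = c(sources, "Drosophila melanogaster",
              "Caenorhabditis elegans", "Caenorhabditis elegans"),
    distance = c(src_dist, 0.6, 0.75, 0.5))

  mp_ids <- sprintf("MP%d", seq_len(n_mps))
  pos_ids <- outer(mp_ids, seq_len(n_pos),
                   function(m, j) sprintf("%s_POS%d", m, j))
  neg_ids <- outer(mp_ids, seq_len(n_neg),
                   function(m, j) sprintf("%s_NEG%d", m, j))
  bg_ids <- sprintf("BG%d", seq_len(n_background))
  human_ids <- c(mp_ids, as.vector(t(pos_ids)), as.vector(t(neg_ids)), bg_ids)
  lens <- sample(300:600, length(human_ids), replace = TRUE)
  cyto <- lapply(seq_along(human_ids), function(i) {
    if (human_ids[i] %in% mp_ids) {
      q <- sample(60:120, 1)
      s <- sample(seq_len(lens[i] - q), 1)
      matrix(c(s, s + q - 1L), ncol = 2)
    } else NULL
  })
  proteome <- protein_table(human_ids, human, lens,
                            is_mp = human_ids %in% mp_ids, cyto = cyto)

  self_exp <- function(len) pmin(170, round(0.5 * len))
  hit_rows <- list()
  tmpl_rows <- list()
  labels_pos <- list(); labels_neg <- list()
  tmpl_lens <- integer()
  add_hit <- function(q, s, ident, l, exp10) {
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      query = q, subject = s, identity = ident, length = as.integer(l),
      evalue = 10^(-max(1, exp10)), stringsAsFactors = FALSE)
  }
  new_tmpl_protein <- function(tag) {
    len <- sample(300:600, 1)
    id <- sprintf("T%s", tag)
    tmpl_lens[id] <<- len
    add_hit(id, id, 1, len, self_exp(len))
    id
  }
  mi_methods_rich <- c("MI:0114", "MI:0077", "MI:0019")
  edge_rows <- list()

  for (mi_ in seq_len(n_mps)) {
    mp <- mp_ids[mi_]
    q_d <- proteome$cyto[[match(mp, proteome$id)]]
    q_len <- q_d[1, 2] - q_d[1, 1] + 1L
    ## network: the MP has known partners among the background proteins;
    ## true partners share several of them, decoys share none
    mp_nb <- sample(bg_ids, min(8, max(1, n_background - 2)))
    for (nb in mp_nb)
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(a = mp, b = nb)
    for (j in seq_len(n_pos)) {
      partner <- pos_ids[mi_, j]
      n_tmpl <- sample(1:2, 1)
      org <- sample(sources, 1)
      for (k in seq_len(n_tmpl)) {
        ta <- new_tmpl_protein(sprintf("%s_P%d_%da", mp, j, k))
        tb <- new_tmpl_protein(sprintf("%s_P%d_%db", mp, j, k))
        tmpl_rows[[length(tmpl_rows) + 1L]] <- list(
          a = ta, b = tb, org = org,
          methods = sample(mi_methods_rich, sample(2:3, 1)),
          types = c("MI:0407", "MI:0915")[seq_len(sample(1:2, 1))],
          refs = sprintf("PM%04d", sample(1e4, sample(2:4, 1))))
        ## strong region hit on the MP-side template protein
        add_hit(sprintf("%s:cr1", mp), ta,
                stats::runif(1, 0.85, 0.95),
                round(q_len * stats::runif(1, 0.9, 1)),
                NA)  # region hits: E-value unused downstream
        hit_rows[[length(hit_rows)]]$evalue <- 1e-50
        ## strong homology: MP is a homolog of A, partner of B
        ea <- self_exp(tmpl_lens[ta]) * stats::runif(1, 0.6, 0.9) +
          stats::rnorm(1, 0, evalue_noise_sd)
        eb <- self_exp(tmpl_lens[tb]) * stats::runif(1, 0.6, 0.9) +
          stats::rnorm(1, 0, evalue_noise_sd)
        add_hit(ta, mp, stats::runif(1, 0.6, 0.9), round(0.8 * tmpl_lens[ta]),
                ea)
        add_hit(tb, partner, stats::runif(1, 0.6, 0.9),
                round(0.8 * tmpl_lens[tb]), eb)
        ## a weaker sibling hit so similarity ranks are informative
        add_hit(tb, sample(bg_ids, 1), stats::runif(1, 0.3, 0.4),
                round(0.4 * tmpl_lens[tb]), stats::runif(1, 45, 60))
      }
      ## shared neighbors with the MP in the human network
      for (nb in sample(mp_nb, min(4, length(mp_nb))))
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(a = partner, b = nb)
      labels_pos[[length(labels_pos) + 1L]] <- data.frame(
        a = mp, b = partner, stringsAsFactors = FALSE)
    }
    for (j in seq_len(n_neg)) {
      decoy <- neg_ids[mi_, j]
      org <- sample(sources, 1)
      ta <- new_tmpl_protein(sprintf("%s_N%d_a", mp, j))
      tb <- new_tmpl_protein(sprintf("%s_N%d_b", mp, j))
      tmpl_rows[[length(tmpl_rows) + 1L]] <- list(
        a = ta, b = tb, org = org,
        methods = "MI:0018", types = "MI:0915",
        refs = sprintf("PM%04d", sample(1e4, 1)))
      ## weak region hit, homology just past the gates
      add_hit(sprintf("%s:cr1", mp), ta, stats::runif(1, 0.25, 0.45),
              round(q_len * stats::runif(1, 0.4, 0.6)), NA)
      hit_rows[[length(hit_rows)]]$evalue <- 1e-20
      add_hit(ta, mp, stats::runif(1, 0.3, 0.5), round(0.4 * tmpl_lens[ta]),
              stats::runif(1, 42, 60) + stats::rnorm(1, 0, evalue_noise_sd))
      add_hit(tb, decoy, stats::runif(1, 0.3, 0.5), round(0.4 * tmpl_lens[tb]),
              stats::runif(1, 42, 60) + stats::rnorm(1, 0, evalue_noise_sd))
      ## decoys sit at the network periphery
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        a = decoy, b = sample(setdiff(bg_ids, mp_nb), 1))
      labels_neg[[length(labels_neg) + 1L]] <- data.frame(
        a = mp, b = decoy, stringsAsFactors = FALSE)
    }
  }
  ## random background edges
  for (i in seq_len(n_background)) {
    pr <- sample(bg_ids, 2)
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(a = pr[1], b = pr[2])
  }

  templates <- ppi_templates(
    protein_a = vapply(tmpl_rows, `[[`, character(1), "a"),
    protein_b = vapply(tmpl_rows, `[[`, character(1), "b"),
    species_a = vapply(tmpl_rows, `[[`, character(1), "org"),
    species_b = vapply(tmpl_rows, `[[`, character(1), "org"),
    methods = lapply(tmpl_rows, `[[`, "methods"),
    types = lapply(tmpl_rows, `[[`, "types"),
    refs = lapply(tmpl_rows, `[[`, "refs"))
  hits <- do.call(rbind, hit_rows)
  hits$evalue <- pmax(hits$evalue, EVALUE_FLOOR)
  network <- ppi_network(do.call(rbind, edge_rows))
  list(proteome = proteome, templates = templates, hits = hits,
       distances = dt, network = network,
       positives = do.call(rbind, labels_pos),
       negatives = do.call(rbind, labels_neg),
       truth = list(seed = seed, mp_ids = mp_ids))
}

#' Generate expression and survival data with planted structure
#'
#' Expression is baseline plus planted differential-expression shifts
#' (log2 fold change `log2fc`, alternating sign), latent-factor
#' co-expression blocks among tumor samples (a single factor per block
#' with loading `sqrt(target_r)`, so two block genes correlate at
#' `target_r` in expectation), and unit-variance Gaussian noise.
#' Survival times are exponential with log hazard
#' `sum_g beta_g * (x_g - mean(x_g))` and independent uniform censoring.
#'
#' @param seed integer seed (required).
#' @param n_genes number of genes (default 200; ids `G1..`).
#' @param n_tumor,n_normal sample counts (defaults 40 and 20).
#' @param deg_genes character vector of planted DEGs (default the first
#'   fifth of the genes).
#' @param log2fc planted absolute log2 fold change (default 2).
#' @param blocks list of gene vectors, one co-expression block each
#'   (default none).
#' @param target_r target within-block Pearson correlation in `(0, 1)`
#'   (default 0.7).
#' @param beta named numeric vector of per-gene log-hazard coefficients
#'   (default none).
#' @param baseline_hazard exponential baseline hazard per month
#'   (default 0.01).
#' @param censor_max upper bound of the uniform censoring time in
#'   months (default 240).
#' @return list with `expr` ([expression_matrix()]), `clinical`
#'   (data.frame `patient`, `time`, `event`) and a `truth` record
#'   (planted DEGs, blocks, beta).
#' @export
make_expression_survival_fixture <- function(seed, n_genes = 200,
                                             n_tumor = 40, n_normal = 20,
                                             deg_genes = NULL, log2fc = 2,
                                             blocks = list(),
                                             target_r = 0.7,
                                             beta = numeric(),
                                             baseline_hazard = 0.01,
                                             censor_max = 240) {
  if (missing(seed)) stop_campnets("seed is required")
  if (target_r <= 0 || target_r >= 1)
    stop_campnets("target correlation must lie in (0, 1)")
  set.seed(seed)
  genes <- sprintf("G%d", seq_len(n_genes))
  if (is.null(deg_genes)) deg_genes <- genes[seq_len(max(1, n_genes %/% 5))]
  if (length(setdiff(deg_genes, genes)))
    stop_campnets("planted DEG not among the generated genes")
  samples <- c(sprintf("T%d", seq_len(n_tumor)),
               sprintf("N%d", seq_len(n_normal)))
  group <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
  base <- stats::rnorm(n_genes, mean = 8, sd = 1)
  vals <- matrix(stats::rnorm(n_genes * length(samples), sd = 1),
                 nrow = n_genes, dimnames = list(genes, samples))
  vals <- vals + base
  ## planted DE shifts in tumor samples, alternating direction
  sign_ <- rep_len(c(1, -1), length(deg_genes))
  vals[deg_genes, group == "tumor"] <-
    vals[deg_genes, group == "tumor"] + sign_ * log2fc
  ## latent-factor blocks among tumor samples: replace the noise of the
  ## block genes with lambda * factor + sqrt(1 - lambda^2) * noise
  lambda <- sqrt(target_r)
  for (blk in blocks) {
    if (length(setdiff(blk, genes)))
      stop_campnets("block gene not among the generated genes")
    f <- stats::rnorm(n_tumor)
    noise <- matrix(stats::rnorm(length(blk) * n_tumor), nrow = length(blk))
    struct <- lambda * matrix(f, nrow = length(blk), ncol = n_tumor,
                              byrow = TRUE) +
      sqrt(1 - lambda^2) * noise
    ## keep each gene's tumor mean (hence its planted fold change) but
    ## replace its noise with the factor structure
    vals[blk, group == "tumor"] <-
      rowMeans(vals[blk, group == "tumor", drop = FALSE]) + struct
  }
  expr <- expression_matrix(vals, group)
  ## proportional-hazards survival for tumor samples
  tumor_ids <- samples[group == "tumor"]
  lp <- rep(0, n_tumor)
  if (length(beta)) {
    if (length(setdiff(names(beta), genes)))
      stop_campnets("beta gene not among the generated genes")
    xb <- vals[names(beta), tumor_ids, drop = FALSE]
    xb <- xb - rowMeans(xb)
    lp <- as.numeric(crossprod(xb, beta))
  }
  t_event <- stats::rexp(n_tumor, rate = baseline_hazard * exp(lp))
  t_cens <- stats::runif(n_tumor, min = 1, max = censor_max)
  time <- pmax(pmin(t_event, t_cens), 0.01)
  event <- as.numeric(t_event <= t_cens)
  clinical <- clinical_table(tumor_ids, time, event)
  list(expr = expr, clinical = clinical,
       truth = list(seed = seed, deg_genes = deg_genes,
                    deg_sign = stats::setNames(sign_, deg_genes),
                    blocks = blocks, target_r = target_r, beta = beta))
}

#' Generate an overlapping pathway collection with a planted association
#'
#' Random gene sets drawn from a universe, a designated cancer-related
#' subset, and optionally one planted pathway whose genes co-occur with
#' a designated community in a co-expression block, so that the
#' community-pathway pair is enriched by construction.
#'
#' @param seed integer seed (required).
#' @param universe character vector of gene identifiers to draw from.
#' @param n_pathways number of random pathways (default 10).
#' @param size_range inclusive range of random pathway sizes (default
#'   `c(10, 25)`).
#' @param planted optional character vector: the gene set of the
#'   planted pathway (named `planted_pathway`).
#' @param n_cancer_related size of the cancer-related subset (the
#'   planted pathway, when present, is always included).
#' @return a [pathway_collection()].
#' @export
make_pathway_fixture <- function(seed, universe, n_pathways = 10,
                                 size_range = c(10, 25), planted = NULL,
                                 n_cancer_related = 4) {
  if (missing(seed)) stop_campnets("seed is required")
  set.seed(seed)
  sets <- lapply(seq_len(n_pathways), function(i)
    sample(universe, sample(size_range[1]:size_range[2], 1)))
  names(sets) <- sprintf("PW%02d", seq_len(n_pathways))
  if (!is.null(planted)) sets <- c(list(planted_pathway = planted), sets)
  cr <- unique(c(if (!is.null(planted)) "planted_pathway",
                 sample(names(sets), min(n_cancer_related, length(sets)))))
  pathway_collection(sets, cr)
}

#' Generate a fully wired pipeline fixture
#'
#' Couples the three generators so the whole analysis runs end to end:
#' a planted community (membrane-protein gene plus partners) whose
#' genes, together with a planted pathway's genes, are differentially
#' expressed and co-expressed through one latent block, plus decoy
#' communities supplying the permutation partner pool, null pathways,
#' and a prognostic signal on the community genes.
#'
#' @param seed integer seed (required).
#' @param n_genes gene universe size (default 120).
#' @param n_tumor,n_normal sample counts (defaults 60 and 25).
#' @param community_size partners of the planted community (default 9).
#' @param pathway_size genes of the planted pathway (default 22).
#' @param n_null_communities decoy communities (default 7).
#' @param beta log-hazard coefficient applied to a few community genes
#'   (default 0.4).
#' @return list with `expr`, `clinical`, `degs`, `coexpr`,
#'   `communities` (planted first), `pathways`, and `truth`.
#' @export
make_campnets_fixture <- function(seed, n_genes = 120, n_tumor = 60,
                                  n_normal = 25, community_size = 9,
                                  pathway_size = 22,
                                  n_null_communities = 7, beta = 0.4) {
  if (missing(seed)) stop_campnets("seed is required")
  genes <- sprintf("G%d", seq_len(n_genes))
  comm_genes <- genes[seq_len(community_size + 1L)]          # mp + partners
  pw_genes <- genes[(community_size + 2L):(community_size + 1L + pathway_size)]
  planted_block <- c(comm_genes, pw_genes)
  deg_genes <- genes[seq_len(min(n_genes, length(planted_block) + 8L))]
  beta_vec <- stats::setNames(rep(beta, 4), comm_genes[2:5])
  es <- make_expression_survival_fixture(
    seed = seed, n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
    deg_genes = deg_genes, log2fc = 2, blocks = list(planted_block),
    target_r = 0.7, beta = beta_vec)
  set.seed(seed + 1L)
  pool_genes <- setdiff(genes, planted_block)
  communities <- c(
    list(mpp_community(comm_genes[1], comm_genes[-1])),
    lapply(seq_len(n_null_communities), function(i)
      mpp_community(sample(pool_genes, 1),
                    sample(pool_genes, community_size))))
  pathways <- make_pathway_fixture(
    seed = seed + 2L, universe = genes, n_pathways = 10,
    planted = pw_genes, n_cancer_related = 4)
  degs <- call_degs(es$expr)
  coexpr <- coexpressed_pairs(es$expr, degs$gene[degs$deg],
                              degs$gene[degs$deg], h = 0.5)
  list(expr = es$expr, clinical = es$clinical, degs = degs,
       coexpr = coexpr, communities = communities, pathways = pathways,
       truth = c(es$truth, list(planted_community = communities[[1]],
                                planted_pathway = "planted_pathway",
                                prognostic_genes = names(beta_vec))))
}
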
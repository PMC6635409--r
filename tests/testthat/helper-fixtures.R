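# Shared helpers: tiny in-code fixtures and independent oracles used by
# the tests. Oracles are deliberately naive (loops, direct formulas) and
# never call the code paths they check.

# direct tail sum of the hypergeometric pmf with exact binomials
brute_hyper_tail <- function(x, M, N, n) {
  i <- x:n
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# exhaustive enumeration over all C(N, n) draws (small N only)
enumerate_hyper_tail <- function(x, M, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= M)  # items 1..M are the "successes"
  mean(hits >= x)
}

# naive re-scorer: enumerates every (region, template, homolog-pair)
# triple with plain loops and independent component arithmetic
brute_force_scores <- function(mp, proteome, templates, hits, network,
                               distances, e_single = 1e-10,
                               e_joint = 1e-40) {
  pi <- match(mp, proteome$id)
  regions <- proteome$cyto[[pi]]
  target_org <- proteome$species[pi]
  humans <- proteome$id[proteome$species == target_org]
  floor_e <- function(e) max(e, 1e-180)
  get_hits <- function(q, s) {
    rows <- hits[hits$query == q & hits$subject == s, , drop = FALSE]
    rows
  }
  # per-pair supporting template organisms (for the conservation term)
  support <- list()
  triples <- list()
  for (ti in seq_len(nrow(templates))) {
    for (side in c("a", "b")) {
      A <- if (side == "a") templates$protein_a[ti] else templates$protein_b[ti]
      B <- if (side == "a") templates$protein_b[ti] else templates$protein_a[ti]
      for (ri in seq_len(nrow(regions))) {
        rh <- get_hits(sprintf("%s:cr%d", mp, ri), A)
        if (nrow(rh) == 0L) next
        ea_rows <- get_hits(A, mp)
        if (nrow(ea_rows) == 0L) next
        ea <- floor_e(min(ea_rows$evalue))
        if (ea > e_single) next
        for (B2 in setdiff(humans, mp)) {
          eb_rows <- get_hits(B, B2)
          if (nrow(eb_rows) == 0L) next
          eb <- floor_e(min(eb_rows$evalue))
          if (eb > e_single) next
          if (sqrt(ea * eb) > e_joint) next
          for (hi in seq_len(nrow(rh))) {
            q_d <- regions[ri, 2] - regions[ri, 1] + 1
            s_irs <- sqrt(rh$identity[hi] * min(1, rh$length[hi] / q_d))
            xm <- length(templates$methods[[ti]])
            xt <- length(templates$types[[ti]])
            xr <- length(templates$refs[[ti]])
            s_qul <- (min(xm, 2) + min(xt, 2) + min(xr, 2)) / 6
            esA <- floor_e(get_hits(A, A)$evalue[1])
            esB <- floor_e(get_hits(B, B)$evalue[1])
            rA <- min(1, max(0, log10(ea) / log10(esA)))
            rB <- min(1, max(0, log10(eb) / log10(esB)))
            s_jss <- sqrt(rA) * sqrt(rB)
            triples[[length(triples) + 1L]] <- data.frame(
              partner = B2, template_i = ti, s_irs = s_irs,
              s_qul = s_qul, s_jss = s_jss, stringsAsFactors = FALSE)
            key <- B2
            support[[key]] <- unique(c(support[[key]], ti))
          }
        }
      }
    }
  }
  if (length(triples) == 0L) return(NULL)
  tr <- do.call(rbind, triples)
  # fractional ranks per template, descending joint similarity
  tr$s_rank <- NA_real_
  for (ti in unique(tr$template_i)) {
    sel <- tr$template_i == ti
    r <- rank(-tr$s_jss[sel], ties.method = "average")
    rmx <- sum(sel)
    tr$s_rank[sel] <- if (rmx == 1) 1 else 1 - log10(r) / log10(rmx)
  }
  # conservation per partner over supporting templates
  org_of <- function(ti) {
    oa <- templates$species_a[ti]; ob <- templates$species_b[ti]
    if (oa == ob) oa else c(oa, ob)
  }
  tr$s_es <- vapply(tr$partner, function(p) {
    tis <- support[[p]]
    orgs <- vapply(tis, function(ti) paste(sort(org_of(ti)), collapse = "+"),
                   character(1))
    tot <- 0
    for (o in unique(orgs)) {
      members <- strsplit(o, "+", fixed = TRUE)[[1L]]
      d <- mean(vapply(members, function(m)
        distance_between(distances, target_org, m), numeric(1)))
      tot <- tot + d * min(sum(orgs == o), 2) / 2
    }
    min(1, tot)
  }, numeric(1))
  tr$s_topo <- vapply(tr$partner, function(p) {
    ndeg <- network$degree[mp]
    if (is.na(ndeg) || ndeg == 0) return(0)
    shared <- length(intersect(network$adj[[mp]], network$adj[[p]]))
    rb <- network$rank[p]
    if (is.na(rb)) rb <- network$r_max
    sqrt((shared / ndeg) * (1 - (rb - 1) / network$r_max))
  }, numeric(1))
  tr$s_sim <- tr$s_irs + tr$s_qul + tr$s_jss + tr$s_rank + tr$s_es + tr$s_topo
  best <- tapply(tr$s_sim, tr$partner, max)
  sort(best, decreasing = TRUE)
}

# a two-gene / 22-gene disjoint enrichment setting mirroring a worked
# community-pathway pair
tiny_enrichment_setting <- function(n_coexpr = 6) {
  inv <- c("EG1", "EG2")
  pw <- sprintf("PWG%02d", 1:22)
  extra <- sprintf("XG%02d", 1:10)
  degs <- data.frame(gene = c(inv, pw, extra),
                     deg = TRUE, stringsAsFactors = FALSE)
  pathways <- pathway_collection(list(
    target = pw,
    other = c(pw[1:5], extra)), cancer_related = "target")
  coexpr <- data.frame(gene_a = rep(inv, length.out = n_coexpr),
                       gene_b = pw[seq_len(n_coexpr)],
                       r = rep(0.8, n_coexpr), stringsAsFactors = FALSE)
  list(community = mpp_community("MPX", c(inv, "NOTDEG")),
       degs = degs, pathways = pathways, coexpr = coexpr)
}

# null enrichment world: random communities, random pathways, noisy
# co-expression; nothing planted
null_enrichment_world <- function(seed, n_genes = 60, n_tumor = 12,
                                  n_communities = 8, comm_size = 8) {
  es <- make_expression_survival_fixture(
    seed = seed, n_genes = n_genes, n_tumor = n_tumor, n_normal = 4,
    deg_genes = sprintf("G%d", seq_len(n_genes)), log2fc = 2)
  degs <- call_degs(es$expr)
  genes <- degs$gene[degs$deg]
  coexpr <- coexpr_index(coexpressed_pairs(es$expr, genes, genes))
  set.seed(seed + 1000L)
  communities <- lapply(seq_len(n_communities), function(i) {
    mem <- sample(genes, comm_size + 1L)
    mpp_community(mem[1L], mem[-1L])
  })
  pathways <- pathway_collection(list(
    pw1 = sample(genes, 15), pw2 = sample(genes, 20),
    pw3 = sample(genes, 12)), cancer_related = "pw1")
  list(degs = degs, coexpr = coexpr, communities = communities,
       pathways = pathways)
}
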
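## The six-component integrated similarity score for interolog-based
## membrane-protein PPI prediction, the two-stage candidate search, and
## ROC/F2 evaluation against labeled positive/negative pairs.
##
## S_SIM = S_irs + S_qul + S_jss + S_rank + S_es + S_topo, each component
## in [0, 1], so S_SIM ranges from 0 to 6.

#' Interacting-region similarity
#'
#' `sqrt(SI * L / Q_d)` where `SI` is the alignment sequence identity
#' between a cytoplasmic region of the membrane protein and a template
#' protein, `L` the aligned length and `Q_d` the region length. `L/Q_d`
#' is clipped at 1 so the score stays in `[0, 1]`.
#'
#' @param si sequence identity fraction in `[0, 1]`.
#' @param l aligned length (>= 1).
#' @param q_d cytoplasmic-region length (>= 1).
#' @return score in `[0, 1]`.
#' @export
score_irs <- function(si, l, q_d) {
  if (any(q_d <= 0)) stop_campnets("region length Q_d must be positive")
  if (any(si < 0 | si > 1)) stop_campnets("identity must lie in [0, 1]")
  if (any(l < 1)) stop_campnets("aligned length must be >= 1")
  sqrt(si * pmin(1, l / q_d))
}

#' Template-quality score
#'
#' Evidence counts (detection methods, interaction types, references)
#' are capped at 2 each and the capped sum divided by 6, yielding a
#' score in `[0, 1]` with the maximum attained at the caps.
#'
#' @param x_m,x_t,x_r raw nonnegative evidence counts.
#' @return score in `[0, 1]`.
#' @export
score_qul <- function(x_m, x_t, x_r) {
  if (any(c(x_m, x_t, x_r) < 0)) stop_campnets("evidence counts must be >= 0")
  (pmin(x_m, 2) + pmin(x_t, 2) + pmin(x_r, 2)) / 6
}

#' Normalized joint sequence similarity
#'
#' Geometric mean of the two per-protein `-log10` E-value ratios, each
#' normalized by the protein's self-alignment E-value (the maximum
#' attainable similarity for its length) and clipped to `[0, 1]`.
#' An E-value of 1 or more carries no similarity signal and contributes
#' a ratio of 0.
#'
#' @param e_a_prime E-value of template protein A against candidate A'.
#' @param e_b_prime E-value of template protein B against candidate B'.
#' @param e_a_self,e_b_self self-alignment E-values of A and B.
#' @return score in `[0, 1]`.
#' @export
score_jss <- function(e_a_prime, e_b_prime, e_a_self, e_b_self) {
  ratio <- function(e_cross, e_self) {
    ## literal-zero guard only; legitimately tiny E-values are kept
    e_cross <- ifelse(e_cross <= 0, EVALUE_FLOOR, e_cross)
    e_self <- ifelse(e_self <= 0, EVALUE_FLOOR, e_self)
    num <- -log10(e_cross)
    den <- -log10(e_self)
    r <- ifelse(num <= 0 | den <= 0, 0, num / den)
    clip01(r)
  }
  sqrt(ratio(e_a_prime, e_a_self)) * sqrt(ratio(e_b_prime, e_b_self))
}

#' Similarity-rank score
#'
#' `1 - log10(r) / log10(r_max)` where `r` is the (possibly fractional)
#' rank of the candidate by joint sequence similarity among all
#' candidates derived from the same template, and `r_max` the candidate
#' count. A single candidate (`r_max = 1`) scores 1.
#'
#' @param r rank, `1 <= r <= r_max`.
#' @param r_max total candidate count for the template.
#' @return score in `[0, 1]`.
#' @export
score_rank <- function(r, r_max) {
  if (any(r_max < 1)) stop_campnets("r_max must be >= 1")
  if (any(r < 1 | r > r_max)) stop_campnets("rank must lie in [1, r_max]")
  n <- max(length(r), length(r_max))
  r <- rep_len(r, n); r_max <- rep_len(r_max, n)
  ifelse(r_max == 1, 1, clip01(1 - log10(r) / log10(r_max)))
}

#' Evolutionary-conservation score
#'
#' Sums, over source organisms contributing at least one supporting
#' template, the normalized evolutionary distance to the target organism
#' weighted by the capped template count (`min(m_f, 2)/2`): a candidate
#' supported by two or more templates in a distant organism is treated
#' as more conserved. The sum is clipped to `[0, 1]`.
#'
#' @param distances numeric vector of normalized distances in `[0, 1]`,
#'   one per source organism.
#' @param counts template counts `m_f >= 1` per organism.
#' @return score in `[0, 1]`; 0 for empty evidence.
#' @export
score_es <- function(distances, counts) {
  if (length(distances) == 0L) return(0)
  if (any(distances < 0 | distances > 1))
    stop_campnets("normalized distances must lie in [0, 1]")
  if (any(counts < 1)) stop_campnets("template counts must be >= 1")
  clip01(sum(distances * pmin(counts, 2) / 2))
}

#' Network-topology score
#'
#' `sqrt((C/N) * D)` where `C` is the number of interaction partners
#' shared between the membrane protein and the candidate, `N` the
#' membrane protein's degree, and `D = 1 - (R_B - 1)/R_max` the
#' normalized fractional degree rank of the candidate (rank 1 = highest
#' degree). Zero when the membrane protein has no known partners.
#'
#' @param c_shared shared-neighbor count, `0 <= C <= N`.
#' @param n_degree degree of the membrane protein.
#' @param r_b fractional degree rank of the candidate.
#' @param r_max fractional rank of the smallest-degree protein.
#' @return score in `[0, 1]`.
#' @export
score_topo <- function(c_shared, n_degree, r_b, r_max) {
  if (any(c_shared > n_degree)) stop_campnets("C cannot exceed N")
  if (any(r_b < 1 | r_b > r_max)) stop_campnets("R_B must lie in [1, R_max]")
  n <- max(length(c_shared), length(n_degree), length(r_b), length(r_max))
  c_shared <- rep_len(c_shared, n); n_degree <- rep_len(n_degree, n)
  r_b <- rep_len(r_b, n); r_max <- rep_len(r_max, n)
  ifelse(n_degree == 0, 0,
         sqrt((c_shared / pmax(n_degree, 1)) * (1 - (r_b - 1) / r_max)))
}

# ---- interaction network ----------------------------------------------

#' Build an interaction network from an edge list
#'
#' Stores the symmetric adjacency, per-protein degree and fractional
#' degree ranks (rank 1 = largest degree, average ranks on ties, in the
#' spirit of a Borda count). `r_max` is the rank of the smallest-degree
#' protein.
#'
#' @param edges data.frame with columns `a`, `b` (undirected edges).
#' @return `list(adj=, degree=, rank=, r_max=)`, class `"ppi_network"`.
#' @export
ppi_network <- function(edges) {
  if (nrow(edges) == 0L)
    return(structure(list(adj = list(), degree = numeric(),
                          rank = numeric(), r_max = 1),
                     class = "ppi_network"))
  keys <- pair_key(edges$a, edges$b)
  keep <- !duplicated(keys) & edges$a != edges$b
  edges <- edges[keep, , drop = FALSE]
  nodes <- sort(unique(c(edges$a, edges$b)))
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    sort(unique(c(edges$b[edges$a == v], edges$a[edges$b == v]))))
  degree <- lengths(adj)
  rk <- rank(-degree, ties.method = "average")
  structure(list(adj = adj, degree = degree,
                 rank = stats::setNames(rk, nodes), r_max = max(rk)),
            class = "ppi_network")
}

network_shared_neighbors <- function(network, a, b) {
  na <- network$adj[[a]]; nb <- network$adj[[b]]
  if (is.null(na) || is.null(nb)) return(0L)
  length(intersect(na, nb))
}

network_topo_score <- function(network, mp, partner) {
  n_deg <- network$degree[mp]
  if (is.na(n_deg) || n_deg == 0) return(0)
  r_b <- network$rank[partner]
  if (is.na(r_b)) r_b <- network$r_max  # unseen protein ranked last
  score_topo(network_shared_neighbors(network, mp, partner),
             unname(n_deg), unname(r_b), network$r_max)
}

# ---- two-stage candidate search ---------------------------------------

#' Predict interaction partners of a membrane protein
#'
#' Stage 1 uses each annotated cytoplasmic region of the membrane
#' protein to select templates whose proteins the region aligns to; the
#' hit side of the template becomes the MP-side template protein A, its
#' partner B. Stage 2 enumerates homologous candidate pairs: the MP must
#' be a homolog of A and candidate partners B' homologs of B, each
#' per-protein E-value at most `e_single` and the joint E-value
#' (geometric mean) at most `e_joint`. Each surviving
#' (region, template, partner) combination is scored with all six
#' components; per partner the maximum integrated score is reported,
#' with the component scores of the maximizing combination.
#'
#' @param mp membrane-protein identifier (must carry cytoplasmic
#'   regions in `proteome`).
#' @param proteome a [protein_table()]; candidate partners are drawn
#'   from proteins of the membrane protein's own organism.
#' @param templates a [ppi_templates()] table; the membrane protein's
#'   own templates should have been removed beforehand with
#'   [exclude_self_templates()].
#' @param hits alignment hit table covering region-to-template-protein
#'   and template-protein-to-proteome searches, including
#'   self-alignments (query == subject) of template proteins. Region
#'   queries are named `<mp>:cr<i>`.
#' @param network a [ppi_network()] of the target organism.
#' @param distances a [distance_table()] of normalized evolutionary
#'   distances between organisms.
#' @param threshold minimum integrated score to keep (default 3.6, the
#'   reported-template operating point; 3.7 for direct templates). Use
#'   0 to keep all scored candidates.
#' @param e_single per-protein homology E-value gate (default 1e-10).
#' @param e_joint joint E-value gate (default 1e-40).
#' @return data.frame with one row per retained partner: `mp`,
#'   `partner`, the six component scores, `s_sim`, and the template pair
#'   achieving the maximum.
#' @export
predict_partners <- function(mp, proteome, templates, hits, network,
                             distances, threshold = 3.6,
                             e_single = 1e-10, e_joint = 1e-40) {
  empty <- data.frame(mp = character(), partner = character(),
                      s_irs = numeric(), s_qul = numeric(),
                      s_jss = numeric(), s_rank = numeric(),
                      s_es = numeric(), s_topo = numeric(),
                      s_sim = numeric(), template_a = character(),
                      template_b = character(), stringsAsFactors = FALSE)
  pi <- match(mp, proteome$id)
  if (is.na(pi)) stop_campnets("membrane protein ", mp, " not in proteome")
  regions <- proteome$cyto[[pi]]
  if (is.null(regions) || nrow(regions) == 0L) {
    warning("membrane protein ", mp, " has no annotated cytoplasmic region",
            call. = FALSE)
    return(empty)
  }
  target_org <- proteome$species[pi]
  target_ids <- proteome$id[proteome$species == target_org]
  region_ids <- sprintf("%s:cr%d", mp, seq_len(nrow(regions)))
  q_d <- regions[, 2L] - regions[, 1L] + 1L

  hits$evalue <- pmax(hits$evalue, EVALUE_FLOOR)
  self_e <- stats::setNames(hits$evalue[hits$query == hits$subject],
                            hits$query[hits$query == hits$subject])
  tmpl_prot <- unique(c(templates$protein_a, templates$protein_b))
  region_hits <- hits[hits$query %in% region_ids &
                        hits$subject %in% tmpl_prot, , drop = FALSE]
  homolog_hits <- hits[hits$query %in% tmpl_prot &
                         hits$subject %in% target_ids &
                         hits$query != hits$subject &
                         hits$evalue <= e_single, , drop = FALSE]
  if (nrow(region_hits) == 0L || nrow(templates) == 0L) return(empty)

  ## stage 1 + 2: enumerate scored (region, template, partner) triples;
  ## s_rank needs all candidates of a template, so collect per template.
  rows <- list()
  for (ti in seq_len(nrow(templates))) {
    ta <- templates$protein_a[ti]; tb <- templates$protein_b[ti]
    rh <- region_hits[region_hits$subject %in% c(ta, tb), , drop = FALSE]
    if (nrow(rh) == 0L) next
    if (is.na(self_e[ta]) || is.na(self_e[tb])) {
      warning("template ", ta, "-", tb,
              " skipped: missing self-alignment E-value", call. = FALSE)
      next
    }
    xq <- count_evidence(templates$methods[[ti]], templates$types[[ti]],
                         templates$refs[[ti]])
    s_qul_t <- score_qul(xq["x_m"], xq["x_t"], xq["x_r"])
    tmpl_rows <- list()
    for (ri in seq_len(nrow(rh))) {
      a_side <- rh$subject[ri]           # hit side = MP-side protein
      b_side <- if (a_side == ta) tb else ta
      reg_idx <- match(rh$query[ri], region_ids)
      s_irs_i <- score_irs(rh$identity[ri], rh$length[ri], q_d[reg_idx])
      ## the MP itself must be a homolog of the MP-side template protein
      e_a <- homolog_hits$evalue[homolog_hits$query == a_side &
                                   homolog_hits$subject == mp]
      if (length(e_a) == 0L) next
      e_a <- min(e_a)
      bh <- homolog_hits[homolog_hits$query == b_side &
                           homolog_hits$subject != mp, , drop = FALSE]
      if (nrow(bh) == 0L) next
      joint <- sqrt(e_a * bh$evalue)
      bh <- bh[joint <= e_joint, , drop = FALSE]
      if (nrow(bh) == 0L) next
      s_jss_i <- score_jss(e_a, bh$evalue, self_e[a_side], self_e[b_side])
      tmpl_rows[[length(tmpl_rows) + 1L]] <- data.frame(
        partner = bh$subject, s_irs = s_irs_i, s_qul = unname(s_qul_t),
        s_jss = s_jss_i, template_a = a_side, template_b = b_side,
        template_i = ti, stringsAsFactors = FALSE)
    }
    if (length(tmpl_rows) == 0L) next
    cand <- do.call(rbind, tmpl_rows)
    ## fractional ranks by descending joint similarity within template
    cand$rank <- rank(-cand$s_jss, ties.method = "average")
    cand$s_rank <- score_rank(cand$rank, nrow(cand))
    rows[[length(rows) + 1L]] <- cand
  }
  if (length(rows) == 0L) return(empty)
  cand <- do.call(rbind, rows)

  ## conservation: per (mp, partner) pair, organisms of all supporting
  ## templates, counts capped at 2 inside score_es
  tmpl_org <- vapply(seq_len(nrow(templates)), function(ti) {
    oa <- templates$species_a[ti]; ob <- templates$species_b[ti]
    if (oa == ob) oa else paste(oa, ob, sep = "\r")
  }, character(1))
  org_dist <- function(orgkey) {
    orgs <- strsplit(orgkey, "\r", fixed = TRUE)[[1L]]
    mean(vapply(orgs, function(o) distance_between(distances, target_org, o),
                numeric(1)))
  }
  es_by_partner <- vapply(split(cand$template_i, cand$partner), function(tis) {
    orgs <- tmpl_org[unique(tis)]
    cnt <- table(orgs)
    score_es(vapply(names(cnt), org_dist, numeric(1)), as.integer(cnt))
  }, numeric(1))
  cand$s_es <- unname(es_by_partner[cand$partner])
  topo_by_partner <- vapply(unique(cand$partner), function(p)
    network_topo_score(network, mp, p), numeric(1))
  cand$s_topo <- unname(topo_by_partner[cand$partner])
  cand$s_sim <- cand$s_irs + cand$s_qul + cand$s_jss + cand$s_rank +
    cand$s_es + cand$s_topo

  best <- do.call(rbind, lapply(split(cand, cand$partner), function(d)
    d[which.max(d$s_sim), , drop = FALSE]))
  out <- data.frame(mp = mp, partner = best$partner,
                    s_irs = best$s_irs, s_qul = best$s_qul,
                    s_jss = best$s_jss, s_rank = best$s_rank,
                    s_es = best$s_es, s_topo = best$s_topo,
                    s_sim = best$s_sim, template_a = best$template_a,
                    template_b = best$template_b, stringsAsFactors = FALSE)
  out <- out[order(-out$s_sim, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out[out$s_sim >= threshold, , drop = FALSE]
}

# ---- evaluation --------------------------------------------------------

#' Evaluate scored pairs against labeled positives and negatives
#'
#' Computes the ROC AUC by the rank statistic (tie-averaged), the
#' precision/recall curve over a grid of thresholds (every distinct
#' score), the F2 score `5PR/(4P + R)` per threshold, and the threshold
#' maximizing F2 (smallest on ties). Labeled pairs without a score are
#' assigned score 0.
#'
#' @param scores named numeric vector: `pair key -> score` (use
#'   [pair_key()]), or a data.frame from [predict_partners()] (keyed on
#'   mp/partner).
#' @param positives,negatives data.frames with columns `a`, `b`
#'   (disjoint label sets).
#' @return `list(auc=, pr_curve=, best_f2=, best_threshold=)`.
#' @export
evaluate_predictions <- function(scores, positives, negatives) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$s_sim, pair_key(scores$mp, scores$partner))
  pos_key <- pair_key(positives$a, positives$b)
  neg_key <- pair_key(negatives$a, negatives$b)
  if (length(pos_key) == 0L || length(neg_key) == 0L)
    stop_campnets("both a positive and a negative class are required")
  if (length(intersect(pos_key, neg_key)))
    stop_campnets("positive and negative sets overlap")
  s <- function(k) ifelse(is.na(scores[k]), 0, scores[k])
  sp <- s(pos_key); sn <- s(neg_key)
  all_s <- c(sp, sn)
  labels <- c(rep(TRUE, length(sp)), rep(FALSE, length(sn)))
  r <- rank(all_s, ties.method = "average")
  auc <- (sum(r[labels]) - length(sp) * (length(sp) + 1) / 2) /
    (length(sp) * length(sn))
  thr <- sort(unique(all_s))
  pr <- t(vapply(thr, function(t) {
    pred <- all_s >= t
    tp <- sum(pred & labels)
    prec <- if (sum(pred) == 0) NA_real_ else tp / sum(pred)
    rec <- tp / length(sp)
    f2 <- if (is.na(prec) || (prec == 0 && rec == 0)) 0 else
      5 * prec * rec / (4 * prec + rec)
    c(threshold = t, precision = prec, recall = rec, f2 = f2)
  }, numeric(4)))
  pr <- as.data.frame(pr)
  best <- which(pr$f2 == max(pr$f2))
  best <- best[which.min(pr$threshold[best])]
  list(auc = unname(auc), pr_curve = pr,
       best_f2 = pr$f2[best], best_threshold = pr$threshold[best])
}
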
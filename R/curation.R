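## Curation of PPI template sets: PSI-MI reliability scoring with parent
## inheritance, the evidence-cap rule feeding the template-quality score,
## the direct-interaction filter, and the RSS-based negative set.

MI_EXPERIMENTAL <- "MI:0045"  # experimental interaction detection
MI_DIRECT <- "MI:0407"        # direct interaction

#' Construct a PSI-MI reliability map
#'
#' Detection-method reliability scores range from 0 (lowest confidence,
#' e.g. genetic interference) to 10 (highest, e.g. X-ray
#' crystallography); high-throughput screens score at most 5. A term
#' without an assigned score inherits the score of its nearest scored
#' ancestor through the parent links.
#'
#' @param scores named integer vector, `MI:NNNN` -> score in 0..10.
#' @param parents named character vector, `MI:NNNN` -> parent `MI:NNNN`.
#' @return `list(scores=, parents=)` with class `"reliability_map"`.
#' @export
reliability_map <- function(scores, parents = character()) {
  scores <- vapply(scores, as.integer, integer(1))
  if (any(scores < 0 | scores > 10))
    stop_campnets("reliability scores must lie in 0..10")
  parents <- vapply(parents, as.character, character(1))
  # reject cycles in the parent structure
  for (code in names(parents)) {
    seen <- character()
    cur <- code
    while (!is.na(cur <- unname(parents[cur]))) {
      if (cur %in% seen || identical(cur, code))
        stop_campnets("cycle in MI parent links at ", code)
      seen <- c(seen, cur)
      if (!cur %in% names(parents)) break
    }
  }
  structure(list(scores = scores, parents = parents),
            class = "reliability_map")
}

#' Read a reliability map from YAML
#'
#' Expected structure: `mi_scores: {MI:NNNN: int}` and
#' `mi_parents: {MI:NNNN: MI:NNNN}`.
#'
#' @param path YAML file path.
#' @return a [reliability_map()].
#' @export
read_reliability_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  reliability_map(unlist(cfg$mi_scores %||% list()),
                  unlist(cfg$mi_parents %||% list()))
}

#' Resolve the reliability score of an MI term
#'
#' Walks parent links until a scored ancestor is found.
#'
#' @param rmap a [reliability_map()].
#' @param code an `MI:NNNN` term code.
#' @return integer score in 0..10; error when unresolvable.
#' @export
mi_score <- function(rmap, code) {
  cur <- code
  repeat {
    s <- rmap$scores[cur]
    if (!is.na(s)) return(unname(s))
    nxt <- rmap$parents[cur]
    if (is.na(nxt)) stop_campnets("unresolvable MI code: ", code)
    cur <- unname(nxt)
  }
}

#' Test MI term ancestry
#'
#' @param code candidate descendant term.
#' @param ancestor candidate ancestor term.
#' @param parents named parent-link vector.
#' @return TRUE when `code` equals `ancestor` or lies below it.
#' @export
mi_is_a <- function(code, ancestor, parents) {
  cur <- code
  steps <- 0L
  repeat {
    if (identical(cur, ancestor)) return(TRUE)
    nxt <- parents[cur]
    if (is.na(nxt)) return(FALSE)
    cur <- unname(nxt)
    steps <- steps + 1L
    if (steps > 1000L) stop_campnets("parent chain too deep at ", code)
  }
}

## Keep only representative terms: when one term in the set is an
## ancestor of another, the child is the representative and the ancestor
## is dropped.
representative_terms <- function(codes, parents) {
  codes <- unique(codes)
  if (length(codes) < 2L) return(codes)
  is_ancestor_of_other <- vapply(codes, function(a) {
    any(vapply(setdiff(codes, a), function(b) mi_is_a(b, a, parents),
               logical(1)))
  }, logical(1))
  codes[!is_ancestor_of_other]
}

#' Count capped template evidence
#'
#' Counts detection methods, interaction types and references for one
#' template, after reducing each MI term set to representative terms
#' (when a term is a subclass of another in the same template, only the
#' child is counted). Each count is capped at 2, so the template-quality
#' score built from them lies in `[0, 1]`.
#'
#' @param methods,types character vectors of MI codes.
#' @param refs character vector of PubMed ids.
#' @param parents MI parent links (named character vector).
#' @return named integer vector `c(x_m=, x_t=, x_r=)`, each in 0..2.
#' @export
count_evidence <- function(methods, types, refs, parents = character()) {
  xm <- length(representative_terms(methods, parents))
  xt <- length(representative_terms(types, parents))
  xr <- length(unique(refs))
  c(x_m = min(xm, 2L), x_t = min(xt, 2L), x_r = min(xr, 2L))
}

#' Filter templates down to direct physical interactions
#'
#' A template is kept when (a) at least one detection method falls under
#' experimental interaction detection (`MI:0045`), (b) an interaction
#' type is direct interaction (`MI:0407`) or a descendant, and (c) the
#' reliability scores of the representative detection methods sum to at
#' least `min_score_sum`, which excludes interactions supported only by
#' a single high-throughput screen (scores <= 5).
#'
#' @param templates table from [ppi_templates()].
#' @param rmap a [reliability_map()]; must resolve every method code.
#' @param min_score_sum minimum summed reliability (default 6).
#' @return the filtered template table.
#' @export
select_direct_templates <- function(templates, rmap, min_score_sum = 6) {
  if (nrow(templates) == 0L) return(templates)
  ## every method code must resolve to a score before filtering
  for (code in unique(unlist(templates$methods))) mi_score(rmap, code)
  keep <- vapply(seq_len(nrow(templates)), function(i) {
    methods <- templates$methods[[i]]
    types <- templates$types[[i]]
    if (length(methods) == 0L) return(FALSE)
    experimental <- vapply(methods, mi_is_a, logical(1),
                           ancestor = MI_EXPERIMENTAL,
                           parents = rmap$parents)
    if (!any(experimental)) return(FALSE)
    direct <- vapply(types, mi_is_a, logical(1),
                     ancestor = MI_DIRECT, parents = rmap$parents)
    if (!any(direct)) return(FALSE)
    reps <- representative_terms(methods, rmap$parents)
    sum(vapply(reps, mi_score, numeric(1), rmap = rmap)) >= min_score_sum
  }, logical(1))
  templates[keep, , drop = FALSE]
}

#' Build the RSS-based negative pair set
#'
#' Among homolog-derived candidate pairs, a pair is called negative when
#' it is not a reported interaction and its gene-ontology relative
#' specificity similarities fall below 0.4. `mode = "or"` flags the pair
#' when either RSS_BP or RSS_CC is below the cutoff (as printed);
#' `mode = "and"` requires both. Pairs with a missing RSS value are
#' excluded.
#'
#' @param candidate_pairs data.frame with columns `a`, `b`.
#' @param rss data.frame with columns `a`, `b`, `rss_bp`, `rss_cc`
#'   (values in `[0, 1]` or `NA`).
#' @param reported_pairs data.frame with columns `a`, `b` of known
#'   interactions (never negative).
#' @param mode `"or"` or `"and"`.
#' @param cutoff RSS cutoff (default 0.4).
#' @return data.frame of negative pairs (columns `a`, `b`).
#' @export
build_negative_set <- function(candidate_pairs, rss, reported_pairs,
                               mode = c("or", "and"), cutoff = 0.4) {
  mode <- match.arg(mode)
  if (nrow(candidate_pairs) == 0L)
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  ok <- stats::complete.cases(rss[, c("rss_bp", "rss_cc")])
  if (any(rss$rss_bp[ok] < 0 | rss$rss_bp[ok] > 1 |
          rss$rss_cc[ok] < 0 | rss$rss_cc[ok] > 1))
    stop_campnets("RSS values must lie in [0, 1]")
  rss_key <- pair_key(rss$a, rss$b)
  cand_key <- pair_key(candidate_pairs$a, candidate_pairs$b)
  rep_key <- if (nrow(reported_pairs)) pair_key(reported_pairs$a,
                                                reported_pairs$b) else character()
  idx <- match(cand_key, rss_key)
  bp <- rss$rss_bp[idx]; cc <- rss$rss_cc[idx]
  low <- if (mode == "or") (bp < cutoff | cc < cutoff) else
    (bp < cutoff & cc < cutoff)
  ## pairs with any missing RSS value are excluded outright
  neg <- !is.na(bp) & !is.na(cc) & low & !(cand_key %in% rep_key)
  out <- candidate_pairs[neg, c("a", "b"), drop = FALSE]
  out[!duplicated(pair_key(out$a, out$b)), , drop = FALSE]
}

#' Exclude a membrane protein's own templates
#'
#' Removes every template involving the given protein, so that its own
#' reported interactions never serve as templates when predicting its
#' partners (leave-one-out against self-support).
#'
#' @param mp protein identifier.
#' @param templates table from [ppi_templates()].
#' @return template table without any row involving `mp`.
#' @export
exclude_self_templates <- function(mp, templates) {
  keep <- templates$protein_a != mp & templates$protein_b != mp
  templates[keep, , drop = FALSE]
}
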
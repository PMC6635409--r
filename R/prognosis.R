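## Per-gene survival statistics, the combined prognostic score for gene
## sets, patient stratification, and Stouffer aggregation across
## cancers. All survival fits use the survival package (Cox proportional
## hazards with Efron tie handling; two-group log-rank via survdiff).

#' Per-gene Cox proportional hazards statistics
#'
#' Univariate Cox regression of 10-year survival on each gene's
#' expression in tumor samples. Follow-up beyond the horizon is censored
#' at the horizon. Constant genes are flagged and carry no estimate.
#'
#' @param expr an [expression_matrix()]; tumor sample names must match
#'   clinical patient ids.
#' @param clinical data.frame `patient`, `time` (months), `event`.
#' @param horizon censoring horizon in months (default 120 = 10 years).
#' @param min_patients minimum matched patients (default 10).
#' @return data.frame `gene`, `coef`, `hr`, `hr_lo`, `hr_hi`, `z`, `p`
#'   (score test), `flagged`.
#' @export
per_gene_cox <- function(expr, clinical, horizon = 120, min_patients = 10) {
  vals <- expr$values[, expr$group == "tumor", drop = FALSE]
  patients <- intersect(colnames(vals), clinical$patient)
  if (length(patients) < min_patients)
    stop_campnets("fewer than ", min_patients, " matched patients")
  vals <- vals[, patients, drop = FALSE]
  cl <- clinical[match(patients, clinical$patient), ]
  time <- pmin(cl$time, horizon)
  event <- ifelse(cl$time > horizon, 0, cl$event)
  if (sum(event) == 0)
    stop_campnets("no events within the horizon; statistics undefined")
  surv <- survival::Surv(time, event)
  out <- lapply(rownames(vals), function(g) {
    x <- vals[g, ]
    if (stats::sd(x) == 0) {
      return(data.frame(gene = g, coef = NA_real_, hr = NA_real_,
                        hr_lo = NA_real_, hr_hi = NA_real_, z = NA_real_,
                        p = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit <- survival::coxph(surv ~ x, ties = "efron")
    sm <- summary(fit)
    data.frame(gene = g, coef = unname(stats::coef(fit)),
               hr = unname(sm$conf.int[1, "exp(coef)"]),
               hr_lo = unname(sm$conf.int[1, "lower .95"]),
               hr_hi = unname(sm$conf.int[1, "upper .95"]),
               z = unname(sm$coefficients[1, "z"]),
               p = unname(sm$sctest["pvalue"]),
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Combined prognostic score of a gene set
#'
#' Per patient, `MV = sum_j w_j E_j` with `w_j = +1` when the gene's
#' hazard ratio is at least 1 and `-1` otherwise (signed weights avoid
#' neutralization between adverse and favorable genes). The reverse
#' coefficient `RC` is `-1` when at least 75% of patients have negative
#' MV (so that low combined scores are not misread as low expression),
#' and `CS = MV * RC`. When 26-74% of patients have negative MV the
#' direction is ambiguous and the set is flagged `mixed_sign`.
#'
#' @param expr an [expression_matrix()] (tumor samples used).
#' @param gene_stats data.frame from [per_gene_cox()].
#' @param gene_set character vector of genes; each must have expression
#'   and an unflagged HR estimate.
#' @return `list(mv = <named numeric>, rc=, cs = <named numeric>,
#'   weights = <named numeric>, mixed_sign=)`.
#' @export
combined_score <- function(expr, gene_stats, gene_set) {
  if (length(gene_set) == 0L) stop_campnets("empty gene set")
  vals <- expr$values[, expr$group == "tumor", drop = FALSE]
  missing <- setdiff(gene_set, rownames(vals))
  if (length(missing))
    stop_campnets("gene without expression: ", missing[1L])
  idx <- match(gene_set, gene_stats$gene)
  if (anyNA(idx))
    stop_campnets("gene without survival statistics: ",
                  gene_set[is.na(idx)][1L])
  hr <- gene_stats$hr[idx]
  if (anyNA(hr))
    stop_campnets("gene with undefined hazard ratio: ",
                  gene_set[is.na(hr)][1L])
  w <- stats::setNames(ifelse(hr >= 1, 1, -1), gene_set)
  mv <- colSums(vals[gene_set, , drop = FALSE] * w)
  frac_neg <- mean(mv < 0)
  rc <- if (frac_neg >= 0.75) -1 else 1
  mixed <- frac_neg >= 0.26 & frac_neg <= 0.74
  list(mv = mv, rc = rc, cs = mv * rc, weights = w, mixed_sign = mixed)
}

#' Stratify patients by combined score and test survival separation
#'
#' The `median` policy splits at the 50th percentile of CS; the `best`
#' policy scans every observed CS value within the interquartile 25-75%
#' band and returns the cutoff minimizing the two-group log-rank P (the
#' minimum is reported without multiplicity correction, so it is
#' optimistic under the null). Patients with `CS >= cutoff` form the
#' high group. The hazard ratio comes from a Cox fit on the group
#' indicator.
#'
#' @param cs result of [combined_score()] (or a named numeric vector of
#'   per-patient scores).
#' @param clinical data.frame `patient`, `time`, `event`.
#' @param policy `"median"` or `"best"`.
#' @param horizon censoring horizon in months (default 120).
#' @return `list(policy=, cutoff=, groups = <named character>,
#'   logrank_p=, hr=, hr_lo=, hr_hi=, z=)`.
#' @export
stratify <- function(cs, clinical, policy = c("median", "best"),
                     horizon = 120) {
  policy <- match.arg(policy)
  scores <- if (is.list(cs)) cs$cs else cs
  patients <- intersect(names(scores), clinical$patient)
  if (length(patients) < 4L) stop_campnets("need at least 4 patients")
  scores <- scores[patients]
  if (stats::sd(scores) == 0) stop_campnets("degenerate score")
  cl <- clinical[match(patients, clinical$patient), ]
  time <- pmin(cl$time, horizon)
  event <- ifelse(cl$time > horizon, 0, cl$event)
  surv <- survival::Surv(time, event)
  logrank_p <- function(cut) {
    grp <- scores >= cut
    if (all(grp) || !any(grp)) return(NA_real_)
    sd_ <- survival::survdiff(surv ~ grp)
    stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  }
  if (policy == "median") {
    cutoff <- stats::median(scores)
    ## a median equal to the maximum would empty the high group; fall
    ## back to the next lower observed value
    if (all(scores >= cutoff) || !any(scores >= cutoff))
      cutoff <- sort(unique(scores))[2L]
    p <- logrank_p(cutoff)
  } else {
    qs <- stats::quantile(scores, c(0.25, 0.75), names = FALSE)
    cand <- sort(unique(scores[scores >= qs[1] & scores <= qs[2]]))
    ps <- vapply(cand, logrank_p, numeric(1))
    ok <- !is.na(ps)
    if (!any(ok)) stop_campnets("no admissible cutoff in the 25-75% band")
    best <- which(ps == min(ps[ok]) & ok)[1L]
    cutoff <- cand[best]
    p <- ps[best]
  }
  grp <- ifelse(scores >= cutoff, "high", "low")
  fit <- survival::coxph(surv ~ I(grp == "high"), ties = "efron")
  sm <- summary(fit)
  list(policy = policy, cutoff = unname(cutoff),
       groups = stats::setNames(grp, patients), logrank_p = unname(p),
       hr = unname(sm$conf.int[1, "exp(coef)"]),
       hr_lo = unname(sm$conf.int[1, "lower .95"]),
       hr_hi = unname(sm$conf.int[1, "upper .95"]),
       z = unname(sm$coefficients[1, "z"]))
}

#' Meta-z of prognostic z-scores across cancers
#'
#' Stouffer's unweighted combination of per-cancer Cox z-scores
#' (positive = adverse, HR > 1). Significance is called at
#' `|meta_z| >= 1.96` (two-sided 5%). A second-level combination of
#' meta-z scores across pathways or communities yields the global
#' meta-z.
#'
#' @param z finite z-scores, one per cancer (or one meta-z per
#'   pathway/community for the global combination).
#' @return `list(meta_z=, significant=)`.
#' @export
prognostic_meta_z <- function(z) {
  mz <- stouffer_z(z)
  list(meta_z = mz, significant = abs(mz) >= 1.96)
}

#' Kaplan-Meier curve coordinates for plotting
#'
#' @param groups named character vector of group labels (from
#'   [stratify()]).
#' @param clinical data.frame `patient`, `time`, `event`.
#' @param horizon censoring horizon in months (default 120).
#' @return data.frame `group`, `time`, `surv`, `n_risk`.
#' @export
km_coordinates <- function(groups, clinical, horizon = 120) {
  patients <- intersect(names(groups), clinical$patient)
  cl <- clinical[match(patients, clinical$patient), ]
  time <- pmin(cl$time, horizon)
  event <- ifelse(cl$time > horizon, 0, cl$event)
  fit <- survival::survfit(survival::Surv(time, event) ~ groups[patients])
  strata <- rep(names(fit$strata) %||% "all",
                fit$strata %||% length(fit$time))
  data.frame(group = sub("^.*=", "", strata), time = fit$time,
             surv = fit$surv, n_risk = fit$n.risk,
             stringsAsFactors = FALSE)
}
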
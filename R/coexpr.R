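## Differential expression calling and co-expressed gene pairs per
## cancer, from tumor/normal log2 expression matrices. DEG contract:
## |log2 fold change| >= 1 and Benjamini-Hochberg adjusted P <= 0.05.

#' Call differentially expressed genes
#'
#' Per-gene Welch two-sample t test of tumor against normal samples on
#' log2 values, Benjamini-Hochberg adjustment across all genes, and the
#' DEG flag at `|log2fc| >= lfc_cutoff` and adjusted `P <= p_cutoff`.
#' A gene with zero variance in both groups gets `p = 1` (its fold
#' change is still reported).
#'
#' @param expr an [expression_matrix()] with >= 2 tumor and >= 2 normal
#'   samples.
#' @param lfc_cutoff absolute log2 fold-change cutoff (default 1).
#' @param p_cutoff adjusted-P cutoff (default 0.05).
#' @return data.frame `gene`, `log2fc` (mean tumor minus mean normal),
#'   `p`, `p_adj`, `direction` (`up`/`down`), `deg` (logical).
#' @export
call_degs <- function(expr, lfc_cutoff = 1, p_cutoff = 0.05) {
  tum <- expr$values[, expr$group == "tumor", drop = FALSE]
  nor <- expr$values[, expr$group == "normal", drop = FALSE]
  n1 <- ncol(tum); n0 <- ncol(nor)
  if (n1 < 2L || n0 < 2L)
    stop_campnets("need at least 2 tumor and 2 normal samples")
  m1 <- rowMeans(tum); m0 <- rowMeans(nor)
  v1 <- apply(tum, 1L, stats::var); v0 <- apply(nor, 1L, stats::var)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- 1  # no variance in either group: no evidence
  p_adj <- stats::p.adjust(p, method = "BH")
  log2fc <- m1 - m0
  data.frame(gene = rownames(expr$values), log2fc = log2fc,
             p = unname(p), p_adj = unname(p_adj),
             direction = ifelse(log2fc >= 0, "up", "down"),
             deg = abs(log2fc) >= lfc_cutoff & p_adj <= p_cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Co-expressed gene pairs over tumor samples
#'
#' Pearson correlation over tumor samples for every cross pair between
#' two gene lists (self-pairs excluded, pairs deduplicated on the
#' unordered key); a pair is retained when `|r| >= h`. The threshold
#' default 0.5 corresponds to a large effect size. Constant genes have
#' an undefined correlation: their pairs are skipped and the skip count
#' reported as a warning. Correlations use pairwise-complete samples
#' with a minimum of 3 shared observations.
#'
#' @param expr an [expression_matrix()] (tumor samples are used) or a
#'   plain numeric matrix of tumor expression.
#' @param genes_a,genes_b character vectors of genes present in the
#'   matrix.
#' @param h absolute-correlation threshold (default 0.5).
#' @return data.frame `gene_a`, `gene_b`, `r` with `|r| >= h`.
#' @export
coexpressed_pairs <- function(expr, genes_a, genes_b, h = 0.5) {
  vals <- if (inherits(expr, "expr_matrix"))
    expr$values[, expr$group == "tumor", drop = FALSE] else expr
  if (ncol(vals) < 3L) stop_campnets("need at least 3 tumor samples")
  missing <- setdiff(unique(c(genes_a, genes_b)), rownames(vals))
  if (length(missing))
    stop_campnets("gene not in expression matrix: ", missing[1L])
  grid <- expand.grid(gene_a = genes_a, gene_b = genes_b,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$gene_a != grid$gene_b, , drop = FALSE]
  if (nrow(grid) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  grid <- grid[!duplicated(pair_key(grid$gene_a, grid$gene_b)), , drop = FALSE]
  sds <- apply(vals[unique(c(grid$gene_a, grid$gene_b)), , drop = FALSE],
               1L, stats::sd)
  constant <- names(sds)[sds == 0 | is.na(sds)]
  skip <- grid$gene_a %in% constant | grid$gene_b %in% constant
  if (any(skip))
    warning(sum(skip), " pair(s) skipped: constant gene expression",
            call. = FALSE)
  grid <- grid[!skip, , drop = FALSE]
  r <- vapply(seq_len(nrow(grid)), function(i) {
    x <- vals[grid$gene_a[i], ]; y <- vals[grid$gene_b[i], ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  keep <- !is.na(r) & abs(r) >= h
  out <- data.frame(gene_a = grid$gene_a[keep], gene_b = grid$gene_b[keep],
                    r = r[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
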
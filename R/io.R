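## Readers and writers for every external table the pipeline touches.
## All formats are UTF-8, tab-separated; lines starting with '#' are
## comments. Parsers validate eagerly so downstream modules can assume
## typed, well-formed in-memory objects.

# ---- alignment hit tables (12-column BLAST outfmt-6 dialect) -----------

#' Read a pairwise-alignment hit table
#'
#' Parses the standard 12-column tabular alignment format
#' (query, subject, percent identity, aligned length, mismatches, gap
#' opens, qstart, qend, sstart, send, E-value, bit score). Percent
#' identity is converted to a fraction in `[0, 1]`. Literal `0.0`
#' E-values are floored at `1e-180` so that `-log10` transforms used by
#' the joint-similarity score stay finite.
#'
#' @param path path to the tab-separated hit table.
#' @return a `data.frame` with columns `query`, `subject`, `identity`
#'   (fraction), `length` (aligned residues) and `evalue`.
#' @export
read_alignment_hits <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      identity = numeric(), length = integer(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop_campnets("alignment hit table: expected 12 tab-separated columns, got ",
                  nf[bad], " on line ", bad)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hits <- data.frame(
    query = m[, 1L], subject = m[, 2L],
    identity = as.numeric(m[, 3L]) / 100,
    length = as.integer(m[, 4L]),
    evalue = as.numeric(m[, 11L]),
    stringsAsFactors = FALSE)
  if (anyNA(hits$identity) || anyNA(hits$length) || anyNA(hits$evalue))
    stop_campnets("alignment hit table: non-numeric identity/length/evalue field")
  if (any(hits$evalue < 0))
    stop_campnets("alignment hit table: negative E-value on line ",
                  which(hits$evalue < 0)[1L])
  if (any(hits$identity < 0 | hits$identity > 1))
    stop_campnets("alignment hit table: identity outside [0, 100]%")
  if (any(hits$length < 1))
    stop_campnets("alignment hit table: aligned length < 1")
  hits$evalue <- pmax(hits$evalue, EVALUE_FLOOR)
  hits
}

#' Write alignment hits in the 12-column tabular dialect
#'
#' Columns not carried in memory (mismatches, gap opens, coordinates,
#' bit score) are emitted as zeros; [read_alignment_hits()] ignores them,
#' so write-then-read round-trips.
#'
#' @param hits data.frame as returned by [read_alignment_hits()].
#' @param path output path.
#' @export
write_alignment_hits <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.4f\t%d\t0\t0\t0\t0\t0\t0\t%g\t0",
                   hits$query, hits$subject, hits$identity * 100,
                   as.integer(hits$length), hits$evalue)
  writeLines(lines, path)
  invisible(path)
}

# ---- protein annotation tables ----------------------------------------

#' Construct a protein annotation table
#'
#' Each protein carries its organism, sequence length, membrane-protein
#' flag and 1-based inclusive cytoplasmic-region intervals (UniProt
#' convention). Intervals must lie within `[1, length]` and be
#' non-overlapping once sorted.
#'
#' @param id character vector of unique protein identifiers.
#' @param species organism name per protein.
#' @param length sequence length (residues) per protein.
#' @param is_mp logical membrane-protein flag per protein.
#' @param cyto list of two-column numeric matrices (start, end), one per
#'   protein; `NULL` entries mean no annotated cytoplasmic region.
#' @return a `data.frame` with a `cyto` list-column.
#' @export
protein_table <- function(id, species, length, is_mp = FALSE, cyto = NULL) {
  n <- base::length(id)
  if (anyDuplicated(id)) stop_campnets("duplicate protein id")
  length <- as.integer(length)
  is_mp <- rep_len(as.logical(is_mp), n)
  species <- rep_len(as.character(species), n)
  if (is.null(cyto)) cyto <- rep(list(NULL), n)
  cyto <- lapply(seq_len(n), function(i) {
    iv <- cyto[[i]]
    if (is.null(iv) || NROW(iv) == 0L) return(NULL)
    iv <- matrix(as.integer(iv), ncol = 2L)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[, 1L] < 1L) || any(iv[, 2L] > length[i]) ||
        any(iv[, 1L] > iv[, 2L]))
      stop_campnets("protein ", id[i], ": cytoplasmic interval outside [1, length]")
    if (NROW(iv) > 1L && any(iv[-1L, 1L] <= iv[-NROW(iv), 2L]))
      stop_campnets("protein ", id[i], ": overlapping cytoplasmic intervals")
    iv
  })
  out <- data.frame(id = as.character(id), species = species,
                    length = length, is_mp = is_mp,
                    stringsAsFactors = FALSE)
  out$cyto <- cyto
  out
}

#' Read a protein annotation table
#'
#' Expects columns: id, species, length, is_mp (0/1), cyto (semicolon-
#' separated `start-end` intervals, or `-` for none).
#'
#' @param path path to the tab-separated table (with header).
#' @return a protein table as from [protein_table()].
#' @export
read_protein_table <- function(path) {
  lines <- read_tsv_lines(path)
  df <- utils::read.table(text = paste(lines, collapse = "\n"),
                          sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  cyto <- lapply(df$cyto, function(s) {
    if (is.na(s) || s == "-" || !nzchar(s)) return(NULL)
    iv <- do.call(rbind, lapply(strsplit(s, ";", fixed = TRUE)[[1L]],
                                function(p) as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])))
    iv
  })
  protein_table(df$id, df$species, df$length, df$is_mp == 1, cyto)
}

#' Write a protein annotation table
#' @param proteins table from [protein_table()].
#' @param path output path.
#' @export
write_protein_table <- function(proteins, path) {
  cyto <- vapply(proteins$cyto, function(iv) {
    if (is.null(iv)) "-" else
      paste(sprintf("%d-%d", iv[, 1L], iv[, 2L]), collapse = ";")
  }, character(1))
  lines <- c("id\tspecies\tlength\tis_mp\tcyto",
             sprintf("%s\t%s\t%d\t%d\t%s", proteins$id, proteins$species,
                     proteins$length, as.integer(proteins$is_mp), cyto))
  writeLines(lines, path)
  invisible(path)
}

# ---- MITAB-like interaction tables ------------------------------------

#' Read a MITAB-like PPI template table
#'
#' A simplified PSI-MI tabular dialect with columns: interactor A,
#' interactor B, species A, species B, detection methods, interaction
#' types, PubMed ids (the last three `|`-separated; MI terms must carry
#' the `MI:` prefix). Records are deduplicated on the unordered protein
#' pair plus species, merging evidence (union of methods, types and
#' references). Rows with a missing accession (`-` or empty) are skipped;
#' the skip count is reported as a warning.
#'
#' @param path path to the tab-separated file (no header).
#' @return a template `data.frame` with list-columns `methods`, `types`
#'   and `refs`; see [ppi_templates()].
#' @export
read_mitab <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) return(ppi_templates())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7L))
    stop_campnets("MITAB table: expected >= 7 columns, got ", min(nf),
                  " on line ", which(nf < 7L)[1L])
  split_terms <- function(s) {
    if (is.na(s) || s == "-" || !nzchar(s)) character() else
      strsplit(s, "|", fixed = TRUE)[[1L]]
  }
  skipped <- 0L
  recs <- list()
  for (f in fields) {
    a <- f[[1L]]; b <- f[[2L]]
    if (a %in% c("", "-") || b %in% c("", "-")) { skipped <- skipped + 1L; next }
    methods <- split_terms(f[[5L]])
    types <- split_terms(f[[6L]])
    mi <- c(methods, types)
    if (length(mi) && any(!grepl("^MI:[0-9]{4}$", mi)))
      stop_campnets("MITAB table: MI term lacking 'MI:' prefix in record ",
                    a, "-", b)
    recs[[length(recs) + 1L]] <- list(
      a = a, b = b, sp_a = f[[3L]], sp_b = f[[4L]],
      methods = methods, types = types, refs = split_terms(f[[7L]]))
  }
  if (skipped > 0L)
    warning(skipped, " MITAB record(s) skipped for missing accession",
            call. = FALSE)
  if (length(recs) == 0L) return(ppi_templates())
  keys <- vapply(recs, function(r)
    paste(pair_key(r$a, r$b), r$sp_a, r$sp_b, sep = "\t"), character(1))
  merged <- lapply(split(recs, keys), function(grp) {
    r1 <- grp[[1L]]
    list(a = min(r1$a, r1$b), b = max(r1$a, r1$b),
         sp_a = r1$sp_a, sp_b = r1$sp_b,
         methods = sort(unique(unlist(lapply(grp, `[[`, "methods")))),
         types = sort(unique(unlist(lapply(grp, `[[`, "types")))),
         refs = sort(unique(unlist(lapply(grp, `[[`, "refs")))))
  })
  merged <- merged[order(names(merged))]
  ppi_templates(
    protein_a = vapply(merged, `[[`, character(1), "a"),
    protein_b = vapply(merged, `[[`, character(1), "b"),
    species_a = vapply(merged, `[[`, character(1), "sp_a"),
    species_b = vapply(merged, `[[`, character(1), "sp_b"),
    methods = lapply(merged, `[[`, "methods"),
    types = lapply(merged, `[[`, "types"),
    refs = lapply(merged, `[[`, "refs"))
}

#' Construct a PPI template table
#'
#' One row per curated interaction used as an interolog template: the two
#' proteins, their organisms, and the PSI-MI evidence (detection-method
#' and interaction-type term codes plus PubMed references).
#'
#' @param protein_a,protein_b protein identifiers.
#' @param species_a,species_b organism of each protein.
#' @param methods,types,refs lists of character vectors (MI codes /
#'   PubMed ids), one element per template.
#' @return a `data.frame` with list-columns, unordered-pair keyed.
#' @export
ppi_templates <- function(protein_a = character(), protein_b = character(),
                          species_a = character(), species_b = character(),
                          methods = list(), types = list(), refs = list()) {
  n <- length(protein_a)
  if (n == 0L) {
    out <- data.frame(protein_a = character(), protein_b = character(),
                      species_a = character(), species_b = character(),
                      stringsAsFactors = FALSE)
    out$methods <- list(); out$types <- list(); out$refs <- list()
    return(out)
  }
  if (length(methods) == 0L) methods <- rep(list(character()), n)
  if (length(types) == 0L) types <- rep(list(character()), n)
  if (length(refs) == 0L) refs <- rep(list(character()), n)
  out <- data.frame(protein_a = as.character(protein_a),
                    protein_b = as.character(protein_b),
                    species_a = rep_len(as.character(species_a), n),
                    species_b = rep_len(as.character(species_b), n),
                    stringsAsFactors = FALSE)
  out$methods <- unname(methods)
  out$types <- unname(types)
  out$refs <- unname(refs)
  rownames(out) <- NULL
  out
}

#' Write templates in the MITAB-like dialect
#' @param templates table from [ppi_templates()].
#' @param path output path.
#' @export
write_mitab <- function(templates, path) {
  join <- function(x) if (length(x) == 0L) "-" else paste(x, collapse = "|")
  lines <- vapply(seq_len(nrow(templates)), function(i) {
    paste(templates$protein_a[i], templates$protein_b[i],
          templates$species_a[i], templates$species_b[i],
          join(templates$methods[[i]]), join(templates$types[[i]]),
          join(templates$refs[[i]]), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- GMT gene sets -----------------------------------------------------

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are collapsed; duplicate set names are an error.
#'
#' @param path path to the GMT file.
#' @param cancer_related optional character vector naming the subset of
#'   pathways regarded as cancer related; every name must exist.
#' @return a pathway collection: `list(pathways = <named list of gene
#'   vectors>, cancer_related = <character>)`.
#' @export
read_gene_sets_gmt <- function(path, cancer_related = character()) {
  lines <- read_tsv_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop_campnets("GMT: line ", which(nf < 3L)[1L], " has fewer than 3 fields")
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_))
    stop_campnets("GMT: duplicate pathway name '",
                  names_[duplicated(names_)][1L], "'")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  pathway_collection(sets, cancer_related)
}

#' Construct a pathway collection
#' @param pathways named list of gene identifier vectors (non-empty).
#' @param cancer_related character subset of `names(pathways)`.
#' @return `list(pathways=, cancer_related=)` with class
#'   `"pathway_collection"`.
#' @export
pathway_collection <- function(pathways, cancer_related = character()) {
  if (length(pathways) && is.null(names(pathways)))
    stop_campnets("pathway collection requires named gene sets")
  if (any(lengths(pathways) == 0L))
    stop_campnets("pathway collection: empty gene set")
  missing <- setdiff(cancer_related, names(pathways))
  if (length(missing))
    stop_campnets("cancer-related pathway not in collection: ",
                  paste(missing, collapse = ", "))
  structure(list(pathways = lapply(pathways, unique),
                 cancer_related = as.character(cancer_related)),
            class = "pathway_collection")
}

#' Write gene sets in GMT format
#' @param collection a pathway collection.
#' @param path output path.
#' @export
write_gene_sets_gmt <- function(collection, path) {
  lines <- vapply(names(collection$pathways), function(nm) {
    paste(c(nm, "na", collection$pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- expression + clinical tables -------------------------------------

#' Construct an expression matrix object
#'
#' @param values numeric matrix, genes in rows (rownames), samples in
#'   columns (colnames), log2 scale.
#' @param group character/factor per sample, levels `tumor` and `normal`.
#' @return `list(values=, group=)` with class `"expr_matrix"`.
#' @export
expression_matrix <- function(values, group) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_campnets("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop_campnets("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop_campnets("duplicate sample ids")
  if (!all(is.finite(values))) stop_campnets("non-finite expression values")
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop_campnets("one group label per sample required")
  if (!all(group %in% c("tumor", "normal")))
    stop_campnets("group labels must be 'tumor' or 'normal'")
  structure(list(values = values, group = group), class = "expr_matrix")
}

#' Read expression and clinical tables together
#'
#' The expression TSV has genes in rows and samples in columns (first
#' column = gene id); the groups TSV maps sample to `tumor`/`normal`; the
#' clinical TSV has columns `patient`, `months`, `event`. Expression
#' samples are restricted to those with clinical records (tumor samples)
#' while normal samples are always kept; a warning reports dropped
#' samples. Zero overlap between tumor samples and patients is an error.
#'
#' @param expr_path expression matrix TSV (header row of sample ids).
#' @param groups_path two-column TSV `sample<TAB>group`.
#' @param clinical_path clinical TSV.
#' @return `list(expr = <expr_matrix>, clinical = <data.frame>)`.
#' @export
read_expression_and_clinical <- function(expr_path, groups_path, clinical_path) {
  expr_df <- utils::read.table(expr_path, sep = "\t", header = TRUE,
                               check.names = FALSE, comment.char = "#",
                               stringsAsFactors = FALSE)
  genes <- as.character(expr_df[[1L]])
  vals <- as.matrix(expr_df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(expr_df[, -1L, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)[1, ]
    stop_campnets("non-numeric expression cell at gene row ", bad[1L],
                  ", sample column ", bad[2L])
  }
  rownames(vals) <- genes
  groups_df <- utils::read.table(groups_path, sep = "\t", header = TRUE,
                                 comment.char = "#", stringsAsFactors = FALSE)
  grp <- groups_df[[2L]][match(colnames(vals), groups_df[[1L]])]
  if (anyNA(grp)) stop_campnets("sample without group label: ",
                                colnames(vals)[is.na(grp)][1L])
  clinical <- read_clinical(clinical_path)
  tumor <- colnames(vals)[grp == "tumor"]
  keep_tumor <- intersect(tumor, clinical$patient)
  if (length(keep_tumor) == 0L)
    stop_campnets("no overlap between tumor samples and clinical patients")
  dropped <- setdiff(tumor, keep_tumor)
  if (length(dropped))
    warning(length(dropped), " tumor sample(s) without clinical record dropped",
            call. = FALSE)
  keep <- colnames(vals) %in% c(keep_tumor, colnames(vals)[grp == "normal"])
  expr <- expression_matrix(vals[, keep, drop = FALSE], grp[keep])
  clinical <- clinical[clinical$patient %in% keep_tumor, , drop = FALSE]
  list(expr = expr, clinical = clinical)
}

#' Read a clinical survival table
#'
#' Columns `patient`, `months`, `event`; times must be positive, events
#' binary, patient ids unique.
#'
#' @param path clinical TSV path.
#' @return data.frame `patient`, `time` (months), `event` (0/1).
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  clinical_table(df$patient, df$months, df$event)
}

#' Construct a clinical survival table
#' @param patient unique patient identifiers.
#' @param time survival/follow-up time in months (> 0).
#' @param event 0 (censored) or 1 (death).
#' @return validated data.frame `patient`, `time`, `event`.
#' @export
clinical_table <- function(patient, time, event) {
  if (anyDuplicated(patient)) stop_campnets("duplicate patient id")
  time <- as.numeric(time); event <- as.numeric(event)
  if (any(!is.finite(time)) || any(time <= 0))
    stop_campnets("survival times must be positive")
  if (!all(event %in% c(0, 1)))
    stop_campnets("event flags must be 0 or 1")
  data.frame(patient = as.character(patient), time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Write expression matrix, groups and clinical tables
#' @param expr an `expr_matrix`.
#' @param clinical a clinical data.frame.
#' @param expr_path,groups_path,clinical_path output paths.
#' @export
write_expression_and_clinical <- function(expr, clinical, expr_path,
                                          groups_path, clinical_path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(expr$values),
                                group = expr$group),
                     groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(patient = clinical$patient,
                                months = clinical$time,
                                event = clinical$event),
                     clinical_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

# ---- evolutionary distance tables -------------------------------------

#' Read a normalized evolutionary distance table
#'
#' Three columns (organism A, organism B, distance in `[0, 1]`); the
#' table is symmetrized and the diagonal fixed at zero. Conflicting
#' asymmetric entries are an error.
#'
#' @param path TSV path (no header).
#' @return a distance table object; query with [distance_between()].
#' @export
read_distance_table <- function(path) {
  lines <- read_tsv_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3L))
    stop_campnets("distance table: expected 3 columns")
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  d <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  distance_table(a, b, d)
}

#' Construct a normalized distance table
#' @param org_a,org_b organism names.
#' @param distance normalized distances in `[0, 1]`.
#' @return named list keyed by unordered organism pair, class
#'   `"distance_table"`.
#' @export
distance_table <- function(org_a, org_b, distance) {
  if (any(!is.finite(distance)) || any(distance < 0 | distance > 1))
    stop_campnets("distances must lie in [0, 1]")
  if (any(org_a == org_b & distance != 0))
    stop_campnets("self-distance must be zero")
  keys <- pair_key(org_a, org_b)
  dup <- duplicated(keys)
  if (any(dup)) {
    ref <- distance[match(keys[dup], keys)]
    if (any(abs(ref - distance[dup]) > 1e-12))
      stop_campnets("asymmetric distance entries for the same organism pair")
  }
  tab <- as.list(distance[!dup])
  names(tab) <- keys[!dup]
  structure(tab, class = "distance_table")
}

#' Look up the normalized distance between two organisms
#' @param dt a distance table.
#' @param a,b organism names.
#' @return numeric distance; zero when `a == b`; error when the pair is
#'   absent.
#' @export
distance_between <- function(dt, a, b) {
  if (a == b) return(0)
  v <- dt[[pair_key(a, b)]]
  if (is.null(v)) stop_campnets("no distance recorded for ", a, " - ", b)
  v
}

#' Write a distance table as TSV
#' @param dt a distance table.
#' @param path output path.
#' @export
write_distance_table <- function(dt, path) {
  m <- pair_unkey(names(dt))
  lines <- sprintf("%s\t%s\t%g", m[, 1L], m[, 2L], unlist(dt))
  writeLines(lines, path)
  invisible(path)
}

#' Normalize raw tree distances to the unit interval
#'
#' Divides raw pairwise phylogenetic distances by the maximum pairwise
#' distance observed, yielding the normalized evolutionary distance
#' consumed by the conservation score.
#'
#' @param org_a,org_b organism names.
#' @param raw raw (nonnegative) distances.
#' @return a distance table with values in `[0, 1]`.
#' @export
normalize_tree_distances <- function(org_a, org_b, raw) {
  if (any(raw < 0)) stop_campnets("raw distances must be nonnegative")
  mx <- max(raw)
  if (mx == 0) return(distance_table(org_a, org_b, raw))
  distance_table(org_a, org_b, raw / mx)
}
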
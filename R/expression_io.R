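# Expression matrix I/O, normalization, QC filtering, replicate averaging
# and z-scoring. Matrices are plain numeric matrices (genes x samples) with
# dimnames; an expression matrix additionally carries a "unit" attribute in
# {"counts", "CPM", "logCPM", "zscore"}, in the spirit of limma/edgeR's
# lightweight containers.

#' Construct a count matrix
#'
#' A count matrix is a genes-by-samples integer matrix with unique row and
#' column names, optionally annotated with a per-gene duplicated-read
#' percentage (as reported by 3' tag-counting pipelines).
#'
#' @param counts numeric matrix of nonnegative integers, genes in rows,
#'   samples in columns; must have unique rownames (gene IDs) and colnames
#'   (sample IDs).
#' @param dup_pct optional numeric vector of per-gene duplicated-read
#'   percentages in \[0, 100\], one per gene (named or in row order).
#' @return an object of class `count_matrix`: the integer matrix with an
#'   optional `dup_pct` attribute.
#' @export
count_matrix <- function(counts, dup_pct = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("counts must have gene rownames and sample colnames")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene ID: ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample ID: ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at (gene '%s', sample '%s'): %s",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])))
  storage.mode(counts) <- "double"
  if (!is.null(dup_pct)) {
    if (!is.null(names(dup_pct))) dup_pct <- dup_pct[gene_ids]
    if (length(dup_pct) != nrow(counts) || anyNA(dup_pct))
      stop("dup_pct must cover every gene")
    if (any(dup_pct < 0 | dup_pct > 100))
      stop("dup_pct must lie in [0, 100]")
    names(dup_pct) <- gene_ids
    attr(counts, "dup_pct") <- dup_pct
  }
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' Read a count matrix from a delimited text file
#'
#' Expects genes in rows with the first column holding gene IDs and the
#' header row holding sample IDs. A column named `dup_pct`, if present, is
#' detached and attached as the per-gene duplicated-read percentage.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; tab by default.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  dup_pct <- NULL
  if ("dup_pct" %in% names(df)) {
    dup_pct <- as.numeric(df[["dup_pct"]])
    df <- df[, setdiff(names(df), "dup_pct"), drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in count matrix")
  rownames(m) <- gene_ids
  out <- count_matrix(m, dup_pct = if (is.null(dup_pct)) NULL else
    stats::setNames(dup_pct, gene_ids))
  message(sprintf("read %d genes x %d samples from %s",
                  nrow(out), ncol(out), path))
  out
}

#' Write a count matrix to a delimited text file
#'
#' Inverse of [read_count_matrix()]: first column `gene_id`, then one column
#' per sample, plus a `dup_pct` column when present.
#'
#' @param m a [count_matrix()].
#' @param path output file path.
#' @param sep field separator.
#' @export
write_count_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE)
  dp <- attr(m, "dup_pct")
  if (!is.null(dp)) df$dup_pct <- dp
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an expression matrix with a unit tag
#'
#' @param values numeric genes-by-samples matrix with dimnames.
#' @param unit one of `"counts"`, `"CPM"`, `"logCPM"`, `"zscore"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, unit = c("counts", "CPM", "logCPM", "zscore")) {
  unit <- match.arg(unit)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ID")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ID")
  attr(values, "unit") <- unit
  class(values) <- c("expr_matrix", setdiff(class(values), "expr_matrix"))
  values
}

#' Unit tag of an expression matrix
#' @param m an `expr_matrix`.
#' @return the unit string.
#' @export
expr_unit <- function(m) attr(m, "unit") %||% "counts"

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild an expr_matrix after subsetting/transforming, keeping metadata
.rewrap <- function(values, template, unit = expr_unit(template)) {
  out <- expr_matrix(values, unit = unit)
  out
}

#' Counts-per-million normalization
#'
#' Scales each sample column to a library size of one million:
#' `value(g, s) = counts(g, s) / total(s) * 1e6`. Column sums of the result
#' are exactly 1e6 (up to floating point).
#'
#' @param m a [count_matrix()] or a counts-unit `expr_matrix`.
#' @return an `expr_matrix` with unit `"CPM"`; a `dup_pct` attribute on the
#'   input is carried along for downstream QC filtering.
#' @export
cpm_normalize <- function(m) {
  totals <- colSums(m)
  if (any(totals <= 0))
    stop("zero-total sample: ",
         paste(colnames(m)[totals <= 0], collapse = ", "))
  vals <- sweep(unclass(m), 2, totals, "/") * 1e6
  out <- expr_matrix(vals, unit = "CPM")
  attr(out, "dup_pct") <- attr(m, "dup_pct")
  out
}

#' QC gene filter: mean CPM and duplicated-read percentage
#'
#' Removes genes whose mean CPM across samples is below `cpm_min` and genes
#' whose duplicated-read percentage exceeds `dup_max` (both inequalities
#' strict, as printed in 3' tag-counting QC conventions: mean CPM < 5
#' removed, dup% > 20 removed). Gene order of survivors is preserved.
#'
#' @param m an `expr_matrix` with unit `"CPM"`.
#' @param dup_pct per-gene duplicated-read percentage; defaults to the
#'   `dup_pct` attribute carried from the count matrix. When unavailable the
#'   duplication criterion is skipped with a warning.
#' @param cpm_min genes with mean CPM strictly below this are removed.
#' @param dup_max genes with dup% strictly above this are removed.
#' @return the filtered `expr_matrix`.
#' @export
filter_genes_qc <- function(m, dup_pct = attr(m, "dup_pct"),
                            cpm_min = 5, dup_max = 20) {
  if (expr_unit(m) != "CPM") stop("filter_genes_qc expects a CPM matrix")
  keep <- rowMeans(m) >= cpm_min
  if (is.null(dup_pct)) {
    warning("dup_pct unavailable; skipping duplicated-read criterion")
  } else {
    if (!is.null(names(dup_pct))) dup_pct <- dup_pct[rownames(m)]
    if (length(dup_pct) != nrow(m) || anyNA(dup_pct))
      stop("dup_pct must cover every gene")
    keep <- keep & (dup_pct <= dup_max)
  }
  if (!any(keep)) stop("empty matrix after QC")
  out <- expr_matrix(unclass(m)[keep, , drop = FALSE], unit = "CPM")
  if (!is.null(dup_pct)) attr(out, "dup_pct") <-
      stats::setNames(dup_pct[keep], rownames(out))
  out
}

#' Remove weakly expressed genes
#'
#' Drops genes whose mean CPM across all samples is strictly below
#' `cpm_min` (default 1), the filter applied to cohort profiles before
#' z-scoring and enrichment analysis.
#'
#' @param m an `expr_matrix` with unit `"CPM"`.
#' @param cpm_min mean-CPM threshold (strict `<` removal).
#' @return the filtered `expr_matrix`.
#' @export
filter_low_expression <- function(m, cpm_min = 1) {
  if (expr_unit(m) != "CPM") stop("filter_low_expression expects a CPM matrix")
  keep <- rowMeans(m) >= cpm_min
  if (!any(keep)) stop("empty matrix after QC")
  expr_matrix(unclass(m)[keep, , drop = FALSE], unit = "CPM")
}

#' Read sample annotations
#'
#' CSV with columns `sample_id`, `group`, `replicate_of`. `replicate_of`
#' names the biological unit a sample is a technical/biological replicate
#' of; samples sharing a `replicate_of` key are averaged together.
#'
#' @param path CSV file path.
#' @return a data.frame with the three columns.
#' @export
read_sample_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "replicate_of")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotation")
  ann
}

#' Average replicate columns
#'
#' Collapses samples sharing a `replicate_of` key to a single column holding
#' their arithmetic mean, the first step of cohort profile preparation.
#'
#' @param m an `expr_matrix`.
#' @param ann data.frame with columns `sample_id` and `replicate_of` (see
#'   [read_sample_annotation()]); every sample in `m` must be annotated.
#' @return an `expr_matrix` with one column per replicate group, named by
#'   the `replicate_of` key, in first-appearance order.
#' @export
average_replicates <- function(m, ann) {
  idx <- match(colnames(m), ann$sample_id)
  if (anyNA(idx))
    stop("sample without annotation: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  key <- as.character(ann$replicate_of[idx])
  groups <- unique(key)
  vals <- vapply(groups, function(g)
    rowMeans(unclass(m)[, key == g, drop = FALSE]), numeric(nrow(m)))
  vals <- matrix(vals, nrow = nrow(m),
                 dimnames = list(rownames(m), groups))
  expr_matrix(vals, unit = expr_unit(m))
}

#' Z-score an expression matrix
#'
#' Centers and scales to unit variance (sample variance, n - 1 denominator)
#' along the chosen axis. `per_gene_across_samples` (the default) removes
#' each gene's baseline so that within-sample ranking reflects relative,
#' not absolute, abundance; `per_sample_across_genes` standardizes each
#' profile instead. Zero-variance elements are dropped (per gene) or
#' rejected (per sample) with a warning rather than producing NaNs.
#'
#' By default CPM values are transformed to log2(CPM + 1) before scaling to
#' stabilize the variance of count-derived data; set `log2_transform =
#' FALSE` to scale the input as-is.
#'
#' @param m an `expr_matrix`.
#' @param axis `"per_gene_across_samples"` or `"per_sample_across_genes"`.
#' @param log2_transform apply log2(x + 1) first when the unit is CPM.
#' @return an `expr_matrix` with unit `"zscore"`.
#' @export
zscore_matrix <- function(m,
                          axis = c("per_gene_across_samples",
                                   "per_sample_across_genes"),
                          log2_transform = TRUE) {
  axis <- match.arg(axis)
  vals <- unclass(m)
  if (log2_transform && expr_unit(m) == "CPM") vals <- log2(vals + 1)
  if (axis == "per_gene_across_samples") {
    if (ncol(vals) < 2) stop("need >= 2 samples to z-score per gene")
    mu <- rowMeans(vals)
    sd <- apply(vals, 1, stats::sd)
    drop <- sd == 0
    if (any(drop)) {
      warning(sprintf("dropping %d zero-variance gene(s) at z-scoring",
                      sum(drop)))
      vals <- vals[!drop, , drop = FALSE]
      mu <- mu[!drop]; sd <- sd[!drop]
      if (!nrow(vals)) stop("empty matrix after dropping constant genes")
    }
    vals <- (vals - mu) / sd
  } else {
    if (nrow(vals) < 2) stop("need >= 2 genes to z-score per sample")
    mu <- colMeans(vals)
    sd <- apply(vals, 2, stats::sd)
    if (any(sd == 0)) stop("constant sample profile cannot be z-scored: ",
                           paste(colnames(vals)[sd == 0], collapse = ", "))
    vals <- sweep(sweep(vals, 2, mu, "-"), 2, sd, "/")
  }
  expr_matrix(vals, unit = "zscore")
}

#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: one set per line, tab-delimited fields
#' `name`, `description`, then member gene IDs. Duplicate members within a
#' line are de-duplicated with a warning; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return a named list of character vectors (the members), each carrying a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm <- f[1]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in gene set '%s' de-duplicated", nm))
      members <- unique(members)
    }
    if (!length(members)) stop(sprintf("gene set '%s' is empty", nm))
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    attr(members, "description") <- f[2]
    sets[[nm]] <- members
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors; a `description` attribute on
#'   each vector is written to the second field (empty otherwise).
#' @param path output file path.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% ""
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples [unit: %s]\n",
              nrow(x), ncol(x), expr_unit(x)))
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count matrix: %d genes x %d samples%s\n", nrow(x), ncol(x),
              if (is.null(attr(x, "dup_pct"))) "" else " (with dup_pct)"))
  invisible(x)
}
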
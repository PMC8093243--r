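# Resistance-signature construction from a cell-line panel: join expression
# with drug response, screen genes by Pearson correlation with AUC, keep the
# top candidates, then reduce to the target size by recursive feature
# elimination driven by linear-SVM weight magnitudes on the response-extreme
# lines. Lower AUC means greater drug sensitivity throughout.

#' Restrict an expression panel and response table to shared cell lines
#'
#' @param expr an `expr_matrix`, samples = cell lines.
#' @param resp data.frame with column `cell_line` and one of `auc` /
#'   `ic50_um`.
#' @param min_shared minimum number of shared lines required.
#' @return list with `expr` and `resp` restricted to the intersection, in
#'   the same order.
#' @export
join_panel <- function(expr, resp, min_shared = 10) {
  if (!"cell_line" %in% names(resp)) stop("response table needs a cell_line column")
  if (anyDuplicated(resp$cell_line)) stop("duplicate cell_line in response table")
  shared <- intersect(colnames(expr), resp$cell_line)
  if (length(shared) < min_shared)
    stop(sprintf("only %d shared cell lines (< %d)", length(shared), min_shared))
  message(sprintf("panel: %d shared cell lines", length(shared)))
  expr2 <- expr_matrix(unclass(expr)[, shared, drop = FALSE],
                       unit = expr_unit(expr))
  resp2 <- resp[match(shared, resp$cell_line), , drop = FALSE]
  rownames(resp2) <- NULL
  list(expr = expr2, resp = resp2)
}

#' Per-gene Pearson correlation with drug response
#'
#' Correlates every gene's expression across the panel with the AUC; genes
#' with positive coefficients are candidate resistance markers (high
#' expression where the drug is least potent).
#'
#' @param expr an `expr_matrix` (CPM or logCPM) over the joined panel.
#' @param resp joined response table with an `auc` column.
#' @return data.frame with columns `gene`, `pcc`, `n`; zero-variance genes
#'   are excluded with a warning.
#' @export
correlate_expression_response <- function(expr, resp) {
  if (!expr_unit(expr) %in% c("CPM", "logCPM"))
    stop("expected CPM or logCPM expression")
  if (!"auc" %in% names(resp)) stop("response table needs an auc column")
  auc <- resp$auc[match(colnames(expr), resp$cell_line)]
  if (anyNA(auc)) stop("every panel line needs an AUC value")
  n <- ncol(expr)
  if (n < 3) stop("need >= 3 cell lines to correlate")
  if (stats::sd(auc) == 0) stop("degenerate response distribution")
  vals <- unclass(expr)
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance gene(s)", sum(sds == 0)))
    vals <- vals[sds > 0, , drop = FALSE]
  }
  pcc <- as.numeric(stats::cor(t(vals), auc))
  data.frame(gene = rownames(vals), pcc = pcc, n = n,
             stringsAsFactors = FALSE)
}

#' Top resistance-associated genes by correlation
#'
#' @param ctab data.frame from [correlate_expression_response()].
#' @param k number of genes to keep (default 1000).
#' @return character vector of `k` genes in descending PCC order; ties at
#'   equal PCC are broken by gene ID (lexicographically smaller first).
#' @export
select_top_markers <- function(ctab, k = 1000) {
  if (k > nrow(ctab)) stop("k exceeds the number of correlated genes")
  ord <- order(-ctab$pcc, ctab$gene, method = "radix")
  ctab$gene[ord][seq_len(k)]
}

#' Label response-extreme cell lines
#'
#' Sensitive lines are those with AUC at or below the `low_q` quantile of
#' the panel's AUC distribution; resistant lines at or above the `high_q`
#' quantile. Quantiles use linear interpolation (the default `stats::quantile`
#' type 7).
#'
#' @param resp response table with `cell_line` and `auc`.
#' @param low_q,high_q tail probabilities (defaults 0.05 and 0.95).
#' @return data.frame with columns `cell_line`, `label` in
#'   {"sensitive", "resistant"}, restricted to the tails.
#' @export
label_extremes <- function(resp, low_q = 0.05, high_q = 0.95) {
  if (low_q >= high_q) stop("tails overlap: low_q must be < high_q")
  if (nrow(resp) < 20) stop("need >= 20 lines so both tails are non-empty")
  auc <- resp$auc
  if (stats::sd(auc) == 0) stop("degenerate response distribution")
  qs <- stats::quantile(auc, c(low_q, high_q), names = FALSE, type = 7)
  lab <- rep(NA_character_, nrow(resp))
  lab[auc <= qs[1]] <- "sensitive"
  lab[auc >= qs[2]] <- "resistant"
  keep <- !is.na(lab)
  data.frame(cell_line = resp$cell_line[keep], label = lab[keep],
             stringsAsFactors = FALSE)
}

# linear-SVM weight vector |w| via kernlab (vanilladot), input pre-standardized
.svm_weights <- function(x, y, C = 1) {
  fit <- kernlab::ksvm(x, y, type = "C-svc",
                       kernel = kernlab::vanilladot(), C = C, scaled = FALSE)
  sv <- kernlab::xmatrix(fit)[[1]]
  co <- kernlab::coef(fit)[[1]]
  as.numeric(crossprod(sv, co))
}

#' Recursive feature elimination with a linear SVM
#'
#' Starting from the candidate genes, repeatedly (i) standardize each
#' feature over the extreme lines (mean 0, unit variance), (ii) fit a
#' linear soft-margin SVM separating sensitive from resistant lines,
#' (iii) rank features by |weight| and drop the lowest
#' `ceiling(step_frac * current)` (never overshooting `target`), until
#' exactly `target` genes remain. The result is ordered by the final
#' fit's |weight|, descending.
#'
#' @param expr an `expr_matrix` restricted (or restrictable) to the
#'   candidate genes; columns must cover all labeled lines.
#' @param labels data.frame from [label_extremes()].
#' @param genes candidate gene IDs (e.g. the top-1000 PCC list); defaults
#'   to all rows of `expr`.
#' @param target final signature size (default 500).
#' @param step_frac fraction of current features eliminated per round.
#' @param C SVM cost parameter.
#' @param seed integer seed (kernlab's optimizer is deterministic for this
#'   problem class, but the seed is fixed for reproducibility).
#' @return character vector of `target` genes, a `weights` attribute
#'   holding the final |w|, and a `provenance` attribute recording the
#'   parameters.
#' @export
rfe_svm_select <- function(expr, labels, genes = rownames(expr),
                           target = 500, step_frac = 0.10, C = 1, seed = 1) {
  genes <- intersect(genes, rownames(expr))
  if (target > length(genes)) stop("target exceeds the number of features")
  miss <- setdiff(labels$cell_line, colnames(expr))
  if (length(miss)) stop("labeled line missing from expression: ",
                         paste(miss, collapse = ", "))
  y <- factor(labels$label, levels = c("sensitive", "resistant"))
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  x_all <- t(unclass(expr)[genes, labels$cell_line, drop = FALSE])
  current <- genes
  w <- rep(NA_real_, length(current))
  old <- .Random.seed_exists(); on.exit(old())
  set.seed(seed)
  repeat {
    x <- x_all[, current, drop = FALSE]
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0] <- 1          # constant features get weight via centering only
    x <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
    w <- abs(.svm_weights(x, y, C = C))
    if (length(current) == target) break
    n_drop <- min(ceiling(step_frac * length(current)),
                  length(current) - target)
    # drop the lowest-|w| features; ties broken by gene ID for determinism
    ord <- order(w, current, method = "radix")
    drop_idx <- ord[seq_len(n_drop)]
    current <- current[-drop_idx]
  }
  out <- current[order(-w, current, method = "radix")]
  attr(out, "weights") <- w[order(-w, current, method = "radix")]
  attr(out, "provenance") <- list(
    n_candidates = length(genes), n_lines = nrow(x_all), target = target,
    step_frac = step_frac, C = C, seed = seed)
  out
}

#' Build a resistance signature from a panel
#'
#' End-to-end wrapper: join, log2(CPM + 1) transform, correlation screen,
#' top-k selection, extreme labeling, and RFE-SVM reduction.
#'
#' @param expr CPM `expr_matrix` over cell lines.
#' @param resp response table with `cell_line` and `auc`.
#' @param top_k size of the correlation-screen shortlist.
#' @param target final signature size.
#' @param low_q,high_q AUC tail probabilities for the class labels.
#' @param seed integer seed.
#' @return the signature gene vector from [rfe_svm_select()], plus a
#'   `pcc_top` attribute with the shortlist.
#' @export
build_signature <- function(expr, resp, top_k = 1000, target = 500,
                            low_q = 0.05, high_q = 0.95, seed = 1) {
  panel <- join_panel(expr, resp)
  lexpr <- panel$expr
  if (expr_unit(lexpr) == "CPM")
    lexpr <- expr_matrix(log2(unclass(lexpr) + 1), unit = "logCPM")
  ctab <- correlate_expression_response(lexpr, panel$resp)
  top <- select_top_markers(ctab, k = top_k)
  labels <- label_extremes(panel$resp, low_q = low_q, high_q = high_q)
  sig <- rfe_svm_select(lexpr, labels, genes = top, target = target,
                        seed = seed)
  attr(sig, "pcc_top") <- top
  sig
}
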
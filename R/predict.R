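# Signature-based response calls: a profile is ranked from most to least
# expressed (z-scores), the resistance signature is scored by the running-sum
# enrichment statistic, and the sign of a significant ES makes the call —
# positive ES (resistance markers highly expressed) = resistant, negative =
# sensitive, non-significant = indeterminate.

#' Predict drug response for one ranked profile
#'
#' @param ranked a [rank_profile()] result for one sample.
#' @param signature character vector of resistance-marker genes.
#' @param nperm permutations for the null.
#' @param seed integer seed.
#' @param fdr_threshold significance threshold (strict `<`); with a single
#'   profile the BH-adjusted FDR equals the permutation p-value.
#' @return data.frame row: `sample`, `es`, `nes`, `p`, `fdr`, `call`.
#' @export
predict_response <- function(ranked, signature, nperm = 10000, seed,
                             fdr_threshold = 0.10) {
  res <- permutation_null(ranked, signature, nperm = nperm, seed = seed)
  fdr <- res$p  # BH with a single test
  call <- if (fdr < fdr_threshold) {
    if (res$es > 0) "resistant" else "sensitive"
  } else "indeterminate"
  data.frame(sample = NA_character_, es = res$es, nes = res$nes,
             p = res$p, fdr = fdr, call = call, stringsAsFactors = FALSE)
}

#' Predict drug response across a cohort
#'
#' Ranks each sample's z-scored profile, scores the signature with a
#' permutation null per sample, then adjusts the cohort's p-values by
#' Benjamini-Hochberg (one test per sample for the single signature) and
#' calls each sample by the sign of its ES. Per-sample failures are
#' returned as flagged rows with an `error` message.
#'
#' @param m an `expr_matrix` with unit `"zscore"` (cohort z-scored jointly,
#'   per gene across samples).
#' @param signature resistance-marker gene vector.
#' @inheritParams predict_response
#' @return list with `calls` (data.frame: sample, es, nes, p, fdr, call,
#'   error) and `summary` (named counts per call).
#' @export
predict_cohort <- function(m, signature, nperm = 1000, seed,
                           fdr_threshold = 0.10) {
  if (expr_unit(m) != "zscore")
    stop("cohort prediction expects jointly z-scored profiles")
  rows <- lapply(seq_len(ncol(m)), function(j) {
    r <- tryCatch({
      ranked <- rank_profile(unclass(m)[, j])
      res <- permutation_null(ranked, signature, nperm = nperm,
                              seed = seed + j * 131L)
      data.frame(sample = colnames(m)[j], es = res$es, nes = res$nes,
                 p = res$p, error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(sample = colnames(m)[j], es = NA_real_, nes = NA_real_,
                 p = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
    r
  })
  calls <- do.call(rbind, rows)
  calls$fdr <- NA_real_
  ok <- !is.na(calls$p)
  calls$fdr[ok] <- stats::p.adjust(calls$p[ok], method = "BH")
  calls$call <- "indeterminate"
  calls$call[ok & calls$fdr < fdr_threshold & calls$es > 0] <- "resistant"
  calls$call[ok & calls$fdr < fdr_threshold & calls$es < 0] <- "sensitive"
  calls$call[!ok] <- NA_character_
  calls <- calls[, c("sample", "es", "nes", "p", "fdr", "call", "error")]
  summary <- table(factor(calls$call,
                          levels = c("sensitive", "resistant",
                                     "indeterminate")))
  list(calls = calls, summary = c(summary))
}

#' Validate signature predictions against measured IC50
#'
#' Truth labels come from the potency rule: lines with IC50 strictly below
#' `threshold_um` (micromolar) are sensitive, all others resistant.
#' Predictions come from [predict_cohort()]; indeterminate calls count as
#' incorrect for whichever truth class they belong to (a conservative
#' choice). Per-class accuracy is correct/total within each truth class;
#' the average accuracy is the macro mean of the two.
#'
#' @param m z-scored `expr_matrix` over the validation lines.
#' @param signature resistance-marker gene vector.
#' @param resp data.frame with `cell_line` and `ic50_um`.
#' @param threshold_um IC50 sensitivity cutoff in micromolar (default 1).
#' @inheritParams predict_cohort
#' @return list with `confusion` (pred x truth table including
#'   indeterminate), `class_accuracy` (percent, per truth class),
#'   `macro_accuracy` (percent), `threshold_um`, and the per-line `calls`.
#' @export
validate_panel <- function(m, signature, resp, threshold_um = 1.0,
                           nperm = 1000, seed, fdr_threshold = 0.10) {
  if (!all(c("cell_line", "ic50_um") %in% names(resp)))
    stop("response table needs cell_line and ic50_um columns")
  miss <- setdiff(colnames(m), resp$cell_line)
  if (length(miss)) stop("line without IC50: ", paste(miss, collapse = ", "))
  truth <- ifelse(resp$ic50_um[match(colnames(m), resp$cell_line)] <
                    threshold_um, "sensitive", "resistant")
  if (length(unique(truth)) < 2)
    stop("a truth class is empty under the IC50 rule")
  pred <- predict_cohort(m, signature, nperm = nperm, seed = seed,
                         fdr_threshold = fdr_threshold)
  calls <- pred$calls
  calls$truth <- truth
  confusion <- table(pred = factor(calls$call,
                                   levels = c("sensitive", "resistant",
                                              "indeterminate")),
                     truth = factor(truth,
                                    levels = c("sensitive", "resistant")))
  class_acc <- vapply(c("sensitive", "resistant"), function(cl) {
    in_cl <- truth == cl
    100 * sum(calls$call[in_cl] == cl, na.rm = TRUE) / sum(in_cl)
  }, numeric(1))
  list(confusion = confusion,
       class_accuracy = class_acc,
       macro_accuracy = mean(class_acc),
       threshold_um = threshold_um,
       calls = calls)
}
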
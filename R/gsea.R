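# Pre-ranked gene set enrichment: weighted Kolmogorov-Smirnov running-sum
# enrichment score, gene-label permutation null, NES, and BH FDR over a
# collection. The running sum increments by |stat|^p / sum_set(|stat|^p) at
# set members and decrements by 1/(N - N_hit) elsewhere; ES is the signed
# maximum deviation from zero. The engine evaluates the sum only at hit
# positions (O(set size) after ranking), which the test suite checks
# against a literal O(N) walk.

#' Rank a profile for enrichment analysis
#'
#' Sorts genes from the most to the least expressed by the supplied
#' statistic (typically a z-score). Ties are broken by gene ID so the
#' ranking is deterministic.
#'
#' @param stats named numeric vector of ranking statistics.
#' @return a `ranked_profile`: a named numeric vector sorted non-increasing.
#' @export
rank_profile <- function(stats) {
  if (is.null(names(stats)) || anyDuplicated(names(stats)))
    stop("stats must be uniquely named by gene")
  if (length(stats) < 2) stop("a ranked profile needs >= 2 genes")
  if (anyNA(stats)) stop("NA ranking statistic")
  ord <- order(-stats, names(stats), method = "radix")
  out <- stats[ord]
  class(out) <- c("ranked_profile", class(out))
  out
}

# hit positions of set members in the ranked profile (sorted, 1-based)
.hit_positions <- function(ranked, set) {
  pos <- which(names(ranked) %in% set)
  sort(pos)
}

# core ES from sorted hit positions; stats is the full ranked vector.
# Returns list(es, peak_index_into_hits, sign).
.es_from_hits <- function(stats, pos, p = 1) {
  N <- length(stats)
  k <- length(pos)
  w <- abs(stats[pos])^p
  sw <- sum(w)
  if (sw == 0) {
    # all-zero weights degenerate to the unweighted KS statistic
    w <- rep(1, k); sw <- k
  }
  w <- w / sw
  cw <- cumsum(w)
  miss <- 1 / (N - k)
  # running sum just after hit j and just before hit j
  top <- cw - (pos - seq_len(k)) * miss
  bottom <- top - w
  j_max <- which.max(top)
  j_min <- which.min(bottom)
  es_pos <- top[j_max]
  es_neg <- bottom[j_min]
  if (es_pos >= -es_neg) {
    list(es = es_pos, peak = j_max, sign = 1L)
  } else {
    list(es = es_neg, peak = j_min, sign = -1L)
  }
}

#' Running-sum enrichment score
#'
#' Computes the weighted KS enrichment score of a gene set against a ranked
#' profile, together with the leading-edge genes: for a positive score, the
#' set members at or before the running-sum maximum; for a negative score,
#' the members at or after the minimum.
#'
#' @param ranked a [rank_profile()] result (or any named, non-increasing
#'   statistic vector).
#' @param set character vector of member gene IDs.
#' @param p weighting exponent on \eqn{|stat|}; 1 by default.
#' @return list with `es`, `leading_edge` (character vector), and
#'   `size_used` (members present in the profile).
#' @export
enrichment_score <- function(ranked, set, p = 1) {
  pos <- .hit_positions(ranked, set)
  N <- length(ranked)
  k <- length(pos)
  if (k == 0) stop("set not represented in the ranked profile")
  if (k >= N) stop("set covers the whole profile; no misses to score")
  r <- .es_from_hits(ranked, pos, p = p)
  hits <- names(ranked)[pos]
  le <- if (r$sign > 0) hits[seq_len(r$peak)] else hits[r$peak:k]
  list(es = unname(r$es), leading_edge = le, size_used = k)
}

#' Gene-label permutation null and p-value
#'
#' Draws `nperm` random gene sets of the same size from the profile and
#' scores each, forming the null ES distribution. The p-value is the
#' two-sided magnitude test with add-one smoothing,
#' \eqn{p = (1 + \#\{|ES_{null}| \ge |ES_{obs}|\}) / (nperm + 1)},
#' so p is never below 1/(nperm + 1) and is uniformly distributed for null
#' sets. NES is ES divided by the mean |null ES| of the same sign.
#'
#' @inheritParams enrichment_score
#' @param nperm number of permutations (>= 100).
#' @param seed integer seed; required for reproducibility.
#' @return list with `es`, `nes`, `p`, `null_es` (numeric vector),
#'   `leading_edge`, `size_used`.
#' @export
permutation_null <- function(ranked, set, nperm = 10000, seed, p = 1) {
  if (missing(seed)) stop("seed is required")
  if (nperm < 100) stop("nperm must be >= 100")
  obs <- enrichment_score(ranked, set, p = p)
  N <- length(ranked)
  k <- obs$size_used
  if (k >= N) stop("set size must be smaller than the profile")
  null_es <- local({
    old <- .Random.seed_exists()
    set.seed(seed)
    on.exit(old())
    vapply(seq_len(nperm), function(i) {
      pos <- sort.int(sample.int(N, k))
      .es_from_hits(ranked, pos, p = p)$es
    }, numeric(1))
  })
  pval <- (1 + sum(abs(null_es) >= abs(obs$es))) / (nperm + 1)
  same <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
  list(es = obs$es, nes = nes, p = pval, null_es = null_es,
       leading_edge = obs$leading_edge, size_used = k)
}

# save/restore RNG state so seeded internals don't clobber the caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Score a gene-set collection against one ranked profile
#'
#' Runs [permutation_null()] for every set, adjusts the permutation
#' p-values by Benjamini-Hochberg across the collection, and flags sets
#' with FDR strictly below `fdr_threshold`. Per-set failures (e.g. a set
#' with no genes in the profile) are returned as flagged rows, not errors.
#'
#' @inheritParams permutation_null
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param fdr_threshold significance threshold on BH FDR (strict `<`).
#' @return data.frame with columns `set`, `size_used`, `es`, `nes`, `p`,
#'   `fdr`, `significant`, `leading_edge` (semicolon-joined), `error`.
#' @export
run_collection <- function(ranked, collection, nperm = 10000, seed,
                           fdr_threshold = 0.10, p = 1) {
  if (!length(collection)) stop("empty gene-set collection")
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    stop("collection sets must have unique names")
  rows <- lapply(seq_along(collection), function(i) {
    res <- tryCatch(
      permutation_null(ranked, collection[[i]], nperm = nperm,
                       seed = seed + i, p = p),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(set = names(collection)[i], size_used = NA_integer_,
                 es = NA_real_, nes = NA_real_, p = NA_real_,
                 leading_edge = NA_character_,
                 error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(set = names(collection)[i], size_used = res$size_used,
                 es = res$es, nes = res$nes, p = res$p,
                 leading_edge = paste(res$leading_edge, collapse = ";"),
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_threshold
  out[, c("set", "size_used", "es", "nes", "p", "fdr", "significant",
          "leading_edge", "error")]
}

#' Score a collection across many samples
#'
#' Convenience wrapper: z-scored expression matrix in, one
#' [run_collection()] per sample column out, stacked with a `sample`
#' column. Each sample's ranking is built by [rank_profile()] on its
#' z-scores.
#'
#' @param m an `expr_matrix` with unit `"zscore"`.
#' @inheritParams run_collection
#' @return data.frame of per-sample, per-set enrichment results.
#' @export
run_collection_cohort <- function(m, collection, nperm = 1000, seed,
                                  fdr_threshold = 0.10, p = 1) {
  if (expr_unit(m) != "zscore")
    stop("cohort enrichment expects z-scored profiles")
  res <- lapply(seq_len(ncol(m)), function(j) {
    ranked <- rank_profile(unclass(m)[, j])
    r <- run_collection(ranked, collection, nperm = nperm,
                        seed = seed + j * 1000L, fdr_threshold = fdr_threshold,
                        p = p)
    r$sample <- colnames(m)[j]
    r
  })
  do.call(rbind, res)
}

#' Median enrichment score by sample group
#'
#' Summarizes per-sample enrichment results as the median ES of each gene
#' set within each annotated group (e.g. tumor grade), the layout used to
#' compare stem-signature activity across cohorts.
#'
#' @param results data.frame from [run_collection_cohort()] (needs columns
#'   `sample`, `set`, `es`).
#' @param ann data.frame with columns `sample_id`, `group`.
#' @return data.frame with columns `group`, `set`, `median_es`.
#' @export
median_by_group <- function(results, ann) {
  idx <- match(results$sample, ann$sample_id)
  if (anyNA(idx))
    stop("sample without annotation: ",
         paste(unique(results$sample[is.na(idx)]), collapse = ", "))
  results$group <- as.character(ann$group[idx])
  groups <- unique(as.character(ann$group))
  sets <- unique(results$set)
  rows <- list()
  for (g in groups) {
    sub <- results[results$group == g & !is.na(results$es), , drop = FALSE]
    if (!nrow(sub)) {
      warning("group '", g, "' has no scored samples; omitted")
      next
    }
    med <- tapply(sub$es, factor(sub$set, levels = sets), stats::median)
    rows[[g]] <- data.frame(group = g, set = sets,
                            median_es = as.numeric(med[sets]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
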
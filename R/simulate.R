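# Synthetic inputs with the statistical structure each pipeline stage
# assumes: a cell-line panel whose planted marker genes and drug response
# (AUC) share a latent resistance score, cohort profiles with a signature
# shifted up or down, and limiting-dilution plates under the single-hit
# model. All generators are pure functions of (parameters, seed).

#' Simulate a cell-line expression/response panel
#'
#' A latent resistance score r_i ~ N(0, 1) per line drives both marker-gene
#' expression and drug response. Log2 expression is
#' e_gi = mu_g + beta * r_i * 1\[g in markers\] + eps_gi with
#' mu_g ~ N(5, 2) and eps ~ N(0, noise_sd); counts are drawn per sample
#' from a multinomial over 2^e with the requested library size; the
#' response is AUC_i = alpha + gamma * r_i + eta_i with eta ~ N(0,
#' noise_sd). Lower AUC = more sensitive, so markers (beta, gamma > 0) are
#' resistance-associated. The AUC scale is arbitrary: only ranks and tail
#' quantiles matter downstream.
#'
#' @param n_lines number of cell lines (default 300).
#' @param n_genes number of genes (default 2000).
#' @param n_markers number of planted resistance markers (default 100).
#' @param beta marker effect on log2 expression per unit latent score.
#' @param gamma latent-score effect on AUC.
#' @param noise_sd shared sd of the expression and response noise.
#' @param lib_size expected reads per line (default 1e6).
#' @param alpha AUC intercept.
#' @param markers optional fixed marker gene IDs (within the `g0001`...
#'   universe); supply these to generate a held-out panel sharing the same
#'   planted biology as a training panel. Default: sampled from the seed.
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()]), `resp` (data.frame
#'   `cell_line`, `auc`), and `truth` (markers, latent scores, parameters).
#' @export
simulate_ccl_panel <- function(n_lines = 300, n_genes = 2000,
                               n_markers = 100, beta = 1.0, gamma = 1.0,
                               noise_sd = 0.5, lib_size = 1e6, alpha = 10,
                               markers = NULL, seed = 1) {
  if (noise_sd < 0 || beta < 0) stop("degenerate parameters")
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (!is.null(markers)) {
    if (!all(markers %in% genes)) stop("markers outside the gene universe")
    n_markers <- length(markers)
  }
  if (n_markers >= n_genes) stop("n_markers must be < n_genes")
  old <- .Random.seed_exists(); on.exit(old())
  set.seed(seed)
  lines <- sprintf("CCL%03d", seq_len(n_lines))
  if (is.null(markers)) markers <- sample(genes, n_markers)
  r <- stats::rnorm(n_lines)
  mu <- stats::rnorm(n_genes, mean = 5, sd = 2)
  e <- matrix(mu, n_genes, n_lines) +
    outer(as.numeric(genes %in% markers), r) * beta +
    matrix(stats::rnorm(n_genes * n_lines, sd = noise_sd), n_genes, n_lines)
  abund <- 2^e
  counts <- vapply(seq_len(n_lines), function(i)
    as.numeric(stats::rmultinom(1, size = lib_size,
                                prob = abund[, i])), numeric(n_genes))
  dimnames(counts) <- list(genes, lines)
  auc <- alpha + gamma * r + stats::rnorm(n_lines, sd = noise_sd)
  list(counts = count_matrix(counts),
       resp = data.frame(cell_line = lines, auc = auc,
                         stringsAsFactors = FALSE),
       truth = list(markers = markers, latent = stats::setNames(r, lines),
                    params = list(n_lines = n_lines, n_genes = n_genes,
                                  n_markers = n_markers, beta = beta,
                                  gamma = gamma, noise_sd = noise_sd,
                                  lib_size = lib_size, alpha = alpha,
                                  seed = seed)))
}

#' Simulate cohort profiles with a planted signature shift
#'
#' Baseline z-like profiles (standard normal per gene) with the signature
#' genes shifted by +effect ("up", enriched: a resistant-looking profile),
#' -effect ("down", depleted: sensitive-looking), or untouched ("null").
#'
#' @param n_samples number of samples; recycled `direction` must match.
#' @param genes the gene universe (character vector).
#' @param signature gene IDs to shift; must be a subset of `genes`.
#' @param direction character vector in {"up", "down", "null"}, one per
#'   sample (recycled if length 1).
#' @param effect shift size in z-units (default 2).
#' @param seed integer seed.
#' @return an `expr_matrix` with unit `"zscore"` and a `direction`
#'   attribute recording the planted truth.
#' @export
simulate_cohort <- function(n_samples, genes, signature, direction = "null",
                            effect = 2, seed = 1) {
  if (!all(signature %in% genes)) stop("signature must be within the gene universe")
  direction <- rep(direction, length.out = n_samples)
  bad <- setdiff(direction, c("up", "down", "null"))
  if (length(bad)) stop("unknown direction: ", paste(bad, collapse = ", "))
  old <- .Random.seed_exists(); on.exit(old())
  set.seed(seed)
  vals <- matrix(stats::rnorm(length(genes) * n_samples),
                 nrow = length(genes),
                 dimnames = list(genes, sprintf("S%02d", seq_len(n_samples))))
  shift <- c(up = effect, down = -effect, null = 0)[direction]
  in_sig <- genes %in% signature
  vals[in_sig, ] <- vals[in_sig, , drop = FALSE] +
    matrix(shift, sum(in_sig), n_samples, byrow = TRUE)
  out <- expr_matrix(vals, unit = "zscore")
  attr(out, "direction") <- stats::setNames(direction, colnames(vals))
  out
}

#' Simulate a limiting-dilution plate under the single-hit model
#'
#' positive ~ Binomial(wells, 1 - exp(-f * dose)) per dose.
#'
#' @param f true clonogenic frequency in \[0, 1\].
#' @param doses cells per well, one row per dose.
#' @param wells_per_dose wells tested at each dose.
#' @param seed integer seed.
#' @return a plate data.frame (`dose`, `tested`, `positive`).
#' @export
simulate_lda <- function(f, doses = c(10, 100, 1000), wells_per_dose = 24,
                         seed = 1) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (any(doses <= 0)) stop("doses must be positive")
  old <- .Random.seed_exists(); on.exit(old())
  set.seed(seed)
  p <- 1 - exp(-f * doses)
  data.frame(dose = doses, tested = wells_per_dose,
             positive = stats::rbinom(length(doses), wells_per_dose, p))
}
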
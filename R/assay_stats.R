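# Assay statistics: single-hit limiting-dilution frequency (complementary
# log-log binomial GLM with a log-dose offset, the ELDA model), likelihood-
# ratio comparison of two experiments, tumor volume and fold changes,
# viability normalization, and 2^-ddCt qPCR copy-number calls.

#' Validate a limiting-dilution plate table
#'
#' @param x data.frame with columns `dose` (cells per well, > 0), `tested`
#'   (wells, > 0), `positive` (0 <= positive <= tested).
#' @return the validated data.frame.
#' @export
lda_experiment <- function(x) {
  need <- c("dose", "tested", "positive")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(x)) stop("limiting-dilution table is empty")
  if (any(x$dose <= 0)) stop("doses must be positive")
  if (any(x$tested <= 0 | x$tested != round(x$tested)))
    stop("tested wells must be positive integers")
  if (any(x$positive < 0 | x$positive > x$tested |
            x$positive != round(x$positive)))
    stop("positive wells must be integers in [0, tested]")
  x
}

# Intercept-only cloglog binomial fit with log-dose offset. Saturated doses
# (all wells positive at a high dose) are routine in limiting-dilution data,
# so glm's fitted-probability-0/1 warning is muffled.
.cloglog_fit <- function(x) {
  # start IRLS from the crude estimate at the most informative (lowest) dose
  frac <- pmin(x$positive / x$tested, 1 - 1 / (2 * x$tested))
  crude <- -log(1 - frac) / x$dose
  start <- log(max(min(crude[crude > 0], na.rm = TRUE), 1e-12))
  withCallingHandlers(
    stats::glm(cbind(positive, tested - positive) ~ 1,
               family = stats::binomial(link = "cloglog"),
               offset = log(dose), data = x, start = start,
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Single-hit limiting-dilution frequency
#'
#' Fits the single-hit Poisson model P(positive | dose n) = 1 - exp(-f n)
#' by maximum binomial likelihood: an intercept-only complementary log-log
#' regression with offset log(n), so f = exp(intercept). The 95% CI is the
#' Wald interval on log f, exponentiated.
#'
#' All-negative data yield a zero point estimate with a one-sided upper
#' bound (flagged); all-positive data leave the frequency unbounded and
#' raise an error.
#'
#' @param x a plate table (see [lda_experiment()]).
#' @return list with `frequency`, `lower`, `upper` (95% CI), `percent`
#'   (100 f), `one_in` (1/f), `boundary` flag, and the `fit` (glm or NULL).
#' @export
#' @examples
#' lda_frequency(data.frame(dose = 100, tested = 24, positive = 12))
lda_frequency <- function(x) {
  x <- lda_experiment(x)
  if (all(x$positive == x$tested))
    stop("frequency unbounded: all wells positive at every dose")
  if (all(x$positive == 0)) {
    # one-sided 95% upper bound from the binomial likelihood at f = 0
    total_cells <- sum(x$dose * x$tested)
    upper <- -log(0.05) / total_cells
    return(list(frequency = 0, lower = 0, upper = upper, percent = 0,
                one_in = Inf, boundary = TRUE, fit = NULL))
  }
  fit <- .cloglog_fit(x)
  logf <- stats::coef(fit)[[1]]
  se <- sqrt(stats::vcov(fit)[1, 1])
  f <- exp(logf)
  ci <- exp(logf + c(-1, 1) * stats::qnorm(0.975) * se)
  list(frequency = f, lower = ci[1], upper = ci[2], percent = 100 * f,
       one_in = 1 / f, boundary = FALSE, fit = fit)
}

#' Compare clonogenic frequencies of two experiments
#'
#' Likelihood-ratio test (1 df) of a shared single-hit frequency against
#' separate frequencies, the chi-squared comparison used for
#' limiting-dilution assays.
#'
#' @param a,b plate tables (see [lda_experiment()]).
#' @return list with `statistic` (chi-squared, 1 df) and `p`.
#' @export
compare_frequencies <- function(a, b) {
  fa <- lda_frequency(a); fb <- lda_frequency(b)
  if (fa$boundary || fb$boundary)
    stop("boundary fit: frequencies cannot be compared")
  both <- rbind(lda_experiment(a)[c("dose", "tested", "positive")],
                lda_experiment(b)[c("dose", "tested", "positive")])
  pooled <- .cloglog_fit(both)
  stat <- as.numeric(stats::deviance(pooled) -
                       (stats::deviance(fa$fit) + stats::deviance(fb$fit)))
  stat <- max(stat, 0)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Ellipsoid tumor volume from caliper axes
#'
#' volume = d^2 * D / 2 with d the minor and D the major axis (mm). If the
#' axes arrive swapped they are exchanged with a warning.
#'
#' @param d minor axis, mm.
#' @param D major axis, mm.
#' @return volume in cubic millimetres.
#' @export
#' @examples
#' tumor_volume(10, 20)  # 1000 mm^3
tumor_volume <- function(d, D) {
  if (any(d <= 0) || any(D <= 0)) stop("axes must be positive")
  swap <- d > D
  if (any(swap)) {
    warning("minor axis exceeds major axis; swapping")
    tmp <- d[swap]; d[swap] <- D[swap]; D[swap] <- tmp
  }
  d^2 * D / 2
}

#' Tumor-volume fold changes versus baseline
#'
#' @param volumes numeric vector of volumes over time for one animal.
#' @param baseline_index index of the day-0 measurement (default 1).
#' @return `volumes / volumes[baseline_index]`.
#' @export
fold_change_series <- function(volumes, baseline_index = 1) {
  if (baseline_index < 1 || baseline_index > length(volumes))
    stop("baseline index out of range")
  base <- volumes[baseline_index]
  if (!is.finite(base) || base <= 0) stop("baseline volume must be positive")
  volumes / base
}

#' Viability fold change versus untreated control
#'
#' mean(treated) / mean(control) over technical replicates.
#'
#' @param treated,control numeric replicate luminescence values.
#' @param min_replicates warn (not error) below this replicate count.
#' @return the fold change.
#' @export
viability_fold_change <- function(treated, control, min_replicates = 6) {
  if (length(treated) < min_replicates || length(control) < min_replicates)
    warning(sprintf("fewer than %d technical replicates", min_replicates))
  mc <- mean(control)
  if (!is.finite(mc) || mc <= 0) stop("control mean must be positive")
  mean(treated) / mc
}

#' qPCR copy-number call by the 2^-ddCt method
#'
#' ddCt = (Ct_target,sample - Ct_norm,sample) -
#' (Ct_target,calibrator - Ct_norm,calibrator); the copy-number ratio is
#' 2^-ddCt (1 = biallelic content against the calibrator gDNA) and ratios
#' strictly below `loss_threshold` are called as allelic loss.
#'
#' @param ct_target_sample,ct_norm_sample,ct_target_cal,ct_norm_cal Ct
#'   values for the target and normalizer gene in the sample and the
#'   calibrator (control gDNA); all finite and positive.
#' @param loss_threshold ratio below which loss is called (default 0.7).
#' @return list with `ddct`, `ratio`, `call` in {"loss", "neutral"}.
#' @export
#' @examples
#' cnv_call(26, 25, 25, 25)  # one extra target cycle: ratio 0.5, loss
cnv_call <- function(ct_target_sample, ct_norm_sample,
                     ct_target_cal, ct_norm_cal, loss_threshold = 0.7) {
  cts <- c(ct_target_sample, ct_norm_sample, ct_target_cal, ct_norm_cal)
  if (length(cts) != 4 || anyNA(cts) || any(!is.finite(cts)) || any(cts <= 0))
    stop("all four Ct values must be finite and positive")
  ddct <- (ct_target_sample - ct_norm_sample) - (ct_target_cal - ct_norm_cal)
  ratio <- 2^(-ddct)
  list(ddct = ddct, ratio = ratio,
       call = if (ratio < loss_threshold) "loss" else "neutral")
}
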
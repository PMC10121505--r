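# Agreement and diagnostic-performance statistics for reader studies:
# intraclass correlation (two-way ANOVA forms), Cohen's kappa,
# Bland-Altman limits of agreement, and sensitivity/specificity/accuracy
# with exact binomial confidence intervals. Significance between two
# estimates is judged by the non-overlap of their 95% CIs.

new_agreement_report <- function(statistic, estimate, lower, upper, n,
                                 band = NA_character_, extra = list()) {
  stopifnot(is.na(lower) || is.na(upper) ||
              (lower <= estimate + 1e-12 && estimate <= upper + 1e-12))
  structure(
    c(list(statistic = statistic, estimate = estimate,
           lower = lower, upper = upper, n = n, band = band), extra),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("%s = %.3f (95%% CI %.3f-%.3f), n = %d%s\n",
              x$statistic, x$estimate, x$lower, x$upper, x$n,
              if (is.na(x$band)) "" else paste0(" [", x$band, "]")))
  invisible(x)
}

koo_band <- function(icc) {
  if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good" else "excellent"
}

landis_koch_band <- function(k) {
  if (k < 0) "poor" else if (k <= 0.2) "slight" else if (k <= 0.4) "fair"
  else if (k <= 0.6) "moderate" else if (k <= 0.8) "substantial"
  else "almost perfect"
}

#' Intraclass correlation coefficient
#'
#' Computed from the balanced two-way ANOVA decomposition of an n x k
#' subjects-by-raters table. The default form is the two-way
#' random-effects, absolute-agreement, single-measure ICC (ICC(2,1) /
#' ICC(A,1)); a two-way consistency form (ICC(3,1) / ICC(C,1)) is also
#' available. Confidence limits use the standard F-distribution
#' construction; the qualitative band follows the Koo thresholds
#' (< 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, > 0.9 excellent).
#'
#' @param ratings n x k numeric matrix or data frame: one row per subject,
#'   one column per rater; no missing entries
#' @param form "agreement" (default) or "consistency"
#' @param conf_level confidence level (default 0.95)
#' @return `agreement_report` with the ICC, CI, n and Koo band
#' @export
icc <- function(ratings, form = c("agreement", "consistency"),
                conf_level = 0.95) {
  form <- match.arg(form)
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings contain missing values; align them first")
  n <- nrow(x); k <- ncol(x)
  if (k < 2) stop("need at least 2 raters")
  if (n < 5) stop("need at least 5 subjects")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)           # between subjects
  ssc <- n * sum((col_m - grand)^2)           # between raters
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps) {
    stop("ICC undefined: no between-subject variance in the ratings")
  }
  alpha <- 1 - conf_level
  if (form == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fl <- (msr / mse) / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- (msr / mse) * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) /
      (msr + (k - 1) * mse + k / n * (msc - mse))
    # Shrout-Fleiss / McGraw-Wong CI for ICC(A,1)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_star <- stats::qf(1 - alpha / 2, n - 1, v)
    lower <- n * (msr - f_star * mse) /
      (f_star * (k * msc + (k * n - k - n) * mse) + n * msr)
    f_star2 <- stats::qf(1 - alpha / 2, v, n - 1)
    upper <- n * (f_star2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_star2 * msr)
  }
  lower <- max(-1, min(lower, est))
  upper <- min(1, max(upper, est))
  new_agreement_report(
    paste0("ICC(", if (form == "agreement") "A,1" else "C,1", ")"),
    est, lower, upper, n, band = koo_band(est),
    extra = list(form = form, ms = c(msr = msr, msc = msc, mse = mse))
  )
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected categorical agreement `(po - pe) / (1 - pe)` with
#' marginal-product expected agreement. The asymptotic standard error
#' gives the CI; the qualitative band follows Landis & Koch.
#'
#' @param a,b equal-length label vectors (factor, character or logical)
#' @param conf_level confidence level
#' @return `agreement_report` with kappa, CI, n and band
#' @export
cohens_kappa <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  a <- factor(as.character(a), levels = lev)
  b <- factor(as.character(b), levels = lev)
  n <- length(a)
  tab <- table(a, b) / n
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe < .Machine$double.eps) {
    stop("kappa undefined: expected agreement is 1 (both raters constant)")
  }
  kap <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  new_agreement_report("kappa", kap,
                       max(-1, min(kap - z * se, kap)),
                       min(1, max(kap + z * se, kap)),
                       n, band = landis_koch_band(kap))
}

#' Bland-Altman analysis of two paired measurement sets
#'
#' Mean difference (first minus second) and limits of agreement
#' `mean +/- 1.96 SD` of the differences, reported in the
#' "mean difference with LoA of +/- half-width" style.
#'
#' @param a,b equal-length numeric vectors (a - b convention)
#' @return list of class `bland_altman`: `mean_diff`, `loa_halfwidth`,
#'   `loa` (lower, upper), `sd_diff`, `n`, plus per-pair `means` and
#'   `differences` for plotting
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (length(a) < 2) stop("need at least 2 paired measurements")
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(
    list(mean_diff = md, sd_diff = sdd, loa_halfwidth = 1.96 * sdd,
         loa = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
         n = length(a), means = (a + b) / 2, differences = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (first - second): mean difference %.2f with LoA of +/- %.2f (n = %d)\n",
              x$mean_diff, x$loa_halfwidth, x$n))
  invisible(x)
}

#' Bland-Altman plot
#' @param x a [bland_altman()] result
#' @param ... passed to [plot()]
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of methods", ylab = "Difference", ...)
  graphics::abline(h = c(x$mean_diff, x$loa), lty = c(1, 2, 2))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#' @param x successes
#' @param n trials
#' @param conf_level confidence level
#' @return c(lower, upper)
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Contingency counts for one stratum
#'
#' @param tp,fp,tn,fn non-negative integer counts
#' @param stratum optional stratum label
#' @return object of class `contingency_counts`
#' @export
contingency_counts <- function(tp, fp, tn, fn, stratum = NA_character_) {
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be non-negative integers")
  }
  if (sum(cnt) == 0) stop("empty contingency table")
  structure(as.list(c(cnt, total = sum(cnt))),
            class = "contingency_counts", stratum = stratum)
}

#' Diagnostic performance with exact confidence intervals
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and accuracy
#' (TP+TN)/total, each with a binomial CI (Clopper-Pearson by default,
#' matching common clinical-statistics software; Wilson optional). A
#' metric whose denominator is zero is returned as NA with a note rather
#' than failing the others.
#'
#' @param counts a [contingency_counts()] (or tp/fp/tn/fn given directly)
#' @param method "clopper-pearson" or "wilson"
#' @param conf_level confidence level
#' @return data frame with columns metric, estimate, lower, upper,
#'   numerator, denominator (estimates unrounded; see
#'   [format_diagnostic_metrics()] for the 3-decimal presentation)
#' @export
diagnostic_metrics <- function(counts, method = c("clopper-pearson", "wilson"),
                               conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "contingency_counts"))
  ci_fun <- if (method == "clopper-pearson") clopper_pearson else wilson_interval
  one <- function(metric, x, n) {
    if (n == 0) {
      return(data.frame(metric = metric, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        numerator = x, denominator = n))
    }
    ci <- ci_fun(x, n, conf_level)
    data.frame(metric = metric, estimate = x / n,
               lower = ci[["lower"]], upper = ci[["upper"]],
               numerator = x, denominator = n)
  }
  out <- rbind(
    one("sensitivity", counts$tp, counts$tp + counts$fn),
    one("specificity", counts$tn, counts$tn + counts$fp),
    one("accuracy", counts$tp + counts$tn, counts$total)
  )
  attr(out, "stratum") <- attr(counts, "stratum")
  attr(out, "method") <- method
  out
}

#' Round diagnostic metrics for presentation (3 decimals)
#' @param metrics a [diagnostic_metrics()] result
#' @return the same data frame with estimate/lower/upper rounded
#' @export
format_diagnostic_metrics <- function(metrics) {
  for (cl in c("estimate", "lower", "upper")) {
    metrics[[cl]] <- round(metrics[[cl]], 3)
  }
  metrics
}

#' Are two estimates significantly different by CI overlap?
#'
#' TRUE iff the confidence intervals are disjoint; intervals that merely
#' touch at an endpoint count as overlapping (not significant).
#'
#' @param a,b `agreement_report`s, or any list/vector with `lower` and
#'   `upper`
#' @return logical
#' @export
ci_overlap_significant <- function(a, b) {
  g <- function(x, f) {
    if (is.list(x)) x[[f]] else unname(x[f])
  }
  la <- g(a, "lower"); ua <- g(a, "upper")
  lb <- g(b, "lower"); ub <- g(b, "upper")
  if (anyNA(c(la, ua, lb, ub))) stop("both confidence intervals must be defined")
  ua < lb || ub < la
}
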
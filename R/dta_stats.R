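#' Build a 2x2 diagnostic table from paired indicators
#'
#' @param test_positive Logical vector: test result per encounter.
#' @param condition_positive Logical vector: condition status per encounter.
#' @return A list of class `tf_2x2` with integer cells `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
build_two_by_two <- function(test_positive, condition_positive) {
  if (length(test_positive) != length(condition_positive)) {
    stop("test and condition indicator vectors must have equal length", call. = FALSE)
  }
  if (anyNA(test_positive) || anyNA(condition_positive)) {
    stop("indicator vectors must not contain NA", call. = FALSE)
  }
  two_by_two(
    tp = sum(test_positive & condition_positive),
    fp = sum(test_positive & !condition_positive),
    fn = sum(!test_positive & condition_positive),
    tn = sum(!test_positive & !condition_positive)
  )
}

#' Construct a 2x2 table from cell counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return A list of class `tf_2x2`.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  structure(as.list(as.integer(cells)), names = names(cells), class = "tf_2x2")
}

# Clopper-Pearson exact binomial interval via beta quantiles
clopper_pearson <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo = lo, hi = hi)
}

# Wilson score interval (alternative CI method)
wilson_interval <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Diagnostic accuracy metrics with exact confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' 2x2 table, each with a binomial confidence interval (Clopper-Pearson
#' exact by default). A metric whose denominator is zero is reported as
#' `NA` (undefined); the others are still computed.
#'
#' @param t A `tf_2x2`.
#' @param ci_level Confidence level (default `0.95`).
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @return A list of class `tf_dta_report`; elements `sensitivity`,
#'   `specificity`, `ppv`, `npv` are named numeric vectors
#'   `c(est, lo, hi)`, plus `youden_j` and the call parameters.
#' @export
#' @examples
#' dta_metrics(two_by_two(59, 71, 6, 47))
dta_metrics <- function(t, ci_level = 0.95,
                        ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(t, "tf_2x2"))
  n <- t$tp + t$fp + t$fn + t$tn
  if (n == 0) stop("empty 2x2 table", call. = FALSE)
  ci_fun <- if (ci_method == "clopper-pearson") clopper_pearson else wilson_interval
  one <- function(x, denom) {
    if (denom == 0) {
      return(c(est = NA_real_, lo = NA_real_, hi = NA_real_))
    }
    ci <- ci_fun(x, denom, ci_level)
    c(est = x / denom, lo = unname(ci["lo"]), hi = unname(ci["hi"]))
  }
  sens <- one(t$tp, t$tp + t$fn)
  spec <- one(t$tn, t$tn + t$fp)
  ppv <- one(t$tp, t$tp + t$fp)
  npv <- one(t$tn, t$tn + t$fn)
  structure(
    list(
      sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
      youden_j = unname(sens["est"] + spec["est"] - 1),
      n = n, ci_level = ci_level, ci_method = ci_method
    ),
    class = "tf_dta_report"
  )
}

#' @export
print.tf_dta_report <- function(x, ...) {
  fmt <- function(m) {
    sprintf("%.1f%% (%.1f%%, %.1f%%)", 100 * m["est"], 100 * m["lo"], 100 * m["hi"])
  }
  cat(sprintf("Diagnostic accuracy (n = %d, %s %.0f%% CI)\n",
              x$n, x$ci_method, 100 * x$ci_level))
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  PPV:        ", fmt(x$ppv), "\n")
  cat("  NPV:        ", fmt(x$npv), "\n")
  cat(sprintf("  Youden J:    %.3f\n", x$youden_j))
  invisible(x)
}

#' Youden's index of a 2x2 table
#'
#' J = sensitivity + specificity - 1.
#'
#' @param t A `tf_2x2` with both sensitivity and specificity defined.
#' @return Numeric in `[-1, 1]`.
#' @export
youden_index <- function(t) {
  stopifnot(inherits(t, "tf_2x2"))
  if (t$tp + t$fn == 0 || t$tn + t$fp == 0) {
    stop("Youden's index undefined: a condition class is empty", call. = FALSE)
  }
  t$tp / (t$tp + t$fn) + t$tn / (t$tn + t$fp) - 1
}

#' Select a marker cutoff by maximizing Youden's index
#'
#' Every distinct observed marker value (plus `Inf`, the never-positive
#' rule) is a candidate threshold; a case is test-positive when its marker
#' is at or above the threshold. Ties are broken towards the smallest
#' threshold.
#'
#' @param marker_values Numeric marker values (e.g. procalcitonin, ng/mL).
#' @param condition Logical condition indicators.
#' @return List with `cutoff` and `youden_j`.
#' @export
select_youden_cutoff <- function(marker_values, condition) {
  if (length(marker_values) != length(condition)) {
    stop("marker and condition vectors must have equal length", call. = FALSE)
  }
  condition <- as.logical(condition)
  if (all(condition) || !any(condition)) {
    stop("cutoff selection needs both condition-positive and condition-negative cases",
         call. = FALSE)
  }
  candidates <- c(sort(unique(marker_values)), Inf)
  best <- list(cutoff = NA_real_, youden_j = -Inf)
  for (thr in candidates) {
    t <- build_two_by_two(marker_values >= thr, condition)
    j <- youden_index(t)
    if (j > best$youden_j + 1e-12) best <- list(cutoff = thr, youden_j = j)
  }
  best
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement between the two binary classifications of the
#' table: kappa = (Po - Pe) / (1 - Pe), with observed agreement
#' Po = (tp + tn)/n and expected agreement Pe from the marginal products.
#' The confidence interval uses the large-sample standard error.
#'
#' @param t A `tf_2x2`.
#' @param ci_level Confidence level (default `0.95`).
#' @return List with `kappa`, `conf_lo`, `conf_hi`, `se`, `n`; `kappa` is
#'   `NA` when the marginals are degenerate (Pe = 1).
#' @export
cohens_kappa <- function(t, ci_level = 0.95) {
  stopifnot(inherits(t, "tf_2x2"))
  n <- t$tp + t$fp + t$fn + t$tn
  if (n == 0) stop("empty 2x2 table", call. = FALSE)
  po <- (t$tp + t$tn) / n
  p_test <- (t$tp + t$fp) / n
  p_cond <- (t$tp + t$fn) / n
  pe <- p_test * p_cond + (1 - p_test) * (1 - p_cond)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(list(kappa = NA_real_, conf_lo = NA_real_, conf_hi = NA_real_,
                se = NA_real_, n = n))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / n) / (1 - pe)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(kappa = kappa, conf_lo = kappa - z * se, conf_hi = kappa + z * se,
       se = se, n = n)
}
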
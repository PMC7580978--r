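#' Blood cultures avoided under the workup rule
#'
#' Counts analyzable encounters for which the algorithm recommends no blood
#' cultures (triple-F score 0 and/or procalcitonin below the cutoff; the
#' union is counted once).
#'
#' @param classified Output of [classify_cohort()] (excluded encounters are
#'   ignored).
#' @param pct_cutoff_ng_ml PCT cutoff in ng/mL (default `0.25`).
#' @return List with `n_total`, `n_bc_avoided`, `bc_avoided_fraction`.
#' @export
simulate_bc_avoidance <- function(classified, pct_cutoff_ng_ml = 0.25) {
  a <- classified[!startsWith(classified$category, "EXCLUDED"), , drop = FALSE]
  missing_pct <- is.na(a$pct_ng_ml)
  if (any(missing_pct)) {
    warning(sprintf("%d encounter(s) without PCT excluded from the workup simulation",
                    sum(missing_pct)), call. = FALSE)
    a <- a[!missing_pct, , drop = FALSE]
  }
  avoided <- a$score == 0L | a$pct_ng_ml < pct_cutoff_ng_ml
  list(
    n_total = nrow(a),
    n_bc_avoided = sum(avoided),
    bc_avoided_fraction = if (nrow(a)) sum(avoided) / nrow(a) else NA_real_
  )
}

#' Antimicrobial-stewardship impact at a treatment threshold
#'
#' With empiric treatment triggered at the \emph{possible}-SUTI level,
#' antimicrobials are withheld in asymptomatic bacteriuria without an
#' alternative focus and narrowed (directed at the documented focus) in
#' asymptomatic bacteriuria with one. At the \emph{probable} level,
#' possible-SUTI encounters are additionally withheld/narrowed by their
#' alternative-focus status. Urocystitis, probable and bacteremic SUTI, and
#' the \emph{S. aureus} alternative-focus group always receive treatment
#' and are never eligible.
#'
#' @param classified Output of [classify_cohort()].
#' @param threshold `"possible"` or `"probable"`.
#' @return List with `threshold`, `n_withheld`, `n_narrowed`, `n_eligible`,
#'   `n_total` and `eligible_fraction` (over the analyzable cohort).
#' @export
simulate_abs_impact <- function(classified, threshold = c("possible", "probable")) {
  threshold <- match.arg(threshold)
  a <- classified[!startsWith(classified$category, "EXCLUDED"), , drop = FALSE]
  withheld <- a$category == "ABU" & !a$alt_focus
  narrowed <- a$category == "ABU" & a$alt_focus
  if (threshold == "probable") {
    withheld <- withheld | (a$category == "POSSIBLE_SUTI" & !a$alt_focus)
    narrowed <- narrowed | (a$category == "POSSIBLE_SUTI" & a$alt_focus)
  }
  list(
    threshold = threshold,
    n_withheld = sum(withheld),
    n_narrowed = sum(narrowed),
    n_eligible = sum(withheld) + sum(narrowed),
    n_total = nrow(a),
    eligible_fraction = if (nrow(a)) (sum(withheld) + sum(narrowed)) / nrow(a) else NA_real_
  )
}

#' Consolidated stewardship report
#'
#' @param classified Output of [classify_cohort()].
#' @param pct_cutoff_ng_ml PCT cutoff for the workup rule.
#' @return A list of class `tf_stewardship` with the blood-culture
#'   avoidance counts and one entry per treatment threshold.
#' @export
stewardship_report <- function(classified, pct_cutoff_ng_ml = 0.25) {
  structure(
    list(
      bc = simulate_bc_avoidance(classified, pct_cutoff_ng_ml),
      possible = simulate_abs_impact(classified, "possible"),
      probable = simulate_abs_impact(classified, "probable")
    ),
    class = "tf_stewardship"
  )
}

#' @export
print.tf_stewardship <- function(x, ...) {
  cat(sprintf("Blood cultures avoided: %d/%d (%.1f%%)\n",
              x$bc$n_bc_avoided, x$bc$n_total, 100 * x$bc$bc_avoided_fraction))
  for (th in c("possible", "probable")) {
    e <- x[[th]]
    cat(sprintf(
      "Threshold %-8s withheld %d, narrowed %d, eligible %d/%d (%.1f%%)\n",
      paste0(th, ":"), e$n_withheld, e$n_narrowed, e$n_eligible, e$n_total,
      100 * e$eligible_fraction
    ))
  }
  invisible(x)
}
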
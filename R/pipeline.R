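#' Category-by-criterion cross table
#'
#' Summarizes, per diagnosis category, how many encounters carry each of
#' the three criteria and an alternative focus.
#'
#' @param classified Output of [classify_cohort()].
#' @return Data frame with one row per category: `n`, `f1`, `f2`, `f3`,
#'   `alt_focus`.
#' @export
table3_cross <- function(classified) {
  a <- classified[!startsWith(classified$category, "EXCLUDED"), , drop = FALSE]
  cats <- c("BACTEREMIC_SUTI", "PROBABLE_SUTI", "POSSIBLE_SUTI",
            "UROCYSTITIS", "ABU", "SA_ALT_FOCUS")
  out <- do.call(rbind, lapply(cats, function(ct) {
    g <- a[a$category == ct, , drop = FALSE]
    data.frame(category = ct, n = nrow(g), f1 = sum(g$f1), f2 = sum(g$f2),
               f3 = sum(g$f3), alt_focus = sum(g$alt_focus),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Procalcitonin diagnostic-accuracy report
#'
#' Crosses the dichotomized marker (positive at or above the cutoff)
#' against any true bacteraemia and against accordant bacteraemia, and
#' computes the accuracy metrics with confidence intervals plus Cohen's
#' kappa for each cross.
#'
#' @param classified Output of [classify_cohort()].
#' @param pct_cutoff_ng_ml Cutoff in ng/mL (default `0.25`).
#' @param ci_level Confidence level.
#' @param ci_method CI method passed to [dta_metrics()].
#' @return List with elements `any_bacteraemia` and
#'   `accordant_bacteraemia`, each holding `table` (`tf_2x2`), `metrics`
#'   (`tf_dta_report`) and `kappa`.
#' @export
table4_report <- function(classified, pct_cutoff_ng_ml = 0.25, ci_level = 0.95,
                          ci_method = "clopper-pearson") {
  a <- classified[!startsWith(classified$category, "EXCLUDED"), , drop = FALSE]
  test <- a$pct_ng_ml >= pct_cutoff_ng_ml
  one <- function(condition) {
    t <- build_two_by_two(test, condition)
    list(table = t,
         metrics = dta_metrics(t, ci_level, ci_method),
         kappa = cohens_kappa(t, ci_level))
  }
  list(
    any_bacteraemia = one(a$bact_status == "true_bacteraemia"),
    accordant_bacteraemia = one(a$accordance == "accordant")
  )
}

#' Run the full analysis pipeline over a cohort
#'
#' Orchestrates inclusion filtering, triple-F scoring, classification,
#' accuracy statistics and the stewardship simulation into one
#' deterministic report, optionally writing the tables to disk.
#'
#' @param input A `tf_cohort` or a path to a cohort file (CSV/JSON).
#' @param pct_cutoff_ng_ml Procalcitonin cutoff in ng/mL.
#' @param cfu_threshold Urine-culture significance threshold in CFU/mL.
#' @param ci_level Confidence level for interval estimates.
#' @param ci_method `"clopper-pearson"` or `"wilson"`.
#' @param constraints Optional constraint ledger; when supplied the cohort
#'   is additionally checked against it.
#' @param vocab Organism vocabulary.
#' @param out_dir Optional output directory; when given, the
#'   classification table, cross table, accuracy report and stewardship
#'   summary are written as CSV plus a JSON run manifest.
#' @return A list of class `tf_report` with `classified`, `categories`,
#'   `cross`, `accuracy`, `accordance_by_organism`, `stewardship`,
#'   `constraint_check` (or `NULL`) and `config`.
#' @export
run_pipeline <- function(input,
                         pct_cutoff_ng_ml = 0.25,
                         cfu_threshold = 1000,
                         ci_level = 0.95,
                         ci_method = "clopper-pearson",
                         constraints = NULL,
                         vocab = default_organisms(),
                         out_dir = NULL) {
  stopifnot(pct_cutoff_ng_ml > 0, cfu_threshold > 0, ci_level > 0, ci_level < 1)
  cohort <- if (inherits(input, "tf_cohort")) input else read_cohort(input, vocab = vocab)
  classified <- classify_cohort(cohort, vocab, cfu_threshold, pct_cutoff_ng_ml)
  analyzed <- classified[!startsWith(classified$category, "EXCLUDED"), , drop = FALSE]

  if (nrow(analyzed) == 0L) {
    report <- structure(
      list(status = "no analyzable encounters", classified = classified,
           categories = table(character()), cross = NULL, accuracy = NULL,
           accordance_by_organism = NULL, stewardship = NULL,
           constraint_check = NULL,
           config = list(pct_cutoff_ng_ml = pct_cutoff_ng_ml,
                         cfu_threshold = cfu_threshold)),
      class = "tf_report"
    )
    return(report)
  }

  report <- structure(
    list(
      status = "ok",
      classified = classified,
      categories = table(factor(analyzed$category,
                                levels = c("BACTEREMIC_SUTI", "PROBABLE_SUTI",
                                           "POSSIBLE_SUTI", "UROCYSTITIS",
                                           "ABU", "SA_ALT_FOCUS"))),
      cross = table3_cross(classified),
      accuracy = table4_report(classified, pct_cutoff_ng_ml, ci_level, ci_method),
      accordance_by_organism = organism_accordance_table(classified),
      stewardship = stewardship_report(classified, pct_cutoff_ng_ml),
      constraint_check = if (!is.null(constraints)) {
        check_constraints(cohort, constraints,
                          vocab = vocab, cfu_threshold = cfu_threshold,
                          pct_cutoff_ng_ml = pct_cutoff_ng_ml)
      },
      config = list(pct_cutoff_ng_ml = pct_cutoff_ng_ml,
                    cfu_threshold = cfu_threshold,
                    ci_level = ci_level, ci_method = ci_method)
    ),
    class = "tf_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(classified, file.path(out_dir, "classification.csv"), row.names = FALSE)
    utils::write.csv(report$cross, file.path(out_dir, "category_cross.csv"), row.names = FALSE)
    utils::write.csv(report$accordance_by_organism,
                     file.path(out_dir, "accordance_by_organism.csv"), row.names = FALSE)
    acc <- report$accuracy
    acc_df <- do.call(rbind, lapply(names(acc), function(nm) {
      m <- acc[[nm]]$metrics
      data.frame(
        condition = nm,
        metric = c("sensitivity", "specificity", "ppv", "npv", "youden_j", "kappa"),
        estimate = c(m$sensitivity["est"], m$specificity["est"], m$ppv["est"],
                     m$npv["est"], m$youden_j, acc[[nm]]$kappa$kappa),
        conf_lo = c(m$sensitivity["lo"], m$specificity["lo"], m$ppv["lo"],
                    m$npv["lo"], NA, acc[[nm]]$kappa$conf_lo),
        conf_hi = c(m$sensitivity["hi"], m$specificity["hi"], m$ppv["hi"],
                    m$npv["hi"], NA, acc[[nm]]$kappa$conf_hi),
        stringsAsFactors = FALSE
      )
    }))
    utils::write.csv(acc_df, file.path(out_dir, "accuracy.csv"), row.names = FALSE)
    st <- report$stewardship
    utils::write.csv(
      data.frame(
        quantity = c("bc_avoided", "eligible_possible", "eligible_probable"),
        count = c(st$bc$n_bc_avoided, st$possible$n_eligible, st$probable$n_eligible),
        total = c(st$bc$n_total, st$possible$n_total, st$probable$n_total),
        fraction = c(st$bc$bc_avoided_fraction, st$possible$eligible_fraction,
                     st$probable$eligible_fraction)
      ),
      file.path(out_dir, "stewardship.csv"), row.names = FALSE
    )
    manifest <- list(
      package_version = as.character(utils::packageVersion("triplef")),
      n_screened = nrow(classified),
      n_analyzed = nrow(analyzed),
      config = report$config
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.tf_report <- function(x, ...) {
  if (!identical(x$status, "ok")) {
    cat("Pipeline report:", x$status, "\n")
    return(invisible(x))
  }
  n_screened <- nrow(x$classified)
  n_analyzed <- sum(x$categories)
  cat(sprintf("Screened %d encounters -> %d analyzable (%d sterile, %d contaminated excluded)\n",
              n_screened, n_analyzed,
              sum(x$classified$category == "EXCLUDED_STERILE"),
              sum(x$classified$category == "EXCLUDED_CONTAMINATION")))
  cat("\nDiagnosis categories:\n")
  for (nm in names(x$categories)) {
    cat(sprintf("  %-16s %3d (%.1f%%)\n", nm, x$categories[[nm]],
                100 * x$categories[[nm]] / n_analyzed))
  }
  cat("\nPCT vs any true bacteraemia:\n")
  print(x$accuracy$any_bacteraemia$metrics)
  cat("\nPCT vs accordant bacteraemia:\n")
  print(x$accuracy$accordant_bacteraemia$metrics)
  cat("\n")
  print(x$stewardship)
  if (!is.null(x$constraint_check)) {
    cat("\n")
    print(x$constraint_check)
  }
  invisible(x)
}
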
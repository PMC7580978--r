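#' F1 "fever": fever, rigors or chills
#'
#' True when fever was documented at triage or during the ED stay, or the
#' patient reported rigors or chills before presentation. When a triage
#' temperature was recorded it additionally triggers the criterion at or
#' above the configured threshold.
#'
#' @param enc An [encounter()].
#' @param fever_temp_threshold_c Temperature cut applied to the optional
#'   `triage_temp_c` field, degrees Celsius (default `38.0`).
#' @return Logical.
#' @export
score_f1 <- function(enc, fever_temp_threshold_c = 38.0) {
  isTRUE(enc$fever_at_triage) ||
    isTRUE(enc$chills_or_rigors_reported) ||
    (!is.na(enc$triage_temp_c) && enc$triage_temp_c >= fever_temp_threshold_c)
}

#' F2 "failure": dysfunction of any organ system
#'
#' True when any organ dysfunction is documented (brain, kidney,
#' circulation, heart, liver, gastrointestinal tract, metabolism, or
#' failure of functioning in the elderly).
#'
#' @param enc An [encounter()].
#' @return Logical.
#' @export
score_f2 <- function(enc) {
  length(enc$organ_dysfunctions) > 0L
}

#' F3 "focus": focal genitourinary symptoms
#'
#' True when any genitourinary symptom is documented (acute dysuria,
#' urgency, frequency, suprapubic tenderness, or flank/costovertebral-angle
#' pain). The returned value carries a `lower_only` attribute: `TRUE` when
#' all documented symptoms are lower-tract (no flank pain), which is what
#' distinguishes urocystitis from upper-tract involvement.
#'
#' @param enc An [encounter()].
#' @return Logical with attribute `lower_only`.
#' @export
score_f3 <- function(enc) {
  present <- length(enc$gu_symptoms) > 0L
  lower_only <- present && all(enc$gu_symptoms %in% tf_lower_gu())
  structure(present, lower_only = lower_only)
}

#' Compute the triple-F score
#'
#' Each criterion present scores 1, absent 0; the score is the sum (0-3).
#'
#' @param enc An [encounter()].
#' @param fever_temp_threshold_c Passed to [score_f1()].
#' @return A list of class `tf_score` with logicals `f1`, `f2`, `f3`,
#'   `lower_only_gu` and integer `score`.
#' @export
#' @examples
#' enc <- encounter("e1", 70, "female", fever_at_triage = TRUE,
#'                  organ_dysfunctions = "kidney", gu_symptoms = "dysuria")
#' compute_triple_f(enc)$score  # 3
compute_triple_f <- function(enc, fever_temp_threshold_c = 38.0) {
  f1 <- score_f1(enc, fever_temp_threshold_c)
  f2 <- score_f2(enc)
  f3 <- score_f3(enc)
  structure(
    list(
      f1 = f1, f2 = f2, f3 = as.logical(f3),
      lower_only_gu = attr(f3, "lower_only"),
      score = as.integer(f1) + as.integer(f2) + as.integer(as.logical(f3))
    ),
    class = "tf_score"
  )
}

#' Features of a systemic reaction
#'
#' Systemic involvement is operationalized as fever (F1), organ failure
#' (F2), or an inflammatory laboratory signal: procalcitonin at or above
#' the cutoff (default 0.25 ng/mL).
#'
#' @param enc An [encounter()]; `pct_ng_ml` must be present.
#' @param triple_f A `tf_score` from [compute_triple_f()].
#' @param pct_cutoff_ng_ml PCT cutoff in ng/mL (default `0.25`).
#' @return Logical.
#' @export
has_systemic_features <- function(enc, triple_f = compute_triple_f(enc),
                                  pct_cutoff_ng_ml = 0.25) {
  if (is.na(enc$pct_ng_ml)) {
    stop("pct_ng_ml is required to assess systemic features", call. = FALSE)
  }
  isTRUE(triple_f$f1) || isTRUE(triple_f$f2) || enc$pct_ng_ml >= pct_cutoff_ng_ml
}

#' Is an alternative infectious focus present?
#'
#' True when a non-urinary focus is documented (pneumonia, port infection,
#' skin and soft tissue infection, influenza, other) or when discordant
#' bacteraemia establishes one: a bloodstream organism absent from the
#' urine culture points to another source.
#'
#' @param enc An [encounter()].
#' @param blood A `tf_bact` with accordance assessed.
#' @return List with logical `present` and character `label` (`NA` when no
#'   focus).
#' @export
determine_alternative_focus <- function(enc, blood) {
  if (!identical(enc$documented_alt_focus, "none")) {
    return(list(present = TRUE, label = enc$documented_alt_focus))
  }
  if (identical(blood$accordance, "discordant")) {
    return(list(present = TRUE, label = "discordant bacteraemia"))
  }
  list(present = FALSE, label = NA_character_)
}

#' Recommend the culture workup from score and procalcitonin
#'
#' Blood cultures (as part of paired urine/blood sampling) are withheld
#' when the triple-F score is 0 and/or PCT is below the cutoff; otherwise
#' paired cultures are obtained.
#'
#' @param triple_f A `tf_score`.
#' @param pct_ng_ml Procalcitonin in ng/mL.
#' @param cutoff PCT cutoff in ng/mL (default `0.25`).
#' @return `"no_blood_cultures"` or `"obtain_PUB"`.
#' @export
recommend_workup <- function(triple_f, pct_ng_ml, cutoff = 0.25) {
  if (is.na(pct_ng_ml)) stop("pct_ng_ml is required", call. = FALSE)
  if (triple_f$score == 0L || pct_ng_ml < cutoff) "no_blood_cultures" else "obtain_PUB"
}

#' Classify one encounter with significant bacteriuria
#'
#' Applies the diagnostic rules in fixed precedence order:
#' \describe{
#'   \item{R1}{\emph{S. aureus} true bacteraemia with concomitant
#'     \emph{S. aureus} bacteriuria: established alternative focus, counted
#'     neither as UTI nor as asymptomatic bacteriuria (`SA_ALT_FOCUS`).}
#'   \item{R2}{Accordant true bacteraemia with a urine uropathogen:
#'     `BACTEREMIC_SUTI` (urinary-source bacteraemia when genitourinary
#'     symptoms are absent).}
#'   \item{R3}{Genitourinary symptoms, systemic features, no alternative
#'     focus: `PROBABLE_SUTI`.}
#'   \item{R4}{Genitourinary symptoms + systemic features + alternative
#'     focus, or no genitourinary symptoms + systemic features + no
#'     alternative focus: `POSSIBLE_SUTI`.}
#'   \item{R5}{Lower-tract symptoms only, no systemic features:
#'     `UROCYSTITIS`.}
#'   \item{R6}{Otherwise `ABU` (including systemic features fully
#'     attributed to an alternative focus).}
#' }
#'
#' @param enc An [encounter()] whose urine culture is significant;
#'   calling this on a sterile or contaminated culture is an error (the
#'   inclusion filter removes those encounters first).
#' @param vocab Organism vocabulary.
#' @param cfu_threshold Urine significance threshold, CFU/mL.
#' @param pct_cutoff_ng_ml PCT cutoff for systemic features and workup.
#' @param fever_temp_threshold_c Optional triage-temperature fever cut.
#' @return A list of class `tf_classification` with `encounter_id`,
#'   `category`, `triple_f`, `systemic_features`,
#'   `alternative_focus_present`, `focus_label`, `urine`, `bacteraemia`,
#'   `workup` and `rationale` (ordered rule identifiers fired).
#' @export
classify_encounter <- function(enc,
                               vocab = default_organisms(),
                               cfu_threshold = 1000,
                               pct_cutoff_ng_ml = 0.25,
                               fever_temp_threshold_c = 38.0) {
  urine <- classify_urine_culture(enc$urine_culture, vocab, cfu_threshold)
  if (!identical(urine$status, "significant")) {
    stop(sprintf(
      "encounter %s: classification requires a significant urine culture (got '%s')",
      enc$encounter_id, urine$status
    ), call. = FALSE)
  }
  blood <- adjudicate_blood_cultures(enc$blood_culture_sets, enc, vocab)
  blood <- assess_accordance(urine, blood)
  tf <- compute_triple_f(enc, fever_temp_threshold_c)
  systemic <- has_systemic_features(enc, tf, pct_cutoff_ng_ml)
  alt <- determine_alternative_focus(enc, blood)
  urine_species <- vapply(urine$significant_isolates, function(i) i$species, character(1))
  sa <- "staphylococcus aureus"

  rationale <- character()
  category <- NULL
  if (identical(blood$status, "true_bacteraemia") &&
      sa %in% blood$organisms && sa %in% urine_species) {
    category <- "SA_ALT_FOCUS"
    rationale <- c(rationale, "R1:s_aureus_bacteraemia_with_bacteriuria")
  } else if (identical(blood$accordance, "accordant")) {
    category <- "BACTEREMIC_SUTI"
    rationale <- c(rationale, "R2:accordant_bacteraemia")
    if (!tf$f3) rationale <- c(rationale, "note:urinary_source_bacteraemia_without_gu_symptoms")
  } else if (tf$f3 && systemic && !alt$present) {
    category <- "PROBABLE_SUTI"
    rationale <- c(rationale, "R3:gu_symptoms_systemic_no_alt_focus")
  } else if ((tf$f3 && systemic && alt$present) || (!tf$f3 && systemic && !alt$present)) {
    category <- "POSSIBLE_SUTI"
    rationale <- c(rationale, "R4:possible_suti")
  } else if (tf$f3 && tf$lower_only_gu && !systemic) {
    category <- "UROCYSTITIS"
    rationale <- c(rationale, "R5:lower_gu_symptoms_no_systemic")
    if (alt$present) rationale <- c(rationale, "note:alt_focus_with_lower_gu_symptoms")
  } else {
    category <- "ABU"
    rationale <- c(rationale, "R6:abu")
    if (systemic && alt$present) {
      rationale <- c(rationale, "note:systemic_features_attributed_to_alt_focus")
    }
  }

  structure(
    list(
      encounter_id = enc$encounter_id,
      category = category,
      triple_f = tf,
      systemic_features = systemic,
      alternative_focus_present = alt$present,
      focus_label = alt$label,
      urine = urine,
      bacteraemia = blood,
      workup = recommend_workup(tf, enc$pct_ng_ml, pct_cutoff_ng_ml),
      rationale = rationale
    ),
    class = "tf_classification"
  )
}

#' Run the inclusion filter and classification over a cohort
#'
#' Applies the urine-culture significance filter (sterile and contaminated
#' cultures are excluded, mirroring the screening flow) and classifies
#' every remaining encounter.
#'
#' @inheritParams classify_encounter
#' @param cohort A `tf_cohort`.
#' @return A data frame with one row per screened encounter:
#'   `encounter_id`, `category`, `f1`, `f2`, `f3`, `score`, `systemic`,
#'   `alt_focus`, `focus_label`, `documented_alt_focus`, `bact_status`,
#'   `accordance`, `dominant_uropathogen`, `workup`, `pct_ng_ml`, `sex`,
#'   `n_urine_pathogens`, `urine_species` (semicolon-joined). Excluded
#'   encounters carry `category` `EXCLUDED_STERILE` /
#'   `EXCLUDED_CONTAMINATION` and `NA` elsewhere. The full per-encounter
#'   classification objects are attached as attribute `"details"`.
#' @export
classify_cohort <- function(cohort,
                            vocab = default_organisms(),
                            cfu_threshold = 1000,
                            pct_cutoff_ng_ml = 0.25,
                            fever_temp_threshold_c = 38.0) {
  if (length(cohort) == 0L) {
    out <- data.frame(
      encounter_id = character(), category = character(),
      f1 = logical(), f2 = logical(), f3 = logical(), score = integer(),
      systemic = logical(), alt_focus = logical(), focus_label = character(),
      documented_alt_focus = character(), bact_status = character(),
      accordance = character(), dominant_uropathogen = character(),
      workup = character(), pct_ng_ml = numeric(), sex = character(),
      n_urine_pathogens = integer(), urine_species = character(),
      stringsAsFactors = FALSE
    )
    attr(out, "details") <- list()
    return(out)
  }
  details <- vector("list", length(cohort))
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    enc <- cohort[[i]]
    urine <- classify_urine_culture(enc$urine_culture, vocab, cfu_threshold)
    if (!identical(urine$status, "significant")) {
      category <- if (urine$status == "sterile") "EXCLUDED_STERILE" else "EXCLUDED_CONTAMINATION"
      details[[i]] <- list(encounter_id = enc$encounter_id, category = category, urine = urine)
      rows[[i]] <- data.frame(
        encounter_id = enc$encounter_id, category = category,
        f1 = NA, f2 = NA, f3 = NA, score = NA_integer_, systemic = NA,
        alt_focus = NA, focus_label = NA_character_,
        documented_alt_focus = enc$documented_alt_focus,
        bact_status = NA_character_, accordance = NA_character_,
        dominant_uropathogen = NA_character_, workup = NA_character_,
        pct_ng_ml = enc$pct_ng_ml, sex = enc$sex,
        n_urine_pathogens = NA_integer_, urine_species = NA_character_,
        stringsAsFactors = FALSE
      )
      next
    }
    cl <- classify_encounter(enc, vocab, cfu_threshold, pct_cutoff_ng_ml, fever_temp_threshold_c)
    details[[i]] <- cl
    urine_species <- vapply(cl$urine$significant_isolates, function(x) x$species, character(1))
    rows[[i]] <- data.frame(
      encounter_id = enc$encounter_id, category = cl$category,
      f1 = cl$triple_f$f1, f2 = cl$triple_f$f2, f3 = cl$triple_f$f3,
      score = cl$triple_f$score, systemic = cl$systemic_features,
      alt_focus = cl$alternative_focus_present, focus_label = cl$focus_label,
      documented_alt_focus = enc$documented_alt_focus,
      bact_status = cl$bacteraemia$status, accordance = cl$bacteraemia$accordance,
      dominant_uropathogen = cl$bacteraemia$dominant_uropathogen,
      workup = cl$workup, pct_ng_ml = enc$pct_ng_ml, sex = enc$sex,
      n_urine_pathogens = length(urine_species),
      urine_species = paste(urine_species, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}
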
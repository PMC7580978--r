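#' Construct a urine or blood isolate
#'
#' @param species Organism name (free text, matched against the vocabulary
#'   after normalization).
#' @param cfu_per_ml Quantitative count in colony-forming units per mL;
#'   `NA` for blood isolates, which are not quantified.
#' @param methicillin_resistant Optional logical, meaningful for
#'   \emph{Staphylococcus aureus} only (`NA` otherwise).
#' @return A list of class `tf_isolate`.
#' @export
isolate <- function(species, cfu_per_ml = NA_real_, methicillin_resistant = NA) {
  stopifnot(is.character(species), length(species) == 1L)
  if (!is.na(cfu_per_ml) && cfu_per_ml < 0) {
    stop("cfu_per_ml must be non-negative", call. = FALSE)
  }
  structure(
    list(
      species = normalize_species(species),
      cfu_per_ml = as.numeric(cfu_per_ml),
      methicillin_resistant = as.logical(methicillin_resistant)
    ),
    class = "tf_isolate"
  )
}

#' Construct an emergency-department encounter record
#'
#' One row of the analysis: a single ED presentation with the raw clinical
#' fields from which everything else (triple-F score, urine significance,
#' bacteraemia status, diagnosis category) is derived. No derived labels are
#' stored on the encounter; the classification pipeline recomputes them.
#'
#' @param encounter_id Unique identifier.
#' @param age_years Age in years; the study includes adults only (>= 18).
#' @param sex `"female"` or `"male"`.
#' @param fever_at_triage Logical; fever documented at triage, during the ED
#'   stay, or as an unequivocal statement of measured fever.
#' @param chills_or_rigors_reported Logical; rigors or chills prior to
#'   presentation.
#' @param organ_dysfunctions Character vector drawn from the failure
#'   enumeration (brain, kidney, circulation, heart, liver, gi_tract,
#'   metabolism, functional_decline_elderly); empty means no organ
#'   dysfunction.
#' @param gu_symptoms Character vector of genitourinary symptoms (dysuria,
#'   urgency, frequency, suprapubic_tenderness, flank_pain); empty means
#'   none documented.
#' @param pct_ng_ml Procalcitonin in ng/mL (equivalently ug/L).
#' @param urine_culture List with `collection_method` and `isolates` (a list
#'   of [isolate()] objects, possibly empty = no growth).
#' @param blood_culture_sets List of blood-culture sets, each a list with
#'   `set_id` and `isolates`. At least one set per encounter (paired
#'   urine/blood sampling is an inclusion criterion).
#' @param intravascular_device Logical; any intravascular device (port,
#'   central line) in place.
#' @param urinary_catheter Logical.
#' @param documented_alt_focus One of none, pneumonia, port_infection, ssti,
#'   influenza, other.
#' @param triage_temp_c Optional triage temperature in degrees Celsius; when
#'   present it contributes to the fever criterion via a configurable
#'   threshold (default 38.0).
#' @return A list of class `tf_encounter`.
#' @export
encounter <- function(encounter_id,
                      age_years,
                      sex,
                      fever_at_triage = FALSE,
                      chills_or_rigors_reported = FALSE,
                      organ_dysfunctions = character(),
                      gu_symptoms = character(),
                      pct_ng_ml = NA_real_,
                      urine_culture = list(collection_method = "midstream", isolates = list()),
                      blood_culture_sets = list(),
                      intravascular_device = FALSE,
                      urinary_catheter = FALSE,
                      documented_alt_focus = "none",
                      triage_temp_c = NA_real_) {
  enc <- structure(
    list(
      encounter_id = as.character(encounter_id),
      age_years = as.numeric(age_years),
      sex = as.character(sex),
      fever_at_triage = isTRUE(fever_at_triage),
      chills_or_rigors_reported = isTRUE(chills_or_rigors_reported),
      organ_dysfunctions = as.character(organ_dysfunctions),
      gu_symptoms = as.character(gu_symptoms),
      pct_ng_ml = as.numeric(pct_ng_ml),
      urine_culture = urine_culture,
      blood_culture_sets = blood_culture_sets,
      intravascular_device = isTRUE(intravascular_device),
      urinary_catheter = isTRUE(urinary_catheter),
      documented_alt_focus = as.character(documented_alt_focus),
      triage_temp_c = as.numeric(triage_temp_c)
    ),
    class = "tf_encounter"
  )
  enc
}

#' Validate an encounter against the type invariants
#'
#' Violations are returned, not raised, so that a whole cohort can be
#' audited in one pass. The adult-age inclusion criterion (>= 18 years) is
#' reported as a violation but does not stop processing.
#'
#' @param enc A [encounter()] object.
#' @return Character vector of violation descriptions; empty if well formed.
#' @export
validate_encounter <- function(enc) {
  enums <- tf_enums()
  v <- character()
  if (!is.na(enc$age_years) && enc$age_years < 18) {
    v <- c(v, sprintf("age_years = %g violates the adult (>= 18) inclusion criterion", enc$age_years))
  }
  if (!enc$sex %in% enums$sex) {
    v <- c(v, sprintf("sex '%s' not in {%s}", enc$sex, paste(enums$sex, collapse = ", ")))
  }
  bad_org <- setdiff(enc$organ_dysfunctions, enums$organ_dysfunctions)
  if (length(bad_org)) {
    v <- c(v, sprintf("unknown organ_dysfunctions: %s", paste(bad_org, collapse = ", ")))
  }
  bad_gu <- setdiff(enc$gu_symptoms, enums$gu_symptoms)
  if (length(bad_gu)) {
    v <- c(v, sprintf("unknown gu_symptoms: %s", paste(bad_gu, collapse = ", ")))
  }
  if (!is.na(enc$pct_ng_ml) && enc$pct_ng_ml < 0) {
    v <- c(v, sprintf("pct_ng_ml = %g is negative", enc$pct_ng_ml))
  }
  if (!enc$urine_culture$collection_method %in% enums$collection_method) {
    v <- c(v, sprintf("unknown urine collection_method '%s'", enc$urine_culture$collection_method))
  }
  if (!enc$documented_alt_focus %in% enums$documented_alt_focus) {
    v <- c(v, sprintf("unknown documented_alt_focus '%s'", enc$documented_alt_focus))
  }
  for (iso in enc$urine_culture$isolates) {
    if (!is.na(iso$cfu_per_ml) && iso$cfu_per_ml < 0) {
      v <- c(v, sprintf("urine isolate %s has negative cfu_per_ml", iso$species))
    }
  }
  ids <- vapply(enc$blood_culture_sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) {
    v <- c(v, "blood culture set_id values are not unique within the encounter")
  }
  v
}

#' Build a cohort from a list of encounters
#'
#' @param encounters List of [encounter()] objects.
#' @return A list of class `tf_cohort`.
#' @export
as_cohort <- function(encounters) {
  stopifnot(all(vapply(encounters, inherits, logical(1), "tf_encounter")))
  structure(encounters, class = "tf_cohort")
}

#' @export
print.tf_cohort <- function(x, ...) {
  cat(sprintf("<tf_cohort> %d encounters\n", length(x)))
  invisible(x)
}

# ---- serialization -------------------------------------------------------

# CSV token formats:
#   urine_isolates: "species:cfu[;species:cfu]", MRSA flagged as "species*"
#   bc_sets:        "set_id:speciesA,speciesB;set_id2:"  (empty = negative set)
# list-valued simple fields (organ_dysfunctions, gu_symptoms) are
# semicolon-joined.

tf_csv_columns <- function() {
  c(
    "encounter_id", "age_years", "sex", "fever_at_triage",
    "chills_or_rigors_reported", "organ_dysfunctions", "gu_symptoms",
    "pct_ng_ml", "urine_collection_method", "urine_isolates", "bc_sets",
    "intravascular_device", "urinary_catheter", "documented_alt_focus"
  )
}

fmt_species_token <- function(iso) {
  tok <- iso$species
  if (isTRUE(iso$methicillin_resistant)) tok <- paste0(tok, "*")
  tok
}

parse_species_token <- function(tok) {
  mr <- NA
  if (grepl("\\*$", tok)) {
    mr <- TRUE
    tok <- sub("\\*$", "", tok)
  } else if (grepl("aureus$", tok)) {
    mr <- FALSE
  }
  list(species = tok, methicillin_resistant = mr)
}

enc_to_row <- function(enc) {
  ui <- vapply(enc$urine_culture$isolates, function(iso) {
    paste0(fmt_species_token(iso), ":", format(iso$cfu_per_ml, scientific = FALSE, trim = TRUE))
  }, character(1))
  bc <- vapply(enc$blood_culture_sets, function(s) {
    paste0(s$set_id, ":", paste(vapply(s$isolates, fmt_species_token, character(1)), collapse = ","))
  }, character(1))
  data.frame(
    encounter_id = enc$encounter_id,
    age_years = enc$age_years,
    sex = enc$sex,
    fever_at_triage = enc$fever_at_triage,
    chills_or_rigors_reported = enc$chills_or_rigors_reported,
    organ_dysfunctions = paste(enc$organ_dysfunctions, collapse = ";"),
    gu_symptoms = paste(enc$gu_symptoms, collapse = ";"),
    pct_ng_ml = enc$pct_ng_ml,
    urine_collection_method = enc$urine_culture$collection_method,
    urine_isolates = paste(ui, collapse = ";"),
    bc_sets = paste(bc, collapse = ";"),
    intravascular_device = enc$intravascular_device,
    urinary_catheter = enc$urinary_catheter,
    documented_alt_focus = enc$documented_alt_focus,
    stringsAsFactors = FALSE
  )
}

split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

row_to_enc <- function(row, vocab, row_id) {
  ui <- lapply(split_tokens(row$urine_isolates), function(tok) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("row %s: malformed urine isolate token '%s'", row_id, tok), call. = FALSE)
    }
    sp <- parse_species_token(parts[1])
    isolate(sp$species, as.numeric(parts[2]), sp$methicillin_resistant)
  })
  bc <- lapply(split_tokens(row$bc_sets), function(tok) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    set_id <- parts[1]
    species <- if (length(parts) > 1L && nzchar(parts[2])) {
      strsplit(parts[2], ",", fixed = TRUE)[[1]]
    } else {
      character()
    }
    list(set_id = set_id, isolates = lapply(species, function(s) {
      sp <- parse_species_token(s)
      isolate(sp$species, NA_real_, sp$methicillin_resistant)
    }))
  })
  all_species <- c(
    vapply(ui, function(i) i$species, character(1)),
    unlist(lapply(bc, function(s) vapply(s$isolates, function(i) i$species, character(1))))
  )
  unknown <- all_species[organism_class(all_species, vocab) == "unknown"]
  if (length(unknown)) {
    stop(sprintf(
      "row %s: species not in the organism vocabulary: %s",
      row_id, paste(unique(unknown), collapse = ", ")
    ), call. = FALSE)
  }
  encounter(
    encounter_id = row$encounter_id,
    age_years = row$age_years,
    sex = row$sex,
    fever_at_triage = as.logical(row$fever_at_triage),
    chills_or_rigors_reported = as.logical(row$chills_or_rigors_reported),
    organ_dysfunctions = split_tokens(row$organ_dysfunctions),
    gu_symptoms = split_tokens(row$gu_symptoms),
    pct_ng_ml = as.numeric(row$pct_ng_ml),
    urine_culture = list(
      collection_method = row$urine_collection_method,
      isolates = ui
    ),
    blood_culture_sets = bc,
    intravascular_device = as.logical(row$intravascular_device),
    urinary_catheter = as.logical(row$urinary_catheter),
    documented_alt_focus = row$documented_alt_focus
  )
}

#' Flatten a cohort to the tabular CSV schema
#'
#' @param x A `tf_cohort`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A data frame with one row per encounter and the documented
#'   column set (list-valued fields as semicolon-joined tokens).
#' @export
as.data.frame.tf_cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(x, enc_to_row))
}

#' Write a cohort to CSV or JSON
#'
#' Serialization is lossless: [read_cohort()] of the written file
#' reconstructs every field.
#'
#' @param cohort A `tf_cohort`.
#' @param path Destination file.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "json")) {
  format <- if (missing(format)) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  } else {
    match.arg(format)
  }
  if (format == "csv") {
    df <- if (length(cohort)) {
      as.data.frame(cohort)
    } else {
      as.data.frame(setNames(rep(list(character()), length(tf_csv_columns())), tf_csv_columns()))
    }
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    recs <- lapply(cohort, function(enc) {
      enc2 <- unclass(enc)
      enc2$triage_temp_c <- NULL
      enc2$urine_culture$isolates <- lapply(enc2$urine_culture$isolates, unclass)
      enc2$blood_culture_sets <- lapply(enc2$blood_culture_sets, function(s) {
        s$isolates <- lapply(s$isolates, unclass)
        s
      })
      enc2
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' Read a cohort from CSV or JSON
#'
#' Every species string is checked against the organism vocabulary; records
#' violating the adult-age inclusion criterion are kept but flagged with a
#' warning (they are removed later by the inclusion filter, not by the
#' reader).
#'
#' @param path Input file.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @param vocab Organism vocabulary, see [default_organisms()].
#' @return A `tf_cohort` in file row order.
#' @export
read_cohort <- function(path, format = c("csv", "json"), vocab = default_organisms()) {
  format <- if (missing(format)) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  } else {
    match.arg(format)
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    missing_cols <- setdiff(tf_csv_columns(), names(df))
    if (length(missing_cols)) {
      stop(sprintf(
        "cohort file is missing mandatory column(s): %s",
        paste(missing_cols, collapse = ", ")
      ), call. = FALSE)
    }
    encs <- lapply(seq_len(nrow(df)), function(i) row_to_enc(df[i, ], vocab, df$encounter_id[i]))
  } else {
    recs <- jsonlite::read_json(path)
    encs <- lapply(recs, function(r) {
      ui <- lapply(r$urine_culture$isolates, function(i) {
        isolate(i$species, i$cfu_per_ml %||% NA_real_, i$methicillin_resistant %||% NA)
      })
      bc <- lapply(r$blood_culture_sets, function(s) {
        list(set_id = s$set_id, isolates = lapply(s$isolates, function(i) {
          isolate(i$species, NA_real_, i$methicillin_resistant %||% NA)
        }))
      })
      all_species <- c(
        vapply(ui, function(i) i$species, character(1)),
        unlist(lapply(bc, function(s) vapply(s$isolates, function(i) i$species, character(1))))
      )
      unknown <- all_species[organism_class(all_species, vocab) == "unknown"]
      if (length(unknown)) {
        stop(sprintf(
          "record %s: species not in the organism vocabulary: %s",
          r$encounter_id, paste(unique(unknown), collapse = ", ")
        ), call. = FALSE)
      }
      encounter(
        encounter_id = r$encounter_id,
        age_years = r$age_years,
        sex = r$sex,
        fever_at_triage = isTRUE(r$fever_at_triage),
        chills_or_rigors_reported = isTRUE(r$chills_or_rigors_reported),
        organ_dysfunctions = unlist(r$organ_dysfunctions) %||% character(),
        gu_symptoms = unlist(r$gu_symptoms) %||% character(),
        pct_ng_ml = r$pct_ng_ml %||% NA_real_,
        urine_culture = list(collection_method = r$urine_culture$collection_method, isolates = ui),
        blood_culture_sets = bc,
        intravascular_device = isTRUE(r$intravascular_device),
        urinary_catheter = isTRUE(r$urinary_catheter),
        documented_alt_focus = r$documented_alt_focus
      )
    })
  }
  underage <- vapply(encs, function(e) !is.na(e$age_years) && e$age_years < 18, logical(1))
  if (any(underage)) {
    warning(sprintf(
      "%d record(s) violate the adult (>= 18) inclusion criterion: %s",
      sum(underage),
      paste(vapply(encs[underage], function(e) e$encounter_id, character(1)), collapse = ", ")
    ), call. = FALSE)
  }
  as_cohort(encs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
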
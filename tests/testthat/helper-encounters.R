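# compact constructors shared by the test files

neg_sets <- function() {
  list(list(set_id = "S1", isolates = list()),
       list(set_id = "S2", isolates = list()))
}

blood_sets <- function(species, n_positive = 2L, mrsa = NA) {
  sets <- neg_sets()
  for (k in seq_len(n_positive)) {
    sets[[k]]$isolates <- lapply(species, function(s) {
      isolate(s, NA_real_, if (s == "staphylococcus aureus") mrsa else NA)
    })
  }
  sets
}

urine_of <- function(..., method = "midstream") {
  list(collection_method = method, isolates = list(...))
}

enc_of <- function(id = "e1", gu = character(), fever = FALSE, organs = character(),
                   pct = 1.0, urine = urine_of(isolate("escherichia coli", 1e5)),
                   bc = neg_sets(), focus = "none", device = FALSE, age = 70,
                   sex = "female", chills = FALSE) {
  encounter(
    encounter_id = id, age_years = age, sex = sex,
    fever_at_triage = fever, chills_or_rigors_reported = chills,
    organ_dysfunctions = organs, gu_symptoms = gu, pct_ng_ml = pct,
    urine_culture = urine, blood_culture_sets = bc,
    intravascular_device = device, documented_alt_focus = focus
  )
}

# fixture cohort and its classification, built once per test run
fixture_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- build_fixture_cohort(seed = 42L)
    value
  }
})

fixture_classified <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- classify_cohort(fixture_cohort())
    value
  }
})

analyzed_rows <- function(classified) {
  classified[!startsWith(classified$category, "EXCLUDED"), , drop = FALSE]
}
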
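test_that("F1 fires on fever, chills, or a triage temperature over the cut", {
  expect_true(score_f1(enc_of(chills = TRUE)))
  expect_false(score_f1(enc_of()))
  warm <- enc_of()
  warm$triage_temp_c <- 38.2
  expect_true(score_f1(warm))
  expect_false(score_f1(warm, fever_temp_threshold_c = 38.5))
})

test_that("F2 is any organ dysfunction and F3 any genitourinary symptom", {
  expect_true(score_f2(enc_of(organs = "kidney")))
  expect_false(score_f2(enc_of()))

  lower <- score_f3(enc_of(gu = "dysuria"))
  expect_true(as.logical(lower))
  expect_true(attr(lower, "lower_only"))

  upper <- score_f3(enc_of(gu = "flank_pain"))
  expect_true(as.logical(upper))
  expect_false(attr(upper, "lower_only"))

  expect_false(as.logical(score_f3(enc_of())))
})

test_that("the triple-F score is the sum of the three indicators", {
  tf <- compute_triple_f(enc_of(fever = TRUE, organs = "kidney", gu = "dysuria"))
  expect_equal(tf$score, 3L)
  expect_true(tf$f1 && tf$f2 && tf$f3)
  expect_equal(compute_triple_f(enc_of())$score, 0L)
})

test_that("systemic features are fever, failure, or PCT at the cutoff", {
  expect_true(has_systemic_features(enc_of(pct = 0.8)))
  expect_false(has_systemic_features(enc_of(pct = 0.1)))
  expect_true(has_systemic_features(enc_of(organs = "kidney", pct = 0.05)))
  expect_true(has_systemic_features(enc_of(pct = 0.25)))  # boundary: >= cutoff
})

test_that("an alternative focus is documented or established by discordant bacteraemia", {
  bl_none <- adjudicate_blood_cultures(neg_sets(), enc_of())
  expect_true(determine_alternative_focus(enc_of(focus = "pneumonia"), bl_none)$present)

  urine <- classify_urine_culture(urine_of(isolate("enterococcus faecalis", 1e4)))
  bl <- assess_accordance(urine, adjudicate_blood_cultures(
    blood_sets("streptococcus pneumoniae"), enc_of()))
  out <- determine_alternative_focus(enc_of(), bl)
  expect_true(out$present)
  expect_equal(out$label, "discordant bacteraemia")

  expect_false(determine_alternative_focus(enc_of(), bl_none)$present)
})

test_that("the workup rule withholds cultures at score 0 and/or low PCT", {
  tf2 <- compute_triple_f(enc_of(fever = TRUE, organs = "kidney"))
  tf0 <- compute_triple_f(enc_of())
  tf3 <- compute_triple_f(enc_of(fever = TRUE, organs = "kidney", gu = "dysuria"))
  expect_equal(recommend_workup(tf2, 1.0), "obtain_PUB")
  expect_equal(recommend_workup(tf0, 3.0), "no_blood_cultures")
  expect_equal(recommend_workup(tf3, 0.1), "no_blood_cultures")
})

test_that("classification reproduces the clinical definitions", {
  # accordant bacteraemia without GU symptoms: urinary-source bacteraemia
  usb <- classify_encounter(enc_of(bc = blood_sets("escherichia coli"), pct = 2))
  expect_equal(usb$category, "BACTEREMIC_SUTI")
  expect_true(any(grepl("urinary_source", usb$rationale)))

  probable <- classify_encounter(enc_of(gu = "dysuria", fever = TRUE, pct = 1))
  expect_equal(probable$category, "PROBABLE_SUTI")

  # febrile ABU: systemic reaction attributed to the documented pneumonia
  abu <- classify_encounter(enc_of(fever = TRUE, focus = "pneumonia", pct = 1))
  expect_equal(abu$category, "ABU")
  expect_true(any(grepl("attributed_to_alt_focus", abu$rationale)))

  uro <- classify_encounter(enc_of(gu = "dysuria", pct = 0.05))
  expect_equal(uro$category, "UROCYSTITIS")

  possible <- classify_encounter(enc_of(fever = TRUE, pct = 1))
  expect_equal(possible$category, "POSSIBLE_SUTI")

  sa <- classify_encounter(enc_of(
    urine = urine_of(isolate("staphylococcus aureus", 1e5)),
    bc = blood_sets("staphylococcus aureus"), organs = "circulation", pct = 2
  ))
  expect_equal(sa$category, "SA_ALT_FOCUS")

  expect_error(
    classify_encounter(enc_of(urine = urine_of(isolate("lactobacillus spp", 1e5)))),
    "significant"
  )
})

test_that("exactly one terminal rule fires for every feature combination", {
  # independent oracle re-deriving the category from the definitions
  oracle <- function(f3, lower_only, systemic, alt, accordant, sa) {
    if (sa) return("SA_ALT_FOCUS")
    if (accordant) return("BACTEREMIC_SUTI")
    if (f3 && systemic && !alt) return("PROBABLE_SUTI")
    if ((f3 && systemic && alt) || (!f3 && systemic && !alt)) return("POSSIBLE_SUTI")
    if (f3 && lower_only && !systemic) return("UROCYSTITIS")
    "ABU"
  }
  grid <- expand.grid(
    gu = c("none", "dysuria", "flank_pain"),
    pct = c(0.05, 1.0),
    focus = c("none", "pneumonia"),
    blood = c("negative", "accordant", "discordant", "sa"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    urine <- if (g$blood == "sa") {
      urine_of(isolate("staphylococcus aureus", 1e5))
    } else {
      urine_of(isolate("escherichia coli", 1e5))
    }
    bc <- switch(g$blood,
      negative = neg_sets(),
      accordant = blood_sets(if (g$blood == "sa") "staphylococcus aureus" else "escherichia coli"),
      discordant = blood_sets("streptococcus pneumoniae"),
      sa = blood_sets("staphylococcus aureus")
    )
    enc <- enc_of(
      id = sprintf("g%03d", i),
      gu = if (g$gu == "none") character() else g$gu,
      pct = g$pct, urine = urine, bc = bc, focus = g$focus
    )
    cl <- classify_encounter(enc)
    # exactly one terminal rule in the trace
    expect_length(grep("^R[1-6]:", cl$rationale), 1L)
    f3 <- g$gu != "none"
    systemic <- g$pct >= 0.25
    alt <- g$focus != "none" || g$blood == "discordant"
    expect_equal(
      cl$category,
      oracle(f3, g$gu == "dysuria", systemic, alt,
             accordant = g$blood %in% c("accordant", "sa"), sa = g$blood == "sa"),
      info = paste(unlist(g), collapse = "/")
    )
  }
})

test_that("probable SUTI never carries a focus or accordant bacteraemia on the fixture", {
  a <- analyzed_rows(fixture_classified())
  p <- a[a$category == "PROBABLE_SUTI", ]
  expect_gt(nrow(p), 0L)
  expect_false(any(p$alt_focus))
  expect_false(any(p$accordance == "accordant"))
})
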
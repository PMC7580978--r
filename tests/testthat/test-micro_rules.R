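test_that("urine cultures partition into significant, sterile and contaminated", {
  sig <- classify_urine_culture(urine_of(isolate("escherichia coli", 1e5)))
  expect_equal(sig$status, "significant")
  expect_length(sig$significant_isolates, 1L)

  expect_equal(classify_urine_culture(urine_of())$status, "sterile")

  three <- classify_urine_culture(urine_of(
    isolate("escherichia coli", 1e4), isolate("klebsiella pneumoniae", 1e4),
    isolate("enterococcus faecalis", 1e4)
  ))
  expect_equal(three$status, "contaminated")

  mixed <- classify_urine_culture(urine_of(
    isolate("escherichia coli", 1e5), isolate("enterococcus faecalis", 1e4)
  ))
  expect_equal(mixed$status, "significant")
  expect_length(mixed$significant_isolates, 2L)

  flora <- classify_urine_culture(urine_of(isolate("lactobacillus spp", 1e5)))
  expect_equal(flora$status, "contaminated")

  low <- classify_urine_culture(urine_of(isolate("escherichia coli", 500)))
  expect_equal(low$status, "contaminated")

  # threshold boundary: exactly 10^3 CFU/mL qualifies
  at <- classify_urine_culture(urine_of(isolate("escherichia coli", 1000)))
  expect_equal(at$status, "significant")
})

test_that("unknown species are demoted to flora with a warning", {
  expect_warning(
    st <- classify_urine_culture(urine_of(isolate("mystery organism", 1e5))),
    "mystery organism"
  )
  expect_equal(st$status, "contaminated")
})

test_that("blood-culture adjudication matches exhaustive enumeration of the rule table", {
  # independent oracle: organism group x positive-set count x device
  oracle <- function(is_review, n_pos, device) {
    if (n_pos == 0) return("none")
    if (!is_review) return("true_bacteraemia")
    if (n_pos >= 2 || device) "true_bacteraemia" else "contaminant_only"
  }
  for (species in c("escherichia coli", "coagulase-negative staphylococci",
                    "viridans streptococci", "streptococcus pneumoniae")) {
    is_review <- species %in% c("coagulase-negative staphylococci", "viridans streptococci")
    for (n_pos in 0:2) {
      for (device in c(FALSE, TRUE)) {
        sets <- if (n_pos == 0) neg_sets() else blood_sets(species, n_positive = n_pos)
        enc <- enc_of(bc = sets, device = device)
        got <- adjudicate_blood_cultures(sets, enc)
        expect_equal(
          got$status, oracle(is_review, n_pos, device),
          info = sprintf("%s pos=%d device=%s", species, n_pos, device)
        )
      }
    }
  }
})

test_that("adjudication requires at least one blood-culture set", {
  expect_error(adjudicate_blood_cultures(list(), enc_of()), "at least one")
})

test_that("accordance is the shared organism between urine and blood", {
  urine_ec <- classify_urine_culture(urine_of(isolate("escherichia coli", 1e5)))
  urine_mix <- classify_urine_culture(urine_of(
    isolate("escherichia coli", 1e5), isolate("enterococcus faecalis", 1e4)
  ))

  enc <- enc_of()
  bl_ec <- adjudicate_blood_cultures(blood_sets("escherichia coli"), enc)
  out <- assess_accordance(urine_ec, bl_ec)
  expect_equal(out$accordance, "accordant")
  expect_equal(out$dominant_uropathogen, "escherichia coli")

  # mixed bacteriuria: blood culture identifies the dominant uropathogen
  out2 <- assess_accordance(urine_mix, bl_ec)
  expect_equal(out2$accordance, "accordant")
  expect_equal(out2$dominant_uropathogen, "escherichia coli")

  urine_ef <- classify_urine_culture(urine_of(isolate("enterococcus faecalis", 1e4)))
  bl_sp <- adjudicate_blood_cultures(blood_sets("streptococcus pneumoniae"), enc)
  out3 <- assess_accordance(urine_ef, bl_sp)
  expect_equal(out3$accordance, "discordant")
  expect_true(is.na(out3$dominant_uropathogen))

  bl_none <- adjudicate_blood_cultures(neg_sets(), enc)
  expect_equal(assess_accordance(urine_ec, bl_none)$accordance, "not_applicable")

  sterile <- classify_urine_culture(urine_of())
  expect_error(assess_accordance(sterile, bl_ec), "significant")
})

test_that("accordant and discordant statuses are mutually exclusive consequences of true bacteraemia", {
  cl <- fixture_classified()
  a <- analyzed_rows(cl)
  expect_true(all(a$bact_status[a$accordance %in% c("accordant", "discordant")] ==
                    "true_bacteraemia"))
  expect_true(all(a$accordance[a$bact_status != "true_bacteraemia"] == "not_applicable"))
})

test_that("per-organism accordance fractions are direct counts", {
  encs <- list(
    enc_of("t1", bc = blood_sets("escherichia coli")),
    enc_of("t2", bc = blood_sets("escherichia coli")),
    enc_of("t3", bc = blood_sets("streptococcus pneumoniae")),  # discordant
    enc_of("t4", urine = urine_of(isolate("enterococcus faecalis", 1e4)))  # never bacteraemic
  )
  tab <- organism_accordance_table(classify_cohort(as_cohort(encs)))
  ec <- tab[tab$species == "escherichia coli", ]
  expect_equal(ec$n_bacteraemic, 3L)
  expect_equal(ec$n_accordant, 2L)
  expect_equal(ec$accordance, 2 / 3)
  expect_false("enterococcus faecalis" %in% tab$species)
})
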
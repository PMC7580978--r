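# deterministic seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build the deterministic 403-record fixture cohort
#'
#' Constructs one admissible cohort of raw encounter records (220 removed
#' by the urine-culture inclusion filter, 183 analyzable) such that running
#' the full pipeline -- significance filtering, blood-culture adjudication,
#' accordance, triple-F scoring, classification, accuracy statistics and
#' stewardship simulation -- reproduces every hard constraint of the
#' printed-count ledger exactly. The builder writes raw clinical fields
#' only; no diagnosis labels are stored, so the round trip through
#' [classify_cohort()] is a genuine end-to-end check. The seed controls
#' only presentation-level arrangement (record order); the aggregate counts
#' are identical for every seed.
#'
#' @param constraints Ledger from [default_constraints()]; an arithmetic
#'   audit failure aborts the build naming the violated relation.
#' @param seed Integer seed.
#' @return A `tf_cohort` of 403 encounters with attribute
#'   `"assignment_log"`, a data frame describing the construction blocks.
#' @export
build_fixture_cohort <- function(constraints = default_constraints(), seed = 1L) {
  bad <- audit_constraints(constraints)
  if (length(bad)) {
    stop("constraint ledger is internally inconsistent: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }

  ecoli <- "escherichia coli"; kpneu <- "klebsiella pneumoniae"
  pmira <- "proteus mirabilis"; efaecalis <- "enterococcus faecalis"
  efaecium <- "enterococcus faecium"; paerug <- "pseudomonas aeruginosa"
  saureus <- "staphylococcus aureus"; sapro <- "staphylococcus saprophyticus"
  mmorg <- "morganella morganii"; ecloa <- "enterobacter cloacae"
  spneu <- "streptococcus pneumoniae"; bfrag <- "bacteroides fragilis"

  neg_sets <- function() list(
    list(set_id = "S1", isolates = list()),
    list(set_id = "S2", isolates = list())
  )
  pos_sets <- function(species, mrsa = NA, n_positive = 2L) {
    iso <- function() lapply(species, function(s) isolate(s, NA_real_, if (s == saureus) mrsa else NA))
    sets <- neg_sets()
    for (k in seq_len(n_positive)) sets[[k]]$isolates <- iso()
    sets
  }
  urine <- function(..., method = "midstream") {
    list(collection_method = method, isolates = list(...))
  }

  encs <- list()
  log <- list()
  add <- function(enc, block) {
    encs[[length(encs) + 1L]] <<- enc
    log[[length(log) + 1L]] <<- block
  }

  # ---- bacteremic SUTI: accordant true bacteraemia (44) ------------------
  b_urine <- c(rep(ecoli, 30), rep(kpneu, 6), rep(pmira, 4), rep(efaecalis, 2), rep(paerug, 2))
  for (i in 1:44) {
    sp <- b_urine[i]
    u <- if (i <= 6) {
      urine(isolate(ecoli, 1e5), isolate(efaecalis, 1e4))
    } else {
      urine(isolate(sp, 1e5), method = if (i %in% 31:36) "single_catheter" else "midstream")
    }
    gu <- if (i %in% 25:34) "dysuria" else if (i %in% 35:44) "flank_pain" else character()
    add(encounter(
      encounter_id = sprintf("B%02d", i),
      age_years = 55 + (i %% 40), sex = "female",  # sex rewritten below
      fever_at_triage = i <= 38,
      organ_dysfunctions = if (i %in% 8:38) "kidney" else character(),
      gu_symptoms = gu,
      pct_ng_ml = if (i <= 2) 0.15 else 2.4,
      urine_culture = u,
      blood_culture_sets = pos_sets(sp),
      urinary_catheter = i %in% 31:36
    ), "bacteremic_suti")
  }

  # ---- S. aureus bacteraemia with S. aureus bacteriuria (5) --------------
  for (i in 1:5) {
    mrsa <- i == 5
    add(encounter(
      encounter_id = sprintf("S%02d", i),
      age_years = 60 + i, sex = "female",
      fever_at_triage = i <= 2,
      organ_dysfunctions = "circulation",
      gu_symptoms = if (i == 1) "flank_pain" else character(),
      pct_ng_ml = 1.8,
      urine_culture = urine(isolate(saureus, 1e5, mrsa)),
      blood_culture_sets = pos_sets(saureus, mrsa = mrsa)
    ), "sa_alt_focus")
  }

  # ---- probable SUTI (26): GU symptoms + systemic, no focus, BC negative -
  p_urine <- c(rep(kpneu, 10), rep(pmira, 6), rep(efaecalis, 6), rep(sapro, 4))
  for (i in 1:26) {
    add(encounter(
      encounter_id = sprintf("P%02d", i),
      age_years = 40 + (i %% 45), sex = "female",
      fever_at_triage = i <= 24,
      chills_or_rigors_reported = i <= 5,
      organ_dysfunctions = if (i >= 10) "circulation" else character(),
      gu_symptoms = if (i <= 13) "dysuria" else "flank_pain",
      pct_ng_ml = if (i <= 15) 0.05 else 1.0,
      urine_culture = urine(isolate(p_urine[i], 1e4)),
      blood_culture_sets = neg_sets()
    ), "probable_suti")
  }

  # ---- possible SUTI (51) ------------------------------------------------
  # O01..O06: discordant bacteraemia establishes the alternative focus
  # (GU symptoms + systemic); O07..O51: no GU symptoms, systemic, no focus.
  o_urine <- c(rep(efaecalis, 4), rep(ecoli, 2), rep(ecoli, 30),
               rep(kpneu, 6), rep(pmira, 3), rep(efaecium, 3), rep(mmorg, 2), sapro)
  o_blood <- c(rep(spneu, 3), rep(bfrag, 3))
  for (i in 1:51) {
    discordant <- i <= 6
    u <- if (i %in% 7:26) {
      urine(isolate(ecoli, 1e5), isolate(efaecalis, 1e4))
    } else {
      urine(isolate(o_urine[i], if (o_urine[i] == ecoli) 1e5 else 1e4))
    }
    add(encounter(
      encounter_id = sprintf("O%02d", i),
      age_years = 45 + (i %% 45), sex = "female",
      fever_at_triage = i <= 44,
      organ_dysfunctions = if (i >= 19) "brain" else character(),
      gu_symptoms = if (discordant) "dysuria" else character(),
      pct_ng_ml = if (discordant && i <= 2) 0.15
                  else if (discordant) 2.0
                  else if (i %in% 7:18) 0.05 else 0.6,
      urine_culture = u,
      blood_culture_sets = if (discordant) pos_sets(o_blood[i]) else neg_sets()
    ), "possible_suti")
  }

  # ---- urocystitis (1): lower GU symptoms, no systemic features ----------
  add(encounter(
    encounter_id = "U01", age_years = 34, sex = "female",
    gu_symptoms = c("dysuria", "urgency"),
    pct_ng_ml = 0.15,
    urine_culture = urine(isolate(ecoli, 1e5)),
    blood_culture_sets = neg_sets()
  ), "urocystitis")

  # ---- ABU (56) ----------------------------------------------------------
  # A01..A10 discordant bacteraemia (focus from blood); A11..A42 documented
  # focus; A43..A48 score 0 + PCT < 0.25 (no focus, non-systemic);
  # A49..A56 score 0 + PCT >= 0.25 with documented focus.
  a_urine <- c(rep(ecoli, 31), rep(kpneu, 8), rep(pmira, 5), rep(efaecium, 4),
               rep(efaecalis, 5), rep(mmorg, 2), ecloa)
  a_blood <- c(rep(bfrag, 5), rep(spneu, 5))
  a_focus <- c(rep("none", 10), rep("pneumonia", 20), rep("port_infection", 9),
               rep("ssti", 3), rep("none", 6), rep("ssti", 4), rep("influenza", 4))
  stopifnot(length(a_focus) == 56)
  for (i in 1:56) {
    u <- if (i %in% 26:31) {
      urine(isolate(ecoli, 1e5), isolate(efaecalis, 1e4))
    } else {
      urine(isolate(a_urine[i], if (a_urine[i] == ecoli) 1e5 else 1e4),
            method = if (i %in% 40:44) "indwelling_at_replacement" else "midstream")
    }
    bc <- if (i <= 10) {
      pos_sets(a_blood[i])
    } else if (i == 20) {
      pos_sets("coagulase-negative staphylococci", n_positive = 1L)  # single-set contaminant
    } else if (i == 21) {
      pos_sets("viridans streptococci", n_positive = 1L)             # single-set contaminant
    } else {
      neg_sets()
    }
    add(encounter(
      encounter_id = sprintf("A%02d", i),
      age_years = 60 + (i %% 35), sex = "female",
      fever_at_triage = i <= 32,
      organ_dysfunctions = if (i %in% 14:42) "functional_decline_elderly" else character(),
      pct_ng_ml = if (i <= 2) 0.15
                  else if (i <= 10) 0.9
                  else if (i <= 29) 0.8
                  else if (i == 30) 0.05
                  else if (i <= 42) 0.15
                  else if (i <= 48) 0.05 else 0.6,
      urine_culture = u,
      blood_culture_sets = bc,
      intravascular_device = a_focus[i] == "port_infection",
      urinary_catheter = i %in% 40:44,
      documented_alt_focus = a_focus[i]
    ), "abu")
  }

  # analyzable sexes: alternate, trimmed to 91 female
  sexes <- rep(c("female", "male"), length.out = length(encs))
  sexes[length(encs)] <- "male"
  stopifnot(sum(sexes == "female") == 91)
  for (i in seq_along(encs)) encs[[i]]$sex <- sexes[i]

  # ---- screened-out records (220): sterile and contaminated cultures -----
  for (i in 1:220) {
    u <- if (i <= 138) {
      urine()
    } else if (i <= 163) {
      urine(isolate("lactobacillus spp", 1e4))
    } else if (i <= 188) {
      urine(isolate("mixed skin flora", 1e3))
    } else if (i <= 208) {
      urine(isolate(ecoli, 1e4), isolate(kpneu, 1e4), isolate(efaecalis, 1e4))
    } else {
      urine(isolate(ecoli, 500))  # uropathogen below the CFU threshold
    }
    add(encounter(
      encounter_id = sprintf("X%03d", i),
      age_years = 40 + (i %% 50),
      sex = if (i %% 2 == 0) "female" else "male",
      fever_at_triage = i %% 3 == 0,
      organ_dysfunctions = if (i %% 4 == 0) "kidney" else character(),
      pct_ng_ml = 0.3,
      urine_culture = u,
      blood_culture_sets = neg_sets()
    ), if (i <= 138) "excluded_sterile" else "excluded_contaminated")
  }

  blocks <- unlist(log)
  ord <- with_seed(seed, sample(length(encs)))
  cohort <- as_cohort(encs[ord])
  attr(cohort, "assignment_log") <- as.data.frame(table(block = blocks),
                                                  stringsAsFactors = FALSE)
  cohort
}
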
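#' Default generative parameters for the stochastic cohort sampler
#'
#' The statistical structure the analysis assumes, calibrated once from the
#' published cohort: diagnosis-category prevalences, conditional Bernoulli
#' rates for the three criteria given the latent category, per-organism
#' accordance probabilities, a urine-organism frequency table, documented
#' alternative-focus rates and labels, and procalcitonin log-normal
#' mixture components by bacteraemia status (bacteraemic: median 0.95
#' ng/mL, sdlog 1; non-bacteraemic: meanlog -0.601, sdlog 3.04 -- matching
#' the published fractions below 0.25 and 0.1 ng/mL).
#'
#' @return A list of class `tf_gen_params`.
#' @export
default_generative_params <- function() {
  p <- list(
    diagnosis_probs = c(bacteremic = 44, probable = 26, possible = 51,
                        urocystitis = 1, abu = 56, sa_alt_focus = 5) / 183,
    f_rates = rbind(
      bacteremic   = c(f1 = 38 / 44, f2 = 31 / 44, f3 = 20 / 44),
      probable     = c(f1 = 24 / 26, f2 = 17 / 26, f3 = 1),
      possible     = c(f1 = 44 / 51, f2 = 33 / 51, f3 = 6 / 51),
      urocystitis  = c(f1 = 0, f2 = 0, f3 = 1),
      abu          = c(f1 = 32 / 56, f2 = 29 / 56, f3 = 0),
      sa_alt_focus = c(f1 = 2 / 5, f2 = 1, f3 = 1 / 5)
    ),
    pct_lognormal = list(
      bacteraemic = c(meanlog = log(0.95), sdlog = 1),
      non_bacteraemic = c(meanlog = -0.601, sdlog = 3.04)
    ),
    urine_organism_freq = c(
      "escherichia coli" = 0.514,
      "klebsiella pneumoniae" = 0.120,
      "enterococcus faecalis" = 0.100,
      "proteus mirabilis" = 0.080,
      "enterococcus faecium" = 0.040,
      "pseudomonas aeruginosa" = 0.040,
      "morganella morganii" = 0.030,
      "staphylococcus saprophyticus" = 0.030,
      "enterobacter cloacae" = 0.046
    ),
    accordance_probs = c(
      "escherichia coli" = 0.853,
      "proteus mirabilis" = 0.60,
      "klebsiella pneumoniae" = 0.50,
      "pseudomonas aeruginosa" = 0.50,
      "enterococcus faecalis" = 0.167,
      "enterococcus faecium" = 0.0
    ),
    accordance_default = 0.5,
    discordant_blood = c("streptococcus pneumoniae", "bacteroides fragilis",
                         "streptococcus pyogenes"),
    mixed_fraction = 0.175,
    focus_prob = c(bacteremic = 0, probable = 0, possible = 0, urocystitis = 0,
                   abu = 40 / 56, sa_alt_focus = 0),
    focus_labels = c(pneumonia = 20, port_infection = 9, ssti = 7, influenza = 4) / 40,
    female_prob = 91 / 183
  )
  structure(p, class = "tf_gen_params")
}

validate_gen_params <- function(params) {
  probs <- c(params$diagnosis_probs, params$urine_organism_freq,
             params$accordance_probs, params$focus_labels,
             as.vector(params$f_rates), params$mixed_fraction,
             params$focus_prob, params$female_prob, params$accordance_default)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(params$diagnosis_probs) - 1) > 1e-8) {
    stop("diagnosis probabilities must sum to 1", call. = FALSE)
  }
  if (abs(sum(params$urine_organism_freq) - 1) > 1e-8) {
    stop("urine organism frequencies must sum to 1", call. = FALSE)
  }
  invisible(params)
}

#' Sample a stochastic cohort of raw encounter records
#'
#' Independent draws from the generative model: a latent diagnosis-type
#' category, conditional fever/failure/focus indicators, genitourinary
#' symptoms, urine organisms, bacteraemia with per-organism accordance,
#' documented alternative foci and a procalcitonin log-normal mixture.
#' Only raw fields are written; the classification pipeline re-derives all
#' labels. Bacteraemic draws receive a pure (single-organism) urine
#' culture so that the per-organism accordance probability is exactly the
#' quantity [organism_accordance_table()] estimates; mixed two-pathogen
#' cultures occur among non-bacteraemic draws.
#'
#' @param params A `tf_gen_params`, see [default_generative_params()].
#' @param n Number of encounters (>= 1).
#' @param seed Integer seed; the caller's RNG state is restored.
#' @return A `tf_cohort` of `n` encounters with attribute `"latent"`, the
#'   character vector of latent categories (diagnostic metadata for
#'   parameter-recovery checks; the pipeline never sees it).
#' @export
sample_cohort <- function(params = default_generative_params(), n, seed = 1L) {
  validate_gen_params(params)
  stopifnot(n >= 1)
  cats <- names(params$diagnosis_probs)
  saureus <- "staphylococcus aureus"

  with_seed(seed, {
    latent <- sample(cats, n, replace = TRUE, prob = params$diagnosis_probs)
    encs <- vector("list", n)
    for (i in seq_len(n)) {
      lat <- latent[i]
      r <- params$f_rates[lat, ]
      f1 <- stats::runif(1) < r["f1"]
      f2 <- stats::runif(1) < r["f2"]
      f3 <- stats::runif(1) < r["f3"]
      gu <- if (f3) {
        if (lat == "urocystitis" || stats::runif(1) < 0.5) "dysuria" else "flank_pain"
      } else {
        character()
      }
      bacteraemic <- lat %in% c("bacteremic", "sa_alt_focus")
      if (lat == "sa_alt_focus") {
        org <- saureus
        blood <- saureus
      } else {
        org <- sample(names(params$urine_organism_freq), 1,
                      prob = params$urine_organism_freq)
        blood <- if (bacteraemic) {
          p_acc <- params$accordance_probs[org]
          if (is.na(p_acc)) p_acc <- params$accordance_default
          if (stats::runif(1) < p_acc) org else sample(params$discordant_blood, 1)
        } else {
          NA_character_
        }
      }
      mixed <- !bacteraemic && org != saureus && stats::runif(1) < params$mixed_fraction
      second <- if (mixed) {
        pool <- setdiff(names(params$urine_organism_freq), org)
        sample(pool, 1, prob = params$urine_organism_freq[pool])
      } else {
        NA_character_
      }
      pct_par <- if (bacteraemic) params$pct_lognormal$bacteraemic else params$pct_lognormal$non_bacteraemic
      pct <- stats::rlnorm(1, pct_par["meanlog"], pct_par["sdlog"])
      focus <- if (stats::runif(1) < params$focus_prob[lat]) {
        sample(names(params$focus_labels), 1, prob = params$focus_labels)
      } else {
        "none"
      }
      isolates <- list(isolate(org, 10^stats::runif(1, 4, 6)))
      if (!is.na(second)) isolates <- c(isolates, list(isolate(second, 10^stats::runif(1, 3, 5))))
      bc <- list(
        list(set_id = "S1", isolates = if (!is.na(blood)) list(isolate(blood)) else list()),
        list(set_id = "S2", isolates = if (!is.na(blood)) list(isolate(blood)) else list())
      )
      encs[[i]] <- encounter(
        encounter_id = sprintf("SIM%06d", i),
        age_years = round(stats::runif(1, 18, 95)),
        sex = if (stats::runif(1) < params$female_prob) "female" else "male",
        fever_at_triage = f1,
        organ_dysfunctions = if (f2) sample(tf_enums()$organ_dysfunctions, 1) else character(),
        gu_symptoms = gu,
        pct_ng_ml = round(pct, 3),
        urine_culture = list(collection_method = "midstream", isolates = isolates),
        blood_culture_sets = bc,
        intravascular_device = focus == "port_infection",
        documented_alt_focus = focus
      )
    }
    cohort <- as_cohort(encs)
    attr(cohort, "latent") <- latent
    cohort
  })
}
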
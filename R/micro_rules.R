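#' Classify a urine culture as significant, sterile or contaminated
#'
#' Quantitative urine cultures are significant when a uropathogen grows at
#' or above the CFU threshold (default 10^3 CFU/mL) in pure culture or in a
#' mixed culture of no more than two pathogenic species. Cultures growing
#' only urogenital flora, more than two pathogenic species, or pathogens
#' all below the threshold are contaminated; no growth is sterile.
#'
#' @param uc Urine culture: a list with `collection_method` and `isolates`.
#' @param vocab Organism vocabulary ([default_organisms()]).
#' @param cfu_threshold Significance threshold in CFU/mL (default `1000`).
#' @return A list of class `tf_urine_status` with `status` (one of
#'   `"significant"`, `"sterile"`, `"contaminated"`) and
#'   `significant_isolates` (at most two qualifying uropathogen isolates).
#' @export
#' @examples
#' uc <- list(collection_method = "midstream",
#'            isolates = list(isolate("Escherichia coli", 1e5)))
#' classify_urine_culture(uc)$status
classify_urine_culture <- function(uc, vocab = default_organisms(), cfu_threshold = 1000) {
  isolates <- uc$isolates
  if (length(isolates) == 0L) {
    return(structure(list(status = "sterile", significant_isolates = list()),
                     class = "tf_urine_status"))
  }
  cls <- organism_class(vapply(isolates, function(i) i$species, character(1)), vocab)
  if (any(cls == "unknown")) {
    warning(sprintf(
      "species not in vocabulary treated as flora: %s",
      paste(unique(vapply(isolates[cls == "unknown"], function(i) i$species, character(1))),
            collapse = ", ")
    ), call. = FALSE)
    cls[cls == "unknown"] <- "flora"
  }
  pathogens <- isolates[cls == "uropathogen"]
  n_species <- length(unique(vapply(pathogens, function(i) i$species, character(1))))
  qualifying <- Filter(function(i) !is.na(i$cfu_per_ml) && i$cfu_per_ml >= cfu_threshold, pathogens)
  status <- if (n_species == 0L || n_species > 2L || length(qualifying) == 0L) {
    "contaminated"
  } else {
    "significant"
  }
  structure(
    list(
      status = status,
      significant_isolates = if (status == "significant") qualifying else list()
    ),
    class = "tf_urine_status"
  )
}

#' Adjudicate blood-culture sets for true bacteraemia vs contamination
#'
#' Any organism outside the contaminant-review groups (coagulase-negative
#' staphylococci, viridans streptococci) in at least one set is accepted as
#' true bacteraemia. Review-group organisms count as true only when grown
#' in two or more sets, or in at least one set with an intravascular device
#' in place; otherwise they are contamination. Accordance with the urine
#' culture is not assessed here; see [assess_accordance()].
#'
#' @param sets List of blood-culture sets (each `list(set_id, isolates)`);
#'   at least one set is required (paired sampling is an inclusion
#'   criterion).
#' @param enc The encounter, supplying the intravascular-device flag.
#' @param vocab Organism vocabulary.
#' @param review_min_sets Number of positive sets at which a review-group
#'   organism is accepted without a device (default `2`).
#' @return A list of class `tf_bact` with `status` (`"none"`,
#'   `"contaminant_only"`, `"true_bacteraemia"`), `organisms` (true
#'   positives only, sorted), `accordance` (`"not_applicable"` until
#'   [assess_accordance()] fills it) and `dominant_uropathogen` (`NA`).
#' @export
adjudicate_blood_cultures <- function(sets, enc, vocab = default_organisms(),
                                      review_min_sets = 2L) {
  if (length(sets) == 0L) {
    stop("at least one blood-culture set is required per encounter", call. = FALSE)
  }
  per_set <- lapply(sets, function(s) {
    unique(vapply(s$isolates, function(i) i$species, character(1)))
  })
  all_species <- unique(unlist(per_set))
  if (length(all_species) == 0L) {
    return(structure(
      list(status = "none", organisms = character(),
           accordance = "not_applicable", dominant_uropathogen = NA_character_),
      class = "tf_bact"
    ))
  }
  review <- normalize_species(vocab$contaminant_review)
  true_orgs <- character()
  for (sp in all_species) {
    n_pos <- sum(vapply(per_set, function(x) sp %in% x, logical(1)))
    is_true <- if (sp %in% review) {
      n_pos >= review_min_sets || (n_pos >= 1L && isTRUE(enc$intravascular_device))
    } else {
      n_pos >= 1L
    }
    if (is_true) true_orgs <- c(true_orgs, sp)
  }
  status <- if (length(true_orgs)) "true_bacteraemia" else "contaminant_only"
  structure(
    list(status = status, organisms = sort(true_orgs),
         accordance = "not_applicable", dominant_uropathogen = NA_character_),
    class = "tf_bact"
  )
}

#' Assess accordance of blood and urine culture results
#'
#' Accordance means the same microorganism was isolated from the
#' significant urine culture and the blood cultures; the shared organism is
#' reported as the dominant uropathogen (when the urine grew two pathogens,
#' the blood culture identifies which one drives the bacteraemia). True
#' bacteraemia with no shared organism is discordant: the bloodstream
#' isolate points to a non-urinary source.
#'
#' @param urine A `tf_urine_status` with `status == "significant"`.
#' @param blood A `tf_bact` from [adjudicate_blood_cultures()].
#' @return The `tf_bact` with `accordance` set to `"accordant"`,
#'   `"discordant"` or `"not_applicable"` (no true bacteraemia) and
#'   `dominant_uropathogen` filled when accordant.
#' @export
assess_accordance <- function(urine, blood) {
  if (!identical(urine$status, "significant")) {
    stop("accordance is only defined for significant urine cultures", call. = FALSE)
  }
  if (!identical(blood$status, "true_bacteraemia")) {
    blood$accordance <- "not_applicable"
    blood$dominant_uropathogen <- NA_character_
    return(blood)
  }
  urine_species <- vapply(urine$significant_isolates, function(i) i$species, character(1))
  shared <- intersect(blood$organisms, urine_species)
  if (length(shared)) {
    blood$accordance <- "accordant"
    # when both urine pathogens appear in blood, the higher-CFU one leads
    cfu <- vapply(urine$significant_isolates, function(i) i$cfu_per_ml, numeric(1))
    ord <- urine_species[order(-cfu)]
    blood$dominant_uropathogen <- ord[ord %in% shared][1]
  } else {
    blood$accordance <- "discordant"
    blood$dominant_uropathogen <- NA_character_
  }
  blood
}

#' Per-organism accordance of bacteraemia in bacteriuric encounters
#'
#' For each uropathogen present in significant urine cultures, computes the
#' fraction of encounters with that organism and any true bacteraemia in
#' which the same organism was also grown from blood. Organisms never seen
#' together with a true bacteraemia are omitted (zero denominator).
#'
#' @param classified Output of [classify_cohort()].
#' @return Data frame with columns `species`, `n_bacteraemic` (denominator),
#'   `n_accordant` (numerator) and `accordance` (fraction).
#' @export
organism_accordance_table <- function(classified) {
  details <- attr(classified, "details")
  analyzed <- Filter(function(d) !startsWith(d$category, "EXCLUDED"), details)
  tab <- list()
  for (d in analyzed) {
    if (!identical(d$bacteraemia$status, "true_bacteraemia")) next
    urine_species <- vapply(d$urine$significant_isolates, function(i) i$species, character(1))
    for (sp in unique(urine_species)) {
      cur <- tab[[sp]] %||% c(denom = 0, num = 0)
      cur["denom"] <- cur["denom"] + 1
      if (sp %in% d$bacteraemia$organisms) cur["num"] <- cur["num"] + 1
      tab[[sp]] <- cur
    }
  }
  if (!length(tab)) {
    return(data.frame(species = character(), n_bacteraemic = integer(),
                      n_accordant = integer(), accordance = numeric()))
  }
  out <- data.frame(
    species = names(tab),
    n_bacteraemic = vapply(tab, function(x) as.integer(x["denom"]), integer(1)),
    n_accordant = vapply(tab, function(x) as.integer(x["num"]), integer(1)),
    stringsAsFactors = FALSE
  )
  out$accordance <- out$n_accordant / out$n_bacteraemic
  rownames(out) <- NULL
  out[order(-out$n_bacteraemic, out$species), , drop = FALSE]
}
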
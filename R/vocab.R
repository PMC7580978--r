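#' Default organism vocabulary
#'
#' Controlled vocabulary used throughout the package to decide whether an
#' isolate counts as a uropathogen, as urogenital/skin flora, or as a
#' non-urinary pathogen. The uropathogen list follows the classical clinical
#' microbiology convention (Enterobacterales, \emph{S. saprophyticus},
#' \emph{S. aureus}, enterococci, \emph{P. aeruginosa}); the
#' `contaminant_review` entry names the organism groups (coagulase-negative
#' staphylococci, viridans-group streptococci) whose presence in blood
#' cultures triggers the contaminant-adjudication rule rather than being
#' accepted as true bacteraemia outright.
#'
#' @return A list with character vectors `uropathogens`, `flora`,
#'   `other_pathogens` and `contaminant_review`. All names are lower case;
#'   [organism_class()] normalizes queries the same way.
#' @seealso [organism_class()], [classify_urine_culture()],
#'   [adjudicate_blood_cultures()]
#' @export
#' @examples
#' vocab <- default_organisms()
#' organism_class("Escherichia coli", vocab)
default_organisms <- function() {
  list(
    uropathogens = c(
      "escherichia coli",
      "staphylococcus saprophyticus",
      "klebsiella pneumoniae",
      "klebsiella oxytoca",
      "enterobacter cloacae",
      "proteus mirabilis",
      "proteus vulgaris",
      "morganella morganii",
      "staphylococcus aureus",
      "enterococcus faecalis",
      "enterococcus faecium",
      "pseudomonas aeruginosa",
      "citrobacter koseri"
    ),
    flora = c(
      "lactobacillus spp",
      "diphtheroids",
      "coagulase-negative staphylococci",
      "viridans streptococci",
      "gardnerella vaginalis",
      "mixed skin flora"
    ),
    other_pathogens = c(
      "streptococcus pneumoniae",
      "streptococcus pyogenes",
      "bacteroides fragilis",
      "listeria monocytogenes"
    ),
    contaminant_review = c(
      "coagulase-negative staphylococci",
      "viridans streptococci"
    )
  )
}

#' Normalize a species string
#'
#' Lower-cases and squeezes whitespace so that vocabulary lookups are
#' insensitive to capitalization and stray spaces.
#'
#' @param species Character vector of organism names.
#' @return Normalized character vector.
#' @export
normalize_species <- function(species) {
  out <- tolower(trimws(species))
  gsub("[[:space:]]+", " ", out)
}

#' Classify an organism name against the vocabulary
#'
#' @param species Character vector of organism names.
#' @param vocab Vocabulary list as returned by [default_organisms()].
#' @return Character vector with values `"uropathogen"`, `"flora"`,
#'   `"other_pathogen"` or `"unknown"`.
#' @export
organism_class <- function(species, vocab = default_organisms()) {
  s <- normalize_species(species)
  out <- rep("unknown", length(s))
  out[s %in% normalize_species(vocab$other_pathogens)] <- "other_pathogen"
  out[s %in% normalize_species(vocab$flora)] <- "flora"
  out[s %in% normalize_species(vocab$uropathogens)] <- "uropathogen"
  out
}

# controlled enumerations used by the encounter constructor / validator
tf_enums <- function() {
  list(
    sex = c("female", "male"),
    organ_dysfunctions = c(
      "brain", "kidney", "circulation", "heart", "liver",
      "gi_tract", "metabolism", "functional_decline_elderly"
    ),
    gu_symptoms = c(
      "dysuria", "urgency", "frequency", "suprapubic_tenderness", "flank_pain"
    ),
    collection_method = c("midstream", "single_catheter", "indwelling_at_replacement"),
    documented_alt_focus = c("none", "pneumonia", "port_infection", "ssti", "influenza", "other"),
    category = c(
      "BACTEREMIC_SUTI", "PROBABLE_SUTI", "POSSIBLE_SUTI", "UROCYSTITIS",
      "ABU", "SA_ALT_FOCUS", "EXCLUDED_STERILE", "EXCLUDED_CONTAMINATION"
    )
  )
}

# lower genitourinary tract symptoms; flank pain is the upper-tract symptom
tf_lower_gu <- function() c("dysuria", "urgency", "frequency", "suprapubic_tenderness")
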
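# Controlled vocabularies shared across the roster reader and the
# diversity/composition metrics.

#' Racial category vocabulary
#'
#' The controlled set of racial categories used throughout the package.
#' Multi-category selections are retained as sets on the record and collapsed
#' to `"Mixed/Biracial"` only where a single discrete category per alter is
#' required (entropy profiles); E-I sameness coding compares the full sets.
#'
#' @return Character vector of canonical category names.
#' @export
race_categories <- function() {
  c("African/Black-American",
    "Asian/Asian-American",
    "European/White-American",
    "Hispanic/Latino-American",
    "Native American",
    "Mixed/Biracial",
    "Other")
}

# alias table: lower-cased, punctuation-stripped token -> canonical category
.race_aliases <- local({
  canon <- c(
    "African/Black-American" = "African/Black-American",
    "african or black-american" = "African/Black-American",
    "african american" = "African/Black-American",
    "black" = "African/Black-American",
    "black-american" = "African/Black-American",
    "asian" = "Asian/Asian-American",
    "asian or asian-american" = "Asian/Asian-American",
    "asian-american" = "Asian/Asian-American",
    "white" = "European/White-American",
    "european or white-american" = "European/White-American",
    "white-american" = "European/White-American",
    "european" = "European/White-American",
    "caucasian" = "European/White-American",
    "hispanic" = "Hispanic/Latino-American",
    "latino" = "Hispanic/Latino-American",
    "latina" = "Hispanic/Latino-American",
    "latino/a" = "Hispanic/Latino-American",
    "hispanic or latino-american" = "Hispanic/Latino-American",
    "hispanic or latino/a-american" = "Hispanic/Latino-American",
    "native american" = "Native American",
    "american indian" = "Native American",
    "mixed" = "Mixed/Biracial",
    "biracial" = "Mixed/Biracial",
    "mixed or biracial" = "Mixed/Biracial",
    "multiracial" = "Mixed/Biracial",
    "other" = "Other")
  full <- race_categories()
  names(full) <- tolower(full)
  c(canon, full)
})

normalize_token <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Normalize race tokens to the canonical vocabulary
#'
#' @param tokens character vector of race labels (any common spelling).
#' @return character vector of canonical categories.
#' @keywords internal
normalize_races <- function(tokens) {
  key <- normalize_token(tokens)
  hit <- .race_aliases[key]
  bad <- is.na(hit)
  if (any(bad)) {
    stop(sprintf(
      "unknown race token(s): %s; expected one of: %s",
      paste(unique(tokens[bad]), collapse = ", "),
      paste(race_categories(), collapse = ", ")), call. = FALSE)
  }
  unname(unique(hit))
}

#' Collapse a multi-category race set to a single discrete category
#'
#' Alters (or egos) reported with more than one racial category are treated as
#' a single `"Mixed/Biracial"` category wherever one discrete category per
#' person is needed, e.g. when building an entropy profile.  A singleton set
#' is returned unchanged.
#'
#' @param races character vector: a person's set of canonical race categories.
#' @return length-1 character category, or `NA_character_` for an empty set.
#' @export
collapse_races <- function(races) {
  races <- races[!is.na(races)]
  if (length(races) == 0L) return(NA_character_)
  if (length(races) > 1L) "Mixed/Biracial" else races
}

#' Language-composition categories
#'
#' Each alter is mapped to one discrete language category for the language
#' entropy profile: monolingual English speakers, English bilinguals,
#' monolingual speakers of another language, multilinguals without English,
#' and preverbal infants (who speak no language yet).
#'
#' @return Character vector of category names.
#' @export
language_categories <- function() {
  c("English-monolingual", "English-bilingual",
    "non-English-monolingual", "other-multilingual", "preverbal")
}

#' Classify one alter's language set into a discrete category
#'
#' @param languages character vector of language names (possibly empty).
#' @param preverbal logical; `TRUE` for an infant who does not yet speak.
#' @return One of [language_categories()], or `NA_character_` when the
#'   language data is missing (neither languages nor a preverbal flag).
#' @export
language_category <- function(languages, preverbal = FALSE) {
  if (isTRUE(preverbal)) return("preverbal")
  languages <- languages[!is.na(languages) & nzchar(languages)]
  if (length(languages) == 0L) return(NA_character_)
  eng <- any(normalize_token(languages) == "english")
  if (eng && length(languages) == 1L) return("English-monolingual")
  if (eng) return("English-bilingual")
  if (length(languages) == 1L) return("non-English-monolingual")
  "other-multilingual"
}

#' Default relationship taxonomy
#'
#' Maps relationship labels to a kin flag.  Kin is any relationship in the
#' immediate or extended family: parents, siblings, grandparents, aunts,
#' uncles, cousins and their step/half/in-law variants.  Teachers, friends,
#' babysitters, neighbors and other non-family contacts are non-kin.
#' The table can be replaced or extended with [read_taxonomy()].
#'
#' @return data.frame with columns `label` (normalized lower-case) and `kin`
#'   (logical).
#' @export
default_taxonomy <- function() {
  kin <- c("mother", "mom", "father", "dad", "parent", "stepmother",
           "stepfather", "sister", "brother", "sibling", "half-sister",
           "half-brother", "stepsister", "stepbrother", "grandmother",
           "grandma", "grandfather", "grandpa", "grandparent",
           "great-grandmother", "great-grandfather", "aunt", "uncle",
           "great-aunt", "great-uncle", "cousin", "second cousin", "niece",
           "nephew", "mother-in-law", "father-in-law")
  nonkin <- c("friend", "family friend", "neighbor", "teacher",
              "daycare teacher", "preschool teacher", "babysitter", "nanny",
              "au pair", "classmate", "playgroup friend", "coach",
              "librarian", "doctor", "pediatrician", "daycare class",
              "preschool class", "daycare/preschool class", "class",
              "playgroup", "godmother", "godfather", "pastor",
              "music teacher", "swim instructor", "gym instructor",
              "parent's friend", "housekeeper")
  data.frame(label = c(kin, nonkin),
             kin = rep(c(TRUE, FALSE), c(length(kin), length(nonkin))),
             stringsAsFactors = FALSE)
}

#' Read a relationship taxonomy from CSV or YAML
#'
#' CSV files need columns `label` and `kin`; YAML files map labels to
#' logical values.
#'
#' @param path file path.
#' @return data.frame with columns `label`, `kin`.
#' @export
read_taxonomy <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML taxonomies")
    lst <- yaml::read_yaml(path)
    tab <- data.frame(label = names(lst),
                      kin = vapply(lst, isTRUE, logical(1)),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("label", "kin") %in% names(tab)))
      stop("taxonomy CSV must have columns 'label' and 'kin'")
    tab$kin <- as.logical(tab$kin)
  }
  tab$label <- normalize_token(tab$label)
  rownames(tab) <- NULL
  tab
}
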
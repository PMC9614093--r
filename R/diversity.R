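# Diversity metrics: Shannon entropy of categorical composition, E-I
# homophily indices, component-level entropy and the diversity typology.
#
# Conventions used throughout: log base 2, 0 * log2(0) == 0, the ego is never
# part of a composition profile, and alters with missing data on an attribute
# are excluded from that attribute's profile/coding (not counted as a
# category of their own).

#' Base-2 Shannon entropy of a category profile
#'
#' `H(X) = -sum p * log2(p)` over the categories with positive proportion.
#' 0 means every member shares one category; the maximum for `k` categories
#' is `log2(k)`, attained at the uniform profile.
#'
#' @param profile named numeric vector of proportions (>= 0, summing to 1).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(profile) {
  if (length(profile) == 0L)
    stop("empty profile", call. = FALSE)
  validate_profile(profile)
  p <- profile[profile > 0]
  -sum(p * log2(p)) + 0  # + 0 avoids IEEE negative zero for a point mass
}

#' Neighborhood entropy
#'
#' Entropy of a zip-level category profile (e.g. census racial or language
#' proportions); the identical computation as [shannon_entropy()], exposed
#' under the name used for the neighborhood-level measures.
#'
#' @inheritParams shannon_entropy
#' @return entropy in bits.
#' @export
neighborhood_entropy <- function(profile) shannon_entropy(profile)

#' Racial composition profile of an alter roster
#'
#' Each alter with known race contributes one discrete category;
#' multi-category alters collapse to `"Mixed/Biracial"` (see
#' [collapse_races()]).  Group nodes and race-missing alters are excluded,
#' and proportions are renormalized over the remaining alters.
#'
#' @param alters alter data.frame for one ego.
#' @return named numeric vector of proportions, or `NULL` when no alter has
#'   a known race.
#' @export
racial_profile <- function(alters) {
  eligible <- !alters$is_group | lengths(alters$races) > 0
  cats <- vapply(alters$races[eligible], collapse_races, "")
  cats <- cats[!is.na(cats)]
  if (length(cats) == 0L) return(NULL)
  tab <- table(cats)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Language composition profile of an alter roster
#'
#' Each alter maps to one of the discrete language categories
#' ([language_category()]); alters with missing language data are excluded.
#'
#' @param alters alter data.frame for one ego.
#' @return named numeric vector of proportions, or `NULL` if no alter has
#'   language data.
#' @export
language_profile <- function(alters) {
  eligible <- !alters$is_group |
    lengths(alters$languages) > 0 | alters$preverbal
  cats <- mapply(language_category,
                 alters$languages[eligible], alters$preverbal[eligible],
                 USE.NAMES = FALSE)
  cats <- cats[!is.na(cats)]
  if (length(cats) == 0L) return(NULL)
  tab <- table(cats)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' E-I homophily index from same/different counts
#'
#' `(D - S) / (D + S)` where `S` and `D` count the alters coded same and
#' different from the child on an attribute.  -1 means the whole coded
#' network matches the child; +1 means it is entirely different.
#'
#' @param n_same,n_different nonnegative counts; their sum must be >= 1.
#' @return numeric in `[-1, 1]`.
#' @export
ei_index <- function(n_same, n_different) {
  stopifnot(n_same >= 0, n_different >= 0)
  if (n_same + n_different < 1)
    stop("E-I index needs at least one coded alter", call. = FALSE)
  (n_different - n_same) / (n_different + n_same)
}

#' Code an alter as same- or different-race relative to the child
#'
#' A monoracial child matches any alter sharing their race; a biracial child
#' matches any alter whose category set intersects the child's race pair.
#' An alter recorded only as `"Mixed/Biracial"` (component races unknown)
#' cannot be compared to a child whose races do not include that label and
#' is coded missing rather than guessed.
#'
#' @param ego_races child's race set (canonical categories).
#' @param alter_races alter's race set; empty means missing.
#' @return `"same"`, `"different"` or `NA`.
#' @export
code_racial_sameness <- function(ego_races, alter_races) {
  if (length(alter_races) == 0L) return(NA_character_)
  if (length(intersect(ego_races, alter_races)) > 0) return("same")
  # bare Mixed/Biracial label without component races: not resolvable
  if (identical(alter_races, "Mixed/Biracial") &&
      !"Mixed/Biracial" %in% ego_races) return(NA_character_)
  "different"
}

#' Code an alter as same- or different-speaker relative to the child
#'
#' Different iff the alter speaks at least one language the child does not
#' speak.  Preverbal alters speak no language outside the child's set and
#' code as same.
#'
#' @param ego_languages child's language set.
#' @param alter_languages alter's language set; empty means missing unless
#'   `preverbal`.
#' @param preverbal logical preverbal flag for the alter.
#' @return `"same"`, `"different"` or `NA`.
#' @export
code_linguistic_sameness <- function(ego_languages, alter_languages,
                                     preverbal = FALSE) {
  if (isTRUE(preverbal)) return("same")
  if (length(alter_languages) == 0L) return(NA_character_)
  norm <- function(x) normalize_token(x)
  if (all(norm(alter_languages) %in% norm(ego_languages))) "same" else "different"
}

# E-I index over an assembled network for one attribute
attribute_ei <- function(net, attribute = c("race", "language")) {
  attribute <- match.arg(attribute)
  a <- net$alters
  person <- !a$is_group
  codes <- if (attribute == "race") {
    vapply(which(person), function(i)
      code_racial_sameness(net$ego$races[[1]], a$races[[i]]), "")
  } else {
    vapply(which(person), function(i)
      code_linguistic_sameness(net$ego$languages[[1]], a$languages[[i]],
                               a$preverbal[i]), "")
  }
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) return(NA_real_)
  ei_index(sum(codes == "same"), sum(codes == "different"))
}

#' Component-level entropy profile
#'
#' Computes the attribute entropy of each connected component over its own
#' members, plus the proportion of components with zero entropy (all members
#' of the component share one category).  Components with no
#' attribute-codable member have undefined entropy and are excluded from the
#' proportion's numerator and denominator.
#'
#' @param net an `ego_network`.
#' @param attribute `"race"` (default) or `"language"`.
#' @return list: `component_entropy` (numeric vector indexed by component,
#'   `NA` where undefined) and `zero_entropy_component_prop` (`NA` when no
#'   component is codable).
#' @export
component_entropy_profile <- function(net, attribute = c("race", "language")) {
  attribute <- match.arg(attribute)
  m <- net$membership
  ent <- vapply(seq_len(net$n_components), function(k) {
    sub <- net$alters[m == k, , drop = FALSE]
    p <- if (attribute == "race") racial_profile(sub) else language_profile(sub)
    if (is.null(p)) NA_real_ else shannon_entropy(p)
  }, 0)
  defined <- !is.na(ent)
  zp <- if (any(defined)) sum(ent[defined] == 0) / sum(defined) else NA_real_
  list(component_entropy = ent, zero_entropy_component_prop = zp)
}

#' Classify a network's diversity typology
#'
#' Partitions networks by how diversity is patterned across components:
#' * `no_diversity` - overall entropy is 0 (every coded alter shares one
#'   category, so every component does too);
#' * `segregated` - overall entropy > 0 but at least half of the components
#'   are internally homogeneous (zero entropy);
#' * `integrated` - overall entropy > 0 and fewer than half of the
#'   components are homogeneous.
#'
#' The edge case of entropy > 0 with *every* component homogeneous (disjoint
#' single-race components of different races) falls under `segregated`, with
#' a warning since the defining studies did not observe it.
#'
#' @param overall_entropy network-level entropy in bits.
#' @param zero_entropy_component_prop proportion of components with zero
#'   entropy.
#' @return list with `type` (one of `"integrated"`, `"segregated"`,
#'   `"no_diversity"`, or `NA` if either input is `NA`) and the inputs.
#' @export
classify_diversity_type <- function(overall_entropy,
                                    zero_entropy_component_prop) {
  zp <- zero_entropy_component_prop
  if (is.na(overall_entropy) || is.na(zp))
    return(list(type = NA_character_, overall_entropy = overall_entropy,
                zero_entropy_component_prop = zp))
  type <- if (overall_entropy == 0) {
    "no_diversity"
  } else if (zp >= 0.5) {
    if (zp >= 1)
      warning("positive entropy with every component homogeneous; ",
              "classified segregated", call. = FALSE)
    "segregated"
  } else {
    "integrated"
  }
  list(type = type, overall_entropy = overall_entropy,
       zero_entropy_component_prop = zp)
}
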
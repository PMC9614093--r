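# End-to-end scoring: roster tables -> per-child metric records.

#' Score a cohort of child ego networks
#'
#' Assembles one ego network per child and computes the full metric set:
#' size, composition (kin/adult/high-intensity proportions), structure
#' (density, components, component ratio), diversity (racial and language
#' entropy, racial and linguistic E-I indices, component-level entropy and
#' the integrated/segregated/no-diversity typology), and neighborhood
#' entropies when zip-level profiles are supplied.
#'
#' The relationship-intensity composite is standardized over the pooled
#' relationships of the *whole cohort passed in* (see [score_intensity()]);
#' per-ego intensity counts are slices of that single pooled median split.
#' Density is reported `NA` for egos whose roster is flagged
#' `density_collected = FALSE`.
#'
#' @param egos ego table (see [read_ego_table()]).
#' @param alters alter table (see [read_alter_table()]); every `ego_id`
#'   must appear in `egos`, and every ego must have at least one alter.
#' @param taxonomy kin taxonomy (see [default_taxonomy()]).
#' @param strict passed to [classify_kin()].
#' @return data.frame of class `csnq_metrics`, one row per ego.  The scored
#'   intensity pool is attached as `attr(, "intensity_pool")`.
#' @export
csnq_score <- function(egos, alters, taxonomy = default_taxonomy(),
                       strict = FALSE) {
  stopifnot(is.data.frame(egos), is.data.frame(alters))
  orphan <- setdiff(unique(alters$ego_id), egos$ego_id)
  if (length(orphan))
    stop("alter rows with unknown ego_id: ", paste(orphan, collapse = ", "))

  # cohort-level intensity pool: person nodes with all three measures
  complete <- !alters$is_group & !is.na(alters$n_activities) &
    !is.na(alters$closeness) & !is.na(alters$prop_waking_hours)
  pool <- NULL
  labels <- rep(NA_character_, nrow(alters))
  if (sum(complete) >= 2L) {
    pool <- score_intensity(alters[complete, c("ego_id", "alter_id",
                                               "n_activities", "closeness",
                                               "prop_waking_hours")])
    labels[complete] <- pool$intensity
  }

  idx <- split(seq_len(nrow(alters)), alters$ego_id)
  rows <- lapply(seq_len(nrow(egos)), function(i) {
    ego <- egos[i, , drop = FALSE]
    ai <- idx[[ego$ego_id]]
    if (is.null(ai))
      stop(sprintf("ego %s has no alters; empty networks are invalid input",
                   ego$ego_id), call. = FALSE)
    net <- assemble_network(ego, alters[ai, , drop = FALSE])
    score_one(net, taxonomy, labels[ai], strict)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "intensity_pool") <- pool
  class(out) <- c("csnq_metrics", "data.frame")
  out
}

score_one <- function(net, taxonomy, intensity_labels, strict = FALSE) {
  ego <- net$ego
  N <- network_size(net)
  n_ties <- nrow(net$ties)
  C <- net$n_components

  comp <- composition_proportions(net, taxonomy, intensity_labels,
                                  strict = strict)

  rp <- racial_profile(net$alters)
  lp <- language_profile(net$alters)
  racial_entropy <- if (is.null(rp)) NA_real_ else shannon_entropy(rp)
  language_entropy <- if (is.null(lp)) NA_real_ else shannon_entropy(lp)

  cep <- component_entropy_profile(net, "race")
  typ <- classify_diversity_type(racial_entropy,
                                 cep$zero_entropy_component_prop)

  nb_race <- ego$neighborhood_race_profile[[1]]
  nb_lang <- ego$neighborhood_language_profile[[1]]

  data.frame(
    ego_id = ego$ego_id,
    age_months = ego$age_months,
    childcare_out_of_home = ego$childcare_out_of_home,
    urbanicity = ifelse(is.na(ego$urbanicity), NA_character_, ego$urbanicity),
    network_size = N,
    n_high_intensity = comp$n_high_intensity,
    n_low_intensity = comp$n_low_intensity,
    prop_high_intensity = comp$prop_high_intensity,
    prop_kin = comp$prop_kin,
    prop_adult = comp$prop_adult,
    n_ties = n_ties,
    density = if (isTRUE(ego$density_collected))
      network_density(n_ties, N) else NA_real_,
    n_components = C,
    component_ratio = component_ratio(C, N),
    racial_entropy = racial_entropy,
    racial_ei = attribute_ei(net, "race"),
    language_entropy = language_entropy,
    linguistic_ei = attribute_ei(net, "language"),
    zero_entropy_component_prop = cep$zero_entropy_component_prop,
    diversity_type = typ$type,
    neighborhood_racial_entropy =
      if (is.null(nb_race)) NA_real_ else shannon_entropy(nb_race),
    neighborhood_language_entropy =
      if (is.null(nb_lang)) NA_real_ else shannon_entropy(nb_lang),
    stringsAsFactors = FALSE)
}

#' @export
print.csnq_metrics <- function(x, ...) {
  cat(sprintf("CSNQ metrics: %d children, %d metric columns\n",
              nrow(x), ncol(x) - 1L))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Summary of a scored cohort
#'
#' Mean, SD, range and non-missing n per metric (the standard descriptive
#' table shape for a cohort of scored networks); see [summary_table()].
#'
#' @param object a `csnq_metrics` data.frame.
#' @param ... unused.
#' @export
summary.csnq_metrics <- function(object, ...) summary_table(object)
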
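# Composition metrics: kin/adult classification and the cohort-level
# relationship-intensity composite.

#' Classify a relationship label as kin or non-kin
#'
#' Kin covers the immediate and extended family (grandparents, aunts, uncles,
#' cousins, ...).  Lookup is case- and whitespace-insensitive.
#'
#' @param label relationship label(s), e.g. `"mother"`, `"daycare teacher"`.
#' @param taxonomy label-to-kin table (see [default_taxonomy()]).
#' @param strict if `TRUE`, unknown labels are an error; otherwise they are
#'   classified non-kin with a warning.
#' @return logical vector (`NA` for empty labels in lenient mode).
#' @export
classify_kin <- function(label, taxonomy = default_taxonomy(), strict = FALSE) {
  key <- normalize_token(label)
  hit <- taxonomy$kin[match(key, taxonomy$label)]
  unknown <- is.na(hit) & nzchar(key)
  if (any(unknown)) {
    if (strict)
      stop("unknown relationship label(s): ",
           paste(unique(label[unknown]), collapse = ", "), call. = FALSE)
    warning("unknown relationship label(s) classified non-kin: ",
            paste(unique(label[unknown]), collapse = ", "), call. = FALSE)
    hit[unknown] <- FALSE
  }
  hit
}

#' Classify an alter as adult or child by age
#'
#' A child is anyone under the age of 13; 13 and over is an adult.
#'
#' @param age_years numeric vector of ages in years (`NA` allowed).
#' @return character vector: `"adult"`, `"child"` or `NA`.
#' @export
classify_adult <- function(age_years) {
  ifelse(is.na(age_years), NA_character_,
         ifelse(age_years < 13, "child", "adult"))
}

#' Score relationship intensity over a cohort pool
#'
#' Standardizes each of the three intensity measures (activity count,
#' parent-rated emotional closeness, proportion of the child's waking hours)
#' as a z-score across the whole pool of relationships, averages the three
#' z-scores per relationship, and median-splits the averages into
#' high/low-intensity labels.
#'
#' The split is computed once over the pooled relationships of the cohort,
#' not per child, so "high intensity" means high relative to every scored
#' relationship in the sample.  Relationships whose average sits exactly at
#' the median are labelled `"low"` (a deterministic tie rule); z-scores use
#' the population (n) denominator, a choice that cannot change the labels.
#'
#' @param pool data.frame with numeric columns `n_activities`, `closeness`,
#'   `prop_waking_hours`; one row per relationship, all three measures
#'   present, at least two rows.
#' @return `pool` with added columns `z_activities`, `z_closeness`,
#'   `z_hours`, `z_mean` and `intensity` (`"high"`/`"low"`).
#' @export
score_intensity <- function(pool) {
  need <- c("n_activities", "closeness", "prop_waking_hours")
  stopifnot(is.data.frame(pool), all(need %in% names(pool)))
  if (nrow(pool) < 2L)
    stop("intensity pool needs at least 2 relationships", call. = FALSE)
  if (anyNA(pool[need]))
    stop("intensity pool rows must have all three measures", call. = FALSE)
  zscore <- function(x, what) {
    s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))  # population sd
    if (s == 0) {
      warning(sprintf("no variance in '%s'; its z-scores set to 0", what),
              call. = FALSE)
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  pool$z_activities <- zscore(pool$n_activities, "n_activities")
  pool$z_closeness <- zscore(pool$closeness, "closeness")
  pool$z_hours <- zscore(pool$prop_waking_hours, "prop_waking_hours")
  pool$z_mean <- (pool$z_activities + pool$z_closeness + pool$z_hours) / 3
  med <- stats::median(pool$z_mean)
  pool$intensity <- ifelse(pool$z_mean > med, "high", "low")
  pool
}

#' Composition proportions for one ego network
#'
#' Proportion of kin, adult and (when intensity labels are available)
#' high-intensity relationships.  Denominators count attribute-eligible
#' alters: group nodes without the relevant attribute and alters missing it
#' are excluded rather than silently counted, so a proportion is `NA` when
#' no alter carries the attribute.
#'
#' @param net an `ego_network`.
#' @param taxonomy kin taxonomy (see [default_taxonomy()]).
#' @param intensity_labels optional character vector (`"high"`/`"low"`/`NA`)
#'   aligned with `net$alters` rows, e.g. a slice of
#'   [score_intensity()]'s output.
#' @param strict passed to [classify_kin()].
#' @return named list: `n_kin`, `prop_kin`, `prop_adult`,
#'   `n_high_intensity`, `n_low_intensity`, `prop_high_intensity`.
#' @export
composition_proportions <- function(net, taxonomy = default_taxonomy(),
                                    intensity_labels = NULL, strict = FALSE) {
  a <- net$alters
  person <- !a$is_group

  lab <- a$relationship
  has_lab <- person & nzchar(trimws(lab))
  kin <- rep(NA, nrow(a))
  if (any(has_lab))
    kin[has_lab] <- classify_kin(lab[has_lab], taxonomy, strict = strict)
  n_kin <- sum(kin, na.rm = TRUE)
  prop_kin <- if (any(!is.na(kin))) n_kin / sum(!is.na(kin)) else NA_real_

  grp <- classify_adult(a$age_years)
  grp[!person] <- NA
  prop_adult <- if (any(!is.na(grp)))
    sum(grp == "adult", na.rm = TRUE) / sum(!is.na(grp)) else NA_real_

  n_hi <- n_lo <- NA_integer_; prop_hi <- NA_real_
  if (!is.null(intensity_labels)) {
    stopifnot(length(intensity_labels) == nrow(a))
    ok <- !is.na(intensity_labels)
    if (any(ok)) {
      n_hi <- sum(intensity_labels[ok] == "high")
      n_lo <- sum(intensity_labels[ok] == "low")
      prop_hi <- n_hi / sum(ok)
    }
  }
  list(n_kin = n_kin, prop_kin = prop_kin, prop_adult = prop_adult,
       n_high_intensity = n_hi, n_low_intensity = n_lo,
       prop_high_intensity = prop_hi)
}
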
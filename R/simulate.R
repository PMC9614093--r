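# Seeded synthetic-cohort generator.
#
# Emulates the statistical structure of a developmental cohort of US
# children aged 6-60 months: network size grows with age (negative-binomial
# counts truncated at 3, mean linear in age), every child has a family
# component of kin plus age-increasing activity contexts, the kin fraction
# declines with age, kin relationships carry higher intensity, and racial /
# linguistic mixes are drawn per ego from urban vs suburban neighborhood
# profiles (alters track the ego's own neighborhood only in the urban
# stratum).  Output is a pure function of (config, seed).

#' Default generator configuration
#'
#' Parameters are calibrated toward the headline cohort moments the
#' generator emulates: mean network size about 11 (SD about 5, range within
#' 3-40), a size-age Spearman correlation around 0.6, and a mean kin
#' proportion around 0.52 declining with age.
#'
#' @param n_egos number of children (default 280).
#' @return list of class `csnq_config`; see the method vignette for the
#'   meaning and unit of each field.
#' @export
default_config <- function(n_egos = 280) {
  structure(list(
    n_egos = n_egos,
    age_range_months = c(6, 60),
    # size ~ NB(mean = size_base + size_age_slope * (age - 33), size = disp),
    # truncated to [size_min, size_max]
    size_base = 11,
    size_age_slope = 0.2,
    size_dispersion = 30,
    size_min = 3,
    size_max = 40,
    # kin fraction: p_kin = kin_base_prop + kin_age_slope * (age - 33)
    # nominal fraction before the 2-kin floor, which lifts the realized
    # cohort mean to about 0.52
    kin_base_prop = 0.48,
    kin_age_slope = -0.006,
    # extra (non-family) contexts: 1 + Poisson(ctx_base +
    # ctx_per_nonkin * n_nonkin), capped at ctx_max, when any non-kin alter
    # exists; bigger rosters mean more activity settings, which fragments
    # large networks and drives density down with size
    ctx_base = 0.2,
    ctx_per_nonkin = 0.25,
    ctx_max = 6,
    # childcare probability: plogis((age - childcare_age_threshold)/12)
    childcare_age_threshold = 30,
    p_urban = 0.65,
    race_profile_urban = c("European/White-American" = 0.45,
                           "African/Black-American" = 0.25,
                           "Hispanic/Latino-American" = 0.15,
                           "Asian/Asian-American" = 0.08,
                           "Mixed/Biracial" = 0.04,
                           "Other" = 0.02,
                           "Native American" = 0.01),
    race_profile_suburban = c("European/White-American" = 0.80,
                              "African/Black-American" = 0.05,
                              "Hispanic/Latino-American" = 0.06,
                              "Asian/Asian-American" = 0.05,
                              "Mixed/Biracial" = 0.02,
                              "Other" = 0.01,
                              "Native American" = 0.01),
    race_profile_concentration = 30,
    lang_profile_urban = c("English" = 0.64, "Spanish" = 0.22, "Other" = 0.14),
    lang_profile_suburban = c("English" = 0.85, "Spanish" = 0.09,
                              "Other" = 0.06),
    lang_profile_concentration = 25,
    p_ego_biracial = 0.15,
    p_ego_bilingual = 0.2,
    p_kin_share_race = 0.9,
    p_alter_race_missing = 0.05,
    p_alter_lang_missing = 0.085,
    p_nonkin_adult = 0.35,
    # intensity distributions (kin vs non-kin)
    kin_activities_mean = 5, nonkin_activities_mean = 2,
    kin_closeness_range = c(5, 7), nonkin_closeness_range = c(1, 5),
    kin_hours_shape = c(4, 8), nonkin_hours_shape = c(1.2, 10)
  ), class = "csnq_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# truncated negative binomial draw
rsize <- function(mu, disp, lo, hi) {
  repeat {
    x <- stats::rnbinom(1, mu = mu, size = disp)
    if (x >= lo && x <= hi) return(x)
  }
}

second_languages <- c("Spanish", "Polish", "Mandarin", "Hindi", "French",
                      "Tagalog", "Arabic")

#' Generate a synthetic cohort of child network rosters
#'
#' @param config generator configuration (see [default_config()]).
#' @param seed integer seed; the output is a pure function of
#'   `(config, seed)`.
#' @return list with data.frames `egos` and `alters` in the schema of
#'   [read_ego_table()] / [read_alter_table()].
#' @export
simulate_cohort <- function(config = default_config(), seed = 1) {
  cfg <- config
  stopifnot(inherits(cfg, "csnq_config"))
  if (cfg$size_min > cfg$size_max)
    stop("infeasible config: size_min > size_max", call. = FALSE)
  if (cfg$age_range_months[1] >= cfg$age_range_months[2])
    stop("infeasible config: empty age range", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  ego_rows <- vector("list", cfg$n_egos)
  alter_rows <- vector("list", cfg$n_egos)
  for (i in seq_len(cfg$n_egos)) {
    g <- simulate_ego(sprintf("ego%03d", i), cfg)
    ego_rows[[i]] <- g$ego
    alter_rows[[i]] <- g$alters
  }
  list(egos = bind_rosters(ego_rows), alters = bind_rosters(alter_rows))
}

bind_rosters <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulate_ego <- function(id, cfg) {
  age <- stats::runif(1, cfg$age_range_months[1], cfg$age_range_months[2])
  urban <- stats::runif(1) < cfg$p_urban
  urbanicity <- if (urban) "urban" else "suburban_rural"

  base_race <- if (urban) cfg$race_profile_urban else cfg$race_profile_suburban
  nb_race <- rdirichlet1(base_race * cfg$race_profile_concentration)
  names(nb_race) <- names(base_race)
  base_lang <- if (urban) cfg$lang_profile_urban else cfg$lang_profile_suburban
  nb_lang <- rdirichlet1(base_lang * cfg$lang_profile_concentration)
  names(nb_lang) <- names(base_lang)

  draw_race <- function(profile) sample(names(profile), 1, prob = profile)
  ego_races <- draw_race(nb_race)
  if (stats::runif(1) < cfg$p_ego_biracial)
    ego_races <- unique(c(ego_races, draw_race(nb_race)))
  ego_races <- setdiff(ego_races, "Mixed/Biracial")
  if (length(ego_races) == 0L) ego_races <- "Mixed/Biracial"

  ego_langs <- "English"
  if (stats::runif(1) < cfg$p_ego_bilingual)
    ego_langs <- c("English", sample(second_languages, 1))

  childcare <- stats::runif(1) <
    stats::plogis((age - cfg$childcare_age_threshold) / 12)

  N <- rsize(cfg$size_base + cfg$size_age_slope * (age - 33),
             cfg$size_dispersion, cfg$size_min, cfg$size_max)
  p_kin <- min(0.95, max(0.05,
               cfg$kin_base_prop + cfg$kin_age_slope * (age - 33)))
  n_kin <- min(N, max(2L, stats::rbinom(1, N, p_kin)))
  n_nonkin <- N - n_kin

  # contexts: family for kin; non-kin spread over activity contexts
  contexts <- list()
  kin_labels <- c("mother", "father")
  if (n_kin > 2)
    kin_labels <- c(kin_labels,
                    sample(c("sister", "brother", "grandmother", "grandfather",
                             "aunt", "uncle", "cousin"), n_kin - 2,
                           replace = TRUE))

  n_ctx <- 0L
  ctx_names <- character(0)
  if (n_nonkin > 0) {
    n_ctx <- min(cfg$ctx_max,
                 1L + stats::rpois(1, cfg$ctx_base + cfg$ctx_per_nonkin * n_nonkin))
    pool <- c("school", "library storytime", "playgroup", "music class",
              "gym class", "swim class", "church", "neighborhood", "art class")
    ctx_names <- sample(pool, n_ctx)
    if (childcare) ctx_names[1] <- "daycare"
  }

  alters <- vector("list", N)
  # the ego's neighborhood drives non-kin composition only in the urban
  # stratum; suburban non-kin draw from the stratum base profile instead
  nonkin_race_src <- if (urban) nb_race else cfg$race_profile_suburban
  nonkin_bilingual_p <- if (urban) 1 - nb_lang[["English"]] else
    1 - cfg$lang_profile_suburban[["English"]]

  for (k in seq_len(N)) {
    kin <- k <= n_kin
    if (kin) {
      relationship <- kin_labels[k]
      ctx <- "family"
      race <- if (stats::runif(1) < cfg$p_kin_share_race)
        sample(ego_races, 1) else draw_race(nonkin_race_src)
      a_age <- switch(relationship,
        mother = stats::runif(1, 25, 45), father = stats::runif(1, 25, 48),
        grandmother = stats::runif(1, 50, 80),
        grandfather = stats::runif(1, 50, 80),
        aunt = stats::runif(1, 22, 55), uncle = stats::runif(1, 22, 55),
        stats::runif(1, 0.5, 12))  # sibling / cousin
      langs <- if (length(ego_langs) > 1 && stats::runif(1) < 0.7)
        ego_langs else "English"
    } else {
      adult <- stats::runif(1) < cfg$p_nonkin_adult
      relationship <- if (adult)
        sample(c("teacher", "babysitter", "family friend", "neighbor"), 1)
      else sample(c("friend", "classmate"), 1)
      ctx <- sample(ctx_names, 1)
      race <- draw_race(nonkin_race_src)
      a_age <- if (adult) stats::runif(1, 20, 60) else stats::runif(1, 0.5, 12)
      langs <- if (stats::runif(1) < nonkin_bilingual_p)
        c("English", sample(second_languages, 1)) else "English"
    }
    races <- if (race == "Mixed/Biracial")
      unique(c(draw_race(nonkin_race_src), draw_race(nonkin_race_src)))
    else race
    preverbal <- a_age < 1.5
    if (preverbal) langs <- character(0)
    if (stats::runif(1) < cfg$p_alter_race_missing) races <- character(0)
    if (!preverbal && stats::runif(1) < cfg$p_alter_lang_missing)
      langs <- character(0)

    rng <- if (kin) cfg$kin_closeness_range else cfg$nonkin_closeness_range
    shp <- if (kin) cfg$kin_hours_shape else cfg$nonkin_hours_shape
    alters[[k]] <- data.frame(
      ego_id = id, alter_id = sprintf("%s_a%02d", id, k),
      is_group = FALSE, age_years = a_age,
      races = I(list(races)), languages = I(list(langs)),
      preverbal = preverbal, relationship = relationship,
      contexts = I(list(ctx)),
      n_activities = stats::rpois(1, if (kin) cfg$kin_activities_mean
                                  else cfg$nonkin_activities_mean),
      closeness = sample(seq(rng[1], rng[2]), 1),
      prop_waking_hours = stats::rbeta(1, shp[1], shp[2]),
      stringsAsFactors = FALSE)
  }
  # childcare children know their class as a group node too
  if (childcare && n_nonkin > 0) {
    k <- N  # repurpose the last non-kin slot as the class group node
    alters[[k]] <- data.frame(
      ego_id = id, alter_id = sprintf("%s_a%02d", id, k),
      is_group = TRUE, age_years = NA_real_,
      races = I(list(character(0))), languages = I(list(character(0))),
      preverbal = FALSE, relationship = "daycare/preschool class",
      contexts = I(list("daycare")),
      n_activities = NA_real_, closeness = NA_real_,
      prop_waking_hours = NA_real_, stringsAsFactors = FALSE)
  }

  ego <- data.frame(
    ego_id = id, age_months = age,
    races = I(list(ego_races)), languages = I(list(ego_langs)),
    childcare_out_of_home = childcare, urbanicity = urbanicity,
    neighborhood_race_profile = I(list(nb_race)),
    neighborhood_language_profile = I(list(nb_lang)),
    density_collected = TRUE, stringsAsFactors = FALSE)
  list(ego = ego, alters = bind_rosters(alters))
}

#' @export
print.csnq_config <- function(x, ...) {
  cat("CSNQ synthetic-cohort configuration\n")
  cat(sprintf("  n_egos: %d, ages %g-%g months\n", x$n_egos,
              x$age_range_months[1], x$age_range_months[2]))
  cat(sprintf("  size: NB(mean = %g %+g*(age-33), size = %g) truncated to [%d, %d]\n",
              x$size_base, x$size_age_slope, x$size_dispersion,
              x$size_min, x$size_max))
  cat(sprintf("  kin fraction: %g %+g*(age-33)\n",
              x$kin_base_prop, x$kin_age_slope))
  cat(sprintf("  urban fraction: %g\n", x$p_urban))
  invisible(x)
}
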
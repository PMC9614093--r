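# Roster builders and independent oracles used across the suite.

make_ego <- function(ego_id = "e1", age_months = 36,
                     races = "European/White-American",
                     languages = "English",
                     childcare = NA, urbanicity = NA_character_,
                     nb_race = NULL, nb_lang = NULL,
                     density_collected = TRUE) {
  data.frame(ego_id = ego_id, age_months = age_months,
             races = I(list(races)), languages = I(list(languages)),
             childcare_out_of_home = childcare, urbanicity = urbanicity,
             neighborhood_race_profile = I(list(nb_race)),
             neighborhood_language_profile = I(list(nb_lang)),
             density_collected = density_collected, stringsAsFactors = FALSE)
}

# vectorized roster builder: one row per alter
make_alters <- function(ego_id = "e1", n = NULL, contexts = "family",
                        races = NA, languages = "English",
                        relationship = "friend", age_years = 30,
                        is_group = FALSE, preverbal = FALSE,
                        n_activities = NA_real_, closeness = NA_real_,
                        prop_waking_hours = NA_real_) {
  as_list_col <- function(x, n) {
    if (is.list(x)) rep_len(x, n)
    else lapply(rep_len(list(x), n), function(v)
      if (length(v) == 1 && is.na(v)) character(0) else as.character(v))
  }
  if (is.null(n))
    n <- max(length(contexts), if (is.list(races)) length(races) else 1,
             length(relationship), length(age_years))
  if (n == 0)
    return(make_alters(ego_id = ego_id, n = 1)[0, , drop = FALSE])
  data.frame(ego_id = ego_id,
             alter_id = sprintf("a%02d", seq_len(n)),
             is_group = rep_len(is_group, n),
             age_years = rep_len(age_years, n),
             races = I(as_list_col(races, n)),
             languages = I(as_list_col(languages, n)),
             preverbal = rep_len(preverbal, n),
             relationship = rep_len(relationship, n),
             contexts = I(as_list_col(contexts, n)),
             n_activities = rep_len(n_activities, n),
             closeness = rep_len(closeness, n),
             prop_waking_hours = rep_len(prop_waking_hours, n),
             stringsAsFactors = FALSE)
}

# random roster of up to n_max alters with random context memberships
random_roster <- function(n_max = 12, n_contexts = 4, ego_id = "r1") {
  n <- sample(2:n_max, 1)
  cx <- lapply(seq_len(n), function(i)
    sample(paste0("c", seq_len(n_contexts)), sample(1:2, 1)))
  races <- lapply(seq_len(n), function(i)
    sample(race_categories()[1:4], 1))
  make_alters(ego_id = ego_id, n = n, contexts = cx, races = races)
}

## ---- independent oracles ----

# component count by brute-force reachability (boolean closure)
oracle_components <- function(alters) {
  n <- nrow(alters)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && length(intersect(alters$contexts[[i]],
                                   alters$contexts[[j]])) > 0)
      adj[i, j] <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  nrow(unique(adj))
}

# tie count by exhaustive pair enumeration
oracle_tie_count <- function(alters) {
  n <- nrow(alters)
  t <- 0L
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (length(intersect(alters$contexts[[i]], alters$contexts[[j]])) > 0)
      t <- t + 1L
  t
}

# entropy by direct summation over a count table
oracle_entropy <- function(counts) {
  p <- counts / sum(counts)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

# Benjamini-Hochberg by direct step-up enumeration
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# exact two-sided rank-sum p by exhaustive permutation of group labels;
# W is the Mann-Whitney U for the first group (wilcox.test's statistic)
oracle_ranksum <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  r <- rank(x)
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(x), n1)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  p <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
  list(W = W_obs, p = p)
}
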
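# Entropy, E-I indices, sameness coding, component-level entropy, typology.

test_that("entropy reproduces the textbook worked values", {
  expect_equal(shannon_entropy(c(a = 0.5, b = 0.5)), 1)
  expect_equal(shannon_entropy(c(a = 0.5, b = 0.25, c = 0.25)), 1.5)
  expect_equal(shannon_entropy(c(a = 1)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_error(shannon_entropy(numeric(0)), "empty")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_equal(neighborhood_entropy(c(u = 0.5, v = 0.5)), 1)
})

test_that("entropy is maximal iff the profile is uniform", {
  set.seed(31)
  for (k in 2:6) {
    expect_equal(shannon_entropy(rep(1 / k, k)), log2(k))
    for (r in 1:10) {
      p <- rgamma(k, 1); p <- p / sum(p)
      expect_lte(shannon_entropy(p), log2(k) + 1e-12)
    }
  }
})

test_that("racial profiles collapse multi-race alters and renormalize", {
  a <- make_alters(n = 4, races = list("European/White-American",
                                       "European/White-American",
                                       "African/Black-American",
                                       "African/Black-American"))
  p <- racial_profile(a)
  expect_equal(unname(p[order(names(p))]), c(0.5, 0.5))

  # a Black;White alter becomes Mixed/Biracial
  b <- make_alters(n = 2, races = list(
    c("African/Black-American", "European/White-American"),
    "Asian/Asian-American"))
  expect_setequal(names(racial_profile(b)),
                  c("Mixed/Biracial", "Asian/Asian-American"))

  # 1 race-missing alter of 5: proportions over the 4 known
  cc <- make_alters(n = 5, races = list("European/White-American",
                                        "European/White-American",
                                        "European/White-American",
                                        "African/Black-American", NA))
  p2 <- racial_profile(cc)
  expect_equal(sum(p2), 1)
  expect_equal(unname(p2["European/White-American"]), 0.75)
  expect_null(racial_profile(make_alters(n = 3, races = NA)))
})

test_that("language categories map speakers, bilinguals and preverbal infants", {
  expect_equal(language_category("English"), "English-monolingual")
  expect_equal(language_category(c("English", "Spanish")), "English-bilingual")
  expect_equal(language_category("Polish"), "non-English-monolingual")
  expect_equal(language_category(c("Polish", "Hindi")), "other-multilingual")
  expect_equal(language_category(character(0), preverbal = TRUE), "preverbal")
  expect_true(is.na(language_category(character(0))))

  a <- make_alters(n = 4, languages = list("English", "English",
                                           c("English", "Spanish"),
                                           c("English", "Spanish")))
  p <- language_profile(a)
  expect_setequal(names(p), c("English-monolingual", "English-bilingual"))
  expect_equal(unname(p), c(0.5, 0.5))
})

test_that("E-I index hits its extremes and the printed bilingual example", {
  expect_equal(ei_index(5, 0), -1)
  expect_equal(ei_index(0, 4), 1)
  expect_equal(ei_index(3, 1), -0.5)
  expect_error(ei_index(0, 0), "at least one")
})

test_that("racial sameness follows the monoracial and biracial rules", {
  w <- "European/White-American"; b <- "African/Black-American"
  a <- "Asian/Asian-American"
  expect_equal(code_racial_sameness(w, w), "same")
  expect_equal(code_racial_sameness(w, b), "different")
  # biracial child: either component race counts as same
  expect_equal(code_racial_sameness(c(b, w), w), "same")
  expect_equal(code_racial_sameness(c(b, w), b), "same")
  expect_equal(code_racial_sameness(c(b, w), a), "different")
  # unresolvable: bare Mixed/Biracial alter vs monoracial child
  expect_true(is.na(code_racial_sameness(w, "Mixed/Biracial")))
  expect_true(is.na(code_racial_sameness(w, character(0))))
})

test_that("linguistic sameness: different iff the alter speaks an unshared language", {
  es <- c("English", "Spanish")
  expect_equal(code_linguistic_sameness(es, c("English", "Dutch")), "different")
  expect_equal(code_linguistic_sameness(es, "English"), "same")
  expect_equal(code_linguistic_sameness(es, es), "same")
  expect_equal(code_linguistic_sameness(es, character(0), preverbal = TRUE),
               "same")
  expect_true(is.na(code_linguistic_sameness(es, character(0))))
})

test_that("the printed 4-alter bilingual network scores EI -0.5 end to end", {
  ego <- make_ego(languages = c("English", "Spanish"))
  a <- make_alters(n = 4, languages = list("English", "English",
                                           c("English", "Spanish"),
                                           c("English", "Dutch")))
  net <- assemble_network(ego, a)
  m <- suppressWarnings(csnq_score(ego, a))
  expect_equal(m$linguistic_ei, -0.5)
  expect_equal(net$n_components, 1L)
})

test_that("component entropies separate a homogeneous family from a mixed school", {
  # family of 5 all White + school of 4 (2 White, 1 Black, 1 Asian)
  races <- c(rep("European/White-American", 5),
             "European/White-American", "European/White-American",
             "African/Black-American", "Asian/Asian-American")
  cx <- c(rep("family", 5), rep("school", 4))
  net <- assemble_network(make_ego(), make_alters(n = 9, contexts = as.list(cx),
                                                  races = as.list(races)))
  cep <- component_entropy_profile(net, "race")
  expect_setequal(round(cep$component_entropy, 2), c(0, 1.5))
  expect_equal(cep$zero_entropy_component_prop, 0.5)

  # single same-race component: proportion 1
  one <- assemble_network(make_ego(),
                          make_alters(n = 3, races = "European/White-American"))
  expect_equal(component_entropy_profile(one)$zero_entropy_component_prop, 1)

  # every component mixed: proportion 0
  races2 <- list("European/White-American", "African/Black-American",
                 "European/White-American", "Asian/Asian-American")
  cx2 <- list("family", "family", "gym", "gym")
  mixed <- assemble_network(make_ego(),
                            make_alters(n = 4, contexts = cx2, races = races2))
  expect_equal(component_entropy_profile(mixed)$zero_entropy_component_prop, 0)
})

test_that("the diversity typology partitions its input space", {
  expect_equal(classify_diversity_type(0, 1)$type, "no_diversity")
  expect_equal(classify_diversity_type(1.22, 0)$type, "integrated")
  expect_equal(classify_diversity_type(0.8, 0.5)$type, "segregated")
  expect_equal(classify_diversity_type(0.9, 0.49)$type, "integrated")
  # disjoint monoracial components of different races: outside the printed
  # bound, classified segregated with a warning
  expect_warning(t <- classify_diversity_type(1, 1), "homogeneous")
  expect_equal(t$type, "segregated")
  expect_true(is.na(classify_diversity_type(NA, 0.5)$type))
})

test_that("all-same networks pin entropy to 0 and EI to -1 together", {
  ego <- make_ego(races = "European/White-American", languages = "English")
  a <- make_alters(n = 5, races = "European/White-American",
                   languages = "English")
  m <- suppressWarnings(csnq_score(ego, a))
  expect_equal(m$racial_entropy, 0)
  expect_equal(m$racial_ei, -1)
  expect_equal(m$language_entropy, 0)
  expect_equal(m$linguistic_ei, -1)
  expect_equal(m$diversity_type, "no_diversity")

  # any different-coded alter strictly raises the EI index
  a$races[[5]] <- "Asian/Asian-American"
  m2 <- suppressWarnings(csnq_score(ego, a))
  expect_gt(m2$racial_ei, m$racial_ei)
})
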
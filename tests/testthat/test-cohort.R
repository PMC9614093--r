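# Cohort-level statistics: rank correlation, FDR, transform, regression,
# rank-sum, report tables.

test_that("spearman_rho handles monotone, tied and missing data", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$value, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$value, -1)
  # frozen from the average-rank formula: ranks (1,2.5,2.5,4) vs (1,2,3.5,3.5)
  r <- spearman_rho(c(1, 2, 2, 4), c(2, 3, 5, 5))
  expect_equal(r$value, 5 / 6, tolerance = 1e-12)
  # invariant under strictly monotone transforms
  set.seed(12)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(spearman_rho(exp(x), y)$value, spearman_rho(x, y)$value)
  # listwise deletion
  r2 <- spearman_rho(c(1, 2, NA, 4), c(4, NA, 2, 1))
  expect_equal(r2$n, 2L)
})

test_that("fdr_adjust matches the step-up oracle and is order-preserving", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (r in 1:50) {
    p <- runif(sample(1:30, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))  # ordering preserved
  }
})

test_that("sqrt+0.5 transform is exact and monotone", {
  expect_equal(sqrt_half_transform(0), sqrt(0.5))
  expect_equal(sqrt_half_transform(3.5), 2)
  x <- sort(runif(50, 0, 30))
  expect_true(all(diff(sqrt_half_transform(x)) > 0))
  expect_error(sqrt_half_transform(-1))
})

test_that("the age x childcare regression recovers a noiseless slope", {
  n <- 60
  d <- data.frame(ego_id = paste0("e", 1:n),
                  age_months = seq(6, 60, length.out = n),
                  childcare_out_of_home = rep(c(TRUE, FALSE), n / 2))
  d$network_size <- (2 * d$age_months)^2 - 0.5   # y = 2*age after transform
  fit <- suppressWarnings(regression_age_childcare(d))  # perfect-fit note
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  beta_age <- fit$coefficients$beta[fit$coefficients$term == "age"]
  expect_equal(beta_age, 2, tolerance = 1e-9)

  # permuted response carries no signal
  set.seed(4)
  d$network_size <- sample(d$network_size)
  expect_lt(regression_age_childcare(d)$r_squared, 0.15)

  d$childcare_out_of_home <- TRUE
  expect_error(regression_age_childcare(d), "constant predictor 'childcare'")
})

test_that("interaction p-values are uniform when the generator has no interaction", {
  set.seed(21)
  pvals <- replicate(60, {
    n <- 50
    d <- data.frame(age_months = runif(n, 6, 60),
                    childcare_out_of_home = runif(n) < 0.5)
    d$network_size <- pmax(0, 5 + 0.1 * d$age_months + rnorm(n, 0, 2))
    fit <- regression_age_childcare(d)
    fit$coefficients$p_value[fit$coefficients$term == "age:childcareTRUE"]
  })
  # type-I rate at 0.05 stays near nominal (binomial 2SE band)
  expect_lt(mean(pvals < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
  expect_gt(mean(pvals < 0.5), 0.30)
})

test_that("rank-sum: identical groups are null, exact path matches enumeration", {
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  # complete separation at n = 3 vs 3: the most extreme of choose(6,3) tables
  sep <- rank_sum_test(c(10, 11, 12), c(1, 2, 3))
  orc <- oracle_ranksum(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$value, orc$W)
  expect_equal(sep$p_value, orc$p, tolerance = 1e-12)
  expect_equal(sep$p_value, 0.1)  # 2/20
})

test_that("rank-sum detection rate rises with the group shift", {
  set.seed(14)
  power <- vapply(c(0, 1.5, 3), function(shift) {
    mean(replicate(40, {
      rank_sum_test(rnorm(15, shift), rnorm(15))$p_value < 0.05
    }))
  }, 0)
  expect_true(all(diff(power) >= 0))
  expect_gt(power[3], 0.8)
})

test_that("the correlation table has the report shape and exact anchor behavior", {
  sim <- simulate_cohort(default_config(40), seed = 2)
  m <- suppressWarnings(csnq_score(sim$egos, sim$alters))
  ct <- correlation_table(m)
  expect_named(ct, c("metric", "anchor", "rho", "p_value", "adjusted_p", "n"))
  expect_true(all(ct$adjusted_p >= ct$p_value - 1e-12, na.rm = TRUE))
  # anchor vs itself is excluded from its own column but correlates 1
  expect_false(any(ct$metric == "network_size" & ct$anchor == "network_size"))
  expect_equal(spearman_rho(m$network_size, m$network_size)$value, 1)
  # an all-missing column reports missing, not an error
  m$density <- NA_real_
  ct2 <- correlation_table(m)
  expect_true(all(is.na(ct2$rho[ct2$metric == "density"])))
})

test_that("summary table is missing-aware and matches hand arithmetic", {
  d <- data.frame(network_size = c(3, 5, 10), density = c(0.2, NA, 0.6),
                  prop_kin = c(1, 1, 1))
  st <- summary_table(d, columns = c("network_size", "density", "prop_kin"))
  expect_equal(st$mean[st$metric == "network_size"], 6)
  expect_equal(st$n[st$metric == "density"], 2L)
  expect_equal(st$mean[st$metric == "density"], 0.4)
  expect_equal(st$sd[st$metric == "prop_kin"], 0)
  expect_equal(st$min[st$metric == "network_size"], 3)
})

test_that("write_analysis emits the two report tables with metadata sidecars", {
  sim <- simulate_cohort(default_config(25), seed = 6)
  m <- suppressWarnings(csnq_score(sim$egos, sim$alters))
  an <- csnq_analyze(m)
  dir <- withr::local_tempdir()
  files <- write_analysis(an, dir, seed = 6)
  expect_true(all(file.exists(files)))
  t1 <- utils::read.csv(file.path(dir, "table1.csv"))
  expect_named(t1, c("metric", "mean", "sd", "min", "max", "n"))
  t2 <- utils::read.csv(file.path(dir, "table2.csv"))
  expect_named(t2, c("metric", "anchor", "rho", "p_value", "adjusted_p", "n"))
  meta <- jsonlite::read_json(file.path(dir, "table1.csv.meta.json"))
  expect_equal(meta$package, "csnq")
  expect_equal(meta$seed, 6L)
})
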
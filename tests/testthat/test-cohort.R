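test_that("scan counts follow the repeat structure", {
  expect_equal(n_scans(cohort_spec()), 177L)
  expect_equal(nrow(simulate_ages(cohort_spec(), seed = 1)), 177L)

  one <- cohort_spec(n_children = 1, n_repeat2 = 0, n_repeat3 = 0)
  tab <- simulate_ages(one, seed = 3)
  expect_equal(nrow(tab), 1L)
  expect_gte(tab$age_days, 363)
  expect_lte(tab$age_days, 2198)

  expect_error(cohort_spec(n_repeat2 = 3, n_repeat3 = 5), "subset")
  expect_error(cohort_spec(n_children = 2, n_repeat2 = 3, n_repeat3 = 0),
               "exceed")
})

test_that("age tables are deterministic given a seed and stay in range", {
  a1 <- simulate_ages(cohort_spec(), seed = 42)
  a2 <- simulate_ages(cohort_spec(), seed = 42)
  expect_identical(a1, a2)
  expect_true(all(a1$age_days >= 363 & a1$age_days <= 2198))
  # repeat scans are ordered and roughly a year apart
  gaps <- unlist(tapply(a1$age_days, a1$child_id, diff))
  expect_true(all(gaps > 0))
  expect_lt(abs(mean(gaps) - 365), 60)
})

test_that("infeasible repeat structures error", {
  bad <- cohort_spec(n_children = 2, n_repeat2 = 1, n_repeat3 = 1,
                     age_range_days = c(363, 800),
                     mean_repeat_gap_days = 365)
  expect_error(simulate_ages(bad, seed = 1), "infeasible")
})

test_that("truncated-normal age option matches analytic truncated moments", {
  spec <- cohort_spec(n_children = 20000, n_repeat2 = 0, n_repeat3 = 0,
                      age_distribution = "truncnorm")
  ages <- simulate_ages(spec, seed = 7)$age_days
  # oracle: moments of N(1044, 523) truncated to [363, 2198]
  mu <- 1044; s <- 523; a <- (363 - mu) / s; b <- (2198 - mu) / s
  Z <- pnorm(b) - pnorm(a)
  m_true <- mu + s * (dnorm(a) - dnorm(b)) / Z
  expect_lt(abs(mean(ages) - m_true), 3 * s / sqrt(length(ages)) + 5)
  expect_true(all(ages >= 363 & ages <= 2198))
})

test_that("noiseless generation lies exactly on the logarithmic trend", {
  tr <- tiny_trajectories(regions = "caudal_middle_frontal",
                          residual_sd = c(thickness_mm = 0, cortical_mwf = 0,
                                          adjacent_mwf = 0))
  co <- simulate_cohort(small_cohort_spec(), tr,
                        tiny_couplings("caudal_middle_frontal"),
                        seed = 1, t1_sd_ms = 0)
  expect_equal(co$thickness_mm, 4.452 - 0.23 * log(co$age_days),
               tolerance = 1e-12)
  expect_equal(co$adjacent_mwf, 0.022 * log(co$age_days) - 0.035,
               tolerance = 1e-12)
  # frozen point value of the trend at the cohort mean age
  expect_equal(4.452 - 0.23 * log(1044), 2.853313, tolerance = 1e-6)
})

test_that("generated residual correlations converge to the spec correlation", {
  spec <- cohort_spec(n_children = 5000, n_repeat2 = 0, n_repeat3 = 0)
  co <- simulate_cohort(spec, tiny_trajectories("insula"),
                        tiny_couplings("insula", r_thickness_adjacent = 0.6,
                                       r_thickness_cortical = 0.6,
                                       r_cortical_adjacent = 0.6),
                        seed = 11)
  res <- sapply(c("thickness_mm", "cortical_mwf", "adjacent_mwf"),
                function(m) age_residuals(co$age_days, co[[m]]))
  cm <- cor(res)
  expect_true(all(abs(cm[upper.tri(cm)] - 0.6) < 0.03))
})

test_that("scan records respect measurement invariants", {
  co <- simulate_cohort(small_cohort_spec(), tiny_trajectories(),
                        tiny_couplings(), seed = 2)
  expect_true(all(co$cortical_mwf >= 0 & co$cortical_mwf <= 1))
  expect_true(all(co$adjacent_mwf >= 0 & co$adjacent_mwf <= 1))
  expect_true(all(co$thickness_mm > 0))
  expect_true(all(co$age_days >= 363 & co$age_days <= 2198))
  # determinism of the full table
  co2 <- simulate_cohort(small_cohort_spec(), tiny_trajectories(),
                         tiny_couplings(), seed = 2)
  expect_identical(co, co2)
})

test_that("non-positive-semi-definite coupling matrices error with the region name", {
  bad <- tiny_couplings("cuneus", r_thickness_adjacent = 0.9,
                        r_thickness_cortical = 0.9,
                        r_cortical_adjacent = -0.9)
  expect_error(simulate_cohort(small_cohort_spec(),
                               tiny_trajectories("cuneus"), bad, seed = 1),
               "cuneus.*positive semi-definite")
})

test_that("optional child-level intercepts induce within-child dependence", {
  tr <- tiny_trajectories("insula",
                          residual_sd = c(thickness_mm = 0.01,
                                          cortical_mwf = 0.01,
                                          adjacent_mwf = 0.01))
  co <- simulate_cohort(cohort_spec(n_children = 40, n_repeat2 = 20,
                                    n_repeat3 = 0),
                        tr, tiny_couplings("insula"), seed = 13,
                        child_intercept_sd = c(thickness_mm = 1,
                                               cortical_mwf = 0,
                                               adjacent_mwf = 0))
  res <- age_residuals(co$age_days, co$thickness_mm)
  twice <- names(which(table(co$child_id) == 2))
  pairs <- t(sapply(twice, function(id) res[co$child_id == id]))
  expect_gt(cor(pairs[, 1], pairs[, 2]), 0.9)   # intercept dominates noise
})
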
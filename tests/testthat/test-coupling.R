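test_that("pearson_r matches hand computations and guards degenerate input", {
  expect_equal(pearson_r(1:10, 2 * (1:10)), 1)
  expect_equal(pearson_r(c(-1, 0, 1), c(1, -2, 1)), 0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  # invariance to positive affine transforms
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(pearson_r(2.5 * x + 3, y), pearson_r(x, y), tolerance = 1e-12)
})

test_that("pearson_p implements the exact t transform", {
  expect_equal(pearson_p(0, 20), 1)
  expect_equal(pearson_p(1, 20), 0)
  expect_equal(pearson_p(-1, 20), 0)
  # dual route: agrees with cor.test on raw data
  set.seed(2)
  for (n in c(10, 50, 177)) {
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    ct <- cor.test(x, y)
    expect_equal(pearson_p(unname(ct$estimate), n), ct$p.value,
                 tolerance = 1e-12)
  }
})

test_that("pearson_p agrees with a permutation null at n = 20", {
  set.seed(3)
  n <- 20
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  r <- pearson_r(x, y)
  B <- 1e5
  perm <- replicate(B, abs(cor(x, sample(y))))
  phat <- mean(perm >= abs(r))
  se <- sqrt(phat * (1 - phat) / B)
  expect_lt(abs(pearson_p(r, n) - phat), 3 * se + 1e-4)
})

test_that("Holm step-down matches the hand example and reference loop", {
  expect_equal(holm_reject(c(0.001, 0.01, 0.02, 0.5)),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(holm_reject(rep(1, 6)), rep(FALSE, 6))
  expect_equal(holm_reject(rep(1e-9, 33)), rep(TRUE, 33))
  expect_equal(holm_reject(numeric(0)), logical(0))
  set.seed(4)
  for (i in 1:50) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_identical(holm_reject(p, 0.05), holm_stepdown_reference(p, 0.05))
    # family larger than the supplied p-vector
    expect_identical(holm_reject(p, 0.05, family_size = m + 5),
                     holm_stepdown_reference(p, 0.05, m = m + 5))
  }
})

test_that("Holm rejections sandwich between Bonferroni and uncorrected", {
  set.seed(5)
  for (i in 1:30) {
    p <- runif(sample(5:66, 1))^2
    holm <- holm_reject(p, 0.05)
    bonf <- p < 0.05 / length(p)
    raw <- p < 0.05
    expect_true(all(bonf[holm == FALSE] == FALSE))  # holm >= bonferroni
    expect_true(all(raw[holm] == TRUE))             # holm <= uncorrected
  }
})

test_that("coupling analysis recovers a generating correlation at n = 177", {
  co <- simulate_cohort(cohort_spec(),
                        tiny_trajectories("supramarginal"),
                        tiny_couplings("supramarginal"), seed = 6)
  res <- coupling_analysis(co, family_size = 33)
  row <- res[res$pair == "thickness_adjacent", ]
  expect_equal(row$n, 177)
  se <- (1 - 0.374^2) / sqrt(177 - 3)   # approximate SE of r at rho = -0.374
  expect_lt(abs(row$r - (-0.374)), 3 * se)
  expect_s3_class(res, "coupling_results")
  expect_true(all(res$family_size == 33))
  # significant flags obey the Holm threshold contract within each family
  for (pn in unique(res$pair)) {
    sel <- res$pair == pn
    expect_identical(res$significant[sel],
                     holm_stepdown_reference(res$p[sel], 0.05, m = 33))
  }
})

test_that("independent measures yield near-zero, non-significant couplings", {
  co <- simulate_cohort(cohort_spec(), tiny_trajectories(),
                        tiny_couplings(r_thickness_adjacent = 0,
                                       r_thickness_cortical = 0,
                                       r_cortical_adjacent = 0),
                        seed = 7)
  res <- coupling_analysis(co)
  expect_true(all(abs(res$r) < 0.3))
  expect_true(mean(res$significant) <= 1 / 6)  # stray rejections are rare
})

test_that("regions with degenerate measures are skipped with a warning", {
  co <- simulate_cohort(small_cohort_spec(), tiny_trajectories(),
                        tiny_couplings(), seed = 8)
  co$cortical_mwf[co$region == "cuneus"] <- 0.05   # constant -> zero variance
  expect_warning(res <- coupling_analysis(co), "skipping region cuneus")
  expect_false("cuneus" %in% res$region)
  expect_true("insula" %in% res$region)
})

test_that("printed p-values are consistent with printed r up to rounding", {
  # the printed r carry 3 decimals; the printed p must lie inside the p-range
  # induced by that rounding, and the r implied by the printed p must round
  # back to the printed r
  ref <- ref_couplings()
  cases <- list(c("supramarginal", "thickness_adjacent"),
                c("inferior_parietal", "thickness_adjacent"),
                c("caudal_middle_frontal", "thickness_adjacent"),
                c("caudal_anterior_cingulate", "thickness_adjacent"),
                c("entorhinal", "cortical_adjacent"))
  for (cs in cases) {
    row <- ref[ref$region == cs[1], ]
    r <- abs(row[[paste0("r_", cs[2])]])
    p_printed <- row[[paste0("p_", cs[2])]]
    expect_gte(p_printed, pearson_p(r + 5e-4, 177))
    expect_lte(p_printed, pearson_p(r - 5e-4, 177))
    r_implied <- uniroot(function(x) pearson_p(x, 177) - p_printed,
                         c(1e-6, 1 - 1e-9), tol = 1e-10)$root
    expect_equal(round(r_implied, 3), r, tolerance = 1e-9)
  }
})
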
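test_that("subject summaries are geometric means over replicate sites", {
  amounts <- tibble::tibble(
    subject_id = "S01", product_code = "REF",
    phase = rep(c("uptake", "clearance"), each = 2),
    replicate_index = c(1, 2, 1, 2),
    q_ug_cm2 = c(0.4, 0.9, 0.3, 0.3)
  )
  su <- subject_summaries(amounts)
  expect_equal(su$q_up, 0.6)
  expect_equal(su$q_cl, 0.3)
  # single replicate is the identity
  su1 <- subject_summaries(amounts[c(1, 3), ])
  expect_equal(su1$q_up, 0.4)
  # four pooled replicates
  pooled <- tibble::tibble(
    subject_id = "S01", product_code = "AVE",
    phase = rep(c("uptake", "clearance"), each = 4),
    replicate_index = rep(1:4, 2),
    q_ug_cm2 = c(1, 1, 4, 4, 1, 1, 4, 4)
  )
  expect_equal(subject_summaries(pooled)$q_up, 2)
  # permutation invariance over replicates
  perm <- amounts[c(2, 1, 4, 3), ]
  expect_equal(subject_summaries(perm)$q_up, su$q_up)
  # a missing phase is an error naming the cell
  expect_error(subject_summaries(amounts[1:2, ]), "clearance")
})

test_that("pooling products combines their replicate sites per subject", {
  amounts <- dplyr::bind_rows(
    tibble::tibble(subject_id = "S01", product_code = "REF",
                   phase = "uptake", replicate_index = 1:2,
                   q_ug_cm2 = c(1, 1)),
    tibble::tibble(subject_id = "S01", product_code = "CPOS",
                   phase = "uptake", replicate_index = 1:2,
                   q_ug_cm2 = c(4, 4))
  )
  ave <- pool_products(amounts, c("REF", "CPOS"), "AVE")
  expect_equal(sort(ave$replicate_index), 1:4)
  expect_equal(exp(mean(log(ave$q_ug_cm2))), 2)
})

test_that("flux and rate constant follow the two-point formulas", {
  expect_equal(flux_in_vivo(0.5, 0.5, 17), 0)
  expect_equal(flux_in_vivo(0.68, 0.45, 17), 1000 * 0.23 / 17)
  expect_equal(flux_in_vivo(0.68, 0.45, 17), 13.5, tolerance = 0.01)
  expect_equal(flux_in_vivo(0.85, 0.96, 17), -6.47, tolerance = 0.01)
  expect_equal(clearance_rate_constant(0.5, 0.5, 17), 0)
  expect_equal(clearance_rate_constant(0.68, 0.45, 17),
               log(0.68 / 0.45) / 17)
  expect_equal(clearance_rate_constant(0.68, 0.45, 17), 0.0243,
               tolerance = 0.01)
  expect_error(clearance_rate_constant(0.5, 0, 17), "positive")
  # inverse relation holds to machine precision
  k <- clearance_rate_constant(0.68, 0.45, 17)
  expect_equal(0.68 * exp(-k * 17), 0.45)
})

test_that("flux, rate constant and the exponential bridge are consistent", {
  set.seed(123)
  for (i in 1:100) {
    q_up <- runif(1, 0.05, 3)
    q_cl <- runif(1, 0.01, q_up)
    dt <- runif(1, 5, 40)
    j <- flux_in_vivo(q_up, q_cl, dt)
    k <- clearance_rate_constant(q_up, q_cl, dt)
    expect_equal(1000 * q_up * (1 - exp(-k * dt)) / dt, j,
                 tolerance = 1e-12)
  }
})

test_that("paired difference test handles typical and degenerate input", {
  x <- c(a = 1.2, b = 0.8, c = 1.5, d = 1.1)
  r0 <- paired_difference_test(x, x)
  expect_equal(r0$mean_difference, 0)
  expect_true(r0$degenerate)
  expect_true(is.na(r0$p_value))

  r1 <- paired_difference_test(x + 0.3, x)
  expect_equal(r1$mean_difference, 0.3)
  expect_equal(r1$ci_low, 0.3)
  expect_equal(r1$p_value, 0)
  expect_true(r1$degenerate)

  expect_warning(r2 <- paired_difference_test(c(a = 1, b = 2, z = 3),
                                              c(a = 2, b = 1, y = 0)),
                 "unpaired")
  expect_equal(r2$n, 2)

  # agreement with t.test on ordinary data
  set.seed(9)
  u <- rnorm(10); v <- rnorm(10)
  mine <- paired_difference_test(u, v)
  ref <- t.test(u, v, paired = TRUE, conf.level = 0.90)
  expect_equal(mine$p_value, unname(ref$p.value))
  expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref$conf.int))
})

test_that("the paired test rejects at its nominal 5% rate under the null", {
  set.seed(2024)
  n <- 10; reps <- 10000
  d <- matrix(rnorm(n * reps), n, reps)   # true difference zero
  tstat <- colMeans(d) / (apply(d, 2, sd) / sqrt(n))
  p <- 2 * pt(-abs(tstat), n - 1)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  # and the implementation agrees with the vectorised oracle on one draw
  one <- paired_difference_test(d[, 1], rep(0, n))
  expect_equal(one$p_value, p[1])
})

test_that("study-level kinetic tables carry geometric means and t intervals", {
  cfg <- synthetic_study_config(n_subjects = 8)
  am <- generate_site_amounts(cfg, seed = 5)
  su <- subject_summaries(am)
  tab <- kinetics_table(su, cfg$design)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$q_up_lo < tab$q_up_gm & tab$q_up_gm < tab$q_up_hi))
  per <- kinetics_by_subject(su, cfg$design)
  expect_equal(sign(per$j_ng_cm2_h), sign(per$k_per_h))
  expect_equal(sign(per$j_ng_cm2_h), sign(per$q_up - per$q_cl))
})
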
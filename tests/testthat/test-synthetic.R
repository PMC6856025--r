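test_that("generation is deterministic given the seed, to the written byte", {
  cfg <- synthetic_study_config(n_subjects = 3)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_study(generate_tape_records(cfg, seed = 42), p1)
  write_study(generate_tape_records(cfg, seed = 42), p2)
  expect_identical(readLines(p1), readLines(p2))
  # and a different seed gives different data
  expect_false(identical(generate_site_amounts(cfg, 1),
                         generate_site_amounts(cfg, 2)))
})

test_that("tape records conserve each site's drug amount before censoring", {
  cfg <- synthetic_study_config(n_subjects = 4)
  study <- generate_tape_records(cfg, seed = 8)
  d <- cfg$design
  raw <- study$tapes |>
    dplyr::group_by(subject_id, product_code, phase, replicate_index) |>
    dplyr::summarise(
      q_raw = sum(extract_conc_ug_ml) * d$extract_volume_ml / d$area_cm2,
      .groups = "drop")
  truth <- attr(study, "site_amounts")
  m <- merge(raw, truth)
  expect_equal(m$q_raw, m$q_ug_cm2, tolerance = 1e-12)
  expect_true(all(study$tapes$n_tapes_in_group <= 8))
})

test_that("LOQ censoring is exercised and applied consistently downstream", {
  cfg <- synthetic_study_config(n_subjects = 6, q_up_ref = 0.08)
  study <- generate_tape_records(cfg, seed = 15)
  d <- cfg$design
  analysed <- site_amounts(study)
  raw <- study$tapes |>
    dplyr::group_by(subject_id, product_code, phase, replicate_index) |>
    dplyr::summarise(
      q_raw = sum(extract_conc_ug_ml) * d$extract_volume_ml / d$area_cm2,
      n_below = sum(extract_conc_ug_ml < d$loq_ug_per_ml),
      .groups = "drop")
  m <- merge(analysed, raw)
  expect_gt(sum(m$n_below), 0)              # censoring path is hit
  censored <- m[m$n_below > 0 & m$q_ug_cm2 > 0.01368, ]
  expect_true(all(censored$q_ug_cm2 < censored$q_raw))
  expect_true(all(m$q_ug_cm2 > 0))          # LOQ/2 floor keeps Q positive
})

test_that("large synthetic studies recover their generating parameters", {
  cfg <- synthetic_study_config(
    n_subjects = 500, nr = 2, sigma_s = 0.4, sigma_w = 0.3,
    products = tibble::tibble(product_code = c("REF", "TEST"),
                              role = c("reference", "test"),
                              gmr = c(1, 0.9)))
  am <- generate_site_amounts(cfg, seed = 100)
  up <- am[am$phase == "uptake", ]
  ref <- up[up$product_code == "REF", c("subject_id", "q_ug_cm2")]
  expect_equal(s_wr(ref), 0.3, tolerance = 0.05)
  su <- subject_summaries(am)
  res <- abe(
    setNames(su$q_up[su$product_code == "TEST"],
             su$subject_id[su$product_code == "TEST"]),
    setNames(su$q_up[su$product_code == "REF"],
             su$subject_id[su$product_code == "REF"]))
  expect_equal(res$gmr, 0.9, tolerance = 0.05)
})

test_that("noise-free generation recovers the diffusion ground truth exactly", {
  cfg <- synthetic_study_config(sigma_s = 0, sigma_w = 0, t_lag_h = 18.9)
  am <- generate_site_amounts(cfg, seed = 1)
  su <- subject_summaries(am[am$product_code == "REF", ])
  fit <- fit_lag_time(su$q_up[1], su$q_cl[1], cfg$design$t_up_h,
                      cfg$design$delta_t_h)
  expect_equal(fit$t_lag_h, 18.9, tolerance = 1e-4)
  expect_equal(su$q_up[1], 0.65)
})

test_that("generated log amounts are consistent with log-normality", {
  cfg <- synthetic_study_config(
    n_subjects = 500, nr = 1,
    products = tibble::tibble(product_code = "REF", role = "reference",
                              gmr = 1))
  ok <- vapply(1:10, function(s) {
    am <- generate_site_amounts(cfg, seed = 1000 + s)
    q <- am$q_ug_cm2[am$phase == "uptake"]
    stats::shapiro.test(log(q))$p.value > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("the statistics-only log-normal clearance mode honours its W", {
  cfg <- synthetic_study_config(sigma_s = 0, sigma_w = 0,
                                clearance_model = "lognormal", w = 0.5)
  am <- generate_site_amounts(cfg, seed = 1)
  su <- subject_summaries(am[am$product_code == "REF", ])
  expect_equal(su$q_cl[1] / su$q_up[1], 0.5)
})

test_that("study-scale replicate variability follows its chi-square sampling law", {
  # 10 subjects, duplicate sites, sigma_w = 0.6: the squared replicate
  # estimator is sigma_w^2 chi^2_nu / nu with nu = n (nr - 1) = 10, so the
  # empirical frequency of s_wr in [0.4, 0.8] must match the chi-square
  # prediction within Monte-Carlo error
  cfg <- synthetic_study_config(n_subjects = 10, nr = 2, sigma_w = 0.6)
  inside <- vapply(1:200, function(s) {
    am <- generate_site_amounts(cfg, seed = s)
    ref <- am[am$phase == "uptake" & am$product_code == "REF",
              c("subject_id", "q_ug_cm2")]
    sw <- s_wr(ref)
    sw >= 0.4 && sw <= 0.8
  }, logical(1))
  nu <- 10
  p_theory <- stats::pchisq(nu * 0.8^2 / 0.6^2, nu) -
    stats::pchisq(nu * 0.4^2 / 0.6^2, nu)
  expect_lt(abs(mean(inside) - p_theory),
            3 * sqrt(p_theory * (1 - p_theory) / 200))
})
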
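test_that("a noise-free trial reproduces the true GMR exactly", {
  sc <- power_scenario(true_gmr = 0.9, sigma_wr = 0, sigma_s = 0,
                       n = 6, nr = 2, seed = 1)
  set.seed(1)
  tr <- simulate_trial(sc)
  expect_equal(unique(as.vector(tr$test / tr$ref)), 0.9)
  expect_equal(unique(as.vector(tr$ref)), 0.65)
})

test_that("simulated log differences are centred on the true log GMR", {
  sc <- power_scenario(true_gmr = 1, sigma_wr = 0.3, sigma_s = 0.4,
                       n = 200, nr = 2, seed = 4)
  set.seed(4)
  tr <- simulate_trial(sc)
  d <- rowMeans(log(tr$test)) - rowMeans(log(tr$ref))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(200))
  # one large trial recovers sigma_wr through the replicate estimator
  expect_equal(s_wr(tr$ref), 0.3, tolerance = 0.1)
})

test_that("power curves are reproducible and respond to GMR and margin", {
  sc <- power_scenario(n = c(8, 12), n_trials = 1000, seed = 7)
  expect_equal(be_power(sc), be_power(sc))
  far <- power_scenario(true_gmr = 3, sigma_wr = 0.3, sigma_s = 0.3,
                        n = 10, method = "sabe", n_trials = 1000, seed = 7)
  expect_lt(be_power(far)$power, 0.01)
  # widening the margin never loses power (same seeds)
  for (method in c("abe", "sabe")) {
    p125 <- be_power(power_scenario(margin = 1.25, method = method,
                                    n = c(6, 10, 16), n_trials = 1500,
                                    seed = 21))
    p133 <- be_power(power_scenario(margin = 1.33, method = method,
                                    n = c(6, 10, 16), n_trials = 1500,
                                    seed = 21))
    expect_true(all(p133$power >= p125$power))
  }
})

test_that("power is monotone in n and in the variance components", {
  curve <- be_power(power_scenario(method = "sabe", n = c(6, 10, 16, 24),
                                   n_trials = 2000, seed = 3))
  tol <- 3 * sqrt(0.25 / 2000)
  expect_true(all(diff(curve$power) > -tol))
  pows <- vapply(c(0.3, 0.6, 0.9), function(sw) {
    be_power(power_scenario(sigma_wr = sw, method = "abe", n = 12,
                            n_trials = 2000, seed = 8))$power
  }, numeric(1))
  expect_true(all(diff(pows) < tol))
})

test_that("subjects_needed returns the smallest adequate n on the grid", {
  sc0 <- power_scenario(true_gmr = 1, sigma_wr = 1e-3, sigma_s = 0,
                        n = c(4, 6, 8), method = "abe",
                        n_trials = 200, seed = 2)
  expect_equal(subjects_needed(sc0)$n_required, 4L)
  # SABE reaches the target with no more subjects than ABE
  grid <- c(6, 10, 14, 20, 28, 40, 60)
  need <- function(method) {
    subjects_needed(power_scenario(true_gmr = 1, sigma_wr = 0.6,
                                   sigma_s = 0.4, n = grid, method = method,
                                   n_trials = 1500, seed = 11))$n_required
  }
  n_abe <- need("abe"); n_sabe <- need("sabe")
  expect_true(is.na(n_abe) || n_sabe <= n_abe)
  expect_false(is.na(n_sabe))
  # unattainable targets are reported, not invented
  hard <- power_scenario(true_gmr = 2, sigma_wr = 0.3, sigma_s = 0.3,
                         n = c(4, 6), method = "abe", n_trials = 300,
                         seed = 5)
  res <- subjects_needed(hard)
  expect_true(is.na(res$n_required))
  expect_false(res$attained)
})

test_that("adding a third replicate site never increases the required n", {
  grid <- seq(4, 20, by = 2)
  need_nr <- function(nr) {
    subjects_needed(power_scenario(true_gmr = 1, sigma_wr = 0.6,
                                   sigma_s = 0.4, n = grid, nr = nr,
                                   method = "sabe", n_trials = 1500,
                                   seed = 17))$n_required
  }
  n2 <- need_nr(2); n3 <- need_nr(3)
  expect_false(is.na(n2) || is.na(n3))
  expect_lte(n3, n2)
})
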
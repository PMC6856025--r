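#' Scenario for Monte-Carlo bioequivalence power estimation
#'
#' Describes the data-generating model of a replicate-site, within-subject
#' comparison on the log scale:
#' `ln Q_{product, j, k} = mu + ln(GMR) 1[test] + S_j + eps_jk`,
#' with subject effects `S_j ~ N(0, sigma_s^2)` shared by both products and
#' independent site noise `eps_jk ~ N(0, sigma_w^2)` (the test product's
#' within-subject SD defaults to the reference's).
#'
#' @param true_gmr True geometric mean ratio (test/reference).
#' @param sigma_wr Within-subject (site-replicate) log SD of the reference.
#' @param sigma_wt Within-subject log SD of the test (default `sigma_wr`).
#' @param sigma_s Between-subject log SD.
#' @param n Vector of subject numbers to evaluate (each >= 3).
#' @param nr Replicate sites per product per subject.
#' @param margin Bioequivalence margin m.
#' @param method `"abe"` or `"sabe"`.
#' @param criterion For SABE: `"full"` applies both the scaled upper bound
#'   and the GMR point constraint; `"scaled_bound"` scores the upper bound
#'   alone (the event whose size is nominally 5% at the scaled boundary).
#' @param n_trials Simulated trials per grid point (default 10000;
#'   5e5 mirrors large production runs).
#' @param seed Master seed; per-grid-point streams are derived from it so
#'   curves are reproducible and nested in `n`.
#' @return A `power_scenario` list.
#' @export
power_scenario <- function(true_gmr = 1, sigma_wr = 0.6, sigma_wt = sigma_wr,
                           sigma_s = 0.4, n = 10, nr = 2, margin = 1.25,
                           method = c("sabe", "abe"),
                           criterion = c("full", "scaled_bound"),
                           n_trials = 10000, seed = 1) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  stopifnot(true_gmr > 0, sigma_wr >= 0, sigma_wt >= 0, sigma_s >= 0,
            all(n >= 3), nr >= 1, margin > 1, n_trials >= 1)
  structure(list(true_gmr = true_gmr, sigma_wr = sigma_wr,
                 sigma_wt = sigma_wt, sigma_s = sigma_s,
                 n = as.integer(n), nr = as.integer(nr), margin = margin,
                 method = method, criterion = criterion,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "power_scenario")
}

.scenario_seed <- function(seed, n) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(n)) %% .Machine$integer.max)
}

#' Simulate one replicate-design trial
#'
#' Draws per-subject, per-replicate amounts for test and reference under
#' the scenario's log-normal variance-component model.
#'
#' @param scenario A [power_scenario()] (its first `n` is used).
#' @param mu Baseline log amount of the reference (default `log(0.65)`,
#'   a typical areal amount in ug/cm^2).
#' @return A list of two n-by-nr matrices, `test` and `ref` (amounts, not
#'   logs).
#' @export
simulate_trial <- function(scenario, mu = log(0.65)) {
  stopifnot(inherits(scenario, "power_scenario"))
  n <- scenario$n[1]
  nr <- scenario$nr
  s <- rnorm(n, 0, scenario$sigma_s)
  ref <- exp(mu + s + matrix(rnorm(n * nr, 0, scenario$sigma_wr), n, nr))
  test <- exp(mu + log(scenario$true_gmr) + s +
                matrix(rnorm(n * nr, 0, scenario$sigma_wt), n, nr))
  list(test = test, ref = ref)
}

# Vectorised pass/fail over many trials for one n. Works on the
# within-subject noise only: the shared subject effect cancels from every
# statistic used by either decider.
.simulate_decisions <- function(n, nr, delta, sigma_wr, sigma_wt, margin,
                                method, criterion, n_trials) {
  lm <- log(margin)
  epsr <- array(rnorm(n * nr * n_trials, 0, sigma_wr), c(n, nr, n_trials))
  epst <- array(rnorm(n * nr * n_trials, 0, sigma_wt), c(n, nr, n_trials))
  mr <- colMeans(aperm(epsr, c(2, 1, 3)))          # n x trials, mean over nr
  mt <- colMeans(aperm(epst, c(2, 1, 3)))
  d <- delta + mt - mr                             # per-subject log differences
  dbar <- colMeans(d)
  sdd <- sqrt(colSums(sweep(d, 2, dbar)^2) / (n - 1))
  se <- sdd / sqrt(n)
  tq <- stats::qt(0.95, n - 1)
  if (method == "abe") {
    return((dbar + tq * se < lm) & (dbar - tq * se > -lm))
  }
  dev <- sweep(epsr, c(1, 3), mr)
  swr2 <- apply(dev^2, 3, sum) / (n * (nr - 1))
  theta <- (lm / 0.25)^2
  nu <- n * (nr - 1)
  eta <- dbar^2 - swr2 * theta
  u <- (abs(dbar) + tq * se)^2 - dbar^2
  v <- swr2 * theta * (nu / stats::qchisq(0.95, nu) - 1)
  scl_ub <- eta + sqrt(u^2 + v^2)
  ok <- scl_ub <= 0
  if (criterion == "full") ok <- ok & (abs(dbar) <= lm)
  ok
}

#' Monte-Carlo power of a bioequivalence decider
#'
#' Estimates, for each subject number in the scenario's grid, the
#' probability that the chosen decider (ABE or SABE) declares
#' bioequivalence under the scenario's data-generating model, with the
#' binomial Monte-Carlo standard error. Deterministic for a given seed.
#'
#' @param scenario A [power_scenario()].
#' @return A `power_curve` tibble: `n`, `power`, `mc_se`, `n_trials`.
#' @examples
#' be_power(power_scenario(n = c(6, 10), n_trials = 500, seed = 7))
#' @export
be_power <- function(scenario) {
  stopifnot(inherits(scenario, "power_scenario"))
  delta <- log(scenario$true_gmr)
  rows <- lapply(scenario$n, function(ni) {
    set.seed(.scenario_seed(scenario$seed, ni))
    ok <- .simulate_decisions(ni, scenario$nr, delta, scenario$sigma_wr,
                              scenario$sigma_wt, scenario$margin,
                              scenario$method, scenario$criterion,
                              scenario$n_trials)
    p <- mean(ok)
    tibble::tibble(n = ni, power = p,
                   mc_se = sqrt(p * (1 - p) / scenario$n_trials),
                   n_trials = scenario$n_trials)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("power_curve", class(out))
  out
}

#' Smallest number of subjects reaching a target power
#'
#' @param scenario A [power_scenario()] whose `n` is the candidate grid.
#' @param target_power Target power (default 0.8).
#' @return A list with `n_required` (NA when the target is not reached on
#'   the grid), `attained` and the underlying `curve`.
#' @export
subjects_needed <- function(scenario, target_power = 0.8) {
  curve <- be_power(scenario)
  hit <- curve$n[curve$power >= target_power]
  list(n_required = if (length(hit) > 0) min(hit) else NA_integer_,
       attained = length(hit) > 0, curve = curve)
}
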
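#' Within-subject standard deviation of log amounts (reference product)
#'
#' The replicate-site (within-subject) variability of the reference product
#' on the log scale,
#' `s_WR = sqrt( sum_jk [ln Q_jk - ln Qbar_j]^2 / (n (nr - 1)) )`,
#' where `Qbar_j` is the geometric mean of subject j's `nr` replicates.
#' This is the closed-form moment estimator used to decide whether a
#' product is highly variable and to scale the bioequivalence criterion.
#'
#' @param ref_replicates An n-by-nr matrix of strictly positive replicate
#'   amounts (rows = subjects), or a data frame with columns `subject_id`
#'   and `q_ug_cm2`. Every subject must have the same number `nr >= 2` of
#'   replicates.
#' @return `s_WR` (log-scale standard deviation, unitless).
#' @examples
#' s_wr(cbind(c(1, 2, 4), c(1, 2, 4) * exp(0.2)))
#' @export
s_wr <- function(ref_replicates) {
  m <- .replicate_matrix(ref_replicates)
  n <- nrow(m)
  nr <- ncol(m)
  if (nr < 2) stop("s_wr is undefined for nr = 1 (no within-subject replication)")
  lm <- log(m)
  dev <- lm - rowMeans(lm)
  sqrt(sum(dev^2) / (n * (nr - 1)))
}

.replicate_matrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("subject_id", "q_ug_cm2") %in% names(x)))
    counts <- table(x$subject_id)
    if (length(unique(counts)) != 1) {
      stop("every subject must have the same number of replicates")
    }
    m <- do.call(rbind, lapply(split(x$q_ug_cm2, x$subject_id), as.numeric))
  } else {
    m <- as.matrix(x)
  }
  if (!is.numeric(m) || any(!is.finite(m)) || any(m <= 0)) {
    stop("replicate amounts must be finite and strictly positive")
  }
  m
}

#' Classify a reference product as highly variable
#'
#' A reference product with within-subject log-scale standard deviation
#' strictly above the regulatory cut-off (0.294 by default) is classified
#' as highly variable, which motivates the reference-scaled assessment.
#'
#' @param s_wr Within-subject log SD, from [s_wr()].
#' @param threshold Cut-off (default 0.294).
#' @return A list with `s_wr`, `threshold` and `is_highly_variable`.
#' @export
classify_variability <- function(s_wr, threshold = 0.294) {
  stopifnot(s_wr >= 0, threshold > 0)
  list(s_wr = s_wr, threshold = threshold,
       is_highly_variable = s_wr > threshold)
}

#' Average bioequivalence (ABE) of log-normal drug amounts
#'
#' Classical average bioequivalence on per-subject paired amounts: with
#' `d_j = ln(test_j) - ln(ref_j)`, the point estimate of the geometric mean
#' ratio is `GMR = exp(mean d)` and the 90% confidence interval is
#' `exp(mean d +/- t_{0.95, n-1} sd(d)/sqrt(n))`. The products are
#' average-bioequivalent when the whole interval lies within `[1/m, m]`
#' (traditionally m = 1.25, i.e. 80-125%).
#'
#' @param test,ref Per-subject amounts (strictly positive), paired by names
#'   when both are named (unpaired subjects are dropped with a warning) or
#'   by position otherwise.
#' @param margin Bioequivalence margin m > 1 (presets 1.25 and 1.33).
#' @param conf_level Confidence level of the interval (default 0.90).
#' @return A `be_result` list: `method`, `gmr`, `ci_low`, `ci_high`,
#'   `margin`, `pass`, `n`, plus `s_wr`, `scl_ub` and related fields set to
#'   `NA` (they belong to the scaled assessment, [sabe()]).
#' @examples
#' set.seed(1)
#' r <- exp(rnorm(10, log(0.65), 0.3))
#' abe(r * 0.9 * exp(rnorm(10, 0, 0.2)), r)
#' @export
abe <- function(test, ref, margin = 1.25, conf_level = 0.90) {
  stopifnot(margin > 1)
  p <- .pair_subjects(test, ref)
  n <- length(p$test)
  if (n < 3) stop("at least 3 paired subjects are required")
  if (any(p$test <= 0) || any(p$ref <= 0)) {
    stop("amounts must be strictly positive")
  }
  d <- log(p$test) - log(p$ref)
  dbar <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
  ci <- exp(dbar + c(-1, 1) * tcrit * se)
  structure(list(
    method = "abe", gmr = exp(dbar), ci_low = ci[1], ci_high = ci[2],
    margin = margin, pass = ci[1] >= 1 / margin && ci[2] <= margin,
    n = n, nr = NA_integer_, s_wr = NA_real_, scl_ub = NA_real_,
    eta_hat = NA_real_, is_highly_variable = NA
  ), class = "be_result")
}

.pair_subjects <- function(test, ref) {
  if (!is.null(names(test)) && !is.null(names(ref))) {
    common <- intersect(names(test), names(ref))
    dropped <- length(union(names(test), names(ref))) - length(common)
    if (dropped > 0) {
      warning(dropped, " unpaired subject(s) excluded from the comparison")
    }
    list(test = unname(test[common]), ref = unname(ref[common]))
  } else {
    if (length(test) != length(ref)) stop("unnamed inputs must have equal length")
    list(test = unname(test), ref = unname(ref))
  }
}

#' Reference-scaled average bioequivalence (SABE)
#'
#' For highly variable endpoints the bioequivalence criterion is scaled by
#' the reference product's within-subject variability. The linearised
#' criterion is `eta = Delta^2 - s_WR^2 (ln m / 0.25)^2`, with `Delta` the
#' mean within-subject log difference (test minus reference, per-subject
#' geometric means over replicates) and `s_WR` from [s_wr()]. Its 95% upper
#' confidence bound `SCl_UB` is assembled by Howe's approximation from
#'
#' * the squared-mean component, via the t-based 95% upper limit on
#'   `|Delta|`: `U = (|Delta| + t_{0.95, n-1} SE)^2 - Delta^2`, and
#' * the scaled-variance component, via the chi-square 95% lower limit on
#'   the within-subject variance:
#'   `V = s_WR^2 ((n(nr-1)) / chisq_{0.95, n(nr-1)} - 1) (ln m / 0.25)^2`,
#'
#' as `SCl_UB = eta_hat + sqrt(U^2 + V^2)`. The products pass the scaled
#' assessment when `SCl_UB <= 0` *and* the point GMR lies within
#' `[1/m, m]`.
#'
#' @param test,ref n-by-nr matrices of replicate amounts (rows = subjects,
#'   aligned across the two matrices), or data frames with columns
#'   `subject_id` and `q_ug_cm2`. The reference replicates feed `s_WR`.
#' @inheritParams abe
#' @return A `be_result` list with `gmr`, `ci_low`, `ci_high` (the ABE-style
#'   interval on the per-subject geometric means), `s_wr`, `eta_hat`,
#'   `scl_ub`, `pass` (the conjunction above), `pass_scaled_bound`
#'   (`SCl_UB <= 0` alone), `n`, `nr` and the high-variability flag.
#' @export
sabe <- function(test, ref, margin = 1.25, conf_level = 0.90) {
  stopifnot(margin > 1)
  mt <- .replicate_matrix(test)
  mr <- .replicate_matrix(ref)
  if (nrow(mt) != nrow(mr)) stop("test and reference must have the same subjects")
  n <- nrow(mr)
  nr <- ncol(mr)
  if (n < 3) stop("at least 3 subjects are required")
  swr <- s_wr(mr)
  gt <- exp(rowMeans(log(mt)))
  gr <- exp(rowMeans(log(mr)))
  base <- abe(gt, gr, margin = margin, conf_level = conf_level)
  d <- log(gt) - log(gr)
  dbar <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  theta <- (log(margin) / 0.25)^2
  eta_hat <- dbar^2 - swr^2 * theta
  nu <- n * (nr - 1)
  u <- (abs(dbar) + stats::qt(0.95, n - 1) * se)^2 - dbar^2
  v <- swr^2 * theta * (nu / stats::qchisq(0.95, nu) - 1)
  scl_ub <- eta_hat + sqrt(u^2 + v^2)
  gmr_ok <- base$gmr >= 1 / margin && base$gmr <= margin
  structure(list(
    method = "sabe", gmr = base$gmr, ci_low = base$ci_low,
    ci_high = base$ci_high, margin = margin,
    pass = (scl_ub <= 0) && gmr_ok,
    pass_scaled_bound = scl_ub <= 0,
    n = n, nr = nr, s_wr = swr, eta_hat = eta_hat, scl_ub = scl_ub,
    is_highly_variable = classify_variability(swr)$is_highly_variable
  ), class = "be_result")
}

#' @export
print.be_result <- function(x, ...) {
  lab <- if (x$method == "abe") "Average bioequivalence" else
    "Reference-scaled average bioequivalence"
  cat(lab, sprintf("(m = %g, n = %d)\n", x$margin, x$n))
  cat(sprintf("  GMR %.3f (90%% CI %.3f-%.3f)\n", x$gmr, x$ci_low, x$ci_high))
  if (x$method == "sabe") {
    cat(sprintf("  s_WR %.3f%s, SCl_UB %+.3f\n", x$s_wr,
                if (isTRUE(x$is_highly_variable)) " (highly variable)" else "",
                x$scl_ub))
  }
  cat("  conclusion:", if (x$pass) "bioequivalent" else "not shown bioequivalent",
      "\n")
  invisible(x)
}
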
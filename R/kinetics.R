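#' Per-subject geometric-mean amounts for each product
#'
#' Collapses replicate application sites to one uptake and one clearance
#' amount per subject and product, using the geometric mean over the
#' replicate-site Q values. Pooled "average" products (e.g. a reference and
#' its duplicated positive control treated as one product with four
#' replicate sites) can be formed first with [pool_products()].
#'
#' @param amounts A tibble of per-site amounts as returned by
#'   [site_amounts()] (columns `subject_id`, `product_code`, `phase`,
#'   `replicate_index`, `q_ug_cm2`).
#' @return A tibble with one row per (subject, product): `q_up`, `q_cl`
#'   (ug/cm^2, geometric means) and `n_replicates_used` per phase.
#' @export
subject_summaries <- function(amounts) {
  stopifnot(all(c("subject_id", "product_code", "phase", "q_ug_cm2") %in%
                  names(amounts)))
  wide <- amounts |>
    dplyr::group_by(.data$subject_id, .data$product_code, .data$phase) |>
    dplyr::summarise(q = geomean(.data$q_ug_cm2), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = c("q", "n"))
  for (col in c("q_uptake", "q_clearance")) {
    if (!(col %in% names(wide)) || anyNA(wide[[col]])) {
      bad <- if (col %in% names(wide)) wide[is.na(wide[[col]]), ] else wide
      stop("missing ", sub("q_", "", col), " phase for subject ",
           bad$subject_id[1], ", product ", bad$product_code[1])
    }
  }
  tibble::tibble(
    subject_id = wide$subject_id,
    product_code = wide$product_code,
    q_up = wide$q_uptake, q_cl = wide$q_clearance,
    n_replicates_up = wide$n_uptake, n_replicates_cl = wide$n_clearance
  )
}

#' Pool two products into a combined pseudo-product
#'
#' Re-labels the sites of the given products as one product so that the
#' geometric mean in [subject_summaries()] runs over all their replicate
#' sites combined (e.g. four sites when pooling a duplicated reference).
#'
#' @param amounts Per-site amounts as in [subject_summaries()].
#' @param products Character vector of product codes to pool.
#' @param name Product code of the pooled product.
#' @return `amounts` for the pooled product only, re-labelled and with
#'   `replicate_index` renumbered within each site group.
#' @export
pool_products <- function(amounts, products, name) {
  sub <- amounts[amounts$product_code %in% products, , drop = FALSE]
  if (nrow(sub) == 0) stop("no sites found for products: ",
                           paste(products, collapse = ", "))
  sub$product_code <- name
  sub |>
    dplyr::group_by(.data$subject_id, .data$phase) |>
    dplyr::mutate(replicate_index = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Clearance flux from the SC into viable tissue
#'
#' The average flux over the clearance interval is the drop in areal drug
#' amount divided by the elapsed time, `J = (Q_up - Q_cl) / delta_t`,
#' reported in ng cm^-2 h^-1 (inputs in ug/cm^2). Negative values are
#' legitimate: measurement variability can make `Q_cl` exceed `Q_up`.
#'
#' @param q_up,q_cl Areal amounts at the end of uptake and clearance,
#'   ug/cm^2 (vectorised).
#' @param delta_t_h Clearance interval, h.
#' @return Flux in ng cm^-2 h^-1.
#' @examples
#' flux_in_vivo(0.68, 0.45, 17)
#' @export
flux_in_vivo <- function(q_up, q_cl, delta_t_h) {
  stopifnot(delta_t_h > 0)
  1000 * (q_up - q_cl) / delta_t_h
}

#' First-order clearance rate constant
#'
#' Under single-exponential clearance of drug from the SC,
#' `k = -ln(Q_cl / Q_up) / delta_t`, in h^-1. The inverse relation
#' `Q_cl = Q_up * exp(-k * delta_t)` holds to machine precision. Negative
#' values (when `Q_cl > Q_up`) are returned as-is.
#'
#' @inheritParams flux_in_vivo
#' @return k in h^-1.
#' @examples
#' clearance_rate_constant(0.68, 0.45, 17)
#' @export
clearance_rate_constant <- function(q_up, q_cl, delta_t_h) {
  stopifnot(delta_t_h > 0)
  if (any(q_up <= 0) || any(q_cl <= 0)) {
    stop("q_up and q_cl must be strictly positive")
  }
  -log(q_cl / q_up) / delta_t_h
}

#' Paired within-subject difference test
#'
#' For metrics that can legitimately be negative (flux, rate constant),
#' products are compared by the per-subject paired differences rather than
#' by log ratios: the mean difference, its t-based confidence interval and
#' the two-sided paired t-test p-value against a true difference of zero.
#'
#' @param values_test,values_ref Numeric vectors of per-subject metrics.
#'   Pairing is by the vectors' names when present (subjects missing from
#'   either side are dropped with a warning), otherwise by position.
#' @param conf_level Confidence level for the interval (default 0.90).
#' @return A list with `mean_difference`, `ci_low`, `ci_high`, `p_value`,
#'   `n` and `degenerate` (`TRUE` when the differences have zero variance,
#'   in which case the interval collapses to a point and the p-value is 0
#'   for a nonzero shift, NA for identical vectors).
#' @export
paired_difference_test <- function(values_test, values_ref,
                                   conf_level = 0.90) {
  if (!is.null(names(values_test)) && !is.null(names(values_ref))) {
    common <- intersect(names(values_test), names(values_ref))
    dropped <- length(union(names(values_test), names(values_ref))) -
      length(common)
    if (dropped > 0) {
      warning(dropped, " unpaired subject(s) excluded from the comparison")
    }
    values_test <- values_test[common]
    values_ref <- values_ref[common]
  } else if (length(values_test) != length(values_ref)) {
    stop("unnamed inputs must have equal length")
  }
  d <- values_test - values_ref
  n <- length(d)
  if (n < 2) stop("at least 2 paired subjects are required")
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(mean_difference = m, ci_low = m, ci_high = m,
                p_value = if (m == 0) NA_real_ else 0,
                n = n, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  tstat <- m / se
  list(mean_difference = m,
       ci_low = m - tcrit * se, ci_high = m + tcrit * se,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 1),
       n = n, degenerate = FALSE)
}

#' Per-subject and study-level kinetic tables
#'
#' Computes, from per-subject geometric-mean summaries, the clearance flux
#' and first-order rate constant for every subject and product
#' (`kinetics_by_subject()`), and the study-level summary per product
#' (`kinetics_table()`): geometric-mean amounts with t-based confidence
#' intervals of the log-mean, and arithmetic-mean flux and rate constant
#' with t-based confidence half-widths.
#'
#' @param summaries Output of [subject_summaries()].
#' @param design A [study_design()].
#' @param conf_level Confidence level (default 0.90).
#' @return A tibble.
#' @export
kinetics_by_subject <- function(summaries, design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  tibble::tibble(
    subject_id = summaries$subject_id,
    product_code = summaries$product_code,
    q_up = summaries$q_up, q_cl = summaries$q_cl,
    j_ng_cm2_h = flux_in_vivo(summaries$q_up, summaries$q_cl,
                              design$delta_t_h),
    k_per_h = clearance_rate_constant(summaries$q_up, summaries$q_cl,
                                      design$delta_t_h)
  )
}

#' @rdname kinetics_by_subject
#' @export
kinetics_table <- function(summaries, design = study_design(),
                           conf_level = 0.90) {
  per <- kinetics_by_subject(summaries, design)
  log_ci <- function(x) {
    lx <- log(x)
    n <- length(lx)
    half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * stats::sd(lx) / sqrt(n)
    c(gm = exp(mean(lx)), lo = exp(mean(lx) - half), hi = exp(mean(lx) + half))
  }
  mean_hw <- function(x) {
    n <- length(x)
    c(mean = mean(x),
      hw = stats::qt(1 - (1 - conf_level) / 2, n - 1) * stats::sd(x) / sqrt(n))
  }
  per |>
    dplyr::group_by(.data$product_code) |>
    dplyr::summarise(
      n = dplyr::n(),
      q_up_gm = log_ci(.data$q_up)[["gm"]],
      q_up_lo = log_ci(.data$q_up)[["lo"]],
      q_up_hi = log_ci(.data$q_up)[["hi"]],
      q_cl_gm = log_ci(.data$q_cl)[["gm"]],
      q_cl_lo = log_ci(.data$q_cl)[["lo"]],
      q_cl_hi = log_ci(.data$q_cl)[["hi"]],
      j_mean = mean_hw(.data$j_ng_cm2_h)[["mean"]],
      j_ci_halfwidth = mean_hw(.data$j_ng_cm2_h)[["hw"]],
      k_mean = mean_hw(.data$k_per_h)[["mean"]],
      k_ci_halfwidth = mean_hw(.data$k_per_h)[["hw"]],
      .groups = "drop"
    )
}
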
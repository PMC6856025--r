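#' Tape-stripping stopping rule
#'
#' Stripping of a site stops when the barrier is mostly removed, as judged
#' by transepidermal water loss (TEWL), or when a maximum tape count is
#' reached. The defaults are the conventional thresholds: an absolute TEWL
#' of 60 g m^-2 h^-1, a rise to more than 6 times the pre-stripping
#' baseline, or 30 tapes.
#'
#' @param tewl_absolute_limit Absolute TEWL limit, g m^-2 h^-1.
#' @param tewl_baseline_multiplier Multiple of the baseline TEWL above which
#'   stripping stops.
#' @param max_tapes Maximum number of tapes per site.
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(tewl_absolute_limit = 60,
                          tewl_baseline_multiplier = 6,
                          max_tapes = 30) {
  stopifnot(tewl_absolute_limit > 0, tewl_baseline_multiplier > 0,
            max_tapes > 0)
  structure(list(tewl_absolute_limit = tewl_absolute_limit,
                 tewl_baseline_multiplier = tewl_baseline_multiplier,
                 max_tapes = as.integer(max_tapes)),
            class = "stopping_rule")
}

#' Evaluate the stopping rule for one site
#'
#' @param tewl_baseline Pre-stripping TEWL reading, g m^-2 h^-1 (> 0).
#' @param tewl_series Numeric vector of TEWL readings taken during
#'   stripping; only the most recent reading enters the decision. May be
#'   empty, in which case only the tape count is assessed (with a warning).
#' @param n_tapes Number of tapes removed so far.
#' @param rule A [stopping_rule()].
#' @return A list with `stop` (logical) and `criterion`: one of
#'   `"absolute_tewl"`, `"tewl_multiple_of_baseline"`, `"max_tapes"`, or
#'   `NA_character_` when stripping continues. When several criteria fire
#'   simultaneously the first in that order is reported; the stop/continue
#'   decision itself does not depend on the order.
#' @examples
#' check_stopping_rule(10, c(12, 25, 61), n_tapes = 12)
#' @export
check_stopping_rule <- function(tewl_baseline, tewl_series, n_tapes,
                                rule = stopping_rule()) {
  stopifnot(inherits(rule, "stopping_rule"))
  if (!is.numeric(tewl_baseline) || length(tewl_baseline) != 1 ||
      tewl_baseline <= 0) {
    stop("tewl_baseline must be a single positive number")
  }
  if (length(tewl_series) == 0) {
    if (n_tapes < rule$max_tapes) {
      warning("no TEWL readings provided; only the tape count was assessed")
      return(list(stop = FALSE, criterion = NA_character_))
    }
    return(list(stop = TRUE, criterion = "max_tapes"))
  }
  latest <- tewl_series[length(tewl_series)]
  if (latest >= rule$tewl_absolute_limit) {
    return(list(stop = TRUE, criterion = "absolute_tewl"))
  }
  if (latest > rule$tewl_baseline_multiplier * tewl_baseline) {
    return(list(stop = TRUE, criterion = "tewl_multiple_of_baseline"))
  }
  if (n_tapes >= rule$max_tapes) {
    return(list(stop = TRUE, criterion = "max_tapes"))
  }
  list(stop = FALSE, criterion = NA_character_)
}

#' Stratum corneum mass per area and thickness for one site
#'
#' The SC mass collected on all tapes of a site, normalised by the sampled
#' area, converts to an apparent thickness through the SC density:
#' 1 mg/cm^2 at a density of 1 g/cm^3 corresponds to 10 um.
#'
#' @param sc_mass_mg Vector of per-tape-group SC masses, mg.
#' @param design A [study_design()] (supplies area and density).
#' @return A list with `mass_mg_per_cm2` and `thickness_um`.
#' @examples
#' sc_mass_and_thickness(c(2.3, 1.2, 1.15), study_design())
#' @export
sc_mass_and_thickness <- function(sc_mass_mg, design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  if (design$area_cm2 <= 0) stop("sampled area must be positive")
  stopifnot(all(sc_mass_mg >= 0))
  mass_per_area <- sum(sc_mass_mg) / design$area_cm2        # mg/cm^2
  # mg/cm^2 / (g/cm^3) = 1e-3 cm = 10 um
  thickness_um <- mass_per_area / design$sc_density_g_per_cm3 * 10
  list(mass_mg_per_cm2 = mass_per_area, thickness_um = thickness_um)
}

#' Areal drug amount Q for one site with LOQ handling
#'
#' Each tape group contributes `extract_conc * extract_volume` micrograms of
#' drug when its extract concentration is at or above the assay limit of
#' quantification (LOQ), and zero otherwise. Q is the summed drug mass
#' normalised by the sampled area. A site in which every group is below the
#' LOQ receives half the areal LOQ, `(LOQ * V / A) / 2`, so that Q stays
#' strictly positive and log-transformable.
#'
#' @param extract_conc_ug_ml Vector of per-group extract concentrations,
#'   ug/mL.
#' @param design A [study_design()].
#' @return Q in ug/cm^2 (always > 0).
#' @examples
#' site_amount_q(c(0.5, 0.2, 0.1), study_design())
#' site_amount_q(c(0.01, 0.02), study_design())  # all below LOQ
#' @export
site_amount_q <- function(extract_conc_ug_ml, design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  stopifnot(length(extract_conc_ug_ml) >= 1, all(extract_conc_ug_ml >= 0))
  v <- design$extract_volume_ml
  a <- design$area_cm2
  quantifiable <- extract_conc_ug_ml >= design$loq_ug_per_ml
  q <- sum(extract_conc_ug_ml[quantifiable] * v) / a
  if (q == 0) q <- (design$loq_ug_per_ml * v / a) / 2
  q
}

#' Depth-resolved concentration profile of one site
#'
#' Depth is expressed as the fraction of the *collected* SC, with interval
#' widths proportional to the per-group SC mass (groups are ordered from
#' the skin surface downwards). The local concentration of each segment is
#' the drug mass in the group divided by the volume of SC it removed.
#'
#' @param sc_mass_mg Per-group SC masses, mg (surface first).
#' @param extract_conc_ug_ml Per-group extract concentrations, ug/mL.
#' @param design A [study_design()].
#' @return A tibble with one row per group: `depth_from`, `depth_to`,
#'   `width` (fractions of collected SC), `concentration_ug_cm3` (NA for a
#'   zero-mass group) and `below_loq`.
#' @export
depth_profile <- function(sc_mass_mg, extract_conc_ug_ml,
                          design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  stopifnot(length(sc_mass_mg) == length(extract_conc_ug_ml),
            all(sc_mass_mg >= 0), all(extract_conc_ug_ml >= 0))
  total <- sum(sc_mass_mg)
  if (total <= 0) stop("total SC mass must be positive for a depth profile")
  width <- sc_mass_mg / total
  depth_to <- cumsum(width)
  depth_from <- c(0, depth_to[-length(depth_to)])
  drug_ug <- extract_conc_ug_ml * design$extract_volume_ml
  sc_volume_cm3 <- (sc_mass_mg / 1000) / design$sc_density_g_per_cm3
  conc <- ifelse(sc_mass_mg > 0, drug_ug / sc_volume_cm3, NA_real_)
  if (any(sc_mass_mg == 0)) {
    warning("zero-mass tape group(s): zero-width segment(s) with undefined ",
            "concentration")
  }
  tibble::tibble(
    group_index = seq_along(sc_mass_mg),
    depth_from = depth_from, depth_to = depth_to, width = width,
    concentration_ug_cm3 = conc,
    below_loq = extract_conc_ug_ml < design$loq_ug_per_ml
  )
}

#' Per-site quality-control and drug-amount tables
#'
#' `qc_table()` reports, for every application site, the number of tapes,
#' the SC mass per area and the apparent SC thickness. `site_amounts()`
#' reports the areal drug amount Q of every site (with the LOQ rule of
#' [site_amount_q()] applied).
#'
#' @param study A `dpk_study`.
#' @return A tibble with one row per application site.
#' @export
qc_table <- function(study) {
  stopifnot(inherits(study, "dpk_study"))
  design <- study$design
  study$tapes |>
    dplyr::group_by(.data$subject_id, .data$product_code, .data$phase,
                    .data$replicate_index) |>
    dplyr::summarise(
      n_tapes = sum(.data$n_tapes_in_group),
      mass_mg_per_cm2 = sum(.data$sc_mass_mg) / design$area_cm2,
      .groups = "drop"
    ) |>
    dplyr::mutate(thickness_um =
                    .data$mass_mg_per_cm2 / design$sc_density_g_per_cm3 * 10)
}

#' @rdname qc_table
#' @export
site_amounts <- function(study) {
  stopifnot(inherits(study, "dpk_study"))
  design <- study$design
  study$tapes |>
    dplyr::group_by(.data$subject_id, .data$product_code, .data$phase,
                    .data$replicate_index) |>
    dplyr::summarise(q_ug_cm2 = site_amount_q(.data$extract_conc_ug_ml, design),
                     .groups = "drop")
}
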
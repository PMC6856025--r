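#' Study design parameters for a tape-stripping study
#'
#' Bundles the fixed design constants of a two-time-point stratum corneum
#' (SC) sampling study: the duration of product application ("uptake"), the
#' interval between product removal and the second sampling ("clearance"),
#' the sampled skin area, the assay constants, and the design dimensions.
#'
#' @param t_up_h Uptake (application) duration in hours.
#' @param delta_t_h Clearance interval in hours, i.e. the time elapsed
#'   between the uptake and clearance measurements.
#' @param area_cm2 Skin area sampled by the tape-strip template, cm^2.
#' @param extract_volume_ml Solvent volume used to extract each tape group, mL.
#' @param loq_ug_per_ml Assay limit of quantification, ug/mL of extract.
#' @param sc_density_g_per_cm3 Assumed density of the stratum corneum,
#'   g/cm^3. The conventional value is 1.
#' @param n_subjects Number of subjects in the study.
#' @param n_replicates Number of replicate application sites per product per
#'   phase (per subject).
#'
#' @return An object of class `study_design` (a named list).
#' @examples
#' study_design()
#' @export
study_design <- function(t_up_h = 6, delta_t_h = 17, area_cm2 = 5,
                         extract_volume_ml = 3.6, loq_ug_per_ml = 0.038,
                         sc_density_g_per_cm3 = 1, n_subjects = 10,
                         n_replicates = 2) {
  d <- list(
    t_up_h = t_up_h, delta_t_h = delta_t_h, area_cm2 = area_cm2,
    extract_volume_ml = extract_volume_ml, loq_ug_per_ml = loq_ug_per_ml,
    sc_density_g_per_cm3 = sc_density_g_per_cm3,
    n_subjects = as.integer(n_subjects), n_replicates = as.integer(n_replicates)
  )
  num <- vapply(d, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("all design fields must be finite numeric scalars: ",
         paste(names(d)[!num], collapse = ", "))
  }
  pos <- vapply(d, function(x) x > 0, logical(1))
  if (!all(pos)) {
    stop("all design fields must be positive: ",
         paste(names(d)[!pos], collapse = ", "))
  }
  if (d$n_replicates < 1) stop("n_replicates must be >= 1")
  structure(d, class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Tape-stripping study design\n")
  cat(sprintf("  uptake %g h, clearance interval %g h\n", x$t_up_h, x$delta_t_h))
  cat(sprintf("  sampled area %g cm^2, extract volume %g mL, LOQ %g ug/mL\n",
              x$area_cm2, x$extract_volume_ml, x$loq_ug_per_ml))
  cat(sprintf("  SC density %g g/cm^3\n", x$sc_density_g_per_cm3))
  cat(sprintf("  %d subjects, %d replicate site(s) per product per phase\n",
              x$n_subjects, x$n_replicates))
  invisible(x)
}

#' Read or write a study design configuration file
#'
#' The configuration is a plain-text key-value (YAML-compatible) file with
#' the same keys as the arguments of [study_design()]. Unknown keys are an
#' error; missing keys take the defaults.
#'
#' @param path Path to the configuration file.
#' @return `read_design()` returns a `study_design`; `write_design()`
#'   invisibly returns `path`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_design))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown design key(s): ", paste(bad, collapse = ", "))
  }
  do.call(study_design, vals)
}

#' @rdname read_design
#' @param design A `study_design` object.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  yaml::write_yaml(unclass(design), path)
  invisible(path)
}
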
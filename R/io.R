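#' @keywords internal
#' @noRd
.study_columns <- c("subject_id", "product_code", "phase", "replicate_index",
                    "group_index", "sc_mass_mg", "extract_conc_ug_ml",
                    "n_tapes_in_group")

.site_key <- c("subject_id", "product_code", "phase", "replicate_index")

#' Read a tidy tape-stripping study table
#'
#' Reads a long/tidy CSV with one row per tape group per application site and
#' returns a validated `dpk_study` object. Required columns:
#' `subject_id`, `product_code`, `phase` (`"uptake"` or `"clearance"`),
#' `replicate_index`, `group_index` (ordinal from the skin surface),
#' `sc_mass_mg`, `extract_conc_ug_ml`. The column `n_tapes_in_group` is
#' optional and defaults to 1.
#'
#' @param path Path to the CSV file.
#' @param design A [study_design()] describing the study constants.
#' @return A `dpk_study`: a list with elements `tapes` (a tibble, one row per
#'   tape group, ordered by site and `group_index`) and `design`.
#' @export
read_study <- function(path, design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  if (!file.exists(path)) stop("study file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_dpk_study(df, design)
}

#' Build a `dpk_study` from an in-memory data frame
#'
#' @param tapes A data frame with the columns documented in [read_study()].
#' @param design A [study_design()].
#' @return A `dpk_study`.
#' @export
as_dpk_study <- function(tapes, design = study_design()) {
  df <- as.data.frame(tapes, stringsAsFactors = FALSE)
  if (!("n_tapes_in_group" %in% names(df))) df$n_tapes_in_group <- 1L
  missing_cols <- setdiff(.study_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df[.study_columns])
  bad_phase <- setdiff(unique(df$phase), c("uptake", "clearance"))
  if (length(bad_phase) > 0) {
    stop("phase must be 'uptake' or 'clearance'; found: ",
         paste(bad_phase, collapse = ", "))
  }
  if (any(df$sc_mass_mg < 0, na.rm = TRUE) || any(is.na(df$sc_mass_mg))) {
    stop("sc_mass_mg must be non-negative and non-missing")
  }
  if (any(df$extract_conc_ug_ml < 0, na.rm = TRUE) ||
      any(is.na(df$extract_conc_ug_ml))) {
    stop("extract_conc_ug_ml must be non-negative and non-missing")
  }
  key <- do.call(paste, c(df[c(.site_key, "group_index")], sep = "\r"))
  if (anyDuplicated(key) > 0) {
    dup <- df[duplicated(key), c(.site_key, "group_index")]
    stop("duplicate tape-group row(s), e.g. subject ", dup$subject_id[1],
         " product ", dup$product_code[1], " ", dup$phase[1],
         " replicate ", dup$replicate_index[1],
         " group ", dup$group_index[1])
  }
  df <- dplyr::arrange(df, .data$subject_id, .data$product_code, .data$phase,
                       .data$replicate_index, .data$group_index)
  structure(list(tapes = df, design = design), class = "dpk_study")
}

#' Write a `dpk_study` back to CSV
#'
#' Inverse of [read_study()]: the written file re-reads to an identical
#' study (round-trip identity on all columns).
#'
#' @param study A `dpk_study`.
#' @param path Output CSV path.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "dpk_study"))
  utils::write.csv(study$tapes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.dpk_study <- function(x, ...) {
  ns <- nrow(dplyr::distinct(x$tapes[.site_key]))
  cat(sprintf("dpk_study: %d application sites, %d tape groups, %d subject(s)\n",
              ns, nrow(x$tapes), length(unique(x$tapes$subject_id))))
  cat("products:", paste(sort(unique(x$tapes$product_code)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Check replicate balance of a study against its design
#'
#' Lists every (subject, product, phase) cell whose number of replicate
#' sites differs from the design's `n_replicates`. An empty report means the
#' study is fully balanced.
#'
#' @param study A `dpk_study`.
#' @return A tibble with columns `subject_id`, `product_code`, `phase`,
#'   `n_replicates_found`, `n_replicates_expected`, `status`
#'   (`"missing"` or `"extra"`). Zero rows when balanced.
#' @export
validate_design_balance <- function(study) {
  stopifnot(inherits(study, "dpk_study"))
  nr <- study$design$n_replicates
  cells <- study$tapes |>
    dplyr::distinct(.data$subject_id, .data$product_code, .data$phase,
                    .data$replicate_index) |>
    dplyr::count(.data$subject_id, .data$product_code, .data$phase,
                 name = "n_replicates_found")
  # cells entirely absent for one phase are also imbalances
  full <- tidyr::expand_grid(
    subject_id = unique(study$tapes$subject_id),
    product_code = unique(study$tapes$product_code),
    phase = c("uptake", "clearance")
  )
  out <- dplyr::left_join(full, cells,
                          by = c("subject_id", "product_code", "phase"))
  out$n_replicates_found[is.na(out$n_replicates_found)] <- 0L
  out$n_replicates_expected <- nr
  out <- out[out$n_replicates_found != nr, , drop = FALSE]
  out$status <- ifelse(out$n_replicates_found < nr, "missing", "extra")
  tibble::as_tibble(out)
}

#' Split a study into per-site tables
#'
#' @param study A `dpk_study`.
#' @return A list of tibbles, one per application site (unique combination
#'   of subject, product, phase and replicate), each ordered by
#'   `group_index`.
#' @export
study_sites <- function(study) {
  stopifnot(inherits(study, "dpk_study"))
  f <- interaction(study$tapes[.site_key], drop = TRUE, lex.order = TRUE)
  split(study$tapes, f)
}
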
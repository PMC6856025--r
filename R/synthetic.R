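#' Configuration of a synthetic tape-stripping study
#'
#' Defines the data-generating model for a complete synthetic study with
#' the statistical structure the analysis pipeline assumes: log-normal
#' per-site amounts with subject-level and within-subject (site) variance
#' components, product effects expressed as true geometric mean ratios
#' against the reference, duplicate sites per product and phase, and
#' clearance amounts derived from the slab-diffusion model so that kinetic
#' and diffusion stages have a recoverable ground truth.
#'
#' Defaults mimic a typical two-product-plus-positive-control study:
#' 10 subjects, duplicate sites, a reference uptake geometric mean of
#' 0.65 ug/cm^2, within-subject log SD 0.6, between-subject log SD 0.4,
#' a true lag time of 18.9 h with 6 h uptake and 17 h clearance
#' (retained fraction W of about 0.8).
#'
#' @param n_subjects Number of subjects.
#' @param products Data frame with columns `product_code`, `role` and
#'   `gmr` (true test/reference geometric mean ratio; 1 for the reference
#'   and its duplicate). Default: reference, positive control (gmr 1) and
#'   a test product with gmr 0.6.
#' @param sigma_s Between-subject log SD.
#' @param sigma_w Within-subject (site) log SD; a single value or one per
#'   product (named).
#' @param nr Replicate sites per product per phase.
#' @param q_up_ref Reference uptake geometric mean, ug/cm^2.
#' @param t_lag_h True diffusional lag time, h.
#' @param design A [study_design()]; supplies uptake duration, clearance
#'   interval, area, extract volume and LOQ (its `n_subjects`/`n_replicates`
#'   are overridden by the arguments here).
#' @param clearance_model `"diffusion"` derives the clearance mean from
#'   [clearance_fraction()] at the true lag time; `"lognormal"` uses the
#'   fixed retained fraction `w` instead (statistics-only mode).
#' @param w Retained fraction for `clearance_model = "lognormal"`.
#' @param tape_model List controlling tape-level generation: `mean_tapes`
#'   (mean tapes per site), `first_singles` (leading tapes extracted
#'   individually), `group_size` (range of tapes per later group),
#'   `mass_per_tape_mg` (mean SC mass on the first tape) and `mass_decline`
#'   (per-tape geometric decline of removed mass).
#' @return A `synthetic_study_config` list.
#' @export
synthetic_study_config <- function(
    n_subjects = 10,
    products = tibble::tibble(
      product_code = c("REF", "CPOS", "TEST"),
      role = c("reference", "positive_control", "test"),
      gmr = c(1, 1, 0.6)),
    sigma_s = 0.4, sigma_w = 0.6, nr = 2, q_up_ref = 0.65, t_lag_h = 18.9,
    design = study_design(n_subjects = n_subjects, n_replicates = nr),
    clearance_model = c("diffusion", "lognormal"), w = NULL,
    tape_model = list(mean_tapes = 14, first_singles = 2,
                      group_size = c(2, 8), mass_per_tape_mg = 0.55,
                      mass_decline = 0.92)) {
  clearance_model <- match.arg(clearance_model)
  stopifnot(n_subjects >= 1, nr >= 1, sigma_s >= 0, all(sigma_w >= 0),
            q_up_ref > 0, t_lag_h > 0, all(products$gmr > 0))
  stopifnot(all(c("product_code", "role", "gmr") %in% names(products)))
  if (clearance_model == "lognormal" && (is.null(w) || w <= 0)) {
    stop("clearance_model = 'lognormal' requires a positive retained fraction w")
  }
  if (length(sigma_w) > 1 &&
      !all(products$product_code %in% names(sigma_w))) {
    stop("per-product sigma_w must be named by product_code")
  }
  structure(list(n_subjects = as.integer(n_subjects), products = products,
                 sigma_s = sigma_s, sigma_w = sigma_w, nr = as.integer(nr),
                 q_up_ref = q_up_ref, t_lag_h = t_lag_h, design = design,
                 clearance_model = clearance_model, w = w,
                 tape_model = tape_model),
            class = "synthetic_study_config")
}

.sigma_w_for <- function(config, product) {
  if (length(config$sigma_w) == 1) unname(config$sigma_w)
  else unname(config$sigma_w[[product]])
}

.true_w <- function(config) {
  if (config$clearance_model == "diffusion") {
    clearance_fraction(config$design$t_up_h / config$t_lag_h,
                       config$design$delta_t_h / config$t_lag_h)
  } else {
    config$w
  }
}

#' Generate per-site areal amounts for a synthetic study
#'
#' Draws `ln Q_up,jk = ln(q_up_ref * gmr_p) + S_j + eps_jk` and
#' `ln Q_cl,jk = ln(q_up_ref * gmr_p * W) + S_j + eps'_jk`, with the
#' subject effect shared across products and phases and independent site
#' noise per replicate. `W` is the retained fraction of the clearance
#' model (see [synthetic_study_config()]).
#'
#' @param config A [synthetic_study_config()].
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A tibble of per-site amounts (`subject_id`, `product_code`,
#'   `role`, `phase`, `replicate_index`, `q_ug_cm2`), with the true
#'   parameter values attached as attribute `"truth"`.
#' @export
generate_site_amounts <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_study_config"))
  set.seed(seed)
  w <- .true_w(config)
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  s_j <- stats::setNames(rnorm(config$n_subjects, 0, config$sigma_s), subjects)
  grid <- tidyr::expand_grid(
    subject_id = subjects,
    product_code = config$products$product_code,
    phase = c("uptake", "clearance"),
    replicate_index = seq_len(config$nr)
  )
  grid <- dplyr::left_join(grid, config$products,
                           by = "product_code")
  sw <- vapply(grid$product_code, function(p) .sigma_w_for(config, p),
               numeric(1))
  mu <- log(config$q_up_ref * grid$gmr) +
    ifelse(grid$phase == "clearance", log(w), 0) +
    s_j[grid$subject_id]
  grid$q_ug_cm2 <- exp(mu + rnorm(nrow(grid), 0, sw))
  out <- grid[, c("subject_id", "product_code", "role", "phase",
                  "replicate_index", "q_ug_cm2")]
  attr(out, "truth") <- list(w = w, t_lag_h = config$t_lag_h,
                             gmr = stats::setNames(config$products$gmr,
                                                   config$products$product_code),
                             sigma_s = config$sigma_s,
                             sigma_w = config$sigma_w,
                             q_up_ref = config$q_up_ref)
  out
}

#' Generate a full tape-level synthetic study
#'
#' Expands per-site amounts into tape-group records: per site, a tape count
#' and per-tape SC masses (declining with depth) are drawn, tapes are
#' grouped (the leading tapes individually, the rest in groups), the
#' site's drug amount is distributed over the groups according to the
#' slab-diffusion concentration profile at the site's sampling time, and
#' extract concentrations follow from the extraction volume. Values below
#' the LOQ are written as generated; the analysis side applies the
#' censoring rule when computing Q.
#'
#' @inheritParams generate_site_amounts
#' @return A `dpk_study` whose `tapes` table carries one row per tape
#'   group. The per-site amounts used are attached as attribute
#'   `"site_amounts"`.
#' @export
generate_tape_records <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_study_config"))
  amounts <- generate_site_amounts(config, seed = seed)
  design <- config$design
  tm <- config$tape_model
  tau_up <- design$t_up_h / config$t_lag_h
  tau_cl <- design$delta_t_h / config$t_lag_h
  xg <- seq(0, 1, length.out = 201)
  prof_up <- uptake_profile(xg, tau_up)
  prof_cl <- clearance_profile(xg, tau_up, tau_cl)
  cum_frac <- function(prof) {
    cumamt <- cumsum((prof[-1] + prof[-length(prof)]) / 2) * diff(xg)
    c(0, cumamt / cumamt[length(cumamt)])
  }
  cf <- list(uptake = cum_frac(prof_up), clearance = cum_frac(prof_cl))

  rows <- lapply(seq_len(nrow(amounts)), function(i) {
    site <- amounts[i, ]
    n_tapes <- max(tm$first_singles + 1,
                   min(30, stats::rpois(1, tm$mean_tapes)))
    mass <- tm$mass_per_tape_mg * tm$mass_decline^(seq_len(n_tapes) - 1) *
      exp(rnorm(n_tapes, 0, 0.15))
    sizes <- c(rep(1, tm$first_singles))
    remaining <- n_tapes - tm$first_singles
    while (remaining > 0) {
      g <- sample(seq(tm$group_size[1], tm$group_size[2]), 1)
      g <- min(g, remaining)
      sizes <- c(sizes, g)
      remaining <- remaining - g
    }
    grp <- rep(seq_along(sizes), sizes)
    gmass <- as.numeric(tapply(mass, grp, sum))
    depth <- cumsum(gmass) / sum(gmass)
    edges <- c(0, depth)
    cfr <- cf[[site$phase]]
    frac <- diff(stats::approx(xg, cfr, xout = edges, rule = 2)$y)
    drug_ug <- site$q_ug_cm2 * design$area_cm2 * frac
    tibble::tibble(
      subject_id = site$subject_id, product_code = site$product_code,
      phase = site$phase, replicate_index = site$replicate_index,
      group_index = seq_along(sizes),
      sc_mass_mg = gmass,
      extract_conc_ug_ml = drug_ug / design$extract_volume_ml,
      n_tapes_in_group = sizes
    )
  })
  study <- as_dpk_study(dplyr::bind_rows(rows), design)
  attr(study, "site_amounts") <- amounts
  study
}
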
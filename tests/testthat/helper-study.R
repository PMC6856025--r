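# Build a minimal tidy tape table in code (no fixture files).
make_tape_rows <- function(subject = "S01", product = "REF", phase = "uptake",
                           replicate = 1L,
                           sc_mass = c(2.0, 1.5, 1.2),
                           conc = c(0.5, 0.2, 0.1)) {
  tibble::tibble(
    subject_id = subject, product_code = product, phase = phase,
    replicate_index = replicate, group_index = seq_along(sc_mass),
    sc_mass_mg = sc_mass, extract_conc_ug_ml = conc,
    n_tapes_in_group = rep(2L, length(sc_mass))
  )
}

# Fully crossed study: every (subject, product, phase, replicate) site gets
# `groups` tape groups.
make_balanced_tapes <- function(subjects, products, replicates = 2L,
                                groups = 3L) {
  grid <- expand.grid(subject_id = subjects, product_code = products,
                      phase = c("uptake", "clearance"),
                      replicate_index = seq_len(replicates),
                      stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    make_tape_rows(grid$subject_id[i], grid$product_code[i], grid$phase[i],
                   grid$replicate_index[i],
                   sc_mass = rep(1.5, groups),
                   conc = seq(0.6, 0.2, length.out = groups))
  }))
}

# Rescale a positive vector so its geometric mean is exactly `target`.
with_geomean <- function(x, target) x * target / exp(mean(log(x)))
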
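# Shared fixtures: small compositions, random geometry systems, and a tiny
# deterministic cohort, all built in code.

fc_hdl <- function(tg = 0.12, ce = 0.95, fc = 0.18, pl = 1.1, apo_a1 = 1.4) {
  fraction_composition("HDL", tg = tg, ce = ce, fc = fc, pl = pl,
                       apo_a1 = apo_a1)
}

fc_ldl <- function(tg = 0.18, ce = 1.9, fc = 0.55, pl = 0.85, apo_b = 0.72) {
  fraction_composition("LDL", tg = tg, ce = ce, fc = fc, pl = pl,
                       apo_b = apo_b)
}

# A bare geometry object without going through compositions, for flux-level
# unit tests where surfaces and ratios are specified directly.
geom <- function(fraction_id, surface, r, tg = r, ce = 1 - r,
                 n_particles = 1, radius = 1) {
  structure(list(fraction_id = fraction_id, n_particles = n_particles,
                 radius = radius, surface = surface, core_tg_ratio = r,
                 tg = tg, ce = ce),
            class = "fraction_geometry")
}

# Random n-fraction system with positive surfaces and ratios in (0, 1).
random_system <- function(n = 5) {
  ids <- head(c("CM", "VLDL_CMR", "IDL", "LDL", "HDL"), n)
  tg <- runif(n, 0.05, 2)
  ce <- runif(n, 0.05, 2)
  lapply(seq_len(n), function(i) {
    geom(ids[i], surface = runif(1, 0.1, 10), r = tg[i] / (tg[i] + ce[i]),
         tg = tg[i], ce = ce[i])
  })
}

# Random composition with all apolipoproteins for geometry property tests.
random_composition <- function(fraction_id = "LDL") {
  fraction_composition(fraction_id,
                       tg = runif(1, 0.01, 2), ce = runif(1, 0.01, 2),
                       fc = runif(1, 0.01, 1), pl = runif(1, 0.01, 2),
                       apo_b = if (fraction_id %in%
                                   cetpflux:::APOB_FRACTIONS)
                         runif(1, 0.005, 1) else NA_real_,
                       apo_a1 = if (fraction_id %in%
                                    cetpflux:::HDL_FRACTIONS)
                         runif(1, 0.2, 2) else NA_real_)
}

# Small deterministic noise-free cohort for pipeline tests.
noise_free_cohort <- function(n_normo = 2, seed = 11) {
  p <- generator_params(n_normo = n_normo, n_htg = 0, n_fcs = 0,
                        biological_cv = 0, apo_cv = 0, multiplier_cv = 0,
                        measurement_cv = 0, incubation_cv = 0)
  generate_cohort(p, seed = seed)
}

write_cohort_csv <- function(rows, path) {
  header <- "subject_id,phenotype,state,fraction,component,value,unit"
  writeLines(c(header, rows), path)
  path
}
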
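# Surface-driven heteroexchange model: fluxes, calibration, integration,
# equilibrium and the discriminating / nondiscriminating comparison.

test_that("two-fraction flux matches the hand-evaluated kernel", {
  geoms <- list(geom("LDL", surface = 1, r = 0.8),
                geom("HDL", surface = 1, r = 0.2))
  res <- instantaneous_tg_flux(geoms, k = 1)
  expect_equal(unname(res$flux[["LDL"]]), -0.3, tolerance = 1e-12)
  expect_equal(unname(res$flux[["HDL"]]), 0.3, tolerance = 1e-12)
  # equal ratios -> all-zero fluxes, not an error
  same <- list(geom("LDL", 2, 0.4), geom("HDL", 5, 0.4), geom("IDL", 1, 0.4))
  expect_true(all(instantaneous_tg_flux(same)$flux == 0))
  expect_error(instantaneous_tg_flux(list(geom("LDL", 1, 0.5))),
               class = "cetpflux_flux_error")
})

test_that("fluxes conserve mass, scale with k and with surfaces", {
  set.seed(601)
  for (i in 1:50) {
    geoms <- random_system(n = sample(2:5, 1))
    k <- runif(1, 0.1, 5)
    res <- instantaneous_tg_flux(geoms, k)
    scale <- max(abs(res$flux), 1)
    expect_lt(abs(sum(res$flux)), 1e-9 * scale)
    # homogeneity: scaling all surfaces by lambda scales fluxes by lambda
    lam <- runif(1, 0.3, 4)
    geoms2 <- lapply(geoms, function(g) { g$surface <- lam * g$surface; g })
    expect_equal(instantaneous_tg_flux(geoms2, k)$flux, lam * res$flux,
                 tolerance = 1e-9)
    # rate constant enters linearly
    expect_equal(instantaneous_tg_flux(geoms, 2 * k)$flux, 2 * res$flux,
                 tolerance = 1e-12)
    # the fraction with maximal r never gains TG
    r <- vapply(geoms, `[[`, numeric(1), "core_tg_ratio")
    expect_lte(res$flux[[which.max(r)]], 0)
  }
})

test_that("calibrate_k solves least squares through the origin", {
  geoms <- list(geom("VLDL_CMR", 2, 0.7), geom("LDL", 3, 0.2),
                geom("HDL", 4, 0.1))
  J1 <- instantaneous_tg_flux(geoms, 1)$flux
  # exact recovery when deltas are a multiple of the unit fluxes
  expect_equal(calibrate_k(geoms, 2 * J1), 2, tolerance = 1e-12)
  # hand least-squares oracle: unit surfaces with r = (0.9, 0.34, 0.26)
  # give J1 = (r_bar - r_i) = 0.4 * (-1, 0.4, 0.6); with deltas
  # 0.4 * (-2.2, 0.7, 1.3) the common 0.4 scale cancels, so
  # k = (2.2 + 0.28 + 0.78) / (1 + 0.16 + 0.36) = 3.26 / 1.52
  geoms_h <- list(geom("VLDL_CMR", 1, 0.9), geom("LDL", 1, 0.34),
                  geom("HDL", 1, 0.26))
  J1_h <- instantaneous_tg_flux(geoms_h, 1)$flux
  expect_equal(unname(J1_h), 0.4 * c(-1, 0.4, 0.6), tolerance = 1e-12)
  k_hand <- calibrate_k(geoms_h, 0.4 * c(VLDL_CMR = -2.2, LDL = 0.7,
                                         HDL = 1.3))
  expect_equal(k_hand, 3.26 / 1.52, tolerance = 1e-12)
  # orthogonal deltas -> k = 0 with a warning
  geoms2 <- list(geom("VLDL_CMR", 1, 0.8), geom("HDL", 1, 0.2))
  J2 <- instantaneous_tg_flux(geoms2, 1)$flux # (-0.3, +0.3)
  expect_warning(k0 <- calibrate_k(geoms2, c(VLDL_CMR = 1, HDL = 1)),
                 class = "cetpflux_calibration_warning")
  expect_equal(k0, 0, tolerance = 1e-12)
  # no gradient -> not identifiable
  flat <- list(geom("VLDL_CMR", 1, 0.5), geom("HDL", 1, 0.5))
  expect_error(calibrate_k(flat, c(VLDL_CMR = 1, HDL = -1)),
               class = "cetpflux_calibration_error")
  expect_error(calibrate_k(geoms, c(LDL = 1)),
               class = "cetpflux_calibration_error")
})

test_that("a measured TRL delta is matched to the CM + VLDL_CMR flux sum", {
  set.seed(602)
  geoms <- random_system(5) # CM, VLDL_CMR, IDL, LDL, HDL
  J1 <- instantaneous_tg_flux(geoms, 1)$flux
  k_true <- 1.7
  measured <- c(TRL = unname(k_true * (J1[["CM"]] + J1[["VLDL_CMR"]])),
                IDL = unname(k_true * J1[["IDL"]]),
                LDL = unname(k_true * J1[["LDL"]]),
                HDL = unname(k_true * J1[["HDL"]]))
  expect_equal(calibrate_k(geoms, measured), k_true, tolerance = 1e-9)
})

test_that("ODE integration matches the two-pool closed form to 1e-6", {
  geoms <- list(geom("VLDL_CMR", surface = 3, r = 0.7, tg = 0.7, ce = 0.3),
                geom("HDL", surface = 5, r = 0.1, tg = 0.05, ce = 0.45))
  k <- 40 # strong exchange so the hour covers several relaxation scales
  state <- exchange_state(geoms, k = k, mode = "ode")
  out <- integrate_exchange(state, duration = 1, dt = 1e-3)
  tg0 <- c(0.7, 0.05)
  totals <- c(1.0, 0.5)
  for (row in c(101, 501, 1001)) {
    t <- out$trajectory$time[row]
    expect_equal(out$trajectory$VLDL_CMR[row],
                 two_pool_closed_form(tg0, totals, c(3, 5), k, t),
                 tolerance = 1e-6)
  }
  # conservation at the end point
  expect_equal(out$state$tg + out$state$ce, totals, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("integration conserves totals, preserves heteroexchange symmetry and relaxes to equilibrium", {
  # fixed system with comparable surfaces/pools so every relaxation mode
  # decays by far more than the 1e-6 convergence target over the horizon
  geoms <- list(geom("VLDL_CMR", surface = 3, r = 0.75, tg = 0.6, ce = 0.2),
                geom("IDL", surface = 4, r = 0.4, tg = 0.2, ce = 0.3),
                geom("LDL", surface = 5, r = 0.1, tg = 0.1, ce = 0.9),
                geom("HDL", surface = 6, r = 0.15, tg = 0.12, ce = 0.68))
  state <- exchange_state(geoms, k = 500, mode = "ode")
  out <- integrate_exchange(state, duration = 50, dt = 5e-3)
  totals <- state$tg + state$ce
  # totals conserved fraction-wise (ce defined by conservation) and grand
  # totals of TG conserved by antisymmetry of the kernel
  expect_equal(out$state$tg + out$state$ce, totals, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(out$state$tg), sum(state$tg), tolerance = 1e-9)
  # per-fraction CE flux is the negative of the TG flux at every step
  d_tg <- out$state$tg - state$tg
  d_ce <- out$state$ce - state$ce
  expect_equal(d_ce, -d_tg, tolerance = 1e-12, ignore_attr = TRUE)
  # long-horizon limit: common ratio
  r_common <- equilibrium_ratio(geoms)
  r_final <- out$state$tg / totals
  expect_true(all(abs(r_final - r_common) < 1e-6))
  # duration 0 is the identity
  out0 <- integrate_exchange(state, duration = 0, dt = 1e-3)
  expect_equal(out0$state$tg, state$tg, ignore_attr = TRUE)
})

test_that("equilibrium ratio is the pooled TG share", {
  geoms <- list(geom("VLDL_CMR", 1, 0.5, tg = 1, ce = 1),
                geom("HDL", 1, 0.5, tg = 3, ce = 3))
  expect_equal(equilibrium_ratio(geoms), 0.5)
  # near-equilibrated state -> near-zero fluxes (hyperchylomicronemia regime)
  geoms2 <- list(geom("VLDL_CMR", 4, 0.501, tg = 0.501, ce = 0.499),
                 geom("LDL", 2, 0.5), geom("HDL", 3, 0.499, tg = 0.499,
                                           ce = 0.501))
  res <- instantaneous_tg_flux(geoms2, k = 1)
  expect_true(all(abs(res$flux) < 0.01 * sum(vapply(geoms2, `[[`,
                                                    numeric(1), "surface"))))
})

test_that("compare_model_configs is null for identical per-particle pools and flags missing CM", {
  # CM and VLDL_CMR with identical per-particle composition: merging
  # changes nothing, so all relative differences are 0. Equal ApoB molar
  # masses make "identical per-particle" exact across the two isoforms.
  const_eq <- molecular_constants(mw_apo_b48 = 512700)
  base <- fraction_composition("CM", tg = 0.4, ce = 0.05, fc = 0.02,
                               pl = 0.1, apo_b = 0.05)
  twin <- fraction_composition("VLDL_CMR", tg = 0.4, ce = 0.05, fc = 0.02,
                               pl = 0.1, apo_b = 0.05)
  rec <- subject_record("A", "normolipidemic", "postprandial", list(
    base, twin,
    fraction_composition("IDL", tg = 0.07, ce = 0.12, fc = 0.04, pl = 0.09,
                         apo_b = 0.0256),
    fc_ldl(), fc_hdl()))
  cmp <- compare_model_configs(rec, const_eq, k_policy = "shared", k = 1)
  expect_true(all(cmp$rel_diff < 1e-6))
  # missing CM -> nondiscriminating-only with warning
  rec2 <- subject_record("B", "normolipidemic", "postprandial", list(
    merge_fractions(base, twin),
    fraction_composition("IDL", tg = 0.07, ce = 0.12, fc = 0.04, pl = 0.09,
                         apo_b = 0.0256),
    fc_ldl(), fc_hdl()))
  expect_warning(cmp2 <- compare_model_configs(rec2, k = 1),
                 class = "cetpflux_comparison_warning")
  expect_null(cmp2$flux_disc)
  expect_s3_class(cmp2$flux_nondisc, "flux_result")
})

test_that("the nondiscriminating model overestimates TG enrichment of LDL and HDL", {
  # merging raises the TRL surface (count-preserving power mean) and with
  # it the surface-weighted mean ratio, so the net TG flux into LDL and
  # HDL is overestimated (signed: J_nondisc >= J_disc) on every draw
  gen <- generate_cohort(generator_params(n_normo = 15, n_htg = 0,
                                          n_fcs = 0), seed = 604)
  for (id in cohort_subjects(gen$dataset, paired = TRUE)) {
    rec <- get_record(gen$dataset, id, "postprandial")
    cmp <- compare_model_configs(rec, k_policy = "shared", k = 1)
    tol <- 1e-9 * max(abs(cmp$flux_disc$flux))
    expect_gte(cmp$flux_nondisc$flux[["LDL"]],
               cmp$flux_disc$flux[["LDL"]] - tol)
    expect_gte(cmp$flux_nondisc$flux[["HDL"]],
               cmp$flux_disc$flux[["HDL"]] - tol)
  }
})

test_that("subject_fluxes calibrates and integrates per record", {
  gen <- noise_free_cohort(n_normo = 1, seed = 605)
  rec <- get_record(gen$dataset, "S01", "postprandial")
  k_true <- gen$truth$S01$k_true
  res <- subject_fluxes(rec, config = "discriminating", k = "calibrate")
  expect_equal(res$k, k_true, tolerance = 1e-9)
  # ode mode over 1 h stays close to the linear per-hour flux
  res_ode <- subject_fluxes(rec, config = "discriminating", k = k_true,
                            mode = "ode", dt = 1e-2)
  expect_equal(res_ode$flux, instantaneous_tg_flux(
    attr(res, "geoms"), k_true)$flux, tolerance = 0.15)
})
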
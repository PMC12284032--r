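# Synthetic cohort generator with known ground truth.
#
# The stated world: fasting fraction compositions are drawn from independent
# log-normals around phenotype-specific medians chosen to satisfy the
# printed cohort ratios (normolipidemic fasting CM TG ~ 9.8% of TRL TG and
# ~6-7% of total TG; CM ApoB 27.5 nmol/l ~ 1.6% of total ApoB and ~13% of
# TRL ApoB; HTG total TG slightly above 2 mmol/l; FCS above 35 mmol/l).
# The postprandial state applies multiplicative shifts: CM PL x4, FC x7,
# TG x8; all VLDL+CMR components up; all LDL components except TG down;
# HDL TG up and CE down. TRL is CM + VLDL+CMR exactly. These medians are
# documented defaults, not the study's per-sample data.

#' Synthetic-data generator parameters
#'
#' @param n_normo,n_htg,n_fcs Subjects per phenotype (defaults 12/2/2, the
#'   evaluated study arms).
#' @param biological_cv Between-subject lognormal CV for lipid
#'   concentrations (default 0.25).
#' @param apo_cv Between-subject CV for apolipoproteins (default 0.20).
#' @param multiplier_cv Lognormal jitter (sdlog) on the postprandial
#'   multipliers (default 0.05, the largest round value keeping the stated
#'   shift directions - including all three non-TG LDL components jointly
#'   down - in >= 95% of subjects).
#' @param measurement_cv Multiplicative measurement noise CV for chamber
#'   concentrations (default 0.02).
#' @param incubation_cv Noise CV on the measured 1-h TG deltas (default
#'   0.02).
#' @param d_true_range Uniform range of the true plasma spillover
#'   coefficient (default `c(0.05, 0.3)`).
#' @param k_true_range Uniform range of the true exchange rate constant in
#'   (umol/l/h)/(m^2/l) (default `c(0.2, 0.35)`, centred on the value that
#'   reproduces fasting fluxes of ~22% of HDL TG and ~11% of LDL TG per hour
#'   at the default median subject).
#' @param apob_detection_limit Left-censoring threshold for ApoB in nmol/l
#'   (default 18); censored values are reported at the limit.
#' @param fcs_postprandial Generate a postprandial state for FCS subjects
#'   (default `FALSE`: the study sampled FCS fasting only).
#' @param correlated Add a shared subject-level lipemia factor to TG-bearing
#'   components (off by default; used for power studies).
#' @param lipemia_sd Sdlog of that shared factor.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_normo = 12, n_htg = 2, n_fcs = 2,
                             biological_cv = 0.25, apo_cv = 0.20,
                             multiplier_cv = 0.05, measurement_cv = 0.02,
                             incubation_cv = 0.02,
                             d_true_range = c(0.05, 0.3),
                             k_true_range = c(0.2, 0.35),
                             apob_detection_limit = 18,
                             fcs_postprandial = FALSE,
                             correlated = FALSE, lipemia_sd = 0.15) {
  stopifnot(n_normo >= 0, n_htg >= 0, n_fcs >= 0, biological_cv >= 0,
            apo_cv >= 0, multiplier_cv >= 0, measurement_cv >= 0,
            incubation_cv >= 0, length(d_true_range) == 2,
            length(k_true_range) == 2, all(d_true_range >= 0),
            all(k_true_range > 0))
  structure(list(n_normo = n_normo, n_htg = n_htg, n_fcs = n_fcs,
                 biological_cv = biological_cv, apo_cv = apo_cv,
                 multiplier_cv = multiplier_cv,
                 measurement_cv = measurement_cv,
                 incubation_cv = incubation_cv,
                 d_true_range = d_true_range, k_true_range = k_true_range,
                 apob_detection_limit = apob_detection_limit,
                 fcs_postprandial = fcs_postprandial,
                 correlated = correlated, lipemia_sd = lipemia_sd),
            class = "generator_params")
}

# Fasting composition medians (mmol/l lipids, g/l apolipoproteins).
fasting_medians <- function(phenotype) {
  normo <- list(
    CM = c(tg = 0.06, ce = 0.004, fc = 0.004, pl = 0.015,
                apo_b = 0.00677, apo_c2 = 0.002, apo_c3 = 0.005,
                apo_e = 0.002),
    VLDL_CMR = c(tg = 0.55, ce = 0.25, fc = 0.12, pl = 0.35, apo_b = 0.094,
                 apo_c2 = 0.003, apo_c3 = 0.010, apo_e = 0.004),
    IDL = c(tg = 0.07, ce = 0.12, fc = 0.04, pl = 0.09, apo_b = 0.0256,
            apo_e = 0.002),
    LDL = c(tg = 0.18, ce = 1.90, fc = 0.55, pl = 0.85, apo_b = 0.72,
            apo_c3 = 0.005),
    HDL = c(tg = 0.12, ce = 0.95, fc = 0.18, pl = 1.10, apo_a1 = 1.40,
            apo_a2 = 0.35, apo_c2 = 0.004, apo_c3 = 0.060, apo_e = 0.004),
    LDS = c(tg = 0.02, ce = 0.01, fc = 0.01, pl = 0.05, apo_a1 = 0.12,
            apo_c3 = 0.010))
  scale_fraction <- function(base, mult) {
    out <- base
    for (nm in names(mult)) out[nm] <- out[nm] * mult[[nm]]
    out
  }
  switch(phenotype,
    normolipidemic = normo,
    HTG = {
      m <- normo
      m$VLDL_CMR <- m$VLDL_CMR * 3.5
      m$CM <- m$CM * 1.6
      m$IDL <- m$IDL * 1.5
      m$HDL <- scale_fraction(m$HDL, c(tg = 1.3, ce = 0.9))
      m
    },
    FCS = list(
      CM = c(tg = 20, ce = 1.2, fc = 1.2, pl = 4.5, apo_b = 0.05,
             apo_c2 = 0.01, apo_c3 = 0.05, apo_e = 0.01),
      VLDL_CMR = c(tg = 16, ce = 1.0, fc = 1.0, pl = 3.8, apo_b = 0.417,
                   apo_c2 = 0.01, apo_c3 = 0.06, apo_e = 0.015),
      IDL = c(tg = 0.10, ce = 0.08, fc = 0.03, pl = 0.07, apo_b = 0.018,
              apo_e = 0.002),
      LDL = c(tg = 0.09, ce = 0.95, fc = 0.28, pl = 0.43, apo_b = 0.36,
              apo_c3 = 0.004),
      HDL = c(tg = 0.06, ce = 0.48, fc = 0.09, pl = 0.55, apo_a1 = 0.70,
              apo_a2 = 0.18, apo_c2 = 0.002, apo_c3 = 0.030,
              apo_e = 0.002),
      LDS = c(tg = 0.03, ce = 0.01, fc = 0.01, pl = 0.05, apo_a1 = 0.12,
              apo_c3 = 0.010)),
    abort_cetp(paste0("invalid phenotype ", phenotype), "generator_error"))
}

# Postprandial multipliers per fraction/component. Directions from the
# observed cohort: CM lipids up strongly (PL x4, FC x7, TG x8), CM ApoB only
# slightly; all VLDL+CMR components up, ApoB by more than CM ApoB; all LDL
# components except TG down; HDL TG up, CE down; ApoC3 shifts from HDL to
# the TG-rich fractions.
postprandial_multipliers <- function() {
  list(
    CM = c(tg = 8, ce = 4, fc = 7, pl = 4, apo_b = 1.3, apo_c2 = 2,
           apo_c3 = 3, apo_e = 2),
    VLDL_CMR = c(tg = 1.8, ce = 1.4, fc = 1.4, pl = 1.4, apo_b = 1.5,
                 apo_c2 = 1.5, apo_c3 = 2.5, apo_e = 1.5),
    IDL = c(tg = 1.1, ce = 1.1, fc = 1.1, pl = 1.1, apo_b = 1.1,
            apo_e = 1.1),
    LDL = c(tg = 1.05, ce = 0.88, fc = 0.88, pl = 0.88, apo_b = 0.9,
            apo_c3 = 0.9),
    HDL = c(tg = 1.5, ce = 0.85, fc = 0.95, pl = 0.97, apo_a1 = 1.0,
            apo_a2 = 1.0, apo_c2 = 0.8, apo_c3 = 0.45, apo_e = 0.9),
    LDS = c(tg = 1.0, ce = 1.0, fc = 1.0, pl = 1.0, apo_a1 = 1.0,
            apo_c3 = 1.0))
}

# Subfraction shares of the parent fraction (fasting / postprandial): ApoB
# moves out of the buoyant LDL1/LDL2; ApoA1 into HDL2b, out of HDL3.
LDL_SHARES_FASTING <- c(LDL1 = 0.08, LDL2 = 0.15, LDL3 = 0.25, LDL4 = 0.25,
                        LDL5 = 0.17, LDL6 = 0.10)
LDL_SHARES_POST <- c(LDL1 = 0.05, LDL2 = 0.11, LDL3 = 0.26, LDL4 = 0.27,
                     LDL5 = 0.19, LDL6 = 0.12)
HDL_SHARES_FASTING <- c(HDL2b = 0.25, HDL2a = 0.30, HDL3 = 0.45)
HDL_SHARES_POST <- c(HDL2b = 0.30, HDL2a = 0.31, HDL3 = 0.39)

sdlog_for_cv <- function(cv) sqrt(log(1 + cv^2))

draw_lognormal <- function(median_values, cv) {
  if (cv == 0) return(median_values)
  median_values * exp(stats::rnorm(length(median_values), 0,
                                   sdlog_for_cv(cv)))
}

make_composition <- function(fraction_id, values, allow_zero_missing = TRUE) {
  args <- as.list(values[names(values) %in% ALL_COMPONENTS])
  do.call(fraction_composition, c(list(fraction_id = fraction_id), args))
}

subfraction_compositions <- function(parent, shares, prefix_ids) {
  vals <- components(parent)
  lapply(prefix_ids, function(id) {
    v <- vals * shares[[id]]
    make_composition(id, v[!is.na(v)])
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws fasting compositions from independent log-normals around the
#' phenotype medians, applies the postprandial multipliers (with lognormal
#' jitter), derives TRL = CM + VLDL+CMR exactly, builds LDL/HDL subfractions
#' as shares of the parent, censors CM ApoB at the detection limit, and
#' simulates measured 1-h TG deltas at a subject-specific true rate constant
#' via [simulate_incubation()]. Deterministic for a fixed seed.
#'
#' @param params A [generator_params()].
#' @param seed Integer seed.
#' @param constants A [molecular_constants()] (for the incubation
#'   simulation).
#' @return List with `dataset` (a [cohort_dataset()]) and `truth` (class
#'   `cohort_truth`: per subject the true CM compositions, `d_true`,
#'   `k_true` and the noise-free deltas).
#' @export
generate_cohort <- function(params = generator_params(), seed = 1,
                            constants = molecular_constants()) {
  set.seed(seed)
  subjects <- list()
  truth <- list()
  specs <- c(rep("normolipidemic", params$n_normo),
             rep("HTG", params$n_htg), rep("FCS", params$n_fcs))
  mults <- postprandial_multipliers()

  for (i in seq_along(specs)) {
    phenotype <- specs[i]
    id <- sprintf("S%02d", i)
    medians <- fasting_medians(phenotype)
    lipemia <- if (params$correlated)
      exp(stats::rnorm(1, 0, params$lipemia_sd)) else 1

    fasting_vals <- lapply(medians, function(base) {
      lip <- intersect(names(base), LIPID_COMPONENTS)
      apo <- setdiff(names(base), lip)
      v <- c(draw_lognormal(base[lip], params$biological_cv),
             draw_lognormal(base[apo], params$apo_cv))
      v[["tg"]] <- v[["tg"]] * lipemia
      v
    })
    states <- list(fasting = fasting_vals)
    if (phenotype != "FCS" || params$fcs_postprandial) {
      states$postprandial <- lapply(stats::setNames(names(fasting_vals),
                                                    names(fasting_vals)),
        function(fid) {
          v <- fasting_vals[[fid]]
          m <- mults[[fid]][names(v)]
          m[is.na(m)] <- 1
          jitter <- if (params$multiplier_cv > 0)
            exp(stats::rnorm(length(v), 0, params$multiplier_cv)) else 1
          v * m * jitter
        })
    }

    d_true <- stats::runif(1, params$d_true_range[1], params$d_true_range[2])
    k_true <- stats::runif(1, params$k_true_range[1], params$k_true_range[2])
    subj_truth <- list(subject_id = id, phenotype = phenotype,
                       d_true = d_true, k_true = k_true, cm = list(),
                       deltas_true = list())

    for (state in names(states)) {
      vals <- states[[state]]
      cm_true <- make_composition("CM", vals$CM)
      subj_truth$cm[[state]] <- cm_true
      cm_reported <- cm_true
      limit_gl <- params$apob_detection_limit * 1e-9 *
        constants$mw[["apo_b48"]]
      if (!is.na(cm_reported$apo_b) && cm_reported$apo_b < limit_gl) {
        cm_reported$apo_b <- limit_gl
      }
      fractions <- list(cm_reported, make_composition("VLDL_CMR",
                                                      vals$VLDL_CMR),
                        make_composition("IDL", vals$IDL),
                        make_composition("LDL", vals$LDL),
                        make_composition("HDL", vals$HDL),
                        make_composition("LDS", vals$LDS))
      trl <- merge_fractions(fractions[[1]], fractions[[2]])
      ldl_shares <- if (state == "fasting") LDL_SHARES_FASTING else
        LDL_SHARES_POST
      hdl_shares <- if (state == "fasting") HDL_SHARES_FASTING else
        HDL_SHARES_POST
      fractions <- c(fractions, list(trl),
                     subfraction_compositions(fractions[[4]], ldl_shares,
                                              LDL_SUBFRACTIONS),
                     subfraction_compositions(fractions[[5]], hdl_shares,
                                              HDL_SUBFRACTIONS))
      rec <- subject_record(id, phenotype, state, fractions)
      sim <- simulate_incubation(rec, k_true, constants,
                                 noise_cv = params$incubation_cv)
      rec$measured_tg_delta <- sim$measured
      subj_truth$deltas_true[[state]] <- sim$true_delta
      subjects[[length(subjects) + 1L]] <- rec
    }
    truth[[id]] <- subj_truth
  }

  dataset <- cohort_dataset(subjects,
                            metadata = list(generator = "cetpflux",
                                            seed = seed,
                                            params = unclass(params)))
  list(dataset = dataset,
       truth = structure(truth, class = "cohort_truth"))
}

#' Forward-simulate a two-chamber measurement
#'
#' The forward process of the spillover correction: all CM material floats
#' into the inner chamber (concentrating by 1/F), a plasma fraction
#' `d_true` spills along, and the outer chamber retains CM-free plasma:
#' `c_in(X) = cm(X)/F + d_true * noncm(X)`, `c_out(X) = noncm(X)`, with
#' `c_in(apo_a1) = d_true * noncm(apo_a1)` since CM carries no ApoA1.
#' Multiplicative lognormal noise (mean 1) at `noise_cv` is applied per
#' measurement.
#'
#' @param cm True CM [fraction_composition()].
#' @param noncm Named numeric vector: component concentrations of the
#'   CM-free plasma (must include `apo_a1 > 0`).
#' @param d_true True spillover coefficient (>= 0).
#' @param constants [chamber_constants()].
#' @param noise_cv Measurement CV (0 = noise free).
#' @param subject_id,state Labels for the resulting measurement.
#' @return An [airfuge_measurement()].
#' @export
simulate_airfuge <- function(cm, noncm, d_true,
                             constants = chamber_constants(),
                             noise_cv = 0, subject_id = "sim",
                             state = "fasting") {
  stopifnot(d_true >= 0, all(noncm >= 0, na.rm = TRUE))
  if (!"apo_a1" %in% names(noncm) || noncm[["apo_a1"]] <= 0) {
    abort_cetp("non-CM plasma must contain ApoA1 > 0", "generator_error")
  }
  cm_vals <- components(cm)
  cm_vals[is.na(cm_vals)] <- 0
  cm_vals[["apo_a1"]] <- 0
  comps <- names(noncm)
  cm_in <- ifelse(comps %in% names(cm_vals), cm_vals[comps], 0)
  c_in <- cm_in / constants$F + d_true * noncm
  c_out <- noncm
  if (noise_cv > 0) {
    sdl <- sdlog_for_cv(noise_cv)
    noise <- function(x) x * exp(stats::rnorm(length(x), -sdl^2 / 2, sdl))
    c_in <- noise(c_in)
    c_out <- noise(c_out)
  }
  airfuge_measurement(subject_id, state,
                      c_in = stats::setNames(c_in, comps),
                      c_out = stats::setNames(c_out, comps))
}

#' Plasma composition without chylomicrons
#'
#' Component-wise sum over every measured fraction except CM (and the
#' derived TRL and subfractions), i.e. the outer-chamber reference of the
#' forward two-chamber process.
#'
#' @param record A [subject_record()].
#' @return Named numeric vector of component concentrations.
#' @export
noncm_plasma <- function(record) {
  ids <- setdiff(names(record$fractions),
                 c("CM", "TRL", LDL_SUBFRACTIONS, HDL_SUBFRACTIONS))
  out <- stats::setNames(numeric(length(ALL_COMPONENTS)), ALL_COMPONENTS)
  for (id in ids) {
    v <- components(record$fractions[[id]])
    v[is.na(v)] <- 0
    out <- out + v
  }
  out
}

#' Simulate the measured 1-h TG redistribution
#'
#' Evaluates the flux model at the subject's true compositions (CM and
#' VLDL+CMR as separate pools - the physical system discriminates) over one
#' hour at `k_true`, reports the deltas on the measured fractions (the
#' merged TRL plus IDL, LDL, HDL) and applies multiplicative noise.
#'
#' @param record A [subject_record()] with the model fractions present.
#' @param k_true True exchange rate constant.
#' @param constants A [molecular_constants()].
#' @param mode `"linear"` (instantaneous flux x 1 h) or `"ode"`.
#' @param noise_cv Measurement CV on the deltas.
#' @param duration Incubation time in hours (default 1).
#' @param dt ODE step size.
#' @return List with `measured` and `true_delta` (named numeric, umol/l).
#' @export
simulate_incubation <- function(record, k_true,
                                constants = molecular_constants(),
                                mode = c("linear", "ode"), noise_cv = 0,
                                duration = 1, dt = 1e-3) {
  mode <- match.arg(mode)
  flux <- subject_fluxes(record, constants, "discriminating", k = k_true,
                         mode = mode, duration = duration, dt = dt)
  J <- flux$flux
  true_delta <- c(TRL = unname(J[["CM"]] + J[["VLDL_CMR"]]),
                  IDL = unname(J[["IDL"]]), LDL = unname(J[["LDL"]]),
                  HDL = unname(J[["HDL"]])) * duration
  measured <- true_delta
  if (noise_cv > 0) {
    sdl <- sdlog_for_cv(noise_cv)
    measured <- true_delta * exp(stats::rnorm(length(true_delta),
                                              -sdl^2 / 2, sdl))
  }
  list(measured = measured, true_delta = true_delta)
}

#' Write a ground-truth object to JSON
#' @param truth A `cohort_truth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  ser <- lapply(truth, function(s) {
    list(subject_id = s$subject_id, phenotype = s$phenotype,
         d_true = s$d_true, k_true = s$k_true,
         cm = lapply(s$cm, function(f) {
           v <- components(f)
           as.list(v[!is.na(v)])
         }),
         deltas_true = s$deltas_true)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
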
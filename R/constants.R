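# Physical and nomenclature constants shared across the package.

AVOGADRO <- 6.02214076e23

LIPID_COMPONENTS <- c("tg", "ce", "fc", "pl")
APO_COMPONENTS <- c("apo_b", "apo_a1", "apo_a2", "apo_c2", "apo_c3", "apo_e")
ALL_COMPONENTS <- c(LIPID_COMPONENTS, APO_COMPONENTS)

LDL_SUBFRACTIONS <- paste0("LDL", 1:6)
HDL_SUBFRACTIONS <- c("HDL2b", "HDL2a", "HDL3")
FRACTION_IDS <- c("CM", "VLDL_CMR", "TRL", "IDL", "LDL", LDL_SUBFRACTIONS,
                  "HDL", HDL_SUBFRACTIONS, "LDS")

# Fractions counted by one ApoB copy per particle vs by ApoA1 stoichiometry.
APOB_FRACTIONS <- c("CM", "VLDL_CMR", "TRL", "IDL", "LDL", LDL_SUBFRACTIONS)
HDL_FRACTIONS <- c("HDL", HDL_SUBFRACTIONS)

PHENOTYPES <- c("normolipidemic", "HTG", "FCS")
STATES <- c("fasting", "postprandial")

# Pools entering the flux model (discriminating / nondiscriminating).
MODEL_FRACTIONS_DISC <- c("CM", "VLDL_CMR", "IDL", "LDL", "HDL")
MODEL_FRACTIONS_NONDISC <- c("TRL", "IDL", "LDL", "HDL")

#' Chamber constants for the two-chamber ultracentrifugation liner
#'
#' The rotor liner consists of an outer chamber (filled with plasma) and an
#' inner chamber (filled with saline) connected by a channel that opens during
#' the spin. Buoyant chylomicrons float from the outer into the inner chamber;
#' the volume ratio `F = v_inner / v_outer` converts inner-chamber
#' concentrations back to the plasma scale.
#'
#' @param v_inner Inner chamber volume in ml (default 0.9).
#' @param v_outer Outer chamber volume in ml (default 2.6).
#' @return An object of class `chamber_constants` with fields `v_inner`,
#'   `v_outer` and `F`.
#' @examples
#' chamber_constants()$F # 0.9 / 2.6
#' @export
chamber_constants <- function(v_inner = 0.9, v_outer = 2.6) {
  stopifnot(is.numeric(v_inner), is.numeric(v_outer),
            v_inner > 0, v_outer > 0)
  if (v_inner >= v_outer) {
    abort_cetp("inner chamber volume must be smaller than outer chamber volume",
               "chamber_error")
  }
  structure(list(v_inner = v_inner, v_outer = v_outer,
                 F = v_inner / v_outer),
            class = "chamber_constants")
}

#' Molecular constants for particle geometry
#'
#' Molar volumes of the lipid classes (nm^3 per molecule), the protein
#' partial specific volume, apolipoprotein molar masses, and the assumed
#' number of ApoA1 copies per HDL particle. All values are exposed here so
#' that recalibration is a configuration change, not a code change.
#'
#' Defaults: molecular volumes tg 1.61, ce 1.17, fc 0.64, pl 1.26 nm^3;
#' protein partial specific volume 0.73 ml/g; molar masses ApoB-100 512700,
#' ApoB-48 246000, ApoA1 28078 g/mol; 3 ApoA1 copies per HDL particle.
#'
#' @param v_tg,v_ce,v_fc,v_pl Molecular volumes in nm^3.
#' @param protein_psv Protein partial specific volume in ml/g.
#' @param mw_apo_b100,mw_apo_b48,mw_apo_a1,mw_apo_a2,mw_apo_c2,mw_apo_c3,mw_apo_e
#'   Molar masses in g/mol.
#' @param apoa1_per_hdl ApoA1 copies per HDL particle (particle counting rule
#'   for HDL and its subfractions).
#' @return An object of class `molecular_constants`.
#' @export
molecular_constants <- function(v_tg = 1.61, v_ce = 1.17, v_fc = 0.64,
                                v_pl = 1.26, protein_psv = 0.73,
                                mw_apo_b100 = 512700, mw_apo_b48 = 246000,
                                mw_apo_a1 = 28078, mw_apo_a2 = 17252,
                                mw_apo_c2 = 8916, mw_apo_c3 = 8764,
                                mw_apo_e = 34237, apoa1_per_hdl = 3) {
  out <- list(v = c(tg = v_tg, ce = v_ce, fc = v_fc, pl = v_pl),
              protein_psv = protein_psv,
              mw = c(apo_b100 = mw_apo_b100, apo_b48 = mw_apo_b48,
                     apo_a1 = mw_apo_a1, apo_a2 = mw_apo_a2,
                     apo_c2 = mw_apo_c2, apo_c3 = mw_apo_c3,
                     apo_e = mw_apo_e),
              apoa1_per_hdl = apoa1_per_hdl)
  if (any(unlist(out[c("v", "protein_psv", "mw", "apoa1_per_hdl")]) <= 0)) {
    abort_cetp("all molecular constants must be strictly positive",
               "constants_error")
  }
  structure(out, class = "molecular_constants")
}

#' Default package configuration
#'
#' Nested list of all tunable constants and model options: chamber volumes,
#' molecular constants, flux-model options, spillover-correction policy and
#' the synthetic-data generator parameters. Serialized as JSON by
#' [write_config()] and shown by the `config show` CLI subcommand.
#'
#' @return A nested list of class `cetpflux_config`.
#' @seealso [read_config()], [write_config()]
#' @export
cetpflux_config <- function() {
  structure(list(
    chamber = unclass(chamber_constants()),
    geometry = unclass(molecular_constants()),
    airfuge = list(policy = "clip", d_warn = 0.5),
    flux = list(mode = "linear", config = "both", k_policy = "shared",
                dt = 1e-3, duration = 1),
    generator = unclass(generator_params())
  ), class = "cetpflux_config")
}

#' Read a configuration file (JSON)
#' @param path Path to a JSON configuration file.
#' @return A `cetpflux_config` list; missing entries are filled from defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_cetp(paste0("config file not found: ", path),
                                     "config_error")
  user <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e) {
                     abort_cetp(paste0("config does not parse: ",
                                       conditionMessage(e)), "config_error")
                   })
  base <- cetpflux_config()
  structure(modify_list_deep(unclass(base), user), class = "cetpflux_config")
}

#' Write a configuration to JSON
#' @param config A configuration list.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

modify_list_deep <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

# Structured conditions: every package error carries class
# c("cetpflux_<sub>", "cetpflux_error", "error").
abort_cetp <- function(message, subclass) {
  stop(errorCondition(message,
                      class = c(paste0("cetpflux_", subclass),
                                "cetpflux_error")))
}

warn_cetp <- function(message, subclass) {
  warning(warningCondition(message,
                           class = c(paste0("cetpflux_", subclass),
                                     "cetpflux_warning")))
}
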
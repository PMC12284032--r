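# Chylomicron quantification from two-chamber ultracentrifugation.
#
# During the spin all buoyant chylomicrons float from the plasma-filled outer
# chamber (volume v_outer) into the saline-filled inner chamber (v_inner),
# dragging along a small amount of plasma. ApoA1 is essentially not
# CM-associated, so the inner/outer ApoA1 ratio D measures that plasma
# spillover, and for any component X the CM-associated concentration on the
# original plasma scale is
#
#   g_b,OC = F * (c_in(X) - D * c_out(X)),   F = v_inner / v_outer.

#' Two-chamber measurement of one plasma sample
#'
#' Component concentrations in the inner and outer chambers after the spin.
#' `c_in(X)` holds both the floated CM-associated material and the plasma
#' spillover; `c_out(X)` is the CM-free plasma reference. Must include
#' `apo_a1` (the spillover tracer) in both chambers, with
#' `c_out["apo_a1"] > 0`.
#'
#' @param subject_id,state Record key.
#' @param c_in,c_out Named numeric vectors of component concentrations
#'   (lipids mmol/l, apolipoproteins g/l).
#' @return An object of class `airfuge_measurement`.
#' @export
airfuge_measurement <- function(subject_id, state, c_in, c_out) {
  state <- match.arg(state, STATES)
  stopifnot(is.numeric(c_in), is.numeric(c_out),
            !is.null(names(c_in)), !is.null(names(c_out)))
  if (any(c(c_in, c_out) < 0, na.rm = TRUE)) {
    abort_cetp("negative chamber concentration", "airfuge_error")
  }
  structure(list(subject_id = as.character(subject_id), state = state,
                 c_in = c_in, c_out = c_out),
            class = "airfuge_measurement")
}

#' Plasma spillover coefficient D
#'
#' Ratio of inner- to outer-chamber ApoA1 concentration. ApoA1 does not
#' float with the chylomicrons, so D quantifies the fraction of plasma
#' carried from the outer into the inner chamber during the spin.
#'
#' @param c_in_apoa1 Inner-chamber ApoA1 concentration (g/l).
#' @param c_out_apoa1 Outer-chamber ApoA1 concentration (g/l), must be > 0.
#' @param d_warn Warn when D exceeds this (default 0.5; D > 1 always warns).
#' @return Dimensionless spillover coefficient `D = c_in / c_out`.
#' @examples
#' plasma_transfer_coefficient(0.3, 1.5) # 0.2
#' @export
plasma_transfer_coefficient <- function(c_in_apoa1, c_out_apoa1,
                                        d_warn = 0.5) {
  if (is.na(c_in_apoa1) || is.na(c_out_apoa1) || c_in_apoa1 < 0) {
    abort_cetp("ApoA1 tracer concentrations must be non-negative numbers",
               "tracer_error")
  }
  if (c_out_apoa1 <= 0) {
    abort_cetp("outer-chamber ApoA1 must be positive (undefined tracer ratio)",
               "tracer_error")
  }
  D <- c_in_apoa1 / c_out_apoa1
  if (D > 1) {
    warn_cetp(sprintf("D = %.3g > 1: more ApoA1 inside than outside is physically implausible",
                      D), "spill_warning")
  } else if (D > d_warn) {
    warn_cetp(sprintf("D = %.3g exceeds plausibility threshold %.3g", D,
                      d_warn), "spill_warning")
  }
  D
}

#' CM-associated concentration of one component
#'
#' Applies the spillover correction
#' `g_b,OC = F * (c_in(X) - D * c_out(X))` for a single component, returning
#' the CM-associated concentration on the original plasma scale. The raw
#' estimate can fall below zero for components that are essentially not
#' CM-associated (measurement noise on a near-zero quantity); the `policy`
#' argument decides whether to clip to 0, keep the negative value, or error.
#'
#' @param c_in_x,c_out_x Inner/outer chamber concentrations of X (>= 0).
#' @param D Spillover coefficient from [plasma_transfer_coefficient()].
#' @param constants [chamber_constants()].
#' @param policy `"clip"` (default), `"keep"` or `"error"`.
#' @return List with `value` (the corrected concentration) and `clipped`
#'   (logical: was a negative raw estimate clipped).
#' @examples
#' cm_component_concentration(1, 0, 0)$value # 0.9/2.6
#' @export
cm_component_concentration <- function(c_in_x, c_out_x, D,
                                       constants = chamber_constants(),
                                       policy = c("clip", "keep", "error")) {
  policy <- match.arg(policy)
  if (any(c(c_in_x, c_out_x, D) < 0, na.rm = TRUE)) {
    abort_cetp("chamber concentrations and D must be non-negative",
               "airfuge_error")
  }
  raw <- constants$F * (c_in_x - D * c_out_x)
  if (is.na(raw) || raw >= 0) return(list(value = raw, clipped = FALSE))
  switch(policy,
         clip = list(value = 0, clipped = TRUE),
         keep = list(value = raw, clipped = TRUE),
         error = abort_cetp(sprintf(
           "negative corrected concentration (%.4g) under policy 'error'",
           raw), "clip_error"))
}

#' Chylomicron composition from a two-chamber measurement
#'
#' Applies [cm_component_concentration()] to every component except the
#' ApoA1 tracer itself; CM ApoA1 is fixed at 0 (ApoA1 is essentially not
#' CM-associated). Returns the CM fraction composition plus the correction
#' diagnostics (D and the set of clipped components).
#'
#' @param m An [airfuge_measurement()].
#' @param constants [chamber_constants()].
#' @param policy Negative-value policy, see [cm_component_concentration()].
#' @param d_warn Plausibility threshold for D.
#' @return List with `cm` (a [fraction_composition()] with
#'   `fraction_id = "CM"`) and `correction` (class `cm_correction`: fields
#'   `g_b_oc`, `D`, `clipped`).
#' @export
cm_profile <- function(m, constants = chamber_constants(),
                       policy = c("clip", "keep", "error"), d_warn = 0.5) {
  policy <- match.arg(policy)
  if (!"apo_a1" %in% names(m$c_in) || !"apo_a1" %in% names(m$c_out)) {
    abort_cetp("ApoA1 tracer missing from chamber measurement",
               "tracer_error")
  }
  D <- plasma_transfer_coefficient(m$c_in[["apo_a1"]], m$c_out[["apo_a1"]],
                                   d_warn = d_warn)
  comps <- setdiff(intersect(names(m$c_in), names(m$c_out)), "apo_a1")
  g <- numeric(0)
  clipped <- character(0)
  for (x in comps) {
    res <- cm_component_concentration(m$c_in[[x]], m$c_out[[x]], D,
                                      constants, policy)
    g[[x]] <- res$value
    if (res$clipped) clipped <- c(clipped, x)
  }
  g[["apo_a1"]] <- 0
  args <- as.list(g[names(g) %in% ALL_COMPONENTS])
  cm <- do.call(fraction_composition,
                c(list(fraction_id = "CM",
                       .allow_negative = identical(policy, "keep")), args))
  correction <- structure(list(g_b_oc = g, D = D, clipped = clipped),
                          class = "cm_correction")
  list(cm = cm, correction = correction)
}

#' @export
print.cm_correction <- function(x, ...) {
  cat("<cm_correction> D =", signif(x$D, 4), "\n")
  if (length(x$clipped))
    cat("  clipped components:", paste(x$clipped, collapse = ", "), "\n")
  invisible(x)
}

#' Split a merged TRL fraction into VLDL+CMR given the CM composition
#'
#' Component-wise difference `TRL - CM`; the remainder is the fraction
#' containing VLDL and chylomicron remnants. Negative remainders (CM estimate
#' exceeding the TRL measurement) are handled per `policy`.
#'
#' @param trl [fraction_composition()] with `fraction_id = "TRL"`.
#' @param cm [fraction_composition()] with `fraction_id = "CM"`.
#' @param policy `"clip"` (default, with a warning), `"keep"` or `"error"`.
#' @return [fraction_composition()] with `fraction_id = "VLDL_CMR"`.
#' @export
split_trl <- function(trl, cm, policy = c("clip", "keep", "error")) {
  policy <- match.arg(policy)
  stopifnot(trl$fraction_id == "TRL", cm$fraction_id == "CM")
  out <- combine_compositions(trl, cm, `-`, "VLDL_CMR",
                              .allow_negative = TRUE)
  v <- components(out)
  # floating dust from an exactly-cancelling correction is zeroed silently
  scale <- pmax(abs(components(trl)), abs(components(cm)), 1, na.rm = TRUE)
  dust <- !is.na(v) & v < 0 & -v <= 1e-12 * scale
  for (nm in names(v)[dust]) out[[nm]] <- 0
  v[dust] <- 0
  neg <- names(v)[which(v < 0)]
  if (length(neg) && policy != "keep") {
    if (policy == "error") {
      abort_cetp(paste0("CM exceeds TRL for: ", paste(neg, collapse = ", ")),
                 "clip_error")
    }
    warn_cetp(paste0("CM exceeds TRL, clipped to 0: ",
                     paste(neg, collapse = ", ")), "clip_warning")
    for (nm in neg) out[[nm]] <- 0
  }
  out
}
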
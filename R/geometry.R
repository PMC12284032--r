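# Particle geometry: counts, radii, total surface areas and core TG ratios.
# Each fraction is modeled as monodisperse spheres. Particle counting uses
# one ApoB copy per particle (ApoB-48 molar mass for CM, ApoB-100 elsewhere)
# for the ApoB-containing fractions, and an ApoA1 stoichiometry
# (copies per particle, default 3) for HDL and its subfractions.
#
# Unit conventions: concentrations mmol/l (lipids) and g/l (protein);
# particle counts nmol/l; molecular volumes nm^3; radii nm; total surface
# m^2 per litre of plasma. Molecules per particle for a lipid X is
# (c_X [mmol/l] * 1e-3) / (N [nmol/l] * 1e-9) = c_X / N * 1e6.

#' Core triglyceride ratio r = TG/(TG + CE)
#'
#' The dimensionless composition parameter of the flux model: the TG share
#' of a fraction's neutral-lipid core, on molar concentrations. The gradient
#' of r across fractions drives the CETP-mediated TG net flux.
#'
#' @param c A [fraction_composition()].
#' @return r in `[0, 1]`.
#' @examples
#' core_tg_fraction(fraction_composition("HDL", tg = 1, ce = 1)) # 0.5
#' @export
core_tg_fraction <- function(c) {
  tot <- c$tg + c$ce
  if (is.na(tot) || tot <= 0) {
    abort_cetp(paste0("undefined core TG ratio: tg + ce = 0 in ",
                      c$fraction_id), "ratio_error")
  }
  c$tg / tot
}

#' Molar particle concentration of a fraction
#'
#' ApoB-containing fractions carry exactly one ApoB copy per particle, so
#' `N = apo_b mass / MW(ApoB)` with the ApoB-48 molar mass for CM and
#' ApoB-100 elsewhere. HDL fractions are counted via ApoA1 assuming a fixed
#' number of copies per particle.
#'
#' @param c A [fraction_composition()].
#' @param constants A [molecular_constants()].
#' @return Particle concentration in nmol/l.
#' @examples
#' # 0.05127 g/l ApoB-100 -> 100 nmol/l particles
#' particle_count(fraction_composition("LDL", tg = 1, ce = 1, apo_b = 0.05127))
#' @export
particle_count <- function(c, constants = molecular_constants()) {
  id <- c$fraction_id
  if (id %in% APOB_FRACTIONS) {
    if (is.na(c$apo_b) || c$apo_b <= 0) {
      abort_cetp(paste0("ApoB required to count particles in ", id),
                 "count_error")
    }
    mw <- if (id == "CM") constants$mw[["apo_b48"]] else
      constants$mw[["apo_b100"]]
    return(c$apo_b / mw * 1e9)
  }
  if (id %in% HDL_FRACTIONS) {
    if (is.na(c$apo_a1) || c$apo_a1 <= 0) {
      abort_cetp(paste0("ApoA1 required to count particles in ", id),
                 "count_error")
    }
    return(c$apo_a1 / constants$mw[["apo_a1"]] * 1e9 /
             constants$apoa1_per_hdl)
  }
  abort_cetp(paste0("no particle counting rule for fraction ", id),
             "count_error")
}

#' Particle geometry of a fraction
#'
#' Computes the per-particle volume from the molar lipid pools and the
#' protein mass (via the partial specific volume), treating the whole
#' particle as one sphere:
#' `V_p = sum_X n_X v_X + m_protein * psv`, `radius = (3 V_p / 4 pi)^(1/3)`,
#' `surface = N * N_A * 4 pi radius^2` per litre. Missing apolipoprotein
#' masses contribute zero protein volume.
#'
#' @param c A [fraction_composition()].
#' @param constants A [molecular_constants()].
#' @param n_particles Optional particle concentration (nmol/l) overriding
#'   the counting rules, used when the count is known from another source
#'   (e.g. a merged fraction whose constituent counts are known).
#' @return An object of class `fraction_geometry` with fields `fraction_id`,
#'   `n_particles` (nmol/l), `radius` (nm), `surface` (m^2/l),
#'   `core_tg_ratio`, and the molar `tg`/`ce` pools (mmol/l) carried along
#'   for the flux model.
#' @export
fraction_surface <- function(c, constants = molecular_constants(),
                             n_particles = NULL) {
  N <- if (is.null(n_particles)) particle_count(c, constants) else
    n_particles
  if (N <= 0) abort_cetp("particle count must be positive", "geometry_error")
  lipids <- components(c, LIPID_COMPONENTS)
  if (all(lipids == 0)) {
    abort_cetp(paste0("degenerate particle: no lipids in ", c$fraction_id),
               "geometry_error")
  }
  n_mol <- lipids / N * 1e6            # molecules per particle
  v_lipid <- sum(n_mol * constants$v[LIPID_COMPONENTS])
  apo_mass <- components(c, APO_COMPONENTS)
  apo_mass[is.na(apo_mass)] <- 0
  particles_per_l <- N * 1e-9 * AVOGADRO
  # g per particle * ml/g * 1e21 nm^3/ml
  v_protein <- sum(apo_mass) / particles_per_l * constants$protein_psv * 1e21
  v_p <- v_lipid + v_protein
  radius <- (3 * v_p / (4 * pi))^(1 / 3)
  surface <- particles_per_l * 4 * pi * radius^2 * 1e-18
  structure(list(fraction_id = c$fraction_id, n_particles = N,
                 radius = radius, surface = surface,
                 core_tg_ratio = core_tg_fraction(c),
                 tg = c$tg, ce = c$ce),
            class = "fraction_geometry")
}

#' @export
print.fraction_geometry <- function(x, ...) {
  cat(sprintf("<fraction_geometry> %s: N = %.4g nmol/l, r = %.4g nm, S = %.4g m2/l, TG/(TG+CE) = %.4g\n",
              x$fraction_id, x$n_particles, x$radius, x$surface,
              x$core_tg_ratio))
  invisible(x)
}

#' Merge two fractions into a combined TRL
#'
#' Component-wise sum of the two compositions, as obtained when CM and
#' VLDL+CMR are not separated (the classical density-gradient "VLDL"
#' fraction). Because the merged fraction is subsequently treated as
#' monodisperse, its computed surface is at least the sum of the split
#' surfaces (the power-mean inequality on per-particle volumes), with
#' equality only for equal radii - the geometric mechanism behind the
#' nondiscriminating model's slight flux overestimation.
#'
#' @param a,b [fraction_composition()] objects.
#' @param fraction_id Fraction id of the merged result (default `TRL`).
#' @return A [fraction_composition()].
#' @export
merge_fractions <- function(a, b, fraction_id = "TRL") {
  combine_compositions(a, b, `+`, fraction_id)
}

#' Count-preserving geometry of a merged TRL pool
#'
#' Treats the union of two fractions as one monodisperse population holding
#' the same particles: the merged particle count is the sum of the
#' constituent counts (each counted with its own ApoB isoform), and the
#' composition is the component-wise sum. This is the "two spheres with
#' identical radii" treatment of the nondiscriminating model; its surface
#' is >= the sum of the split surfaces, with equality iff the radii are
#' equal. Counting the merged ApoB mass entirely as ApoB-100 instead (as
#' one must for a TRL measured without a CM split) is *not*
#' count-preserving and is handled by [fraction_surface()] directly.
#'
#' @param a,b [fraction_composition()] objects (typically CM and VLDL+CMR).
#' @param constants A [molecular_constants()].
#' @return A `fraction_geometry` for the merged pool.
#' @export
merged_trl_geometry <- function(a, b, constants = molecular_constants()) {
  n <- particle_count(a, constants) + particle_count(b, constants)
  fraction_surface(merge_fractions(a, b), constants, n_particles = n)
}

#' Geometry table for a subject record
#'
#' Convenience wrapper running [fraction_surface()] over a set of fractions.
#'
#' @param record A [subject_record()].
#' @param fractions Fraction ids to include.
#' @param constants A [molecular_constants()].
#' @return Named list of `fraction_geometry` objects.
#' @export
record_geometry <- function(record, fractions = MODEL_FRACTIONS_DISC,
                            constants = molecular_constants()) {
  missing <- setdiff(fractions, names(record$fractions))
  if (length(missing)) {
    abort_cetp(paste0("subject ", record$subject_id, ": missing fraction(s) ",
                      paste(missing, collapse = ", ")), "geometry_error")
  }
  stats::setNames(lapply(fractions, function(id) {
    fraction_surface(record$fractions[[id]], constants)
  }), fractions)
}
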
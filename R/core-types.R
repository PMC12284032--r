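# Domain types. Lipid concentrations are molar (mmol/l), apolipoprotein
# concentrations are mass (g/l); conversion to molar happens only inside the
# particle-geometry stage.

#' Lipoprotein fraction composition
#'
#' Lipid and apolipoprotein concentrations of one lipoprotein fraction.
#' Lipids (`tg`, `ce`, `fc`, `pl`) are molar concentrations in mmol/l;
#' apolipoproteins are mass concentrations in g/l (`NA` when not measured).
#' Cholesteryl ester is the difference between total and free cholesterol,
#' so `ce >= 0` is enforced alongside non-negativity of all concentrations.
#'
#' @param fraction_id One of `CM`, `VLDL_CMR`, `TRL`, `IDL`, `LDL`,
#'   `LDL1`..`LDL6`, `HDL`, `HDL2b`, `HDL2a`, `HDL3`, `LDS`.
#' @param tg,ce,fc,pl Triglyceride, cholesteryl ester, free cholesterol and
#'   phospholipid concentrations (mmol/l).
#' @param apo_b,apo_a1,apo_a2,apo_c2,apo_c3,apo_e Apolipoprotein mass
#'   concentrations (g/l), `NA` if unmeasured.
#' @param .allow_negative Internal: permit negative values (used by the
#'   `keep` clipping policy of the spillover correction).
#' @return An object of class `fraction_composition`.
#' @examples
#' fraction_composition("HDL", tg = 0.12, ce = 0.95, fc = 0.18, pl = 1.1,
#'                      apo_a1 = 1.4)
#' @export
fraction_composition <- function(fraction_id, tg = 0, ce = 0, fc = 0, pl = 0,
                                 apo_b = NA_real_, apo_a1 = NA_real_,
                                 apo_a2 = NA_real_, apo_c2 = NA_real_,
                                 apo_c3 = NA_real_, apo_e = NA_real_,
                                 .allow_negative = FALSE) {
  fraction_id <- match.arg(fraction_id, FRACTION_IDS)
  vals <- c(tg = tg, ce = ce, fc = fc, pl = pl, apo_b = apo_b,
            apo_a1 = apo_a1, apo_a2 = apo_a2, apo_c2 = apo_c2,
            apo_c3 = apo_c3, apo_e = apo_e)
  if (!.allow_negative && any(vals < 0, na.rm = TRUE)) {
    bad <- names(vals)[which(vals < 0)]
    abort_cetp(paste0("negative concentration in fraction ", fraction_id,
                      ": ", paste(bad, collapse = ", ")), "composition_error")
  }
  structure(c(list(fraction_id = fraction_id), as.list(vals)),
            class = "fraction_composition")
}

#' @export
print.fraction_composition <- function(x, ...) {
  cat("<fraction_composition>", x$fraction_id, "\n")
  v <- components(x)
  v <- v[!is.na(v)]
  cat(paste0("  ", names(v), " = ", signif(v, 6),
             ifelse(names(v) %in% LIPID_COMPONENTS, " mmol/l", " g/l")),
      sep = "\n")
  invisible(x)
}

#' Extract the component vector of a fraction composition
#'
#' @param x A `fraction_composition`.
#' @param which Components to extract (default: all ten).
#' @return Named numeric vector (lipids mmol/l, apolipoproteins g/l).
#' @export
components <- function(x, which = ALL_COMPONENTS) {
  vapply(which, function(nm) as.numeric(x[[nm]]), numeric(1))
}

# Component-wise arithmetic used by merge/split. NA-aware: NA + x = x for
# apolipoproteins (unmeasured treated as absent), but NA - measured stays NA.
combine_compositions <- function(a, b, op = `+`, fraction_id,
                                 .allow_negative = FALSE) {
  va <- components(a)
  vb <- components(b)
  out <- op(ifelse(is.na(va), 0, va), ifelse(is.na(vb), 0, vb))
  out[is.na(va) & is.na(vb)] <- NA_real_
  do.call(fraction_composition,
          c(list(fraction_id = fraction_id, .allow_negative = .allow_negative),
            as.list(out)))
}

#' Per-subject, per-state record
#'
#' Holds the fraction compositions of one subject in one metabolic state
#' plus, optionally, the measured 1-hour triglyceride redistribution
#' (37 vs 4 degree C incubation deltas, in umol/l) per fraction.
#'
#' @param subject_id Subject identifier.
#' @param phenotype `normolipidemic`, `HTG` or `FCS`.
#' @param state `fasting` or `postprandial`.
#' @param fractions List of [fraction_composition()] objects; at most one per
#'   fraction id.
#' @param measured_tg_delta Optional named numeric vector mapping fraction id
#'   to the measured 1-h TG change (umol/l).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, phenotype, state, fractions = list(),
                           measured_tg_delta = NULL) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  state <- match.arg(state, STATES)
  ids <- vapply(fractions, function(f) f$fraction_id, character(1))
  if (anyDuplicated(ids)) {
    abort_cetp(paste0("subject ", subject_id, ": duplicate fraction(s) ",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "record_error")
  }
  names(fractions) <- ids
  if (!is.null(measured_tg_delta)) {
    stopifnot(is.numeric(measured_tg_delta), !is.null(names(measured_tg_delta)))
    bad <- setdiff(names(measured_tg_delta), FRACTION_IDS)
    if (length(bad)) {
      abort_cetp(paste0("unknown fraction in measured_tg_delta: ",
                        paste(bad, collapse = ", ")), "record_error")
    }
  }
  structure(list(subject_id = as.character(subject_id), phenotype = phenotype,
                 state = state, fractions = fractions,
                 measured_tg_delta = measured_tg_delta),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record>", x$subject_id, paste0("(", x$phenotype, ", ",
      x$state, ")"), "\n  fractions:",
      paste(names(x$fractions), collapse = ", "), "\n")
  if (!is.null(x$measured_tg_delta))
    cat("  measured 1-h TG deltas for:",
        paste(names(x$measured_tg_delta), collapse = ", "), "\n")
  invisible(x)
}

#' Cohort dataset
#'
#' A collection of [subject_record()]s (typically paired fasting and
#' postprandial records per subject) plus free-form provenance metadata.
#'
#' @param subjects List of subject records.
#' @param metadata Named list of provenance information.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(subjects = list(), metadata = list()) {
  keys <- vapply(subjects, function(s) paste(s$subject_id, s$state, sep = "/"),
                 character(1))
  if (anyDuplicated(keys)) {
    abort_cetp(paste0("duplicate (subject, state) record(s): ",
                      paste(unique(keys[duplicated(keys)]), collapse = ", ")),
               "dataset_error")
  }
  names(subjects) <- keys
  structure(list(subjects = subjects, metadata = metadata),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  ids <- unique(vapply(x$subjects, `[[`, character(1), "subject_id"))
  cat("<cohort_dataset>", length(x$subjects), "records,", length(ids),
      "subjects\n")
  invisible(x)
}

#' Fetch one record from a cohort
#' @param d A `cohort_dataset`.
#' @param subject_id,state Record key.
#' @return The matching [subject_record()], or `NULL`.
#' @export
get_record <- function(d, subject_id, state) {
  d$subjects[[paste(subject_id, state, sep = "/")]]
}

#' Subject identifiers of a cohort
#' @param d A `cohort_dataset`.
#' @param phenotype Optional filter.
#' @param paired If `TRUE`, restrict to subjects with both states present.
#' @return Character vector of subject ids.
#' @export
cohort_subjects <- function(d, phenotype = NULL, paired = FALSE) {
  ids <- vapply(d$subjects, `[[`, character(1), "subject_id")
  ph <- vapply(d$subjects, `[[`, character(1), "phenotype")
  keep <- if (is.null(phenotype)) rep(TRUE, length(ids)) else ph %in% phenotype
  ids <- unique(ids[keep])
  if (paired) {
    ids <- ids[vapply(ids, function(i) {
      !is.null(get_record(d, i, "fasting")) &&
        !is.null(get_record(d, i, "postprandial"))
    }, logical(1))]
  }
  ids
}

# Total plasma TG of a record, summing non-overlapping fractions. Uses the
# CM + VLDL_CMR split when available, the merged TRL otherwise.
total_tg <- function(record) {
  fr <- record$fractions
  trl_tg <- if (!is.null(fr$CM) || !is.null(fr$VLDL_CMR)) {
    sum(c(fr$CM$tg, fr$VLDL_CMR$tg))
  } else if (!is.null(fr$TRL)) fr$TRL$tg else 0
  others <- c("IDL", "LDL", "HDL", "LDS")
  trl_tg + sum(vapply(others, function(id) {
    if (is.null(fr[[id]])) 0 else fr[[id]]$tg
  }, numeric(1)))
}

#' Validation report
#'
#' @param errors,warnings Data frames with columns `subject_id`, `field`,
#'   `message`.
#' @param n_pass Number of records without errors.
#' @return An object of class `validation_report`.
#' @export
validation_report <- function(errors = report_frame(),
                              warnings = report_frame(), n_pass = 0L) {
  structure(list(errors = errors, warnings = warnings, n_pass = n_pass),
            class = "validation_report")
}

report_frame <- function(subject_id = character(), field = character(),
                         message = character()) {
  data.frame(subject_id = subject_id, field = field, message = message,
             stringsAsFactors = FALSE)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", nrow(x$errors), "error(s),", nrow(x$warnings),
      "warning(s),", x$n_pass, "record(s) pass\n")
  if (nrow(x$errors)) {
    cat("errors:\n")
    print(x$errors, row.names = FALSE)
  }
  if (nrow(x$warnings)) {
    cat("warnings:\n")
    print(x$warnings, row.names = FALSE)
  }
  invisible(x)
}
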
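#' Validate a cohort dataset
#'
#' Checks every type invariant and flags study-design exclusions. Findings
#' never raise conditions: everything goes into the returned report.
#'
#' Errors: negative concentrations; a merged TRL fraction that does not equal
#' the component-wise sum of CM and VLDL+CMR within tolerance; inconsistent
#' phenotype between a subject's fasting and postprandial records.
#'
#' Warnings: FCS subjects (loss of measurement precision at extreme TG);
#' subjects whose total plasma TG changed by less than `tg_change_threshold`
#' between states (study exclusion rule, kept as a warning so downstream
#' stages can apply an explicit include list); a record with only one state;
#' LDL1-LDL6 ApoB not summing to LDL ApoB within `subfraction_tol`
#' (separation losses).
#'
#' @param d A [cohort_dataset()].
#' @param tol Relative tolerance for the TRL = CM + VLDL+CMR identity.
#' @param subfraction_tol Relative mismatch tolerated between summed
#'   subfraction ApoB and the parent LDL ApoB before warning (default 10%).
#' @param tg_change_threshold Minimum relative total-TG change between states
#'   (default 0.20).
#' @return A [validation_report()].
#' @export
validate_dataset <- function(d, tol = 1e-6, subfraction_tol = 0.10,
                             tg_change_threshold = 0.20) {
  errors <- list()
  warnings <- list()
  add <- function(store, subject_id, field, message) {
    c(store, list(report_frame(subject_id, field, message)))
  }
  failed <- character()

  for (s in d$subjects) {
    key <- paste(s$subject_id, s$state, sep = "/")
    for (f in s$fractions) {
      v <- components(f)
      if (any(v < 0, na.rm = TRUE)) {
        errors <- add(errors, s$subject_id,
                      paste0(s$state, "/", f$fraction_id),
                      paste0("negative concentration: ",
                             paste(names(v)[which(v < 0)], collapse = ", ")))
        failed <- c(failed, key)
      }
    }
    fr <- s$fractions
    if (!is.null(fr$TRL) && !is.null(fr$CM) && !is.null(fr$VLDL_CMR)) {
      expect <- combine_compositions(fr$CM, fr$VLDL_CMR, `+`, "TRL")
      ve <- components(expect)
      vt <- components(fr$TRL)
      both <- !is.na(ve) & !is.na(vt)
      scale <- pmax(abs(ve[both]), abs(vt[both]), 1e-12)
      if (any(abs(ve[both] - vt[both]) / scale > tol)) {
        errors <- add(errors, s$subject_id, paste0(s$state, "/TRL"),
                      "TRL does not equal CM + VLDL_CMR component-wise")
        failed <- c(failed, key)
      }
    }
    if (!is.null(fr$LDL) && !is.na(fr$LDL$apo_b) && fr$LDL$apo_b > 0) {
      subs <- fr[names(fr) %in% LDL_SUBFRACTIONS]
      if (length(subs) == length(LDL_SUBFRACTIONS)) {
        apo_sum <- sum(vapply(subs, function(f) {
          if (is.na(f$apo_b)) 0 else f$apo_b
        }, numeric(1)))
        if (abs(apo_sum - fr$LDL$apo_b) / fr$LDL$apo_b > subfraction_tol) {
          warnings <- add(warnings, s$subject_id, paste0(s$state, "/LDL"),
                          sprintf("LDL subfraction ApoB sum deviates %.1f%% from LDL ApoB",
                                  100 * abs(apo_sum - fr$LDL$apo_b) /
                                    fr$LDL$apo_b))
        }
      }
    }
  }

  for (id in cohort_subjects(d)) {
    fast <- get_record(d, id, "fasting")
    post <- get_record(d, id, "postprandial")
    recs <- Filter(Negate(is.null), list(fast, post))
    ph <- unique(vapply(recs, `[[`, character(1), "phenotype"))
    if (length(ph) > 1) {
      errors <- add(errors, id, "phenotype",
                    "phenotype differs between fasting and postprandial records")
      failed <- c(failed, paste(id, STATES, sep = "/"))
      next
    }
    if (ph == "FCS") {
      warnings <- add(warnings, id, "phenotype",
                      "FCS sample: reduced measurement precision expected at extreme TG")
    }
    if (is.null(fast) || is.null(post)) {
      warnings <- add(warnings, id, "state",
                      paste0("only one state present (",
                             recs[[1]]$state, ")"))
      next
    }
    tg_f <- total_tg(fast)
    tg_p <- total_tg(post)
    if (tg_f > 0 && abs(tg_p - tg_f) / tg_f < tg_change_threshold) {
      warnings <- add(warnings, id, "total_tg",
                      sprintf("excluded: <%.0f%% change in total TG (%.1f%%)",
                              100 * tg_change_threshold,
                              100 * abs(tg_p - tg_f) / tg_f))
    }
  }

  errors <- if (length(errors)) do.call(rbind, errors) else report_frame()
  warnings <- if (length(warnings)) do.call(rbind, warnings) else
    report_frame()
  validation_report(errors, warnings,
                    n_pass = length(d$subjects) -
                      length(unique(failed[failed %in% names(d$subjects)])))
}
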
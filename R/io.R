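# Tabular IO. Long (tidy) CSV layout: one row per
# (subject_id, phenotype, state, fraction, component, value, unit);
# extensible to subfractions without schema change.

COHORT_COLUMNS <- c("subject_id", "phenotype", "state", "fraction",
                    "component", "value", "unit")
AIRFUGE_COLUMNS <- c("subject_id", "state", "chamber", "component", "value",
                     "unit")
DELTA_COLUMNS <- c("subject_id", "state", "fraction", "delta_umol_l")

# Accepted unit spellings and the factor converting them to the canonical
# unit (mmol/l for lipids, g/l for apolipoproteins).
LIPID_UNITS <- c("mmol/l" = 1, "mmol/L" = 1, "umol/l" = 1e-3,
                 "µmol/l" = 1e-3, "mol/l" = 1e3)
APO_UNITS <- c("g/l" = 1, "g/L" = 1, "mg/l" = 1e-3, "mg/dl" = 1e-2)

normalize_value <- function(component, value, unit) {
  tab <- if (component %in% c(LIPID_COMPONENTS, "cholesterol_total"))
    LIPID_UNITS else APO_UNITS
  if (!unit %in% names(tab)) return(NA_real_)
  value * tab[[unit]]
}

#' Read a cohort composition table
#'
#' Reads a long-format CSV with columns `subject_id`, `phenotype`, `state`,
#' `fraction`, `component`, `value`, `unit` into a [cohort_dataset()]. Units
#' are normalized to mmol/l (lipids) and g/l (apolipoproteins). A component
#' `cholesterol_total` together with `fc` yields `ce` as their difference
#' (total minus free cholesterol). Row-level problems (unparseable values,
#' unknown names, duplicates, negative concentrations) are collected and
#' raised as a single schema error listing each offending row.
#'
#' @param path CSV file path.
#' @param schema Table schema identifier (only `"long"` is defined).
#' @return A [cohort_dataset()]. Measured 1-h TG deltas are read separately
#'   via [read_deltas()].
#' @export
read_cohort <- function(path, schema = "long") {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort_cetp(paste0("file not found: ", path),
                                     "io_error")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(COHORT_COLUMNS, names(tab))
  if (length(missing)) {
    abort_cetp(paste0("missing column(s): ", paste(missing, collapse = ", ")),
               "schema_error")
  }
  errs <- character()
  tab$num <- suppressWarnings(as.numeric(tab$value))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (is.na(r$num)) {
      errs <- c(errs, sprintf("row %d (%s): unparseable value '%s'",
                              i, r$subject_id, r$value))
      next
    }
    if (!r$fraction %in% FRACTION_IDS)
      errs <- c(errs, sprintf("row %d (%s): unknown fraction '%s'",
                              i, r$subject_id, r$fraction))
    if (!r$component %in% c(ALL_COMPONENTS, "cholesterol_total"))
      errs <- c(errs, sprintf("row %d (%s): unknown component '%s'",
                              i, r$subject_id, r$component))
    if (!r$state %in% STATES)
      errs <- c(errs, sprintf("row %d (%s): unknown state '%s'",
                              i, r$subject_id, r$state))
    if (!r$phenotype %in% PHENOTYPES)
      errs <- c(errs, sprintf("row %d (%s): unknown phenotype '%s'",
                              i, r$subject_id, r$phenotype))
  }
  if (!length(errs)) {
    tab$norm <- mapply(normalize_value, tab$component, tab$num, tab$unit)
    bad_unit <- which(is.na(tab$norm))
    for (i in bad_unit)
      errs <- c(errs, sprintf("row %d (%s): unknown unit '%s' for %s", i,
                              tab$subject_id[i], tab$unit[i], tab$component[i]))
    neg <- which(!is.na(tab$norm) & tab$norm < 0)
    for (i in neg)
      errs <- c(errs, sprintf("row %d (%s): negative %s in %s", i,
                              tab$subject_id[i], tab$component[i],
                              tab$fraction[i]))
    key <- paste(tab$subject_id, tab$state, tab$fraction, tab$component)
    for (k in unique(key[duplicated(key)]))
      errs <- c(errs, sprintf("duplicate measurement: %s", k))
  }
  if (length(errs)) {
    abort_cetp(paste0("cohort table errors:\n  ",
                      paste(errs, collapse = "\n  ")), "read_error")
  }

  subjects <- list()
  for (grp in split(tab, paste(tab$subject_id, tab$state, sep = "/"))) {
    fractions <- lapply(split(grp, grp$fraction), build_fraction)
    subjects[[length(subjects) + 1L]] <-
      subject_record(grp$subject_id[1], grp$phenotype[1], grp$state[1],
                     fractions = unname(fractions))
  }
  cohort_dataset(subjects, metadata = list(source = path, schema = schema))
}

build_fraction <- function(rows) {
  vals <- stats::setNames(rows$norm, rows$component)
  if ("cholesterol_total" %in% names(vals)) {
    if ("ce" %in% names(vals)) {
      abort_cetp(sprintf(
        "subject %s, fraction %s: both ce and cholesterol_total given",
        rows$subject_id[1], rows$fraction[1]), "read_error")
    }
    fc <- if ("fc" %in% names(vals)) vals[["fc"]] else 0
    ce <- vals[["cholesterol_total"]] - fc
    if (ce < 0) {
      abort_cetp(sprintf(
        "subject %s, fraction %s: total cholesterol below free cholesterol",
        rows$subject_id[1], rows$fraction[1]), "read_error")
    }
    vals <- c(vals[names(vals) != "cholesterol_total"], ce = ce)
  }
  args <- as.list(vals[names(vals) %in% ALL_COMPONENTS])
  do.call(fraction_composition, c(list(fraction_id = rows$fraction[1]), args))
}

#' Write a cohort composition table
#'
#' Inverse of [read_cohort()]: emits the long CSV layout with canonical
#' units. Round-trips numerically to within 1e-9 relative tolerance.
#'
#' @param d A [cohort_dataset()].
#' @param path Output CSV path.
#' @export
write_cohort <- function(d, path) {
  rows <- list()
  for (s in d$subjects) {
    for (f in s$fractions) {
      v <- components(f)
      v <- v[!is.na(v)]
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, phenotype = s$phenotype, state = s$state,
        fraction = f$fraction_id, component = names(v),
        value = format(unname(v), digits = 17, scientific = TRUE, trim = TRUE),
        unit = ifelse(names(v) %in% LIPID_COMPONENTS, "mmol/l", "g/l"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read measured 1-h TG redistribution deltas
#'
#' CSV columns: `subject_id`, `state`, `fraction`, `delta_umol_l` (TG change
#' over 1 h at 37 vs 4 degree C, umol/l). Attaches deltas to the matching
#' records of `d`.
#'
#' @param path CSV path.
#' @param d A [cohort_dataset()] to annotate.
#' @return The annotated dataset.
#' @export
read_deltas <- function(path, d) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(DELTA_COLUMNS, names(tab))
  if (length(missing)) {
    abort_cetp(paste0("missing column(s): ", paste(missing, collapse = ", ")),
               "schema_error")
  }
  for (grp in split(tab, paste(tab$subject_id, tab$state, sep = "/"))) {
    key <- paste(grp$subject_id[1], grp$state[1], sep = "/")
    if (is.null(d$subjects[[key]])) {
      abort_cetp(paste0("deltas refer to unknown record ", key), "read_error")
    }
    d$subjects[[key]]$measured_tg_delta <-
      stats::setNames(grp$delta_umol_l, grp$fraction)
  }
  d
}

#' Write measured deltas
#' @param d A [cohort_dataset()] with `measured_tg_delta` entries.
#' @param path Output CSV path.
#' @export
write_deltas <- function(d, path) {
  rows <- list()
  for (s in d$subjects) {
    md <- s$measured_tg_delta
    if (is.null(md)) next
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = s$subject_id, state = s$state, fraction = names(md),
      delta_umol_l = format(unname(md), digits = 17, trim = TRUE),
      stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read two-chamber (Airfuge) measurements
#'
#' CSV columns: `subject_id`, `state`, `chamber` (`inner`/`outer`),
#' `component`, `value`, `unit`. Returns one [airfuge_measurement()] per
#' (subject, state).
#'
#' @param path CSV path.
#' @return A list of `airfuge_measurement` objects.
#' @export
read_airfuge <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(AIRFUGE_COLUMNS, names(tab))
  if (length(missing)) {
    abort_cetp(paste0("missing column(s): ", paste(missing, collapse = ", ")),
               "schema_error")
  }
  bad <- setdiff(unique(tab$chamber), c("inner", "outer"))
  if (length(bad)) {
    abort_cetp(paste0("unknown chamber: ", paste(bad, collapse = ", ")),
               "read_error")
  }
  tab$norm <- mapply(normalize_value, tab$component, tab$value, tab$unit)
  if (anyNA(tab$norm)) abort_cetp("unknown unit in airfuge table", "read_error")
  lapply(split(tab, paste(tab$subject_id, tab$state, sep = "/")), function(g) {
    inner <- g[g$chamber == "inner", ]
    outer <- g[g$chamber == "outer", ]
    airfuge_measurement(g$subject_id[1], g$state[1],
                        c_in = stats::setNames(inner$norm, inner$component),
                        c_out = stats::setNames(outer$norm, outer$component))
  })
}

#' Write two-chamber measurements
#' @param measurements List of `airfuge_measurement` objects.
#' @param path Output CSV path.
#' @export
write_airfuge <- function(measurements, path) {
  rows <- lapply(measurements, function(m) {
    comps <- union(names(m$c_in), names(m$c_out))
    data.frame(
      subject_id = m$subject_id, state = m$state,
      chamber = rep(c("inner", "outer"), each = length(comps)),
      component = rep(comps, 2),
      value = format(c(m$c_in[comps], m$c_out[comps]), digits = 17,
                     trim = TRUE),
      unit = rep(ifelse(comps %in% LIPID_COMPONENTS, "mmol/l", "g/l"), 2),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
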
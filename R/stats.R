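# Paired fasting/postprandial cohort statistics: percentage changes, exact
# Wilcoxon signed-rank tests, Spearman correlations, and the ApoC3
# redistribution analysis.

#' Percentage change between fasting and postprandial values
#' @param fasting,postprandial Paired values; `fasting` must be nonzero.
#' @return `100 * (postprandial - fasting) / fasting`.
#' @export
percent_change <- function(fasting, postprandial) {
  if (any(fasting == 0)) {
    abort_cetp("percent change undefined for fasting value 0", "stats_error")
  }
  100 * (postprandial - fasting) / fasting
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired test. Zero differences are dropped; tied absolute
#' differences receive average ranks. For `n <= 25` the null distribution of
#' the positive-rank sum `W+` is computed exactly over all `2^n` sign
#' assignments (via the shift-algorithm convolution, which handles
#' half-integer average ranks); above 25 a normal approximation with
#' continuity and tie correction is used. The two-sided p value is
#' `min(1, 2 * min(P(W+ <= w), P(W+ >= w)))`.
#'
#' @param deltas Numeric vector of paired differences.
#' @return List with `statistic` (W+), `p_value`, `n` (nonzero differences)
#'   and `method`.
#' @examples
#' wilcoxon_signed_rank(1:12)$p_value # 2/4096
#' @export
wilcoxon_signed_rank <- function(deltas) {
  d <- deltas[deltas != 0]
  n <- length(d)
  if (n < 5) {
    abort_cetp(sprintf("insufficient data: %d nonzero difference(s), need >= 5",
                       n), "stats_error")
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    # distribution of W+ on doubled ranks (integers even with .5 ties)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)  # f[s + 1] = #assignments with 2*W+ = s
    f[1L] <- 1
    for (rv in r2) {
      shifted <- c(numeric(rv), f[seq_len(total + 1L - rv)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- round(2 * w)
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks. Two-sided p value via the
#' t approximation for `n >= 10` and by exact enumeration of all
#' permutations of one margin for `n < 10`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`, neither constant.
#' @return List with `rho`, `p_value`, `n` and `method`.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort_cetp("x and y must have equal length",
                                 "stats_error")
  if (n < 4) abort_cetp("need at least 4 pairs", "stats_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_cetp("rho undefined for a constant vector", "stats_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- all_permutations(n)
    rx_c <- rx - mean(rx)
    ry_c <- ry - mean(ry)
    # rho under permutation of y, up to the common scale factor
    stat <- abs(matrix(ry_c[perms], nrow(perms), n) %*% rx_c)
    obs <- abs(sum(rx_c * ry_c))
    p <- mean(stat >= obs - 1e-9)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

#' ApoC3 redistribution ratio
#'
#' Quantifies the postprandial shift of ApoC3 out of HDL:
#' `(post HDL ApoC3 - fasting HDL ApoC3) / (HDL ApoC3 + VLDL ApoC3)`, with
#' the denominator taken in the fasting state by default and `VLDL` meaning
#' the VLDL+CMR fraction (the merged TRL is used when no split is present;
#' `vldl_includes_cm` adds the CM ApoC3). Negative values mean ApoC3 left
#' HDL (redistributed to the TG-rich fractions).
#'
#' @param fasting,postprandial [subject_record()]s of the same subject.
#' @param denominator_state `"fasting"` (default) or `"postprandial"`.
#' @param vldl_includes_cm Include CM ApoC3 in the denominator.
#' @return Dimensionless ratio.
#' @export
apoc3_redistribution_ratio <- function(fasting, postprandial,
                                       denominator_state = c("fasting",
                                                             "postprandial"),
                                       vldl_includes_cm = FALSE) {
  denominator_state <- match.arg(denominator_state)
  get_apoc3 <- function(rec, id) {
    f <- rec$fractions[[id]]
    if (is.null(f) || is.na(f$apo_c3)) NA_real_ else f$apo_c3
  }
  hdl_f <- get_apoc3(fasting, "HDL")
  hdl_p <- get_apoc3(postprandial, "HDL")
  den_rec <- if (denominator_state == "fasting") fasting else postprandial
  vldl <- get_apoc3(den_rec, "VLDL_CMR")
  if (is.na(vldl)) vldl <- get_apoc3(den_rec, "TRL")
  if (vldl_includes_cm) {
    cm <- get_apoc3(den_rec, "CM")
    if (!is.na(cm)) vldl <- vldl + cm
  }
  hdl_den <- get_apoc3(den_rec, "HDL")
  if (anyNA(c(hdl_f, hdl_p, vldl, hdl_den))) {
    abort_cetp("ApoC3 missing in HDL or VLDL fraction", "stats_error")
  }
  den <- hdl_den + vldl
  if (den == 0) abort_cetp("ApoC3 denominator is zero", "stats_error")
  (hdl_p - hdl_f) / den
}

TABLE1_PARAMETERS <- c("d_hdl2b_apoa1", "d_hdl_apoc3", "d_total_tg",
                       "d_cm_pl", "d_hdl_surface_share", "d_vldl_tg",
                       "d_hdl2a_apoa1")

#' Correlates of postprandial ApoC3 redistribution
#'
#' For each paired normolipidemic subject, computes the ApoC3 redistribution
#' ratio ([apoc3_redistribution_ratio()]) and a set of candidate
#' delta-parameters (postprandial minus fasting): HDL2b ApoA1, HDL ApoC3,
#' total TG, CM PL, the HDL surface share S_HDL/(S_HDL + S_TRL), VLDL+CMR
#' TG, and HDL2a ApoA1. Each parameter is Spearman-correlated with the
#' ratio; rows are sorted by `|rho|`. No multiplicity adjustment by default
#' (`adjust = "BH"` enables Benjamini-Hochberg).
#'
#' @param cohort A [cohort_dataset()].
#' @param constants A [molecular_constants()] (for the surface parameter).
#' @param parameters Candidate parameter names (subset of the defaults).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param ... Passed to [apoc3_redistribution_ratio()].
#' @return Data frame of class `correlation_table` with columns `parameter`,
#'   `rho`, `p`, sorted by decreasing `|rho|`.
#' @export
table1_analysis <- function(cohort, constants = molecular_constants(),
                            parameters = TABLE1_PARAMETERS,
                            adjust = c("none", "BH"), ...) {
  adjust <- match.arg(adjust)
  parameters <- match.arg(parameters, TABLE1_PARAMETERS, several.ok = TRUE)
  ids <- cohort_subjects(cohort, phenotype = "normolipidemic", paired = TRUE)
  if (length(ids) < 6) {
    abort_cetp(sprintf("need >= 6 paired normolipidemic subjects, have %d",
                       length(ids)), "stats_error")
  }
  ratio <- vapply(ids, function(i) {
    apoc3_redistribution_ratio(get_record(cohort, i, "fasting"),
                               get_record(cohort, i, "postprandial"), ...)
  }, numeric(1))
  param_mat <- vapply(ids, function(i) {
    fast <- get_record(cohort, i, "fasting")
    post <- get_record(cohort, i, "postprandial")
    vapply(parameters, function(p) {
      tryCatch(delta_parameter(p, fast, post, constants),
               cetpflux_error = function(e) NA_real_)
    }, numeric(1))
  }, numeric(length(parameters)))
  param_mat <- matrix(param_mat, nrow = length(parameters),
                      dimnames = list(parameters, ids))

  rows <- lapply(parameters, function(p) {
    v <- param_mat[p, ]
    ok <- !is.na(v)
    if (sum(ok) < 4) {
      warn_cetp(paste0("parameter ", p, " skipped: insufficient data"),
                "stats_warning")
      return(NULL)
    }
    sp <- spearman_rho(v[ok], ratio[ok])
    data.frame(parameter = p, rho = sp$rho, p = sp$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-abs(out$rho)), ]
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  out
}

delta_parameter <- function(name, fast, post, constants) {
  comp <- function(rec, fraction, component) {
    f <- rec$fractions[[fraction]]
    if (is.null(f) || is.na(f[[component]])) {
      abort_cetp(paste0("missing ", component, " in ", fraction),
                 "stats_error")
    }
    f[[component]]
  }
  switch(name,
    d_hdl2b_apoa1 = comp(post, "HDL2b", "apo_a1") -
      comp(fast, "HDL2b", "apo_a1"),
    d_hdl_apoc3 = comp(post, "HDL", "apo_c3") - comp(fast, "HDL", "apo_c3"),
    d_total_tg = total_tg(post) - total_tg(fast),
    d_cm_pl = comp(post, "CM", "pl") - comp(fast, "CM", "pl"),
    d_vldl_tg = comp(post, "VLDL_CMR", "tg") - comp(fast, "VLDL_CMR", "tg"),
    d_hdl2a_apoa1 = comp(post, "HDL2a", "apo_a1") -
      comp(fast, "HDL2a", "apo_a1"),
    d_hdl_surface_share = hdl_surface_share(post, constants) -
      hdl_surface_share(fast, constants),
    abort_cetp(paste0("unknown parameter ", name), "stats_error"))
}

hdl_surface_share <- function(rec, constants) {
  fr <- rec$fractions
  if (is.null(fr$HDL)) abort_cetp("missing HDL", "stats_error")
  s_trl <- if (!is.null(fr$CM) && !is.null(fr$VLDL_CMR)) {
    merged_trl_geometry(fr$CM, fr$VLDL_CMR, constants)$surface
  } else if (!is.null(fr$TRL)) {
    fraction_surface(fr$TRL, constants)$surface
  } else {
    abort_cetp("cannot form TRL surface", "stats_error")
  }
  s_hdl <- fraction_surface(fr$HDL, constants)$surface
  s_hdl / (s_hdl + s_trl)
}

#' Paired percentage changes across a cohort
#'
#' One row per (subject, fraction, component) for paired subjects, with the
#' percentage change between states. Summaries elsewhere report quartiles
#' (median, Q1, Q3).
#'
#' @param cohort A [cohort_dataset()].
#' @param phenotype Phenotype filter (default normolipidemic).
#' @return Data frame: `subject_id`, `variable`, `fasting`, `postprandial`,
#'   `pct_change`.
#' @export
paired_changes <- function(cohort, phenotype = "normolipidemic") {
  rows <- list()
  for (id in cohort_subjects(cohort, phenotype = phenotype, paired = TRUE)) {
    fast <- get_record(cohort, id, "fasting")
    post <- get_record(cohort, id, "postprandial")
    for (fid in intersect(names(fast$fractions), names(post$fractions))) {
      vf <- components(fast$fractions[[fid]])
      vp <- components(post$fractions[[fid]])
      ok <- !is.na(vf) & !is.na(vp) & vf != 0
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id,
        variable = paste(fid, names(vf)[ok], sep = "."),
        fasting = unname(vf[ok]), postprandial = unname(vp[ok]),
        pct_change = percent_change(unname(vf[ok]), unname(vp[ok])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
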
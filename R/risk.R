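#' Three-tier risk subtype from dichotomized features
#'
#' Dichotomizes total node volume and total drainage distance at the
#' given cutoffs and maps the 2x2 combination onto the three risk
#' subtypes. Large volume and distant drainage are the favorable sides,
#' and both dichotomies are inclusive on the favorable side (a value
#' exactly at the cutoff is L-tLNV / D-tLND):
#'
#' * L-tLNV and D-tLND -> LRS (low risk)
#' * L-tLNV and N-tLND -> MRS (moderate risk)
#' * S-tLNV and D-tLND -> MRS
#' * S-tLNV and N-tLND -> HRS (high risk)
#'
#' @param tLNV,tLND numeric feature vectors (mm^3, mm); missing values
#'   are an error — no imputation.
#' @param cutoffs named vector `c(tLNV = , tLND = )`; defaults to the
#'   published pair from [published_cutoffs()].
#' @return data.frame with `tLNV_class` (`"S-tLNV"`/`"L-tLNV"`),
#'   `tLND_class` (`"N-tLND"`/`"D-tLND"`) and `subtype` (factor
#'   LRS < MRS < HRS).
#' @examples
#' classify_risk(c(100, 50), c(200, 100))  # LRS, HRS at 71.5 / 140.5
#' @export
classify_risk <- function(tLNV, tLND, cutoffs = published_cutoffs()) {
  stopifnot(length(tLNV) == length(tLND),
            all(c("tLNV", "tLND") %in% names(cutoffs)))
  if (anyNA(tLNV) || anyNA(tLND) || any(!is.finite(tLNV)) ||
      any(!is.finite(tLND)))
    stop("missing or non-finite feature value (no imputation)")
  large <- tLNV >= cutoffs[["tLNV"]]
  distant <- tLND >= cutoffs[["tLND"]]
  subtype <- ifelse(large & distant, "LRS",
                    ifelse(!large & !distant, "HRS", "MRS"))
  data.frame(tLNV_class = ifelse(large, "L-tLNV", "S-tLNV"),
             tLND_class = ifelse(distant, "D-tLND", "N-tLND"),
             subtype = factor(subtype, levels = c("LRS", "MRS", "HRS")))
}

#' Published feature cutoffs
#'
#' The cutoff pair reported for the original training cohort
#' (71.5 mm^3 for tLNV, 140.5 mm for tLND), shipped for apply-only
#' use. These values are transferred from cohorts that are not
#' distributed with the package; they are not re-derived here and need
#' not transfer to other populations — prefer learning cohort-specific
#' cutoffs with [find_optimal_cutoff()] when training data exist.
#'
#' @return named numeric vector `c(tLNV = 71.5, tLND = 140.5)` with
#'   attribute `source = "published-2025, transferred"`.
#' @export
published_cutoffs <- function() {
  structure(c(tLNV = 71.5, tLND = 140.5),
            source = "published-2025, transferred")
}

.five_year_days <- 1826

#' Stratified prognostic report for risk subtypes
#'
#' For each requested endpoint: per-subtype Kaplan-Meier curves,
#' five-year survival rates (KM estimate at 1826 days; `"not reached"`
#' when a group's follow-up ends earlier — never extrapolated), the
#' global and pairwise log-rank tests, and Cox hazard ratios for MRS
#' and HRS versus LRS, optionally adjusted for covariates. A subtype
#' absent from the cohort is reported as absent and contrasts
#' involving it are skipped.
#'
#' @param cohort data.frame with `subtype` (or `subtype_true`) plus
#'   `<endpoint>_time` / `<endpoint>_event` columns.
#' @param endpoints subset of `c("os", "dfs")` present in the cohort.
#' @param covariates optional character vector of covariate columns to
#'   adjust the Cox model with.
#' @param five_year_days evaluation time of the "five-year" rate.
#' @return object of class `lnmts_report` (nested list per endpoint:
#'   `km` curves, `five_year` rates, `logrank_global`,
#'   `logrank_pairwise`, `cox`, `cox_adjusted`).
#' @export
stratified_report <- function(cohort, endpoints = c("os", "dfs"),
                              covariates = NULL,
                              five_year_days = .five_year_days) {
  st <- cohort$subtype %||% cohort$subtype_true
  if (is.null(st)) stop("cohort lacks a 'subtype' column")
  st <- factor(as.character(st), levels = c("LRS", "MRS", "HRS"))
  present <- levels(st)[table(st) > 0]
  out <- list(subtypes_present = present,
              subtypes_absent = setdiff(levels(st), present),
              five_year_days = five_year_days,
              boundary_rule = "favorable side inclusive: L-tLNV iff tLNV >= cutoff, D-tLND iff tLND >= cutoff")

  for (ep in endpoints) {
    tc <- paste0(ep, "_time"); ec <- paste0(ep, "_event")
    if (!all(c(tc, ec) %in% names(cohort))) next
    tm <- cohort[[tc]]; evv <- cohort[[ec]]
    res <- list()
    res$km <- lapply(stats::setNames(present, present), function(s)
      km_estimate(tm[st == s], evv[st == s]))
    res$five_year <- vapply(present, function(s) {
      as.numeric(km_survival_at(res$km[[s]], five_year_days))
    }, numeric(1L))
    res$logrank_global <- if (length(present) >= 2L)
      logrank_test(tm[st %in% present], evv[st %in% present],
                   droplevels(st[st %in% present])) else NULL
    pairs <- if (length(present) >= 2L) utils::combn(present, 2L,
                                                     simplify = FALSE)
             else list()
    res$logrank_pairwise <- lapply(pairs, function(pr) {
      sel <- st %in% pr
      list(groups = pr,
           test = logrank_test(tm[sel], evv[sel], droplevels(st[sel])))
    })
    others <- intersect(c("MRS", "HRS"), present)
    if ("LRS" %in% present && length(others)) {
      xm <- vapply(others, function(s) as.numeric(st == s),
                   numeric(length(st)))
      colnames(xm) <- paste0(others, "_vs_LRS")
      res$cox <- cox_fit(tm, evv, xm)
      if (!is.null(covariates)) {
        xa <- cbind(xm, as.matrix(cohort[, covariates, drop = FALSE]))
        res$cox_adjusted <- cox_fit(tm, evv, xa)
      }
    }
    out[[ep]] <- res
  }
  structure(out, class = "lnmts_report")
}

#' @export
print.lnmts_report <- function(x, ...) {
  cat("LNs-MTS stratified prognostic report\n")
  cat(" ", x$boundary_rule, "\n")
  if (length(x$subtypes_absent))
    cat("  absent subtypes (contrasts skipped):",
        paste(x$subtypes_absent, collapse = ", "), "\n")
  for (ep in intersect(c("os", "dfs"), names(x))) {
    res <- x[[ep]]
    cat(sprintf("\n== %s ==\n", toupper(ep)))
    fy <- ifelse(is.na(res$five_year), "not reached",
                 sprintf("%.1f%%", 100 * res$five_year))
    cat(sprintf("  %d-day survival: %s\n", x$five_year_days,
                paste(sprintf("%s %s", names(res$five_year), fy),
                      collapse = ", ")))
    if (!is.null(res$logrank_global))
      cat(sprintf("  global log-rank: chi-square = %.4g, df = %d, p = %.3g\n",
                  res$logrank_global$statistic, res$logrank_global$df,
                  res$logrank_global$p.value))
    if (!is.null(res$cox)) {
      cat("  Cox HR vs LRS:\n")
      for (i in seq_along(res$cox$hr))
        cat(sprintf("    %s: HR = %.3f (95%% CI %.3f-%.3f)\n",
                    names(res$cox$coefficients)[i], res$cox$hr[i],
                    res$cox$ci_lower[i], res$cox$ci_upper[i]))
    }
  }
  invisible(x)
}
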